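truthConc <- c(NAA = 8, Cr = 8, GABA = 2.5, Glu = 10, Ins = 5.5, Lac = 1.5)

test_that("spectrum synthesis is linear, deterministic and validated", {
    bs <- defaultBasisSet()
    zero <- synthesizeSpectrum(bs, setNames(rep(0, 6), names(truthConc)))
    expect_true(all(zero@intensity == 0))

    # doubling one concentration doubles exactly that contribution
    base <- synthesizeSpectrum(bs, truthConc)
    doubled <- truthConc; doubled["Glu"] <- 2 * doubled["Glu"]
    sp2 <- synthesizeSpectrum(bs, doubled)
    gluOnly <- synthesizeSpectrum(bs, c(Glu = truthConc[["Glu"]]))
    expect_equal(sp2@intensity - base@intensity, gluOnly@intensity,
                 tolerance = 1e-12)

    # reproducible noise
    a <- synthesizeSpectrum(bs, truthConc, noiseSd = 0.1, seed = 4)
    b <- synthesizeSpectrum(bs, truthConc, noiseSd = 0.1, seed = 4)
    expect_identical(a@intensity, b@intensity)
    expect_error(synthesizeSpectrum(bs, c(Bogus = 1)), "unknown metabolite")
    expect_error(synthesizeSpectrum(bs, c(Glu = -1)), ">= 0")
    expect_error(synthesizeSpectrum(bs, truthConc, noiseSd = 0.1), "seed")
})

test_that("noiseless spectra are refit exactly", {
    bs <- defaultBasisSet()
    sp <- synthesizeSpectrum(bs, truthConc, baselineCoeffs = c(0.3, -0.1, 0.05))
    fit <- fitSpectrum(sp, bs, baselineDegree = 2, noiseSd = 1)
    expect_equal(estimates(fit)[names(truthConc)], truthConc,
                 tolerance = 1e-8)
    expect_equal(fit@baseline, c(0.3, -0.1, 0.05), tolerance = 1e-6)
})

test_that("CRLB percent SD scales linearly with the noise level", {
    bs <- defaultBasisSet()
    s1 <- synthesizeSpectrum(bs, truthConc, noiseSd = 0.02, seed = 9)
    s2 <- synthesizeSpectrum(bs, truthConc, noiseSd = 0.04, seed = 9)
    f1 <- fitSpectrum(s1, bs, noiseSd = 0.02)
    f2 <- fitSpectrum(s2, bs, noiseSd = 0.04)
    expect_equal(unname(crlbPct(f2) / crlbPct(f1)), rep(2, 6),
                 tolerance = 0.02)
})

test_that("an absent metabolite gets a zero estimate and unusable CRLB", {
    bs <- defaultBasisSet()
    conc <- truthConc; conc["Lac"] <- 0
    set.seed(2)
    hits <- replicate(20, {
        sp <- synthesizeSpectrum(bs, conc, noiseSd = 0.3,
                                 seed = sample.int(1e6, 1))
        fit <- fitSpectrum(sp, bs, noiseSd = 0.3)
        c(est = estimates(fit)[["Lac"]], crlb = crlbPct(fit)[["Lac"]])
    })
    expect_lt(median(hits["est", ]), 0.2)
    expect_gt(median(hits["crlb", ]), 50)  # Inf when pinned at zero
})

test_that("fit residuals are orthogonal to the active design columns", {
    bs <- defaultBasisSet()
    sp <- synthesizeSpectrum(bs, truthConc, baselineCoeffs = c(0.2, 0.1),
                             noiseSd = 0.05, seed = 21)
    fit <- fitSpectrum(sp, bs, baselineDegree = 1, noiseSd = 0.05)
    G <- socialMRS:::.basisMatrix(bs, sp@ppm)
    Bm <- socialMRS:::.baselineMatrix(sp@ppm, 1)
    active <- names(which(estimates(fit) > 0))
    resid <- sp@intensity -
        as.numeric(G[, names(estimates(fit))] %*% estimates(fit)) -
        as.numeric(Bm %*% fit@baseline)
    proj <- crossprod(cbind(G[, active], Bm), resid)
    expect_lt(max(abs(proj)), 1e-6 * length(resid))
})

test_that("collinear basis vectors are detected and named", {
    pk <- defaultBasisSet()@peaks
    dup <- pk[pk$metabolite == "NAA", ]
    dup$metabolite <- "NAA2"
    bs <- basisSet(rbind(pk, dup))
    sp <- synthesizeSpectrum(bs, c(NAA = 8))
    expect_error(fitSpectrum(sp, bs, noiseSd = 1), "NAA2|NAA")
})

test_that("noise SD is recovered from the signal-free window", {
    bs <- defaultBasisSet()
    sp <- synthesizeSpectrum(bs, truthConc, noiseSd = 0.2, seed = 31)
    fit <- fitSpectrum(sp, bs)  # noiseSd estimated from [9, 10] ppm
    expect_equal(fit@noiseSd, 0.2, tolerance = 0.15)
})

test_that("basis sets and spectra round-trip as text", {
    bs <- defaultBasisSet()
    p <- tempfile(fileext = ".csv")
    writeBasisSet(bs, p)
    back <- readBasisSet(p)
    expect_equal(back@peaks$center_ppm, bs@peaks$center_ppm)
    expect_identical(back@lineshape, bs@lineshape)

    sp <- synthesizeSpectrum(bs, truthConc)
    ps <- tempfile(fileext = ".tsv")
    writeSpectrum(sp, ps)
    sp2 <- readSpectrum(ps)
    expect_equal(sp2@intensity, sp@intensity, tolerance = 1e-12)
})
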