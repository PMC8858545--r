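#' Construct a basis set for the toy spectral quantifier
#'
#' @param peaks data.frame with columns metabolite, center_ppm, amplitude,
#'   linewidth_ppm (one row per peak).
#' @param lineshape "lorentzian" (default) or "gaussian".
#' @return A validated [BasisSet-class].
#' @export
basisSet <- function(peaks, lineshape = c("lorentzian", "gaussian")) {
    lineshape <- match.arg(lineshape)
    new("BasisSet", peaks = as.data.frame(peaks), lineshape = lineshape)
}

#' A small built-in demonstration basis set
#'
#' Six metabolites with approximate 1H chemical shifts (NAA, Cr, GABA, Glu,
#' Ins, Lac), Lorentzian lineshapes, moderate spectral overlap. Purely a toy
#' for exercising the linear-combination fitter.
#'
#' @return A [BasisSet-class].
#' @export
defaultBasisSet <- function() {
    peaks <- data.frame(
        metabolite = c("NAA",
                       "Cr", "Cr",
                       "GABA", "GABA", "GABA",
                       "Glu", "Glu", "Glu",
                       "Ins", "Ins",
                       "Lac", "Lac"),
        center_ppm = c(2.008,
                       3.027, 3.913,
                       1.889, 2.284, 3.012,
                       2.120, 2.350, 3.746,
                       3.520, 3.614,
                       1.313, 4.099),
        amplitude = c(3.0,
                      3.0, 2.0,
                      2.0, 2.0, 2.0,
                      1.0, 1.0, 1.0,
                      2.0, 2.0,
                      3.0, 1.0),
        linewidth_ppm = 0.035,
        stringsAsFactors = FALSE)
    basisSet(peaks, "lorentzian")
}

#' Read / write a basis set as a structured text file
#'
#' Plain CSV of the peak table preceded by a `# lineshape: <kind>` header
#' line.
#'
#' @param path file path.
#' @return [readBasisSet()]: a [BasisSet-class]; [writeBasisSet()]: the path,
#'   invisibly.
#' @export
readBasisSet <- function(path) {
    first <- readLines(path, n = 1L)
    shape <- sub("^#\\s*lineshape:\\s*", "", first)
    peaks <- read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
    basisSet(peaks, shape)
}

#' @rdname readBasisSet
#' @param basis a [BasisSet-class].
#' @export
writeBasisSet <- function(basis, path) {
    writeLines(paste0("# lineshape: ", basis@lineshape), path)
    suppressWarnings(write.table(basis@peaks, path, sep = ",",
                                 row.names = FALSE, append = TRUE,
                                 qmethod = "double"))
    invisible(path)
}

## Per-metabolite basis vectors evaluated on a ppm grid.
.basisMatrix <- function(basis, ppm) {
    mets <- unique(basis@peaks$metabolite)
    G <- vapply(mets, function(m) {
        pk <- basis@peaks[basis@peaks$metabolite == m, , drop = FALSE]
        v <- numeric(length(ppm))
        for (i in seq_len(nrow(pk))) {
            if (basis@lineshape == "lorentzian") {
                hw <- pk$linewidth_ppm[i] / 2  # half width at half maximum
                v <- v + pk$amplitude[i] * hw^2 /
                    ((ppm - pk$center_ppm[i])^2 + hw^2)
            } else {
                sg <- pk$linewidth_ppm[i] / (2 * sqrt(2 * log(2)))
                v <- v + pk$amplitude[i] *
                    exp(-(ppm - pk$center_ppm[i])^2 / (2 * sg^2))
            }
        }
        v
    }, numeric(length(ppm)))
    colnames(G) <- mets
    G
}

## Baseline polynomial columns on a [-1, 1]-normalised axis (intercept first).
.baselineMatrix <- function(ppm, degree) {
    x <- 2 * (ppm - min(ppm)) / (max(ppm) - min(ppm)) - 1
    vapply(0:degree, function(k) x^k, numeric(length(ppm)))
}

#' Synthesize a toy 1H spectrum from a basis set
#'
#' intensity = sum_m c_m basis_m(ppm) + polynomial baseline + iid Gaussian
#' noise. Deterministic given `seed`.
#'
#' @param basis a [BasisSet-class].
#' @param concentrations named non-negative numeric; names must be basis
#'   metabolites.
#' @param baselineCoeffs polynomial baseline coefficients (intercept first)
#'   on the \[-1, 1\]-normalised ppm axis; default none.
#' @param noiseSd Gaussian noise SD (arbitrary units).
#' @param seed RNG seed, required when `noiseSd > 0`.
#' @param ppm the chemical-shift grid, strictly monotone decreasing.
#' @return A [Spectrum-class].
#' @export
#' @examples
#' sp <- synthesizeSpectrum(defaultBasisSet(),
#'                          c(NAA = 8, Cr = 8, GABA = 2.5, Glu = 10,
#'                            Ins = 5.5, Lac = 1.5),
#'                          noiseSd = 0.05, seed = 1)
#' sp
synthesizeSpectrum <- function(basis, concentrations, baselineCoeffs = 0,
                               noiseSd = 0, seed = NULL,
                               ppm = seq(10.2, 0.2, length.out = 2048)) {
    stopifnot(is(basis, "BasisSet"))
    mets <- unique(basis@peaks$metabolite)
    unknown <- setdiff(names(concentrations), mets)
    if (length(unknown))
        stop("unknown metabolite name(s): ", paste(unknown, collapse = ", "))
    if (any(concentrations < 0))
        stop("concentrations must be >= 0")
    G <- .basisMatrix(basis, ppm)
    y <- as.numeric(G[, names(concentrations), drop = FALSE] %*%
                    concentrations)
    Bm <- .baselineMatrix(ppm, length(baselineCoeffs) - 1L)
    y <- y + as.numeric(Bm %*% baselineCoeffs)
    if (noiseSd > 0) {
        if (is.null(seed))
            stop("a seed is required when noiseSd > 0")
        set.seed(as.integer(seed))
        y <- y + rnorm(length(ppm), 0, noiseSd)
    }
    new("Spectrum", ppm = ppm, intensity = y, noiseSd = as.numeric(noiseSd))
}

## Noise SD estimated from a signal-free ppm window after removing a linear
## trend within the window.
.estimateNoiseSd <- function(spectrum, window = c(9, 10)) {
    sel <- spectrum@ppm >= window[1L] & spectrum@ppm <= window[2L]
    if (sum(sel) < 10L)
        stop("noise window [", window[1L], ", ", window[2L],
             "] ppm contains too few points")
    y <- spectrum@intensity[sel]
    x <- spectrum@ppm[sel]
    r <- lm(y ~ x)$residuals
    sqrt(sum(r^2) / (length(r) - 2L))
}

#' Fit a spectrum as a non-negative linear combination of basis vectors
#'
#' Estimates metabolite concentrations by non-negative least squares against
#' the basis vectors plus an unconstrained low-order polynomial baseline
#' (the baseline columns are split into positive and negative parts so the
#' whole problem stays an NNLS). The covariance of the estimates on the
#' active set is sigma^2 (G'G)^-1 with G the active design columns, and the
#' Cramer-Rao percent SD is 100 * sqrt(variance) / estimate (infinite for a
#' zero estimate). When `noiseSd` is not supplied it is estimated from a
#' signal-free window (default 9-10 ppm).
#'
#' @param spectrum a [Spectrum-class].
#' @param basis a [BasisSet-class].
#' @param baselineDegree baseline polynomial degree (default 2).
#' @param noiseSd noise SD for the covariance; estimated when `NULL`.
#' @param noiseWindow ppm window for noise estimation.
#' @return A [QuantFit-class].
#' @export
#' @examples
#' truth <- c(NAA = 8, Cr = 8, GABA = 2.5, Glu = 10, Ins = 5.5, Lac = 1.5)
#' sp <- synthesizeSpectrum(defaultBasisSet(), truth)
#' fit <- fitSpectrum(sp, defaultBasisSet(), noiseSd = 0.05)
#' estimates(fit)
fitSpectrum <- function(spectrum, basis, baselineDegree = 2,
                        noiseSd = NULL, noiseWindow = c(9, 10)) {
    stopifnot(is(spectrum, "Spectrum"), is(basis, "BasisSet"))
    G <- .basisMatrix(basis, spectrum@ppm)
    mets <- colnames(G)
    Bm <- .baselineMatrix(spectrum@ppm, baselineDegree)
    nb <- ncol(Bm)
    if (length(spectrum@ppm) <= ncol(G) + nb)
        stop("grid shorter than the number of free parameters")

    qrG <- qr(G)
    if (qrG$rank < ncol(G)) {
        dropped <- mets[qrG$pivot[(qrG$rank + 1L):ncol(G)]]
        stop("rank-deficient basis: collinear metabolite(s): ",
             paste(dropped, collapse = ", "))
    }

    # NNLS with free baseline: split baseline columns into +/- parts
    A <- cbind(G, Bm, -Bm)
    fit <- pracma::lsqnonneg(A, spectrum@intensity)
    est <- setNames(fit$x[seq_along(mets)], mets)
    bpos <- fit$x[length(mets) + seq_len(nb)]
    bneg <- fit$x[length(mets) + nb + seq_len(nb)]
    bl <- bpos - bneg

    if (is.null(noiseSd))
        noiseSd <- .estimateNoiseSd(spectrum, noiseWindow)

    active <- which(est > 0)
    cov <- matrix(0, length(mets), length(mets),
                  dimnames = list(mets, mets))
    crlb <- setNames(rep(Inf, length(mets)), mets)
    if (length(active)) {
        Ga <- cbind(G[, active, drop = FALSE], Bm)
        XtXi <- solve(crossprod(Ga))
        covA <- noiseSd^2 * XtXi[seq_along(active), seq_along(active),
                                 drop = FALSE]
        cov[active, active] <- covA
        crlb[active] <- 100 * sqrt(diag(covA)) / est[active]
    }
    new("QuantFit", estimates = est, crlbPct = crlb, covariance = cov,
        baseline = bl, noiseSd = as.numeric(noiseSd))
}

#' Write / read a spectrum as two-column text (ppm, intensity)
#'
#' @param spectrum a [Spectrum-class].
#' @param path file path.
#' @return [readSpectrum()]: a [Spectrum-class]; [writeSpectrum()]: the path,
#'   invisibly.
#' @export
writeSpectrum <- function(spectrum, path) {
    write.table(data.frame(ppm = spectrum@ppm,
                           intensity = spectrum@intensity),
                path, sep = "\t", row.names = FALSE)
    invisible(path)
}

#' @rdname writeSpectrum
#' @export
readSpectrum <- function(path) {
    d <- read.table(path, header = TRUE)
    new("Spectrum", ppm = d$ppm, intensity = d$intensity,
        noiseSd = NA_real_)
}
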