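.needGgplot <- function() {
    if (!requireNamespace("ggplot2", quietly = TRUE))
        stop("plotting requires the ggplot2 package")
}

#' Volcano plot of a correlation screen
#'
#' Pearson r against -log10 of the permutation p-value, one point per
#' feature, colored by quantile tier (q95: p < 0.05; q975: p < 0.025).
#'
#' @param screen data.frame from [screenFeatures()].
#' @return A ggplot object.
#' @export
plotVolcano <- function(screen) {
    .needGgplot()
    ggplot2::ggplot(screen,
                    ggplot2::aes(x = r, y = neg_log10_p,
                                 color = tier)) +
        ggplot2::geom_hline(yintercept = -log10(c(0.05, 0.025)),
                            linetype = "dotted", color = "grey50") +
        ggplot2::geom_point(size = 2) +
        ggplot2::geom_text(ggplot2::aes(label = feature),
                           vjust = -0.8, size = 2.6, show.legend = FALSE) +
        ggplot2::scale_color_manual(
            values = c(none = "grey60", q95 = "deeppink", q975 = "cyan3")) +
        ggplot2::labs(x = "Pearson r",
                      y = expression(-log[10] ~ p[perm])) +
        ggplot2::theme_classic()
}

#' Scatter plot of a feature against a behavior index with its linear fit
#'
#' @param se feature table from [buildFeatureTable()].
#' @param feature,region feature to plot.
#' @param index behavior index column in `colData`.
#' @return A ggplot object with the least-squares line and 95% confidence
#'   band.
#' @export
plotFeatureFit <- function(se, feature, region, index = "pi_preference") {
    .needGgplot()
    rd <- as.data.frame(SummarizedExperiment::rowData(se))
    i <- which(rd$region == region & rd$feature == feature)
    if (!length(i)) stop("feature not found")
    d <- data.frame(
        x = SummarizedExperiment::colData(se)[[index]],
        y = SummarizedExperiment::assay(se, "concentration")[i, ],
        genotype = SummarizedExperiment::colData(se)$genotype)
    d <- d[complete.cases(d), ]
    ggplot2::ggplot(d, ggplot2::aes(x = x, y = y)) +
        ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                             color = "black", linetype = "solid",
                             level = 0.95) +
        ggplot2::geom_point(ggplot2::aes(color = genotype), size = 2) +
        ggplot2::labs(x = index, y = paste(region, feature)) +
        ggplot2::theme_classic()
}

#' Plot a binormal ROC curve
#'
#' @param roc a `"binormalRoc"` object.
#' @return A ggplot object.
#' @export
plotRocCurve <- function(roc) {
    .needGgplot()
    stopifnot(inherits(roc, "binormalRoc"))
    ggplot2::ggplot(roc$curve, ggplot2::aes(x = fpr, y = tpr)) +
        ggplot2::geom_abline(slope = 1, intercept = 0,
                             linetype = "dashed", color = "grey60") +
        ggplot2::geom_path(linewidth = 0.8) +
        ggplot2::annotate("text", x = 0.7, y = 0.15,
                          label = sprintf("AUC = %.3f", roc$auc)) +
        ggplot2::labs(x = "1 - specificity", y = "sensitivity") +
        ggplot2::theme_classic()
}
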