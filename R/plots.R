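#' Manhattan plot of a scan result
#'
#' Every tested SNP appears exactly once; SNPs with `NA` p-values are drawn
#' at the baseline so no marker is silently dropped. Dotted lines mark the
#' Bonferroni significant and suggestive thresholds when supplied.
#'
#' @param scan a `scan_result`.
#' @param thresholds optional [bonferroni_thresholds()] object.
#' @param highlight optional SNP ids drawn emphasized (e.g. ensemble hits).
#' @return A ggplot object.
#' @export
manhattan_plot <- function(scan, thresholds = NULL, highlight = NULL) {
  df <- as.data.frame(scan)
  df$chr <- factor(df$chr, levels = unique(df$chr))
  chr_len <- tapply(df$pos, df$chr, max)
  offset <- c(0, cumsum(as.numeric(chr_len)))[seq_along(chr_len)]
  names(offset) <- names(chr_len)
  df$x <- df$pos + offset[as.character(df$chr)]
  df$logp <- -log10(df$p)
  df$logp[is.na(df$logp)] <- 0
  ticks <- tapply(df$x, df$chr, mean)
  gp <- ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$logp,
                                         colour = .data$chr)) +
    ggplot2::geom_point(size = 0.8, show.legend = FALSE) +
    ggplot2::scale_x_continuous(breaks = as.numeric(ticks),
                                labels = names(ticks)) +
    ggplot2::labs(x = "chromosome", y = expression(-log[10](italic(p))),
                  title = paste(attr(scan, "engine"), "scan:",
                                attr(scan, "response"),
                                paste0("(", df$coding[1], ")"))) +
    ggplot2::theme_minimal()
  if (!is.null(thresholds)) {
    gp <- gp +
      ggplot2::geom_hline(yintercept = -log10(thresholds$significant),
                          linetype = "dotted") +
      ggplot2::geom_hline(yintercept = -log10(thresholds$suggestive),
                          linetype = "dotted", colour = "grey50")
  }
  if (!is.null(highlight)) {
    hl <- df[df$snp %in% highlight, , drop = FALSE]
    gp <- gp + ggplot2::geom_point(data = hl, colour = "red", size = 2)
  }
  gp
}

#' Quantile-quantile plot of scan p-values
#'
#' @param scan a `scan_result`.
#' @return A ggplot object.
#' @export
qq_plot <- function(scan) {
  p <- scan$p[!is.na(scan$p)]
  n <- length(p)
  df <- data.frame(expected = -log10(stats::ppoints(n)),
                   observed = -log10(sort(p)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$expected, y = .data$observed)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(expected ~ -log[10](italic(p))),
                  y = expression(observed ~ -log[10](italic(p))),
                  title = paste(attr(scan, "engine"), "QQ:",
                                attr(scan, "response"))) +
    ggplot2::theme_minimal()
}
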