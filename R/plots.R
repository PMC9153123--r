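# The three report figures: region-comparison scatter, expected
# frequency curves, and null odds-ratio distributions. Base graphics,
# deliberately minimal.

#' Scatter plot of per-codon selection estimates between two regions
#'
#' Points with 95% posterior error bars, the y = x identity line and the
#' fitted Deming line; shifted codons are highlighted.
#'
#' @param report A `comparison_report`.
#' @param ... Passed to [graphics::plot()].
#' @return `invisible(NULL)`.
#' @export
plot_comparison <- function(report, ...) {
  tab <- report$table
  rng <- range(c(tab$lo_A, tab$hi_A, tab$lo_B, tab$hi_B))
  graphics::plot(tab$mean_A, tab$mean_B, xlim = rng, ylim = rng,
                 xlab = expression(Delta * eta ~ "(region A)"),
                 ylab = expression(Delta * eta ~ "(region B)"),
                 pch = 19, col = ifelse(tab$shift, "firebrick", "grey40"),
                 ...)
  graphics::segments(tab$lo_A, tab$mean_B, tab$hi_A, tab$mean_B,
                     col = "grey70")
  graphics::segments(tab$mean_A, tab$lo_B, tab$mean_A, tab$hi_B,
                     col = "grey70")
  graphics::abline(0, 1, lty = 3)
  graphics::abline(report$deming$intercept, report$deming$slope)
  graphics::legend("topleft", bty = "n", legend = c(
    sprintf("slope = %.3f (%.3f - %.3f)", report$deming$slope,
            report$deming$ci[["lo"]], report$deming$ci[["hi"]]),
    sprintf("rho_S = %.3f", report$spearman)))
  invisible(NULL)
}

#' Expected codon frequency curves for one family
#'
#' @param family A `codon_family`.
#' @param params A [parameter_set()].
#' @param phi_grid Grid of phi values (default 0 to 4).
#' @param ... Passed to [graphics::matplot()].
#' @return `invisible(NULL)`.
#' @export
plot_frequency_curves <- function(family, params,
                                  phi_grid = seq(0, 4, length.out = 81),
                                  ...) {
  m <- expected_frequency_curve(family, params, phi_grid)
  graphics::matplot(phi_grid, m, type = "l", lty = 1,
                    xlab = expression(phi),
                    ylab = "expected codon frequency",
                    main = family$family_id, ...)
  graphics::legend("topright", legend = family$codons, bty = "n",
                   lty = 1, col = seq_len(ncol(m)))
  invisible(NULL)
}

#' Box plots of simulated null odds-ratio distributions by position
#'
#' Optionally overlays observed odds ratios as reference points, and
#' always draws the OR = 1 line the distributions need not be centered
#' on.
#'
#' @param nulldist A `null_or_distribution`.
#' @param ... Passed to [graphics::boxplot()].
#' @return `invisible(NULL)`.
#' @export
plot_or_distributions <- function(nulldist, ...) {
  graphics::boxplot(nulldist$or, names = paste0("pos ",
                                                nulldist$positions),
                    ylab = "odds ratio (non-optimal enrichment)", ...)
  graphics::abline(h = 1, lty = 3)
  if (!is.null(nulldist$observed)) {
    graphics::points(seq_along(nulldist$positions),
                     unlist(nulldist$observed), pch = 4, col = "red",
                     cex = 1.5)
  }
  invisible(NULL)
}
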