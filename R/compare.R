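# Quantifying how selection differs between two fitted regions:
# rescaling to the genome-wide most selectively-favored codon, Deming
# (errors-in-variables) regression of the per-codon posterior means,
# codon-specific shift calls from non-overlapping 95% posterior
# intervals, Spearman correlation, and an exact binomial audit of the
# shift-call false-positive rate.

#' Most selectively-favored codon of each family from a null fit
#'
#' Under the model's `exp(-delta_eta * phi)` form, smaller `delta_eta`
#' means more favored, so the favored codon is the one with minimal
#' posterior-mean `delta_eta` in the null (no-region-differences) fit.
#' Exact ties break alphabetically (reported via a message).
#'
#' @param null_fit A `posterior_samples` from the null-model fit (or a
#'   named vector of posterior-mean delta_eta over codons).
#' @param families A [codon_family_table()] (taken from `null_fit` when
#'   available).
#' @return Named character vector: family id -> favored codon.
#' @export
select_favored_codons <- function(null_fit,
                                  families = codon_family_table()) {
  if (inherits(null_fit, "posterior_samples")) {
    families <- null_fit$families
    means <- colMeans(null_fit$draws)
  } else {
    means <- null_fit
  }
  out <- stats::setNames(character(length(families$families)),
                         names(families$families))
  for (fid in names(families$families)) {
    f <- families$families[[fid]]
    m <- means[f$codons]
    if (sum(m == min(m)) > 1) {
      message("favored-codon tie in family ", fid,
              "; alphabetically first codon chosen")
    }
    out[fid] <- f$codons[which.min(m)] # which.min takes the first = alphabetical
  }
  out
}

#' Rescale selection draws relative to the favored codons
#'
#' Subtracts, draw by draw, the `delta_eta` of each family's favored
#' codon from every codon of that family. In the null fit itself the
#' favored codon then sits at exactly 0 with synonyms >= 0 (up to MCMC
#' noise); in region fits, negative rescaled values signal a
#' region-specific change in which codon is favored. Rescaling is
#' idempotent.
#'
#' @param draws Kept x codon draws matrix (columns named by codon), or a
#'   `posterior_samples`.
#' @param favored Named character vector family -> favored codon, from
#'   [select_favored_codons()].
#' @param families A [codon_family_table()].
#' @return Rescaled draws matrix of the same shape.
#' @export
rescale_to_reference <- function(draws, favored,
                                 families = codon_family_table()) {
  if (inherits(draws, "posterior_samples")) {
    families <- draws$families
    draws <- draws$draws
  }
  miss <- setdiff(names(families$families), names(favored))
  if (length(miss)) {
    stop("favored-codon table missing families: ",
         paste(miss, collapse = ", "))
  }
  out <- draws
  for (fid in names(families$families)) {
    f <- families$families[[fid]]
    fav <- favored[[fid]]
    if (!fav %in% f$codons) {
      stop("favored codon ", fav, " is not in family ", fid)
    }
    out[, f$codons] <- draws[, f$codons, drop = FALSE] - draws[, fav]
  }
  out
}

#' Deming (errors-in-variables) regression
#'
#' Model-II regression accounting for error in both axes. The slope is
#' the closed form
#' `(s_yy - lambda * s_xx + sqrt((s_yy - lambda * s_xx)^2 +
#'   4 * lambda * s_xy^2)) / (2 * s_xy)`
#' with the intercept through the means; `lambda` is the ratio of the
#' y-error variance to the x-error variance (1 = the textbook default).
#' The 95% CI for the slope is a leave-one-out jackknife by default; a
#' normal-theory CI from the jackknife SE is the same here, and the
#' `"normal"` option uses the jackknife SE with a normal quantile.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @param lambda Positive error-variance ratio.
#' @param ci `"jackknife"` (t quantile) or `"normal"` (z quantile).
#' @param level CI level (default 0.95).
#' @return Object of class `deming_fit`: `slope`, `intercept`,
#'   `ci` (lo, hi), `se`, `lambda`, `n`.
#' @export
deming_fit <- function(x, y, lambda = 1,
                       ci = c("jackknife", "normal"), level = 0.95) {
  ci <- match.arg(ci)
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("deming_fit needs at least 3 points")
  if (!is.finite(lambda) || lambda <= 0) stop("lambda must be positive")
  slope_of <- function(x, y) {
    sxx <- sum((x - mean(x))^2)
    syy <- sum((y - mean(y))^2)
    sxy <- sum((x - mean(x)) * (y - mean(y)))
    if (sxy == 0) {
      if (isTRUE(all.equal(syy, lambda * sxx))) {
        stop("Deming slope undefined: s_xy = 0 with s_yy = lambda * s_xx")
      }
      return(if (syy < lambda * sxx) 0 else
        stop("Deming slope undefined (vertical): s_xy = 0, s_yy > lambda * s_xx"))
    }
    (syy - lambda * sxx +
        sqrt((syy - lambda * sxx)^2 + 4 * lambda * sxy^2)) / (2 * sxy)
  }
  b <- slope_of(x, y)
  a <- mean(y) - b * mean(x)
  loo <- vapply(seq_len(n), function(i) slope_of(x[-i], y[-i]), numeric(1))
  pseudo <- n * b - (n - 1) * loo
  se <- stats::sd(pseudo) / sqrt(n)
  centre <- mean(pseudo)
  qv <- if (ci == "jackknife") stats::qt(1 - (1 - level) / 2, df = n - 1)
        else stats::qnorm(1 - (1 - level) / 2)
  structure(list(slope = b, intercept = a,
                 ci = c(lo = centre - qv * se, hi = centre + qv * se),
                 se = se, lambda = lambda, n = n, level = level),
            class = "deming_fit")
}

#' @export
print.deming_fit <- function(x, ...) {
  cat(sprintf("Deming regression: slope = %.3f (%.0f%% CI %.3f - %.3f), intercept = %.3f, lambda = %.3g, n = %d\n",
              x$slope, 100 * x$level, x$ci[["lo"]], x$ci[["hi"]],
              x$intercept, x$lambda, x$n))
  invisible(x)
}

#' Codon-specific shift calls from posterior intervals
#'
#' A codon is called shifted between regions A and B iff its posterior
#' intervals are disjoint; intervals sharing an endpoint count as
#' overlapping (no shift -- the conservative reading). Direction is
#' `sign(mean_B - mean_A)`.
#'
#' @param int_a,int_b Interval matrices (columns `lo`, `hi`, rows =
#'   codons) from [posterior_interval()] at the same level.
#' @param mean_a,mean_b Named posterior means for the same codons.
#' @return Data frame `codon`, `shift` (logical), `direction`
#'   (-1/0/+1).
#' @export
detect_shifts <- function(int_a, int_b, mean_a, mean_b) {
  codons <- rownames(int_a)
  stopifnot(identical(codons, rownames(int_b)))
  disjoint <- int_a[, "hi"] < int_b[, "lo"] | int_b[, "hi"] < int_a[, "lo"]
  data.frame(codon = codons,
             shift = unname(disjoint),
             direction = ifelse(disjoint,
                                sign(mean_b[codons] - mean_a[codons]), 0),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Spearman rank correlation of per-codon selection estimates
#'
#' Rank correlation with average ranks for ties; errors on zero
#' variance.
#'
#' @param x,y Numeric vectors (>= 3 points).
#' @return Scalar rho.
#' @export
spearman_corr <- function(x, y) {
  if (length(x) < 3 || length(x) != length(y)) {
    stop("need >= 3 paired points")
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("Spearman correlation undefined: zero variance")
  }
  stats::cor(x, y, method = "spearman")
}

#' One-tailed exact binomial false-positive test
#'
#' `P(X >= k)` for `X ~ Binomial(n, p0)` (alternative "greater"): the
#' probability of observing at least the seen number of shift calls if
#' the per-comparison false-positive rate is `p0`.
#'
#' @param k_shifts Observed shift calls (0 <= k <= n).
#' @param n_comparisons Total comparisons.
#' @param p0 Null false-positive rate (default 0.05).
#' @return One-tailed p-value.
#' @export
binomial_fp_test <- function(k_shifts, n_comparisons, p0 = 0.05) {
  stopifnot(k_shifts >= 0, k_shifts <= n_comparisons)
  if (k_shifts == 0) return(1)
  stats::pbinom(k_shifts - 1, n_comparisons, p0, lower.tail = FALSE)
}

#' Compare selection estimates between two fitted regions
#'
#' Full pairwise comparison: rescale both fits to the null-model favored
#' codons, compute per-codon means and posterior intervals, call
#' codon-specific shifts, Deming-regress region B on region A, and audit
#' the shift-call count with the exact binomial test. The favored codon
#' of each family is identically 0 after rescaling and is excluded,
#' leaving 40 comparisons for the standard code with serine split.
#'
#' @param fit_a,fit_b `posterior_samples` for regions A and B.
#' @param favored Named family -> favored codon vector (typically from
#'   [select_favored_codons()] on the null fit).
#' @param lambda Deming error-variance ratio; `NULL` (default) uses the
#'   ratio of the mean posterior variances of B to A.
#' @param level Posterior-interval level (default 0.95).
#' @param p0 Null false-positive rate for the binomial audit.
#' @return Object of class `comparison_report`: `table` (per-codon
#'   means, intervals, shift calls), `deming` (`deming_fit`),
#'   `spearman`, `n_shifts`, `n_comparisons`, `binomial_p`.
#' @export
compare_regions <- function(fit_a, fit_b, favored, lambda = NULL,
                            level = 0.95, p0 = 0.05) {
  families <- fit_a$families
  ra <- rescale_to_reference(fit_a$draws, favored, families)
  rb <- rescale_to_reference(fit_b$draws, favored, families)
  keep <- setdiff(colnames(ra), unname(favored))
  ra <- ra[, keep, drop = FALSE]
  rb <- rb[, keep, drop = FALSE]
  mean_a <- colMeans(ra)
  mean_b <- colMeans(rb)
  int_a <- posterior_interval(ra, level)
  int_b <- posterior_interval(rb, level)
  if (is.null(lambda)) {
    va <- mean(apply(ra, 2L, stats::var))
    vb <- mean(apply(rb, 2L, stats::var))
    lambda <- vb / va
  }
  dem <- deming_fit(mean_a, mean_b, lambda = lambda, level = level)
  shifts <- detect_shifts(int_a, int_b, mean_a, mean_b)
  tab <- data.frame(codon = keep,
                    family_id = unname(families$family_of[keep]),
                    mean_A = unname(mean_a), lo_A = int_a[, "lo"],
                    hi_A = int_a[, "hi"],
                    mean_B = unname(mean_b), lo_B = int_b[, "lo"],
                    hi_B = int_b[, "hi"],
                    shift = shifts$shift, direction = shifts$direction,
                    row.names = NULL, stringsAsFactors = FALSE)
  k <- sum(tab$shift)
  structure(list(table = tab, deming = dem,
                 spearman = spearman_corr(mean_a, mean_b),
                 n_shifts = k, n_comparisons = nrow(tab),
                 binomial_p = binomial_fp_test(k, nrow(tab), p0),
                 level = level, p0 = p0),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("comparison of selection estimates between two regions\n")
  print(x$deming)
  cat(sprintf("Spearman rho_S = %.3f\n", x$spearman))
  cat(sprintf("%d/%d codon-specific shifts (binomial p = %.3f vs rate %.2f)\n",
              x$n_shifts, x$n_comparisons, x$binomial_p, x$p0))
  invisible(x)
}

#' Serialize a comparison report
#'
#' Writes the per-codon table as TSV and the summary (slope, CI,
#' Spearman rho, binomial p) as JSON.
#'
#' @param report A `comparison_report`.
#' @param tsv_path,json_path Output paths.
#' @return `invisible(NULL)`.
#' @export
write_comparison_report <- function(report, tsv_path, json_path) {
  utils::write.table(report$table, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  jsonlite::write_json(
    list(slope = report$deming$slope,
         slope_ci = as.list(report$deming$ci),
         intercept = report$deming$intercept,
         lambda = report$deming$lambda,
         spearman = report$spearman,
         n_shifts = report$n_shifts,
         n_comparisons = report$n_comparisons,
         binomial_p = report$binomial_p,
         level = report$level),
    json_path, auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}
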