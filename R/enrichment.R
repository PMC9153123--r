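# Position-wise enrichment of non-optimal codons in helices: per-position
# Fisher's exact odds ratios against all other aligned positions, and
# simulated null distributions of those odds ratios under uniform
# selection. The point of the null distributions: amino-acid composition
# biases and gene expression alone can displace the odds ratios from 1
# even when selection is identical at every position.

#' Align helix codons by position from the helix start
#'
#' Column `p` collects the codon at helix-relative position `p` from
#' every helix of length >= `p`.
#'
#' @param segments Helix segments: data frame `gene_id`, `start`, `end`
#'   (1-based inclusive codon coordinates).
#' @param genome Named list of per-gene codon vectors or an
#'   `annotated_genome`.
#' @param max_position Largest helix-relative position retained.
#' @return List of length `max_position`; element `p` is the character
#'   vector of codons observed at position `p`.
#' @export
align_helices_by_position <- function(segments, genome, max_position) {
  stopifnot(max_position >= 1)
  codons <- as_codon_list(genome)
  out <- vector("list", max_position)
  for (p in seq_len(max_position)) {
    lens <- segments$end - segments$start + 1L
    keep <- lens >= p
    if (!any(keep)) {
      out[[p]] <- character(0)
      next
    }
    g <- segments$gene_id[keep]
    pos <- segments$start[keep] + p - 1L
    out[[p]] <- vapply(seq_along(g),
                       function(i) codons[[g[i]]][pos[i]], character(1))
  }
  out
}

#' Read a codon optimality classification table
#'
#' CSV with columns `codon`, `class` where class is `optimal` or
#' `non-optimal`. The classification is consumed as an external input
#' (e.g. derived from a translational-efficiency metric); it is not
#' computed here.
#'
#' @param path File path.
#' @return Named character vector codon -> class.
#' @export
read_optimality_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("codon", "class") %in% names(df))) {
    stop("optimality table must have columns codon, class")
  }
  if (!all(df$class %in% c("optimal", "non-optimal"))) {
    stop("optimality classes must be 'optimal' or 'non-optimal'")
  }
  stats::setNames(df$class, df$codon)
}

#' Per-position odds ratio of non-optimal codon enrichment
#'
#' Builds the 2x2 table (non-optimal, optimal) at position `p` versus
#' pooled over the comparison stratum -- by default all other aligned
#' positions, optionally only positions beyond the analyzed window.
#' The reported odds ratio is the sample cross-product `ad / bc`; the
#' conditional-MLE estimate that R's exact test reports is available via
#' `or_estimate = "cmle"`. The p-value is the two-sided Fisher's exact
#' test.
#'
#' @param aligned Positional codon lists from
#'   [align_helices_by_position()].
#' @param p Position analyzed (1-based).
#' @param optimality Named codon -> class vector (see
#'   [read_optimality_table()]).
#' @param comparison `"others"` (all other positions) or
#'   `"beyond_window"` (positions > `window`).
#' @param window Analysis window size used by `"beyond_window"`.
#' @param or_estimate `"cross_product"` (default) or `"cmle"`.
#' @return Object of class `position_or`: `position`, `table` (2x2),
#'   `odds_ratio`, `p_value`, `degenerate` flag (zero margin).
#' @export
position_odds_ratio <- function(aligned, p, optimality,
                                comparison = c("others", "beyond_window"),
                                window = 4,
                                or_estimate = c("cross_product", "cmle")) {
  comparison <- match.arg(comparison)
  or_estimate <- match.arg(or_estimate)
  if (p > length(aligned) || !length(aligned[[p]])) {
    stop("position ", p, " is not populated")
  }
  at_p <- aligned[[p]]
  other_idx <- if (comparison == "others") setdiff(seq_along(aligned), p)
               else setdiff(seq_along(aligned), seq_len(window))
  others <- unlist(aligned[other_idx], use.names = FALSE)
  classify <- function(cds) {
    cl <- optimality[cds]
    cl <- cl[!is.na(cl)] # codons without a classification are dropped
    c(nonopt = sum(cl == "non-optimal"), opt = sum(cl == "optimal"))
  }
  cp <- classify(at_p)
  co <- classify(others)
  tab <- matrix(c(cp["nonopt"], cp["opt"], co["nonopt"], co["opt"]),
                2, 2, byrow = TRUE,
                dimnames = list(c("position", "others"),
                                c("non-optimal", "optimal")))
  a <- tab[1, 1]; b <- tab[1, 2]; c2 <- tab[2, 1]; d <- tab[2, 2]
  degenerate <- any(rowSums(tab) == 0) || any(colSums(tab) == 0)
  or <- if (b * c2 == 0) {
    if (a * d == 0) NaN else Inf
  } else a * d / (b * c2)
  ft <- stats::fisher.test(tab)
  structure(list(position = p, table = tab,
                 odds_ratio = if (or_estimate == "cross_product") or
                              else unname(ft$estimate),
                 p_value = ft$p.value, degenerate = degenerate,
                 comparison = comparison),
            class = "position_or")
}

#' @export
print.position_or <- function(x, ...) {
  cat(sprintf("position %d: OR = %.3f, Fisher p = %.4g%s\n",
              x$position, x$odds_ratio, x$p_value,
              if (x$degenerate) " (degenerate margin)" else ""))
  invisible(x)
}

#' Simulated null distribution of per-position odds ratios
#'
#' Re-simulates codons under uniform selection (no positional
#' differences, no flips) on the template genome's amino acids and phi,
#' `n_replicates` times, recomputing the per-position odds ratios each
#' time. Comparing an observed odds ratio to this distribution -- rather
#' than to 1 -- is the evolutionary null for position-enrichment tests.
#'
#' @param genome Template `annotated_genome`.
#' @param segments Helix segments (gene_id, start, end).
#' @param optimality Named codon -> class vector.
#' @param params Truth [parameter_set()] (default: template's).
#' @param n_replicates Number of simulated genomes (>= 2).
#' @param positions Positions analyzed (default 1:4).
#' @param observed Optional named numeric of observed odds ratios per
#'   position to locate within the replicate range.
#' @param seed Master seed.
#' @param ... Passed to [position_odds_ratio()].
#' @return Object of class `null_or_distribution`: `or` (replicates x
#'   positions matrix), `quantiles` (2.5/25/50/75/97.5% per position),
#'   `observed`, `observed_inside` (logical per position, if observed
#'   given), `fisher_p` (replicates x positions).
#' @export
null_or_distribution <- function(genome, segments, optimality,
                                 params = genome$params,
                                 n_replicates = 100, positions = 1:4,
                                 observed = NULL, seed = 1L, ...) {
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  reps <- simulate_null_replicates(genome, params, n_replicates, seed)
  max_pos <- max(positions)
  or <- pv <- matrix(NA_real_, n_replicates, length(positions),
                     dimnames = list(NULL, paste0("pos", positions)))
  for (r in seq_len(n_replicates)) {
    aligned <- align_helices_by_position(segments, reps[[r]], max_pos)
    for (i in seq_along(positions)) {
      res <- position_odds_ratio(aligned, positions[i], optimality, ...)
      or[r, i] <- res$odds_ratio
      pv[r, i] <- res$p_value
    }
  }
  qs <- apply(or, 2L, stats::quantile,
              probs = c(0.025, 0.25, 0.5, 0.75, 0.975), na.rm = TRUE)
  inside <- NULL
  if (!is.null(observed)) {
    inside <- vapply(seq_along(positions), function(i) {
      obs <- observed[[paste0("pos", positions[i])]] %||%
        observed[[i]]
      obs >= min(or[, i], na.rm = TRUE) & obs <= max(or[, i], na.rm = TRUE)
    }, logical(1))
    names(inside) <- paste0("pos", positions)
  }
  structure(list(or = or, quantiles = qs, fisher_p = pv,
                 positions = positions, n_replicates = n_replicates,
                 observed = observed, observed_inside = inside,
                 seed = seed),
            class = "null_or_distribution")
}

#' @export
print.null_or_distribution <- function(x, ...) {
  cat("null odds-ratio distribution over", x$n_replicates,
      "simulated genomes\n")
  print(signif(x$quantiles, 3))
  invisible(x)
}
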