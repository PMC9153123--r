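# Model comparison by the Deviance Information Criterion. Groupings
# fitted to identical data coverage (same codons, differently grouped)
# are directly comparable; DIC components add across the independent
# groups of a scheme.

#' Deviance Information Criterion of a fitted model
#'
#' Classic Spiegelhalter form: `D_bar` is the mean deviance over
#' posterior draws, `D_hat` the deviance at the per-parameter posterior
#' means, `p_D = D_bar - D_hat` the effective parameter count, and
#' `DIC = D_bar + p_D`. The variance-based alternative
#' `p_V = var(D) / 2` is available via `version = "pV"`.
#'
#' @param samples A `posterior_samples` object (or any list with
#'   `draws`, `deviance` and `loglik_at`).
#' @param version `"pD"` (default) or `"pV"`.
#' @return Object of class `dic_result`: `D_bar`, `D_hat`, `p_D`, `DIC`,
#'   `version`, `n_obs`.
#' @export
compute_dic <- function(samples, version = c("pD", "pV")) {
  version <- match.arg(version)
  if (length(samples$deviance) < 2) stop("need at least 2 draws for DIC")
  D_bar <- mean(samples$deviance)
  theta_hat <- colMeans(samples$draws)
  D_hat <- -2 * samples$loglik_at(theta_hat)
  p_D <- if (version == "pD") D_bar - D_hat
         else stats::var(samples$deviance) / 2
  structure(list(D_bar = D_bar, D_hat = D_hat, p_D = p_D,
                 DIC = D_bar + p_D, version = version,
                 n_obs = samples$n_obs %||% NA_real_),
            class = "dic_result")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.dic_result <- function(x, ...) {
  cat(sprintf("DIC = %.2f (D_bar = %.2f, D_hat = %.2f, p_%s = %.2f)\n",
              x$DIC, x$D_bar, x$D_hat,
              if (x$version == "pD") "D" else "V", x$p_D))
  invisible(x)
}

#' Sum DIC components over the independent groups of one scheme
#'
#' For a grouping scheme fitted group-by-group, deviances and effective
#' parameter counts add, so the scheme's DIC is the sum of its group
#' DICs.
#'
#' @param dics List of `dic_result`, one per group.
#' @return A `dic_result` for the whole scheme.
#' @export
combine_group_dics <- function(dics) {
  structure(list(D_bar = sum(vapply(dics, `[[`, numeric(1), "D_bar")),
                 D_hat = sum(vapply(dics, `[[`, numeric(1), "D_hat")),
                 p_D = sum(vapply(dics, `[[`, numeric(1), "p_D")),
                 DIC = sum(vapply(dics, `[[`, numeric(1), "DIC")),
                 version = dics[[1]]$version,
                 n_obs = sum(vapply(dics, function(d)
                   d$n_obs %||% NA_real_, numeric(1)))),
            class = "dic_result")
}

#' Rank grouping models by DIC
#'
#' Produces the model-comparison table: models sorted by DIC with
#' `delta_DIC = DIC_i - DIC_best` (the best model has 0; all values are
#' >= 0) and a qualitative support band following the usual rules of
#' thumb: < 2 substantial, 2-4 strong, 4-7 less, 7-10 little, >= 10
#' essentially none.
#'
#' @param dics Named list of `dic_result` objects (names are scheme
#'   ids). All models must have been fitted to identical data coverage;
#'   mismatched total counts (`n_obs`) are refused.
#' @return Data frame with columns `scheme`, `DIC`, `delta_DIC`,
#'   `support`, sorted ascending by DIC.
#' @export
compare_models <- function(dics) {
  if (is.null(names(dics)) || any(names(dics) == "")) {
    stop("dics must be a named list (names = scheme ids)")
  }
  n_obs <- vapply(dics, function(d) d$n_obs %||% NA_real_, numeric(1))
  known <- n_obs[!is.na(n_obs)]
  if (length(known) > 1 && length(unique(known)) > 1) {
    stop("models were fitted to different data coverage (n_obs differ); ",
         "DIC values are not comparable")
  }
  dic <- vapply(dics, `[[`, numeric(1), "DIC")
  out <- data.frame(scheme = names(dics), DIC = unname(dic),
                    stringsAsFactors = FALSE)
  out <- out[order(out$DIC), , drop = FALSE]
  out$delta_DIC <- out$DIC - out$DIC[1]
  out$support <- cut(out$delta_DIC, c(-Inf, 2, 4, 7, 10, Inf),
                     labels = c("substantial", "strong", "less",
                                "little", "none"),
                     right = FALSE)
  rownames(out) <- NULL
  out
}

#' Fit one grouping scheme and compute its DIC
#'
#' Convenience wrapper used by the model-comparison workflow: partitions
#' the genome under `scheme`, runs a selection-only fit per group, and
#' returns the combined DIC plus the per-group fits.
#'
#' @param genome Named list of codon vectors or `annotated_genome`.
#' @param label_track Named list of per-codon labels.
#' @param scheme A grouping scheme (see [enumerate_schemes()]).
#' @param fixed_params [parameter_set()] with the fixed delta_M.
#' @param phis Named phi vector.
#' @param settings [mcmc_settings()].
#' @param seed Integer seed (per-group seeds derived from it).
#' @param exclude_first_n Leading codons excluded per gene.
#' @return List with `dic` (`dic_result`), `fits` (per-group
#'   `posterior_samples`), `partition`.
#' @export
fit_scheme <- function(genome, label_track, scheme, fixed_params, phis,
                       settings = mcmc_settings(), seed = 1L,
                       exclude_first_n = 35) {
  part <- build_partitions(genome, label_track, scheme,
                           fixed_params$families, exclude_first_n)
  grp_names <- names(part$groups)
  fits <- vector("list", length(grp_names))
  names(fits) <- grp_names
  for (i in seq_along(grp_names)) {
    fits[[i]] <- fit_selection_only(part$groups[[i]]$counts, fixed_params,
                                    phis, settings,
                                    seed = seed + i - 1L)
  }
  dic <- combine_group_dics(lapply(fits, compute_dic))
  list(dic = dic, fits = fits, partition = part)
}
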