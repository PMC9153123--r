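# Bayesian estimation of the codon model by adaptive random-walk
# Metropolis. Region fits estimate delta_eta per codon with delta_M and
# phi fixed at genome-wide values; the full fit samples delta_M,
# delta_eta and per-gene phi jointly under the E[phi] = 1 constraint.
#
# Priors (weakly informative; they keep zero-count families finite):
# independent N(0, 10^2) on each free delta_M and delta_eta, lognormal
# on phi with meanlog = -sdlog^2/2.

#' MCMC chain settings
#'
#' @param iterations Total iterations (default 20000).
#' @param burnin Burn-in iterations discarded (default half); proposal
#'   adaptation is frozen at the end of burn-in.
#' @param thin Keep every `thin`-th post-burn-in iteration (default 10).
#' @param adapt_interval Iterations between proposal-scale adaptations
#'   during burn-in.
#' @param target_acceptance Target acceptance rate for scalar proposals
#'   (0.3, inside the 20-40% band appropriate for random-walk samplers).
#' @param initial_scale Initial random-walk standard deviation.
#' @return List of settings.
#' @export
mcmc_settings <- function(iterations = 20000L, burnin = iterations %/% 2L,
                          thin = 10L, adapt_interval = 50L,
                          target_acceptance = 0.3, initial_scale = 0.1) {
  stopifnot(iterations >= 2, burnin >= 0, burnin < iterations, thin >= 1)
  list(iterations = as.integer(iterations), burnin = as.integer(burnin),
       thin = as.integer(thin), adapt_interval = as.integer(adapt_interval),
       target_acceptance = target_acceptance,
       initial_scale = initial_scale)
}

# Sample delta_eta for one family, delta_M and phi fixed. Returns kept
# draws (n_kept x k), loglik trace and acceptance.
.sample_family_eta <- function(N, phi, dM, settings, prior_sd) {
  k <- length(dM)
  rs <- rowSums(N)
  use <- rs > 0
  n_kept <- (settings$iterations - settings$burnin) %/% settings$thin
  draws <- matrix(0, n_kept, k)
  if (!any(use)) {
    # zero-count family: posterior equals the prior
    for (j in 2:k) draws[, j] <- stats::rnorm(n_kept, 0, prior_sd)
    return(list(draws = draws, ll = numeric(n_kept), acceptance = NA_real_,
                zero_count = TRUE))
  }
  N <- N[use, , drop = FALSE]
  phi <- phi[use]
  rs <- rs[use]
  cN <- colSums(N)
  cNphi <- colSums(N * phi)
  constM <- -sum(cN * dM)
  dM_row <- matrix(-dM, nrow(N), k, byrow = TRUE)
  ll_fun <- function(eta) {
    E <- dM_row - tcrossprod(phi, eta)
    constM - sum(cNphi * eta) - sum(rs * .row_lse(E))
  }
  eta <- numeric(k)
  scales <- rep(settings$initial_scale, k)
  ll <- ll_fun(eta)
  lltrace <- numeric(n_kept)
  acc_total <- prop_total <- 0L
  acc_win <- prop_win <- numeric(k)
  free <- 2:k # reference codon (index 1) fixed at 0
  for (it in seq_len(settings$iterations)) {
    for (j in free) {
      prop <- eta
      prop[j] <- eta[j] + stats::rnorm(1L, 0, scales[j])
      llp <- ll_fun(prop)
      la <- llp - ll + (eta[j]^2 - prop[j]^2) / (2 * prior_sd^2)
      prop_win[j] <- prop_win[j] + 1
      prop_total <- prop_total + 1L
      if (is.finite(la) && log(stats::runif(1L)) < la) {
        eta <- prop
        ll <- llp
        acc_win[j] <- acc_win[j] + 1
        acc_total <- acc_total + 1L
      }
    }
    if (it <= settings$burnin && it %% settings$adapt_interval == 0L) {
      rate <- acc_win / pmax(prop_win, 1)
      scales <- pmin(pmax(scales * exp(rate - settings$target_acceptance),
                          1e-4), 10)
      acc_win[] <- prop_win[] <- 0
    }
    if (it > settings$burnin &&
        (it - settings$burnin) %% settings$thin == 0L) {
      kk <- (it - settings$burnin) %/% settings$thin
      draws[kk, ] <- eta
      lltrace[kk] <- ll
    }
  }
  list(draws = draws, ll = lltrace,
       acceptance = acc_total / max(prop_total, 1L), zero_count = FALSE)
}

#' Fit selection coefficients to one region, mutation bias and phi fixed
#'
#' Region ("selection-only") fit: posterior draws of the 40 free
#' `delta_eta` given codon counts for one region group, with `delta_M`
#' and per-gene `phi` fixed (typically at genome-wide estimates or, in
#' simulation studies, at truth). Families are conditionally independent
#' given `delta_M` and `phi`, so each family's chain runs separately;
#' aligned kept draws form valid joint posterior draws. A family with
#' zero total counts returns prior draws with a warning.
#'
#' @param counts Gene x codon count matrix (see [codon_count_matrix()]).
#' @param fixed_params A [parameter_set()] supplying the fixed `delta_M`
#'   (its `delta_eta` is ignored).
#' @param phis Named phi vector covering `rownames(counts)`.
#' @param settings [mcmc_settings()].
#' @param seed Integer seed (mandatory for reproducible reports).
#' @param prior_sd Normal prior standard deviation on each delta_eta.
#' @return Object of class `posterior_samples`: `draws` (kept x 59
#'   matrix over all codons; reference columns identically 0),
#'   `deviance` (per kept draw, -2 log-likelihood), `loglik_at`
#'   (function of a named delta_eta vector), `acceptance` per family,
#'   `n_obs` total codon counts, plus settings and seed.
#' @export
fit_selection_only <- function(counts, fixed_params, phis,
                               settings = mcmc_settings(), seed = 1L,
                               prior_sd = 10) {
  set.seed(seed)
  families <- fixed_params$families
  ids <- rownames(counts)
  if (!all(ids %in% names(phis))) stop("phis do not cover all genes in counts")
  phi <- unname(phis[ids])
  fam_list <- families$families
  n_kept <- (settings$iterations - settings$burnin) %/% settings$thin
  draws <- matrix(0, n_kept, length(families$codons),
                  dimnames = list(NULL, families$codons))
  ll_total <- numeric(n_kept)
  acceptance <- stats::setNames(numeric(length(fam_list)), names(fam_list))
  zero_fams <- character(0)
  fam_data <- list()
  for (fid in names(fam_list)) {
    f <- fam_list[[fid]]
    N <- counts[, f$codons, drop = FALSE]
    dM <- unname(fixed_params$delta_M[f$codons])
    res <- .sample_family_eta(N, phi, dM, settings, prior_sd)
    draws[, f$codons] <- res$draws
    ll_total <- ll_total + res$ll
    acceptance[fid] <- res$acceptance
    if (res$zero_count) zero_fams <- c(zero_fams, fid)
    fam_data[[fid]] <- list(N = N, dM = dM, codons = f$codons)
  }
  if (length(zero_fams)) {
    warning("families with zero counts returned prior draws: ",
            paste(zero_fams, collapse = ", "))
  }
  loglik_at <- function(eta) {
    tot <- 0
    for (fd in fam_data) {
      tot <- tot + .family_loglik(fd$N, phi, fd$dM,
                                  unname(eta[fd$codons]))
    }
    tot
  }
  structure(list(draws = draws, deviance = -2 * ll_total,
                 loglik_at = loglik_at,
                 acceptance = acceptance,
                 zero_count_families = zero_fams,
                 n_obs = sum(counts), settings = settings, seed = seed,
                 families = families, kind = "selection_only"),
            class = "posterior_samples")
}

#' @export
print.posterior_samples <- function(x, ...) {
  cat("posterior_samples (", x$kind, "): ", nrow(x$draws), " kept draws x ",
      ncol(x$draws), " parameters; mean deviance ",
      signif(mean(x$deviance), 6), "\n", sep = "")
  invisible(x)
}

#' Joint genome-wide fit of mutation bias, selection and expression
#'
#' Samples the 40 free `delta_M`, 40 free `delta_eta` and per-gene `phi`
#' jointly. Codon parameters use scalar random-walk updates per family;
#' all phi are updated in one vectorized sweep (genes are conditionally
#' independent given the codon parameters). After every phi sweep, phi
#' is renormalized to mean 1 and `delta_eta` rescaled by the same factor
#' so the E\[phi\] = 1 identifiability constraint holds exactly.
#'
#' @param counts Gene x codon count matrix over the whole genome.
#' @param families A [codon_family_table()].
#' @param settings [mcmc_settings()].
#' @param seed Integer seed.
#' @param prior_sd Normal prior sd on each delta_M / delta_eta.
#' @param phi_prior_sdlog Lognormal prior sdlog on phi.
#' @return A `posterior_samples` object whose `draws` columns are named
#'   `dM.<codon>`, `eta.<codon>` and `phi.<gene>`.
#' @export
fit_full <- function(counts, families = codon_family_table(),
                     settings = mcmc_settings(), seed = 1L,
                     prior_sd = 10, phi_prior_sdlog = 1.5) {
  set.seed(seed)
  ids <- rownames(counts)
  G <- length(ids)
  if (G < 2) stop("fit_full needs at least 2 genes")
  fam_list <- families$families
  fam_data <- lapply(fam_list, function(f) {
    N <- counts[, f$codons, drop = FALSE]
    list(N = N, rs = rowSums(N), cN = colSums(N), codons = f$codons,
         k = f$n_aa)
  })
  dM <- eta <- stats::setNames(numeric(length(families$codons)),
                               families$codons)
  phi <- rep(1, G)
  fam_ll <- function(fd, dMf, etaf, cNphi_f) {
    E <- matrix(-dMf, nrow(fd$N), fd$k, byrow = TRUE) -
      tcrossprod(phi, etaf)
    -sum(fd$cN * dMf) - sum(cNphi_f * etaf) - sum(fd$rs * .row_lse(E))
  }
  n_kept <- (settings$iterations - settings$burnin) %/% settings$thin
  par_names <- c(paste0("dM.", families$codons),
                 paste0("eta.", families$codons),
                 paste0("phi.", ids))
  draws <- matrix(0, n_kept, length(par_names),
                  dimnames = list(NULL, par_names))
  ll_kept <- numeric(n_kept)
  scales_dM <- scales_eta <- stats::setNames(
    rep(settings$initial_scale, length(families$codons)), families$codons)
  scales_ridge <- scales_dM * 0 + 0.3
  scales_phi <- rep(0.2, G)
  acc_dM <- prop_dM <- scales_dM * 0
  acc_eta <- prop_eta <- scales_eta * 0
  acc_ridge <- prop_ridge <- scales_dM * 0
  acc_phi <- prop_phi <- numeric(G)
  acc_total <- prop_total <- 0
  ml <- -phi_prior_sdlog^2 / 2
  for (it in seq_len(settings$iterations)) {
    cNphi <- lapply(fam_data, function(fd) colSums(fd$N * phi))
    for (fid in names(fam_list)) {
      fd <- fam_data[[fid]]
      cds <- fd$codons
      dMf <- unname(dM[cds])
      etaf <- unname(eta[cds])
      llf <- fam_ll(fd, dMf, etaf, cNphi[[fid]])
      for (j in 2:fd$k) {
        # delta_M update
        prop <- dMf
        prop[j] <- dMf[j] + stats::rnorm(1L, 0, scales_dM[cds[j]])
        llp <- fam_ll(fd, prop, etaf, cNphi[[fid]])
        la <- llp - llf + (dMf[j]^2 - prop[j]^2) / (2 * prior_sd^2)
        prop_dM[cds[j]] <- prop_dM[cds[j]] + 1
        prop_total <- prop_total + 1
        if (is.finite(la) && log(stats::runif(1L)) < la) {
          dMf <- prop
          llf <- llp
          acc_dM[cds[j]] <- acc_dM[cds[j]] + 1
          acc_total <- acc_total + 1
        }
        # delta_eta update
        prop <- etaf
        prop[j] <- etaf[j] + stats::rnorm(1L, 0, scales_eta[cds[j]])
        llp <- fam_ll(fd, dMf, prop, cNphi[[fid]])
        la <- llp - llf + (etaf[j]^2 - prop[j]^2) / (2 * prior_sd^2)
        prop_eta[cds[j]] <- prop_eta[cds[j]] + 1
        prop_total <- prop_total + 1
        if (is.finite(la) && log(stats::runif(1L)) < la) {
          etaf <- prop
          llf <- llp
          acc_eta[cds[j]] <- acc_eta[cds[j]] + 1
          acc_total <- acc_total + 1
        }
        # correlated "ridge" move: dM_j and eta_j are anti-correlated a
        # posteriori (only dM_j + eta_j * phi is strongly identified
        # near phi = 1), so propose along the ridge to mix the contrast
        dd <- stats::rnorm(1L, 0, scales_ridge[cds[j]])
        propM <- dMf
        propE <- etaf
        propM[j] <- dMf[j] + dd
        propE[j] <- etaf[j] - dd
        llp <- fam_ll(fd, propM, propE, cNphi[[fid]])
        la <- llp - llf +
          (dMf[j]^2 - propM[j]^2 + etaf[j]^2 - propE[j]^2) /
          (2 * prior_sd^2)
        prop_ridge[cds[j]] <- prop_ridge[cds[j]] + 1
        prop_total <- prop_total + 1
        if (is.finite(la) && log(stats::runif(1L)) < la) {
          dMf <- propM
          etaf <- propE
          llf <- llp
          acc_ridge[cds[j]] <- acc_ridge[cds[j]] + 1
          acc_total <- acc_total + 1
        }
      }
      dM[cds] <- dMf
      eta[cds] <- etaf
    }
    # vectorized per-gene phi update (independent given codon params)
    gene_ll <- function(ph) {
      tot <- numeric(G)
      for (fd in fam_data) {
        etaf <- unname(eta[fd$codons])
        dMf <- unname(dM[fd$codons])
        E <- matrix(-dMf, G, fd$k, byrow = TRUE) - tcrossprod(ph, etaf)
        tot <- tot - as.numeric(fd$N %*% dMf) -
          ph * as.numeric(fd$N %*% etaf) - fd$rs * .row_lse(E)
      }
      tot
    }
    cur_gll <- gene_ll(phi)
    phi_prop <- phi * exp(stats::rnorm(G, 0, scales_phi))
    prop_gll <- gene_ll(phi_prop)
    # lognormal prior + Jacobian of the log-scale proposal
    la <- prop_gll - cur_gll +
      stats::dlnorm(phi_prop, ml, phi_prior_sdlog, log = TRUE) -
      stats::dlnorm(phi, ml, phi_prior_sdlog, log = TRUE) +
      log(phi_prop) - log(phi)
    acc <- is.finite(la) & log(stats::runif(G)) < la
    phi[acc] <- phi_prop[acc]
    acc_phi <- acc_phi + acc
    prop_phi <- prop_phi + 1
    acc_total <- acc_total + sum(acc)
    prop_total <- prop_total + G
    # identifiability: renormalize phi to mean 1, rescale eta to keep
    # the eta * phi products unchanged
    cmean <- mean(phi)
    phi <- phi / cmean
    eta <- eta * cmean
    if (it <= settings$burnin && it %% settings$adapt_interval == 0L) {
      adapt <- function(s, a, p) {
        pmin(pmax(s * exp(a / pmax(p, 1) - settings$target_acceptance),
                  1e-4), 10)
      }
      scales_dM <- adapt(scales_dM, acc_dM, prop_dM)
      scales_eta <- adapt(scales_eta, acc_eta, prop_eta)
      scales_ridge <- adapt(scales_ridge, acc_ridge, prop_ridge)
      scales_phi <- adapt(scales_phi, acc_phi, prop_phi)
      acc_dM[] <- prop_dM[] <- acc_eta[] <- prop_eta[] <- 0
      acc_ridge[] <- prop_ridge[] <- 0
      acc_phi[] <- prop_phi[] <- 0
    }
    if (it > settings$burnin &&
        (it - settings$burnin) %% settings$thin == 0L) {
      kk <- (it - settings$burnin) %/% settings$thin
      cNphi <- lapply(fam_data, function(fd) colSums(fd$N * phi))
      ll <- 0
      for (fid in names(fam_list)) {
        fd <- fam_data[[fid]]
        ll <- ll + fam_ll(fd, unname(dM[fd$codons]),
                          unname(eta[fd$codons]), cNphi[[fid]])
      }
      draws[kk, ] <- c(dM, eta, phi)
      ll_kept[kk] <- ll
    }
  }
  overall_acc <- acc_total / max(prop_total, 1)
  if (overall_acc < 0.05) {
    warning("overall acceptance rate ", signif(overall_acc, 2),
            " < 5% after adaptation; chain may not be mixing")
  }
  loglik_at <- function(theta) {
    dMv <- theta[paste0("dM.", families$codons)]
    etav <- theta[paste0("eta.", families$codons)]
    phiv <- unname(theta[paste0("phi.", ids)])
    tot <- 0
    for (fd in fam_data) {
      tot <- tot + .family_loglik(fd$N, phiv,
                                  unname(dMv[paste0("dM.", fd$codons)]),
                                  unname(etav[paste0("eta.", fd$codons)]))
    }
    tot
  }
  structure(list(draws = draws, deviance = -2 * ll_kept,
                 loglik_at = loglik_at,
                 acceptance = overall_acc, n_obs = sum(counts),
                 settings = settings, seed = seed, families = families,
                 gene_ids = ids, kind = "full"),
            class = "posterior_samples")
}

#' Equal-tailed posterior intervals
#'
#' @param samples A `posterior_samples` object or a draws matrix.
#' @param level Interval probability in (0, 1); 0.95 gives the
#'   2.5%/97.5% quantiles.
#' @param parameters Optional column subset.
#' @return Matrix with columns `lo`, `hi` (one row per parameter).
#' @export
posterior_interval <- function(samples, level = 0.95, parameters = NULL) {
  if (level <= 0 || level >= 1) stop("level must be in (0, 1)")
  draws <- if (inherits(samples, "posterior_samples")) samples$draws
           else as.matrix(samples)
  if (!is.null(parameters)) draws <- draws[, parameters, drop = FALSE]
  a <- (1 - level) / 2
  q <- t(apply(draws, 2L, stats::quantile, probs = c(a, 1 - a),
               names = FALSE))
  colnames(q) <- c("lo", "hi")
  q
}
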