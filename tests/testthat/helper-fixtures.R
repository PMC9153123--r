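# Shared fixtures. Everything is built in code; no binary data.

FAM <- codon_family_table()

# reference codon of every family (alphabetically first)
ref_codons <- function(families = FAM) {
  vapply(families$families, function(f) f$codons[f$reference_index],
         character(1))
}

free_codons <- function(families = FAM) {
  setdiff(families$codons, ref_codons(families))
}

# parameter_set with selected codons overridden
params_with <- function(delta_M = NULL, delta_eta = NULL,
                        families = FAM) {
  dm <- de <- stats::setNames(numeric(length(families$codons)),
                              families$codons)
  if (!is.null(delta_M)) dm[names(delta_M)] <- delta_M
  if (!is.null(delta_eta)) de[names(delta_eta)] <- delta_eta
  parameter_set(dm, de, families)
}

# the lysine family AAA/AAG: the canonical 2-codon test family
fam2 <- FAM$families[["K"]]
# alanine GCA/GCC/GCG/GCT: 4-codon test family
fam4 <- FAM$families[["A"]]

# deterministic small truth set used across MCMC tests
truth_params <- function(seed = 421L) random_parameter_set(FAM, seed = seed)

# site-by-site log-likelihood oracle: loops sites and multiplies
# per-site probabilities from codon_probabilities (independent of the
# count-matrix aggregation path in loglikelihood()).
brute_force_loglik <- function(gene_codons, params, phis,
                               families = FAM) {
  ll <- 0
  for (g in names(gene_codons)) {
    for (codon in gene_codons[[g]]) {
      fid <- families$family_of[codon]
      if (is.na(fid)) next
      fid <- unname(fid)
      p <- codon_probabilities(families$families[[fid]], params,
                               unname(phis[g]))
      ll <- ll + log(p[[codon]])
    }
  }
  ll
}

# hypergeometric enumeration oracle for the two-sided Fisher p-value:
# enumerates every table with the observed margins using choose().
fisher_p_oracle <- function(a, b, c, d) {
  m1 <- a + b
  m2 <- c + d
  n1 <- a + c
  prob <- function(x) {
    choose(m1, x) * choose(m2, n1 - x) / choose(m1 + m2, n1)
  }
  lo <- max(0, n1 - m2)
  hi <- min(m1, n1)
  probs <- vapply(lo:hi, prob, numeric(1))
  p_obs <- prob(a)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# mock posterior_samples with prescribed deviances and D_hat
mock_samples <- function(deviances, d_hat, draws = NULL) {
  if (is.null(draws)) {
    draws <- matrix(seq_along(deviances), ncol = 1,
                    dimnames = list(NULL, "x"))
  }
  list(draws = draws, deviance = deviances,
       loglik_at = function(theta) -d_hat / 2, n_obs = 10)
}
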