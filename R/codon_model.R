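# Selection-mutation-drift codon model: softmax of -(delta_M + delta_eta * phi)
# over the synonymous codons of one family. All evaluations use
# max-subtraction (log-sum-exp) for overflow safety.

.row_lse <- function(E) {
  m <- E[, 1L]
  k <- ncol(E)
  if (k > 1L) for (j in 2L:k) m <- pmax(m, E[, j])
  m + log(rowSums(exp(E - m)))
}

#' Codon probabilities for one synonymous family
#'
#' Probability of each synonymous codon in a gene with production rate
#' `phi` under the selection-mutation-drift model:
#' `p_i = exp(-dM_i - deta_i * phi) / sum_j exp(-dM_j - deta_j * phi)`.
#' At `phi = 0` selection is absent and mutation bias alone sets the
#' frequencies; at `phi = 1` the gene has average expression and
#' `delta_eta` equals s*Ne.
#'
#' @param family A `codon_family` (an element of
#'   `codon_family_table()$families`).
#' @param params A [parameter_set()].
#' @param phi Non-negative scalar production rate.
#' @return Named probability vector over `family$codons` (sums to 1).
#' @examples
#' fam <- codon_family_table()
#' p <- uniform_parameter_set(fam)
#' codon_probabilities(fam$families[["K"]], p, phi = 1) # (0.5, 0.5)
#' @export
codon_probabilities <- function(family, params, phi) {
  if (!inherits(family, "codon_family") || family$n_aa < 2L) {
    stop("family must be a codon_family with at least 2 codons")
  }
  if (!is.numeric(phi) || length(phi) != 1L || !is.finite(phi) || phi < 0) {
    stop("phi must be a single finite non-negative number")
  }
  dM <- params$delta_M[family$codons]
  de <- params$delta_eta[family$codons]
  x <- -dM - de * phi
  x <- x - max(x)
  p <- exp(x)
  p / sum(p)
}

#' All-zero parameter set (uniform synonymous usage)
#'
#' @param families A [codon_family_table()].
#' @return A [parameter_set()] with `delta_M = delta_eta = 0` everywhere.
#' @export
uniform_parameter_set <- function(families = codon_family_table()) {
  z <- stats::setNames(numeric(length(families$codons)), families$codons)
  parameter_set(z, z, families)
}

#' Expected codon frequency curves across a grid of production rates
#'
#' Evaluates [codon_probabilities()] at each value of `phi_grid`; used to
#' visualise how small shifts in selection translate into expected codon
#' frequencies as gene expression varies.
#'
#' @inheritParams codon_probabilities
#' @param phi_grid Non-empty numeric vector of non-negative phi values.
#' @return Matrix with one row per grid value (rownames = phi) and one
#'   column per codon; every row sums to 1.
#' @export
expected_frequency_curve <- function(family, params, phi_grid) {
  if (length(phi_grid) == 0L) stop("phi_grid must be non-empty")
  out <- t(vapply(phi_grid,
                  function(phi) codon_probabilities(family, params, phi),
                  numeric(family$n_aa)))
  rownames(out) <- as.character(phi_grid)
  colnames(out) <- family$codons
  out
}

#' Count codons of a gene over unmasked sites
#'
#' Tallies codons into the columns of the family table. ATG and TGG
#' (single-codon amino acids) are ignored for model counts. A stop codon
#' at an unmasked site is an error (coding sequences are expected to have
#' their trailing stop stripped on read; see [read_cds_fasta()]).
#'
#' @param codons Character vector of uppercase DNA codons (one gene).
#' @param site_mask Logical vector, same length; `TRUE` sites are
#'   counted. `NULL` counts all sites.
#' @param families A [codon_family_table()].
#' @param gene_id Identifier used in error messages.
#' @return Named integer vector over `families$codons`.
#' @export
count_codons <- function(codons, site_mask = NULL,
                         families = codon_family_table(),
                         gene_id = "sequence") {
  if (is.null(site_mask)) site_mask <- rep(TRUE, length(codons))
  if (length(site_mask) != length(codons)) {
    stop("site_mask length must equal sequence length for ", gene_id)
  }
  used <- codons[site_mask]
  if (length(used)) {
    if (any(!grepl("^[ACGT]{3}$", used))) {
      stop("gene ", gene_id, ": codon with non-ACGT base or wrong length: ",
           paste(unique(used[!grepl("^[ACGT]{3}$", used)]), collapse = ", "))
    }
    if (any(used %in% c("TAA", "TAG", "TGA"))) {
      stop("gene ", gene_id, ": internal stop codon at unmasked site")
    }
  }
  tab <- table(factor(used, levels = families$codons))
  out <- stats::setNames(as.integer(tab), families$codons)
  out
}

#' Codon count matrix for a set of genes
#'
#' Sufficient statistics for the model likelihood: a gene x codon integer
#' matrix over the family table's codons.
#'
#' @param genome Named list of per-gene codon vectors (or an
#'   [annotated_genome]).
#' @param masks Optional named list of logical site masks, aligned with
#'   `genome`.
#' @param families A [codon_family_table()].
#' @return Integer matrix, rownames = gene ids, colnames = codons.
#' @export
codon_count_matrix <- function(genome, masks = NULL,
                               families = codon_family_table()) {
  genome <- as_codon_list(genome)
  ids <- names(genome)
  if (is.null(ids)) stop("genome must be a named list of codon vectors")
  out <- matrix(0L, length(ids), length(families$codons),
                dimnames = list(ids, families$codons))
  for (g in ids) {
    out[g, ] <- count_codons(genome[[g]],
                             if (is.null(masks)) NULL else masks[[g]],
                             families, gene_id = g)
  }
  out
}

# Coerce annotated_genome or plain list to a named list of codon vectors.
as_codon_list <- function(genome) {
  if (inherits(genome, "annotated_genome")) {
    stats::setNames(lapply(genome$genes, `[[`, "codons"),
                    vapply(genome$genes, `[[`, character(1), "id"))
  } else {
    genome
  }
}

# log-likelihood of one family's counts. N: genes x k counts, phi: gene
# vector, dM/eta: length-k. Uses the identity
#   sum_g sum_j N[g,j] * (-dM_j - eta_j phi_g) = -cN.dM - cNphi.eta
# so only the log-sum-exp term needs the full G x k matrix.
.family_loglik <- function(N, phi, dM, eta) {
  rs <- rowSums(N)
  use <- rs > 0
  if (!any(use)) return(0)
  N <- N[use, , drop = FALSE]
  phi <- phi[use]
  rs <- rs[use]
  E <- matrix(-dM, nrow(N), length(dM), byrow = TRUE) - tcrossprod(phi, eta)
  sum(N * E) - sum(rs * .row_lse(E))
}

#' Model log-likelihood of a codon count matrix
#'
#' Multinomial log-likelihood `sum_g sum_families sum_i n_ig log p_ig`
#' under the selection-mutation-drift model (no multinomial coefficient;
#' sites are independent given the gene's phi).
#'
#' @param counts Gene x codon matrix as from [codon_count_matrix()].
#' @param params A [parameter_set()].
#' @param phis Named numeric vector of per-gene phi covering
#'   `rownames(counts)`.
#' @return Scalar log-likelihood.
#' @export
loglikelihood <- function(counts, params, phis) {
  ids <- rownames(counts)
  if (is.null(ids)) stop("counts must have gene ids as rownames")
  if (!all(ids %in% names(phis))) {
    stop("phis missing genes: ",
         paste(utils::head(setdiff(ids, names(phis)), 5), collapse = ", "))
  }
  phi <- unname(phis[ids])
  fams <- params$families$families
  ll <- 0
  for (f in fams) {
    ll <- ll + .family_loglik(counts[, f$codons, drop = FALSE], phi,
                              unname(params$delta_M[f$codons]),
                              unname(params$delta_eta[f$codons]))
  }
  ll
}
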