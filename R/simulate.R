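# Forward simulator of annotated coding sequences under the
# selection-mutation-drift model. The model's stationary distribution is
# sampled directly per site -- there is no generational dynamics.
#
# Amino-acid templates use family ids as symbols (the 19 multi-codon
# families, with serine represented as "S4"/"S2" so every site maps to
# exactly one family) plus "M" and "W", which are emitted verbatim.

#' Draw a random truth parameter set
#'
#' Non-reference codons get `delta_M ~ N(0, sd_delta_M^2)` and
#' `delta_eta ~ N(0, sd_delta_eta^2)`; reference codons stay at 0. The
#' defaults give mutation-bias and selection magnitudes comparable to
#' genome-wide fits in fast-growing microbes (|delta_M| mostly < 2,
#' |delta_eta| mostly < 1).
#'
#' @param families A [codon_family_table()].
#' @param sd_delta_M,sd_delta_eta Standard deviations of the draws.
#' @param seed Optional integer seed.
#' @return A [parameter_set()].
#' @export
random_parameter_set <- function(families = codon_family_table(),
                                 sd_delta_M = 1, sd_delta_eta = 0.4,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  dm <- de <- stats::setNames(numeric(length(families$codons)),
                              families$codons)
  for (f in families$families) {
    free <- f$codons[-f$reference_index]
    dm[free] <- stats::rnorm(length(free), 0, sd_delta_M)
    de[free] <- stats::rnorm(length(free), 0, sd_delta_eta)
  }
  parameter_set(dm, de, families)
}

#' Simulate per-gene protein production rates
#'
#' phi is lognormal with `meanlog = -sdlog^2/2` so that `E[phi] = 1`,
#' matching the model's identifiability convention that the average
#' expression across genes is 1.
#'
#' @param n_genes Number of genes (>= 1).
#' @param sdlog Lognormal spread on the log scale (>= 0); `0` gives all
#'   phi = 1.
#' @param seed Optional integer seed.
#' @return Named numeric vector of phi (names `g0001`, ...).
#' @export
simulate_expression <- function(n_genes, sdlog = 1, seed = NULL) {
  if (n_genes < 1) stop("n_genes must be >= 1")
  if (sdlog < 0) stop("sdlog must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  phi <- stats::rlnorm(n_genes, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  stats::setNames(phi, sprintf("g%04d", seq_len(n_genes)))
}

#' Segment grammar for structure annotations
#'
#' Describes how per-codon structure labels and amino acids are
#' generated: genes are tilings of alternating labeled segments whose
#' lengths are `min_length + Geometric` with the requested mean, and each
#' label draws amino acids (family-id symbols) from its own composition.
#' One label may impose a distinct composition at chosen positions near
#' the start of each of its segments (to reproduce position-dependent
#' amino-acid confounding at e.g. helix starts).
#'
#' @param labels Character vector of structure labels.
#' @param composition Named list (per label) of named probability vectors
#'   over amino-acid symbols; each must sum to 1.
#' @param mean_length,min_length Per-label segment length parameters
#'   (recycled).
#' @param head_positions,head_label,head_composition Optional override:
#'   within segments of `head_label`, the segment-relative positions in
#'   `head_positions` (e.g. `2:3`) draw from `head_composition`.
#' @return An object of class `label_grammar`.
#' @export
label_grammar <- function(labels, composition,
                          mean_length = 8, min_length = 2,
                          head_positions = integer(0), head_label = NULL,
                          head_composition = NULL) {
  stopifnot(length(labels) >= 1, all(labels %in% names(composition)))
  for (lab in labels) {
    if (abs(sum(composition[[lab]]) - 1) > 1e-8) {
      stop("composition for label ", lab, " does not sum to 1")
    }
  }
  mean_length <- rep_len(mean_length, length(labels))
  min_length <- rep_len(min_length, length(labels))
  if (any(mean_length < min_length)) {
    stop("mean_length must be >= min_length")
  }
  if (length(head_positions)) {
    stopifnot(!is.null(head_label), !is.null(head_composition))
    if (abs(sum(head_composition) - 1) > 1e-8) {
      stop("head_composition does not sum to 1")
    }
  }
  structure(list(labels = labels,
                 composition = composition,
                 mean_length = stats::setNames(mean_length, labels),
                 min_length = stats::setNames(min_length, labels),
                 head_positions = as.integer(head_positions),
                 head_label = head_label,
                 head_composition = head_composition),
            class = "label_grammar")
}

#' Uniform grammar helper
#'
#' Grammar in which every label draws uniformly over the 19 family
#' symbols -- the neutral composition used by default in simulations.
#'
#' @inheritParams label_grammar
#' @param families A [codon_family_table()].
#' @export
uniform_grammar <- function(labels, families = codon_family_table(),
                            mean_length = 8, min_length = 2) {
  syms <- names(families$families)
  comp <- stats::setNames(
    rep(list(stats::setNames(rep(1 / length(syms), length(syms)), syms)),
        length(labels)),
    labels)
  label_grammar(labels, comp, mean_length, min_length)
}

# Draw one segment length: min + geometric with the requested mean.
.seg_length <- function(mean_len, min_len) {
  if (mean_len <= min_len) return(as.integer(min_len))
  as.integer(min_len + stats::rgeom(1L, 1 / (1 + mean_len - min_len)))
}

#' Simulate per-gene structure labels and amino-acid templates
#'
#' @param n_genes Number of genes.
#' @param gene_lengths Integer vector of gene lengths in codons (length
#'   `n_genes`, or a scalar recycled).
#' @param grammar A [label_grammar()].
#' @param seed Optional integer seed.
#' @return Named list per gene with elements `labels` and `aa`
#'   (amino-acid symbols: family ids).
#' @export
simulate_annotations <- function(n_genes, gene_lengths, grammar,
                                 seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  gene_lengths <- rep_len(as.integer(gene_lengths), n_genes)
  labs <- grammar$labels
  out <- vector("list", n_genes)
  for (g in seq_len(n_genes)) {
    L <- gene_lengths[g]
    lab_vec <- character(L)
    aa_vec <- character(L)
    pos <- 1L
    cur <- sample(labs, 1L)
    while (pos <= L) {
      len <- min(.seg_length(grammar$mean_length[[cur]],
                             grammar$min_length[[cur]]), L - pos + 1L)
      idx <- pos:(pos + len - 1L)
      lab_vec[idx] <- cur
      comp <- grammar$composition[[cur]]
      aa_vec[idx] <- sample(names(comp), len, replace = TRUE, prob = comp)
      if (length(grammar$head_positions) &&
          identical(cur, grammar$head_label)) {
        head_idx <- idx[grammar$head_positions[grammar$head_positions <= len]]
        if (length(head_idx)) {
          fc <- grammar$head_composition
          aa_vec[head_idx] <- sample(names(fc), length(head_idx),
                                     replace = TRUE, prob = fc)
        }
      }
      pos <- pos + len
      if (length(labs) > 1L) cur <- sample(setdiff(labs, cur), 1L)
    }
    out[[g]] <- list(labels = lab_vec, aa = aa_vec)
  }
  names(out) <- sprintf("g%04d", seq_len(n_genes))
  out
}

#' Choose the amino-acid sites whose selection sign is flipped
#'
#' Exactly `round(flip_fraction * N)` sites carrying `region_label`
#' (pooled across the genome) are selected without replacement, where
#' `round` is R's round-half-to-even. Flips are confined to the
#' designated region label.
#'
#' @param labels Named list of per-gene label vectors.
#' @param region_label The label designating the heterogeneous-selection
#'   region.
#' @param flip_fraction Fraction in \[0, 1\] of region sites to flip.
#' @param seed Optional integer seed.
#' @return Named list of per-gene logical flip masks.
#' @export
flip_selection_sites <- function(labels, region_label, flip_fraction,
                                 seed = NULL) {
  if (flip_fraction < 0 || flip_fraction > 1) {
    stop("flip_fraction must be in [0, 1]")
  }
  if (!is.null(seed)) set.seed(seed)
  masks <- lapply(labels, function(l) rep(FALSE, length(l)))
  site_gene <- rep(seq_along(labels),
                   vapply(labels, length, integer(1)))
  site_pos <- unlist(lapply(labels, seq_along), use.names = FALSE)
  in_region <- unlist(labels, use.names = FALSE) == region_label
  region_idx <- which(in_region)
  n_flip <- round(flip_fraction * length(region_idx))
  if (n_flip > 0) {
    chosen <- region_idx[sample.int(length(region_idx), n_flip)]
    for (s in chosen) masks[[site_gene[s]]][site_pos[s]] <- TRUE
  }
  names(masks) <- names(labels)
  masks
}

#' Sample codons for annotated amino-acid templates
#'
#' Each site's codon is drawn from [codon_probabilities()] given the
#' gene's phi, with `delta_eta` multiplied by -1 at flipped sites.
#' "M" and "W" sites emit ATG and TGG verbatim. The simulated codons
#' always translate back to the template amino acids.
#'
#' @param annotations As returned by [simulate_annotations()] (per-gene
#'   `labels` + `aa`).
#' @param params Truth [parameter_set()].
#' @param phis Named phi vector covering the genes.
#' @param flips Optional named list of logical flip masks
#'   (see [flip_selection_sites()]); `NULL` means no flips.
#' @param seed Optional integer seed.
#' @return An object of class `annotated_genome`: list with `genes`
#'   (each: `id`, `codons`, `labels`, `aa`, `flipped`, `phi`), plus the
#'   truth `params` and `seed` used.
#' @export
simulate_codons <- function(annotations, params, phis, flips = NULL,
                            seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  ids <- names(annotations)
  if (!all(ids %in% names(phis))) stop("phis missing genes")
  fams <- params$families
  lens <- vapply(annotations, function(a) length(a$aa), integer(1))
  gene_of_site <- rep(seq_along(ids), lens)
  aa_all <- unlist(lapply(annotations, `[[`, "aa"), use.names = FALSE)
  flip_all <- if (is.null(flips)) rep(FALSE, length(aa_all)) else
    unlist(flips[ids], use.names = FALSE)
  phi_site <- unname(phis[ids])[gene_of_site]
  known <- c(names(fams$families), "M", "W")
  if (!all(aa_all %in% known)) {
    stop("unknown amino-acid symbol(s): ",
         paste(unique(setdiff(aa_all, known)), collapse = ", "))
  }
  codon_all <- character(length(aa_all))
  codon_all[aa_all == "M"] <- "ATG"
  codon_all[aa_all == "W"] <- "TGG"
  sign_site <- ifelse(flip_all, -1, 1)
  for (fid in names(fams$families)) {
    f <- fams$families[[fid]]
    idx <- which(aa_all == fid)
    if (!length(idx)) next
    dM <- unname(params$delta_M[f$codons])
    de <- unname(params$delta_eta[f$codons])
    # site x codon utilities; sign flip negates selection only
    E <- matrix(-dM, length(idx), f$n_aa, byrow = TRUE) -
      tcrossprod(sign_site[idx] * phi_site[idx], de)
    E <- E - apply(E, 1L, max)
    P <- exp(E)
    P <- P / rowSums(P)
    cum <- t(apply(P, 1L, cumsum))
    u <- stats::runif(length(idx))
    pick <- rowSums(cum < u) + 1L
    codon_all[idx] <- f$codons[pick]
  }
  genes <- vector("list", length(ids))
  off <- 0L
  for (g in seq_along(ids)) {
    idx <- off + seq_len(lens[g])
    genes[[g]] <- list(id = ids[g],
                       codons = codon_all[idx],
                       labels = annotations[[g]]$labels,
                       aa = annotations[[g]]$aa,
                       flipped = flip_all[idx],
                       phi = unname(phis[ids[g]]))
    off <- off + lens[g]
  }
  names(genes) <- ids
  structure(list(genes = genes, params = params, seed = seed),
            class = "annotated_genome")
}

#' @export
print.annotated_genome <- function(x, ...) {
  n <- length(x$genes)
  total <- sum(vapply(x$genes, function(g) length(g$codons), integer(1)))
  cat("annotated_genome:", n, "genes,", total, "codons\n")
  invisible(x)
}

#' Accessors for annotated genomes
#'
#' @param genome An `annotated_genome`.
#' @return Named list (codons, labels, aa, flip masks) or named numeric
#'   (phi) over genes.
#' @export
genome_codons <- function(genome) {
  stats::setNames(lapply(genome$genes, `[[`, "codons"), names(genome$genes))
}

#' @rdname genome_codons
#' @export
genome_labels <- function(genome) {
  stats::setNames(lapply(genome$genes, `[[`, "labels"), names(genome$genes))
}

#' @rdname genome_codons
#' @export
genome_aa <- function(genome) {
  stats::setNames(lapply(genome$genes, `[[`, "aa"), names(genome$genes))
}

#' @rdname genome_codons
#' @export
genome_flips <- function(genome) {
  stats::setNames(lapply(genome$genes, `[[`, "flipped"), names(genome$genes))
}

#' @rdname genome_codons
#' @export
genome_phis <- function(genome) {
  vapply(genome$genes, `[[`, numeric(1), "phi")
}

#' Simulate a full annotated genome
#'
#' Convenience wrapper: expression, annotations, flip mask and codons in
#' one call. Gene lengths are Poisson around `mean_length` (floored at
#' 10 codons).
#'
#' @param n_genes Number of genes.
#' @param mean_length Mean gene length in codons.
#' @param sdlog Lognormal spread of phi.
#' @param params Truth [parameter_set()]; default
#'   [random_parameter_set()] under the current RNG state.
#' @param grammar A [label_grammar()]; default two uniform labels
#'   `A`/`B`.
#' @param flip_fraction Fraction of `flip_label` sites whose selection
#'   sign is flipped.
#' @param flip_label Label designating the heterogeneous-selection
#'   region.
#' @param seed Integer seed (mandatory for reproducibility; recorded in
#'   the result).
#' @return An `annotated_genome`.
#' @export
simulate_genome <- function(n_genes = 300, mean_length = 300, sdlog = 1,
                            params = NULL, grammar = NULL,
                            flip_fraction = 0, flip_label = "B",
                            seed = 1L) {
  set.seed(seed)
  if (is.null(params)) params <- random_parameter_set(params_families())
  if (is.null(grammar)) grammar <- uniform_grammar(c("A", "B"))
  phis <- simulate_expression(n_genes, sdlog)
  lens <- pmax(10L, stats::rpois(n_genes, mean_length))
  ann <- simulate_annotations(n_genes, lens, grammar)
  flips <- if (flip_fraction > 0) {
    flip_selection_sites(lapply(ann, `[[`, "labels"), flip_label,
                         flip_fraction)
  } else NULL
  g <- simulate_codons(ann, params, phis, flips)
  g$seed <- seed
  g$flip_fraction <- flip_fraction
  g$flip_label <- flip_label
  g
}

params_families <- function() codon_family_table()

#' Replicate uniform-selection null genomes
#'
#' Re-draws codons independently for each replicate on the same
#' amino-acid templates, labels and phi, with no sign flips -- the
#' evolutionary null in which the strength and direction of selection is
#' identical across all structure labels.
#'
#' @param genome Template `annotated_genome` (its `aa`, `labels`, `phi`
#'   are reused).
#' @param params Truth [parameter_set()] (default: the template's).
#' @param n_replicates Number of replicates (>= 1).
#' @param seed Master seed; per-replicate seeds are derived
#'   deterministically from it.
#' @return List of `annotated_genome` replicates.
#' @export
simulate_null_replicates <- function(genome, params = genome$params,
                                     n_replicates = 100, seed = 1L) {
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  ann <- lapply(genome$genes, function(g)
    list(labels = g$labels, aa = g$aa))
  phis <- genome_phis(genome)
  lapply(seq_len(n_replicates), function(r) {
    simulate_codons(ann, params, phis, flips = NULL, seed = rep_seeds[r])
  })
}
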