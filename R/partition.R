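# Conversion of structure information into per-codon labels and
# construction of the region groupings ("models") whose codon counts the
# fitter consumes. Coordinates are 1-based inclusive codon units; the
# initiator ATG counts as codon 1.

#' Collapse a DSSP string to three-class secondary structure
#'
#' H/G/I -> helix (`"H"`), E/B -> sheet (`"E"`), S/T/. -> coil (`"C"`).
#' The `.` symbol is DSSP's catch-all for residues matching no other
#' class. Optionally, 3_10- and pi-helix residues (G, I) can be dropped
#' (returned as `NA`, i.e. unassigned) to restrict helices to
#' alpha-helices only.
#'
#' @param dssp_string Single string over the alphabet `HGIEBST.`.
#' @param exclude_310_pi Logical; if `TRUE`, G and I become `NA`.
#' @return Character vector of per-residue labels `"H"`, `"E"`, `"C"`
#'   (and `NA` when excluded).
#' @export
dssp_to_three_class <- function(dssp_string, exclude_310_pi = FALSE) {
  stopifnot(length(dssp_string) == 1L)
  ch <- strsplit(dssp_string, "", fixed = TRUE)[[1]]
  if (length(ch) == 0L) return(character(0))
  map <- c(H = "H", G = "H", I = "H", E = "E", B = "E",
           S = "C", T = "C", "." = "C")
  if (exclude_310_pi) map[c("G", "I")] <- NA_character_
  bad <- which(!ch %in% names(map))
  if (length(bad)) {
    stop("unknown DSSP character '", ch[bad[1]], "' at position ", bad[1])
  }
  unname(map[ch])
}

#' Threshold per-residue disorder quasi-probabilities
#'
#' Scores strictly greater than the threshold are classified disordered
#' (`"D"`); scores less than or equal to it are structured (`"S"`). The
#' boundary value 0.5 is therefore structured.
#'
#' @param scores Numeric vector of quasi-probabilities in \[0, 1\].
#' @param threshold Classification threshold (default 0.5).
#' @return Character vector of `"S"`/`"D"` labels.
#' @export
disorder_from_scores <- function(scores, threshold = 0.5) {
  if (any(!is.finite(scores)) || any(scores < 0 | scores > 1)) {
    stop("disorder scores must lie in [0, 1]")
  }
  ifelse(scores > threshold, "D", "S")
}

#' Combine secondary-structure and disorder tracks into composite labels
#'
#' Labels become e.g. `"H^S"` (structured helix) or `"C^D"` (disordered
#' coil). `NA` in either input yields `NA` (unassigned). Both component
#' tracks are recoverable from the composite.
#'
#' @param ss_track Character vector over `"H"`, `"E"`, `"C"`.
#' @param disorder_track Character vector over `"S"`, `"D"`, same length.
#' @return Character vector of composite labels.
#' @export
combine_labels <- function(ss_track, disorder_track) {
  if (length(ss_track) != length(disorder_track)) {
    stop("secondary-structure and disorder tracks differ in length")
  }
  ifelse(is.na(ss_track) | is.na(disorder_track), NA_character_,
         paste0(ss_track, "^", disorder_track))
}

#' Run-length segments of a label track
#'
#' @param labels Named list of per-gene label vectors.
#' @return Data frame with columns `gene_id`, `start`, `end`, `label`
#'   (1-based inclusive codon coordinates); `NA` runs are omitted.
#' @export
segments_from_labels <- function(labels) {
  out <- lapply(names(labels), function(g) {
    r <- rle(labels[[g]])
    end <- cumsum(r$lengths)
    start <- end - r$lengths + 1L
    keep <- !is.na(r$values)
    data.frame(gene_id = g, start = start[keep], end = end[keep],
               label = r$values[keep], stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' All grouping schemes over a label alphabet
#'
#' Enumerates every set partition of the label alphabet (the full model
#' family over 2-6 labels; 5 schemes for a 3-letter alphabet), including
#' the all-merged null, the all-separate model, and every two-way merge.
#' Scheme ids are stable: group names concatenate their labels with `+`
#' in alphabet order, groups join with `|`.
#'
#' @param labels Character vector (the label alphabet, size 2-6).
#' @return List of schemes; each is a list with `scheme_id` and `map`
#'   (named character: label -> group name).
#' @export
enumerate_schemes <- function(labels) {
  n <- length(labels)
  if (n < 2 || n > 6) stop("label alphabet must have 2-6 labels")
  # restricted growth strings enumerate set partitions
  parts <- list()
  grow <- function(assign, mx) {
    i <- length(assign) + 1L
    if (i > n) {
      parts[[length(parts) + 1L]] <<- assign
      return(invisible())
    }
    for (b in seq_len(mx + 1L)) grow(c(assign, b), max(mx, b))
  }
  grow(integer(0), 0L)
  lapply(parts, function(assign) {
    groups <- split(labels, assign)
    gnames <- vapply(groups, paste, character(1), collapse = "+")
    map <- stats::setNames(rep(gnames, lengths(groups)),
                           unlist(groups, use.names = FALSE))
    map <- map[labels]
    list(scheme_id = paste(unique(unname(map)), collapse = "|"),
         map = map)
  })
}

#' Build one scheme from a scheme-id string
#'
#' `"H+E|C"` maps H and E to one group and C to another; `"H|E|C"` keeps
#' all separate.
#'
#' @param scheme_id Scheme-id string.
#' @return A scheme list as in [enumerate_schemes()].
#' @export
parse_scheme <- function(scheme_id) {
  groups <- strsplit(scheme_id, "|", fixed = TRUE)[[1]]
  map <- unlist(lapply(groups, function(g) {
    labs <- strsplit(g, "+", fixed = TRUE)[[1]]
    stats::setNames(rep(g, length(labs)), labs)
  }))
  list(scheme_id = scheme_id, map = map)
}

#' Partition a genome's codons into region groups
#'
#' Drops the first `exclude_first_n` codons of every gene (reducing the
#' impact of distinct selection at the 5' gene end), assigns every
#' remaining labeled codon to exactly one group per the scheme, and
#' returns per-group codon count matrices plus site lists. Codons with
#' `NA` labels ("unassigned") are dropped from every group of every
#' scheme, so schemes over the same track always cover identical codon
#' sets -- the property that licenses DIC comparison between schemes.
#'
#' @param genome Named list of per-gene codon vectors, or an
#'   `annotated_genome`.
#' @param label_track Named list of per-codon label vectors covering all
#'   genes of `genome`.
#' @param scheme A scheme (see [enumerate_schemes()], [parse_scheme()]).
#' @param families A [codon_family_table()].
#' @param exclude_first_n Number of leading codons excluded per gene
#'   (default 35).
#' @return Object of class `region_partition`: list with `groups` (per
#'   group: `counts` matrix and `sites` data frame of gene_id /
#'   codon_index), `scheme`, and `exclude_first_n`.
#' @export
build_partitions <- function(genome, label_track, scheme,
                             families = codon_family_table(),
                             exclude_first_n = 35) {
  stopifnot(exclude_first_n >= 0)
  codons <- as_codon_list(genome)
  missing <- setdiff(names(codons), names(label_track))
  if (length(missing)) {
    stop("genes missing from label track: ",
         paste(utils::head(missing, 10), collapse = ", "))
  }
  for (g in names(codons)) {
    if (length(label_track[[g]]) != length(codons[[g]])) {
      stop("label track length mismatch for gene ", g)
    }
  }
  group_names <- unique(unname(scheme$map))
  groups <- stats::setNames(vector("list", length(group_names)),
                            group_names)
  for (grp in group_names) {
    grp_labels <- names(scheme$map)[scheme$map == grp]
    masks <- lapply(names(codons), function(g) {
      lab <- label_track[[g]]
      m <- !is.na(lab) & lab %in% grp_labels
      if (exclude_first_n > 0) {
        m[seq_len(min(exclude_first_n, length(m)))] <- FALSE
      }
      m
    })
    names(masks) <- names(codons)
    counts <- codon_count_matrix(codons, masks, families)
    sites <- do.call(rbind, lapply(names(masks), function(g) {
      idx <- which(masks[[g]])
      if (!length(idx)) return(NULL)
      data.frame(gene_id = g, codon_index = idx, stringsAsFactors = FALSE)
    }))
    groups[[grp]] <- list(counts = counts, sites = sites)
  }
  structure(list(groups = groups, scheme = scheme,
                 exclude_first_n = exclude_first_n),
            class = "region_partition")
}

#' Label structure-segment termini and cores
#'
#' Splits every segment of length >= `min_length` into its first and
#' last `terminus_size` codons and a (possibly empty) core. In
#' `"combined_termini"` mode both ends share the label `"termini"`; in
#' `"nc_separate"` mode they are `"N-terminus"` and `"C-terminus"`.
#' Segments shorter than `min_length` are excluded entirely. Segments
#' long enough to include but too short for two disjoint termini
#' (`min_length <= L < 2 * terminus_size`) are an error, since their
#' labeling is undefined.
#'
#' @param segments Data frame `gene_id`, `start`, `end`, `label`
#'   (1-based inclusive), e.g. from [segments_from_labels()].
#' @param gene_lengths Named integer vector of gene lengths in codons.
#' @param terminus_size Number of codons per terminus (typically 2 or 3).
#' @param min_length Minimum segment length (in codons) to include.
#' @param mode `"combined_termini"` or `"nc_separate"`.
#' @return Named list of per-gene label vectors (`NA` outside included
#'   segments).
#' @export
split_termini <- function(segments, gene_lengths, terminus_size = 2,
                          min_length = 2 * terminus_size,
                          mode = c("combined_termini", "nc_separate")) {
  mode <- match.arg(mode)
  stopifnot(terminus_size >= 1)
  track <- lapply(gene_lengths, function(L) rep(NA_character_, L))
  for (i in seq_len(nrow(segments))) {
    g <- segments$gene_id[i]
    s <- segments$start[i]
    e <- segments$end[i]
    L <- e - s + 1L
    if (L < min_length) next
    if (L < 2 * terminus_size) {
      stop("segment ", g, ":", s, "-", e, " is included (length ", L,
           " >= min_length) but too short for disjoint termini of size ",
           terminus_size)
    }
    n_idx <- s:(s + terminus_size - 1L)
    c_idx <- (e - terminus_size + 1L):e
    core_idx <- setdiff(s:e, c(n_idx, c_idx))
    if (mode == "combined_termini") {
      track[[g]][c(n_idx, c_idx)] <- "termini"
    } else {
      track[[g]][n_idx] <- "N-terminus"
      track[[g]][c_idx] <- "C-terminus"
    }
    if (length(core_idx)) track[[g]][core_idx] <- "core"
  }
  track
}

#' Label the second and third codons of helices vs the remainder
#'
#' For each helix segment of length >= `min_length`, codons 2 and 3
#' (relative to the helix start) get label `"pos23"` and codons 1 and
#' 4..L get `"remainder"`; shorter helices are excluded.
#'
#' @param segments Helix segments (data frame `gene_id`, `start`, `end`).
#' @param gene_lengths Named integer vector of gene lengths in codons.
#' @param min_length Minimum helix length (default 6).
#' @return Named list of per-gene label vectors (`NA` outside included
#'   helices).
#' @export
positions_2_3_split <- function(segments, gene_lengths, min_length = 6) {
  track <- lapply(gene_lengths, function(L) rep(NA_character_, L))
  for (i in seq_len(nrow(segments))) {
    g <- segments$gene_id[i]
    s <- segments$start[i]
    e <- segments$end[i]
    if (e - s + 1L < min_length) next
    track[[g]][s:e] <- "remainder"
    track[[g]][c(s + 1L, s + 2L)] <- "pos23"
  }
  track
}
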