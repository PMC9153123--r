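# File formats: CDS FASTA (codon-aligned), per-codon annotation TSV,
# segment TSV, DSSP/disorder tracks, JSON run configs and manifests.

#' Read codon-aligned coding sequences from FASTA
#'
#' Sequences are uppercased and split into codons; length must be
#' divisible by 3; a trailing stop codon is stripped and recorded;
#' internal stops and non-ACGT bases are per-record errors. By default
#' any bad record aborts the read with a per-record report; with
#' `skip_bad_records = TRUE` bad records are dropped with a warning.
#'
#' @param path FASTA file path.
#' @param skip_bad_records Drop bad records instead of aborting.
#' @return Named list of per-gene codon vectors, with attribute
#'   `stripped_stop` (named logical).
#' @export
read_cds_fasta <- function(path, skip_bad_records = FALSE) {
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0) stop("no sequences in ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  chars <- toupper(as.character(seqs))
  out <- list()
  stripped <- logical(0)
  errors <- character(0)
  stops <- c("TAA", "TAG", "TGA")
  for (i in seq_along(chars)) {
    s <- chars[i]
    id <- ids[i]
    if (nchar(s) %% 3 != 0) {
      errors <- c(errors, paste0(id, ": length ", nchar(s),
                                 " not divisible by 3"))
      next
    }
    cods <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
    had_stop <- FALSE
    if (length(cods) && cods[length(cods)] %in% stops) {
      cods <- cods[-length(cods)]
      had_stop <- TRUE
    }
    if (any(!grepl("^[ACGT]{3}$", cods))) {
      errors <- c(errors, paste0(id, ": non-ACGT base"))
      next
    }
    if (any(cods %in% stops)) {
      errors <- c(errors, paste0(id, ": internal stop codon at codon ",
                                 which(cods %in% stops)[1]))
      next
    }
    out[[id]] <- cods
    stripped[id] <- had_stop
  }
  if (length(errors)) {
    msg <- paste(errors, collapse = "\n  ")
    if (skip_bad_records) {
      warning("skipped bad records:\n  ", msg)
    } else {
      stop("bad records (use skip_bad_records to drop them):\n  ", msg)
    }
  }
  if (!length(out)) stop("no valid sequences in ", path)
  attr(out, "stripped_stop") <- stripped
  out
}

#' Write codon sequences to FASTA
#'
#' @param genome Named list of codon vectors or `annotated_genome`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_cds_fasta <- function(genome, path) {
  codons <- as_codon_list(genome)
  x <- Biostrings::DNAStringSet(vapply(codons, paste, character(1),
                                       collapse = ""))
  names(x) <- names(codons)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Read/write per-codon annotation tracks
#'
#' TSV with columns `gene_id`, `codon_index` (1-based), `label` and
#' optionally `flipped` (0/1).
#'
#' @param path File path.
#' @param labels Named list of per-codon label vectors.
#' @param flips Optional named list of logical flip masks.
#' @return `read_annotation_track` returns a list with `labels` and
#'   `flips` (named lists per gene).
#' @export
read_annotation_track <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "codon_index", "label")
  if (!all(need %in% names(df))) {
    stop("annotation track needs columns ", paste(need, collapse = ", "))
  }
  labels <- flips <- list()
  for (g in unique(df$gene_id)) {
    sub <- df[df$gene_id == g, , drop = FALSE]
    L <- max(sub$codon_index)
    lab <- rep(NA_character_, L)
    lab[sub$codon_index] <- sub$label
    labels[[g]] <- lab
    if ("flipped" %in% names(df)) {
      fl <- rep(FALSE, L)
      fl[sub$codon_index] <- sub$flipped == 1
      flips[[g]] <- fl
    }
  }
  list(labels = labels, flips = if (length(flips)) flips else NULL)
}

#' @rdname read_annotation_track
#' @export
write_annotation_track <- function(labels, path, flips = NULL) {
  df <- do.call(rbind, lapply(names(labels), function(g) {
    data.frame(gene_id = g, codon_index = seq_along(labels[[g]]),
               label = labels[[g]],
               flipped = if (is.null(flips)) 0L
                         else as.integer(flips[[g]]),
               stringsAsFactors = FALSE)
  }))
  df <- df[!is.na(df$label), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read/write segment tables (gene_id, start, end, label; 1-based
#' inclusive)
#'
#' @param path File path.
#' @param segments Segment data frame.
#' @export
read_segment_table <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("gene_id", "start", "end", "label")
  if (!all(need %in% names(df))) {
    stop("segment table needs columns ", paste(need, collapse = ", "))
  }
  if (any(df$end < df$start)) stop("segment with end < start")
  df
}

#' @rdname read_segment_table
#' @export
write_segment_table <- function(segments, path) {
  utils::write.table(segments, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a raw DSSP track (TSV: gene_id, dssp_string)
#'
#' @param path File path.
#' @param exclude_310_pi Passed to [dssp_to_three_class()].
#' @return Named list of per-residue three-class label vectors.
#' @export
read_dssp_track <- function(path, exclude_310_pi = FALSE) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "dssp_string") %in% names(df))) {
    stop("DSSP track needs columns gene_id, dssp_string")
  }
  stats::setNames(lapply(df$dssp_string, dssp_to_three_class,
                         exclude_310_pi = exclude_310_pi),
                  df$gene_id)
}

#' Read a disorder-score track (TSV: gene_id, comma-separated scores)
#'
#' @param path File path.
#' @param threshold Passed to [disorder_from_scores()].
#' @return Named list of per-residue `"S"`/`"D"` label vectors.
#' @export
read_disorder_track <- function(path, threshold = 0.5) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = "character")
  if (!all(c("gene_id", "scores") %in% names(df))) {
    stop("disorder track needs columns gene_id, scores")
  }
  stats::setNames(lapply(df$scores, function(s) {
    disorder_from_scores(as.numeric(strsplit(s, ",", fixed = TRUE)[[1]]),
                         threshold)
  }), df$gene_id)
}

#' Read a run configuration (JSON)
#'
#' Declarative key/value configuration for the command-line pipeline;
#' a `seed` entry is mandatory. Command-line flags override config
#' entries.
#'
#' @param path JSON file path.
#' @return Named list.
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  if (is.null(cfg$seed)) stop("run config must set a seed")
  cfg
}

# Write the self-describing manifest every CLI command leaves behind.
write_manifest <- function(outdir, command, options, seed, t0) {
  jsonlite::write_json(
    list(command = command,
         options = options,
         seed = seed,
         package = "cubshift",
         version = as.character(utils::packageVersion("cubshift")),
         wall_time_sec = as.numeric(difftime(Sys.time(), t0,
                                             units = "secs"))),
    file.path(outdir, "manifest.json"), auto_unbox = TRUE, digits = NA,
    null = "null")
  invisible(NULL)
}
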