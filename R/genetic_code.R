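#' Synonymous codon families under the standard genetic code
#'
#' Builds the table of synonymous-codon families used throughout the
#' package: the 59 sense codons belonging to amino acids with two or more
#' synonyms (the 61 sense codons minus the single-codon amino acids ATG
#' and TGG; stop codons excluded). To satisfy the weak-selection
#' assumption of the codon model, serine is split into two families: the
#' four-codon group TCN (`"S4"`) and the two-codon group AGC/AGT (`"S2"`),
#' giving 19 families. Leucine and arginine are kept as single six-codon
#' families.
#'
#' Families and codons within families are ordered alphabetically; the
#' alphabetically first codon of each family is the fitting reference
#' (a pure reparameterization -- presentation rescaling to the most
#' selectively-favored codon happens in [rescale_to_reference()]).
#' With one reference per family there are `59 - 19 = 40` free parameters
#' per parameter class (delta M or delta eta).
#'
#' @param serine_split Logical; split serine into S4 (TCN) and S2
#'   (AGC/AGT). `TRUE` is the standard configuration; `FALSE` gives 18
#'   families with a single six-codon serine family.
#' @return An object of class `codon_family_table`: a list with elements
#'   `families` (named list of `codon_family` objects, each with
#'   `family_id`, `codons`, `reference_index`, `n_aa`), `codons` (all
#'   codons in table order), `family_of` (named character, codon ->
#'   family id), `n_free` (free parameters per class) and `serine_split`.
#' @examples
#' fam <- codon_family_table()
#' length(fam$families)   # 19
#' fam$n_free             # 40
#' @export
codon_family_table <- function(serine_split = TRUE) {
  gc <- Biostrings::GENETIC_CODE
  sense <- gc[gc != "*"]
  by_aa <- split(names(sense), unname(sense))
  by_aa <- by_aa[vapply(by_aa, length, integer(1)) >= 2L] # drops M, W
  if (isTRUE(serine_split)) {
    ser <- sort(by_aa[["S"]])
    by_aa[["S"]] <- NULL
    by_aa[["S4"]] <- ser[startsWith(ser, "TC")]
    by_aa[["S2"]] <- ser[startsWith(ser, "AG")]
  }
  ids <- sort(names(by_aa))
  families <- lapply(ids, function(id) {
    codons <- sort(by_aa[[id]])
    structure(
      list(family_id = id, codons = codons, reference_index = 1L,
           n_aa = length(codons)),
      class = "codon_family"
    )
  })
  names(families) <- ids
  codons <- unlist(lapply(families, `[[`, "codons"), use.names = FALSE)
  family_of <- rep(ids, times = vapply(families, `[[`, integer(1), "n_aa"))
  names(family_of) <- codons
  structure(
    list(families = families, codons = codons, family_of = family_of,
         n_free = length(codons) - length(families),
         serine_split = isTRUE(serine_split)),
    class = "codon_family_table"
  )
}

#' @export
print.codon_family_table <- function(x, ...) {
  cat("codon family table:", length(x$families), "families,",
      length(x$codons), "codons,", x$n_free, "free parameters per class",
      if (x$serine_split) "(serine split S4/S2)" else "", "\n")
  invisible(x)
}

#' Per-codon mutation-bias and selection parameters
#'
#' Bundles the two per-codon parameter classes of the codon model:
#' `delta_M`, the log ratio of mutation rates between a codon and its
#' family's reference codon, and `delta_eta`, the selection coefficient
#' relative to the reference in units of s*Ne for a gene of average
#' expression (phi = 1). The reference codon of every family must carry
#' exactly 0 in both classes.
#'
#' @param delta_M,delta_eta Named numeric vectors over all codons of
#'   `families` (names are codons). Reference codons must be 0; all
#'   values finite.
#' @param families A [codon_family_table()].
#' @return An object of class `parameter_set` with elements `delta_M`,
#'   `delta_eta` (full named vectors in table order) and `families`.
#' @export
parameter_set <- function(delta_M, delta_eta, families) {
  stopifnot(inherits(families, "codon_family_table"))
  delta_M <- delta_M[families$codons]
  delta_eta <- delta_eta[families$codons]
  if (anyNA(delta_M) || anyNA(delta_eta)) {
    stop("parameter_set: delta_M/delta_eta must cover every codon in the family table")
  }
  if (!all(is.finite(delta_M)) || !all(is.finite(delta_eta))) {
    stop("parameter_set: all parameter values must be finite")
  }
  refs <- vapply(families$families,
                 function(f) f$codons[f$reference_index], character(1))
  bad <- refs[delta_M[refs] != 0 | delta_eta[refs] != 0]
  if (length(bad)) {
    stop("parameter_set: reference codons must have delta_M = delta_eta = 0: ",
         paste(bad, collapse = ", "))
  }
  names(delta_M) <- names(delta_eta) <- families$codons
  structure(list(delta_M = delta_M, delta_eta = delta_eta,
                 families = families),
            class = "parameter_set")
}

#' @export
print.parameter_set <- function(x, ...) {
  cat("parameter_set over", length(x$delta_M), "codons; range delta_M [",
      paste(signif(range(x$delta_M), 3), collapse = ", "),
      "], range delta_eta [",
      paste(signif(range(x$delta_eta), 3), collapse = ", "), "]\n")
  invisible(x)
}

#' @export
as.data.frame.parameter_set <- function(x, ...) {
  data.frame(family_id = unname(x$families$family_of[names(x$delta_M)]),
             codon = names(x$delta_M),
             delta_M = unname(x$delta_M),
             delta_eta = unname(x$delta_eta),
             stringsAsFactors = FALSE)
}

#' Read/write a parameter table (CSV with family_id, codon, delta_M, delta_eta)
#'
#' Reference rows are present with zeros, matching the on-disk contract
#' used by the command-line interface.
#'
#' @param path File path.
#' @param params A [parameter_set()].
#' @param families A [codon_family_table()] used to validate the file.
#' @return `read_parameter_table` returns a [parameter_set()];
#'   `write_parameter_table` returns `path` invisibly.
#' @export
read_parameter_table <- function(path, families = codon_family_table()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "codon", "delta_M", "delta_eta")
  if (!all(need %in% names(df))) {
    stop("parameter table must have columns ", paste(need, collapse = ", "))
  }
  dm <- stats::setNames(df$delta_M, df$codon)
  de <- stats::setNames(df$delta_eta, df$codon)
  parameter_set(dm, de, families)
}

#' @rdname read_parameter_table
#' @export
write_parameter_table <- function(params, path) {
  utils::write.csv(as.data.frame(params), path, row.names = FALSE)
  invisible(path)
}

#' Read/write a gene expression table (CSV with gene_id, phi)
#'
#' phi is the evolutionary-average protein production rate of a gene,
#' scaled so the genome mean is 1.
#'
#' @param path File path.
#' @param phi Named numeric vector of per-gene phi (all positive).
#' @return `read_expression_table` returns a named numeric vector.
#' @export
read_expression_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("gene_id", "phi") %in% names(df))) {
    stop("expression table must have columns gene_id, phi")
  }
  phi <- stats::setNames(df$phi, df$gene_id)
  if (any(!is.finite(phi)) || any(phi <= 0)) {
    stop("all phi must be positive and finite")
  }
  phi
}

#' @rdname read_expression_table
#' @export
write_expression_table <- function(phi, path) {
  utils::write.csv(data.frame(gene_id = names(phi), phi = unname(phi)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Translate codons to one-letter amino acids
#'
#' @param codons Character vector of uppercase DNA codons.
#' @return Character vector of one-letter amino acids (`"*"` for stops).
#' @export
translate_codons <- function(codons) {
  gc <- Biostrings::GENETIC_CODE
  aa <- gc[codons]
  if (anyNA(aa)) {
    stop("invalid codon(s): ",
         paste(unique(codons[is.na(aa)]), collapse = ", "))
  }
  unname(aa)
}
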