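#' Load the reference set of known DPP-IV inhibitory peptides
#'
#' The release-frequency statistic counts digest fragments whose sequence
#' appears in a reference set of peptides with the activity of interest.
#' The shipped set is a small curation of food-derived DPP-IV inhibitory
#' peptides from the published literature (with IC50 annotations where
#' reported); it is a stand-in for a full bioactive-peptide database
#' snapshot, which users can supply via `path`.
#'
#' @param path Optional path to a tab-delimited file with a `sequence`
#'   column (optional `ic50_um`, `source`).
#' @return A `data.frame` with at least a `sequence` column; duplicate
#'   sequences are dropped (set semantics).
#' @export
dppiv_reference <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "dppiv_reference.tsv", package = "dppscreen")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  if (!"sequence" %in% names(df)) {
    stop("reference table needs a 'sequence' column", call. = FALSE)
  }
  df$sequence <- toupper(df$sequence)
  df[!duplicated(df$sequence) & nchar(df$sequence) > 0, , drop = FALSE]
}

.reference_sequences <- function(reference) {
  if (is.data.frame(reference)) unique(reference$sequence)
  else unique(as.character(reference))
}

#' Frequency of release of active fragments (A value)
#'
#' The BIOPEP-style statistic A = d / N, where N is the protein length in
#' residues and d the number of complete-digest fragments whose sequence is
#' in the activity reference set. By default d counts fragment occurrences
#' with multiplicity (two identical released fragments both matching count
#' twice, as fragments in a hydrolysate would); set
#' `count = "distinct"` to count each matching sequence once.
#'
#' @param sequence Protein sequence string.
#' @param fragments Complete-digest fragments of the protein: a character
#'   vector, or a [digest()] data frame (its `n_missed == 0` rows are used).
#' @param reference Reference peptide set: character vector or a data frame
#'   with a `sequence` column (see [dppiv_reference()]).
#' @param count `"occurrence"` (default) or `"distinct"`.
#' @return A single number in \[0, 1\].
#' @examples
#' a_value("AYFGK", c("AY", "F", "GK"), c("AY", "GK"))  # 2/5
#' @export
a_value <- function(sequence, fragments, reference,
                    count = c("occurrence", "distinct")) {
  count <- match.arg(count)
  if (is.data.frame(fragments)) {
    fragments <- fragments$sequence[fragments$n_missed == 0]
  }
  fragments <- as.character(fragments)
  n <- nchar(sequence)
  if (sum(nchar(fragments)) != n ||
      paste(fragments, collapse = "") != sequence) {
    # order-tolerant check: fragments must tile the protein
    if (sum(nchar(fragments)) != n) {
      stop("fragments do not tile the protein (length mismatch)",
           call. = FALSE)
    }
    stop("fragments do not tile the protein (sequence mismatch)",
         call. = FALSE)
  }
  ref <- .reference_sequences(reference)
  matched <- fragments[fragments %in% ref]
  d <- if (count == "occurrence") length(matched) else length(unique(matched))
  d / n
}

#' Rank enzyme combinations by total release frequency (sum-A)
#'
#' Evaluates every enzyme subset of size 1 up to `max_combo_size` from the
#' catalogue: each subset digests every protein to completion (one-pot
#' union-of-sites model, 0 missed cleavages), A is computed per protein
#' against the reference set, and subsets are ranked by the sum of A over
#' proteins. With the default five-enzyme catalogue and `max_combo_size = 2`
#' this evaluates the 15 single- and two-enzyme groups.
#'
#' @param proteins Protein table ([read_fasta()] output).
#' @param catalogue Named rule list from [enzyme_catalogue()]; `NULL` loads
#'   the shipped catalogue.
#' @param max_combo_size Largest subset size, in 1..3 (default 2).
#' @param reference Reference peptide set (default [dppiv_reference()]).
#' @param count Passed to [a_value()].
#' @return A `data.frame` with columns `enzymes` (names joined by `+`),
#'   `combo_size`, one `A_<protein id>` column per protein, and `sum_a`;
#'   sorted by `sum_a` descending with ties broken lexicographically by the
#'   enzyme name string. Attribute `n_groups` records how many subsets were
#'   evaluated.
#' @export
rank_combos <- function(proteins, catalogue = NULL, max_combo_size = 2,
                        reference = dppiv_reference(),
                        count = c("occurrence", "distinct")) {
  count <- match.arg(count)
  if (is.null(catalogue)) catalogue <- enzyme_catalogue()
  if (length(catalogue) == 0) stop("enzyme catalogue is empty", call. = FALSE)
  stopifnot(max_combo_size %in% 1:3)
  enz <- sort(names(catalogue))
  subsets <- unlist(lapply(seq_len(min(max_combo_size, length(enz))),
                           function(k) combn(enz, k, simplify = FALSE)),
                    recursive = FALSE)
  ref <- .reference_sequences(reference)
  rows <- lapply(subsets, function(s) {
    a <- vapply(seq_len(nrow(proteins)), function(i) {
      frags <- digest(proteins$sequence[i], catalogue[s], max_missed = 0)
      a_value(proteins$sequence[i], frags, ref, count = count)
    }, numeric(1))
    c(list(enzymes = paste(s, collapse = "+"), combo_size = length(s)),
      setNames(as.list(a), paste0("A_", proteins$id)),
      list(sum_a = sum(a)))
  })
  res <- do.call(rbind, lapply(rows, function(r)
    as.data.frame(r, stringsAsFactors = FALSE)))
  res <- res[order(-res$sum_a, res$enzymes), , drop = FALSE]
  rownames(res) <- NULL
  attr(res, "n_groups") <- length(subsets)
  res
}
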