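#' Read protein sequences from a FASTA file
#'
#' Parses a multi-record FASTA file into a protein table. Sequences are
#' upper-cased and validated against the 20-letter canonical amino-acid
#' alphabet; ambiguity and rare codes (B, J, O, U, X, Z) are rejected because
#' digestion statistics are meaningless over wildcards.
#'
#' @param path Path to a FASTA file.
#' @param noncanonical Policy for sequences containing non-canonical residues:
#'   `"error"` (default) aborts naming the offending residue, `"skip"` drops
#'   the record with a warning.
#' @return A `data.frame` with columns `id`, `description`, `sequence`, one
#'   row per FASTA record, input order preserved.
#' @examples
#' tf <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1 demo", "AYFGK"), tf)
#' read_fasta(tf)
#' @export
read_fasta <- function(path, noncanonical = c("error", "skip")) {
  noncanonical <- match.arg(noncanonical)
  if (!file.exists(path)) stop("FASTA file not found: ", path, call. = FALSE)
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0) stop("FASTA file is empty: ", path, call. = FALSE)
  headers <- names(aa)
  ids <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) == 0)) {
    stop("FASTA record with empty sequence: ",
         paste(ids[nchar(seqs) == 0], collapse = ", "), call. = FALSE)
  }
  ok <- is_canonical(seqs)
  if (!all(ok)) {
    if (noncanonical == "error") {
      assert_canonical(seqs, what = paste0("record ", ids[!ok][1]))
    }
    warning("skipping ", sum(!ok), " record(s) with non-canonical residues: ",
            paste(ids[!ok], collapse = ", "), call. = FALSE)
    ids <- ids[ok]; desc <- desc[ok]; seqs <- seqs[ok]
  }
  data.frame(id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write protein sequences to a FASTA file
#'
#' @param proteins A protein table as returned by [read_fasta()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$id, proteins$description),
                proteins$id)
  writeLines(paste0(">", hdr, "\n", proteins$sequence), path)
  invisible(path)
}

.detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

.read_delim_auto <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) sep <- .detect_sep(path)
  df <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                   check.names = FALSE, na.strings = character())
  # "NA"/"" mark missing cells everywhere except the sequence column,
  # where "NA" is the Asn-Ala dipeptide
  for (col in setdiff(names(df), "sequence")) {
    if (is.character(df[[col]])) df[[col]][df[[col]] %in% c("NA", "")] <- NA
  }
  df
}

.require_columns <- function(df, required, path) {
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop("missing required column(s) in ", path, ": ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

SOLUBILITY_CLASSES <- c("VS", "S", "MS", "PS")

#' Read a peptide identification table
#'
#' Reads a delimited text table emulating MS search-engine peptide output.
#' Required columns: `sequence`, `identification_score`, `source` (one of
#' `casein`, `whey`, `both`). Optional: `retention_time` (min),
#' `mass_observed` (Da). Missing optional cells stay `NA`; they are never
#' silently defaulted.
#'
#' @param path Path to a tab- or comma-delimited file with a header row.
#' @param sep Field separator; `NULL` (default) auto-detects tab vs comma.
#' @param noncanonical Policy for peptides with non-canonical residues:
#'   `"skip"` (default) drops the row with a warning, `"error"` aborts.
#' @return A `data.frame` with the typed columns above, row order preserved.
#' @export
read_peptide_table <- function(path, sep = NULL,
                               noncanonical = c("skip", "error")) {
  noncanonical <- match.arg(noncanonical)
  df <- .read_delim_auto(path, sep)
  .require_columns(df, c("sequence", "identification_score", "source"), path)
  df$sequence <- toupper(as.character(df$sequence))
  df$identification_score <- suppressWarnings(
    as.numeric(df$identification_score))
  if (nrow(df) > 0) {
    if (any(is.na(df$identification_score))) {
      stop("unparseable identification_score at row ",
           which(is.na(df$identification_score))[1], call. = FALSE)
    }
    if (any(df$identification_score < 0)) {
      stop("identification_score must be >= 0 (row ",
           which(df$identification_score < 0)[1], ")", call. = FALSE)
    }
    bad_src <- !df$source %in% c("casein", "whey", "both") & !is.na(df$source)
    if (any(bad_src)) {
      stop("invalid source value at row ", which(bad_src)[1],
           " (must be casein, whey or both)", call. = FALSE)
    }
    ok <- is_canonical(df$sequence) & nchar(df$sequence) > 0
    if (!all(ok)) {
      if (noncanonical == "error") assert_canonical(df$sequence, "peptide")
      warning("skipping ", sum(!ok),
              " peptide row(s) with non-canonical residues", call. = FALSE)
      df <- df[ok, , drop = FALSE]
    }
  }
  for (opt in c("retention_time", "mass_observed")) {
    if (opt %in% names(df)) df[[opt]] <- as.numeric(df[[opt]])
  }
  rownames(df) <- NULL
  df
}

#' Read an external-predictor score table
#'
#' Reads the plug-in table through which external predictor outputs
#' (bioactivity ranker, toxicity classifier, dipeptide scorecard, docking,
#' ADME panels) enter the screening funnel. Only `sequence` is required;
#' every predictor column is optional and stays explicitly `NA` when absent.
#' Recognised columns: `bioactivity_score` (in \[0,1\]), `toxic` (logical),
#' `scm_score`, `dock_success` (logical), three solubility classes
#' (`solubility_esol`, `solubility_ali`, `solubility_silicos_it`; vocabulary
#' VS/S/MS/PS), `gi_absorption` (High/Low), and logical `bbb_permeant`,
#' `pgp_substrate`, `cyp1a2`, `cyp2c19`, `cyp2c9`, `cyp2d6`, `cyp3a4`.
#'
#' @inheritParams read_peptide_table
#' @return A typed `data.frame`, row order preserved.
#' @export
read_predictor_table <- function(path, sep = NULL) {
  df <- .read_delim_auto(path, sep)
  .require_columns(df, "sequence", path)
  df$sequence <- toupper(as.character(df$sequence))
  num_cols <- c("bioactivity_score", "scm_score")
  bool_cols <- c("toxic", "dock_success", "bbb_permeant", "pgp_substrate",
                 "cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4")
  sol_cols <- c("solubility_esol", "solubility_ali", "solubility_silicos_it")
  for (col in intersect(num_cols, names(df))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- is.na(v) & !is.na(df[[col]])
    if (any(bad)) stop("unparseable ", col, " at row ", which(bad)[1],
                       call. = FALSE)
    df[[col]] <- v
  }
  for (col in intersect(bool_cols, names(df))) {
    df[[col]] <- .parse_bool(df[[col]], col)
  }
  for (col in intersect(sol_cols, names(df))) {
    bad <- !df[[col]] %in% SOLUBILITY_CLASSES & !is.na(df[[col]])
    if (any(bad)) {
      stop("invalid solubility class '", df[[col]][bad][1], "' in ", col,
           " at row ", which(bad)[1], " (allowed: ",
           paste(SOLUBILITY_CLASSES, collapse = ", "), ")", call. = FALSE)
    }
  }
  if ("gi_absorption" %in% names(df)) {
    bad <- !df$gi_absorption %in% c("High", "Low") & !is.na(df$gi_absorption)
    if (any(bad)) stop("invalid gi_absorption at row ", which(bad)[1],
                       " (allowed: High, Low)", call. = FALSE)
  }
  if ("bioactivity_score" %in% names(df)) {
    v <- df$bioactivity_score
    if (any(v < 0 | v > 1, na.rm = TRUE)) {
      stop("bioactivity_score outside [0, 1] at row ",
           which(v < 0 | v > 1)[1], call. = FALSE)
    }
  }
  rownames(df) <- NULL
  df
}

.parse_bool <- function(x, col) {
  if (is.logical(x)) return(x)
  up <- toupper(as.character(x))
  out <- rep(NA, length(x))
  out[up %in% c("TRUE", "YES", "1", "T")] <- TRUE
  out[up %in% c("FALSE", "NO", "0", "F")] <- FALSE
  bad <- is.na(out) & !is.na(x)
  if (any(bad)) stop("unparseable boolean in ", col, " at row ",
                     which(bad)[1], call. = FALSE)
  out
}

#' Write a delimited table deterministically
#'
#' Tab-separated, no quoting, no row names; the round-trip partner of the
#' table readers.
#'
#' @param df A data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_delim_table <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  invisible(path)
}

#' Write funnel run reports
#'
#' Writes the machine-readable per-peptide stage ledger
#' (`<prefix>_ledger.tsv`, rows ordered lexicographically by sequence so
#' repeated runs are byte-identical) and a human-readable stage summary
#' (`<prefix>_summary.txt`).
#'
#' @param funnel A `funnel_result` object from [run_funnel()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix, default `"funnel"`.
#' @return Named character vector of the two paths written, invisibly.
#' @export
write_report <- function(funnel, dir, prefix = "funnel") {
  if (!inherits(funnel, "funnel_result")) {
    stop("write_report() expects a funnel_result object", call. = FALSE)
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  ledger <- funnel$ledger[order(funnel$ledger$sequence), , drop = FALSE]
  ledger_path <- file.path(dir, paste0(prefix, "_ledger.tsv"))
  write_delim_table(ledger, ledger_path)
  summary_path <- file.path(dir, paste0(prefix, "_summary.txt"))
  con <- file(summary_path, "w")
  on.exit(close(con))
  writeLines(format_funnel_summary(funnel), con)
  invisible(c(ledger = ledger_path, summary = summary_path))
}

#' Build a pipeline run configuration
#'
#' Collects every tunable the end-to-end run uses. Thresholds default to the
#' published screen settings: bioactivity ranker score > 0.5, scorecard
#' score > 294; in silico digestion for release-frequency ranking assumes a
#' complete digest (0 missed cleavages) while the MS emulation allows 2.
#'
#' @param fasta Path to the protein FASTA input.
#' @param peptide_table Path to the peptide identification table (optional;
#'   when `NULL` peptides come from the digest).
#' @param predictor_table Path to the external-predictor score table.
#' @param enzymes Character vector of enzyme names from the catalogue, or
#'   `"rank"` to pick the top-ranked combination automatically.
#' @param enzyme_catalogue Path to an enzyme rule file; `NULL` uses the
#'   shipped catalogue.
#' @param bioactivity_threshold,scm_threshold Funnel stage thresholds.
#' @param max_missed Missed cleavages for the digestion step.
#' @param max_combo_size Largest enzyme combination evaluated when ranking.
#' @param seed Integer seed controlling any randomised step.
#' @param out_dir Output directory for reports.
#' @return A named list with class `run_config`.
#' @export
run_config <- function(fasta, peptide_table = NULL, predictor_table = NULL,
                       enzymes = "rank", enzyme_catalogue = NULL,
                       bioactivity_threshold = 0.5, scm_threshold = 294,
                       max_missed = 0, max_combo_size = 2, seed = 1L,
                       out_dir = "dppscreen_run") {
  stopifnot(is.finite(bioactivity_threshold), is.finite(scm_threshold),
            max_missed >= 0, max_combo_size %in% 1:3)
  structure(list(fasta = fasta, peptide_table = peptide_table,
                 predictor_table = predictor_table, enzymes = enzymes,
                 enzyme_catalogue = enzyme_catalogue,
                 bioactivity_threshold = bioactivity_threshold,
                 scm_threshold = scm_threshold, max_missed = max_missed,
                 max_combo_size = max_combo_size, seed = as.integer(seed),
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from a JSON file
#'
#' @param path Path to a JSON file whose keys match the [run_config()]
#'   arguments.
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  vals <- jsonlite::read_json(path, simplifyVector = TRUE)
  unknown <- setdiff(names(vals), names(formals(run_config)))
  if (length(unknown) > 0) {
    stop("unknown config key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(run_config, vals)
}
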