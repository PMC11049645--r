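#' Sequence-characteristic rule for DPP-IV inhibitory peptides
#'
#' The motif rule used in the screen: a peptide is flagged when its
#' N-terminal residue is Trp/Leu/Ile/Phe, and/or its second N-terminal
#' residue is Pro/Ala, and/or its C-terminal residue is Pro (inclusive OR).
#'
#' @param sequence Character vector of canonical peptides (length >= 1 each).
#' @return A `data.frame` with one row per peptide: `sequence`, logical
#'   columns `rule_n_terminal`, `rule_second_position`, `rule_c_terminal`,
#'   the overall `pass`, and `matched_rules` (comma-joined clause names,
#'   empty when none match).
#' @examples
#' sequence_rule_filter(c("YPF", "LLLP", "GGG"))
#' @export
sequence_rule_filter <- function(sequence) {
  assert_canonical(sequence, "peptide")
  if (any(nchar(sequence) < 1)) stop("empty peptide", call. = FALSE)
  lens <- nchar(sequence)
  r1 <- substr(sequence, 1, 1) %in% c("W", "L", "I", "F")
  r2 <- lens >= 2 & substr(sequence, 2, 2) %in% c("P", "A")
  r3 <- substr(sequence, lens, lens) == "P"
  matched <- mapply(function(a, b, c) {
    paste(c("n_terminal", "second_position", "c_terminal")[c(a, b, c)],
          collapse = ",")
  }, r1, r2, r3)
  data.frame(sequence = sequence, rule_n_terminal = r1,
             rule_second_position = r2, rule_c_terminal = r3,
             pass = r1 | r2 | r3, matched_rules = unname(matched),
             stringsAsFactors = FALSE)
}

.all_dipeptides <- function() {
  as.vector(outer(AA20, AA20, paste0))
}

#' Score a peptide against a dipeptide scorecard matrix
#'
#' Scorecard-method (SCM) scoring: the peptide's L - 1 overlapping
#' dipeptides are looked up in a 400-entry propensity matrix and combined.
#' The default combination is the mean weight, so the published pass
#' threshold applies uniformly across peptide lengths; `mode = "sum"` gives
#' the plain dipeptide-composition sum.
#'
#' @param sequence Character vector of peptides (each length >= 2).
#' @param matrix Named numeric vector keyed by all 400 canonical dipeptides
#'   (see [synthetic_scm_matrix()], [read_scm_matrix()]).
#' @param mode `"mean"` (default) or `"sum"`.
#' @return Numeric vector of scores.
#' @export
scm_score <- function(sequence, matrix, mode = c("mean", "sum")) {
  mode <- match.arg(mode)
  dips <- .all_dipeptides()
  if (!all(dips %in% names(matrix)) || any(!is.finite(matrix[dips]))) {
    stop("scorecard matrix must supply a finite weight for all 400 dipeptides",
         call. = FALSE)
  }
  assert_canonical(sequence, "peptide")
  if (any(nchar(sequence) < 2)) {
    stop("scorecard score undefined for length-1 peptide", call. = FALSE)
  }
  vapply(sequence, function(s) {
    n <- nchar(s)
    w <- matrix[substring(s, 1:(n - 1), 2:n)]
    if (mode == "mean") mean(w) else sum(w)
  }, numeric(1), USE.NAMES = FALSE)
}

#' Generate a synthetic scorecard matrix
#'
#' The published scorecard matrix for DPP-IV inhibition is not redistributed
#' here; this SYNTHETIC stand-in exists so the scoring and funnel machinery
#' is fully testable offline. Weights are drawn around the configured centre,
#' with a bonus for dipeptides carrying the motif residues (Pro anywhere,
#' W/L/I/F first) so that motif-rich peptides tend to score high, loosely
#' mimicking the real matrix's structure. Drop in the genuine matrix with
#' [read_scm_matrix()] for real analyses.
#'
#' @param seed Integer seed.
#' @param centre,spread Normal location/scale for the base weights.
#' @param motif_bonus Added to dipeptides with motif residues.
#' @return Named numeric vector over the 400 canonical dipeptides.
#' @export
synthetic_scm_matrix <- function(seed = 42L, centre = 250, spread = 60,
                                 motif_bonus = 80) {
  dips <- .all_dipeptides()
  set.seed(as.integer(seed))
  w <- rnorm(length(dips), centre, spread)
  motif <- grepl("P", dips) | substr(dips, 1, 1) %in% c("W", "L", "I", "F")
  w[motif] <- w[motif] + motif_bonus
  setNames(w, dips)
}

#' Read a scorecard matrix from a file
#'
#' @param path Tab- or comma-delimited file with columns `dipeptide` and
#'   `weight`, one row per canonical dipeptide (all 400 required).
#' @return Named numeric vector over the 400 dipeptides.
#' @export
read_scm_matrix <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  # na.strings must stay empty: "NA" is the Asn-Ala dipeptide
  df <- read.delim(path, sep = .detect_sep(path), stringsAsFactors = FALSE,
                   na.strings = character())
  .require_columns(df, c("dipeptide", "weight"), path)
  m <- setNames(as.numeric(df$weight), toupper(df$dipeptide))
  missing <- setdiff(.all_dipeptides(), names(m))
  if (length(missing) > 0) {
    stop("scorecard matrix incomplete; first missing dipeptide: ",
         missing[1], call. = FALSE)
  }
  m[.all_dipeptides()]
}

#' ADME filter over predicted absorption/solubility/metabolism classes
#'
#' Table-driven drug-likeness filtering of peptide candidates. The default
#' predicate chain mirrors the published screen: require high predicted
#' gastrointestinal absorption, then exclude peptides whose Silicos-IT
#' solubility class is "PS" (poorly soluble), then exclude predicted
#' inhibitors of any of the five cytochrome P450 isoforms. Predicates are
#' re-orderable and individually removable via `chain`, because published
#' candidate tables are sometimes composed before the CYP exclusion is
#' applied.
#'
#' @param table A predictor table ([read_predictor_table()]) containing the
#'   ADME columns each enabled predicate needs.
#' @param chain Character vector of predicate names, in order, from
#'   `"gi_absorption"`, `"solubility"`, `"cyp"`.
#' @return A `data.frame`: `sequence`, logical `pass`, and `reasons`
#'   (semicolon-joined names of failing predicates, empty when passing).
#' @export
adme_filter <- function(table,
                        chain = c("gi_absorption", "solubility", "cyp")) {
  chain <- match.arg(chain, several.ok = TRUE)
  needed <- list(
    gi_absorption = "gi_absorption",
    solubility = "solubility_silicos_it",
    cyp = c("cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6", "cyp3a4"))
  cols <- unlist(needed[chain])
  miss <- setdiff(cols, names(table))
  if (length(miss) > 0) {
    stop("ADME filter needs missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  for (col in cols) {
    if (any(is.na(table[[col]]))) {
      stop("missing ", col, " value for peptide ",
           table$sequence[is.na(table[[col]])][1], call. = FALSE)
    }
  }
  fails <- lapply(chain, function(p) {
    switch(p,
      gi_absorption = table$gi_absorption != "High",
      solubility = table$solubility_silicos_it == "PS",
      cyp = Reduce(`|`, table[needed$cyp]))
  })
  names(fails) <- chain
  reasons <- vapply(seq_len(nrow(table)), function(i) {
    paste(chain[vapply(fails, `[`, logical(1), i)], collapse = ";")
  }, character(1))
  data.frame(sequence = table$sequence,
             pass = !Reduce(`|`, fails),
             reasons = reasons, stringsAsFactors = FALSE)
}

#' Configure the screening funnel
#'
#' @param stages Ordered character vector of stages to run, from
#'   `"bioactivity"` (ranker score and toxicity), `"dppiv"` (scorecard
#'   threshold AND docking success AND sequence-characteristic rule),
#'   `"adme"`, `"novelty"` (external annotation column `novel`).
#' @param bioactivity_threshold Pass requires score strictly above this
#'   (default 0.5).
#' @param scm_threshold Pass requires scorecard score strictly above this
#'   (default 294, the published cut-off).
#' @param adme_chain Passed to [adme_filter()].
#' @return A list of class `funnel_config`.
#' @export
funnel_config <- function(stages = c("bioactivity", "dppiv", "adme"),
                          bioactivity_threshold = 0.5, scm_threshold = 294,
                          adme_chain = c("gi_absorption", "solubility",
                                         "cyp")) {
  stages <- match.arg(stages, c("bioactivity", "dppiv", "adme", "novelty"),
                      several.ok = TRUE)
  stopifnot(is.finite(bioactivity_threshold), is.finite(scm_threshold))
  structure(list(stages = stages,
                 bioactivity_threshold = bioactivity_threshold,
                 scm_threshold = scm_threshold, adme_chain = adme_chain),
            class = "funnel_config")
}

.funnel_required_fields <- function(stage, config) {
  switch(stage,
    bioactivity = c("bioactivity_score", "toxic"),
    dppiv = c("scm_score", "dock_success"),
    adme = unlist(list(gi_absorption = "gi_absorption",
                       solubility = "solubility_silicos_it",
                       cyp = c("cyp1a2", "cyp2c19", "cyp2c9", "cyp2d6",
                               "cyp3a4"))[config$adme_chain],
                  use.names = FALSE),
    novelty = "novel")
}

#' Run the multi-stage virtual screening funnel
#'
#' Pushes each peptide through the configured stages in order, recording a
#' verdict per stage (`pass` / `fail` / `not_evaluated`) in a provenance
#' ledger; a peptide failing stage k is never evaluated at later stages and
#' verdicts are never overwritten. Stage semantics:
#' \describe{
#'   \item{bioactivity}{ranker score strictly above the threshold AND not
#'     toxic.}
#'   \item{dppiv}{three-way consensus: scorecard score strictly above the
#'     threshold AND docking success AND the sequence-characteristic rule.
#'     Single-method and intersection counts among the peptides entering
#'     this stage are reported in the summary (Venn-style accounting).}
#'   \item{adme}{the [adme_filter()] chain.}
#'   \item{novelty}{the external `novel` annotation is `TRUE`.}
#' }
#'
#' @param peptides Character vector of peptide sequences to screen.
#' @param predictor_table Predictor table supplying every field the enabled
#'   stages need for each evaluated peptide; a missing field for an
#'   evaluated peptide is an error naming peptide and field.
#' @param config A [funnel_config()].
#' @return An object of class `funnel_result`: list with `ledger`
#'   (per-peptide stage verdicts, inputs and final status), `summary`
#'   (per-stage counts), `venn` (single/pairwise/triple counts for the
#'   dppiv stage methods, when run) and `config`.
#' @export
run_funnel <- function(peptides, predictor_table, config = funnel_config()) {
  stopifnot(inherits(config, "funnel_config"))
  peptides <- as.character(peptides)
  idx <- match(peptides, predictor_table$sequence)
  if (any(is.na(idx))) {
    stop("peptide ", peptides[is.na(idx)][1], " absent from predictor table",
         call. = FALSE)
  }
  tab <- predictor_table[idx, , drop = FALSE]
  n <- length(peptides)
  ledger <- data.frame(sequence = peptides, stringsAsFactors = FALSE)
  alive <- rep(TRUE, n)
  reason <- rep("", n)
  venn <- NULL
  for (stage in config$stages) {
    fields <- .funnel_required_fields(stage, config)
    miss <- setdiff(fields, names(tab))
    verdict <- rep("not_evaluated", n)
    if (any(alive)) {
      if (length(miss) > 0) {
        stop("stage '", stage, "' needs field '", miss[1],
             "' for peptide ", peptides[alive][1], call. = FALSE)
      }
      for (f in fields) {
        bad <- alive & is.na(tab[[f]])
        if (any(bad)) {
          stop("missing ", f, " for evaluated peptide ",
               peptides[bad][1], call. = FALSE)
        }
      }
      res <- switch(stage,
        bioactivity = {
          ok <- tab$bioactivity_score > config$bioactivity_threshold &
            !tab$toxic
          why <- ifelse(tab$bioactivity_score <= config$bioactivity_threshold,
                        "bioactivity_score<=threshold",
                        ifelse(tab$toxic, "toxic", ""))
          list(ok = ok, why = why)
        },
        dppiv = {
          scm_ok <- tab$scm_score > config$scm_threshold
          dock_ok <- tab$dock_success
          seq_ok <- sequence_rule_filter(peptides)$pass
          venn <- list(
            n_entering = sum(alive),
            scm = sum(scm_ok & alive), dock = sum(dock_ok & alive),
            seq_rule = sum(seq_ok & alive),
            scm_dock = sum(scm_ok & dock_ok & alive),
            scm_seq = sum(scm_ok & seq_ok & alive),
            dock_seq = sum(dock_ok & seq_ok & alive),
            all_three = sum(scm_ok & dock_ok & seq_ok & alive))
          why <- vapply(seq_len(n), function(i) {
            paste(c(if (!scm_ok[i]) "scm_score<=threshold",
                    if (!dock_ok[i]) "dock_failure",
                    if (!seq_ok[i]) "sequence_rule"), collapse = ";")
          }, character(1))
          list(ok = scm_ok & dock_ok & seq_ok, why = why)
        },
        adme = {
          af <- adme_filter(tab, chain = config$adme_chain)
          list(ok = af$pass, why = af$reasons)
        },
        novelty = list(ok = tab$novel,
                       why = ifelse(tab$novel, "", "known_peptide")))
      verdict[alive & res$ok] <- "pass"
      verdict[alive & !res$ok] <- "fail"
      reason[alive & !res$ok] <- paste0(stage, ": ",
                                        res$why[alive & !res$ok])
      alive <- alive & res$ok
    }
    ledger[[paste0("stage_", stage)]] <- verdict
  }
  ledger$final_status <- ifelse(alive, "pass", "fail")
  ledger$fail_reason <- reason
  stage_cols <- paste0("stage_", config$stages)
  summary <- data.frame(
    stage = config$stages,
    evaluated = vapply(stage_cols, function(cc)
      sum(ledger[[cc]] != "not_evaluated"), integer(1)),
    pass = vapply(stage_cols, function(cc)
      sum(ledger[[cc]] == "pass"), integer(1)),
    fail = vapply(stage_cols, function(cc)
      sum(ledger[[cc]] == "fail"), integer(1)),
    not_evaluated = vapply(stage_cols, function(cc)
      sum(ledger[[cc]] == "not_evaluated"), integer(1)),
    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(ledger = ledger, summary = summary, venn = venn,
                 config = config, n_input = n,
                 n_survivors = sum(alive)),
            class = "funnel_result")
}

format_funnel_summary <- function(x) {
  out <- c(sprintf("screening funnel: %d peptides in, %d survivors",
                   x$n_input, x$n_survivors), "",
           utils::capture.output(print(x$summary, row.names = FALSE)))
  if (!is.null(x$venn)) {
    v <- x$venn
    out <- c(out, "",
      sprintf("dppiv stage methods (of %d entering): scorecard %d, docking %d, sequence rule %d",
              v$n_entering, v$scm, v$dock, v$seq_rule),
      sprintf("pairwise: scm&dock %d, scm&seq %d, dock&seq %d; all three %d",
              v$scm_dock, v$scm_seq, v$dock_seq, v$all_three))
  }
  out
}

#' @export
print.funnel_result <- function(x, ...) {
  writeLines(format_funnel_summary(x))
  invisible(x)
}
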