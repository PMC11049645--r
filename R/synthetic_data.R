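# Fixed per-stream offsets: one root seed expands to independent sub-seeds,
# so adding a generator never perturbs the streams of existing ones.
.STREAM_OFFSETS <- c(proteins = 101L, peptide_table = 211L,
                     predictor_table = 307L, dose_response = 401L)

sub_seed <- function(seed, stream) {
  offset <- .STREAM_OFFSETS[[stream]]
  as.integer((as.double(seed) * 1009 + offset) %% 2147483629)
}

#' Generate synthetic protein sequences
#'
#' Seeded generator standing in for downloaded milk-protein FASTA input.
#' Sequences are drawn residue-by-residue from `composition` (uniform over
#' the canonical 20 by default; see [milk_like_composition()] for a
#' casein-flavoured alternative). In planted mode, known reference peptides
#' are embedded at random positions flanked by a guaranteed cut residue for
#' a chosen enzyme, making the downstream release-frequency statistic
#' analytically known.
#'
#' @param n Number of proteins (>= 1).
#' @param length_range Integer length range, inclusive.
#' @param composition Named numeric vector of residue weights over (a subset
#'   of) the canonical alphabet; `NULL` = uniform.
#' @param seed Integer seed.
#' @param planted Optional list with elements `peptides` (character vector
#'   to embed), `k` (plants per protein) and `cut_residue` (single residue,
#'   e.g. `"K"`, providing the cut site N-terminal of each plant). Because a
#'   cut-after (P1) rule releases fragments that end with a cut residue, the
#'   implied cut set is `cut_residue` plus the final residue of every plant;
#'   each plant is inserted as `cut_residue + plant`, plants must not carry
#'   any cut-set residue at a non-final position, and the background
#'   composition is restricted to exclude the cut set. A complete digest
#'   with the rule returned in the `planted_rule` attribute then releases
#'   each plant exactly, making the release-frequency statistic k/N by
#'   construction.
#' @return A protein table (`id`, `description`, `sequence`), as
#'   [read_fasta()] returns.
#' @export
gen_proteins <- function(n, length_range = c(80L, 200L), composition = NULL,
                         seed = 1L, planted = NULL) {
  if (n < 1 || any(length_range < 1)) {
    stop("protein count and lengths must be positive", call. = FALSE)
  }
  if (is.null(composition)) {
    composition <- setNames(rep(1, 20), AA20)
  }
  if (!all(names(composition) %in% AA20) || any(composition < 0) ||
      sum(composition) <= 0) {
    stop("invalid residue composition", call. = FALSE)
  }
  set.seed(sub_seed(seed, "proteins"))
  lens <- sample(seq(length_range[1], length_range[2]), n, replace = TRUE)
  cutset <- NULL
  if (!is.null(planted)) {
    cut <- planted$cut_residue
    stopifnot(length(cut) == 1, cut %in% AA20)
    finals <- substr(planted$peptides, nchar(planted$peptides),
                     nchar(planted$peptides))
    cutset <- unique(c(cut, finals))
    interiors <- substr(planted$peptides, 1, nchar(planted$peptides) - 1)
    clash <- vapply(interiors, function(s)
      any(strsplit(s, "")[[1]] %in% cutset), logical(1))
    if (any(clash)) {
      stop("planted peptide(s) carry a cut-set residue internally: ",
           paste(planted$peptides[clash], collapse = ", "),
           " (cut set ", paste(cutset, collapse = ""), ")", call. = FALSE)
    }
    composition <- composition[setdiff(names(composition), cutset)]
    if (length(composition) == 0 || sum(composition) <= 0) {
      stop("background composition empty after excluding the cut set",
           call. = FALSE)
    }
  }
  draw <- function(len) {
    paste(sample(names(composition), len, replace = TRUE,
                 prob = composition / sum(composition)), collapse = "")
  }
  seqs <- vapply(lens, draw, character(1))
  if (!is.null(planted)) {
    # insert "K<pep>" at interior positions: the flanking K cuts before the
    # plant, the plant's own final residue (in the cut set) cuts after it,
    # and the cut-set-free background contributes no sites, so a complete
    # digest with the planted rule releases each plant exactly
    seqs <- vapply(seqs, function(s) {
      # k distinct original positions, inserted right-to-left so no plant
      # can land inside another
      pos <- sort(sample(seq(2, nchar(s) - 1), planted$k), decreasing = TRUE)
      peps <- sample(planted$peptides, planted$k, replace = TRUE)
      for (i in seq_len(planted$k)) {
        ins <- paste0(planted$cut_residue, peps[i])
        s <- paste0(substr(s, 1, pos[i] - 1), ins, substr(s, pos[i], nchar(s)))
      }
      s
    }, character(1), USE.NAMES = FALSE)
  }
  out <- data.frame(id = sprintf("synth_prot_%02d", seq_len(n)),
                    description = "synthetic protein",
                    sequence = seqs, stringsAsFactors = FALSE)
  if (!is.null(cutset)) {
    attr(out, "planted_rule") <- enzyme_rule("planted", cutset)
  }
  out
}

#' Casein-like residue composition
#'
#' A bundled alternative to the uniform background: elevated Pro/Gln/Leu
#' weight loosely mimicking casein composition. Documented for realism,
#' never asserted against any published frequency.
#'
#' @return Named numeric weight vector over the 20 canonical residues.
#' @export
milk_like_composition <- function() {
  w <- setNames(rep(1, 20), AA20)
  w[c("P", "Q", "L")] <- c(2.5, 2.0, 2.0)
  w[c("E", "K", "V", "S")] <- 1.5
  w[c("C", "W")] <- 0.3
  w
}

#' Generate a synthetic peptide identification table
#'
#' Emulates MS search-engine peptide output (sequence, identification
#' score, source label) by subsampling digest fragments, assigning strictly
#' positive identification scores and casein/whey/both source labels with
#' configured proportions.
#'
#' @param fragments A [digest()]/[digest_combo()] data frame or character
#'   vector of peptide sequences.
#' @param subsample Fraction of fragments retained (default 1).
#' @param source_props Named proportions over `casein`, `whey`, `both`.
#' @param score_range Identification scores drawn uniformly in this range.
#' @param seed Integer seed.
#' @return A peptide table (`sequence`, `identification_score`, `source`,
#'   `retention_time`, `mass_observed`).
#' @export
gen_peptide_table <- function(fragments, subsample = 1,
                              source_props = c(casein = 0.25, whey = 0.4,
                                               both = 0.35),
                              score_range = c(5, 60), seed = 1L) {
  seqs <- if (is.data.frame(fragments)) fragments$sequence else
    as.character(fragments)
  stopifnot(subsample > 0, subsample <= 1,
            all(names(source_props) %in% c("casein", "whey", "both")))
  set.seed(sub_seed(seed, "peptide_table"))
  keep <- sort(sample(seq_along(seqs), ceiling(subsample * length(seqs))))
  seqs <- seqs[keep]
  n <- length(seqs)
  data.frame(
    sequence = seqs,
    identification_score = runif(n, score_range[1], score_range[2]),
    source = sample(names(source_props), n, replace = TRUE,
                    prob = source_props / sum(source_props)),
    retention_time = round(runif(n, 5, 60), 3),
    mass_observed = round(monoisotopic_mass(seqs) +
                            rnorm(n, 0, 0.002), 4),
    stringsAsFactors = FALSE)
}

#' Generate a synthetic external-predictor score table
#'
#' Stands in for the web predictors the funnel consumes (bioactivity ranker,
#' toxicity classifier, scorecard, docking, ADME panel). In random mode each
#' field is drawn from its configured distribution; in designed mode an
#' explicit truth table (a data frame with a `sequence` column plus any
#' predictor columns to pin) overrides the draws, which is how funnel tests
#' construct exact expected outcomes.
#'
#' @param peptides Character vector of peptide sequences.
#' @param bioactivity_shape1,bioactivity_shape2 Beta parameters for the
#'   bioactivity score in \[0, 1\].
#' @param p_toxic,p_dock Bernoulli probabilities for toxicity and docking
#'   success.
#' @param scm_mean,scm_sd Normal parameters for the scorecard score.
#' @param p_gi_high Probability of High gastrointestinal absorption.
#' @param sol_props Proportions over the VS/S/MS/PS solubility classes.
#' @param p_cyp Probability each CYP isoform flag is TRUE.
#' @param designed Optional truth table; every peptide present in
#'   `peptides` must appear in it when given (error otherwise), and its
#'   non-`NA` cells replace the random draws.
#' @param seed Integer seed.
#' @return A predictor table with one row per peptide, in input order.
#' @export
gen_predictor_table <- function(peptides,
                                bioactivity_shape1 = 1.2,
                                bioactivity_shape2 = 1.8,
                                p_toxic = 0.02, p_dock = 0.9,
                                scm_mean = 310, scm_sd = 40,
                                p_gi_high = 0.9,
                                sol_props = c(VS = 0.5, S = 0.2, MS = 0.2,
                                              PS = 0.1),
                                p_cyp = 0.05,
                                designed = NULL, seed = 1L) {
  peptides <- as.character(peptides)
  n <- length(peptides)
  set.seed(sub_seed(seed, "predictor_table"))
  tab <- data.frame(
    sequence = peptides,
    bioactivity_score = stats::rbeta(n, bioactivity_shape1,
                                     bioactivity_shape2),
    toxic = runif(n) < p_toxic,
    scm_score = rnorm(n, scm_mean, scm_sd),
    dock_success = runif(n) < p_dock,
    solubility_esol = sample(names(sol_props), n, TRUE,
                             sol_props / sum(sol_props)),
    solubility_ali = sample(names(sol_props), n, TRUE,
                            sol_props / sum(sol_props)),
    solubility_silicos_it = sample(names(sol_props), n, TRUE,
                                   sol_props / sum(sol_props)),
    gi_absorption = ifelse(runif(n) < p_gi_high, "High", "Low"),
    bbb_permeant = FALSE, pgp_substrate = TRUE,
    cyp1a2 = runif(n) < p_cyp, cyp2c19 = runif(n) < p_cyp,
    cyp2c9 = runif(n) < p_cyp, cyp2d6 = runif(n) < p_cyp,
    cyp3a4 = runif(n) < p_cyp,
    stringsAsFactors = FALSE)
  if (!is.null(designed)) {
    idx <- match(peptides, designed$sequence)
    if (any(is.na(idx))) {
      stop("designed truth table is missing peptide ",
           peptides[is.na(idx)][1], call. = FALSE)
    }
    for (col in setdiff(names(designed), "sequence")) {
      v <- designed[[col]][idx]
      if (col %in% names(tab)) {
        tab[[col]][!is.na(v)] <- v[!is.na(v)]
      } else {
        tab[[col]] <- v
      }
    }
  }
  tab
}

#' Generate a synthetic dose-response table
#'
#' Responses follow a 4PL truth curve with additive Gaussian noise, the
#' stated world of the IC50-recovery tests: inhibition plates read at 7
#' doses in triplicate with a few percent measurement noise.
#'
#' @param ic50 True inflection concentration (> 0).
#' @param hill,bottom,top Remaining truth-curve parameters.
#' @param doses Strictly positive dose vector.
#' @param reps Replicates per dose.
#' @param noise_sd Gaussian noise SD in response units (percent points).
#' @param seed Integer seed.
#' @return A `data.frame` with `concentration`, `replicate`, `response`.
#' @export
gen_dose_response <- function(ic50, hill = 1, bottom = 0, top = 100,
                              doses = 10^seq(0.5, 3.5, length.out = 7),
                              reps = 3, noise_sd = 3, seed = 1L) {
  stopifnot(ic50 > 0, all(doses > 0), reps >= 1, noise_sd >= 0)
  set.seed(sub_seed(seed, "dose_response"))
  grid <- expand.grid(replicate = seq_len(reps), concentration = doses)
  truth <- .fourpl(grid$concentration, bottom, top, log10(ic50), hill)
  data.frame(concentration = grid$concentration,
             replicate = grid$replicate,
             response = truth + rnorm(nrow(grid), 0, noise_sd))
}
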