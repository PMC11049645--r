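# standard IUPAC monoisotopic residue masses (Da); peptide mass adds one water
RESIDUE_MASS <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406, N = 114.04293,
  D = 115.02694, Q = 128.05858, K = 128.09496, E = 129.04259, M = 131.04049,
  H = 137.05891, F = 147.06841, R = 156.10111, Y = 163.06333, W = 186.07931)
WATER_MASS <- 18.010565

#' Monoisotopic mass tables used for peptide masses
#'
#' @return A list with the 20 residue masses (`residues`, Da) and the water
#'   mass added once per peptide (`water`, Da).
#' @export
residue_mass_table <- function() {
  list(residues = RESIDUE_MASS, water = WATER_MASS)
}

#' Monoisotopic peptide mass
#'
#' Sum of standard IUPAC monoisotopic residue masses plus one water.
#' Matches LC-MS peptide tables to within their printed rounding
#' (about 0.01 Da).
#'
#' @param sequence Character vector of canonical peptide sequences.
#' @return Numeric vector of masses in Da.
#' @examples
#' monoisotopic_mass(c("IPI", "YPF"))  # 341.23, 425.20
#' @export
monoisotopic_mass <- function(sequence) {
  assert_canonical(sequence, "peptide")
  vapply(strsplit(sequence, ""), function(ch) {
    sum(RESIDUE_MASS[ch]) + WATER_MASS
  }, numeric(1))
}

#' Length and molecular-weight class counts for a peptide set
#'
#' Bins peptides by residue count (3, 4, 5, other) and by monoisotopic mass
#' (< 500, 500–1000, > 1000 Da); each classification partitions the input.
#' Short low-mass peptides are the hallmark of competitive DPP-IV inhibitors,
#' which is why these particular bins matter for the screen.
#'
#' @param peptides Character vector of peptide sequences.
#' @return A list with named integer vectors `length_counts`
#'   (`"3"`, `"4"`, `"5"`, `"other"`) and `mw_counts`
#'   (`"<500"`, `"500-1000"`, `">1000"`).
#' @export
length_mw_bins <- function(peptides) {
  lens <- nchar(peptides)
  length_counts <- c(
    "3" = sum(lens == 3), "4" = sum(lens == 4), "5" = sum(lens == 5),
    "other" = sum(!lens %in% 3:5))
  if (length(peptides) == 0) {
    mw_counts <- c("<500" = 0L, "500-1000" = 0L, ">1000" = 0L)
  } else {
    mw <- monoisotopic_mass(peptides)
    mw_counts <- c("<500" = sum(mw < 500),
                   "500-1000" = sum(mw >= 500 & mw <= 1000),
                   ">1000" = sum(mw > 1000))
  }
  list(length_counts = length_counts, mw_counts = mw_counts)
}

#' Positional amino-acid frequency profile
#'
#' Tallies residue frequencies at the three positions that drive DPP-IV
#' inhibitory activity: the N-terminal residue, the second N-terminal
#' residue, and the C-terminal residue. Each position's frequencies are
#' computed over the peptides long enough to define it and sum to 1.
#' For length-1 peptides the N- and C-terminal positions coincide and both
#' are tallied; the second position is undefined for them. For length-2
#' peptides residue 2 is both the second and the C-terminal residue and
#' counts in both tallies.
#'
#' @param peptides Non-empty character vector of peptide sequences.
#' @param min_length_for_position Minimum peptide length required to tally a
#'   peptide at all (default 1).
#' @return A list of class `positional_profile` with, per position
#'   (`n_terminal`, `second_position`, `c_terminal`), a 20-entry frequency
#'   vector over the canonical alphabet and the denominator used.
#' @export
positional_profile <- function(peptides, min_length_for_position = 1) {
  peptides <- peptides[nchar(peptides) >= min_length_for_position]
  if (length(peptides) == 0) stop("peptide set is empty", call. = FALSE)
  assert_canonical(peptides, "peptide")
  tally <- function(residues) {
    counts <- table(factor(residues, levels = AA20))
    n <- length(residues)
    list(frequency = as.numeric(counts) / max(n, 1), denominator = n)
  }
  lens <- nchar(peptides)
  nterm <- tally(substr(peptides, 1, 1))
  second <- tally(substr(peptides[lens >= 2], 2, 2))
  cterm <- tally(substr(peptides, lens, lens))
  out <- list(n_terminal = nterm, second_position = second, c_terminal = cterm)
  for (pos in names(out)) names(out[[pos]]$frequency) <- AA20
  structure(out, class = "positional_profile")
}

#' @export
print.positional_profile <- function(x, digits = 3, ...) {
  cat("<positional_profile>\n")
  for (pos in names(x)) {
    f <- x[[pos]]$frequency
    top <- sort(f[f > 0], decreasing = TRUE)
    cat(sprintf("  %-16s (n = %d): %s\n", pos, x[[pos]]$denominator,
                paste(sprintf("%s %.1f%%", names(head(top, 5)),
                              100 * head(top, 5)), collapse = ", ")))
  }
  invisible(x)
}

#' Fraction of peptides matching the DPP-IV sequence characteristics
#'
#' Two readings of the aggregate positional statistic are returned, since
#' the denominator convention differs between reports: `peptide_fraction`
#' is the fraction of peptides matching at least one characteristic rule,
#' and `position_frequency_sum` is the sum over the three positions of the
#' frequency mass carried by the rule residues at that position.
#'
#' @param peptides Character vector of peptide sequences.
#' @return A list with `peptide_fraction` and `position_frequency_sum`.
#' @export
characteristic_fraction <- function(peptides) {
  flt <- sequence_rule_filter(peptides)
  prof <- positional_profile(peptides)
  psum <- sum(prof$n_terminal$frequency[c("W", "L", "I", "F")]) +
    sum(prof$second_position$frequency[c("P", "A")]) +
    prof$c_terminal$frequency[["P"]]
  list(peptide_fraction = mean(flt$pass), position_frequency_sum = psum)
}
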