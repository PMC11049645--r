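# Independent brute-force oracles and small fixture builders. These stay
# deliberately naive so they never share code paths with the implementation.

AA <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
        "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

# test every position against every rule, one at a time
brute_cut_sites <- function(sequence, rules) {
  if (inherits(rules, "enzyme_rule")) rules <- list(rules)
  ch <- strsplit(sequence, "")[[1]]
  sites <- integer(0)
  for (i in seq_len(max(0, length(ch) - 1))) {
    for (r in rules) {
      if (ch[i] %in% r$cut_after && !(ch[i + 1] %in% r$blocked_p1prime)) {
        sites <- c(sites, i)
        break
      }
    }
  }
  sites
}

# split at brute-force sites, then enumerate adjacent concatenations
brute_digest <- function(sequence, rules, max_missed = 0) {
  sites <- brute_cut_sites(sequence, rules)
  bounds <- c(0, sites, nchar(sequence))
  pieces <- character(0)
  starts <- integer(0); ends <- integer(0); missed <- integer(0)
  k <- length(bounds) - 1
  for (i in seq_len(k)) {
    for (j in i:min(k, i + max_missed)) {
      pieces <- c(pieces, substr(sequence, bounds[i] + 1, bounds[j + 1]))
      starts <- c(starts, bounds[i] + 1)
      ends <- c(ends, bounds[j + 1])
      missed <- c(missed, j - i)
    }
  }
  df <- data.frame(sequence = pieces, start = starts, end = ends,
                   n_missed = missed, stringsAsFactors = FALSE)
  df[order(df$start, df$end), ]
}

random_protein <- function(len) paste(sample(AA, len, TRUE), collapse = "")

random_rule <- function(name = "r") {
  enzyme_rule(name, sample(AA, sample(1:6, 1)),
              if (runif(1) < 0.5) sample(AA, sample(0:2, 1)) else character())
}

# naive dipeptide tally scorer
brute_scm <- function(sequence, matrix, mode = "mean") {
  n <- nchar(sequence)
  w <- numeric(0)
  for (i in 1:(n - 1)) w <- c(w, matrix[[substr(sequence, i, i + 1)]])
  if (mode == "mean") mean(w) else sum(w)
}

write_tmp <- function(lines, ext = ".txt") {
  path <- tempfile(fileext = ext)
  writeLines(lines, path)
  path
}

# designed 10-peptide truth table spanning the funnel stages, with the
# expected verdicts enumerated by hand (see test-screening.R)
designed_funnel_fixture <- function() {
  peptides <- c("LPAA", "YPFF", "GGGG", "LLKP", "APAP",
                "WVSP", "FFPA", "PGGG", "LAPL", "IGGP")
  truth <- data.frame(
    sequence = peptides,
    bioactivity_score = c(0.9, 0.8, 0.4, 0.7, 0.6,
                          0.9, 0.55, 0.51, 0.52, 0.95),
    toxic = c(FALSE, FALSE, FALSE, TRUE, FALSE,
              FALSE, FALSE, FALSE, FALSE, FALSE),
    scm_score = c(300, 300, 300, 300, 290,
                  300, 300, 300, 300, 300),
    dock_success = c(TRUE, TRUE, TRUE, TRUE, TRUE,
                     FALSE, TRUE, TRUE, TRUE, TRUE),
    solubility_silicos_it = c("VS", "S", "VS", "VS", "VS",
                              "VS", "PS", "VS", "VS", "MS"),
    gi_absorption = c("High", "High", "High", "High", "High",
                      "High", "High", "High", "Low", "High"),
    cyp1a2 = FALSE, cyp2c19 = FALSE, cyp2c9 = FALSE,
    cyp2d6 = c(FALSE, FALSE, FALSE, FALSE, FALSE,
               FALSE, FALSE, FALSE, FALSE, TRUE),
    cyp3a4 = FALSE,
    stringsAsFactors = FALSE)
  # hand enumeration:
  #  LPAA: bio .9 pass; scm 300 & dock & seq(L at N) pass; adme pass  -> pass
  #  YPFF: bio pass; seq rule P at pos2 pass; adme pass               -> pass
  #  GGGG: bio 0.4 fails stage 1
  #  LLKP: toxic fails stage 1
  #  APAP: scm 290 <= 294 fails dppiv
  #  WVSP: dock failure fails dppiv
  #  FFPA: PS solubility fails adme
  #  PGGG: seq rule: P at N-term only matches pos2/C-term? P first, G second,
  #        G last => no clause matches -> fails dppiv (sequence rule)
  #  LAPL: Low GI fails adme
  #  IGGP: CYP2D6 inhibitor fails adme
  expected <- data.frame(
    sequence = peptides,
    stage_bioactivity = c("pass", "pass", "fail", "fail", "pass",
                          "pass", "pass", "pass", "pass", "pass"),
    stage_dppiv = c("pass", "pass", "not_evaluated", "not_evaluated",
                    "fail", "fail", "pass", "fail", "pass", "pass"),
    stage_adme = c("pass", "pass", "not_evaluated", "not_evaluated",
                   "not_evaluated", "not_evaluated", "fail",
                   "not_evaluated", "fail", "fail"),
    final_status = c("pass", "pass", "fail", "fail", "fail",
                     "fail", "fail", "fail", "fail", "fail"),
    stringsAsFactors = FALSE)
  list(truth = truth, expected = expected)
}
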