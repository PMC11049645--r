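test_that("sequence-characteristic rule matches the DPP-IV motif clauses", {
  out <- sequence_rule_filter(c("YPF", "LLLP", "GGG"))
  expect_equal(out$pass, c(TRUE, TRUE, FALSE))
  expect_equal(out$matched_rules[1], "second_position")  # P at position 2
  expect_equal(out$matched_rules[2], "n_terminal,c_terminal")  # L..P
  expect_equal(out$matched_rules[3], "")
  # single residue: position 1 is also the C-terminal
  expect_true(sequence_rule_filter("W")$pass)
  expect_true(sequence_rule_filter("P")$pass)  # C-terminal P clause
  expect_false(sequence_rule_filter("G")$pass)
  expect_error(sequence_rule_filter("A1C"), "non-canonical")
})

test_that("scorecard scoring combines overlapping dipeptide weights", {
  zero <- setNames(rep(0, 400), as.vector(outer(AA, AA, paste0)))
  expect_equal(scm_score("YPFL", zero), 0)
  m <- zero; m[["AA"]] <- 294
  expect_equal(scm_score("AAA", m), 294)  # mean of identical weights
  m2 <- zero; m2[["AC"]] <- 100; m2[["CA"]] <- 300
  expect_equal(scm_score("ACA", m2), 200)
  expect_equal(scm_score("ACA", m2, mode = "sum"), 400)
  expect_error(scm_score("A", m2), "length-1")
  expect_error(scm_score("AC", m2[-1]), "400")
})

test_that("scorecard scores equal a brute-force tally on short peptides", {
  mat <- synthetic_scm_matrix(seed = 9)
  set.seed(407)
  for (i in 1:60) {
    pep <- random_protein(sample(2:6, 1))
    expect_equal(scm_score(pep, mat), brute_scm(pep, mat))
    expect_equal(scm_score(pep, mat, "sum"), brute_scm(pep, mat, "sum"))
  }
  # synthetic matrix is deterministic under its seed
  expect_identical(mat, synthetic_scm_matrix(seed = 9))
})

test_that("scorecard matrices round-trip through files", {
  mat <- synthetic_scm_matrix(seed = 3)
  path <- tempfile(fileext = ".tsv")
  write_delim_table(data.frame(dipeptide = names(mat), weight = mat), path)
  expect_equal(read_scm_matrix(path), mat)
})

test_that("ADME filter applies the published predicate chain", {
  tab <- read_predictor_table(
    system.file("extdata", "candidate_adme.tsv", package = "dppscreen"))
  out <- adme_filter(tab)
  # LFF row: poorly soluble and CYP inhibitor, both reasons named
  lff <- out[out$sequence == "LFF", ]
  expect_false(lff$pass)
  expect_match(lff$reasons, "solubility")
  expect_match(lff$reasons, "cyp")
  expect_true(out$pass[out$sequence == "YPF"])

  low <- data.frame(sequence = "YPF", gi_absorption = "Low",
                    solubility_silicos_it = "VS", cyp1a2 = FALSE,
                    cyp2c19 = FALSE, cyp2c9 = FALSE, cyp2d6 = FALSE,
                    cyp3a4 = FALSE, stringsAsFactors = FALSE)
  expect_false(adme_filter(low)$pass)  # Low GI fails regardless

  # re-orderable / reducible chain
  no_cyp <- adme_filter(tab, chain = c("gi_absorption", "solubility"))
  expect_equal(sum(!no_cyp$pass), 5)  # only the PS rows fail
  expect_error(adme_filter(tab[, c("sequence", "gi_absorption")]),
               "solubility_silicos_it")
  tab_na <- tab; tab_na$gi_absorption[3] <- NA
  expect_error(adme_filter(tab_na), tab$sequence[3])
})

test_that("funnel reproduces a hand-enumerated designed truth table", {
  fx <- designed_funnel_fixture()
  fun <- run_funnel(fx$truth$sequence, fx$truth)
  led <- fun$ledger
  for (col in names(fx$expected)) {
    expect_equal(led[[col]], fx$expected[[col]], label = col)
  }
  expect_equal(fun$n_survivors, 2)
  # Venn accounting among the 8 peptides entering the dppiv stage
  expect_equal(fun$venn$n_entering, 8)
  expect_equal(fun$venn$scm, 7)
  expect_equal(fun$venn$dock, 7)
  expect_equal(fun$venn$seq_rule, 7)
  expect_equal(fun$venn$scm_dock, 6)
  expect_equal(fun$venn$scm_seq, 6)
  expect_equal(fun$venn$dock_seq, 6)
  expect_equal(fun$venn$all_three, 5)
})

test_that("funnel ledger conserves counts and survivors never increase", {
  set.seed(408)
  for (i in 1:20) {
    peps <- unique(vapply(sample(2:8, 40, TRUE), random_protein,
                          character(1)))
    pred <- gen_predictor_table(peps, seed = i, p_toxic = 0.2,
                                p_dock = 0.6, scm_mean = 294, scm_sd = 30,
                                p_gi_high = 0.7, p_cyp = 0.2)
    fun <- run_funnel(peps, pred)
    s <- fun$summary
    # conservation at every stage
    expect_true(all(s$pass + s$fail + s$not_evaluated == length(peps)))
    # monotone survivor counts across stages
    expect_true(all(diff(s$pass) <= 0))
    # three-way intersection bounded by each single-method count
    v <- fun$venn
    expect_lte(v$all_three, min(v$scm, v$dock, v$seq_rule))
    expect_lte(v$all_three, min(v$scm_dock, v$scm_seq, v$dock_seq))
    # verdict vocabulary and no evaluation after a failure
    led <- fun$ledger
    failed_bio <- led$stage_bioactivity == "fail"
    expect_true(all(led$stage_dppiv[failed_bio] == "not_evaluated"))
    expect_true(all(led$stage_adme[failed_bio] == "not_evaluated"))
  }
})

test_that("funnel edge cases: thresholds, all-pass, missing fields", {
  pred <- data.frame(sequence = "YPF", bioactivity_score = 0.4,
                     toxic = FALSE, scm_score = 400, dock_success = TRUE,
                     stringsAsFactors = FALSE)
  fun <- run_funnel("YPF", pred,
                    funnel_config(stages = c("bioactivity", "dppiv")))
  expect_equal(fun$ledger$stage_bioactivity, "fail")
  expect_equal(fun$ledger$stage_dppiv, "not_evaluated")
  expect_match(fun$ledger$fail_reason, "bioactivity")
  # a score exactly at the threshold fails the strict > rule
  pred$bioactivity_score <- 0.5
  expect_equal(run_funnel("YPF", pred, funnel_config(
    stages = c("bioactivity", "dppiv")))$ledger$stage_bioactivity, "fail")

  # designed all-pass table: survivors = input, all Venn counts equal
  peps <- c("LPA", "YPW", "IAP")
  allpass <- data.frame(sequence = peps, bioactivity_score = 0.9,
                        toxic = FALSE, scm_score = 400, dock_success = TRUE,
                        solubility_silicos_it = "VS", gi_absorption = "High",
                        cyp1a2 = FALSE, cyp2c19 = FALSE, cyp2c9 = FALSE,
                        cyp2d6 = FALSE, cyp3a4 = FALSE,
                        stringsAsFactors = FALSE)
  fun2 <- run_funnel(peps, allpass)
  expect_equal(fun2$n_survivors, 3)
  expect_true(all(unlist(fun2$venn[c("scm", "dock", "seq_rule",
                                     "all_three")]) == 3))

  expect_error(run_funnel("YPF", pred[, c("sequence", "bioactivity_score")]),
               "toxic")
  pred_na <- pred; pred_na$toxic <- NA
  expect_error(run_funnel("YPF", pred_na), "YPF")
  expect_error(run_funnel("GGG", pred), "absent")
})
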