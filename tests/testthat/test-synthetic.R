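test_that("generators are deterministic in the seed and sensitive to it", {
  p1 <- gen_proteins(4, c(50, 80), seed = 7)
  p2 <- gen_proteins(4, c(50, 80), seed = 7)
  expect_identical(p1, p2)
  expect_false(identical(p1$sequence, gen_proteins(4, c(50, 80),
                                                   seed = 8)$sequence))

  t1 <- gen_peptide_table(c("YPF", "LLLP", "IPI", "AAG"), seed = 3)
  expect_identical(t1, gen_peptide_table(c("YPF", "LLLP", "IPI", "AAG"),
                                         seed = 3))
  pr1 <- gen_predictor_table(c("YPF", "LLLP"), seed = 3)
  expect_identical(pr1, gen_predictor_table(c("YPF", "LLLP"), seed = 3))
  d1 <- gen_dose_response(100, seed = 3)
  expect_identical(d1, gen_dose_response(100, seed = 3))
})

test_that("protein generator honours composition and planted mode", {
  allA <- gen_proteins(3, c(20, 30), composition = c(A = 1), seed = 1)
  expect_true(all(grepl("^A+$", allA$sequence)))
  expect_error(gen_proteins(0, c(10, 20)), "positive")

  planted <- gen_proteins(5, c(50, 50), seed = 2,
                          planted = list(peptides = c("YPF", "WV"),
                                         k = 3, cut_residue = "K"))
  rule <- attr(planted, "planted_rule")
  expect_setequal(rule$cut_after, c("K", "F", "V"))
  for (i in seq_len(nrow(planted))) {
    prot <- planted$sequence[i]
    frags <- digest(prot, rule)
    # the construction is the oracle: exactly k plants are released whole
    expect_equal(a_value(prot, frags, c("YPF", "WV")), 3 / nchar(prot))
  }
  # a plant carrying a cut-set residue internally is rejected
  expect_error(gen_proteins(2, c(50, 50), seed = 2,
                            planted = list(peptides = c("YPF", "LLLP"),
                                           k = 2, cut_residue = "K")),
               "internally")
})

test_that("peptide-table generator controls subsampling and labels", {
  frags <- c("YPF", "LLLP", "IPI", "GAG", "PPL", "WVA")
  full <- gen_peptide_table(frags, subsample = 1, seed = 4)
  expect_equal(nrow(full), length(frags))
  expect_true(all(full$identification_score > 0))
  half <- gen_peptide_table(frags, subsample = 0.5, seed = 4)
  expect_equal(nrow(half), 3)
  onlyboth <- gen_peptide_table(frags, source_props = c(both = 1), seed = 4)
  expect_true(all(onlyboth$source == "both"))
  # observed masses track the computed monoisotopic masses
  expect_true(all(abs(full$mass_observed -
                        monoisotopic_mass(full$sequence)) < 0.01))
})

test_that("predictor generator supports distributions and designed truth", {
  peps <- c("YPF", "LLLP", "IPI")
  none_toxic <- gen_predictor_table(peps, p_toxic = 0, seed = 5)
  expect_true(all(!none_toxic$toxic))
  all_dock <- gen_predictor_table(peps, p_dock = 1, seed = 5)
  expect_true(all(all_dock$dock_success))
  expect_true(all(none_toxic$bioactivity_score >= 0 &
                    none_toxic$bioactivity_score <= 1))

  designed <- data.frame(sequence = peps,
                         bioactivity_score = c(0.9, 0.2, NA),
                         dock_success = c(TRUE, FALSE, TRUE))
  tab <- gen_predictor_table(peps, designed = designed, seed = 5)
  expect_equal(tab$bioactivity_score[1:2], c(0.9, 0.2))
  expect_equal(tab$dock_success, c(TRUE, FALSE, TRUE))
  # NA cells in the design fall back to the random draw
  expect_false(is.na(tab$bioactivity_score[3]))
  expect_error(gen_predictor_table(c(peps, "GGG"), designed = designed),
               "GGG")
})

test_that("dose-response generator reproduces its truth curve at zero noise", {
  doses <- c(1, 10, 100, 200, 1000, 1e4)
  d <- gen_dose_response(ic50 = 200, hill = 1, bottom = 0, top = 100,
                         doses = doses, reps = 1, noise_sd = 0, seed = 1)
  expect_equal(d$response[d$concentration == 200], 50)  # midpoint at IC50
  expect_true(all(diff(d$response[order(d$concentration)]) > 0))
  expect_error(gen_dose_response(-5), "ic50 > 0")
})
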