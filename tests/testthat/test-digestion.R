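test_that("cut_sites follows P1/P1' semantics", {
  expect_equal(cut_sites("AYFGK", enzyme_rule("e", "YFW")), c(2L, 3L))
  expect_equal(cut_sites("AAAA", enzyme_rule("e", "K")), integer(0))
  # single eligible site cancelled by the P1' exception
  expect_equal(cut_sites("AKPA", enzyme_rule("e", "K", "P")), integer(0))
  # final residue is never a site even when it matches P1
  expect_equal(cut_sites("AK", enzyme_rule("e", "K")), integer(0))
  expect_error(cut_sites("AXA", enzyme_rule("e", "K")), "non-canonical")
})

test_that("digest tiles the protein and enumerates missed cleavages", {
  rule <- enzyme_rule("e", "YFW")
  d0 <- digest("AYFGK", rule, max_missed = 0)
  expect_equal(d0$sequence, c("AY", "F", "GK"))
  expect_equal(d0$start, c(1L, 3L, 4L))
  expect_equal(d0$end, c(2L, 3L, 5L))
  expect_equal(paste(d0$sequence, collapse = ""), "AYFGK")

  # no cut sites: the whole protein is the single fragment
  dn <- digest("GGGG", rule)
  expect_equal(dn$sequence, "GGGG")
  expect_equal(dn$n_missed, 0L)

  d1 <- digest("AYFGK", rule, max_missed = 1)
  extra <- d1[d1$n_missed == 1, ]
  expect_setequal(extra$sequence, c("AYF", "FGK"))
  expect_true(all(d1$sequence == substring("AYFGK", d1$start, d1$end)))
})

test_that("digestion matches the brute-force oracle on random proteins", {
  set.seed(401)
  for (i in 1:200) {
    prot <- random_protein(sample(2:30, 1))
    rules <- replicate(sample(1:3, 1), random_rule(), simplify = FALSE)
    mm <- sample(0:2, 1)
    got <- digest(prot, rules, max_missed = mm)
    want <- brute_digest(prot, rules, max_missed = mm)
    expect_equal(got$sequence, want$sequence)
    expect_equal(got$start, want$start)
    expect_equal(got$n_missed, want$n_missed)
    # conservation: complete-digest fragments reconstruct the protein
    complete <- got[got$n_missed == 0, ]
    expect_identical(paste(complete$sequence, collapse = ""), prot)
    expect_equal(sum(nchar(complete$sequence)), nchar(prot))
  }
})

test_that("adding an enzyme never decreases the cut-site count", {
  set.seed(402)
  for (i in 1:50) {
    prot <- random_protein(sample(5:30, 1))
    r1 <- random_rule("a"); r2 <- random_rule("b")
    s1 <- cut_sites(prot, r1)
    s12 <- cut_sites(prot, list(r1, r2))
    expect_gte(length(s12), length(s1))
    expect_true(all(s1 %in% s12))
  }
})

test_that("digest_combo is the union-of-sites model with provenance", {
  cat <- enzyme_catalogue()
  prot <- data.frame(id = "p", sequence = "AYKAYK", stringsAsFactors = FALSE)

  one <- digest_combo(prot, "papain", cat)
  attr(one, "cut_provenance") <- NULL
  expect_equal(one, digest("AYKAYK", cat[["papain"]], protein_id = "p"))

  # disjoint site sets: fragment count = |sites1| + |sites2| + 1
  c1 <- enzyme_rule("c1", "Y"); c2 <- enzyme_rule("c2", "K")
  cat2 <- list(c1 = c1, c2 = c2)
  both <- digest_combo(prot, c("c1", "c2"), cat2)
  n1 <- length(cut_sites(prot$sequence, c1))
  n2 <- length(cut_sites(prot$sequence, c2))
  expect_equal(nrow(both), n1 + n2 + 1)

  # order symmetry
  rev2 <- digest_combo(prot, c("c2", "c1"), cat2)
  attr(both, "cut_provenance") <- NULL
  attr(rev2, "cut_provenance") <- NULL
  expect_equal(both, rev2)

  prov <- attr(digest_combo(prot, c("c1", "c2"), cat2), "cut_provenance")
  expect_equal(prov$p[["2"]], "c1")  # Y at 2 cut only by c1
  expect_equal(prov$p[["3"]], "c2")

  expect_error(digest_combo(prot, "pepsin", cat), "unknown enzyme")
  expect_error(digest_combo(prot, "pepsin", cat), "proteinase_k")
})

test_that("the shipped catalogue loads all five food-industry proteases", {
  cat <- enzyme_catalogue()
  expect_setequal(names(cat),
                  c("proteinase_k", "papain", "thermolysin", "bromelain",
                    "subtilisin"))
  expect_setequal(cat$proteinase_k$cut_after,
                  c("A", "F", "I", "L", "T", "V", "W", "Y"))
  expect_setequal(cat$papain$cut_after, c("R", "K"))
  expect_equal(cat$papain$blocked_p1prime, "P")
})
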