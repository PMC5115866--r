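# ROC, recovery, negative-set construction, shared labels, calibration
# bins, complex recovery and seeded member prediction.

test_that("roc_curve matches the rank-statistic oracle", {
  mk <- function(pos, neg, role = "evaluate") {
    keys_p <- pair_key(sprintf("p%02d", seq_along(pos)), "X")
    keys_n <- pair_key(sprintf("n%02d", seq_along(neg)), "X")
    list(scores = setNames(c(pos, neg), c(keys_p, keys_n)),
         refs = reference_sets(keys_p, keys_n, role = role))
  }
  # perfectly separated
  a <- mk(c(10, 9), c(1, 2))
  expect_equal(roc_curve(a$scores, a$refs)$auc, 1.0)
  # no discrimination
  b <- mk(c(5, 5), c(5, 5, 5))
  expect_equal(roc_curve(b$scores, b$refs)$auc, 0.5)
  # one intruding negative: brute-force rank enumeration gives 0.875
  d <- mk(c(3, 2), c(2.5, 1, 0, 0))
  expect_equal(auc_oracle(c(3, 2), c(2.5, 1, 0, 0)), 0.875)
  expect_equal(roc_curve(d$scores, d$refs)$auc, 0.875)

  # random small instances against the enumeration oracle
  set.seed(31)
  for (rep in 1:25) {
    pos <- round(rexp(sample(3:12, 1), 0.2), 1)
    neg <- round(rexp(sample(3:12, 1), 0.5), 1)
    z <- mk(pos, neg)
    expect_equal(roc_curve(z$scores, z$refs)$auc, auc_oracle(pos, neg),
                 tolerance = 1e-12)
  }
  expect_error(roc_curve(a$scores, mk(1, 1, role = "train")$refs), "evaluate")
})

test_that("unscored reference pairs count at the neutral LR", {
  refs <- reference_sets(c("a|b", "c|d"), c("e|f", "g|h"), role = "evaluate")
  scores <- c("a|b" = 100)     # everything else unscored -> LR 1
  r <- roc_curve(scores, refs)
  expect_equal(r$auc, auc_oracle(c(100, 1), c(1, 1)))
  expect_equal(recovery_fraction(c("a|b", "c|d"), scores, 50), 0.5)
})

test_that("recovery_fraction counts strict exceedances", {
  scores <- setNames(c(700, 650, 601, 600), c("a|b", "c|d", "e|f", "g|h"))
  expect_equal(recovery_fraction(names(scores), scores, 600), 0.75)
  expect_equal(recovery_fraction(names(scores), scores, 0), 1.0)
  expect_equal(recovery_fraction(c("x|y", "u|v"), scores, 600), 0.0)
  expect_error(recovery_fraction(character(), scores, 600), "empty")
})

test_that("compartment negatives honor quotas, rules and exclusions", {
  proteins <- data.frame(
    protein_id = c(sprintf("m%d", 1:4), sprintf("n%d", 1:3),
                   sprintf("t%d", 1:2), sprintf("e%d", 1:2), "dual"),
    compartment = c(rep("m", 4), rep("n", 3), rep("t", 2), rep("e", 2), "m"))
  proteins <- rbind(proteins, data.frame(protein_id = "dual", compartment = "n"))
  rules <- list(c("m", "n"), c("n", "t"), c("n", "e"), c("t", "e"))
  quota <- c(m = 2L, n = 1L, t = 1L, e = 1L)
  keys <- build_compartment_negatives(proteins, quota, rules, seed = 5)
  expect_length(keys, 2 + 1 + 1 + 1)
  expect_false(any(grepl("dual", keys)))   # dual-annotated excluded
  # deterministic under a fixed seed
  expect_identical(keys, build_compartment_negatives(proteins, quota, rules, seed = 5))
  expect_false(identical(keys,
    build_compartment_negatives(proteins, quota, rules, seed = 6)))
  # excluded proteins never sampled
  keys2 <- build_compartment_negatives(proteins, quota, rules,
                                       exclusions = "t1")
  expect_false(any(grepl("t1", keys2, fixed = TRUE)))
  expect_error(
    build_compartment_negatives(proteins, c(m = 10L, n = 1L, t = 1L, e = 1L), rules),
    "compartment 'm'")
})

test_that("full-scale compartment crossing reproduces the quota product", {
  pool <- data.frame(
    protein_id = sprintf("q%05d", 1:4000),
    compartment = rep(c("membrane", "nucleoplasm", "mitochondria", "er"),
                      times = c(2400, 700, 500, 400)))
  quota <- c(membrane = 2000L, nucleoplasm = 500L, mitochondria = 500L, er = 383L)
  rules <- list(c("membrane", "nucleoplasm"), c("nucleoplasm", "mitochondria"),
                c("nucleoplasm", "er"), c("mitochondria", "er"))
  keys <- build_compartment_negatives(pool, quota, rules, seed = 1)
  expect_length(keys, 2000 * 500 + 500 * 500 + 500 * 383 + 500 * 383)
  expect_length(keys, 1633000)
})

test_that("shared_label_fraction counts intersecting label sets", {
  labels <- list(a = c("x", "y"), b = "x", c = "z", d = character())
  res <- shared_label_fraction(pair_key(c("a", "a", "a"), c("b", "c", "d")), labels)
  expect_equal(res$fraction, 1 / 3)
  expect_equal(res$per_label$fraction[res$per_label$label == "x"], 1 / 3)
  all_shared <- shared_label_fraction("a|b", labels)
  expect_equal(all_shared$fraction, 1.0)
  expect_equal(shared_label_fraction("a|c", labels)$fraction, 0.0)
})

test_that("probability_true_vs_lr bins the positive fraction", {
  scores <- setNames(c(5, 15, 25, 25, 25, 25, 25, 25, 25, 25),
                     pair_key(letters[1:10], LETTERS[1:10]))
  pos <- names(scores)[c(1, 3, 4)]
  out <- probability_true_vs_lr(scores, pos, c(0, 10, 20, 30, 40))
  expect_equal(out$fraction_positive[1], 1.0)
  expect_equal(out$fraction_positive[3], 2 / 8)
  expect_true(is.na(out$fraction_positive[4]))   # empty bin reported absent
  expect_error(probability_true_vs_lr(scores, pos, c(0, 10)), "cover")
})

test_that("complex recovery matches the threshold-sweep oracle", {
  sc <- setNames(c(1000, 700, 10), pair_key(c("A", "B", "A"), c("B", "C", "C")))
  expect_equal(complex_recovery_lr(c("A", "B", "C"), sc), 700)
  expect_equal(complex_recovery_lr(c("A", "B"), setNames(850, "A|B")), 850)
  expect_equal(complex_recovery_lr(c("A", "B", "Z"), sc), 0)  # Z has no edges

  set.seed(17)
  universe <- sprintf("U%02d", 1:30)
  for (rep in 1:60) {
    members <- sample(universe, sample(3:8, 1))
    npairs <- choose(length(members), 2)
    idx <- t(combn(members, 2))
    present <- runif(npairs) < 0.7
    sc <- setNames(round(rexp(sum(present), 1 / 500), 1),
                   pair_key(idx[present, 1], idx[present, 2]))
    expect_equal(complex_recovery_lr(members, sc),
                 recovery_oracle(members, sc), info = rep)
  }
})

test_that("random complex null is seeded and near zero on sparse scores", {
  set.seed(23)
  universe <- sprintf("U%03d", 1:200)
  idx <- t(combn(universe[1:60], 2))
  keep <- runif(nrow(idx)) < 0.05
  scores <- setNames(rexp(sum(keep), 1 / 300), pair_key(idx[keep, 1], idx[keep, 2]))
  complexes <- lapply(1:30, function(i) sample(universe, sample(3:6, 1)))
  names(complexes) <- paste0("c", 1:30)
  null1 <- random_complex_null(complexes, universe, scores, seed = 9)
  null2 <- random_complex_null(complexes, universe, scores, seed = 9)
  expect_identical(null1, null2)
  expect_lte(mean(null1$recovery_lr >= 600), 0.02)
  # threshold 0 recovers everything by construction
  expect_equal(null1$curve$fraction[null1$curve$threshold == 0], 1.0)
  expect_error(random_complex_null(complexes, universe[1:2], scores), "smaller")
})

test_that("seeded member prediction ranks candidates deterministically", {
  members <- c("S1", "S2", "M1", "M2", "M3")
  sc <- c(setNames(c(1000, 900, 800), pair_key(c("S1", "S1", "S1"),
                                               c("M1", "M2", "M3"))),
          setNames(c(950, 20), pair_key(c("S2", "S2"), c("D1", "M3"))),
          setNames(700, pair_key("D2", "S1")))
  res <- seeded_member_prediction(members, c("S1", "S2"), sc)
  # ranking: M1 1000, D1 950, M2 900, M3 800, D2 700
  expect_identical(res$candidates$protein, c("M1", "D1", "M2", "M3", "D2"))
  expect_true(res$found_all)
  expect_equal(res$rank_of_last_member, 4L)
  expect_true(res$within_k)

  # a member below threshold breaks found_all
  sc2 <- sc
  sc2[pair_key("S1", "M3")] <- 100
  sc2[pair_key("S2", "M3")] <- 20
  res2 <- seeded_member_prediction(members, c("S1", "S2"), sc2)
  expect_false(res2$found_all)
  expect_true(is.na(res2$rank_of_last_member))

  expect_error(seeded_member_prediction(members, c("S1", "ZZ"), sc), "belong")
})
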