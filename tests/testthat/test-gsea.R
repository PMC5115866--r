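# Ranked-list gene set enrichment.

test_that("rank_interactors sorts by LR with deterministic ties", {
  scores <- setNames(c(900, 50, 600, 600),
                     pair_key(c("A", "A", "A", "A"), c("B", "C", "D", "E")))
  r <- rank_interactors("A", scores)
  expect_identical(r$protein, c("B", "D", "E", "C"))  # tie at 600: D before E
  expect_false("A" %in% r$protein)
  # unscored universe members append at the neutral LR
  r2 <- rank_interactors("A", scores, universe = c("A", "B", "C", "D", "E", "F", "G"))
  expect_identical(tail(r2$protein, 2), c("F", "G"))
  expect_equal(tail(r2$lr, 2), c(1, 1))
})

test_that("enrichment score reproduces simple walks", {
  ranked <- data.frame(protein = c("a", "b", "c", "d"), lr = c(10, 10, 10, 10))
  expect_equal(enrichment_score(ranked, "a"), 1.0)          # single top hit
  expect_equal(enrichment_score(ranked, c("a", "b", "c", "d")), 1.0)  # all hits
  expect_error(enrichment_score(ranked, "zz"), "no gene-set member")
  # uniformly interleaved members with equal weights give a small ES
  ranked2 <- data.frame(protein = sprintf("g%02d", 1:20), lr = rep(5, 20))
  es <- enrichment_score(ranked2, sprintf("g%02d", seq(2, 20, by = 2)))
  expect_lt(abs(es), 0.15)
})

test_that("enrichment score equals the prefix-sum oracle", {
  set.seed(41)
  for (rep in 1:40) {
    n <- sample(10:50, 1)
    ranked <- data.frame(protein = sprintf("g%03d", 1:n),
                         lr = sort(rexp(n, 1 / 200), decreasing = TRUE))
    members <- sample(ranked$protein, sample(2:(n - 1), 1))
    hits <- ranked$protein %in% members
    w <- pmax(log10(pmax(ranked$lr, 1)), 0)
    expect_equal(enrichment_score(ranked, members), es_oracle(hits, w),
                 tolerance = 1e-9, info = rep)
    # the fast position-based evaluator used by the permutation loop agrees
    expect_equal(ppilr:::.es_from_positions(which(hits), w, n),
                 es_oracle(hits, w), tolerance = 1e-12)
  }
})

test_that("appended zero-weight tail items barely move the ES", {
  # The miss decrement is 1/(N - N_hits), so appending k tail items perturbs
  # any prefix value by at most k/(N + k - N_hits); for a positive ES the
  # perturbation is a weak increase.  Exact invariance is impossible for the
  # running-sum statistic as defined.
  set.seed(53)
  for (rep in 1:10) {
    n <- sample(12:40, 1)
    ranked <- data.frame(protein = sprintf("g%02d", 1:n),
                         lr = sort(rexp(n, 1 / 100), decreasing = TRUE) + 1)
    members <- sample(ranked$protein[1:6], 3)
    base <- enrichment_score(ranked, members)
    k <- sample(1:5, 1)
    longer <- rbind(ranked, data.frame(protein = sprintf("t%02d", 1:k), lr = 1))
    es2 <- enrichment_score(longer, members)
    expect_lte(abs(es2 - base), k / (n + k - 3))
    if (base > 0) expect_gte(es2, base)
  }
})

test_that("enrichment analysis flags planted sets and controls the null", {
  set.seed(43)
  n <- 120
  planted <- sprintf("hit%02d", 1:15)
  rest <- sprintf("bg%03d", 1:(n - 15))
  ranked <- data.frame(protein = c(planted, rest),
                       lr = sort(rexp(n, 1 / 400), decreasing = TRUE))
  sets <- c(list(PLANTED = planted),
            lapply(setNames(1:12, paste0("RND", 1:12)),
                   function(i) sample(c(planted, rest), 15)))
  # 13 sets under BH at q < 0.01 need min-p below 0.01/13, hence >= 1300
  # label permutations for the planted set to clear the cutoff
  res <- enrichment_analysis(ranked, sets, n_permutations = 2000, seed = 7)
  expect_identical(res$set[1], "PLANTED")
  expect_true(res$enriched[res$set == "PLANTED"])
  expect_equal(first_correct_rank(res, "PLANTED"), 1L)
  # determinism under a fixed seed
  res2 <- enrichment_analysis(ranked, sets, n_permutations = 2000, seed = 7)
  expect_identical(res, res2)
  expect_error(enrichment_analysis(ranked, sets, n_permutations = 50), "100")
})

test_that("null rankings are flagged at roughly the FDR level", {
  set.seed(47)
  n <- 150
  prots <- sprintf("p%03d", 1:n)
  flagged <- 0L
  tested <- 0L
  for (rep in 1:5) {
    ranked <- data.frame(protein = sample(prots), lr = sort(rexp(n, 1 / 100),
                                                            decreasing = TRUE))
    sets <- lapply(setNames(1:20, paste0("S", 1:20)),
                   function(i) sample(prots, 12))
    res <- enrichment_analysis(ranked, sets, n_permutations = 150, seed = rep)
    flagged <- flagged + sum(res$enriched)
    tested <- tested + nrow(res)
  }
  expect_lte(flagged / tested, 0.05)   # q < 0.01 should flag almost nothing
})

test_that("first_correct_rank scans sorted results", {
  res <- data.frame(set = c("s1", "s2", "s3"), term = c("t_a", "t_b", "t_c"),
                    rank = 1:3)
  expect_equal(first_correct_rank(res, "t_a"), 1L)
  expect_equal(first_correct_rank(res, c("t_c", "t_zzz")), 3L)
  expect_true(is.na(first_correct_rank(res, "t_q")))
})
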