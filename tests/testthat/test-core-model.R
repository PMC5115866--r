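# Core model: pair keys, bin partitions, LR fitting, evidence combination.

test_that("pair keys are canonical and symmetric", {
  expect_identical(pair_key("B", "A"), pair_key("A", "B"))
  expect_identical(pair_key(c("x", "q"), c("a", "z")), c("a|x", "q|z"))
  expect_error(pair_key("a|b", "c"), "must not contain")
  m <- pair_unkey(pair_key(c("B", "Z"), c("A", "Y")))
  expect_identical(unname(m[, "a"]), c("A", "Y"))
})

test_that("bin partitions assign exhaustively and exclusively", {
  nb <- numeric_bins(c(-Inf, 0, 1, Inf))
  expect_identical(bin_index(nb, c(-5, 0, 0.5, 1, 2)), c(1L, 1L, 2L, 2L, 3L))
  cb <- categorical_bins(c("x", "y"))
  expect_identical(bin_index(cb, c("y", "x", "z")), c(2L, 1L, NA_integer_))
  gb <- grid_bins(list(n = list(c(0, 0), c(1, 1), c(2, 5), c(6, Inf)),
                       d = list(c(0, 100), c(101, Inf))))
  expect_equal(n_bins(gb), 8L)
  # (n=3, d=50) lands in the ([2,5],[0,100]) cell
  expect_identical(gb$labels[bin_index(gb, cbind(n = 3, d = 50))], "[2,5]x[0,100]")
  # every (n, d) in a lattice maps to exactly one bin
  lat <- expand.grid(n = 0:12, d = c(0, 50, 100, 101, 5000))
  expect_false(anyNA(bin_index(gb, lat)))
  # quantile bins cover the whole line
  qb <- quantile_bins(rnorm(500), 10)
  expect_false(anyNA(bin_index(qb, c(-1e6, 0, 1e6))))
})

make_refs <- function(npos, nneg, role = "train") {
  reference_sets(pair_key(sprintf("p%03d", seq_len(npos)), "POS"),
                 pair_key(sprintf("n%03d", seq_len(nneg)), "NEG"),
                 role = role)
}

test_that("fit_binned_lr reproduces hand-computed percentage ratios", {
  bins <- categorical_bins(c("A", "B"))
  refs <- make_refs(10, 10)
  # pos counts {A:8, B:2}, neg counts {A:2, B:8}
  scores <- setNames(c(rep("A", 8), rep("B", 2), rep("A", 2), rep("B", 8)),
                     c(refs$positives, refs$negatives))
  m <- fit_binned_lr(scores, refs, bins, pseudo_count = 0)
  expect_equal(lookup_lr(m, "A"), 4.0)
  expect_equal(lookup_lr(m, "B"), 0.25)

  # identical distributions: every LR is 1
  scores2 <- setNames(rep(c("A", "B"), 10), c(refs$positives, refs$negatives))
  m2 <- fit_binned_lr(scores2, refs, bins, pseudo_count = 0)
  expect_equal(unname(m2$lr), c(1, 1))
  expect_equal(lookup_lr(m2, "A"), 1.0)
  expect_equal(lookup_lr(m2, "B"), 1.0)

  # pseudo-count plug-in: pos {A:10, B:0}, neg {A:0, B:10}, k = 0.5
  scores3 <- setNames(c(rep("A", 10), rep("B", 10)),
                      c(refs$positives, refs$negatives))
  m3 <- fit_binned_lr(scores3, refs, bins, pseudo_count = 0.5)
  expect_equal(lookup_lr(m3, "A"), (10.5 / 11) / (0.5 / 11))
  expect_equal(lookup_lr(m3, "A"), 21.0)
})

test_that("fit_binned_lr validates its inputs", {
  bins <- categorical_bins(c("A", "B"))
  refs <- make_refs(4, 4)
  scores <- setNames(rep("A", 8), c(refs$positives, refs$negatives))
  expect_error(fit_binned_lr(scores, make_refs(3, 3, role = "evaluate"), bins),
               "train")
  bad <- setNames(c(rep("A", 4), rep("C", 4)), c(refs$positives, refs$negatives))
  expect_error(fit_binned_lr(bad, refs, bins), "outside every bin")
  expect_error(reference_sets("a|b", "a|b"), "overlap")
  # pairs lacking evidence are excluded, not counted
  partial <- setNames(c("A", "A", "B"), c(refs$positives[1:2], refs$negatives[1]))
  m <- fit_binned_lr(partial, refs, bins, pseudo_count = 0)
  expect_equal(m$n_pos, 2)
  expect_equal(m$n_neg, 1)
})

test_that("negative-distribution LR average is 1 at pseudo-count 0", {
  set.seed(7)
  for (rep in 1:10) {
    nb <- sample(2:6, 1)
    bins <- categorical_bins(LETTERS[seq_len(nb)])
    refs <- make_refs(60, 80)
    scores <- setNames(sample(LETTERS[seq_len(nb)], 140, replace = TRUE,
                              prob = runif(nb) + 0.2),
                       c(refs$positives, refs$negatives))
    m <- fit_binned_lr(scores, refs, bins, pseudo_count = 0)
    p_neg <- m$neg_counts / m$n_neg
    p_pos <- m$pos_counts / m$n_pos
    finite <- is.finite(m$lr)
    expect_equal(sum(p_neg[finite] * m$lr[finite]), sum(p_pos[finite]),
                 tolerance = 1e-9)
    # when no bin is empty this is exactly 1
    if (all(m$neg_counts > 0)) {
      expect_equal(sum(p_neg * m$lr), 1, tolerance = 1e-9)
    }
  }
})

test_that("combine_evidence follows the max/product rule", {
  cs <- combine_evidence(c(SM = 100, PrP = 50, PR = 2, GO = 3))
  expect_equal(cs$lr_total, 600)
  expect_equal(cs$lr_structural, 200)
  expect_equal(combine_evidence()$lr_total, 1)           # empty product
  expect_equal(combine_evidence(c(SM = 300, PrP = 10, PR = 3))$lr_structural, 900)
  # single present non-structural channel passes through unchanged
  for (ch in c("PR", "GO", "PP", "OR", "EP")) {
    x <- setNames(2.5, ch)
    expect_equal(combine_evidence(x)$lr_total, 2.5)
  }
  expect_error(combine_evidence(c(GO = -1)), "nonnegative")
  expect_error(combine_evidence(c(XX = 2)), "unknown channel")
  # squared-PR variant is exposed but off by default
  expect_equal(combine_evidence(c(SM = 10, PR = 3), square_pr = TRUE)$lr_total, 90)
  expect_equal(combine_evidence(c(SM = 10, PR = 3))$lr_total, 30)
})

test_that("combine_evidence_df matches the scalar combiner", {
  set.seed(11)
  tab <- as.data.frame(matrix(rexp(7 * 40), ncol = 7,
                              dimnames = list(NULL, c("SM", "PrP", "PR", "GO",
                                                      "PP", "OR", "EP"))))
  for (j in seq_along(tab)) tab[[j]][runif(40) < 0.4] <- NA  # absent channels
  got <- combine_evidence_df(tab)
  want <- t(vapply(seq_len(nrow(tab)), function(i) {
    v <- unlist(tab[i, ])
    cs <- combine_evidence(v[!is.na(v)])
    c(cs$lr_total, cs$lr_structural)
  }, numeric(2)))
  expect_equal(got$lr_total, want[, 1])
  expect_equal(got$lr_structural, want[, 2])
})

test_that("lr_total is monotone in every channel LR", {
  set.seed(3)
  for (rep in 1:20) {
    base <- setNames(rexp(7), c("SM", "PrP", "PR", "GO", "PP", "OR", "EP"))
    ch <- sample(names(base), 1)
    bumped <- base
    bumped[ch] <- bumped[ch] * (1 + runif(1))
    expect_gte(combine_evidence(bumped)$lr_total,
               combine_evidence(base)$lr_total)
  }
})

test_that("reliability threshold is strict", {
  expect_true(classify_reliable(600.1))
  expect_false(classify_reliable(600))
  expect_false(classify_reliable(1))
  expect_identical(classify_reliable(c(601, 599), threshold = 600),
                   c(TRUE, FALSE))
})

test_that("models survive a JSON round trip", {
  refs <- make_refs(10, 10)
  scores <- setNames(c(rnorm(10, 1), rnorm(10)), c(refs$positives, refs$negatives))
  m <- fit_binned_lr(scores, refs, quantile_bins(scores, 4), channel = "SM")
  path <- withr::local_tempfile(fileext = ".json")
  write_models_json(list(SM = m), path)
  back <- read_models_json(path)$SM
  probe <- c(-2, 0, 0.7, 3)
  expect_equal(lookup_lr(back, probe), lookup_lr(m, probe))
  expect_equal(back$pseudo_count, m$pseudo_count)
})
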