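# Orthology vectors and the dimensional backoff.

test_that("species with interacting orthologs are counted once each", {
  map <- data.frame(protein_id = c("A", "A", "B", "B", "B"),
                    species = c("yeast", "fly", "yeast", "yeast", "fly"),
                    ortholog_id = c("yA", "fA", "yB1", "yB2", "fB"))
  ia <- data.frame(species = c("yeast", "yeast", "fly", "worm"),
                   protein_1 = c("yA", "yA", "fA", "wA"),
                   protein_2 = c("yB1", "yB2", "fB", "wB"))
  # two ortholog pairs interact in yeast but yeast counts once
  expect_equal(count_orthologous_interactions("A", "B", map, ia), 2L)
  expect_equal(count_orthologous_interactions("A", "Z", map, ia), 0L)
  # orthologs exist but never co-listed as interacting
  ia0 <- data.frame(species = "yeast", protein_1 = "yA", protein_2 = "yOther")
  expect_equal(count_orthologous_interactions("A", "B", map, ia0), 0L)
})

test_that("vector encoding thresholds counts at the >1 level", {
  expect_identical(unname(orthology_vector(c(1, 3, 0, 0))), c(1L, 2L, 0L, 0L))
  expect_identical(unname(orthology_vector(c(0, 0, 0, 0))), c(0L, 0L, 0L, 0L))
  expect_identical(unname(orthology_vector(c(2, 2, 2, 2))), c(2L, 2L, 2L, 2L))
  # monotone in counts
  set.seed(2)
  for (rep in 1:20) {
    cnt <- sample(0:5, 4, replace = TRUE)
    bump <- cnt + sample(c(0, 1), 4, replace = TRUE)
    expect_true(all(orthology_vector(bump) >= orthology_vector(cnt)))
  }
})

test_that("backoff order descends through dimensions deterministically", {
  ord <- orthology_backoff_order()
  expect_length(ord, 15)
  expect_identical(ord[[1]], 1:4)
  expect_identical(ord[[2]], c(1L, 2L, 3L))
  expect_identical(ord[[3]], c(1L, 2L, 4L))
  expect_identical(lengths(ord), c(4L, rep(3L, 4), rep(2L, 6), rep(1L, 4)))
})

make_or_fixture <- function(n_per_side = 60, seed = 19) {
  set.seed(seed)
  pos_keys <- pair_key(sprintf("p%03d", 1:n_per_side), "POS")
  neg_keys <- pair_key(sprintf("n%03d", 1:n_per_side), "NEG")
  refs <- reference_sets(pos_keys, neg_keys, role = "train")
  # positives concentrate on (1,1,0,0)-like vectors, negatives on zeros
  vecs <- rbind(
    cbind(sample(0:2, n_per_side, TRUE, c(.2, .5, .3)),
          sample(0:2, n_per_side, TRUE, c(.3, .5, .2)), 0L, 0L),
    cbind(sample(0:2, n_per_side, TRUE, c(.8, .15, .05)),
          sample(0:2, n_per_side, TRUE, c(.85, .1, .05)), 0L, 0L))
  rownames(vecs) <- c(pos_keys, neg_keys)
  colnames(vecs) <- ORTHOLOGY_SOURCES
  list(refs = refs, vecs = vecs)
}

test_that("backoff serves supported bins first, then lower dimensions, then 1", {
  fx <- make_or_fixture()
  models <- fit_orthology_models(fx$vecs, fx$refs, pseudo_count = 0.5)
  # a frequent vector is served by the full 4-dimensional model
  v_common <- c(1L, 1L, 0L, 0L)
  expect_gte(sum(bin_support(models[[1]], paste(v_common, collapse = ","))), 10)
  expect_equal(score_orthology(v_common, models, min_support = 10),
               lookup_lr(models[[1]], "1,1,0,0"))
  # a vector never seen in training backs off; with min_support below 1 the
  # 4-dim pseudo-count LR would be used, with a high floor it falls through
  v_rare <- c(2L, 2L, 2L, 2L)
  lr_rare <- score_orthology(v_rare, models, min_support = 10)
  hit <- NULL
  for (j in seq_along(models)) {
    ss <- attr(models, "subsets")[[j]]
    lab <- paste(v_rare[ss], collapse = ",")
    if (bin_support(models[[j]], lab) >= 10) { hit <- lookup_lr(models[[j]], lab); break }
  }
  expect_equal(lr_rare, hit)
  # nothing supported anywhere -> neutral 1
  expect_equal(score_orthology(v_rare, models, min_support = 1e6), 1.0)
  # vectorized scoring agrees with scalar calls
  m <- rbind(v_common, v_rare, c(0L, 0L, 0L, 0L))
  expect_equal(score_orthology(m, models, 10),
               vapply(1:3, function(i) score_orthology(m[i, ], models, 10),
                      numeric(1)))
})

test_that("combining sources beats a noise-dominated single source", {
  w <- small_world()
  refs_tr <- w$refs_train
  refs_te <- w$refs_test
  vecs <- w$or_vectors
  set.seed(4)
  vecs[, "union_group"] <- sample(vecs[, "union_group"])  # one source scrambled
  multi <- fit_orthology_models(vecs, refs_tr)
  single <- fit_orthology_models(vecs, refs_tr,
                                 subsets = list(4L))  # the noisy source alone
  auc_of <- function(models) {
    key_all <- c(refs_te$positives, refs_te$negatives)
    key_all <- key_all[key_all %in% rownames(vecs)]
    lr <- score_orthology(vecs[key_all, , drop = FALSE], models, min_support = 10)
    names(lr) <- key_all
    roc_curve(lr, refs_te)$auc
  }
  expect_gte(auc_of(multi), auc_of(single))
})
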