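# Shared fixtures, built once per test run and memoized.  The "small" world
# keeps unit/property tests fast; the "default" world (the stated 2,000
# protein configuration) is only built by the acceptance suite.

.world_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, .world_cache)) assign(key, force(expr), .world_cache)
  get(key, .world_cache)
}

small_world <- function() {
  cached("small", generate_world(world_config(n_proteins = 300L, n_modules = 10L,
                                              seed = 42L)))
}

small_models <- function() cached("small_models", train_models(small_world()))

small_scores <- function() {
  cached("small_scores", score_map(score_pairs(small_world(), small_models())))
}

default_world <- function() cached("default", generate_world(world_config(seed = 101L)))

default_scores <- function() {
  cached("default_scores", {
    w <- default_world()
    score_map(score_pairs(w, train_models(w)))
  })
}

# Independent rank-statistic AUC oracle: P(pos > neg) + 0.5 P(pos == neg),
# by explicit enumeration of all positive/negative score comparisons.
auc_oracle <- function(pos, neg) {
  cmp <- outer(pos, neg, function(p, q) (p > q) + 0.5 * (p == q))
  mean(cmp)
}

# Independent bottleneck-threshold oracle for complex recovery: sweep every
# distinct edge weight (plus 0) and test connectivity by breadth-first
# search on the thresholded member graph.
recovery_oracle <- function(members, scores) {
  k <- length(members)
  w <- matrix(0, k, k, dimnames = list(members, members))
  for (i in seq_len(k - 1L)) {
    for (j in (i + 1L):k) {
      lr <- scores[pair_key(members[i], members[j])]
      w[i, j] <- w[j, i] <- if (is.na(lr)) 0 else lr
    }
  }
  connected_at <- function(t) {
    adj <- w >= t
    seen <- c(1L)
    frontier <- c(1L)
    while (length(frontier) > 0L) {
      nxt <- setdiff(which(apply(adj[frontier, , drop = FALSE], 2L, any)), seen)
      seen <- c(seen, nxt)
      frontier <- nxt
    }
    length(seen) == k
  }
  for (t in sort(unique(c(w[upper.tri(w)])), decreasing = TRUE)) {
    if (connected_at(t)) return(t)
  }
  0
}

# Independent prefix-sum oracle for the GSEA running-sum statistic.
es_oracle <- function(hits, weights) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == n) return(1)
  wh <- weights[hits]
  if (sum(wh) == 0) wh <- rep(1, nh)
  tot <- sum(wh)
  run <- 0
  best <- 0
  hi <- 0L
  for (i in seq_len(n)) {
    if (hits[i]) {
      hi <- hi + 1L
      run <- run + wh[hi] / tot
    } else {
      run <- run - 1 / (n - nh)
    }
    if (abs(run) > abs(best)) best <- run
  }
  best
}
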