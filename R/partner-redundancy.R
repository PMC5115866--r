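#' Partner-redundancy features for one ordered pair
#'
#' Partner redundancy reflects that if proteins structurally similar to A are
#' already known to interact with B, an A-B interaction is more likely.  The
#' features are
#' * `n` — number of structural neighbors of A (excluding A and B
#'   themselves) known to interact with B in the within-species experimental
#'   set;
#' * `d` — total number of known partners of B in that set (B's degree);
#' * `m` — number of neighbor-neighbor interactions: pairs (x, y) with x a
#'   neighbor of A, y a neighbor of B (again excluding A and B), reported to
#'   interact in experimental data from any species.
#'
#' `n`/`d` feed the first (within-species) network; `m` feeds the weaker but
#' broader second network.
#'
#' @param a,b protein ids.
#' @param neighborhoods named list: protein id -> character vector of
#'   structurally similar protein ids.
#' @param known_human character vector of canonical pair keys of
#'   within-species experimental interactions.
#' @param known_any_species character vector of canonical pair keys of
#'   experimental interactions pooled across species.
#' @return list with `n`, `d`, `m`.
#' @export
compute_pr_features <- function(a, b, neighborhoods, known_human,
                                known_any_species = character()) {
  nb_a <- setdiff(unique(neighborhoods[[a]] %||% character()), c(a, b))
  nb_b <- setdiff(unique(neighborhoods[[b]] %||% character()), c(a, b))
  n <- if (length(nb_a) > 0L) sum(pair_key(nb_a, rep(b, length(nb_a))) %in% known_human) else 0L
  deg <- pair_unkey(known_human)
  d <- sum(deg[, "a"] == b | deg[, "b"] == b)
  m <- 0L
  if (length(nb_a) > 0L && length(nb_b) > 0L) {
    grid <- expand.grid(x = nb_a, y = nb_b, stringsAsFactors = FALSE)
    grid <- grid[grid$x != grid$y, , drop = FALSE]
    m <- length(unique(pair_key(grid$x, grid$y)[
      pair_key(grid$x, grid$y) %in% known_any_species]))
  }
  list(n = as.integer(n), d = as.integer(d), m = as.integer(m))
}

#' Default partner-redundancy bin partitions
#'
#' The first network bins the `(n, d)` feature pair: `n` in `{0}`, `{1}`,
#' `[2,5]`, `[6,Inf)` crossed with `d` in `[0,100]`, `(100,Inf)` (only the
#' `([2,5],[0,100])` cell is fixed by convention; the rest are package
#' defaults).  The second network bins `m` into `{0}`, `{1}`, `[2,5]`,
#' `[6,20]`, `[21,Inf)`.
#'
#' @name pr_bins
#' @export
pr_first_bins <- function() {
  grid_bins(list(
    n = list(c(0, 0), c(1, 1), c(2, 5), c(6, Inf)),
    d = list(c(0, 100), c(101, Inf))
  ))
}

#' @rdname pr_bins
#' @export
pr_second_bins <- function() {
  grid_bins(list(m = list(c(0, 0), c(1, 1), c(2, 5), c(6, 20), c(21, Inf))))
}

#' Train the two partner-redundancy networks
#'
#' @param features data frame with columns `n`, `d`, `m` and rownames (or a
#'   `pair` column) of canonical pair keys.
#' @param refs training [reference_sets()].
#' @param first_bins,second_bins bin partitions (defaults [pr_first_bins()],
#'   [pr_second_bins()]).
#' @param pseudo_count per-bin pseudo-count.
#' @return list with models `first` (over `(n,d)`) and `second` (over `m`).
#' @export
fit_pr_models <- function(features, refs, first_bins = pr_first_bins(),
                          second_bins = pr_second_bins(), pseudo_count = 0.5) {
  keys <- rownames(features) %||% features$pair
  stopifnot(!is.null(keys))
  nd <- as.matrix(features[, c("n", "d")])
  rownames(nd) <- keys
  mm <- as.matrix(features[, "m", drop = FALSE])
  rownames(mm) <- keys
  list(
    first = fit_binned_lr(nd, refs, first_bins, pseudo_count, channel = "PR(n,d)"),
    second = fit_binned_lr(mm, refs, second_bins, pseudo_count, channel = "PR(m)")
  )
}

#' Partner-redundancy LR with first-then-second network fallback
#'
#' The LR is taken from the first network when its `(n, d)` bin carries at
#' least `min_support` training pairs; otherwise from the second network
#' (which requires a structure or structural model of B so that B's
#' neighborhood is defined); otherwise the evidence is neutral (LR 1).
#'
#' @param features list or one-row data frame with `n`, `d`, `m`; matrices /
#'   multi-row frames are scored per row.
#' @param models model pair from [fit_pr_models()].
#' @param min_support minimum first-network bin training count (default 10).
#' @param b_has_structure logical (recycled): is a structure or model of B
#'   available for the second network?
#' @return numeric LR vector with attribute `which_network`
#'   (`"first"`/`"second"`/`"none"` per pair).
#' @export
score_pr <- function(features, models, min_support = 10, b_has_structure = TRUE) {
  df <- as.data.frame(features)
  nd <- as.matrix(df[, c("n", "d")])
  mm <- as.matrix(df[, "m", drop = FALSE])
  b_has_structure <- rep_len(b_has_structure, nrow(df))

  sup <- bin_support(models$first, nd)
  use_first <- !is.na(sup) & sup >= min_support
  out <- rep(1, nrow(df))
  which_net <- rep("none", nrow(df))
  if (any(use_first)) {
    out[use_first] <- lookup_lr(models$first, nd[use_first, , drop = FALSE])
    which_net[use_first] <- "first"
  }
  use_second <- !use_first & b_has_structure
  if (any(use_second)) {
    out[use_second] <- lookup_lr(models$second, mm[use_second, , drop = FALSE])
    which_net[use_second] <- "second"
  }
  attr(out, "which_network") <- which_net
  out
}

#' Partner-redundancy features for a table of pairs
#'
#' Vectorized [compute_pr_features()] over both pair orientations; `n` and
#' `d` are reported for the `(a, b)` orientation as given, plus the reversed
#' orientation (columns `n_rev`, `d_rev`) so callers can score both and keep
#' the stronger evidence (unordered-pair symmetry).
#'
#' @inheritParams compute_pr_features
#' @param pairs data frame with columns `protein_a`, `protein_b`.
#' @return data frame `n`, `d`, `m`, `n_rev`, `d_rev`, rownames = canonical
#'   pair keys.
#' @export
pr_feature_table <- function(pairs, neighborhoods, known_human,
                             known_any_species = character()) {
  known_human <- unique(known_human)
  known_any_species <- unique(known_any_species)
  deg_tab <- table(as.vector(pair_unkey(known_human)))
  degree_of <- function(p) {
    d <- deg_tab[p]
    ifelse(is.na(d), 0L, as.integer(d))
  }
  a <- as.character(pairs$protein_a)
  b <- as.character(pairs$protein_b)
  np <- length(a)

  # long table of (pair index, excluded-and-deduped neighbor) per side
  expand_nbhd <- function(of, other) {
    nbs <- neighborhoods[of]
    nbs[vapply(nbs, is.null, logical(1))] <- list(character())
    len <- lengths(nbs)
    idx <- rep(seq_len(np), len)
    nb <- unlist(nbs, use.names = FALSE)
    keep <- !is.na(nb) & nb != of[idx] & nb != other[idx] &
      !duplicated(paste0(idx, "\r", nb))
    list(idx = idx[keep], nb = nb[keep])
  }
  nb_a <- expand_nbhd(a, b)
  nb_b <- expand_nbhd(b, a)

  one_dir <- function(nb_side, to) {
    if (length(nb_side$idx) == 0L) return(integer(np))
    hit <- pair_key(nb_side$nb, to[nb_side$idx]) %in% known_human
    tabulate(nb_side$idx[hit], nbins = np)
  }

  # neighbor-neighbor cross product, any-species interactions
  len_a <- tabulate(nb_a$idx, nbins = np)
  len_b <- tabulate(nb_b$idx, nbins = np)
  split_a <- split(nb_a$nb, factor(nb_a$idx, levels = seq_len(np)))
  split_b <- split(nb_b$nb, factor(nb_b$idx, levels = seq_len(np)))
  cross_idx <- rep(seq_len(np), len_a * len_b)
  cross_x <- unlist(mapply(function(x, y) rep(x, times = length(y)),
                           split_a, split_b, SIMPLIFY = FALSE), use.names = FALSE)
  cross_y <- unlist(mapply(function(x, y) rep(y, each = length(x)),
                           split_a, split_b, SIMPLIFY = FALSE), use.names = FALSE)
  m <- integer(np)
  if (length(cross_idx) > 0L) {
    ok <- cross_x != cross_y
    ck <- pair_key(cross_x[ok], cross_y[ok])
    ci <- cross_idx[ok]
    hit <- ck %in% known_any_species & !duplicated(paste0(ci, "\r", ck))
    m <- tabulate(ci[hit], nbins = np)
  }

  out <- data.frame(n = one_dir(nb_a, b), d = degree_of(b), m = m,
                    n_rev = one_dir(nb_b, a), d_rev = degree_of(a))
  rownames(out) <- pair_key(a, b)
  out
}
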