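#' Complex recovery threshold
#'
#' The largest LR cutoff at which all members of a multi-protein complex
#' still form a connected graph, taking edges from the score map (member
#' pairs without a score get weight 0, so disconnection is well defined).
#' This bottleneck threshold equals the minimum edge weight on a maximum
#' spanning tree of the member-induced weighted graph, which is how it is
#' computed here (igraph minimum-spanning tree on negated weights).
#'
#' @param members character vector of >= 2 protein ids.
#' @param scores named numeric vector of LRs keyed by canonical pair key.
#' @return nonnegative real: the recovery threshold (0 if the complex is
#'   only connected once zero-weight edges are admitted).
#' @examples
#' sc <- c(1000, 700, 10)
#' names(sc) <- pair_key(c("A", "B", "A"), c("B", "C", "C"))
#' complex_recovery_lr(c("A", "B", "C"), sc)  # 700
#' @export
complex_recovery_lr <- function(members, scores) {
  members <- unique(as.character(members))
  stopifnot(length(members) >= 2L)
  idx <- t(utils::combn(members, 2L))
  w <- unname(scores[pair_key(idx[, 1L], idx[, 2L])])
  w[is.na(w)] <- 0
  g <- igraph::graph_from_data_frame(
    data.frame(from = idx[, 1L], to = idx[, 2L], weight = -w),
    directed = FALSE, vertices = members)
  tree <- igraph::mst(g, weights = igraph::E(g)$weight)
  min(-igraph::E(tree)$weight)
}

#' Recovery-vs-threshold curve for a set of complexes
#'
#' @param complexes named list: complex id -> character vector of members.
#' @param scores named numeric vector of LRs.
#' @param thresholds cutoffs at which to report the fraction of complexes
#'   with recovery LR >= threshold; defaults to the distinct recovery LRs
#'   plus the canonical 600 gridpoint.
#' @return list with `recovery_lr` (named per complex) and `curve` (data
#'   frame `threshold`, `fraction`).
#' @export
complex_recovery_curve <- function(complexes, scores, thresholds = NULL) {
  rec <- vapply(complexes, complex_recovery_lr, numeric(1), scores = scores)
  if (is.null(thresholds)) thresholds <- sort(unique(c(rec, 600)))
  frac <- vapply(thresholds, function(t) mean(rec >= t), numeric(1))
  list(recovery_lr = rec,
       curve = data.frame(threshold = thresholds, fraction = frac))
}

#' Random-complex null recovery curve
#'
#' Replaces every complex with an equal-sized set of proteins drawn uniformly
#' from the universe, then computes the recovery curve.  Quantifies how much
#' complex recovery is an artifact of overall score density.
#'
#' @inheritParams complex_recovery_curve
#' @param protein_universe character vector of all protein ids to sample
#'   from.
#' @param seed integer seed (fixed seed gives an identical curve).
#' @return as [complex_recovery_curve()], for the randomized complexes.
#' @export
random_complex_null <- function(complexes, protein_universe, scores,
                                seed = 1L, thresholds = NULL) {
  protein_universe <- unique(as.character(protein_universe))
  sizes <- vapply(complexes, length, integer(1))
  if (max(sizes) > length(protein_universe)) {
    stop("protein universe smaller than the largest complex")
  }
  null_cx <- with_seed(seed, lapply(sizes, function(k) sample(protein_universe, k)))
  names(null_cx) <- names(complexes)
  complex_recovery_curve(null_cx, scores, thresholds = thresholds)
}

#' Seeded complex-member prediction
#'
#' Given two seed members of a complex, candidate members are all proteins
#' scoring above the reliability threshold against either seed, ranked by the
#' larger of the two seed LRs (ties broken lexicographically by id).  Reports
#' whether every non-seed member appears among the candidates and the rank of
#' the deepest true member.
#'
#' @param members the complex's protein ids.
#' @param seed_pair character vector of two member ids used as seeds.
#' @param scores named numeric vector of LRs.
#' @param threshold strict LR cutoff for candidacy (default 600).
#' @param k rank budget to compare against (default 10).
#' @return list with `found_all`, `rank_of_last_member` (`NA` when not all
#'   found), `within_k`, and the ranked `candidates` data frame.
#' @export
seeded_member_prediction <- function(members, seed_pair, scores,
                                     threshold = 600, k = 10L) {
  members <- unique(as.character(members))
  seed_pair <- as.character(seed_pair)
  stopifnot(length(seed_pair) == 2L)
  if (!all(seed_pair %in% members)) stop("seed proteins must belong to the complex")

  keys <- names(scores)
  m <- pair_unkey(keys)
  touch1 <- m[, "a"] %in% seed_pair
  touch2 <- m[, "b"] %in% seed_pair
  sel <- (touch1 | touch2) & !(touch1 & touch2)
  partner <- ifelse(m[sel, "a"] %in% seed_pair, m[sel, "b"], m[sel, "a"])
  lr <- unname(scores[sel])
  best <- tapply(lr, partner, max)
  best <- best[best > threshold]
  ord <- order(-best, names(best))
  candidates <- data.frame(protein = names(best)[ord], lr = unname(best)[ord],
                           rank = seq_along(ord), stringsAsFactors = FALSE)

  targets <- setdiff(members, seed_pair)
  hit <- targets %in% candidates$protein
  found_all <- all(hit)
  rank_last <- if (found_all && length(targets) > 0L) {
    max(candidates$rank[match(targets, candidates$protein)])
  } else NA_integer_
  list(found_all = found_all, rank_of_last_member = rank_last,
       within_k = isTRUE(found_all && rank_last <= k), candidates = candidates)
}
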