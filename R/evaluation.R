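#' ROC curve over reference sets
#'
#' At every distinct score threshold t, `TPR = |positives with LR > t| /
#' n_pos` and `FPR = |negatives with LR > t| / n_neg`.  Reference pairs with
#' no score are assigned the neutral LR of 1.  The area under the curve is
#' computed by trapezoidal integration over the full step curve, which equals
#' the rank statistic (probability that a random positive outscores a random
#' negative, ties counting one half).
#'
#' @param scores named numeric vector of total LRs (names are canonical pair
#'   keys).
#' @param refs a [reference_sets()] object with role `"evaluate"`.
#' @return list with `curve` (data frame `threshold`, `tpr`, `fpr`) and
#'   `auc`.
#' @export
roc_curve <- function(scores, refs) {
  stopifnot(inherits(refs, "reference_sets"))
  if (refs$role != "evaluate") stop("reference sets must have role 'evaluate'")
  if (length(refs$positives) == 0L || length(refs$negatives) == 0L) {
    stop("ROC requires non-empty positive and negative sets")
  }
  get_lr <- function(keys) {
    lr <- unname(scores[keys])
    lr[is.na(lr)] <- 1
    lr
  }
  pos <- get_lr(refs$positives)
  neg <- get_lr(refs$negatives)
  thr <- sort(unique(c(pos, neg)), decreasing = TRUE)
  tpr <- vapply(thr, function(t) mean(pos > t), numeric(1))
  fpr <- vapply(thr, function(t) mean(neg > t), numeric(1))
  curve <- data.frame(threshold = c(Inf, thr), tpr = c(0, tpr), fpr = c(0, fpr))
  # trapezoid over (fpr, tpr), endpoints (0,0) and (1,1)
  xs <- c(curve$fpr, 1)
  ys <- c(curve$tpr, 1)
  auc <- sum(diff(xs) * (utils::head(ys, -1) + utils::tail(ys, -1)) / 2)
  list(curve = curve, auc = auc)
}

#' Fraction of a pair set recovered above a score threshold
#'
#' Also serves plain overlap counting: `recovery_fraction(set, scores, t) *
#' length(set)` is the number of set members predicted above `t`.  Unscored
#' pairs count with the neutral LR of 1.
#'
#' @param pair_set character vector of canonical pair keys (non-empty).
#' @param scores named numeric vector of LRs.
#' @param threshold strict cutoff.
#' @return fraction in `[0, 1]`.
#' @export
recovery_fraction <- function(pair_set, scores, threshold) {
  if (length(pair_set) == 0L) stop("pair set is empty")
  lr <- unname(scores[pair_set])
  lr[is.na(lr)] <- 1
  mean(lr > threshold)
}

#' Compartment-crossed negative reference pairs
#'
#' Emulates negative-set construction from subcellular localization: sample a
#' quota of proteins per compartment (deterministically for a fixed seed),
#' then emit all cross-compartment pairs listed in `pairing_rules`.  Proteins
#' annotated to more than one of the quota compartments, or listed in
#' `exclusions` (e.g. the positive reference set's proteins), never appear.
#'
#' @param proteins data frame with columns `protein_id`, `compartment` (long
#'   format, one row per annotation).
#' @param quota named integer vector: compartment -> number of proteins to
#'   sample.
#' @param pairing_rules list of length-2 character vectors naming compartment
#'   pairs to cross (e.g. `list(c("membrane","nucleoplasm"))`).
#' @param exclusions character vector of protein ids to drop before sampling.
#' @param seed integer seed; the result is a pure function of inputs + seed.
#' @return character vector of canonical pair keys.
#' @export
build_compartment_negatives <- function(proteins, quota, pairing_rules,
                                        exclusions = character(), seed = 1L) {
  stopifnot(all(c("protein_id", "compartment") %in% names(proteins)))
  quota_comps <- names(quota)
  stopifnot(!is.null(quota_comps), all(quota_comps %in% unique(proteins$compartment)) || TRUE)
  ann <- unique(proteins[proteins$compartment %in% quota_comps,
                         c("protein_id", "compartment")])
  n_ann <- table(ann$protein_id)
  multi <- names(n_ann)[n_ann > 1L]
  ann <- ann[!(ann$protein_id %in% c(multi, exclusions)), ]

  groups <- with_seed(seed, {
    lapply(stats::setNames(quota_comps, quota_comps), function(cmp) {
      pool <- sort(ann$protein_id[ann$compartment == cmp])
      k <- quota[[cmp]]
      if (length(pool) < k) {
        stop(sprintf("compartment '%s' has only %d eligible proteins (quota %d)",
                     cmp, length(pool), k))
      }
      sample(pool, k)
    })
  })
  keys <- unlist(lapply(pairing_rules, function(rule) {
    stopifnot(length(rule) == 2L)
    g1 <- groups[[rule[1L]]]
    g2 <- groups[[rule[2L]]]
    grid <- expand.grid(a = g1, b = g2, stringsAsFactors = FALSE)
    pair_key(grid$a, grid$b)
  }), use.names = FALSE)
  unique(keys)
}

#' Fraction of pairs whose proteins share an annotation label
#'
#' @param pairs character vector of canonical pair keys (non-empty).
#' @param labels named list: protein id -> character vector of labels.
#' @return list with `fraction` (overall) and `per_label` (data frame
#'   `label`, `fraction` of pairs where both proteins carry that label).
#' @export
shared_label_fraction <- function(pairs, labels) {
  if (length(pairs) == 0L) stop("pair set is empty")
  m <- pair_unkey(pairs)
  la <- labels[m[, "a"]]
  lb <- labels[m[, "b"]]
  shared <- mapply(function(x, y) length(intersect(x, y)) > 0L, la, lb)
  all_labels <- sort(unique(unlist(labels)))
  per <- vapply(all_labels, function(l) {
    mean(mapply(function(x, y) (l %in% x) && (l %in% y), la, lb))
  }, numeric(1))
  list(fraction = mean(shared),
       per_label = data.frame(label = all_labels, fraction = unname(per),
                              stringsAsFactors = FALSE))
}

#' Fraction of positive pairs per LR bin
#'
#' The empirical probability that a scored pair belongs to the positive set,
#' as a function of its LR bin (a calibration-style curve).
#'
#' @param scores named numeric vector of LRs.
#' @param positives character vector of canonical pair keys.
#' @param lr_breaks increasing numeric break points defining LR bins (passed
#'   to [numeric_bins()]); must cover the observed LR range.
#' @return data frame `bin`, `n`, `fraction_positive` (`NA` for empty bins).
#' @export
probability_true_vs_lr <- function(scores, positives, lr_breaks) {
  part <- numeric_bins(lr_breaks)
  idx <- bin_index(part, unname(scores))
  if (anyNA(idx)) stop("lr_breaks do not cover the observed LR range")
  is_pos <- names(scores) %in% positives
  n <- tabulate(idx, nbins = n_bins(part))
  npos <- tabulate(idx[is_pos], nbins = n_bins(part))
  data.frame(bin = part$labels, n = n,
             fraction_positive = ifelse(n > 0, npos / n, NA_real_),
             stringsAsFactors = FALSE)
}
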