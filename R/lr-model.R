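#' Reference interaction sets
#'
#' Labelled positive ("high-confidence"-style) and negative pair collections.
#' Positives and negatives must be disjoint.  The role records whether the
#' sets are intended for model training or for evaluation.
#'
#' @param positives,negatives character vectors of canonical pair keys (see
#'   [pair_key()]), or two-column matrices/data frames of protein ids.
#' @param role `"train"` or `"evaluate"`.
#' @return an object of class `reference_sets`.
#' @export
reference_sets <- function(positives, negatives, role = c("train", "evaluate")) {
  role <- match.arg(role)
  as_keys <- function(x) {
    if (is.matrix(x) || is.data.frame(x)) pair_key(x[[1]] %||% x[, 1], x[[2]] %||% x[, 2])
    else as.character(x)
  }
  pos <- unique(as_keys(positives))
  neg <- unique(as_keys(negatives))
  overlap <- intersect(pos, neg)
  if (length(overlap) > 0L) {
    stop("positives and negatives overlap (e.g. ", overlap[1L], ")")
  }
  structure(list(positives = pos, negatives = neg, role = role),
            class = "reference_sets")
}

#' @export
print.reference_sets <- function(x, ...) {
  cat(sprintf("<reference_sets (%s): %d positives, %d negatives>\n",
              x$role, length(x$positives), length(x$negatives)))
  invisible(x)
}

#' Fit a binned likelihood-ratio model for one evidence channel
#'
#' For each bin b the likelihood ratio is the fraction of positive reference
#' pairs whose score falls in b divided by the fraction of negative reference
#' pairs in b.  A per-bin pseudo-count regularizes sparse bins:
#' \deqn{LR_b = \frac{(pos_b + k)/(n_{pos} + Bk)}{(neg_b + k)/(n_{neg} + Bk)}}
#' with B the number of bins and k the pseudo-count.  Pairs in the reference
#' sets that lack a score for this channel are excluded from the channel's
#' counts (evidence coverage is heterogeneous by design).
#'
#' @param channel_scores named vector of channel scores; names are canonical
#'   pair keys.  Categorical channels pass character scores; grid channels
#'   pass a data frame/matrix with rownames set to pair keys.
#' @param refs a [reference_sets()] object with role `"train"`.
#' @param bins a [bin_partition].
#' @param pseudo_count nonnegative per-bin pseudo-count (default 0.5).
#' @param channel channel name stored in the model (informational).
#' @return an object of class `binned_lr_model` with elements `lr`,
#'   `pos_counts`, `neg_counts`, `n_pos`, `n_neg`, `pseudo_count`, `bins`.
#' @examples
#' refs <- reference_sets(pair_key(letters[1:4], LETTERS[1:4]),
#'                        pair_key(letters[5:8], LETTERS[5:8]))
#' sc <- c(1, 2, 1, 1, 9, 9, 9, 2)
#' names(sc) <- c(pair_key(letters[1:4], LETTERS[1:4]),
#'                pair_key(letters[5:8], LETTERS[5:8]))
#' m <- fit_binned_lr(sc, refs, numeric_bins(c(-Inf, 5, Inf)), pseudo_count = 0)
#' lookup_lr(m, 0)   # low-score bin LR
#' @export
fit_binned_lr <- function(channel_scores, refs, bins, pseudo_count = 0.5,
                          channel = "X") {
  stopifnot(inherits(refs, "reference_sets"))
  if (refs$role != "train") stop("reference sets must have role 'train'")
  stopifnot(inherits(bins, "bin_partition"), pseudo_count >= 0)
  if (length(refs$positives) == 0L || length(refs$negatives) == 0L) {
    stop("training requires non-empty positive and negative sets")
  }

  key_of <- function(x) if (is.null(dim(x))) names(x) else rownames(x)
  take <- function(x, keys) {
    i <- match(keys, key_of(x))
    keep <- !is.na(i)
    if (is.null(dim(x))) x[i[keep]] else x[i[keep], , drop = FALSE]
  }
  count_in_bins <- function(scored, who) {
    if (NROW(scored) == 0L) return(integer(n_bins(bins)))
    idx <- bin_index(bins, scored)
    if (anyNA(idx)) {
      bad <- key_of(scored)[which(is.na(idx))[1L]] %||% "<unnamed>"
      stop(sprintf("%s pair '%s' has a %s score outside every bin",
                   who, bad, channel))
    }
    tabulate(idx, nbins = n_bins(bins))
  }

  pos_scored <- take(channel_scores, refs$positives)
  neg_scored <- take(channel_scores, refs$negatives)
  pos_counts <- count_in_bins(pos_scored, "positive")
  neg_counts <- count_in_bins(neg_scored, "negative")
  n_pos <- sum(pos_counts)
  n_neg <- sum(neg_counts)
  if (n_pos == 0L || n_neg == 0L) {
    stop("no scored training pairs in the ", channel,
         " channel for the positive or negative set")
  }

  B <- n_bins(bins)
  p_pos <- (pos_counts + pseudo_count) / (n_pos + B * pseudo_count)
  p_neg <- (neg_counts + pseudo_count) / (n_neg + B * pseudo_count)
  lr <- p_pos / p_neg
  lr[p_neg == 0] <- ifelse(p_pos[p_neg == 0] == 0, 1, Inf)

  structure(list(channel = channel, bins = bins, lr = lr,
                 pos_counts = pos_counts, neg_counts = neg_counts,
                 n_pos = n_pos, n_neg = n_neg, pseudo_count = pseudo_count),
            class = "binned_lr_model")
}

#' @export
print.binned_lr_model <- function(x, ...) {
  cat(sprintf("<binned_lr_model '%s': %d bins, %d pos / %d neg, pseudo = %g>\n",
              x$channel, n_bins(x$bins), x$n_pos, x$n_neg, x$pseudo_count))
  invisible(x)
}

#' Look up the likelihood ratio for a score
#'
#' @param model a [fit_binned_lr()] model.
#' @param score one or more scores bin-assignable under the model's partition.
#' @return numeric vector of per-bin LRs.
#' @export
lookup_lr <- function(model, score) {
  stopifnot(inherits(model, "binned_lr_model"))
  idx <- bin_index(model$bins, score)
  if (anyNA(idx)) stop("score does not map to any bin of channel ", model$channel)
  model$lr[idx]
}

# Total training support (pos + neg count) of the bin a score falls in.
bin_support <- function(model, score) {
  idx <- bin_index(model$bins, score)
  out <- rep(NA_real_, length(idx))
  ok <- !is.na(idx)
  out[ok] <- model$pos_counts[idx[ok]] + model$neg_counts[idx[ok]]
  out
}

#' Combine per-channel likelihood ratios into the final naive-Bayes score
#'
#' The structural-modeling (SM) and protein-peptide (PrP) channels describe
#' mutually exclusive interaction geometries, so only the larger of the two
#' enters the product; all other channels multiply.  Absent channels (`NA` or
#' omitted) contribute a neutral factor 1:
#' \deqn{LR = \max(LR_{SM}, LR_{PrP}) \cdot LR_{PR} \cdot LR_{GO} \cdot
#'   LR_{PP} \cdot LR_{OR} \cdot LR_{EP}}
#' The structural component \eqn{\max(LR_{SM}, LR_{PrP}) \cdot LR_{PR}} is
#' reported separately as `lr_structural` (the criterion for a direct physical
#' interaction).  The partner-redundancy factor is applied once by default;
#' `square_pr = TRUE` applies it twice.
#'
#' @param per_channel_lrs named numeric vector or list with any subset of
#'   `SM`, `PrP`, `PR`, `GO`, `PP`, `OR`, `EP`; `NA` means absent.
#' @param square_pr apply the PR factor twice (default `FALSE`).
#' @return an object of class `combined_score` with `lr_total`,
#'   `lr_structural` and the per-channel LRs.
#' @examples
#' combine_evidence(c(SM = 100, PrP = 50, PR = 2, GO = 3))  # lr_total 600
#' @export
combine_evidence <- function(per_channel_lrs = numeric(), square_pr = FALSE) {
  lrs <- rep(NA_real_, length(PPI_CHANNELS))
  names(lrs) <- PPI_CHANNELS
  if (length(per_channel_lrs) > 0L) {
    v <- unlist(per_channel_lrs)
    unknown <- setdiff(names(v), PPI_CHANNELS)
    if (length(unknown) > 0L) stop("unknown channel(s): ", paste(unknown, collapse = ", "))
    lrs[names(v)] <- as.numeric(v)
  }
  if (any(!is.na(lrs) & lrs < 0)) stop("likelihood ratios must be nonnegative")

  f <- function(x) ifelse(is.na(x), 1, x)  # absent channel -> neutral factor
  sm_prp <- if (is.na(lrs["SM"]) && is.na(lrs["PrP"])) 1 else max(lrs["SM"], lrs["PrP"], na.rm = TRUE)
  pr <- f(lrs["PR"])
  lr_structural <- unname(sm_prp * pr)
  lr_total <- unname(sm_prp * pr^(if (square_pr) 2 else 1) *
                     f(lrs["GO"]) * f(lrs["PP"]) * f(lrs["OR"]) * f(lrs["EP"]))
  structure(list(lr_total = lr_total, lr_structural = lr_structural,
                 channels = lrs), class = "combined_score")
}

#' @export
print.combined_score <- function(x, ...) {
  cat(sprintf("<combined_score: lr_total = %.6g, lr_structural = %.6g>\n",
              x$lr_total, x$lr_structural))
  invisible(x)
}

#' Vectorized evidence combination over a table of per-channel LRs
#'
#' @param lr_table data frame with any subset of columns `SM`, `PrP`, `PR`,
#'   `GO`, `PP`, `OR`, `EP` (`NA` = absent for that pair).
#' @inheritParams combine_evidence
#' @return data frame with columns `lr_total` and `lr_structural`.
#' @export
combine_evidence_df <- function(lr_table, square_pr = FALSE) {
  lr_table <- as.data.frame(lr_table)
  get_col <- function(ch) {
    if (ch %in% names(lr_table)) as.numeric(lr_table[[ch]]) else rep(NA_real_, nrow(lr_table))
  }
  cols <- lapply(PPI_CHANNELS, get_col)
  names(cols) <- PPI_CHANNELS
  if (any(vapply(cols, function(x) any(!is.na(x) & x < 0), logical(1)))) {
    stop("likelihood ratios must be nonnegative")
  }
  f <- function(x) ifelse(is.na(x), 1, x)
  # max over present SM/PrP (absent treated as -Inf, both absent -> 1)
  sm <- ifelse(is.na(cols$SM), -Inf, cols$SM)
  pp <- ifelse(is.na(cols$PrP), -Inf, cols$PrP)
  sm_prp <- pmax(sm, pp)
  sm_prp[sm_prp == -Inf] <- 1
  pr <- f(cols$PR)
  lr_structural <- sm_prp * pr
  lr_total <- sm_prp * pr^(if (square_pr) 2 else 1) *
    f(cols$GO) * f(cols$PP) * f(cols$OR) * f(cols$EP)
  data.frame(lr_total = lr_total, lr_structural = lr_structural)
}

#' Reliability call for a combined score
#'
#' A prediction is "reliable" when its total likelihood ratio strictly
#' exceeds the cutoff (default 600, the value at which a random reference
#' pair set is essentially never recovered).
#'
#' @param score a `combined_score` or a numeric vector of total LRs.
#' @param threshold positive cutoff (default 600); the comparison is strict.
#' @return logical vector.
#' @export
classify_reliable <- function(score, threshold = 600) {
  stopifnot(threshold > 0)
  lr <- if (inherits(score, "combined_score")) score$lr_total else as.numeric(score)
  lr > threshold
}

# --- model serialization -----------------------------------------------------

#' Serialize / restore binned LR models as JSON
#'
#' Models (or named lists of models, nested one level for the orthology
#' backoff family and the partner-redundancy pair) round-trip through a plain
#' JSON representation holding bins, LRs, training counts and pseudo-count.
#'
#' @param model a `binned_lr_model` or a (possibly nested) named list of them.
#' @param path file path.
#' @name model_io
#' @export
write_models_json <- function(model, path) {
  enc <- function(x) {
    if (inherits(x, "binned_lr_model")) {
      list(.class = "binned_lr_model", channel = x$channel,
           bins = partition_to_list(x$bins), lr = x$lr,
           pos_counts = x$pos_counts, neg_counts = x$neg_counts,
           n_pos = x$n_pos, n_neg = x$n_neg, pseudo_count = x$pseudo_count)
    } else if (is.list(x)) {
      lapply(x, enc)
    } else x
  }
  jsonlite::write_json(enc(model), path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname model_io
#' @export
read_models_json <- function(path) {
  dec <- function(x) {
    if (is.list(x) && identical(x$.class, "binned_lr_model")) {
      structure(list(channel = x$channel, bins = partition_from_list(x$bins),
                     lr = as.numeric(unlist(x$lr)),
                     pos_counts = as.numeric(unlist(x$pos_counts)),
                     neg_counts = as.numeric(unlist(x$neg_counts)),
                     n_pos = x$n_pos, n_neg = x$n_neg,
                     pseudo_count = x$pseudo_count),
                class = "binned_lr_model")
    } else if (is.list(x)) {
      lapply(x, dec)
    } else x
  }
  dec(jsonlite::read_json(path))
}
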