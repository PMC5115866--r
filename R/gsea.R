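#' Rank a query protein's interactors by LR
#'
#' All proteins with a score against the query are sorted by descending LR
#' (ties broken lexicographically by id); proteins of `universe` without a
#' score are appended with the neutral LR of 1.  The query never appears in
#' its own list.
#'
#' @param query protein id.
#' @param scores named numeric vector of LRs keyed by canonical pair key.
#' @param universe optional character vector of all protein ids.
#' @return data frame `protein`, `lr`, sorted; class `ranked_interactors`
#'   with the query stored as an attribute.
#' @export
rank_interactors <- function(query, scores, universe = NULL) {
  keys <- names(scores)
  m <- pair_unkey(keys)
  sel <- (m[, "a"] == query) != (m[, "b"] == query)  # xor: exclude self-pairs
  partner <- ifelse(m[sel, "a"] == query, m[sel, "b"], m[sel, "a"])
  lr <- unname(scores[sel])
  best <- tapply(lr, partner, max)
  df <- data.frame(protein = names(best), lr = unname(best),
                   stringsAsFactors = FALSE)
  if (!is.null(universe)) {
    extra <- setdiff(setdiff(universe, query), df$protein)
    if (length(extra) > 0L) {
      df <- rbind(df, data.frame(protein = extra, lr = 1))
    }
  }
  df <- df[order(-df$lr, df$protein), , drop = FALSE]
  rownames(df) <- NULL
  structure(df, query = query, class = c("ranked_interactors", "data.frame"))
}

# Per-item running-sum weights for a ranked list.
gsea_item_weights <- function(lr, weight_mode = c("log10", "raw", "rank"),
                              weight_exponent = 1) {
  weight_mode <- match.arg(weight_mode)
  w <- switch(weight_mode,
    log10 = pmax(log10(pmax(lr, 1)), 0),
    raw = pmax(lr, 0),
    rank = rep(1, length(lr))
  )
  abs(w)^weight_exponent
}

#' Weighted running-sum enrichment score
#'
#' Walking down the ranked list, each gene-set hit increments the running sum
#' by its weight (normalized by the total hit weight) and each miss
#' decrements it by `1/(N - N_hits)`; the enrichment score is the maximum
#' signed deviation from zero.  Weights default to `log10(max(lr, 1))`, which
#' keeps a single extreme LR from dominating the walk; when every hit weight
#' is zero (e.g. all LRs at the neutral 1) hits fall back to equal weights so
#' that the statistic remains defined.
#'
#' @param ranked a [rank_interactors()] result or a data frame with columns
#'   `protein`, `lr`, already sorted.
#' @param set_members character vector of gene-set member ids.
#' @param weight_exponent exponent applied to the weights (default 1).
#' @param weight_mode `"log10"` (default), `"raw"`, or `"rank"` (unweighted).
#' @return signed enrichment score in `[-1, 1]`.
#' @export
enrichment_score <- function(ranked, set_members, weight_exponent = 1,
                             weight_mode = "log10") {
  hits <- ranked$protein %in% set_members
  if (!any(hits)) stop("no gene-set member present in the ranking universe")
  w <- gsea_item_weights(ranked$lr, weight_mode, weight_exponent)
  .es_core(hits, w)
}

# Running-sum core shared by the observed statistic and the permutation null.
.es_core <- function(hits, w) {
  n <- length(hits)
  nh <- sum(hits)
  if (nh == n) return(1)
  wh <- w * hits
  tot <- sum(wh)
  if (tot == 0) {
    wh <- as.numeric(hits)
    tot <- nh
  }
  run <- cumsum(wh / tot - (!hits) / (n - nh))
  run[which.max(abs(run))]
}

# ES from hit positions only; used by the permutation loop (O(n_hits)).
.es_from_positions <- function(pos, w, n) {
  nh <- length(pos)
  if (nh == n) return(1)
  pos <- sort(pos)
  wh <- w[pos]
  tot <- sum(wh)
  if (tot == 0) {
    wh <- rep(1, nh)
    tot <- nh
  }
  cum_hit <- cumsum(wh) / tot
  miss_step <- 1 / (n - nh)
  after <- cum_hit - (pos - seq_len(nh)) * miss_step           # just after each hit
  before <- c(0, cum_hit[-nh]) - (pos - seq_len(nh)) * miss_step  # just before
  es_pos <- max(after)
  es_neg <- min(before)
  if (abs(es_pos) >= abs(es_neg)) es_pos else es_neg
}

#' Gene-set enrichment analysis of a ranked interactor list
#'
#' Nominal p-values come from a gene-label permutation null: each permutation
#' shuffles which positions of the ranking are hits (equivalently, permutes
#' the gene labels) and recomputes the enrichment score for every set; the
#' one-sided p-value counts permuted scores at least as large as the observed
#' one (with the +1 correction).  q-values are Benjamini-Hochberg across the
#' tested sets; sets with `q < q_threshold` are flagged enriched.  Results
#' are sorted by decreasing enrichment score.
#'
#' @inheritParams enrichment_score
#' @param sets named list of character vectors (gene sets), or a list with
#'   `members` and `term` fields per set as returned by [read_gmt()].
#' @param n_permutations number of label permutations (>= 100; default 1000).
#' @param seed integer seed for the permutation stream.
#' @param q_threshold enrichment FDR cutoff (default 0.01).
#' @return data frame `set`, `term`, `es`, `p`, `q`, `enriched`, `rank`.
#' @export
enrichment_analysis <- function(ranked, sets, n_permutations = 1000L, seed = 1L,
                                q_threshold = 0.01, weight_exponent = 1,
                                weight_mode = "log10") {
  stopifnot(n_permutations >= 100L)
  members <- lapply(sets, function(s) if (is.list(s)) s$members else s)
  terms <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    if (is.list(s) && !is.null(s$term)) s$term else names(sets)[i]
  }, character(1))

  n <- nrow(ranked)
  w <- gsea_item_weights(ranked$lr, weight_mode, weight_exponent)
  hit_idx <- lapply(members, function(mem) which(ranked$protein %in% mem))
  usable <- lengths(hit_idx) > 0L
  es_obs <- rep(NA_real_, length(sets))
  es_obs[usable] <- vapply(hit_idx[usable], .es_from_positions, numeric(1),
                           w = w, n = n)

  sizes <- lengths(hit_idx)
  p <- rep(NA_real_, length(sets))
  exceed <- integer(length(sets))
  with_seed(seed, {
    for (b in seq_len(n_permutations)) {
      perm <- sample.int(n)
      for (i in which(usable)) {
        es_b <- .es_from_positions(perm[seq_len(sizes[i])], w, n)
        if (es_b >= es_obs[i]) exceed[i] <- exceed[i] + 1L
      }
    }
  })
  p[usable] <- (1 + exceed[usable]) / (n_permutations + 1)
  q <- rep(NA_real_, length(sets))
  q[usable] <- stats::p.adjust(p[usable], method = "BH")

  out <- data.frame(set = names(sets) %||% paste0("set", seq_along(sets)),
                    term = terms, es = es_obs, p = p, q = q,
                    enriched = !is.na(q) & q < q_threshold,
                    stringsAsFactors = FALSE)
  out <- out[order(-ifelse(is.na(out$es), -Inf, out$es), out$set), , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Rank of the first correct annotation
#'
#' Scans the sorted enrichment results for the first gene set whose
#' associated term belongs to the query's known annotations.
#'
#' @param results data frame from [enrichment_analysis()] (sorted, with
#'   `term` and `rank` columns).
#' @param true_terms character vector of accepted annotation terms.
#' @return 1-based rank (integer), or `NA` if no result matches.
#' @export
first_correct_rank <- function(results, true_terms) {
  hit <- which(results$term %in% true_terms)
  if (length(hit) == 0L) return(NA_integer_)
  results$rank[hit[1L]]
}
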