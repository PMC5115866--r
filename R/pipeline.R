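#' Train all channel models on a world's training references
#'
#' Continuous supplied channels (SM, PrP, GO, PP) and the expression score
#' (EP) are discretized by equal-frequency quantile bins of the training
#' pool; the orthology channel trains the full backoff family of categorical
#' vector models; partner redundancy trains the two-network pair.
#'
#' @param world a `ppi_world` from [generate_world()] (or any list exposing
#'   the same elements).
#' @param n_bins quantile bins per continuous channel (default 10).
#' @param pseudo_count per-bin pseudo-count (default 0.5).
#' @return named list of models: one `binned_lr_model` per continuous
#'   channel and `EP`, plus `OR` (backoff family) and `PR` (first/second).
#' @export
train_models <- function(world, n_bins = 10L, pseudo_count = 0.5) {
  refs <- world$refs_train
  ev <- world$evidence
  keys <- pair_key(ev$protein_a, ev$protein_b)
  train_keys <- c(refs$positives, refs$negatives)

  models <- list()
  for (ch in intersect(c("SM", "PrP", "GO", "PP"), names(ev))) {
    sc <- stats::setNames(ev[[ch]], keys)
    sc <- sc[!is.na(sc)]
    pool <- sc[names(sc) %in% train_keys]
    models[[ch]] <- fit_binned_lr(sc, refs, quantile_bins(pool, n_bins),
                                  pseudo_count, channel = ch)
  }
  ep <- world$ep[!is.na(world$ep)]
  ep_pool <- ep[names(ep) %in% train_keys]
  models$EP <- fit_binned_lr(ep, refs, quantile_bins(ep_pool, n_bins),
                             pseudo_count, channel = "EP")
  models$OR <- fit_orthology_models(world$or_vectors, refs, pseudo_count)
  models$PR <- fit_pr_models(world$pr_features, refs, pseudo_count = pseudo_count)
  models
}

#' Score every candidate pair of a world
#'
#' Looks up each channel's LR (neutral where evidence is absent), applies the
#' orthology dimensional backoff and the partner-redundancy two-network
#' fallback, and combines the channels into total and structural LRs.  The
#' asymmetric partner-redundancy features are evaluated in both pair
#' orientations and the larger LR is kept, so scores respect unordered-pair
#' symmetry.
#'
#' @param world a `ppi_world`.
#' @param models model list from [train_models()].
#' @param min_support minimum bin training support for the orthology backoff
#'   and the first partner-redundancy network (default 10).
#' @param reliable_threshold strict LR cutoff for the `reliable` flag
#'   (default 600).
#' @param square_pr see [combine_evidence()].
#' @return data frame: `pair`, `protein_a`, `protein_b`, one `lr_<channel>`
#'   column per channel, `lr_total`, `lr_structural`, `reliable`.
#' @export
score_pairs <- function(world, models, min_support = 10,
                        reliable_threshold = 600, square_pr = FALSE) {
  ev <- world$evidence
  keys <- pair_key(ev$protein_a, ev$protein_b)
  lr_tab <- data.frame(row.names = seq_along(keys))

  for (ch in intersect(c("SM", "PrP", "GO", "PP"), names(models))) {
    val <- ev[[ch]]
    lr <- rep(NA_real_, length(val))
    ok <- !is.na(val)
    lr[ok] <- lookup_lr(models[[ch]], val[ok])
    lr_tab[[ch]] <- lr
  }
  ep <- unname(world$ep[keys])
  lr_ep <- rep(NA_real_, length(keys))
  ok <- !is.na(ep)
  lr_ep[ok] <- lookup_lr(models$EP, ep[ok])
  lr_tab$EP <- lr_ep

  lr_tab$OR <- score_orthology(world$or_vectors[keys, , drop = FALSE],
                               models$OR, min_support)

  fx <- world$pr_features[keys, , drop = FALSE]
  has_s <- stats::setNames(world$proteins$has_structure, world$proteins$protein_id)
  fwd <- score_pr(data.frame(n = fx$n, d = fx$d, m = fx$m), models$PR,
                  min_support, b_has_structure = unname(has_s[ev$protein_b]))
  bwd <- score_pr(data.frame(n = fx$n_rev, d = fx$d_rev, m = fx$m), models$PR,
                  min_support, b_has_structure = unname(has_s[ev$protein_a]))
  lr_tab$PR <- pmax(as.numeric(fwd), as.numeric(bwd))

  comb <- combine_evidence_df(lr_tab, square_pr = square_pr)
  out <- data.frame(pair = keys, protein_a = ev$protein_a,
                    protein_b = ev$protein_b, stringsAsFactors = FALSE)
  for (ch in names(lr_tab)) out[[paste0("lr_", ch)]] <- lr_tab[[ch]]
  out$lr_total <- comb$lr_total
  out$lr_structural <- comb$lr_structural
  out$reliable <- classify_reliable(comb$lr_total, reliable_threshold)
  out
}

#' Extract a named LR vector from a score table
#'
#' @param score_table result of [score_pairs()].
#' @param column which LR column to extract (default `"lr_total"`).
#' @return named numeric vector keyed by canonical pair key, as consumed by
#'   the evaluation and annotation functions.
#' @export
score_map <- function(score_table, column = "lr_total") {
  stats::setNames(score_table[[column]], score_table$pair)
}
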