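#' Orthology-evidence sources
#'
#' Orthology evidence is drawn from four source groups: the `gopher`, `oma`
#' and `kegg` databases plus the pooled `union_group` of the remaining
#' orthology resources.  For a protein pair, each source contributes the
#' number of distinct species in which some ortholog of one protein is
#' reported to interact with some ortholog of the other; counts are encoded
#' per source as 0, 1 or ">1" (stored as 2), forming a four-component
#' interaction vector.
#'
#' @name orthology_evidence
NULL

#' @rdname orthology_evidence
#' @format `ORTHOLOGY_SOURCES` is the fixed source order of vector
#'   components.
#' @export
ORTHOLOGY_SOURCES <- c("gopher", "oma", "kegg", "union_group")

#' Count species with an orthologous interaction for one pair
#'
#' @param a,b protein ids.
#' @param ortholog_map data frame with columns `protein_id`, `species`,
#'   `ortholog_id` (one orthology source).
#' @param interactions data frame of interactions observed in other species,
#'   columns `species`, `protein_1`, `protein_2` (ortholog ids).
#' @return integer: number of distinct species in which some ortholog of `a`
#'   interacts with some ortholog of `b`.  A protein absent from the map
#'   yields 0.
#' @export
count_orthologous_interactions <- function(a, b, ortholog_map, interactions) {
  oa <- ortholog_map[ortholog_map$protein_id == a, c("species", "ortholog_id")]
  ob <- ortholog_map[ortholog_map$protein_id == b, c("species", "ortholog_id")]
  if (nrow(oa) == 0L || nrow(ob) == 0L) return(0L)
  cand <- merge(oa, ob, by = "species", suffixes = c("_a", "_b"))
  cand <- cand[cand$ortholog_id_a != cand$ortholog_id_b, , drop = FALSE]
  if (nrow(cand) == 0L) return(0L)
  known <- unique(paste(interactions$species,
                        pair_key(interactions$protein_1, interactions$protein_2),
                        sep = "@"))
  probe <- paste(cand$species, pair_key(cand$ortholog_id_a, cand$ortholog_id_b),
                 sep = "@")
  length(unique(cand$species[probe %in% known]))
}

#' Encode per-source species counts as an orthology vector
#'
#' Counts map 0 -> 0, 1 -> 1, and anything larger -> 2 (the ">1" level).
#'
#' @param counts_per_source integer vector of four nonnegative counts, in
#'   [ORTHOLOGY_SOURCES] order.
#' @return integer vector of components in `{0, 1, 2}` named by source.
#' @export
orthology_vector <- function(counts_per_source) {
  stopifnot(length(counts_per_source) == length(ORTHOLOGY_SOURCES),
            all(counts_per_source >= 0))
  stats::setNames(pmin(as.integer(counts_per_source), 2L), ORTHOLOGY_SOURCES)
}

# Bin label of a vector restricted to a source subset, e.g. "1,2,0".
orthology_bin_label <- function(vectors, subset) {
  m <- matrix(as.integer(vectors), ncol = length(ORTHOLOGY_SOURCES))
  apply(m[, subset, drop = FALSE], 1L, paste, collapse = ",")
}

# All 3^k component combinations for a subset of sources.
orthology_bin_levels <- function(subset) {
  combos <- expand.grid(rep(list(0:2), length(subset)))[, rev(seq_along(subset)), drop = FALSE]
  apply(combos, 1L, paste, collapse = ",")
}

#' Default backoff priority over source subsets
#'
#' The full four-source model is consulted first; on insufficient support the
#' search backs off through all three-source subsets, then two-, then
#' one-source subsets, each level in fixed lexicographic order over
#' [ORTHOLOGY_SOURCES] indices.  The order is arbitrary but deterministic and
#' documented, so scoring is reproducible.
#'
#' @return list of integer index vectors into [ORTHOLOGY_SOURCES].
#' @export
orthology_backoff_order <- function() {
  out <- list()
  for (k in 4:1) {
    cs <- utils::combn(4L, k)
    for (j in seq_len(ncol(cs))) out[[length(out) + 1L]] <- cs[, j]
  }
  out
}

#' Train the orthology model family
#'
#' Fits one categorical binned-LR model per source subset in the backoff
#' order, all from the same training reference sets.  The bin domain of each
#' model is the full set of component combinations for its subset, so every
#' vector maps to a bin.
#'
#' @param vectors matrix (pairs x 4 sources) of vector components in
#'   `{0,1,2}` with rownames set to canonical pair keys, as produced by
#'   [orthology_vector_table()].
#' @param refs training [reference_sets()].
#' @param pseudo_count per-bin pseudo-count (see [fit_binned_lr()]).
#' @param subsets list of source-index subsets (default
#'   [orthology_backoff_order()]).
#' @return named list of `binned_lr_model`s keyed by subset label (e.g.
#'   `"gopher+oma+kegg"`).
#' @export
fit_orthology_models <- function(vectors, refs, pseudo_count = 0.5,
                                 subsets = orthology_backoff_order()) {
  stopifnot(is.matrix(vectors), ncol(vectors) == 4L, !is.null(rownames(vectors)))
  models <- lapply(subsets, function(ss) {
    scores <- stats::setNames(orthology_bin_label(vectors, ss), rownames(vectors))
    fit_binned_lr(scores, refs, categorical_bins(orthology_bin_levels(ss)),
                  pseudo_count = pseudo_count,
                  channel = paste0("OR[", paste(ORTHOLOGY_SOURCES[ss], collapse = "+"), "]"))
  })
  names(models) <- vapply(subsets, function(ss)
    paste(ORTHOLOGY_SOURCES[ss], collapse = "+"), character(1))
  attr(models, "subsets") <- subsets
  models
}

#' Score an orthology vector with dimensional backoff
#'
#' Consults the highest-dimensional model first; when the training support
#' (positive + negative count) of the vector's bin falls below `min_support`,
#' backs off through the configured lower-dimensional subsets until a
#' supported bin is found.  With no supported bin at any dimension the
#' evidence is neutral (LR 1).
#'
#' @param vector integer vector of four components in `{0,1,2}` (see
#'   [orthology_vector()]), or a pairs-by-4 matrix for vectorized scoring.
#' @param models model family from [fit_orthology_models()].
#' @param min_support minimum bin training count (default 10).
#' @return numeric LR (vector when a matrix is supplied).
#' @export
score_orthology <- function(vector, models, min_support = 10) {
  subsets <- attr(models, "subsets") %||% orthology_backoff_order()
  m <- if (is.matrix(vector)) vector else matrix(as.integer(vector), nrow = 1L)
  out <- rep(1, nrow(m))
  resolved <- rep(FALSE, nrow(m))
  for (j in seq_along(models)) {
    if (all(resolved)) break
    lab <- orthology_bin_label(m[!resolved, , drop = FALSE], subsets[[j]])
    sup <- bin_support(models[[j]], lab)
    ok <- !is.na(sup) & sup >= min_support
    if (any(ok)) {
      idx <- which(!resolved)[ok]
      out[idx] <- lookup_lr(models[[j]], lab[ok])
      resolved[idx] <- TRUE
    }
  }
  out
}

#' Orthology vectors for a table of pairs
#'
#' Vectorized computation of [count_orthologous_interactions()] across all
#' four sources: for each pair and source, the number of distinct species in
#' which orthologs of the two proteins are reported to interact, encoded
#' through [orthology_vector()].
#'
#' @param pairs data frame with columns `protein_a`, `protein_b`.
#' @param ortholog_maps named list of per-source ortholog maps (data frames
#'   `protein_id`, `species`, `ortholog_id`) keyed by [ORTHOLOGY_SOURCES].
#' @param interactions data frame `species`, `protein_1`, `protein_2`.
#' @return integer matrix (pairs x 4) of components in `{0,1,2}`, rownames =
#'   canonical pair keys.
#' @export
orthology_vector_table <- function(pairs, ortholog_maps, interactions) {
  stopifnot(all(ORTHOLOGY_SOURCES %in% names(ortholog_maps)))
  keys <- pair_key(pairs$protein_a, pairs$protein_b)
  out <- matrix(0L, nrow = length(keys), ncol = length(ORTHOLOGY_SOURCES),
                dimnames = list(keys, ORTHOLOGY_SOURCES))
  ia <- unique(data.frame(species = as.character(interactions$species),
                          o1 = as.character(interactions$protein_1),
                          o2 = as.character(interactions$protein_2),
                          stringsAsFactors = FALSE))
  ia <- ia[ia$o1 != ia$o2, , drop = FALSE]
  if (nrow(ia) == 0L) return(out)
  for (src in ORTHOLOGY_SOURCES) {
    map <- ortholog_maps[[src]]
    # map interactions back to human pairs via the (species, ortholog) owners
    owner_key <- paste(map$species, map$ortholog_id, sep = "@")
    owners <- split(as.character(map$protein_id), owner_key)
    o1_owners <- owners[paste(ia$species, ia$o1, sep = "@")]
    o2_owners <- owners[paste(ia$species, ia$o2, sep = "@")]
    l1 <- lengths(o1_owners)
    l2 <- lengths(o2_owners)
    n_comb <- l1 * l2
    if (sum(n_comb) == 0L) next
    row_id <- rep(seq_len(nrow(ia)), n_comb)
    p1 <- unlist(mapply(function(x, y) rep(x, times = length(y)),
                        o1_owners, o2_owners, SIMPLIFY = FALSE), use.names = FALSE)
    p2 <- unlist(mapply(function(x, y) rep(y, each = length(x)),
                        o1_owners, o2_owners, SIMPLIFY = FALSE), use.names = FALSE)
    ok <- p1 != p2
    if (!any(ok)) next
    hit <- unique(data.frame(key = pair_key(p1[ok], p2[ok]),
                             species = ia$species[row_id[ok]],
                             stringsAsFactors = FALSE))
    counts <- table(hit$key)  # distinct species per human pair
    got <- counts[keys]
    got[is.na(got)] <- 0L
    out[, src] <- pmin(as.integer(got), 2L)
  }
  out
}
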