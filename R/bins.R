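#' Bin partitions for evidence channels
#'
#' Every evidence channel is discretized into a finite, exhaustive, mutually
#' exclusive set of bins before likelihood-ratio estimation.  Three partition
#' flavours cover the channels used here:
#'
#' * **categorical** — labelled bins matched by exact value (used for the
#'   orthology interaction vectors, where a bin is a discrete vector such as
#'   `"1,2,0,0"`);
#' * **numeric** — intervals over the real line defined by break points (used
#'   for continuous supplied scores: structural-modeling, protein-peptide,
#'   gene-ontology, phylogenetic-profile, expression);
#' * **grid** — a cross product of per-dimension closed integer ranges (used
#'   for the partner-redundancy `(n, d)` and `m` bins, e.g. the bin
#'   `([2,5],[0,100])`).
#'
#' @name bin_partition
NULL

new_bin_partition <- function(type, labels, ...) {
  structure(list(type = type, labels = labels, ...), class = "bin_partition")
}

#' @describeIn bin_partition Categorical partition over explicit levels.
#' @param levels character vector of bin labels (the full score domain).
#' @export
categorical_bins <- function(levels) {
  levels <- as.character(levels)
  stopifnot(length(levels) > 0L, !anyDuplicated(levels))
  new_bin_partition("categorical", labels = levels)
}

#' @describeIn bin_partition Interval partition from sorted break points.
#'   Bins are `[b1,b2], (b2,b3], ...` (first interval closed on both ends);
#'   pass `-Inf`/`Inf` end points for an exhaustive partition of the line.
#' @param breaks strictly increasing numeric vector of length >= 2.
#' @export
numeric_bins <- function(breaks) {
  breaks <- as.numeric(breaks)
  stopifnot(length(breaks) >= 2L, !is.unsorted(breaks, strictly = TRUE))
  labels <- paste0(
    ifelse(seq_len(length(breaks) - 1L) == 1L, "[", "("),
    format(breaks[-length(breaks)], trim = TRUE), ",",
    format(breaks[-1L], trim = TRUE), "]"
  )
  new_bin_partition("numeric", labels = labels, breaks = breaks)
}

#' @describeIn bin_partition Equal-frequency interval partition estimated from
#'   a training pool; outer edges widened to `+/-Inf` so any later score maps
#'   to a bin.  Duplicate quantiles collapse, so fewer than `n` bins may
#'   result.
#' @param x numeric training scores.
#' @param n target number of bins (default 10).
#' @export
quantile_bins <- function(x, n = 10L) {
  x <- x[is.finite(x)]
  stopifnot(length(x) > 0L, n >= 1L)
  qs <- unique(stats::quantile(x, probs = seq(0, 1, length.out = n + 1L),
                               names = FALSE, type = 7))
  if (length(qs) < 2L) qs <- c(qs, qs + 1)
  qs[1L] <- -Inf
  qs[length(qs)] <- Inf
  numeric_bins(qs)
}

#' @describeIn bin_partition Cross product of per-dimension closed integer
#'   ranges.  `dims` is a named list; each element is a list of `c(lo, hi)`
#'   ranges (use `Inf` for an open upper end).  Ranges within a dimension must
#'   be disjoint and, jointly, cover all nonnegative integers that can occur.
#' @param dims named list of range lists, e.g.
#'   `list(n = list(c(0,0), c(1,1), c(2,5), c(6,Inf)))`.
#' @export
grid_bins <- function(dims) {
  stopifnot(is.list(dims), length(dims) >= 1L, !is.null(names(dims)))
  fmt_range <- function(r) {
    stopifnot(length(r) == 2L, r[1] <= r[2])
    if (r[1] == r[2]) format(r[1], trim = TRUE)
    else paste0("[", format(r[1], trim = TRUE), ",", format(r[2], trim = TRUE), "]")
  }
  dim_labels <- lapply(dims, function(rs) vapply(rs, fmt_range, character(1)))
  combos <- expand.grid(rev(dim_labels), stringsAsFactors = FALSE)[, rev(seq_along(dims)), drop = FALSE]
  labels <- apply(combos, 1L, paste, collapse = "x")
  new_bin_partition("grid", labels = labels, dims = dims)
}

#' Number of bins in a partition
#' @param partition a [bin_partition] object.
#' @export
n_bins <- function(partition) {
  stopifnot(inherits(partition, "bin_partition"))
  length(partition$labels)
}

# First range index containing each value, NA if none.
.range_index <- function(values, ranges) {
  idx <- rep(NA_integer_, length(values))
  for (i in seq_along(ranges)) {
    hit <- is.na(idx) & values >= ranges[[i]][1] & values <= ranges[[i]][2]
    idx[hit] <- i
  }
  idx
}

#' Assign scores to bins
#'
#' @param partition a [bin_partition].
#' @param scores for categorical partitions a character vector; for numeric
#'   partitions a numeric vector; for grid partitions a matrix or data frame
#'   with one column per dimension (in partition order).
#' @return integer vector of bin indices, `NA` where a score falls outside the
#'   partition.
#' @export
bin_index <- function(partition, scores) {
  stopifnot(inherits(partition, "bin_partition"))
  switch(partition$type,
    categorical = match(as.character(scores), partition$labels),
    numeric = {
      x <- as.numeric(scores)
      i <- findInterval(x, partition$breaks, left.open = TRUE, rightmost.closed = FALSE)
      i[!is.na(x) & x == partition$breaks[1L]] <- 1L  # closed lower end of first bin
      i[i < 1L | i >= length(partition$breaks)] <- NA_integer_
      i
    },
    grid = {
      m <- as.matrix(as.data.frame(scores))
      stopifnot(ncol(m) == length(partition$dims))
      sizes <- vapply(partition$dims, length, integer(1))
      idx_by_dim <- lapply(seq_along(partition$dims), function(j) {
        .range_index(as.numeric(m[, j]), partition$dims[[j]])
      })
      # row-major: first dimension varies slowest
      out <- rep(1L, nrow(m))
      for (j in seq_along(partition$dims)) {
        mult <- if (j < length(sizes)) prod(sizes[(j + 1L):length(sizes)]) else 1L
        out <- out + (idx_by_dim[[j]] - 1L) * as.integer(mult)
      }
      out[Reduce(`|`, lapply(idx_by_dim, is.na))] <- NA_integer_
      out
    },
    stop("unknown partition type: ", partition$type)
  )
}

#' @export
print.bin_partition <- function(x, ...) {
  cat(sprintf("<bin_partition: %s, %d bins>\n", x$type, n_bins(x)))
  utils::head(x$labels, 12L) |> paste(collapse = ", ") |> cat("\n")
  invisible(x)
}

# --- serialization -----------------------------------------------------------

partition_to_list <- function(p) {
  out <- list(type = p$type, labels = p$labels)
  if (p$type == "numeric") out$breaks <- p$breaks
  if (p$type == "grid") out$dims <- lapply(p$dims, function(rs) lapply(rs, as.numeric))
  out
}

partition_from_list <- function(x) {
  switch(x$type,
    categorical = categorical_bins(unlist(x$labels)),
    numeric = numeric_bins(unlist(x$breaks)),
    grid = grid_bins(lapply(x$dims, function(rs) lapply(rs, unlist))),
    stop("unknown partition type in JSON: ", x$type)
  )
}
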