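#' Canonical unordered pair keys
#'
#' A protein pair is identified by an unordered key: the two ids joined by
#' `"|"` after lexicographic sorting, so `pair_key("B","A") == pair_key("A","B")`.
#' Protein ids must therefore not contain the `"|"` character.
#'
#' @param a,b character vectors of protein ids (recycled to common length).
#' @return character vector of canonical keys.
#' @examples
#' pair_key("TP53", "MDM2")
#' pair_key(c("b", "a"), c("a", "b"))  # identical keys
#' @export
pair_key <- function(a, b) {
  a <- as.character(a)
  b <- as.character(b)
  stopifnot(length(a) == length(b) || length(a) == 1L || length(b) == 1L)
  if (any(grepl("|", c(a, b), fixed = TRUE))) {
    stop("protein ids must not contain the '|' character")
  }
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

#' Split canonical pair keys back into a two-column matrix
#' @param keys character vector of keys produced by [pair_key()].
#' @return character matrix with columns `a`, `b`.
#' @export
pair_unkey <- function(keys) {
  if (length(keys) == 0L) {
    return(matrix(character(), ncol = 2L, dimnames = list(NULL, c("a", "b"))))
  }
  parts <- strsplit(keys, "|", fixed = TRUE)
  m <- matrix(unlist(parts), ncol = 2L, byrow = TRUE)
  colnames(m) <- c("a", "b")
  m
}

# Evidence channels in combination order.  SM/PrP compete via max; the rest
# multiply.
PPI_CHANNELS <- c("SM", "PrP", "PR", "GO", "PP", "OR", "EP")

# Run code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards.  All seeded operations in the package go
# through this so that library calls never perturb user RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      get(".Random.seed", globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed) %% .Machine$integer.max)
  }
  force(code)
}

# Derive a reproducible child seed from a base seed and a stream label,
# staying below 2^31.
child_seed <- function(seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  (as.integer(seed) * 1009L + as.integer(h %% 100003L)) %% 2147483587L
}

`%||%` <- function(x, y) if (is.null(x)) y else x
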