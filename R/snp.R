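#' Variant-interface contingency table
#'
#' 2x2 classification of protein residues by interface membership and
#' mutation status, used to test whether variants concentrate in predicted
#' interaction interfaces.  Cells follow the convention: `n11` interfacial
#' mutated, `n10` non-interfacial mutated, `n01` interfacial unmutated,
#' `n00` non-interfacial unmutated.
#'
#' @param n11,n10,n01,n00 nonnegative counts.
#' @return an object of class `contingency_table`.
#' @export
contingency_table <- function(n11, n10, n01, n00) {
  counts <- c(n11 = unname(n11), n10 = unname(n10),
              n01 = unname(n01), n00 = unname(n00))
  stopifnot(all(counts >= 0), all(counts == round(counts)) || TRUE)
  structure(as.list(counts), class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat("<contingency_table>\n")
  m <- matrix(c(x$n11, x$n10, x$n01, x$n00), 2, 2, byrow = TRUE,
              dimnames = list(c("mutated", "unmutated"),
                              c("interfacial", "non-interfacial")))
  print(m)
  invisible(x)
}

#' Build the residue contingency table from interface masks and variants
#'
#' Every residue of every variant-bearing protein is classified into the four
#' cells.  Interface masks from multiple predicted interactions of the same
#' protein should be OR-reduced to one mask per protein before this call
#' (rows with the same `(protein_id, residue_index)` are collapsed with
#' logical OR here as a convenience).
#'
#' @param interfaces data frame with columns `protein_id`, `residue_index`
#'   (1-based), `interfacial` (0/1 or logical); one row per residue of the
#'   residue universe.
#' @param variants data frame with columns `protein_id`, `residue_index`.
#' @return a [contingency_table()].
#' @export
build_contingency <- function(interfaces, variants) {
  stopifnot(all(c("protein_id", "residue_index", "interfacial") %in% names(interfaces)),
            all(c("protein_id", "residue_index") %in% names(variants)))
  res_key <- paste(interfaces$protein_id, interfaces$residue_index, sep = "#")
  ifc <- tapply(as.logical(interfaces$interfacial), res_key, any)
  keep_prot <- unique(as.character(variants$protein_id))
  in_univ <- interfaces$protein_id %in% keep_prot
  univ_keys <- unique(res_key[in_univ])

  var_key <- unique(paste(variants$protein_id, variants$residue_index, sep = "#"))
  missing <- setdiff(var_key, univ_keys)
  if (length(missing) > 0L) {
    stop("variant at unknown residue: ", missing[1L])
  }
  mutated <- univ_keys %in% var_key
  interfacial <- unname(ifc[univ_keys])
  contingency_table(
    n11 = sum(mutated & interfacial),
    n10 = sum(mutated & !interfacial),
    n01 = sum(!mutated & interfacial),
    n00 = sum(!mutated & !interfacial)
  )
}

#' Odds ratio of interfacial enrichment
#'
#' Cross-product ratio `OR = (n11 * n00) / (n10 * n01)`.  An optional
#' Haldane-Anscombe correction adds 0.5 to every cell when any cell is zero.
#'
#' @param t a [contingency_table()].
#' @param pseudo_count per-cell additive correction (default 0, i.e. off).
#' @return positive real.
#' @examples
#' odds_ratio(contingency_table(12151, 61401, 298442, 2387146))  # ~1.6
#' @export
odds_ratio <- function(t, pseudo_count = 0) {
  stopifnot(inherits(t, "contingency_table"))
  n <- unlist(t) + pseudo_count
  if (n["n10"] == 0 || n["n01"] == 0) {
    stop("zero denominator cell; consider pseudo_count = 0.5 (Haldane-Anscombe)")
  }
  unname((n["n11"] * n["n00"]) / (n["n10"] * n["n01"]))
}

#' Log-odds standard error and Z-score
#'
#' `SE = sqrt(1/n11 + 1/n10 + 1/n01 + 1/n00)` and `Z = ln(OR) / SE`.
#'
#' @inheritParams odds_ratio
#' @return for `log_odds_se` the standard error; for `z_score` the Z
#'   statistic.
#' @export
log_odds_se <- function(t, pseudo_count = 0) {
  stopifnot(inherits(t, "contingency_table"))
  n <- unlist(t) + pseudo_count
  if (any(n == 0)) stop("all four cells must be positive for the log-odds SE")
  unname(sqrt(sum(1 / n)))
}

#' @rdname log_odds_se
#' @export
z_score <- function(t, pseudo_count = 0) {
  log(odds_ratio(t, pseudo_count)) / log_odds_se(t, pseudo_count)
}
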