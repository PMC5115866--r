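#' Tab-separated I/O helpers
#'
#' All tabular inputs and outputs are tab-separated with a header row; empty
#' cells denote absent values.  Floats are serialized with 6 significant
#' digits; likelihood ratios above 10^6 are written in full, never clipped.
#'
#' @param path file path.
#' @name tsv_io
NULL

#' @rdname tsv_io
#' @export
read_tsv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- tryCatch(
    utils::read.delim(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE,
                      check.names = FALSE, na.strings = c("", "NA")),
    error = function(e) stop("malformed TSV '", path, "': ", conditionMessage(e)))
  if (nrow(df) == 0L) stop("input file '", path, "' has no data rows")
  df
}

#' @rdname tsv_io
#' @param df data frame to write.
#' @export
write_tsv <- function(df, path) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) signif(x, 6))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "")
  invisible(path)
}

#' Read evidence TSV into the internal evidence table
#'
#' Expected columns: `protein_a`, `protein_b`, then one column per evidence
#' channel; empty cells mark absent evidence.
#'
#' @param path evidence TSV path.
#' @export
read_evidence_tsv <- function(path) {
  df <- read_tsv(path)
  need <- c("protein_a", "protein_b")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    stop("evidence file '", path, "' lacks column(s): ", paste(miss, collapse = ", "))
  }
  df
}

#' Read / write gene sets in GMT format
#'
#' One set per line: name, associated term (description slot), then member
#' ids, tab-separated.
#'
#' @param path GMT file path.
#' @return named list of `list(members, term)`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1L]]
    if (length(f) < 3L) stop("malformed GMT line (need name, term, >=1 member): ", l)
    list(members = f[-(1:2)], term = f[2L])
  })
  names(out) <- vapply(lines, function(l)
    strsplit(l, "\t", fixed = TRUE)[[1L]][1L], character(1), USE.NAMES = FALSE)
  out
}

#' @rdname read_gmt
#' @param sets named list of character vectors or `list(members, term)`.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(seq_along(sets), function(i) {
    s <- sets[[i]]
    mem <- if (is.list(s)) s$members else s
    term <- if (is.list(s) && !is.null(s$term)) s$term else names(sets)[i]
    paste(c(names(sets)[i], term, mem), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write a generated world as a directory of plain-text inputs
#'
#' Emits exactly the dialects the readers consume: evidence, reference,
#' complex, compartment, interface, variant, correlation and ortholog-map
#' TSVs, gene sets as GMT, and a JSON manifest recording the configuration
#' and seed.
#'
#' @param world a `ppi_world`.
#' @param dir output directory (created if missing).
#' @export
write_world <- function(world, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_tsv(world$evidence, p("evidence.tsv"))
  write_tsv(world$proteins, p("proteins.tsv"))
  write_tsv(world$compartments, p("compartments.tsv"))
  ref_df <- function(refs) {
    rbind(data.frame(pair = refs$positives, label = "positive"),
          data.frame(pair = refs$negatives, label = "negative"))
  }
  write_tsv(ref_df(world$refs_train), p("refs_train.tsv"))
  write_tsv(ref_df(world$refs_test), p("refs_test.tsv"))
  write_tsv(world$correlations, p("correlations.tsv"))
  write_tsv(world$expression_manifest, p("expression_manifest.tsv"))
  maps <- do.call(rbind, lapply(names(world$ortholog_maps), function(src) {
    cbind(source = src, world$ortholog_maps[[src]])
  }))
  write_tsv(maps, p("ortholog_maps.tsv"))
  write_tsv(world$species_interactions, p("species_interactions.tsv"))
  nb <- data.frame(
    protein_id = rep(names(world$neighborhoods), lengths(world$neighborhoods)),
    neighbor_id = unlist(world$neighborhoods, use.names = FALSE))
  write_tsv(nb, p("neighborhoods.tsv"))
  write_tsv(data.frame(pair = world$known_human), p("known_human.tsv"))
  write_tsv(data.frame(pair = world$known_any), p("known_any.tsv"))
  cx <- data.frame(
    complex_id = rep(names(world$complexes), lengths(world$complexes)),
    member_id = unlist(world$complexes, use.names = FALSE))
  write_tsv(cx, p("complexes.tsv"))
  write_gmt(world$gene_sets, p("gene_sets.gmt"))
  write_tsv(data.frame(protein_id = names(world$true_terms),
                       term = unname(world$true_terms)), p("true_terms.tsv"))
  write_tsv(world$interfaces, p("interfaces.tsv"))
  write_tsv(world$variants, p("variants.tsv"))
  write_tsv(data.frame(pair = world$true_edges), p("true_edges.tsv"))
  jsonlite::write_json(list(generator = "ppilr", seed = world$config$seed,
                            n_proteins = world$config$n_proteins,
                            n_modules = world$config$n_modules),
                       p("manifest.json"), auto_unbox = TRUE)
  invisible(dir)
}

#' Read a world bundle back from disk
#'
#' Reconstructs the in-memory `ppi_world` pieces the pipeline needs
#' (reference sets, evidence, derived feature tables) from a directory
#' written by [write_world()].
#'
#' @param dir directory produced by [write_world()].
#' @return a `ppi_world`-compatible list.
#' @export
read_world <- function(dir) {
  p <- function(f) file.path(dir, f)
  evidence <- read_evidence_tsv(p("evidence.tsv"))
  proteins <- read_tsv(p("proteins.tsv"))
  refs_of <- function(f, role) {
    df <- read_tsv(p(f))
    reference_sets(df$pair[df$label == "positive"],
                   df$pair[df$label == "negative"], role = role)
  }
  maps_long <- read_tsv(p("ortholog_maps.tsv"))
  ortholog_maps <- lapply(stats::setNames(ORTHOLOGY_SOURCES, ORTHOLOGY_SOURCES),
                          function(src) maps_long[maps_long$source == src, -1L])
  nb_df <- read_tsv(p("neighborhoods.tsv"))
  neighborhoods <- split(nb_df$neighbor_id, nb_df$protein_id)
  cx_df <- read_tsv(p("complexes.tsv"))
  correlations <- read_tsv(p("correlations.tsv"))
  manifest <- read_tsv(p("expression_manifest.tsv"))
  species_interactions <- read_tsv(p("species_interactions.tsv"))
  known_human <- read_tsv(p("known_human.tsv"))$pair
  known_any <- read_tsv(p("known_any.tsv"))$pair
  pairs <- data.frame(protein_a = evidence$protein_a,
                      protein_b = evidence$protein_b, stringsAsFactors = FALSE)
  tt <- read_tsv(p("true_terms.tsv"))
  ep_tab <- ep_score_table(correlations, manifest)
  world <- list(
    proteins = proteins,
    compartments = read_tsv(p("compartments.tsv")),
    evidence = evidence,
    pairs = pairs,
    refs_train = refs_of("refs_train.tsv", "train"),
    refs_test = refs_of("refs_test.tsv", "evaluate"),
    correlations = correlations,
    expression_manifest = manifest,
    ortholog_maps = ortholog_maps,
    species_interactions = species_interactions,
    neighborhoods = neighborhoods,
    known_human = known_human,
    known_any = known_any,
    complexes = split(cx_df$member_id, cx_df$complex_id),
    gene_sets = read_gmt(p("gene_sets.gmt")),
    true_terms = stats::setNames(tt$term, tt$protein_id),
    interfaces = read_tsv(p("interfaces.tsv")),
    variants = read_tsv(p("variants.tsv")),
    true_edges = read_tsv(p("true_edges.tsv"))$pair,
    ep = stats::setNames(ep_tab$EP, ep_tab$pair),
    or_vectors = orthology_vector_table(pairs, ortholog_maps, species_interactions),
    pr_features = pr_feature_table(pairs, neighborhoods, known_human, known_any)
  )
  class(world) <- "ppi_world"
  world
}
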