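#' Configuration of the synthetic interactome world
#'
#' The generator plants a ground-truth interaction graph (a block model of
#' functional modules over a sparse background) and emits every input the
#' scoring, evaluation and annotation machinery consumes: per-channel
#' evidence scores, reference sets, ortholog maps and other-species
#' interaction lists, per-dataset expression correlations, structural
#' neighborhoods and known-interaction sets, compartment annotations,
#' complexes, gene sets, and interface/variant placements with a planted
#' enrichment.  Defaults describe a 2,000-protein world with evidence
#' strengths that give clearly separated but overlapping score
#' distributions; see the methods vignette for the rationale behind each
#' value.
#'
#' @param n_proteins number of proteins (default 2000).
#' @param n_modules number of functional modules (default 50).
#' @param p_within within-module true-edge probability (default 0.25).
#' @param p_background cross-module true-edge probability (default 5e-4).
#' @param neg_candidate_ratio sampled non-edge candidate pairs per true edge
#'   (default 5).
#' @param channels per-channel emission settings for the supplied continuous
#'   scores: named list of `list(mean_pos, mean_neg, sd, coverage)`.
#' @param expression list: `n_human_datasets`, `species` (non-human),
#'   `r_pos_mean`, `r_pos_sd`, `r_neg_sd`, `coverage`.
#' @param orthology list: `species`, `ortholog_coverage`, `source_coverage`
#'   (per orthology source), `p_propagate` (chance a true pair's orthologs
#'   interact in a species where both are mapped), `n_noise_per_species`.
#' @param pr list: `neighborhood_rate` (Poisson mean of structural-neighbor
#'   count), `scope` (`"module"` or `"global"`), `known_human_frac` (fraction
#'   of training-side true edges visible as known interactions),
#'   `known_from_true` (FALSE replaces known sets by random pairs, for null
#'   worlds), `has_structure_prob`.
#' @param compartments list: `freqs` (named label frequencies), `dual_prob`
#'   (chance of a second label), `quota_frac` (per-label fraction of
#'   `n_proteins` sampled into the compartment-crossed negative set),
#'   `pairing_rules`.
#' @param complexes list: `n`, `size_range`.
#' @param gene_sets list: `dropout`, `n_decoys`.
#' @param snp list: `protein_length`, `interface_fraction`,
#'   `n_variant_proteins`, `variants_per_protein`, `theta` (planted
#'   interfacial odds enrichment; default 1.6).
#' @param hc_observe_prob chance a true edge is "published" into an HC-style
#'   reference set (default 0.7).
#' @param train_frac fraction of true edges assigned to the training split
#'   (edge-disjoint from the test split; default 0.5).
#' @param seed integer seed; a fixed seed yields byte-identical worlds.
#' @return a `world_config` list.
#' @export
world_config <- function(n_proteins = 2000L,
                         n_modules = 50L,
                         p_within = 0.25,
                         p_background = 5e-4,
                         neg_candidate_ratio = 5,
                         channels = list(
                           SM = list(mean_pos = 2.0, mean_neg = 0, sd = 1, coverage = 0.5),
                           PrP = list(mean_pos = 1.5, mean_neg = 0, sd = 1, coverage = 0.3),
                           GO = list(mean_pos = 1.5, mean_neg = 0, sd = 1, coverage = 0.8),
                           PP = list(mean_pos = 1.0, mean_neg = 0, sd = 1, coverage = 0.6)
                         ),
                         expression = list(n_human_datasets = 3L,
                                           species = c("mouse", "rat", "chicken", "zebrafish",
                                                       "fly", "nematode", "dog", "macaque",
                                                       "budding_yeast", "fission_yeast"),
                                           r_pos_mean = 0.4, r_pos_sd = 0.25,
                                           r_neg_sd = 0.3, coverage = 0.6),
                         orthology = list(species = paste0("sp", 1:5),
                                          ortholog_coverage = 0.8,
                                          source_coverage = c(gopher = 0.7, oma = 0.6,
                                                              kegg = 0.5, union_group = 0.8),
                                          p_propagate = 0.35,
                                          n_noise_per_species = 200L),
                         pr = list(neighborhood_rate = 4, scope = "module",
                                   known_human_frac = 0.6, known_from_true = TRUE,
                                   has_structure_prob = 0.6),
                         compartments = list(
                           freqs = c(membrane = 0.40, nucleoplasm = 0.25,
                                     mitochondria = 0.20, er = 0.15),
                           dual_prob = 0.05,
                           quota_frac = c(membrane = 0.10, nucleoplasm = 0.025,
                                          mitochondria = 0.025, er = 0.019),
                           pairing_rules = list(c("membrane", "nucleoplasm"),
                                                c("nucleoplasm", "mitochondria"),
                                                c("nucleoplasm", "er"),
                                                c("mitochondria", "er"))
                         ),
                         complexes = list(n = 40L, size_range = c(3L, 8L)),
                         gene_sets = list(dropout = 0.1, n_decoys = NULL),
                         snp = list(protein_length = 150L, interface_fraction = 0.15,
                                    n_variant_proteins = 300L, variants_per_protein = 10,
                                    theta = 1.6),
                         hc_observe_prob = 0.7,
                         train_frac = 0.5,
                         seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins), n_modules = as.integer(n_modules),
              p_within = p_within, p_background = p_background,
              neg_candidate_ratio = neg_candidate_ratio, channels = channels,
              expression = expression, orthology = orthology, pr = pr,
              compartments = compartments, complexes = complexes,
              gene_sets = gene_sets, snp = snp,
              hc_observe_prob = hc_observe_prob, train_frac = train_frac,
              seed = as.integer(seed))
  probs <- c(p_within, p_background, hc_observe_prob, train_frac,
             expression$coverage, orthology$p_propagate,
             vapply(channels, `[[`, numeric(1), "coverage"))
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(cfg, class = "world_config")
}

#' Null-world configuration (zero planted signal)
#'
#' Keeps the module structure (so labels still exist) but removes every
#' statistical difference between true pairs and non-pairs: identical channel
#' emissions, zero-mean expression correlations, no orthologous propagation,
#' global structural neighborhoods and known-interaction sets drawn from
#' random pairs.
#'
#' @param ... overrides passed on to [world_config()].
#' @export
null_world_config <- function(...) {
  cfg <- world_config(...)
  cfg$channels <- lapply(cfg$channels, function(ch) {
    ch$mean_pos <- ch$mean_neg
    ch
  })
  cfg$expression$r_pos_mean <- 0
  cfg$expression$r_pos_sd <- cfg$expression$r_neg_sd
  cfg$orthology$p_propagate <- 0
  cfg$pr$scope <- "global"
  cfg$pr$known_from_true <- FALSE
  cfg$snp$theta <- 1
  cfg
}

#' Generate a complete synthetic world
#'
#' @param config a [world_config()].
#' @return a `ppi_world` list; see the individual elements' documentation in
#'   the methods vignette.  Identical seeds give identical worlds.
#' @export
generate_world <- function(config = world_config()) {
  stopifnot(inherits(config, "world_config"))
  with_seed(config$seed, .generate_world_impl(config))
}

.generate_world_impl <- function(cfg) {
  n <- cfg$n_proteins
  ids <- sprintf("P%04d", seq_len(n))
  modules <- stats::setNames(sample.int(cfg$n_modules, n, replace = TRUE), ids)
  has_structure <- stats::setNames(
    stats::runif(n) < cfg$pr$has_structure_prob, ids)

  ## --- true interaction graph (block model) -------------------------------
  same_module_pairs <- do.call(rbind, lapply(seq_len(cfg$n_modules), function(k) {
    mem <- ids[modules == k]
    if (length(mem) < 2L) return(NULL)
    t(utils::combn(mem, 2L))
  }))
  within_keep <- stats::runif(nrow(same_module_pairs)) < cfg$p_within
  true_within <- same_module_pairs[within_keep, , drop = FALSE]
  n_bg <- stats::rbinom(1L, size = as.integer(min(n * (n - 1) / 2, 2^31 - 1)),
                        prob = cfg$p_background)
  bg_a <- sample(ids, n_bg, replace = TRUE)
  bg_b <- sample(ids, n_bg, replace = TRUE)
  ok <- bg_a != bg_b & modules[bg_a] != modules[bg_b]
  true_edges <- unique(c(pair_key(true_within[, 1L], true_within[, 2L]),
                         pair_key(bg_a[ok], bg_b[ok])))

  ## --- compartments --------------------------------------------------------
  comp_labels <- names(cfg$compartments$freqs)
  comp1 <- sample(comp_labels, n, replace = TRUE, prob = cfg$compartments$freqs)
  dual <- stats::runif(n) < cfg$compartments$dual_prob
  comp2 <- vapply(seq_len(n), function(i) {
    if (!dual[i]) return(NA_character_)
    sample(setdiff(comp_labels, comp1[i]), 1L)
  }, character(1))
  compartments <- rbind(
    data.frame(protein_id = ids, compartment = comp1, stringsAsFactors = FALSE),
    data.frame(protein_id = ids[dual], compartment = comp2[dual],
               stringsAsFactors = FALSE))
  compartments <- compartments[order(compartments$protein_id,
                                     compartments$compartment), ]
  rownames(compartments) <- NULL

  ## --- reference splits ----------------------------------------------------
  is_train_edge <- stats::runif(length(true_edges)) < cfg$train_frac
  observed <- stats::runif(length(true_edges)) < cfg$hc_observe_prob
  hc_train <- true_edges[is_train_edge & observed]
  hc_test <- true_edges[!is_train_edge & observed]

  ## --- candidate non-edges -------------------------------------------------
  n_neg <- ceiling(cfg$neg_candidate_ratio * length(true_edges))
  neg_a <- sample(ids, 3L * n_neg, replace = TRUE)
  neg_b <- sample(ids, 3L * n_neg, replace = TRUE)
  neg_keys <- pair_key(neg_a, neg_b)
  keep <- neg_a != neg_b & !(neg_keys %in% true_edges) & !duplicated(neg_keys)
  neg_candidates <- utils::head(neg_keys[keep], n_neg)

  ## --- compartment-crossed negatives (evaluation N-analog) -----------------
  quota <- pmax(round(cfg$compartments$quota_frac * n), 2L)
  names(quota) <- names(cfg$compartments$quota_frac)
  comp_neg <- build_compartment_negatives(
    compartments, quota, cfg$compartments$pairing_rules,
    exclusions = character(), seed = child_seed(cfg$seed, "comp_neg"))
  comp_neg <- setdiff(comp_neg, true_edges)

  neg_train <- utils::head(neg_candidates, floor(length(neg_candidates) / 2))
  refs_train <- reference_sets(hc_train, neg_train, role = "train")
  refs_test <- reference_sets(hc_test, comp_neg, role = "evaluate")

  ## --- complexes (sampled modules) ----------------------------------------
  cx_modules <- sample(rep(seq_len(cfg$n_modules),
                           length.out = cfg$complexes$n))
  complexes <- lapply(seq_along(cx_modules), function(i) {
    mem <- ids[modules == cx_modules[i]]
    k <- sample(seq(cfg$complexes$size_range[1L], cfg$complexes$size_range[2L]), 1L)
    sample(mem, min(k, length(mem)))
  })
  names(complexes) <- sprintf("CPX%03d", seq_along(complexes))

  ## --- evidence universe ---------------------------------------------------
  cx_pairs <- unlist(lapply(complexes, function(mem) {
    idx <- t(utils::combn(mem, 2L))
    pair_key(idx[, 1L], idx[, 2L])
  }), use.names = FALSE)
  universe <- unique(c(true_edges, neg_candidates, comp_neg, cx_pairs))
  um <- pair_unkey(universe)
  is_true <- universe %in% true_edges
  pairs <- data.frame(protein_a = um[, "a"], protein_b = um[, "b"],
                      is_true = is_true, stringsAsFactors = FALSE)

  ## --- continuous channel emissions ---------------------------------------
  npairs <- nrow(pairs)
  evidence <- data.frame(protein_a = pairs$protein_a, protein_b = pairs$protein_b,
                         stringsAsFactors = FALSE)
  for (ch in names(cfg$channels)) {
    par <- cfg$channels[[ch]]
    mu <- ifelse(is_true, par$mean_pos, par$mean_neg)
    val <- stats::rnorm(npairs, mean = mu, sd = par$sd)
    val[stats::runif(npairs) >= par$coverage] <- NA_real_
    evidence[[ch]] <- val
  }

  ## --- expression correlations --------------------------------------------
  ex <- cfg$expression
  datasets <- data.frame(
    dataset = c(sprintf("human_ds%d", seq_len(ex$n_human_datasets)), ex$species),
    species = c(rep("human", ex$n_human_datasets), ex$species),
    role = c(rep("human", ex$n_human_datasets), rep("orth", length(ex$species))),
    stringsAsFactors = FALSE)
  corr_list <- lapply(seq_len(nrow(datasets)), function(j) {
    present <- stats::runif(npairs) < ex$coverage
    if (!any(present)) return(NULL)
    mu <- ifelse(is_true[present], ex$r_pos_mean, 0)
    sd <- ifelse(is_true[present], ex$r_pos_sd, ex$r_neg_sd)
    r <- pmin(pmax(stats::rnorm(sum(present), mu, sd), -0.99), 0.99)
    data.frame(dataset = datasets$dataset[j],
               protein_1 = pairs$protein_a[present],
               protein_2 = pairs$protein_b[present],
               pearson_r = r, stringsAsFactors = FALSE)
  })
  correlations <- do.call(rbind, corr_list)

  ## --- orthology -----------------------------------------------------------
  ot <- cfg$orthology
  orth_long <- do.call(rbind, lapply(ot$species, function(sp) {
    mapped <- ids[stats::runif(n) < ot$ortholog_coverage]
    if (length(mapped) == 0L) return(NULL)
    data.frame(protein_id = mapped, species = sp,
               ortholog_id = paste0(mapped, "@", sp), stringsAsFactors = FALSE)
  }))
  ortholog_maps <- lapply(stats::setNames(ORTHOLOGY_SOURCES, ORTHOLOGY_SOURCES),
                          function(src) {
    keep <- stats::runif(nrow(orth_long)) < ot$source_coverage[[src]]
    orth_long[keep, , drop = FALSE]
  })
  # propagate true edges into other species where both orthologs exist
  tm <- pair_unkey(true_edges)
  mapped_by_sp <- split(orth_long$protein_id, orth_long$species)
  prop_list <- lapply(ot$species, function(sp) {
    m <- mapped_by_sp[[sp]] %||% character()
    both <- tm[, "a"] %in% m & tm[, "b"] %in% m
    hit <- both & stats::runif(nrow(tm)) < ot$p_propagate
    if (!any(hit)) return(NULL)
    data.frame(species = sp,
               protein_1 = paste0(tm[hit, "a"], "@", sp),
               protein_2 = paste0(tm[hit, "b"], "@", sp),
               stringsAsFactors = FALSE)
  })
  noise_list <- lapply(ot$species, function(sp) {
    m <- unique(orth_long$ortholog_id[orth_long$species == sp])
    if (length(m) < 2L || ot$n_noise_per_species == 0L) return(NULL)
    data.frame(species = sp,
               protein_1 = sample(m, ot$n_noise_per_species, replace = TRUE),
               protein_2 = sample(m, ot$n_noise_per_species, replace = TRUE),
               stringsAsFactors = FALSE)
  })
  species_interactions <- do.call(rbind, c(prop_list, noise_list))
  species_interactions <- species_interactions[
    species_interactions$protein_1 != species_interactions$protein_2, , drop = FALSE]

  ## --- partner redundancy inputs ------------------------------------------
  nb_sizes <- stats::rpois(n, cfg$pr$neighborhood_rate)
  neighborhoods <- lapply(seq_len(n), function(i) {
    pool <- if (identical(cfg$pr$scope, "module")) {
      setdiff(ids[modules == modules[i]], ids[i])
    } else setdiff(ids, ids[i])
    if (length(pool) == 0L || nb_sizes[i] == 0L) return(character())
    sample(pool, min(nb_sizes[i], length(pool)))
  })
  names(neighborhoods) <- ids
  if (isTRUE(cfg$pr$known_from_true)) {
    train_edges <- true_edges[is_train_edge]
    known_human <- train_edges[stats::runif(length(train_edges)) < cfg$pr$known_human_frac]
  } else {
    ka <- sample(ids, length(true_edges), replace = TRUE)
    kb <- sample(ids, length(true_edges), replace = TRUE)
    known_human <- unique(pair_key(ka, kb)[ka != kb])
  }
  # any-species known interactions: human set plus propagated pairs mapped
  # back to their human proteins
  prop_back <- if (!is.null(species_interactions) && nrow(species_interactions) > 0L) {
    pk <- species_interactions
    pair_key(sub("@.*$", "", pk$protein_1), sub("@.*$", "", pk$protein_2))
  } else character()
  known_any <- unique(c(known_human, prop_back))

  ## --- gene sets ------------------------------------------------------------
  gs <- cfg$gene_sets
  real_sets <- lapply(seq_len(cfg$n_modules), function(k) {
    mem <- ids[modules == k]
    mem <- mem[stats::runif(length(mem)) >= gs$dropout]
    list(members = mem, term = sprintf("term_module%02d", k))
  })
  names(real_sets) <- sprintf("MODULE_SET_%02d", seq_len(cfg$n_modules))
  n_decoys <- gs$n_decoys %||% cfg$n_modules
  decoy_sizes <- sample(vapply(real_sets, function(s) length(s$members), integer(1)),
                        n_decoys, replace = TRUE)
  decoys <- lapply(seq_len(n_decoys), function(j) {
    list(members = sample(ids, decoy_sizes[j]),
         term = sprintf("term_decoy%02d", j))
  })
  names(decoys) <- sprintf("DECOY_SET_%02d", seq_len(n_decoys))
  gene_sets <- c(real_sets, decoys)
  true_terms <- stats::setNames(sprintf("term_module%02d", modules), ids)

  ## --- interfaces and variants ---------------------------------------------
  sv <- cfg$snp
  var_prot <- sample(ids, min(sv$n_variant_proteins, n))
  L <- sv$protein_length
  n_ifc <- round(sv$interface_fraction * L)
  interfaces <- data.frame(
    protein_id = rep(var_prot, each = L),
    residue_index = rep(seq_len(L), times = length(var_prot)),
    interfacial = 0L, stringsAsFactors = FALSE)
  ifc_rows <- unlist(lapply(seq_along(var_prot), function(i) {
    (i - 1L) * L + sample(L, n_ifc)
  }))
  interfaces$interfacial[ifc_rows] <- 1L
  phi <- n_ifc / L
  p_ifc <- sv$theta * phi / (sv$theta * phi + (1 - phi))
  ifc_flag <- matrix(interfaces$interfacial, nrow = L)  # column i = protein i
  variants <- do.call(rbind, lapply(seq_along(var_prot), function(i) {
    p <- var_prot[i]
    k <- stats::rpois(1L, sv$variants_per_protein)
    if (k == 0L) return(NULL)
    ifc_pos <- which(ifc_flag[, i] == 1L)
    non_pos <- which(ifc_flag[, i] == 0L)
    take_ifc <- sum(stats::runif(k) < p_ifc)
    take_ifc <- min(take_ifc, length(ifc_pos))
    take_non <- min(k - take_ifc, length(non_pos))
    data.frame(protein_id = p,
               residue_index = c(sample(ifc_pos, take_ifc),
                                 sample(non_pos, take_non)),
               stringsAsFactors = FALSE)
  }))

  ## --- precomputed derived feature tables ----------------------------------
  ep_tab <- ep_score_table(correlations, datasets)
  ep <- stats::setNames(ep_tab$EP, ep_tab$pair)
  or_vectors <- orthology_vector_table(pairs, ortholog_maps, species_interactions)
  pr_features <- pr_feature_table(pairs, neighborhoods, known_human, known_any)

  structure(list(
    config = cfg,
    proteins = data.frame(protein_id = ids,
                          module = unname(modules),
                          has_structure = unname(has_structure),
                          stringsAsFactors = FALSE),
    compartments = compartments,
    modules = modules,
    true_edges = true_edges,
    pairs = pairs,
    evidence = evidence,
    correlations = correlations,
    expression_manifest = datasets,
    ortholog_maps = ortholog_maps,
    species_interactions = species_interactions,
    neighborhoods = neighborhoods,
    known_human = known_human,
    known_any = known_any,
    refs_train = refs_train,
    refs_test = refs_test,
    complexes = complexes,
    gene_sets = gene_sets,
    true_terms = true_terms,
    interfaces = interfaces,
    variants = variants,
    ep = ep,
    or_vectors = or_vectors,
    pr_features = pr_features
  ), class = "ppi_world")
}

#' @export
print.ppi_world <- function(x, ...) {
  cat(sprintf(paste0("<ppi_world: %d proteins, %d modules, %d true edges, ",
                     "%d candidate pairs, seed %d>\n"),
              x$config$n_proteins, x$config$n_modules, length(x$true_edges),
              nrow(x$pairs), x$config$seed))
  invisible(x)
}
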