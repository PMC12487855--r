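#' Run a multi-stage screen/cell-state pipeline
#'
#' Executes pipeline stages in order, each writing its outputs plus a run
#' manifest into its own subdirectory of `out_dir`. Stage seeds are
#' derived deterministically from the single global seed, so one
#' `seed` reproduces a whole run bit-identically.
#'
#' The config is a list (or path to a YAML file) with an element `stages`:
#' a list of `list(stage = <name>, params = <named list>)`. Known stages:
#' `simulate-screen`, `score-screen`, `integrate`, `simulate-cells`,
#' `score-cells`, `compare-groups`.
#'
#' @param config List or YAML file path.
#' @param out_dir Output directory (created if absent).
#' @param seed Global integer seed.
#' @return Invisible exit status: 0 on success. Unknown stages are
#'   rejected before any stage runs; an empty stage list is a no-op
#'   success.
#' @export
run_pipeline <- function(config, out_dir = ".", seed = 1L) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  stages <- config$stages %||% list()
  known <- c("simulate-screen", "score-screen", "integrate",
             "simulate-cells", "score-cells", "compare-groups")
  stage_names <- vapply(stages, function(s) s$stage %||% "", character(1))
  unknown <- setdiff(stage_names, known)
  if (length(unknown)) {
    stop_invalid("unknown stage(s): %s", paste(unknown, collapse = ", "))
  }
  if (!length(stages)) return(invisible(0L))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (i in seq_along(stages)) {
    s <- stages[[i]]
    stage_dir <- file.path(out_dir, sprintf("%02d_%s", i, s$stage))
    dir.create(stage_dir, showWarnings = FALSE, recursive = TRUE)
    stage_seed <- derive_seed(seed, paste0(s$stage, i))
    run_stage(s$stage, s$params %||% list(), stage_dir, stage_seed)
  }
  invisible(0L)
}

run_stage <- function(stage, params, out_dir, seed) {
  switch(stage,
         "simulate-screen" = stage_simulate_screen(params, out_dir, seed),
         "score-screen" = stage_score_screen(params, out_dir, seed),
         "integrate" = stage_integrate(params, out_dir, seed),
         "simulate-cells" = stage_simulate_cells(params, out_dir, seed),
         "score-cells" = stage_score_cells(params, out_dir, seed),
         "compare-groups" = stage_compare_groups(params, out_dir, seed),
         stop_invalid("unknown stage '%s'", stage))
}

require_input <- function(path, what) {
  if (is.null(path) || !file.exists(path)) {
    stop_invalid("missing input file for %s: %s", what,
                 if (is.null(path)) "(not given)" else path)
  }
  path
}

stage_simulate_screen <- function(params, out_dir, seed) {
  seed <- params$seed %||% seed
  lib <- simulate_library(params$n_genes %||% 100L,
                          params$sgrnas_per_gene %||% 5L,
                          params$n_ntc %||% 50L, seed = seed,
                          species = params$species %||% "human")
  effects <- if (!is.null(params$effects_file)) {
    ef <- read_tsv(require_input(params$effects_file, "simulate-screen"))
    effect_spec(ef$gene, ef$growth_effect %||% 0, ef$drug_effect %||% 0,
                ef$knockdown %||% 1)
  } else NULL
  sim <- simulate_screen(lib, effects,
                         doublings = c(vehicle = params$d_vehicle %||% 10,
                                       drug = params$d_drug %||% 5),
                         replicates = params$replicates %||% 2L,
                         depth = params$depth %||% 500,
                         dispersion = params$dispersion %||% 0.05,
                         seed = seed)
  write_sgrna_library(lib, file.path(out_dir, "library.csv"))
  write_count_table(sim$counts, file.path(out_dir, "counts.tsv"))
  write_tsv(sim$truth, file.path(out_dir, "truth.tsv"))
  write_manifest("simulate-screen", params,
                 inputs = if (!is.null(params$effects_file)) params$effects_file
                          else character(0),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

stage_score_screen <- function(params, out_dir, seed) {
  counts_path <- require_input(params$counts, "score-screen")
  lib_path <- require_input(params$library, "score-screen")
  lib <- read_sgrna_library(lib_path)
  tab <- read_count_table(counts_path, lib)
  cfg <- screen_config(pseudocount = params$pseudocount %||% 1,
                       doublings = c(vehicle = params$d_vehicle %||% 10,
                                     drug = params$d_drug %||% 5),
                       alpha = params$alpha %||% 0.05,
                       top_k = params$top_k %||% 3L)
  if (!is.null(params$target_depth)) {
    tab <- downsample_counts(tab, params$target_depth, seed = seed)
  }
  kinds <- params$phenotypes %||% c("gamma", "tau", "rho")
  phenos <- compute_phenotypes(tab, lib, cfg, kinds = kinds)
  write_tsv(phenos, file.path(out_dir, "element_phenotypes.tsv"))
  genes <- do.call(rbind, lapply(kinds, function(k) score_genes(phenos, k, cfg)))
  write_tsv(genes, file.path(out_dir, "gene_scores.tsv"))
  hits <- do.call(rbind, lapply(kinds, function(k) {
    h <- call_hits(genes[genes$kind == k, ], cfg$alpha)
    if (!length(h$sensitizing) && !length(h$resistance)) return(NULL)
    data.frame(kind = k,
               gene = c(h$sensitizing, h$resistance),
               class = rep(c("sensitizing", "resistance"),
                           c(length(h$sensitizing), length(h$resistance))),
               stringsAsFactors = FALSE)
  }))
  if (is.null(hits)) {
    hits <- data.frame(kind = character(0), gene = character(0),
                       class = character(0))
  }
  write_tsv(hits, file.path(out_dir, "hits.tsv"))
  write_manifest("score-screen", params, inputs = c(counts_path, lib_path),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

stage_integrate <- function(params, out_dir, seed) {
  a <- read_tsv(require_input(params$screen_a, "integrate"))
  b <- read_tsv(require_input(params$screen_b, "integrate"))
  class(a) <- class(b) <- c("gene_score_table", "data.frame")
  emap <- if (!is.null(params$map)) {
    m <- read_tsv(require_input(params$map, "integrate"))
    names(m)[1:2] <- c("symbol_a", "symbol_b")
    m
  } else NULL
  omap <- map_orthologs(unique(a$gene), unique(b$gene), emap)
  alpha <- params$alpha %||% 0.05
  kind <- params$kind %||% "rho"
  hits <- conserved_hits(a, b, omap, kind = kind, alpha = alpha)
  write_tsv(hits$provenance, file.path(out_dir, "conserved_hits.tsv"))
  if ("gamma" %in% a$kind && "gamma" %in% b$kind) {
    consensus <- consensus_signature(a, b, omap, alpha = alpha)
    write_tsv(attr(consensus, "provenance"),
              file.path(out_dir, "consensus_growth_signature.tsv"))
  }
  write_manifest("integrate", params,
                 inputs = c(params$screen_a, params$screen_b,
                            params$map %||% character(0)),
                 seed = seed, path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

stage_simulate_cells <- function(params, out_dir, seed) {
  seed <- params$seed %||% seed
  modules <- if (!is.null(params$genesets)) {
    gmt_to_modules(read_gmt(require_input(params$genesets, "simulate-cells")))
  } else synthetic_meta_modules(params$genes_per_module %||% 30L)
  n_per_state <- unlist(params$n_per_state %||%
                          list(MES = 200, AC = 200, OPC = 200, NPC = 200))
  pop <- simulate_cells(n_per_state, modules,
                        effect_size = params$effect_size %||% 1.0,
                        noise_sd = params$noise_sd %||% 0.5,
                        cycling_fraction = params$cycling_fraction %||% 0.2,
                        seed = seed)
  expr <- data.frame(cell_id = rownames(pop$expression), pop$expression,
                     check.names = FALSE)
  write_tsv(expr, file.path(out_dir, "expression.tsv"))
  write_tsv(data.frame(cell_id = rownames(pop$expression),
                       true_state = pop$true_state,
                       true_cycling = pop$true_cycling),
            file.path(out_dir, "truth.tsv"))
  write_gmt(c(modules$state_modules, modules$cycling_modules),
            file.path(out_dir, "modules.gmt"))
  write_manifest("simulate-cells", params, seed = seed,
                 path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

# Interpret a GMT list as a meta-module set; set names must contain the
# state/cycling keys (e.g. "MES", "MES-like", "G1S").
gmt_to_modules <- function(sigs) {
  find <- function(key) {
    hit <- grep(key, names(sigs), ignore.case = TRUE, value = TRUE)
    if (!length(hit)) stop_invalid("GMT lacks a '%s' signature", key)
    sigs[[hit[1]]]
  }
  meta_module_set(
    state_modules = list(MES = find("MES"), AC = find("^AC|AC-like"),
                         OPC = find("OPC"), NPC = find("NPC")),
    cycling_modules = list(G1S = find("G1S|G1.S"), G2M = find("G2M|G2.M"))
  )
}

stage_score_cells <- function(params, out_dir, seed) {
  expr_path <- require_input(params$expr, "score-cells")
  df <- read_tsv(expr_path)
  expr <- as.matrix(df[, -1, drop = FALSE])
  rownames(expr) <- df[[1]]
  modules <- gmt_to_modules(read_gmt(require_input(params$genesets,
                                                   "score-cells")))
  res <- score_states(expr, modules, n_bins = params$n_bins %||% 25L,
                      n_ctrl = params$n_ctrl %||% 100L,
                      seed = params$seed %||% seed,
                      cycling_threshold = params$cycling_threshold %||% 0.1)
  write_tsv(res, file.path(out_dir, "cell_states.tsv"))
  props <- state_proportions(res, rep("all", nrow(res)))
  write_tsv(props, file.path(out_dir, "state_proportions.tsv"))
  write_manifest("score-cells", params,
                 inputs = c(expr_path, params$genesets),
                 seed = params$seed %||% seed,
                 path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}

stage_compare_groups <- function(params, out_dir, seed) {
  scores_path <- require_input(params$scores, "compare-groups")
  labels_path <- require_input(params$labels, "compare-groups")
  scores <- read_tsv(scores_path)
  labels <- read_tsv(labels_path)
  merged <- merge(scores, labels, by = 1)
  res <- compare_groups_ranktest(merged[[2]], merged[[3]])
  write_tsv(data.frame(statistic = res$statistic, p_value = res$p_value),
            file.path(out_dir, "rank_test.tsv"))
  write_manifest("compare-groups", params,
                 inputs = c(scores_path, labels_path), seed = seed,
                 path = file.path(out_dir, "manifest.json"))
  invisible(out_dir)
}
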