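#' Gene signatures and meta-module sets
#'
#' A gene signature is a named, non-empty list of unique gene symbols. A
#' meta-module set bundles the four glioblastoma tumor cell-state
#' signatures (MES-like, AC-like, OPC-like, NPC-like) with the two
#' cell-cycle signatures (G1S, G2M); it is the input to cell-state
#' assignment and cycling calls.
#'
#' @param name Signature name.
#' @param genes Character vector of gene symbols; duplicates are collapsed.
#' @return `gene_signature()`: a list of class `gene_signature` with
#'   fields `name` and `genes`.
#' @export
gene_signature <- function(name, genes) {
  genes <- as.character(genes)
  if (!length(genes)) {
    stop_invalid("signature '%s' has an empty gene list", name)
  }
  structure(list(name = as.character(name), genes = unique(genes)),
            class = "gene_signature")
}

#' @rdname gene_signature
#' @param state_modules Named list of four `gene_signature`s with names
#'   `MES`, `AC`, `OPC`, `NPC`.
#' @param cycling_modules Named list of two `gene_signature`s with names
#'   `G1S`, `G2M`.
#' @return `meta_module_set()`: a list of class `meta_module_set`.
#' @export
meta_module_set <- function(state_modules, cycling_modules) {
  states <- c("MES", "AC", "OPC", "NPC")
  cyc <- c("G1S", "G2M")
  if (!setequal(names(state_modules), states)) {
    stop_invalid("state_modules must be named %s", paste(states, collapse = ", "))
  }
  if (!setequal(names(cycling_modules), cyc)) {
    stop_invalid("cycling_modules must be named %s", paste(cyc, collapse = ", "))
  }
  ok <- function(s) inherits(s, "gene_signature") && length(s$genes) > 0
  if (!all(vapply(state_modules, ok, logical(1))) ||
      !all(vapply(cycling_modules, ok, logical(1)))) {
    stop_invalid("all six signatures must be non-empty gene_signature objects")
  }
  structure(list(state_modules = state_modules[states],
                 cycling_modules = cycling_modules[cyc]),
            class = "meta_module_set")
}

# Fixed tie-break/assignment order for the four tumor cell states.
STATE_ORDER <- c("MES", "AC", "OPC", "NPC")

#' Synthetic meta-module set
#'
#' Builds a deterministic set of disjoint synthetic signatures (gene
#' symbols `MES_g1`, `AC_g1`, ...) for use with [simulate_cells()] and in
#' tests; real analyses should load curated signatures from a GMT file
#' with [read_gmt()].
#'
#' @param genes_per_module Genes per signature.
#' @return A [meta_module_set].
#' @export
synthetic_meta_modules <- function(genes_per_module = 30L) {
  genes_per_module <- check_count_arg(genes_per_module, "genes_per_module")
  mk <- function(nm) gene_signature(nm, sprintf("%s_g%d", nm,
                                                seq_len(genes_per_module)))
  meta_module_set(
    state_modules = stats::setNames(lapply(STATE_ORDER, mk), STATE_ORDER),
    cycling_modules = list(G1S = mk("G1S"), G2M = mk("G2M"))
  )
}

#' Module score with bin-matched control genes
#'
#' Scores a gene signature per cell as the mean expression of its genes
#' minus the mean expression of pooled control genes, where controls are
#' drawn from expression bins matched to each signature gene: all genes
#' are ranked by mean expression across cells and cut into `n_bins`
#' equal-size bins; for each signature gene, `n_ctrl` control genes are
#' sampled from its bin (with replacement when the bin holds fewer than
#' `n_ctrl` genes). Subtracting bin-matched controls removes per-cell
#' depth/complexity effects: the score is exactly invariant to adding a
#' constant to all genes of a cell.
#'
#' @param expression Cells x genes numeric matrix (log-normalized scale),
#'   with cell rownames and gene colnames.
#' @param signature A [gene_signature]; at least one of its genes must be
#'   present in the matrix (absentees are dropped with a warning).
#' @param n_bins Number of expression bins (default 25).
#' @param n_ctrl Control genes sampled per signature gene (default 100).
#' @param seed Integer seed; control sampling (and hence the scores) is
#'   bit-reproducible under it.
#' @return Named numeric vector of per-cell scores.
#' @export
module_score <- function(expression, signature, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L) {
  stopifnot(is.matrix(expression), inherits(signature, "gene_signature"))
  n_bins <- check_count_arg(n_bins, "n_bins")
  n_ctrl <- check_count_arg(n_ctrl, "n_ctrl")
  genes <- colnames(expression)
  if (is.null(genes)) stop_invalid("expression must have gene colnames")
  present <- intersect(signature$genes, genes)
  absent <- setdiff(signature$genes, genes)
  if (!length(present)) {
    stop_invalid("signature '%s': none of its genes are in the matrix (missing: %s%s)",
                 signature$name,
                 paste(utils::head(absent, 5), collapse = ", "),
                 if (length(absent) > 5) ", ..." else "")
  }
  if (length(absent)) {
    warning(sprintf("signature '%s': %d gene(s) absent from matrix",
                    signature$name, length(absent)), call. = FALSE)
  }

  # equal-size bins by mean expression; ties resolved by gene name so the
  # binning is deterministic
  gene_means <- colMeans(expression)
  ord <- order(gene_means, genes)
  bin_of <- integer(length(genes))
  nb <- min(n_bins, length(ord))
  bin_of[ord] <- pmin(nb, ceiling(seq_along(ord) / (length(ord) / nb)))
  names(bin_of) <- genes
  bins <- split(genes, bin_of)

  ctrl_pool <- with_seed(seed, {
    unlist(lapply(present, function(g) {
      b <- bins[[as.character(bin_of[[g]])]]
      sample(b, n_ctrl, replace = length(b) < n_ctrl)
    }), use.names = FALSE)
  })

  sig_mean <- rowMeans(expression[, present, drop = FALSE])
  ctrl_mean <- rowMeans(expression[, ctrl_pool, drop = FALSE])
  sig_mean - ctrl_mean
}

#' Score all six meta-modules per cell
#'
#' Convenience wrapper running [module_score()] for the four state
#' signatures and the two cycling signatures, then calling state
#' assignment and the cycling flag.
#'
#' @param expression Cells x genes matrix (log-normalized scale).
#' @param modules A [meta_module_set].
#' @inheritParams module_score
#' @param cycling_threshold Passed to [assign_cycling()].
#' @return A data frame of class `cell_state_result`: one row per cell
#'   with columns `cell_id`, `MES`, `AC`, `OPC`, `NPC`, `G1S`, `G2M`,
#'   `state`, `cycling`; scoring parameters are kept as attributes.
#' @export
score_states <- function(expression, modules, n_bins = 25L, n_ctrl = 100L,
                         seed = 1L, cycling_threshold = 0.1) {
  stopifnot(inherits(modules, "meta_module_set"))
  all_sigs <- c(modules$state_modules, modules$cycling_modules)
  score_mat <- vapply(seq_along(all_sigs), function(i) {
    module_score(expression, all_sigs[[i]], n_bins = n_bins, n_ctrl = n_ctrl,
                 seed = derive_seed(seed, names(all_sigs)[i]))
  }, numeric(nrow(expression)))
  colnames(score_mat) <- names(all_sigs)
  out <- data.frame(cell_id = rownames(expression) %||% as.character(seq_len(nrow(expression))),
                    score_mat, stringsAsFactors = FALSE)
  out$state <- assign_state(score_mat[, STATE_ORDER, drop = FALSE])
  out$cycling <- assign_cycling(score_mat[, "G1S"], score_mat[, "G2M"],
                                threshold = cycling_threshold)
  rownames(out) <- NULL
  structure(out, n_bins = n_bins, n_ctrl = n_ctrl, seed = seed,
            cycling_threshold = cycling_threshold,
            class = c("cell_state_result", "data.frame"))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Assign each cell to its maximal meta-module state
#'
#' Argmax over the four state scores with a fixed deterministic tie-break
#' order: MES, AC, OPC, NPC.
#'
#' @param scores Cells x 4 numeric matrix (or data frame) with columns
#'   `MES`, `AC`, `OPC`, `NPC`; all values must be finite.
#' @return Character vector of state labels.
#' @export
assign_state <- function(scores) {
  scores <- as.matrix(scores)
  if (!all(STATE_ORDER %in% colnames(scores))) {
    stop_invalid("scores must have columns %s", paste(STATE_ORDER, collapse = ", "))
  }
  scores <- scores[, STATE_ORDER, drop = FALSE]
  if (any(!is.finite(scores))) stop_invalid("state scores must be finite")
  STATE_ORDER[apply(scores, 1, which.max)]
}

#' Flag cycling cells from the two cell-cycle module scores
#'
#' A cell is cycling when the larger of its G1/S and G2/M module scores
#' exceeds `threshold`.
#'
#' @param g1s_score,g2m_score Numeric vectors of cell-cycle module scores.
#' @param threshold Cycling cutoff (default 0.1).
#' @return Logical vector.
#' @export
assign_cycling <- function(g1s_score, g2m_score, threshold = 0.1) {
  if (any(!is.finite(g1s_score)) || any(!is.finite(g2m_score))) {
    stop_invalid("cycling scores must be finite")
  }
  pmax(g1s_score, g2m_score) > threshold
}

#' Per-group cell-state proportions
#'
#' @param results A `cell_state_result` (or any data frame with a `state`
#'   column) covering all cells.
#' @param group_labels Per-cell group labels, same length as rows of
#'   `results`.
#' @return Data frame: one row per group, columns `group`, `n`, and one
#'   fraction per state (`MES`, `AC`, `OPC`, `NPC`); fractions sum to 1
#'   within each group. Empty groups (levels with no cells) are dropped
#'   with a warning.
#' @export
state_proportions <- function(results, group_labels) {
  stopifnot(is.data.frame(results), "state" %in% names(results))
  if (length(group_labels) != nrow(results)) {
    stop_invalid("group_labels must cover all %d cells", nrow(results))
  }
  if (is.factor(group_labels) && any(table(group_labels) == 0)) {
    warning("empty group(s) excluded", call. = FALSE)
  }
  groups <- split(factor(results$state, levels = STATE_ORDER),
                  as.character(group_labels))
  out <- do.call(rbind, lapply(names(groups), function(g) {
    tab <- table(groups[[g]])
    data.frame(group = g, n = length(groups[[g]]),
               as.list(as.numeric(tab) / sum(tab)),
               stringsAsFactors = FALSE)
  }))
  names(out)[-(1:2)] <- STATE_ORDER
  rownames(out) <- NULL
  out
}

#' Compare signature scores between two cell groups
#'
#' Two-sided Wilcoxon rank-sum (Mann-Whitney) comparison of per-cell
#' scores between two groups, using the same engine as the screen-side
#' [mannwhitney_vs_ntc()]: exact for small tie-free inputs, normal
#' approximation with continuity and tie correction otherwise.
#'
#' @param scores Per-cell numeric vector.
#' @param groups Per-cell labels with exactly two levels, or a logical
#'   vector.
#' @return List with `statistic` (Mann-Whitney U of the first group) and
#'   `p_value`.
#' @export
compare_groups_ranktest <- function(scores, groups) {
  if (length(scores) != length(groups)) {
    stop_invalid("scores and groups must have equal length")
  }
  lev <- if (is.logical(groups)) c(TRUE, FALSE) else sort(unique(as.character(groups)))
  if (length(lev) != 2L) {
    stop_invalid("groups must have exactly 2 levels, found %d", length(lev))
  }
  x <- scores[groups == lev[1]]
  y <- scores[groups == lev[2]]
  if (!length(x) || !length(y)) stop_invalid("both groups must be non-empty")
  rank_sum_test(x, y)
}
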