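#' Simulate a single-cell population with planted states
#'
#' Generates a cells x genes expression matrix on the log-normalized scale
#' with known ground truth for testing cell-state scoring. Baseline
#' expression is `|Normal(0, noise_sd)|` per gene per cell (nonnegative,
#' right-skewed, as log-normalized data are). Each cell's true-state
#' signature genes receive an additive `effect_size` shift; a planted
#' fraction of cycling cells receives `effect_size` on one of the two
#' cycling signatures (chosen at random per cell). Additional background
#' genes give the control-gene bins material to draw from. No UMI
#' sampling, doublets or ambient RNA are modeled: every in-scope scoring
#' operation consumes normalized expression.
#'
#' @param n_per_state Named integer vector of cells per state; names must
#'   be a subset of `MES`, `AC`, `OPC`, `NPC` (a missing or zero entry
#'   simply omits that state).
#' @param signatures A [meta_module_set]; all its genes appear in the
#'   matrix.
#' @param effect_size Additive shift (log2 units, >= 0) applied to a
#'   cell's own-state signature genes and to cycling cells' cycling genes.
#' @param noise_sd Baseline noise SD (> 0).
#' @param cycling_fraction Fraction of cells planted as cycling, in
#'   \[0, 1\].
#' @param n_background Extra non-signature genes.
#' @param seed Integer seed; the population is bit-reproducible under it.
#' @return A list of class `synthetic_cell_population` with `expression`
#'   (cells x genes matrix), `true_state`, `true_cycling`, `effect_size`,
#'   `noise_sd`, and `seed`.
#' @examples
#' pop <- simulate_cells(c(MES = 20, AC = 20, OPC = 20, NPC = 20),
#'                       synthetic_meta_modules(10), effect_size = 1,
#'                       noise_sd = 0.5, seed = 1)
#' dim(pop$expression)
#' @export
simulate_cells <- function(n_per_state, signatures, effect_size = 1.0,
                           noise_sd = 0.5, cycling_fraction = 0.2,
                           n_background = 300L, seed = 1L) {
  stopifnot(inherits(signatures, "meta_module_set"))
  effect_size <- check_scalar(effect_size, "effect_size", min = 0)
  noise_sd <- check_scalar(noise_sd, "noise_sd")
  if (noise_sd <= 0) stop_invalid("`noise_sd` must be > 0")
  cycling_fraction <- check_scalar(cycling_fraction, "cycling_fraction",
                                   min = 0, max = 1)
  n_background <- check_count_arg(n_background, "n_background", min = 0L)
  bad <- setdiff(names(n_per_state), STATE_ORDER)
  if (length(bad)) {
    stop_invalid("unknown state(s) in n_per_state: %s", paste(bad, collapse = ", "))
  }
  n_per_state <- n_per_state[n_per_state > 0]
  if (!length(n_per_state)) stop_invalid("n_per_state is empty")

  sig_genes <- lapply(c(signatures$state_modules, signatures$cycling_modules),
                      `[[`, "genes")
  genes <- unique(c(unlist(sig_genes, use.names = FALSE),
                    if (n_background > 0) sprintf("BG_g%d", seq_len(n_background))))
  true_state <- rep(names(n_per_state), times = n_per_state)
  n_cells <- length(true_state)
  cell_ids <- sprintf("cell_%04d", seq_len(n_cells))

  with_seed(seed, {
    true_state <- sample(true_state)  # shuffle so state is not row-ordered
    expr <- matrix(abs(stats::rnorm(n_cells * length(genes), 0, noise_sd)),
                   nrow = n_cells, ncol = length(genes),
                   dimnames = list(cell_ids, genes))
    for (st in unique(true_state)) {
      g <- sig_genes[[st]]
      expr[true_state == st, g] <- expr[true_state == st, g] + effect_size
    }
    true_cycling <- stats::runif(n_cells) < cycling_fraction
    which_cyc <- sample(c("G1S", "G2M"), n_cells, replace = TRUE)
    for (cm in c("G1S", "G2M")) {
      rows <- true_cycling & which_cyc == cm
      if (any(rows)) {
        expr[rows, sig_genes[[cm]]] <- expr[rows, sig_genes[[cm]]] + effect_size
      }
    }
    structure(list(expression = expr, true_state = true_state,
                   true_cycling = true_cycling, effect_size = effect_size,
                   noise_sd = noise_sd, seed = as.integer(seed)),
              class = "synthetic_cell_population")
  })
}

#' @export
print.synthetic_cell_population <- function(x, ...) {
  cat(sprintf("synthetic cell population: %d cells x %d genes (effect %g, noise SD %g, seed %d)\n",
              nrow(x$expression), ncol(x$expression), x$effect_size,
              x$noise_sd, x$seed))
  invisible(x)
}
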