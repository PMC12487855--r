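#' sgRNA library objects
#'
#' An sgRNA library is the catalog of screen elements (single guides or
#' guide pairs, each counted as one element) together with their gene
#' targets and non-targeting flags. It is the universe over which all
#' screen statistics are defined: non-targeting control (NTC) elements
#' supply the null location (median) and scale (SD) used to center and
#' standardize phenotypes.
#'
#' @param elements A data frame with columns `element_id` (unique strings),
#'   `gene` (gene symbol, `NA` for non-targeting elements), `is_ntc`
#'   (logical), and optionally `protospacer`.
#' @param species Label for the library species, e.g. `"human"` or
#'   `"mouse"`.
#' @return An object of class `sgrna_library`: the validated element data
#'   frame with a `species` attribute.
#' @examples
#' lib <- sgrna_library(data.frame(
#'   element_id = c("g1_sg1", "ntc_1", "ntc_2"),
#'   gene = c("GENE1", NA, NA),
#'   is_ntc = c(FALSE, TRUE, TRUE)
#' ))
#' n_ntc(lib)
#' @export
sgrna_library <- function(elements, species = "unspecified") {
  stopifnot(is.data.frame(elements))
  required <- c("element_id", "gene", "is_ntc")
  missing <- setdiff(required, names(elements))
  if (length(missing)) {
    stop_invalid("library is missing column(s): %s",
                 paste(missing, collapse = ", "))
  }
  elements$element_id <- as.character(elements$element_id)
  elements$gene <- as.character(elements$gene)
  elements$is_ntc <- as.logical(elements$is_ntc)
  if (anyDuplicated(elements$element_id)) {
    stop_invalid("duplicate element_id in library: %s",
                 paste(unique(elements$element_id[duplicated(elements$element_id)]),
                       collapse = ", "))
  }
  if (any(elements$is_ntc & !is.na(elements$gene))) {
    stop_invalid("non-targeting elements must have gene = NA")
  }
  if (any(!elements$is_ntc & is.na(elements$gene))) {
    stop_invalid("targeting elements must have a gene symbol")
  }
  if (!any(!elements$is_ntc)) {
    stop_invalid("library must contain at least one targeting element")
  }
  if (!"protospacer" %in% names(elements)) elements$protospacer <- NA_character_
  rownames(elements) <- NULL
  structure(elements, species = species,
            class = c("sgrna_library", "data.frame"))
}

#' @rdname sgrna_library
#' @param library An `sgrna_library`.
#' @export
n_ntc <- function(library) sum(library$is_ntc)

#' @rdname sgrna_library
#' @export
ntc_ids <- function(library) library$element_id[library$is_ntc]

#' @export
print.sgrna_library <- function(x, ...) {
  cat(sprintf("sgRNA library (%s): %d elements (%d targeting %d genes, %d non-targeting)\n",
              attr(x, "species"), nrow(x), sum(!x$is_ntc),
              length(unique(x$gene[!x$is_ntc])), sum(x$is_ntc)))
  invisible(x)
}

#' Simulate an sgRNA library
#'
#' Builds a synthetic library of `n_genes * sgrnas_per_gene` targeting
#' elements plus `n_ntc` non-targeting control elements, with deterministic
#' random protospacer sequences. Dual-guide pairs are modeled as single
#' elements, so "element" below means one countable library member.
#'
#' @param n_genes Number of targeted genes (>= 1).
#' @param sgrnas_per_gene Elements per gene (>= 1).
#' @param n_ntc Number of non-targeting control elements (>= 0).
#' @param seed Integer seed; the library is bit-reproducible under it.
#' @param species Species label attached to the library.
#' @param gene_prefix Prefix for synthetic gene symbols. Mouse-style
#'   capitalization is applied automatically when `species = "mouse"` so
#'   that case-insensitive ortholog matching across simulated human/mouse
#'   screens works out of the box.
#' @return An [sgrna_library].
#' @examples
#' lib <- simulate_library(n_genes = 3, sgrnas_per_gene = 2, n_ntc = 4, seed = 1)
#' nrow(lib)  # 10
#' @export
simulate_library <- function(n_genes, sgrnas_per_gene, n_ntc = 0L, seed = 1L,
                             species = "human", gene_prefix = "GENE") {
  n_genes <- check_count_arg(n_genes, "n_genes")
  sgrnas_per_gene <- check_count_arg(sgrnas_per_gene, "sgrnas_per_gene")
  n_ntc <- check_count_arg(n_ntc, "n_ntc", min = 0L)

  genes <- sprintf("%s%05d", gene_prefix, seq_len(n_genes))
  if (identical(species, "mouse")) {
    genes <- paste0(substr(genes, 1, 1),
                    tolower(substr(genes, 2, nchar(genes))))
  }
  gene_col <- rep(genes, each = sgrnas_per_gene)
  target_ids <- paste0(gene_col, "_sg", rep(seq_len(sgrnas_per_gene), n_genes))
  ntc_col <- if (n_ntc > 0) sprintf("NTC_%05d", seq_len(n_ntc)) else character(0)

  n_total <- length(target_ids) + n_ntc
  protospacers <- with_seed(seed, {
    vapply(seq_len(n_total), function(i) {
      paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE), collapse = "")
    }, character(1))
  })

  sgrna_library(
    data.frame(
      element_id = c(target_ids, ntc_col),
      gene = c(gene_col, rep(NA_character_, n_ntc)),
      is_ntc = c(rep(FALSE, length(target_ids)), rep(TRUE, n_ntc)),
      protospacer = protospacers,
      stringsAsFactors = FALSE
    ),
    species = species
  )
}

#' Ground-truth perturbation effects for simulation
#'
#' One record per gene giving the planted per-doubling log2 fitness effects
#' used by [simulate_screen()]: `growth_effect` is the true growth
#' phenotype (gamma) of a full-knockdown element relative to non-targeting
#' controls, `drug_effect` the additional per-doubling effect under drug
#' (so with equal vehicle/drug doublings it is the true rho), and
#' `knockdown` the per-element efficiency scaling both.
#'
#' @param gene Character vector of gene symbols (unique).
#' @param growth_effect Per-doubling log2 fitness effect in vehicle
#'   (recycled).
#' @param drug_effect Additional per-doubling log2 fitness effect under
#'   drug (recycled).
#' @param knockdown Knockdown efficiency in (0, 1] (recycled).
#' @return A data frame of class `effect_spec`.
#' @examples
#' effect_spec(c("GENE00001", "GENE00002"), growth_effect = c(-0.4, 0))
#' @export
effect_spec <- function(gene, growth_effect = 0, drug_effect = 0,
                        knockdown = 1) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) {
    stop_invalid("effect_spec requires one record per gene; duplicated: %s",
                 paste(unique(gene[duplicated(gene)]), collapse = ", "))
  }
  out <- data.frame(gene = gene,
                    growth_effect = rep_len(as.numeric(growth_effect),
                                            length(gene)),
                    drug_effect = rep_len(as.numeric(drug_effect),
                                          length(gene)),
                    knockdown = rep_len(as.numeric(knockdown), length(gene)),
                    stringsAsFactors = FALSE)
  if (any(!is.finite(out$growth_effect)) || any(!is.finite(out$drug_effect))) {
    stop_invalid("growth_effect and drug_effect must be finite")
  }
  if (any(out$knockdown <= 0 | out$knockdown > 1)) {
    stop_invalid("knockdown must lie in (0, 1]")
  }
  class(out) <- c("effect_spec", "data.frame")
  out
}
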