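#' Map gene symbols between two screens
#'
#' Builds the ortholog pairing used to integrate a human and a mouse
#' screen. With no explicit map, symbols are matched case-insensitively
#' (mouse "Shoc2" pairs with human "SHOC2"); an explicit two-column map
#' overrides this and is restricted to the observed symbols. Symbols are
#' otherwise treated case-sensitively throughout the package.
#'
#' @param genes_a,genes_b Non-empty character vectors of gene symbols from
#'   the two screens.
#' @param explicit_map Optional data frame with columns `symbol_a`,
#'   `symbol_b`. Duplicated symbols on either side (one-to-many pairs)
#'   are an error listing the offenders.
#' @return Data frame of class `ortholog_map` with columns `symbol_a`,
#'   `symbol_b`; unmatched symbols are attached as attributes
#'   `unmatched_a` / `unmatched_b`.
#' @examples
#' map_orthologs(c("TP53", "SHOC2"), c("Tp53", "Shoc2"))
#' @export
map_orthologs <- function(genes_a, genes_b, explicit_map = NULL) {
  genes_a <- unique(as.character(genes_a))
  genes_b <- unique(as.character(genes_b))
  if (!length(genes_a) || !length(genes_b)) {
    stop_invalid("both symbol lists must be non-empty")
  }
  if (!is.null(explicit_map)) {
    stopifnot(is.data.frame(explicit_map))
    if (!all(c("symbol_a", "symbol_b") %in% names(explicit_map))) {
      stop_invalid("explicit_map needs columns symbol_a, symbol_b")
    }
    em <- unique(explicit_map[, c("symbol_a", "symbol_b")])
    dup <- c(em$symbol_a[duplicated(em$symbol_a)],
             em$symbol_b[duplicated(em$symbol_b)])
    if (length(dup)) {
      stop_invalid("ambiguous mapping: symbol(s) mapped more than once: %s",
                   paste(unique(dup), collapse = ", "))
    }
    pairs <- em[em$symbol_a %in% genes_a & em$symbol_b %in% genes_b, ,
                drop = FALSE]
  } else {
    idx <- match(toupper(genes_a), toupper(genes_b))
    pairs <- data.frame(symbol_a = genes_a[!is.na(idx)],
                        symbol_b = genes_b[idx[!is.na(idx)]],
                        stringsAsFactors = FALSE)
  }
  rownames(pairs) <- NULL
  structure(pairs,
            unmatched_a = setdiff(genes_a, pairs$symbol_a),
            unmatched_b = setdiff(genes_b, pairs$symbol_b),
            class = c("ortholog_map", "data.frame"))
}

#' Conserved hits across two screens
#'
#' A gene pair is a conserved sensitizing hit when it is significant
#' (q < alpha) with a negative score in BOTH screens, and a conserved
#' resistance hit when significant with a positive score in both.
#' Pairs significant in both screens but with discordant signs are never
#' hits; they are listed in the provenance table with
#' `status = "discordant"`.
#'
#' @param table_a,table_b `gene_score_table`s from [score_genes()] for the
#'   same phenotype kind.
#' @param ortholog_map An [map_orthologs()] result (non-empty).
#' @param kind Phenotype kind to integrate (checked against the tables).
#' @param alpha FDR threshold applied in both screens.
#' @return List of class `conserved_hits`: character vectors `sensitizing`
#'   and `resistance` (symbols of screen A), and a `provenance` data frame
#'   carrying both source scores and q-values for every evaluated pair.
#' @export
conserved_hits <- function(table_a, table_b, ortholog_map, kind = "rho",
                           alpha = 0.05) {
  stopifnot(is.data.frame(table_a), is.data.frame(table_b),
            inherits(ortholog_map, "ortholog_map"))
  if (!nrow(ortholog_map)) {
    stop_invalid("no overlap: ortholog map is empty")
  }
  for (tb in list(table_a, table_b)) {
    if (!all(c("gene", "kind", "score", "q_value") %in% names(tb))) {
      stop_invalid("gene score tables need gene/kind/score/q_value columns")
    }
  }
  a <- table_a[table_a$kind == kind, , drop = FALSE]
  b <- table_b[table_b$kind == kind, , drop = FALSE]
  if (!nrow(a) || !nrow(b)) {
    stop_invalid("kind '%s' absent from one of the score tables", kind)
  }
  ia <- match(ortholog_map$symbol_a, a$gene)
  ib <- match(ortholog_map$symbol_b, b$gene)
  keep <- !is.na(ia) & !is.na(ib)
  prov <- data.frame(
    symbol_a = ortholog_map$symbol_a[keep],
    symbol_b = ortholog_map$symbol_b[keep],
    score_a = a$score[ia[keep]], q_a = a$q_value[ia[keep]],
    score_b = b$score[ib[keep]], q_b = b$q_value[ib[keep]],
    score_std_a = if ("score_std" %in% names(a)) a$score_std[ia[keep]] else NA_real_,
    score_std_b = if ("score_std" %in% names(b)) b$score_std[ib[keep]] else NA_real_,
    stringsAsFactors = FALSE
  )
  sig <- prov$q_a < alpha & prov$q_b < alpha
  concordant <- sign(prov$score_a) == sign(prov$score_b)
  prov$status <- "not_conserved"
  prov$status[sig & concordant & prov$score_a < 0] <- "sensitizing"
  prov$status[sig & concordant & prov$score_a > 0] <- "resistance"
  prov$status[sig & !concordant] <- "discordant"
  structure(list(sensitizing = prov$symbol_a[prov$status == "sensitizing"],
                 resistance = prov$symbol_a[prov$status == "resistance"],
                 provenance = prov, kind = kind, alpha = alpha),
            class = "conserved_hits")
}

#' @export
print.conserved_hits <- function(x, ...) {
  cat(sprintf("conserved %s hits (alpha %g): %d sensitizing, %d resistance, %d discordant\n",
              x$kind, x$alpha, length(x$sensitizing), length(x$resistance),
              sum(x$provenance$status == "discordant")))
  invisible(x)
}

#' Consensus growth signature across two screens
#'
#' Genes required for growth in both screens: significant (q < alpha) with
#' a negative growth (gamma) score in each, returned sorted by the mean of
#' the two standardized scores (most depleted first).
#'
#' @param growth_a,growth_b `gene_score_table`s for the gamma phenotype.
#' @param ortholog_map An [map_orthologs()] result.
#' @param alpha FDR threshold applied in both screens.
#' @return Character vector of screen-A symbols, with the provenance table
#'   attached as attribute `provenance`.
#' @export
consensus_signature <- function(growth_a, growth_b, ortholog_map,
                                alpha = 0.05) {
  hits <- conserved_hits(growth_a, growth_b, ortholog_map, kind = "gamma",
                         alpha = alpha)
  prov <- hits$provenance
  sel <- prov[prov$status == "sensitizing", , drop = FALSE]
  mean_std <- rowMeans(cbind(sel$score_std_a, sel$score_std_b))
  if (all(is.na(mean_std)) && nrow(sel)) {
    mean_std <- rowMeans(cbind(sel$score_a, sel$score_b))
  }
  out <- sel$symbol_a[order(mean_std)]
  attr(out, "provenance") <- sel[order(mean_std), , drop = FALSE]
  out
}
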