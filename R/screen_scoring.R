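#' Screen scoring configuration
#'
#' Bundles the tunable parameters of screen phenotype scoring. Doublings
#' are the per-condition population doublings used to put phenotypes on a
#' per-doubling scale: gamma uses the vehicle doublings, tau and rho the
#' drug doublings.
#'
#' @param pseudocount Nonnegative pseudocount added to relative abundances
#'   (see [compute_log2_ratio()]); default 1.
#' @param doublings Named numeric vector with entries `vehicle` and `drug`,
#'   both > 0.
#' @param alpha FDR threshold for hit calling, in (0, 1).
#' @param top_k Number of top-ranked elements averaged per gene.
#' @param target_depth Optional integer depth for [downsample_counts()].
#' @return A list of class `screen_config`.
#' @export
screen_config <- function(pseudocount = 1, doublings = c(vehicle = 10, drug = 5),
                          alpha = 0.05, top_k = 3L, target_depth = NULL) {
  pseudocount <- check_scalar(pseudocount, "pseudocount", min = 0)
  if (!all(c("vehicle", "drug") %in% names(doublings)) ||
      any(doublings[c("vehicle", "drug")] <= 0)) {
    stop_invalid("doublings must name 'vehicle' and 'drug', both > 0")
  }
  alpha <- check_scalar(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop_invalid("`alpha` must lie in (0, 1)")
  top_k <- check_count_arg(top_k, "top_k")
  if (!is.null(target_depth)) {
    target_depth <- check_count_arg(target_depth, "target_depth")
  }
  structure(list(pseudocount = pseudocount,
                 doublings = doublings[c("vehicle", "drug")],
                 alpha = alpha, top_k = top_k, target_depth = target_depth),
            class = "screen_config")
}

#' Downsample a count table to a common depth
#'
#' Subsamples each sample column without replacement (multivariate
#' hypergeometric) so its total equals `target_depth` exactly, emulating
#' downsampling of trimmed sequencing reads to equivalent amounts across
#' samples. Every output count is bounded by its input count and the draw
#' is seed-deterministic.
#'
#' @param table A [count_table].
#' @param target_depth Target column total; must not exceed any column sum.
#' @param seed Integer seed.
#' @return A [count_table] whose column sums all equal `target_depth`.
#' @export
downsample_counts <- function(table, target_depth, seed = 1L) {
  stopifnot(inherits(table, "count_table"))
  target_depth <- check_count_arg(target_depth, "target_depth", min = 0L)
  totals <- colSums(table$counts)
  low <- totals < target_depth
  if (any(low)) {
    stop_invalid("target_depth %d exceeds the total of sample(s): %s",
                 target_depth,
                 paste(colnames(table$counts)[low], collapse = ", "))
  }
  out <- with_seed(seed, {
    apply_cols <- table$counts
    for (j in seq_len(ncol(apply_cols))) {
      apply_cols[, j] <- rmvhyper(table$counts[, j], target_depth)
    }
    apply_cols
  })
  count_table(out, table$sample_meta)
}

# Sequential-conditional draw from the multivariate hypergeometric
# distribution: k balls drawn without replacement from an urn with
# counts[i] balls of color i.
rmvhyper <- function(counts, k) {
  n <- length(counts)
  out <- integer(n)
  remaining_draw <- k
  remaining_pool <- sum(counts)
  for (i in seq_len(n)) {
    if (remaining_draw == 0L) break
    ci <- counts[i]
    x <- stats::rhyper(1, m = ci, n = remaining_pool - ci, k = remaining_draw)
    out[i] <- x
    remaining_draw <- remaining_draw - x
    remaining_pool <- remaining_pool - ci
  }
  out
}

#' Log2 ratio of relative sgRNA abundances
#'
#' Converts two count vectors to relative abundances with a pseudocount
#' and returns the element-wise log2 ratio. The pseudocount is applied on
#' the relative-abundance scale: frequency = (count + pc) / (total + pc *
#' n), which makes ratios invariant to overall sequencing depth.
#'
#' @param numerator_counts,denominator_counts Equal-length nonnegative
#'   count vectors.
#' @param pseudocount Nonnegative; must be > 0 if any count is zero.
#' @return Numeric vector of finite log2 ratios.
#' @examples
#' compute_log2_ratio(c(0, 3), c(3, 0), pseudocount = 1)  # -2, +2
#' @export
compute_log2_ratio <- function(numerator_counts, denominator_counts,
                               pseudocount = 1) {
  if (length(numerator_counts) != length(denominator_counts)) {
    stop_invalid("count vectors must have equal length")
  }
  if (any(numerator_counts < 0) || any(denominator_counts < 0)) {
    stop_invalid("counts must be nonnegative")
  }
  pseudocount <- check_scalar(pseudocount, "pseudocount", min = 0)
  if (pseudocount == 0 &&
      (any(numerator_counts == 0) || any(denominator_counts == 0))) {
    stop_invalid("zero count with pseudocount 0 gives undefined log ratios")
  }
  n <- length(numerator_counts)
  fn <- (numerator_counts + pseudocount) /
    (sum(numerator_counts) + pseudocount * n)
  fd <- (denominator_counts + pseudocount) /
    (sum(denominator_counts) + pseudocount * n)
  log2(fn / fd)
}

#' Center log ratios on the non-targeting control median
#'
#' Subtracts the median log2 ratio of the non-targeting control elements,
#' so the NTC median of the returned vector is exactly zero.
#'
#' @param ratios Named numeric vector of per-element log2 ratios (names =
#'   element ids).
#' @param library An [sgrna_library] with at least 2 NTC elements present
#'   in `ratios`.
#' @return Centered ratios, same names and order.
#' @export
center_by_ntc <- function(ratios, library) {
  stopifnot(inherits(library, "sgrna_library"))
  if (is.null(names(ratios))) {
    stop_invalid("`ratios` must be named by element_id")
  }
  ntc <- intersect(ntc_ids(library), names(ratios))
  if (length(ntc) < 2L) {
    stop_invalid(
      "insufficient controls: need >= 2 non-targeting elements in ratios, found %d",
      length(ntc))
  }
  ratios - stats::median(ratios[ntc])
}

#' Element-level screen phenotypes (gamma, tau, rho)
#'
#' Computes the three screen phenotypes per library element from a count
#' table. Replicate samples of each condition are first summed into one
#' pseudo-sample; replicate-resolved ratios are used only by
#' [wald_test_replicates()]. For each phenotype kind the raw log2 ratio of
#' relative abundances ([compute_log2_ratio()]) is centered on the
#' non-targeting control (NTC) median, divided by the number of population
#' doublings, and finally standardized by the SD of the NTC phenotypes:
#'
#' * gamma = center(log2(vehicle / T0)) / d_vehicle  (growth)
#' * tau   = center(log2(drug / T0)) / d_drug        (drug)
#' * rho   = center(log2(drug / vehicle)) / d_drug   (drug/growth ratio)
#'
#' Elements present in the library but absent from the table are treated
#' as count 0.
#'
#' @param table A [count_table] with T0, vehicle and (for tau/rho) drug
#'   samples.
#' @param library An [sgrna_library] (>= 2 NTC elements).
#' @param config A [screen_config].
#' @param kinds Which phenotypes to compute.
#' @return A data frame of class `element_phenotypes` in long form:
#'   `element_id`, `gene`, `is_ntc`, `kind`, `raw`, `centered`,
#'   `phenotype`, `standardized`.
#' @export
compute_phenotypes <- function(table, library, config = screen_config(),
                               kinds = c("gamma", "tau", "rho")) {
  stopifnot(inherits(table, "count_table"), inherits(library, "sgrna_library"),
            inherits(config, "screen_config"))
  kinds <- match.arg(kinds, c("gamma", "tau", "rho"), several.ok = TRUE)

  needed_conditions <- unique(unlist(list(
    gamma = c("T0", "vehicle"), tau = c("T0", "drug"),
    rho = c("vehicle", "drug"))[kinds]))
  have <- unique(table$sample_meta$condition)
  missing <- setdiff(needed_conditions, have)
  if (length(missing)) {
    stop_invalid("missing condition(s) in count table: %s",
                 paste(missing, collapse = ", "))
  }

  # align to the library universe; absent elements become count 0
  sums <- vapply(have, function(cc) {
    v <- condition_sum(table, cc)
    out <- stats::setNames(numeric(nrow(library)), library$element_id)
    shared <- intersect(names(v), library$element_id)
    out[shared] <- v[shared]
    out
  }, numeric(nrow(library)))

  spec <- list(gamma = c("vehicle", "T0", "vehicle"),
               tau = c("drug", "T0", "drug"),
               rho = c("drug", "vehicle", "drug"))
  res <- lapply(kinds, function(k) {
    s <- spec[[k]]
    d <- unname(config$doublings[[if (s[3] == "vehicle") "vehicle" else "drug"]])
    raw <- compute_log2_ratio(sums[, s[1]], sums[, s[2]], config$pseudocount)
    names(raw) <- library$element_id
    centered <- center_by_ntc(raw, library)
    phenotype <- centered / d
    sd_ntc <- stats::sd(phenotype[library$is_ntc])
    if (!is.finite(sd_ntc) || sd_ntc == 0) {
      stop_invalid("NTC phenotype SD is zero or undefined for kind '%s'", k)
    }
    list(sd_ntc = sd_ntc,
         table = data.frame(element_id = library$element_id,
                            gene = library$gene, is_ntc = library$is_ntc,
                            kind = k, raw = unname(raw),
                            centered = unname(centered),
                            phenotype = unname(phenotype),
                            standardized = unname(phenotype / sd_ntc),
                            stringsAsFactors = FALSE))
  })
  out <- do.call(rbind, lapply(res, `[[`, "table"))
  rownames(out) <- NULL
  structure(out, doublings = config$doublings,
            pseudocount = config$pseudocount,
            ntc_sd = stats::setNames(vapply(res, `[[`, numeric(1), "sd_ntc"),
                                     kinds),
            class = c("element_phenotypes", "data.frame"))
}

#' Gene-level scores as the mean of the top-k elements
#'
#' Per gene, ranks its elements by absolute phenotype (sign preserved,
#' ties broken by element_id lexicographic order), takes the `top_k`
#' strongest and averages them; genes with fewer than `top_k` elements use
#' all of theirs. Non-targeting controls never contribute to a gene.
#'
#' @param phenos An `element_phenotypes` data frame from
#'   [compute_phenotypes()].
#' @param kind One of `"gamma"`, `"tau"`, `"rho"`.
#' @param top_k Number of elements averaged (default 3).
#' @param value Which representation to average: `"phenotype"`
#'   (per-doubling scale) or `"standardized"`.
#' @return Data frame: `gene`, `kind`, `score`, `score_std`, `n_elements`,
#'   `direction`.
#' @export
gene_scores_topk <- function(phenos, kind, top_k = 3L, value = "phenotype") {
  stopifnot(inherits(phenos, "element_phenotypes"))
  top_k <- check_count_arg(top_k, "top_k")
  value <- match.arg(value, c("phenotype", "standardized"))
  sub <- phenos[phenos$kind == kind & !phenos$is_ntc, , drop = FALSE]
  if (!nrow(sub)) {
    stop_invalid("phenotype kind '%s' not present in `phenos`", kind)
  }
  scale_std <- 1 / attr(phenos, "ntc_sd")[[kind]]
  groups <- split(sub, sub$gene)
  score <- vapply(groups, function(g) {
    ord <- order(-abs(g[[value]]), g$element_id)
    mean(g[[value]][ord[seq_len(min(top_k, nrow(g)))]])
  }, numeric(1))
  n_el <- vapply(groups, nrow, integer(1))
  out <- data.frame(gene = names(groups), kind = kind, score = unname(score),
                    score_std = if (value == "standardized") unname(score)
                                else unname(score) * scale_std,
                    n_elements = unname(n_el),
                    direction = ifelse(score > 0, "resistance",
                                       ifelse(score < 0, "sensitizing", "zero")),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Mann-Whitney U test of a gene's elements against the NTC distribution
#'
#' Two-sided rank-sum comparison of the phenotype values of one
#' perturbation's elements with the distribution of the non-targeting
#' control elements. The p-value is exact (full enumeration of rank
#' placements) when the combined sample size is at most 12 and there are
#' no ties; otherwise the normal approximation with continuity and tie
#' correction is used.
#'
#' @param gene_phenotypes,ntc_phenotypes Non-empty numeric vectors.
#' @return Two-sided p-value.
#' @export
mannwhitney_vs_ntc <- function(gene_phenotypes, ntc_phenotypes) {
  rank_sum_test(gene_phenotypes, ntc_phenotypes)$p_value
}

# Shared rank-sum engine for screen and single-cell comparisons.
rank_sum_test <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop_invalid("both groups must be non-empty")
  }
  ties <- anyDuplicated(c(x, y)) > 0
  exact <- (length(x) + length(y) <= 12L) && !ties
  w <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided", exact = exact,
                       correct = TRUE))
  list(statistic = unname(w$statistic), p_value = min(1, unname(w$p.value)))
}

#' Per-element Wald test across replicates
#'
#' For each element, tests whether its replicate log2 ratios are centered
#' at zero: z = mean / (s / sqrt(n)) with s the replicate SD, two-sided
#' p-value from the standard normal. Elements with zero replicate variance
#' get a variance floor equal to the median replicate SD over the
#' non-targeting control elements.
#'
#' @param per_replicate_log2ratios Replicates x elements matrix (colnames
#'   = element ids), e.g. from [replicate_log2_ratios()].
#' @param library An [sgrna_library].
#' @return Named vector of two-sided p-values, one per element.
#' @export
wald_test_replicates <- function(per_replicate_log2ratios, library) {
  stopifnot(is.matrix(per_replicate_log2ratios),
            inherits(library, "sgrna_library"))
  m <- per_replicate_log2ratios
  if (nrow(m) < 2L) {
    stop_invalid("insufficient replicates: Wald test needs >= 2, got %d",
                 nrow(m))
  }
  if (is.null(colnames(m))) stop_invalid("matrix must have element colnames")
  n <- nrow(m)
  mu <- colMeans(m)
  s <- apply(m, 2, stats::sd)
  ntc <- intersect(ntc_ids(library), colnames(m))
  floor_sd <- stats::median(s[ntc])
  zero_var <- s == 0
  if (any(zero_var)) {
    if (!is.finite(floor_sd) || floor_sd == 0) {
      stop_invalid("zero-variance elements present but NTC variance floor is 0")
    }
    s[zero_var] <- floor_sd
  }
  z <- mu / (s / sqrt(n))
  stats::setNames(2 * stats::pnorm(-abs(z)), colnames(m))
}

#' Replicate-resolved log2 ratios between two conditions
#'
#' Pairs replicates of the numerator and denominator conditions by
#' replicate id and computes one per-element NTC-centered log2 ratio per
#' replicate pair; input to [wald_test_replicates()].
#'
#' @param table A [count_table].
#' @param library An [sgrna_library].
#' @param numerator,denominator Condition labels.
#' @param pseudocount Passed to [compute_log2_ratio()].
#' @param center Center each replicate's ratios on the NTC median
#'   (default TRUE).
#' @return Replicates x elements matrix of log2 ratios.
#' @export
replicate_log2_ratios <- function(table, library, numerator, denominator,
                                  pseudocount = 1, center = TRUE) {
  stopifnot(inherits(table, "count_table"), inherits(library, "sgrna_library"))
  meta <- table$sample_meta
  reps <- intersect(meta$replicate[meta$condition == numerator],
                    meta$replicate[meta$condition == denominator])
  if (length(reps) < 2L) {
    stop_invalid("insufficient replicates: conditions '%s' and '%s' share %d replicate id(s), need >= 2",
                 numerator, denominator, length(reps))
  }
  out <- t(vapply(sort(reps), function(r) {
    s_num <- meta$sample[meta$condition == numerator & meta$replicate == r]
    s_den <- meta$sample[meta$condition == denominator & meta$replicate == r]
    num <- rowSums(table$counts[, s_num, drop = FALSE])
    den <- rowSums(table$counts[, s_den, drop = FALSE])
    v <- compute_log2_ratio(num, den, pseudocount)
    names(v) <- rownames(table$counts)
    if (center) v <- center_by_ntc(v, library)
    v
  }, numeric(nrow(table$counts))))
  rownames(out) <- paste0("r", sort(reps))
  out
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up false discovery rate control with monotonicity enforcement;
#' q >= p element-wise.
#'
#' @param p_values Numeric vector of p-values in \[0, 1\].
#' @return Vector of q-values, same length and names.
#' @export
adjust_fdr <- function(p_values) {
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop_invalid("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Gene-level score table with Mann-Whitney p-values and FDR
#'
#' Combines [gene_scores_topk()] with per-gene Mann-Whitney tests against
#' the non-targeting control phenotype distribution and Benjamini-Hochberg
#' adjustment.
#'
#' @inheritParams gene_scores_topk
#' @param config A [screen_config] supplying `top_k`.
#' @return Data frame of class `gene_score_table`: `gene`, `kind`,
#'   `score`, `score_std`, `p_value`, `q_value`, `n_elements`,
#'   `direction`.
#' @export
score_genes <- function(phenos, kind, config = screen_config()) {
  stopifnot(inherits(phenos, "element_phenotypes"))
  sub <- phenos[phenos$kind == kind, , drop = FALSE]
  if (!nrow(sub)) stop_invalid("phenotype kind '%s' not present", kind)
  scores <- gene_scores_topk(phenos, kind, top_k = config$top_k)
  ntc_vals <- sub$phenotype[sub$is_ntc]
  by_gene <- split(sub$phenotype[!sub$is_ntc], sub$gene[!sub$is_ntc])
  p <- vapply(scores$gene, function(g) {
    mannwhitney_vs_ntc(by_gene[[g]], ntc_vals)
  }, numeric(1))
  scores$p_value <- unname(p)
  scores$q_value <- adjust_fdr(scores$p_value)
  scores <- scores[, c("gene", "kind", "score", "score_std", "p_value",
                       "q_value", "n_elements", "direction")]
  class(scores) <- c("gene_score_table", "data.frame")
  scores
}

#' Call sensitizing and resistance hits
#'
#' Splits genes significant at `q < alpha` by the sign of their score:
#' negative scores sensitize (stronger depletion), positive confer
#' resistance. Significant genes with a score of exactly 0 are reported
#' separately as indeterminate.
#'
#' @param genes A `gene_score_table` from [score_genes()].
#' @param alpha FDR threshold.
#' @return List with character vectors `sensitizing`, `resistance`,
#'   `indeterminate`.
#' @export
call_hits <- function(genes, alpha = 0.05) {
  stopifnot(is.data.frame(genes), "q_value" %in% names(genes))
  alpha <- check_scalar(alpha, "alpha", min = 0, max = 1)
  sig <- genes$q_value < alpha
  list(sensitizing = genes$gene[sig & genes$score < 0],
       resistance = genes$gene[sig & genes$score > 0],
       indeterminate = genes$gene[sig & genes$score == 0])
}
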