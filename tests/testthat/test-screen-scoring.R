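test_that("downsample_counts draws exact without-replacement subsamples", {
  lib <- tiny_library(2, 1, 2)  # 4 elements
  m <- matrix(c(4L, 6L, 0L, 0L,
                10L, 0L, 0L, 0L), ncol = 2,
              dimnames = list(lib$element_id, c("T0_r1", "vehicle_r1")))
  ct <- count_table(m)
  ds <- downsample_counts(ct, 5, seed = 1)
  expect_equal(unname(colSums(ds$counts)), c(5, 5))
  expect_true(all(ds$counts <= m))
  # forced outcome: a column [10,0,0,0] must downsample to [5,0,0,0]
  expect_equal(unname(ds$counts[, "vehicle_r1"]), c(5L, 0L, 0L, 0L))

  # seed-deterministic replay, different seeds may differ
  expect_identical(downsample_counts(ct, 5, seed = 42)$counts,
                   downsample_counts(ct, 5, seed = 42)$counts)

  # target above a column total names the offending sample
  expect_error(downsample_counts(ct, 11, seed = 1), "T0_r1")
})

test_that("downsampled columns are hypergeometric draws, not truncation", {
  m <- matrix(c(5L, 5L), ncol = 1, dimnames = list(c("a", "b"), "T0_r1"))
  lib <- sgrna_library(data.frame(element_id = c("a", "b", "n1", "n2"),
                                  gene = c("G1", "G2", NA, NA),
                                  is_ntc = c(FALSE, FALSE, TRUE, TRUE)))
  ct <- count_table(rbind(m, n1 = 3L, n2 = 7L))
  draws <- vapply(1:200, function(s) {
    downsample_counts(ct, 4, seed = s)$counts["a", 1]
  }, integer(1))
  # marginal of a multivariate hypergeometric: mean k*K/N = 4*5/20 = 1
  expect_equal(mean(draws), 1, tolerance = 0.15)
  expect_true(all(draws <= 4) && length(unique(draws)) > 1)
})

test_that("compute_log2_ratio applies the pseudocount on the frequency scale", {
  # hand arithmetic: freq = (count + pc) / (total + pc * n)
  expect_equal(compute_log2_ratio(c(0, 3), c(3, 0), pseudocount = 1),
               c(-2, 2))
  # identical vectors give exactly zero everywhere
  v <- c(5, 1, 9, 0)
  expect_equal(compute_log2_ratio(v, v, 1), rep(0, 4))
  # depth-invariance: scaling both totals leaves pc = 0 ratios unchanged
  a <- c(8, 2, 6); b <- c(2, 4, 10)
  expect_equal(compute_log2_ratio(a * 10, b * 10, 0),
               compute_log2_ratio(a, b, 0))
  expect_error(compute_log2_ratio(c(0, 1), c(1, 1), 0), "undefined")
  expect_error(compute_log2_ratio(1:3, 1:2, 1), "equal length")
})

test_that("center_by_ntc zeroes the NTC median and is shift-invariant", {
  lib <- sgrna_library(data.frame(
    element_id = c("geneA", "ntc1", "ntc2", "ntc3"),
    gene = c("A", NA, NA, NA),
    is_ntc = c(FALSE, TRUE, TRUE, TRUE)))
  r <- c(geneA = 3, ntc1 = 1, ntc2 = 1, ntc3 = 2)
  expect_equal(center_by_ntc(r, lib),
               c(geneA = 2, ntc1 = 0, ntc2 = 0, ntc3 = 1))
  # all-equal ratios center to zero
  expect_equal(unname(center_by_ntc(setNames(rep(2, 4), names(r)), lib)),
               rep(0, 4))
  # adding a constant to all raw ratios leaves centered values unchanged
  expect_equal(center_by_ntc(r + 5, lib), center_by_ntc(r, lib))

  # odd NTC count: centered NTC median is exactly 0
  ids <- c("g1", paste0("n", 1:101))
  lib2 <- sgrna_library(data.frame(element_id = ids,
                                   gene = c("G", rep(NA, 101)),
                                   is_ntc = c(FALSE, rep(TRUE, 101))))
  r2 <- setNames(c(0.5, withr::with_seed(5, runif(101, -1, 1))), ids)
  centered <- center_by_ntc(r2, lib2)
  expect_identical(median(centered[-1]), 0)
})

test_that("compute_phenotypes implements gamma/tau/rho with NTC standardization", {
  lib <- tiny_library(4, 3, 5)
  ct <- tiny_counts(lib)
  cfg <- screen_config(doublings = c(vehicle = 10, drug = 5))
  ph <- compute_phenotypes(ct, lib, cfg)
  expect_s3_class(ph, "element_phenotypes")
  expect_setequal(unique(ph$kind), c("gamma", "tau", "rho"))

  # phenotype = centered / doublings (gamma: vehicle doublings)
  g <- ph[ph$kind == "gamma", ]
  expect_equal(g$phenotype, g$centered / 10)
  r <- ph[ph$kind == "rho", ]
  expect_equal(r$phenotype, r$centered / 5)

  # NTC median of centered values is 0; standardized NTC SD is 1
  for (k in c("gamma", "tau", "rho")) {
    sub <- ph[ph$kind == k, ]
    expect_equal(median(sub$centered[sub$is_ntc]), 0)
    expect_equal(sd(sub$standardized[sub$is_ntc]), 1, tolerance = 1e-9)
  }

  # log identity: raw rho = raw tau - raw gamma, exactly
  wide <- reshape(ph[, c("element_id", "kind", "raw")], idvar = "element_id",
                  timevar = "kind", direction = "wide")
  expect_equal(wide$raw.rho, wide$raw.tau - wide$raw.gamma,
               tolerance = 1e-12)

  # missing condition errors
  veh_only <- count_table(ct$counts[, grep("drug", colnames(ct$counts),
                                           invert = TRUE, value = TRUE)])
  expect_error(compute_phenotypes(veh_only, lib, cfg, kinds = "tau"),
               "missing condition")
})

test_that("gamma recovers a planted growth effect from a simulated screen", {
  lib <- simulate_library(50, 5, n_ntc = 40, seed = 1)
  eff <- effect_spec("GENE00001", growth_effect = -0.2)
  sim <- simulate_screen(lib, eff, doublings = c(vehicle = 10, drug = 5),
                         replicates = 3, depth = 1000, dispersion = 0.01,
                         seed = 11)
  ph <- compute_phenotypes(sim$counts, lib, screen_config())
  g <- ph[ph$kind == "gamma" & !ph$is_ntc & ph$gene == "GENE00001", ]
  expect_true(mean(g$phenotype) > -0.25 && mean(g$phenotype) < -0.15)
})

test_that("gene_scores_topk averages the top elements by |phenotype|", {
  lib <- sgrna_library(data.frame(
    element_id = c(paste0("A_sg", 1:5), paste0("B_sg", 1:2), "n1", "n2", "n3"),
    gene = c(rep("A", 5), rep("B", 2), NA, NA, NA),
    is_ntc = c(rep(FALSE, 7), TRUE, TRUE, TRUE)))
  ph <- structure(
    data.frame(element_id = lib$element_id, gene = lib$gene,
               is_ntc = lib$is_ntc, kind = "gamma",
               raw = 0, centered = 0,
               phenotype = c(-4, -3, -1, 0, 2, -1, -2, 0.1, -0.1, 0),
               standardized = c(-4, -3, -1, 0, 2, -1, -2, 0.1, -0.1, 0) / 0.1),
    ntc_sd = c(gamma = 0.1),
    class = c("element_phenotypes", "data.frame"))
  gs <- gene_scores_topk(ph, "gamma", top_k = 3)
  expect_equal(gs$score[gs$gene == "A"], mean(c(-4, -3, 2)))
  # fewer elements than top_k: use all
  expect_equal(gs$score[gs$gene == "B"], -1.5)
  expect_equal(gs$n_elements, c(5L, 2L))
  expect_equal(gs$direction, c("sensitizing", "sensitizing"))
  expect_equal(gs$score_std, gs$score / 0.1)

  # absolute-value tie at the cut rank resolved by element_id order
  ph2 <- ph
  ph2$phenotype <- c(-3, 2, -1, 1, 0, -1, -2, 0.1, -0.1, 0)
  gs2 <- gene_scores_topk(ph2, "gamma", top_k = 3)
  # |.| ranking: -3, 2, then tie between A_sg3 (-1) and A_sg4 (1) -> A_sg3
  expect_equal(gs2$score[gs2$gene == "A"], mean(c(-3, 2, -1)))
  expect_error(gene_scores_topk(ph, "tau", 3), "not present")
})

test_that("mannwhitney_vs_ntc gives exact small-sample p-values", {
  expect_equal(mannwhitney_vs_ntc(3, c(0, 1, 2)), 0.5)
  expect_equal(mannwhitney_vs_ntc(c(10, 11, 12), c(0:4)), 2 / 56)
  # identical tied groups sit at the U midpoint
  expect_equal(mannwhitney_vs_ntc(c(1, 2), c(1, 2)), 1.0)
  expect_error(mannwhitney_vs_ntc(numeric(0), 1:3), "non-empty")
})

test_that("rank-sum engine matches full enumeration on tie-free inputs", {
  set.seed(101)
  for (n1 in 1:5) {
    for (n2 in seq_len(10 - n1)) {
      x <- sample(seq(1, 200), n1)
      y <- sample(setdiff(seq(1, 200), x), n2)
      expect_equal(mannwhitney_vs_ntc(x, y), mw_enumerate_p(x, y),
                   tolerance = 1e-12,
                   info = sprintf("n1=%d n2=%d", n1, n2))
    }
  }
})

test_that("wald_test_replicates matches the closed form and its floor rule", {
  lib <- sgrna_library(data.frame(element_id = c("a", "n1", "n2", "n3"),
                                  gene = c("A", NA, NA, NA),
                                  is_ntc = c(FALSE, TRUE, TRUE, TRUE)))
  m <- rbind(r1 = c(a = 0.5, n1 = 0.1, n2 = -0.2, n3 = 0.05),
             r2 = c(a = 0.7, n1 = 0.2, n2 = -0.1, n3 = 0.00),
             r3 = c(a = 0.6, n1 = 0.0, n2 = -0.3, n3 = -0.05))
  p <- wald_test_replicates(m, lib)
  z <- 0.6 / (0.1 / sqrt(3))
  expect_equal(unname(p["a"]), 2 * pnorm(-abs(z)), tolerance = 1e-12)

  # sign symmetry
  expect_equal(wald_test_replicates(-m, lib), p, tolerance = 1e-12)

  # zero-variance element falls back to the NTC median SD floor; a
  # zero-mean zero-variance element must give p = 1
  m2 <- m
  m2[, "a"] <- 0
  p2 <- wald_test_replicates(m2, lib)
  expect_equal(unname(p2["a"]), 1)

  expect_error(wald_test_replicates(m[1, , drop = FALSE], lib),
               "insufficient replicates")
})

test_that("adjust_fdr is Benjamini-Hochberg with monotonicity", {
  expect_equal(adjust_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(adjust_fdr(0.2), 0.2)
  expect_equal(adjust_fdr(rep(1, 5)), rep(1, 5))
  expect_error(adjust_fdr(c(0.5, 1.2)), "\\[0, 1\\]")
  set.seed(202)
  for (i in 1:20) {
    p <- runif(sample(1:50, 1))
    q <- adjust_fdr(p)
    expect_equal(q, bh_oracle(p), tolerance = 1e-12)
    expect_true(all(q >= p - 1e-15))
  }
})

test_that("call_hits splits significant genes by sign", {
  tab <- data.frame(gene = c("A", "B", "C", "D"),
                    score = c(-0.3, 0.2, -0.5, 0),
                    q_value = c(0.01, 0.04, 0.2, 0.02))
  h <- call_hits(tab, alpha = 0.05)
  expect_equal(h$sensitizing, "A")
  expect_equal(h$resistance, "B")
  expect_equal(h$indeterminate, "D")
  h0 <- call_hits(tab, alpha = 1e-9)
  expect_length(h0$sensitizing, 0)
  expect_length(h0$resistance, 0)
})

test_that("replicate-resolved ratios feed a calibrated Wald test", {
  lib <- simulate_library(30, 3, n_ntc = 20, seed = 6)
  sim <- simulate_screen(lib, NULL, replicates = 3, depth = 500,
                         dispersion = 0.01, seed = 7)
  m <- replicate_log2_ratios(sim$counts, lib, "drug", "vehicle")
  expect_equal(dim(m), c(3, nrow(lib)))
  p <- wald_test_replicates(m, lib)
  # no planted effects: the bulk of p-values stays away from zero
  expect_gt(median(p), 0.2)
  expect_true(all(p >= 0 & p <= 1))
})
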