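#' Simulate a pooled CRISPRi screen count table
#'
#' Generates seed-deterministic sgRNA counts for a T0, a vehicle, and a
#' drug condition under an exponential growth model with per-doubling log2
#' fitness offsets. Element i of gene g starts at abundance
#' `a_i ~ LogNormal(0, abundance_sdlog)`; after `d_c` population doublings
#' in condition c its expected relative abundance is
#' `a_i * 2^(d_c * (1 + k_i * phi))`, where `phi` is the gene's
#' `growth_effect` in vehicle, `growth_effect + drug_effect` under drug,
#' and 0 for non-targeting controls, and `k_i` is the element knockdown.
#' Proportions are renormalized per sample and counts drawn
#' negative-binomial (Gamma-Poisson) with mean
#' `depth * n_elements * proportion` and variance `mu + dispersion * mu^2`,
#' independently per replicate. `dispersion = 0` gives Poisson counts.
#'
#' @param library An [sgrna_library].
#' @param effects An [effect_spec]; genes absent from it default to zero
#'   effects. Genes not present in the library are an error.
#' @param doublings Named numeric vector of population doublings per
#'   condition; must contain `vehicle` and `drug` (both >= 0); `T0` is
#'   fixed at 0.
#' @param replicates Number of replicates per condition (>= 1).
#' @param depth Mean reads per element per sample (> 0).
#' @param dispersion Negative-binomial overdispersion (>= 0), default 0.05.
#' @param seed Integer seed; regeneration with identical arguments is
#'   bit-identical.
#' @param abundance_sdlog SD (log scale) of the initial abundance skew.
#' @return A list of class `simulated_screen` with elements `library`,
#'   `counts` (a [count_table]), `effects`, `truth` (per-element true
#'   gamma/tau/rho), `doublings`, `depth`, `dispersion`, and `seed`.
#' @examples
#' lib <- simulate_library(10, 2, n_ntc = 5, seed = 1)
#' eff <- effect_spec("GENE00001", growth_effect = -0.3)
#' sim <- simulate_screen(lib, eff, replicates = 2, depth = 200, seed = 1)
#' sim$counts
#' @export
simulate_screen <- function(library, effects = NULL,
                            doublings = c(vehicle = 10, drug = 5),
                            replicates = 2L, depth = 500, dispersion = 0.05,
                            seed = 1L, abundance_sdlog = 0.5) {
  stopifnot(inherits(library, "sgrna_library"))
  replicates <- check_count_arg(replicates, "replicates")
  depth <- check_scalar(depth, "depth")
  if (depth <= 0) stop_invalid("`depth` must be > 0")
  dispersion <- check_scalar(dispersion, "dispersion", min = 0)
  if (!all(c("vehicle", "drug") %in% names(doublings))) {
    stop_invalid("doublings must name 'vehicle' and 'drug'")
  }
  if (any(doublings < 0)) stop_invalid("doublings must be >= 0")
  d <- c(T0 = 0, vehicle = unname(doublings["vehicle"]),
         drug = unname(doublings["drug"]))

  if (is.null(effects)) effects <- effect_spec(character(0))
  stopifnot(inherits(effects, "effect_spec") || is.data.frame(effects))
  lib_genes <- unique(library$gene[!library$is_ntc])
  unknown <- setdiff(effects$gene, lib_genes)
  if (length(unknown)) {
    stop_invalid("effects name gene(s) absent from the library: %s",
                 paste(unknown, collapse = ", "))
  }

  n <- nrow(library)
  idx <- match(library$gene, effects$gene)
  g_eff <- ifelse(is.na(idx), 0, effects$growth_effect[idx])
  d_eff <- ifelse(is.na(idx), 0, effects$drug_effect[idx])
  kd <- ifelse(is.na(idx), 1, effects$knockdown[idx])
  g_eff[library$is_ntc] <- 0
  d_eff[library$is_ntc] <- 0
  kd[library$is_ntc] <- 0

  # per-condition fitness offset phi (per-doubling, log2)
  phi <- cbind(T0 = 0, vehicle = kd * g_eff, drug = kd * (g_eff + d_eff))

  conditions <- c("T0", "vehicle", "drug")
  sample_names <- as.vector(vapply(conditions, function(cc) {
    paste0(cc, "_r", seq_len(replicates))
  }, character(replicates)))

  counts <- with_seed(seed, {
    a <- stats::rlnorm(n, 0, abundance_sdlog)
    out <- matrix(0L, nrow = n, ncol = length(sample_names),
                  dimnames = list(library$element_id, sample_names))
    for (cc in conditions) {
      w <- a * 2 ^ (d[cc] * (1 + phi[, cc]))
      p <- w / sum(w)
      mu <- depth * n * p
      for (r in seq_len(replicates)) {
        col <- paste0(cc, "_r", r)
        x <- if (dispersion == 0) {
          stats::rpois(n, mu)
        } else {
          stats::rnbinom(n, size = 1 / dispersion, mu = mu)
        }
        out[, col] <- as.integer(x)
      }
    }
    out
  })

  truth <- data.frame(
    element_id = library$element_id,
    gene = library$gene,
    is_ntc = library$is_ntc,
    gamma_true = kd * g_eff,
    tau_true = kd * (g_eff + d_eff),
    rho_true = if (d["drug"] > 0) {
      (d["drug"] * kd * (g_eff + d_eff) - d["vehicle"] * kd * g_eff) / d["drug"]
    } else NA_real_,
    stringsAsFactors = FALSE
  )

  structure(list(library = library, counts = count_table(counts),
                 effects = effects, truth = truth,
                 doublings = d[c("vehicle", "drug")], depth = depth,
                 dispersion = dispersion, seed = as.integer(seed)),
            class = "simulated_screen")
}

#' @export
print.simulated_screen <- function(x, ...) {
  cat(sprintf("simulated screen: %d elements, depth %g, dispersion %g, seed %d\n",
              nrow(x$library), x$depth, x$dispersion, x$seed))
  print(x$counts)
  invisible(x)
}
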