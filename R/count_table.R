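#' Count table objects
#'
#' A count table holds elements x samples nonnegative integer sgRNA counts
#' together with per-sample metadata (condition and replicate id). It is
#' the raw input to all screen scoring.
#'
#' @param counts Integer matrix, elements in rows (rownames = element ids),
#'   samples in columns (colnames = sample ids).
#' @param sample_meta Data frame with columns `sample`, `condition`
#'   (one of `"T0"`, `"vehicle"`, `"drug"`), `replicate`. Row order must
#'   cover all columns of `counts`. If `NULL`, metadata are parsed from
#'   sample names of the form `<condition>_r<replicate>`.
#' @return An object of class `count_table`: a list with elements `counts`
#'   and `sample_meta`.
#' @examples
#' m <- matrix(1:6, nrow = 3,
#'             dimnames = list(c("a", "b", "c"), c("T0_r1", "vehicle_r1")))
#' ct <- count_table(m)
#' ct$sample_meta
#' @export
count_table <- function(counts, sample_meta = NULL) {
  stopifnot(is.matrix(counts))
  if (is.null(rownames(counts)) || is.null(colnames(counts))) {
    stop_invalid("counts must have element rownames and sample colnames")
  }
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop_invalid("counts must be nonnegative integers")
  }
  storage.mode(counts) <- "integer"
  if (is.null(sample_meta)) {
    sample_meta <- parse_sample_names(colnames(counts))
  }
  stopifnot(is.data.frame(sample_meta))
  needed <- c("sample", "condition", "replicate")
  if (!all(needed %in% names(sample_meta))) {
    stop_invalid("sample_meta needs columns: %s", paste(needed, collapse = ", "))
  }
  sample_meta$sample <- as.character(sample_meta$sample)
  sample_meta$condition <- as.character(sample_meta$condition)
  missing <- setdiff(colnames(counts), sample_meta$sample)
  if (length(missing)) {
    stop_invalid("sample_meta lacks entries for sample(s): %s",
                 paste(missing, collapse = ", "))
  }
  sample_meta <- sample_meta[match(colnames(counts), sample_meta$sample), ,
                             drop = FALSE]
  rownames(sample_meta) <- NULL
  bad <- setdiff(unique(sample_meta$condition), c("T0", "vehicle", "drug"))
  if (length(bad)) {
    stop_invalid("unknown condition(s): %s (expected T0/vehicle/drug)",
                 paste(bad, collapse = ", "))
  }
  structure(list(counts = counts, sample_meta = sample_meta),
            class = "count_table")
}

parse_sample_names <- function(samples) {
  m <- regmatches(samples, regexec("^(T0|vehicle|drug)_r([0-9]+)$", samples))
  bad <- samples[vapply(m, length, 1L) == 0L]
  if (length(bad)) {
    stop_invalid(
      "cannot parse condition/replicate from sample name(s): %s; supply sample_meta",
      paste(bad, collapse = ", "))
  }
  data.frame(sample = samples,
             condition = vapply(m, `[`, "", 2L),
             replicate = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

#' @export
print.count_table <- function(x, ...) {
  tab <- table(x$sample_meta$condition)
  cat(sprintf("count table: %d elements x %d samples (%s)\n",
              nrow(x$counts), ncol(x$counts),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' @rdname count_table
#' @param x A `count_table`.
#' @param condition Condition label.
#' @export
samples_for <- function(x, condition) {
  x$sample_meta$sample[x$sample_meta$condition == condition]
}

# Sum replicate columns of one condition into a single pseudo-sample
# vector. Used for phenotype point estimates.
condition_sum <- function(table, condition) {
  s <- samples_for(table, condition)
  if (!length(s)) {
    stop_invalid("count table has no '%s' samples", condition)
  }
  rowSums(table$counts[, s, drop = FALSE])
}
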