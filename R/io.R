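#' Read and write sgRNA libraries
#'
#' Libraries are stored as CSV with columns
#' `element_id,gene,is_ntc,protospacer` (gene empty for non-targeting
#' elements).
#'
#' @param path File path.
#' @param species Species label attached on read.
#' @return `read_sgrna_library()`: an [sgrna_library].
#' @export
read_sgrna_library <- function(path, species = "unspecified") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character")
  if (!"is_ntc" %in% names(df)) stop_invalid("library CSV lacks is_ntc column")
  df$is_ntc <- df$is_ntc %in% c("TRUE", "true", "1")
  df$gene[df$gene == ""] <- NA_character_
  sgrna_library(df, species = species)
}

#' @rdname read_sgrna_library
#' @param library An [sgrna_library].
#' @export
write_sgrna_library <- function(library, path) {
  stopifnot(inherits(library, "sgrna_library"))
  df <- as.data.frame(library)
  df$gene[is.na(df$gene)] <- ""
  utils::write.csv(df[, c("element_id", "gene", "is_ntc", "protospacer")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a count table from TSV
#'
#' Expects a TSV whose first column holds element ids and whose header row
#' holds sample ids. Sample condition/replicate metadata come from a
#' sidecar data frame or, by default, from sample names of the form
#' `<condition>_r<replicate>`. When a library is supplied, elements
#' unknown to it are dropped with a warning (the exclusion list is kept as
#' attribute `excluded`), and library elements missing from the file are
#' filled with 0 counts and logged via message.
#'
#' @param path TSV path.
#' @param library Optional [sgrna_library] to validate against.
#' @param sample_meta Optional data frame (`sample`, `condition`,
#'   `replicate`).
#' @return A [count_table].
#' @export
read_count_table <- function(path, library = NULL, sample_meta = NULL) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop_invalid("count TSV needs an id column plus samples")
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop_invalid("duplicate element id(s) in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(m)) {
    bad <- which(is.na(suppressWarnings(apply(df[, -1, drop = FALSE], 2,
                                              as.numeric))), arr.ind = TRUE)
    stop_invalid("non-numeric count at row %s, column '%s' of %s",
                 ids[bad[1, 1]], colnames(df)[-1][bad[1, 2]], path)
  }
  neg <- which(m < 0, arr.ind = TRUE)
  if (nrow(neg)) {
    stop_invalid("negative count at element '%s', sample '%s' in %s",
                 ids[neg[1, 1]], colnames(m)[neg[1, 2]], path)
  }
  rownames(m) <- ids
  excluded <- character(0)
  if (!is.null(library)) {
    excluded <- setdiff(ids, library$element_id)
    if (length(excluded)) {
      warning(sprintf("%d element(s) not in library excluded (e.g. %s)",
                      length(excluded), excluded[1]), call. = FALSE)
      m <- m[setdiff(ids, excluded), , drop = FALSE]
    }
    missing <- setdiff(library$element_id, rownames(m))
    if (length(missing)) {
      message(sprintf("%d library element(s) absent from %s filled with 0",
                      length(missing), path))
      fill <- matrix(0L, nrow = length(missing), ncol = ncol(m),
                     dimnames = list(missing, colnames(m)))
      m <- rbind(m, fill)
      m <- m[library$element_id, , drop = FALSE]
    }
  }
  out <- count_table(m, sample_meta)
  attr(out, "excluded") <- excluded
  out
}

#' @rdname read_count_table
#' @param table A [count_table].
#' @export
write_count_table <- function(table, path) {
  stopifnot(inherits(table, "count_table"))
  df <- data.frame(element_id = rownames(table$counts), table$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read and write GMT gene-set files
#'
#' Standard GMT: one set per line, tab-separated fields `name`,
#' `description`, then member genes. Duplicate genes within a set are
#' collapsed with a warning; a line with no genes is an error naming the
#' set.
#'
#' @param path GMT path.
#' @return `read_gmt()`: a named list of [gene_signature]s (empty list for
#'   an empty file, with a warning).
#' @export
read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning(sprintf("GMT file %s is empty", path), call. = FALSE)
    return(list())
  }
  sigs <- lapply(lines, function(l) {
    f <- strsplit(l, "\t", fixed = TRUE)[[1]]
    genes <- f[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (!length(genes)) {
      stop_invalid("GMT set '%s' has an empty gene list", f[1])
    }
    if (anyDuplicated(genes)) {
      warning(sprintf("GMT set '%s': %d duplicate gene(s) collapsed",
                      f[1], sum(duplicated(genes))), call. = FALSE)
    }
    gene_signature(f[1], genes)
  })
  stats::setNames(sigs, vapply(sigs, `[[`, "", "name"))
}

#' @rdname read_gmt
#' @param signatures A list of [gene_signature]s.
#' @param description Description field written for each set.
#' @export
write_gmt <- function(signatures, path, description = "na") {
  lines <- vapply(signatures, function(s) {
    paste(c(s$name, description, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write element phenotypes / gene scores as TSV
#'
#' @param x A data frame (e.g. `element_phenotypes` or
#'   `gene_score_table`).
#' @param path Output TSV path.
#' @export
write_tsv <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_tsv
#' @export
read_tsv <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
}

#' Write a run manifest
#'
#' Every pipeline stage emits a JSON manifest recording the command, all
#' parameter values, input-file checksums, the seed, the package version
#' and a timestamp, so deterministic stages can be reproduced
#' bit-identically.
#'
#' @param command Stage name.
#' @param params Named list of parameter values.
#' @param inputs Character vector of input file paths (md5-checksummed).
#' @param seed Integer seed used by the stage (or NULL).
#' @param path Output JSON path.
#' @export
write_manifest <- function(command, params, inputs = character(0),
                           seed = NULL, path) {
  manifest <- list(
    command = command,
    params = params,
    inputs = if (length(inputs)) {
      data.frame(path = inputs, md5 = unname(tools::md5sum(inputs)),
                 stringsAsFactors = FALSE)
    } else NULL,
    seed = seed,
    version = as.character(utils::packageVersion("screenstate")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  invisible(path)
}
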