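#' Read a raw microarray spot table
#'
#' A spot table holds one row per (spot, sample) measurement: the spot
#' identifier, the gene symbol it probes (empty for control spots), the
#' sample label `"<phenotype>.<replica>"`, foreground and background
#' fluorescence, and a quality flag (`ok` or `corrupted`).  One file may hold
#' a single array or a long table covering several samples.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param dialect Either `"simple_tsv"` (columns `spot_id`, `gene`, `sample`,
#'   `fg`, `bg`, `flag`) or `"agilent_like"` (feature-extraction style columns
#'   `FeatureNum`, `GeneName`, `Sample`, `gMeanSignal`, `gBGMeanSignal`,
#'   `IsFlagged`, mapped onto the simple layout; `IsFlagged != 0` means
#'   corrupted).
#' @return A `spot_table`: a validated data frame with the six mandatory
#'   columns; any further input columns are preserved untouched.
#' @seealso [spot_table()] for constructing one in memory,
#'   [write_spot_table()] for the inverse operation.
#' @export
read_spot_table <- function(path, dialect = c("simple_tsv", "agilent_like")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = NA, na.strings = character())
  if (dialect == "agilent_like") {
    map <- c(FeatureNum = "spot_id", GeneName = "gene", Sample = "sample",
             gMeanSignal = "fg", gBGMeanSignal = "bg", IsFlagged = "flag")
    missing <- setdiff(names(map), names(df))
    if (length(missing))
      stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
    names(df)[match(names(map), names(df))] <- map
    df$flag <- ifelse(df$flag %in% c(0, "0"), "ok", "corrupted")
  }
  spot_table(df)
}

#' Construct and validate a spot table
#'
#' @param df Data frame with at least the columns `spot_id`, `gene`,
#'   `sample`, `fg`, `bg`, `flag`.
#' @return The validated data frame with class `spot_table`.
#' @export
spot_table <- function(df) {
  mandatory <- c("spot_id", "gene", "sample", "fg", "bg", "flag")
  missing <- setdiff(mandatory, names(df))
  if (length(missing))
    stop("missing mandatory column(s): ", paste(missing, collapse = ", "))
  df$spot_id <- as.character(df$spot_id)
  df$gene <- as.character(df$gene)
  df$gene[is.na(df$gene)] <- ""
  df$sample <- as.character(df$sample)
  df$fg <- as.numeric(df$fg)
  df$bg <- as.numeric(df$bg)
  df$flag <- as.character(df$flag)
  bad <- which(!is.finite(df$fg) | df$fg < 0 | !is.finite(df$bg) | df$bg < 0)
  if (length(bad))
    stop("negative or non-finite fg/bg at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  badflag <- which(!df$flag %in% c("ok", "corrupted"))
  if (length(badflag))
    stop("flag must be 'ok' or 'corrupted'; offending row(s): ",
         paste(utils::head(badflag, 5L), collapse = ", "))
  parse_sample_labels(unique(df$sample))      # errors on malformed labels
  dup <- duplicated(df[c("spot_id", "sample")])
  if (any(dup))
    stop("duplicated (spot_id, sample) measurement(s), e.g. spot ",
         df$spot_id[which(dup)[1L]])
  class(df) <- c("spot_table", "data.frame")
  df
}

#' Write a spot table to TSV
#'
#' @param x A `spot_table` (or plain data frame with the mandatory columns).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_spot_table <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read gene sets from a GMT file
#'
#' Standard GMT: one tab-separated line per set, `name`, `description`, then
#' gene symbols.  Duplicate symbols within a line are retained once,
#' preserving first-occurrence order.
#'
#' @param path Path to a GMT file.
#' @return A named list of `gene_set` objects, each a list with elements
#'   `name`, `description` and `genes`.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- lapply(seq_along(lines), function(i) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    if (length(fields) < 3L)
      stop("GMT line ", i, " has fewer than 3 tab-separated fields")
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    genes <- genes[!duplicated(toupper(genes))]
    if (!length(genes)) stop("GMT line ", i, " names no genes")
    structure(list(name = fields[[1L]], description = fields[[2L]],
                   genes = genes),
              class = "gene_set")
  })
  names(sets) <- vapply(sets, `[[`, "", "name")
  sets
}

#' @export
print.gene_set <- function(x, ...) {
  cat("Gene set", x$name, "-", x$description, "\n")
  cat(" ", length(x$genes), "genes:",
      paste(utils::head(x$genes, 8L), collapse = ", "),
      if (length(x$genes) > 8L) "..." else "", "\n")
  invisible(x)
}

#' Construct an interaction list around a central gene block
#'
#' Describes the curated neighbourhood of a pathway block (for instance
#' Akt1/Akt2/Akt3): upstream activators and inhibitors, downstream activated
#' and inhibited genes.  Used by [interaction_consistency()] to test whether
#' observed expression coordination carries the signs the pathway topology
#' predicts.
#'
#' @param center_block Character vector of central gene symbols.
#' @param partners Data frame with columns `gene` and `role`; `role` must be
#'   one of `upstream_activator`, `upstream_inhibitor`, `downstream_activated`,
#'   `downstream_inhibited`.
#' @return An `interaction_list` object.
#' @export
interaction_list <- function(center_block, partners) {
  roles <- c("upstream_activator", "upstream_inhibitor",
             "downstream_activated", "downstream_inhibited")
  if (!length(center_block)) stop("center_block must name at least one gene")
  if (!all(c("gene", "role") %in% names(partners)))
    stop("partners needs columns 'gene' and 'role'")
  partners$gene <- as.character(partners$gene)
  partners$role <- as.character(partners$role)
  bad <- setdiff(unique(partners$role), roles)
  if (length(bad))
    stop("unknown role(s): ", paste(bad, collapse = ", "))
  conflict <- tapply(partners$role, toupper(partners$gene),
                     function(r) length(unique(r)) > 1L)
  if (any(conflict))
    stop("partner(s) listed with conflicting roles: ",
         paste(names(conflict)[conflict], collapse = ", "))
  partners <- partners[!duplicated(toupper(partners$gene)), , drop = FALSE]
  structure(list(center_block = as.character(center_block),
                 partners = partners[c("gene", "role")]),
            class = "interaction_list")
}

#' Read an interaction list from TSV
#'
#' @param path TSV with header columns `gene` and `role`.
#' @param center_block Character vector with the central gene symbols.
#' @return An [interaction_list()].
#' @export
read_interactions <- function(path, center_block) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  interaction_list(center_block, df)
}

#' Write a results table to TSV
#'
#' Emits any of the pipeline's tabular results (regulation records,
#' quantifier tables, network edge lists, ...) with a stable column order and
#' floating-point values at 6 significant digits, so that a write-then-read
#' round trip reproduces the values at that precision.
#'
#' @param records Non-empty data frame (or object coercible to one).
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_results_table <- function(records, path) {
  df <- as.data.frame(records)
  if (!nrow(df) || !ncol(df)) stop("refusing to write an empty results table")
  for (j in seq_along(df))
    if (is.double(df[[j]])) df[[j]] <- signif(df[[j]], 6L)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build a fabric object from a normalized expression matrix
#'
#' Re-analysis entry point for data distributed as a series-matrix-like TSV
#' (first column gene identifiers, remaining columns one sample each,
#' labelled `"<phenotype>.<replica>"`).  Each gene is treated as probed by a
#' single spot.  Values must be strictly positive.
#'
#' @param x Path to a TSV file, or a numeric matrix with gene rownames and
#'   sample-label colnames.
#' @param renormalize If `TRUE` (default) each phenotype is rescaled so the
#'   median-gene AVE is exactly 1, the unit in which all downstream
#'   quantifiers are expressed.
#' @return A [fabric] object.
#' @export
fabric_from_matrix <- function(x, renormalize = TRUE) {
  if (is.character(x)) {
    df <- utils::read.delim(x, stringsAsFactors = FALSE, check.names = FALSE)
    if (ncol(df) < 3L) stop("expression matrix needs >= 2 sample columns")
    mat <- as.matrix(df[-1L])
    rownames(mat) <- as.character(df[[1L]])
  } else {
    mat <- as.matrix(x)
  }
  if (is.null(rownames(mat)) || is.null(colnames(mat)))
    stop("expression matrix needs gene rownames and sample colnames")
  storage.mode(mat) <- "double"
  if (any(!is.finite(mat)) || any(mat <= 0))
    stop("expression values must be finite and strictly positive")
  info <- parse_sample_labels(colnames(mat))
  build_fabric_from_values(values = mat,
                           spot_id = paste0(rownames(mat), "_1"),
                           gene = rownames(mat),
                           sample_info = info,
                           renormalize = renormalize,
                           trace = NULL,
                           filter_report = NULL)
}
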