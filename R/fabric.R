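#' Fit the genomic-fabric quantifiers of a redundant-spot experiment
#'
#' The main entry point of the package.  Takes raw spot tables covering
#' every profiled sample, applies the spot-quality filter (a spot must be
#' `ok` and have foreground at least twice the background in every sample),
#' background-subtracts, runs the alternating intra-/inter-array median-gene
#' normalization until the error of estimate drops below `tol` percent, and
#' computes the per-gene quantifiers of every phenotype: average expression
#' level AVE (in units of the phenotype's median gene), relative expression
#' variability REV (the chi-square mid-interval estimate of the pooled
#' coefficient of variation, in percent) and spot redundancy R.
#'
#' @param x A `spot_table`, a list of them, or a directory containing
#'   `*.tsv` spot tables (read with [read_spot_table()]).
#' @param tol Normalization convergence tolerance, in percent.
#' @param max_iter Maximum normalization iterations.
#' @param dialect Spot-table dialect, used only when `x` is a directory.
#' @return An object of class `fabric`: a list with per-phenotype
#'   `tensors` (gene x spot x replica expression), `quantifiers` (data frame
#'   of gene, R, df, correction, AVE, REV), the spot `filter` report and the
#'   `normalization` trace.  Use [coordination()], [regulation()],
#'   [gch()], [fabric_network()] and [interaction_consistency()] on it.
#' @examples
#' des <- default_design("tiny", n_genes = 40)
#' sim <- simulate_experiment(des)
#' fit <- fabric(sim$tables)
#' fit
#' head(quantifiers(fit, "MRLp"))
#' @export
fabric <- function(x, tol = 5, max_iter = 100L,
                   dialect = c("simple_tsv", "agilent_like")) {
  cl <- match.call()
  if (is.character(x) && length(x) == 1L && dir.exists(x)) {
    dialect <- match.arg(dialect)
    files <- list.files(x, pattern = "\\.tsv$", full.names = TRUE)
    if (!length(files)) stop("no .tsv spot tables found in ", x)
    x <- lapply(files, read_spot_table, dialect = dialect)
  }
  cmb <- combine_spot_tables(x)
  flt <- filter_spots_internal(cmb)
  keep <- flt$keep_mask
  if (!any(keep)) stop("no spot survived the quality filter")
  values <- cmb$fg[keep, , drop = FALSE] - cmb$bg[keep, , drop = FALSE]
  gene <- cmb$gene[keep]
  spot_id <- cmb$spots[keep]
  nonpos <- rowSums(values <= 0) > 0L
  if (any(nonpos)) {
    flt$report$nonpositive_after_subtraction <- sum(nonpos)
    values <- values[!nonpos, , drop = FALSE]
    gene <- gene[!nonpos]
    spot_id <- spot_id[!nonpos]
    if (!nrow(values)) stop("no spot left after background subtraction")
  }
  nrm <- normalize_values(values, gene, tol = tol, max_iter = max_iter)
  build_fabric_from_values(nrm$values, spot_id, gene, cmb$sample_info,
                           renormalize = TRUE, trace = nrm$trace,
                           filter_report = flt$report, call = cl)
}

#' Extract the quantifier table of one phenotype
#'
#' @param fit A [fabric] object.
#' @param phenotype Phenotype label; defaults to the first one.
#' @return Data frame with columns `gene`, `R`, `df`, `correction`, `AVE`,
#'   `REV` (percent).
#' @export
quantifiers <- function(fit, phenotype = NULL) {
  stopifnot(inherits(fit, "fabric"))
  phenotype <- match_phenotype(fit, phenotype)
  fit$quantifiers[[phenotype]]
}

match_phenotype <- function(fit, phenotype) {
  if (is.null(phenotype)) return(fit$phenotypes[[1L]])
  if (!phenotype %in% fit$phenotypes)
    stop("unknown phenotype '", phenotype, "'; available: ",
         paste(fit$phenotypes, collapse = ", "))
  phenotype
}

#' @export
print.fabric <- function(x, ...) {
  cat("Genomic fabric fit\n")
  cat("  phenotypes:", paste(x$phenotypes, collapse = ", "), "\n")
  t1 <- x$tensors[[1L]]
  cat("  ", length(t1$genes), " genes, ", length(t1$spot_id),
      " spots/sample, ", t1$n_replicas, " replicas per phenotype\n", sep = "")
  if (!is.null(x$filter))
    cat("  filter: kept ", x$filter$kept, "/", x$filter$n_spots,
        " spots (", x$filter$corrupted, " corrupted, ",
        x$filter$low_signal, " low-signal)\n", sep = "")
  if (!is.null(x$normalization$trace))
    cat("  normalization: ", x$normalization$iterations,
        " iteration(s), final error ",
        signif(utils::tail(x$normalization$trace, 1L), 3L), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.fabric <- function(object, ...) {
  out <- lapply(object$phenotypes, function(p) {
    q <- object$quantifiers[[p]]
    c(genes = nrow(q),
      median_AVE = stats::median(q$AVE),
      median_REV = stats::median(q$REV),
      q25_REV = unname(stats::quantile(q$REV, 0.25)),
      q75_REV = unname(stats::quantile(q$REV, 0.75)),
      max_R = max(q$R))
  })
  res <- do.call(rbind, out)
  rownames(res) <- object$phenotypes
  structure(list(table = res, filter = object$filter),
            class = "summary.fabric")
}

#' @export
print.summary.fabric <- function(x, ...) {
  cat("Per-phenotype gene quantifiers\n")
  print(signif(x$table, 4L))
  if (length(x$filter$genes_lost))
    cat("genes lost to filtering:", length(x$filter$genes_lost), "\n")
  invisible(x)
}

#' Average expression levels as a gene-by-phenotype matrix
#'
#' @param object A [fabric] object.
#' @param measure `"AVE"` (default) or `"REV"`.
#' @param ... Unused.
#' @return Numeric matrix, genes in rows, phenotypes in columns.
#' @export
coef.fabric <- function(object, measure = c("AVE", "REV"), ...) {
  measure <- match.arg(measure)
  genes <- object$tensors[[1L]]$genes
  m <- vapply(object$phenotypes, function(p) {
    q <- object$quantifiers[[p]]
    q[[measure]][match(genes, q$gene)]
  }, numeric(length(genes)))
  rownames(m) <- genes
  m
}

#' Plot expression level against variability
#'
#' Draws the AVE-REV scatter of one phenotype on a log expression axis: the
#' homeostatic-control view of the transcriptome, with tightly controlled
#' (low-REV) genes at the bottom.
#'
#' @param x A [fabric] object.
#' @param phenotype Phenotype label; defaults to the first one.
#' @param ... Passed to [graphics::plot()].
#' @export
plot.fabric <- function(x, phenotype = NULL, ...) {
  phenotype <- match_phenotype(x, phenotype)
  q <- x$quantifiers[[phenotype]]
  graphics::plot(q$AVE, q$REV, log = "x",
                 xlab = "AVE (median-gene units)", ylab = "REV (%)",
                 main = paste("Expression control,", phenotype), ...)
  invisible(x)
}
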