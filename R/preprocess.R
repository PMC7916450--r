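# Combine one or more spot tables into aligned spot x sample matrices.
# Errors if a spot is measured in some samples but not others, or if one
# spot id maps to different gene symbols.
combine_spot_tables <- function(tables) {
  if (inherits(tables, "data.frame")) tables <- list(tables)
  tables <- lapply(tables, function(t) {
    if (!inherits(t, "spot_table")) t <- spot_table(t)
    as.data.frame(t)[c("spot_id", "gene", "sample", "fg", "bg", "flag")]
  })
  df <- do.call(rbind, tables)
  spots <- unique(df$spot_id)
  samples <- unique(df$sample)
  info <- parse_sample_labels(samples)
  # canonical sample order, independent of input row order
  ord <- order(info$phenotype, info$replica, method = "radix")
  samples <- samples[ord]
  info <- info[ord, , drop = FALSE]

  gene_of <- tapply(df$gene, df$spot_id, function(g) unique(g))
  multi <- vapply(gene_of, length, 1L) > 1L
  if (any(multi))
    stop("spot(s) mapped to more than one gene symbol: ",
         paste(utils::head(names(gene_of)[multi], 5L), collapse = ", "))
  gene <- vapply(gene_of, `[`, "", 1L)[spots]

  ri <- match(df$spot_id, spots)
  ci <- match(df$sample, samples)
  fill <- function(v) {
    m <- matrix(NA_real_, length(spots), length(samples),
                dimnames = list(spots, samples))
    m[cbind(ri, ci)] <- v
    m
  }
  fg <- fill(df$fg)
  bg <- fill(df$bg)
  ok <- fill(as.numeric(df$flag == "ok"))
  if (anyNA(fg)) {
    hole <- which(is.na(fg), arr.ind = TRUE)[1L, ]
    stop("spot ", spots[hole[1L]], " is absent from sample ",
         samples[hole[2L]])
  }
  list(spots = spots, gene = gene, samples = samples, sample_info = info,
       fg = fg, bg = bg, ok = ok == 1)
}

#' Filter corrupted and low-signal spots
#'
#' A spot survives only if it is flagged `ok` in every profiled sample and
#' its foreground fluorescence is at least twice the background in every
#' sample.  A gene survives if at least one of its spots survives.
#'
#' @param tables A `spot_table` or list of them, jointly covering every
#'   sample of the experiment.
#' @return A list with `kept` (surviving spot ids) and `report`, a list
#'   counting rejections by cause (`corrupted`, `low_signal`) and naming
#'   `genes_lost` entirely.
#' @export
filter_spots <- function(tables) {
  cmb <- combine_spot_tables(tables)
  filter_spots_internal(cmb)
}

filter_spots_internal <- function(cmb) {
  corrupted <- rowSums(!cmb$ok) > 0L
  low <- rowSums(cmb$fg < 2 * cmb$bg) > 0L
  keep <- !corrupted & !low
  genes_all <- setdiff(unique(cmb$gene), "")
  genes_kept <- setdiff(unique(cmb$gene[keep]), "")
  report <- list(
    n_spots = length(cmb$spots),
    n_samples = length(cmb$samples),
    kept = sum(keep),
    corrupted = sum(corrupted),
    low_signal = sum(low & !corrupted),
    genes_lost = setdiff(genes_all, genes_kept)
  )
  list(kept = cmb$spots[keep], report = report, keep_mask = keep)
}

# Iterative intra-/inter-array normalization of background-subtracted
# intensities to the median gene.  The error of estimate is the maximum
# relative inter-iteration change of the per-sample scaling factors, in %.
normalize_values <- function(values, gene, tol = 5, max_iter = 100L) {
  is_gene <- gene != ""
  gidx <- match(gene[is_gene], unique(gene[is_gene]))
  trace <- numeric(0L)
  for (iter in seq_len(max_iter)) {
    spot_avg <- rowsum(values[is_gene, , drop = FALSE], gidx)
    spot_avg <- spot_avg / as.vector(table(gidx))
    med <- apply(spot_avg, 2L, stats::median)
    err <- 100 * max(abs(med - 1))
    trace <- c(trace, err)
    if (err < tol) {
      return(list(values = values, trace = trace, iterations = iter,
                  converged = TRUE))
    }
    values <- sweep(values, 2L, med, "/")
    # inter-array step: align everything to the geometric mean of the
    # per-sample medians; exactly 1 after the intra division, so this is the
    # identity here and convergence is reached on the next pass
    values <- values / exp(mean(log(med / med)))
  }
  stop(structure(class = c("genofabric_convergence_error", "error",
                           "condition"),
                 list(message = paste0("normalization did not converge in ",
                                       max_iter, " iterations (last error ",
                                       if (length(trace))
                                         signif(trace[length(trace)], 4L)
                                       else NA, "%)"),
                      call = sys.call(-1L), trace = trace)))
}

#' Normalize filtered spot tables to the median gene
#'
#' Background-subtracted intensities are alternately rescaled within and
#' between arrays to the expression level of the median gene until the
#' maximum error of estimate falls below `tol` percent; each phenotype is
#' then expressed in units of its median-gene AVE.
#'
#' @param tables A `spot_table` or list of them.
#' @param tol Convergence tolerance for the error of estimate, in percent.
#' @param max_iter Maximum number of alternating iterations.
#' @return A list with `tensors` (one `gene_spot_tensor` per phenotype) and
#'   `trace` (error of estimate per iteration, in percent).
#' @export
normalize_spots <- function(tables, tol = 5, max_iter = 100L) {
  fit <- fabric(tables, tol = tol, max_iter = max_iter)
  list(tensors = fit$tensors, trace = fit$normalization$trace)
}

# Assemble per-phenotype tensors and quantifiers from a positive
# spots x samples value matrix. The shared core of fabric() and
# fabric_from_matrix().
build_fabric_from_values <- function(values, spot_id, gene, sample_info,
                                     renormalize = TRUE, trace = NULL,
                                     filter_report = NULL, call = NULL) {
  is_gene <- gene != ""
  values <- values[is_gene, , drop = FALSE]
  spot_id <- spot_id[is_gene]
  gene <- gene[is_gene]
  # canonical gene and spot order, independent of input row order
  genes <- sort(unique(gene), method = "radix")
  ord <- order(match(gene, genes), spot_id, method = "radix")
  values <- values[ord, , drop = FALSE]
  spot_id <- spot_id[ord]
  gene <- gene[ord]

  phenos <- unique(sample_info$phenotype)
  tensors <- list()
  for (p in phenos) {
    sel <- which(sample_info$phenotype == p)
    sel <- sel[order(sample_info$replica[sel])]
    if (length(sel) < 2L)
      stop("phenotype ", p, " has fewer than 2 replicas")
    v <- values[, sel, drop = FALSE]
    if (renormalize) {
      sg <- rowsum(v, match(gene, genes))
      ave <- rowMeans(sg / as.vector(table(match(gene, genes))))
      v <- v / stats::median(ave)
    }
    tensors[[p]] <- new_tensor(p, genes, gene, spot_id, v)
  }
  quant <- lapply(tensors, ave_rev)
  structure(list(tensors = tensors,
                 quantifiers = quant,
                 filter = filter_report,
                 normalization = list(trace = trace,
                                      iterations = length(trace),
                                      converged = TRUE),
                 phenotypes = phenos,
                 call = call),
            class = "fabric")
}

new_tensor <- function(phenotype, genes, gene, spot_id, values) {
  if (any(!is.finite(values)) || any(values <= 0))
    stop("tensor values must be finite and strictly positive")
  spot_gene <- match(gene, genes)
  mu <- rowMeans(values)
  s <- apply(values, 1L, stats::sd)
  structure(list(phenotype = phenotype,
                 genes = genes,
                 R = as.integer(tabulate(spot_gene, length(genes))),
                 spot_id = spot_id,
                 spot_gene = spot_gene,
                 n_replicas = ncol(values),
                 values = values,
                 mu = mu,
                 s = s),
            class = "gene_spot_tensor")
}

#' @export
print.gene_spot_tensor <- function(x, ...) {
  cat("Gene-spot tensor, phenotype", x$phenotype, "\n")
  cat(" ", length(x$genes), "genes,", length(x$spot_id), "spots,",
      x$n_replicas, "replicas\n")
  cat("  redundancy 1..", max(x$R), "; median AVE ",
      signif(stats::median(rowsum(x$mu, x$spot_gene)[, 1L] / x$R), 6L),
      "\n", sep = "")
  invisible(x)
}
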