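#' Chi-square mid-interval correction for a pooled coefficient of variation
#'
#' The pooled CV of a finitely replicated gene underestimates the population
#' variability; the mid-interval estimate corrects it with the average of the
#' two bounds of the chi-square confidence interval of the variance,
#' `0.5 * (df / chi2(df; 0.975) + df / chi2(df; 0.025))`, where
#' `chi2(df; q)` is the quantile with upper-tail probability `q` (so the
#' first term is the larger one).  The correction exceeds 1 for every finite
#' `df` and tends to 1 as `df` grows.
#'
#' @param df Degrees of freedom, `n_replicas * R - 1` for a gene probed by
#'   `R` spots.
#' @return The correction coefficient (vectorised over `df`).
#' @export
rev_correction <- function(df) {
  if (any(df < 1)) stop("degrees of freedom must be >= 1")
  0.5 * (df / stats::qchisq(0.025, df) + df / stats::qchisq(0.975, df))
}

# Per-gene AVE and REV of one tensor.
ave_rev <- function(tensor) {
  g <- tensor$spot_gene
  R <- tensor$R
  n <- tensor$n_replicas
  if (any(tensor$mu <= 0))
    stop("zero spot mean for gene ",
         tensor$genes[g[which(tensor$mu <= 0)[1L]]])
  AVE <- rowsum(tensor$mu, g)[, 1L] / R
  cv2 <- rowsum((tensor$s / tensor$mu)^2, g)[, 1L] / R
  df <- n * R - 1L
  corr <- rev_correction(df)
  data.frame(gene = tensor$genes,
             R = R,
             df = df,
             correction = corr,
             AVE = unname(AVE),
             REV = unname(corr * sqrt(cv2) * 100),
             row.names = NULL,
             stringsAsFactors = FALSE)
}

#' Significance cutoff for expression correlation at given redundancy
#'
#' Two genes probed by `R_a` and `R_b` spots contribute
#' `n_replicas * min(R_a, R_b)` paired observations to their expression
#' correlation; the two-tailed critical Pearson value at level `alpha` is
#' `t_c / sqrt(t_c^2 + df)` with `df = n_replicas * min(R_a, R_b) - 2`.
#' With 4 replicas this gives 0.95 for single-spot genes, 0.707 for two
#' spots and 0.273 for the maximum redundancy of 13.
#'
#' @param R_a,R_b Spot redundancies of the two genes (`R_b` defaults to
#'   `R_a`); vectorised.
#' @param alpha Two-tailed significance level.
#' @param n_replicas Number of biological replicas per phenotype.
#' @return The critical absolute correlation.
#' @examples
#' cor_cutoff(1)   # 0.950
#' cor_cutoff(2)   # 0.707
#' cor_cutoff(13)  # 0.273
#' @export
cor_cutoff <- function(R_a, R_b = R_a, alpha = 0.05, n_replicas = 4L) {
  if (any(R_a < 1) || any(R_b < 1)) stop("redundancy must be >= 1")
  df <- n_replicas * pmin(R_a, R_b) - 2
  if (any(df < 1)) stop("correlation cutoff undefined: df < 1")
  tc <- stats::qt(1 - alpha / 2, df)
  tc / sqrt(tc^2 + df)
}

#' Classify pairwise expression coordination
#'
#' Synergistic if `COR` exceeds the redundancy-dependent cutoff,
#' antagonistic if below its negative, independent if inside the
#' `independence_band`, otherwise not significant.
#'
#' @param cor Pearson expression correlation(s).
#' @param cutoff Significance cutoff(s), from [cor_cutoff()].
#' @param independence_band Half-width of the independence interval.
#' @return Character vector with values `synergistic`, `antagonistic`,
#'   `independent` or `not_significant` (`NA` propagates).
#' @export
classify_coordination <- function(cor, cutoff, independence_band = 0.025) {
  out <- rep(NA_character_, length(cor))
  out[!is.na(cor) & cor > cutoff] <- "synergistic"
  out[!is.na(cor) & cor < -cutoff] <- "antagonistic"
  out[!is.na(cor) & abs(cor) < independence_band] <- "independent"
  out[!is.na(cor) & is.na(out)] <- "not_significant"
  out
}

# spot-centered deviations of a tensor
tensor_deviations <- function(tensor) {
  tensor$values - tensor$mu
}

# per-gene structures used by every correlation routine:
#  U  - replica-resolved, spot-averaged deviations (genes x n), row-normalized
#  stacks - for each redundancy group R >= 2, the stacked (genes x n*R)
#           normalized deviation matrix (spots paired by within-gene index)
# rows with zero variance are flagged and left as zero vectors
cor_structures <- function(tensor, idx = seq_along(tensor$genes)) {
  D <- tensor_deviations(tensor)
  n <- tensor$n_replicas
  # spots are stored in contiguous gene blocks
  offset <- cumsum(tensor$R) - tensor$R
  U_all <- rowsum(D, tensor$spot_gene) / tensor$R
  U <- U_all[idx, , drop = FALSE]
  norm_u <- sqrt(rowSums(U^2))
  defined <- norm_u > 0
  U[defined, ] <- U[defined, , drop = FALSE] / norm_u[defined]
  U[!defined, ] <- 0
  R <- tensor$R[idx]
  stacks <- list()
  for (r in unique(R[R >= 2L])) {
    members <- which(R == r)
    X <- matrix(0, length(members), n * r)
    for (jj in seq_along(members)) {
      rows <- offset[idx[members[jj]]] + seq_len(r)
      v <- as.vector(D[rows, , drop = FALSE])
      nv <- sqrt(sum(v^2))
      if (nv > 0) X[jj, ] <- v / nv
    }
    stacks[[as.character(r)]] <- list(members = members, X = X)
  }
  list(U = U, R = R, stacks = stacks, defined = defined,
       genes = tensor$genes[idx], n = n)
}

# dense COR matrix over the selected genes (unit diagonal, NA for
# zero-variance genes); same-redundancy pairs pooled over index-paired
# spots, mixed-redundancy pairs on spot-averaged deviations
cor_matrix_from_structures <- function(st) {
  C <- tcrossprod(st$U)
  for (blk in st$stacks) {
    C[blk$members, blk$members] <- tcrossprod(blk$X)
  }
  diag(C) <- 1
  C[!st$defined, ] <- NA_real_
  C[, !st$defined] <- NA_real_
  diag(C)[!st$defined] <- NA_real_
  dimnames(C) <- list(st$genes, st$genes)
  C
}

#' Pearson expression correlation between two genes
#'
#' Correlates the spot-centered expression deviations of two genes across
#' biological replicas.  When both genes have the same spot redundancy the
#' sum runs over all (spot, replica) cells with spots paired by index; with
#' unequal redundancy the per-replica spot-averaged deviations are used and
#' the effective sample size is `n_replicas * min(R_a, R_b)`.
#'
#' @param tensor A `gene_spot_tensor` (component of a [fabric] fit).
#' @param gene_a,gene_b Gene symbols.
#' @return One-row data frame: `gene_a`, `gene_b`, `COR`, `n_eff`.
#' @export
compute_cor <- function(tensor, gene_a, gene_b) {
  ia <- match(gene_a, tensor$genes)
  ib <- match(gene_b, tensor$genes)
  if (is.na(ia)) stop("gene not in tensor: ", gene_a)
  if (is.na(ib)) stop("gene not in tensor: ", gene_b)
  n <- tensor$n_replicas
  if (ia == ib)
    return(data.frame(gene_a = gene_a, gene_b = gene_b, COR = 1,
                      n_eff = n * tensor$R[ia], stringsAsFactors = FALSE))
  D <- tensor_deviations(tensor)
  vec <- function(i, pooled) {
    rows <- which(tensor$spot_gene == i)
    if (pooled) as.vector(D[rows, , drop = FALSE])
    else colMeans(D[rows, , drop = FALSE])
  }
  pooled <- tensor$R[ia] == tensor$R[ib]
  va <- vec(ia, pooled); vb <- vec(ib, pooled)
  den <- sqrt(sum(va^2) * sum(vb^2))
  cor_ab <- if (den > 0) sum(va * vb) / den else NA_real_
  data.frame(gene_a = gene_a, gene_b = gene_b, COR = cor_ab,
             n_eff = n * min(tensor$R[ia], tensor$R[ib]),
             stringsAsFactors = FALSE)
}

#' Pairwise coordination analysis of a phenotype
#'
#' Computes the expression correlation of every unordered pair among the
#' requested genes, the redundancy-dependent significance cutoff of each
#' pair, and the coordination class.
#'
#' @param fit A [fabric] object.
#' @param phenotype Phenotype label; defaults to the first one.
#' @param genes Gene symbols to analyse (default: all quantified genes).
#' @param alpha Two-tailed significance level for the cutoffs.
#' @param independence_band Half-width of the independence interval.
#' @return Data frame of class `fabric_coordination` with columns `gene_a`,
#'   `gene_b`, `COR`, `n_eff`, `cutoff`, `class`.  Genes with zero
#'   expression variance are excluded and listed in the
#'   `"undefined_genes"` attribute.
#' @export
coordination <- function(fit, phenotype = NULL, genes = NULL, alpha = 0.05,
                         independence_band = 0.025) {
  stopifnot(inherits(fit, "fabric"))
  phenotype <- match_phenotype(fit, phenotype)
  tensor <- fit$tensors[[phenotype]]
  idx <- if (is.null(genes)) seq_along(tensor$genes)
         else {
           i <- match(genes, tensor$genes)
           if (anyNA(i)) stop("gene(s) not quantified: ",
                              paste(genes[is.na(i)], collapse = ", "))
           i
         }
  st <- cor_structures(tensor, idx)
  C <- cor_matrix_from_structures(st)
  G <- length(idx)
  if (G < 2L) stop("need at least two genes")
  pair <- which(upper.tri(C), arr.ind = TRUE)
  Rmin <- pmin(st$R[pair[, 1L]], st$R[pair[, 2L]])
  cutoff <- cor_cutoff(Rmin, Rmin, alpha = alpha, n_replicas = st$n)
  corv <- C[pair]
  out <- data.frame(gene_a = st$genes[pair[, 1L]],
                    gene_b = st$genes[pair[, 2L]],
                    COR = corv,
                    n_eff = st$n * Rmin,
                    cutoff = cutoff,
                    class = classify_coordination(corv, cutoff,
                                                  independence_band),
                    stringsAsFactors = FALSE)
  undefined <- st$genes[!st$defined]
  out <- out[!is.na(out$COR), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            class = c("fabric_coordination", "data.frame"),
            phenotype = phenotype, alpha = alpha,
            independence_band = independence_band,
            undefined_genes = undefined)
}

#' @export
print.fabric_coordination <- function(x, ...) {
  cat("Coordination analysis, phenotype", attr(x, "phenotype"),
      "-", nrow(x), "gene pairs\n")
  print(table(factor(x$class, levels = c("synergistic", "antagonistic",
                                         "independent",
                                         "not_significant"))))
  if (length(attr(x, "undefined_genes")))
    cat("undefined (zero-variance) genes:",
        paste(attr(x, "undefined_genes"), collapse = ", "), "\n")
  invisible(x)
}
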