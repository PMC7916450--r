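#' Gene-specific fold-change cutoff from expression variabilities
#'
#' Instead of a fixed 1.5x or 2x threshold, each gene's significant-fold
#' requirement combines the relative expression variabilities (REV, percent)
#' it shows in the two compared phenotypes:
#' `CUT = 1 + sqrt(2 * (REV_P^2 + REV_Q^2)) / 100`.
#' A perfectly stable gene (both REVs zero) has CUT = 1; REVs of 50 percent
#' in both phenotypes give CUT = 2.
#'
#' @param rev_p,rev_q REV of the gene in the two phenotypes, in percent
#'   (vectorised).
#' @return The fold-change cutoff (>= 1).
#' @export
compute_cut <- function(rev_p, rev_q) {
  if (any(rev_p < 0) || any(rev_q < 0)) stop("REV must be >= 0")
  1 + sqrt(2 * (rev_p^2 + rev_q^2)) / 100
}

#' Weighted individual regulation score
#'
#' `WIR = AVE_ref * sign(x) * (|x| - 1) * (1 - p)`: the reference-level
#' weighted, confidence-damped net fold-change of one gene in a contrast.
#' Unlike the uniform +1/-1 measure it applies to all genes and
#' discriminates their contributions.
#'
#' @param ave_ref AVE of the gene in the reference phenotype.
#' @param x Signed expression ratio (`|x| >= 1`, negative for
#'   down-regulation).
#' @param p Welch t-test p-value of the means' equality.
#' @return The WIR score (vectorised).
#' @export
wir_score <- function(ave_ref, x, p) {
  if (any(abs(x) < 1)) stop("|x| must be >= 1")
  ave_ref * sign(x) * (abs(x) - 1) * (1 - p)
}

#' Weighted pathway regulation score
#'
#' The mean squared WIR over the quantified genes of a pathway.
#'
#' @param wir Vector of WIR scores of the pathway's quantified genes.
#' @return `mean(wir^2)`.
#' @export
wpr_score <- function(wir) {
  if (!length(wir)) stop("WPR undefined for an empty gene set")
  mean(wir^2)
}

#' Per-gene regulation between two phenotypes
#'
#' For every gene quantified in both phenotypes computes the signed
#' expression ratio `x` (ratio of AVEs, negative reciprocal when expression
#' drops), the gene-specific fold cutoff CUT from the two REVs, the
#' two-tailed Welch (heteroscedastic) t-test p-value on the per-replica
#' spot-averaged expressions, the significance call
#' (`|x| > CUT` and `p < alpha`), the uniform +1/-1 measure, and the
#' weighted individual regulation WIR.
#'
#' @param fit A [fabric] object.
#' @param phenotype Test phenotype P.
#' @param reference Reference phenotype Q.
#' @param alpha Significance level of the Welch test.
#' @return Data frame of class `fabric_regulation` with columns `gene`,
#'   `x`, `CUT`, `p`, `significant`, `uniform`, `WIR`.  Genes absent from
#'   one phenotype are listed in the `"absent_genes"` attribute.
#' @export
regulation <- function(fit, phenotype, reference, alpha = 0.05) {
  stopifnot(inherits(fit, "fabric"))
  phenotype <- match_phenotype(fit, phenotype)
  reference <- match_phenotype(fit, reference)
  if (phenotype == reference) stop("phenotype and reference must differ")
  tp <- fit$tensors[[phenotype]]
  tq <- fit$tensors[[reference]]
  if (tp$n_replicas != tq$n_replicas)
    stop("phenotypes have different replica counts")
  qp <- fit$quantifiers[[phenotype]]
  qq <- fit$quantifiers[[reference]]
  genes <- intersect(qp$gene, qq$gene)
  absent <- union(setdiff(qp$gene, genes), setdiff(qq$gene, genes))
  ip <- match(genes, qp$gene)
  iq <- match(genes, qq$gene)

  # per-replica spot-averaged expression, genes x replicas
  repl_expr <- function(tensor, idx) {
    (rowsum(tensor$values, tensor$spot_gene) / tensor$R)[idx, , drop = FALSE]
  }
  Ap <- repl_expr(tp, match(genes, tp$genes))
  Aq <- repl_expr(tq, match(genes, tq$genes))

  ave_p <- qp$AVE[ip]
  ave_q <- qq$AVE[iq]
  ratio <- ave_p / ave_q
  x <- ifelse(ratio >= 1, ratio, -1 / ratio)
  cut <- compute_cut(qp$REV[ip], qq$REV[iq])
  p <- welch_p(Ap, Aq)
  significant <- abs(x) > cut & p < alpha
  out <- data.frame(gene = genes,
                    x = x,
                    CUT = cut,
                    p = p,
                    significant = significant,
                    uniform = ifelse(significant, sign(x), 0),
                    WIR = wir_score(ave_q, x, p),
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("fabric_regulation", "data.frame"),
            contrast = c(phenotype = phenotype, reference = reference),
            alpha = alpha,
            absent_genes = absent)
}

#' @export
print.fabric_regulation <- function(x, ...) {
  ct <- attr(x, "contrast")
  cat("Regulation ", ct[["phenotype"]], " vs ", ct[["reference"]],
      " (alpha = ", attr(x, "alpha"), ")\n", sep = "")
  cat("  ", nrow(x), " genes: ", sum(x$uniform > 0), " up-, ",
      sum(x$uniform < 0), " down-regulated\n", sep = "")
  top <- x[order(-abs(x$WIR)), , drop = FALSE]
  cat("  largest |WIR|:\n")
  print(utils::head(as.data.frame(top), 5L), digits = 4)
  invisible(x)
}

#' Pathway-level regulation from per-gene records
#'
#' For each gene set computes the weighted pathway regulation
#' (mean squared WIR over the pathway's quantified genes) and the
#' percentages of significantly up- and down-regulated genes.
#'
#' @param reg A [regulation()] result.
#' @param gene_sets A list of `gene_set` objects (see [read_gmt()]), or a
#'   single one.
#' @return Data frame with columns `pathway`, `n_genes`, `WPR`, `pct_up`,
#'   `pct_down`.  Gene symbols are matched case-insensitively.
#' @export
pathway_regulation <- function(reg, gene_sets) {
  stopifnot(inherits(reg, "fabric_regulation"))
  if (inherits(gene_sets, "gene_set")) gene_sets <- list(gene_sets)
  up <- toupper(reg$gene)
  rows <- lapply(gene_sets, function(gs) {
    hit <- up %in% toupper(gs$genes)
    if (!any(hit))
      stop("no quantified gene in pathway ", gs$name)
    sub <- reg[hit, , drop = FALSE]
    data.frame(pathway = gs$name,
               n_genes = nrow(sub),
               WPR = wpr_score(sub$WIR),
               pct_up = 100 * mean(sub$uniform > 0),
               pct_down = 100 * mean(sub$uniform < 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
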