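# GCH closed form: (mean REV / gene REV) * exp((4/N) * sum COR^2 - 1)
gch_score <- function(rev, center_rev, sum_cor_sq, N) {
  (center_rev / rev) * exp((4 / N) * sum_cor_sq - 1)
}

# per-gene sum over j != i of COR_ij^2, computed in row blocks so chip-scale
# universes never materialise the full correlation matrix
sum_cor_sq <- function(st, block_size = 1000L) {
  G <- nrow(st$U)
  S <- numeric(G)
  for (start in seq(1L, G, by = block_size)) {
    rows <- start:min(start + block_size - 1L, G)
    M <- st$U[rows, , drop = FALSE] %*% t(st$U)
    S[rows] <- rowSums(M^2)
  }
  # same-redundancy pairs (R >= 2) are pooled over index-paired spots, not
  # spot-averaged: swap in the stacked-deviation correlations for those blocks
  for (blk in st$stacks) {
    W <- tcrossprod(blk$X)
    V <- tcrossprod(st$U[blk$members, , drop = FALSE])
    S[blk$members] <- S[blk$members] + rowSums(W^2) - rowSums(V^2)
  }
  S[st$defined] <- S[st$defined] - 1   # remove the self term
  S
}

#' Gene commanding height of every quantified gene
#'
#' GCH combines expression control (low REV, i.e. tight homeostatic
#' regulation) with expression coordination (large squared correlations with
#' the rest of the transcriptome):
#' `GCH_i = (<REV> / REV_i) * exp((4/N) * sum_{j != i} COR_ij^2 - 1)`.
#' The top-ranked gene is the phenotype's Gene Master Regulator (GMR).
#'
#' @param fit A [fabric] object.
#' @param phenotype Phenotype label; defaults to the first one.
#' @param center `"mean"` (default) or `"median"`: the REV summary used for
#'   `<REV>`.
#' @param block_size Row-block size for the correlation accumulation.
#' @return Data frame of class `gch_table` with columns `gene`, `REV`,
#'   `sum_cor_sq`, `GCH`, `rank` and `infinite_control`.  Genes with
#'   `REV = 0` are flagged `infinite_control` and left out of the ranking
#'   rather than dominating it.
#' @export
gch <- function(fit, phenotype = NULL, center = c("mean", "median"),
                block_size = 1000L) {
  stopifnot(inherits(fit, "fabric"))
  center <- match.arg(center)
  phenotype <- match_phenotype(fit, phenotype)
  tensor <- fit$tensors[[phenotype]]
  q <- fit$quantifiers[[phenotype]]
  st <- cor_structures(tensor)
  S <- sum_cor_sq(st, block_size = block_size)
  N <- length(st$genes)
  center_rev <- if (center == "mean") mean(q$REV) else stats::median(q$REV)
  infinite <- q$REV == 0
  score <- rep(NA_real_, N)
  score[!infinite] <- gch_score(q$REV[!infinite], center_rev,
                                S[!infinite], N)
  rank <- rep(NA_integer_, N)
  rankable <- which(!infinite)
  ord <- rankable[order(-score[rankable], q$gene[rankable])]
  rank[ord] <- seq_along(ord)
  out <- data.frame(gene = q$gene,
                    REV = q$REV,
                    sum_cor_sq = S,
                    GCH = score,
                    rank = rank,
                    infinite_control = infinite,
                    row.names = NULL,
                    stringsAsFactors = FALSE)
  structure(out,
            class = c("gch_table", "data.frame"),
            phenotype = phenotype, center_REV = center_rev, N = N)
}

#' @export
print.gch_table <- function(x, ...) {
  cat("Gene commanding heights, phenotype", attr(x, "phenotype"),
      "-", attr(x, "N"), "genes\n")
  cat("  GMR:", x$gene[which(x$rank == 1L)], "\n")
  print(utils::head(as.data.frame(x)[order(x$rank), ], 5L), digits = 4)
  if (any(x$infinite_control))
    cat("  zero-REV genes excluded from ranking:",
        paste(x$gene[x$infinite_control], collapse = ", "), "\n")
  invisible(x)
}

#' Rank the gene hierarchy and extract the top commanding genes
#'
#' @param table A [gch()] result.
#' @param top_k How many top-ranked genes to return (ties broken
#'   lexicographically by symbol).
#' @return The `top_k` highest-GCH rows, ordered by rank; the first row is
#'   the phenotype's Gene Master Regulator.
#' @export
rank_gmr <- function(table, top_k = 15L) {
  stopifnot(inherits(table, "gch_table"))
  ranked <- table[!is.na(table$rank), , drop = FALSE]
  ranked <- ranked[order(ranked$rank), , drop = FALSE]
  utils::head(ranked, top_k)
}

#' Coordination network within and between two pathway fabrics
#'
#' Partitions the quantified genes of two gene sets into set-a-only,
#' set-b-only and shared nodes, classifies every unordered pair, and counts
#' the coordination classes — the tabular form of an inter-fabric
#' coordination heat map.
#'
#' @param fit A [fabric] object.
#' @param set_a,set_b `gene_set` objects (see [read_gmt()]).
#' @param phenotype Phenotype label; defaults to the first one.
#' @param alpha Significance level for the coordination cutoffs.
#' @param independence_band Half-width of the independence interval.
#' @return An object of class `fabric_network`: list with `nodes` (gene,
#'   partition), `edges` (the [coordination()] table) and `counts` (pairs
#'   per class).
#' @export
fabric_network <- function(fit, set_a, set_b, phenotype = NULL,
                           alpha = 0.05, independence_band = 0.025) {
  stopifnot(inherits(fit, "fabric"))
  phenotype <- match_phenotype(fit, phenotype)
  tensor <- fit$tensors[[phenotype]]
  quantified <- function(gs) {
    hit <- toupper(tensor$genes) %in% toupper(gs$genes)
    tensor$genes[hit]
  }
  ga <- quantified(set_a)
  gb <- quantified(set_b)
  nodes_genes <- union(ga, gb)
  if (length(nodes_genes) < 2L)
    stop("fewer than two quantified genes across the two sets")
  partition <- ifelse(nodes_genes %in% ga & nodes_genes %in% gb, "shared",
                      ifelse(nodes_genes %in% ga, "a_only", "b_only"))
  edges <- coordination(fit, phenotype, genes = nodes_genes, alpha = alpha,
                        independence_band = independence_band)
  counts <- table(factor(edges$class,
                         levels = c("synergistic", "antagonistic",
                                    "independent", "not_significant")))
  structure(list(nodes = data.frame(gene = nodes_genes,
                                    partition = partition,
                                    stringsAsFactors = FALSE),
                 edges = edges,
                 counts = counts,
                 phenotype = phenotype,
                 sets = c(a = set_a$name, b = set_b$name)),
            class = "fabric_network")
}

#' @export
print.fabric_network <- function(x, ...) {
  cat("Fabric coordination network ", x$sets[["a"]], " x ", x$sets[["b"]],
      ", phenotype ", x$phenotype, "\n", sep = "")
  print(table(x$nodes$partition))
  cat("  ", sum(x$counts), " pairs:\n", sep = "")
  print(x$counts)
  invisible(x)
}

#' Class adjacency matrix of a fabric network
#'
#' @param net A [fabric_network()] result.
#' @return Square character matrix of coordination classes (diagonal
#'   `NA`), suitable for [write_results_table()] export.
#' @export
network_adjacency <- function(net) {
  stopifnot(inherits(net, "fabric_network"))
  g <- net$nodes$gene
  m <- matrix(NA_character_, length(g), length(g), dimnames = list(g, g))
  ia <- match(net$edges$gene_a, g)
  ib <- match(net$edges$gene_b, g)
  m[cbind(ia, ib)] <- net$edges$class
  m[cbind(ib, ia)] <- net$edges$class
  m
}

#' Sign consistency of observed coordination with a curated interaction list
#'
#' If a pathway diagram is faithful, upstream activators and downstream
#' activated genes should be synergistically expressed with the central
#' block, and upstream inhibitors and downstream inhibited genes
#' antagonistically.  For every (center, partner) pair this compares the
#' observed coordination class with the sign the role predicts: a
#' significant class of the predicted sign `confirms`, a significant class
#' of the opposite sign `contradicts`, anything else is `unresolved`.
#'
#' @param fit A [fabric] object.
#' @param interactions An [interaction_list()].
#' @param phenotype Phenotype label; defaults to the first one.
#' @param alpha Significance level for the coordination cutoffs.
#' @param independence_band Half-width of the independence interval.
#' @return An object of class `consistency_report`: list with `pairs`
#'   (center, partner, role, expected sign, COR, class, verdict) and
#'   `summary` (per-role class and verdict counts).  Genes not quantified
#'   are listed in `missing_genes`.
#' @export
interaction_consistency <- function(fit, interactions, phenotype = NULL,
                                    alpha = 0.05,
                                    independence_band = 0.025) {
  stopifnot(inherits(fit, "fabric"), inherits(interactions,
                                              "interaction_list"))
  phenotype <- match_phenotype(fit, phenotype)
  tensor <- fit$tensors[[phenotype]]
  find <- function(g) tensor$genes[match(toupper(g), toupper(tensor$genes))]
  centers <- find(interactions$center_block)
  partners <- find(interactions$partners$gene)
  missing <- c(interactions$center_block[is.na(centers)],
               interactions$partners$gene[is.na(partners)])
  roles <- interactions$partners$role[!is.na(partners)]
  partners <- partners[!is.na(partners)]
  centers <- centers[!is.na(centers)]
  if (!length(centers) || !length(partners))
    stop("no quantified center or partner genes")

  expected <- ifelse(roles %in% c("upstream_activator",
                                  "downstream_activated"), 1L, -1L)
  rows <- list()
  for (ci in seq_along(centers)) {
    for (pi in seq_along(partners)) {
      if (toupper(centers[ci]) == toupper(partners[pi])) next
      cc <- compute_cor(tensor, centers[ci], partners[pi])
      Rmin <- min(tensor$R[match(c(centers[ci], partners[pi]),
                                 tensor$genes)])
      cut <- cor_cutoff(Rmin, Rmin, alpha = alpha,
                        n_replicas = tensor$n_replicas)
      cls <- classify_coordination(cc$COR, cut, independence_band)
      verdict <- "unresolved"
      if (!is.na(cls) && cls %in% c("synergistic", "antagonistic")) {
        observed <- if (cls == "synergistic") 1L else -1L
        verdict <- if (observed == expected[pi]) "confirms" else
          "contradicts"
      }
      rows[[length(rows) + 1L]] <-
        data.frame(center = centers[ci], partner = partners[pi],
                   role = roles[pi], expected_sign = expected[pi],
                   COR = cc$COR, cutoff = cut, class = cls,
                   verdict = verdict, stringsAsFactors = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  rownames(pairs) <- NULL
  cls_lev <- c("synergistic", "antagonistic", "independent",
               "not_significant")
  summary <- do.call(rbind, lapply(split(pairs, pairs$role), function(d) {
    cbind(data.frame(role = d$role[[1L]], n_pairs = nrow(d)),
          as.data.frame(as.list(table(factor(d$class, levels = cls_lev)))),
          data.frame(confirms = sum(d$verdict == "confirms"),
                     contradicts = sum(d$verdict == "contradicts")))
  }))
  rownames(summary) <- NULL
  structure(list(pairs = pairs, summary = summary,
                 phenotype = phenotype, missing_genes = missing),
            class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat("Interaction sign-consistency, phenotype", x$phenotype, "\n")
  cat("  ", nrow(x$pairs), " center-partner pairs; ",
      sum(x$pairs$verdict == "confirms"), " confirm, ",
      sum(x$pairs$verdict == "contradicts"), " contradict\n", sep = "")
  print(x$summary)
  if (length(x$missing_genes))
    cat("  not quantified:", paste(x$missing_genes, collapse = ", "), "\n")
  invisible(x)
}
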