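default_redundancy <- c(`1` = 0.70, `2` = 0.12, `3` = 0.06, `4` = 0.04,
                        `5` = 0.03, `6` = 0.02, `7` = 0.01, `8` = 0.005,
                        `9` = 0.004, `10` = 0.003, `11` = 0.003,
                        `12` = 0.003, `13` = 0.002)

#' Design of a synthetic redundant-spot microarray experiment
#'
#' Describes a study with several phenotypes, a fixed number of biological
#' replicas each, and 1-13 spots redundantly probing every gene.  A gene's
#' fluorescence is multiplicative log-normal: a gene-specific base level, a
#' planted phenotype fold, a fixed per-spot bias, a per-replica biological
#' effect with gene-specific coefficient of variation (shared by all spots
#' of the gene, optionally loaded on a module-level latent replicate factor
#' to plant synergistic or antagonistic coordination), and an independent
#' per-measurement technical noise.  Background is constant with jitter, and
#' a fraction of spot measurements is flagged corrupted.
#'
#' @param n_genes Number of genes.
#' @param phenotypes Phenotype labels.
#' @param n_replicas Biological replicas per phenotype (>= 2).
#' @param redundancy_dist Named probability vector over redundancies 1..13.
#' @param base_level_log_mean,base_level_log_sd Log-normal parameters of the
#'   gene base fluorescence.
#' @param bio_cv_range Range the per-gene biological replicate CV is drawn
#'   from (uniform).
#' @param spot_bias_sd Log-sd of the fixed multiplicative spot bias.
#' @param tech_cv CV of the independent per-measurement technical noise.
#' @param bg_level Background fluorescence level.
#' @param bg_jitter_sd Log-sd of the background jitter.
#' @param corrupted_rate Probability a (spot, sample) measurement is flagged
#'   corrupted.
#' @param redundancy_override `NULL`, or an integer vector of spot
#'   redundancies named by gene index, forcing those genes' R regardless of
#'   `redundancy_dist`.
#' @param planted_folds `NULL` or a data frame with columns `gene` (index in
#'   `1..n_genes`), `phenotype`, `fold` (signed, `|fold| >= 1`; negative
#'   means down-regulation) and optionally `cv` (forces that gene's
#'   biological CV).
#' @param coordination_modules List of modules, each a list with `genes`
#'   (indices), `loadings` (+1/-1 per gene) and `latent_sd`; genes of one
#'   module share a latent replicate factor, same-sign loadings making them
#'   synergistic and opposite signs antagonistic.
#' @param seed Integer seed; the whole experiment is deterministic given it.
#' @return A validated `fabric_design` object.
#' @seealso [default_design()], [simulate_experiment()]
#' @export
fabric_design <- function(n_genes,
                          phenotypes = c("MRLp", "MRLlpr", "Fn14ko"),
                          n_replicas = 4L,
                          redundancy_dist = default_redundancy,
                          base_level_log_mean = log(500),
                          base_level_log_sd = 1,
                          bio_cv_range = c(0.02, 0.40),
                          spot_bias_sd = 0.15,
                          tech_cv = 0.05,
                          bg_level = 50,
                          bg_jitter_sd = 0.05,
                          corrupted_rate = 0.01,
                          redundancy_override = NULL,
                          planted_folds = NULL,
                          coordination_modules = list(),
                          seed = 1L) {
  stopifnot(n_genes >= 1, n_replicas >= 2, length(phenotypes) >= 1)
  rd <- redundancy_dist
  if (is.null(names(rd)) ||
      !all(as.integer(names(rd)) %in% 1:13) ||
      any(rd < 0) || any(rd > 1) || abs(sum(rd) - 1) > 1e-8)
    stop("redundancy_dist must be probabilities over 1..13 summing to 1")
  stopifnot(length(bio_cv_range) == 2L, bio_cv_range[1L] > 0,
            diff(bio_cv_range) >= 0, tech_cv >= 0, spot_bias_sd >= 0,
            bg_level > 0, corrupted_rate >= 0, corrupted_rate <= 1)
  if (!is.null(redundancy_override)) {
    gi <- as.integer(names(redundancy_override))
    if (is.null(names(redundancy_override)) || anyNA(gi) ||
        any(gi < 1 | gi > n_genes) ||
        any(redundancy_override < 1 | redundancy_override > 13))
      stop("redundancy_override must map gene indices to R in 1..13")
  }
  if (!is.null(planted_folds)) {
    if (!all(c("gene", "phenotype", "fold") %in% names(planted_folds)))
      stop("planted_folds needs columns gene, phenotype, fold")
    if (any(planted_folds$gene < 1 | planted_folds$gene > n_genes))
      stop("planted fold gene index outside 1..n_genes")
    if (!all(planted_folds$phenotype %in% phenotypes))
      stop("planted fold phenotype not in design")
    if (any(abs(planted_folds$fold) < 1))
      stop("planted folds must satisfy |fold| >= 1")
    if (anyDuplicated(planted_folds[c("gene", "phenotype")]))
      stop("a gene may carry one planted fold per phenotype")
  }
  mod_genes <- integer(0L)
  for (m in coordination_modules) {
    if (!all(c("genes", "loadings", "latent_sd") %in% names(m)))
      stop("each module needs genes, loadings, latent_sd")
    if (any(m$genes < 1 | m$genes > n_genes))
      stop("module gene index outside 1..n_genes")
    if (length(m$loadings) != length(m$genes) ||
        !all(m$loadings %in% c(-1, 1)))
      stop("module loadings must be +1/-1, one per gene")
    if (m$latent_sd <= 0) stop("latent_sd must be positive")
    if (any(m$genes %in% mod_genes))
      stop("modules may not share genes")
    mod_genes <- c(mod_genes, m$genes)
  }
  structure(list(n_genes = as.integer(n_genes),
                 phenotypes = phenotypes,
                 n_replicas = as.integer(n_replicas),
                 redundancy_dist = rd,
                 base_level_log_mean = base_level_log_mean,
                 base_level_log_sd = base_level_log_sd,
                 bio_cv_range = bio_cv_range,
                 spot_bias_sd = spot_bias_sd,
                 tech_cv = tech_cv,
                 bg_level = bg_level,
                 bg_jitter_sd = bg_jitter_sd,
                 corrupted_rate = corrupted_rate,
                 redundancy_override = redundancy_override,
                 planted_folds = planted_folds,
                 coordination_modules = coordination_modules,
                 seed = as.integer(seed)),
            class = "fabric_design")
}

#' @export
print.fabric_design <- function(x, ...) {
  cat("Synthetic experiment design:", x$n_genes, "genes,",
      length(x$phenotypes), "phenotypes x", x$n_replicas, "replicas\n")
  cat("  redundancy 1..13, P(R=1) =", x$redundancy_dist[["1"]],
      "; bio CV", paste(x$bio_cv_range * 100, collapse = "-"), "%\n")
  cat("  planted folds:",
      if (is.null(x$planted_folds)) 0 else nrow(x$planted_folds),
      "; coordination modules:", length(x$coordination_modules),
      "; seed", x$seed, "\n")
  invisible(x)
}

#' Ready-made experiment designs
#'
#' `"tiny"` (200 genes) runs the full pipeline in seconds and is the default
#' scale of the test-suite; `"paper_like"` (17,000 genes) matches the shape
#' of a chip-scale study with 3 phenotypes and 4 replicas.
#'
#' @param scale `"tiny"` or `"paper_like"`.
#' @param ... Overrides passed on to [fabric_design()].
#' @return A `fabric_design`.
#' @export
default_design <- function(scale = c("tiny", "paper_like"), ...) {
  scale <- match.arg(scale)
  args <- list(...)
  if (is.null(args$n_genes))
    args$n_genes <- if (scale == "tiny") 200L else 17000L
  do.call(fabric_design, args)
}

#' Simulate a redundant-spot experiment with known ground truth
#'
#' Generates one spot table per profiled sample under the model described in
#' [fabric_design()], plus the ground truth needed to validate every
#' downstream stage: planted fold multipliers, module memberships and
#' loadings, per-gene biological CVs and the corrupted measurements.
#'
#' @param design A [fabric_design()].
#' @return List with `tables` (named list of `spot_table`, one per sample)
#'   and `truth` (list: `multipliers` gene x phenotype matrix, `folds`,
#'   `modules`, `cv`, `corrupted` data frames).  The caller's RNG state is
#'   left untouched; the output is a deterministic function of
#'   `design$seed`.
#' @export
simulate_experiment <- function(design) {
  stopifnot(inherits(design, "fabric_design"))
  with_preserved_seed({
    set.seed(design$seed)
    d <- design
    G <- d$n_genes
    sym <- sprintf("Gene%05d", seq_len(G))

    R <- sample(as.integer(names(d$redundancy_dist)), G, replace = TRUE,
                prob = d$redundancy_dist)
    if (!is.null(d$redundancy_override))
      R[as.integer(names(d$redundancy_override))] <-
        as.integer(d$redundancy_override)
    L <- stats::rlnorm(G, d$base_level_log_mean, d$base_level_log_sd)
    cv <- stats::runif(G, d$bio_cv_range[1L], d$bio_cv_range[2L])
    if (!is.null(d$planted_folds) && "cv" %in% names(d$planted_folds)) {
      pf <- d$planted_folds
      cv[pf$gene[!is.na(pf$cv)]] <- pf$cv[!is.na(pf$cv)]
    }
    sd_bio <- sqrt(log(1 + cv^2))
    sd_tech <- sqrt(log(1 + d$tech_cv^2))

    spot_gene <- rep(seq_len(G), R)
    spot_k <- sequence(R)
    spot_id <- sprintf("%s_s%02d", sym[spot_gene], spot_k)
    n_spots <- length(spot_id)
    bias <- stats::rnorm(n_spots, 0, d$spot_bias_sd)

    n_ctrl <- max(2L, round(0.01 * G))
    ctrl_id <- sprintf("Ctrl%03d", seq_len(n_ctrl))
    ctrl_level <- stats::rlnorm(n_ctrl, d$base_level_log_mean,
                                d$base_level_log_sd)

    mult <- matrix(1, G, length(d$phenotypes),
                   dimnames = list(sym, d$phenotypes))
    if (!is.null(d$planted_folds)) {
      pf <- d$planted_folds
      m <- ifelse(pf$fold >= 1, pf$fold, 1 / abs(pf$fold))
      mult[cbind(pf$gene, match(pf$phenotype, d$phenotypes))] <- m
    }

    lam <- numeric(G)
    module_of <- rep(NA_integer_, G)
    mod_rows <- list()
    for (mi in seq_along(d$coordination_modules)) {
      m <- d$coordination_modules[[mi]]
      lam[m$genes] <- m$loadings * m$latent_sd
      module_of[m$genes] <- mi
      mod_rows[[mi]] <- data.frame(gene = sym[m$genes], module = mi,
                                   loading = m$loadings,
                                   latent_sd = m$latent_sd,
                                   stringsAsFactors = FALSE)
    }

    tables <- list()
    corrupted <- list()
    for (p in d$phenotypes) {
      pm <- mult[, p]
      for (xi in seq_len(d$n_replicas)) {
        eps <- stats::rnorm(G, 0, sd_bio)
        z <- if (length(d$coordination_modules))
          stats::rnorm(length(d$coordination_modules)) else numeric(0L)
        w <- eps
        has_mod <- !is.na(module_of)
        if (any(has_mod))
          w[has_mod] <- w[has_mod] + lam[has_mod] * z[module_of[has_mod]]
        signal <- L[spot_gene] * pm[spot_gene] * exp(bias) *
          exp(w[spot_gene]) * exp(stats::rnorm(n_spots, 0, sd_tech))
        ctrl_sig <- ctrl_level * exp(stats::rnorm(n_ctrl, 0, sd_tech))
        fg <- c(d$bg_level + signal, d$bg_level + ctrl_sig)
        bg <- d$bg_level * exp(stats::rnorm(n_spots + n_ctrl, 0,
                                            d$bg_jitter_sd))
        flag <- ifelse(stats::runif(n_spots + n_ctrl) < d$corrupted_rate,
                       "corrupted", "ok")
        label <- paste0(p, ".", xi)
        tab <- spot_table(data.frame(
          spot_id = c(spot_id, ctrl_id),
          gene = c(sym[spot_gene], rep("", n_ctrl)),
          sample = label,
          fg = fg,
          bg = bg,
          flag = flag,
          stringsAsFactors = FALSE))
        tables[[label]] <- tab
        if (any(flag == "corrupted"))
          corrupted[[label]] <- data.frame(
            sample = label,
            spot_id = c(spot_id, ctrl_id)[flag == "corrupted"],
            stringsAsFactors = FALSE)
      }
    }
    folds <- d$planted_folds
    if (!is.null(folds)) folds$gene_symbol <- sym[folds$gene]
    modules <- if (length(mod_rows)) do.call(rbind, mod_rows) else
      data.frame(gene = character(0L), module = integer(0L),
                 loading = numeric(0L), latent_sd = numeric(0L))
    overlap <- intersect(modules$gene,
                         if (is.null(folds)) character(0L) else
                           folds$gene_symbol)
    truth <- list(
      multipliers = mult,
      folds = folds,
      modules = modules,
      cv = data.frame(gene = sym, cv = cv, R = R,
                      stringsAsFactors = FALSE),
      corrupted = if (length(corrupted)) do.call(rbind, corrupted) else
        data.frame(sample = character(0L), spot_id = character(0L)),
      overlap = overlap
    )
    rownames(truth$corrupted) <- NULL
    list(tables = tables, truth = truth)
  })
}

#' True signed expression ratio implied by the planted folds
#'
#' @param truth The `truth` component of a [simulate_experiment()] result.
#' @param phenotype,reference Phenotype labels of the contrast.
#' @return Named vector of signed ratios in the convention of
#'   [regulation()]: the plain ratio when expression rises, the negative
#'   reciprocal when it falls.
#' @export
true_expression_ratio <- function(truth, phenotype, reference) {
  m <- truth$multipliers[, phenotype] / truth$multipliers[, reference]
  ifelse(m >= 1, m, -1 / m)
}
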