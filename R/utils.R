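#' Number of distinct gene pairs in a correlation universe
#'
#' For `n` quantified genes the coordination analysis evaluates one Pearson
#' correlation per unordered pair, i.e. `n (n - 1) / 2` values per phenotype.
#'
#' @param n Number of genes (non-negative integer).
#' @return The number of unordered pairs, as a double to avoid integer
#'   overflow for chip-scale universes.
#' @examples
#' pair_count(4L)
#' @export
pair_count <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0 || n != floor(n))
    stop("'n' must be a single non-negative integer")
  n <- as.double(n)
  n * (n - 1) / 2
}

# split "<phenotype>.<k>" labels; the last dot separates the replica index
parse_sample_labels <- function(labels) {
  m <- regmatches(labels, regexec("^(.+)\\.([0-9]+)$", labels))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("sample label(s) not of the form '<phenotype>.<replica>': ",
         paste(unique(labels[bad]), collapse = ", "))
  data.frame(
    sample    = labels,
    phenotype = vapply(m, `[`, "", 2L),
    replica   = as.integer(vapply(m, `[`, "", 3L)),
    stringsAsFactors = FALSE
  )
}

# vectorised two-tailed Welch t-test p-values for equal-length groups;
# rows of x and y are genes, columns replicas
welch_p <- function(x, y) {
  n1 <- ncol(x); n2 <- ncol(y)
  m1 <- rowMeans(x); m2 <- rowMeans(y)
  v1 <- apply(x, 1L, stats::var); v2 <- apply(y, 1L, stats::var)
  se2 <- v1 / n1 + v2 / n2
  df <- se2^2 / ((v1 / n1)^2 / (n1 - 1) + (v2 / n2)^2 / (n2 - 1))
  t <- (m1 - m2) / sqrt(se2)
  p <- 2 * stats::pt(-abs(t), df)
  degenerate <- se2 == 0
  if (any(degenerate)) p[degenerate] <- ifelse(m1[degenerate] == m2[degenerate], 1, 0)
  p
}

# restore the caller's RNG state on exit; used by every stochastic entry point
with_preserved_seed <- function(code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  }
  force(code)
}
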