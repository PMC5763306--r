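#' Regulator influence scores
#'
#' The influence of regulator j in sample k summarises its transcriptional
#' effect as the scaled difference between the mean expression of its
#' activated targets and that of its repressed targets, i.e. the Welch
#' two-sample t statistic computed within the sample over target genes:
#' \deqn{I_{jk} = \frac{\bar X_A - \bar X_R}
#'   {\sqrt{s_A^2/n_A + s_R^2/n_R}}}
#' with unbiased sample variances and set sizes \eqn{n_A}, \eqn{n_R}. A whole
#' expression profile of thousands of genes is thereby reduced to a handful
#' of regulator activity scores, one per sample.
#'
#' Targets absent from the expression matrix are dropped before computing. A
#' regulator needs at least \code{min_targets} activated and repressed
#' targets with expression (variance needs n >= 2); otherwise its entries are
#' undefined (\code{NA}). When both variances are zero the statistic is 0 for
#' equal means and is otherwise clamped to \code{+/-clamp} with a warning, so
#' saturated values do not propagate infinities into downstream regression.
#'
#' @param net RegulatoryNetwork.
#' @param expr expression matrix, genes x samples.
#' @param min_targets minimum activated and repressed target count (each)
#'   required for a defined score; default 2.
#' @param center_genes subtract each gene's mean across samples first.
#'   Default FALSE: scores are computed on values as given.
#' @param clamp magnitude assigned to zero-variance, unequal-mean cases.
#' @return numeric matrix, regulators x samples, \code{NA} where undefined.
#' @export
compute_influence <- function(net, expr, min_targets = 2,
                              center_genes = FALSE, clamp = 1e6) {
  expr <- as_expression_matrix(expr)
  if (min_targets < 2) stop("min_targets must be >= 2 (variance needs n >= 2)")
  if (center_genes) expr <- expr - rowMeans(expr, na.rm = TRUE)
  regs <- net$regulators
  infl <- matrix(NA_real_, length(regs), ncol(expr),
                 dimnames = list(regs, colnames(expr)))
  saturated <- 0L
  for (j in regs) {
    A <- intersect(activated_targets(net, j), rownames(expr))
    R <- intersect(repressed_targets(net, j), rownames(expr))
    if (length(A) < min_targets || length(R) < min_targets) next
    xa <- expr[A, , drop = FALSE]
    xr <- expr[R, , drop = FALSE]
    ma <- colMeans(xa); mr <- colMeans(xr)
    va <- apply(xa, 2L, stats::var)
    vr <- apply(xr, 2L, stats::var)
    den <- sqrt(va / length(A) + vr / length(R))
    num <- ma - mr
    val <- num / den
    zero_den <- !is.na(den) & den == 0
    val[zero_den & num == 0] <- 0
    sat <- zero_den & num != 0
    if (any(sat, na.rm = TRUE)) {
      saturated <- saturated + sum(sat, na.rm = TRUE)
      val[sat] <- sign(num[sat]) * clamp
    }
    infl[j, ] <- val
  }
  if (saturated > 0L)
    warning(sprintf(
      "%d influence value(s) had zero variance in both target sets; clamped to +/-%g",
      saturated, clamp))
  infl
}

#' Read an influence matrix from TSV (regulators x samples)
#' @param path input file path.
#' @return numeric matrix.
#' @export
read_influence <- function(path) {
  m <- read_expression(path)
  m
}

#' Write an influence matrix to TSV
#' @param infl numeric matrix, regulators x samples.
#' @param path output file path.
#' @export
write_influence <- function(infl, path) {
  df <- data.frame(regulator = rownames(infl), infl, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
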