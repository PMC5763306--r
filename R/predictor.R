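#' Fit the linear influence-to-expression model
#'
#' For each target gene i with regulator set Pa(i) in the network, fits the
#' per-gene linear model
#' \deqn{x_{ik} = \sum_{j \in Pa(i)} \beta_j I_{jk}}
#' by ordinary least squares over training samples shared between the
#' expression and influence matrices. There is no intercept by default (the
#' model form has none); set \code{intercept = TRUE} when working with
#' uncentred log expression. Samples in which any required influence is
#' undefined are dropped for that gene. Genes with no regulator in the
#' network, or with fewer than p+1 usable samples (p = number of
#' covariates), are skipped and recorded.
#'
#' @param net RegulatoryNetwork defining Pa(i).
#' @param infl influence matrix (regulators x samples), e.g. from
#'   \code{\link{compute_influence}}.
#' @param expr training expression matrix (genes x samples).
#' @param targets genes to model; default all rows of \code{expr}.
#' @param intercept include an intercept term.
#' @param ridge nonnegative ridge penalty lambda; 0 (default) is plain OLS.
#'   Rank-deficient OLS designs fall back to the minimum-norm solution with
#'   a warning.
#' @return object of class \code{LinearInfluenceModel}: per-gene regulators
#'   and coefficients, plus a skip report and training metadata.
#' @export
fit_influence_model <- function(net, infl, expr, targets = NULL,
                                intercept = FALSE, ridge = 0) {
  expr <- as_expression_matrix(expr)
  if (is.null(targets)) targets <- rownames(expr)
  samples <- intersect(colnames(infl), colnames(expr))
  if (length(samples) == 0L) stop("no shared samples between infl and expr")
  genes <- list()
  skipped <- data.frame(gene = character(), reason = character(),
                        stringsAsFactors = FALSE)
  skip <- function(g, why)
    rbind(skipped, data.frame(gene = g, reason = why, stringsAsFactors = FALSE))
  for (g in targets) {
    if (!g %in% rownames(expr)) { skipped <- skip(g, "not in expression"); next }
    pa <- intersect(regulators_of(net, g), rownames(infl))
    if (length(pa) == 0L) { skipped <- skip(g, "no regulators"); next }
    X <- t(infl[pa, samples, drop = FALSE])
    y <- expr[g, samples]
    ok <- stats::complete.cases(X) & !is.na(y)
    X <- X[ok, , drop = FALSE]
    y <- y[ok]
    p <- length(pa) + as.integer(intercept)
    if (length(y) < p + 1L) { skipped <- skip(g, "too few samples"); next }
    if (intercept) X <- cbind(`(Intercept)` = 1, X)
    beta <- solve_ls(X, y, ridge = ridge, gene = g)
    fitted <- as.vector(X %*% beta)
    genes[[g]] <- list(regulators = pa, beta = stats::setNames(beta, colnames(X)),
                       n_train = length(y),
                       rss = sum((y - fitted)^2))
  }
  structure(list(genes = genes, intercept = intercept, ridge = ridge,
                 n_samples = length(samples), skipped = skipped),
            class = "LinearInfluenceModel")
}

solve_ls <- function(X, y, ridge = 0, gene = "") {
  if (ridge > 0) {
    XtX <- crossprod(X) + diag(ridge, ncol(X))
    return(as.vector(solve(XtX, crossprod(X, y))))
  }
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    warning("rank-deficient design for gene '", gene,
            "'; using minimum-norm solution")
    sv <- svd(X)
    pos <- sv$d > max(dim(X)) * .Machine$double.eps * sv$d[1L]
    return(as.vector(sv$v[, pos, drop = FALSE] %*%
                       ((t(sv$u[, pos, drop = FALSE]) %*% y) / sv$d[pos])))
  }
  as.vector(qr.coef(qr_x, y))
}

#' @export
print.LinearInfluenceModel <- function(x, ...) {
  cat(sprintf(
    "LinearInfluenceModel: %d genes modeled, %d skipped, %d training samples%s\n",
    length(x$genes), nrow(x$skipped), x$n_samples,
    if (x$intercept) " (with intercept)" else ""))
  invisible(x)
}

#' Predict expression from context influences
#'
#' Applies the trained coefficients to context-specific influence scores:
#' \eqn{\hat x_{ik} = \sum_j \beta_j I_{jk}}. The context influences must be
#' computed with the same network the model was trained on. A gene-sample
#' prediction is \code{NA} when a required regulator influence is undefined
#' in that sample; genes missing a regulator row entirely are dropped from
#' the output (the downstream GPR discard rule then ignores them).
#'
#' @param object LinearInfluenceModel.
#' @param infl influence matrix (regulators x samples) for the new context.
#' @param ... unused.
#' @return expression matrix of predictions (modeled genes x context samples).
#' @export
predict.LinearInfluenceModel <- function(object, infl, ...) {
  genes <- names(object$genes)
  keep <- vapply(genes, function(g)
    all(object$genes[[g]]$regulators %in% rownames(infl)), logical(1))
  genes <- genes[keep]
  out <- matrix(NA_real_, length(genes), ncol(infl),
                dimnames = list(genes, colnames(infl)))
  for (g in genes) {
    m <- object$genes[[g]]
    X <- t(infl[m$regulators, , drop = FALSE])
    if (object$intercept) X <- cbind(`(Intercept)` = 1, X)
    out[g, ] <- as.vector(X %*% m$beta)
  }
  out
}

#' Serialize a linear influence model to JSON
#' @param model LinearInfluenceModel
#' @param path output path.
#' @export
write_influence_model <- function(model, path) {
  obj <- list(intercept = model$intercept, ridge = model$ridge,
              n_samples = model$n_samples,
              genes = lapply(model$genes, function(m)
                list(regulators = m$regulators,
                     beta = as.list(m$beta),
                     n_train = m$n_train, rss = m$rss)),
              skipped = model$skipped)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a linear influence model from JSON
#' @param path input path.
#' @return LinearInfluenceModel
#' @export
read_influence_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  genes <- lapply(obj$genes, function(m)
    list(regulators = unlist(m$regulators),
         beta = unlist(m$beta),
         n_train = m$n_train, rss = m$rss))
  skipped <- if (length(obj$skipped) == 0L)
    data.frame(gene = character(), reason = character())
  else do.call(rbind, lapply(obj$skipped, as.data.frame))
  structure(list(genes = genes, intercept = isTRUE(obj$intercept),
                 ridge = obj$ridge, n_samples = obj$n_samples,
                 skipped = skipped),
            class = "LinearInfluenceModel")
}
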