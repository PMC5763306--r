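# Flux balance analysis: max c.v subject to S v = 0, lb <= v <= ub.
#
# The LP is solved by a two-phase primal simplex implemented here (dense
# tableau-free form: the basis system is re-solved each iteration, which is
# cheap at the model sizes this package targets). Bland's anti-cycling rule
# makes termination unconditional, which matters because steady-state rows
# with zero right-hand side make FBA bases highly degenerate. Variables are
# shifted by lb so the solver sees x >= 0; upper bounds enter as slack rows.
# Model validation requires finite bounds, so the LP is always bounded.

LP_FEAS_TOL <- 1e-6
LP_PIVOT_TOL <- 1e-9

# minimize obj'x s.t. A x = b, x >= 0, starting from a feasible basis.
simplex_iterate <- function(obj, A, b, basis) {
  m <- nrow(A)
  it <- 0L
  repeat {
    it <- it + 1L
    if (it > 20000L) stop("simplex iteration limit reached")
    B <- A[, basis, drop = FALSE]
    xB <- solve(B, b)
    y <- solve(t(B), obj[basis])
    red <- obj - as.vector(crossprod(A, y))
    red[basis] <- 0
    enter <- which(red < -LP_PIVOT_TOL)
    if (length(enter) == 0L)
      return(list(status = "optimal", basis = basis, xB = xB,
                  value = sum(obj[basis] * xB)))
    j <- min(enter)  # Bland's rule
    d <- solve(B, A[, j])
    pos <- which(d > LP_PIVOT_TOL)
    if (length(pos) == 0L) return(list(status = "unbounded"))
    ratios <- xB[pos] / d[pos]
    rmin <- min(ratios)
    cand <- pos[ratios <= rmin + LP_PIVOT_TOL]
    leave <- cand[which.min(basis[cand])]  # Bland tie-break
    basis[leave] <- j
  }
}

# two-phase simplex for min obj'x, A x = b, x >= 0 (b of any sign)
solve_std_lp <- function(obj, A, b) {
  m <- nrow(A); n <- ncol(A)
  neg <- b < 0
  A[neg, ] <- -A[neg, , drop = FALSE]
  b[neg] <- -b[neg]
  # phase 1: artificials
  A1 <- cbind(A, diag(m))
  obj1 <- c(rep(0, n), rep(1, m))
  r1 <- simplex_iterate(obj1, A1, b, basis = n + seq_len(m))
  if (r1$status != "optimal" || r1$value > LP_FEAS_TOL)
    return(list(status = "infeasible"))
  basis <- r1$basis
  # drive artificials out of the basis; drop redundant rows
  drop_rows <- integer()
  for (k in seq_along(basis)) {
    if (basis[k] <= n) next
    B <- A1[, basis, drop = FALSE]
    ek <- numeric(length(basis)); ek[k] <- 1
    wtA <- as.vector(crossprod(A, solve(t(B), ek)))
    j <- which(abs(wtA) > LP_PIVOT_TOL & !(seq_len(n) %in% basis))
    if (length(j) > 0L) basis[k] <- min(j) else drop_rows <- c(drop_rows, k)
  }
  if (length(drop_rows) > 0L) {
    rows <- setdiff(seq_len(m), drop_rows)
    A <- A[rows, , drop = FALSE]
    b <- b[rows]
    basis <- basis[-drop_rows]
  }
  r2 <- simplex_iterate(obj, A, b, basis = basis)
  if (r2$status != "optimal") return(list(status = r2$status))
  x <- numeric(n)
  x[r2$basis] <- r2$xB
  list(status = "optimal", x = x, value = sum(obj * x))
}

#' Solve a bounded linear program
#'
#' Optimizes \code{cc . v} subject to \code{S v = b} and finite box bounds.
#' Fixed variables (lb == ub) are eliminated up front; the rest are shifted
#' to be nonnegative and upper bounds enter as slack rows of the standard
#' form solved by the two-phase simplex.
#'
#' @param cc objective coefficients.
#' @param S equality constraint matrix.
#' @param b equality right-hand side.
#' @param lb,ub finite variable bounds.
#' @param maximize maximize (TRUE) or minimize.
#' @return list with \code{status} ("optimal", "infeasible" or "unbounded"),
#'   \code{x}, \code{objective}.
#' @keywords internal
solve_lp <- function(cc, S, b, lb, ub, maximize = TRUE) {
  n <- length(cc)
  stopifnot(length(lb) == n, length(ub) == n, ncol(S) == n,
            all(is.finite(lb)), all(is.finite(ub)))
  fixed <- (ub - lb) < 1e-12
  x <- lb  # fixed variables sit at lb
  free <- which(!fixed)
  if (length(free) == 0L) {
    resid <- as.vector(S %*% x) - b
    status <- if (max(abs(resid)) <= LP_FEAS_TOL) "optimal" else "infeasible"
    return(list(status = status, x = x, objective = sum(cc * x)))
  }
  Sf <- S[, free, drop = FALSE]
  lf <- lb[free]; uf <- ub[free]
  nf <- length(free)
  # shift z = v - lf >= 0; S z = b - S lb; z + s = uf - lf
  rhs <- b - as.vector(S %*% lb)
  zero_row <- apply(Sf, 1L, function(r) all(r == 0))
  if (any(zero_row & abs(rhs) > LP_FEAS_TOL))
    return(list(status = "infeasible", x = x, objective = NA_real_))
  Sf <- Sf[!zero_row, , drop = FALSE]
  rhs <- rhs[!zero_row]
  m_eq <- nrow(Sf)
  A <- rbind(cbind(Sf, matrix(0, m_eq, nf)),
             cbind(diag(nf), diag(nf)))
  bb <- c(rhs, uf - lf)
  obj <- c(if (maximize) -cc[free] else cc[free], rep(0, nf))
  res <- solve_std_lp(obj, A, bb)
  if (res$status != "optimal")
    return(list(status = res$status, x = x, objective = NA_real_))
  x[free] <- res$x[seq_len(nf)] + lf
  list(status = "optimal", x = x, objective = sum(cc * x))
}

#' Solve the flux balance analysis LP of a model
#'
#' Maximizes (or minimizes) the objective reaction's flux under steady state
#' (S v = 0) and the model's flux bounds. Infeasibility is reported in the
#' solution status, not raised. Optimal solutions are checked against the
#' steady-state and bound invariants at tolerance 1e-6.
#'
#' @param model MetabolicModel.
#' @param sense "max" (default) or "min".
#' @return object of class \code{FluxSolution}: named \code{fluxes},
#'   \code{objective_value}, \code{status}.
#' @export
solve_fba <- function(model, sense = c("max", "min")) {
  sense <- match.arg(sense)
  cc <- as.numeric(model$reactions == model$objective)
  res <- solve_lp(cc, model$S, rep(0, length(model$metabolites)),
                  model$lb, model$ub, maximize = (sense == "max"))
  if (res$status != "optimal")
    return(structure(list(fluxes = NULL, objective_value = NA_real_,
                          status = res$status), class = "FluxSolution"))
  v <- stats::setNames(res$x, model$reactions)
  resid <- max(abs(as.vector(model$S %*% v)))
  if (resid > LP_FEAS_TOL ||
      any(v < model$lb - LP_FEAS_TOL) || any(v > model$ub + LP_FEAS_TOL))
    stop("FBA solution violates feasibility tolerance (residual ",
         format(resid), ")")
  structure(list(fluxes = v, objective_value = res$objective,
                 status = "optimal"), class = "FluxSolution")
}

#' @export
print.FluxSolution <- function(x, ...) {
  cat(sprintf("FluxSolution: status=%s, objective=%s\n", x$status,
              format(x$objective_value)))
  invisible(x)
}

#' Write a flux solution as a TSV flux table
#' @param sol FluxSolution
#' @param path output path.
#' @param exchanges_only restrict to exchange reactions of \code{model}.
#' @param model required when \code{exchanges_only = TRUE}.
#' @export
write_fluxes <- function(sol, path, exchanges_only = FALSE, model = NULL) {
  if (sol$status != "optimal") stop("no fluxes: solution status is ", sol$status)
  fl <- sol$fluxes
  if (exchanges_only) {
    if (is.null(model)) stop("model needed for exchanges_only")
    fl <- fl[names(fl) %in% model$exchange]
  }
  utils::write.table(
    data.frame(reaction = names(fl), flux = unname(fl)),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
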