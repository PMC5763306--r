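#' Calibration objective
#'
#' Agreement between observed and simulated biomass yield, scored as
#' \deqn{-\ln(|v_{obs} - v_{sim}| / v_{obs})}
#' (natural log; the base only shifts the scale, the argmax is invariant).
#' The objective grows as the simulated yield approaches the observation; the
#' relative error is floored at \code{eps * v_obs} so a perfect match gives a
#' large finite value instead of infinity.
#'
#' @param v_obs observed growth rate (> 0).
#' @param v_sim simulated biomass yield (>= 0); vectorized.
#' @param eps relative-error floor, default 1e-9.
#' @return objective value(s).
#' @export
calibration_objective <- function(v_obs, v_sim, eps = 1e-9) {
  if (!is.numeric(v_obs) || length(v_obs) != 1L || is.na(v_obs) || v_obs <= 0)
    stop("v_obs must be a positive scalar")
  rel <- pmax(abs(v_obs - v_sim) / v_obs, eps)
  -log(rel)
}

#' Calibrate the condition-specific softplus offset theta
#'
#' Simulated growth is a nondecreasing function of theta that saturates at
#' the plain-FBA optimum, so matching an attainable observed growth rate is a
#' one-dimensional unimodal problem. The calibrator first evaluates the
#' objective on a uniform grid of \code{grid_n} points on
#' [\code{grid_lo}, \code{grid_hi}], then refines around the best grid point
#' with deterministic golden-section search (reproducible; no random
#' surrogate). When the plain-FBA optimum itself falls short of the observed
#' growth (beyond relative tolerance \code{tol_under}), no theta can close
#' the gap — the result carries status \code{"fba_underestimates"} and the
#' best grid theta, without refinement.
#'
#' @param model,net,lin_model,context,sample,context_type,min_targets passed
#'   to \code{\link{simulate_fluxes}}.
#' @param v_obs observed growth rate (> 0).
#' @param grid_lo,grid_hi,grid_n uniform theta grid (default 10 points on
#'   [-10, 10]).
#' @param max_calls budget of simulate calls (grid included), default 50.
#' @param tol_under relative tolerance of the underestimation test.
#' @param eps relative-error floor of the objective.
#' @return object of class \code{CalibrationResult}: \code{theta_opt},
#'   \code{v_sim_opt}, \code{rel_error}, \code{status} ("converged",
#'   "fba_underestimates" or "failed"), \code{n_calls}, \code{method}, and an
#'   \code{objective_trace} data.frame (theta, v_sim, objective, rel_error).
#' @export
calibrate_theta <- function(model, net, lin_model, context, v_obs,
                            sample = NULL,
                            context_type = c("expression", "influence"),
                            grid_lo = -10, grid_hi = 10, grid_n = 10,
                            max_calls = 50, tol_under = 1e-3,
                            min_targets = 2, eps = 1e-9) {
  context_type <- match.arg(context_type)
  if (v_obs <= 0) stop("v_obs must be positive")
  calls <- 0L
  trace <- data.frame(theta = numeric(), v_sim = numeric(),
                      objective = numeric(), rel_error = numeric())
  growth <- function(theta) {
    calls <<- calls + 1L
    sol <- simulate_fluxes(model, net, lin_model, context, theta,
                           sample = sample, context_type = context_type,
                           min_targets = min_targets)
    v <- if (sol$status == "optimal") sol$objective_value else NA_real_
    obj <- if (is.na(v)) NA_real_ else calibration_objective(v_obs, v, eps)
    rel <- if (is.na(v)) NA_real_ else abs(v_obs - v) / v_obs
    trace[nrow(trace) + 1L, ] <<- c(theta, v, obj, rel)
    v
  }

  fba_opt <- solve_fba(model)$objective_value
  grid <- seq(grid_lo, grid_hi, length.out = grid_n)
  vg <- vapply(grid, growth, numeric(1))
  if (all(is.na(vg))) {
    return(structure(list(theta_opt = NA_real_, v_sim_opt = NA_real_,
                          rel_error = NA_real_, status = "failed",
                          n_calls = calls, method = "grid+golden-section",
                          objective_trace = trace),
                     class = "CalibrationResult"))
  }
  obj_g <- calibration_objective(v_obs, vg, eps)
  best <- which.max(obj_g)
  underestimates <- !is.na(fba_opt) && fba_opt < v_obs * (1 - tol_under)
  if (underestimates) {
    return(structure(list(theta_opt = grid[best], v_sim_opt = vg[best],
                          rel_error = abs(v_obs - vg[best]) / v_obs,
                          status = "fba_underestimates",
                          n_calls = calls, method = "grid+golden-section",
                          objective_trace = trace),
                     class = "CalibrationResult"))
  }

  # golden-section refinement on the bracket around the best grid point
  h <- if (grid_n > 1L) grid[2L] - grid[1L] else (grid_hi - grid_lo) / 2
  lo <- max(grid_lo, grid[best] - h)
  hi <- min(grid_hi, grid[best] + h)
  phi <- (sqrt(5) - 1) / 2
  x1 <- hi - phi * (hi - lo)
  x2 <- lo + phi * (hi - lo)
  f <- function(theta) {
    v <- growth(theta)
    if (is.na(v)) -Inf else calibration_objective(v_obs, v, eps)
  }
  f1 <- f(x1); f2 <- f(x2)
  while (calls < max_calls && (hi - lo) > 1e-7 &&
         max(trace$objective, na.rm = TRUE) < -log(1e-6)) {
    if (f1 >= f2) {
      hi <- x2; x2 <- x1; f2 <- f1
      x1 <- hi - phi * (hi - lo)
      f1 <- f(x1)
    } else {
      lo <- x1; x1 <- x2; f1 <- f2
      x2 <- lo + phi * (hi - lo)
      f2 <- f(x2)
    }
  }
  ibest <- which.max(trace$objective)
  structure(list(theta_opt = trace$theta[ibest],
                 v_sim_opt = trace$v_sim[ibest],
                 rel_error = trace$rel_error[ibest],
                 status = "converged", n_calls = calls,
                 method = "grid+golden-section",
                 objective_trace = trace),
            class = "CalibrationResult")
}

#' @export
print.CalibrationResult <- function(x, ...) {
  cat(sprintf(
    "CalibrationResult: status=%s, theta=%.6g, simulated growth=%.6g, rel. error=%.3g (%d simulate calls)\n",
    x$status, x$theta_opt, x$v_sim_opt, x$rel_error, x$n_calls))
  invisible(x)
}

#' Write a calibration trace as TSV
#' @param result CalibrationResult
#' @param path output path.
#' @export
write_calibration_trace <- function(result, path) {
  utils::write.table(result$objective_trace, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
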