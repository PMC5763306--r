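#' Perturb an expression matrix by row permutation
#'
#' The noise model behind the robustness protocol: a fraction \code{level}
#' of genes is selected uniformly at random (seeded), and within each sample
#' the values of the selected genes are shuffled among those rows. The
#' multiset of values per sample is preserved — only the gene assignment is
#' randomized. \code{level = 0} is the identity; the same seed always yields
#' the same output.
#'
#' @param expr expression matrix (genes x samples).
#' @param level fraction of genes to permute, in [0, 1].
#' @param seed integer seed.
#' @return perturbed expression matrix of the same shape.
#' @export
perturb_expression <- function(expr, level, seed) {
  expr <- as_expression_matrix(expr)
  if (level < 0 || level > 1) stop("level must be in [0, 1]")
  k <- floor(level * nrow(expr))
  if (k < 2L) return(expr)
  out <- expr
  rs <- local({
    set.seed(seed)
    rows <- sample(nrow(expr), k)
    perms <- replicate(ncol(expr), sample(k), simplify = FALSE)
    list(rows = rows, perms = perms)
  })
  for (s in seq_len(ncol(expr)))
    out[rs$rows, s] <- expr[rs$rows[rs$perms[[s]]], s]
  out
}

#' Normalized mean squared error on exchange fluxes
#'
#' Mean over the observed exchange reactions of
#' \eqn{((v_{sim} - v_{obs}) / s)^2} with the normalization constant
#' \eqn{s = \max |v_{obs}|} over those reactions, so the statistic is
#' unit-free (doubling all observed and simulated fluxes leaves it
#' unchanged).
#'
#' @param v_sim FluxSolution (or a named flux vector).
#' @param v_obs named numeric vector of observed exchange fluxes; names must
#'   be reactions of the solution.
#' @param log10 also return the base-10 log of the error.
#' @return the error, or \code{c(error, log10_error)} when
#'   \code{log10 = TRUE}.
#' @export
exchange_flux_error <- function(v_sim, v_obs, log10 = FALSE) {
  if (length(v_obs) == 0L || is.null(names(v_obs)))
    stop("v_obs must be a nonempty named vector")
  fl <- if (inherits(v_sim, "FluxSolution")) v_sim$fluxes else v_sim
  if (!all(names(v_obs) %in% names(fl)))
    stop("observed exchange missing from solution: ",
         setdiff(names(v_obs), names(fl))[1L])
  s <- max(abs(v_obs))
  if (s == 0) stop("all observed fluxes are zero; normalization undefined")
  err <- mean(((fl[names(v_obs)] - v_obs) / s)^2)
  if (log10) c(error = err, log10_error = log10(err)) else err
}

#' Robustness of flux predictions to expression noise
#'
#' The robustness protocol: for each noise level and replicate, the context
#' expression is perturbed (\code{\link{perturb_expression}}), the pipeline
#' is rerun (influence, prediction, softplus constraints, FBA at the
#' calibrated theta), and the normalized exchange-flux error against the
#' reference fluxes is recorded. With \code{input = "raw"} the perturbed
#' expression is fed directly into the GPR rules instead, which isolates
#' the contribution of the influence/prediction stage. Replicate seeds are
#' derived independently from \code{seed}, so errors do not depend on
#' replicate order.
#'
#' @param model,net,lin_model,sample,min_targets passed to
#'   \code{\link{simulate_fluxes}}.
#' @param context expression matrix for the condition.
#' @param theta calibrated softplus offset of the condition.
#' @param v_obs named vector of reference exchange fluxes.
#' @param levels noise levels in [0, 1].
#' @param replicates replicates per level.
#' @param seed integer master seed.
#' @param input "influence" (full pipeline, default) or "raw".
#' @return data.frame (level, replicate, error, log10_error).
#' @export
robustness_run <- function(model, net, lin_model, context, theta, v_obs,
                           levels = c(0, 0.1, 0.25, 0.5, 1),
                           replicates = 20, seed = 1,
                           sample = NULL, input = c("influence", "raw"),
                           min_targets = 2) {
  input <- match.arg(input)
  rows <- list()
  for (li in seq_along(levels)) {
    for (rep in seq_len(replicates)) {
      sub_seed <- (seed * 1000L + li * 100L + rep) %% .Machine$integer.max
      pert <- perturb_expression(context, levels[li], sub_seed)
      sol <- simulate_fluxes(model, net, lin_model, pert, theta,
                             sample = sample,
                             use_raw_expression = (input == "raw"),
                             min_targets = min_targets)
      err <- if (sol$status == "optimal")
        exchange_flux_error(sol, v_obs) else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(level = levels[li], replicate = rep, error = err,
                   log10_error = log10(err))
    }
  }
  do.call(rbind, rows)
}
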