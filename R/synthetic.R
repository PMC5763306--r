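# Synthetic benchmark generators. Every generator is a pure function of its
# parameters and seed, and ships the ground truth alongside the object so
# recovery tests never have to re-derive it.

#' Toy metabolic models
#'
#' Three small models exercising every downstream stage:
#' \itemize{
#'   \item \code{chain}: uptake -> A -> B -> biomass, unit stoichiometry,
#'     uptake capped at 10. The FBA optimum equals the uptake bound.
#'   \item \code{branch}: two substrates with distinct biomass yields
#'     (0.8 and 0.4) feeding a common biomass drain.
#'   \item \code{diauxic}: glucose can be fermented (yield 0.5 biomass,
#'     1.5 ethanol per glucose, GPR \code{"FERM1 or FERM2"}) or respired
#'     (yield 1.0, GPR \code{"RESP1 and RESP2"}); ethanol can be respired
#'     (yield 0.3, GPR \code{"ADH2 and ACS1"}). Exchange reactions follow
#'     the convention "metabolite ->" (negative flux = uptake): glucose
#'     uptake up to 10, ethanol free to enter or leave. Regulation acting on
#'     the GPRs can thus switch the model between fermentative and
#'     respiratory phases.
#' }
#'
#' @param kind "chain", "branch" or "diauxic".
#' @return MetabolicModel
#' @export
make_toy_model <- function(kind = c("chain", "branch", "diauxic")) {
  kind <- match.arg(kind)
  if (kind == "chain") {
    S <- matrix(0, 3, 4, dimnames = list(
      c("A", "B", "BIO"),
      c("uptake", "conv", "synth", "biomass")))
    S["A", "uptake"] <- 1
    S["A", "conv"] <- -1; S["B", "conv"] <- 1
    S["B", "synth"] <- -1; S["BIO", "synth"] <- 1
    S["BIO", "biomass"] <- -1
    return(metabolic_model(S, lb = rep(0, 4), ub = c(10, 1000, 1000, 1000),
                           objective = "biomass"))
  }
  if (kind == "branch") {
    S <- matrix(0, 3, 6, dimnames = list(
      c("S1", "S2", "X"),
      c("upt1", "upt2", "conv1", "conv2", "biomass", "leak")))
    S["S1", "upt1"] <- 1
    S["S2", "upt2"] <- 1
    S["S1", "conv1"] <- -1; S["X", "conv1"] <- 0.8
    S["S2", "conv2"] <- -1; S["X", "conv2"] <- 0.4
    S["X", "biomass"] <- -1
    S["S1", "leak"] <- -1
    return(metabolic_model(S, lb = rep(0, 6), ub = c(5, 5, 1000, 1000, 1000, 1000),
                           objective = "biomass"))
  }
  S <- matrix(0, 3, 6, dimnames = list(
    c("glc", "eth", "x"),
    c("EX_glc", "EX_eth", "FERM", "RESPG", "RESPE", "BIOMASS")))
  S["glc", "EX_glc"] <- -1
  S["eth", "EX_eth"] <- -1
  S["glc", "FERM"] <- -1; S["x", "FERM"] <- 0.5; S["eth", "FERM"] <- 1.5
  S["glc", "RESPG"] <- -1; S["x", "RESPG"] <- 1
  S["eth", "RESPE"] <- -1; S["x", "RESPE"] <- 0.3
  S["x", "BIOMASS"] <- -1
  metabolic_model(
    S,
    lb = c(-10, -10, 0, 0, 0, 0),
    ub = c(0, 1000, 1000, 1000, 1000, 1000),
    objective = "BIOMASS",
    gpr = list(FERM = "FERM1 or FERM2",
               RESPG = "RESP1 and RESP2",
               RESPE = "ADH2 and ACS1"))
}

#' Generate a planted signed regulatory network
#'
#' Each target gets \code{edges_per_target} distinct regulators; the first
#' is always an activator, further ones are activators with probability
#' \code{p_activate}. The ground-truth edge table is attached as attribute
#' \code{"truth"}.
#'
#' @param n_regs number of regulators (>= 2), ids R1..Rn.
#' @param n_targets number of target genes, ids G1..Gm.
#' @param edges_per_target regulators per target.
#' @param seed integer seed.
#' @param p_activate probability that a non-first edge activates.
#' @return RegulatoryNetwork with attribute \code{"truth"}.
#' @export
make_planted_network <- function(n_regs, n_targets, edges_per_target = 2,
                                 seed = 1, p_activate = 0.6) {
  if (n_regs < 2) stop("n_regs must be >= 2")
  set.seed(seed)
  regs <- paste0("R", seq_len(n_regs))
  targets <- paste0("G", seq_len(n_targets))
  rows <- list()
  for (g in targets) {
    k <- min(edges_per_target, n_regs)
    chosen <- sample(regs, k)
    signs <- c(1, ifelse(stats::runif(k - 1) < p_activate, 1, -1))
    rows[[g]] <- data.frame(regulator = chosen, target = g, sign = signs)
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  net <- regulatory_network(truth)
  attr(net, "truth") <- truth
  net
}

#' Generate expression data from a planted network
#'
#' Regulator profiles are standard-normal per sample. Each target combines
#' its regulators through the min rule that the downstream statistics
#' assume: \code{m = min(activator values, -repressor values)}, and
#' \itemize{
#'   \item \code{linear_influence}: target value \code{w * m + noise} — so
#'     influence scores are informative and the linear influence model holds
#'     approximately;
#'   \item \code{discrete_logic}: regulator profiles are first discretized
#'     at one SD and the target is \code{w * min(discrete states) + noise} —
#'     thresholded AND/OR logic for co-regulator mining recovery.
#' }
#'
#' @param net RegulatoryNetwork (e.g. from
#'   \code{\link{make_planted_network}}).
#' @param n_samples number of samples.
#' @param noise_sd gaussian noise SD on the standard-normal scale
#'   (default 0.2).
#' @param regime "linear_influence" or "discrete_logic".
#' @param seed integer seed.
#' @param w effect size (default 1).
#' @param regulator_values optional regulators x samples matrix overriding
#'   the random regulator profiles (used to construct condition-specific
#'   contexts).
#' @param baselines optional named vector of per-gene baseline offsets added
#'   to the generated values (constant across samples). Log-scale expression
#'   has gene-specific baselines spanning a wide range; passing the same
#'   vector to training and context calls keeps them consistent.
#' @return expression matrix with regulators and targets as rows.
#' @export
make_expression <- function(net, n_samples, noise_sd = 0.2,
                            regime = c("linear_influence", "discrete_logic"),
                            seed = 1, w = 1, regulator_values = NULL,
                            baselines = NULL) {
  regime <- match.arg(regime)
  set.seed(seed)
  regs <- net$regulators
  targets <- sort_c(unique(net$edges$target))
  samples <- if (!is.null(regulator_values)) colnames(regulator_values)
  else paste0("s", seq_len(n_samples))
  if (is.null(regulator_values)) {
    reg_expr <- matrix(stats::rnorm(length(regs) * n_samples),
                       length(regs), n_samples,
                       dimnames = list(regs, samples))
  } else {
    stopifnot(all(regs %in% rownames(regulator_values)))
    reg_expr <- regulator_values[regs, , drop = FALSE]
    n_samples <- ncol(reg_expr)
  }
  drive <- if (regime == "discrete_logic") {
    if (stats::sd(as.vector(reg_expr)) == 0) sign(reg_expr)
    else discretize(reg_expr, 1, scale = "sd")
  } else reg_expr
  tgt_expr <- matrix(NA_real_, length(targets), n_samples,
                     dimnames = list(targets, samples))
  for (g in targets) {
    act <- net$edges$regulator[net$edges$target == g & net$edges$sign > 0]
    rep_ <- net$edges$regulator[net$edges$target == g & net$edges$sign < 0]
    parts <- rbind(drive[act, , drop = FALSE], -drive[rep_, , drop = FALSE])
    m <- apply(parts, 2L, min)
    tgt_expr[g, ] <- w * m + stats::rnorm(n_samples, sd = noise_sd)
  }
  out <- rbind(reg_expr, tgt_expr)
  if (!is.null(baselines)) {
    hit <- intersect(rownames(out), names(baselines))
    out[hit, ] <- out[hit, , drop = FALSE] + baselines[hit]
  }
  as_expression_matrix(out)
}

#' Assemble the diauxic benchmark
#'
#' The complete synthetic study used across the higher-level tests: the
#' diauxic toy model, a hand-crafted two-regulator network over its GPR
#' genes (a glucose-state regulator activating fermentation genes and
#' repressing respiration/ethanol-usage genes, and an ethanol-state
#' regulator doing the reverse), a training expression set drawn from the
#' generative model, the influence matrix and fitted linear model, and a
#' two-sample context ("glucose" and "ethanol") built by clamping the
#' regulator profiles at +/-2 SD.
#'
#' @param seed integer seed.
#' @param n_train training samples (default 100).
#' @param noise_sd generative noise SD (default 0.2).
#' @param baseline_sd SD of the per-gene baseline offsets (default 2;
#'   log-scale expression spans several log units between genes, and this
#'   heterogeneity is what makes raw expression fragile under cross-gene
#'   permutation while regulon-averaged influence degrades gracefully).
#' @return list with elements \code{model}, \code{net}, \code{expr_train},
#'   \code{infl_train}, \code{lin_model}, \code{context} (expression matrix
#'   with samples "glucose" and "ethanol").
#' @export
make_diauxic_benchmark <- function(seed = 1, n_train = 100, noise_sd = 0.2,
                                   baseline_sd = 2) {
  model <- make_toy_model("diauxic")
  # regulons hold the metabolic (GPR) genes plus filler targets: influence
  # is an average over a regulator's whole regulon, and its robustness rests
  # on regulons being much larger than the handful of enzyme genes
  edges <- rbind(
    data.frame(regulator = "R_glc",
               target = c("FERM1", "FERM2", "HXT1", paste0("GFA", 1:8)),
               sign = 1),
    data.frame(regulator = "R_glc",
               target = c("ADH2", "ACS1", "RESP1", paste0("GFR", 1:8)),
               sign = -1),
    data.frame(regulator = "R_eth",
               target = c("ADH2", "ACS1", "RESP1", "RESP2", paste0("EFA", 1:8)),
               sign = 1),
    data.frame(regulator = "R_eth",
               target = c("FERM1", "FERM2", paste0("EFR", 1:8)), sign = -1))
  net <- regulatory_network(edges)
  genes <- sort_c(unique(c(net$regulators, edges$target)))
  set.seed(seed + 2000L)
  baselines <- stats::setNames(stats::rnorm(length(genes), sd = baseline_sd),
                               genes)
  expr_train <- make_expression(net, n_train, noise_sd = noise_sd,
                                regime = "linear_influence", seed = seed,
                                baselines = baselines)
  infl_train <- compute_influence(net, expr_train)
  # log-scale expression has gene-specific baselines, so the linear
  # influence model is fitted with an intercept here
  lin_model <- fit_influence_model(net, infl_train, expr_train,
                                   targets = sort_c(unique(edges$target)),
                                   intercept = TRUE)
  reg_ctx <- matrix(c(2, -2, -2, 2), 2, 2,
                    dimnames = list(c("R_glc", "R_eth"),
                                    c("glucose", "ethanol")))
  context <- make_expression(net, 2, noise_sd = noise_sd,
                             regime = "linear_influence",
                             seed = seed + 1000L,
                             regulator_values = reg_ctx,
                             baselines = baselines)
  list(model = model, net = net, expr_train = expr_train,
       infl_train = infl_train, lin_model = lin_model, context = context)
}
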