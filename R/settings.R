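#' Estimator and pipeline settings
#'
#' Collects the numerical knobs of the Laplace estimator and the default
#' sizes of the downstream pipeline stages. Every value can be overridden;
#' the defaults are the ones used throughout the package documentation.
#'
#' @param method Marginal-likelihood approximation: `"laplace"` (normative)
#'   or `"importance"` (Monte-Carlo cross-check).
#' @param hessian Inner (per-subject) curvature for the Laplace correction:
#'   `"fd"` (default; full second-order Hessian by finite differences of
#'   the analytic inner gradient, i.e. the classical Laplace approximation)
#'   or `"gauss_newton"` (drops the residual-weighted second-derivative
#'   term; faster and exact when the model is log-linear in the random
#'   effects, but its parameter-dependent approximation error biases the
#'   variance estimates of strongly nonlinear random effects, so it is not
#'   used for final estimation). The mode search itself always uses
#'   Gauss-Newton steps.
#' @param inner_tol Convergence tolerance of the per-subject empirical
#'   Bayes optimisation.
#' @param outer_tol Relative convergence tolerance of the population-level
#'   optimisation.
#' @param outer_iter_max Iteration cap for the population optimiser (per
#'   epoch).
#' @param max_epochs Maximum optimisation epochs; within an epoch the
#'   per-subject inner starting values are frozen so the objective is
#'   deterministic, and they are refreshed at the incumbent optimum between
#'   epochs.
#' @param epoch_tol OFV change between epochs below which the fit is
#'   declared stable.
#' @param is_draws Monte-Carlo draws per subject for `method =
#'   "importance"`.
#' @param refine `"importance"` appends an importance-sampling refinement
#'   stage to [scr_fit]: a fixed mixture-of-Gaussians proposal is built on
#'   the per-subject Laplace modes (two components where the posterior is
#'   bimodal), and the common-random-numbers IS objective is optimised
#'   from the Laplace solution. This follows the estimator used in the
#'   original analysis and removes the residual single-mode expansion
#'   bias; `"none"` (default) stops at the Laplace solution.
#' @param refine_draws Draws per subject for the refinement stage.
#' @param refine_rounds Maximum proposal re-adaptation rounds of the
#'   refinement stage (each round rebuilds the proposal at the incumbent
#'   optimum and re-optimises; stops early once the parameters stop
#'   moving).
#' @param is_seed Fixed seed for the refinement draws (local; the caller's
#'   RNG state is untouched).
#' @param is_inflation Variance inflation of the proposal components.
#' @param linear_fast_path Use the closed-form marginal likelihood when the
#'   only random effect is on `ksyn_gfr0` (the model is then exactly
#'   log-linear; the result equals the Laplace value).
#' @param theta_bounds,omega2_bounds,sigma2_bounds Box bounds (natural
#'   scale) enforced during estimation.
#' @param gamma_max Upper bound for the Hill coefficient typical value; the
#'   likelihood flattens for very steep maturation curves.
#' @param trace Print per-epoch progress messages during fitting.
#' @param fix_omega2 Character vector of parameter names whose
#'   between-subject variance is held at its starting value during
#'   estimation (used for staged fitting from distant starts).
#' @param nested_tol Tolerance for a negative likelihood-ratio statistic
#'   before it is treated as a nested-fit violation ([lrt]).
#' @param sim_n,sim_grid_by Cohort-simulation defaults (700 subjects,
#'   0.1-day grid).
#' @param vpc_reps Visual-predictive-check replicates (500).
#' @param alpha_in,alpha_out Forward-inclusion / backward-elimination
#'   significance levels (0.001 / 0.0001).
#' @param r2_threshold Covariate screening threshold on r^2 (0.1).
#' @return A list of class `"scr_settings"`.
#' @export
scr_settings <- function(method = c("laplace", "importance"),
                         hessian = c("fd", "gauss_newton"),
                         inner_tol = 1e-8,
                         outer_tol = 1e-6,
                         outer_iter_max = 500,
                         max_epochs = 12,
                         epoch_tol = 0.01,
                         is_draws = 1000,
                         refine = c("none", "importance"),
                         refine_draws = 300,
                         refine_rounds = 4,
                         is_seed = 1357,
                         is_inflation = 1.5,
                         linear_fast_path = TRUE,
                         theta_bounds = c(1e-4, 1e4),
                         omega2_bounds = c(1e-6, 4),
                         sigma2_bounds = c(1e-8, 4),
                         gamma_max = 100,
                         fix_omega2 = character(0),
                         trace = FALSE,
                         nested_tol = 0.01,
                         sim_n = 700, sim_grid_by = 0.1,
                         vpc_reps = 500,
                         alpha_in = 0.001, alpha_out = 0.0001,
                         r2_threshold = 0.1) {
  structure(list(method = match.arg(method), hessian = match.arg(hessian),
                 inner_tol = inner_tol, outer_tol = outer_tol,
                 outer_iter_max = outer_iter_max,
                 max_epochs = max_epochs, epoch_tol = epoch_tol,
                 is_draws = is_draws,
                 refine = match.arg(refine),
                 refine_draws = refine_draws,
                 refine_rounds = refine_rounds,
                 is_seed = is_seed, is_inflation = is_inflation,
                 linear_fast_path = linear_fast_path,
                 theta_bounds = theta_bounds, omega2_bounds = omega2_bounds,
                 sigma2_bounds = sigma2_bounds, gamma_max = gamma_max,
                 fix_omega2 = fix_omega2, trace = trace,
                 nested_tol = nested_tol, sim_n = sim_n,
                 sim_grid_by = sim_grid_by, vpc_reps = vpc_reps,
                 alpha_in = alpha_in, alpha_out = alpha_out,
                 r2_threshold = r2_threshold),
            class = "scr_settings")
}
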