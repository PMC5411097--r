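#' Reference single-spacer scenario
#'
#' The standard coexistence/oscillation setup used throughout the package:
#' a small all-wild-type inoculum (`n(0) = 1000`) meets a larger phage
#' population (`v(0) = 1e4`) at carrying capacity `K = 1e5`, with burst size
#' `b = 100`, acquisition probability `alpha = 1e-4`, and (in units of the
#' wild-type growth rate) adsorption `g = 1e-5`, lysis `mu = 1`, spacer loss
#' `kappa = 2e-3`. The spacer failure probability and the growth-rate ratio
#' are left configurable; the default `eta = 0.005` sits well inside the
#' coexistence phase.
#'
#' @param eta Spacer failure probability.
#' @param r Growth-rate ratio `f1/f0`.
#' @param ... Overrides for any other [single_spacer_params()] argument
#'   (e.g. `kappa = 0`, `b = 50`).
#' @param t_max,n_outputs Simulation window forwarded to [sim_config()].
#' @return An object of class `crisprdyn_scenario`: list with `name`,
#'   `params`, `initial_state`, `config`, and `expectation` (the regime
#'   predicted by [classify_regime()]).
#' @seealso [multi_spacer_scenario()], [unused_capacity_sweep()],
#'   [run_scenario()]
#' @examples
#' sc <- single_spacer_scenario()
#' sc$expectation$regime
#' @export
single_spacer_scenario <- function(eta = 0.005, r = 1, ..., t_max = 1e4,
                                   n_outputs = 400L) {
  base <- list(f0 = 1, r = r, K = 1e5, kappa = 2e-3, g = 1e-5, eta = eta,
               alpha = 1e-4, mu = 1, b = 100)
  over <- list(...)
  bad <- setdiff(names(over), c(names(base), "dilution", "phage_decay"))
  if (length(bad))
    stop("unknown parameter override(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  base[names(over)] <- over
  params <- do.call(single_spacer_params, base)
  structure(list(name = "single-spacer-reference",
                 params = params,
                 initial_state = single_state(n0 = 1000, v = 1e4),
                 config = sim_config(t_max = t_max, n_outputs = n_outputs),
                 expectation = list(regime = classify_regime(params))),
            class = "crisprdyn_scenario")
}

#' Scenario family for the unused-capacity curve
#'
#' Generates the single-spacer parameter grid along which the unused
#' capacity `F` is studied as a function of `eta * b`: burst size `b = 100`,
#' equal growth rates (`r = 1`), spacer loss rate `kappa = 1e-2` (units of
#' `f0`), crossed over a grid of `eta * b` values in `[0, 1)` and a set of
#' acquisition probabilities. For grid points below the critical failure
#' probability the analytic `F` is finite and increases with `eta`,
#' diverging as `eta * b` approaches 1; at fixed `eta` it decreases linearly
#' with `alpha`.
#'
#' @param eta_b_grid Grid of `eta * b` products in `[0, 1)`.
#' @param alpha_values Acquisition probabilities to cross with the grid.
#' @return A list of `crisprdyn_scenario` objects (one per grid point), each
#'   carrying the scenario's analytic expectation where it exists.
#' @examples
#' specs <- unused_capacity_sweep(eta_b_grid = c(0, 0.5),
#'                                alpha_values = c(0, 1e-2))
#' length(specs)
#' @export
unused_capacity_sweep <- function(eta_b_grid = seq(0, 0.95, by = 0.05),
                                  alpha_values = c(0, 1e-4, 1e-2)) {
  if (any(eta_b_grid < 0 | eta_b_grid >= 1))
    stop("eta_b_grid values must lie in [0, 1)", call. = FALSE)
  b <- 100
  grid <- expand.grid(eta_b = eta_b_grid, alpha = alpha_values,
                      KEEP.OUT.ATTRS = FALSE)
  lapply(seq_len(nrow(grid)), function(i) {
    eta <- grid$eta_b[i] / b
    alpha <- grid$alpha[i]
    params <- single_spacer_params(f0 = 1, r = 1, K = 1e5, kappa = 1e-2,
                                   g = 1e-5, eta = eta, alpha = alpha,
                                   mu = 1, b = b)
    regime <- classify_regime(params)
    F_analytic <- if (regime == "coexistence")
      unused_capacity_single(params) else NA_real_
    # mixed inoculum: with alpha = 0 immunity cannot be acquired de novo,
    # so the sweep starts from a population that already carries the spacer
    structure(list(name = sprintf("capacity-sweep-etab%g-alpha%g",
                                  grid$eta_b[i], alpha),
                   params = params,
                   initial_state = single_state(n0 = 900, n1 = 100, v = 1e4),
                   config = sim_config(),
                   expectation = list(regime = regime, F = F_analytic)),
              class = "crisprdyn_scenario")
  })
}

#' Reference N-spacer scenarios
#'
#' Generates the multi-spacer regimes used to study spacer diversity:
#' `N = 20` spacer types by default, burst size `b = 100`, capacity
#' `K = 1e5`, and (in units of the common growth rate) lysis `mu = 1`,
#' adsorption `g = 1e-4`, spacer loss `kappa = 1e-2`, with overall
#' acquisition probability `sum(alpha_i) = 0.0972`. The per-spacer grids are
#' linear (the reference publications leave them unspecified); failure
#' probabilities span `eta_range`, kept below `1/b` so coexistence stays
#' attainable.
#'
#' Modes:
#' \describe{
#'   \item{`acquisition_varying`}{`alpha_i` on an increasing linear grid
#'     normalized to `alpha_total`; constant `eta_i = eta_const`. Steady-state
#'     abundances are then exactly proportional to `alpha_i`.}
#'   \item{`effectiveness_varying`}{constant `alpha_i = alpha_total / N`;
#'     `eta_i` on an increasing grid. The most effective (lowest-`eta`)
#'     spacer dominates, the more so the smaller `alpha_total`.}
#'   \item{`correlated`}{both grids vary, rank-paired in the same order:
#'     more effective spacers are harder to acquire.}
#'   \item{`anticorrelated`}{rank-paired in opposite order: more effective
#'     spacers are also easier to acquire, skewing the distribution further.}
#'   \item{`constant`}{fully symmetric: `alpha_i = alpha_total / N`,
#'     `eta_i = eta_const`.}
#' }
#'
#' @param mode One of the five modes above.
#' @param N Number of spacer types, >= 2.
#' @param alpha_total Overall acquisition probability `sum(alpha_i)`, in
#'   (0, 1).
#' @param eta_range Length-2 range of the failure-probability grid.
#' @param eta_const Common failure probability for the constant-`eta` modes.
#' @param t_max,n_outputs Simulation window forwarded to [sim_config()].
#' @return A `crisprdyn_scenario` (see [single_spacer_scenario()]).
#' @examples
#' sc <- multi_spacer_scenario("effectiveness_varying")
#' sum(sc$params$alpha_vec)
#' @export
multi_spacer_scenario <- function(mode = c("acquisition_varying",
                                           "effectiveness_varying",
                                           "correlated", "anticorrelated",
                                           "constant"),
                                  N = 20L, alpha_total = 0.0972,
                                  eta_range = c(5e-4, 9.5e-3),
                                  eta_const = 0.005,
                                  t_max = 2e4, n_outputs = 400L) {
  mode <- match.arg(mode)
  N <- as.integer(N)
  if (N < 2L) stop("N must be at least 2", call. = FALSE)
  if (alpha_total <= 0 || alpha_total >= 1)
    stop("alpha_total must lie in (0, 1)", call. = FALSE)
  eta_grid <- seq(eta_range[1L], eta_range[2L], length.out = N)
  alpha_ramp <- seq_len(N) / sum(seq_len(N)) * alpha_total
  alpha_flat <- rep(alpha_total / N, N)
  av <- switch(mode,
    acquisition_varying = alpha_ramp,
    effectiveness_varying = alpha_flat,
    correlated = alpha_ramp,          # alpha increases with eta
    anticorrelated = rev(alpha_ramp), # alpha decreases with eta
    constant = alpha_flat)
  ev <- switch(mode,
    acquisition_varying = rep(eta_const, N),
    constant = rep(eta_const, N),
    eta_grid)
  params <- multi_spacer_params(f = 1, K = 1e5, kappa = 1e-2, g = 1e-4,
                                mu = 1, b = 100, alpha_vec = av,
                                eta_vec = ev)
  structure(list(name = paste0("multi-", gsub("_", "-", mode)),
                 params = params,
                 initial_state = multi_state(n0 = 1000, n_vec = numeric(N),
                                             v = 1e4),
                 config = sim_config(t_max = t_max, n_outputs = n_outputs),
                 expectation = list(regime = classify_regime(params),
                                    mode = mode)),
            class = "crisprdyn_scenario")
}

#' @export
print.crisprdyn_scenario <- function(x, ...) {
  cat(sprintf("Scenario '%s'\n", x$name))
  print(x$params)
  cat(sprintf("  initial state: n_total = %g, v = %g\n",
              total_bacteria(x$initial_state),
              x$initial_state[[length(x$initial_state)]]))
  cat(sprintf("  expected regime: %s\n", x$expectation$regime))
  invisible(x)
}

#' Run a scenario end to end
#'
#' Convenience wrapper: integrates the scenario's model from its initial
#' state under its simulation settings.
#'
#' @param scenario A `crisprdyn_scenario`.
#' @param config Optional [sim_config()] override.
#' @return A `crisprdyn_trajectory`.
#' @export
run_scenario <- function(scenario, config = NULL) {
  stopifnot(inherits(scenario, "crisprdyn_scenario"))
  integrate_model(scenario$params, scenario$initial_state,
                  if (is.null(config)) scenario$config else config)
}
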