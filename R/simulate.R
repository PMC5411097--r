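#' Simulation settings
#'
#' Controls the integration window, output grid and numerical thresholds of
#' [integrate_model()]. Defaults suit the reference parameter regimes, where
#' time is measured in units of the inverse wild-type growth rate: `t_max =
#' 1e4` is long enough for the damped oscillations of the coexistence phase
#' to settle when the spacer loss rate is at least ~1e-3, and the tight
#' solver tolerances are needed because populations traverse many orders of
#' magnitude during near-extinction transients.
#'
#' @param t_max End time of the integration (units of 1/f0), > 0.
#' @param n_outputs Number of points in the output grid.
#' @param rel_tol,abs_tol Relative and absolute solver tolerances.
#' @param steady_tol Relative right-hand-side norm below which the endpoint
#'   counts as a steady state (see [detect_steady_state()]).
#' @param extinction_threshold Population level below which a population
#'   counts as extinct for classification; `NULL` (default) means `1e-6 * K`,
#'   chosen because the deterministic equations never reach exactly zero.
#' @param grid `"log"` (default) for a logarithmically spaced output grid —
#'   the transients span decades in time — or `"linear"`.
#' @return An object of class `sim_config`.
#' @examples
#' sim_config(t_max = 500, n_outputs = 200)
#' @export
sim_config <- function(t_max = 1e4, n_outputs = 400L, rel_tol = 1e-8,
                       abs_tol = 1e-10, steady_tol = 1e-6,
                       extinction_threshold = NULL,
                       grid = c("log", "linear")) {
  grid <- match.arg(grid)
  if (!is.numeric(t_max) || t_max <= 0) stop("t_max must be > 0", call. = FALSE)
  if (rel_tol <= 0 || abs_tol <= 0 || steady_tol <= 0)
    stop("tolerances must be positive", call. = FALSE)
  if (!is.null(extinction_threshold) && extinction_threshold < 0)
    stop("extinction_threshold must be >= 0", call. = FALSE)
  n_outputs <- as.integer(n_outputs)
  if (n_outputs < 10L) stop("n_outputs must be at least 10", call. = FALSE)
  structure(list(t_max = t_max, n_outputs = n_outputs, rel_tol = rel_tol,
                 abs_tol = abs_tol, steady_tol = steady_tol,
                 extinction_threshold = extinction_threshold, grid = grid),
            class = "sim_config")
}

output_times <- function(config) {
  if (config$grid == "linear")
    return(seq(0, config$t_max, length.out = config$n_outputs))
  # log grid spanning six decades up to t_max, with t = 0 prepended
  c(0, 10^seq(log10(config$t_max) - 6, log10(config$t_max),
              length.out = config$n_outputs - 1L))
}

#' Integrate the population dynamics
#'
#' Solves the single- or N-spacer ODE system (chosen by the class of
#' `params`) with the stiff-capable `lsoda` integrator from \pkg{deSolve}.
#' The right-hand sides are evaluated exactly as written, without clamping:
#' the equations preserve the non-negative orthant analytically, and the
#' solver is only allowed excursions below zero of the order of its absolute
#' tolerance (beyond `-100 * abs_tol` the run aborts).
#'
#' @param params A [single_spacer_params()] or [multi_spacer_params()] object.
#' @param initial_state A non-negative state vector of matching layout
#'   ([single_state()] / [multi_state()]).
#' @param config A [sim_config()].
#' @return An object of class `crisprdyn_trajectory`: a list with `times`
#'   (the output grid), `states` (matrix, one row per time point, named
#'   columns), `params`, `config`, `model` (`"single"` or `"multi"`), and
#'   `diagnostics` from the solver.
#' @seealso [classify_outcome()], [transient_summary()],
#'   [detect_steady_state()], [as.data.frame.crisprdyn_trajectory()]
#' @examples
#' sc <- single_spacer_scenario(eta = 0.005)
#' traj <- integrate_model(sc$params, sc$initial_state,
#'                         sim_config(t_max = 100, n_outputs = 50))
#' utils::tail(as.data.frame(traj), 2)
#' @export
integrate_model <- function(params, initial_state, config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  if (any(initial_state < 0))
    stop("initial state must be non-negative", call. = FALSE)
  if (inherits(params, "single_spacer_params")) {
    if (length(initial_state) != 5L)
      stop("single-spacer state must have 5 components", call. = FALSE)
    rhs <- single_rhs
    nms <- c("n0", "n1", "I0", "I1", "v")
    model <- "single"
  } else if (inherits(params, "multi_spacer_params")) {
    if (length(initial_state) != 2L * params$N + 3L)
      stop("state length does not match 2N + 3", call. = FALSE)
    rhs <- multi_rhs
    nms <- multi_state_names(params$N)
    model <- "multi"
  } else stop("unknown parameter class", call. = FALSE)

  y0 <- as.numeric(initial_state)
  names(y0) <- nms
  times <- output_times(config)
  func <- function(t, y, p) list(as.numeric(rhs(y, p)))
  out <- deSolve::ode(y = y0, times = times, func = func, parms = params,
                      method = "lsoda", rtol = config$rel_tol,
                      atol = config$abs_tol, maxsteps = 50000L)
  istate <- attr(out, "istate")
  diag <- list(istate = istate, rstate = attr(out, "rstate"))
  if (nrow(out) < length(times) || (!is.null(istate) && istate[1L] < 0))
    stop("ODE solver failed before t_max; solver istate = ",
         if (is.null(istate)) NA else istate[1L], call. = FALSE)
  states <- unname(out[, -1L, drop = FALSE])
  colnames(states) <- nms
  low <- min(states)
  if (low < -100 * config$abs_tol)
    stop(sprintf(paste0("trajectory left the non-negative orthant (min = ",
                        "%.3g, limit = %.3g); tighten the solver tolerances"),
                 low, -100 * config$abs_tol), call. = FALSE)
  structure(list(times = times, states = states, params = params,
                 config = config, model = model, diagnostics = diag),
            class = "crisprdyn_trajectory")
}

#' @export
print.crisprdyn_trajectory <- function(x, ...) {
  cat(sprintf("CRISPR dynamics trajectory (%s-spacer model)\n", x$model))
  cat(sprintf("  %d time points on [0, %g] (1/f0 units), %s grid\n",
              length(x$times), max(x$times), x$config$grid))
  fin <- x$states[nrow(x$states), ]
  cat(sprintf("  endpoint: n_total = %.6g, v = %.6g\n",
              sum(fin[-length(fin)]), fin[[length(fin)]]))
  invisible(x)
}

#' @describeIn integrate_model Flatten a trajectory to a data frame with
#'   columns `time`, the populations, and `n_total`.
#' @param x A `crisprdyn_trajectory`.
#' @param row.names,optional,... Passed on conventionally (unused).
#' @export
as.data.frame.crisprdyn_trajectory <- function(x, row.names = NULL,
                                               optional = FALSE, ...) {
  df <- data.frame(time = x$times, x$states, check.names = FALSE)
  df$n_total <- rowSums(x$states[, -ncol(x$states), drop = FALSE])
  df
}

# final state of a trajectory, as a named vector
final_state <- function(traj) {
  traj$states[nrow(traj$states), ]
}

#' Detect a settled steady state at the end of a trajectory
#'
#' Declares the trajectory settled when the scaled right-hand-side norm
#' `max|RHS| / (max|state| + 1)` stays below `steady_tol` over the last 5%
#' of the output grid.
#'
#' @param traj A `crisprdyn_trajectory`.
#' @param steady_tol Threshold; defaults to the trajectory's
#'   `config$steady_tol`.
#' @return The final state (named vector) if settled, otherwise `NULL`.
#' @export
detect_steady_state <- function(traj, steady_tol = NULL) {
  stopifnot(inherits(traj, "crisprdyn_trajectory"))
  if (is.null(steady_tol)) steady_tol <- traj$config$steady_tol
  rhs <- if (traj$model == "single") single_rhs else multi_rhs
  n <- nrow(traj$states)
  tail_rows <- seq.int(max(1L, n - ceiling(0.05 * n) + 1L), n)
  for (i in tail_rows) {
    s <- traj$states[i, ]
    r <- max(abs(rhs(s, traj$params))) / (max(abs(s)) + 1)
    if (r >= steady_tol) return(NULL)
  }
  final_state(traj)
}

#' Classify the outcome of a simulated run
#'
#' Maps a trajectory to one of the asymptotic regimes. The deterministic
#' equations never reach zero exactly, so extinction is declared below a
#' configurable threshold (default `1e-6 * K`). Order of checks: total
#' bacteria below threshold is bacterial extinction (the phage then persists
#' with nothing left to adsorb it); otherwise phage below threshold is phage
#' extinction; if both populations persist the run must have settled
#' ([detect_steady_state()]) to be called coexistence — an unsettled
#' transient is refused with an error of class `crisprdyn_undetermined`.
#'
#' @param traj A `crisprdyn_trajectory`.
#' @param extinction_threshold Override for the threshold (counts).
#' @return One of `"coexistence"`, `"phage_extinction"`,
#'   `"bacterial_extinction"`.
#' @seealso [classify_regime()] for the analytic phase boundaries.
#' @export
classify_outcome <- function(traj, extinction_threshold = NULL) {
  stopifnot(inherits(traj, "crisprdyn_trajectory"))
  if (is.null(extinction_threshold))
    extinction_threshold <- traj$config$extinction_threshold
  if (is.null(extinction_threshold))
    extinction_threshold <- 1e-6 * traj$params$K
  fin <- final_state(traj)
  v <- fin[[length(fin)]]
  n_tot <- sum(fin[-length(fin)])
  if (n_tot < extinction_threshold) return("bacterial_extinction")
  if (v < extinction_threshold) return("phage_extinction")
  if (is.null(detect_steady_state(traj)))
    stop(structure(class = c("crisprdyn_undetermined", "error", "condition"),
                   list(message = paste0(
                     "undetermined outcome: both populations persist but ",
                     "the trajectory has not settled by t_max; integrate ",
                     "longer or relax steady_tol"),
                     call = sys.call())))
  "coexistence"
}

#' Transient statistics of a trajectory
#'
#' Summarizes the characteristic early-time behavior: the phage population
#' rises to a peak when the first infected cells burst, then falls as
#' immunity spreads, and — because spacers keep being lost — may oscillate
#' before settling. Local maxima are counted on the raw output grid without
#' smoothing.
#'
#' @param traj A `crisprdyn_trajectory`.
#' @return An object of class `transient_summary`: list with `v_peak`,
#'   `t_peak`, `v_min_post_peak`, `n_bottleneck` (minimum total bacteria),
#'   and `oscillation_count` (strict local maxima of the phage population
#'   after the peak).
#' @examples
#' sc <- single_spacer_scenario(eta = 0.005)
#' traj <- integrate_model(sc$params, sc$initial_state,
#'                         sim_config(t_max = 1000, n_outputs = 300))
#' transient_summary(traj)
#' @export
transient_summary <- function(traj) {
  stopifnot(inherits(traj, "crisprdyn_trajectory"))
  v <- traj$states[, ncol(traj$states)]
  n_tot <- rowSums(traj$states[, -ncol(traj$states), drop = FALSE])
  ipk <- which.max(v)
  post <- v[ipk:length(v)]
  osc <- 0L
  if (length(v) >= 3L) {
    i <- 2:(length(v) - 1L)
    loc_max <- i[v[i] > v[i - 1L] & v[i] > v[i + 1L]]
    osc <- sum(loc_max > ipk)
  }
  structure(list(v_peak = v[[ipk]], t_peak = traj$times[[ipk]],
                 v_min_post_peak = min(post), n_bottleneck = min(n_tot),
                 oscillation_count = as.integer(osc)),
            class = "transient_summary")
}

#' @export
print.transient_summary <- function(x, ...) {
  cat("Transient summary\n")
  cat(sprintf("  phage peak: v = %.6g at t = %.4g\n", x$v_peak, x$t_peak))
  cat(sprintf("  post-peak phage minimum: %.6g\n", x$v_min_post_peak))
  cat(sprintf("  bacterial bottleneck: n = %.6g\n", x$n_bottleneck))
  cat(sprintf("  phage oscillations after the peak: %d\n",
              x$oscillation_count))
  invisible(x)
}

#' Write a trajectory to CSV
#'
#' One row per output time with columns `time`, `n0`, `n_1..n_N` (or `n1`
#' for the single-spacer model, written as `n_1`), `I0`, `I_1..I_N`, `v`,
#' `n_total`.
#'
#' @param traj A `crisprdyn_trajectory`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_trajectory_csv <- function(traj, path) {
  df <- as.data.frame(traj)
  if (traj$model == "single")
    names(df) <- c("time", "n0", "n_1", "I0", "I_1", "v", "n_total")
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Write a run summary to JSON
#'
#' Combines the outcome classification, the transient statistics and (when
#' reached) the steady state into one JSON document.
#'
#' @param traj A `crisprdyn_trajectory`.
#' @param path Output file path; if `NULL` the JSON string is returned.
#' @return The path (invisibly) or a JSON string.
#' @export
write_summary_json <- function(traj, path = NULL) {
  outcome <- tryCatch(classify_outcome(traj),
                      crisprdyn_undetermined = function(e) "undetermined")
  ts <- transient_summary(traj)
  ss <- detect_steady_state(traj)
  x <- list(outcome = outcome, v_peak = ts$v_peak, t_peak = ts$t_peak,
            v_min_post_peak = ts$v_min_post_peak,
            n_bottleneck = ts$n_bottleneck,
            oscillation_count = ts$oscillation_count,
            steady_state = if (is.null(ss)) NULL else as.list(ss))
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
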