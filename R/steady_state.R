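#' Fraction of unused carrying capacity at coexistence (single spacer)
#'
#' In the coexistence phase (spacer loss `kappa > 0`, failure probability
#' below the critical value) the bacterial population settles below
#' capacity, `n = K (1 - F)`. With equal growth rates (`r = 1`) the unused
#' fraction is
#' \deqn{F = \frac{\kappa}{f_0}\,\frac{b(1-\alpha) - 1}{(b-1)(1 - b\eta)}.}
#' `F` grows linearly with the spacer loss rate, decreases linearly with the
#' acquisition probability, and diverges as `eta` approaches `1/b`, where
#' CRISPR immunity stops being able to control the phage. Callers must check
#' `F < 1` for a physical coexistence state.
#'
#' @param params A [single_spacer_params()] object with `r = 1` and
#'   `eta < 1/b`.
#' @return The unused capacity fraction `F` (dimensionless).
#' @seealso [critical_failure_probability()], [spacer_ratio_single()],
#'   [unused_capacity_multi()], [steady_state_numeric()] for `r != 1`.
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' unused_capacity_single(p)  # ~0.02: population 2% below capacity
#' @export
unused_capacity_single <- function(params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (params$r != 1)
    stop("the closed form for F holds only for equal growth rates (r = 1); ",
         "use steady_state_numeric() for r != 1", call. = FALSE)
  if (1 - params$b * params$eta <= 0)
    stop("1 - b*eta <= 0: CRISPR immunity cannot control the phage and the ",
         "coexistence formula is invalid", call. = FALSE)
  with(params, (kappa / f0) * (b * (1 - alpha) - 1) /
         ((b - 1) * (1 - b * eta)))
}

#' Critical spacer failure probability
#'
#' Coexistence requires the spacer failure probability to stay below
#' \deqn{\eta_c = \frac{1}{b}\left(1 - \frac{\kappa}{f_0}\,
#'   \frac{b(1-\alpha)-1}{b-1}\right),}
#' the value at which the unused capacity `F` reaches 1 and the bacterial
#' population is driven to zero. This is the equal-growth-rate form; the
#' correction for `r != 1` is of order `(r-1)/b^2` and is not included (for
#' `r != 1` locate the boundary numerically via [steady_state_numeric()]).
#' Without spacer loss (`kappa = 0`) it reduces to `1/b`, the point where
#' one failed defense per burst breaks even.
#'
#' @param params A [single_spacer_params()] object with `b > 1`.
#' @return The critical failure probability (dimensionless).
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-5,
#'                           eta = 0, alpha = 0, b = 100)
#' critical_failure_probability(p)  # 0.0099, just below 1/b
#' @export
critical_failure_probability <- function(params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (params$b <= 1)
    stop("the critical failure probability requires burst size b > 1",
         call. = FALSE)
  with(params,
       (1 / b) * (1 - (kappa / f0) * (b * (1 - alpha) - 1) / (b - 1)))
}

#' Steady-state ratio of spacer-enhanced to wild-type bacteria
#'
#' At coexistence the healthy populations satisfy
#' \deqn{\frac{n_1}{n_0} = \frac{b(1-\alpha) - 1}{1 - b\eta},}
#' independently of the growth rates of the two types. Measuring this ratio
#' (with acquisition disabled, `alpha = 0`) therefore gives a direct handle
#' on the spacer's failure probability once the burst size is known.
#'
#' @param params A [single_spacer_params()] object with `1 - b*eta > 0`.
#' @return The ratio `n1/n0` (dimensionless).
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' spacer_ratio_single(p)  # 197.98
#' @export
spacer_ratio_single <- function(params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (1 - params$b * params$eta <= 0)
    stop("1 - b*eta <= 0: no coexistence steady state exists", call. = FALSE)
  with(params, (b * (1 - alpha) - 1) / (1 - b * eta))
}

#' Mean spacer failure probability of a population
#'
#' The abundance-weighted mean failure probability
#' \deqn{\bar\eta = \frac{\sum_i \eta_i n_i}{\sum_i n_i}}
#' over the healthy spacer-enhanced compartments. It always lies between the
#' smallest and largest `eta_i`.
#'
#' @param n_vec Non-negative abundances per spacer type (positive sum).
#' @param eta_vec Failure probabilities per spacer type, same length.
#' @return The weighted mean failure probability.
#' @examples
#' mean_failure_probability(c(1, 3), c(0, 0.01))  # 0.0075
#' @export
mean_failure_probability <- function(n_vec, eta_vec) {
  if (length(n_vec) != length(eta_vec))
    stop("n_vec and eta_vec must have the same length", call. = FALSE)
  if (any(n_vec < 0))
    stop("abundances must be non-negative", call. = FALSE)
  s <- sum(n_vec)
  if (s <= 0)
    stop("mean failure probability is undefined for an all-zero population",
         call. = FALSE)
  sum(eta_vec * n_vec) / s
}

#' Fraction of unused capacity at coexistence (N spacers)
#'
#' The multi-spacer analogue of [unused_capacity_single()], written in terms
#' of the mean failure probability of the standing spacer distribution:
#' \deqn{F = \frac{\kappa}{f}\,\frac{b(1-\alpha) - 1}{(1 - b\bar\eta)(b-1)},
#'   \qquad \alpha = \sum_i \alpha_i.}
#' Because `eta_bar` itself depends on the steady-state distribution this is
#' an implicit characterization; [solve_coexistence_multi()] closes it.
#'
#' @param eta_bar Mean failure probability (with `1 - b*eta_bar > 0`).
#' @param params A [multi_spacer_params()] object.
#' @return The unused capacity fraction `F`.
#' @export
unused_capacity_multi <- function(eta_bar, params) {
  stopifnot(inherits(params, "multi_spacer_params"))
  if (1 - params$b * eta_bar <= 0)
    stop("1 - b*eta_bar <= 0: CRISPR immunity cannot control the phage and ",
         "the coexistence formula is invalid", call. = FALSE)
  alpha <- sum(params$alpha_vec)
  with(params, (kappa / f) * (b * (1 - alpha) - 1) /
         ((1 - b * eta_bar) * (b - 1)))
}

# Per-spacer abundance ratios n_i/n0 at the coexistence point, given eta_bar.
# Returns NULL when any denominator kappa - f*F*(1 - eta_i*b) is <= 0 (the
# analytic branch breaks down: the best spacer's population would diverge).
coexistence_ratios <- function(eta_bar, params) {
  F <- unused_capacity_multi(eta_bar, params)
  denom <- params$kappa - params$f * F * (1 - params$eta_vec * params$b)
  if (any(denom <= 0)) return(NULL)
  list(F = F, rho = params$alpha_vec * params$b * params$f * F / denom,
       denom = denom)
}

#' Analytic coexistence steady state of the N-spacer model
#'
#' Solves the implicit steady-state equations of the multi-spacer model. At
#' coexistence the phage pressure satisfies `g v = b f F`, the per-spacer
#' abundances obey
#' \deqn{\frac{n_i}{n_0} = \frac{\alpha_i\, b f F}
#'   {\kappa - f F (1 - \eta_i b)},}
#' and `F` is tied to the mean failure probability `eta_bar` of the very
#' distribution these ratios define (see [unused_capacity_multi()]). The
#' function finds the self-consistent `eta_bar` by a bracketed root search
#' on `[min(eta_i), max(eta_i)]` (restricted to the subinterval where all
#' abundance denominators are positive), then assembles the full state: the
#' absolute scale comes from `n_total = K (1 - F)`, and the infected
#' compartments from stationarity, `I0 = g v n0 / mu` and
#' `I_i = eta_i g v n_i / mu`.
#'
#' Spacer loss is essential: with `kappa = 0` no coexistence state exists
#' (the function errors). If the solved point violates positivity (`F >= 1`
#' or a non-positive abundance denominator) the solution is returned with
#' `valid = FALSE` rather than as an error.
#'
#' @param params A [multi_spacer_params()] object with `kappa > 0` and at
#'   least one positive `alpha_i`.
#' @param tol Root-finding tolerance on `eta_bar` (default 1e-15, i.e.
#'   essentially machine precision; the self-consistency residual of the
#'   returned solution is at the 1e-12 level or better).
#' @param scan_points Number of points in the sign scan used to detect
#'   multiple roots of the self-consistency residual (a warning is issued if
#'   more than one sign change is found).
#' @return An object of class `coexistence_solution`: a list with elements
#'   `F`, `eta_bar`, `v_star`, `n0_star`, `n_vec_star`, `I0_star`,
#'   `I_vec_star`, `n_total`, `valid`, and `residual_norm` (the maximum
#'   absolute component of [multi_rhs()] at the assembled state).
#' @seealso [spacer_fractions()], [steady_state_numeric()]
#' @examples
#' p <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
#'                          alpha_vec = rep(0.0972 / 20, 20),
#'                          eta_vec = seq(5e-4, 9.5e-3, length.out = 20))
#' sol <- solve_coexistence_multi(p)
#' sol$eta_bar
#' sol$n_total / p$K  # = 1 - F
#' @export
solve_coexistence_multi <- function(params, tol = 1e-15, scan_points = 100) {
  stopifnot(inherits(params, "multi_spacer_params"))
  if (params$kappa <= 0)
    stop("coexistence requires spacer loss (kappa > 0): without it the ",
         "wild type is not replenished and no mixed steady state exists",
         call. = FALSE)
  if (all(params$alpha_vec == 0))
    stop("at least one spacer must be acquirable (alpha_i > 0)",
         call. = FALSE)
  b <- params$b
  eta <- params$eta_vec
  invalid <- function(eta_bar = NA_real_, F = NA_real_) {
    structure(list(F = F, eta_bar = eta_bar, v_star = NA_real_,
                   n0_star = NA_real_, n_vec_star = rep(NA_real_, params$N),
                   I0_star = NA_real_, I_vec_star = rep(NA_real_, params$N),
                   n_total = NA_real_, valid = FALSE,
                   residual_norm = NA_real_),
              class = "coexistence_solution")
  }
  if (b * (1 - sum(params$alpha_vec)) - 1 <= 0)
    return(invalid())  # phage cannot sustain itself: F would be <= 0

  lo <- min(eta[params$alpha_vec > 0])
  hi0 <- min(max(eta[params$alpha_vec > 0]), (1 - 1e-12) / b)
  if (1 - b * lo <= 0) return(invalid())

  resid <- function(eta_bar) {
    cr <- coexistence_ratios(eta_bar, params)
    if (is.null(cr)) return(NA_real_)
    eta_bar - sum(eta * cr$rho) / sum(cr$rho)
  }

  r_lo <- resid(lo)
  if (is.na(r_lo)) return(invalid())  # ratios diverge already at min(eta)

  if (diff(range(eta)) == 0 || hi0 <= lo) {
    # all spacers identical in failure probability: eta_bar is known exactly
    eta_star <- lo
  } else if (r_lo == 0) {
    eta_star <- lo
  } else {
    # The mean failure probability is a continuous function of eta_bar on
    # the interval between min(eta) and the first pole of the abundance
    # denominators (F increases with eta_bar, so denominators shrink
    # monotonically). The residual is <= 0 at min(eta) and -> +(pole - lo)
    # as the most effective spacer's denominator vanishes, so a root is
    # bracketed; locate the pole by bisection on validity first.
    hi <- hi0
    if (is.na(resid(hi))) {
      a <- lo; bnd <- hi0
      for (k in seq_len(80L)) {
        mid <- (a + bnd) / 2
        if (is.na(resid(mid))) bnd <- mid else a <- mid
      }
      hi <- a
    }
    r_hi <- resid(hi)
    if (is.na(r_hi) || r_hi < 0) return(invalid())
    grid <- seq(lo, hi, length.out = scan_points)
    rv <- vapply(grid, resid, numeric(1))
    sgn <- sign(rv[!is.na(rv)])
    if (sum(diff(sgn[sgn != 0]) != 0) > 1L)
      warning("multiple self-consistent eta_bar candidates detected; ",
              "returning the smallest", call. = FALSE)
    eta_star <- stats::uniroot(resid, c(lo, hi), tol = tol)$root
  }

  cr <- coexistence_ratios(eta_star, params)
  if (is.null(cr) || cr$F >= 1 || cr$F <= 0)
    return(invalid(eta_star, if (is.null(cr)) NA_real_ else cr$F))
  F <- cr$F
  rho <- cr$rho
  v_star <- b * params$f * F / params$g
  gv <- params$g * v_star  # = b f F
  # n_total = n0 * (1 + gv/mu + sum(rho_i (1 + eta_i gv/mu))) = K (1 - F)
  scale <- 1 + gv / params$mu + sum(rho * (1 + eta * gv / params$mu))
  n0 <- params$K * (1 - F) / scale
  n_vec <- rho * n0
  I0 <- gv * n0 / params$mu
  I_vec <- eta * gv * n_vec / params$mu
  state <- multi_state(n0 = n0, n_vec = n_vec, I0 = I0, I_vec = I_vec,
                       v = v_star)
  res <- max(abs(multi_rhs(state, params)))
  structure(list(F = F, eta_bar = eta_star, v_star = v_star, n0_star = n0,
                 n_vec_star = n_vec, I0_star = I0, I_vec_star = I_vec,
                 n_total = n0 + sum(n_vec) + I0 + sum(I_vec),
                 valid = TRUE, residual_norm = res),
            class = "coexistence_solution")
}

#' @export
print.coexistence_solution <- function(x, ...) {
  cat("Multi-spacer coexistence steady state\n")
  if (!x$valid) {
    cat("  INVALID: no physical coexistence solution for these parameters\n")
    if (is.finite(x$eta_bar))
      cat(sprintf("  (candidate eta_bar = %g, F = %g)\n", x$eta_bar, x$F))
    return(invisible(x))
  }
  cat(sprintf("  unused capacity F = %.6g  (n_total = %.6g = K(1-F))\n",
              x$F, x$n_total))
  cat(sprintf("  mean failure probability eta_bar = %.6g\n", x$eta_bar))
  cat(sprintf("  phage v* = %.6g, wild type n0* = %.6g\n",
              x$v_star, x$n0_star))
  cat(sprintf("  RHS residual at assembled state: %.3g\n", x$residual_norm))
  invisible(x)
}

#' Convert a coexistence solution to its full state vector
#'
#' @param solution A valid `coexistence_solution` from
#'   [solve_coexistence_multi()].
#' @return A [multi_state()] vector.
#' @export
coexistence_state <- function(solution) {
  stopifnot(inherits(solution, "coexistence_solution"))
  if (!isTRUE(solution$valid))
    stop("cannot assemble a state from an invalid coexistence solution",
         call. = FALSE)
  multi_state(n0 = solution$n0_star, n_vec = solution$n_vec_star,
              I0 = solution$I0_star, I_vec = solution$I_vec_star,
              v = solution$v_star)
}

#' Analytic coexistence steady state of the single-spacer model
#'
#' Assembles the full five-component coexistence fixed point for equal
#' growth rates (`r = 1`): unused capacity from
#' [unused_capacity_single()], the spacer/wild-type ratio from
#' [spacer_ratio_single()], phage pressure `g v = b f0 F`, infected
#' compartments from stationarity, and absolute scale from
#' `n_total = K (1 - F)`. Unlike the N-spacer solve this is regular at
#' `alpha = 0` (the acquisition terms cancel from the closed forms).
#' Returns `valid = FALSE` when the coexistence conditions fail
#' (`kappa = 0`, `F >= 1`, or `b * eta >= 1`).
#'
#' @param params A [single_spacer_params()] object with `r = 1`.
#' @return A `coexistence_solution` (length-1 spacer vectors); see
#'   [solve_coexistence_multi()].
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' solve_coexistence_single(p)
#' @export
solve_coexistence_single <- function(params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (params$r != 1)
    stop("the closed-form steady state holds only for equal growth rates ",
         "(r = 1); use steady_state_numeric() for r != 1", call. = FALSE)
  invalid <- structure(
    list(F = NA_real_, eta_bar = params$eta, v_star = NA_real_,
         n0_star = NA_real_, n_vec_star = NA_real_, I0_star = NA_real_,
         I_vec_star = NA_real_, n_total = NA_real_, valid = FALSE,
         residual_norm = NA_real_),
    class = "coexistence_solution")
  if (params$kappa <= 0 || 1 - params$b * params$eta <= 0) return(invalid)
  F <- unused_capacity_single(params)
  rho <- spacer_ratio_single(params)
  if (F >= 1 || F <= 0 || rho <= 0) return(invalid)
  gv <- params$b * params$f0 * F
  v_star <- gv / params$g
  scale <- 1 + gv / params$mu + rho * (1 + params$eta * gv / params$mu)
  n0 <- params$K * (1 - F) / scale
  n1 <- rho * n0
  I0 <- gv * n0 / params$mu
  I1 <- params$eta * gv * n1 / params$mu
  st <- single_state(n0 = n0, n1 = n1, I0 = I0, I1 = I1, v = v_star)
  structure(list(F = F, eta_bar = params$eta, v_star = v_star, n0_star = n0,
                 n_vec_star = n1, I0_star = I0, I_vec_star = I1,
                 n_total = n0 + n1 + I0 + I1, valid = TRUE,
                 residual_norm = max(abs(single_rhs(st, params)))),
            class = "coexistence_solution")
}

#' Numeric steady state by damped Newton iteration
#'
#' Finds a root of the full right-hand side ([single_rhs()] or
#' [multi_rhs()], chosen by the class of `params`) starting from a guess,
#' using Newton's method with a numerically differenced Jacobian, backtracking
#' line search on the residual norm, and Levenberg-style regularization when
#' the Jacobian is near singular. Serves as an independent check on the
#' analytic coexistence formulas and as the only available steady-state
#' solver when their assumptions (equal growth rates) do not hold.
#'
#' @param params A [single_spacer_params()] or [multi_spacer_params()] object.
#' @param guess_state Non-negative starting state of matching length (a
#'   long-time integration endpoint or an analytic assembly works well).
#' @param tol Convergence threshold on `max|RHS| / (max|state| + 1)`.
#' @param max_iter Maximum Newton iterations.
#' @return The state vector at the root (same layout as the guess).
#' @seealso [solve_coexistence_multi()], [detect_steady_state()]
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' guess <- single_state(n0 = 500, n1 = 9e4, I0 = 100, I1 = 100, v = 2e5)
#' steady_state_numeric(p, guess)
#' @export
steady_state_numeric <- function(params, guess_state, tol = 1e-10,
                                 max_iter = 200L) {
  rhs <- if (inherits(params, "single_spacer_params")) single_rhs
         else if (inherits(params, "multi_spacer_params")) multi_rhs
         else stop("unknown parameter class", call. = FALSE)
  x <- as.numeric(guess_state)
  nms <- names(guess_state)
  if (any(x < 0)) stop("guess state must be non-negative", call. = FALSE)
  m <- length(x)
  fx <- as.numeric(rhs(x, params))
  rnorm0 <- function(x, fx) max(abs(fx)) / (max(abs(x)) + 1)
  for (it in seq_len(max_iter)) {
    if (rnorm0(x, fx) < tol) {
      names(x) <- nms
      return(x)
    }
    # forward-difference Jacobian with state-scaled steps
    J <- matrix(0, m, m)
    h <- pmax(abs(x), 1) * sqrt(.Machine$double.eps)
    for (j in seq_len(m)) {
      xp <- x; xp[j] <- xp[j] + h[j]
      J[, j] <- (as.numeric(rhs(xp, params)) - fx) / h[j]
    }
    step <- tryCatch(solve(J, -fx), error = function(e) NULL)
    lambda <- 1e-8 * max(abs(J))
    while (is.null(step)) {
      step <- tryCatch(solve(J + lambda * diag(m), -fx),
                       error = function(e) NULL)
      lambda <- lambda * 10
      if (lambda > 1e12 * max(abs(J)))
        stop("singular Jacobian in steady_state_numeric", call. = FALSE)
    }
    # backtracking line search on the residual norm
    t_ls <- 1
    f0n <- max(abs(fx))
    repeat {
      xn <- x + t_ls * step
      fn <- tryCatch(as.numeric(rhs(xn, params)), error = function(e) NULL)
      if (!is.null(fn) && all(is.finite(fn)) && max(abs(fn)) < f0n) break
      t_ls <- t_ls / 2
      if (t_ls < 1e-12) {
        xn <- x + step  # accept the full step as a last resort
        fn <- as.numeric(rhs(xn, params))
        break
      }
    }
    x <- xn
    fx <- fn
  }
  if (rnorm0(x, fx) < tol) {
    names(x) <- nms
    return(x)
  }
  stop(sprintf(paste0("steady_state_numeric did not converge in %d ",
                      "iterations (relative residual %.3g, tolerance %.3g)"),
               max_iter, rnorm0(x, fx), tol), call. = FALSE)
}

#' Classify the asymptotic regime from parameters alone
#'
#' Applies the analytic phase boundaries. For the single-spacer model:
#' with spacer loss (`kappa > 0`) and failure probability below the critical
#' value ([critical_failure_probability()]) bacteria and phage coexist;
#' without spacer loss (`kappa = 0`) an effective spacer (`eta < 1/b`)
#' drives the phage extinct and bacteria reach capacity; in all remaining
#' cases (including the boundaries themselves, where the coexistence
#' formulas diverge) the phage overwhelms the bacteria. For the multi-spacer
#' model the boundaries are evaluated conservatively: with `kappa > 0` the
#' label is `"coexistence"` exactly when [solve_coexistence_multi()] returns
#' a valid positive solution; with `kappa = 0` the phage is driven extinct
#' when some acquirable spacer (`alpha_i > 0`) has `eta_i < 1/b`.
#'
#' @param params A [single_spacer_params()] or [multi_spacer_params()]
#'   object.
#' @return One of `"coexistence"`, `"phage_extinction"`,
#'   `"bacterial_extinction"`.
#' @seealso [classify_outcome()] for trajectory-based classification.
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 2e-3, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' classify_regime(p)
#' @export
classify_regime <- function(params) {
  UseMethod("classify_regime")
}

#' @export
classify_regime.single_spacer_params <- function(params) {
  b <- params$b
  if (params$kappa > 0) {
    eta_c <- critical_failure_probability(params)
    if (params$eta < eta_c) return("coexistence")
    return("bacterial_extinction")
  }
  if (params$eta < 1 / b) return("phage_extinction")
  "bacterial_extinction"
}

#' @export
classify_regime.multi_spacer_params <- function(params) {
  if (params$kappa > 0) {
    sol <- tryCatch(solve_coexistence_multi(params),
                    error = function(e) NULL)
    if (!is.null(sol) && isTRUE(sol$valid)) return("coexistence")
    return("bacterial_extinction")
  }
  acquirable <- params$alpha_vec > 0
  if (any(acquirable) && min(params$eta_vec[acquirable]) < 1 / params$b)
    return("phage_extinction")
  "bacterial_extinction"
}

#' Serialize a coexistence solution to JSON
#'
#' @param solution A `coexistence_solution`.
#' @param path Output file path; if `NULL`, the JSON string is returned.
#' @return The file path (invisibly) or a JSON string.
#' @export
write_coexistence_json <- function(solution, path = NULL) {
  stopifnot(inherits(solution, "coexistence_solution"))
  x <- unclass(solution)
  json <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA, null = "null",
                           na = "null")
  if (is.null(path)) return(json)
  writeLines(json, path)
  invisible(path)
}
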