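#' Right-hand side of the single-spacer ODE system
#'
#' Evaluates the exact time derivatives of the five populations. Healthy
#' bacteria grow logistically against the total bacterial load `n` (infected
#' cells occupy capacity but do not divide); spacer-enhanced cells lose their
#' spacer at rate `kappa`; phage adsorb onto healthy cells at rate `g*v`
#' (reduced by the factor `eta` for spacer carriers); infected cells lyse at
#' rate `mu`, releasing `b` phage, except that a fraction `alpha` of infected
#' wild-type cells instead survives and acquires the spacer:
#' \deqn{\dot n_0 = f_0 (1 - n/K) n_0 + \kappa n_1 - g v n_0}
#' \deqn{\dot n_1 = f_1 (1 - n/K) n_1 - \kappa n_1 - \eta g v n_1 + \alpha \mu I_0}
#' \deqn{\dot I_0 = g v n_0 - \mu I_0}
#' \deqn{\dot I_1 = \eta g v n_1 - \mu I_1}
#' \deqn{\dot v = b (1-\alpha) \mu I_0 + b \mu I_1 - g v (n_0 + n_1)}
#' with `f1 = r * f0` and `n = n0 + n1 + I0 + I1`. The adsorption loss in the
#' phage equation involves healthy bacteria only, exactly as the model is
#' formulated. Optional dilution removes every population at rate
#' `dilution`, and free phage additionally decays at rate `phage_decay`.
#'
#' @param state A [single_state()] vector (any numeric length-5 vector in
#'   the same order is accepted).
#' @param params A [single_spacer_params()] object.
#' @return Named numeric vector of the five derivatives (counts/time).
#' @seealso [total_derivative_single()], [multi_rhs()], [integrate_model()]
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 2e-3, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' single_rhs(single_state(n0 = 1000, v = 1e4), p)
#' @export
single_rhs <- function(state, params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (length(state) != 5L)
    stop("single-spacer state must have 5 components", call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state: the solution has blown up or the input is ",
         "corrupt", call. = FALSE)
  n0 <- state[[1L]]; n1 <- state[[2L]]; I0 <- state[[3L]]
  I1 <- state[[4L]]; v <- state[[5L]]
  p <- params
  n <- n0 + n1 + I0 + I1
  grow <- (1 - n / p$K)
  f1 <- p$r * p$f0
  dn0 <- p$f0 * grow * n0 + p$kappa * n1 - p$g * v * n0
  dn1 <- f1 * grow * n1 - p$kappa * n1 - p$eta * p$g * v * n1 +
    p$alpha * p$mu * I0
  dI0 <- p$g * v * n0 - p$mu * I0
  dI1 <- p$eta * p$g * v * n1 - p$mu * I1
  dv <- p$b * (1 - p$alpha) * p$mu * I0 + p$b * p$mu * I1 -
    p$g * v * (n0 + n1)
  d <- c(n0 = dn0, n1 = dn1, I0 = dI0, I1 = dI1, v = dv)
  if (p$dilution > 0) d <- d - p$dilution * c(n0, n1, I0, I1, v)
  if (p$phage_decay > 0) d[[5L]] <- d[[5L]] - p$phage_decay * v
  d
}

#' Right-hand side of the N-spacer ODE system
#'
#' The N-spacer generalization of [single_rhs()]: all bacteria grow at the
#' common rate `f`, spacer type `i` has acquisition probability `alpha_i`
#' and failure probability `eta_i`, and the phage equation gains
#' `b (1 - sum(alpha_i)) mu I0` from wild-type lysis plus `b mu sum(I_i)`
#' from lysis of spacer carriers, minus adsorption onto healthy bacteria
#' `g v (n0 + sum(n_i))`.
#'
#' @param state A [multi_state()] vector of length `2N + 3`.
#' @param params A [multi_spacer_params()] object with matching `N`.
#' @return Named numeric vector of the `2N + 3` derivatives.
#' @seealso [total_derivative_multi()], [embed_single_as_multi()]
#' @examples
#' p <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
#'                          alpha_vec = c(0.01, 0.02), eta_vec = c(0, 0.005))
#' multi_rhs(multi_state(n0 = 1000, n_vec = c(0, 0), v = 1e4), p)
#' @export
multi_rhs <- function(state, params) {
  stopifnot(inherits(params, "multi_spacer_params"))
  N <- params$N
  if (length(state) != 2L * N + 3L)
    stop("state length ", length(state), " does not match 2N + 3 = ",
         2L * N + 3L, call. = FALSE)
  if (any(!is.finite(state)))
    stop("non-finite state: the solution has blown up or the input is ",
         "corrupt", call. = FALSE)
  ix <- multi_idx(N)
  n0 <- state[[ix$n0]]; ni <- state[ix$n]; I0 <- state[[ix$I0]]
  Ii <- state[ix$I]; v <- state[[ix$v]]
  p <- params
  n <- n0 + sum(ni) + I0 + sum(Ii)
  grow <- p$f * (1 - n / p$K)
  dn0 <- grow * n0 + p$kappa * sum(ni) - p$g * v * n0
  dni <- grow * ni - p$kappa * ni - p$eta_vec * p$g * v * ni +
    p$alpha_vec * p$mu * I0
  dI0 <- p$g * v * n0 - p$mu * I0
  dIi <- p$eta_vec * p$g * v * ni - p$mu * Ii
  dv <- p$b * (1 - sum(p$alpha_vec)) * p$mu * I0 + p$b * p$mu * sum(Ii) -
    p$g * v * (n0 + sum(ni))
  d <- c(dn0, dni, dI0, dIi, dv)
  if (p$dilution > 0) d <- d - p$dilution * as.numeric(state)
  if (p$phage_decay > 0) d[[ix$v]] <- d[[ix$v]] - p$phage_decay * v
  names(d) <- multi_state_names(N)
  d
}

#' Time derivative of the total bacterial population (single spacer)
#'
#' The closed equation for `n = n0 + n1 + I0 + I1`:
#' \deqn{\dot n = f_0 (n_0 + r n_1)(1 - n/K) - \mu (1-\alpha) I_0 - \mu I_1}
#' (minus `dilution * n` if dilution is active). For any state it equals the
#' sum of the four bacterial components of [single_rhs()]: the adsorption,
#' spacer-loss and acquisition terms are internal transfers between
#' compartments and cancel.
#'
#' @inheritParams single_rhs
#' @return A single number (counts/time).
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 2e-3, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' s <- single_state(n0 = 1000, n1 = 10, I0 = 5, v = 1e4)
#' total_derivative_single(s, p)
#' sum(single_rhs(s, p)[1:4])
#' @export
total_derivative_single <- function(state, params) {
  stopifnot(inherits(params, "single_spacer_params"))
  n0 <- state[[1L]]; n1 <- state[[2L]]; I0 <- state[[3L]]; I1 <- state[[4L]]
  p <- params
  n <- n0 + n1 + I0 + I1
  dn <- p$f0 * (n0 + p$r * n1) * (1 - n / p$K) -
    p$mu * (1 - p$alpha) * I0 - p$mu * I1
  if (p$dilution > 0) dn <- dn - p$dilution * n
  dn
}

#' Time derivative of the total bacterial population (N spacers)
#'
#' The multi-spacer total-bacteria equation: healthy bacteria
#' `n - sum(I_i), i = 0..N` grow logistically and infected cells are removed
#' by lysis,
#' \deqn{\dot n = f (1 - n/K)\,(n - \textstyle\sum_{i=0}^N I_i)
#'   - \mu (1-\alpha) I_0 - \mu \sum_{i=1}^N I_i,}
#' with `alpha = sum(alpha_vec)`. Equals the sum of the `2N + 2` bacterial
#' components of [multi_rhs()] for every state.
#'
#' @inheritParams multi_rhs
#' @return A single number (counts/time).
#' @export
total_derivative_multi <- function(state, params) {
  stopifnot(inherits(params, "multi_spacer_params"))
  N <- params$N
  if (length(state) != 2L * N + 3L)
    stop("state length does not match 2N + 3", call. = FALSE)
  ix <- multi_idx(N)
  n0 <- state[[ix$n0]]; ni <- state[ix$n]; I0 <- state[[ix$I0]]
  Ii <- state[ix$I]
  p <- params
  n <- n0 + sum(ni) + I0 + sum(Ii)
  alpha <- sum(p$alpha_vec)
  dn <- p$f * (1 - n / p$K) * (n0 + sum(ni)) -
    p$mu * (1 - alpha) * I0 - p$mu * sum(Ii)
  if (p$dilution > 0) dn <- dn - p$dilution * n
  dn
}
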