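#' Parameters of the single-spacer model
#'
#' Bundles all rates and probabilities of the one-spacer-type model. The
#' populations are: healthy wild type `n0`, healthy spacer-enhanced `n1`,
#' infected wild type `I0`, infected spacer-enhanced `I1`, and free phage
#' `v`. Rates are typically expressed in units of the wild-type growth rate
#' (i.e. `f0 = 1`); any consistent unit system is accepted.
#'
#' @param f0 Wild-type maximum growth rate (1/time), > 0.
#' @param r Growth-rate ratio `f1/f0` of spacer-enhanced to wild-type
#'   bacteria (dimensionless), > 0. Spacer toxicity or Cas expression cost
#'   would give `r < 1`; evidence suggests `r` is close to 1.
#' @param K Carrying capacity (cells), > 0.
#' @param kappa Spacer loss rate (1/time), >= 0. Spacer-enhanced cells revert
#'   to wild type at this rate; `kappa > 0` is what makes host-virus
#'   coexistence possible.
#' @param g Phage adsorption (encounter) rate (1/(phage x time)), > 0.
#' @param eta Spacer failure probability in \[0, 1\]: the chance the spacer
#'   fails to block an infection. `1 - eta` is the spacer's effectiveness.
#' @param alpha Spacer acquisition probability in \[0, 1): the chance an
#'   infected wild-type cell survives the infection and integrates a spacer.
#' @param mu Lysis rate of infected cells (1/time), > 0; `1/mu` is the mean
#'   latent period.
#' @param b Burst size (phage released per lysis), >= 1.
#' @param dilution Optional removal rate applied to every population
#'   (1/time), >= 0. Default 0 (closed culture).
#' @param phage_decay Optional additional decay rate of free phage (1/time),
#'   >= 0. Default 0.
#'
#' @return An object of class `single_spacer_params` (a validated list).
#' @seealso [multi_spacer_params()], [single_rhs()], [single_spacer_scenario()]
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 2e-3, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' unused_capacity_single(p)
#' @export
single_spacer_params <- function(f0 = 1, r = 1, K, kappa, g, eta, alpha,
                                 mu = f0, b, dilution = 0, phage_decay = 0) {
  p <- list(f0 = f0, r = r, K = K, kappa = kappa, g = g, eta = eta,
            alpha = alpha, mu = mu, b = b, dilution = dilution,
            phage_decay = phage_decay)
  for (nm in names(p)) {
    x <- p[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (p$f0 <= 0 || p$K <= 0 || p$g <= 0 || p$mu <= 0)
    stop("f0, K, g and mu must be positive", call. = FALSE)
  if (p$r <= 0) stop("growth-rate ratio 'r' must be positive", call. = FALSE)
  if (p$kappa < 0 || p$dilution < 0 || p$phage_decay < 0)
    stop("kappa, dilution and phage_decay must be non-negative", call. = FALSE)
  if (p$eta < 0 || p$eta > 1)
    stop("failure probability 'eta' must lie in [0, 1]", call. = FALSE)
  if (p$alpha < 0 || p$alpha >= 1)
    stop("acquisition probability 'alpha' must lie in [0, 1)", call. = FALSE)
  if (p$b < 1) stop("burst size 'b' must be >= 1", call. = FALSE)
  structure(p, class = "single_spacer_params")
}

#' Parameters of the N-spacer model
#'
#' Generalizes [single_spacer_params()] to `N` spacer types, each with its
#' own acquisition probability `alpha_i` and failure probability `eta_i`.
#' All bacteria (with or without spacers) grow at the common rate `f`. The
#' per-spacer acquisition events are disjoint, so the overall acquisition
#' probability `sum(alpha_vec)` must be below 1.
#'
#' @param f Common maximum growth rate (1/time), > 0.
#' @param K,kappa,g,mu,b,dilution,phage_decay As in [single_spacer_params()].
#' @param alpha_vec Length-N vector of per-spacer acquisition probabilities,
#'   each >= 0, summing to < 1.
#' @param eta_vec Length-N vector of per-spacer failure probabilities, each
#'   in \[0, 1\].
#'
#' @return An object of class `multi_spacer_params` with an `N` element.
#' @seealso [multi_rhs()], [solve_coexistence_multi()], [multi_spacer_scenario()]
#' @examples
#' p <- multi_spacer_params(K = 1e5, kappa = 1e-2, g = 1e-4, b = 100,
#'                          alpha_vec = rep(0.0972 / 20, 20),
#'                          eta_vec = seq(5e-4, 9.5e-3, length.out = 20))
#' p$N
#' @export
multi_spacer_params <- function(f = 1, K, kappa, g, mu = f, b,
                                alpha_vec, eta_vec,
                                dilution = 0, phage_decay = 0) {
  scal <- list(f = f, K = K, kappa = kappa, g = g, mu = mu, b = b,
               dilution = dilution, phage_decay = phage_decay)
  for (nm in names(scal)) {
    x <- scal[[nm]]
    if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
      stop("'", nm, "' must be a single finite number", call. = FALSE)
  }
  if (!is.numeric(alpha_vec) || !is.numeric(eta_vec))
    stop("alpha_vec and eta_vec must be numeric vectors", call. = FALSE)
  if (length(alpha_vec) != length(eta_vec))
    stop("alpha_vec and eta_vec must have the same length", call. = FALSE)
  N <- length(alpha_vec)
  if (N < 1L) stop("at least one spacer type is required", call. = FALSE)
  if (any(!is.finite(alpha_vec)) || any(!is.finite(eta_vec)))
    stop("alpha_vec and eta_vec must be finite", call. = FALSE)
  if (any(alpha_vec < 0))
    stop("per-spacer acquisition probabilities must be >= 0", call. = FALSE)
  if (sum(alpha_vec) >= 1)
    stop("sum(alpha_vec) must be < 1: the per-spacer acquisitions are ",
         "disjoint events whose total is the overall acquisition probability",
         call. = FALSE)
  if (any(eta_vec < 0 | eta_vec > 1))
    stop("per-spacer failure probabilities must lie in [0, 1]", call. = FALSE)
  if (scal$f <= 0 || scal$K <= 0 || scal$g <= 0 || scal$mu <= 0)
    stop("f, K, g and mu must be positive", call. = FALSE)
  if (scal$kappa < 0 || scal$dilution < 0 || scal$phage_decay < 0)
    stop("kappa, dilution and phage_decay must be non-negative", call. = FALSE)
  if (scal$b < 1) stop("burst size 'b' must be >= 1", call. = FALSE)
  structure(c(scal, list(N = N, alpha_vec = as.numeric(alpha_vec),
                         eta_vec = as.numeric(eta_vec))),
            class = "multi_spacer_params")
}

#' Embed a single-spacer parameter set in the N-spacer model
#'
#' Produces the `N = 1` multi-spacer parameter set equivalent to a
#' single-spacer one. The multi-spacer model assumes all bacteria grow at
#' the same rate, so the embedding requires `r = 1`; with it, the two
#' right-hand sides agree exactly for every state (see [multi_rhs()]).
#'
#' @param params A [single_spacer_params()] object with `r = 1`.
#' @return A [multi_spacer_params()] object with `N = 1`.
#' @examples
#' p <- single_spacer_params(K = 1e5, kappa = 2e-3, g = 1e-5,
#'                           eta = 0.005, alpha = 1e-4, b = 100)
#' embed_single_as_multi(p)$alpha_vec
#' @export
embed_single_as_multi <- function(params) {
  stopifnot(inherits(params, "single_spacer_params"))
  if (params$r != 1)
    stop("the multi-spacer model assumes equal growth rates for all ",
         "bacteria; embedding requires r = 1 (got r = ", params$r, ")",
         call. = FALSE)
  multi_spacer_params(f = params$f0, K = params$K, kappa = params$kappa,
                      g = params$g, mu = params$mu, b = params$b,
                      alpha_vec = params$alpha, eta_vec = params$eta,
                      dilution = params$dilution,
                      phage_decay = params$phage_decay)
}

#' @export
print.single_spacer_params <- function(x, ...) {
  cat("Single-spacer CRISPR model parameters\n")
  cat(sprintf("  growth: f0 = %g, r = f1/f0 = %g, K = %g\n", x$f0, x$r, x$K))
  cat(sprintf("  spacer: kappa = %g, eta = %g, alpha = %g\n",
              x$kappa, x$eta, x$alpha))
  cat(sprintf("  phage:  g = %g, mu = %g, b = %g\n", x$g, x$mu, x$b))
  if (x$dilution > 0 || x$phage_decay > 0)
    cat(sprintf("  open system: dilution = %g, phage_decay = %g\n",
                x$dilution, x$phage_decay))
  invisible(x)
}

#' @export
print.multi_spacer_params <- function(x, ...) {
  cat(sprintf("Multi-spacer CRISPR model parameters (N = %d spacer types)\n",
              x$N))
  cat(sprintf("  growth: f = %g, K = %g\n", x$f, x$K))
  cat(sprintf("  spacer: kappa = %g, sum(alpha_i) = %g, eta_i in [%g, %g]\n",
              x$kappa, sum(x$alpha_vec), min(x$eta_vec), max(x$eta_vec)))
  cat(sprintf("  phage:  g = %g, mu = %g, b = %g\n", x$g, x$mu, x$b))
  if (x$dilution > 0 || x$phage_decay > 0)
    cat(sprintf("  open system: dilution = %g, phage_decay = %g\n",
                x$dilution, x$phage_decay))
  invisible(x)
}
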