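#' Population state of the single-spacer model
#'
#' A named numeric vector `(n0, n1, I0, I1, v)`: healthy wild type, healthy
#' spacer-enhanced, infected wild type, infected spacer-enhanced, free phage.
#'
#' @param n0,n1,I0,I1,v Non-negative population sizes (counts).
#' @return A named numeric vector of length 5.
#' @seealso [multi_state()], [total_bacteria()]
#' @examples
#' single_state(n0 = 1000, v = 1e4)
#' @export
single_state <- function(n0 = 0, n1 = 0, I0 = 0, I1 = 0, v = 0) {
  s <- c(n0 = n0, n1 = n1, I0 = I0, I1 = I1, v = v)
  if (!is.numeric(s) || length(s) != 5L || any(!is.finite(s)))
    stop("state components must be single finite numbers", call. = FALSE)
  if (any(s < 0)) stop("populations must be non-negative", call. = FALSE)
  storage.mode(s) <- "double"
  s
}

#' Population state of the N-spacer model
#'
#' A named numeric vector `(n0, n_1..n_N, I0, I_1..I_N, v)` of length
#' `2N + 3`: healthy wild type, healthy bacteria per spacer type, infected
#' wild type, infected bacteria per spacer type, free phage.
#'
#' @param n0,I0,v Scalar populations as in [single_state()].
#' @param n_vec,I_vec Length-N vectors of healthy / infected bacteria per
#'   spacer type. `I_vec` defaults to zeros matching `n_vec`.
#' @return A named numeric vector of length `2 * N + 3`.
#' @examples
#' multi_state(n0 = 1000, n_vec = rep(0, 20), v = 1e4)
#' @export
multi_state <- function(n0 = 0, n_vec, I0 = 0, I_vec = NULL, v = 0) {
  if (missing(n_vec) || !is.numeric(n_vec) || length(n_vec) < 1L)
    stop("'n_vec' must be a numeric vector with one entry per spacer type",
         call. = FALSE)
  N <- length(n_vec)
  if (is.null(I_vec)) I_vec <- numeric(N)
  if (length(I_vec) != N)
    stop("'I_vec' must have the same length as 'n_vec'", call. = FALSE)
  s <- c(n0, n_vec, I0, I_vec, v)
  if (any(!is.finite(s))) stop("state components must be finite", call. = FALSE)
  if (any(s < 0)) stop("populations must be non-negative", call. = FALSE)
  names(s) <- multi_state_names(N)
  storage.mode(s) <- "double"
  s
}

multi_state_names <- function(N) {
  c("n0", paste0("n_", seq_len(N)), "I0", paste0("I_", seq_len(N)), "v")
}

# index helpers for the flat multi-spacer state vector
multi_idx <- function(N) {
  list(n0 = 1L, n = 1L + seq_len(N), I0 = N + 2L,
       I = N + 2L + seq_len(N), v = 2L * N + 3L)
}

#' Total number of bacteria in a state
#'
#' Sums all bacterial compartments (healthy and infected, with and without
#' spacers); free phage is excluded. This is the quantity an optical density
#' measurement tracks.
#'
#' @param state A state vector from [single_state()] or [multi_state()] (or
#'   any numeric vector laid out the same way).
#' @return A single number, `n = n0 + sum(n_i) + I0 + sum(I_i)`.
#' @examples
#' total_bacteria(single_state(n0 = 1000, n1 = 50, v = 1e4))
#' @export
total_bacteria <- function(state) {
  sum(state[-length(state)])
}

# N implied by a flat multi state vector of length 2N+3
multi_state_N <- function(state) {
  N2 <- length(state) - 3L
  if (N2 < 2L || N2 %% 2L != 0L)
    stop("multi-spacer state must have length 2N + 3", call. = FALSE)
  N2 %/% 2L
}
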