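#' Spacer distribution of a multi-spacer state
#'
#' Normalized fractions `f_i = n_i / sum(n_j)` over the healthy
#' spacer-enhanced compartments; wild-type and infected cells are excluded.
#' This is the quantity spacer sequencing of the healthy population would
#' estimate.
#'
#' @param x A [multi_state()] vector, a `crisprdyn_trajectory` (its final
#'   state is used), or a valid `coexistence_solution`.
#' @return An object of class `spacer_distribution`: a numeric vector of
#'   fractions summing to 1.
#' @seealso [shannon_entropy()], [winner_share()]
#' @examples
#' p <- multi_spacer_scenario("acquisition_varying")$params
#' spacer_fractions(solve_coexistence_multi(p))
#' @export
spacer_fractions <- function(x) {
  if (inherits(x, "coexistence_solution")) {
    if (!isTRUE(x$valid))
      stop("invalid coexistence solution has no spacer distribution",
           call. = FALSE)
    n_vec <- x$n_vec_star
  } else if (inherits(x, "crisprdyn_trajectory")) {
    if (x$model != "multi")
      stop("spacer fractions require the multi-spacer model", call. = FALSE)
    s <- x$states[nrow(x$states), ]
    n_vec <- s[multi_idx(x$params$N)$n]
  } else {
    N <- multi_state_N(x)
    n_vec <- as.numeric(x)[multi_idx(N)$n]
  }
  tot <- sum(n_vec)
  if (tot <= 0)
    stop("no spacer-enhanced bacteria: the spacer distribution is undefined",
         call. = FALSE)
  structure(as.numeric(n_vec) / tot, class = "spacer_distribution")
}

check_distribution <- function(dist) {
  d <- as.numeric(dist)
  if (any(d < 0) || abs(sum(d) - 1) > 1e-12)
    stop("not a valid distribution: fractions must be non-negative and sum ",
         "to 1", call. = FALSE)
  d
}

#' Shannon entropy of a spacer distribution
#'
#' `-sum(f_i * log(f_i))` in nats, with the `0 * log(0) = 0` convention.
#' Ranges from 0 (all bacteria share one spacer type — winner-take-all) to
#' `log(N)` (uniform spacer usage).
#'
#' @param dist A [spacer_fractions()] result (or any probability vector).
#' @return Entropy in nats.
#' @examples
#' shannon_entropy(rep(1 / 20, 20))  # log(20)
#' @export
shannon_entropy <- function(dist) {
  d <- check_distribution(dist)
  d <- d[d > 0]
  -sum(d * log(d))
}

#' Share of the most abundant spacer
#'
#' The maximum fraction in the distribution: 1 means complete
#' winner-take-all, `1/N` a perfectly uniform repertoire.
#'
#' @inheritParams shannon_entropy
#' @return The largest fraction.
#' @export
winner_share <- function(dist) {
  max(check_distribution(dist))
}

#' Index of the most abundant spacer
#'
#' @inheritParams shannon_entropy
#' @return The index of the largest fraction (first on ties).
#' @export
winner_index <- function(dist) {
  which.max(check_distribution(dist))
}

#' @export
print.spacer_distribution <- function(x, ...) {
  d <- as.numeric(x)
  cat(sprintf("Spacer distribution over %d types\n", length(d)))
  cat(sprintf("  entropy = %.4g nats (max %.4g), winner: type %d at %.3g\n",
              shannon_entropy(d), log(length(d)), winner_index(d),
              winner_share(d)))
  invisible(x)
}

#' Summarize spacer diversity as a list / JSON
#'
#' @param dist A [spacer_fractions()] result.
#' @param path Optional path; when given, the summary is written as JSON.
#' @return A list with `fractions`, `entropy`, `winner_index`,
#'   `winner_share` (invisibly when writing to a file).
#' @export
diversity_summary <- function(dist, path = NULL) {
  d <- check_distribution(dist)
  out <- list(fractions = d, entropy = shannon_entropy(d),
              winner_index = winner_index(d), winner_share = winner_share(d))
  if (!is.null(path)) {
    writeLines(jsonlite::toJSON(out, auto_unbox = TRUE, digits = NA), path)
    return(invisible(out))
  }
  out
}
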