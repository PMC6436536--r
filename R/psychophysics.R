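#' Probability of a correct numerosity comparison under the Gaussian ANS model
#'
#' The approximate number sense (ANS) is modelled as noisy Gaussian magnitude
#' representations: a set of `n` items is represented as a draw from
#' `Normal(n, (w * n)^2)`, where `w` is the Weber fraction.  The probability of
#' correctly judging which of two sets is larger is then the probability that
#' the larger set's representation exceeds the smaller set's:
#'
#' \deqn{p = \Phi\!\left(\frac{|n_1 - n_2|}{w\sqrt{n_1^2 + n_2^2}}\right)}
#'
#' with \eqn{\Phi} the standard normal CDF.  A smaller `w` means sharper
#' representations and higher accuracy.
#'
#' @param n_small Integer count of the less numerous set (>= 1). Vectorised.
#' @param n_large Integer count of the more numerous set (>= `n_small`).
#' @param w Weber fraction, a positive scalar.
#' @return Probability of a correct response, in `[0.5, 1)`.
#' @examples
#' p_correct(5, 15, 0.3)   # an easy 1:3 ratio
#' p_correct(11, 12, 0.3)  # a hard 11:12 ratio
#' @export
p_correct <- function(n_small, n_large, w) {
  if (!is.numeric(w) || length(w) != 1L || !is.finite(w) || w <= 0)
    stop("`w` must be a single positive finite number", call. = FALSE)
  if (any(n_small < 1) || any(n_large < 1))
    stop("counts must be >= 1", call. = FALSE)
  if (any(n_small > n_large))
    stop("`n_small` must not exceed `n_large`", call. = FALSE)
  stats::pnorm((n_large - n_small) / (w * sqrt(n_small^2 + n_large^2)))
}

# Per-trial discriminability |n1 - n2| / sqrt(n1^2 + n2^2); w divides this.
trial_signal <- function(n_small, n_large) {
  (n_large - n_small) / sqrt(n_small^2 + n_large^2)
}

#' Session log-likelihood of a Weber fraction
#'
#' Bernoulli log-likelihood of a set of comparison trials under the Gaussian
#' ANS model, optionally mixed with a lapse process: with lapse rate
#' `lapse`, the effective per-trial accuracy is
#' `(1 - lapse) * p_correct + lapse * 0.5`.  Per-trial probabilities are
#' clamped to `[1e-9, 1 - 1e-9]` inside the log so the likelihood stays finite
#' at extreme `w`.
#'
#' @param trials A trials data frame with columns `n_small`, `n_large` and
#'   `is_correct` (logical), as produced by [simulate_session()] or
#'   [read_trials()].  Extra columns are ignored.
#' @param w Weber fraction (positive scalar).
#' @param lapse Lapse/guessing rate in `[0, 0.5)`; default 0 (no lapse).
#' @return The summed log-likelihood (<= 0).  An empty trial set gives 0.
#' @export
session_loglik <- function(trials, w, lapse = 0) {
  if (!is.numeric(lapse) || length(lapse) != 1L || lapse < 0 || lapse >= 0.5)
    stop("`lapse` must be in [0, 0.5)", call. = FALSE)
  trials <- as_trials(trials)
  if (nrow(trials) == 0L) return(0)
  p <- p_correct(trials$n_small, trials$n_large, w)
  p_eff <- (1 - lapse) * p + lapse * 0.5
  p_eff <- pmin(pmax(p_eff, 1e-9), 1 - 1e-9)
  sum(log(ifelse(trials$is_correct, p_eff, 1 - p_eff)))
}

# Coerce/validate the minimal trial-table contract used by the likelihood.
as_trials <- function(trials) {
  if (!is.data.frame(trials))
    stop("`trials` must be a data frame", call. = FALSE)
  if (nrow(trials) == 0L) return(trials)
  need <- c("n_small", "n_large", "is_correct")
  miss <- setdiff(need, names(trials))
  if (length(miss))
    stop("trials table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (any(trials$n_small %% 1 != 0) || any(trials$n_large %% 1 != 0))
    stop("dot counts must be integers", call. = FALSE)
  trials
}
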