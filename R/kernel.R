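#' Transition probability kernel over a time gap
#'
#' Computes `expm(rate_matrix * dt)`, the probability of occupying each
#' state at the end of a gap of `dt` years given the state at its start.
#' Entries are clipped at 0 and rows renormalized against floating-point
#' drift.
#'
#' @param rate_matrix S x S rate matrix (off-diagonals nonnegative, rows
#'   summing to zero).
#' @param dt gap length in years (nonnegative).
#' @return S x S stochastic matrix.
#' @export
transition_matrix <- function(rate_matrix, dt) {
  rate_matrix <- as.matrix(rate_matrix)
  if (dt < 0) stop("dt must be nonnegative")
  check_rate_matrix(rate_matrix)
  .cpp_transmat(rate_matrix, dt)
}

check_rate_matrix <- function(Q) {
  if (nrow(Q) != ncol(Q)) stop("rate matrix must be square")
  off <- Q
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(Q)) > 1e-8)) stop("rate matrix rows must sum to 0")
  invisible(Q)
}

#' Per-visit emission likelihood
#'
#' Probability of an observed antibody triple under a state's emission
#' row: the product over non-missing antibodies of `p` if positive and
#' `1 - p` if negative; an all-missing visit contributes 1
#' (missing-at-random).
#'
#' @param emission_row 3 Bernoulli positivity probabilities.
#' @param obs observation triple coded 1 (positive), 0 (negative), NA
#'   (missing).
#' @return a probability.
#' @export
emission_likelihood <- function(emission_row, obs) {
  stopifnot(length(emission_row) == 3, length(obs) == 3,
            all(emission_row >= 0 & emission_row <= 1))
  keep <- !is.na(obs)
  if (!all(obs[keep] %in% c(0, 1))) stop("obs must be coded 0/1/NA")
  prod(ifelse(obs[keep] == 1, emission_row[keep], 1 - emission_row[keep]))
}

#' Forward-backward smoothing for one participant series
#'
#' Scaled forward-backward over the visit sequence, using the matrix
#' exponential kernel for each inter-visit gap and the Bernoulli emission
#' likelihood at each visit. Returns per-visit posterior state
#' probabilities, per-interval endpoint-pair posteriors, and the exact
#' observation log-likelihood.
#'
#' @param params a [cthmm_params] object.
#' @param ages strictly increasing visit ages (years).
#' @param obs visit-by-antibody matrix coded 1/0/NA.
#' @return list with `loglik`, `gamma` (V x S per-visit posteriors), and
#'   `xi` (S x S x (V-1) endpoint-pair posteriors per interval).
#' @export
forward_backward <- function(params, ages, obs) {
  stopifnot(inherits(params, "cthmm_params"))
  obs <- as.matrix(obs)
  if (length(ages) != nrow(obs)) stop("ages and obs must align")
  if (length(ages) > 1 && any(diff(ages) <= 0))
    stop("visit ages must be strictly increasing")
  m <- obs
  storage.mode(m) <- "integer"
  m[is.na(m)] <- -1L
  .cpp_forward_backward(params$rate_matrix, params$emissions,
                        params$initial_dist, m, diff(ages))
}

#' Endpoint-conditioned dwell and jump expectations
#'
#' Expected time spent in each state and expected count of each jump over
#' an interval of length `dt`, conditional on occupying `start` at the
#' interval's beginning and `end` at its close. These are the sufficient
#' statistics of the EM E-step; they are computed from the spectral
#' decomposition of the rate matrix (with an augmented-matrix-exponential
#' fallback for defective matrices).
#'
#' @param rate_matrix S x S rate matrix.
#' @param dt interval length in years.
#' @param start,end 1-based state indices at the interval endpoints.
#' @return list with `dwell` (length-S vector summing to `dt`) and `jumps`
#'   (S x S matrix of expected transition counts).
#' @export
endpoint_conditioned_stats <- function(rate_matrix, dt, start, end) {
  rate_matrix <- as.matrix(rate_matrix)
  check_rate_matrix(rate_matrix)
  if (dt < 0) stop("dt must be nonnegative")
  S <- nrow(rate_matrix)
  stopifnot(start >= 1, start <= S, end >= 1, end <= S)
  out <- .cpp_endpoint_stats(rate_matrix, dt, start - 1L, end - 1L)
  list(dwell = as.numeric(out$dwell), jumps = out$jumps)
}
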