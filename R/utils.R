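#' Minimum-cost assignment (Hungarian algorithm)
#'
#' Solves the linear assignment problem for a square cost matrix by the
#' shortest-augmenting-path form of the Hungarian algorithm, O(n^3).
#' Used to match fitted latent states to reference states by the L1
#' distance between emission rows.
#'
#' @param cost square numeric cost matrix; `cost[i, j]` is the cost of
#'   assigning row `i` to column `j`.
#' @return integer vector `a` with `a[i]` the column assigned to row `i`,
#'   minimizing `sum(cost[cbind(seq_len(n), a)])`.
#' @export
hungarian_assignment <- function(cost) {
  cost <- as.matrix(cost)
  n <- nrow(cost)
  stopifnot(ncol(cost) == n, n >= 1, all(is.finite(cost)))
  u <- numeric(n)
  v <- numeric(n + 1)
  p <- integer(n + 1)    # p[j + 1]: row matched to column j (0 = free)
  way <- integer(n + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0
    minv <- rep(Inf, n + 1)
    used <- rep(FALSE, n + 1)
    repeat {
      used[j0 + 1] <- TRUE
      i0 <- p[j0 + 1]
      delta <- Inf
      j1 <- -1
      for (j in seq_len(n)) {
        if (!used[j + 1]) {
          cur <- cost[i0, j] - u[i0] - v[j + 1]
          if (cur < minv[j + 1]) {
            minv[j + 1] <- cur
            way[j + 1] <- j0
          }
          if (minv[j + 1] < delta) {
            delta <- minv[j + 1]
            j1 <- j
          }
        }
      }
      for (j in 0:n) {
        if (used[j + 1]) {
          if (p[j + 1] > 0) u[p[j + 1]] <- u[p[j + 1]] + delta
          v[j + 1] <- v[j + 1] - delta
        } else {
          minv[j + 1] <- minv[j + 1] - delta
        }
      }
      j0 <- j1
      if (p[j0 + 1] == 0) break
    }
    repeat {
      j1 <- way[j0 + 1]
      p[j0 + 1] <- p[j1 + 1]
      j0 <- j1
      if (j0 == 0) break
    }
  }
  assignment <- integer(n)
  for (j in seq_len(n)) if (p[j + 1] > 0) assignment[p[j + 1]] <- j
  assignment
}

#' Match fitted states to reference states by emission rows
#'
#' Canonical state matching for parameter-recovery experiments: finds the
#' one-to-one assignment of fitted states to reference states minimizing
#' the total L1 distance between emission probability rows.
#'
#' @param reference_emissions S x 3 matrix of reference emission
#'   probabilities (one row per state).
#' @param fitted_emissions S x 3 matrix of fitted emission probabilities.
#' @return integer vector `m` with `m[i]` the fitted state matched to
#'   reference state `i`.
#' @export
match_states <- function(reference_emissions, fitted_emissions) {
  reference_emissions <- as.matrix(reference_emissions)
  fitted_emissions <- as.matrix(fitted_emissions)
  stopifnot(nrow(reference_emissions) == nrow(fitted_emissions),
            ncol(reference_emissions) == ncol(fitted_emissions))
  S <- nrow(reference_emissions)
  cost <- matrix(0, S, S)
  for (i in seq_len(S)) {
    for (j in seq_len(S)) {
      cost[i, j] <- sum(abs(reference_emissions[i, ] - fitted_emissions[j, ]))
    }
  }
  hungarian_assignment(cost)
}

# derive a 32-bit-safe stream seed from a base seed and an index
derive_seed <- function(seed, index, salt = 0L) {
  as.integer((as.numeric(seed) + 1000003 * as.numeric(index) +
                7919 * as.numeric(salt)) %% 2147483629) + 1L
}

# probability that at least two of three independent Bernoulli are positive
prob_multiple_positive <- function(p) {
  stopifnot(length(p) == 3)
  p1 <- p[1]; p2 <- p[2]; p3 <- p[3]
  p1 * p2 * (1 - p3) + p1 * (1 - p2) * p3 + (1 - p1) * p2 * p3 + p1 * p2 * p3
}

`%||%` <- function(a, b) if (is.null(a)) b else a
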