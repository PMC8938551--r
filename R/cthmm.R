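#' Fit a continuous-time hidden Markov model by EM
#'
#' Maximum-likelihood estimation of a CT-HMM over irregularly sampled
#' three-antibody binary panels. Each E-step runs scaled forward-backward
#' per participant and accumulates endpoint-conditioned expected dwell
#' times and jump counts across the inter-visit intervals; the M-step sets
#' off-diagonal rates to expected jumps over expected dwell of the source
#' state, emissions to the posterior-weighted positive fraction over
#' non-missing observations, and the initial distribution to the
#' normalized first-visit posteriors. The rate matrix is kept dense during
#' learning: chain structure is discovered, not imposed. The best of
#' `n_restarts` randomized initializations is returned.
#'
#' @param data a [t1d_cohort]; every participant must have at least two
#'   visits. Visits at identical ages must be merged first (see
#'   [merge_duplicate_visits()]).
#' @param n_states number of latent states.
#' @param n_restarts number of candidate runs polished to convergence.
#' @param n_screen number of short screening runs from randomized
#'   initializations; the `n_restarts` best (by log-likelihood after
#'   `screen_iter` iterations) are continued to convergence. Defaults to
#'   `4 * n_restarts`; set equal to `n_restarts` to disable screening.
#' @param screen_iter EM iterations per screening run.
#' @param screen_temper optional deterministic-annealing temperature for
#'   the screening bursts: emission likelihood terms are raised to this
#'   power (values below 1 flatten them, smoothing the likelihood
#'   surface during exploration); polishing always runs at temperature
#'   1. The default leaves tempering off.
#' @param max_iter maximum EM iterations per polished restart.
#' @param split_merge_rounds rounds of split-merge refinement applied to
#'   the best restart: each round proposes moves that merge the two most
#'   similar states (by emission rows) and re-split a heavily occupied
#'   one, keeping the state count fixed, and accepts a move only if it
#'   improves the log-likelihood after re-running EM. This escapes the
#'   characteristic local optima of state-space models in which two
#'   genuine states are fused while another is split spuriously. Set to
#'   0 to disable.
#' @param tol relative log-likelihood change declaring convergence.
#' @param seed integer seed; restart `r` uses a stream derived from
#'   (seed, r).
#' @param emission_prior Beta pseudo-count added symmetrically to each
#'   emission estimate (maximum a posteriori M-step under a
#'   Beta(1 + a, 1 + a) prior). The default 0.5 is a weak Jeffreys-style
#'   regularization that keeps poorly occupied states off the 0/1
#'   boundary; set to 0 for plain maximum likelihood.
#' @param max_states guard on `n_states`.
#' @param verbose print per-restart progress.
#' @return object of class `cthmm` with elements `params`
#'   ([cthmm_params]), `loglik`, `loglik_trace`, `n_iter`, `converged`,
#'   `seed`, `restart_logliks`, `n_participants`, `n_visits`, `call`.
#' @seealso [decode_states()], [run_state_search()],
#'   [decompose_trajectories()]
#' @export
cthmm <- function(data, n_states, n_restarts = 5, n_screen = NULL,
                  screen_iter = 50, screen_temper = 1, max_iter = 500,
                  split_merge_rounds = 2,
                  tol = 1e-6, seed = 1L, emission_prior = 0.5,
                  max_states = 40L, verbose = FALSE) {
  cl <- match.call()
  ser <- if (inherits(data, "t1d_cohort")) cohort_series(data) else data
  if (!length(ser$obs)) stop("empty dataset")
  if (n_states < 1) stop("n_states must be at least 1")
  if (n_states > max_states)
    stop("n_states exceeds the configured cap (", max_states, ")")
  nv <- vapply(ser$obs, nrow, integer(1))
  if (any(nv < 2))
    stop(sum(nv < 2), " participant(s) have fewer than 2 visits; ",
         "transitions cannot be estimated")
  n_screen <- n_screen %||% (4L * n_restarts)
  if (n_screen < n_restarts) stop("n_screen must be >= n_restarts")
  # screening phase: short EM bursts from randomized starting points
  starts <- vector("list", n_screen)
  screen_ll <- numeric(n_screen)
  for (r in seq_len(n_screen)) {
    init <- random_init(n_states, derive_seed(seed, r, salt = 17L))
    if (n_screen > n_restarts) {
      # deterministic annealing: screening bursts run with flattened
      # emission terms, which melts the spurious near-tied optima that
      # sharp emission commitments create, then polishing restores the
      # full likelihood
      burst <- em_run(init, ser, max_iter = screen_iter, tol = 0,
                      emission_prior = emission_prior,
                      temper = screen_temper)
      starts[[r]] <- burst$params
      screen_ll[r] <- burst$loglik
    } else {
      starts[[r]] <- init
      screen_ll[r] <- r  # no screening: keep submission order
    }
  }
  keep <- order(-screen_ll)[seq_len(n_restarts)]
  if (n_screen == n_restarts) keep <- seq_len(n_restarts)
  runs <- vector("list", n_restarts)
  restart_ll <- numeric(n_restarts)
  for (k in seq_along(keep)) {
    runs[[k]] <- em_run(starts[[keep[k]]], ser, max_iter = max_iter,
                        tol = tol, emission_prior = emission_prior)
    restart_ll[k] <- runs[[k]]$loglik
    if (verbose)
      message(sprintf("restart %d: loglik %.4f after %d iterations",
                      k, runs[[k]]$loglik, runs[[k]]$n_iter))
  }
  best <- runs[[which.max(restart_ll)]]
  if (split_merge_rounds > 0 && n_states >= 3) {
    # refine the leading restarts, not only the winner: a slightly
    # shallower basin often sits one split-merge move from the deepest
    # optimum, while the incumbent's own moves all fail
    for (k in utils::head(order(-restart_ll), 3)) {
      ref <- refine_split_merge(runs[[k]], ser,
                                rounds = split_merge_rounds,
                                max_iter = max_iter, tol = tol,
                                emission_prior = emission_prior,
                                seed = derive_seed(seed, k, salt = 23L),
                                verbose = verbose)
      if (ref$loglik > best$loglik) best <- ref
    }
  }
  structure(list(params = best$params,
                 loglik = best$loglik,
                 loglik_trace = best$trace,
                 n_iter = best$n_iter,
                 converged = best$converged,
                 seed = seed,
                 restart_logliks = restart_ll,
                 n_participants = length(ser$obs),
                 n_visits = sum(nv),
                 call = cl),
            class = "cthmm")
}

# randomized EM starting point: emissions uniform(0.05, 0.95); per-row exit
# mass c drawn log-uniform in [0.05, 1], spread evenly over destinations
random_init <- function(S, seed) {
  set.seed(seed)
  emis <- matrix(stats::runif(S * 3, 0.05, 0.95), S, 3)
  Q <- matrix(0, S, S)
  if (S > 1) {
    for (i in seq_len(S)) {
      c_i <- exp(stats::runif(1, log(0.05), log(1)))
      Q[i, -i] <- c_i / S
      Q[i, i] <- -sum(Q[i, -i])
    }
  }
  init <- stats::runif(S, 0.5, 1.5)
  cthmm_params(init / sum(init), Q, emis)
}

# Split-merge (SMEM-style) refinement: propose merging the most similar
# state pairs while re-splitting a heavily occupied state, keeping the
# state count fixed; accept a proposal only when EM from the modified
# parameters beats the incumbent log-likelihood.
refine_split_merge <- function(run, ser, rounds, max_iter, tol,
                               emission_prior, seed, verbose = FALSE,
                               n_merge_pairs = 4, n_split_cands = 3,
                               probe_iter = 60) {
  for (round in seq_len(rounds)) {
    p <- run$params
    S <- p$n_states
    es <- .cpp_estep(p$rate_matrix, p$emissions, p$initial_dist,
                     ser$obs, ser$gaps)
    occ <- as.numeric(es$dwell)
    d <- as.matrix(stats::dist(p$emissions, method = "manhattan"))
    d[upper.tri(d, diag = TRUE)] <- Inf
    ord <- order(d)[seq_len(min(n_merge_pairs, sum(is.finite(d))))]
    pairs <- lapply(ord, function(o)
      c(row(d)[o], col(d)[o]))
    improved <- FALSE
    prop_id <- 0
    for (pr in pairs) {
      avail <- setdiff(order(-occ), pr)
      splits <- avail[seq_len(min(n_split_cands, length(avail)))]
      for (k in splits) {
        prop_id <- prop_id + 1
        cand <- propose_merge_split(p, pr[1], pr[2], k, occ,
                                    derive_seed(seed, prop_id,
                                                salt = round))
        probe <- em_run(cand, ser, max_iter = probe_iter, tol = tol * 10,
                        emission_prior = emission_prior)
        if (probe$loglik > run$loglik + 1e-3) {
          polished <- em_run(probe$params, ser, max_iter = max_iter,
                             tol = tol, emission_prior = emission_prior)
          if (polished$loglik > run$loglik) {
            if (verbose)
              message(sprintf(
                "split-merge round %d: merge (%d,%d), split %d: %.4f -> %.4f",
                round, pr[1], pr[2], k, run$loglik, polished$loglik))
            run <- polished
            improved <- TRUE
          }
        }
      }
    }
    if (!improved) break
  }
  run
}

# merge state j into i (occupancy-weighted) and re-initialize slot j as a
# perturbed copy of state k
propose_merge_split <- function(p, i, j, k, occ, seed) {
  set.seed(seed)
  em <- p$emissions
  Q <- p$rate_matrix
  init <- p$initial_dist
  w <- occ[c(i, j)]
  w <- if (sum(w) > 0) w / sum(w) else c(0.5, 0.5)
  em[i, ] <- w[1] * em[i, ] + w[2] * em[j, ]
  Q[i, ] <- w[1] * Q[i, ] + w[2] * Q[j, ]
  Q[, i] <- Q[, i] + Q[, j]
  init[i] <- init[i] + init[j]
  # slot j: split of k
  em[j, ] <- pmin(pmax(em[k, ] + stats::runif(3, -0.15, 0.15), 0.01), 0.99)
  Q[j, ] <- Q[k, ]
  Q[, j] <- Q[, k] / 2
  Q[, k] <- Q[, k] / 2
  init[j] <- init[k] / 2
  init[k] <- init[k] / 2
  diag(Q) <- 0
  Q[Q < 0] <- 0
  Q[i, i] <- 0; Q[j, j] <- 0
  diag(Q) <- -rowSums(Q)
  init <- pmax(init, 1e-8)
  cthmm_params(init / sum(init), Q, em)
}

# one EM run to convergence; the trace records the log-likelihood of the
# parameters entering each E-step
em_run <- function(params, ser, max_iter, tol, emission_prior = 0.5,
                   temper = 1) {
  trace <- numeric(0)
  converged <- FALSE
  it <- 0
  prev_params <- params
  repeat {
    it <- it + 1
    es <- .cpp_estep(params$rate_matrix, params$emissions,
                     params$initial_dist, ser$obs, ser$gaps, temper)
    ll <- es$total_loglik
    trace <- c(trace, ll)
    if (it > 1 && is.finite(ll) && is.finite(trace[it - 1]) &&
        ll < trace[it - 1] - 1e-6) {
      # EM ascends exactly; any measurable drop flags numerical
      # breakdown in the E-step (or convergence-scale oscillation).
      # Revert to the last sane parameters and stop there.
      params <- prev_params
      trace <- trace[seq_len(it - 1)]
      break
    }
    prev_params <- params
    params <- m_step(params, es, emission_prior = emission_prior)
    if (it > 1) {
      prev <- trace[it - 1]
      if (is.finite(ll) && is.finite(prev) &&
          abs(ll - prev) <= tol * (abs(prev) + 1e-12)) {
        converged <- TRUE
        break
      }
    }
    if (it >= max_iter) break
  }
  final_ll <- sum(.cpp_loglik(params$rate_matrix, params$emissions,
                              params$initial_dist, ser$obs, ser$gaps))
  trace <- c(trace, final_ll)
  list(params = params, loglik = final_ll, trace = trace, n_iter = it,
       converged = converged)
}

m_step <- function(params, es, emission_prior = 0.5) {
  S <- params$n_states
  Q <- matrix(0, S, S)
  if (S > 1) {
    for (i in seq_len(S)) {
      if (es$dwell[i] > 1e-9) {
        # numerical safety bound only: rates this size are never
        # identifiable from visit-scale gaps and the bound binds only
        # for degenerate near-zero dwell estimates
        Q[i, -i] <- pmin(es$jumps[i, -i] / es$dwell[i], 1e6)
      } else if (any(params$rate_matrix[i, -i] > 0)) {
        # a state with (numerically) no occupancy: the E-step carries no
        # information about its parameters, and jumps/dwell would be a
        # noise ratio. Freeze its row (coordinate-ascent M-step, still
        # monotone).
        Q[i, -i] <- params$rate_matrix[i, -i]
      } else {
        # unvisited state: floor rates so the kernel stays well-defined
        Q[i, -i] <- 1e-8
      }
    }
    diag(Q) <- -rowSums(Q)
  }
  emis <- params$emissions
  pos <- es$emission_pos_weight + emission_prior
  tot <- es$emission_obs_weight + 2 * emission_prior
  upd <- tot > 0
  emis[upd] <- pos[upd] / tot[upd]
  # emissions live in [1e-4, 1 - 1e-4]: boundary values are never
  # identifiable from panels of this size, and near-deterministic
  # emission terms destabilize the scaled smoothing recursions
  emis <- pmin(pmax(emis, 1e-4), 1 - 1e-4)
  init <- es$initial_weight / sum(es$initial_weight)
  init <- pmax(init, 1e-10)  # smoothing keeps held-out likelihoods finite
  init <- init / sum(init)
  cthmm_params(init, Q, emis)
}

#' Bayesian Information Criterion of a CT-HMM fit
#'
#' `-2 loglik + k log(n_visits)` with `k = (S - 1) + S (S - 1) + 3 S` free
#' parameters (initial distribution, off-diagonal rates, emissions). The
#' sample size convention is the total number of visits.
#'
#' @param loglik total log-likelihood.
#' @param n_states number of latent states S.
#' @param n_visits total visit count used as BIC sample size.
#' @return the BIC score (smaller is better).
#' @export
cthmm_bic <- function(loglik, n_states, n_visits) {
  if (n_visits < 1) stop("n_visits must be at least 1")
  k <- (n_states - 1) + n_states * (n_states - 1) + 3 * n_states
  -2 * loglik + k * log(n_visits)
}

#' @export
logLik.cthmm <- function(object, ...) {
  S <- object$params$n_states
  structure(object$loglik,
            df = (S - 1) + S * (S - 1) + 3 * S,
            nobs = object$n_visits, class = "logLik")
}

#' @export
coef.cthmm <- function(object, ...) {
  list(initial_dist = object$params$initial_dist,
       rate_matrix = object$params$rate_matrix,
       emissions = object$params$emissions)
}

#' @export
print.cthmm <- function(x, ...) {
  cat(sprintf("CT-HMM fit: %d states, %d participants, %d visits\n",
              x$params$n_states, x$n_participants, x$n_visits))
  cat(sprintf("  log-likelihood %.3f (BIC %.1f), %d EM iterations%s\n",
              x$loglik, cthmm_bic(x$loglik, x$params$n_states, x$n_visits),
              x$n_iter, if (x$converged) "" else " [not converged]"))
  invisible(x)
}

#' @export
summary.cthmm <- function(object, ...) {
  p <- object$params
  em <- round(p$emissions, 3)
  colnames(em) <- toupper(ANTIBODIES)
  rownames(em) <- p$state_names %||% paste0("S", seq_len(p$n_states))
  out <- list(n_states = p$n_states, emissions = em,
              initial_dist = round(p$initial_dist, 4),
              exit_rates = round(-diag(p$rate_matrix), 4),
              loglik = object$loglik,
              bic = cthmm_bic(object$loglik, p$n_states, object$n_visits),
              n_iter = object$n_iter, converged = object$converged,
              restart_logliks = object$restart_logliks)
  class(out) <- "summary.cthmm"
  out
}

#' @export
print.summary.cthmm <- function(x, ...) {
  cat(sprintf("CT-HMM with %d latent states\n", x$n_states))
  cat(sprintf("log-likelihood %.3f   BIC %.1f   iterations %d%s\n",
              x$loglik, x$bic, x$n_iter,
              if (x$converged) "" else " (max_iter reached)"))
  cat("\nEmission probabilities (P positive):\n")
  print(cbind(x$emissions, init = x$initial_dist,
              exit_rate = x$exit_rates))
  cat("\nrestart log-likelihoods: ",
      paste(sprintf("%.2f", x$restart_logliks), collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.cthmm <- function(x, which = c("emissions", "trace"), ...) {
  which <- match.arg(which)
  if (which == "trace") {
    plot(seq_along(x$loglik_trace), x$loglik_trace, type = "b",
         xlab = "EM iteration", ylab = "log-likelihood",
         main = "EM convergence", ...)
  } else {
    p <- x$params
    image(seq_len(3), seq_len(p$n_states), t(p$emissions)[, p$n_states:1],
          col = hcl.colors(64, "Green-Orange", rev = TRUE), zlim = c(0, 1),
          axes = FALSE, xlab = "", ylab = "latent state",
          main = "Emission probabilities")
    axis(1, at = 1:3, labels = toupper(ANTIBODIES))
    labels <- p$state_names %||% paste0("S", seq_len(p$n_states))
    axis(2, at = seq_len(p$n_states), labels = rev(labels), las = 1)
  }
  invisible(x)
}

#' Simulate observation panels from a fitted CT-HMM
#'
#' Forward-simulates participant series from the fitted parameters (latent
#' path, visit schedule, Bernoulli observations). The fitted model carries
#' no diagnosis hazard, so simulated participants are censored at the end
#' of follow-up.
#'
#' @param object a fitted `cthmm`.
#' @param nsim number of participants to simulate.
#' @param seed integer seed.
#' @param visit_schedule,missingness_rate schedule and missingness
#'   settings, defaulting to the generator defaults.
#' @param ... unused.
#' @return a [t1d_cohort].
#' @export
simulate.cthmm <- function(object, nsim = 100, seed = 1L,
                           visit_schedule = list(first_visit = c(0.25, 1),
                                                 gap = c(0.25, 1),
                                                 max_follow_up = 15),
                           missingness_rate = 0, ...) {
  S <- object$params$n_states
  cfg <- ground_truth_config(
    n_participants = nsim, chain_weights = 1, chain_sizes = S,
    emission_table = object$params$emissions,
    rate_scale = rep(Inf, S), visit_schedule = visit_schedule,
    diagnosis_hazards = rep(0, S), missingness_rate = missingness_rate,
    seed = seed)
  simulate_cohort(cfg, params = object$params)
}

#' Label visits with latent states
#'
#' Decodes each participant's visit sequence under a fitted model, either
#' by the most probable joint path (Viterbi, the default; ties broken
#' toward the lower state index) or by per-visit maximum posterior
#' marginals.
#'
#' @param object a fitted `cthmm` or a [cthmm_params] object.
#' @param cohort a [t1d_cohort] to label.
#' @param method `"viterbi"` or `"posterior"`.
#' @return data frame `participant_id`, `age_years`, `state` (1-based).
#' @export
decode_states <- function(object, cohort, method = c("viterbi", "posterior")) {
  method <- match.arg(method)
  p <- if (inherits(object, "cthmm")) object$params else object
  stopifnot(inherits(p, "cthmm_params"))
  ser <- cohort_series(cohort)
  out <- vector("list", length(ser$obs))
  for (k in seq_along(ser$obs)) {
    if (method == "viterbi") {
      st <- .cpp_viterbi(p$rate_matrix, p$emissions, p$initial_dist,
                         ser$obs[[k]], ser$gaps[[k]]) + 1L
    } else {
      fb <- .cpp_forward_backward(p$rate_matrix, p$emissions, p$initial_dist,
                                  ser$obs[[k]], ser$gaps[[k]])
      st <- apply(fb$gamma, 1, which.max)
    }
    out[[k]] <- data.frame(participant_id = ser$ids[k],
                           age_years = ser$ages[[k]], state = st)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' @rdname decode_states
#' @param newdata a [t1d_cohort] to label.
#' @param ... passed on.
#' @export
predict.cthmm <- function(object, newdata, method = "viterbi", ...) {
  decode_states(object, newdata, method = method)
}

# per-series forward log-likelihoods under a parameter set
series_logliks <- function(params, ser) {
  .cpp_loglik(params$rate_matrix, params$emissions, params$initial_dist,
              ser$obs, ser$gaps)
}
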