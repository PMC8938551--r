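# Independent oracles and small fixtures used across the suite.

ANTIBODY_COLS <- c("gada", "iaa", "ia2a")

# random valid rate matrix
random_rate_matrix <- function(S, lo = 0.1, hi = 1.5) {
  Q <- matrix(stats::runif(S * S, lo, hi), S, S)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q
}

random_params <- function(S, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  init <- stats::runif(S, 0.2, 1)
  cthmm_params(init / sum(init), random_rate_matrix(S),
               matrix(stats::runif(S * 3, 0.05, 0.95), S, 3))
}

# brute-force total observation probability by path enumeration
enum_loglik <- function(params, ages, obs) {
  S <- params$n_states
  V <- length(ages)
  Ps <- lapply(seq_len(max(V - 1, 0)), function(v)
    transition_matrix(params$rate_matrix, ages[v + 1] - ages[v]))
  grid <- expand.grid(rep(list(seq_len(S)), V))
  tot <- 0
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    pr <- params$initial_dist[st[1]] *
      emission_likelihood(params$emissions[st[1], ], obs[1, ])
    if (V > 1) {
      for (v in seq_len(V - 1)) {
        pr <- pr * Ps[[v]][st[v], st[v + 1]] *
          emission_likelihood(params$emissions[st[v + 1], ], obs[v + 1, ])
      }
    }
    tot <- tot + pr
  }
  log(tot)
}

# maximum single-path probability by enumeration (Viterbi oracle)
enum_best_path_prob <- function(params, ages, obs) {
  S <- params$n_states
  V <- length(ages)
  Ps <- lapply(seq_len(max(V - 1, 0)), function(v)
    transition_matrix(params$rate_matrix, ages[v + 1] - ages[v]))
  grid <- expand.grid(rep(list(seq_len(S)), V))
  best <- -Inf
  for (r in seq_len(nrow(grid))) {
    st <- as.integer(grid[r, ])
    pr <- params$initial_dist[st[1]] *
      emission_likelihood(params$emissions[st[1], ], obs[1, ])
    if (V > 1) {
      for (v in seq_len(V - 1)) {
        pr <- pr * Ps[[v]][st[v], st[v + 1]] *
          emission_likelihood(params$emissions[st[v + 1], ], obs[v + 1, ])
      }
    }
    best <- max(best, pr)
  }
  best
}

# probability of a specific state path (for Viterbi comparison)
path_prob <- function(params, ages, obs, st) {
  V <- length(ages)
  pr <- params$initial_dist[st[1]] *
    emission_likelihood(params$emissions[st[1], ], obs[1, ])
  if (V > 1) {
    for (v in seq_len(V - 1)) {
      P <- transition_matrix(params$rate_matrix, ages[v + 1] - ages[v])
      pr <- pr * P[st[v], st[v + 1]] *
        emission_likelihood(params$emissions[st[v + 1], ], obs[v + 1, ])
    }
  }
  pr
}

# Monte-Carlo endpoint-conditioned dwell/jump expectations by rejection
# sampling of Markov jump paths
mc_endpoint_stats <- function(Q, dt, start, end, n_samples, seed = 1) {
  set.seed(seed)
  S <- nrow(Q)
  dwell <- numeric(S)
  jumps <- matrix(0, S, S)
  accepted <- 0
  for (i in seq_len(n_samples)) {
    s <- start
    t_now <- 0
    dw <- numeric(S)
    jp <- matrix(0, S, S)
    repeat {
      rate <- -Q[s, s]
      hold <- if (rate > 0) stats::rexp(1, rate) else Inf
      if (t_now + hold >= dt) {
        dw[s] <- dw[s] + dt - t_now
        break
      }
      dw[s] <- dw[s] + hold
      t_now <- t_now + hold
      probs <- Q[s, ]
      probs[s] <- 0
      s_new <- sample.int(S, 1, prob = probs)
      jp[s, s_new] <- jp[s, s_new] + 1
      s <- s_new
    }
    if (s == end) {
      accepted <- accepted + 1
      dwell <- dwell + dw
      jumps <- jumps + jp
    }
  }
  list(dwell = dwell / accepted, jumps = jumps / accepted,
       n_accepted = accepted)
}

# small deterministic cohort fixture for IO and filter tests
toy_cohort <- function() {
  visits <- data.frame(
    participant_id = c("A", "A", "A", "B", "B", "C", "C", "C"),
    age_years = c(0.5, 2.0, 2.5, 1.0, 3.0, 0.75, 1.5, 4.0),
    gada = c(0, 1, 1, 0, 0, NA, 1, 1),
    iaa = c(0, 0, 1, 0, 0, 0, 0, 0),
    ia2a = c(0, 0, 0, NA, 0, 0, 0, 1))
  participants <- data.frame(
    participant_id = c("A", "B", "C"),
    sex = c("M", "F", "F"),
    hla_dr = c("DR3/4", "DR4/X", "DRX/X"),
    diagnosed = c(1, 0, 0),
    diagnosis_age_years = c(3.5, NA, NA),
    last_obs_age_years = c(3.5, 3.0, 4.0))
  t1d_cohort(visits, participants)
}
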