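# EM fitting: closed-form degenerate cases, monotonicity, equivariance,
# sufficient-statistic conservation, decoding, serialization.

small_fit_cohort <- function(n = 40, seed = 5) {
  cfg <- ground_truth_config(n_participants = n, seed = seed)
  co <- simulate_cohort(cfg)
  nv <- table(co$visits$participant_id)
  subset_cohort(co, names(nv)[nv >= 2])
}

test_that("one-state fit recovers empirical positivity fractions", {
  co <- small_fit_cohort()
  fit <- cthmm(co, n_states = 1, n_restarts = 1, max_iter = 10, seed = 1,
               emission_prior = 0)
  v <- co$visits
  emp <- vapply(ANTIBODY_COLS, function(ab) mean(v[[ab]], na.rm = TRUE),
                numeric(1))
  expect_equal(unname(fit$params$emissions[1, ]), unname(emp),
               tolerance = 1e-4)
})

test_that("EM log-likelihood trace is non-decreasing", {
  co <- small_fit_cohort()
  # plain maximum likelihood: the exact EM ascent guarantee
  fit <- cthmm(co, n_states = 4, n_restarts = 2, max_iter = 60,
               tol = 1e-7, seed = 2, emission_prior = 0)
  expect_true(all(diff(fit$loglik_trace) > -1e-6))
  expect_true(fit$loglik >= max(fit$restart_logliks) - 1e-9)
  # under the default weak emission prior the *data* log-likelihood may
  # wiggle at the prior's scale (MAP-EM ascends the penalized
  # objective), but the run still climbs overall
  fit2 <- cthmm(co, n_states = 4, n_restarts = 1, max_iter = 60,
                tol = 1e-7, seed = 2)
  tr <- fit2$loglik_trace
  expect_true(all(diff(tr) > -1e-6))
  expect_gte(tr[length(tr)], tr[1])
})

test_that("expected dwell equals observed follow-up span per participant", {
  co <- small_fit_cohort(n = 15, seed = 8)
  ser <- t1dtraj:::cohort_series(co)
  p <- random_params(3, seed = 4)
  es <- t1dtraj:::.cpp_estep(p$rate_matrix, p$emissions, p$initial_dist,
                             ser$obs, ser$gaps)
  total_span <- sum(vapply(ser$ages, function(a) max(a) - min(a),
                           numeric(1)))
  expect_equal(sum(es$dwell), total_span, tolerance = 1e-6)
  expect_true(all(es$dwell >= -1e-9))
  expect_true(all(es$jumps >= -1e-9))
})

test_that("fit is equivariant under permutation of the initialization", {
  co <- small_fit_cohort(n = 25, seed = 12)
  ser <- t1dtraj:::cohort_series(co)
  p0 <- random_params(3, seed = 42)
  perm <- c(3, 1, 2)
  p0_perm <- cthmm_params(p0$initial_dist[perm],
                          p0$rate_matrix[perm, perm],
                          p0$emissions[perm, ])
  runA <- t1dtraj:::em_run(p0, ser, max_iter = 40, tol = 1e-8)
  runB <- t1dtraj:::em_run(p0_perm, ser, max_iter = 40, tol = 1e-8)
  expect_equal(runA$loglik, runB$loglik, tolerance = 1e-8)
  expect_equal(runA$params$emissions[perm, ], runB$params$emissions,
               tolerance = 1e-8)
})

test_that("parameters of a 3-state chain are recovered from simulated data", {
  em3 <- rbind(c(0.05, 0.05, 0.05),
               c(0.90, 0.70, 0.10),
               c(0.20, 0.10, 0.95))
  cfg <- ground_truth_config(
    n_participants = 500, chain_weights = 1, chain_sizes = 3,
    emission_table = em3, rate_scale = c(2, 3, Inf),
    diagnosis_hazards = c(0, 0.05, 0.1), missingness_rate = 0.05,
    seed = 77)
  co <- simulate_cohort(cfg)
  nv <- table(co$visits$participant_id)
  co <- subset_cohort(co, names(nv)[nv >= 2])
  fit <- cthmm(co, n_states = 3, n_restarts = 3, max_iter = 300,
               tol = 1e-6, seed = 3)
  m <- match_states(em3, fit$params$emissions)
  expect_equal(unname(fit$params$emissions[m, ]), unname(em3),
               tolerance = 0.05)
})

test_that("Viterbi decoding attains the enumerated best path probability", {
  for (s in 1:20) {
    set.seed(300 + s)
    p <- random_params(2)
    ages <- sort(runif(3, 0.2, 5))
    while (any(diff(ages) < 1e-3)) ages <- sort(runif(3, 0.2, 5))
    obs <- matrix(sample(c(0L, 1L, NA), 9, replace = TRUE,
                         prob = c(0.45, 0.45, 0.1)), 3, 3)
    co <- t1d_cohort(
      data.frame(participant_id = "X", age_years = ages,
                 gada = obs[, 1], iaa = obs[, 2], ia2a = obs[, 3]),
      data.frame(participant_id = "X", sex = "M", hla_dr = "DR3/4",
                 diagnosed = 0, diagnosis_age_years = NA,
                 last_obs_age_years = max(ages)))
    lab <- decode_states(p, co)
    expect_equal(path_prob(p, ages, obs, lab$state),
                 enum_best_path_prob(p, ages, obs), tolerance = 1e-10)
  }
})

test_that("single-state decoding labels every visit with that state", {
  p1 <- cthmm_params(1, matrix(0, 1, 1), matrix(0.5, 1, 3))
  co <- toy_cohort()
  lab <- decode_states(p1, co)
  expect_true(all(lab$state == 1))
  # posterior decoding agrees with Viterbi on a 1-state model
  lab2 <- decode_states(p1, co, method = "posterior")
  expect_identical(lab$state, lab2$state)
})

test_that("BIC uses the visit-count convention and the free-parameter formula", {
  expect_equal(cthmm_bic(0, 1, 1), 0)
  # S = 2: k = 1 + 2 + 6 = 9
  expect_equal(cthmm_bic(-10, 2, exp(1)), 20 + 9)
  co <- small_fit_cohort(n = 30, seed = 21)
  fit <- cthmm(co, n_states = 2, n_restarts = 1, max_iter = 30, seed = 1)
  expect_equal(BIC(fit),
               cthmm_bic(fit$loglik, 2, nrow(co$visits)),
               tolerance = 1e-9)
})

test_that("model JSON serialization round-trips bit-exactly", {
  co <- small_fit_cohort(n = 20, seed = 3)
  fit <- cthmm(co, n_states = 3, n_restarts = 1, max_iter = 20, seed = 9)
  path <- tempfile(fileext = ".json")
  write_cthmm(fit, path)
  back <- read_cthmm(path)
  expect_identical(back$initial_dist, fit$params$initial_dist)
  expect_identical(back$rate_matrix, unname(fit$params$rate_matrix))
  expect_identical(back$emissions, unname(fit$params$emissions))
})

test_that("fit rejects invalid inputs", {
  co <- toy_cohort()
  # add a single-visit participant: transitions cannot be estimated
  co1 <- co
  co1$visits <- rbind(co1$visits,
                      data.frame(participant_id = "E", age_years = 1,
                                 gada = 1, iaa = 0, ia2a = 0))
  co1$participants <- rbind(co1$participants,
                            data.frame(participant_id = "E", sex = "M",
                                       hla_dr = "DR4/X", diagnosed = 0,
                                       diagnosis_age_years = NA,
                                       last_obs_age_years = 1))
  expect_error(cthmm(co1, n_states = 3), "fewer than 2 visits")
  co2 <- subset_cohort(co, c("A", "C"))
  expect_error(cthmm(co2, n_states = 50), "cap")
  expect_error(cthmm(list(obs = list(), gaps = list()), n_states = 2),
               "empty")
})

test_that("duplicate-age visits merge with conflict detection", {
  v <- data.frame(participant_id = c("A", "A", "A"),
                  age_years = c(1, 1, 2),
                  gada = c(1, NA, 0), iaa = c(NA, 0, 0),
                  ia2a = c(NA, NA, 1))
  p <- data.frame(participant_id = "A", sex = "M", hla_dr = "DR3/4",
                  diagnosed = 0, diagnosis_age_years = NA,
                  last_obs_age_years = 2)
  expect_error(t1d_cohort(v, p), "duplicate")
  co <- merge_duplicate_visits(structure(list(visits = v,
                                              participants = p),
                                         class = "t1d_cohort"))
  expect_equal(nrow(co$visits), 2)
  expect_equal(co$visits$gada[1], 1)
  expect_equal(co$visits$iaa[1], 0)
  expect_true(is.na(co$visits$ia2a[1]))
  v2 <- v
  v2$gada[2] <- 0
  expect_error(merge_duplicate_visits(
    structure(list(visits = v2, participants = p), class = "t1d_cohort")),
    "conflicting")
})
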