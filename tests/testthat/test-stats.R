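# Downstream statistics: chi-square, ANOVA/Tukey, Kaplan-Meier, log-rank,
# survival dataset construction.

test_that("chi-square equals the direct textbook summation", {
  direct <- function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }
  for (s in 1:20) {
    set.seed(400 + s)
    m <- matrix(rpois(12, lambda = 20) + 1, 3, 4)
    res <- chi_square(m)
    expect_equal(res$statistic, direct(m), tolerance = 1e-10)
    expect_equal(res$df, 6)
    expect_equal(res$p_value, pchisq(direct(m), 6, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # proportional rows: statistic 0
  m0 <- rbind(c(10, 20, 30), c(20, 40, 60))
  expect_equal(chi_square(m0)$statistic, 0, tolerance = 1e-10)
  expect_error(chi_square(rbind(c(0, 0), c(1, 2))), "zero margin")
  expect_error(chi_square(matrix(1, 1, 3)), "at least 2")
})

test_that("published cohort composition reproduces the printed chi-square statistics", {
  tab <- t1di_table1()
  sex <- chi_square(tab$sex)
  expect_equal(sex$statistic, 10.59, tolerance = 0.005)
  expect_equal(sex$df, 5)
  expect_equal(sex$n, 2145)
  expect_equal(round(sex$p_value, 4), 0.0602, tolerance = 0.001)
  hla <- chi_square(tab$hla_dr[setdiff(rownames(tab$hla_dr), "Unknown"), ])
  expect_equal(hla$statistic, 161.53, tolerance = 0.05)
  expect_equal(hla$df, 15)
})

test_that("one-way ANOVA matches the hand-worked sums of squares", {
  g <- list(a = c(6, 8, 4, 5, 3, 4),
            b = c(8, 12, 9, 11, 6, 8),
            c = c(13, 9, 11, 8, 7, 12))
  # hand computation: SSB = sum n_i (mean_i - grand)^2, SSW = sum within
  means <- vapply(g, mean, numeric(1))
  grand <- mean(unlist(g))
  ssb <- sum(6 * (means - grand)^2)
  ssw <- sum(vapply(g, function(x) sum((x - mean(x))^2), numeric(1)))
  f_hand <- (ssb / 2) / (ssw / 15)
  res <- anova_tukey(g)
  expect_equal(res$test$statistic, f_hand, tolerance = 1e-6)
  expect_equal(res$test$df, c(2, 15))
  expect_equal(nrow(res$pairwise), 3)
  expect_true(all(res$pairwise$p_adj >= 0 & res$pairwise$p_adj <= 1))
  # identical group means: F = 0
  res0 <- anova_tukey(list(x = c(1, 2, 3), y = c(2, 1, 3)))
  expect_equal(res0$test$statistic, 0, tolerance = 1e-12)
  expect_error(anova_tukey(list(x = 1, y = c(1, 2))), "at least 2 values")
})

test_that("Kaplan-Meier estimate matches hand-worked product-limit tables", {
  # no events: survival 1 everywhere
  d0 <- data.frame(time = c(1, 2, 3), event = 0, stratum = "s")
  f0 <- km_estimate(d0)
  expect_true(all(f0$surv == 1))
  # all events, no censoring: empirical survival function
  d1 <- data.frame(time = c(1, 2, 3), event = 1, stratum = "s")
  f1 <- km_estimate(d1)
  expect_equal(summary(f1, times = 2.5)$surv, 1 / 3, tolerance = 1e-12)
  # interleaved censoring, hand-worked:
  # times 1(e) 2(c) 3(e) 4(e) 5(c): S(1)=4/5, S(3)=4/5*2/3, S(4)=4/15*1/2...
  d2 <- data.frame(time = c(1, 2, 3, 4, 5),
                   event = c(1, 0, 1, 1, 0), stratum = "s")
  f2 <- km_estimate(d2)
  expect_equal(summary(f2, times = 1)$surv, 4 / 5, tolerance = 1e-12)
  expect_equal(summary(f2, times = 3)$surv, 4 / 5 * 2 / 3,
               tolerance = 1e-12)
  expect_equal(summary(f2, times = 4.5)$surv, 4 / 5 * 2 / 3 * 1 / 2,
               tolerance = 1e-12)
  # with no censoring the estimate is the empirical survival function
  set.seed(11)
  tt <- rexp(40)
  d3 <- data.frame(time = tt, event = 1, stratum = "s")
  f3 <- km_estimate(d3)
  at <- quantile(tt, c(0.25, 0.5, 0.9))
  for (a in at)
    expect_equal(summary(f3, times = a)$surv, mean(tt > a),
                 tolerance = 1e-12)
})

test_that("survival_at reads the right-continuous step function", {
  d <- data.frame(time = c(1, 2, 3), event = c(1, 1, 1), stratum = "s")
  f <- km_estimate(d)
  expect_equal(survival_at(f, 0)$estimate, 1)
  expect_equal(survival_at(f, 2.5)$estimate, 1 / 3)
  out <- survival_at(f, 10)
  expect_true(out$extrapolated)
  expect_equal(out$estimate, 0)
  expect_false(survival_at(f, 2.5)$extrapolated)
  expect_error(survival_at(f, -1), "nonnegative")
})

test_that("log-rank separates extreme strata and is scale-invariant", {
  set.seed(5)
  early <- data.frame(time = runif(50, 0, 1), event = 1, stratum = "a")
  none <- data.frame(time = rep(10, 50), event = 0, stratum = "b")
  res <- log_rank(rbind(early, none))
  expect_lt(res$overall$p_value, 0.001)
  expect_equal(res$overall$df, 1)
  # identical strata (duplicated data): statistic 0
  dup <- rbind(transform(early, stratum = "a"),
               transform(early, stratum = "b"))
  expect_equal(log_rank(dup)$overall$statistic, 0, tolerance = 1e-9)
  # invariance to time rescaling
  set.seed(6)
  d <- data.frame(time = rexp(60, rep(c(1, 2), each = 30)),
                  event = rbinom(60, 1, 0.8),
                  stratum = rep(c("a", "b"), each = 30))
  r1 <- log_rank(d)
  d2 <- transform(d, time = time * 365.25)
  r2 <- log_rank(d2)
  expect_equal(r1$overall$statistic, r2$overall$statistic,
               tolerance = 1e-10)
  expect_error(log_rank(data.frame(time = 1:3, event = 1,
                                   stratum = "only")), "2 strata")
  # pairwise table covers all pairs
  d3 <- rbind(d, transform(early, stratum = "c"))
  r3 <- log_rank(d3)
  expect_equal(nrow(r3$pairwise), 3)
})

test_that("ANOVA and log-rank hold their nominal type-I error under the null", {
  set.seed(13)
  n_reps <- 1000
  rej_f <- 0
  rej_lr <- 0
  for (i in seq_len(n_reps)) {
    g <- list(a = rnorm(15), b = rnorm(15), c = rnorm(15))
    if (anova_tukey(g)$test$p_value < 0.05) rej_f <- rej_f + 1
    d <- data.frame(time = rexp(60, 0.5),
                    event = rbinom(60, 1, 0.7),
                    stratum = rep(c("x", "y"), each = 30))
    if (log_rank(d)$overall$p_value < 0.05) rej_lr <- rej_lr + 1
  }
  expect_gt(rej_f / n_reps, 0.03)
  expect_lt(rej_f / n_reps, 0.07)
  expect_gt(rej_lr / n_reps, 0.03)
  expect_lt(rej_lr / n_reps, 0.07)
})

test_that("survival datasets measure time from reference-state entry", {
  lab <- data.frame(
    participant_id = rep(c("a", "b", "c"), each = 3),
    age_years = rep(c(1, 3, 6), 3),
    state = c(1, 2, 2,   1, 1, 1,   1, 2, 3))
  asg <- data.frame(participant_id = c("a", "b", "c"),
                    chain = 1, ambiguous = FALSE)
  Q <- matrix(0, 3, 3); Q[1, 2] <- 1; Q[2, 3] <- 1
  diag(Q) <- -rowSums(Q)
  p <- cthmm_params(c(1, 0, 0), Q,
                    rbind(c(0.05, 0.05, 0.05), c(0.9, 0.2, 0.1),
                          c(0.9, 0.1, 0.9)))
  traj <- decompose_trajectories(
    p, data.frame(participant_id = "z", age_years = 1, state = 1))
  co <- t1d_cohort(
    data.frame(participant_id = rep(c("a", "b", "c"), each = 3),
               age_years = rep(c(1, 3, 6), 3),
               gada = 0, iaa = 0, ia2a = 0),
    data.frame(participant_id = c("a", "b", "c"),
               sex = c("M", "F", "M"),
               hla_dr = c("DR3/4", "DR4/X", "DR3/X"),
               diagnosed = c(1, 0, 0),
               diagnosis_age_years = c(7, NA, NA),
               last_obs_age_years = c(7, 6, 6)))
  sv <- build_survival_dataset(asg, lab, co, traj,
                               reference = "first_positive",
                               strata = "chain")
  # participant a entered state 2 at age 3, diagnosed at 7: time 4, event
  expect_equal(sv$time[sv$participant_id == "a"], 4)
  expect_equal(sv$event[sv$participant_id == "a"], 1)
  # participant b never entered the reference state: excluded and counted
  expect_false("b" %in% sv$participant_id)
  expect_equal(attr(sv, "exclusions")$never_in_reference, 1)
  # median split produces near-equal strata
  fx_lab <- data.frame(
    participant_id = rep(sprintf("p%02d", 1:20), each = 2),
    age_years = as.vector(rbind(seq(1, 4.8, 0.2), seq(6, 9.8, 0.2))),
    state = rep(c(1, 2), 20))
  fx_asg <- data.frame(participant_id = sprintf("p%02d", 1:20),
                       chain = 1, ambiguous = FALSE)
  fx_co <- t1d_cohort(
    data.frame(participant_id = fx_lab$participant_id,
               age_years = fx_lab$age_years, gada = 0, iaa = 0, ia2a = 0),
    data.frame(participant_id = sprintf("p%02d", 1:20), sex = "M",
               hla_dr = "DR3/4", diagnosed = 0,
               diagnosis_age_years = NA, last_obs_age_years = 10))
  sv2 <- build_survival_dataset(fx_asg, fx_lab, fx_co, traj,
                                strata = "entry_age_median")
  sizes <- table(sv2$stratum)
  expect_lte(abs(diff(as.numeric(sizes))), 1)
  expect_error(build_survival_dataset(asg, lab, co, traj,
                                      reference = "TR9-9"),
               "absent")
})
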