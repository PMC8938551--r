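# Trajectory decomposition, participant assignment, seroconversion, and
# pattern composition.

# labeled cohort where the truth is known: decode the simulated cohort
# with the generating parameters
labeled_fixture <- function(n = 300, seed = 19) {
  cfg <- ground_truth_config(n_participants = n, seed = seed)
  co <- simulate_cohort(cfg)
  nv <- table(co$visits$participant_id)
  co <- subset_cohort(co, names(nv)[nv >= 2])
  p <- make_ground_truth_model(cfg)
  list(cohort = co, params = p, labelings = decode_states(p, co),
       config = cfg)
}

test_that("block-structured rate matrices decompose into their chains", {
  fx <- labeled_fixture(n = 150, seed = 23)
  traj <- decompose_trajectories(fx$params, fx$labelings)
  expect_equal(length(traj$chains), 3)
  expect_setequal(lengths(traj$chains), c(3, 5, 3))
  # naming: TR1 multiple-first, TR2 IAA-first, TR3 GADA-first
  post_start <- vapply(traj$chains, `[`, integer(1), 2)
  em <- fx$params$emissions
  expect_equal(unname(em[post_start[1], ]), c(0.93, 0.62, 0.94))
  expect_equal(unname(em[post_start[2], 2]), 0.86)
  expect_equal(unname(em[post_start[3], 1]), 0.98)
  # j = 0 names each chain start
  expect_equal(traj$state_names[traj$start_states],
               c("TR1-0", "TR2-0", "TR3-0"))
  # two-block toy matrix gives two chains
  Q <- matrix(0, 4, 4)
  Q[1, 2] <- 1; Q[3, 4] <- 1
  diag(Q) <- -rowSums(Q)
  em4 <- rbind(c(0.05, 0.05, 0.05), c(0.9, 0.9, 0.9),
               c(0.1, 0.1, 0.1), c(0.2, 0.9, 0.1))
  p4 <- cthmm_params(c(0.5, 0, 0.5, 0), Q, em4)
  lab4 <- data.frame(participant_id = c("a", "a", "b", "b"),
                     age_years = c(1, 2, 1, 2), state = c(1, 2, 3, 4))
  traj4 <- decompose_trajectories(p4, lab4)
  expect_equal(length(traj4$chains), 2)
  expect_false(traj4$degenerate)
})

test_that("a threshold above all rates flags a degenerate decomposition", {
  fx <- labeled_fixture(n = 60, seed = 29)
  traj <- decompose_trajectories(fx$params, fx$labelings,
                                 rate_threshold = 10)
  expect_equal(length(traj$chains), 11)
  expect_true(traj$degenerate)
})

test_that("naming is stable under permutation of state indices", {
  fx <- labeled_fixture(n = 150, seed = 31)
  perm <- c(4, 9, 1, 7, 2, 11, 3, 8, 10, 5, 6)
  inv <- order(perm)
  pp <- cthmm_params(fx$params$initial_dist[perm],
                     fx$params$rate_matrix[perm, perm],
                     fx$params$emissions[perm, ])
  labp <- fx$labelings
  labp$state <- inv[labp$state]
  trajA <- decompose_trajectories(fx$params, fx$labelings)
  trajB <- decompose_trajectories(pp, labp)
  expect_equal(lengths(trajA$chains), lengths(trajB$chains))
  asgA <- assign_participants(fx$labelings, trajA)
  asgB <- assign_participants(labp, trajB)
  expect_equal(asgA$chain, asgB$chain)
  expect_equal(asgA$state_sequence, asgB$state_sequence)
})

test_that("participants are assigned to chains with ambiguity exclusion", {
  fx <- labeled_fixture()
  traj <- decompose_trajectories(fx$params, fx$labelings)
  asg <- assign_participants(fx$labelings, traj, cohort = fx$cohort)
  expect_true(all(is.na(asg$chain[asg$ambiguous])))
  expect_true(all(!is.na(asg$chain[!asg$ambiguous])))
  # chains are disjoint by construction; decoding errors are rare
  expect_lte(mean(asg$ambiguous), 0.05)
  # noiseless labels (the generator's true states) recover the chain of
  # origin exactly
  tv <- attr(fx$cohort, "truth")$visit_states
  lab_true <- data.frame(participant_id = tv$participant_id,
                         age_years = tv$age_years, state = tv$true_state)
  asg_true <- assign_participants(lab_true, traj)
  truth <- attr(fx$cohort, "truth")$chains
  expect_equal(asg_true$chain,
               truth$chain[match(asg_true$participant_id,
                                 truth$participant_id)])
  # decoding the Bernoulli observations with the true parameters still
  # recovers the chain for the vast majority
  ok <- asg[!asg$ambiguous, ]
  agree <- mean(ok$chain ==
                  truth$chain[match(ok$participant_id,
                                    truth$participant_id)])
  expect_gte(agree, 0.9)
  # first-positive entry age never precedes the first visit
  first_visit <- tapply(fx$cohort$visits$age_years,
                        fx$cohort$visits$participant_id, min)
  has <- !is.na(asg$first_positive_entry_age)
  expect_true(all(asg$first_positive_entry_age[has] >=
                    as.numeric(first_visit[asg$participant_id[has]]) - 1e-9))
  # hand-built two-chain paths
  lab <- data.frame(participant_id = c("u", "u", "v", "v"),
                    age_years = c(1, 2, 1, 2),
                    state = c(1, 2, 1, 9))
  asg2 <- assign_participants(lab, traj)
  expect_equal(asg2$chain[asg2$participant_id == "u"], 1)
  expect_true(asg2$ambiguous[asg2$participant_id == "v"])
})

test_that("seroconversion requires same-antibody persistence by default", {
  mkv <- function(...) {
    m <- rbind(...)
    data.frame(age_years = m[, 1], gada = m[, 2], iaa = m[, 3],
               ia2a = m[, 4])
  }
  # GADA+ at 2.0 and 2.5: seroconversion at 2.0
  v <- mkv(c(2.0, 1, 0, 0), c(2.5, 1, 0, 0))
  expect_equal(seroconversion_age(v), 2.0)
  # never positive
  v2 <- mkv(c(1, 0, 0, 0), c(2, 0, 0, 0))
  expect_true(is.na(seroconversion_age(v2)))
  # different antibodies at consecutive visits: no event under the
  # same-antibody rule, an event under the any-antibody rule
  v3 <- mkv(c(2.0, 1, 0, 0), c(2.5, 0, 1, 0))
  expect_true(is.na(seroconversion_age(v3)))
  expect_equal(seroconversion_age(v3, rule = "any_antibody"), 2.0)
  # missing values do not count as positive
  v4 <- mkv(c(1, NA, 0, 0), c(2, 1, 0, 0), c(3, 1, 0, 0))
  expect_equal(seroconversion_age(v4), 2)
})

test_that("state entry ages summarize decoded visits", {
  lab <- data.frame(participant_id = c("a", "a", "b", "b", "c"),
                    age_years = c(1, 3, 2, 5, 3),
                    state = c(1, 2, 1, 2, 2))
  asg <- data.frame(participant_id = c("a", "b", "c"),
                    chain = 1, ambiguous = FALSE)
  tab <- state_entry_ages(asg, lab)
  expect_equal(tab$n_entered[1:2], c(2, 3))
  expect_equal(tab$median_entry_age[1], 1.5)
  expect_equal(tab$median_entry_age[2], 3)
  # diagnosed enter earlier than undiagnosed under the default hazards
  fx <- labeled_fixture(n = 400, seed = 41)
  traj <- decompose_trajectories(fx$params, fx$labelings)
  asg2 <- assign_participants(fx$labelings, traj)
  tab2 <- state_entry_ages(asg2, fx$labelings, fx$cohort, traj)
  comp <- tab2[!is.na(tab2$median_entry_age_diagnosed) &
                 !is.na(tab2$median_entry_age_undiagnosed) &
                 tab2$n_entered >= 30, ]
  expect_true(mean(comp$median_entry_age_diagnosed <=
                     comp$median_entry_age_undiagnosed + 0.5) >= 0.7)
})

test_that("pattern-by-age composition identifies the dominant trajectories", {
  fx <- labeled_fixture(n = 2000, seed = 43)
  traj <- decompose_trajectories(fx$params, fx$labelings)
  asg <- assign_participants(fx$labelings, traj)
  pat <- pattern_by_age(asg, fx$cohort)
  expect_true(all(pat$age_bin %in% 2:7))
  props <- pat[, c("TR1", "TR2", "TR3")]
  nonempty <- pat$n > 0
  expect_equal(unname(rowSums(props[nonempty, ])),
               rep(1, sum(nonempty)), tolerance = 1e-9)
  expect_true(all(is.na(props[!nonempty, ])))
  # IAA-only visits belong predominantly to the IAA-first trajectory:
  # plurality in every usable bin, outright majority where the pattern is
  # common (young ages; older IAA-only bins are mostly background noise)
  iaa_only <- pat[pat$pattern == "IAA+" & pat$n >= 10, ]
  expect_true(all(iaa_only$TR2 > iaa_only$TR1 &
                    iaa_only$TR2 > iaa_only$TR3))
  expect_true(all(iaa_only$TR2[iaa_only$n >= 40] > 0.5))
  # GADA-only visits belong overwhelmingly to the GADA-first trajectory
  gada_only <- pat[pat$pattern == "GADA+" & pat$n >= 40, ]
  expect_true(all(gada_only$TR3 > 0.6))
})
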