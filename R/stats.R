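#' Pearson chi-square test of association
#'
#' Two-sided Pearson chi-square on a contingency table of counts, without
#' continuity correction; expected counts from the row/column margins,
#' `df = (rows - 1)(cols - 1)`.
#'
#' @param counts matrix of nonnegative counts with at least 2 rows and 2
#'   columns.
#' @return list of class `t1d_test` with `statistic`, `df`, `p_value`,
#'   `n`, `method`.
#' @export
chi_square <- function(counts) {
  counts <- as.matrix(counts)
  if (nrow(counts) < 2 || ncol(counts) < 2)
    stop("contingency table needs at least 2 rows and 2 columns")
  if (any(counts < 0)) stop("counts must be nonnegative")
  rz <- rowSums(counts) == 0
  cz <- colSums(counts) == 0
  if (any(rz))
    stop("zero margin in row(s): ",
         paste(rownames(counts)[rz] %||% which(rz), collapse = ", "))
  if (any(cz))
    stop("zero margin in column(s): ",
         paste(colnames(counts)[cz] %||% which(cz), collapse = ", "))
  ht <- stats::chisq.test(counts, correct = FALSE)
  structure(list(statistic = unname(ht$statistic),
                 df = unname(ht$parameter),
                 p_value = unname(ht$p.value),
                 n = sum(counts),
                 method = "Pearson chi-square (no continuity correction)"),
            class = "t1d_test")
}

#' @export
print.t1d_test <- function(x, ...) {
  dftxt <- paste(x$df, collapse = ", ")
  cat(sprintf("%s\n  statistic = %.4g, df = %s, p = %.4g%s\n", x$method,
              x$statistic, dftxt, x$p_value,
              if (!is.null(x$n)) sprintf(", n = %d", x$n) else ""))
  invisible(x)
}

#' One-way ANOVA with Tukey HSD post-hoc comparisons
#'
#' Two-sided one-way analysis of variance across groups, followed by
#' Tukey honest-significant-difference pairwise comparisons (studentized
#' range adjustment; no further multiplicity correction).
#'
#' @param groups named list of numeric vectors, one per group, each with
#'   at least 2 values.
#' @return list with `test` (a `t1d_test` carrying the F statistic and
#'   its two df) and `pairwise` (data frame of Tukey comparisons:
#'   difference, interval, adjusted p).
#' @export
anova_tukey <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2))
    stop("every group needs at least 2 values")
  nm <- names(groups) %||% paste0("g", seq_along(groups))
  df <- data.frame(value = unlist(groups, use.names = FALSE),
                   group = factor(rep(nm, vapply(groups, length,
                                                 integer(1)))))
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  pairwise <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                         lwr = tk[, "lwr"], upr = tk[, "upr"],
                         p_adj = tk[, "p adj"], row.names = NULL)
  test <- structure(list(statistic = an[["F value"]][1],
                         df = c(an[["Df"]][1], an[["Df"]][2]),
                         p_value = an[["Pr(>F)"]][1],
                         n = nrow(df),
                         method = "One-way ANOVA"),
                    class = "t1d_test")
  list(test = test, pairwise = pairwise)
}

#' Kaplan-Meier diabetes-free survival curves
#'
#' Product-limit estimator per stratum with Greenwood variance and
#' log-log transformed 95 percent confidence intervals (clipped to
#' [0, 1]); ties handled by the simultaneous-death convention.
#'
#' @param data survival data frame with columns `time` (years from entry
#'   into the reference state), `event` (1 = diagnosis), `stratum`.
#' @param conf_level confidence level.
#' @return a [survival::survfit] object.
#' @export
km_estimate <- function(data, conf_level = 0.95) {
  check_survival_data(data)
  if (length(unique(data$stratum)) > 1) {
    survival::survfit(survival::Surv(time, event) ~ stratum, data = data,
                      conf.type = "log-log", conf.int = conf_level)
  } else {
    survival::survfit(survival::Surv(time, event) ~ 1, data = data,
                      conf.type = "log-log", conf.int = conf_level)
  }
}

check_survival_data <- function(data) {
  stopifnot(all(c("time", "event", "stratum") %in% names(data)))
  if (!nrow(data)) stop("empty survival dataset")
  if (any(data$time < 0)) stop("survival times must be nonnegative")
  invisible(data)
}

#' Survival curve table
#'
#' Tidy per-stratum step-function table of a Kaplan-Meier fit.
#'
#' @param fit a [survival::survfit] object.
#' @return data frame `stratum`, `time`, `at_risk`, `events`, `survival`,
#'   `ci_low`, `ci_high`.
#' @export
km_table <- function(fit) {
  s <- summary(fit)
  strat <- if (is.null(s$strata)) "all" else sub("^stratum=", "",
                                                 as.character(s$strata))
  data.frame(stratum = strat, time = s$time, at_risk = s$n.risk,
             events = s$n.event, survival = s$surv,
             ci_low = pmax(s$lower, 0), ci_high = pmin(s$upper, 1))
}

#' Survival probability at a time point
#'
#' Right-continuous step-function value of each stratum's Kaplan-Meier
#' curve at time `t` with its confidence interval. When `t` exceeds a
#' stratum's last observed time the last value is returned, flagged
#' extrapolated.
#'
#' @param fit a [survival::survfit] object from [km_estimate()].
#' @param t time in years (nonnegative).
#' @return data frame `stratum`, `time`, `estimate`, `ci_low`, `ci_high`,
#'   `extrapolated`.
#' @export
survival_at <- function(fit, t) {
  if (t < 0) stop("t must be nonnegative")
  s <- summary(fit, times = t, extend = TRUE)
  strat <- if (is.null(s$strata)) "all" else sub("^stratum=", "",
                                                 as.character(s$strata))
  maxt <- if (is.null(fit$strata)) max(fit$time)
          else tapply(fit$time, rep(names(fit$strata), fit$strata), max)[
            sub("^stratum=", "", names(fit$strata))]
  if (is.null(fit$strata)) {
    extra <- t > maxt
  } else {
    extra <- as.numeric(t > maxt)[match(strat,
                                        sub("^stratum=", "",
                                            names(fit$strata)))] > 0
  }
  data.frame(stratum = strat, time = t, estimate = s$surv,
             ci_low = ifelse(is.na(s$lower), NA, pmax(s$lower, 0)),
             ci_high = ifelse(is.na(s$upper), NA, pmin(s$upper, 1)),
             extrapolated = extra)
}

#' Log-rank tests across survival strata
#'
#' Overall two-sided log-rank chi-square across all strata
#' (df = strata - 1), plus unadjusted pairwise tests on each stratum
#' pair.
#'
#' @param data survival data frame (`time`, `event`, `stratum`).
#' @return list with `overall` (a `t1d_test`) and `pairwise` (data frame
#'   of per-pair statistics and p-values).
#' @export
log_rank <- function(data) {
  check_survival_data(data)
  strata <- sort(unique(as.character(data$stratum)))
  if (length(strata) < 2) stop("log-rank needs at least 2 strata")
  sd <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                           data = data)
  df <- length(strata) - 1
  overall <- structure(list(statistic = unname(sd$chisq), df = df,
                            p_value = stats::pchisq(sd$chisq, df,
                                                    lower.tail = FALSE),
                            n = nrow(data),
                            method = "Log-rank test"),
                       class = "t1d_test")
  pairs <- utils::combn(strata, 2)
  pw <- lapply(seq_len(ncol(pairs)), function(i) {
    d <- data[data$stratum %in% pairs[, i], , drop = FALSE]
    s2 <- survival::survdiff(survival::Surv(time, event) ~ stratum,
                             data = d)
    data.frame(stratum_a = pairs[1, i], stratum_b = pairs[2, i],
               statistic = unname(s2$chisq),
               p_value = stats::pchisq(s2$chisq, 1, lower.tail = FALSE))
  })
  list(overall = overall, pairwise = do.call(rbind, pw))
}

#' Build a survival dataset from trajectory assignments
#'
#' Time is measured from each participant's first entry (decoded visit)
#' into a reference state to diagnosis or censoring at last observation;
#' the event is diagnosis. Participants never decoded into a reference
#' state, and ambiguous participants, are excluded and counted.
#'
#' @param assignments from [assign_participants()].
#' @param labelings from [decode_states()].
#' @param cohort a [t1d_cohort].
#' @param traj_model a `trajectory_model` (for state names).
#' @param reference `"first_positive"` (each chain's state j = 1) or a
#'   character vector of state names such as
#'   `c("TR1-1", "TR2-4", "TR3-2")`.
#' @param strata stratification: `"chain"`, `"sex"`, `"hla_dr"` (DR3/4 vs
#'   DR4/X; others dropped), `"entry_age_median"` (before/after the
#'   cohort's median reference-entry age), or `"reference_state"`.
#' @return data frame `participant_id`, `time`, `event`, `stratum`,
#'   `entry_age`; exclusion counts in attribute `"exclusions"`.
#' @export
build_survival_dataset <- function(assignments, labelings, cohort,
                                   traj_model,
                                   reference = "first_positive",
                                   strata = c("chain", "sex", "hla_dr",
                                              "entry_age_median",
                                              "reference_state")) {
  strata <- match.arg(strata)
  if (identical(reference, "first_positive")) {
    ref_states <- vapply(traj_model$chains, function(ch)
      if (length(ch) > 1) ch[2] else NA_integer_, integer(1))
    ref_states <- ref_states[!is.na(ref_states)]
  } else {
    ref_states <- match(reference, traj_model$state_names)
    if (anyNA(ref_states))
      stop("reference state(s) absent from model: ",
           paste(reference[is.na(ref_states)], collapse = ", "))
  }
  ok <- assignments[!assignments$ambiguous, , drop = FALSE]
  lab <- labelings[labelings$participant_id %in% ok$participant_id &
                     labelings$state %in% ref_states, , drop = FALSE]
  entry <- stats::aggregate(age_years ~ participant_id, data = lab,
                            FUN = min)
  first_rows <- lab[order(lab$participant_id, lab$age_years), ]
  first_rows <- first_rows[!duplicated(first_rows$participant_id), ]
  p <- cohort$participants
  idx <- match(entry$participant_id, p$participant_id)
  end_age <- ifelse(p$diagnosed[idx] == 1, p$diagnosis_age_years[idx],
                    p$last_obs_age_years[idx])
  out <- data.frame(participant_id = entry$participant_id,
                    time = pmax(end_age - entry$age_years, 0),
                    event = p$diagnosed[idx],
                    entry_age = entry$age_years)
  out$reference_state <-
    traj_model$state_names[first_rows$state[
      match(out$participant_id, first_rows$participant_id)]]
  out$chain <- ok$chain[match(out$participant_id, ok$participant_id)]
  out$stratum <- switch(
    strata,
    chain = paste0("TR", out$chain),
    sex = p$sex[idx],
    hla_dr = ifelse(p$hla_dr[idx] %in% c("DR3/4", "DR4/X"), p$hla_dr[idx],
                    NA_character_),
    entry_age_median = {
      med <- stats::median(out$entry_age)
      ifelse(out$entry_age <= med, sprintf("entry<=%.2fy", med),
             sprintf("entry>%.2fy", med))
    },
    reference_state = out$reference_state)
  dropped_na <- sum(is.na(out$stratum))
  out <- out[!is.na(out$stratum), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "exclusions") <- list(
    ambiguous = sum(assignments$ambiguous),
    never_in_reference = sum(!ok$participant_id %in% entry$participant_id),
    missing_stratum = dropped_na)
  out
}
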