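#' Longitudinal autoantibody cohort
#'
#' Container for a longitudinal islet-autoantibody cohort: a visits table
#' (one row per participant visit with age and GADA/IAA/IA-2A positivity)
#' and a participants table (sex, HLA-DR category, diagnosis outcome).
#'
#' @param visits data frame with columns `participant_id` (character),
#'   `age_years` (numeric), and `gada`, `iaa`, `ia2a` coded 0/1/NA.
#' @param participants data frame with columns `participant_id`, `sex`
#'   (`"M"`/`"F"`), `hla_dr` (one of `"DR3/4"`, `"DR4/X"`, `"DR3/X"`,
#'   `"DRX/X"`, `"Unknown"`), `diagnosed` (0/1), `diagnosis_age_years`
#'   (numeric, NA unless diagnosed), `last_obs_age_years` (numeric).
#' @return object of class `t1d_cohort`.
#' @export
t1d_cohort <- function(visits, participants) {
  visits <- as.data.frame(visits)
  participants <- as.data.frame(participants)
  obj <- structure(list(visits = visits, participants = participants),
                   class = "t1d_cohort")
  validate_cohort(obj)
  obj
}

#' Validate a cohort object
#'
#' Checks the visit/participant schemas: required columns, value ranges,
#' referential integrity, strictly increasing ages, no duplicate
#' (participant, age) rows, and outcome consistency. Errors name the
#' offending rows.
#'
#' @param cohort a [t1d_cohort] object.
#' @return the cohort, invisibly, if valid.
#' @export
validate_cohort <- function(cohort) {
  v <- cohort$visits
  p <- cohort$participants
  need_v <- c("participant_id", "age_years", ANTIBODIES)
  need_p <- c("participant_id", "sex", "hla_dr", "diagnosed",
              "diagnosis_age_years", "last_obs_age_years")
  miss <- setdiff(need_v, names(v))
  if (length(miss)) stop("visits table missing columns: ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_p, names(p))
  if (length(miss)) stop("participants table missing columns: ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(p$participant_id))
    stop("duplicate participant_id in participants table: row(s) ",
         paste(which(duplicated(p$participant_id)), collapse = ", "))
  unknown <- !v$participant_id %in% p$participant_id
  if (any(unknown))
    stop("visits reference unknown participant(s) at row(s) ",
         paste(utils::head(which(unknown), 5), collapse = ", "))
  bad_age <- !is.finite(v$age_years) | v$age_years < 0
  if (any(bad_age))
    stop("invalid visit age at row(s) ",
         paste(utils::head(which(bad_age), 5), collapse = ", "))
  for (ab in ANTIBODIES) {
    bad <- !(is.na(v[[ab]]) | v[[ab]] %in% c(0, 1))
    if (any(bad))
      stop("column '", ab, "' must be 0/1/NA; bad row(s) ",
           paste(utils::head(which(bad), 5), collapse = ", "))
  }
  dup <- duplicated(v[c("participant_id", "age_years")])
  if (any(dup))
    stop("duplicate (participant, age) visit row(s) ",
         paste(utils::head(which(dup), 5), collapse = ", "),
         "; merge them explicitly before modeling")
  bad_sex <- !p$sex %in% c("M", "F")
  if (any(bad_sex))
    stop("sex must be M/F; bad participant row(s) ",
         paste(utils::head(which(bad_sex), 5), collapse = ", "))
  bad_hla <- !p$hla_dr %in% HLA_LEVELS
  if (any(bad_hla))
    stop("unknown hla_dr category at participant row(s) ",
         paste(utils::head(which(bad_hla), 5), collapse = ", "))
  if (!all(p$diagnosed %in% c(0, 1)))
    stop("diagnosed must be 0/1")
  bad_dx <- (p$diagnosed == 1) != !is.na(p$diagnosis_age_years)
  if (any(bad_dx))
    stop("diagnosis_age_years must be present iff diagnosed; row(s) ",
         paste(utils::head(which(bad_dx), 5), collapse = ", "))
  last_visit <- tapply(v$age_years, v$participant_id, max)
  idx <- match(p$participant_id, names(last_visit))
  has_visits <- !is.na(idx)
  short <- has_visits &
    p$last_obs_age_years < as.numeric(last_visit)[idx] - 1e-9
  if (any(short))
    stop("last_obs_age_years precedes final visit for participant row(s) ",
         paste(utils::head(which(short), 5), collapse = ", "))
  invisible(cohort)
}

#' @export
print.t1d_cohort <- function(x, ...) {
  cat("Longitudinal islet-autoantibody cohort\n")
  cat(sprintf("  participants: %d (%d diagnosed)\n",
              nrow(x$participants), sum(x$participants$diagnosed == 1)))
  cat(sprintf("  visits: %d, ages %.2f-%.2f years\n", nrow(x$visits),
              min(x$visits$age_years), max(x$visits$age_years)))
  excl <- attr(x, "exclusion_report")
  if (!is.null(excl))
    cat("  filtered (", excl$mode, " mode): ", excl$n_excluded,
        " participant(s) excluded\n", sep = "")
  invisible(x)
}

#' Read / write a cohort CSV pair
#'
#' `read_cohort()` reads and validates the two-file cohort format;
#' `write_cohort()` writes it losslessly (positivity coded 0/1/NA, ages in
#' decimal years). Unknown extra columns are preserved.
#'
#' @param visits_path,participants_path file paths of the two CSV tables.
#' @return `read_cohort()` returns a [t1d_cohort]; `write_cohort()` returns
#'   the paths invisibly.
#' @export
read_cohort <- function(visits_path, participants_path) {
  v <- utils::read.csv(visits_path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  p <- utils::read.csv(participants_path, stringsAsFactors = FALSE,
                       colClasses = c(participant_id = "character"))
  t1d_cohort(v, p)
}

#' @param cohort a [t1d_cohort].
#' @rdname read_cohort
#' @export
write_cohort <- function(cohort, visits_path, participants_path) {
  validate_cohort(cohort)
  utils::write.csv(cohort$visits, visits_path, row.names = FALSE)
  utils::write.csv(cohort$participants, participants_path, row.names = FALSE)
  invisible(c(visits_path, participants_path))
}

#' Apply the cohort inclusion filters
#'
#' Analysis mode keeps participants with at least one antibody measurement
#' at or before age 2.5 years, at least one positive measurement during
#' follow-up, and at least two visits. Training mode additionally requires
#' diagnosis within 15 years of follow-up and three or more visits.
#'
#' @param cohort a [t1d_cohort].
#' @param mode `"analysis"` or `"training"`.
#' @param early_age age cutoff (years) for the first-measurement rule.
#' @return the filtered [t1d_cohort]; the per-rule exclusion counts are
#'   attached as attribute `"exclusion_report"`.
#' @export
cohort_filter <- function(cohort, mode = c("analysis", "training"),
                          early_age = 2.5) {
  mode <- match.arg(mode)
  v <- cohort$visits
  p <- cohort$participants
  ids <- p$participant_id
  measured <- !is.na(v$gada) | !is.na(v$iaa) | !is.na(v$ia2a)
  pos <- (v$gada %in% 1) | (v$iaa %in% 1) | (v$ia2a %in% 1)
  early_ok <- ids %in% unique(v$participant_id[measured & v$age_years <= early_age])
  ever_pos <- ids %in% unique(v$participant_id[pos])
  n_visits <- table(v$participant_id)[ids]
  n_visits[is.na(n_visits)] <- 0
  enough <- as.numeric(n_visits) >= 2
  keep <- early_ok & ever_pos & enough
  report <- list(
    mode = mode,
    n_in = length(ids),
    no_early_measurement = sum(!early_ok),
    never_positive = sum(!ever_pos),
    too_few_visits = sum(!enough)
  )
  if (mode == "training") {
    dx15 <- p$diagnosed == 1 & !is.na(p$diagnosis_age_years) &
      p$diagnosis_age_years <= 15
    three <- as.numeric(n_visits) >= 3
    report$not_diagnosed_within_15y <- sum(!dx15)
    report$fewer_than_three_visits <- sum(!three)
    keep <- keep & dx15 & three
  }
  report$n_excluded <- sum(!keep)
  report$n_out <- sum(keep)
  out <- subset_cohort(cohort, ids[keep])
  attr(out, "exclusion_report") <- report
  out
}

#' Subset a cohort by participant ids
#'
#' @param cohort a [t1d_cohort].
#' @param ids participant ids to keep.
#' @return a [t1d_cohort] restricted to `ids`; simulation truth metadata,
#'   if present, is subset accordingly.
#' @export
subset_cohort <- function(cohort, ids) {
  out <- structure(list(
    visits = cohort$visits[cohort$visits$participant_id %in% ids, ,
                           drop = FALSE],
    participants = cohort$participants[
      cohort$participants$participant_id %in% ids, , drop = FALSE]
  ), class = "t1d_cohort")
  rownames(out$visits) <- NULL
  rownames(out$participants) <- NULL
  truth <- attr(cohort, "truth")
  if (!is.null(truth)) {
    truth$paths <- truth$paths[truth$paths$participant_id %in% ids, ,
                               drop = FALSE]
    truth$visit_states <- truth$visit_states[
      truth$visit_states$participant_id %in% ids, , drop = FALSE]
    truth$chains <- truth$chains[truth$chains$participant_id %in% ids, ,
                                 drop = FALSE]
    attr(out, "truth") <- truth
  }
  attr(out, "config") <- attr(cohort, "config")
  out
}

#' Merge visits recorded at identical ages
#'
#' Collapses duplicate (participant, age) visit rows into one, combining
#' non-missing observations; conflicting non-missing values are an error.
#' Needed before modeling because a zero-length inter-visit interval has no
#' transition kernel.
#'
#' @param cohort a [t1d_cohort] (possibly failing the duplicate-row check).
#' @return a [t1d_cohort] with unique (participant, age) rows.
#' @export
merge_duplicate_visits <- function(cohort) {
  v <- cohort$visits
  key <- paste(v$participant_id, format(v$age_years, digits = 15))
  if (!anyDuplicated(key)) return(cohort)
  pieces <- lapply(split(v, key), function(d) {
    for (ab in ANTIBODIES) {
      vals <- unique(d[[ab]][!is.na(d[[ab]])])
      if (length(vals) > 1)
        stop("conflicting ", ab, " values at age ", d$age_years[1],
             " for participant ", d$participant_id[1])
      d[[ab]][1] <- if (length(vals)) vals else NA
    }
    d[1, , drop = FALSE]
  })
  v <- do.call(rbind, pieces)
  v <- v[order(v$participant_id, v$age_years), , drop = FALSE]
  rownames(v) <- NULL
  out <- cohort
  out$visits <- v
  out
}

# Convert a cohort to the per-participant series lists consumed by the
# compiled kernels: integer observation matrices (1/0/-1) and gap vectors.
cohort_series <- function(cohort) {
  v <- cohort$visits
  v <- v[order(v$participant_id, v$age_years), , drop = FALSE]
  ids <- unique(v$participant_id)
  split_idx <- split(seq_len(nrow(v)), factor(v$participant_id, levels = ids))
  obs_list <- vector("list", length(ids))
  gaps_list <- vector("list", length(ids))
  ages_list <- vector("list", length(ids))
  for (k in seq_along(ids)) {
    rows <- split_idx[[k]]
    m <- as.matrix(v[rows, ANTIBODIES])
    storage.mode(m) <- "integer"
    m[is.na(m)] <- -1L
    ages <- v$age_years[rows]
    if (any(diff(ages) <= 0))
      stop("visit ages not strictly increasing for participant ", ids[k])
    obs_list[[k]] <- m
    gaps_list[[k]] <- diff(ages)
    ages_list[[k]] <- ages
  }
  list(ids = ids, obs = obs_list, gaps = gaps_list, ages = ages_list)
}

#' Published cohort composition table
#'
#' The published distribution of undiagnosed and diagnosed participants
#' across the three trajectories by sex and HLA-DR category (counts). The
#' six columns are trajectory-by-outcome groups; these counts drive the
#' default covariate frequencies of the synthetic generator and the
#' chi-square association examples.
#'
#' @return list with integer matrices `sex` (2 x 6) and `hla_dr` (5 x 6);
#'   columns `UD.TR1 ... D.TR3`.
#' @export
t1di_table1 <- function() {
  cols <- c("UD.TR1", "UD.TR2", "UD.TR3", "D.TR1", "D.TR2", "D.TR3")
  sex <- matrix(c(283, 145, 409, 155, 146, 52,
                  200, 112, 353, 101, 127, 62),
                nrow = 2, byrow = TRUE,
                dimnames = list(c("M", "F"), cols))
  hla <- matrix(c(73, 48, 141, 93, 106, 41,
                  298, 140, 421, 139, 138, 55,
                  70, 23, 85, 15, 19, 16,
                  42, 45, 112, 9, 10, 2,
                  0, 1, 3, 0, 0, 0),
                nrow = 5, byrow = TRUE,
                dimnames = list(HLA_LEVELS, cols))
  list(sex = sex, hla_dr = hla)
}
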