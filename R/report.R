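#' Render the static analysis report
#'
#' Writes deterministic tables and static figures for a fitted model and
#' its trajectory decomposition: (a) a waterfall figure of per-participant
#' visits colored by decoded state against age, split by outcome; (b) the
#' transition-diagram table (per-state entry counts, exit counts by
#' outcome, transition counts, median entry/exit ages) and its figure;
#' (c) survival curve figures per requested stratification; (d) the
#' pattern-by-age composition table and stacked-proportion figure; and a
#' run manifest (seed, package version, input checksums).
#'
#' @param fit a fitted `cthmm`.
#' @param traj_model a `trajectory_model`.
#' @param assignments from [assign_participants()].
#' @param labelings from [decode_states()].
#' @param cohort the analyzed [t1d_cohort].
#' @param out_dir output directory (created if missing).
#' @param survival_strata stratifications to plot.
#' @param seed seed recorded in the manifest.
#' @return invisibly, the manifest list.
#' @export
render_report <- function(fit, traj_model, assignments, labelings, cohort,
                          out_dir, survival_strata = "chain", seed = NA) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  empty <- !nrow(assignments)

  # (b) transition-diagram table
  ages_tab <- state_entry_ages(assignments, labelings, cohort, traj_model)
  trans <- transition_counts(assignments, labelings, cohort, traj_model)
  tab <- merge(ages_tab, trans$state_table, by = "state", all.x = TRUE,
               sort = TRUE)
  utils::write.csv(tab, file.path(out_dir, "state_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(trans$transitions,
                   file.path(out_dir, "transition_counts.csv"),
                   row.names = FALSE)

  # (d) pattern-by-age
  if (!empty) {
    pat <- pattern_by_age(assignments, cohort)
    utils::write.csv(pat, file.path(out_dir, "pattern_by_age.csv"),
                     row.names = FALSE)
    plot_pattern_by_age(pat, file.path(out_dir, "pattern_by_age.png"))
  } else {
    writeLines("no participants", file.path(out_dir, "pattern_by_age.csv"))
  }

  utils::write.csv(assignments, file.path(out_dir, "assignments.csv"),
                   row.names = FALSE)

  # (a) waterfall
  plot_waterfall(assignments, labelings, cohort, traj_model,
                 file.path(out_dir, "waterfall.png"))
  # (b) transition diagram figure
  plot_transition_diagram(traj_model, tab,
                          file.path(out_dir, "transition_diagram.png"))

  # (c) survival curves
  if (!empty) {
    for (st in survival_strata) {
      sv <- try(build_survival_dataset(assignments, labelings, cohort,
                                       traj_model, strata = st),
                silent = TRUE)
      if (inherits(sv, "try-error") || !nrow(sv)) next
      if (length(unique(sv$stratum)) < 1) next
      km <- km_estimate(sv)
      utils::write.csv(km_table(km),
                       file.path(out_dir, paste0("survival_", st, ".csv")),
                       row.names = FALSE)
      grDevices::png(file.path(out_dir, paste0("survival_", st, ".png")),
                     width = 900, height = 700)
      plot(km, col = seq_along(unique(sv$stratum)), lwd = 2,
           xlab = "years from reference-state entry",
           ylab = "diabetes-free survival",
           main = paste("Diabetes-free survival by", st))
      legend("bottomleft", legend = sort(unique(sv$stratum)),
             col = seq_along(unique(sv$stratum)), lwd = 2, bty = "n")
      grDevices::dev.off()
    }
  }

  manifest <- list(
    seed = seed,
    package_version = as.character(utils::packageVersion("t1dtraj")),
    r_version = as.character(getRversion()),
    n_participants = nrow(cohort$participants),
    n_visits = nrow(cohort$visits),
    n_states = fit$params$n_states,
    loglik = fit$loglik,
    chains = lengths(traj_model$chains),
    input_checksum = cohort_checksum(cohort))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}

cohort_checksum <- function(cohort) {
  tmp <- tempfile(fileext = ".csv")
  on.exit(unlink(tmp))
  utils::write.csv(cohort$visits, tmp, row.names = FALSE)
  unname(tools::md5sum(tmp))
}

transition_counts <- function(assignments, labelings, cohort, traj_model) {
  keep <- assignments$participant_id[!assignments$ambiguous]
  lab <- labelings[labelings$participant_id %in% keep, , drop = FALSE]
  S <- length(traj_model$state_names)
  dx <- stats::setNames(cohort$participants$diagnosed,
                        cohort$participants$participant_id)
  enter <- integer(S); exit_d <- integer(S); exit_ud <- integer(S)
  trans <- list()
  for (d in split(lab, lab$participant_id)) {
    d <- d[order(d$age_years), , drop = FALSE]
    runs <- rle(d$state)$values
    enter[runs] <- enter[runs] + 1L
    lastst <- runs[length(runs)]
    if (dx[d$participant_id[1]] == 1) exit_d[lastst] <- exit_d[lastst] + 1L
    else exit_ud[lastst] <- exit_ud[lastst] + 1L
    if (length(runs) > 1)
      for (i in seq_len(length(runs) - 1))
        trans[[length(trans) + 1]] <- c(runs[i], runs[i + 1])
  }
  tr <- if (length(trans)) {
    m <- do.call(rbind, trans)
    ag <- stats::aggregate(list(n = rep(1, nrow(m))),
                           by = list(from = m[, 1], to = m[, 2]), FUN = sum)
    ag$from_name <- traj_model$state_names[ag$from]
    ag$to_name <- traj_model$state_names[ag$to]
    ag
  } else {
    data.frame(from = integer(), to = integer(), n = integer(),
               from_name = character(), to_name = character())
  }
  list(state_table = data.frame(state = seq_len(S), n_enter = enter,
                                n_exit_diagnosed = exit_d,
                                n_exit_censored = exit_ud),
       transitions = tr)
}

plot_waterfall <- function(assignments, labelings, cohort, traj_model,
                           path) {
  grDevices::png(path, width = 1000, height = 800)
  on.exit(grDevices::dev.off())
  if (!nrow(assignments)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "no participants")
    return(invisible())
  }
  dx <- stats::setNames(cohort$participants$diagnosed,
                        cohort$participants$participant_id)
  keep <- assignments[!assignments$ambiguous, , drop = FALSE]
  lab <- labelings[labelings$participant_id %in% keep$participant_id, ,
                   drop = FALSE]
  ord <- keep$participant_id[order(keep$chain,
                                   keep$first_positive_entry_age)]
  ypos <- stats::setNames(seq_along(ord), ord)
  S <- length(traj_model$state_names)
  cols <- hcl.colors(S, "Dark 3")
  graphics::par(mfrow = c(1, 2), mar = c(4, 2, 3, 1))
  for (grp in c(1, 0)) {
    ids <- names(dx)[dx == grp]
    d <- lab[lab$participant_id %in% ids, , drop = FALSE]
    plot(NA, xlim = c(0, max(labelings$age_years)),
         ylim = c(0, length(ord) + 1), xlab = "age (years)", ylab = "",
         yaxt = "n",
         main = if (grp == 1) "Diagnosed" else "Undiagnosed")
    if (nrow(d))
      graphics::points(d$age_years, ypos[d$participant_id], pch = 16,
                       cex = 0.4, col = cols[d$state])
  }
  invisible()
}

plot_transition_diagram <- function(traj_model, state_table, path) {
  grDevices::png(path, width = 1000, height = 700)
  on.exit(grDevices::dev.off())
  n_chain <- length(traj_model$chains)
  plot(NA, xlim = c(0, max(state_table$median_exit_age, 10,
                           na.rm = TRUE) + 2),
       ylim = c(0, n_chain + 1), xlab = "age (years)", ylab = "",
       yaxt = "n", main = "State transition diagram")
  for (k in seq_len(n_chain)) {
    ch <- traj_model$chains[[k]]
    y <- n_chain - k + 1
    for (j in seq_along(ch)) {
      s <- ch[j]
      row <- state_table[state_table$state == s, , drop = FALSE]
      x0 <- row$median_entry_age
      x1 <- row$median_exit_age
      if (!nrow(row) || is.na(x0)) next
      if (is.na(x1) || x1 <= x0) x1 <- x0 + 0.3
      graphics::rect(x0, y - 0.3, x1, y + 0.3, border = "grey30",
                     col = "grey90")
      graphics::text((x0 + x1) / 2, y,
                     paste0(traj_model$state_names[s], "\n(",
                            row$n_entered, ")"), cex = 0.8)
    }
  }
  graphics::axis(2, at = n_chain:1, labels = paste0("TR", seq_len(n_chain)),
                 las = 1)
  invisible()
}

plot_pattern_by_age <- function(pat, path) {
  grDevices::png(path, width = 1100, height = 700)
  on.exit(grDevices::dev.off())
  pats <- unique(pat$pattern)
  chains <- grep("^TR", names(pat), value = TRUE)
  graphics::par(mfrow = c(2, 4), mar = c(3, 3, 2, 1))
  for (pn in pats) {
    d <- pat[pat$pattern == pn, , drop = FALSE]
    m <- t(as.matrix(d[, chains]))
    m[is.na(m)] <- 0
    graphics::barplot(m, names.arg = d$age_bin, col = seq_along(chains),
                      main = pn, ylim = c(0, 1), border = NA)
  }
  invisible()
}
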