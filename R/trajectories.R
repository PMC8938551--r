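#' Decompose a fitted state space into progression trajectories
#'
#' Builds a directed graph on latent states with an edge wherever the
#' fitted transition rate exceeds `rate_threshold`, takes weakly connected
#' components as candidate trajectories, orders states within each
#' component topologically (ties broken by median entry age of decoded
#' visits), and names chains `TR{k}-{j}`: the chain start (j = 0) is the
#' component state with the lowest total emission probability, and chains
#' are ranked for naming by descending probability that the post-start
#' state is multiple-antibody positive. On fits resembling the published
#' model this yields TR1 = multiple-antibody-first, TR2 = IAA-first,
#' TR3 = GADA-first.
#'
#' @param object a fitted `cthmm` or [cthmm_params].
#' @param labelings decoded visits from [decode_states()].
#' @param rate_threshold rate below which an edge is pruned; default 1
#'   percent of the largest off-diagonal rate. Rates beyond one event
#'   per day (365/year) are ignored when computing the default
#'   reference: they are far below any visit gap's resolution and arise
#'   only as numerical artifacts of near-zero dwell estimates.
#' @return object of class `trajectory_model`: `chains` (list of ordered
#'   state-index vectors), `state_names`, `start_states`, `summaries`
#'   (per-state entry/exit statistics), `rate_threshold`, `degenerate`
#'   flag (any singleton component), `cyclic` flag (topological order fell
#'   back to entry-age order).
#' @export
decompose_trajectories <- function(object, labelings, rate_threshold = NULL) {
  p <- if (inherits(object, "cthmm")) object$params else object
  stopifnot(inherits(p, "cthmm_params"))
  S <- p$n_states
  Q <- p$rate_matrix
  off <- Q
  diag(off) <- 0
  if (is.null(rate_threshold)) {
    sane <- off[off > 0 & off <= 365]
    rate_threshold <- 0.01 * if (length(sane)) max(sane) else max(off)
  }
  adj <- (off > rate_threshold) * 1
  entry_age <- median_entry_ages(labelings, S)
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "directed")
  comp <- igraph::components(g, mode = "weak")
  chains <- list()
  cyclic <- FALSE
  for (k in seq_len(comp$no)) {
    members <- which(comp$membership == k)
    if (length(members) == 1) {
      chains[[length(chains) + 1]] <- members
      next
    }
    sub <- igraph::induced_subgraph(g, members)
    depth <- tryCatch({
      ord <- as.integer(igraph::topo_sort(sub))
      if (length(ord) < length(members)) stop("cycle")
      d <- rep(0, length(members))
      A <- adj[members, members, drop = FALSE]
      for (vtx in ord)
        for (w in which(A[vtx, ] > 0))
          d[w] <- max(d[w], d[vtx] + 1)
      d
    }, error = function(e) NULL)
    if (is.null(depth)) {
      cyclic <- TRUE
      warning("thresholded transition graph is cyclic in one component; ",
              "falling back to entry-age ordering")
      depth <- rank(entry_age[members], ties.method = "first")
    }
    ordered <- members[order(depth, entry_age[members], members)]
    # the chain start is the state with the lowest total emission probability
    start <- members[which.min(rowSums(p$emissions[members, , drop = FALSE]))]
    ordered <- c(start, ordered[ordered != start])
    chains[[length(chains) + 1]] <- ordered
  }
  # rank chains by P(multiple-antibody positive) of the post-start state
  multi_p <- vapply(chains, function(ch) {
    probe <- if (length(ch) > 1) ch[2] else ch[1]
    prob_multiple_positive(p$emissions[probe, ])
  }, numeric(1))
  chains <- chains[order(-multi_p)]
  state_names <- rep(NA_character_, S)
  for (k in seq_along(chains))
    state_names[chains[[k]]] <- paste0("TR", k, "-",
                                       seq_along(chains[[k]]) - 1)
  structure(list(chains = chains,
                 state_names = state_names,
                 start_states = vapply(chains, `[`, integer(1), 1),
                 emissions = p$emissions,
                 rate_threshold = rate_threshold,
                 degenerate = any(lengths(chains) == 1),
                 cyclic = cyclic,
                 entry_age = entry_age),
            class = "trajectory_model")
}

median_entry_ages <- function(labelings, S) {
  if (!nrow(labelings)) return(rep(NA_real_, S))
  first_age <- stats::aggregate(
    age_years ~ participant_id + state, data = labelings, FUN = min)
  vapply(seq_len(S), function(s) {
    ages <- first_age$age_years[first_age$state == s]
    if (length(ages)) stats::median(ages) else NA_real_
  }, numeric(1))
}

#' @export
print.trajectory_model <- function(x, digits = 2, ...) {
  cat(sprintf("Trajectory decomposition: %d chain(s), sizes {%s}\n",
              length(x$chains),
              paste(lengths(x$chains), collapse = ", ")))
  for (k in seq_along(x$chains)) {
    ch <- x$chains[[k]]
    cat(sprintf("  TR%d: %s\n", k,
                paste(x$state_names[ch], collapse = " -> ")))
  }
  if (x$degenerate) cat("  [degenerate: singleton component(s) present]\n")
  invisible(x)
}

#' @export
plot.trajectory_model <- function(x, ...) {
  em <- x$emissions
  S <- nrow(em)
  ord <- unlist(x$chains)
  image(seq_len(3), seq_len(length(ord)), t(em[ord, , drop = FALSE])[,
        length(ord):1],
        col = hcl.colors(64, "Green-Orange", rev = TRUE), zlim = c(0, 1),
        axes = FALSE, xlab = "", ylab = "",
        main = "Trajectory states: antibody positivity probabilities")
  axis(1, at = 1:3, labels = toupper(ANTIBODIES))
  axis(2, at = seq_along(ord), labels = rev(x$state_names[ord]), las = 1)
  invisible(x)
}

#' Assign participants to trajectories
#'
#' A participant whose decoded states all lie in one chain is assigned to
#' that chain; one whose path touches two or more chains is flagged
#' ambiguous and excluded from downstream statistics.
#'
#' @param labelings decoded visits from [decode_states()].
#' @param traj_model a `trajectory_model`.
#' @param cohort optional [t1d_cohort]; if given, seroconversion ages are
#'   computed from the observed antibody panels.
#' @param seroconversion_rule persistence rule passed to
#'   [seroconversion_age()].
#' @return data frame with one row per participant: `chain` (NA when
#'   ambiguous), `ambiguous`, `state_sequence` (semicolon-joined state
#'   names), `first_positive_entry_age` (first visit decoded to an
#'   antibody-positive state of the assigned chain), `seroconversion_age`.
#'   The number of ambiguous participants is attached as attribute
#'   `"n_ambiguous"`.
#' @export
assign_participants <- function(labelings, traj_model, cohort = NULL,
                                seroconversion_rule = "same_antibody") {
  chain_of_state <- rep(NA_integer_, length(traj_model$state_names))
  for (k in seq_along(traj_model$chains))
    chain_of_state[traj_model$chains[[k]]] <- k
  pos_state <- rep(FALSE, length(traj_model$state_names))
  for (k in seq_along(traj_model$chains))
    pos_state[traj_model$chains[[k]][-1]] <- TRUE
  sero <- NULL
  if (!is.null(cohort)) sero <- seroconversion_ages(cohort,
                                                    rule = seroconversion_rule)
  pieces <- lapply(split(labelings, labelings$participant_id), function(d) {
    d <- d[order(d$age_years), , drop = FALSE]
    ch <- unique(chain_of_state[d$state])
    amb <- length(ch) > 1
    pos <- pos_state[d$state]
    data.frame(
      participant_id = d$participant_id[1],
      chain = if (amb) NA_integer_ else ch,
      ambiguous = amb,
      state_sequence = paste(traj_model$state_names[d$state],
                             collapse = ";"),
      first_positive_entry_age = if (!amb && any(pos))
        d$age_years[which(pos)[1]] else NA_real_)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  if (!is.null(sero))
    out$seroconversion_age <- sero[match(out$participant_id, names(sero))]
  attr(out, "n_ambiguous") <- sum(out$ambiguous)
  out
}

#' Seroconversion age of one participant
#'
#' The first of two consecutive visits at which an islet autoantibody is
#' persistently positive. Under the default `"same_antibody"` rule the
#' same antibody must be positive at both visits; `"any_antibody"`
#' requires only overall positivity at both.
#'
#' @param visits data frame of one participant's visits (`age_years`,
#'   `gada`, `iaa`, `ia2a` coded 0/1/NA), ordered or orderable by age.
#' @param rule `"same_antibody"` or `"any_antibody"`.
#' @return the seroconversion age in years, or NA if never seroconverted.
#' @export
seroconversion_age <- function(visits,
                               rule = c("same_antibody", "any_antibody")) {
  rule <- match.arg(rule)
  visits <- visits[order(visits$age_years), , drop = FALSE]
  V <- nrow(visits)
  if (V < 2) return(NA_real_)
  m <- as.matrix(visits[, ANTIBODIES]) == 1
  m[is.na(m)] <- FALSE
  for (i in seq_len(V - 1)) {
    hit <- if (rule == "same_antibody") any(m[i, ] & m[i + 1, ])
           else any(m[i, ]) && any(m[i + 1, ])
    if (hit) return(visits$age_years[i])
  }
  NA_real_
}

#' Seroconversion ages for all participants of a cohort
#'
#' @param cohort a [t1d_cohort].
#' @inheritParams seroconversion_age
#' @return named numeric vector of seroconversion ages (NA when never
#'   seroconverted).
#' @export
seroconversion_ages <- function(cohort,
                                rule = c("same_antibody", "any_antibody")) {
  rule <- match.arg(rule)
  vapply(split(cohort$visits, cohort$visits$participant_id),
         seroconversion_age, numeric(1), rule = rule)
}

#' Per-state entry and exit age summaries
#'
#' For each latent state: how many participants entered it, the median
#' age at first and last decoded visit in the state, and the same figures
#' split by diagnosis outcome. Ambiguous participants are excluded.
#'
#' @param assignments from [assign_participants()].
#' @param labelings from [decode_states()].
#' @param cohort optional [t1d_cohort] for the outcome split.
#' @param traj_model optional `trajectory_model` supplying state names.
#' @return data frame with one row per state.
#' @export
state_entry_ages <- function(assignments, labelings, cohort = NULL,
                             traj_model = NULL) {
  keep <- assignments$participant_id[!assignments$ambiguous]
  lab <- labelings[labelings$participant_id %in% keep, , drop = FALSE]
  S <- if (!is.null(traj_model)) length(traj_model$state_names)
       else if (nrow(labelings)) max(labelings$state) else 0L
  dx <- NULL
  if (!is.null(cohort))
    dx <- stats::setNames(cohort$participants$diagnosed,
                          cohort$participants$participant_id)
  if (nrow(lab)) {
    per <- stats::aggregate(age_years ~ participant_id + state, data = lab,
                            FUN = min)
    per$exit_age <- stats::aggregate(age_years ~ participant_id + state,
                                     data = lab, FUN = max)$age_years
  } else {
    per <- data.frame(participant_id = character(), state = integer(),
                      age_years = numeric(), exit_age = numeric())
  }
  rows <- lapply(seq_len(S), function(s) {
    d <- per[per$state == s, , drop = FALSE]
    base <- data.frame(
      state = s,
      state_name = if (!is.null(traj_model)) traj_model$state_names[s]
                   else as.character(s),
      n_entered = nrow(d),
      median_entry_age = if (nrow(d)) stats::median(d$age_years) else NA_real_,
      median_exit_age = if (nrow(d)) stats::median(d$exit_age) else NA_real_)
    if (!is.null(dx)) {
      g <- dx[d$participant_id] == 1
      base$n_diagnosed <- sum(g)
      base$median_entry_age_diagnosed <-
        if (any(g)) stats::median(d$age_years[g]) else NA_real_
      base$median_entry_age_undiagnosed <-
        if (any(!g)) stats::median(d$age_years[!g]) else NA_real_
    }
    base
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Trajectory composition of antibody patterns by age
#'
#' For each of the seven nonzero antibody-positivity patterns and each
#' one-year age bin, the proportion of pattern-holding (non-ambiguous)
#' participants belonging to each trajectory, with the denominator count.
#' Only visits with all three antibodies observed contribute; ages are
#' binned `[k, k + 1)`.
#'
#' @param assignments from [assign_participants()].
#' @param cohort a [t1d_cohort].
#' @param ages integer bin starts (default `2:7`).
#' @return data frame with columns `pattern`, `age_bin`, `n`, and one
#'   proportion column per chain (NA when the bin is empty).
#' @export
pattern_by_age <- function(assignments, cohort, ages = 2:7) {
  chains <- sort(unique(assignments$chain[!assignments$ambiguous]))
  v <- cohort$visits
  v <- v[stats::complete.cases(v[, ANTIBODIES]), , drop = FALSE]
  asg <- assignments[!assignments$ambiguous, , drop = FALSE]
  v <- v[v$participant_id %in% asg$participant_id, , drop = FALSE]
  v$chain <- asg$chain[match(v$participant_id, asg$participant_id)]
  pats <- expand.grid(gada = 0:1, iaa = 0:1, ia2a = 0:1)
  pats <- pats[rowSums(pats) > 0, , drop = FALSE]
  pat_name <- function(g, i, a)
    paste(c("GADA+", "IAA+", "IA2A+")[c(g, i, a) == 1], collapse = "/")
  rows <- list()
  for (r in seq_len(nrow(pats))) {
    pn <- pat_name(pats$gada[r], pats$iaa[r], pats$ia2a[r])
    hit <- v$gada == pats$gada[r] & v$iaa == pats$iaa[r] &
      v$ia2a == pats$ia2a[r]
    for (a in ages) {
      inbin <- hit & v$age_years >= a & v$age_years < a + 1
      holders <- unique(v[inbin, c("participant_id", "chain")])
      n <- nrow(holders)
      props <- if (n > 0) as.numeric(table(factor(holders$chain,
                                                  levels = chains)) / n)
               else rep(NA_real_, length(chains))
      row <- data.frame(pattern = pn, age_bin = a, n = n)
      for (k in seq_along(chains)) row[[paste0("TR", chains[k])]] <- props[k]
      rows[[length(rows) + 1]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write trajectory assignments to CSV
#'
#' @param assignments from [assign_participants()].
#' @param path output CSV path.
#' @export
write_assignments <- function(assignments, path) {
  utils::write.csv(assignments, path, row.names = FALSE)
  invisible(path)
}
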