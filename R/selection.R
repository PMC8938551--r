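#' Bootstrapped model-order search
#'
#' Repeated random sub-sampling over a range of candidate state counts:
#' for each state count and replicate, participants are split at random
#' into training and held-out sets (each participant's entire visit
#' history on one side only), the model is fit on the training split, and
#' the replicate is scored by the training-set BIC and the per-visit
#' predictive log-likelihood of the held-out split. Every row is
#' reproducible from its recorded seed.
#'
#' @param data a [t1d_cohort] (already filtered to modelable
#'   participants).
#' @param state_range integer vector of candidate state counts.
#' @param n_reps replicates per state count.
#' @param split_fraction training fraction of participants (in (0, 1)).
#' @param seed integer base seed; row seeds are derived from it.
#' @param n_restarts,max_iter,tol EM settings for the search-stage fits
#'   (cheaper than the final refit by design).
#' @param verbose print per-row progress.
#' @return object of class `cthmm_search`: a list with `table` (one row
#'   per (n_states, replicate): seeds, train log-likelihood, BIC, held-out
#'   per-visit predictive log-likelihood) and the call settings.
#' @export
run_state_search <- function(data, state_range = 2:20, n_reps = 100,
                             split_fraction = 0.7, seed = 1L,
                             n_restarts = 2, max_iter = 150, tol = 1e-4,
                             verbose = FALSE) {
  stopifnot(inherits(data, "t1d_cohort"))
  if (!length(state_range)) stop("state_range is empty")
  if (split_fraction <= 0 || split_fraction >= 1)
    stop("split_fraction must lie in (0, 1)")
  ser <- cohort_series(data)
  n <- length(ser$ids)
  n_train <- round(split_fraction * n)
  if (n_train < 1 || n_train >= n)
    stop("dataset too small to split at fraction ", split_fraction)
  rows <- vector("list", length(state_range) * n_reps)
  fits <- vector("list", length(rows))
  r <- 0
  for (S in state_range) {
    for (rep in seq_len(n_reps)) {
      r <- r + 1
      row_seed <- derive_seed(seed, rep, salt = S)
      # the split depends on the replicate only: every candidate state
      # count is evaluated on the same sub-samples (paired comparison)
      set.seed(derive_seed(seed, rep, salt = 0L))
      train_idx <- sort(sample.int(n, n_train))
      set.seed(row_seed)
      test_idx <- setdiff(seq_len(n), train_idx)
      tr <- list(ids = ser$ids[train_idx], obs = ser$obs[train_idx],
                 gaps = ser$gaps[train_idx], ages = ser$ages[train_idx])
      te <- list(ids = ser$ids[test_idx], obs = ser$obs[test_idx],
                 gaps = ser$gaps[test_idx], ages = ser$ages[test_idx])
      fit <- cthmm(tr, n_states = S, n_restarts = n_restarts,
                   n_screen = n_restarts, max_iter = max_iter, tol = tol,
                   split_merge_rounds = 0, seed = row_seed)
      test_ll <- sum(series_logliks(fit$params, te))
      test_visits <- sum(vapply(te$obs, nrow, integer(1)))
      rows[[r]] <- data.frame(
        n_states = S, replicate = rep, seed = row_seed,
        train_loglik = fit$loglik,
        bic = cthmm_bic(fit$loglik, S, fit$n_visits),
        heldout_loglik_per_visit = test_ll / test_visits,
        n_train = length(train_idx), n_test = length(test_idx))
      fits[[r]] <- fit
      if (verbose)
        message(sprintf("S=%d rep=%d: BIC %.1f, held-out %.4f/visit",
                        S, rep, rows[[r]]$bic,
                        rows[[r]]$heldout_loglik_per_visit))
    }
  }
  structure(list(table = do.call(rbind, rows), fits = fits,
                 state_range = state_range, n_reps = n_reps,
                 split_fraction = split_fraction, seed = seed),
            class = "cthmm_search")
}

#' @export
print.cthmm_search <- function(x, ...) {
  cat(sprintf("Model-order search: %d state counts x %d replicates\n",
              length(x$state_range), x$n_reps))
  print(search_summary(x))
  invisible(x)
}

#' Per-state-count summary of a model-order search
#'
#' @param search a `cthmm_search` object.
#' @return data frame with mean BIC and mean held-out per-visit
#'   log-likelihood per candidate state count.
#' @export
search_summary <- function(search) {
  tb <- search$table
  agg <- do.call(rbind, lapply(split(tb, tb$n_states), function(d)
    data.frame(n_states = d$n_states[1],
               mean_bic = mean(d$bic),
               mean_heldout = mean(d$heldout_loglik_per_visit),
               n_reps = nrow(d))))
  agg <- agg[order(agg$n_states), , drop = FALSE]
  rownames(agg) <- NULL
  agg
}

#' Select the model order and refit on the full cohort
#'
#' Under the default `"heldout"` rule the state count with the highest
#' mean held-out per-visit predictive log-likelihood wins: predictive
#' likelihood on the held-out splits is the primary selector, with the
#' BIC table kept as a reported diagnostic. The `"bic_band"` rule
#' instead restricts candidates to state counts whose mean BIC lies
#' within `bic_band` (a fraction of the BIC spread) of the minimum mean
#' BIC before applying the held-out criterion; training-set BIC is known
#' to underestimate hidden-Markov model order at moderate sample sizes,
#' so at desk scale this rule tends to choose the smallest candidate.
#' The winning order is refit on the full dataset with full EM settings.
#'
#' @param search a `cthmm_search` from [run_state_search()].
#' @param data the full [t1d_cohort] for the final refit.
#' @param rule `"heldout"` (default) or `"bic_band"`.
#' @param bic_band width of the BIC candidate band as a fraction of the
#'   spread of mean BIC across state counts (used by `"bic_band"`).
#' @param refit refit at the chosen order (otherwise return the order
#'   only).
#' @param n_restarts,max_iter,tol,seed EM settings for the refit.
#' @return object of class `cthmm_selection`: `n_states`, `fit` (the
#'   refit `cthmm` or NULL), `candidates`, `summary`.
#' @export
select_model <- function(search, data = NULL,
                         rule = c("heldout", "bic_band"),
                         bic_band = 0.01, refit = TRUE,
                         n_restarts = 5, max_iter = 500, tol = 1e-6,
                         seed = NULL) {
  stopifnot(inherits(search, "cthmm_search"))
  rule <- match.arg(rule)
  agg <- search_summary(search)
  if (!nrow(agg)) stop("empty search table")
  cand <- agg
  if (rule == "bic_band") {
    spread <- diff(range(agg$mean_bic))
    cut <- min(agg$mean_bic) + bic_band * spread
    cand <- agg[agg$mean_bic <= cut + 1e-12, , drop = FALSE]
  }
  winner <- cand$n_states[which.max(cand$mean_heldout)]
  fit <- NULL
  if (refit) {
    if (is.null(data)) stop("data is required to refit the selected order")
    fit <- cthmm(data, n_states = winner, n_restarts = n_restarts,
                 max_iter = max_iter, tol = tol,
                 seed = seed %||% search$seed)
  }
  structure(list(n_states = winner, fit = fit, candidates = cand,
                 summary = agg, rule = rule, bic_band = bic_band),
            class = "cthmm_selection")
}

#' @export
print.cthmm_selection <- function(x, ...) {
  cat(sprintf("Selected model order: %d latent states\n", x$n_states))
  cat("BIC-band candidates:\n")
  print(x$candidates)
  if (!is.null(x$fit)) print(x$fit)
  invisible(x)
}

#' Write a model-order search table to CSV
#'
#' @param search a `cthmm_search`.
#' @param path output CSV path.
#' @export
write_search_table <- function(search, path) {
  utils::write.csv(search$table, path, row.names = FALSE)
  invisible(path)
}
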