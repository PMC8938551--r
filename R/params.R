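#' CT-HMM parameter set
#'
#' Bundles the parameters of a continuous-time hidden Markov model over
#' binary three-antibody panels: initial state distribution, transition
#' rate matrix (off-diagonals nonnegative, rows summing to zero), and
#' per-state Bernoulli emission probabilities for GADA, IAA and IA-2A.
#'
#' @param initial_dist numeric vector of S initial-state probabilities.
#' @param rate_matrix S x S rate matrix.
#' @param emissions S x 3 matrix of emission probabilities.
#' @param state_names optional character vector of state names.
#' @return object of class `cthmm_params`.
#' @export
cthmm_params <- function(initial_dist, rate_matrix, emissions,
                         state_names = NULL) {
  rate_matrix <- as.matrix(rate_matrix)
  emissions <- as.matrix(emissions)
  S <- length(initial_dist)
  if (!all(dim(rate_matrix) == c(S, S)))
    stop("rate_matrix must be ", S, " x ", S)
  if (nrow(emissions) != S || ncol(emissions) != 3)
    stop("emissions must be ", S, " x 3")
  if (abs(sum(initial_dist) - 1) > 1e-10)
    stop("initial_dist must sum to 1")
  if (any(initial_dist < 0)) stop("initial_dist must be nonnegative")
  off <- rate_matrix
  diag(off) <- 0
  if (any(off < 0)) stop("off-diagonal rates must be nonnegative")
  if (any(abs(rowSums(rate_matrix)) > 1e-8))
    stop("rate_matrix rows must sum to 0")
  if (any(emissions < 0 | emissions > 1))
    stop("emissions must lie in [0, 1]")
  if (!is.null(state_names) && length(state_names) != S)
    stop("state_names must have length ", S)
  structure(list(n_states = S,
                 initial_dist = as.numeric(initial_dist),
                 rate_matrix = rate_matrix,
                 emissions = emissions,
                 state_names = state_names),
            class = "cthmm_params")
}

#' @export
print.cthmm_params <- function(x, digits = 3, ...) {
  cat(sprintf("CT-HMM parameters: %d latent states\n", x$n_states))
  em <- round(x$emissions, digits)
  colnames(em) <- toupper(ANTIBODIES)
  rownames(em) <- x$state_names %||% paste0("S", seq_len(x$n_states))
  print(em)
  invisible(x)
}

#' Serialize / restore a CT-HMM model as JSON
#'
#' Writes the parameter set (and optional fit metadata) to JSON at full
#' double precision (17 significant digits), so a write/read round trip is
#' bit-exact.
#'
#' @param x a `cthmm_params` or fitted `cthmm` object.
#' @param path output file path.
#' @return `write_cthmm()` returns `path` invisibly; `read_cthmm()` returns
#'   a `cthmm_params` object (with metadata in attribute `"metadata"`).
#' @export
write_cthmm <- function(x, path) {
  meta <- list(package_version = as.character(utils::packageVersion("t1dtraj")))
  if (inherits(x, "cthmm")) {
    meta$seed <- x$seed
    meta$loglik <- x$loglik
    meta$n_iter <- x$n_iter
    p <- x$params
  } else {
    p <- x
  }
  stopifnot(inherits(p, "cthmm_params"))
  payload <- list(
    n_states = p$n_states,
    initial_dist = p$initial_dist,
    rate_matrix = as.numeric(t(p$rate_matrix)),  # row-major
    emissions = as.numeric(t(p$emissions)),
    state_names = p$state_names,
    metadata = meta
  )
  json <- jsonlite::toJSON(payload, digits = I(17), auto_unbox = TRUE,
                           null = "null", pretty = TRUE)
  writeLines(json, path)
  invisible(path)
}

#' @rdname write_cthmm
#' @export
read_cthmm <- function(path) {
  payload <- jsonlite::fromJSON(path)
  S <- payload$n_states
  out <- cthmm_params(
    initial_dist = payload$initial_dist,
    rate_matrix = matrix(payload$rate_matrix, S, S, byrow = TRUE),
    emissions = matrix(payload$emissions, S, 3, byrow = TRUE),
    state_names = payload$state_names
  )
  attr(out, "metadata") <- payload$metadata
  out
}
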