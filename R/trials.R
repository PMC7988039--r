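#' Simulate matching-to-sample trial records
#'
#' Generates synthetic behavioral trials with the statistical structure of
#' the cross-modal matching experiment: independent Bernoulli outcomes at
#' a stated true accuracy, against a chance level of 1/`n_alternatives`.
#' Identical seeds give identical records; the caller's RNG state is left
#' untouched.
#'
#' @param case_kind Target case label (`"AF"`, `"WF"`, `"FB"`, `"SF"`).
#' @param n Number of trials (>= 1).
#' @param true_accuracy Probability of a correct match in `[0, 1]`.
#' @param n_alternatives Number of alternative objects (2 or 4).
#' @param seed Optional integer seed.
#' @return A data frame with columns `case_kind`, `n_alternatives`,
#'   `correct`.
#' @export
#' @examples
#' simulate_trials("AF", 96, 0.927, 4, seed = 1)
simulate_trials <- function(case_kind, n, true_accuracy, n_alternatives,
                            seed = NULL) {
  stopifnot(n >= 1)
  if (!is.numeric(true_accuracy) || true_accuracy < 0 || true_accuracy > 1) {
    stop("true_accuracy must be a probability in [0, 1]")
  }
  if (!n_alternatives %in% c(2L, 4L)) {
    stop("n_alternatives must be 2 or 4")
  }
  draw <- function() stats::runif(n) < true_accuracy
  correct <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  data.frame(case_kind = rep(case_kind, n),
             n_alternatives = rep(as.integer(n_alternatives), n),
             correct = correct,
             stringsAsFactors = FALSE)
}

#' Write / read trial records as CSV
#'
#' @param trials Trial data frame from [simulate_trials()].
#' @param path CSV file path.
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(trials, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  tr <- utils::read.csv(path, stringsAsFactors = FALSE)
  tr$correct <- as.logical(tr$correct)
  tr
}
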