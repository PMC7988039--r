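#' Exact binomial test by direct summation
#'
#' Tail probability of the binomial distribution computed by summing the
#' exact terms (no normal approximation). The one-sided `"greater"`
#' alternative -- is performance above chance? -- returns
#' `P(X >= n_correct)`; the two-sided alternative sums all outcomes whose
#' probability does not exceed that of the observed count.
#'
#' @param n_correct Observed number of correct trials.
#' @param n_trials Total number of trials.
#' @param chance Chance success probability in `(0, 1)`, e.g. 0.25 for
#'   four alternatives and 0.5 for two.
#' @param alternative `"greater"` (default) or `"two_sided"`.
#' @return The exact p-value.
#' @export
#' @examples
#' binomial_test(10, 10, 0.5)          # 0.5^10
#' binomial_test(89, 96, 0.25)         # far below 0.01
binomial_test <- function(n_correct, n_trials, chance,
                          alternative = c("greater", "two_sided")) {
  alternative <- match.arg(alternative)
  if (n_trials < 1 || n_correct < 0 || n_correct > n_trials) {
    stop("need 0 <= n_correct <= n_trials with n_trials >= 1")
  }
  if (chance <= 0 || chance >= 1) stop("chance must be in (0, 1)")
  terms <- stats::dbinom(0:n_trials, n_trials, chance)
  if (alternative == "greater") {
    p <- sum(terms[(n_correct + 1):(n_trials + 1)])
  } else {
    p_obs <- terms[n_correct + 1]
    p <- sum(terms[terms <= p_obs * (1 + 1e-7)])
  }
  min(1, p)
}

#' Summarize one behavioral case
#'
#' Computes matching accuracy and the exact binomial p-value against the
#' chance level implied by the number of alternatives (1/2 or 1/4), with
#' significance at the 0.05 level. Trial sets mixing 2- and 4-alternative
#' designs must be split per stratum before summarizing.
#'
#' @param trials Data frame with columns `case_kind`, `n_alternatives`,
#'   `correct` (see [simulate_trials()]).
#' @param alternative Sidedness passed to [binomial_test()].
#' @return A one-row data frame: `case_kind`, `n_trials`, `n_correct`,
#'   `chance_level`, `accuracy`, `p_value`, `significant`.
#' @export
#' @examples
#' tr <- simulate_trials("AF", 96, 0.927, 4, seed = 1)
#' summarize_case(tr)
summarize_case <- function(trials, alternative = "greater") {
  if (nrow(trials) == 0) stop("empty trial list")
  if (length(unique(trials$case_kind)) != 1) {
    stop("all trials must share one case_kind")
  }
  if (length(unique(trials$n_alternatives)) != 1) {
    stop("mixed n_alternatives: split per stratum before summarizing")
  }
  n <- nrow(trials)
  k <- sum(trials$correct)
  chance <- 1 / trials$n_alternatives[1]
  p <- binomial_test(k, n, chance, alternative)
  data.frame(case_kind = trials$case_kind[1], n_trials = n, n_correct = k,
             chance_level = chance, accuracy = k / n, p_value = p,
             significant = p < 0.05, stringsAsFactors = FALSE)
}

#' Monte-Carlo power of the exact binomial test
#'
#' Estimates `P(p_value < 0.05)` of the one-sided exact test at each true
#' accuracy by simulating binomial trial counts.
#'
#' @param n_trials Trials per synthetic experiment.
#' @param chance Chance level.
#' @param true_accuracy_grid Numeric vector of true accuracies in
#'   `[0, 1]`.
#' @param n_replicates Monte-Carlo replicates per grid point (>= 100).
#' @param seed Optional integer seed.
#' @return Data frame with `true_accuracy` and `power`.
#' @export
power_curve <- function(n_trials, chance, true_accuracy_grid,
                        n_replicates = 1000, seed = NULL) {
  if (n_replicates < 100) stop("n_replicates must be >= 100")
  if (any(true_accuracy_grid < 0 | true_accuracy_grid > 1)) {
    stop("true accuracies must lie in [0, 1]")
  }
  # exact upper-tail table P(X >= k) once per n
  tail_p <- rev(cumsum(rev(stats::dbinom(0:n_trials, n_trials, chance))))
  run <- function() {
    vapply(true_accuracy_grid, function(a) {
      k <- stats::rbinom(n_replicates, n_trials, a)
      mean(tail_p[k + 1] < 0.05)
    }, numeric(1))
  }
  pw <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  data.frame(true_accuracy = true_accuracy_grid, power = pw)
}
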