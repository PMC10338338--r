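#' Clock distributions
#'
#' A fate clock (time from treatment to mitosis, or to cell-cycle exit) is
#' described either parametrically as a log-normal law — the natural choice
#' for right-skewed positive times — or non-parametrically by an empirical
#' sample. A point mass at `Inf` (`median = Inf`) represents a disabled
#' clock (e.g. mitosis under CDK1 inhibition).
#'
#' @param family `"LOGNORMAL"` or `"EMPIRICAL"`.
#' @param median Median time in hours (LOGNORMAL; may be `Inf`).
#' @param log_sd Log-scale standard deviation (LOGNORMAL, >= 0).
#' @param sample Positive times in hours (EMPIRICAL).
#' @return An object of class `clock_distribution`.
#' @examples
#' clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
#' @export
clock_distribution <- function(family = c("LOGNORMAL", "EMPIRICAL"),
                               median = NULL, log_sd = NULL, sample = NULL) {
  family <- match.arg(family)
  if (family == "LOGNORMAL") {
    if (is.null(median) || is.null(log_sd)) {
      abort("LOGNORMAL clocks need `median` and `log_sd`.")
    }
    if (median <= 0) abort("`median` must be positive.")
    if (log_sd < 0) abort("`log_sd` must be non-negative.")
    out <- list(family = family, median = median, log_sd = log_sd, sample = NULL)
  } else {
    if (is.null(sample) || length(sample) == 0) {
      abort("EMPIRICAL clocks need a non-empty `sample`.")
    }
    if (any(!is.finite(sample)) || any(sample <= 0)) {
      abort("EMPIRICAL sample times must all be positive and finite.")
    }
    out <- list(family = family, median = stats::median(sample), log_sd = NULL,
                sample = as.numeric(sample))
  }
  structure(out, class = "clock_distribution")
}

#' @export
print.clock_distribution <- function(x, ...) {
  if (x$family == "LOGNORMAL") {
    cat("<clock_distribution> LOGNORMAL(median ", x$median, " h, log-sd ",
        x$log_sd, ")\n", sep = "")
  } else {
    cat("<clock_distribution> EMPIRICAL, n = ", length(x$sample),
        ", median ", signif(x$median, 4), " h\n", sep = "")
  }
  invisible(x)
}

#' Fit a clock distribution to observed times
#'
#' For the log-normal family the median is the exponential of the mean
#' log-time and the dispersion is the standard deviation of the log-times;
#' the empirical family simply stores the sample for resampling.
#'
#' @param times Uncensored clock times in hours (>= 5, all positive).
#' @param family `"LOGNORMAL"` (default) or `"EMPIRICAL"`.
#' @return A [clock_distribution()].
#' @examples
#' fit_clock_distribution(c(5, 10, 20))  # errors: fewer than 5 times
#' fit_clock_distribution(rep(10, 6))    # median 10, log_sd 0
#' @export
fit_clock_distribution <- function(times, family = c("LOGNORMAL", "EMPIRICAL")) {
  family <- match.arg(family)
  times <- times[!is.na(times)]
  if (length(times) < 5) {
    abort("At least 5 uncensored clock times are required (censored-only input?).")
  }
  if (any(times <= 0)) abort("Clock times must be positive.")
  if (family == "LOGNORMAL") {
    clock_distribution("LOGNORMAL", median = exp(mean(log(times))),
                       log_sd = sd(log(times)))
  } else {
    clock_distribution("EMPIRICAL", sample = times)
  }
}

draw_clock <- function(clock, n) {
  if (clock$family == "LOGNORMAL") {
    if (is.infinite(clock$median)) return(rep(Inf, n))
    rlnorm(n, meanlog = log(clock$median), sdlog = clock$log_sd)
  } else {
    sample(clock$sample, n, replace = TRUE)
  }
}

#' Monte Carlo competition between the exit and mitosis clocks
#'
#' Draws `n` independent (exit, mitosis) time pairs from the two
#' pre-competition distributions and lets the earlier clock win; exact ties
#' go to mitosis (they have probability zero under continuous families).
#' The winner-side times are the post-competition distributions: the exit
#' times actually observed in a population are the subset of exit-clock
#' draws that beat their own mitosis clock, hence stochastically smaller
#' than the pre-competition exit distribution.
#'
#' @param exit_clock,mitosis_clock [clock_distribution()] objects.
#' @param n Number of simulated cells (>= 1).
#' @param seed Integer seed; the draw is reproducible.
#' @param keep_pairs If `TRUE`, retain the full table of sampled pairs.
#' @return An object of class `competition_outcome` with fields `n`,
#'   `exit_fraction`, `winner_times_exit`, `winner_times_mitosis` and
#'   (optionally) `sampled_pairs` (a tibble with `t_exit`, `t_mitosis`,
#'   `winner`).
#' @examples
#' ex <- clock_distribution("LOGNORMAL", median = 15.1, log_sd = 0.22)
#' mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
#' simulate_competition(ex, mi, n = 1000, seed = 1)$exit_fraction
#' @export
simulate_competition <- function(exit_clock, mitosis_clock, n, seed,
                                 keep_pairs = FALSE) {
  stopifnot(inherits(exit_clock, "clock_distribution"),
            inherits(mitosis_clock, "clock_distribution"))
  if (n < 1) abort("`n` must be at least 1.")
  set.seed(seed)
  t_exit <- draw_clock(exit_clock, n)
  t_mit <- draw_clock(mitosis_clock, n)
  exit_wins <- t_exit < t_mit # ties go to mitosis
  out <- list(
    n = n,
    exit_fraction = mean(exit_wins),
    winner_times_exit = t_exit[exit_wins],
    winner_times_mitosis = t_mit[!exit_wins]
  )
  if (keep_pairs) {
    out$sampled_pairs <- tibble::tibble(
      t_exit = t_exit, t_mitosis = t_mit,
      winner = ifelse(exit_wins, "EXIT", "MITOSIS")
    )
  }
  structure(out, class = "competition_outcome")
}

#' @export
print.competition_outcome <- function(x, ...) {
  cat("<competition_outcome> n = ", x$n, ", exit fraction = ",
      signif(x$exit_fraction, 4), "\n", sep = "")
  invisible(x)
}

#' @rdname simulate_competition
#' @param x A `competition_outcome`.
#' @param ... Unused.
#' @method tidy competition_outcome
#' @export
tidy.competition_outcome <- function(x, ...) {
  tibble::tibble(
    winner = c(rep("EXIT", length(x$winner_times_exit)),
               rep("MITOSIS", length(x$winner_times_mitosis))),
    time_h = c(x$winner_times_exit, x$winner_times_mitosis)
  )
}

#' @rdname simulate_competition
#' @method glance competition_outcome
#' @export
glance.competition_outcome <- function(x, ...) {
  tibble::tibble(
    n = x$n,
    exit_fraction = x$exit_fraction,
    median_exit_h = stats::median(x$winner_times_exit),
    median_mitosis_h = stats::median(x$winner_times_mitosis)
  )
}

#' Analytic probability that the exit clock wins
#'
#' For two independent log-normal clocks, `log(T_exit) - log(T_mitosis)` is
#' normal, so `P(T_exit < T_mitosis) = Phi((log m_mit - log m_exit) /
#' sqrt(s_exit^2 + s_mit^2))`. This closed form is the oracle against which
#' the Monte Carlo competition is checked.
#'
#' @inheritParams simulate_competition
#' @return The probability that the exit clock beats the mitosis clock.
#' @examples
#' ex <- clock_distribution("LOGNORMAL", median = 15, log_sd = 0.22)
#' mi <- clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18)
#' analytic_exit_probability(ex, mi)  # about 0.138
#' @export
analytic_exit_probability <- function(exit_clock, mitosis_clock) {
  stopifnot(inherits(exit_clock, "clock_distribution"),
            inherits(mitosis_clock, "clock_distribution"))
  if (exit_clock$family != "LOGNORMAL" || mitosis_clock$family != "LOGNORMAL") {
    abort("Analytic exit probability requires LOGNORMAL clocks on both sides.")
  }
  if (is.infinite(exit_clock$median)) return(0)
  if (is.infinite(mitosis_clock$median)) return(1)
  s <- sqrt(exit_clock$log_sd^2 + mitosis_clock$log_sd^2)
  dm <- log(mitosis_clock$median) - log(exit_clock$median)
  if (s == 0) return(as.numeric(dm > 0)) # degenerate: tie goes to mitosis
  pnorm(dm / s)
}

#' Compare simulated and observed post-competition distributions
#'
#' Two-sample Kolmogorov-Smirnov test of the winner-side times on one side
#' of the competition against an observed sample of the same fate's times.
#'
#' @param sim A `competition_outcome`.
#' @param observed_times Observed winner times in hours (non-empty).
#' @param side `"EXIT"` or `"MITOSIS"`.
#' @return A one-row tibble with `side`, `ks_statistic`, `p_value`,
#'   `n_sim`, `n_obs`.
#' @export
compare_post_competition <- function(sim, observed_times, side = c("EXIT", "MITOSIS")) {
  side <- match.arg(side)
  stopifnot(inherits(sim, "competition_outcome"))
  sim_times <- if (side == "EXIT") sim$winner_times_exit else sim$winner_times_mitosis
  observed_times <- observed_times[!is.na(observed_times)]
  if (length(sim_times) == 0 || length(observed_times) == 0) {
    abort("Both the simulated and the observed sample must be non-empty.")
  }
  ks <- suppressWarnings(ks.test(sim_times, observed_times))
  tibble::tibble(
    side = side,
    ks_statistic = unname(ks$statistic),
    p_value = ks$p.value,
    n_sim = length(sim_times),
    n_obs = length(observed_times)
  )
}
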