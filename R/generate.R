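#' Generate a synthetic population of single-cell reporter traces
#'
#' Each cell carries two fate clocks that start at treatment: a mitosis
#' clock (remaining time to division) and a cell-cycle exit clock (time for
#' cyclin A2-driven CDK2 activity to decay below the 0.6 commitment
#' threshold once the mitogen arm is blocked). The earlier clock wins.
#'
#' Per cell, the S-to-mitosis duration `D` is drawn from a log-normal law
#' (median `s_to_m_duration_median`), the treatment lands a uniform offset
#' `u` after S-phase entry, and the remaining mitosis time is
#' `R = max(D - u, 0.5) + delay_hours` (infinite under CDK1 inhibition).
#' The exit clock is the kinetic prediction [predict_exit_time()] scaled by
#' a median-one log-normal cell factor (infinite under DMSO or with
#' constitutive cyclin A2). Channels follow the winning fate: CDK2 activity
#' rises through S/G2 (about 0.8 to 1.2-1.4), collapses at division, or
#' declines through 0.6 along the cyclin A2 decay law; APC/C activity is
#' high in G0/G1, switches off at S entry, and returns after division or
#' premature reactivation at exit; the cyclin A2 channel is proportional to
#' the clean CDK2 trajectory. Gaussian sensor noise (s.d. 0.03) is added to
#' the activity channels and 4% multiplicative noise to cyclin A2.
#'
#' @param preset A [make_preset()] result.
#' @param treatment A [treatment_program()].
#' @param n_cells Number of cells (>= 1).
#' @param seed Integer seed; output is reproducible.
#' @param horizon Recording length in hours.
#' @param dt Sampling step in hours (0.2 h, about one frame per 12 min).
#' @param keep_truth If `TRUE`, attach the generating landmarks as a tibble
#'   in `attr(x, "truth")` so the analysis stage can be validated; by
#'   default the analysis runs blind.
#' @param noise If `FALSE`, sensor noise is omitted (clean channels for
#'   detector validation).
#' @return A long tibble with columns `cell_id`, `time_h`, `cdk2`, `apc`,
#'   `ccna2`, `divided` (0/1 event flag), `treatment`, `treatment_time_h`,
#'   `preset`.
#' @examples
#' tr <- generate_population(make_preset("MCF10A"),
#'                           treatment_program("CDK46I"),
#'                           n_cells = 5, seed = 1)
#' dplyr::count(tr, cell_id)
#' @export
generate_population <- function(preset, treatment, n_cells, seed,
                                horizon = 48, dt = 0.2, keep_truth = FALSE,
                                noise = TRUE) {
  stopifnot(inherits(preset, "population_preset"),
            inherits(treatment, "treatment_program"))
  if (!is.numeric(n_cells) || n_cells < 1) abort("`n_cells` must be at least 1.")
  if (missing(seed)) abort("A `seed` is required for reproducible generation.")
  tt <- treatment$treatment_time
  if (tt < preset$treatment_offset_window || tt >= horizon) {
    abort("`treatment_time` must allow a full offset window before it and lie inside the recording.")
  }
  set.seed(seed)
  times <- seq(0, horizon, by = dt)
  nt <- length(times)
  params <- as_kinetic_params(preset)
  t_exit_base <- predict_exit_time(params)

  u <- runif(n_cells, 0, preset$treatment_offset_window)
  D <- rlnorm(n_cells, log(preset$s_to_m_duration_median), preset$s_to_m_log_sd)
  R <- pmax(D - u, 0.5) + treatment$delay_hours
  if (blocks_mitosis(treatment)) R <- rep(Inf, n_cells)
  cf <- rlnorm(n_cells, 0, preset$exit_clock_dispersion)
  Tex <- if (triggers_exit_clock(treatment)) t_exit_base * cf else rep(Inf, n_cells)
  exit_wins <- Tex < R # ties go to mitosis
  reenter <- treatment$label == "DMSO" ||
    (treatment$label == "MEKI_DOSE" && treatment$dose < 1)

  cdk2_l <- vector("list", n_cells)
  apc_l <- vector("list", n_cells)
  div_l <- vector("list", n_cells)
  truth_fate <- character(n_cells)

  for (i in seq_len(n_cells)) {
    s_i <- tt - u[i]
    cdk2 <- numeric(nt)
    apc <- rep(1, nt)
    divided <- integer(nt)

    # G1 before S entry: slow CDK2 build-up
    pre <- times < s_i
    cdk2[pre] <- 0.3 + 0.5 * times[pre] / s_i

    s_entries <- s_i
    divisions <- numeric(0)

    if (exit_wins[i]) {
      exit_abs <- tt + Tex[i]
      mid <- times >= s_i & times < tt
      cdk2[mid] <- 0.8 + 0.4 * (times[mid] - s_i) / max(u[i], dt)
      post <- times >= tt
      cdk2[post] <- 1.2 * predict_protein(params, (times[post] - tt) / cf[i])
      apc <- apc_off_on(times, s_on = s_i, back_on = exit_abs, apc,
                        reactivation_ramp = 1)
      truth_fate[i] <- if (exit_abs <= horizon) "EXIT" else "COMMITTED"
    } else if (is.infinite(R[i])) {
      # mitosis blocked and no exit trigger: committed plateau
      mid <- times >= s_i
      cdk2[mid] <- pmin(0.8 + 0.4 * (times[mid] - s_i) / max(u[i], dt), 1.2)
      apc <- apc_off_on(times, s_on = s_i, back_on = Inf, apc)
      truth_fate[i] <- "COMMITTED"
    } else {
      m1 <- tt + R[i]
      grow <- times >= s_i & times < m1
      cdk2[grow] <- 0.8 + 0.6 * (times[grow] - s_i) / (m1 - s_i)
      if (m1 <= horizon) {
        divisions <- m1
        if (reenter) {
          # daughters re-enter: G1 gap, new S entry, next division
          d_prev <- m1
          repeat {
            g <- runif(1, 4, 6)
            s_next <- d_prev + g
            D_next <- rlnorm(1, log(preset$s_to_m_duration_median),
                             preset$s_to_m_log_sd)
            d_next <- s_next + D_next
            gap <- times >= d_prev & times < s_next
            cdk2[gap] <- 0.1 + 0.7 * (times[gap] - d_prev) / g
            if (s_next >= horizon) break
            cyc <- times >= s_next & times < min(d_next, horizon + dt)
            cdk2[cyc] <- 0.8 + 0.6 * (times[cyc] - s_next) / (d_next - s_next)
            s_entries <- c(s_entries, s_next)
            if (d_next > horizon) break
            divisions <- c(divisions, d_next)
            d_prev <- d_next
          }
        } else {
          post <- times >= m1
          cdk2[post] <- 0.1 # daughters arrest in G0
        }
      }
      apc <- apc_cycles(times, s_entries, divisions, reenter)
      truth_fate[i] <- if (m1 <= horizon) "MITOSIS" else "COMMITTED"
    }

    for (d in divisions) divided[which(times >= d)[1]] <- 1L

    if (noise) {
      cdk2_l[[i]] <- pmax(cdk2 + rnorm(nt, 0, 0.03), 0)
      apc_l[[i]] <- pmin(pmax(apc + rnorm(nt, 0, 0.03), 0), 1.5)
    } else {
      cdk2_l[[i]] <- cdk2
      apc_l[[i]] <- apc
    }
    div_l[[i]] <- divided
  }

  cdk2_all <- unlist(cdk2_l, use.names = FALSE)
  ids <- sprintf("cell_%05d", seq_len(n_cells))
  out <- tibble::tibble(
    cell_id = rep(ids, each = nt),
    time_h = rep(times, n_cells),
    cdk2 = cdk2_all,
    apc = unlist(apc_l, use.names = FALSE),
    ccna2 = (100 / 1.2) * pmax(cdk2_all, 1e-3) *
      (if (noise) exp(rnorm(nt * n_cells, 0, 0.04)) else 1),
    divided = unlist(div_l, use.names = FALSE),
    treatment = treatment$label,
    treatment_time_h = tt,
    preset = preset$name
  )
  if (keep_truth) {
    attr(out, "truth") <- tibble::tibble(
      cell_id = ids,
      s_entry = tt - u,
      treatment_offset = u,
      mitosis_clock = R,
      exit_clock = Tex,
      fate = truth_fate,
      event_time = tt + pmin(R, Tex)
    )
  }
  out
}

# APC/C channel for a single S entry followed by one reactivation event
# (exit or none): switch-like inactivation at S entry (well under the 1 h
# the detector allows), gradual reactivation over `reactivation_ramp`
# hours at `back_on`.
apc_off_on <- function(times, s_on, back_on, apc, reactivation_ramp = 1) {
  off <- times >= s_on & times < back_on
  apc[off] <- 0.02
  on <- times >= back_on
  if (any(on)) {
    apc[on] <- pmin(1, 0.02 + 0.98 * (times[on] - back_on) / reactivation_ramp)
  }
  apc
}

# APC/C channel over repeated cycles: off from each S entry until the next
# division, high in each G1 gap.
apc_cycles <- function(times, s_entries, divisions, reenter) {
  apc <- rep(1, length(times))
  for (k in seq_along(s_entries)) {
    back_on <- if (k <= length(divisions)) divisions[k] else Inf
    off <- times >= s_entries[k] & times < back_on
    apc[off] <- 0.02
  }
  apc
}

#' Generate a pure-decay cyclin A2 assay
#'
#' Emulates a translation-shutoff style measurement of cyclin A2 stability:
#' from `t = 0` each cell's cyclin A2 channel decays exponentially with the
#' preset's protein half-life, under multiplicative log-normal sensor noise
#' of coefficient `noise_cv`. Other channels are omitted.
#'
#' @inheritParams generate_population
#' @param noise_cv Coefficient of variation of the multiplicative noise
#'   (>= 0; 0 gives the exact exponential).
#' @return A long tibble with columns `cell_id`, `time_h`, `ccna2`,
#'   `preset`.
#' @examples
#' a <- generate_decay_assay(make_preset("RPE1"), n_cells = 3,
#'                           noise_cv = 0, seed = 1)
#' @export
generate_decay_assay <- function(preset, n_cells, noise_cv, seed,
                                 horizon = 24, dt = 1) {
  stopifnot(inherits(preset, "population_preset"))
  if (!is.numeric(noise_cv) || noise_cv < 0) abort("`noise_cv` must be >= 0.")
  if (n_cells < 1) abort("`n_cells` must be at least 1.")
  set.seed(seed)
  times <- seq(0, horizon, by = dt)
  nt <- length(times)
  decay <- 100 * exp(-log(2) * times / preset$protein_half_life)
  noise <- if (noise_cv > 0) exp(rnorm(nt * n_cells, 0, noise_cv)) else 1
  tibble::tibble(
    cell_id = rep(sprintf("cell_%05d", seq_len(n_cells)), each = nt),
    time_h = rep(times, n_cells),
    ccna2 = rep(decay, n_cells) * noise,
    preset = preset$name
  )
}

#' Per-cell half-life estimates from a decay assay
#'
#' Applies [estimate_half_life()] to each cell of a decay-assay table.
#'
#' @param assay A tibble from [generate_decay_assay()] (columns `cell_id`,
#'   `time_h`, `ccna2`).
#' @return A tibble with one row per cell: `cell_id`, `half_life`,
#'   `standard_error`, `n_points`, `r_squared`.
#' @export
estimate_half_lives <- function(assay) {
  if (!all(c("cell_id", "time_h", "ccna2") %in% names(assay))) {
    abort("`assay` needs columns `cell_id`, `time_h`, `ccna2`.")
  }
  assay |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ estimate_half_life(.x$time_h, .x$ccna2)) |>
    dplyr::ungroup()
}
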