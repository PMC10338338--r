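#' Build an ODE model of the mitogen-to-CDK2 pathway
#'
#' Two architectures of the pathway connecting mitogen signalling to CDK2
#' activity are supported.
#'
#' `FEEDBACK` is a minimal ultrasensitive Rb-E2F switch: CDK4/6 (driven by
#' mitogen `S`) and CDK2 both phosphorylate Rb; phosphorylated Rb releases
#' E2F through a steep Hill function; E2F drives cyclin E/A synthesis and
#' hence CDK2. The CDK2 -> Rb -> E2F -> CDK2 loop is self-sustaining: once
#' on, CDK2 maintains Rb phosphorylation without any mitogen input, giving
#' bistability and hysteresis (an irreversible high branch at `S = 0`).
#'
#' `FEEDFORWARD` is a chain with no return edge: mitogen -> CDK4/6 (fast
#' saturating activation) -| active p107/p130 repressor (relaxation time
#' about 15 min, i.e. dephosphorylation complete within 1-2 h) -| CCNA2
#' transcription; mRNA decays with a 2 h half-life, cyclin A2 protein with
#' half-life `h_p` (12 h default); CDK2 activity is a saturating readout of
#' cyclin A2, and Rb phosphorylation is a passive readout with no
#' transcriptional consequence. The chain is monotone, so the steady state
#' is unique for every mitogen level: no hysteresis, only a transient
#' "apparent irreversibility" window while the protein pool decays.
#'
#' @param architecture `"FEEDBACK"` or `"FEEDFORWARD"`.
#' @param overrides Named list of parameter overrides; unknown names error.
#' @return An object of class `network_model` with fields `architecture`,
#'   `params`, `state_names` and the derivative function `rhs`.
#' @examples
#' build_network("FEEDFORWARD")
#' @export
build_network <- function(architecture = c("FEEDFORWARD", "FEEDBACK"),
                          overrides = list()) {
  architecture <- match.arg(architecture)
  defaults <- if (architecture == "FEEDBACK") {
    list(
      tau4 = 0.25, # h, CDK4/6 activation time scale
      k_e2f = 1, d_e2f = 0.5, # E2F synthesis (Rb-gated) / decay
      k_cdk2 = 1.5, d_cdk2 = 1, K_e2f = 0.5, # cyclin E/A-CDK2 from E2F
      K_rb = 0.55, hill_rb = 4, # ultrasensitive Rb gate on E2F release
      kp_cdk4 = 0.85, kp_cdk2 = 1.6, k_dephos = 1.2 # Rb (de)phosphorylation
    )
  } else {
    list(
      tau4 = 0.25, # h, CDK4/6 activation time scale
      tau_rep = 0.25, # h, p107/p130 (de)phosphorylation relaxation
      K_cdk4 = 0.4, hill_rep = 4, # repressor inactivation by CDK4/6
      mrna_half_life = 2, # h
      protein_half_life = 12, # h
      cdk2_max = 1.5, K_ccna2 = 0.25, tau_cdk2 = 0.1, # CDK2 readout
      kp_rb = 2, k_dephos_rb = 1 # passive Rb phosphorylation readout
    )
  }
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown)) {
    abort(paste0("Unknown parameter override(s): ",
                 paste(unknown, collapse = ", "), ". Available: ",
                 paste(names(defaults), collapse = ", ")))
  }
  params <- utils::modifyList(defaults, overrides)
  if (architecture == "FEEDBACK") {
    state_names <- c("cdk46", "e2f", "cdk2", "rb_phos")
    rhs <- function(t, y, p) {
      with(as.list(c(y, p)), {
        gate <- rb_phos^hill_rb / (K_rb^hill_rb + rb_phos^hill_rb)
        d_cdk46 <- (p$S - cdk46) / tau4
        d_e2f_v <- k_e2f * gate - d_e2f * e2f
        d_cdk2_v <- k_cdk2 * e2f / (K_e2f + e2f) - d_cdk2 * cdk2
        d_rb <- (kp_cdk4 * cdk46 + kp_cdk2 * cdk2) * (1 - rb_phos) -
          k_dephos * rb_phos
        list(c(d_cdk46, d_e2f_v, d_cdk2_v, d_rb))
      })
    }
  } else {
    state_names <- c("cdk46", "repressor", "mrna", "ccna2", "cdk2", "rb_phos")
    rhs <- function(t, y, p) {
      with(as.list(c(y, p)), {
        lam_m <- log(2) / mrna_half_life
        lam_p <- log(2) / protein_half_life
        cdk4_gate <- cdk46^hill_rep / (K_cdk4^hill_rep + cdk46^hill_rep)
        rep_target <- if (isTRUE(p$knockout_repressor)) 0 else 1 - cdk4_gate
        d_cdk46 <- (p$S - cdk46) / tau4
        d_rep <- (rep_target - repressor) / tau_rep
        d_mrna <- if (isTRUE(p$constitutive_ccna2)) {
          lam_m * (1 - mrna)
        } else {
          lam_m * (1 - repressor) - lam_m * mrna
        }
        d_ccna2 <- lam_p * mrna - lam_p * ccna2
        d_cdk2 <- (cdk2_max * ccna2 / (K_ccna2 + ccna2) - cdk2) / tau_cdk2
        d_rb <- kp_rb * cdk2 * (1 - rb_phos) - k_dephos_rb * rb_phos
        list(c(d_cdk46, d_rep, d_mrna, d_ccna2, d_cdk2, d_rb))
      })
    }
  }
  structure(
    list(architecture = architecture, params = params,
         state_names = state_names, rhs = rhs),
    class = "network_model"
  )
}

#' @export
print.network_model <- function(x, ...) {
  cat("<network_model> ", x$architecture, " (",
      length(x$state_names), " states: ",
      paste(x$state_names, collapse = ", "), ")\n", sep = "")
  invisible(x)
}

#' Mitogen schedules
#'
#' A piecewise-constant mitogen input plus perturbation flags: segments are
#' given as (start hour, level) pairs covering `t >= 0`;
#' `knockout_repressor` removes p107/p130 (transcription can no longer be
#' repressed) and `constitutive_ccna2` uncouples CCNA2 transcription from
#' the repressor (unregulated-promoter rescue).
#'
#' @param starts Segment start times in hours; the first must be 0.
#' @param levels Mitogen levels in `[0, 1]`, one per segment.
#' @param knockout_repressor,constitutive_ccna2 Perturbation flags.
#' @return An object of class `mitogen_schedule`.
#' @examples
#' mitogen_schedule(c(0), c(0))             # mitogen removal at t = 0
#' mitogen_schedule(c(0, 24), c(0, 1))      # re-addition at 24 h
#' @export
mitogen_schedule <- function(starts = 0, levels = 0,
                             knockout_repressor = FALSE,
                             constitutive_ccna2 = FALSE) {
  if (length(starts) != length(levels)) {
    abort("`starts` and `levels` must have equal length.")
  }
  if (starts[1] != 0 || is.unsorted(starts, strictly = TRUE)) {
    abort("Segments must start at t = 0 and be strictly increasing.")
  }
  if (any(levels < 0 | levels > 1)) abort("Mitogen levels must lie in [0, 1].")
  structure(
    list(starts = starts, levels = levels,
         knockout_repressor = isTRUE(knockout_repressor),
         constitutive_ccna2 = isTRUE(constitutive_ccna2)),
    class = "mitogen_schedule"
  )
}

mitogen_at <- function(schedule, t) {
  schedule$levels[findInterval(t, schedule$starts)]
}

# Proliferating (high-branch) and quiescent (low-branch) initial states at
# mitogen level S.
branch_init <- function(model, S, init = c("HIGH", "LOW")) {
  init <- match.arg(init)
  if (model$architecture == "FEEDBACK") {
    y <- if (init == "HIGH") c(cdk46 = S, e2f = 1.5, cdk2 = 1.2, rb_phos = 0.7)
         else c(cdk46 = S, e2f = 0, cdk2 = 0, rb_phos = 0)
  } else {
    y <- if (init == "HIGH") {
      c(cdk46 = 1, repressor = 0, mrna = 1, ccna2 = 1, cdk2 = 1.2,
        rb_phos = 2 / 3)
    } else {
      c(cdk46 = 0, repressor = 1, mrna = 0, ccna2 = 0, cdk2 = 0, rb_phos = 0)
    }
  }
  y
}

#' Simulate a network trajectory under a mitogen schedule
#'
#' Integrates the model with a stiff-capable solver (`deSolve::ode`,
#' lsoda), segment by segment over the piecewise-constant mitogen input,
#' reporting states on a 0.1 h grid.
#'
#' @param model A [build_network()] result.
#' @param schedule A [mitogen_schedule()].
#' @param horizon Hours to simulate (> 0).
#' @param init Initial branch: `"HIGH"` (proliferating) or `"LOW"`
#'   (quiescent), or a named numeric state vector.
#' @param dt Output grid step in hours.
#' @param rtol Relative integration tolerance.
#' @return A tibble with `time_h`, one column per state, and `mitogen`.
#' @examples
#' m <- build_network("FEEDFORWARD")
#' tr <- simulate_network(m, mitogen_schedule(0, 0), horizon = 24)
#' @export
simulate_network <- function(model, schedule, horizon, init = "HIGH",
                             dt = 0.1, rtol = 1e-8) {
  stopifnot(inherits(model, "network_model"),
            inherits(schedule, "mitogen_schedule"))
  if (horizon <= 0) abort("`horizon` must be positive.")
  y <- if (is.character(init)) {
    branch_init(model, mitogen_at(schedule, 0), init)
  } else {
    stats::setNames(as.numeric(init), model$state_names)
  }
  p <- model$params
  p$knockout_repressor <- schedule$knockout_repressor
  p$constitutive_ccna2 <- schedule$constitutive_ccna2
  bounds <- c(schedule$starts[schedule$starts < horizon], horizon)
  pieces <- list()
  for (k in seq_len(length(bounds) - 1)) {
    p$S <- schedule$levels[k]
    tseq <- seq(bounds[k], bounds[k + 1], by = dt)
    if (tail(tseq, 1) < bounds[k + 1]) tseq <- c(tseq, bounds[k + 1])
    sol <- deSolve::ode(y, tseq, model$rhs, p, method = "lsoda",
                        rtol = rtol, atol = rtol * 0.01)
    if (attr(sol, "istate")[1] < 0) {
      abort(paste0("Integration failed in segment ", k, " (t = ", bounds[k],
                   "-", bounds[k + 1], " h) of the ", model$architecture,
                   " model."))
    }
    y <- sol[nrow(sol), -1]
    piece <- tibble::as_tibble(as.data.frame(sol))
    names(piece)[1] <- "time_h"
    piece$mitogen <- schedule$levels[k]
    pieces[[k]] <- if (k > 1) piece[-1, ] else piece
  }
  out <- dplyr::bind_rows(pieces)
  out[out < 0 & out > -1e-9] <- 0 # clip integrator round-off
  out
}

#' Steady state of a network at fixed mitogen level
#'
#' Integrates from the designated branch initial condition until the
#' derivative norm falls below `tol` (capped at `max_hours`).
#'
#' @inheritParams simulate_network
#' @param S Mitogen level in `[0, 1]`.
#' @param tol Convergence threshold on `max |dx/dt|`.
#' @param max_hours Integration cap.
#' @return A named numeric state vector with attribute `converged`.
#' @export
steady_state <- function(model, S, init = c("HIGH", "LOW"), tol = 1e-8,
                         max_hours = 500) {
  init <- match.arg(init)
  if (S < 0 || S > 1) abort("`S` must lie in [0, 1].")
  p <- model$params
  p$S <- S
  y <- branch_init(model, S, init)
  t_done <- 0
  repeat {
    chunk <- min(100, max_hours - t_done)
    sol <- deSolve::ode(y, c(0, chunk), model$rhs, p, method = "lsoda",
                        rtol = 1e-10, atol = 1e-12)
    y <- sol[nrow(sol), -1]
    t_done <- t_done + chunk
    dmax <- max(abs(unlist(model$rhs(t_done, y, p))))
    if (dmax < tol || t_done >= max_hours) break
  }
  converged <- dmax < tol
  if (!converged) {
    warning("Steady state not reached within ", max_hours,
            " h (max |dx/dt| = ", signif(dmax, 3), ").")
  }
  structure(y, converged = converged)
}

#' CDK2 dose-response to MEK inhibition
#'
#' Maps each MEKi dose `d` to mitogen level `S = 1 - d`, then reports CDK2
#' activity at `eval_time` (or at steady state with `eval_time = Inf`) from
#' the requested branch initial condition: `HIGH` corresponds to post-R
#' cells (proliferating when treated), `LOW` to pre-R cells.
#'
#' @inheritParams simulate_network
#' @param doses MEKi doses in `[0, 1]`.
#' @param eval_time Evaluation time in hours, or `Inf` for steady state.
#' @return A tibble with `dose`, `mitogen`, `branch`, `cdk2`.
#' @export
dose_response <- function(model, doses, eval_time, init = c("HIGH", "LOW")) {
  init <- match.arg(init)
  if (any(doses < 0 | doses > 1)) abort("`doses` must lie in [0, 1].")
  cdk2 <- vapply(doses, function(d) {
    S <- 1 - d
    if (is.infinite(eval_time)) {
      unname(steady_state(model, S, init)[["cdk2"]])
    } else {
      tr <- simulate_network(model, mitogen_schedule(0, S), horizon = eval_time,
                             init = init)
      tr$cdk2[nrow(tr)]
    }
  }, numeric(1))
  tibble::tibble(dose = doses, mitogen = 1 - doses, branch = init, cdk2 = cdk2)
}

#' Hysteresis width of the CDK2 dose-response
#'
#' Scans both branch curves over a fine mitogen grid at the given
#' evaluation time and measures the gap between the mitogen level at which
#' the LOW (quiescent) branch switches on and the level at which the HIGH
#' (proliferating) branch switches off, each defined by the half-maximal
#' CDK2 crossing found by monotone interpolation. A branch that never
#' crosses is assigned the grid boundary (0 for a high branch that never
#' switches off). Width 0 (within grid resolution) means no hysteresis.
#'
#' @inheritParams dose_response
#' @param dose_resolution Grid step of the mitogen scan.
#' @return A one-row tibble with `width`, `up_threshold`, `down_threshold`
#'   (mitogen units) and `half_max`.
#' @export
hysteresis_width <- function(model, eval_time = Inf, dose_resolution = 0.005) {
  S_grid <- seq(0, 1, by = dose_resolution)
  hi <- dose_response(model, 1 - S_grid, eval_time, "HIGH")$cdk2
  lo <- dose_response(model, 1 - S_grid, eval_time, "LOW")$cdk2
  half_max <- (max(hi, lo) + min(hi, lo)) / 2
  cross_up <- function(curve) {
    # smallest S at which the curve reaches half-max (curves rise with S)
    if (max(curve) < half_max) return(1)
    if (curve[1] >= half_max) return(0)
    j <- which(curve >= half_max)[1]
    approx(curve[(j - 1):j], S_grid[(j - 1):j], xout = half_max)$y
  }
  mono_tol <- 0.05 * max(hi, lo)
  if (any(diff(hi) < -mono_tol) || any(diff(lo) < -mono_tol)) {
    abort("Branch dose-response curve is not monotone in mitogen level; cannot place half-max thresholds.")
  }
  up <- cross_up(lo)
  down <- cross_up(hi)
  tibble::tibble(width = max(up - down, 0), up_threshold = up,
                 down_threshold = down, half_max = half_max)
}
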