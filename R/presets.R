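#' Cell-line population presets
#'
#' A preset bundles the kinetic and clock parameters that characterise one
#' cell line in the competing-clocks model: the cyclin A2 protein and mRNA
#' half-lives that set the cell-cycle exit clock, the threshold ratio
#' (pre-treatment cyclin A2 relative to the level at which CDK2 activity
#' crosses the 0.6 commitment threshold), the mitosis-clock distribution,
#' and the cell-to-cell dispersion of the exit clock.
#'
#' Built-in presets differ only in cyclin A2 protein half-life:
#' `MCF10A` 12 h, `RPE1` 10 h, `RPE1_CCNA2dd` 5 h (inducible degron tag),
#' `RPE1_CCNA2dd_DIA` 2 h (degron plus DIA cocktail), `U2OS` 13 h.
#'
#' @param name Preset label, one of `"MCF10A"`, `"RPE1"`, `"RPE1_CCNA2dd"`,
#'   `"RPE1_CCNA2dd_DIA"`, `"U2OS"`.
#' @return An object of class `population_preset`: a list with fields
#'   `name`, `protein_half_life` (h), `mrna_half_life` (h),
#'   `threshold_ratio`, `mitosis_clock` (a [clock_distribution()]),
#'   `exit_clock_dispersion` (log-scale s.d.), `s_to_m_duration_median` (h)
#'   and `treatment_offset_window` (h).
#' @examples
#' make_preset("MCF10A")$protein_half_life
#' @export
make_preset <- function(name) {
  half_lives <- c(
    MCF10A = 12, RPE1 = 10, RPE1_CCNA2dd = 5, RPE1_CCNA2dd_DIA = 2,
    U2OS = 13
  )
  if (length(name) != 1L || !name %in% names(half_lives)) {
    abort(paste0(
      "Unknown preset '", paste(name, collapse = ","), "'. Available presets: ",
      paste(names(half_lives), collapse = ", ")
    ))
  }
  structure(
    list(
      name = name,
      protein_half_life = unname(half_lives[[name]]),
      mrna_half_life = 2,
      threshold_ratio = 2,
      mitosis_clock = clock_distribution("LOGNORMAL", median = 11, log_sd = 0.18),
      exit_clock_dispersion = 0.22,
      s_to_m_duration_median = 14,
      s_to_m_log_sd = 0.10,
      treatment_offset_window = 6
    ),
    class = "population_preset"
  )
}

#' @export
print.population_preset <- function(x, ...) {
  cat("<population_preset> ", x$name, "\n", sep = "")
  cat("  cyclin A2 protein half-life: ", x$protein_half_life, " h\n", sep = "")
  cat("  cyclin A2 mRNA half-life:    ", x$mrna_half_life, " h\n", sep = "")
  cat("  threshold ratio (rho):       ", x$threshold_ratio, "\n", sep = "")
  cat("  mitosis clock:               LOGNORMAL(median ",
      x$mitosis_clock$median, " h, log-sd ", x$mitosis_clock$log_sd, ")\n",
      sep = "")
  invisible(x)
}

treatment_labels <- c(
  "DMSO", "MITOGEN_REMOVAL", "MEKI", "CDK46I", "CDK1I", "CDK46I_CDK1I",
  "MEKI_DOSE"
)

#' Treatment programs
#'
#' Describes the perturbation applied to a simulated population: the drug
#' (or vehicle) label, an optional S-phase stall that extends the mitosis
#' clock, an optional unregulated-promoter cyclin A2 rescue, and the time on
#' the recording clock at which the treatment lands.
#'
#' Labels: `DMSO` (vehicle; neither clock triggered), `MITOGEN_REMOVAL`,
#' `MEKI`, `CDK46I` (all three block the mitogen arm and start the exit
#' clock), `CDK1I` (blocks mitosis only), `CDK46I_CDK1I` (both), and
#' `MEKI_DOSE` (partial MEK inhibition at relative `dose`; in the trace
#' generator only the full dose triggers the exit clock, partial doses are
#' interpreted by the ODE module as mitogen level `S = 1 - dose`).
#'
#' @param label One of the labels above.
#' @param delay_hours Non-negative S-phase stall added to the mitosis clock
#'   (the standard series uses 0, 2, 4, 6 h).
#' @param constitutive_ccna2 If `TRUE`, cyclin A2 is expressed from an
#'   unregulated promoter and the exit clock never fires.
#' @param treatment_time Hours on the recording clock at which treatment is
#'   applied.
#' @param dose Relative dose in `[0, 1]`, used by `MEKI_DOSE` only.
#' @return An object of class `treatment_program`.
#' @examples
#' treatment_program("CDK46I", delay_hours = 2)
#' @export
treatment_program <- function(label, delay_hours = 0, constitutive_ccna2 = FALSE,
                              treatment_time = 12, dose = 1) {
  if (length(label) != 1L || !label %in% treatment_labels) {
    abort(paste0(
      "Unknown treatment '", paste(label, collapse = ","),
      "'. Available: ", paste(treatment_labels, collapse = ", ")
    ))
  }
  if (!is.numeric(delay_hours) || delay_hours < 0) {
    abort("`delay_hours` must be a non-negative number of hours.")
  }
  if (!is.numeric(dose) || dose < 0 || dose > 1) {
    abort("`dose` must lie in [0, 1].")
  }
  structure(
    list(
      label = label,
      delay_hours = delay_hours,
      constitutive_ccna2 = isTRUE(constitutive_ccna2),
      treatment_time = treatment_time,
      dose = dose
    ),
    class = "treatment_program"
  )
}

#' @export
print.treatment_program <- function(x, ...) {
  cat("<treatment_program> ", x$label,
      if (x$label == "MEKI_DOSE") paste0(" (dose ", x$dose, ")"),
      " at t = ", x$treatment_time, " h",
      if (x$delay_hours > 0) paste0(", +", x$delay_hours, " h S-phase delay"),
      if (x$constitutive_ccna2) ", constitutive cyclin A2",
      "\n", sep = "")
  invisible(x)
}

# Does this treatment start the cell-cycle exit clock (loss of the mitogen
# arm)?  Mitogen removal, MEKi and CDK4/6i are equivalent triggers; partial
# MEKi doses below 1 leave enough mitogen signalling to maintain cyclin A2.
triggers_exit_clock <- function(treatment) {
  if (treatment$constitutive_ccna2) return(FALSE)
  lab <- treatment$label
  lab %in% c("MITOGEN_REMOVAL", "MEKI", "CDK46I", "CDK46I_CDK1I") ||
    (lab == "MEKI_DOSE" && treatment$dose >= 1)
}

# Does this treatment disable the mitosis clock?
blocks_mitosis <- function(treatment) {
  treatment$label %in% c("CDK1I", "CDK46I_CDK1I")
}
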