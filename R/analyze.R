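#' Trace-analysis configuration
#'
#' Thresholds and debounce windows used to extract landmarks from reporter
#' traces. CDK2 activity below `cdk2_exit_threshold` (default 0.6, the
#' commitment threshold) sustained for `exit_sustain_hours` marks
#' cell-cycle exit; APC/C activity below `apc_off_threshold` sustained for
#' `apc_sustain_hours` marks S-phase entry; a one-frame CDK2 collapse of at
#' least `mitosis_drop_fraction` of the running maximum marks mitosis when
#' no division events are recorded.
#'
#' @param cdk2_exit_threshold CDK2 exit threshold (0 < theta < 1.5).
#' @param apc_off_threshold APC/C inactivation threshold.
#' @param exit_sustain_hours Hours a CDK2 crossing must persist.
#' @param apc_sustain_hours Hours an APC/C crossing must persist.
#' @param mitosis_drop_fraction One-frame drop fraction for the fallback
#'   mitosis detector.
#' @return An object of class `analysis_config`.
#' @export
analysis_config <- function(cdk2_exit_threshold = 0.6, apc_off_threshold = 0.5,
                            exit_sustain_hours = 2, apc_sustain_hours = 1,
                            mitosis_drop_fraction = 0.5) {
  if (cdk2_exit_threshold <= 0 || cdk2_exit_threshold >= 1.5) {
    abort("`cdk2_exit_threshold` must lie in (0, 1.5).")
  }
  structure(
    list(cdk2_exit_threshold = cdk2_exit_threshold,
         apc_off_threshold = apc_off_threshold,
         exit_sustain_hours = exit_sustain_hours,
         apc_sustain_hours = apc_sustain_hours,
         mitosis_drop_fraction = mitosis_drop_fraction),
    class = "analysis_config"
  )
}

# Candidate downward crossings of `values` below `threshold`, scored with a
# noise-tolerant debounce: a crossing counts if at least 90% of the frames
# in the following `sustain` window stay below the threshold (a one-frame
# blip is rejected, a one-frame upward noise spike does not disqualify a
# genuine crossing). The window must fit inside the recording.
sustained_crossings <- function(times, values, threshold, sustain) {
  below <- values < threshold
  n <- length(times)
  starts <- which(below & !c(FALSE, below[-n]))
  keep <- logical(length(starts))
  for (k in seq_along(starts)) {
    j <- starts[k]
    if (times[j] + sustain > times[n] + 1e-9) next
    win <- times >= times[j] & times <= times[j] + sustain + 1e-9
    keep[k] <- mean(below[win]) >= 0.9
  }
  starts[keep]
}

#' Detect S-phase entry from the APC/C channel
#'
#' APC/C inactivation marks S-phase entry: the first time APC/C activity
#' falls below the off-threshold and stays below for the debounce window.
#'
#' @param trace A single-cell tibble with columns `time_h` and `apc`.
#' @param cfg An [analysis_config()].
#' @return The S-entry time in hours, or `NA` if the APC/C never switches
#'   off.
#' @export
detect_s_entry <- function(trace, cfg = analysis_config()) {
  if (!"apc" %in% names(trace) || all(is.na(trace$apc))) {
    abort("Trace has no `apc` channel; S-phase entry needs the APC/C reporter.")
  }
  idx <- sustained_crossings(trace$time_h, trace$apc, cfg$apc_off_threshold,
                             cfg$apc_sustain_hours)
  if (length(idx) == 0) NA_real_ else trace$time_h[idx[1]]
}

#' Detect mitosis
#'
#' If division events are recorded (`divided` flag), mitosis is the first
#' division after the treatment time. Otherwise a one-frame collapse of
#' CDK2 activity by at least `mitosis_drop_fraction` of its running
#' maximum, while that maximum exceeds 1.0, is scored as mitosis.
#'
#' @param trace A single-cell tibble with `time_h`, `cdk2` and optionally
#'   `divided` and `treatment_time_h`.
#' @inheritParams detect_s_entry
#' @return Mitosis time in hours, or `NA`.
#' @export
detect_mitosis <- function(trace, cfg = analysis_config()) {
  tt <- if ("treatment_time_h" %in% names(trace)) trace$treatment_time_h[1] else -Inf
  if ("divided" %in% names(trace) && any(trace$divided == 1)) {
    dts <- trace$time_h[trace$divided == 1]
    dts <- dts[dts > tt]
    return(if (length(dts)) dts[1] else NA_real_)
  }
  v <- trace$cdk2
  n <- length(v)
  if (n < 2) return(NA_real_)
  rmax <- cummax(v)
  drop <- c(0, v[-n] - v[-1])
  hit <- which(drop >= cfg$mitosis_drop_fraction * c(0, rmax[-n]) &
                 c(0, rmax[-n]) > 1.0)
  if (length(hit)) trace$time_h[hit[1]] else NA_real_
}

#' Detect cell-cycle exit
#'
#' The first time after treatment that CDK2 activity crosses below the exit
#' threshold and remains below for the debounce window, with no division
#' between treatment and the crossing (a post-mitotic daughter's low CDK2
#' is not an exit). The crossing time is linearly interpolated between the
#' bracketing frames.
#'
#' @inheritParams detect_mitosis
#' @return Exit time in hours, or `NA`.
#' @export
detect_exit <- function(trace, cfg = analysis_config()) {
  tt <- if ("treatment_time_h" %in% names(trace)) trace$treatment_time_h[1] else -Inf
  times <- trace$time_h
  v <- trace$cdk2
  theta <- cfg$cdk2_exit_threshold
  idx <- sustained_crossings(times, v, theta, cfg$exit_sustain_hours)
  idx <- idx[times[idx] > tt]
  if (length(idx) == 0) return(NA_real_)
  first_div <- Inf
  if ("divided" %in% names(trace) && any(trace$divided == 1)) {
    dts <- times[trace$divided == 1]
    dts <- dts[dts > tt]
    if (length(dts)) first_div <- dts[1]
  }
  for (j in idx) {
    # a crossing at or after a division is the mitotic collapse (or a
    # daughter's G1 state), not an exit
    if (times[j] >= first_div) return(NA_real_)
    if (j == 1) return(times[1])
    # interpolate the theta crossing between frames j-1 and j (v0 >= theta
    # by construction of the run start, v1 < theta)
    t0 <- times[j - 1]; t1 <- times[j]
    v0 <- v[j - 1]; v1 <- v[j]
    return(t0 + (v0 - theta) / (v0 - v1) * (t1 - t0))
  }
  NA_real_
}

#' Classify per-cell fates from a trace table
#'
#' Extracts S-phase entry, mitosis and exit landmarks for every cell,
#' decides pre-/post-R status at the treatment frame (APC/C off, with a 1 h
#' boundary grace for cells treated just after APC/C inactivation), and
#' assigns the fate by the earlier of the two events: `MITOSIS`, `EXIT`,
#' `COMMITTED` (CDK2 still above threshold at the end of the recording with
#' neither event) or `PRE_R`. Endpoint states: `G0LIKE_4N` (exit without
#' division), `G0_2N` (division followed by daughter arrest), `CYCLING`
#' (repeated division), `COMMITTED_HIGH`.
#'
#' @param traces A long trace tibble (see [generate_population()]).
#' @inheritParams detect_s_entry
#' @return A tibble with one row per cell: `cell_id`, `s_entry_time`,
#'   `mitosis_time`, `exit_time`, `post_r_at_treatment`,
#'   `treatment_offset`, `fate`, `endpoint`.
#' @export
classify_fates <- function(traces, cfg = analysis_config()) {
  needed <- c("cell_id", "time_h", "cdk2", "apc", "treatment_time_h")
  missing_cols <- setdiff(needed, names(traces))
  if (length(missing_cols)) {
    abort(paste0("Trace table is missing column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  traces |>
    dplyr::group_by(.data$cell_id) |>
    dplyr::group_modify(~ classify_one(.x, cfg)) |>
    dplyr::ungroup()
}

classify_one <- function(tr, cfg) {
  tt <- tr$treatment_time_h[1]
  s_entry <- detect_s_entry(tr, cfg)
  m_time <- detect_mitosis(tr, cfg)
  e_time <- detect_exit(tr, cfg)
  apc_at_tt <- tr$apc[which.min(abs(tr$time_h - tt))]
  post_r <- isTRUE(apc_at_tt < cfg$apc_off_threshold) ||
    (!is.na(s_entry) && tt - s_entry >= 0 && tt - s_entry <= 1)
  offset <- if (post_r && !is.na(s_entry) && s_entry <= tt) tt - s_entry else NA_real_

  if (!post_r) {
    fate <- "PRE_R"
    endpoint <- NA_character_
  } else if (is.na(m_time) && is.na(e_time)) {
    fate <- "COMMITTED"
    endpoint <- "COMMITTED_HIGH"
  } else if (!is.na(e_time) && (is.na(m_time) || e_time < m_time)) {
    fate <- "EXIT"
    m_time <- NA_real_
    endpoint <- "G0LIKE_4N"
  } else {
    fate <- "MITOSIS"
    e_time <- NA_real_
    n_div <- if ("divided" %in% names(tr)) sum(tr$divided == 1 & tr$time_h > tt) else 1L
    last <- nrow(tr)
    arrested <- tr$cdk2[last] < cfg$cdk2_exit_threshold &&
      tr$apc[last] > cfg$apc_off_threshold
    endpoint <- if (n_div >= 2) "CYCLING" else if (arrested) "G0_2N" else "CYCLING"
  }
  tibble::tibble(
    s_entry_time = s_entry,
    mitosis_time = m_time,
    exit_time = e_time,
    post_r_at_treatment = post_r,
    treatment_offset = offset,
    fate = fate,
    endpoint = endpoint
  )
}

#' Exit fraction binned by cell-cycle position at treatment
#'
#' Bins post-R cells by their treatment offset (hours since S-phase entry
#' when the treatment landed) and reports the fraction that exited among
#' cells with a decided fate (exits / (exits + mitoses)) per bin. Cells
#' closer to S-phase entry at treatment are expected to exit more often.
#'
#' @param features A [classify_fates()] table restricted to post-R cells
#'   (pre-R rows are dropped with a message if present).
#' @param bin_width Bin width in hours (> 0).
#' @return A tibble with `bin_mid`, `n` (decided cells), `k` (exits) and
#'   `fraction`; empty bins are reported with `n = 0`.
#' @export
exit_fraction_by_offset <- function(features, bin_width = 1) {
  if (!is.numeric(bin_width) || bin_width <= 0) {
    abort("`bin_width` must be a positive number of hours.")
  }
  f <- dplyr::filter(features, .data$post_r_at_treatment,
                     !is.na(.data$treatment_offset))
  if (nrow(f) == 0) {
    return(tibble::tibble(bin_mid = numeric(), n = integer(), k = integer(),
                          fraction = numeric()))
  }
  f <- dplyr::filter(f, .data$fate %in% c("EXIT", "MITOSIS"))
  edges <- seq(0, ceiling(max(f$treatment_offset) / bin_width) * bin_width,
               by = bin_width)
  if (length(edges) < 2) edges <- c(0, bin_width)
  f$bin <- cut(f$treatment_offset, breaks = edges, include.lowest = TRUE,
               right = FALSE)
  counts <- f |>
    dplyr::count(.data$bin, .data$fate) |>
    tidyr::pivot_wider(names_from = "fate", values_from = "n",
                       values_fill = 0L)
  all_bins <- tibble::tibble(bin = cut(edges[-length(edges)] + bin_width / 2,
                                       breaks = edges, include.lowest = TRUE,
                                       right = FALSE))
  out <- dplyr::left_join(all_bins, counts, by = "bin")
  k <- if ("EXIT" %in% names(out)) tidyr::replace_na(out$EXIT, 0L) else rep(0L, nrow(out))
  m <- if ("MITOSIS" %in% names(out)) tidyr::replace_na(out$MITOSIS, 0L) else rep(0L, nrow(out))
  tibble::tibble(
    bin_mid = edges[-length(edges)] + bin_width / 2,
    n = as.integer(k + m),
    k = as.integer(k),
    fraction = ifelse(k + m > 0, k / (k + m), NA_real_)
  )
}

#' Logistic regression of exit outcome on treatment offset
#'
#' Maximum-likelihood logistic fit of the per-cell binary outcome (exit = 1,
#' mitosis = 0) on the treatment offset, with a two-sided Wald test of the
#' slope. A single-outcome population (e.g. vehicle-treated cells, which
#' never exit) or perfect separation is flagged as degenerate rather than
#' silently returned.
#'
#' @param features A [classify_fates()] table.
#' @return An object of class `exit_logistic` with fields `slope`,
#'   `intercept`, `slope_se`, `p_value`, `degenerate`, `reason`, `n`, and
#'   the underlying `fit` when non-degenerate. Use [tidy()] / [glance()]
#'   for tabular summaries.
#' @export
fit_exit_logistic <- function(features) {
  f <- dplyr::filter(features, .data$post_r_at_treatment,
                     .data$fate %in% c("EXIT", "MITOSIS"),
                     !is.na(.data$treatment_offset))
  res <- list(slope = NA_real_, intercept = NA_real_, slope_se = NA_real_,
              p_value = NA_real_, degenerate = TRUE, reason = NULL,
              n = nrow(f), fit = NULL)
  if (nrow(f) == 0) {
    res$reason <- "no decided post-R cells"
    return(structure(res, class = "exit_logistic"))
  }
  y <- as.integer(f$fate == "EXIT")
  if (length(unique(y)) < 2) {
    res$reason <- "single outcome class"
    return(structure(res, class = "exit_logistic"))
  }
  if (length(unique(f$treatment_offset)) < 2) {
    res$reason <- "degenerate offsets"
    return(structure(res, class = "exit_logistic"))
  }
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    glm(y ~ offset_h, data = data.frame(y = y, offset_h = f$treatment_offset),
        family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                conditionMessage(w))) {
        sep_warn <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  slope <- coef(fit)[["offset_h"]]
  se <- summary(fit)$coefficients["offset_h", "Std. Error"]
  if (sep_warn || abs(slope) > 15) {
    res$reason <- "perfect separation"
    res$slope <- sign(slope) * Inf
    return(structure(res, class = "exit_logistic"))
  }
  z <- slope / se
  structure(
    list(slope = slope, intercept = coef(fit)[["(Intercept)"]], slope_se = se,
         p_value = 2 * pnorm(-abs(z)), degenerate = FALSE, reason = NULL,
         n = length(y), fit = fit),
    class = "exit_logistic"
  )
}

#' @export
print.exit_logistic <- function(x, ...) {
  if (x$degenerate) {
    cat("<exit_logistic> degenerate (", x$reason, "), n = ", x$n, "\n", sep = "")
  } else {
    cat("<exit_logistic> slope = ", signif(x$slope, 4), " per h (SE ",
        signif(x$slope_se, 3), "), Wald p = ", format(x$p_value, digits = 3),
        ", n = ", x$n, "\n", sep = "")
  }
  invisible(x)
}

#' @rdname fit_exit_logistic
#' @param x An `exit_logistic` object.
#' @param ... Unused.
#' @method tidy exit_logistic
#' @export
tidy.exit_logistic <- function(x, ...) {
  if (x$degenerate) {
    return(tibble::tibble(term = character(), estimate = numeric(),
                          std.error = numeric(), statistic = numeric(),
                          p.value = numeric()))
  }
  s <- summary(x$fit)$coefficients
  tibble::tibble(
    term = rownames(s), estimate = s[, "Estimate"],
    std.error = s[, "Std. Error"], statistic = s[, "z value"],
    p.value = s[, "Pr(>|z|)"]
  )
}

#' @rdname fit_exit_logistic
#' @method glance exit_logistic
#' @export
glance.exit_logistic <- function(x, ...) {
  tibble::tibble(
    slope = x$slope, intercept = x$intercept, slope_se = x$slope_se,
    p_value = x$p_value, degenerate = x$degenerate, n = x$n
  )
}

#' Cell ordering for fate heat maps
#'
#' Orders cells the way commitment heat maps are drawn: dividing cells
#' first in ascending order of mitosis time, then non-dividers in ascending
#' order of exit time (committed cells, with neither event, last). Ties
#' preserve input order.
#'
#' @param features A [classify_fates()] table.
#' @return A character vector of `cell_id`s in display order.
#' @export
order_for_heatmap <- function(features) {
  dividers <- !is.na(features$mitosis_time)
  top <- features[dividers, ]
  bottom <- features[!dividers, ]
  c(top$cell_id[order(top$mitosis_time)],
    bottom$cell_id[order(bottom$exit_time, na.last = TRUE)])
}
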