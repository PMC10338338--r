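# Hand-built single-cell traces on a regular grid for detector tests.
make_trace <- function(times, cdk2 = NULL, apc = NULL, divided = NULL,
                       treatment_time = 0, cell_id = "c1") {
  n <- length(times)
  tibble::tibble(
    cell_id = cell_id,
    time_h = times,
    cdk2 = if (is.null(cdk2)) rep(1, n) else cdk2,
    apc = if (is.null(apc)) rep(1, n) else apc,
    ccna2 = NA_real_,
    divided = if (is.null(divided)) rep(0L, n) else divided,
    treatment = "TEST",
    treatment_time_h = treatment_time,
    preset = "TEST"
  )
}

# A features table built directly (bypassing trace generation) for logistic
# and binning tests.
make_features <- function(offset, fate, post_r = TRUE) {
  tibble::tibble(
    cell_id = sprintf("c%04d", seq_along(offset)),
    s_entry_time = 0,
    mitosis_time = ifelse(fate == "MITOSIS", 20, NA_real_),
    exit_time = ifelse(fate == "EXIT", 20, NA_real_),
    post_r_at_treatment = post_r,
    treatment_offset = offset,
    fate = fate,
    endpoint = NA_character_
  )
}
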