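#' Multichannel ECG recording
#'
#' Container for sampled lead signals on one shared time axis (1 ms default
#' step), with optional beat annotations (QRS onset and J-point).
#'
#' @param signals n_leads x n_time numeric matrix (mV).
#' @param times Time axis (ms).
#' @param leads Lead names.
#' @param lead_system One of `"electrodes"`, `"bspm"`, `"12lead"`, `"vcg"`.
#' @param qrs_onset,j_point Optional annotations (ms).
#' @return An object of class `ecg_recording`.
#' @export
ecg_recording <- function(signals, times, leads, lead_system,
                          qrs_onset = NULL, j_point = NULL) {
  signals <- as.matrix(signals)
  if (ncol(signals) != length(times))
    stop("signal columns must match the time axis", call. = FALSE)
  if (nrow(signals) != length(leads))
    stop("signal rows must match the lead names", call. = FALSE)
  rownames(signals) <- leads
  structure(list(signals = signals, times = as.numeric(times),
                 leads = as.character(leads), lead_system = lead_system,
                 qrs_onset = qrs_onset, j_point = j_point),
            class = "ecg_recording")
}

#' @export
print.ecg_recording <- function(x, ...) {
  cat(sprintf("ECG recording [%s]: %d leads x %d samples (%.0f-%.0f ms)\n",
              x$lead_system, length(x$leads), length(x$times),
              min(x$times), max(x$times)))
  if (!is.null(x$j_point)) cat(sprintf("  J-point: %.1f ms\n", x$j_point))
  invisible(x)
}

.std_electrodes <- c("RA", "LA", "LL", "RL", "V1", "V2", "V3", "V4", "V5", "V6")
.lead12_names <- c("I", "II", "III", "aVR", "aVL", "aVF",
                   "V1", "V2", "V3", "V4", "V5", "V6")

#' Derive the standard 12-lead ECG from electrode potentials
#'
#' Limb leads from RA/LA/LL, augmented leads from Goldberger's terminals,
#' and precordial leads V1-V6 referenced to the Wilson central terminal
#' (mean of RA, LA, LL). Lead III is computed as II - I, so the Einthoven
#' identity holds exactly (bit for bit) on every derived recording.
#'
#' @param rec An `ecg_recording` containing at least electrodes RA, LA, LL
#'   and V1..V6 (by name).
#' @return An `ecg_recording` with lead system `"12lead"`.
#' @export
derive_12lead <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  need <- setdiff(c("RA", "LA", "LL", paste0("V", 1:6)), rec$leads)
  if (length(need))
    stop("missing electrodes: ", paste(need, collapse = ", "), call. = FALSE)
  s <- rec$signals
  RA <- s["RA", ]; LA <- s["LA", ]; LL <- s["LL", ]
  wct <- (RA + LA + LL) / 3
  I <- LA - RA; II <- LL - RA
  # III computed from I and II so the Einthoven identity III = II - I holds
  # to the last bit (algebraically identical to LL - LA)
  out <- rbind(
    I = I, II = II, III = II - I,
    aVR = RA - (LA + LL) / 2, aVL = LA - (RA + LL) / 2, aVF = LL - (RA + LA) / 2,
    V1 = s["V1", ] - wct, V2 = s["V2", ] - wct, V3 = s["V3", ] - wct,
    V4 = s["V4", ] - wct, V5 = s["V5", ] - wct, V6 = s["V6", ] - wct)
  ecg_recording(out, rec$times, .lead12_names, "12lead",
                qrs_onset = rec$qrs_onset, j_point = rec$j_point)
}

#' Extract the 192-lead body-surface recording
#'
#' @param rec An `ecg_recording` of raw electrode potentials from
#'   [forward()].
#' @return An `ecg_recording` with lead system `"bspm"`.
#' @export
derive_bspm <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  rows <- grep("^B\\d{3}$", rec$leads)
  if (length(rows) != 192L)
    stop("recording does not contain the 192-electrode grid", call. = FALSE)
  ecg_recording(rec$signals[rows, , drop = FALSE], rec$times,
                rec$leads[rows], "bspm",
                qrs_onset = rec$qrs_onset, j_point = rec$j_point)
}

#' Vectorcardiographic signals from the dipole sequence
#'
#' The three orthogonal leads are the components of the summed total heart
#' vector in torso axes: X toward the left, Y toward the back (posterior),
#' Z cranial.
#'
#' @param seq A [build_sequence()] result.
#' @param qrs_onset,j_point Optional annotations (ms).
#' @return An `ecg_recording` with lead system `"vcg"`.
#' @export
derive_vcg <- function(seq, qrs_onset = NULL, j_point = NULL) {
  hv <- total_heart_vector(seq)
  ecg_recording(hv, seq$times, c("X", "Y", "Z"), "vcg",
                qrs_onset = qrs_onset, j_point = j_point)
}

#' Restrict a recording to one lead system
#'
#' @param rec Raw electrode recording (from [forward()]).
#' @param lead_system `"bspm"` or `"12lead"`.
#' @return The derived `ecg_recording`.
#' @export
derive_leads <- function(rec, lead_system = c("12lead", "bspm")) {
  lead_system <- match.arg(lead_system)
  if (lead_system == "12lead") derive_12lead(rec) else derive_bspm(rec)
}
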