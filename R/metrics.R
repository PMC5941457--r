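#' Locate the T-wave analysis window
#'
#' The window starts at the J-point. Its end is found from the across-lead
#' root-mean-square signal: after the global T-wave peak (the maximum of the
#' across-lead RMS beyond the J-point), the window ends at the first sample
#' whose RMS is at or below 0.005 mV. One shared window is used for all
#' leads so that the mean T-wave vectors of the two beats are co-registered.
#'
#' @param rec An `ecg_recording`.
#' @param j_point J-point (ms); defaults to the recording's annotation.
#' @param settle_threshold RMS settling threshold (mV), default 0.005.
#' @return List with `t_start` and `t_end` (ms).
#' @export
find_twave_window <- function(rec, j_point = rec$j_point,
                              settle_threshold = 0.005) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (is.null(j_point)) stop("no J-point annotation", call. = FALSE)
  tt <- rec$times
  if (j_point < tt[1] || j_point > tt[length(tt)])
    stop("J-point outside the beat window", call. = FALSE)
  sel <- which(tt >= j_point)
  rms <- sqrt(colMeans(rec$signals[, sel, drop = FALSE]^2))
  ipk <- which.max(rms)
  after <- which(rms <= settle_threshold & seq_along(rms) > ipk)
  if (ipk == 1L && rms[1] <= settle_threshold) after <- 2L # flat signal
  if (!length(after))
    stop("signal does not settle below the RMS threshold after the T peak",
         call. = FALSE)
  list(t_start = j_point, t_end = tt[sel[after[1]]])
}

#' Mean T-wave value of a sampled signal window
#'
#' Arithmetic mean of the samples between `t_start` and `t_end` (inclusive);
#' the divisor is the number of samples, making the result a true mean in mV
#' at any sampling rate.
#'
#' @param x Numeric vector of samples in the window.
#' @return Mean (mV).
#' @export
t_mean <- function(x) {
  if (!length(x)) stop("empty T-wave window", call. = FALSE)
  mean(x)
}

#' Per-lead mean T-wave vector
#'
#' @param rec An `ecg_recording`.
#' @param window A [find_twave_window()] result.
#' @return Named numeric vector (one mean per lead, mV).
#' @export
mean_twave_vector <- function(rec, window = find_twave_window(rec)) {
  sel <- rec$times >= window$t_start & rec$times <= window$t_end
  if (!any(sel)) stop("empty T-wave window", call. = FALSE)
  rowMeans(rec$signals[, sel, drop = FALSE])
}

#' Per-lead TWA amplitude (differential method)
#'
#' Absolute difference of the mean T-wave values of two consecutive beats,
#' per lead.
#'
#' @param t_even,t_odd Mean T-wave vectors of the even and odd beat.
#' @return Non-negative numeric vector (mV).
#' @export
twa_amplitude <- function(t_even, t_odd) {
  if (length(t_even) != length(t_odd))
    stop("mean T-wave vectors differ in dimension", call. = FALSE)
  abs(t_even - t_odd)
}

#' Vector magnitude alternans
#'
#' Euclidean norm of the difference of the even and odd mean T-wave vectors,
#' divided by the number of leads.
#'
#' @inheritParams twa_amplitude
#' @param n Number of leads; defaults to the vector dimension.
#' @return VMA (mV).
#' @export
vma <- function(t_even, t_odd, n = length(t_even)) {
  if (length(t_even) != length(t_odd))
    stop("mean T-wave vectors differ in dimension", call. = FALSE)
  if (n == 0) stop("lead count must be positive", call. = FALSE)
  sqrt(sum((t_even - t_odd)^2)) / n
}

#' Vector angle alternans
#'
#' Angle between the even and odd mean T-wave vectors: the arc cosine of
#' their cosine similarity (clamped to \[-1, 1\] against floating-point
#' overshoot).
#'
#' @inheritParams twa_amplitude
#' @return Angle in radians, in \[0, pi\].
#' @export
vaa <- function(t_even, t_odd) {
  if (length(t_even) != length(t_odd))
    stop("mean T-wave vectors differ in dimension", call. = FALSE)
  ne <- sqrt(sum(t_even^2)); no <- sqrt(sum(t_odd^2))
  if (ne == 0 || no == 0) {
    if (ne == 0 && no == 0) return(0)  # identical (null) beats
    stop("undefined angle: zero mean T-wave vector", call. = FALSE)
  }
  acos(max(-1, min(1, sum(t_even * t_odd) / (ne * no))))
}

#' QT interval of one beat
#'
#' Time from the Q point (global QRS onset, the earliest activation onset)
#' to the end of the T wave as located by [find_twave_window()].
#'
#' @param rec An `ecg_recording` with `qrs_onset` and `j_point` annotations.
#' @return QT interval (ms).
#' @export
qt_interval <- function(rec) {
  stopifnot(inherits(rec, "ecg_recording"))
  if (is.null(rec$qrs_onset)) stop("missing QRS onset annotation", call. = FALSE)
  w <- find_twave_window(rec)
  w$t_end - rec$qrs_onset
}

#' QT alternans of a beat pair
#'
#' Absolute difference of the QT intervals of the even and odd beat,
#' measured on the 12-lead recording.
#'
#' @param pair A [simulate_beat_pair()] result.
#' @return QT alternans (ms).
#' @export
qt_alternans <- function(pair) {
  leads <- beat_pair_leads(pair, "12lead")
  abs(qt_interval(leads$even) - qt_interval(leads$odd))
}

#' Lead with the maximal TWA amplitude
#'
#' Ties are broken by the canonical 12-lead order
#' (I, II, III, aVR, aVL, aVF, V1..V6).
#'
#' @param amplitudes Named per-lead TWA amplitudes (12-lead).
#' @return Lead name.
#' @export
max_twa_lead <- function(amplitudes) {
  ord <- intersect(.lead12_names, names(amplitudes))
  if (!length(ord)) ord <- names(amplitudes)
  a <- amplitudes[ord]
  ord[which.max(a)]  # which.max returns the first (canonical-order) maximum
}

#' TWA summary of a beat pair on one lead system
#'
#' Computes the shared T-wave window (union of both beats' windows so both
#' means are taken over the same support), the per-lead TWA amplitudes, VMA,
#' VAA, the 10 uV detection flags, and for the 12-lead system the maximal
#' lead and QT alternans.
#'
#' @param pair A [simulate_beat_pair()] result.
#' @param lead_system `"12lead"`, `"bspm"` or `"vcg"`.
#' @param detection_threshold Detection threshold in mV (default 0.010,
#'   i.e. 10 uV), boundary inclusive.
#' @return An object of class `twa_result`.
#' @export
compute_twa <- function(pair, lead_system = c("12lead", "bspm", "vcg"),
                        detection_threshold = 0.010) {
  lead_system <- match.arg(lead_system)
  leads <- beat_pair_leads(pair, lead_system)
  we <- find_twave_window(leads$even)
  wo <- find_twave_window(leads$odd)
  w <- list(t_start = min(we$t_start, wo$t_start),
            t_end = max(we$t_end, wo$t_end))
  te <- mean_twave_vector(leads$even, w)
  to <- mean_twave_vector(leads$odd, w)
  amp <- twa_amplitude(te, to)
  res <- list(
    lead_system = lead_system,
    window = w,
    t_mean_even = te, t_mean_odd = to,
    amplitudes = amp,
    vma = vma(te, to),
    vaa = vaa(te, to),
    detected = amp >= detection_threshold,
    max_lead = if (lead_system == "12lead") max_twa_lead(amp) else names(which.max(amp)),
    qt_alternans = if (lead_system == "12lead") qt_alternans(pair) else NA_real_,
    spec = pair$spec
  )
  structure(res, class = "twa_result")
}

#' @export
print.twa_result <- function(x, ...) {
  cat(sprintf("TWA result [%s] for %s %s %s\n", x$lead_system,
              x$spec$mechanism, x$spec$topology, x$spec$layer))
  cat(sprintf("  max TWA %.1f uV at %s; VMA %.2f uV; VAA %.3f rad\n",
              1000 * max(x$amplitudes), x$max_lead, 1000 * x$vma, x$vaa))
  if (!is.na(x$qt_alternans))
    cat(sprintf("  QT alternans %.1f ms\n", x$qt_alternans))
  cat(sprintf("  %d/%d leads at/above the 10 uV detection threshold\n",
              sum(x$detected), length(x$detected)))
  invisible(x)
}

#' Body-surface TWA amplitude map
#'
#' Arranges the 192 per-lead TWA amplitudes on the electrode grid: 12 rows
#' (cranial to caudal) by 16 columns (anterior midline, then leftward around
#' the torso), matching the row-major electrode ordering of the layout.
#' The per-map minimum and maximum are recorded so each map can be drawn on
#' its own scale.
#'
#' @param amplitudes 192 per-lead TWA amplitudes (BSPM ordering).
#' @param n_rows,n_cols Grid layout (12 x 16).
#' @return A `twa_map`: list with `map` (matrix), `min`, `max`.
#' @export
bspm_twa_map <- function(amplitudes, n_rows = 12L, n_cols = 16L) {
  if (length(amplitudes) != n_rows * n_cols)
    stop(sprintf("expected %d amplitudes for a %dx%d layout, got %d",
                 n_rows * n_cols, n_rows, n_cols, length(amplitudes)),
         call. = FALSE)
  m <- matrix(amplitudes, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  structure(list(map = m, min = min(m), max = max(m)), class = "twa_map")
}

#' Cosine similarity of two TWA maps
#'
#' Pattern-comparison metric used for map classification: the cosine of the
#' angle between the flattened amplitude maps.
#'
#' @param a,b `twa_map` objects or plain matrices.
#' @return Cosine similarity in \[-1, 1\].
#' @export
map_similarity <- function(a, b) {
  va <- as.numeric(if (inherits(a, "twa_map")) a$map else a)
  vb <- as.numeric(if (inherits(b, "twa_map")) b$map else b)
  sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
}
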