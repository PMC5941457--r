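#' Parameterized transmembrane action-potential template
#'
#' A smooth piecewise curve: resting potential before activation, a fast
#' cosine-ramp upstroke, a brief phase-1 decline from the peak to the plateau,
#' a constant phase-II plateau, and a cosine-shaped phase-3 repolarization
#' that reaches the resting potential exactly at the end of repolarization.
#' The end of repolarization is derived from the configured APD, defined as
#' APD90 (time from upstroke onset to 90% repolarization of the peak-to-rest
#' amplitude).
#'
#' @param rest Resting potential (mV).
#' @param peak Peak (end-of-upstroke) potential (mV).
#' @param plateau Phase-II plateau potential (mV).
#' @param upstroke Upstroke duration (ms).
#' @param notch Duration of the phase-1 peak-to-plateau transition (ms).
#' @param phase2_end End of the plateau / start of phase 3 relative to
#'   activation (ms); may be given as a fraction of APD (value < 1).
#' @param apd Action-potential duration APD90 (ms).
#' @param shape Exponent of the phase-3 cosine ramp. The default 0.5 gives a
#'   brisk terminal repolarization (the curve reaches the resting potential
#'   about a dozen milliseconds after APD90, as in recorded ventricular APs);
#'   1 gives a plain raised cosine with a much slower final approach.
#' @param p2_factor Phase-II amplitude factor relative to the template's
#'   nominal plateau (used by [scale_phase2()]; 1 for reference templates).
#' @return An object of class `ap_template`.
#' @export
ap_template <- function(rest = -90, peak = 25, plateau = 10,
                        upstroke = 2, notch = 10, phase2_end = 0.62,
                        apd = 300, shape = 0.5, p2_factor = 1) {
  if (phase2_end < 1) phase2_end <- phase2_end * apd
  if (apd <= upstroke + notch)
    stop("APD must exceed the upstroke and phase-1 durations", call. = FALSE)
  if (phase2_end <= upstroke + notch || phase2_end >= apd)
    stop("phase-2 end must lie between phase 1 and the APD", call. = FALSE)
  if (!(rest < plateau && plateau < peak))
    stop("need rest < plateau < peak", call. = FALSE)
  amp <- peak - rest
  ap_amp <- plateau - rest
  q <- 0.1 * amp / ap_amp           # residual fraction of plateau height at APD90
  if (q >= 1)
    stop("plateau too low: APD90 level above the plateau", call. = FALSE)
  # phase-3 ramp w(u) = (0.5*(1+cos(pi*u)))^shape must equal q at the APD
  u_apd <- acos(2 * q^(1 / shape) - 1) / pi
  t_end <- phase2_end + (apd - phase2_end) / u_apd
  structure(list(rest = rest, peak = peak, plateau = plateau,
                 upstroke = upstroke, notch = notch, phase2_end = phase2_end,
                 apd = apd, shape = shape, p2_factor = p2_factor,
                 t_full_repol = t_end),
            class = "ap_template")
}

#' @export
print.ap_template <- function(x, ...) {
  cat(sprintf(
    "AP template: rest %.0f mV, peak %.0f mV, plateau %.0f mV (x%.2f), APD90 %.0f ms (full repol %.0f ms)\n",
    x$rest, x$peak, x$plateau, x$p2_factor, x$apd, x$t_full_repol))
  invisible(x)
}

#' Evaluate an action-potential template
#'
#' Total function of time since local activation: returns the resting
#' potential for any time before the upstroke or after full repolarization.
#'
#' @param tpl An [ap_template()].
#' @param t Time since activation (ms); vectorized.
#' @return Membrane potential (mV), same length as `t`.
#' @export
ap_value <- function(tpl, t) {
  stopifnot(inherits(tpl, "ap_template"))
  t <- as.numeric(t)
  v <- rep(tpl$rest, length(t))
  t1 <- tpl$upstroke + tpl$notch
  t2 <- tpl$phase2_end
  t3 <- tpl$t_full_repol
  amp_pl <- tpl$plateau - tpl$rest

  s <- t >= 0 & t < tpl$upstroke
  if (any(s))
    v[s] <- tpl$rest + (tpl$peak - tpl$rest) * 0.5 * (1 - cos(pi * t[s] / tpl$upstroke))
  s <- t >= tpl$upstroke & t < t1
  if (any(s)) {
    u <- (t[s] - tpl$upstroke) / tpl$notch
    v[s] <- tpl$plateau + (tpl$peak - tpl$plateau) * 0.5 * (1 + cos(pi * u))
  }
  s <- t >= t1 & t < t2
  if (any(s)) v[s] <- tpl$plateau
  s <- t >= t2 & t < t3
  if (any(s)) {
    u <- (t[s] - t2) / (t3 - t2)
    v[s] <- tpl$rest + amp_pl * (0.5 * (1 + cos(pi * u)))^tpl$shape
  }

  if (tpl$p2_factor != 1) {
    # phase-II amplitude modulation: full weight on the plateau, fading in
    # over phase 1 and out over phase 3 so that the upstroke and every value
    # at or beyond the APD are untouched
    h <- numeric(length(t))
    s <- t >= tpl$upstroke & t < t1
    h[s] <- 0.5 * (1 - cos(pi * (t[s] - tpl$upstroke) / tpl$notch))
    s <- t >= t1 & t <= t2
    h[s] <- 1
    s <- t > t2 & t < tpl$apd
    h[s] <- 0.5 * (1 + cos(pi * (t[s] - t2) / (tpl$apd - t2)))
    v <- tpl$rest + (v - tpl$rest) * (1 + (tpl$p2_factor - 1) * h)
  }
  v
}

#' Scale the action-potential duration
#'
#' Scales the APD and the phase-2/3 boundaries by a factor, keeping the
#' upstroke, phase-1 and all voltage levels unchanged. Used to impose
#' beat-to-beat APD alternans.
#'
#' @param tpl An [ap_template()].
#' @param factor Positive scale factor (e.g. 0.96 / 1.04 for the +-4% beats).
#' @return A new `ap_template`.
#' @export
scale_apd <- function(tpl, factor) {
  stopifnot(inherits(tpl, "ap_template"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0)
    stop("APD scale factor must be a single positive number", call. = FALSE)
  t0 <- tpl$upstroke + tpl$notch
  ap_template(rest = tpl$rest, peak = tpl$peak, plateau = tpl$plateau,
              upstroke = tpl$upstroke, notch = tpl$notch,
              phase2_end = t0 + (tpl$phase2_end - t0) * factor,
              apd = tpl$apd * factor,
              shape = tpl$shape, p2_factor = tpl$p2_factor)
}

#' Scale the phase-II (plateau) amplitude
#'
#' Scales the plateau height above the resting potential by a factor,
#' leaving the APD, the upstroke and all values at or beyond the APD
#' unchanged. Used to impose beat-to-beat amplitude alternans.
#'
#' @param tpl An [ap_template()].
#' @param factor Factor in (0, 1.5]; 0.90 models the 10% phase-II decrease.
#' @return A new `ap_template`.
#' @export
scale_phase2 <- function(tpl, factor) {
  stopifnot(inherits(tpl, "ap_template"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0 || factor > 1.5)
    stop("phase-II scale factor must lie in (0, 1.5]", call. = FALSE)
  tpl$p2_factor <- tpl$p2_factor * factor
  tpl
}

#' Per-layer action-potential templates
#'
#' The transmural AP gradient of the model: the endocardial layer L1
#' (Purkinje-like) has an APD of 378 ms; the mid-myocardial layers L3 and L4
#' carry the longest working-myocardium APDs (prolonged mid-myocardial
#' repolarization), L2 is intermediate and the epicardial layer L5 is
#' shortest. All other template parameters are shared between layers.
#'
#' @param apd Named numeric vector of APD90 values (ms) for L1..L5.
#' @param ... Further arguments passed to [ap_template()] for every layer.
#' @return Named list (`L1`..`L5`) of `ap_template` objects.
#' @export
layer_ap_table <- function(apd = c(L1 = 378, L2 = 312, L3 = 334, L4 = 330, L5 = 292),
                           ...) {
  stopifnot(identical(names(apd), paste0("L", 1:5)))
  lapply(apd, function(a) ap_template(apd = a, ...))
}

#' Sample an AP template on a regular time grid
#'
#' @param tpl An [ap_template()].
#' @param dt Sampling step (ms).
#' @param t_max End of the sampling window (ms); defaults to just past full
#'   repolarization.
#' @return A data.frame with columns `t` (ms) and `mV`.
#' @export
sample_ap <- function(tpl, dt = 1, t_max = NULL) {
  if (is.null(t_max)) t_max <- tpl$t_full_repol + 5 * dt
  t <- seq(0, t_max, by = dt)
  data.frame(t = t, mV = ap_value(tpl, t))
}
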