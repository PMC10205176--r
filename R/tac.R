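#' Time-activity curve
#'
#' A TAC holds one activity value (kBq/mL) per frame of a schedule; each value
#' is understood as the frame-duration-weighted average of the underlying
#' continuous concentration over the frame interval.
#'
#' @param values numeric vector, one activity value per frame (kBq/mL).
#' @param schedule the [frame_schedule()] the values are sampled on.
#' @return An object of class `tac`.
#' @export
tac <- function(values, schedule) {
  if (length(values) != n_frames(schedule)) {
    stop("TAC length must equal the number of frames")
  }
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(values = as.numeric(values), schedule = schedule),
            class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC: %d frames, peak %.3g kBq/mL at %.1f min\n",
              length(x$values), max(x$values),
              frame_mid_min(x$schedule)[which.max(x$values)]))
  invisible(x)
}

# Fine time grid (minutes) covering the scan, used for continuous-curve
# evaluation and convolution. dt = 0.05 min keeps discretisation error of the
# SRTM convolution well below the tolerances used downstream.
fine_grid <- function(schedule, dt_min = 0.05) {
  seq(0, total_duration_s(schedule) / 60, by = dt_min)
}

# Average a continuous curve (sampled on t_fine, minutes) over each frame.
frame_average <- function(values_fine, t_fine, schedule) {
  starts <- schedule$start_s / 60
  ends <- frame_end_s(schedule) / 60
  vapply(seq_len(n_frames(schedule)), function(k) {
    sel <- t_fine >= starts[k] - 1e-9 & t_fine <= ends[k] + 1e-9
    tt <- t_fine[sel]
    vv <- values_fine[sel]
    sum(diff(tt) * (vv[-1] + vv[-length(vv)]) / 2) / (tt[length(tt)] - tt[1])
  }, numeric(1))
}

# Bi-exponential bolus rise-and-washout input shape, normalised so that the
# continuous peak equals `amplitude`.
biexp_curve <- function(t_min, amplitude, rise_per_min, wash_per_min) {
  raw <- exp(-wash_per_min * t_min) - exp(-rise_per_min * t_min)
  t_peak <- log(rise_per_min / wash_per_min) / (rise_per_min - wash_per_min)
  peak <- exp(-wash_per_min * t_peak) - exp(-rise_per_min * t_peak)
  amplitude * raw / peak
}

#' Simulate a reference-tissue time-activity curve
#'
#' Evaluates a bi-exponential rise-and-washout bolus curve
#' \eqn{C(t) \propto e^{-\lambda_w t} - e^{-\lambda_r t}} (peak scaled to
#' `amplitude`) and averages it over each frame interval, which is how a
#' scanner reports frame activities.
#'
#' @param schedule a [frame_schedule()].
#' @param amplitude peak activity of the continuous curve (kBq/mL), > 0.
#' @param rise_per_min uptake rate constant (1/min); larger = faster rise.
#' @param wash_per_min washout rate constant (1/min); must be < `rise_per_min`.
#' @return A [tac()].
#' @export
simulate_reference_tac <- function(schedule, amplitude = 30,
                                   rise_per_min = 2, wash_per_min = 0.05) {
  if (!is.finite(amplitude) || amplitude <= 0) stop("amplitude must be > 0")
  if (wash_per_min >= rise_per_min) stop("washout must be slower than rise")
  t_fine <- fine_grid(schedule)
  cf <- biexp_curve(t_fine, amplitude, rise_per_min, wash_per_min)
  tac(frame_average(cf, t_fine, schedule), schedule)
}

# exp(-k t) convolution of a curve sampled on a uniform fine grid, by the
# recursive trapezoid rule: I_{n+1} = I_n e^{-k dt} + dt/2 (c_{n+1} + c_n e^{-k dt}).
exp_conv <- function(values_fine, t_fine, k) {
  dt <- t_fine[2] - t_fine[1]
  e <- exp(-k * dt)
  out <- numeric(length(values_fine))
  for (n in seq_len(length(values_fine) - 1L)) {
    out[n + 1L] <- out[n] * e + dt / 2 * (values_fine[n + 1L] + values_fine[n] * e)
  }
  out
}

#' Simulate a target-tissue TAC with the simplified reference tissue model
#'
#' Generates the closed-form SRTM response
#' \deqn{C_T(t) = R_1 C_{ref}(t) + \left(k_2 - \frac{R_1 k_2}{1+BP}\right)
#'   \left(C_{ref} \otimes e^{-k_2 t/(1+BP)}\right)(t)}
#' whose implied total distribution volume ratio is \eqn{1 + BP}. The
#' reference curve is linearly interpolated onto a fine grid for the
#' convolution term and the result is averaged back onto the frames; the
#' direct \eqn{R_1 C_{ref}} term uses the frame values themselves, so
#' `R1 = 1, BP = 0` reproduces the reference TAC exactly.
#'
#' @param ref_tac reference-tissue [tac()].
#' @param R1 ratio of tracer delivery, target over reference (unitless, > 0).
#' @param k2 reference-efflux rate constant (1/min, > 0).
#' @param BP binding potential (unitless, >= 0); DVR = 1 + BP.
#' @param schedule frame schedule; defaults to the reference TAC's.
#' @return A [tac()] of the target tissue.
#' @export
simulate_target_tac <- function(ref_tac, R1, k2, BP,
                                schedule = ref_tac$schedule) {
  if (!is.finite(R1) || R1 <= 0) stop("R1 must be > 0")
  if (!is.finite(k2) || k2 <= 0) stop("k2 must be > 0")
  if (!is.finite(BP) || BP < 0) stop("BP must be >= 0")
  if (!same_schedule(ref_tac$schedule, schedule)) {
    stop("reference TAC and schedule must agree")
  }
  coef <- k2 - R1 * k2 / (1 + BP)
  vals <- R1 * ref_tac$values
  if (abs(coef) > 0) {
    t_fine <- fine_grid(schedule)
    mid <- frame_mid_min(schedule)
    ref_fine <- stats::approx(c(0, mid), c(0, ref_tac$values),
                              xout = t_fine, rule = 2)$y
    conv <- exp_conv(ref_fine, t_fine, k2 / (1 + BP))
    vals <- vals + coef * frame_average(conv, t_fine, schedule)
  }
  tac(vals, schedule)
}

# Area under a TAC by trapezoid on (0, frame midpoints), assuming C(0) = 0.
# Used to normalise TAC shapes for the supervised cluster decomposition.
tac_auc <- function(values, schedule) {
  t <- c(0, frame_mid_min(schedule))
  v <- c(0, values)
  sum(diff(t) * (v[-1] + v[-length(v)]) / 2)
}

#' Kinetic class basis for supervised cluster analysis
#'
#' Builds the four canonical tissue-class TACs the supervised cluster
#' decomposition works with: grey matter without specific binding (the
#' reference input itself), white matter (slow, low delivery), blood (sharp
#' early peak, fast washout) and grey matter with specific binding (elevated
#' retention via a nominal binding potential). Shapes are chosen to be
#' linearly distinguishable after area-normalisation.
#'
#' @param schedule a [frame_schedule()].
#' @param amplitude peak of the grey-matter reference curve (kBq/mL).
#' @param bp_specific nominal binding potential of the specific-binding class.
#' @return Object of class `kinetic_class_basis`: list with `class_names`,
#'   `class_tacs` (frames x 4 matrix, kBq/mL) and `schedule`.
#' @export
make_kinetic_basis <- function(schedule, amplitude = 30, bp_specific = 0.3) {
  ref <- simulate_reference_tac(schedule, amplitude)
  white <- simulate_target_tac(ref, R1 = 0.35, k2 = 0.05, BP = 0)
  t_fine <- fine_grid(schedule)
  blood_fine <- biexp_curve(t_fine, 3 * amplitude,
                            rise_per_min = 8, wash_per_min = 0.3)
  blood <- tac(frame_average(blood_fine, t_fine, schedule), schedule)
  grey_sb <- simulate_target_tac(ref, R1 = 1, k2 = 0.15, BP = bp_specific)
  m <- cbind(grey_no_binding = ref$values,
             white_matter = white$values,
             blood = blood$values,
             grey_specific_binding = grey_sb$values)
  stopifnot(all(m >= 0))
  structure(list(class_names = colnames(m), class_tacs = m,
                 schedule = schedule),
            class = "kinetic_class_basis")
}

#' @export
print.kinetic_class_basis <- function(x, ...) {
  cat("Kinetic class basis:", paste(x$class_names, collapse = ", "),
      sprintf("(%d frames)\n", nrow(x$class_tacs)))
  invisible(x)
}

#' Read a kinetic class basis from CSV
#'
#' For real acquisitions the population class curves must be supplied as a
#' CSV with one column per class, one row per frame and a header of class
#' names; the first column must be the non-binding grey-matter class used to
#' rank reference candidates.
#'
#' @param path CSV file path.
#' @param schedule the [frame_schedule()] of the acquisition.
#' @return A `kinetic_class_basis`.
#' @export
read_kinetic_basis <- function(path, schedule) {
  m <- as.matrix(utils::read.csv(path, check.names = FALSE))
  if (nrow(m) != n_frames(schedule)) {
    stop("basis rows must equal the number of frames")
  }
  if (any(m < 0)) stop("class TACs must be non-negative")
  structure(list(class_names = colnames(m), class_tacs = m,
                 schedule = schedule),
            class = "kinetic_class_basis")
}
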