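#' Configuration for the synthetic gait generator
#'
#' Defines the study conditions emulated by the generator: a dominant
#' double-bump flexion/extension waveform (stance peak ~15 deg near 14% of
#' the cycle, swing peak ~60 deg near 72%), a physiologically small
#' ab/adduction oscillation (range well under the ~7 deg asymptomatic
#' bound) on top of an optional fixed frontal deformity, axial rotation
#' with substantial range (~12 deg) and a flexion-coupled (screw-home)
#' component, smooth stride-to-stride noise, and a known rigid misalignment
#' of the knee joint coordinate system that induces cross-talk.
#'
#' The true frontal and axial oscillation waveforms are constructed
#' orthogonal (over the 101-point grid) to the flexion waveform and to each
#' other: zero true cross-axis correlation is the condition under which the
#' principal axes coincide with the anatomical axes, and is the stated
#' assumption of the correction. The flexion-to-rotation `coupling` relaxes
#' it deliberately.
#'
#' @param n_subjects cohort size.
#' @param n_cycles gait cycles per subject.
#' @param stance_peak,swing_peak flexion bump amplitudes above baseline
#'   (degrees).
#' @param stance_time,swing_time bump centers as fractions of the cycle.
#' @param stance_width,swing_width bump widths (fraction of cycle).
#' @param flexion_base baseline flexion (degrees).
#' @param abd_amplitude half-range of the true ab/adduction oscillation
#'   (degrees).
#' @param abd_bound physiological bound on the true ab/adduction range
#'   (degrees); oscillation plus noise is rescaled if it would exceed it.
#' @param deformity fixed true varus/valgus offset (degrees, + = varus).
#' @param rot_amplitude half-range of the axial rotation oscillation
#'   (degrees).
#' @param rot_offset static axial rotation offset (degrees).
#' @param coupling linear gain from centered flexion to axial rotation.
#' @param noise_sd SD (degrees) of the smooth per-cycle noise per channel.
#' @param mis_angle misalignment magnitude (degrees) for single-subject
#'   simulation.
#' @param mis_axis misalignment axis, see [misalignment_matrix()].
#' @param mis_range range (degrees) from which per-subject misalignment
#'   magnitudes are drawn uniformly in [simulate_cohort()].
#' @param frame which segment frames the misalignment reorients, see
#'   [apply_misalignment()]; `"shared"` models a misplacement of the knee
#'   marker that defines the flexion axis of both thigh and shank frames.
#' @param posture_flexion knee flexion (degrees) held during the static
#'   posture trial (mild flexion contracture typical of knee OA).
#' @param seed integer seed recorded in all outputs.
#' @return An object of class `"gait_sim_config"`.
#' @export
gait_sim_config <- function(n_subjects = 20L, n_cycles = 20L,
                            stance_peak = 12, swing_peak = 57,
                            stance_time = 0.14, swing_time = 0.72,
                            stance_width = 0.07, swing_width = 0.11,
                            flexion_base = 3,
                            abd_amplitude = 1.5, abd_bound = 7,
                            deformity = 0,
                            rot_amplitude = 6, rot_offset = 0,
                            coupling = 0.15,
                            noise_sd = 1,
                            mis_angle = 10, mis_axis = "longitudinal",
                            mis_range = c(8, 15),
                            frame = c("shared", "proximal", "distal"),
                            posture_flexion = 8,
                            seed = 1L) {
  frame <- match.arg(frame)
  cfg <- list(n_subjects = as.integer(n_subjects),
              n_cycles = as.integer(n_cycles),
              stance_peak = stance_peak, swing_peak = swing_peak,
              stance_time = stance_time, swing_time = swing_time,
              stance_width = stance_width, swing_width = swing_width,
              flexion_base = flexion_base,
              abd_amplitude = abd_amplitude, abd_bound = abd_bound,
              deformity = deformity,
              rot_amplitude = rot_amplitude, rot_offset = rot_offset,
              coupling = coupling, noise_sd = noise_sd,
              mis_angle = mis_angle, mis_axis = mis_axis,
              mis_range = mis_range, frame = frame,
              posture_flexion = posture_flexion,
              seed = as.integer(seed))
  amps <- c(cfg$stance_peak, cfg$swing_peak, cfg$abd_amplitude,
            cfg$rot_amplitude, cfg$noise_sd)
  if (any(!is.finite(amps)) || any(amps < 0))
    stop("amplitudes and noise SD must be finite and >= 0")
  if (abs(cfg$mis_angle) >= 45 || any(abs(cfg$mis_range) >= 45))
    stop("misalignment magnitudes must stay below 45 degrees")
  if (cfg$n_subjects < 0L || cfg$n_cycles < 1L)
    stop("need n_subjects >= 0 and n_cycles >= 1")
  structure(cfg, class = "gait_sim_config")
}

#' @export
print.gait_sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "Synthetic gait configuration: %d subject(s) x %d cycle(s)\n",
    "  flexion %g..%g deg, abd osc +/-%g deg (bound %g), deformity %g deg\n",
    "  rotation +/-%g deg, coupling %g, noise SD %g deg\n",
    "  misalignment %g deg about %s axis (%s frames), seed %d\n"),
    x$n_subjects, x$n_cycles, x$flexion_base,
    x$flexion_base + x$swing_peak, x$abd_amplitude, x$abd_bound,
    x$deformity, x$rot_amplitude, x$coupling, x$noise_sd, x$mis_angle,
    if (is.character(x$mis_axis)) x$mis_axis else "custom",
    x$frame, x$seed))
  invisible(x)
}

# percent-of-cycle grid shared by all generated cycles
cycle_grid <- function() seq(0, 1, length.out = 101L)

#' Closed-form flexion/extension waveform
#'
#' Sum of two periodic Gaussian bumps (stance and swing) over a baseline,
#' evaluated at fractions of the gait cycle.
#'
#' @param t fractions of the gait cycle in `[0, 1]`.
#' @param config a [gait_sim_config()].
#' @return flexion angle in degrees.
#' @export
flexion_waveform <- function(t, config = gait_sim_config()) {
  bump <- function(t, center, width) {
    d <- pmin(abs(t - center), 1 - abs(t - center))  # periodic distance
    exp(-0.5 * (d / width)^2)
  }
  config$flexion_base +
    config$stance_peak * bump(t, config$stance_time, config$stance_width) +
    config$swing_peak * bump(t, config$swing_time, config$swing_width)
}

# residual of y after least-squares projection onto columns of basis
# (lm.fit tolerates rank-deficient bases, e.g. an all-zero flexion waveform)
project_out <- function(y, basis) {
  as.numeric(stats::lm.fit(basis, y)$residuals)
}

# Subject-level deterministic waveforms: flexion plus frontal/axial
# oscillations orthogonalized against flexion and each other. Uses the
# current RNG state (for the oscillation phases).
subject_waveforms <- function(config) {
  t <- cycle_grid()
  fl <- flexion_waveform(t, config)
  B <- cbind(1, fl)
  ph <- stats::runif(2, 0, 2 * pi)
  ab <- project_out(sin(4 * pi * t + ph[1]), B)
  ab <- if (max(abs(ab)) > 0) ab / max(abs(ab)) * config$abd_amplitude else ab
  rt <- project_out(sin(2 * pi * t + ph[2]), cbind(B, ab))
  rt <- if (max(abs(rt)) > 0) rt / max(abs(rt)) * config$rot_amplitude else rt
  list(t = t, flexion = fl, abd_osc = ab, rot_osc = rt)
}

# smooth stride-to-stride noise: cubic spline through coarse Gaussian knots
smooth_noise <- function(sd, n_knots = 13L) {
  if (sd <= 0) return(rep(0, 101L))
  k <- seq(0, 1, length.out = n_knots)
  stats::spline(k, stats::rnorm(n_knots, 0, sd), xout = cycle_grid(),
                method = "fmm")$y
}

#' Generate one true (misalignment-free) gait cycle
#'
#' Evaluates the subject waveforms and adds smooth per-cycle noise. The
#' true ab/adduction motion (oscillation plus noise, about the deformity
#' offset) is rescaled if its range would exceed the physiological bound.
#' Uses the current RNG state; seed upstream for reproducibility (as
#' [simulate_subject()] does).
#'
#' @param config a [gait_sim_config()].
#' @param waveforms optional precomputed output of the internal
#'   subject-waveform builder; when `NULL`, waveforms (oscillation phases)
#'   are drawn first.
#' @return an [angle_cycle()]: 101 x 3 matrix of true angles (degrees).
#' @export
simulate_true_cycle <- function(config = gait_sim_config(),
                                waveforms = NULL) {
  wf <- if (is.null(waveforms)) subject_waveforms(config) else waveforms
  flex <- wf$flexion + smooth_noise(config$noise_sd)
  abd_motion <- wf$abd_osc + smooth_noise(config$noise_sd)
  rng <- diff(range(abd_motion))
  if (rng > config$abd_bound)  # ligamentous constraint: rescale about midrange
    abd_motion <- (abd_motion - mean(range(abd_motion))) *
      config$abd_bound / rng
  abd <- config$deformity + abd_motion
  rot <- config$rot_offset +
    config$coupling * (flex - mean(wf$flexion)) +
    wf$rot_osc + smooth_noise(config$noise_sd)
  angle_cycle(cbind(flex, abd, rot))
}

#' Pass a true cycle through a coordinate-system misalignment
#'
#' Applies [apply_misalignment()] samplewise: the generative model of
#' cross-talk. With the identity misalignment the cycle is unchanged.
#'
#' @param cycle 101 x 3 matrix of true angles (degrees).
#' @param mis 3x3 misalignment rotation.
#' @param convention a [cardan_convention()].
#' @param frame frame model, see [apply_misalignment()].
#' @return the observed (cross-talk contaminated) [angle_cycle()].
#' @export
induce_crosstalk <- function(cycle, mis,
                             convention = cardan_convention(),
                             frame = c("shared", "proximal", "distal")) {
  frame <- match.arg(frame)
  angle_cycle(apply_misalignment(as.matrix(cycle), mis, convention, frame))
}

#' Simulate one subject/side with ground truth
#'
#' Draws the subject's oscillation phases, generates `n_cycles` true cycles
#' with independent smooth noise, passes all of them (and the static
#' posture pose) through one subject-specific misalignment, and returns the
#' observed data together with the generating truth. Fully reproducible:
#' the RNG is seeded from `config$seed` and the subject index.
#'
#' @param config a [gait_sim_config()].
#' @param subject subject index (also used in the subject id).
#' @param mis_angle override of `config$mis_angle` (degrees), used by
#'   [simulate_cohort()] for per-subject draws.
#' @param side side label for the generated data.
#' @return list with `observed` (a [subject_side()] including the observed
#'   posture) and `truth` (true cycles, true posture, misalignment matrix
#'   and magnitude, deformity, config).
#' @export
simulate_subject <- function(config = gait_sim_config(), subject = 1L,
                             mis_angle = config$mis_angle,
                             side = "right") {
  set.seed(config$seed + 1009L * as.integer(subject))
  wf <- subject_waveforms(config)
  mis <- misalignment_matrix(mis_angle, config$mis_axis)
  true_cycles <- replicate(config$n_cycles,
                           simulate_true_cycle(config, wf),
                           simplify = FALSE)
  obs_cycles <- lapply(true_cycles, induce_crosstalk, mis = mis,
                       frame = config$frame)
  true_posture <- c(flexion = config$posture_flexion,
                    abduction = config$deformity, rotation = 0)
  obs_posture <- apply_misalignment(true_posture, mis,
                                    frame = config$frame)
  observed <- subject_side(obs_cycles,
                           subject = sprintf("SYN%02d", subject),
                           side = side, posture = obs_posture)
  truth <- list(cycles = true_cycles, posture = true_posture,
                misalignment = mis, mis_angle = mis_angle,
                deformity = config$deformity, config = config)
  list(observed = observed, truth = truth)
}

#' Simulate a cohort of subjects
#'
#' Per-subject misalignment magnitudes are drawn uniformly from
#' `config$mis_range` (recorded in each subject's truth); everything else
#' follows [simulate_subject()]. Reproducible from `config$seed`.
#'
#' @param config a [gait_sim_config()].
#' @return list of `config$n_subjects` elements, each as returned by
#'   [simulate_subject()]; the drawn misalignment magnitudes are attached
#'   as attribute `mis_angles`.
#' @export
simulate_cohort <- function(config = gait_sim_config()) {
  if (config$n_subjects == 0L)
    return(structure(list(), mis_angles = numeric(0)))
  set.seed(config$seed)
  ms <- stats::runif(config$n_subjects, config$mis_range[1],
                     config$mis_range[2])
  out <- lapply(seq_len(config$n_subjects), function(i)
    simulate_subject(config, subject = i, mis_angle = ms[i]))
  attr(out, "mis_angles") <- ms
  out
}
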