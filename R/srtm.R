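#' Time-activity curve
#'
#' Frame-averaged activity values tied to a frame schedule.
#'
#' @param values numeric vector, one activity value per frame.
#' @param schedule a [frame_schedule()].
#' @return An object of class `tac`.
#' @export
tac <- function(values, schedule) {
  stopifnot(inherits(schedule, "frame_schedule"))
  values <- as.numeric(values)
  if (length(values) != schedule$n_frames)
    stop("TAC length ", length(values), " does not match schedule (",
         schedule$n_frames, " frames)")
  if (any(!is.finite(values))) stop("TAC values must be finite")
  structure(list(values = values, schedule = schedule), class = "tac")
}

#' @export
print.tac <- function(x, ...) {
  cat(sprintf("TAC: %d frames over %.1f min, peak %.3g at %.1f min\n",
              x$schedule$n_frames, x$schedule$total_duration / 60,
              max(x$values), x$schedule$mid[which.max(x$values)] / 60))
  invisible(x)
}

# fine sampling grid (midpoints of dt-second subintervals) covering the
# schedule; times returned in minutes together with the frame index of
# each sample, so fine curves can be frame-averaged by group means
fine_grid <- function(schedule, dt = 1) {
  total <- schedule$start[schedule$n_frames] +
    schedule$duration[schedule$n_frames]
  t_sec <- seq(dt / 2, total, by = dt)
  frame <- findInterval(t_sec, schedule$start)
  list(t_min = t_sec / 60, frame = frame, dt_min = dt / 60)
}

frame_average <- function(fine_values, frame, n_frames) {
  as.numeric(tapply(fine_values, factor(frame, levels = seq_len(n_frames)),
                    mean))
}

#' Gamma-variate reference-region input curve
#'
#' The reference-region activity is modelled as the gamma variate
#' `Cref(t) = A * t * exp(-t / tau)` with `t` in minutes: a fast rise to a
#' peak at `t = tau` followed by washout, the usual single-bump shape of a
#' bolus tracer in a non-binding region. `reference_tac()` returns the
#' frame-averaged curve using the closed-form integral of `t exp(-t/tau)`
#' over each frame; `reference_tac_fine()` returns the instantaneous curve
#' on a fine grid, as needed by the SRTM convolution.
#'
#' @param schedule a [frame_schedule()].
#' @param A amplitude (> 0, arbitrary activity units per minute of rise).
#' @param tau washout time constant in minutes (> 0); the curve peaks at
#'   `t = tau`.
#' @return `reference_tac()`: a [tac()]. `reference_tac_fine()`: a list
#'   with `t_min`, `values`, `frame`, `dt_min`.
#' @export
reference_tac <- function(schedule, A = 1, tau = 15) {
  stopifnot(inherits(schedule, "frame_schedule"))
  if (A <= 0 || tau <= 0) stop("A and tau must be positive")
  # antiderivative of t exp(-t/tau): -tau (t + tau) exp(-t/tau)
  antider <- function(t) -tau * (t + tau) * exp(-t / tau)
  t0 <- schedule$start / 60
  t1 <- (schedule$start + schedule$duration) / 60
  means <- A * (antider(t1) - antider(t0)) / (t1 - t0)
  tac(means, schedule)
}

#' @rdname reference_tac
#' @param dt fine-grid step in seconds (<= 1 s recommended).
#' @export
reference_tac_fine <- function(schedule, A = 1, tau = 15, dt = 1) {
  if (A <= 0 || tau <= 0) stop("A and tau must be positive")
  g <- fine_grid(schedule, dt)
  g$values <- A * g$t_min * exp(-g$t_min / tau)
  g
}

#' SRTM kinetic parameters
#'
#' Parameters of the simplified reference tissue model used as the forward
#' simulator: `R1` (target/reference delivery ratio, dimensionless), `k2`
#' (target efflux rate, 1/min) and `BP` (binding potential, dimensionless,
#' > -1). The implied distribution volume ratio is `DVR = 1 + BP`.
#'
#' @param R1 delivery ratio, > 0.
#' @param k2 efflux rate in 1/min, > 0.
#' @param BP binding potential, > -1.
#' @return A list of class `srtm_params`.
#' @export
srtm_params <- function(R1 = 1, k2 = 0.4, BP = 0) {
  if (R1 <= 0) stop("R1 must be positive")
  if (k2 <= 0) stop("k2 must be positive")
  if (BP <= -1) stop("BP must be greater than -1 (DVR must be positive)")
  structure(list(R1 = R1, k2 = k2, BP = BP, DVR = 1 + BP),
            class = "srtm_params")
}

#' Forward-simulate a target TAC under the simplified reference tissue model
#'
#' Evaluates the SRTM solution
#' `CT(t) = R1 Cref(t) + (k2 - R1 k2a) (Cref * exp(-k2a t))(t)` with
#' `k2a = k2 / (1 + BP)` on the fine grid of the reference curve (the
#' convolution uses an exact exponential-decay recursion with trapezoidal
#' source integration, stable at any step), then frame-averages onto the
#' schedule. With `R1 = 1` and `BP = 0` the model collapses to
#' `CT = Cref` identically.
#'
#' @param reference_fine a fine-grid reference curve from
#'   [reference_tac_fine()] (<= 1 s resolution).
#' @param params an [srtm_params()].
#' @param schedule a [frame_schedule()].
#' @return A frame-averaged [tac()].
#' @export
srtm_tac <- function(reference_fine, params, schedule) {
  stopifnot(inherits(params, "srtm_params"))
  ct <- srtm_fine(reference_fine, params)
  tac(frame_average(ct, reference_fine$frame, schedule$n_frames), schedule)
}

# fine-grid SRTM solution (internal; shared by srtm_tac and the simulator)
srtm_fine <- function(reference_fine, params) {
  k2a <- params$k2 / (1 + params$BP)
  cref <- reference_fine$values
  dt <- reference_fine$dt_min
  E <- exp(-k2a * dt)
  n <- length(cref)
  conv <- numeric(n)
  # first sample sits dt/2 after t=0 where Cref(0)=0
  conv[1] <- dt / 2 * (cref[1] + 0 * E)
  for (i in 2:n)
    conv[i] <- conv[i - 1] * E + dt / 2 * (cref[i] + cref[i - 1] * E)
  params$R1 * cref + (params$k2 - params$R1 * k2a) * conv
}
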