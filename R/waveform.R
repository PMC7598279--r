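#' Inlet velocity waveform over one cardiac cycle
#'
#' Three parametric templates standardise the inflow boundary condition:
#' \describe{
#'   \item{flat}{constant plateau at `peak_velocity` for the whole cycle —
#'     the steady extreme.}
#'   \item{sharp}{a narrow systolic raised-cosine burst (full width a quarter
#'     of the period) over a small diastolic baseline (10% of peak) — the
#'     pulsatile extreme.}
#'   \item{real}{a triphasic template typical of the infrarenal aorta:
#'     systolic peak, one brief reverse-flow phase, low diastolic forward
#'     flow.}
#' }
#' Samples are placed at `t_k = (k - 1) / n * period`, `k = 1..n`, so the
#' uniform step is `period / n` and the series tiles the cycle periodically.
#'
#' @param kind `"flat"`, `"sharp"` or `"real"`.
#' @param peak_velocity peak inlet velocity, m/s (> 0).
#' @param period cardiac period, s (> 0).
#' @param n_samples number of samples over the cycle (>= 8).
#' @return An object of class `velocity_waveform` with fields `times` (s),
#'   `velocities` (m/s) and `kind`.
#' @export
make_waveform <- function(kind = c("flat", "sharp", "real"),
                          peak_velocity = 0.4, period = 1.0,
                          n_samples = 64) {
  kind <- match.arg(kind)
  if (peak_velocity <= 0) stop("peak_velocity must be > 0")
  if (period <= 0) stop("period must be > 0")
  n <- as.integer(n_samples)
  if (n < 8L) stop("need at least 8 samples per cycle")
  t <- (seq_len(n) - 1L) / n * period
  p <- peak_velocity
  v <- switch(kind,
    flat = rep(p, n),
    sharp = {
      w <- 0.25 * period
      t0 <- 0.125 * period
      base <- 0.1 * p
      burst <- ifelse(abs(t - t0) <= w / 2,
                      0.5 * (1 + cos(2 * pi * (t - t0) / w)), 0)
      base + (p - base) * burst
    },
    real = {
      ts <- 0.30 * period   # systolic forward phase
      tr <- 0.15 * period   # reverse phase
      v <- numeric(n)
      i1 <- t < ts
      v[i1] <- p * sin(pi * t[i1] / ts)^2
      i2 <- t >= ts & t < ts + tr
      v[i2] <- -0.15 * p * sin(pi * (t[i2] - ts) / tr)^2
      i3 <- t >= ts + tr
      v[i3] <- 0.05 * p * sin(pi * (t[i3] - ts - tr) / (period - ts - tr))^2
      v
    })
  velocity_waveform(t, v, kind)
}

#' Construct a velocity waveform from tabulated samples
#'
#' @param times sample times, s; strictly increasing, spanning one period.
#' @param velocities inlet velocities, m/s.
#' @param kind label for the waveform.
#' @return A `velocity_waveform`.
#' @export
velocity_waveform <- function(times, velocities, kind = "real") {
  times <- as.numeric(times)
  velocities <- as.numeric(velocities)
  if (length(times) < 8L) stop("waveform needs >= 8 samples")
  if (length(times) != length(velocities)) stop("times/velocities length mismatch")
  if (any(diff(times) <= 0)) stop("times must be strictly increasing")
  if (!all(is.finite(velocities)) || !all(is.finite(times))) {
    stop("waveform samples must be finite")
  }
  structure(list(times = times, velocities = velocities,
                 kind = as.character(kind)),
            class = "velocity_waveform")
}

#' @export
print.velocity_waveform <- function(x, ...) {
  cat(sprintf("velocity_waveform '%s': %d samples, peak %.3f m/s, mean %.3f m/s\n",
              x$kind, length(x$times), max(x$velocities), mean(x$velocities)))
  invisible(x)
}

#' @export
plot.velocity_waveform <- function(x, ...) {
  graphics::plot(x$times, x$velocities, type = "l",
                 xlab = "time [s]", ylab = "inlet velocity [m/s]",
                 main = sprintf("'%s' waveform", x$kind), ...)
  graphics::abline(h = 0, lty = 3)
  invisible(x)
}

#' Read / write a waveform as 2-column CSV (time_s, velocity_m_s)
#'
#' @param path CSV path.
#' @param kind label to attach on read.
#' @return [read_waveform()] returns a `velocity_waveform`;
#'   [write_waveform()] returns the path invisibly.
#' @export
read_waveform <- function(path, kind = "real") {
  d <- utils::read.csv(path)
  if (ncol(d) < 2L) stop("waveform CSV needs columns time_s, velocity_m_s")
  velocity_waveform(d[[1]], d[[2]], kind)
}

#' @rdname read_waveform
#' @param waveform a `velocity_waveform` to serialise.
#' @export
write_waveform <- function(waveform, path) {
  utils::write.csv(data.frame(time_s = waveform$times,
                              velocity_m_s = waveform$velocities),
                   path, row.names = FALSE)
  invisible(path)
}
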