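#' Voltage-ramp sweep series
#'
#' Whole-cell currents sampled along repeated linear voltage ramps
#' (typically -150 to +150 mV), one sweep per ramp, with the membrane
#' capacitance used for current-density normalization.
#'
#' @param times Sweep onset times (s).
#' @param V Command-voltage grid (mV), identical for every sweep.
#' @param I Current matrix (pA), `length(V)` rows x `length(times)` columns.
#' @param C_m Membrane capacitance (pF), > 0.
#' @param ref_sweep Index of the leak-reference sweep (first sweep after
#'   break-in by default).
#' @return Object of class `ramp_series`.
#' @export
ramp_series <- function(times, V, I, C_m, ref_sweep = 1L) {
  I <- as.matrix(I)
  if (nrow(I) != length(V) || ncol(I) != length(times))
    stop("I must be length(V) x length(times)")
  if (!is.numeric(C_m) || C_m <= 0) stop("C_m must be > 0")
  if (ref_sweep < 1 || ref_sweep > length(times)) stop("invalid ref_sweep")
  structure(list(times = times, V = V, I = I, C_m = C_m,
                 ref_sweep = as.integer(ref_sweep)),
            class = "ramp_series")
}

#' @export
print.ramp_series <- function(x, ...) {
  cat(sprintf("Voltage-ramp series: %d sweeps over %.4g s, ramp %g..%g mV, C_m = %.3g pF\n",
              ncol(x$I), diff(range(x$times)), min(x$V), max(x$V), x$C_m))
  invisible(x)
}

#' Current-density development over time
#'
#' Extracts, for every sweep, the current at `v_extract` (linear
#' interpolation on the voltage grid), optionally leak-subtracts it against
#' the reference sweep, and divides by the membrane capacitance to obtain
#' the current density (pA/pF). `CD_max` is the extremum (largest absolute
#' value, sign preserved) of the 3-sweep running-median smoothed series.
#'
#' @param ramps A [ramp_series()] object.
#' @param v_extract Extraction potential (mV), default -130.
#' @param leak_subtract Subtract the reference sweep point-wise (default
#'   TRUE).
#' @param smooth Width of the running median applied before taking the
#'   extremum (odd, default 3).
#' @return Object of class `cd_trace`: data frame `t`, `CD` with attributes
#'   `CD_max` and `v_extract`.
#' @export
cd_trace <- function(ramps, v_extract = -130, leak_subtract = TRUE,
                     smooth = 3) {
  stopifnot(inherits(ramps, "ramp_series"))
  if (v_extract < min(ramps$V) || v_extract > max(ramps$V))
    stop("v_extract outside the ramp voltage range")
  at_v <- apply(ramps$I, 2, function(col)
    stats::approx(ramps$V, col, xout = v_extract)$y)
  if (leak_subtract) at_v <- at_v - at_v[ramps$ref_sweep]
  cd <- at_v / ramps$C_m
  sm <- if (length(cd) >= smooth) stats::runmed(cd, smooth) else cd
  out <- data.frame(t = ramps$times, CD = cd)
  attr(out, "CD_max") <- sm[which.max(abs(sm))]
  attr(out, "v_extract") <- v_extract
  class(out) <- c("cd_trace", "data.frame")
  out
}

#' @export
print.cd_trace <- function(x, ...) {
  cat(sprintf("Current density at %g mV: %d sweeps, CD_max = %.4g pA/pF\n",
              attr(x, "v_extract"), nrow(x), attr(x, "CD_max")))
  invisible(x)
}

#' Leak-subtracted, capacitance-normalized I-V curve of one sweep
#'
#' @param ramps A [ramp_series()] object.
#' @param sweep Sweep index.
#' @param leak_subtract Subtract the reference sweep (default TRUE).
#' @return Data frame `V` (mV), `CD` (pA/pF).
#' @export
iv_curve <- function(ramps, sweep, leak_subtract = TRUE) {
  stopifnot(inherits(ramps, "ramp_series"))
  if (sweep < 1 || sweep > ncol(ramps$I)) stop("sweep does not exist")
  I <- ramps$I[, sweep]
  if (leak_subtract) I <- I - ramps$I[, ramps$ref_sweep]
  data.frame(V = ramps$V, CD = I / ramps$C_m)
}

#' Voltage-step protocol with tail currents
#'
#' Currents recorded during steps to a range of test potentials followed by
#' a fixed repolarization to -100 mV; the tail segment at -100 mV carries
#' the instantaneous-current information used for apparent-open-probability
#' analysis.
#'
#' @param V_test Test potentials (mV), e.g. seq(-160, 80, by = 20).
#' @param tails Tail-current matrix (pA): samples x test potentials,
#'   sampled from the instant of the step to -100 mV.
#' @param fs Sampling rate (Hz).
#' @return Object of class `step_protocol`.
#' @export
step_protocol <- function(V_test, tails, fs) {
  tails <- as.matrix(tails)
  if (ncol(tails) != length(V_test))
    stop("tails must have one column per test potential")
  if (nrow(tails) < 10) stop("tail segments need >= 10 samples")
  if (fs <= 0) stop("fs must be > 0")
  structure(list(V_test = V_test, tails = tails, fs = fs),
            class = "step_protocol")
}

#' @export
print.step_protocol <- function(x, ...) {
  cat(sprintf("Voltage-step protocol: %d test potentials (%g..%g mV), %d tail samples at %g kHz\n",
              length(x$V_test), min(x$V_test), max(x$V_test),
              nrow(x$tails), x$fs / 1000))
  invisible(x)
}

# Fit one tail current with a single exponential A*exp(-t/tau) + c,
# skipping the first `skip` samples (residual capacitive transient), and
# refitting once on a window of ~5 fitted time constants.
fit_tail <- function(y, fs, skip = 2) {
  n <- length(y)
  t <- (seq_len(n) - 1) / fs
  use <- (skip + 1):n
  guess <- function(tt, yy) {
    c0 <- mean(yy[tt >= stats::quantile(tt, 0.8)])
    a0 <- yy[1] - c0
    if (a0 == 0) a0 <- stats::sd(yy) + 1e-12
    # crude tau: time to decay to 1/e of the initial deviation
    dev <- abs(yy - c0)
    i_e <- which(dev <= abs(a0) / exp(1))
    tau0 <- if (length(i_e)) max(tt[i_e[1]] - tt[1], 1 / fs) else diff(range(tt)) / 3
    list(A = a0, tau = tau0, c = c0)
  }
  # Levenberg-Marquardt on the raw residuals (nls.lm rather than nlsLM:
  # exactly noiseless tails make the final nls-object construction
  # rank-deficient, while the coefficients themselves are fine)
  do_fit <- function(idx) {
    ti <- t[idx]; yi <- y[idx]
    g <- guess(ti, yi)
    fit <- minpack.lm::nls.lm(
      par = list(A = g$A, tau = g$tau, c = g$c),
      fn = function(p) yi - (p$A * exp(-ti / p$tau) + p$c),
      lower = c(-Inf, 1e-9, -Inf),
      control = minpack.lm::nls.lm.control(maxiter = 200))
    if (fit$info %in% c(0, 9)) stop("tail fit did not converge")
    fit$par
  }
  cf <- do_fit(use)
  win_end <- min(n, skip + max(10, ceiling(5 * cf$tau * fs)))
  if (win_end > skip + 5 && win_end < n) cf <- do_fit((skip + 1):win_end)
  list(A = cf$A, tau = cf$tau, c = cf$c)
}

#' Apparent open probability from instantaneous tail currents
#'
#' Fits every tail current with a single exponential extrapolated to the
#' instant of the repolarizing step to -100 mV (skipping the first samples
#' to avoid the residual capacitive transient), takes the exponential
#' amplitude `A` as the instantaneous tail amplitude, and normalizes the
#' amplitudes to the largest absolute value over test potentials. Because
#' the driving force at -100 mV is common to all test potentials, the
#' normalized amplitude is the apparent open probability at the end of each
#' test pulse.
#'
#' @param steps A [step_protocol()] object.
#' @param skip Samples skipped at the start of each tail (default 2).
#' @return Object of class `po_curve`: data frame `V` (mV), `amplitude`
#'   (pA), `tau_tail` (s), `Po`, `ok` (fit success flag).
#' @export
tail_po <- function(steps, skip = 2) {
  stopifnot(inherits(steps, "step_protocol"))
  fits <- lapply(seq_along(steps$V_test), function(k) {
    tryCatch(fit_tail(steps$tails[, k], steps$fs, skip),
             error = function(e) NULL)
  })
  ok <- !vapply(fits, is.null, logical(1))
  amp <- rep(NA_real_, length(ok)); tau <- rep(NA_real_, length(ok))
  amp[ok] <- vapply(fits[ok], `[[`, numeric(1), "A")
  tau[ok] <- vapply(fits[ok], `[[`, numeric(1), "tau")
  if (!any(ok)) stop("all tail fits failed")
  po <- abs(amp) / max(abs(amp), na.rm = TRUE)
  out <- data.frame(V = steps$V_test, amplitude = amp, tau_tail = tau,
                    Po = po, ok = ok)
  class(out) <- c("po_curve", "data.frame")
  out
}

#' @export
print.po_curve <- function(x, ...) {
  cat("Apparent open probability from instantaneous tail currents\n")
  print.data.frame(format(x, digits = 3), row.names = FALSE)
  invisible(x)
}

#' @export
plot.po_curve <- function(x, ...) {
  plot(x$V, x$Po, type = "b", pch = 16, ylim = c(0, 1.05),
       xlab = "test potential (mV)", ylab = "apparent open probability", ...)
  invisible(x)
}

#' Read / write ramp series as long-format CSV
#'
#' Columns `sweep`, `sweep_time`, `V`, `I`; capacitance and reference sweep
#' are stored on the first rows' `C_m`, `ref_sweep` columns.
#' @param path File path.
#' @param ramps A [ramp_series()] object.
#' @return `read_ramp_csv` returns a `ramp_series`.
#' @export
read_ramp_csv <- function(path) {
  d <- utils::read.csv(path)
  sweeps <- sort(unique(d$sweep))
  V <- d$V[d$sweep == sweeps[1]]
  I <- vapply(sweeps, function(s) d$I[d$sweep == s], numeric(length(V)))
  times <- vapply(sweeps, function(s) d$sweep_time[d$sweep == s][1],
                  numeric(1))
  ramp_series(times, V, I, C_m = d$C_m[1], ref_sweep = d$ref_sweep[1])
}

#' @rdname read_ramp_csv
#' @export
write_ramp_csv <- function(ramps, path) {
  long <- do.call(rbind, lapply(seq_along(ramps$times), function(s)
    data.frame(sweep = s, sweep_time = ramps$times[s], V = ramps$V,
               I = ramps$I[, s])))
  long$C_m <- ramps$C_m
  long$ref_sweep <- ramps$ref_sweep
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}
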