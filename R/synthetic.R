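#' Synthetic three-cube FRET data with known ground truth
#'
#' Forward model mirroring the sensitized-emission estimator: clusters are
#' disks with log-normal donor intensity `D`; the donor-channel signal is
#' `D * (1 - E_true)`, the true sensitized emission `D * E_true`, and the
#' acceptor signal `D` times a per-cluster acceptor/donor expression ratio.
#' Measured channels add spectral bleed-through/cross-talk (exactly
#' consistent with [efret_image()]'s correction, so the zero-noise
#' round-trip is exact), per-channel background, multiplicative ("shot-like")
#' and additive Gaussian noise.
#'
#' @param E_true True FRET efficiency in `[0, 1)`.
#' @param n_clusters Number of cluster disks.
#' @param dim Image size in pixels (square).
#' @param factors A [fret_factors()] object (defaults to typical GFP/RFP
#'   optics).
#' @param background Per-channel background counts (A, B, C).
#' @param ad_ratio Median acceptor/donor expression ratio.
#' @param ad_sdlog Log-SD of the per-cluster acceptor/donor ratio.
#' @param donor_mean Median cluster donor intensity (counts).
#' @param noise_mult SD of multiplicative noise (fraction of signal).
#' @param noise_add SD of additive noise (counts).
#' @param n_controls Donor-only and acceptor-only control images generated.
#' @param seed RNG seed.
#' @return List with `sample` ([fret_images()]), `donor_only`,
#'   `acceptor_only` (lists of control [fret_images()]), `masks` (integer
#'   label matrix of the true clusters) and `truth` (all ground-truth
#'   parameters, including the seed).
#' @export
gen_fret_images <- function(E_true = 0.15, n_clusters = 50, dim = 192,
                            factors = fret_factors(alpha = 0.02, beta = 0.12,
                                                   gamma = 0.08, delta = 0.01),
                            background = c(50, 40, 45),
                            ad_ratio = 1, ad_sdlog = 0.2,
                            donor_mean = 800,
                            noise_mult = 0.05, noise_add = 2,
                            n_controls = 2, seed = 1) {
  if (E_true < 0 || E_true >= 1) stop("E_true must lie in [0, 1)")
  set.seed(seed)
  ad <- factors$alpha * factors$delta

  place_clusters <- function(n, rad = c(2, 4)) {
    lab <- matrix(0L, dim, dim)
    centers <- matrix(NA_real_, n, 3)
    k <- 0; tries <- 0
    while (k < n && tries < 50 * n) {
      tries <- tries + 1
      r <- stats::runif(1, rad[1], rad[2])
      x <- stats::runif(1, r + 1, dim - r - 1)
      y <- stats::runif(1, r + 1, dim - r - 1)
      if (k > 0 && any((centers[seq_len(k), 1] - x)^2 +
                         (centers[seq_len(k), 2] - y)^2 <
                         (centers[seq_len(k), 3] + r + 1)^2)) next
      k <- k + 1
      centers[k, ] <- c(x, y, r)
    }
    if (k < n) stop("could not place ", n, " non-overlapping clusters")
    for (j in seq_len(n)) {
      xr <- pmax(1, floor(centers[j, 1] - centers[j, 3])):
        pmin(dim, ceiling(centers[j, 1] + centers[j, 3]))
      yr <- pmax(1, floor(centers[j, 2] - centers[j, 3])):
        pmin(dim, ceiling(centers[j, 2] + centers[j, 3]))
      for (xx in xr) for (yy in yr)
        if ((xx - centers[j, 1])^2 + (yy - centers[j, 2])^2 <=
            centers[j, 3]^2) lab[xx, yy] <- j
    }
    lab
  }

  compose <- function(Dimg, Cimg, E) {
    A_d <- Dimg * (1 - E)
    Fc <- Dimg * E
    A <- (A_d + factors$alpha * Cimg) / (1 - ad)
    C <- (Cimg + factors$delta * A_d) / (1 - ad)
    B <- Fc + factors$beta * A_d + factors$gamma * Cimg
    list(A = A, B = B, C = C)
  }
  noisy <- function(img, bg) {
    sig <- img + bg
    out <- sig * (1 + stats::rnorm(length(sig), 0, noise_mult)) +
      stats::rnorm(length(sig), 0, noise_add)
    matrix(pmax(out, 0), nrow(img), ncol(img))
  }
  to_images <- function(ch) {
    fret_images(noisy(ch$A, background[1]), noisy(ch$B, background[2]),
                noisy(ch$C, background[3]), background = background)
  }

  lab <- place_clusters(n_clusters)
  Dint <- stats::rlnorm(n_clusters, log(donor_mean), 0.3)
  adr <- stats::rlnorm(n_clusters, log(ad_ratio), ad_sdlog)
  Dimg <- matrix(0, dim, dim); Cimg <- matrix(0, dim, dim)
  for (j in seq_len(n_clusters)) {
    Dimg[lab == j] <- Dint[j]
    Cimg[lab == j] <- Dint[j] * adr[j]
  }
  sample_set <- to_images(compose(Dimg, Cimg, E_true))

  gen_control <- function(kind) {
    lab_c <- place_clusters(max(10, n_clusters %/% 2))
    ints <- stats::rlnorm(max(lab_c), log(donor_mean), 0.3)
    img <- matrix(0, dim, dim)
    img[lab_c > 0] <- ints[lab_c[lab_c > 0]]
    ch <- if (kind == "donor") compose(img, matrix(0, dim, dim), 0)
    else compose(matrix(0, dim, dim), img, 0)
    to_images(ch)
  }
  donor_only <- lapply(seq_len(n_controls), function(i) gen_control("donor"))
  acceptor_only <- lapply(seq_len(n_controls), function(i) gen_control("acceptor"))

  list(sample = sample_set, donor_only = donor_only,
       acceptor_only = acceptor_only, masks = lab,
       truth = list(E_true = E_true, factors = unclass(factors),
                    background = background, ad_ratio = ad_ratio,
                    ad_sdlog = ad_sdlog, donor_mean = donor_mean,
                    noise_mult = noise_mult, noise_add = noise_add,
                    n_clusters = n_clusters, seed = seed))
}

#' Synthetic FRAP trace with known recovery constant
#'
#' Emulates a confocal FRAP recording: a pre-bleach plateau, an
#' instantaneous bleach to `1 - bleach_depth` of baseline, recovery
#' `M * (1 - exp(-t / tau))` toward the mobile fraction, an acquisition
#' autobleach decay shared by the bleached and control regions, and
#' additive Gaussian noise.
#'
#' @param tau Recovery time constant (s).
#' @param M Mobile fraction in (0, 1].
#' @param bleach_depth Fraction of baseline intensity removed by the bleach.
#' @param duration Post-bleach recording length (s); default 300 s (5 min).
#' @param fs Sampling rate (Hz); default 1.
#' @param pre_s Pre-bleach baseline length (s).
#' @param autobleach Total fractional intensity loss of the control region
#'   over the recording due to acquisition bleaching (exponential decay).
#' @param noise_sd SD of additive noise (units of baseline intensity).
#' @param seed RNG seed.
#' @return A [frap_trace()] with attribute `truth`.
#' @export
gen_frap_trace <- function(tau = 427, M = 0.85, bleach_depth = 0.8,
                           duration = 300, fs = 1, pre_s = 10,
                           autobleach = 0.1, noise_sd = 0.02, seed = 1) {
  if (tau <= 0) stop("tau must be > 0")
  set.seed(seed)
  t <- seq(-pre_s, duration, by = 1 / fs)
  post <- t >= 0
  f0 <- 1 - bleach_depth
  bleach <- ifelse(post, f0 + (1 - f0) * M * (1 - exp(-pmax(t, 0) / tau)), 1)
  control <- rep(1, length(t))
  ab <- exp(log(1 - autobleach) * (t - t[1]) / (max(t) - t[1]))
  Fb <- bleach * ab + stats::rnorm(length(t), 0, noise_sd)
  Fc <- control * ab + stats::rnorm(length(t), 0, noise_sd)
  tr <- frap_trace(t, pmax(Fb, 0), pmax(Fc, 1e-6),
                   bleach_frame = which(post)[1])
  attr(tr, "truth") <- list(tau = tau, M = M, bleach_depth = bleach_depth,
                            autobleach = autobleach, noise_sd = noise_sd,
                            fs = fs, duration = duration, seed = seed)
  tr
}

# CRAC-like inward-rectifying IV shape (pA per nS of peak conductance):
# linear driving force toward the reversal potential, suppressed at
# depolarized potentials.
crac_iv_shape <- function(V, v_rev = 55, v_mid = -20, v_slope = 30) {
  (V - v_rev) / (1 + exp((V - v_mid) / v_slope))
}

#' Synthetic voltage-ramp series
#'
#' Builds a CRAC-like whole-cell ramp recording: an inward-rectifying IV
#' shape with positive reversal potential, a conductance that develops over
#' time (parametric sigmoid, or proportional to a simulated current trace
#' supplied via `current_trace`), an ohmic leak, and additive noise. The
#' conductance is scaled so that the peak current density at -130 mV equals
#' `cd_target` (pA/pF).
#'
#' @param n_sweeps Number of ramp sweeps.
#' @param sweep_dt Interval between sweeps (s).
#' @param V Ramp voltage grid (mV).
#' @param C_m Membrane capacitance (pF).
#' @param cd_target Peak current density at -130 mV (pA/pF, negative for
#'   inward).
#' @param t_half,t_slope Sigmoid activation midpoint and slope (s), used
#'   when `current_trace` is NULL.
#' @param current_trace Optional [socm_run()] result; its `I(t)` (linearly
#'   interpolated, normalized to its maximum) drives the conductance.
#' @param v_rev Reversal potential (mV).
#' @param g_leak Ohmic leak conductance (nS).
#' @param noise_sd Additive current noise SD (pA).
#' @param seed RNG seed.
#' @return A [ramp_series()] with attribute `truth`.
#' @export
gen_ramp_series <- function(n_sweeps = 120, sweep_dt = 2,
                            V = seq(-150, 150, by = 2), C_m = 12,
                            cd_target = -20, t_half = 80, t_slope = 25,
                            current_trace = NULL, v_rev = 60,
                            g_leak = 0.5, noise_sd = 1, seed = 1) {
  set.seed(seed)
  times <- (seq_len(n_sweeps) - 1) * sweep_dt
  G_rel <- if (is.null(current_trace)) {
    g <- 1 / (1 + exp(-(times - t_half) / t_slope))
    (g - g[1]) / (1 - g[1])  # zero at the reference sweep
  } else {
    tr <- current_trace$trace
    gi <- stats::approx(tr$t, tr$I, xout = pmin(times, max(tr$t)),
                        rule = 2)$y
    if (max(gi) > 0) gi / max(gi) else gi
  }
  shape <- crac_iv_shape(V, v_rev = v_rev)
  s130 <- stats::approx(V, shape, xout = -130)$y
  g_max <- cd_target * C_m / s130   # so that peak CD(-130 mV) = cd_target
  I <- vapply(seq_len(n_sweeps), function(s)
    g_max * G_rel[s] * shape + g_leak * V +
      stats::rnorm(length(V), 0, noise_sd),
    numeric(length(V)))
  rs <- ramp_series(times, V, I, C_m = C_m, ref_sweep = 1L)
  attr(rs, "truth") <- list(cd_target = cd_target, v_rev = v_rev,
                            g_leak = g_leak, g_max = g_max, C_m = C_m,
                            G_rel = G_rel, noise_sd = noise_sd, seed = seed)
  rs
}

#' Synthetic voltage-step protocol with exponential tail currents
#'
#' Tails at -100 mV are single exponentials whose instantaneous amplitude is
#' proportional to the apparent open probability at the end of each test
#' pulse (`po_profile`), riding on a constant offset, with a brief
#' capacitive transient on the first samples and additive noise.
#'
#' The default `po_profile` emulates fast Ca2+-dependent inactivation:
#' `Po(V) = 1 - a / (1 + exp((V - Vh) / k))` with `a = 0.3`, `Vh = -100`,
#' `k = 20`, giving Po(-160 mV) of about 0.7.
#'
#' @param V_test Test potentials (mV).
#' @param po_profile Function of V returning Po in [0, 1], or a numeric
#'   vector matching `V_test`.
#' @param drive Instantaneous tail current at Po = 1 (pA, negative inward).
#' @param tau_tail Tail decay time constant (s).
#' @param offset Steady current offset at -100 mV (pA).
#' @param fs Sampling rate (Hz).
#' @param tail_s Tail segment length (s).
#' @param transient Amplitude of the residual capacitive transient on the
#'   first two samples (pA).
#' @param noise_sd Additive noise SD (pA).
#' @param seed RNG seed.
#' @return A [step_protocol()] with attribute `truth`.
#' @export
gen_step_protocol <- function(V_test = seq(-160, 80, by = 20),
                              po_profile = NULL, drive = -120,
                              tau_tail = 0.004, offset = -8,
                              fs = 10000, tail_s = 0.02,
                              transient = 300, noise_sd = 1.5, seed = 1) {
  set.seed(seed)
  po <- if (is.null(po_profile)) {
    function(V) 1 - 0.3 / (1 + exp((V + 100) / 20))
  } else if (is.function(po_profile)) po_profile else NULL
  po_v <- if (is.null(po)) {
    if (length(po_profile) != length(V_test))
      stop("po_profile vector must match V_test")
    po_profile
  } else po(V_test)
  if (any(po_v < 0 | po_v > 1)) stop("Po profile must lie in [0, 1]")

  n <- round(tail_s * fs)
  t <- (seq_len(n) - 1) / fs
  tails <- vapply(seq_along(V_test), function(k) {
    y <- drive * po_v[k] * exp(-t / tau_tail) + offset
    y[1] <- y[1] + transient
    if (n >= 2) y[2] <- y[2] + transient * 0.35
    y + stats::rnorm(n, 0, noise_sd)
  }, numeric(n))
  sp <- step_protocol(V_test, tails, fs)
  attr(sp, "truth") <- list(po = po_v, drive = drive, tau_tail = tau_tail,
                            offset = offset, transient = transient,
                            noise_sd = noise_sd, seed = seed)
  sp
}
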