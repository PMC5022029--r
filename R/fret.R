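#' Three-channel FRET image set
#'
#' Container for one three-cube sensitized-emission acquisition: a donor
#' channel (`A`, donor excitation / donor emission), a FRET channel (`B`,
#' donor excitation / acceptor emission) and an acceptor channel (`C`,
#' acceptor excitation / acceptor emission), with per-channel background
#' levels.
#'
#' @param A,B,C Numeric matrices of equal dimensions (intensity counts).
#' @param background Length-3 numeric vector of background levels for
#'   (A, B, C), subtracted before any computation.
#' @param pixel_size Pixel edge length (um), metadata only.
#' @return Object of class `fret_images`.
#' @export
fret_images <- function(A, B, C, background = c(0, 0, 0), pixel_size = 0.1) {
  A <- as.matrix(A); B <- as.matrix(B); C <- as.matrix(C)
  if (!all(dim(A) == dim(B)) || !all(dim(A) == dim(C)))
    stop("A, B and C must have identical dimensions")
  if (length(background) != 3) stop("background must have length 3")
  structure(list(A = A, B = B, C = C, background = as.numeric(background),
                 pixel_size = pixel_size),
            class = "fret_images")
}

#' @export
print.fret_images <- function(x, ...) {
  cat(sprintf("Three-cube FRET image set: %d x %d px (pixel %.3g um), background (A,B,C) = %s\n",
              nrow(x$A), ncol(x$A), x$pixel_size,
              paste(signif(x$background, 3), collapse = ", ")))
  invisible(x)
}

# background-subtract and clip at zero
bgsub <- function(img, bg) pmax(img - bg, 0)

#' Calibrate bleed-through and cross-talk factors
#'
#' Determines the four spectral correction factors from single-labelled
#' control cells, as done once per experimental day:
#' \describe{
#'   \item{beta}{donor bleed-through into the FRET channel, median of `B/A`
#'     over donor-only pixels}
#'   \item{delta}{donor cross-talk into the acceptor channel, median of `C/A`
#'     over donor-only pixels}
#'   \item{gamma}{acceptor cross-excitation into the FRET channel, median of
#'     `B/C` over acceptor-only pixels}
#'   \item{alpha}{acceptor cross-talk into the donor channel, median of `A/C`
#'     over acceptor-only pixels}
#' }
#' Backgrounds are subtracted first; medians are taken over the brightest
#' half of the pixels of the denominator channel for robustness.
#'
#' @param donor_only A [fret_images()] object, or list of them, from cells
#'   expressing only the donor construct.
#' @param acceptor_only Same, for acceptor-only cells.
#' @return Object of class `fret_factors` with elements `alpha`, `beta`,
#'   `gamma`, `delta`.
#' @export
fret_calibrate <- function(donor_only, acceptor_only) {
  as_list <- function(x) if (inherits(x, "fret_images")) list(x) else x
  donor_only <- as_list(donor_only); acceptor_only <- as_list(acceptor_only)

  ratio_med <- function(sets, num, den) {
    vals <- unlist(lapply(sets, function(s) {
      n <- bgsub(s[[num]], s$background[match(num, c("A", "B", "C"))])
      d <- bgsub(s[[den]], s$background[match(den, c("A", "B", "C"))])
      # signal pixels: above half of the (robust) maximum intensity, so
      # background pixels never enter the ratio medians
      keep <- d > 0.5 * stats::quantile(d, 0.995) & d > 0
      if (!any(keep))
        stop("calibration error: no usable pixels in channel ", den)
      n[keep] / d[keep]
    }))
    stats::median(vals)
  }
  f <- structure(list(
    alpha = ratio_med(acceptor_only, "A", "C"),
    beta  = ratio_med(donor_only, "B", "A"),
    gamma = ratio_med(acceptor_only, "B", "C"),
    delta = ratio_med(donor_only, "C", "A")
  ), class = "fret_factors")
  if (f$beta >= 1 || f$gamma >= 1)
    warning("beta or gamma >= 1; check the control images")
  f
}

#' @export
print.fret_factors <- function(x, ...) {
  cat(sprintf("FRET correction factors: alpha = %.4g, beta = %.4g, gamma = %.4g, delta = %.4g\n",
              x$alpha, x$beta, x$gamma, x$delta))
  invisible(x)
}

#' Bleed-through/cross-talk factor constructor
#'
#' @param alpha,beta,gamma,delta Non-negative correction factors; `beta` and
#'   `gamma` should be < 1 for sane optics.
#' @return Object of class `fret_factors`.
#' @export
fret_factors <- function(alpha = 0, beta = 0, gamma = 0, delta = 0) {
  vals <- c(alpha, beta, gamma, delta)
  if (any(vals < 0)) stop("correction factors must be >= 0")
  structure(list(alpha = alpha, beta = beta, gamma = gamma, delta = delta),
            class = "fret_factors")
}

#' Per-pixel apparent FRET efficiency map
#'
#' Computes the donor-normalized sensitized-emission FRET efficiency from
#' background-subtracted images. Cross-talk-corrected donor and acceptor
#' signals `A' = A - alpha * C` and `C' = C - delta * A` replace the raw
#' channels; the corrected FRET signal is `Fc = B - beta * A' - gamma * C'`
#' and the apparent efficiency `E = Fc / (Fc + A')`, clipped to [0, 1].
#' Pixels with `A' <= 0` are masked (`NA`).
#'
#' @param images A [fret_images()] object.
#' @param factors A [fret_factors()] object.
#' @return Numeric matrix of `E` values in [0, 1] (NA where masked).
#' @export
efret_image <- function(images, factors) {
  stopifnot(inherits(images, "fret_images"), inherits(factors, "fret_factors"))
  A0 <- bgsub(images$A, images$background[1])
  B0 <- bgsub(images$B, images$background[2])
  C0 <- bgsub(images$C, images$background[3])
  Ac <- A0 - factors$alpha * C0
  Cc <- C0 - factors$delta * A0
  Fc <- B0 - factors$beta * Ac - factors$gamma * Cc
  E <- Fc / (Fc + Ac)
  E[Ac <= 0] <- NA_real_
  E[!is.na(E) & E < 0] <- 0
  E[!is.na(E) & E > 1] <- 1
  E
}

#' Per-cluster FRET efficiency with expression-ratio filter
#'
#' Averages the corrected channel intensities over each cluster mask,
#' computes the cluster's acceptor/donor ratio and apparent FRET efficiency,
#' and applies the expression filter used per experimental day: only clusters
#' whose acceptor/donor ratio lies within mean +/- 1 SD of the day's
#' distribution are retained.
#'
#' @param images A [fret_images()] object.
#' @param factors A [fret_factors()] object.
#' @param cluster_masks Either an integer label matrix (0 = background,
#'   k = cluster k) or a list of logical matrices.
#' @return Object of class `cluster_fret`: data frame with columns `cluster`,
#'   `mean_A`, `mean_B`, `mean_C` (corrected channel means), `ad_ratio`,
#'   `E_fret`, `included`. Attribute `warning_empty` is TRUE when no cluster
#'   survives the filter.
#' @export
cluster_fret <- function(images, factors, cluster_masks) {
  stopifnot(inherits(images, "fret_images"), inherits(factors, "fret_factors"))
  masks <- normalize_masks(cluster_masks, dim(images$A))
  if (length(masks) == 0) stop("no cluster masks supplied")

  A0 <- bgsub(images$A, images$background[1])
  B0 <- bgsub(images$B, images$background[2])
  C0 <- bgsub(images$C, images$background[3])
  Ac <- A0 - factors$alpha * C0
  Cc <- C0 - factors$delta * A0

  res <- do.call(rbind, lapply(seq_along(masks), function(k) {
    m <- masks[[k]]
    mA <- mean(Ac[m]); mB <- mean(B0[m]); mC <- mean(Cc[m])
    Fc <- mB - factors$beta * mA - factors$gamma * mC
    E <- if (mA > 0) Fc / (Fc + mA) else NA_real_
    data.frame(cluster = k, mean_A = mA, mean_B = mB, mean_C = mC,
               ad_ratio = if (mA > 0) mC / mA else NA_real_,
               E_fret = min(max(E, 0), 1))
  }))
  mu <- mean(res$ad_ratio, na.rm = TRUE)
  sdv <- stats::sd(res$ad_ratio, na.rm = TRUE)
  if (is.na(sdv)) sdv <- 0  # single cluster: its ratio equals the mean
  res$included <- !is.na(res$ad_ratio) &
    res$ad_ratio >= mu - sdv & res$ad_ratio <= mu + sdv
  if (!any(res$included)) {
    warning("no clusters survive the acceptor/donor ratio filter")
    attr(res, "warning_empty") <- TRUE
  } else attr(res, "warning_empty") <- FALSE
  class(res) <- c("cluster_fret", "data.frame")
  res
}

normalize_masks <- function(cluster_masks, dm) {
  if (is.list(cluster_masks)) {
    lapply(cluster_masks, function(m) {
      m <- as.matrix(m)
      if (!all(dim(m) == dm)) stop("mask dimensions must match the images")
      if (!any(m)) stop("cluster masks must be non-empty")
      m > 0
    })
  } else {
    lab <- as.matrix(cluster_masks)
    if (!all(dim(lab) == dm)) stop("mask dimensions must match the images")
    ids <- sort(unique(lab[lab > 0]))
    if (length(ids) == 0) stop("cluster masks must be non-empty")
    lapply(ids, function(k) lab == k)
  }
}

#' @export
summary.cluster_fret <- function(object, ...) {
  inc <- object[object$included, ]
  out <- list(n_total = nrow(object), n_included = nrow(inc),
              mean_E = mean(inc$E_fret), sem_E = stats::sd(inc$E_fret) /
                sqrt(max(nrow(inc), 1)))
  class(out) <- "summary.cluster_fret"
  out
}

#' @export
print.summary.cluster_fret <- function(x, ...) {
  cat(sprintf("%d of %d clusters pass the acceptor/donor ratio filter\n",
              x$n_included, x$n_total))
  cat(sprintf("apparent FRET efficiency: %.3f +/- %.3f (mean +/- s.e.m.)\n",
              x$mean_E, x$sem_E))
  invisible(x)
}

#' Segment clusters by intensity thresholding
#'
#' Simple helper producing cluster masks from a (typically acceptor-channel)
#' image: threshold at a quantile of the positive intensities, then label
#' connected components (requires the EBImage package); components smaller
#' than `min_px` pixels are dropped.
#'
#' @param img Numeric matrix.
#' @param q Intensity quantile used as threshold (default 0.98).
#' @param min_px Minimum component size in pixels.
#' @return Integer label matrix (0 = background).
#' @export
segment_clusters <- function(img, q = 0.98, min_px = 4) {
  if (!requireNamespace("EBImage", quietly = TRUE))
    stop("segment_clusters() requires the EBImage package")
  thr <- stats::quantile(img[img > 0], q)
  lab <- EBImage::bwlabel(img >= thr)
  lab <- as.matrix(lab)
  counts <- table(lab[lab > 0])
  drop <- as.integer(names(counts)[counts < min_px])
  lab[lab %in% drop] <- 0L
  ids <- sort(unique(lab[lab > 0]))
  relab <- integer(max(lab) + 1L)
  relab[ids + 1L] <- seq_along(ids)
  matrix(relab[lab + 1L], nrow(lab), ncol(lab))
}
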