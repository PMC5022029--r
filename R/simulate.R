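#' Run a stochastic channel-assembly trajectory
#'
#' Simulates one trajectory of the reaction-diffusion model from a fresh
#' initial state ([socm_init_state()]) up to `params$t_end`, sampling the
#' CRAC current and species counts on a regular time grid. Identical
#' `(params, geometry, seed)` give bit-identical traces.
#'
#' @param params A [socm_params()] object.
#' @param geometry A [socm_geometry()] object.
#' @param record_dt Sampling interval of the output grid (s); must satisfy
#'   `0 < record_dt <= t_end`.
#' @param seed RNG seed (defaults to `params$seed`).
#' @param keep_state Return the final `socm_state` as well (default TRUE).
#' @return Object of class `socm_trace`: a list with `trace` (data frame
#'   `t`, `I`, `N_dimer_free`, `N_dimer_trapped`, `N_tet`, `N_hex`,
#'   `N_locked`), `final_state` (unless `keep_state = FALSE`), `params`,
#'   `geometry`, `seed`, `n_events` and `params_hash`.
#' @examples
#' \donttest{
#' tr <- socm_run(socm_params(N_orai_dimer = 30, N_stim = 120, t_end = 60),
#'                socm_geometry_reduced(), record_dt = 5, seed = 1)
#' tr
#' }
#' @export
socm_run <- function(params, geometry, record_dt = 1, seed = params$seed,
                     keep_state = TRUE) {
  validate_socm_params(params)
  stopifnot(inherits(geometry, "socm_geometry"))
  if (!is.numeric(record_dt) || record_dt <= 0 || record_dt > params$t_end)
    stop("'record_dt' must satisfy 0 < record_dt <= t_end")
  set.seed(seed)
  state <- socm_init_state(params, geometry)
  es <- state_to_engine(state, geometry)
  out <- .socm_engine(engine_geom(geometry), unclass(params), es,
                      params$t_end, record_dt, 0, 1e4)
  trace <- as.data.frame(out$trace)
  res <- list(trace = trace,
              final_state = if (keep_state) engine_to_state(out$state, geometry),
              params = params, geometry = geometry,
              seed = as.integer(seed), n_events = out$n_events,
              params_hash = config_hash(unclass(params)))
  class(res) <- "socm_trace"
  res
}

#' @export
print.socm_trace <- function(x, ...) {
  tr <- x$trace
  cat(sprintf("Stochastic channel-assembly trajectory (seed %d, %.4g events)\n",
              x$seed, x$n_events))
  cat(sprintf("  %d samples over %.4g s; I(end) = %.4g, max I = %.4g\n",
              nrow(tr), max(tr$t), tr$I[nrow(tr)], max(tr$I)))
  cat(sprintf("  final counts: %d free / %d trapped dimers, %d tetramers, %d hexamers (%d locked channels)\n",
              tr$N_dimer_free[nrow(tr)], tr$N_dimer_trapped[nrow(tr)],
              tr$N_tet[nrow(tr)], tr$N_hex[nrow(tr)], tr$N_locked[nrow(tr)]))
  invisible(x)
}

#' @export
summary.socm_trace <- function(object, ...) {
  tr <- object$trace
  n <- nrow(tr)
  n_ch <- tr$N_tet[n] + tr$N_hex[n]
  structure(list(
    seed = object$seed,
    I_end = tr$I[n], I_max = max(tr$I),
    t_half = if (max(tr$I) > 0) tr$t[which(tr$I >= max(tr$I) / 2)[1]] else NA_real_,
    locked_fraction = if (n_ch > 0) tr$N_locked[n] / n_ch else NA_real_,
    counts_end = tr[n, c("N_dimer_free", "N_dimer_trapped", "N_tet",
                         "N_hex", "N_locked")]
  ), class = "summary.socm_trace")
}

#' @export
print.summary.socm_trace <- function(x, ...) {
  cat(sprintf("I(end) = %.4g (max %.4g, half-max reached at %.4g s)\n",
              x$I_end, x$I_max, x$t_half))
  if (!is.na(x$locked_fraction))
    cat(sprintf("realized locked-channel fraction O_inh/O_tot = %.3f\n",
                x$locked_fraction))
  print(x$counts_end, row.names = FALSE)
  invisible(x)
}

#' @export
plot.socm_trace <- function(x, which = c("current", "counts"), ...) {
  which <- match.arg(which)
  tr <- x$trace
  if (which == "current") {
    plot(tr$t, tr$I, type = "l", xlab = "time (s)",
         ylab = "I (arbitrary units)", ...)
  } else {
    matplot(tr$t, tr[, c("N_dimer_free", "N_dimer_trapped", "N_tet", "N_hex")],
            type = "l", lty = 1, xlab = "time (s)", ylab = "count", ...)
    legend("right", legend = c("free dimer", "trapped dimer", "tetramer",
                               "hexamer"), col = 1:4, lty = 1, bty = "n")
  }
  invisible(x)
}

#' Write a trajectory to CSV with a JSON metadata sidecar
#'
#' Writes the sampled trace as `<stem>.csv` (columns `t`, `I`,
#' `N_dimer_free`, `N_dimer_trapped`, `N_tet`, `N_hex`, `N_locked`) and run
#' metadata (parameter values, parameter hash, seed) as `<stem>.meta.json`.
#'
#' @param trace A `socm_trace` object.
#' @param stem Output path without extension.
#' @return Invisibly, the two file paths.
#' @export
write_trace <- function(trace, stem) {
  stopifnot(inherits(trace, "socm_trace"))
  csv <- paste0(stem, ".csv"); meta <- paste0(stem, ".meta.json")
  utils::write.csv(trace$trace, csv, row.names = FALSE)
  jsonlite::write_json(list(params = unclass(trace$params),
                            params_hash = trace$params_hash,
                            seed = trace$seed,
                            n_events = trace$n_events),
                       meta, auto_unbox = TRUE, digits = NA)
  invisible(c(csv, meta))
}

#' Map a channel-level inhibited fraction to a dimer-level oxidized fraction
#'
#' Oxidation flags live on dimers, and a channel is locked iff any
#' constituent dimer is oxidized. Under random assortment of dimers into
#' channels, a tetramer (2 dimers) is clean with probability `(1-f)^2` and a
#' hexamer (3 dimers) with `(1-f)^3`. Given a desired channel-level locked
#' fraction (e.g. 0.95) and the hexamer share of the channel population,
#' this solves for the dimer-level `f_ox` to pass to [socm_params()] or
#' [apply_oxidation()].
#'
#' @param locked_fraction Desired `O_inhibited / O_total`, in [0, 1).
#' @param hex_weight Fraction of channels that are hexamers (default 1;
#'   baseline runs are hexamer-dominated).
#' @return Dimer-level oxidized fraction `f_ox` in [0, 1].
#' @examples
#' fox_for_locked_fraction(0.95)          # ~ 0.632 for pure hexamers
#' @export
fox_for_locked_fraction <- function(locked_fraction, hex_weight = 1) {
  if (locked_fraction < 0 || locked_fraction >= 1)
    stop("'locked_fraction' must lie in [0, 1)")
  if (hex_weight < 0 || hex_weight > 1)
    stop("'hex_weight' must lie in [0, 1]")
  clean <- 1 - locked_fraction
  g <- function(f) hex_weight * (1 - f)^3 +
    (1 - hex_weight) * (1 - f)^2 - clean
  stats::uniroot(g, c(0, 1), tol = 1e-10)$root
}
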