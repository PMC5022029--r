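#' Initialize the membrane state
#'
#' Places `N_orai_dimer` free dimers uniformly at random over the lattice
#' subvolumes, flags exactly `round(f_ox * N_orai_dimer)` of them as oxidized
#' (random identity, deterministic count), and assigns all STIM1 sites to
#' junctions proportionally to junction area (largest-remainder rounding).
#' No channels exist initially.
#'
#' @param params A [socm_params()] object.
#' @param geometry A [socm_geometry()] object.
#' @return An object of class `socm_state`: list with
#'   \describe{
#'     \item{dimers}{data frame `sv` (subvolume index), `bound`, `oxidized`}
#'     \item{channels}{data frame `species` ("tetramer"/"hexamer"), `sv`,
#'       `junction`, `n_ox` (oxidized constituent dimers), `locked`}
#'     \item{stim_free}{free STIM1 sites per junction}
#'     \item{t}{current time (s)}
#'   }
#' @examples
#' st <- socm_init_state(socm_params(N_orai_dimer = 10, N_stim = 40,
#'                                   f_ox = 0.5),
#'                       socm_geometry_reduced())
#' sum(st$dimers$oxidized)  # exactly 5
#' @export
socm_init_state <- function(params, geometry) {
  validate_socm_params(params)
  stopifnot(inherits(geometry, "socm_geometry"))
  nj <- nrow(geometry$junctions)
  if (params$N_stim > 0 && nj == 0)
    stop("configuration error: N_stim > 0 but the geometry has no junctions")

  n <- params$N_orai_dimer
  nsv <- geometry$nx * geometry$ny
  sv <- sample.int(nsv, n, replace = TRUE)
  n_ox <- round(params$f_ox * n)
  ox <- logical(n)
  if (n_ox > 0) ox[sample.int(n, n_ox)] <- TRUE

  stim_free <- allot_proportional(params$N_stim,
                                  geometry$junctions$radius^2)

  structure(list(
    dimers = data.frame(sv = sv, bound = FALSE, oxidized = ox),
    channels = data.frame(species = character(0), sv = integer(0),
                          junction = integer(0), n_ox = integer(0),
                          locked = logical(0)),
    stim_free = stim_free,
    t = 0
  ), class = "socm_state")
}

# largest-remainder apportionment of n items over weights
allot_proportional <- function(n, w) {
  if (length(w) == 0) return(integer(0))
  q <- n * w / sum(w)
  a <- floor(q)
  rem <- n - sum(a)
  if (rem > 0) {
    idx <- order(q - a, decreasing = TRUE)[seq_len(rem)]
    a[idx] <- a[idx] + 1
  }
  as.integer(a)
}

#' @export
print.socm_state <- function(x, ...) {
  nfree <- sum(!x$dimers$bound); nb <- sum(x$dimers$bound)
  ntet <- sum(x$channels$species == "tetramer")
  nhex <- sum(x$channels$species == "hexamer")
  cat(sprintf(
    "Membrane state at t = %.4g s: %d free + %d trapped dimers, %d tetramers, %d hexamers (%d locked), %d free STIM1 sites\n",
    x$t, nfree, nb, ntet, nhex, sum(x$channels$locked), sum(x$stim_free)))
  invisible(x)
}

#' Instantaneous CRAC current of a membrane state
#'
#' The current is the open-probability-weighted count of unlocked channels:
#' `I = i_unit * (P_hex * N_hex_unlocked + P_tet * N_tet_unlocked +
#' P_dim * N_dimer_trapped_unoxidized)`. Locked channels (any oxidized
#' constituent dimer) contribute zero; free dimers never conduct, and trapped
#' dimers only if `P_dim > 0` (default 0).
#'
#' @param state A `socm_state` object.
#' @param params A [socm_params()] object.
#' @return A single non-negative number (arbitrary current units).
#' @export
compute_current <- function(state, params) {
  stopifnot(inherits(state, "socm_state"))
  ch <- state$channels
  n_hex_u <- sum(ch$species == "hexamer" & !ch$locked)
  n_tet_u <- sum(ch$species == "tetramer" & !ch$locked)
  n_dim_u <- sum(state$dimers$bound & !state$dimers$oxidized)
  params$i_unit * (params$P_hex * n_hex_u + params$P_tet * n_tet_u +
                     params$P_dim * n_dim_u)
}

#' Total Orai1 monomer count of a state
#'
#' Conserved quantity of the simulator: `2 * dimers + 4 * tetramers +
#' 6 * hexamers`.
#' @param state A `socm_state` object.
#' @return Integer monomer count.
#' @export
monomer_count <- function(state) {
  2L * nrow(state$dimers) +
    4L * sum(state$channels$species == "tetramer") +
    6L * sum(state$channels$species == "hexamer")
}

# ---- conversions between the user-facing state and the engine arrays -------

state_to_engine <- function(state, geometry) {
  nsv <- geometry$nx * geometry$ny
  d <- state$dimers
  free <- d[!d$bound, , drop = FALSE]
  trapped <- d[d$bound, , drop = FALSE]
  tab <- function(sv) tabulate(sv, nbins = nsv)
  ch <- state$channels
  tet <- ch[ch$species == "tetramer", , drop = FALSE]
  hex <- ch[ch$species == "hexamer", , drop = FALSE]
  list(
    free_sv = as.integer(free$sv), free_ox = as.integer(free$oxidized),
    b0 = tab(trapped$sv[!trapped$oxidized]),
    b1 = tab(trapped$sv[trapped$oxidized]),
    T0 = tab(tet$sv[tet$n_ox == 0]), T1 = tab(tet$sv[tet$n_ox == 1]),
    T2 = tab(tet$sv[tet$n_ox == 2]),
    H0 = tab(hex$sv[hex$n_ox == 0]), H1 = tab(hex$sv[hex$n_ox == 1]),
    H2 = tab(hex$sv[hex$n_ox == 2]), H3 = tab(hex$sv[hex$n_ox == 3]),
    stim_free = as.integer(state$stim_free),
    t = state$t
  )
}

engine_to_state <- function(es, geometry) {
  jof <- geometry$junction_of
  expand <- function(counts, n_ox, species) {
    svs <- rep(which(counts > 0), counts[counts > 0])
    if (length(svs) == 0)
      return(data.frame(species = character(0), sv = integer(0),
                        junction = integer(0), n_ox = integer(0),
                        locked = logical(0)))
    data.frame(species = species, sv = svs, junction = jof[svs],
               n_ox = n_ox, locked = n_ox > 0)
  }
  b_expand <- function(counts, oxidized) {
    svs <- rep(which(counts > 0), counts[counts > 0])
    data.frame(sv = svs, bound = rep(TRUE, length(svs)),
               oxidized = rep(oxidized, length(svs)))
  }
  dimers <- rbind(
    data.frame(sv = es$free_sv, bound = rep(FALSE, length(es$free_sv)),
               oxidized = as.logical(es$free_ox)),
    b_expand(es$b0, FALSE), b_expand(es$b1, TRUE))
  channels <- rbind(
    expand(es$T0, 0L, "tetramer"), expand(es$T1, 1L, "tetramer"),
    expand(es$T2, 2L, "tetramer"),
    expand(es$H0, 0L, "hexamer"), expand(es$H1, 1L, "hexamer"),
    expand(es$H2, 2L, "hexamer"), expand(es$H3, 3L, "hexamer"))
  structure(list(dimers = dimers, channels = channels,
                 stim_free = es$stim_free, t = es$t),
            class = "socm_state")
}

#' Advance the state by stochastic events
#'
#' Executes `n_events` exact-Gillespie events (diffusive hop, trap, untrap,
#' dimer+dimer association, tetramer+dimer association, or disassembly),
#' advancing time by exponentially distributed waiting times. With an empty
#' propensity set the state is returned with `t` advanced to `t_end`
#' (absorbing). Assembly follows the any-subunit locking rule: a product
#' channel is locked iff any constituent dimer is oxidized, and disassembly
#' restores the constituent oxidation flags.
#'
#' Uses R's RNG stream; call `set.seed()` for reproducibility.
#'
#' @param state A `socm_state` object.
#' @param params A [socm_params()] object.
#' @param geometry A [socm_geometry()] object.
#' @param n_events Number of events to execute (default 1).
#' @param t_end Absorbing end time (default `params$t_end`).
#' @return The advanced `socm_state`.
#' @export
socm_step <- function(state, params, geometry, n_events = 1,
                      t_end = params$t_end) {
  validate_socm_params(params)
  stopifnot(inherits(state, "socm_state"), inherits(geometry, "socm_geometry"))
  es <- state_to_engine(state, geometry)
  out <- .socm_engine(engine_geom(geometry), unclass(params), es,
                      t_end, -1, n_events, 1e4)
  engine_to_state(out$state, geometry)
}

engine_geom <- function(geometry) {
  list(nx = geometry$nx, ny = geometry$ny, h = geometry$h,
       junction_of = as.integer(geometry$junction_of),
       junction_svs = lapply(geometry$junction_svs, as.integer))
}
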