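# Hand-built membrane states and tiny geometries for unit tests.

# smallest well-mixed geometry: a single subvolume that is one junction
geom_one_sv <- function() {
  socm_geometry(domain_side = 0.2, lattice_spacing = 0.2,
                n_junctions = 1, junction_radius = 0.1)
}

# small open lattice without junctions (pure diffusion)
geom_diffusion <- function(side = 1) {
  socm_geometry(domain_side = side, lattice_spacing = 0.2, n_junctions = 0)
}

# a state with given trapped dimers / channels placed in subvolume `sv`
make_state <- function(geometry, free_sv = integer(0), free_ox = logical(0),
                       trapped_sv = integer(0), trapped_ox = logical(0),
                       channels = NULL, stim_free = NULL, t = 0) {
  nj <- nrow(geometry$junctions)
  if (is.null(stim_free)) stim_free <- rep(0L, nj)
  if (is.null(channels))
    channels <- data.frame(species = character(0), sv = integer(0),
                           junction = integer(0), n_ox = integer(0),
                           locked = logical(0))
  dimers <- rbind(
    data.frame(sv = as.integer(free_sv),
               bound = rep(FALSE, length(free_sv)),
               oxidized = as.logical(free_ox)),
    data.frame(sv = as.integer(trapped_sv),
               bound = rep(TRUE, length(trapped_sv)),
               oxidized = as.logical(trapped_ox)))
  structure(list(dimers = dimers, channels = channels,
                 stim_free = as.integer(stim_free), t = t),
            class = "socm_state")
}

# parameters with every rate zeroed; individual rates switched on per test
params_quiet <- function(...) {
  args <- utils::modifyList(
    list(D_O = 0, D_trapped = 0, k_trap = 0, k_untrap = 0, k_dd = 0,
         k_td = 0, k_dis_tet = 0, k_dis_hex = 0, N_orai_dimer = 0,
         N_stim = 0),
    list(...))
  do.call(socm_params, args)
}

count_species <- function(state) {
  c(free = sum(!state$dimers$bound), trapped = sum(state$dimers$bound),
    tet = sum(state$channels$species == "tetramer"),
    hex = sum(state$channels$species == "hexamer"),
    locked = sum(state$channels$locked))
}
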