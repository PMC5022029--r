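test_that("initial state places dimers and oxidation flags as specified", {
  g <- socm_geometry_reduced()

  set.seed(1)
  st0 <- socm_init_state(socm_params(N_orai_dimer = 40, N_stim = 480,
                                     f_ox = 0), g)
  expect_false(any(st0$dimers$oxidized))
  expect_false(any(st0$dimers$bound))
  expect_equal(nrow(st0$channels), 0)

  st1 <- socm_init_state(socm_params(N_orai_dimer = 40, N_stim = 480,
                                     f_ox = 1), g)
  expect_true(all(st1$dimers$oxidized))

  # deterministic count, random identity
  for (s in 1:5) {
    set.seed(s)
    st <- socm_init_state(socm_params(N_orai_dimer = 100, N_stim = 480,
                                      f_ox = 0.5), g)
    expect_identical(sum(st$dimers$oxidized), 50L)
  }
})

test_that("STIM1 sites are allotted proportionally to junction area", {
  g <- socm_geometry_reduced()
  st <- socm_init_state(socm_params(N_stim = 480), g)
  # equal-radius junctions share sites equally
  expect_true(all(st$stim_free == 60L))
  expect_identical(sum(st$stim_free), 480L)
  # non-divisible totals differ by at most one site between junctions
  st2 <- socm_init_state(socm_params(N_stim = 479), g)
  expect_identical(sum(st2$stim_free), 479L)
  expect_lte(diff(range(st2$stim_free)), 1L)
})

test_that("STIM1 without junctions is a configuration error", {
  g <- geom_diffusion()
  expect_error(socm_init_state(socm_params(N_stim = 100), g), "junction")
  expect_silent(st <- socm_init_state(socm_params(N_stim = 0,
                                                  N_orai_dimer = 5), g))
})

test_that("parameter invariants are enforced", {
  expect_error(socm_params(P_hex = 0.1, P_tet = 0.5), "P_hex")
  expect_error(socm_params(f_ox = 1.5), "f_ox")
  expect_error(socm_params(k_dd = -1), "k_dd")
  expect_error(socm_params(stim_per_dimer = 0), "stim_per_dimer")
})

test_that("oxidation modifiers scale rates as measured and are not idempotent", {
  p <- socm_params(D_O = 0.1)

  same <- apply_oxidation(p, oxidation_modifiers(1, 1, 1), f_ox = 0)
  expect_equal(unclass(same), unclass(p))

  ox <- apply_oxidation(p, oxidation_modifiers(), f_ox = 0.63)
  expect_equal(ox$D_O, 0.066)
  expect_equal(ox$k_dd, p$k_dd / 2.25)
  expect_equal(ox$k_td, p$k_td / 2.25)
  expect_equal(ox$k_trap, p$k_trap * 1.4)
  expect_equal(ox$f_ox, 0.63)
  # original untouched
  expect_equal(p$D_O, 0.1)

  twice <- apply_oxidation(ox, oxidation_modifiers(), f_ox = 0.63)
  expect_false(isTRUE(all.equal(twice$D_O, ox$D_O)))
  expect_equal(twice$D_O, 0.1 * 0.66^2)

  expect_error(apply_oxidation(p, oxidation_modifiers(), f_ox = 2), "f_ox")
})

test_that("current is the open-probability-weighted count of unlocked channels", {
  g <- geom_one_sv()
  p <- params_quiet(P_hex = 0.8, P_tet = 0.2, i_unit = 1)
  sv <- g$junction_svs[[1]]

  empty <- make_state(g)
  expect_identical(compute_current(empty, p), 0)

  hex3 <- make_state(g, channels = data.frame(
    species = rep("hexamer", 3), sv = sv, junction = 1L, n_ox = 0L,
    locked = FALSE))
  expect_equal(compute_current(hex3, p), 2.4)

  # 2 hexamers (1 locked) + 4 tetramers (2 locked): 0.8 + 2 * 0.2 = 1.2
  mixed <- make_state(g, channels = data.frame(
    species = c("hexamer", "hexamer", rep("tetramer", 4)),
    sv = sv, junction = 1L,
    n_ox = c(0L, 1L, 0L, 0L, 2L, 1L),
    locked = c(FALSE, TRUE, FALSE, FALSE, TRUE, TRUE)))
  expect_equal(compute_current(mixed, p), 1.2)

  # locked channels and dimers contribute nothing by default
  dimers <- make_state(g, trapped_sv = rep(sv, 3),
                       trapped_ox = c(FALSE, FALSE, TRUE))
  expect_identical(compute_current(dimers, p), 0)
  p_dim <- params_quiet(P_hex = 0.8, P_tet = 0.2, P_dim = 0.1)
  expect_equal(compute_current(dimers, p_dim), 0.2)  # oxidized dimer excluded
})

test_that("channel-level locked fraction maps to dimer-level f_ox", {
  # pure hexamers: 1 - (1 - f)^3 = 0.95  =>  f = 1 - 0.05^(1/3)
  expect_equal(fox_for_locked_fraction(0.95), 1 - 0.05^(1 / 3),
               tolerance = 1e-6)
  # pure tetramers
  expect_equal(fox_for_locked_fraction(0.75, hex_weight = 0),
               0.5, tolerance = 1e-6)
  expect_equal(fox_for_locked_fraction(0), 0, tolerance = 1e-6)
  expect_error(fox_for_locked_fraction(1), "locked_fraction")
})
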