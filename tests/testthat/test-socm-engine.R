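test_that("a state with no possible events only advances time", {
  g <- geom_one_sv()
  p <- params_quiet(t_end = 50)
  st <- make_state(g)
  set.seed(1)
  out <- socm_step(st, p, g)
  expect_equal(out$t, 50)
  expect_equal(nrow(out$dimers), 0)
})

test_that("with a single propensity the next reaction is forced", {
  g <- geom_one_sv()
  sv <- g$junction_svs[[1]]
  p <- params_quiet(k_dd = 0.5, t_end = 1e6)

  # two clean trapped dimers -> unlocked tetramer
  set.seed(2)
  st <- make_state(g, trapped_sv = rep(sv, 2), trapped_ox = c(FALSE, FALSE))
  out <- socm_step(st, p, g)
  expect_equal(unname(count_species(out)),
               c(0L, 0L, 1L, 0L, 0L))
  expect_false(out$channels$locked)

  # any oxidized constituent locks the product
  st_ox <- make_state(g, trapped_sv = rep(sv, 2), trapped_ox = c(TRUE, FALSE))
  out_ox <- socm_step(st_ox, p, g)
  expect_true(out_ox$channels$locked)
  expect_identical(out_ox$channels$n_ox, 1L)
})

test_that("assembly and disassembly round-trip preserves oxidation flags", {
  g <- geom_one_sv()
  sv <- g$junction_svs[[1]]
  set.seed(3)

  # three clean dimers -> tetramer -> hexamer
  p_asm <- params_quiet(k_dd = 1, k_td = 1, t_end = 1e6)
  st <- make_state(g, trapped_sv = rep(sv, 3), trapped_ox = rep(FALSE, 3))
  st <- socm_step(st, p_asm, g, n_events = 2)
  expect_equal(unname(count_species(st)), c(0L, 0L, 0L, 1L, 0L))

  # disassemble twice: hexamer -> tetramer + dimer -> 3 dimers
  p_dis <- params_quiet(k_dis_tet = 1, k_dis_hex = 1, t_end = 1e6)
  st <- socm_step(st, p_dis, g, n_events = 2)
  expect_equal(unname(count_species(st)), c(0L, 3L, 0L, 0L, 0L))
  expect_true(all(st$dimers$bound))
  expect_false(any(st$dimers$oxidized))

  # mixed oxidation: flags are restored exactly on full disassembly
  st2 <- make_state(g, trapped_sv = rep(sv, 3),
                    trapped_ox = c(TRUE, TRUE, FALSE))
  st2 <- socm_step(st2, p_asm, g, n_events = 2)
  expect_identical(st2$channels$n_ox, 2L)
  expect_true(st2$channels$locked)
  st2 <- socm_step(st2, p_dis, g, n_events = 2)
  expect_identical(sum(st2$dimers$oxidized), 2L)
})

test_that("trapping consumes STIM1 sites and untrapping releases them", {
  g <- geom_one_sv()
  sv <- g$junction_svs[[1]]
  p <- params_quiet(k_trap = 1, t_end = 1e6)
  set.seed(4)
  st <- make_state(g, free_sv = sv, free_ox = FALSE, stim_free = 8L)
  out <- socm_step(st, p, g)
  expect_true(out$dimers$bound)
  expect_identical(out$stim_free, 4L)

  p_un <- params_quiet(k_untrap = 1, t_end = 1e6)
  out2 <- socm_step(out, p_un, g)
  expect_false(out2$dimers$bound)
  expect_identical(out2$stim_free, 8L)

  # fewer free sites than stim_per_dimer: trapping impossible, absorbing
  st_low <- make_state(g, free_sv = sv, free_ox = FALSE, stim_free = 3L)
  out3 <- socm_step(st_low, p, g)
  expect_false(out3$dimers$bound)
  expect_equal(out3$t, p$t_end)
})

test_that("a lone diffusing dimer visits subvolumes uniformly", {
  g <- geom_diffusion(side = 1)  # 5 x 5 lattice
  nsv <- g$nx * g$ny
  p <- params_quiet(D_O = 0.5, t_end = 1e9)
  start_sv <- 1L  # corner start; ~300 hop attempts mix the 5x5 lattice
  set.seed(42)
  finals <- vapply(1:600, function(i) {
    st <- make_state(g, free_sv = start_sv, free_ox = FALSE)
    socm_step(st, p, g, n_events = 300)$dimers$sv
  }, integer(1))
  tab <- tabulate(finals, nbins = nsv)
  pval <- stats::chisq.test(tab, p = rep(1 / nsv, nsv))$p.value
  expect_gt(pval, 1e-3)
})

test_that("Orai1 monomers are conserved along trajectories", {
  g <- socm_geometry_reduced()
  p <- socm_params(N_stim = 480, N_orai_dimer = 240, t_end = 200)
  tr <- socm_run(p, g, record_dt = 20, seed = 7)
  with(tr$trace, expect_true(all(
    2 * (N_dimer_free + N_dimer_trapped) + 4 * N_tet + 6 * N_hex ==
      2 * p$N_orai_dimer)))
  expect_identical(monomer_count(tr$final_state), 2L * p$N_orai_dimer)
})

test_that("identical parameters and seed give bit-identical traces", {
  g <- socm_geometry_reduced()
  p <- socm_params(N_stim = 480, N_orai_dimer = 120, t_end = 120)
  a <- socm_run(p, g, record_dt = 10, seed = 11)
  b <- socm_run(p, g, record_dt = 10, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_identical(a$n_events, b$n_events)
  c_ <- socm_run(p, g, record_dt = 10, seed = 12)
  expect_false(identical(a$trace$I, c_$trace$I))
})

test_that("current is identically zero without STIM1 or with full oxidation", {
  g <- socm_geometry_reduced()
  p0 <- socm_params(N_stim = 0, N_orai_dimer = 60, t_end = 100)
  tr0 <- socm_run(p0, g, record_dt = 10, seed = 1)
  expect_true(all(tr0$trace$I == 0))
  expect_true(all(tr0$trace$N_dimer_trapped == 0))

  p1 <- socm_params(N_stim = 480, N_orai_dimer = 120, f_ox = 1, t_end = 150)
  tr1 <- socm_run(p1, g, record_dt = 10, seed = 1)
  expect_true(all(tr1$trace$I == 0))
  # channels do form, but all are locked
  n <- nrow(tr1$trace)
  expect_identical(tr1$trace$N_locked[n],
                   tr1$trace$N_tet[n] + tr1$trace$N_hex[n])
  expect_gt(tr1$trace$N_locked[n], 0L)
})

test_that("current stays zero until the store is depleted", {
  g <- socm_geometry_reduced()
  p <- socm_params(N_stim = 480, N_orai_dimer = 120, t_end = 200,
                   store_depletion_time = 100)
  tr <- socm_run(p, g, record_dt = 10, seed = 5)
  expect_true(all(tr$trace$I[tr$trace$t < 100] == 0))
  expect_true(all(tr$trace$N_dimer_trapped[tr$trace$t < 100] == 0))
  expect_gt(tr$trace$I[nrow(tr$trace)], 0)
})

test_that("well-mixed species counts match the mass-action ODE", {
  skip_if_not_installed("deSolve")
  g <- geom_one_sv()
  # one subvolume is exactly well-stirred; copy numbers kept large enough
  # that the mean-field closure of the pair terms is accurate
  p <- socm_params(D_O = 0, k_trap = 5e-4, k_untrap = 0.1, k_dd = 2e-4,
                   k_td = 5e-4, k_dis_tet = 0.005, k_dis_hex = 0.005,
                   N_orai_dimer = 150, N_stim = 400, t_end = 100)

  deriv <- function(t, y, parms) {
    with(as.list(c(y, parms)), {
      trap <- k_trap * S * F
      untrap <- k_untrap * B
      dd <- k_dd * B * (B - 1) / 2
      td <- k_td * Tt * B
      dist <- k_dis_tet * Tt
      dish <- k_dis_hex * H
      list(c(F = -trap + untrap,
             B = trap - untrap - 2 * dd - td + 2 * dist + dish,
             Tt = dd - td - dist + dish,
             H = td - dish,
             S = -spd * trap + spd * untrap))
    })
  }
  ode <- deSolve::lsoda(
    c(F = 150, B = 0, Tt = 0, H = 0, S = 400), times = c(0, 50, 100), deriv,
    c(k_trap = p$k_trap, k_untrap = p$k_untrap, k_dd = p$k_dd,
      k_td = p$k_td, k_dis_tet = p$k_dis_tet, k_dis_hex = p$k_dis_hex,
      spd = p$stim_per_dimer))

  n_seeds <- 40
  sims <- vapply(seq_len(n_seeds), function(s) {
    tr <- socm_run(p, g, record_dt = 50, seed = 100 + s)$trace
    c(tr$N_dimer_free[2:3], tr$N_dimer_trapped[2:3], tr$N_tet[2:3],
      tr$N_hex[2:3])
  }, numeric(8))
  means <- rowMeans(sims)
  ses <- apply(sims, 1, sd) / sqrt(n_seeds)
  expected <- c(ode[2:3, "F"], ode[2:3, "B"], ode[2:3, "Tt"], ode[2:3, "H"])
  expect_true(all(abs(means - expected) <= 3 * ses + 1e-9),
              info = paste("sim:", paste(round(means, 2), collapse = " "),
                           "ode:", paste(round(expected, 2), collapse = " ")))
})
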