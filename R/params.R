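#' Simulation parameters for the stochastic channel-assembly model
#'
#' Kinetic and composition parameters of the reaction-diffusion model of
#' store-operated channel assembly. Free Orai1 dimers diffuse on the lattice;
#' at ER-PM junctions clustered STIM1 traps dimers (each trapped dimer
#' consuming `stim_per_dimer` STIM1 sites); co-resident trapped dimers
#' associate pairwise into tetramers, and a tetramer plus a further trapped
#' dimer forms the fully assembled hexameric channel. Hexamers carry the
#' highest open probability, tetramers a lower one, and dimers are
#' non-conducting by default. A channel containing any oxidized dimer is
#' "locked" and conducts nothing.
#'
#' The kinetic defaults are calibration products, frozen once: they were
#' chosen so that the baseline current develops sigmoidally and approaches
#' steady state by 600 s and the Orai1:STIM1 ratio sweep peaks at 0.5 (see the
#' package vignette and `tools/calibrate.R`).
#'
#' @param D_O Free-dimer diffusion coefficient (um^2/s).
#' @param D_trapped Diffusion coefficient of junction-bound species (um^2/s);
#'   0 = immobile once trapped (default).
#' @param k_trap STIM1-Orai1 trapping rate (per s per available STIM1 site per
#'   free dimer in a junction subvolume).
#' @param k_untrap Trapped-dimer unbinding rate (per s).
#' @param k_dd Trapped dimer + dimer association rate (per s per co-resident
#'   pair).
#' @param k_td Tetramer + trapped dimer association rate (per s per
#'   co-resident pair).
#' @param k_dis_tet,k_dis_hex Channel disassembly rates (per s).
#' @param P_hex,P_tet,P_dim Open probabilities of unlocked hexamers, tetramers
#'   and trapped dimers (`P_hex > P_tet >= 0`; dimers default to 0).
#' @param i_unit Single-open-channel current weight (arbitrary units).
#' @param stim_per_dimer STIM1 sites consumed per trapped dimer (>= 1;
#'   default 4, i.e. two STIM1 per Orai1 monomer).
#' @param N_orai_dimer Number of Orai1 dimers.
#' @param N_stim Total STIM1 sites (shared over junctions).
#' @param f_ox Fraction of Orai1 dimers flagged oxidized, in [0, 1].
#' @param t_end Simulated duration (s).
#' @param store_depletion_time Time at which STIM1 sites become available (s).
#' @param seed RNG seed used by [socm_run()] when none is given explicitly.
#' @return An object of class `socm_params` (named list).
#' @examples
#' p <- socm_params(N_orai_dimer = 60, N_stim = 480)
#' p$f_ox
#' @export
socm_params <- function(D_O = 0.1,
                        D_trapped = 0,
                        k_trap = 0.05,
                        k_untrap = 0.001,
                        k_dd = 1.0,
                        k_td = 0.01,
                        k_dis_tet = 2e-4,
                        k_dis_hex = 2e-4,
                        P_hex = 0.8,
                        P_tet = 0.05,
                        P_dim = 0,
                        i_unit = 1,
                        stim_per_dimer = 4,
                        N_orai_dimer = 300,
                        N_stim = 1200,
                        f_ox = 0,
                        t_end = 600,
                        store_depletion_time = 0,
                        seed = 1L) {
  p <- structure(list(
    D_O = D_O, D_trapped = D_trapped, k_trap = k_trap, k_untrap = k_untrap,
    k_dd = k_dd, k_td = k_td, k_dis_tet = k_dis_tet, k_dis_hex = k_dis_hex,
    P_hex = P_hex, P_tet = P_tet, P_dim = P_dim, i_unit = i_unit,
    stim_per_dimer = as.integer(stim_per_dimer),
    N_orai_dimer = as.integer(N_orai_dimer), N_stim = as.integer(N_stim),
    f_ox = f_ox, t_end = t_end,
    store_depletion_time = store_depletion_time, seed = as.integer(seed)
  ), class = "socm_params")
  validate_socm_params(p)
  p
}

validate_socm_params <- function(p) {
  rates <- c("D_O", "D_trapped", "k_trap", "k_untrap", "k_dd", "k_td",
             "k_dis_tet", "k_dis_hex", "i_unit", "t_end",
             "store_depletion_time")
  for (nm in rates) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0)
      stop("'", nm, "' must be a single non-negative number")
  }
  for (nm in c("P_hex", "P_tet", "P_dim")) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1 || is.na(v) || v < 0 || v > 1)
      stop("'", nm, "' must lie in [0, 1]")
  }
  if (!(p$P_hex > p$P_tet))
    stop("'P_hex' must exceed 'P_tet' (hexamers have the highest open probability)")
  if (p$f_ox < 0 || p$f_ox > 1) stop("'f_ox' must lie in [0, 1]")
  if (p$stim_per_dimer < 1) stop("'stim_per_dimer' must be >= 1")
  if (p$N_orai_dimer < 0 || p$N_stim < 0)
    stop("particle counts must be non-negative")
  invisible(p)
}

#' @export
print.socm_params <- function(x, ...) {
  cat("Stochastic channel-assembly parameters\n")
  cat(sprintf("  D_O = %.3g um^2/s (trapped: %.3g), k_trap = %.3g, k_untrap = %.3g\n",
              x$D_O, x$D_trapped, x$k_trap, x$k_untrap))
  cat(sprintf("  k_dd = %.3g, k_td = %.3g, k_dis(tet/hex) = %.3g/%.3g per s\n",
              x$k_dd, x$k_td, x$k_dis_tet, x$k_dis_hex))
  cat(sprintf("  Po: hexamer %.2f, tetramer %.2f, dimer %.2f; i_unit = %.3g\n",
              x$P_hex, x$P_tet, x$P_dim, x$i_unit))
  cat(sprintf("  %d Orai1 dimers, %d STIM1 sites (%d per trapped dimer), f_ox = %.3g\n",
              x$N_orai_dimer, x$N_stim, x$stim_per_dimer, x$f_ox))
  cat(sprintf("  t_end = %.4g s, store depletion at %.4g s, seed = %d\n",
              x$t_end, x$store_depletion_time, x$seed))
  invisible(x)
}

#' Oxidation effect modifiers
#'
#' Multiplicative factors describing how H2O2 oxidation of Orai1 alters the
#' measured kinetics: slowed lateral diffusion (factor 0.66 on `D_O`), a
#' 2.25-fold weaker Orai1-Orai1 subunit interaction (factor 1/2.25 on `k_dd`
#' and `k_td`) and a 1.4-fold stronger STIM1-Orai1 interaction (factor 1.4 on
#' `k_trap`).
#'
#' @param m_D Factor on the free-dimer diffusion coefficient (default 0.66).
#' @param m_assoc Factor on the subunit association rates (default 1/2.25).
#' @param m_trap Factor on the trapping rate (default 1.4).
#' @return Object of class `oxidation_modifiers`.
#' @export
oxidation_modifiers <- function(m_D = 0.66, m_assoc = 1 / 2.25, m_trap = 1.4) {
  if (any(c(m_D, m_assoc, m_trap) <= 0)) stop("all modifiers must be > 0")
  structure(list(m_D = m_D, m_assoc = m_assoc, m_trap = m_trap),
            class = "oxidation_modifiers")
}

#' @export
print.oxidation_modifiers <- function(x, ...) {
  cat(sprintf("Oxidation modifiers: D_O x %.3g, association x %.3g, trapping x %.3g\n",
              x$m_D, x$m_assoc, x$m_trap))
  invisible(x)
}

#' Apply oxidation modifiers to a parameter set
#'
#' Returns a new parameter set describing the oxidized condition: the
#' diffusion coefficient, subunit association rates and trapping rate are
#' scaled by the modifiers, and the oxidized-dimer fraction is set to `f_ox`.
#' The input is not modified, and the operation is deliberately not
#' idempotent: applying the modifiers twice scales the rates twice.
#'
#' @param params A [socm_params()] object.
#' @param modifiers An [oxidation_modifiers()] object.
#' @param f_ox Fraction of dimers flagged oxidized in the returned set.
#' @return A new `socm_params` object.
#' @examples
#' p <- socm_params()
#' ox <- apply_oxidation(p, oxidation_modifiers(), f_ox = 0.63)
#' ox$D_O / p$D_O   # 0.66
#' @export
apply_oxidation <- function(params, modifiers = oxidation_modifiers(),
                            f_ox = params$f_ox) {
  stopifnot(inherits(params, "socm_params"),
            inherits(modifiers, "oxidation_modifiers"))
  if (!is.numeric(f_ox) || length(f_ox) != 1 || is.na(f_ox) ||
      f_ox < 0 || f_ox > 1)
    stop("'f_ox' must lie in [0, 1]")
  q <- params
  q$D_O <- params$D_O * modifiers$m_D
  q$k_dd <- params$k_dd * modifiers$m_assoc
  q$k_td <- params$k_td * modifiers$m_assoc
  q$k_trap <- params$k_trap * modifiers$m_trap
  q$f_ox <- f_ox
  validate_socm_params(q)
  q
}
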