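#' Packaged desk-scale ionic-liquid demo run
#'
#' Builds the reference single-bead melt — 1,000 residues at the 30%:70%
#' charged:neutral partitioning (150 cation/anion and 350 neutral
#' acid/base pairs) — and runs Brownian dynamics with proton-exchange
#' updates under the four packaged reactions and the cubic composition
#' feedback (c = 300). Defaults: bead diameter 5 Angstrom, screened Coulomb
#' with dielectric 40 (ion contact energy about one kT at 300 K), 0.02 ps
#' timestep and an exchange check every 0.4 ps (20 steps); 250 update
#' cycles. The 160 Angstrom box sets the density so that a donor finds an
#' acceptor within the transfer distance in only a few percent of the
#' update checks: proton transfers must be rare events on the update-check
#' time scale (of order 10 per molecule over thousands of checks, as in the
#' atomistic production runs), which is the regime the cubic feedback rule
#' is designed to stabilise. At liquid-like packing every molecule reacts
#' at almost every check and the composition saturates the feedback clamp
#' instead of fluctuating around the reference.
#'
#' @param seed Integer seed; derives the packing, noise and acceptance
#'   streams.
#' @param n_cycles Number of exchange-update cycles (>= 1).
#' @param steps_per_cycle Dynamics steps between updates.
#' @param n_ion_pairs,n_neutral_pairs Composition (defaults 150/350).
#' @param box_edge Cubic box edge, Angstrom.
#' @param r_max Bead-scale transfer distance criterion, Angstrom.
#' @param timestep Integrator timestep, ps.
#' @param stride Reporting stride in steps.
#' @param forcefield A [toy_forcefield()]; default the demo melt model.
#' @return A `hop_run` (see [run_dynamics()]).
#' @export
pil_demo <- function(seed = 1, n_cycles = 250, steps_per_cycle = 20,
                     n_ion_pairs = 150, n_neutral_pairs = 350,
                     box_edge = 160, r_max = 6, timestep = 0.02,
                     stride = steps_per_cycle,
                     forcefield = toy_forcefield(epsilon = 0.2, sigma = 5,
                                                 screening_length = 5,
                                                 cutoff = 12,
                                                 dielectric = 40)) {
  sys <- build_system(n_ion_pairs, n_neutral_pairs, box_spec(box_edge),
                      min_separation = 4.5, seed = seed)
  run_dynamics(sys, forcefield,
               integrator_config(timestep = timestep,
                                 n_steps = n_cycles * steps_per_cycle,
                                 seed = seed + 1L),
               update_config(interval_ps = steps_per_cycle * timestep,
                             seed = seed + 2L),
               bead_reactions(r_max), stride = stride)
}

#' Charged fraction of a residue family over the update cycles
#'
#' Fraction of residues of one template pair that are in a given (typically
#' the protonated, charged) state at each update cycle — the quantity the
#' composition feedback holds near its reference value.
#'
#' @param cycles `cycles` data frame from [run_dynamics()].
#' @param state Counted state (default `"IM1H"`).
#' @param family All states of the residue family (default
#'   `c("IM1H", "IM1")`).
#' @return Data frame: `time_ps`, `fraction`.
#' @export
species_fraction <- function(cycles, state = "IM1H",
                             family = c("IM1H", "IM1")) {
  sub <- cycles[cycles$species %in% family, , drop = FALSE]
  tot <- tapply(sub$count, sub$time_ps, sum)
  num <- tapply(ifelse(sub$species == state, sub$count, 0L), sub$time_ps,
                sum)
  t <- as.numeric(names(tot))
  ord <- order(t)
  data.frame(time_ps = t[ord], fraction = as.numeric(num / tot)[ord])
}
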