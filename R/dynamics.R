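#' Toy bead forcefield
#'
#' Nonbonded model for the single-bead engine: a purely repulsive WCA sphere
#' (uniform epsilon/sigma for all beads) plus a screened Coulomb (Yukawa)
#' interaction between bead charges,
#' `U_c = kC q_i q_j exp(-r/lambda) / (eps_r r)`, truncated at the cutoff
#' and shifted so the pair energy is zero there. Screening replaces Ewald
#' summation: it keeps the engine dependency-free and stable while
#' preserving charge ordering qualitatively.
#'
#' @param epsilon WCA well depth, kcal/mol (0 disables the repulsion).
#' @param sigma Bead diameter, Angstrom.
#' @param screening_length Yukawa screening length, Angstrom; `Inf` gives an
#'   unscreened 1/r interaction.
#' @param cutoff Interaction cutoff, Angstrom (must stay below half the
#'   smallest box edge when used).
#' @param dielectric Relative dielectric constant dividing the Coulomb
#'   coupling; the packaged melt demo uses 40 so the ion-contact energy is
#'   about one kT at 300 K.
#' @param shift Shift the Coulomb pair energy to zero at the cutoff.
#' @param units A [charmm_units()] object.
#' @return Object of class `toy_forcefield`.
#' @export
toy_forcefield <- function(epsilon = 0.2, sigma = 5,
                           screening_length = 5, cutoff = 15,
                           dielectric = 1, shift = TRUE,
                           units = charmm_units()) {
  stopifnot(sigma > 0, epsilon >= 0, cutoff > 0, dielectric > 0,
            screening_length > 0)
  structure(list(epsilon = epsilon, sigma = sigma,
                 screening_length = screening_length, cutoff = cutoff,
                 dielectric = dielectric, shift = shift, units = units),
            class = "toy_forcefield")
}

#' Forces and energy components of the toy forcefield
#'
#' Evaluates `-grad U` for the WCA + screened-Coulomb potential under the
#' minimum-image convention. Newton's third law holds pairwise, so the
#' forces sum to zero.
#'
#' @param system An [md_system()] (one interaction site per atom; the toy
#'   systems are single-bead residues).
#' @param forcefield A [toy_forcefield()].
#' @return List with `forces` (n x 3 matrix, kcal mol^-1 Angstrom^-1) and
#'   `energy` (named vector: `wca`, `coulomb`).
#' @export
compute_forces <- function(system, forcefield) {
  n <- nrow(system$positions)
  if (is.finite(forcefield$cutoff) &&
      forcefield$cutoff >= min(system$box) / 2)
    stop(sprintf("cutoff %.3g A must be below half the smallest box edge (%.3g A)",
                 forcefield$cutoff, min(system$box) / 2), call. = FALSE)
  q <- system$atoms$charge
  kC <- forcefield$units$coulomb_constant / forcefield$dielectric
  if (n == 0 || (forcefield$epsilon <= 0 && all(q == 0)))
    return(list(forces = matrix(0, n, 3), energy = c(wca = 0, coulomb = 0)))
  lam <- if (is.finite(forcefield$screening_length))
    forcefield$screening_length else -1
  res <- pair_forces_cpp(system$positions, as.numeric(system$box), q,
                         forcefield$epsilon, forcefield$sigma, lam,
                         forcefield$cutoff, kC, isTRUE(forcefield$shift))
  list(forces = res$forces,
       energy = c(wca = res$e_wca, coulomb = res$e_coulomb))
}

#' Integrator configuration for the Brownian propagator
#'
#' @param timestep Time step, ps (> 0).
#' @param temperature Temperature, K (>= 0; 0 is the deterministic
#'   noise-free limit).
#' @param friction Friction coefficient, ps^-1 (> 0).
#' @param seed RNG seed for the thermal noise stream.
#' @param n_steps Number of steps a run propagates.
#' @param units A [charmm_units()] object.
#' @return Object of class `integrator_config`.
#' @export
integrator_config <- function(timestep = 0.02, temperature = 300,
                              friction = 10, seed = 1, n_steps = 1000,
                              units = charmm_units()) {
  stopifnot(timestep > 0, temperature >= 0, friction > 0, n_steps >= 0)
  structure(list(timestep = timestep, temperature = temperature,
                 friction = friction, seed = as.integer(seed),
                 n_steps = as.integer(n_steps), units = units),
            class = "integrator_config")
}

#' Free diffusion coefficient of the Brownian propagator
#'
#' `D0 = kB T / (m gamma)` in Angstrom^2/ps (the energy-to-AKMA conversion
#' is applied internally).
#'
#' @param cfg An [integrator_config()].
#' @param mass Particle mass, u.
#' @return D0 in Angstrom^2/ps.
#' @export
free_diffusion_coefficient <- function(cfg, mass) {
  kBT <- cfg$units$boltzmann_constant * cfg$temperature
  kBT * cfg$units$kcal_per_akma / (mass * cfg$friction)
}

#' One overdamped (Brownian) dynamics step
#'
#' Position update `x += (D0/kBT) F dt + sqrt(2 D0 dt) xi` with per-particle
#' `D0 = kBT/(m gamma)` and standard-normal noise `xi`; positions are
#' refolded into the box. Reproducible given the RNG state (the runner
#' keeps a dedicated noise stream).
#'
#' @param system An [md_system()].
#' @param forces n x 3 force matrix, kcal mol^-1 Angstrom^-1.
#' @param cfg An [integrator_config()].
#' @return The propagated system (time advanced by one step).
#' @export
brownian_step <- function(system, forces, cfg) {
  n <- nrow(system$positions)
  m <- system$atoms$mass
  if (any(m <= 0))
    stop("Brownian propagation requires positive atom masses", call. = FALSE)
  akma <- cfg$units$kcal_per_akma
  mobility <- akma / (m * cfg$friction)            # A^2 mol / (kcal ps)
  kBT <- cfg$units$boltzmann_constant * cfg$temperature
  D0 <- kBT * mobility
  dt <- cfg$timestep
  noise <- matrix(stats::rnorm(3 * n), n, 3) * sqrt(2 * D0 * dt)
  new_pos <- system$positions + forces * (mobility * dt) + noise
  if (!all(is.finite(new_pos)))
    stop("numerical blow-up: non-finite positions; reduce the timestep",
         call. = FALSE)
  system$positions <- fold_positions(new_pos, system$box)
  system$time <- system$time + dt
  system
}

#' Exchange-update configuration
#'
#' @param interval_ps Time between transfer checks, ps (> 0); the atomistic
#'   production protocol uses 10 ps, the toy demo a bead-scale interval.
#' @param seed RNG seed of the dedicated acceptance stream.
#' @param mode `"instantaneous"` (default) or `"interpolated"` state swaps.
#' @param n_lambda_steps Lambda increments for interpolated swaps (>= 1).
#' @param conflict_policy Only `"greedy"` (shortest-distance-first maximal
#'   matching) is implemented.
#' @return Object of class `update_config`.
#' @export
update_config <- function(interval_ps, seed = 1,
                          mode = c("instantaneous", "interpolated"),
                          n_lambda_steps = 1, conflict_policy = "greedy") {
  mode <- match.arg(mode)
  stopifnot(interval_ps > 0, n_lambda_steps >= 1,
            conflict_policy == "greedy")
  structure(list(interval_ps = interval_ps, seed = as.integer(seed),
                 mode = mode, n_lambda_steps = as.integer(n_lambda_steps),
                 conflict_policy = conflict_policy),
            class = "update_config")
}

#' Run Brownian dynamics with periodic proton-exchange updates
#'
#' Alternates segments of overdamped dynamics with exchange updates exactly
#' every `update_cfg$interval_ps`: at each update the reaction probabilities
#' are refreshed from the current composition (cubic feedback), candidates
#' are detected and conflict-resolved, accepted transfers are executed, and
#' one event row per transfer is logged. Thermal noise and acceptance draws
#' use separate seeded RNG streams, so the event log is reproducible.
#'
#' @param system An [md_system()].
#' @param forcefield A [toy_forcefield()].
#' @param integrator An [integrator_config()].
#' @param update_cfg An [update_config()], or `NULL` for a plain dynamics
#'   run without exchanges.
#' @param reactions List of [transfer_reaction()] (required with
#'   `update_cfg`).
#' @param stride Reporting stride in steps; the update interval must be a
#'   multiple of it. Frames (trajectory, charge and energy reports) are
#'   emitted every `stride` steps plus the initial frame.
#' @return List of class `hop_run`: `trajectory` ([xyz_trajectory()]),
#'   `events`, `charges` (per-frame charge report), `energies`, `cycles`
#'   (per-update species counts and working probabilities),
#'   `initial_species`, `system` (final state), `probability_state`.
#' @examples
#' \donttest{
#' sys <- build_system(5, 10, box_spec(25), min_separation = 4, seed = 7)
#' run <- run_dynamics(sys, toy_forcefield(dielectric = 40, cutoff = 10),
#'                     integrator_config(n_steps = 40, seed = 1),
#'                     update_config(interval_ps = 0.2, seed = 2),
#'                     bead_reactions(), stride = 5)
#' nrow(run$events)
#' }
#' @export
run_dynamics <- function(system, forcefield, integrator, update_cfg = NULL,
                         reactions = NULL, stride = 10) {
  dt <- integrator$timestep
  n_steps <- integrator$n_steps
  do_updates <- !is.null(update_cfg)
  if (do_updates) {
    if (is.null(reactions))
      stop("reactions are required when update_cfg is given", call. = FALSE)
    interval_steps <- round(update_cfg$interval_ps / dt)
    if (abs(interval_steps * dt - update_cfg$interval_ps) > 1e-9 ||
        interval_steps < 1)
      stop("update interval must be a positive multiple of the timestep",
           call. = FALSE)
    if (interval_steps %% stride != 0)
      stop("update interval must be a multiple of the reporting stride",
           call. = FALSE)
    pstate <- probability_state(reactions, system)
    ex_stream <- rng_stream(update_cfg$seed)
  } else pstate <- NULL
  dyn_stream <- rng_stream(integrator$seed)

  n_frames <- n_steps %/% stride + 1L
  n_at <- nrow(system$positions)
  coords <- array(NA_real_, c(n_frames, n_at, 3))
  times <- numeric(n_frames)
  charges_l <- vector("list", n_frames)
  energies_l <- vector("list", n_frames)
  cycles_l <- list()
  events_l <- list()
  initial_species <- system$residues$species

  record <- function(fr) {
    coords[fr, , ] <<- system$positions
    times[fr] <<- system$time
    charges_l[[fr]] <<- report_charges(system)
    energies_l[[fr]] <<- report_energies(system, forcefield)
  }
  record(1L)

  for (step in seq_len(n_steps)) {
    fe <- compute_forces(system, forcefield)
    system <- draw_from(dyn_stream, brownian_step(system, fe$forces,
                                                  integrator))
    if (do_updates && step %% interval_steps == 0L) {
      pstate <- refresh_probabilities(pstate, system)
      cands <- find_candidates(system, reactions)
      pairs <- resolve_conflicts(cands)
      acc <- draw_from(ex_stream, accept_transfers(pairs, pstate))
      if (update_cfg$mode == "instantaneous" || !nrow(acc)) {
        upd <- execute_update(system, acc, reactions)
        system <- upd$system
        ev <- upd$events
      } else {
        ev <- execute_update(system, acc, reactions)$events  # event rows
        for (k in seq_len(nrow(acc)))
          system <- interpolate_states(system, acc[k, ], reactions,
                                       update_cfg$n_lambda_steps,
                                       dynamics_hook = function(s, lam) {
                                         f <- compute_forces(s, forcefield)
                                         draw_from(dyn_stream,
                                                   brownian_step(s, f$forces,
                                                                 integrator))
                                       })
      }
      if (nrow(ev)) events_l[[length(events_l) + 1L]] <- ev
      cnts <- table(factor(system$residues$species))
      cycles_l[[length(cycles_l) + 1L]] <- data.frame(
        time_ps = system$time,
        species = names(cnts), count = as.integer(cnts),
        stringsAsFactors = FALSE)
    }
    if (step %% stride == 0L) record(step %/% stride + 1L)
  }

  events <- if (length(events_l)) do.call(rbind, events_l) else empty_events()
  rownames(events) <- NULL
  structure(list(
    trajectory = xyz_trajectory(coords, times, system$box,
                                system$atoms$name),
    events = events,
    charges = do.call(rbind, charges_l),
    energies = do.call(rbind, energies_l),
    cycles = if (length(cycles_l)) do.call(rbind, cycles_l) else
      data.frame(time_ps = numeric(), species = character(),
                 count = integer(), stringsAsFactors = FALSE),
    initial_species = initial_species,
    probability_state = pstate,
    system = system), class = "hop_run")
}

#' @export
print.hop_run <- function(x, ...) {
  cat(sprintf("hop_run: %d frames, %d residues, %d transfer events, t = %g..%g ps\n",
              dim(x$trajectory$coords)[1], nrow(x$system$residues),
              nrow(x$events), min(x$trajectory$times),
              max(x$trajectory$times)))
  invisible(x)
}
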