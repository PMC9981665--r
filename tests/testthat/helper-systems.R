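# shared fixture builders and brute-force oracles (all generated in code)

# two single-bead residues separated by `d` along x, centered in the box
two_bead_system <- function(species = c("IM1H", "OAC"), d = 10,
                            box_edge = 50) {
  c0 <- box_edge / 2
  pos <- rbind(c(c0 - d / 2, c0, c0), c(c0 + d / 2, c0, c0))
  md_system(species, bead_templates(), pos, box = box_spec(box_edge))
}

# n beads of each of the four species, uniform random positions
random_bead_system <- function(n_each = 10, box_edge = 30, seed = 1) {
  species <- rep(c("IM1H", "OAC", "IM1", "HOAC"), each = n_each)
  pos <- withr::with_seed(seed, matrix(runif(3 * length(species)) * box_edge,
                                       ncol = 3))
  md_system(species, bead_templates(), pos, box = box_spec(box_edge))
}

# O(N^2) minimum-image distance oracle between two point sets
brute_force_cross <- function(a, b, box, rmax) {
  out <- NULL
  for (i in seq_len(nrow(a))) {
    d <- sweep(b, 2, a[i, ])
    d <- d - matrix(box, nrow(b), 3, byrow = TRUE) *
      round(d / matrix(box, nrow(b), 3, byrow = TRUE))
    dist <- sqrt(rowSums(d^2))
    hit <- which(dist < rmax)
    if (length(hit))
      out <- rbind(out, cbind(i, hit, dist[hit]))
  }
  out
}

# continuous (unwrapped) Gaussian random-walk center array [frame, res, 3]
make_walk <- function(n_frames, n_res, step_sd, start = NULL, seed = 1) {
  withr::with_seed(seed, {
    if (is.null(start)) start <- matrix(runif(3 * n_res) * 10, n_res, 3)
    steps <- array(rnorm((n_frames - 1) * n_res * 3, sd = step_sd),
                   c(n_frames - 1, n_res, 3))
    out <- array(NA_real_, c(n_frames, n_res, 3))
    out[1, , ] <- start
    for (f in 2:n_frames) out[f, , ] <- out[f - 1, , ] + steps[f - 1, , ]
    out
  })
}

# fold an unwrapped center array into the box
fold_walk <- function(walk, box) {
  out <- walk
  for (k in 1:3) out[, , k] <- out[, , k] - box[k] * floor(out[, , k] / box[k])
  out
}

# plain Brownian run of non-interacting beads; returns centers, times, D0
free_bead_run <- function(n = 500, n_steps = 4000, dt = 0.5, stride = 10,
                          box_edge = 200, temperature = 300, friction = 10,
                          seed = 1) {
  species <- rep(c("IM1", "HOAC"), length.out = n)  # neutral: no forces
  pos <- withr::with_seed(seed, matrix(runif(3 * n) * box_edge, ncol = 3))
  sys <- md_system(species, bead_templates(), pos, box = box_spec(box_edge))
  ff <- toy_forcefield(epsilon = 0, cutoff = 10)
  cfg <- integrator_config(timestep = dt, temperature = temperature,
                           friction = friction, seed = seed,
                           n_steps = n_steps)
  run <- run_dynamics(sys, ff, cfg, stride = stride)
  centers <- trajectory_residue_centers(run$trajectory, sys)
  list(run = run, system = sys, centers = centers,
       times = run$trajectory$times,
       D0 = free_diffusion_coefficient(cfg, 100))
}

# direct evaluation of the dipole-jump formula with explicit positions
# r_j = r_i + rij (the oracle for the eight correction cases)
direct_dipole_jump <- function(qi_b, qj_b, qi_a, qj_a, ri, rij) {
  rj <- ri + rij
  (qi_a * ri + qj_a * rj) - (qi_b * ri + qj_b * rj)
}
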