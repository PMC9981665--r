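test_that("fold/unfold round-trips continuous random walks exactly", {
  box <- c(12, 15, 9)
  walk <- make_walk(n_frames = 120, n_res = 20, step_sd = 0.8, seed = 31)
  folded <- fold_walk(walk, box)
  un <- unfold_centers(folded, box)
  # unfolding is anchored at the first (folded) frame
  shift <- walk[1, , ] - folded[1, , ]
  for (f in c(1, 50, 120))
    expect_equal(un[f, , ] + shift, walk[f, , ], tolerance = 1e-9)
  # consecutive displacements equal minimum-image displacements of the input
  d_un <- un[2, , ] - un[1, , ]
  d_mi <- min_image(folded[2, , ] - folded[1, , ], box)
  expect_equal(d_un, d_mi, tolerance = 1e-12)
})

test_that("a boundary crossing unfolds monotonically without box jumps", {
  box <- c(10, 10, 10)
  x <- c(9.2, 9.8, 0.4, 1.0)  # crosses +x over 4 frames
  centers <- array(0, c(4, 1, 3))
  centers[, 1, 1] <- x
  centers[, 1, 2] <- 5; centers[, 1, 3] <- 5
  un <- unfold_centers(centers, box)
  expect_equal(un[, 1, 1], c(9.2, 9.8, 10.4, 11.0), tolerance = 1e-12)
  expect_true(all(diff(un[, 1, 1]) > 0))
  # static particles unfold to themselves
  st <- array(rep(c(3, 4, 5), each = 5), c(5, 1, 3))
  expect_identical(unfold_centers(st, box), st)
})

test_that("unfolding flags steps larger than the credible maximum", {
  box <- c(20, 20, 20)
  centers <- array(5, c(3, 2, 3))
  centers[3, 2, 1] <- 12  # residue 2 jumps 7 A between frames 2 and 3
  expect_error(unfold_centers(centers, box, max_step = 5),
               "residue 2.*frames.*2.*3")
})

test_that("segments are cut at transfer events and filtered by length", {
  tpl <- bead_templates()
  times <- seq(0, 10, by = 0.5)
  centers <- array(1, c(length(times), 2, 3))
  no_ev <- protonhop:::empty_events()
  segs <- cut_segments(centers, times, no_ev, c("IM1H", "OAC"), tpl,
                       min_length = 5)
  expect_identical(nrow(segs), 2L)
  expect_identical(segs$state, c("IM1H", "OAC"))
  expect_equal(segs$end_ps - segs$start_ps, c(10, 10))

  # one mid-run event for residue 1: two segments with flipped labels
  ev <- protonhop:::empty_events()
  ev[1, ] <- list(5.0, 1L, 2L, "IM1H+OAC->IM1+HOAC", 1L, -1L, 0L, 0L,
                  1, 1, 1, 1, 1, 1, 0, 0, 0)
  segs2 <- cut_segments(centers, times, ev, c("IM1H", "OAC"), tpl,
                        min_length = 4)
  s1 <- segs2[segs2$residue == 1, ]
  expect_identical(s1$state, c("IM1H", "IM1"))
  expect_equal(s1$start_ps, c(0, 5))
  expect_equal(s1$end_ps, c(4.5, 10))

  # event at 30% of the run with min length 50%: only the tail survives
  ev3 <- ev; ev3$time_ps <- 3.0
  segs3 <- cut_segments(centers, times, ev3, c("IM1H", "OAC"), tpl,
                        min_length = 5)
  s3 <- segs3[segs3$residue == 1, ]
  expect_identical(nrow(s3), 1L)
  expect_identical(s3$state, "IM1")
  expect_equal(s3$start_ps, 3)
  # unknown residue id in an event is a consistency error
  ev4 <- ev; ev4$residue_j <- 9L
  expect_error(cut_segments(centers, times, ev4, c("IM1H", "OAC"), tpl),
               "unknown residue")
})

test_that("diffusion is zero for static systems and equal for equal paths", {
  tpl <- bead_templates()
  times <- seq(0, 20, by = 0.5)
  nf <- length(times)
  walk <- make_walk(nf, 1, step_sd = 0.8, seed = 5)[, 1, ]
  centers <- array(NA_real_, c(nf, 2, 3))
  centers[, 1, ] <- walk
  centers[, 2, ] <- walk  # residue 2 follows the identical path
  segs <- cut_segments(centers, times, protonhop:::empty_events(),
                       c("IM1H", "IM1"), tpl, min_length = 10)
  D <- diffusion_coefficient(centers, times, segs, tpl)
  d_states <- D$D_A2_ps[D$group == "state"]
  expect_equal(d_states[1], d_states[2], tolerance = 1e-12)
  # pooled value equals the common value
  expect_equal(D$D_A2_ps[D$group == "pair"], d_states[1], tolerance = 1e-12)

  static <- array(2, c(nf, 1, 3))
  segs_s <- cut_segments(static, times, protonhop:::empty_events(), "IM1H",
                         tpl, min_length = 10)
  Ds <- diffusion_coefficient(static, times, segs_s, tpl)
  expect_equal(Ds$D_A2_ps, c(0, 0), tolerance = 1e-12)
})

test_that("collective dipole reproduces hand-computed cases", {
  times <- c(0, 1)
  # all-neutral system: M identically zero
  c0 <- array(runif(2 * 3 * 3), c(2, 3, 3))
  ds0 <- collective_dipole(c0, times, c(0, 0, 0))
  expect_equal(ds0$raw, matrix(0, 2, 3))
  # one +1 residue moving +1 A in x
  c1 <- array(0, c(2, 1, 3))
  c1[2, 1, 1] <- 1
  ds1 <- collective_dipole(c1, times, 1)
  expect_equal(ds1$raw[2, ] - ds1$raw[1, ], c(1, 0, 0))
  # rigid translation of a +1/-1 pair leaves M constant
  c2 <- array(0, c(2, 2, 3))
  c2[1, 1, ] <- c(0, 0, 0); c2[1, 2, ] <- c(3, 0, 0)
  c2[2, 1, ] <- c(5, 2, 1); c2[2, 2, ] <- c(8, 2, 1)
  ds2 <- collective_dipole(c2, times, c(1, -1))
  expect_equal(ds2$raw[1, ], ds2$raw[2, ], tolerance = 1e-12)
})

test_that("the reaction scheme generates exactly eight correction cases", {
  cfg <- default_templates()
  cases <- enumerate_correction_cases(cfg$reactions, cfg$templates)
  expect_identical(nrow(cases), 8L)
  expect_identical(nrow(unique(cases[, 1:4])), 8L)
  # each case matches the direct evaluation of the dipole-jump formula
  ri <- c(2.5, -1, 4); rij <- c(1.2, -0.3, 0.8)
  for (k in seq_len(nrow(cases))) {
    got <- dipole_correction(cases$qi_before[k], cases$qj_before[k],
                             cases$qi_after[k], cases$qj_after[k], rij)
    oracle <- direct_dipole_jump(cases$qi_before[k], cases$qj_before[k],
                                 cases$qi_after[k], cases$qj_after[k],
                                 ri, rij)
    expect_equal(got, oracle, tolerance = 1e-12)
    expect_equal(got, cases$coef_rij[k] * rij, tolerance = 1e-12)
  }
  # the sign convention of the printed table: (0,0) -> (+1,-1) gives -rij,
  # its reversed partner (+1,-1) -> (0,0) gives +rij
  expect_equal(dipole_correction(0, 0, 1, -1, rij), -rij)
  expect_equal(dipole_correction(1, -1, 0, 0, rij), rij)
  expect_error(dipole_correction(2, 0, 1, 1, rij), "unsupported")
})

test_that("transfer corrections replace box-scale jumps by bounded ones", {
  box <- c(20, 20, 20)
  times <- c(0, 1, 2)
  # +1 and -1 residues facing each other across the periodic boundary
  centers <- array(0, c(3, 2, 3))
  centers[, 1, 1] <- 0.5; centers[, 2, 1] <- 19.5
  centers[, 1, 2:3] <- 5; centers[, 2, 2:3] <- 5
  charges <- rbind(c(1, -1), c(0, 0), c(0, 0))  # transfer at t = 1
  ds <- collective_dipole(centers, times, charges)
  raw_jump <- ds$raw[2, ] - ds$raw[1, ]
  expect_equal(abs(raw_jump[1]), 19)  # of order the box length
  ev <- protonhop:::empty_events()
  rij <- min_image(centers[2, 2, ] - centers[2, 1, ], box)
  expect_equal(rij[1], -1)
  ev[1, ] <- list(1.0, 1L, 2L, "IM1H+OAC->IM1+HOAC", 1L, -1L, 0L, 0L,
                  0.5, 5, 5, 19.5, 5, 5, rij[1], rij[2], rij[3])
  cd <- transfer_correction(ds, ev, centers)
  corr_jump <- cd$corrected[2, ] - cd$corrected[1, ]
  # bounded by |q| (r_max + bead diameter), never of order L
  expect_lt(sqrt(sum(corr_jump^2)), 1 * (6 + 5))
  expect_equal(corr_jump, dipole_correction(1, -1, 0, 0, rij),
               tolerance = 1e-12)
  # correction is piecewise constant, changing only at the event frame
  expect_equal(cd$correction[1, ], c(0, 0, 0))
  expect_equal(cd$correction[2, ], cd$correction[3, ])
  expect_equal(cd$corrected, cd$raw + cd$correction, tolerance = 1e-12)
  # without events the corrected series equals the raw one exactly
  cd0 <- transfer_correction(ds, protonhop:::empty_events(), centers)
  expect_identical(cd0$corrected, cd0$raw)
})

test_that("conductivity matches Nernst-Einstein for independent ions", {
  # M_J is a single collective random walk, so the slope error depends on
  # the lag/run-length ratio, not the ion count: fit short lags of a long
  # series
  n <- 200; nf <- 20000; dt <- 1
  D_true <- 0.1                       # A^2/ps per particle
  step_sd <- sqrt(2 * D_true * dt)    # per dimension
  walk <- make_walk(nf, n, step_sd, seed = 41)
  times <- (seq_len(nf) - 1) * dt
  q <- rep(c(1, -1), n / 2)
  V <- 50^3
  Tk <- 300
  ds <- collective_dipole(walk, times, q)
  res <- conductivity(ds, V, Tk, fit_window = c(5, 20))
  u <- charmm_units()
  kBT <- u$boltzmann_constant * Tk
  sigma_ne <- sum(q^2 * D_true) / (V * kBT)
  expect_lt(abs(res$sigma_internal / sigma_ne - 1), 0.10)
  # unit conversion checked against an independent SI evaluation
  e_C <- 1.602176634e-19; NA_ <- 6.02214076e23; kB_SI <- 1.380649e-23
  sigma_SI <- sum(q^2) * e_C^2 * (D_true * 1e-8) /
    (V * 1e-30 * kB_SI * Tk)              # S/m
  expect_lt(abs(res$sigma_mS_cm / (sigma_SI * 10) *
                  (sigma_ne / res$sigma_internal) - 1), 0.01)
})

test_that("conductivity is invariant under rigid translation and relabeling", {
  n <- 40; nf <- 400; dt <- 1
  walk <- make_walk(nf, n, 0.5, seed = 43)
  times <- (seq_len(nf) - 1) * dt
  q <- rep(c(1, -1), n / 2)
  base <- conductivity(collective_dipole(walk, times, q), 30^3, 300,
                       fit_window = c(20, 100))
  shifted <- walk
  for (k in 1:3) shifted[, , k] <- shifted[, , k] + c(7, -3, 11)[k]
  s2 <- conductivity(collective_dipole(shifted, times, q), 30^3, 300,
                     fit_window = c(20, 100))
  # the system is neutral, so a rigid shift leaves M_J unchanged
  expect_equal(s2$sigma_internal, base$sigma_internal, tolerance = 1e-9)
  perm <- sample(n)
  s3 <- conductivity(collective_dipole(walk[, perm, ], times, q[perm]),
                     30^3, 300, fit_window = c(20, 100))
  expect_equal(s3$sigma_internal, base$sigma_internal, tolerance = 1e-9)
})

test_that("neutral-only systems report zero conductivity with a warning", {
  walk <- make_walk(50, 4, 0.5, seed = 3)
  ds <- collective_dipole(walk, seq_len(50) - 1, rep(0, 4))
  expect_warning(res <- conductivity(ds, 1000, 300), "neutral")
  expect_identical(res$sigma_mS_cm, 0)
})

test_that("corrected and raw conductivity agree on transfer-free runs", {
  walk <- make_walk(300, 20, 0.5, seed = 44)
  times <- seq_len(300) - 1
  q <- rep(c(1, -1), 10)
  ds <- collective_dipole(walk, times, q)
  cd <- transfer_correction(ds, protonhop:::empty_events(), walk)
  raw <- conductivity(ds, 8000, 300, fit_window = c(20, 80))
  cor <- conductivity(cd, 8000, 300, fit_window = c(20, 80))
  expect_identical(raw$sigma_internal, cor$sigma_internal)
})
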