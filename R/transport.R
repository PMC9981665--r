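#' Residue-center trajectory from an atom trajectory
#'
#' Computes per-frame residue centers (mass-weighted over non-dummy atoms),
#' reassembling residues split across the periodic boundary by unfolding
#' atoms relative to the residue's first atom before averaging. Single-bead
#' residues return the bead coordinates unchanged.
#'
#' @param trajectory An [xyz_trajectory()].
#' @param system The [md_system()] the trajectory belongs to (supplies the
#'   residue map, masses and dummy flags).
#' @return Numeric array `[frame, residue, 3]` of folded centers.
#' @export
trajectory_residue_centers <- function(trajectory, system) {
  nf <- dim(trajectory$coords)[1]
  nr <- nrow(system$residues)
  box <- as.numeric(system$box)
  if (all(system$residues$atom_start == system$residues$atom_end))
    return(trajectory$coords[, system$residues$atom_start, , drop = FALSE])
  out <- array(NA_real_, c(nf, nr, 3))
  for (i in seq_len(nr)) {
    idx <- system$residues$atom_start[i]:system$residues$atom_end[i]
    keep <- idx[!system$atoms$dummy[idx]]
    w <- system$atoms$mass[keep]
    if (sum(w) <= 0) w <- rep(1, length(keep))
    w <- w / sum(w)
    for (f in seq_len(nf)) {
      at <- trajectory$coords[f, keep, , drop = FALSE][1, , , drop = TRUE]
      at <- matrix(at, ncol = 3)
      ref <- at[1, ]
      rel <- min_image(sweep(at, 2, ref), box)
      ctr <- ref + colSums(rel * w)
      out[f, i, ] <- ctr - floor(ctr / box) * box
    }
  }
  out
}

#' Unfold a folded center trajectory
#'
#' Removes periodic wrapping by accumulating minimum-image frame-to-frame
#' displacements, anchored at the first frame. Valid when every residue
#' moves less than half a box edge between consecutive frames; a
#' minimum-image step reaching `max_step` raises an aliasing error naming
#' the frame and residue.
#'
#' @param centers Numeric array `[frame, residue, 3]` of folded centers.
#' @param box Box edge lengths (length-3) or a [box_spec()].
#' @param max_step Largest credible per-frame displacement, Angstrom;
#'   defaults to half the smallest box edge.
#' @return Array of the same shape with continuous (unfolded) coordinates.
#' @export
unfold_centers <- function(centers, box, max_step = min(box) / 2) {
  box <- as.numeric(box)
  nf <- dim(centers)[1]
  out <- centers
  if (nf < 2) return(out)
  for (f in 2:nf) {
    d <- centers[f, , , drop = FALSE] - centers[f - 1, , , drop = FALSE]
    for (k in 1:3) d[1, , k] <- d[1, , k] - box[k] * round(d[1, , k] / box[k])
    step <- sqrt(d[1, , 1]^2 + d[1, , 2]^2 + d[1, , 3]^2)
    if (any(step >= max_step)) {
      r <- which.max(step)
      stop(sprintf(paste0("aliasing: residue %d moved %.3g A between frames",
                          " %d and %d (max credible step %.3g A)"),
                   r, max(step), f - 1, f, max_step), call. = FALSE)
    }
    out[f, , ] <- out[f - 1, , ] + d[1, , ]
  }
  out
}

#' Cut residue time series at proton-transfer events
#'
#' Partitions every residue's unfolded timeline at the times of its transfer
#' events, labels each piece with the protonation state held during it, and
#' keeps only pieces of at least `min_length`. This prevents mixing the
#' mobility of charged and neutral forms of a residue in the diffusion
#' analysis. The frame recorded at an event time already reflects the new
#' state and opens the new segment.
#'
#' @param centers Unfolded array `[frame, residue, 3]` from
#'   [unfold_centers()].
#' @param times Frame times, ps.
#' @param events Transfer-event data frame (sorted by time).
#' @param initial_species State of every residue at the first frame.
#' @param templates Template list used to flip states along the event log.
#' @param min_length Minimum segment duration, ps; defaults to half the
#'   trajectory span.
#' @return Data frame with one row per surviving segment: `residue`,
#'   `state`, `start_ps`, `end_ps`, `frame_start`, `frame_end`.
#' @export
cut_segments <- function(centers, times, events, initial_species, templates,
                         min_length = (max(times) - min(times)) / 2) {
  nr <- dim(centers)[2]
  if (nrow(events)) {
    if (is.unsorted(events$time_ps)) stop("events must be sorted by time",
                                          call. = FALSE)
    bad <- setdiff(unique(c(events$residue_i, events$residue_j)),
                   seq_len(nr))
    if (length(bad))
      stop("event references unknown residue id(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
  }
  segs <- list()
  for (r in seq_len(nr)) {
    ev_t <- sort(events$time_ps[events$residue_i == r |
                                  events$residue_j == r])
    bounds <- c(min(times), ev_t, max(times) + 1e-9)
    state <- initial_species[r]
    for (s in seq_len(length(bounds) - 1)) {
      # frames in [bound_s, bound_{s+1}): the event-time frame starts the
      # new segment
      in_seg <- which(times >= bounds[s] - 1e-9 & times < bounds[s + 1])
      if (s > 1) state <- other_state(find_template(templates, state), state)
      if (length(in_seg) >= 2) {
        dur <- times[max(in_seg)] - times[min(in_seg)]
        if (dur >= min_length) {
          segs[[length(segs) + 1L]] <- data.frame(
            residue = r, state = state,
            start_ps = times[min(in_seg)], end_ps = times[max(in_seg)],
            frame_start = min(in_seg), frame_end = max(in_seg),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (!length(segs))
    return(data.frame(residue = integer(), state = character(),
                      start_ps = numeric(), end_ps = numeric(),
                      frame_start = integer(), frame_end = integer(),
                      stringsAsFactors = FALSE))
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

# lag-averaged MSD over a list of coordinate matrices (one per segment),
# multiple time origins with the given stride; returns (lag_frames, msd,
# weight) with weight = number of origin pairs entering each lag
msd_accumulate <- function(seg_coords, max_lag, origin_stride = 1) {
  sums <- numeric(max_lag)
  wts <- numeric(max_lag)
  for (X in seg_coords) {
    m <- nrow(X)
    for (lag in seq_len(min(max_lag, m - 1))) {
      org <- seq(1, m - lag, by = origin_stride)
      d <- X[org + lag, , drop = FALSE] - X[org, , drop = FALSE]
      sums[lag] <- sums[lag] + sum(d * d)
      wts[lag] <- wts[lag] + length(org)
    }
  }
  keep <- wts > 0
  data.frame(lag_frames = seq_len(max_lag)[keep], msd = sums[keep] / wts[keep],
             weight = wts[keep])
}

#' Segment-averaged mean-squared displacement per species
#'
#' @param centers Unfolded array `[frame, residue, 3]`.
#' @param times Frame times, ps (uniform spacing assumed).
#' @param segments Data frame from [cut_segments()].
#' @param max_lag_frac Largest lag as a fraction of the longest segment.
#' @param max_lag_ps Optional explicit largest lag in ps (overrides
#'   `max_lag_frac` when the segments are long enough).
#' @param origin_stride Time-origin stride in frames.
#' @return Data frame with `species`, `lag_ps`, `msd` (Angstrom^2),
#'   `weight`.
#' @export
msd_by_species <- function(centers, times, segments, max_lag_frac = 0.4,
                           max_lag_ps = NULL, origin_stride = 1) {
  if (!nrow(segments)) stop("no segments to analyse", call. = FALSE)
  dt <- diff(times[1:2])
  out <- list()
  for (sp in unique(segments$state)) {
    sel <- segments[segments$state == sp, , drop = FALSE]
    seg_coords <- lapply(seq_len(nrow(sel)), function(k)
      centers[sel$frame_start[k]:sel$frame_end[k], sel$residue[k], ,
              drop = TRUE])
    longest <- max(sel$frame_end - sel$frame_start)
    max_lag <- max(1L, floor(max_lag_frac * longest))
    if (!is.null(max_lag_ps))
      max_lag <- max(1L, min(longest, floor(max_lag_ps / dt)))
    m <- msd_accumulate(seg_coords, max_lag, origin_stride)
    out[[sp]] <- data.frame(species = sp, lag_ps = m$lag_frames * dt,
                            msd = m$msd, weight = m$weight,
                            stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Diffusion coefficients from the Einstein relation
#'
#' `D = slope/6` of the segment-averaged MSD, least-squares fitted over the
#' stated lag window. Per-state coefficients are reported together with
#' pooled coefficients per residue pair (protonated and deprotonated forms
#' combined), mirroring the combined imidazole-type and carboxylate-type
#' values of the study analysis.
#'
#' @param centers,times,segments As in [msd_by_species()].
#' @param templates Template list (to pool states into pairs).
#' @param fit_window Lag window `(t1, t2)` in ps; default 10 to 30 percent
#'   of the trajectory span.
#' @param origin_stride Time-origin stride in frames.
#' @param units A [charmm_units()] object.
#' @return Data frame: `species`, `group` (`"state"` or `"pair"`),
#'   `D_A2_ps`, `D_m2_s`, `n_segments`.
#' @export
diffusion_coefficient <- function(centers, times, segments, templates,
                                  fit_window = NULL, origin_stride = 1,
                                  units = charmm_units()) {
  if (!nrow(segments)) stop("no segments to analyse", call. = FALSE)
  span <- max(times) - min(times)
  if (is.null(fit_window)) fit_window <- c(0.10, 0.30) * span
  msd <- msd_by_species(centers, times, segments,
                        max_lag_ps = fit_window[2],
                        origin_stride = origin_stride)
  fit_D <- function(m) {
    w <- m[m$lag_ps >= fit_window[1] & m$lag_ps <= fit_window[2], ,
           drop = FALSE]
    if (nrow(w) < 2)
      stop("fit window contains fewer than 2 MSD points", call. = FALSE)
    unname(stats::coef(stats::lm(msd ~ lag_ps, data = w))[2] / 6)
  }
  res <- list()
  for (sp in unique(segments$state)) {
    D <- fit_D(msd[msd$species == sp, , drop = FALSE])
    res[[length(res) + 1L]] <- data.frame(
      species = sp, group = "state", D_A2_ps = D,
      D_m2_s = D * units$A2ps_to_m2s,
      n_segments = sum(segments$state == sp), stringsAsFactors = FALSE)
  }
  # pooled over the two states of each template pair
  pair_of <- function(sp) find_template(templates, sp)$name_protonated
  pairs <- vapply(segments$state, pair_of, "")
  for (pr in unique(pairs)) {
    states <- unique(segments$state[pairs == pr])
    sub <- msd[msd$species %in% states, , drop = FALSE]
    agg <- stats::aggregate(cbind(ms = msd * weight, w = weight) ~ lag_ps,
                            data = sub, FUN = sum)
    pooled <- data.frame(lag_ps = agg$lag_ps, msd = agg$ms / agg$w)
    D <- fit_D(pooled)
    res[[length(res) + 1L]] <- data.frame(
      species = pr, group = "pair", D_A2_ps = D,
      D_m2_s = D * units$A2ps_to_m2s,
      n_segments = sum(pairs == pr), stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Collective translational dipole moment
#'
#' `M_J(t) = sum_i q_i(t) r_i(t)` over residues, with unfolded centers and
#' the instantaneous residue charges.
#'
#' @param centers Unfolded array `[frame, residue, 3]`.
#' @param times Frame times, ps.
#' @param charges Either a numeric vector (constant residue charges) or a
#'   `frames x residues` matrix of instantaneous charges (e.g. pivoted from
#'   the charge report).
#' @return Object of class `dipole_series`: list with `times`, `raw`
#'   (frames x 3, e Angstrom), `corrected` (`NULL` until
#'   [transfer_correction()]), `correction` (cumulative per-frame
#'   correction).
#' @export
collective_dipole <- function(centers, times, charges) {
  nf <- dim(centers)[1]; nr <- dim(centers)[2]
  if (is.matrix(charges)) {
    stopifnot(nrow(charges) == nf, ncol(charges) == nr)
    qm <- charges
  } else {
    stopifnot(length(charges) == nr)
    qm <- matrix(charges, nf, nr, byrow = TRUE)
  }
  M <- sapply(1:3, function(k) rowSums(qm * centers[, , k, drop = TRUE]))
  M <- matrix(M, nf, 3)
  structure(list(times = times, raw = M, corrected = NULL,
                 correction = matrix(0, nf, 3), charges = qm),
            class = "dipole_series")
}

#' Pivot a charge report into a frames x residues matrix
#'
#' Turns the long-format per-frame charge report of [run_dynamics()] into
#' the instantaneous charge matrix consumed by [collective_dipole()].
#'
#' @param charge_report Data frame with `time_ps`, `residue_id`,
#'   `charge_e` (one row per residue per frame).
#' @return Numeric matrix, frames (sorted by time) x residues (sorted by
#'   id).
#' @export
charge_matrix <- function(charge_report) {
  t_lv <- sort(unique(charge_report$time_ps))
  r_lv <- sort(unique(charge_report$residue_id))
  m <- matrix(NA_real_, length(t_lv), length(r_lv))
  m[cbind(match(charge_report$time_ps, t_lv),
          match(charge_report$residue_id, r_lv))] <- charge_report$charge_e
  if (anyNA(m)) stop("charge report is not a complete time x residue grid",
                     call. = FALSE)
  m
}

#' Dipole-moment correction of one proton transfer
#'
#' Direct evaluation of the transfer contribution
#' `delta M_J = q_i^a r_i + q_j^a r_j - q_i^b r_i - q_j^b r_j`
#' with the minimum-image geometry `r_j = r_i + r_ij`, which reduces to
#' `(q_j^a - q_j^b) r_ij` by charge conservation. The charge pattern must be
#' one of the eight transition types generated by the packaged reaction
#' scheme (single unit-proton hops among charges -1, 0, +1).
#'
#' @param qi_before,qj_before,qi_after,qj_after Integer residue charges, e.
#' @param rij Minimum-image displacement `r_j - r_i`, Angstrom (3-vector).
#' @return The correction vector, e Angstrom.
#' @export
dipole_correction <- function(qi_before, qj_before, qi_after, qj_after,
                              rij) {
  dqi <- qi_after - qi_before
  dqj <- qj_after - qj_before
  qs <- c(qi_before, qj_before, qi_after, qj_after)
  if (dqi + dqj != 0 || abs(dqj) != 1 || any(abs(qs) > 1))
    stop(sprintf("unsupported transfer charge pattern (%d,%d) -> (%d,%d)",
                 qi_before, qj_before, qi_after, qj_after), call. = FALSE)
  dqj * rij
}

#' Enumerate the transfer correction cases of a reaction scheme
#'
#' Lists every distinct charge transition `(q_i^b, q_j^b) -> (q_i^a,
#' q_j^a)` reachable from the given reactions, considering both role
#' assignments of the two molecules, together with the coefficient of
#' `r_ij` in the dipole correction. The packaged four-reaction scheme
#' yields exactly eight cases.
#'
#' @param reactions List of [transfer_reaction()] objects.
#' @param templates Template list supplying the state charges.
#' @return Data frame: `qi_before`, `qj_before`, `qi_after`, `qj_after`,
#'   `coef_rij` (+1 or -1).
#' @export
enumerate_correction_cases <- function(reactions, templates) {
  rows <- list()
  for (rx in reactions) {
    q <- function(state) {
      tpl <- find_template(templates, state)
      as.integer(round(residue_charge(tpl, state)))
    }
    qb <- c(q(rx$reactants[1]), q(rx$reactants[2]))
    qa <- c(q(rx$products[1]), q(rx$products[2]))
    for (ord in list(1:2, 2:1)) {
      rows[[length(rows) + 1L]] <- data.frame(
        qi_before = qb[ord[1]], qj_before = qb[ord[2]],
        qi_after = qa[ord[1]], qj_after = qa[ord[2]],
        coef_rij = qa[ord[2]] - qb[ord[2]])
    }
  }
  out <- unique(do.call(rbind, rows))
  rownames(out) <- NULL
  out
}

#' Apply per-transfer corrections to a collective dipole series
#'
#' Unfolding a trajectory across a proton transfer turns the short
#' minimum-image hop into an apparent jump of order the box length in
#' `M_J`. For each logged event this replaces the raw unfolded jump by the
#' physical contribution `delta M_J` evaluated with the minimum-image
#' displacement recorded in the event, accumulated as an additive
#' correction series (the raw data remain available).
#'
#' @param dipole A `dipole_series` from [collective_dipole()].
#' @param events Transfer-event data frame.
#' @param centers The unfolded center array the series was built from.
#' @return The `dipole_series` with `corrected` and `correction` filled in.
#' @export
transfer_correction <- function(dipole, events, centers) {
  nf <- length(dipole$times)
  corr <- matrix(0, nf, 3)
  if (nrow(events)) {
    for (k in seq_len(nrow(events))) {
      fe <- match(TRUE, dipole$times >= events$time_ps[k] - 1e-9)
      if (is.na(fe) || fe < 2) next  # event before the second frame: no jump
      dqi <- events$qi_after[k] - events$qi_before[k]
      dqj <- events$qj_after[k] - events$qj_before[k]
      raw_jump <- dqi * centers[fe, events$residue_i[k], ] +
        dqj * centers[fe, events$residue_j[k], ]
      rij <- c(events$rij_x[k], events$rij_y[k], events$rij_z[k])
      dM <- dipole_correction(events$qi_before[k], events$qj_before[k],
                              events$qi_after[k], events$qj_after[k], rij)
      corr[fe:nf, ] <- corr[fe:nf, , drop = FALSE] +
        matrix(dM - raw_jump, nf - fe + 1, 3, byrow = TRUE)
    }
  }
  dipole$correction <- corr
  dipole$corrected <- dipole$raw + corr
  dipole
}

#' Static conductivity from the collective dipole displacement
#'
#' `sigma(0) = slope(<|Delta M_J(t)|^2>) / (6 V kB T)`, the Einstein-
#' relation analogue for charge transport. Uses the corrected series when
#' available.
#'
#' @param dipole A `dipole_series`.
#' @param volume Box volume, Angstrom^3.
#' @param temperature Temperature, K.
#' @param fit_window Lag window `(t1, t2)` in ps; default 10 to 30 percent
#'   of the series span.
#' @param origin_stride Time-origin stride in frames.
#' @param units A [charmm_units()] object.
#' @return List: `sigma_internal` (e^2 mol ps^-1 Angstrom^-1 kcal^-1),
#'   `sigma_mS_cm`, `slope` (e^2 Angstrom^2/ps) and the fitted window.
#' @export
conductivity <- function(dipole, volume, temperature, fit_window = NULL,
                         origin_stride = 1, units = charmm_units()) {
  M <- if (!is.null(dipole$corrected)) dipole$corrected else dipole$raw
  if (all(M == 0)) {
    warning("neutral-only system: conductivity is zero")
    return(list(sigma_internal = 0, sigma_mS_cm = 0, slope = 0,
                fit_window = fit_window))
  }
  span <- max(dipole$times) - min(dipole$times)
  if (is.null(fit_window)) fit_window <- c(0.10, 0.30) * span
  dt <- diff(dipole$times[1:2])
  max_lag <- floor(fit_window[2] / dt) + 1L
  m <- msd_accumulate(list(M), max_lag, origin_stride)
  m$lag_ps <- m$lag_frames * dt
  w <- m[m$lag_ps >= fit_window[1] & m$lag_ps <= fit_window[2], ,
         drop = FALSE]
  if (nrow(w) < 2)
    stop("fit window contains fewer than 2 dipole MSD points", call. = FALSE)
  slope <- unname(stats::coef(stats::lm(msd ~ lag_ps, data = w))[2])
  kBT <- units$boltzmann_constant * temperature
  sigma <- slope / (6 * volume * kBT)
  list(sigma_internal = sigma, sigma_mS_cm = sigma * units$cond_to_mS_cm,
       slope = slope, fit_window = fit_window)
}
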