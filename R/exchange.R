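# donor state of a reaction = the reactant that is its template's
# protonated name (it flips to deprotonated); the other reactant accepts
reaction_roles <- function(reaction, templates) {
  t1 <- find_template(templates, reaction$reactants[1])
  donor_first <- reaction$reactants[1] == t1$name_protonated &&
    reaction$products[1] == t1$name_deprotonated
  di <- if (donor_first) 1L else 2L
  ai <- 3L - di
  list(donor_state = reaction$reactants[di],
       acceptor_state = reaction$reactants[ai],
       donor_product = reaction$products[di],
       acceptor_product = reaction$products[ai])
}

# global atom indices of named site atoms for residues currently in `state`
site_positions <- function(system, state, site_names) {
  res <- system$residues[system$residues$species == state, , drop = FALSE]
  if (!nrow(res))
    return(list(pos = matrix(0, 0, 3), residue = integer(), atom = character()))
  tpl <- find_template(system$templates, state)
  cur_names <- state_atom_rows(tpl, state)$name
  offs <- match(site_names, cur_names)
  if (anyNA(offs))
    stop(sprintf("site atom(s) %s not found in state %s",
                 paste(site_names[is.na(offs)], collapse = ", "), state),
         call. = FALSE)
  idx <- as.vector(outer(offs - 1L, res$atom_start, `+`))  # sites x residues
  list(pos = system$positions[idx, , drop = FALSE],
       residue = rep(res$id, each = length(offs)),
       atom = rep(site_names, times = nrow(res)))
}

#' Find proton-transfer candidate pairs
#'
#' For every reaction, locates all donor-hydrogen / acceptor-site pairs with
#' minimum-image distance below the reaction's `r_max`. Multi-site acceptors
#' (e.g. both carboxylate oxygens) are each checked and the closest site per
#' donor/acceptor residue pair is recorded.
#'
#' @param system An [md_system()].
#' @param reactions List of [transfer_reaction()] objects.
#' @return Data frame with columns `donor_res`, `acceptor_res`,
#'   `donor_atom`, `acceptor_atom`, `distance` (Angstrom), `reaction`.
#' @export
find_candidates <- function(system, reactions) {
  out <- list()
  for (rx in reactions) {
    if (rx$r_max >= min(system$box) / 2)
      stop(sprintf("r_max %.3g A must be below half the smallest box edge (%.3g A)",
                   rx$r_max, min(system$box) / 2), call. = FALSE)
    roles <- reaction_roles(rx, system$templates)
    dt <- find_template(system$templates, roles$donor_state)
    at <- find_template(system$templates, roles$acceptor_state)
    don <- site_positions(system, roles$donor_state, dt$donor_atoms)
    acc <- site_positions(system, roles$acceptor_state, at$acceptor_atoms)
    if (!nrow(don$pos) || !nrow(acc$pos)) next
    hits <- cross_pairs_cpp(don$pos, acc$pos, as.numeric(system$box),
                            rx$r_max)
    if (!nrow(hits)) next
    df <- data.frame(
      donor_res = don$residue[hits[, 1]],
      acceptor_res = acc$residue[hits[, 2]],
      donor_atom = don$atom[hits[, 1]],
      acceptor_atom = acc$atom[hits[, 2]],
      distance = hits[, 3],
      reaction = rx$name, stringsAsFactors = FALSE)
    df <- df[df$donor_res != df$acceptor_res, , drop = FALSE]
    if (!nrow(df)) next
    # closest acceptor site per residue pair
    key <- paste(df$donor_res, df$acceptor_res)
    df <- df[order(key, df$distance), , drop = FALSE]
    df <- df[!duplicated(paste(df$donor_res, df$acceptor_res)), , drop = FALSE]
    out[[length(out) + 1L]] <- df
  }
  if (!length(out))
    return(data.frame(donor_res = integer(), acceptor_res = integer(),
                      donor_atom = character(), acceptor_atom = character(),
                      distance = numeric(), reaction = character(),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Resolve overlapping transfer candidates
#'
#' A residue may only take part in one transfer per update. Candidates are
#' resolved by greedy shortest-distance-first maximal matching (the shortest
#' hydrogen bond is the most reaction-prone contact); ties are broken by
#' (donor id, acceptor id).
#'
#' @param candidates Data frame from [find_candidates()].
#' @return Subset of `candidates` in which every residue appears at most
#'   once.
#' @export
resolve_conflicts <- function(candidates) {
  if (!nrow(candidates)) return(candidates)
  ord <- order(candidates$distance, candidates$donor_res,
               candidates$acceptor_res)
  candidates <- candidates[ord, , drop = FALSE]
  used <- integer()
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    d <- candidates$donor_res[i]; a <- candidates$acceptor_res[i]
    if (!(d %in% used) && !(a %in% used)) {
      keep[i] <- TRUE
      used <- c(used, d, a)
    }
  }
  res <- candidates[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Cubic feedback update of a reaction probability
#'
#' The working probability of a transfer reaction is steered around its
#' reference value by the count of the monitor species:
#' \deqn{p = p_{ref} + c\,(n_{now}/n_{ref} - 1)^3}
#' clamped to `[0, 1]`. The cubic power preserves the sign of the deviation:
#' fewer monitor molecules than the reference lower the probability of the
#' reaction consuming them, more molecules raise it.
#'
#' @param p_ref Reference probability (fraction).
#' @param c Feedback prefactor.
#' @param n_now Current count of the monitor species.
#' @param n_ref Reference (initial) count (> 0).
#' @return Updated probability in `[0, 1]`.
#' @examples
#' update_probability(0.994, 300, 150, 150)  # fixed point: 0.994
#' update_probability(0.098, 300, 110, 100)  # 0.098 + 300 * 0.001 = 0.398
#' @export
update_probability <- function(p_ref, c, n_now, n_ref) {
  if (any(n_ref <= 0)) stop("n_ref must be > 0", call. = FALSE)
  p <- p_ref + c * (n_now / n_ref - 1)^3
  pmin(pmax(p, 0), 1)
}

#' Initialise the per-reaction probability state
#'
#' Snapshots the current counts of every reaction's monitor species as the
#' reference counts of the feedback rule. Reactions whose monitor species is
#' absent at initialisation (reference count 0) keep `p = p_ref` for the
#' whole run, as the feedback ratio is undefined for them.
#'
#' @param reactions List of [transfer_reaction()] objects.
#' @param system An [md_system()] providing the reference composition.
#' @return Data frame of class `probability_state` with one row per
#'   reaction: `reaction`, `monitor`, `p_ref`, `c`, `n_ref`, `n_now`, `p`.
#' @export
probability_state <- function(reactions, system) {
  counts <- table(factor(system$residues$species))
  df <- data.frame(
    reaction = vapply(reactions, `[[`, "", "name"),
    monitor = vapply(reactions, `[[`, "", "monitor"),
    p_ref = vapply(reactions, `[[`, 1, "p_ref"),
    c = vapply(reactions, `[[`, 1, "c"),
    n_ref = vapply(reactions, function(r) {
      n <- counts[r$monitor]; as.integer(ifelse(is.na(n), 0L, n))
    }, 1L), stringsAsFactors = FALSE)
  df$n_now <- df$n_ref
  # a monitor species absent at initialisation cannot drive the feedback;
  # such reactions keep p = p_ref for the whole run
  df$p <- ifelse(df$n_ref > 0,
                 update_probability(df$p_ref, df$c, df$n_now,
                                    pmax(df$n_ref, 1L)),
                 df$p_ref)
  class(df) <- c("probability_state", "data.frame")
  df
}

#' Refresh reaction probabilities from the current composition
#'
#' Applies [update_probability()] to every reaction using the counts of its
#' monitor species at the start of the update event (i.e. before any
#' acceptance draw).
#'
#' @param pstate A [probability_state()].
#' @param system Current [md_system()].
#' @return The updated `probability_state`.
#' @export
refresh_probabilities <- function(pstate, system) {
  counts <- table(factor(system$residues$species))
  n <- counts[pstate$monitor]
  pstate$n_now <- as.integer(ifelse(is.na(n), 0L, n))
  pstate$p <- ifelse(pstate$n_ref > 0,
                     update_probability(pstate$p_ref, pstate$c,
                                        pstate$n_now,
                                        pmax(pstate$n_ref, 1L)),
                     pstate$p_ref)
  pstate
}

#' Probability-gated acceptance of transfer candidates
#'
#' Each (conflict-free) candidate pair is accepted independently with its
#' reaction's current probability, using the R random number generator in
#' its current state; callers that need a dedicated acceptance stream manage
#' the RNG state around the call (as [run_dynamics()] does).
#'
#' @param pairs Data frame from [resolve_conflicts()].
#' @param pstate A [probability_state()].
#' @return The accepted subset of `pairs`.
#' @export
accept_transfers <- function(pairs, pstate) {
  if (!nrow(pairs)) return(pairs)
  p <- pstate$p[match(pairs$reaction, pstate$reaction)]
  if (anyNA(p))
    stop("candidate references a reaction absent from the probability state",
         call. = FALSE)
  keep <- stats::runif(nrow(pairs)) < p
  res <- pairs[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# expected reaction object by name
reaction_by_name <- function(reactions, name) {
  for (r in reactions) if (r$name == name) return(r)
  stop("unknown reaction: ", name, call. = FALSE)
}

#' Execute accepted proton transfers
#'
#' Swaps every accepted donor residue to its deprotonated state and every
#' acceptor to its protonated state, and emits one transfer event per pair
#' with integer charges before/after, the folded residue centers at event
#' time and the minimum-image displacement `r_ij = mimage(com_j - com_i)`.
#' The total system charge is conserved exactly and within each update the
#' number of protonations equals the number of deprotonations.
#'
#' @param system An [md_system()].
#' @param accepted Data frame from [accept_transfers()] (disjoint pairs).
#' @param reactions The reaction list the candidates were generated from.
#' @param mode Parameter swap mode, see [apply_residue_state()].
#' @return List with elements `system` (updated) and `events` (data frame:
#'   `time_ps`, `residue_i`, `residue_j`, `reaction`, `qi_before`,
#'   `qj_before`, `qi_after`, `qj_after`, `comi_x..z`, `comj_x..z`,
#'   `rij_x..z`).
#' @export
execute_update <- function(system, accepted, reactions,
                           mode = c("all_nonbonded", "charges_only")) {
  mode <- match.arg(mode)
  ev <- empty_events()
  if (!nrow(accepted)) return(list(system = system, events = ev))
  centers <- residue_centers(system)
  rows <- vector("list", nrow(accepted))
  for (k in seq_len(nrow(accepted))) {
    d <- accepted$donor_res[k]; a <- accepted$acceptor_res[k]
    rx <- reaction_by_name(reactions, accepted$reaction[k])
    roles <- reaction_roles(rx, system$templates)
    if (system$residues$species[d] != roles$donor_state ||
        system$residues$species[a] != roles$acceptor_state)
      stop(sprintf(paste0("residue %d/%d in state %s/%s inconsistent with",
                          " reaction %s"), d, a,
                   system$residues$species[d], system$residues$species[a],
                   rx$name), call. = FALSE)
    qi_b <- system$residues$charge[d]; qj_b <- system$residues$charge[a]
    system <- apply_residue_state(system, d, roles$donor_product, mode)
    system <- apply_residue_state(system, a, roles$acceptor_product, mode)
    qi_a <- system$residues$charge[d]; qj_a <- system$residues$charge[a]
    rij <- min_image(centers[a, ] - centers[d, ], as.numeric(system$box))
    rows[[k]] <- data.frame(
      time_ps = system$time, residue_i = d, residue_j = a,
      reaction = rx$name,
      qi_before = qi_b, qj_before = qj_b, qi_after = qi_a, qj_after = qj_a,
      comi_x = centers[d, 1], comi_y = centers[d, 2], comi_z = centers[d, 3],
      comj_x = centers[a, 1], comj_y = centers[a, 2], comj_z = centers[a, 3],
      rij_x = rij[1], rij_y = rij[2], rij_z = rij[3],
      stringsAsFactors = FALSE)
  }
  ev <- do.call(rbind, rows)
  rownames(ev) <- NULL
  list(system = system, events = ev)
}

empty_events <- function() {
  data.frame(time_ps = numeric(), residue_i = integer(),
             residue_j = integer(), reaction = character(),
             qi_before = integer(), qj_before = integer(),
             qi_after = integer(), qj_after = integer(),
             comi_x = numeric(), comi_y = numeric(), comi_z = numeric(),
             comj_x = numeric(), comj_y = numeric(), comj_z = numeric(),
             rij_x = numeric(), rij_y = numeric(), rij_z = numeric(),
             stringsAsFactors = FALSE)
}

#' Interpolated (multi-step) state swap
#'
#' Non-equilibrium alternative to the instantaneous swap: the partial
#' charges of donor and acceptor follow the linear path
#' `q(lambda) = (1 - lambda) q_source + lambda q_target` over
#' `lambda = k/n_steps`, with a user hook (typically a few dynamics steps)
#' invoked between increments. The endpoint applies the full target
#' parameter set, so `n_steps = 1` with a null hook is identical to the
#' instantaneous swap.
#'
#' @param system An [md_system()].
#' @param pair One-row data frame (or list) with `donor_res`,
#'   `acceptor_res`, `reaction`.
#' @param reactions Reaction list.
#' @param n_steps Number of lambda increments (>= 1).
#' @param dynamics_hook Optional `function(system, lambda)` returning a
#'   (possibly propagated) system, called after each intermediate increment.
#' @return The updated system at lambda = 1.
#' @export
interpolate_states <- function(system, pair, reactions, n_steps = 1,
                               dynamics_hook = NULL) {
  stopifnot(n_steps >= 1)
  rx <- reaction_by_name(reactions, pair$reaction)
  roles <- reaction_roles(rx, system$templates)
  d <- pair$donor_res; a <- pair$acceptor_res
  q_src <- function(id, state) {
    tpl <- find_template(system$templates, state)
    state_atom_rows(tpl, state)$charge
  }
  qd0 <- q_src(d, system$residues$species[d])
  qd1 <- q_src(d, roles$donor_product)
  qa0 <- q_src(a, system$residues$species[a])
  qa1 <- q_src(a, roles$acceptor_product)
  for (k in seq_len(n_steps)) {
    lam <- k / n_steps
    if (k < n_steps) {
      di <- system$residues$atom_start[d]:system$residues$atom_end[d]
      ai <- system$residues$atom_start[a]:system$residues$atom_end[a]
      system$atoms$charge[di] <- (1 - lam) * qd0 + lam * qd1
      system$atoms$charge[ai] <- (1 - lam) * qa0 + lam * qa1
      if (!is.null(dynamics_hook)) system <- dynamics_hook(system, lam)
    } else {
      system <- apply_residue_state(system, d, roles$donor_product,
                                    "all_nonbonded")
      system <- apply_residue_state(system, a, roles$acceptor_product,
                                    "all_nonbonded")
    }
  }
  system
}
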