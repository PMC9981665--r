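#' Orthorhombic box specification
#'
#' @param lengths Numeric vector of three positive edge lengths, Angstrom. A
#'   single value is recycled to a cubic box.
#' @return Numeric length-3 vector of class `box_spec`.
#' @export
box_spec <- function(lengths) {
  if (length(lengths) == 1) lengths <- rep(lengths, 3)
  stopifnot(length(lengths) == 3, all(is.finite(lengths)), all(lengths > 0))
  structure(as.numeric(lengths), class = "box_spec")
}

# template whose protonated or deprotonated name matches `state`
find_template <- function(templates, state) {
  for (t in templates)
    if (state %in% c(t$name_protonated, t$name_deprotonated)) return(t)
  stop(sprintf("residue state '%s' not defined by any template", state),
       call. = FALSE)
}

# per-atom parameter rows of `template` in state `state`, in canonical
# (protonated-list) atom order, with a dummy flag
state_atom_rows <- function(template, state) {
  if (state == template$name_protonated) {
    at <- template$atoms_protonated
    at$dummy <- FALSE
  } else {
    at <- template$atoms_deprotonated[template$atom_mapping, , drop = FALSE]
    at$dummy <- at$name %in% template$dummy_atoms
  }
  rownames(at) <- NULL
  at
}

#' Assemble a simulation system from species labels and positions
#'
#' Builds the full per-atom parameter bookkeeping for a set of residues in
#' given protonation states. Atoms of each residue occupy a contiguous index
#' range, ordered by residue id; per-atom parameters are taken from the
#' residue's template in its current state.
#'
#' @param species Character vector: current state name of each residue.
#' @param templates Named list of [residue_dual_template()] objects (any
#'   state name must resolve to one template).
#' @param positions Numeric matrix (total atoms x 3), Angstrom; folded into
#'   the box. `NULL` gives zeros (e.g. topology-only systems).
#' @param box A [box_spec()].
#' @param time Current simulation time, ps.
#' @param masses Optional per-atom masses (u); by default guessed from atom
#'   names (beads 100 u, lone pairs and dummies keep their name-derived 0).
#' @return Object of class `md_system`: list with `positions`, `box`,
#'   `residues` (data frame: id, species, pair, atom_start, atom_end,
#'   charge), `atoms` (per-atom parameter data frame), `templates`, `time`.
#' @export
md_system <- function(species, templates, positions = NULL,
                      box = box_spec(50), time = 0, masses = NULL) {
  species <- as.character(species)
  n_res <- length(species)
  atoms_list <- vector("list", n_res)
  pair <- character(n_res)
  for (i in seq_len(n_res)) {
    tpl <- find_template(templates, species[i])
    pair[i] <- tpl$name_protonated
    at <- state_atom_rows(tpl, species[i])
    at$residue_id <- i
    atoms_list[[i]] <- at
  }
  atoms <- if (n_res) do.call(rbind, atoms_list) else
    data.frame(name = character(), type = character(),
               lj_epsilon = numeric(), lj_rmin_half = numeric(),
               charge = numeric(), polarizability = numeric(),
               thole = numeric(), dummy = logical(),
               residue_id = integer(), stringsAsFactors = FALSE)
  n_atoms_per <- if (n_res) vapply(atoms_list, nrow, 1L) else integer()
  ends <- cumsum(n_atoms_per)
  starts <- ends - n_atoms_per + 1L
  if (is.null(positions)) positions <- matrix(0, nrow(atoms), 3)
  positions <- as.matrix(positions)
  if (nrow(positions) != nrow(atoms))
    stop(sprintf("positions have %d rows but the topology defines %d atoms",
                 nrow(positions), nrow(atoms)), call. = FALSE)
  if (nrow(positions) && !all(is.finite(positions)))
    stop("positions must be finite", call. = FALSE)
  if (nrow(positions)) positions <- fold_positions(positions, box)
  atoms$mass <- if (is.null(masses)) guess_mass(atoms$name) else masses
  residues <- data.frame(
    id = seq_len(n_res), species = species, pair = pair,
    atom_start = as.integer(starts), atom_end = as.integer(ends),
    charge = if (n_res) as.integer(round(vapply(atoms_list, function(a)
      sum(a$charge), 1))) else integer(),
    stringsAsFactors = FALSE)
  structure(list(positions = positions, box = box, residues = residues,
                 atoms = atoms, templates = templates, time = time),
            class = "md_system")
}

#' @export
print.md_system <- function(x, ...) {
  tab <- table(x$residues$species)
  cat(sprintf("md_system: %d residues / %d atoms, box %.4g x %.4g x %.4g A, t = %g ps\n",
              nrow(x$residues), nrow(x$atoms), x$box[1], x$box[2], x$box[3],
              x$time))
  if (length(tab))
    cat("  composition:", paste(sprintf("%s=%d", names(tab), tab),
                                collapse = ", "), "\n")
  cat(sprintf("  total charge: %+d e\n", sum(x$residues$charge)))
  invisible(x)
}

#' Total system charge
#' @param system An [md_system()].
#' @return Integer net charge in e.
#' @export
total_charge <- function(system) sum(system$residues$charge)

#' Pack a single-bead ionic-liquid box
#'
#' Places `2 * n_ion_pairs + 2 * n_neutral_pairs` single-bead residues
#' (cation/anion and neutral acid/base pairs) uniformly at random in an
#' orthorhombic box, rejecting positions closer than `min_separation` to any
#' previously placed bead (minimum image). Deterministic for a given seed.
#' The packaged study composition is 150 ion pairs and 350 neutral pairs, a
#' 30%:70% charged:neutral partitioning of 1,000 residues.
#'
#' @param n_ion_pairs Number of cation/anion (IM1H/OAC) pairs.
#' @param n_neutral_pairs Number of neutral (IM1/HOAC) pairs.
#' @param box A [box_spec()].
#' @param min_separation Minimum allowed bead-bead distance, Angstrom.
#' @param seed Integer RNG seed.
#' @param templates Templates resolving the four species; default
#'   [bead_templates()].
#' @param max_attempts Rejection-sampling bound per bead before a capacity
#'   error is raised.
#' @return An [md_system()] with one bead per residue and net charge 0.
#' @examples
#' sys <- build_system(3, 7, box_spec(30), min_separation = 4, seed = 1)
#' table(sys$residues$species)
#' @export
build_system <- function(n_ion_pairs, n_neutral_pairs, box = box_spec(55),
                         min_separation = 4.5, seed = 1,
                         templates = bead_templates(),
                         max_attempts = 2000L) {
  stopifnot(n_ion_pairs >= 0, n_neutral_pairs >= 0)
  for (t in templates)
    if (nrow(t$atoms_protonated) != 1)
      stop("build_system packs single-bead residues only", call. = FALSE)
  species <- c(rep(c("IM1H", "OAC"), n_ion_pairs),
               rep(c("IM1", "HOAC"), n_neutral_pairs))
  n <- length(species)
  pos <- matrix(NA_real_, n, 3)
  if (n > 0) {
    with_seed(seed, {
      placed <- 0L
      while (placed < n) {
        ok <- FALSE
        for (att in seq_len(max_attempts)) {
          cand <- runif(3) * box
          if (placed == 0L) { ok <- TRUE; break }
          d <- min_image(sweep(pos[seq_len(placed), , drop = FALSE], 2, cand),
                         box)
          if (min(rowSums(d^2)) >= min_separation^2) { ok <- TRUE; break }
        }
        if (!ok)
          stop(sprintf(paste0("packing failure: could not place bead %d of %d",
                              " at min_separation %.3g A in the given box"),
                       placed + 1L, n, min_separation), call. = FALSE)
        placed <- placed + 1L
        pos[placed, ] <- cand
      }
    })
  } else pos <- matrix(0, 0, 3)
  # shuffle species over positions so charge classes are well mixed
  species <- with_seed(seed + 1L, sample(species))
  md_system(species, templates, pos, box = box, time = 0)
}

#' Switch a residue to a protonation state
#'
#' Applies the template parameters of `target_state` to one residue, either
#' the partial charges only or all nonbonded parameters (charges, LJ,
#' polarizabilities, Thole, atom names/types, dummy flags). Atom count and
#' ordering are unchanged; applying the current state is a no-op and
#' applying A, then B, then A restores the original parameters exactly.
#'
#' @param system An [md_system()].
#' @param residue_id Residue id (1-based).
#' @param target_state One of the residue template's two state names.
#' @param mode `"all_nonbonded"` (default) or `"charges_only"`.
#' @return The updated system.
#' @export
apply_residue_state <- function(system, residue_id, target_state,
                                mode = c("all_nonbonded", "charges_only")) {
  mode <- match.arg(mode)
  res <- system$residues[residue_id, ]
  tpl <- find_template(system$templates, res$species)
  if (!(target_state %in% c(tpl$name_protonated, tpl$name_deprotonated)))
    stop(sprintf("state '%s' unknown for residue %d (%s/%s)", target_state,
                 residue_id, tpl$name_protonated, tpl$name_deprotonated),
         call. = FALSE)
  idx <- res$atom_start:res$atom_end
  new_at <- state_atom_rows(tpl, target_state)
  if (mode == "charges_only") {
    system$atoms$charge[idx] <- new_at$charge
  } else {
    keep_mass <- system$atoms$mass[idx]
    keep_rid <- system$atoms$residue_id[idx]
    for (col in c("name", "type", "lj_epsilon", "lj_rmin_half", "charge",
                  "polarizability", "thole", "dummy"))
      system$atoms[[col]][idx] <- new_at[[col]]
    system$atoms$mass[idx] <- keep_mass
    system$atoms$residue_id[idx] <- keep_rid
  }
  system$residues$species[residue_id] <- target_state
  system$residues$charge[residue_id] <-
    as.integer(round(sum(new_at$charge)))
  system
}

#' Residue centers of the current configuration
#'
#' Mass-weighted center of each residue's non-dummy atoms (folded
#' coordinates). Single-bead residues return the bead position. Residues
#' whose non-dummy atoms all have zero mass fall back to the unweighted
#' mean.
#'
#' @param system An [md_system()].
#' @return Numeric matrix (n_residues x 3), Angstrom.
#' @export
residue_centers <- function(system) {
  n <- nrow(system$residues)
  out <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    idx <- system$residues$atom_start[i]:system$residues$atom_end[i]
    keep <- idx[!system$atoms$dummy[idx]]
    w <- system$atoms$mass[keep]
    if (sum(w) <= 0) w <- rep(1, length(keep))
    out[i, ] <- colSums(system$positions[keep, , drop = FALSE] * w) / sum(w)
  }
  out
}

#' Current charge report
#'
#' One row per residue with its current state and integer charge; the charge
#' column sums to the total system charge. Reporters never mutate the
#' system.
#'
#' @param system An [md_system()].
#' @return Data frame with columns `time_ps`, `residue_id`, `state`,
#'   `charge_e`.
#' @export
report_charges <- function(system) {
  data.frame(time_ps = rep(system$time, nrow(system$residues)),
             residue_id = system$residues$id,
             state = system$residues$species,
             charge_e = system$residues$charge,
             stringsAsFactors = FALSE)
}

#' Current energy report
#'
#' Evaluates the toy forcefield on the current configuration and reports
#' each force component and their total (which the components sum to
#' exactly).
#'
#' @param system An [md_system()].
#' @param forcefield A [toy_forcefield()].
#' @return Data frame with columns `time_ps`, `component`
#'   (`"wca"`, `"coulomb"`, `"total"`) and `energy_kcal_mol`.
#' @export
report_energies <- function(system, forcefield) {
  fe <- compute_forces(system, forcefield)
  data.frame(time_ps = system$time,
             component = c("wca", "coulomb", "total"),
             energy_kcal_mol = c(fe$energy[["wca"]], fe$energy[["coulomb"]],
                                 fe$energy[["wca"]] + fe$energy[["coulomb"]]),
             stringsAsFactors = FALSE)
}
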