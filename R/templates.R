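#' Per-atom parameters of one protonation state
#'
#' Builds a one-row data frame holding the nonbonded parameters of one atom
#' in one protonation state. Lennard-Jones well depths and polarizabilities
#' are stored as magnitudes (CHARMM parameter files print them with a
#' negative sign). Dummy atoms carry zero charge and zero polarizability.
#'
#' @param name Atom name (e.g. "H7").
#' @param type Atom type (e.g. "HDP1A", "DUMH").
#' @param lj_epsilon LJ well depth magnitude, kcal/mol (>= 0).
#' @param lj_rmin_half LJ r_min/2, Angstrom (> 0).
#' @param charge Partial charge, e.
#' @param polarizability Atomic polarizability magnitude, Angstrom^3 (>= 0;
#'   0 for non-polarizable or dummy atoms).
#' @param thole Thole damping parameter (dimensionless, 0 if unused).
#' @return A one-row data frame.
#' @export
atom_params <- function(name, type, lj_epsilon, lj_rmin_half, charge,
                        polarizability = 0, thole = 0) {
  stopifnot(lj_rmin_half > 0)
  data.frame(name = as.character(name), type = as.character(type),
             lj_epsilon = abs(lj_epsilon), lj_rmin_half = lj_rmin_half,
             charge = charge, polarizability = abs(polarizability),
             thole = thole, stringsAsFactors = FALSE)
}

#' Dual-state residue template
#'
#' A residue prone to proton exchange is represented in a single topology
#' with two discrete protonation states sharing one atom list. Swapping
#' states swaps every atom's nonbonded parameters; the transferable hydrogen
#' of the protonated state is kept as a dummy atom (zero charge, negligible
#' LJ) in the deprotonated state.
#'
#' The constructor performs no validation so that defective templates can be
#' inspected with [validate_mapping()]; the config loader rejects templates
#' with violations.
#'
#' @param name_protonated,name_deprotonated Residue state names.
#' @param atoms_protonated,atoms_deprotonated Data frames of [atom_params()]
#'   rows, one per atom, in topology order.
#' @param atom_mapping Integer vector: `atom_mapping[i]` is the row of
#'   `atoms_deprotonated` corresponding to row i of `atoms_protonated`.
#'   Default is the identity (states share atom order).
#' @param donor_atoms Names of transferable hydrogens (protonated state).
#' @param acceptor_atoms Names of heavy-atom acceptor sites (deprotonated
#'   state).
#' @param dummy_atoms Names of atoms that are dummies in the deprotonated
#'   state; empty for coarse single-bead templates, where the acidic proton
#'   is implicit in the bead.
#' @return An object of class `residue_dual_template`.
#' @export
residue_dual_template <- function(name_protonated, name_deprotonated,
                                  atoms_protonated, atoms_deprotonated,
                                  atom_mapping = NULL,
                                  donor_atoms, acceptor_atoms,
                                  dummy_atoms = character()) {
  if (is.null(atom_mapping)) atom_mapping <- seq_len(nrow(atoms_protonated))
  structure(list(
    name_protonated = name_protonated,
    name_deprotonated = name_deprotonated,
    atoms_protonated = atoms_protonated,
    atoms_deprotonated = atoms_deprotonated,
    atom_mapping = as.integer(atom_mapping),
    donor_atoms = as.character(donor_atoms),
    acceptor_atoms = as.character(acceptor_atoms),
    dummy_atoms = as.character(dummy_atoms)
  ), class = "residue_dual_template")
}

#' @export
print.residue_dual_template <- function(x, ...) {
  cat(sprintf("residue dual template %s <-> %s (%d atoms)\n",
              x$name_protonated, x$name_deprotonated,
              nrow(x$atoms_protonated)))
  cat("  donors:", paste(x$donor_atoms, collapse = ", "),
      "| acceptors:", paste(x$acceptor_atoms, collapse = ", "),
      "| dummies:", if (length(x$dummy_atoms)) paste(x$dummy_atoms, collapse = ", ") else "(none)",
      "\n")
  invisible(x)
}

#' Check the atom mapping and site definitions of a template
#'
#' Verifies the single-topology invariants: both states have the same number
#' of atoms, the mapping between them is a bijection, donor/acceptor/dummy
#' names exist in their respective states, dummy atoms are chargeless and
#' non-polarizable, and (when the deprotonated state declares dummy atoms)
#' every donor hydrogen maps onto a dummy atom.
#'
#' @param template A [residue_dual_template()].
#' @return Character vector of human-readable violations; empty if the
#'   template is valid.
#' @export
validate_mapping <- function(template) {
  v <- character()
  np <- nrow(template$atoms_protonated)
  nd <- nrow(template$atoms_deprotonated)
  pn <- template$atoms_protonated$name
  dn <- template$atoms_deprotonated$name
  if (np != nd) {
    extra <- if (np > nd) setdiff(pn, dn) else setdiff(dn, pn)
    v <- c(v, sprintf("unmatched atoms between states: %s",
                      paste(extra, collapse = ", ")))
  }
  m <- template$atom_mapping
  if (length(m) != np || anyNA(m) || any(m < 1) || any(m > max(nd, 1)) ||
      anyDuplicated(m)) {
    v <- c(v, "atom_mapping is not a bijection between the two atom lists")
  }
  miss_d <- setdiff(template$donor_atoms, pn)
  if (length(miss_d))
    v <- c(v, sprintf("donor atom(s) missing from protonated state of %s: %s",
                      template$name_protonated, paste(miss_d, collapse = ", ")))
  miss_a <- setdiff(template$acceptor_atoms, dn)
  if (length(miss_a))
    v <- c(v, sprintf("acceptor atom(s) missing from deprotonated state of %s: %s",
                      template$name_deprotonated, paste(miss_a, collapse = ", ")))
  miss_u <- setdiff(template$dummy_atoms, dn)
  if (length(miss_u))
    v <- c(v, sprintf("dummy atom(s) missing from deprotonated state of %s: %s",
                      template$name_deprotonated, paste(miss_u, collapse = ", ")))
  if (length(template$dummy_atoms) && !length(miss_d) && !length(v)) {
    for (d in template$donor_atoms) {
      i <- match(d, pn)
      mapped <- dn[m[i]]
      if (!(mapped %in% template$dummy_atoms))
        v <- c(v, sprintf("donor %s maps to non-dummy atom %s", d, mapped))
    }
  }
  if (!length(miss_u)) {
    du <- template$atoms_deprotonated[dn %in% template$dummy_atoms, , drop = FALSE]
    bad <- du$name[abs(du$charge) > 0 | du$polarizability > 0]
    if (length(bad))
      v <- c(v, sprintf("dummy atom(s) with nonzero charge or polarizability: %s",
                        paste(bad, collapse = ", ")))
  }
  v
}

#' Net charge of a template state
#'
#' @param template A [residue_dual_template()].
#' @param state_name One of the template's two state names.
#' @return Sum of per-atom charges, e.
#' @export
residue_charge <- function(template, state_name) {
  atoms <- template_atoms(template, state_name)
  sum(atoms$charge)
}

# atoms data frame of one state; errors on unknown state name
template_atoms <- function(template, state_name) {
  if (state_name == template$name_protonated) return(template$atoms_protonated)
  if (state_name == template$name_deprotonated) return(template$atoms_deprotonated)
  stop(sprintf("state '%s' is not a state of template %s/%s", state_name,
               template$name_protonated, template$name_deprotonated),
       call. = FALSE)
}

# the partner state name
other_state <- function(template, state_name) {
  if (state_name == template$name_protonated) return(template$name_deprotonated)
  if (state_name == template$name_deprotonated) return(template$name_protonated)
  stop(sprintf("state '%s' is not a state of template %s/%s", state_name,
               template$name_protonated, template$name_deprotonated),
       call. = FALSE)
}

#' Proton-transfer reaction definition
#'
#' A directed reaction between two residue states: the donor (a residue in
#' its protonated state) hands its acidic hydrogen to the acceptor (a residue
#' in its deprotonated state). A transfer is attempted when a donor-hydrogen
#' / acceptor-site distance falls below `r_max`, and executed with the
#' current reaction probability. The probability starts at `p_ref` and is
#' adjusted by the cubic feedback rule (see [update_probability()]) using
#' the count of the monitor species.
#'
#' @param reactants Character vector of two residue-state names; the first
#'   is the monitor species of the feedback rule.
#' @param products Character vector of two residue-state names, positionally
#'   matching `reactants` (each product is the partner state of its
#'   reactant).
#' @param r_max Distance criterion, Angstrom.
#' @param p_ref Reference probability as a fraction in `[0, 1]`.
#' @param c Feedback prefactor (dimensionless); 300 in the study systems.
#' @param monitor Residue-state name whose count drives the feedback;
#'   defaults to `reactants[1]`.
#' @return An object of class `transfer_reaction`.
#' @export
transfer_reaction <- function(reactants, products, r_max, p_ref, c = 300,
                              monitor = reactants[1]) {
  stopifnot(length(reactants) == 2, length(products) == 2)
  if (!is.numeric(r_max) || r_max <= 0) stop("r_max must be > 0", call. = FALSE)
  if (!is.numeric(p_ref) || p_ref < 0 || p_ref > 1)
    stop("p_ref must be a fraction in [0, 1]", call. = FALSE)
  structure(list(
    reactants = as.character(reactants), products = as.character(products),
    r_max = r_max, p_ref = p_ref, c = c, monitor = as.character(monitor),
    name = paste0(paste(reactants, collapse = "+"), "->",
                  paste(products, collapse = "+"))
  ), class = "transfer_reaction")
}

#' @export
print.transfer_reaction <- function(x, ...) {
  cat(sprintf("%s  (r_max %.3g A, p_ref %.3g, c %.3g, monitor %s)\n",
              x$name, x$r_max, x$p_ref, x$c, x$monitor))
  invisible(x)
}

#' Load residue templates and transfer reactions from config files
#'
#' Reads one or more YAML documents with `residue_pairs` and `reactions`
#' sections, merges them, validates every template mapping and the
#' referential integrity of the reactions, and returns the parsed objects.
#' Reaction probabilities are given in the files on the percent scale
#' (`p_ref_percent`) and converted to fractions on load.
#'
#' @param paths Character vector of YAML file paths; sections from all files
#'   are merged.
#' @return A list of class `exchange_config` with elements `templates`
#'   (named list of [residue_dual_template()]) and `reactions` (list of
#'   [transfer_reaction()]).
#' @examples
#' cfg <- default_templates()
#' names(cfg$templates)
#' length(cfg$reactions)
#' @export
load_templates <- function(paths) {
  docs <- lapply(unname(paths), yaml::read_yaml)
  pairs <- do.call(c, c(lapply(docs, function(d) d$residue_pairs), list(NULL)))
  rxns <- do.call(c, c(lapply(docs, function(d) d$reactions), list(NULL)))

  templates <- list()
  for (p in pairs) {
    need <- c("name_protonated", "name_deprotonated", "atoms")
    if (!all(need %in% names(p)))
      stop("residue pair entry missing fields: ",
           paste(setdiff(need, names(p)), collapse = ", "), call. = FALSE)
    mk <- function(state) {
      do.call(rbind, lapply(p$atoms, function(a) {
        s <- a[[state]]
        atom_params(a$name, s$type, s$lj_epsilon, s$lj_rmin_half, s$charge,
                    polarizability = s$polarizability %||% 0,
                    thole = s$thole %||% 0)
      }))
    }
    tpl <- residue_dual_template(
      p$name_protonated, p$name_deprotonated,
      atoms_protonated = mk("protonated"),
      atoms_deprotonated = mk("deprotonated"),
      donor_atoms = unlist(p$donor_atoms),
      acceptor_atoms = unlist(p$acceptor_atoms),
      dummy_atoms = as.character(unlist(p$dummy_atoms))
    )
    viol <- validate_mapping(tpl)
    if (length(viol))
      stop(sprintf("invalid template %s/%s: %s", tpl$name_protonated,
                   tpl$name_deprotonated, paste(viol, collapse = "; ")),
           call. = FALSE)
    templates[[tpl$name_protonated]] <- tpl
  }

  known <- unlist(lapply(templates, function(t)
    c(t$name_protonated, t$name_deprotonated)))
  reactions <- lapply(rxns, function(r) {
    rr <- unlist(r$reactants); pp <- unlist(r$products)
    undef <- setdiff(c(rr, pp), known)
    if (length(undef))
      stop("reaction references undefined residue state(s): ",
           paste(undef, collapse = ", "), call. = FALSE)
    p_ref <- if (!is.null(r$p_ref_percent)) r$p_ref_percent / 100 else r$p_ref
    rx <- transfer_reaction(rr, pp, r_max = r$r_max, p_ref = p_ref,
                            c = r$c %||% 300,
                            monitor = r$monitor %||% rr[1])
    check_reaction(rx, templates)
    rx
  })

  structure(list(templates = templates, reactions = reactions),
            class = "exchange_config")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# consistency of a reaction against the template set: each product is the
# partner state of its reactant and exactly one proton moves
check_reaction <- function(reaction, templates) {
  tpl_of <- function(state) {
    for (t in templates)
      if (state %in% c(t$name_protonated, t$name_deprotonated)) return(t)
    stop("reaction references undefined residue state: ", state, call. = FALSE)
  }
  flips <- integer(2)
  for (i in 1:2) {
    t <- tpl_of(reaction$reactants[i])
    if (reaction$products[i] != other_state(t, reaction$reactants[i]))
      stop(sprintf("reaction %s: product %s is not the partner state of %s",
                   reaction$name, reaction$products[i],
                   reaction$reactants[i]), call. = FALSE)
    flips[i] <- if (reaction$reactants[i] == t$name_protonated) -1L else 1L
  }
  if (sum(flips) != 0L)
    stop(sprintf("reaction %s does not move exactly one proton",
                 reaction$name), call. = FALSE)
  invisible(TRUE)
}

#' Write an exchange config back to a YAML file
#'
#' Inverse of [load_templates()]: writing a loaded config and loading it
#' again reproduces all fields.
#'
#' @param config An `exchange_config` from [load_templates()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_templates <- function(config, path) {
  pairs <- lapply(config$templates, function(t) {
    atoms <- lapply(seq_len(nrow(t$atoms_protonated)), function(i) {
      row <- function(df, j) list(
        type = df$type[j], lj_epsilon = df$lj_epsilon[j],
        lj_rmin_half = df$lj_rmin_half[j], charge = df$charge[j],
        polarizability = df$polarizability[j], thole = df$thole[j])
      list(name = t$atoms_protonated$name[i],
           protonated = row(t$atoms_protonated, i),
           deprotonated = row(t$atoms_deprotonated, t$atom_mapping[i]))
    })
    list(name_protonated = t$name_protonated,
         name_deprotonated = t$name_deprotonated,
         donor_atoms = as.list(t$donor_atoms),
         acceptor_atoms = as.list(t$acceptor_atoms),
         dummy_atoms = as.list(t$dummy_atoms),
         atoms = atoms)
  })
  names(pairs) <- NULL
  rxns <- lapply(config$reactions, function(r) {
    list(reactants = as.list(r$reactants), products = as.list(r$products),
         r_max = r$r_max, p_ref_percent = r$p_ref * 100, c = r$c,
         monitor = r$monitor)
  })
  txt <- yaml::as.yaml(list(residue_pairs = pairs, reactions = rxns),
                       precision = 15)
  writeLines(txt, path)
  invisible(path)
}

#' Packaged residue templates and reactions for the imidazolium acetate system
#'
#' Loads the shipped configuration for the protic ionic liquid
#' 1-methylimidazolium acetate: the Im1H+/Im1 dual template (atomistic
#' parameters as published for that pair), a constructed acetate HOAc/OAc-
#' stand-in (synthetic parameters; see the file
#' `acetate_templates_synthetic.yml`), and the four transfer reactions with
#' their distance criterion (1.55 Angstrom), reference probabilities and
#' feedback constant c = 300.
#'
#' @return An `exchange_config`; see [load_templates()].
#' @export
default_templates <- function() {
  files <- c("imidazolium_templates.yml", "acetate_templates_synthetic.yml",
             "transfer_reactions.yml")
  paths <- vapply(files, function(f)
    system.file("extdata", f, package = "protonhop", mustWork = TRUE), "")
  load_templates(paths)
}

#' Single-bead residue templates for the toy engine
#'
#' Coarse-grained counterparts of the four species: each residue is one bead
#' whose charge is +1/0 e (imidazolium/imidazole) or 0/-1 e (acetic
#' acid/acetate). Donor and acceptor sites coincide with the bead center and
#' the acidic proton is implicit, so there is no dummy atom.
#'
#' @param lj_epsilon,lj_rmin_half Bookkeeping LJ parameters carried on the
#'   bead records (the toy forcefield uses its own global epsilon/sigma).
#' @return Named list of two [residue_dual_template()] objects (`IM1H`,
#'   `HOAC`).
#' @export
bead_templates <- function(lj_epsilon = 0.2, lj_rmin_half = 2.8) {
  bead <- function(type, charge)
    atom_params("BD", type, lj_epsilon, lj_rmin_half, charge)
  im <- residue_dual_template(
    "IM1H", "IM1",
    atoms_protonated = bead("IM1H", 1),
    atoms_deprotonated = bead("IM1", 0),
    donor_atoms = "BD", acceptor_atoms = "BD")
  ac <- residue_dual_template(
    "HOAC", "OAC",
    atoms_protonated = bead("HOAC", 0),
    atoms_deprotonated = bead("OAC", -1),
    donor_atoms = "BD", acceptor_atoms = "BD")
  list(IM1H = im, HOAC = ac)
}

#' Transfer reactions for the single-bead toy system
#'
#' The four packaged reactions (same species names, reference probabilities
#' and feedback constant as the atomistic config) with the distance
#' criterion rescaled to bead dimensions: 1.55 Angstrom is an atomistic
#' hydrogen-bond criterion, while bead donor/acceptor sites sit at the bead
#' centers, so the toy default is 1.2 times the bead contact distance.
#'
#' @param r_max Distance criterion in Angstrom (default 1.2 * 5 = 6).
#' @return List of [transfer_reaction()] objects.
#' @export
bead_reactions <- function(r_max = 6.0) {
  cfg <- default_templates()
  lapply(cfg$reactions, function(r)
    transfer_reaction(r$reactants, r$products, r_max = r_max,
                      p_ref = r$p_ref, c = r$c, monitor = r$monitor))
}
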