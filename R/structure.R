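# normalise cutoffs to a named species x species matrix
cutoff_matrix <- function(cutoffs, species_levels) {
  ns <- length(species_levels)
  if (is.matrix(cutoffs)) {
    stopifnot(nrow(cutoffs) == ns, ncol(cutoffs) == ns)
    m <- cutoffs
  } else {
    m <- matrix(cutoffs, ns, ns)
  }
  dimnames(m) <- list(species_levels, species_levels)
  m
}

#' First-shell neighbor assignment of one frame
#'
#' Neighbors under the minimum-image convention within a per-species-pair
#' radial cutoff. With symmetric cutoffs the relation is symmetric: l in
#' the shell of k iff k in the shell of l.
#'
#' @param positions Residue-center matrix (n x 3), folded.
#' @param species Character vector of species labels (length n).
#' @param box Box lengths (length-3) or [box_spec()].
#' @param cutoffs Scalar or species x species matrix of shell radii,
#'   Angstrom (all below half the smallest box edge).
#' @return Data frame: `center`, `neighbor` (residue indices, both
#'   directions), `center_species`, `neighbor_species`, `distance`.
#' @export
first_shell_neighbors <- function(positions, species, box, cutoffs) {
  box <- as.numeric(box)
  lv <- sort(unique(species))
  cm <- cutoff_matrix(cutoffs, lv)
  if (any(cm >= min(box) / 2))
    stop(sprintf("shell cutoff must be below half the smallest box edge (%.3g A)",
                 min(box) / 2), call. = FALSE)
  hits <- self_pairs_cpp(as.matrix(positions), box, max(cm))
  if (!nrow(hits))
    return(data.frame(center = integer(), neighbor = integer(),
                      center_species = character(),
                      neighbor_species = character(), distance = numeric(),
                      stringsAsFactors = FALSE))
  i <- hits[, 1]; j <- hits[, 2]; d <- hits[, 3]
  both <- data.frame(center = c(i, j), neighbor = c(j, i),
                     distance = c(d, d), stringsAsFactors = FALSE)
  both$center_species <- species[both$center]
  both$neighbor_species <- species[both$neighbor]
  keep <- both$distance < cm[cbind(both$center_species,
                                   both$neighbor_species)]
  out <- both[keep, c("center", "neighbor", "center_species",
                      "neighbor_species", "distance")]
  rownames(out) <- NULL
  out
}

#' Shell-resolved potential of mean force
#'
#' For each ordered species pair (k, l), compares the trajectory-averaged
#' concentration of l in the first shell of k,
#' `c_l(shell) = N_kl / V_k`, with the bulk concentration `c_l = N_l / V`:
#' \deqn{PMF_{kl} = -k_B T \ln\frac{c_l(shell=1)}{c_l}}
#' Negative values indicate preferential coordination (enrichment), positive
#' values depletion. The first shell is a sphere of the per-pair cutoff
#' radius, so `V_k = (4/3) pi r_kl^3`. Pairs never observed in a shell
#' (`N_kl = 0`) are reported as `Inf` (a depletion floor) and flagged.
#'
#' @param centers Folded center array `[frame, residue, 3]` (a single n x 3
#'   frame is accepted).
#' @param species Species label per residue.
#' @param box Box lengths or [box_spec()].
#' @param cutoffs Scalar or species x species cutoff matrix, Angstrom.
#' @param temperature Temperature, K.
#' @param units A [charmm_units()] object.
#' @return Object of class `pmf_matrix`: list with `pmf` (kcal/mol),
#'   `pmf_kJ` (kJ/mol), `counts` (mean shell coordination numbers N_kl),
#'   `shell_volumes` (V_k per pair), `bulk_concentration` (c_l),
#'   `depleted` (logical matrix), `species`, `temperature`.
#' @export
shell_pmf <- function(centers, species, box, cutoffs, temperature = 300,
                      units = charmm_units()) {
  if (length(dim(centers)) == 2)
    centers <- array(centers, c(1, nrow(centers), 3))
  nf <- dim(centers)[1]
  if (nf < 1) stop("need at least one frame", call. = FALSE)
  box <- as.numeric(box)
  lv <- sort(unique(species))
  ns <- length(lv)
  cm <- cutoff_matrix(cutoffs, lv)
  if (any(cm <= 0)) stop("shell volume V_k must be positive", call. = FALSE)
  n_per <- table(factor(species, levels = lv))
  counts <- matrix(0, ns, ns, dimnames = list(lv, lv))
  for (f in seq_len(nf)) {
    nb <- first_shell_neighbors(centers[f, , , drop = TRUE], species, box,
                                cm)
    if (nrow(nb)) {
      tab <- table(factor(nb$center_species, levels = lv),
                   factor(nb$neighbor_species, levels = lv))
      counts <- counts + unclass(tab)
    }
  }
  # mean neighbors of species l around one molecule of species k
  n_kl <- sweep(counts / nf, 1, as.numeric(n_per), "/")
  v_k <- (4 / 3) * pi * cm^3
  vol <- prod(box)
  c_bulk <- as.numeric(n_per) / vol
  ratio <- sweep(n_kl / v_k, 2, c_bulk, "/")
  kBT <- units$boltzmann_constant * temperature
  pmf <- -kBT * log(ratio)
  structure(list(pmf = pmf, pmf_kJ = pmf * 4.184, counts = n_kl,
                 shell_volumes = v_k, bulk_concentration = c_bulk,
                 depleted = n_kl == 0, species = lv,
                 temperature = temperature), class = "pmf_matrix")
}

#' @export
print.pmf_matrix <- function(x, ...) {
  cat(sprintf("shell-resolved PMF (kcal/mol) at %g K; negative = enrichment\n",
              x$temperature))
  print(round(x$pmf, 4))
  invisible(x)
}

#' Tidy a PMF matrix into a long data frame
#'
#' @param x A `pmf_matrix`.
#' @param row.names,optional,... Ignored (data frame method signature).
#' @return Long data frame: `center_species`, `neighbor_species`,
#'   `pmf_kcal_mol`, `pmf_kJ_mol`, `n_shell`, `depleted`. Depleted entries
#'   carry `NA` instead of numeric infinity so written tables stay finite.
#' @export
as.data.frame.pmf_matrix <- function(x, row.names = NULL, optional = FALSE,
                                     ...) {
  lv <- x$species
  g <- expand.grid(center_species = lv, neighbor_species = lv,
                   stringsAsFactors = FALSE)
  idx <- cbind(g$center_species, g$neighbor_species)
  pm <- x$pmf[idx]
  dep <- x$depleted[idx]
  pm[dep] <- NA_real_
  data.frame(g, pmf_kcal_mol = pm, pmf_kJ_mol = pm * 4.184,
             n_shell = if (!is.null(x$counts)) x$counts[idx] else NA_real_,
             depleted = dep, stringsAsFactors = FALSE)
}

#' Difference between two shell PMF matrices
#'
#' Entrywise `a - b` (e.g. with-transfer minus without-transfer run);
#' antisymmetric under argument swap.
#'
#' @param a,b `pmf_matrix` objects over the same species set.
#' @return A `pmf_matrix` holding the differences (`counts` dropped).
#' @export
delta_pmf <- function(a, b) {
  if (!identical(a$species, b$species))
    stop("PMF matrices cover different species sets", call. = FALSE)
  d <- a$pmf - b$pmf
  structure(list(pmf = d, pmf_kJ = d * 4.184, counts = NULL,
                 shell_volumes = NULL, bulk_concentration = NULL,
                 depleted = a$depleted | b$depleted, species = a$species,
                 temperature = a$temperature), class = "pmf_matrix")
}

#' Radial distribution function of a species pair
#'
#' Minimum-image pair histogram normalised by the ideal-gas expectation;
#' used to pick first-shell cutoffs as the first RDF minimum after the
#' contact peak.
#'
#' @param centers Folded center array `[frame, residue, 3]` or one n x 3
#'   frame.
#' @param species Species label per residue.
#' @param pair Character vector `c(k, l)` of the two species.
#' @param box Box lengths or [box_spec()].
#' @param r_max Histogram range, Angstrom (default: half the smallest box
#'   edge).
#' @param dr Bin width, Angstrom.
#' @return Data frame: `r` (bin centers), `g` (RDF).
#' @export
pair_rdf <- function(centers, species, pair, box, r_max = NULL, dr = 0.2) {
  if (length(dim(centers)) == 2)
    centers <- array(centers, c(1, nrow(centers), 3))
  box <- as.numeric(box)
  if (is.null(r_max)) r_max <- min(box) / 2 * 0.99
  nf <- dim(centers)[1]
  ik <- which(species == pair[1])
  il <- which(species == pair[2])
  if (!length(ik) || !length(il))
    stop("species pair not present in the system", call. = FALSE)
  breaks <- seq(0, r_max, by = dr)
  h <- numeric(length(breaks) - 1)
  same <- pair[1] == pair[2]
  for (f in seq_len(nf)) {
    fr <- centers[f, , , drop = TRUE]
    if (same) {
      hits <- self_pairs_cpp(fr[ik, , drop = FALSE], box, r_max)
      d <- rep(hits[, 3], 2)  # count both directions
    } else {
      hits <- cross_pairs_cpp(fr[ik, , drop = FALSE],
                              fr[il, , drop = FALSE], box, r_max)
      d <- hits[, 3]
    }
    if (length(d)) h <- h + graphics::hist(d, breaks = breaks,
                                           plot = FALSE)$counts
  }
  r_lo <- breaks[-length(breaks)]; r_hi <- breaks[-1]
  shell_v <- (4 / 3) * pi * (r_hi^3 - r_lo^3)
  rho_l <- length(il) / prod(box)
  norm <- nf * length(ik) * rho_l * shell_v
  data.frame(r = (r_lo + r_hi) / 2, g = h / norm)
}

#' First minimum of an RDF after its main peak
#'
#' @param rdf Data frame from [pair_rdf()].
#' @return The radius of the first local minimum following the global
#'   maximum of g(r), Angstrom.
#' @export
first_shell_cutoff <- function(rdf) {
  pk <- which.max(rdf$g)
  if (pk >= nrow(rdf) - 1) stop("RDF has no minimum after its peak",
                                call. = FALSE)
  g <- rdf$g
  for (i in (pk + 1):(nrow(rdf) - 1)) {
    if (g[i] <= g[i - 1] && g[i] <= g[i + 1]) return(rdf$r[i])
  }
  rdf$r[which.min(g[(pk + 1):nrow(rdf)]) + pk]
}
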