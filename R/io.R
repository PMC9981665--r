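#' Write a topology file (CHARMM/X-PLOR PSF dialect)
#'
#' Writes the atom and bond sections of an extended-format PSF: atom id,
#' segment, residue id (1-based), residue (state) name, atom name, atom
#' type, charge and mass. The package's systems carry no bonded terms, so
#' the bond section is empty; angle/dihedral sections are omitted.
#'
#' @param system An [md_system()].
#' @param path Output file path.
#' @param segid Segment name written for all atoms.
#' @return `path`, invisibly.
#' @export
write_psf <- function(system, path, segid = "SYS") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("PSF EXT", "",
               sprintf("%10d !NTITLE", 1L),
               sprintf("* generated by protonhop at t = %g ps", system$time),
               ""), con)
  n <- nrow(system$atoms)
  writeLines(sprintf("%10d !NATOM", n), con)
  if (n > 0) {
    rid <- system$atoms$residue_id
    lines <- sprintf("%10d %-8s %-8d %-8s %-8s %-8s %14.6f %14.6f %8d",
                     seq_len(n), segid, rid,
                     system$residues$species[rid],
                     system$atoms$name, system$atoms$type,
                     system$atoms$charge, system$atoms$mass, 0L)
    writeLines(lines, con)
  }
  writeLines(c("", sprintf("%10d !NBOND: bonds", 0L), ""), con)
  invisible(path)
}

#' Read a topology file (CHARMM/X-PLOR PSF dialect)
#'
#' Parses the atom section written by [write_psf()] (or any whitespace-
#' delimited PSF atom section with the same column order), reconstructs the
#' residue composition and validates every residue (state) name against the
#' supplied templates. Bond and later sections are ignored. Positions are
#' initialised to zero; attach coordinates with [read_xyz()] frames.
#'
#' @param path PSF file path.
#' @param templates Named list of [residue_dual_template()] objects.
#' @param box A [box_spec()] (a PSF carries no box information).
#' @return An [md_system()].
#' @export
read_psf <- function(path, templates, box = box_spec(50)) {
  lines <- readLines(path)
  hdr <- grep("!NATOM", lines)
  if (length(hdr) != 1)
    stop("malformed PSF: expected exactly one !NATOM section in ", path,
         call. = FALSE)
  n <- suppressWarnings(as.integer(sub("\\s*!NATOM.*$", "", lines[hdr])))
  if (is.na(n)) stop("malformed PSF: unreadable atom count at line ", hdr,
                     call. = FALSE)
  if (n == 0)
    return(md_system(character(), templates, matrix(0, 0, 3), box = box))
  rec <- lines[(hdr + 1):(hdr + n)]
  fields <- strsplit(trimws(rec), "\\s+")
  bad <- which(vapply(fields, length, 1L) < 8)
  if (length(bad))
    stop("malformed PSF atom record at line ", hdr + bad[1], call. = FALSE)
  f <- function(k) vapply(fields, `[[`, "", k)
  rid <- as.integer(f(3))
  resname <- f(4)
  aname <- f(5)
  atype <- f(6)
  charge <- as.numeric(f(7))
  mass <- as.numeric(f(8))
  if (anyNA(rid) || anyNA(charge) || anyNA(mass))
    stop("malformed PSF atom record: non-numeric field in ", path,
         call. = FALSE)
  # residues appear as contiguous blocks, 1-based ids in file order
  res_first <- !duplicated(rid)
  species <- resname[res_first]
  known <- unlist(lapply(templates, function(t)
    c(t$name_protonated, t$name_deprotonated)))
  undef <- setdiff(unique(species), known)
  if (length(undef))
    stop("PSF residue name(s) not defined by any template: ",
         paste(undef, collapse = ", "), call. = FALSE)
  sys <- md_system(species, templates, matrix(0, n, 3), box = box,
                   masses = mass)
  # carry the file's printed charges (they equal the template values to
  # printed precision)
  sys$atoms$charge <- charge
  sys$atoms$name <- aname
  sys$atoms$type <- atype
  sys
}

#' Trajectory container
#'
#' @param coords Numeric array `[frame, atom, 3]`, folded coordinates in
#'   Angstrom.
#' @param times Frame times, ps.
#' @param box A [box_spec()].
#' @param atom_names Character vector of atom names (one per atom).
#' @return Object of class `xyz_trajectory`.
#' @export
xyz_trajectory <- function(coords, times, box, atom_names = NULL) {
  stopifnot(length(dim(coords)) == 3, dim(coords)[3] == 3,
            dim(coords)[1] == length(times))
  if (is.null(atom_names)) atom_names <- rep("BD", dim(coords)[2])
  structure(list(coords = coords, times = as.numeric(times),
                 box = box_spec(box), atom_names = atom_names),
            class = "xyz_trajectory")
}

#' @export
print.xyz_trajectory <- function(x, ...) {
  cat(sprintf("xyz_trajectory: %d frames x %d atoms, t = %g..%g ps, box %.4g %.4g %.4g A\n",
              dim(x$coords)[1], dim(x$coords)[2], min(x$times), max(x$times),
              x$box[1], x$box[2], x$box[3]))
  invisible(x)
}

#' Write an XYZ trajectory with box metadata
#'
#' Extended-XYZ dialect: per frame, the atom count line, then a comment line
#' `time= <ps> box= <Lx> <Ly> <Lz>`, then one `name x y z` line per atom.
#' Coordinates are printed with 8 decimals (lossless round trip at that
#' precision).
#'
#' @param trajectory An [xyz_trajectory()] (or an [md_system()], written as
#'   a single frame).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_xyz <- function(trajectory, path) {
  if (inherits(trajectory, "md_system")) {
    trajectory <- xyz_trajectory(
      array(trajectory$positions, c(1, nrow(trajectory$positions), 3)),
      times = trajectory$time, box = trajectory$box,
      atom_names = trajectory$atoms$name)
  }
  con <- file(path, "w")
  on.exit(close(con))
  n_at <- dim(trajectory$coords)[2]
  for (fr in seq_len(dim(trajectory$coords)[1])) {
    writeLines(as.character(n_at), con)
    writeLines(sprintf("time= %.8f box= %.8f %.8f %.8f",
                       trajectory$times[fr], trajectory$box[1],
                       trajectory$box[2], trajectory$box[3]), con)
    xyz <- trajectory$coords[fr, , , drop = FALSE]
    writeLines(sprintf("%-6s %16.8f %16.8f %16.8f", trajectory$atom_names,
                       xyz[1, , 1], xyz[1, , 2], xyz[1, , 3]), con)
  }
  invisible(path)
}

#' Read an XYZ trajectory with box metadata
#'
#' Inverse of [write_xyz()]. Every frame must carry the
#' `time= ... box= Lx Ly Lz` comment line; frames with inconsistent atom
#' counts raise a parse error naming the offending line.
#'
#' @param path XYZ file path.
#' @return An [xyz_trajectory()].
#' @export
read_xyz <- function(path) {
  lines <- readLines(path)
  pos <- 1L
  frames <- list(); times <- numeric(); box <- NULL; nm <- NULL
  n_at <- NA_integer_
  while (pos <= length(lines)) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    n <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(n))
      stop("XYZ parse error at line ", pos, ": expected atom count",
           call. = FALSE)
    if (!is.na(n_at) && n != n_at)
      stop("XYZ parse error at line ", pos, ": frame has ", n,
           " atoms, previous frames ", n_at, call. = FALSE)
    n_at <- n
    cm <- lines[pos + 1L]
    m <- regmatches(cm, regexec(
      "time=\\s*([-0-9.eE+]+)\\s+box=\\s*([-0-9.eE+]+)\\s+([-0-9.eE+]+)\\s+([-0-9.eE+]+)",
      cm))[[1]]
    if (length(m) != 5)
      stop("XYZ parse error at line ", pos + 1L,
           ": comment must carry 'time= <ps> box= <Lx> <Ly> <Lz>'",
           call. = FALSE)
    times <- c(times, as.numeric(m[2]))
    box <- as.numeric(m[3:5])
    if (pos + 1L + n > length(lines))
      stop("XYZ parse error: truncated frame starting at line ", pos,
           call. = FALSE)
    rec <- strsplit(trimws(lines[pos + 1L + seq_len(n)]), "\\s+")
    if (any(vapply(rec, length, 1L) < 4))
      stop("XYZ parse error: short atom record in frame starting at line ",
           pos, call. = FALSE)
    if (is.null(nm)) nm <- vapply(rec, `[[`, "", 1)
    xyz <- matrix(as.numeric(unlist(lapply(rec, `[`, 2:4))), ncol = 3,
                  byrow = TRUE)
    if (anyNA(xyz))
      stop("XYZ parse error: non-numeric coordinate in frame starting at line ",
           pos, call. = FALSE)
    frames[[length(frames) + 1L]] <- xyz
    pos <- pos + 2L + n
  }
  if (!length(frames)) stop("XYZ file contains no frames: ", path,
                            call. = FALSE)
  coords <- array(NA_real_, c(length(frames), n_at, 3))
  for (i in seq_along(frames)) coords[i, , ] <- frames[[i]]
  xyz_trajectory(coords, times, box, nm)
}

#' Write or read a transfer-event log (TSV)
#'
#' The event log is the contract between the exchange engine and the
#' transport analyses: one row per executed transfer with the residue ids,
#' reaction name, integer charges before/after, the folded residue centers
#' at event time and the minimum-image displacement
#' `r_ij = minimum_image(com_j - com_i)`.
#'
#' @param events Data frame of transfer events (see [execute_update()]).
#' @param path File path.
#' @return `path` (write) or the events data frame (read).
#' @export
write_events <- function(events, path) {
  utils::write.table(events, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE)
}
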