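# internal geometry and RNG helpers

#' Minimum-image displacement
#'
#' @param d Numeric vector of length 3 or an n x 3 matrix of raw
#'   displacement vectors.
#' @param box Box edge lengths, length-3 numeric (orthorhombic).
#' @return Displacements mapped into `[-L/2, L/2)` per component.
#' @export
min_image <- function(d, box) {
  if (is.matrix(d)) {
    sweep_box <- matrix(box, nrow(d), 3, byrow = TRUE)
    d - sweep_box * round(d / sweep_box)
  } else {
    d - box * round(d / box)
  }
}

# fold positions into [0, L)
fold_positions <- function(pos, box) {
  b <- matrix(box, nrow(pos), 3, byrow = TRUE)
  pos - floor(pos / b) * b
}

# evaluate code under a temporary RNG seed, restoring the caller's RNG state
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# independent RNG streams: each stream stores its own .Random.seed snapshot
# so that e.g. exchange acceptance draws never perturb the dynamics noise
rng_stream <- function(seed) {
  e <- new.env(parent = emptyenv())
  with_seed(seed, e$state <- get(".Random.seed", envir = globalenv()))
  e
}

draw_from <- function(stream, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  assign(".Random.seed", stream$state, envir = globalenv())
  res <- force(code)
  stream$state <- get(".Random.seed", envir = globalenv())
  if (had) assign(".Random.seed", old, envir = globalenv())
  else rm(".Random.seed", envir = globalenv())
  res
}

# guess an atomic mass (u) from an atom name; lone pairs and dummies get 0
guess_mass <- function(name) {
  vapply(name, function(nm) {
    if (grepl("^LP", nm)) return(0)
    switch(substr(nm, 1, 1),
           H = 1.008, C = 12.011, N = 14.007, O = 15.999, S = 32.06,
           B = 100, 12.011)  # BD beads get 100 u
  }, numeric(1), USE.NAMES = FALSE)
}
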