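#' Toy molecule templates
#'
#' Small rigid molecules used by the synthetic training-set generator:
#' `"diatomic"` (2 atoms, types X/Y, charges +-q), `"bent3"` (bent
#' triatomic Y-X-Y), `"quad4"` (planar 4-atom quadrupolar unit),
#' `"ring6"` (6-atom ring with alternating charges). Charges are chosen
#' so that electrostatics contributes an appreciable share of the
#' intermolecular energy; all templates are net neutral.
#'
#' @param template Template name.
#' @param q Charge scale in e.
#' @return An `xtl_molecule` at the origin with identity orientation.
#' @export
toy_molecule <- function(template = c("bent3", "diatomic", "quad4", "ring6"),
                         q = 0.25) {
  template <- match.arg(template)
  build <- function(el, ty, loc, ch) {
    loc <- sweep(loc, 2, colMeans(loc))
    rigid_molecule(el, ty, loc, ch)
  }
  switch(template,
    diatomic = build(c("C", "N"), c("X", "Y"),
                     rbind(c(0.6, 0, 0), c(-0.6, 0, 0)), c(q, -q)),
    bent3 = build(c("O", "H", "H"), c("X", "Y", "Y"),
                  rbind(c(0, 0.4, 0), c(0.95, -0.35, 0), c(-0.95, -0.35, 0)),
                  c(-2 * q, q, q)),
    quad4 = build(c("C", "C", "N", "N"), c("X", "X", "Y", "Y"),
                  rbind(c(1.2, 0.7, 0), c(-1.2, 0.7, 0),
                        c(1.2, -0.7, 0), c(-1.2, -0.7, 0)),
                  c(q, q, -q, -q)),
    ring6 = build(rep(c("C", "N"), 3), rep(c("X", "Y"), 3),
                  {
                    th <- (0:5) * pi / 3
                    cbind(1.39 * cos(th), 1.39 * sin(th), 0)
                  },
                  rep(c(q, -q), 3)))
}

#' Specification of one synthetic toy crystal
#'
#' @param template Molecule template (see [toy_molecule()]).
#' @param sg Space group: `"P1"`, `"P-1"` or `"P21"`.
#' @param cell_min,cell_max Range the random cell lengths are drawn
#'   from (Angstrom). Angles for triclinic cells are drawn in
#'   (75, 105) degrees.
#' @param q Charge scale (e).
#' @param min_contact Minimum allowed initial intermolecular contact
#'   (Angstrom); packings violating it are redrawn.
#' @return A list of class `xtl_toyspec`.
#' @export
toy_spec <- function(template = "bent3", sg = "P-1",
                     cell_min = 5.5, cell_max = 8.5, q = 0.25,
                     min_contact = 2.2) {
  stopifnot(sg %in% c("P1", "P-1", "P21"))
  structure(list(template = template, sg = sg, cell_min = cell_min,
                 cell_max = cell_max, q = q, min_contact = min_contact),
            class = "xtl_toyspec")
}

#' Generate a random toy crystal
#'
#' Draws a cell compatible with the space group's crystal system, places
#' one molecule at a random center and orientation, and rejects packings
#' with intermolecular contacts below `spec$min_contact` (bounded
#' retries). Deterministic given `(spec, seed)`.
#'
#' @param spec A [toy_spec()].
#' @param seed Integer seed.
#' @param max_try Maximum packing attempts.
#' @return An `xtl_crystal`.
#' @export
make_toy_crystal <- function(spec, seed, max_try = 200) {
  mol0 <- toy_molecule(spec$template, q = spec$q)
  rng <- local_rng(seed)
  for (t in seq_len(max_try)) {
    lat <- switch(sg_system(spec$sg),
      triclinic = lattice(rng(1, spec$cell_min, spec$cell_max),
                          rng(1, spec$cell_min, spec$cell_max),
                          rng(1, spec$cell_min, spec$cell_max),
                          rng(1, 75, 105), rng(1, 75, 105), rng(1, 75, 105),
                          system = "triclinic"),
      monoclinic = lattice(rng(1, spec$cell_min, spec$cell_max),
                           rng(1, spec$cell_min, spec$cell_max),
                           rng(1, spec$cell_min, spec$cell_max),
                           90, rng(1, 85, 110), 90,
                           system = "monoclinic"))
    mol <- mol0
    mol$center <- rng(3, 0.05, 0.45)
    v <- rng(3, -1, 1); v <- v / sqrt(sum(v^2))
    mol$quat <- axis_angle_to_quat(v * rng(1, 0, pi))
    cr <- tryCatch(
      crystal(lat, sg_ops(spec$sg), list(mol),
              label = sprintf("%s_%s_seed%d", spec$template, spec$sg, seed)),
      error = function(e) NULL)
    if (is.null(cr)) next
    st <- crystal_sites(cr, expand = TRUE, wrap = FALSE)
    dmin <- min_intermolecular_distance(st, cell_matrix(lat))
    if (dmin >= spec$min_contact) return(cr)
  }
  stop("toy packing rejection: no valid packing after ", max_try,
       " attempts (spec ", spec$template, "/", spec$sg, ", seed ", seed, ")",
       call. = FALSE)
}

# Minimum intermolecular (different instance, or any-image) distance.
min_intermolecular_distance <- function(st, M) {
  n <- nrow(st$cart)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dmin <- Inf
  for (s in seq_len(nrow(shifts))) {
    sh <- as.numeric(M %*% as.numeric(shifts[s, ]))
    home <- all(shifts[s, ] == 0)
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (home && st$instance[i] == st$instance[j]) next
        d <- sqrt(sum((st$cart[j, ] + sh - st$cart[i, ])^2))
        dmin <- min(dmin, d)
      }
    }
  }
  dmin
}

# Deterministic local RNG that does not disturb the global stream.
local_rng <- function(seed) {
  env <- new.env()
  env$state <- {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    set.seed(seed)
    s <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv()) else
      rm(".Random.seed", envir = globalenv())
    s
  }
  function(n, lo = 0, hi = 1) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    assign(".Random.seed", env$state, globalenv())
    x <- stats::runif(n, lo, hi)
    env$state <- get(".Random.seed", globalenv())
    if (!is.null(old)) assign(".Random.seed", old, globalenv())
    x
  }
}

#' Default "true" potential set for the synthetic study
#'
#' Two atom types X and Y with Buckingham parameters of the magnitude
#' used for C and H in transferable exp-6 force fields; B values are
#' fixed (never fitted), the six A and C parameters (XX, XY, YY) are
#' free with lower bound zero.
#'
#' @param mode `"explicit"` (all cross pairs independent) or
#'   `"combine"`.
#' @return An `xtl_potentials`.
#' @export
toy_potentials <- function(mode = "explicit") {
  free <- array(FALSE, c(2, 2, 3))
  if (mode == "explicit") {
    free[, , 1] <- TRUE; free[, , 3] <- TRUE     # A and C free, B fixed
  } else {
    free[, , 1] <- diag(2) > 0; free[, , 3] <- diag(2) > 0
  }
  potential_set(c("X", "Y"),
                A = matrix(c(2.2e5, 6.9e4, 6.9e4, 2.2e4), 2),
                B = matrix(c(3.60, 3.67, 3.67, 3.74), 2),
                C = matrix(c(2200, 595, 595, 161), 2),
                free = free, mode = mode)
}

#' Generate a synthetic reference training set
#'
#' Each toy crystal is relaxed to a lattice-energy minimum under the
#' "true" parameters; the relaxed geometry becomes the reference
#' geometry and its intermolecular energy the reference energy, so that
#' the total merit function vanishes identically at the true parameters.
#' Crystals failing the minimization (or relaxing to shallow, weakly
#' bound packings) are regenerated with a new sub-seed.
#'
#' @param specs List of [toy_spec()]s (one entry generated per spec).
#' @param pots_true The true `xtl_potentials`.
#' @param seed Integer master seed.
#' @param lm_opts [latmin_options()].
#' @param max_regen Regeneration attempts per spec.
#' @return List of [reference_entry()] objects.
#' @export
generate_reference_set <- function(specs, pots_true, seed,
                                   lm_opts = latmin_options(),
                                   max_regen = 20) {
  entries <- vector("list", length(specs))
  for (i in seq_along(specs)) {
    done <- FALSE
    for (t in seq_len(max_regen)) {
      sub <- (seed * 1000L + i * 100L + t) %% .Machine$integer.max
      cr <- tryCatch(make_toy_crystal(specs[[i]], sub),
                     error = function(e) NULL)
      if (is.null(cr)) next
      lm <- minimize_lattice(cr, pots_true, opts = lm_opts)
      if (lm$status != "converged") next
      if (!is.finite(lm$U_star) || lm$U_star > -5) next   # too weakly bound
      cr_star <- lm$crystal
      cr_star$label <- sprintf("%s_%02d", cr$label, t)
      entries[[i]] <- reference_entry(cr_star, lm$U_star,
                                      label = cr_star$label)
      done <- TRUE
      break
    }
    if (!done)
      stop("persistent lattice-minimization failure generating entry ", i,
           " (spec ", specs[[i]]$template, "/", specs[[i]]$sg, ")",
           call. = FALSE)
  }
  entries
}

#' Multiplicative log-uniform parameter perturbation
#'
#' Each free parameter is multiplied by `exp(u)` with `u` uniform on
#' `(-log(1+scale), log(1+scale))`; deterministic per seed and always
#' within `[p/(1+scale), p*(1+scale)]`.
#'
#' @param p Parameter vector.
#' @param scale Relative perturbation scale in (0, 1]; 0 returns `p`.
#' @param seed Integer seed.
#' @return Perturbed vector.
#' @export
perturb_parameters <- function(p, scale, seed) {
  if (scale == 0) return(p)
  stopifnot(scale > 0, scale <= 1)
  rng <- local_rng(seed)
  u <- rng(length(p), -log(1 + scale), log(1 + scale))
  p * exp(u)
}

#' Default toy training-set specification list
#'
#' A mixed set of templates and space groups sized for fitting the six
#' X/Y Buckingham A and C parameters.
#'
#' @param n Number of structures.
#' @return List of [toy_spec()]s.
#' @export
default_toy_specs <- function(n = 12) {
  templates <- rep(c("bent3", "quad4", "ring6"), length.out = n)
  sgs <- rep(c("P-1", "P1", "P-1", "P21"), length.out = n)
  lapply(seq_len(n), function(i)
    toy_spec(templates[i], sgs[i],
             cell_min = 5.5 + 0.25 * (i %% 4),
             cell_max = 8.0 + 0.25 * (i %% 3)))
}
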