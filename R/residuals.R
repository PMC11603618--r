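#' Reference training-set entry
#'
#' Couples a reference crystal geometry (with charges and atom types)
#' with its reference intermolecular energy and the geometry/energy
#' weights used in the merit function.
#'
#' @param crystal An `xtl_crystal` at the reference geometry.
#' @param u_ref Reference intermolecular energy, kJ/mol per molecule.
#' @param w_g,w_e Non-negative geometry and energy weights. By
#'   convention `w_e` defaults to 0 when any atom type is a polarized
#'   hydrogen (`Hp`), excluding hydrogen-bonded structures from the
#'   energy fit; otherwise both default to 1.
#' @param label Structure identifier.
#' @return An object of class `xtl_ref_entry`.
#' @export
reference_entry <- function(crystal, u_ref, w_g = 1, w_e = NULL,
                            label = crystal$label) {
  if (is.null(w_e)) {
    types <- unlist(lapply(crystal$molecules, function(m) m$type))
    w_e <- if (any(types == "Hp")) 0 else 1
  }
  stopifnot(w_g >= 0, w_e >= 0, is.finite(u_ref))
  structure(list(crystal = crystal, u_ref = u_ref, w_g = w_g, w_e = w_e,
                 label = label),
            class = "xtl_ref_entry")
}

#' @export
print.xtl_ref_entry <- function(x, ...) {
  cat(sprintf("<reference entry '%s': U_ref=%.4f kJ/mol, w_G=%g, w_E=%g>\n",
              x$label, x$u_ref, x$w_g, x$w_e))
  invisible(x)
}

#' Unit-cell geometry residuals
#'
#' Relative deviations of the free cell parameters from the reference,
#' normalized by the square root of the number of residuals of this
#' type: `X_i = ((x_i - x_i_ref) / x_i_ref) / sqrt(n_x)`.
#'
#' @param lat,ref_lat `xtl_lattice` objects of the same crystal system.
#' @return Numeric vector of length `n_x`.
#' @export
lattice_residuals <- function(lat, ref_lat) {
  if (lat$system != ref_lat$system)
    stop("lattice residuals require matching crystal systems", call. = FALSE)
  x <- free_cell_values(lat)
  xr <- free_cell_values(ref_lat)
  ((x - xr) / xr) / sqrt(length(x))
}

#' Relative fractional-coordinate residuals
#'
#' Fractional coordinates of the asymmetric unit measured relative to
#' the first atom listed (removing the translational degeneracy), with
#' each component mapped to the periodic image nearest its reference
#' value, normalized by `sqrt(3 N_at - 3)`.
#'
#' @param frac,ref_frac `N_at x 3` matrices of asymmetric-unit
#'   fractional coordinates in identical atom order.
#' @return Numeric vector of length `3 N_at - 3`.
#' @export
coord_residuals <- function(frac, ref_frac) {
  frac <- as.matrix(frac); ref_frac <- as.matrix(ref_frac)
  n <- nrow(frac)
  if (n < 2) stop("coordinate residuals need at least two atoms",
                  call. = FALSE)
  stopifnot(nrow(ref_frac) == n)
  Y <- sweep(frac[-1, , drop = FALSE], 2, frac[1, ])
  Yr <- sweep(ref_frac[-1, , drop = FALSE], 2, ref_frac[1, ])
  D <- Y - Yr
  D <- D - round(D)
  as.numeric(t(D)) / sqrt(3 * n - 3)
}

#' Energy residual
#'
#' Relative, sign-preserving deviation of the optimized intermolecular
#' energy from the reference: `(U_star - U_ref) / |U_ref|` (the
#' magnitude denominator keeps overbinding and underbinding on opposite
#' signs regardless of the sign of `U_ref`; `denominator = "signed"`
#' divides by `U_ref` instead).
#'
#' @param u_star,u_ref Energies in kJ/mol; `u_ref` must be nonzero.
#' @param denominator `"abs"` (default) or `"signed"`.
#' @return Scalar residual.
#' @export
energy_residual <- function(u_star, u_ref, denominator = c("abs", "signed")) {
  denominator <- match.arg(denominator)
  if (u_ref == 0) stop("energy residual undefined for U_ref = 0",
                       call. = FALSE)
  den <- if (denominator == "abs") abs(u_ref) else u_ref
  (u_star - u_ref) / den
}

#' Merit function of one structure
#'
#' Weighted sum of squares of the geometry and energy residuals:
#' `MF = 0.5 (w_G (||X||^2 + ||Y||^2) + w_E E^2)`.
#'
#' @param X,Y Geometry residual vectors ([lattice_residuals()],
#'   [coord_residuals()]).
#' @param E Scalar energy residual.
#' @param w_g,w_e Non-negative weights.
#' @return Scalar merit value.
#' @export
merit_function <- function(X, Y, E, w_g = 1, w_e = 1) {
  stopifnot(w_g >= 0, w_e >= 0)
  0.5 * (w_g * (sum(X^2) + sum(Y^2)) + w_e * E^2)
}

#' Number of residuals contributed by a structure
#'
#' `n_x` free cell parameters plus `3 N_at - 3` relative coordinates
#' plus one energy residual.
#'
#' @param cr An `xtl_crystal`.
#' @return Integer count.
#' @export
count_residuals <- function(cr) {
  nat <- sum(vapply(cr$molecules, n_atoms, 0L))
  n_free_cell(cr$lattice) + (3L * nat - 3L) + 1L
}

# Residual set of one optimized structure against its reference entry.
# Returns X, Y, E, MF plus the weighted residual vector (the square-root
# weights folded in, so TMF = 0.5 * sum(wres^2)).
structure_residuals <- function(cr_star, entry,
                                denominator = "abs") {
  X <- lattice_residuals(cr_star$lattice, entry$crystal$lattice)
  f <- crystal_sites(cr_star, expand = FALSE, wrap = FALSE)$frac
  fr <- crystal_sites(entry$crystal, expand = FALSE, wrap = FALSE)$frac
  Y <- coord_residuals(f, fr)
  list(X = X, Y = Y)
}

# Full per-structure evaluation: lattice minimization from a given
# starting geometry followed by residual assembly.
evaluate_structure <- function(entry, pots, start_crystal = NULL,
                               lm_opts = latmin_options(),
                               denominator = "abs",
                               want_sensitivity = FALSE) {
  start <- if (is.null(start_crystal)) entry$crystal else start_crystal
  lm <- minimize_lattice(start, pots, opts = lm_opts)
  if (lm$status %in% c("overlap_failure", "not_converged", "saddle")) {
    return(list(ok = FALSE, lm = lm, label = entry$label))
  }
  geo <- structure_residuals(lm$crystal, entry, denominator)
  E <- energy_residual(lm$U_star, entry$u_ref, denominator)
  MF <- merit_function(geo$X, geo$Y, E, entry$w_g, entry$w_e)
  wres <- c(sqrt(entry$w_g) * geo$X, sqrt(entry$w_g) * geo$Y,
            sqrt(entry$w_e) * E)
  out <- list(ok = TRUE, lm = lm, label = entry$label,
              X = geo$X, Y = geo$Y, E = E, MF = MF, wres = wres)
  if (want_sensitivity) {
    sens <- tryCatch(
      structure_sensitivity(lm, entry, pots, lm_opts$energy,
                            denominator = denominator),
      error = function(e) NULL)
    if (is.null(sens)) return(list(ok = FALSE, lm = lm, label = entry$label))
    out$jac <- sens$wjac
    out$dMF_dp <- sens$dMF_dp
  }
  out
}

#' Total merit function over a training set
#'
#' Runs the lattice minimization for every entry (starting from the
#' reference geometry unless per-structure starting crystals are given)
#' and sums the per-structure merit functions. Lattice-minimization
#' failures are reported in the diagnostics, not raised.
#'
#' @param entries List of [reference_entry()] objects.
#' @param pots An `xtl_potentials`.
#' @param starts Optional list of starting `xtl_crystal`s (dynamic
#'   starting points), parallel to `entries`.
#' @param lm_opts [latmin_options()].
#' @param denominator Energy-residual convention (see
#'   [energy_residual()]).
#' @return List with `TMF` (NA if any structure failed), `valid`,
#'   `per_structure` (data.frame of label, MF, U_star, status),
#'   `results` (per-structure evaluation records).
#' @export
total_merit <- function(entries, pots, starts = NULL,
                        lm_opts = latmin_options(), denominator = "abs") {
  res <- vector("list", length(entries))
  for (i in seq_along(entries)) {
    res[[i]] <- evaluate_structure(entries[[i]], pots,
                                   if (!is.null(starts)) starts[[i]],
                                   lm_opts, denominator)
  }
  ok <- vapply(res, function(r) r$ok, TRUE)
  per <- data.frame(
    label = vapply(res, function(r) r$label, ""),
    MF = vapply(res, function(r) if (r$ok) r$MF else NA_real_, 0),
    U_star = vapply(res, function(r) r$lm$U_star, 0),
    status = vapply(res, function(r) r$lm$status, ""),
    stringsAsFactors = FALSE)
  list(TMF = if (all(ok)) sum(per$MF) else NA_real_,
       valid = all(ok),
       failed = per$label[!ok],
       per_structure = per,
       results = res)
}
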