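#' Crystal lattice
#'
#' A unit cell described by the six cell parameters and a crystal system.
#' The crystal system determines which of the six parameters are free
#' (independent under the space-group constraints): triclinic 6,
#' monoclinic 4 (a, b, c, beta; unique axis b), orthorhombic 3,
#' tetragonal 2, hexagonal/trigonal 2, cubic 1.
#'
#' @param a,b,c Cell lengths in Angstrom.
#' @param alpha,beta,gamma Cell angles in degrees.
#' @param system Crystal system, one of `"triclinic"`, `"monoclinic"`,
#'   `"orthorhombic"`, `"tetragonal"`, `"hexagonal"`, `"cubic"`.
#' @return An object of class `xtl_lattice`.
#' @export
lattice <- function(a, b, c, alpha = 90, beta = 90, gamma = 90,
                    system = "triclinic") {
  system <- match.arg(system, c("triclinic", "monoclinic", "orthorhombic",
                                "tetragonal", "hexagonal", "cubic"))
  lat <- structure(list(a = a, b = b, c = c,
                        alpha = alpha, beta = beta, gamma = gamma,
                        system = system),
                   class = "xtl_lattice")
  validate_lattice(lat)
  lat
}

validate_lattice <- function(lat) {
  len <- c(lat$a, lat$b, lat$c)
  ang <- c(lat$alpha, lat$beta, lat$gamma)
  if (any(!is.finite(c(len, ang))) || any(len <= 0))
    stop("invalid lattice: non-positive or non-finite cell length",
         call. = FALSE)
  if (any(ang <= 0) || any(ang >= 180))
    stop("invalid lattice: cell angles must lie in (0, 180) degrees",
         call. = FALSE)
  if (cell_volume(lat) <= 1e-6)
    stop("invalid lattice: degenerate cell (volume <= 1e-6 A^3)",
         call. = FALSE)
  invisible(lat)
}

#' @export
print.xtl_lattice <- function(x, ...) {
  cat(sprintf("<lattice %s: a=%.4f b=%.4f c=%.4f alpha=%.3f beta=%.3f gamma=%.3f>\n",
              x$system, x$a, x$b, x$c, x$alpha, x$beta, x$gamma))
  invisible(x)
}

# Names of the free cell parameters for each crystal system.
free_cell_params <- function(system) {
  switch(system,
         triclinic    = c("a", "b", "c", "alpha", "beta", "gamma"),
         monoclinic   = c("a", "b", "c", "beta"),
         orthorhombic = c("a", "b", "c"),
         tetragonal   = c("a", "c"),
         hexagonal    = c("a", "c"),
         cubic        = "a",
         stop("unknown crystal system: ", system))
}

#' Number of free cell parameters of a lattice
#'
#' @param lat An `xtl_lattice`.
#' @return Integer count n_x of independent cell parameters.
#' @export
n_free_cell <- function(lat) length(free_cell_params(lat$system))

# Rebuild a full lattice from the free parameters, regenerating the
# constrained entries (never read from the variable vector).
lattice_from_free <- function(system, vals) {
  nm <- free_cell_params(system)
  stopifnot(length(vals) == length(nm))
  v <- stats::setNames(as.list(vals), nm)
  full <- switch(system,
    triclinic    = list(v$a, v$b, v$c, v$alpha, v$beta, v$gamma),
    monoclinic   = list(v$a, v$b, v$c, 90, v$beta, 90),
    orthorhombic = list(v$a, v$b, v$c, 90, 90, 90),
    tetragonal   = list(v$a, v$a, v$c, 90, 90, 90),
    hexagonal    = list(v$a, v$a, v$c, 90, 90, 120),
    cubic        = list(v$a, v$a, v$a, 90, 90, 90))
  lattice(full[[1]], full[[2]], full[[3]], full[[4]], full[[5]], full[[6]],
          system = system)
}

free_cell_values <- function(lat) {
  unlist(lat[free_cell_params(lat$system)], use.names = TRUE)
}

#' Fractional-to-Cartesian cell matrix
#'
#' Returns the 3x3 matrix `M` whose columns are the lattice vectors in a
#' Cartesian frame with `a` along x and `b` in the x-y plane, so that
#' Cartesian coordinates are `M %*% f` for fractional `f`.
#' `det(M)` equals the cell volume.
#'
#' @param lat An `xtl_lattice`.
#' @return A 3x3 numeric matrix (Angstrom).
#' @export
cell_matrix <- function(lat) {
  validate_lattice(lat)
  d <- pi / 180
  ca <- cos(lat$alpha * d); cb <- cos(lat$beta * d)
  cg <- cos(lat$gamma * d); sg <- sin(lat$gamma * d)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) stop("invalid lattice: impossible angle combination",
                    call. = FALSE)
  v <- sqrt(v2)
  matrix(c(lat$a, 0, 0,
           lat$b * cg, lat$b * sg, 0,
           lat$c * cb, lat$c * (ca - cb * cg) / sg, lat$c * v / sg),
         nrow = 3, ncol = 3)
}

#' Cell volume in cubic Angstrom
#' @param lat An `xtl_lattice`.
#' @return Scalar volume.
#' @export
cell_volume <- function(lat) {
  d <- pi / 180
  ca <- cos(lat$alpha * d); cb <- cos(lat$beta * d); cg <- cos(lat$gamma * d)
  v2 <- 1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg
  if (v2 <= 0) return(0)
  lat$a * lat$b * lat$c * sqrt(v2)
}

# Analytic derivatives of cell_matrix with respect to the six full cell
# parameters (lengths per Angstrom, angles per DEGREE). Returns a list of
# six 3x3 matrices named a, b, c, alpha, beta, gamma.
cell_matrix_grad <- function(lat) {
  d <- pi / 180
  al <- lat$alpha * d; be <- lat$beta * d; ga <- lat$gamma * d
  ca <- cos(al); sa <- sin(al)
  cb <- cos(be); sb <- sin(be)
  cg <- cos(ga); sg <- sin(ga)
  v <- sqrt(1 - ca^2 - cb^2 - cg^2 + 2 * ca * cb * cg)
  a <- lat$a; b <- lat$b; cc <- lat$c

  dv_dal <- sa * (ca - cb * cg) / v
  dv_dbe <- sb * (cb - ca * cg) / v
  dv_dga <- sg * (cg - ca * cb) / v

  m0 <- function() matrix(0, 3, 3)
  dMa <- m0(); dMa[1, 1] <- 1
  dMb <- m0(); dMb[1, 2] <- cg; dMb[2, 2] <- sg
  dMc <- m0(); dMc[1, 3] <- cb; dMc[2, 3] <- (ca - cb * cg) / sg
  dMc[3, 3] <- v / sg

  dMal <- m0()
  dMal[2, 3] <- cc * (-sa) / sg
  dMal[3, 3] <- cc * dv_dal / sg
  dMal <- dMal * d

  dMbe <- m0()
  dMbe[1, 3] <- -cc * sb
  dMbe[2, 3] <- cc * sb * cg / sg
  dMbe[3, 3] <- cc * dv_dbe / sg
  dMbe <- dMbe * d

  dMga <- m0()
  dMga[1, 2] <- -b * sg
  dMga[2, 2] <- b * cg
  dMga[2, 3] <- cc * (cb * sg^2 - (ca - cb * cg) * cg) / sg^2
  dMga[3, 3] <- cc * (dv_dga * sg - v * cg) / sg^2
  dMga <- dMga * d

  list(a = dMa, b = dMb, c = dMc, alpha = dMal, beta = dMbe, gamma = dMga)
}
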