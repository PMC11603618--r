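#' Rigid molecule
#'
#' A rigid molecule of the asymmetric unit: atoms carry an element, an
#' atom-type label, a point charge (e) and local Cartesian coordinates
#' (Angstrom) relative to the molecular center (the unweighted centroid,
#' which must be the zero vector). The placement in the cell is given by
#' a fractional center and an orientation stored as a unit quaternion;
#' an incremental axis-angle rotation (`rot_inc`) about the stored
#' orientation carries the optimizer's orientation degrees of freedom.
#'
#' @param element Character vector of element symbols.
#' @param type Character vector of atom-type labels.
#' @param local n x 3 matrix of local Cartesian coordinates (Angstrom),
#'   centroid zero.
#' @param charge Numeric vector of point charges (e).
#' @param center Length-3 fractional center of mass.
#' @param quat Unit quaternion (w, x, y, z); default identity.
#' @return An object of class `xtl_molecule`.
#' @export
rigid_molecule <- function(element, type, local, charge,
                           center = c(0, 0, 0), quat = c(1, 0, 0, 0)) {
  local <- matrix(as.numeric(local), ncol = 3)
  n <- nrow(local)
  stopifnot(length(element) == n, length(type) == n, length(charge) == n)
  cen <- colMeans(local)
  if (sqrt(sum(cen^2)) > 1e-10)
    stop("molecule local coordinates must have zero centroid (got |c| = ",
         format(sqrt(sum(cen^2))), " A)", call. = FALSE)
  if (abs(sum(quat^2) - 1) > 1e-12)
    stop("orientation quaternion must have unit norm", call. = FALSE)
  structure(list(element = as.character(element), type = as.character(type),
                 local = local, charge = as.numeric(charge),
                 center = as.numeric(center) %% 1,
                 quat = as.numeric(quat), rot_inc = c(0, 0, 0)),
            class = "xtl_molecule")
}

#' @export
print.xtl_molecule <- function(x, ...) {
  cat(sprintf("<rigid molecule: %d atoms (%s), q_net=%+.3f e>\n",
              nrow(x$local), paste(x$element, collapse = ""),
              sum(x$charge)))
  invisible(x)
}

n_atoms <- function(mol) nrow(mol$local)

# Effective rotation including the incremental axis-angle about the base
# orientation: R_eff = exp([rot_inc]_x) R(quat).
mol_rotation <- function(mol) expmap(mol$rot_inc) %*% quat_to_mat(mol$quat)

# Fold the incremental rotation into the base quaternion and reset it.
rebase_molecule <- function(mol) {
  if (any(mol$rot_inc != 0)) {
    mol$quat <- quat_normalize(
      quat_multiply(axis_angle_to_quat(mol$rot_inc), mol$quat))
    mol$rot_inc <- c(0, 0, 0)
  }
  mol
}

#' Crystal structure
#'
#' A periodic crystal: lattice, space-group operators, and the rigid
#' molecules of the asymmetric unit. `Z = Z' * |ops|` molecules per cell.
#'
#' @param lattice An `xtl_lattice`.
#' @param ops List of `xtl_symop`; the first must be the identity.
#' @param molecules List of `xtl_molecule` (the asymmetric unit, length Z').
#' @param label Structure identifier.
#' @param check Validate invariants (charge neutrality, atom overlap).
#' @return An object of class `xtl_crystal`.
#' @export
crystal <- function(lattice, ops, molecules, label = "crystal", check = TRUE) {
  stopifnot(inherits(lattice, "xtl_lattice"), length(ops) >= 1,
            length(molecules) >= 1)
  if (!is_identity_op(ops[[1]]))
    stop("the first symmetry operator must be the identity", call. = FALSE)
  cr <- structure(list(lattice = lattice, ops = ops, molecules = molecules,
                       label = label),
                  class = "xtl_crystal")
  if (check) validate_crystal(cr)
  cr
}

#' @export
print.xtl_crystal <- function(x, ...) {
  cat(sprintf("<crystal '%s': %s, %d ops, Z'=%d, Z=%d, %d atoms/cell>\n",
              x$label, x$lattice$system, length(x$ops),
              length(x$molecules), crystal_Z(x),
              sum(vapply(x$molecules, n_atoms, 0L)) * length(x$ops)))
  invisible(x)
}

#' Molecules per unit cell
#' @param cr An `xtl_crystal`.
#' @return Integer Z.
#' @export
crystal_Z <- function(cr) length(cr$ops) * length(cr$molecules)

validate_crystal <- function(cr) {
  qtot <- sum(vapply(cr$molecules, function(m) sum(m$charge), 0)) *
    length(cr$ops)
  if (abs(qtot) > 1e-8)
    stop(sprintf("unit cell not charge neutral (net %.3e e)", qtot),
         call. = FALSE)
  st <- crystal_sites(cr, expand = TRUE)
  d <- min_site_distance(st$cart, cell_matrix(cr$lattice))
  if (d < 0.5)
    stop(sprintf("atom overlap in unit cell: minimum distance %.3f A", d),
         call. = FALSE)
  invisible(cr)
}

# Minimum distance between distinct sites including nearest periodic images.
min_site_distance <- function(cart, M) {
  n <- nrow(cart)
  if (n < 2) return(Inf)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  dmin <- Inf
  for (s in seq_len(nrow(shifts))) {
    off <- M %*% as.numeric(shifts[s, ])
    for (i in seq_len(n - 1)) {
      dd <- sweep(cart[(i + 1):n, , drop = FALSE], 2,
                  cart[i, ] - as.numeric(off))
      dmin <- min(dmin, sqrt(min(rowSums(dd^2))))
    }
  }
  dmin
}

#' All atom sites in the unit cell
#'
#' Expands the asymmetric unit through the symmetry operators. With
#' `expand = FALSE` only the asymmetric unit (identity operator) is
#' returned. Fractional coordinates of expanded sites are wrapped to
#' `[0, 1)`; the Cartesian coordinates correspond to the wrapped
#' fractional positions when `wrap = TRUE`.
#'
#' @param cr An `xtl_crystal`.
#' @param expand Apply all symmetry operators.
#' @param wrap Wrap fractional coordinates to `[0, 1)`.
#' @return List with `frac`, `cart` (n x 3 matrices), and per-site
#'   vectors `element`, `type`, `charge`, `mol` (asymmetric-molecule
#'   index), `op` (operator index), `instance` (unique molecule-image id).
#' @export
crystal_sites <- function(cr, expand = TRUE, wrap = expand) {
  M <- cell_matrix(cr$lattice)
  Minv <- solve(M)
  ops <- if (expand) cr$ops else cr$ops[1]
  nmol <- length(cr$molecules)
  nk <- length(ops) * nmol
  out_f <- vector("list", nk)
  el <- ty <- vector("list", nk); ch <- mo <- op_i <- vector("list", nk)
  idx <- 0L
  for (k in seq_along(ops)) {
    for (m in seq_len(nmol)) {
      mol <- cr$molecules[[m]]
      R <- mol_rotation(mol)
      v <- mol$local %*% t(R)                    # n x 3 Cartesian offsets
      fmol <- sweep(v %*% t(Minv), 2, mol$center, "+")  # n x 3 fractional
      f <- apply_symop(ops[[k]], fmol)
      idx <- idx + 1L
      out_f[[idx]] <- f
      el[[idx]] <- mol$element; ty[[idx]] <- mol$type
      ch[[idx]] <- mol$charge
      mo[[idx]] <- rep.int(m, nrow(f)); op_i[[idx]] <- rep.int(k, nrow(f))
    }
  }
  frac <- do.call(rbind, out_f)
  if (wrap) frac <- frac %% 1
  cart <- frac %*% t(M)
  nat <- vapply(out_f, nrow, 0L)
  list(frac = frac, cart = cart, element = unlist(el), type = unlist(ty),
       charge = unlist(ch), mol = unlist(mo), op = unlist(op_i),
       instance = rep.int(seq_len(nk), nat))
}

#' Expand symmetry to all unit-cell sites
#'
#' Wrapper over [crystal_sites()] that additionally rejects special
#' positions: two symmetry images of the same atom closer than 1e-4 in
#' fractional space cannot be represented by the rigid whole-molecule
#' model.
#'
#' @param cr An `xtl_crystal`.
#' @return See [crystal_sites()].
#' @export
expand_symmetry <- function(cr) {
  st <- crystal_sites(cr, expand = TRUE)
  n <- nrow(st$frac)
  if (length(cr$ops) > 1) {
    for (i in seq_len(n - 1)) {
      ji <- (i + 1):n
      same_atom <- st$mol[ji] == st$mol[i] & st$op[ji] != st$op[i]
      if (!any(same_atom)) next
      d <- st$frac[ji[same_atom], , drop = FALSE]
      d <- sweep(d, 2, st$frac[i, ])
      d <- d - round(d)
      if (min(sqrt(rowSums(d^2))) < 1e-4)
        stop("special position: symmetry images of an atom coincide; ",
             "the rigid whole-molecule model cannot represent this",
             call. = FALSE)
    }
  }
  st
}

## ---- Rigid-variable vector Omega ------------------------------------

#' Extract the rigid-body variable vector
#'
#' The variable vector concatenates the free cell parameters (lengths in
#' Angstrom, angles in degrees), the fractional centers of all asymmetric
#' molecules, and the incremental axis-angle orientation parameters
#' (radians) of all asymmetric molecules, in that order. Its length is
#' `n_x + 6 Z'`.
#'
#' @param cr An `xtl_crystal`.
#' @return Named numeric vector.
#' @export
omega_extract <- function(cr) {
  cell <- free_cell_values(cr$lattice)
  names(cell) <- paste0("cell.", free_cell_params(cr$lattice$system))
  cen <- unlist(lapply(seq_along(cr$molecules), function(m)
    stats::setNames(cr$molecules[[m]]$center,
                    paste0("mol", m, ".c", 1:3))))
  rot <- unlist(lapply(seq_along(cr$molecules), function(m)
    stats::setNames(cr$molecules[[m]]$rot_inc,
                    paste0("mol", m, ".r", 1:3))))
  c(cell, cen, rot)
}

#' Apply a rigid-body variable vector
#'
#' Returns the crystal at the geometry described by `omega` (see
#' [omega_extract()] for the ordering). Constrained cell parameters are
#' regenerated from the crystal system, never read from `omega`.
#' Orientation entries are incremental axis-angle rotations about each
#' molecule's stored base orientation.
#'
#' @param cr An `xtl_crystal`.
#' @param omega Numeric vector of length `n_x + 6 Z'`.
#' @param check Validate the resulting lattice.
#' @return An `xtl_crystal`.
#' @export
omega_apply <- function(cr, omega, check = TRUE) {
  nx <- n_free_cell(cr$lattice)
  nm <- length(cr$molecules)
  if (length(omega) != nx + 6 * nm)
    stop(sprintf("omega has length %d, expected %d", length(omega),
                 nx + 6 * nm), call. = FALSE)
  cr$lattice <- lattice_from_free(cr$lattice$system, omega[seq_len(nx)])
  for (m in seq_len(nm)) {
    cr$molecules[[m]]$center <- omega[nx + 3 * (m - 1) + 1:3]
    cr$molecules[[m]]$rot_inc <- omega[nx + 3 * nm + 3 * (m - 1) + 1:3]
  }
  if (check) validate_lattice(cr$lattice)
  cr
}

#' Set crystal geometry (rebased)
#'
#' Applies `omega` and folds the orientation increments into the stored
#' quaternions, so that `omega_extract()` of the result has zero
#' orientation entries and the geometry is unchanged.
#'
#' @inheritParams omega_apply
#' @return An `xtl_crystal` at the new geometry with rebased orientations.
#' @export
set_geometry <- function(cr, omega, check = TRUE) {
  cr <- omega_apply(cr, omega, check = check)
  cr$molecules <- lapply(cr$molecules, rebase_molecule)
  cr
}

omega_length <- function(cr) n_free_cell(cr$lattice) + 6 * length(cr$molecules)

# Scale factors putting omega components on comparable (Angstrom/radian)
# footing: lengths 1, angles deg->rad, fractions and rotations 1.
omega_scales <- function(cr) {
  nm_cell <- free_cell_params(cr$lattice$system)
  s_cell <- ifelse(nm_cell %in% c("alpha", "beta", "gamma"), pi / 180, 1)
  c(s_cell, rep(1, 6 * length(cr$molecules)))
}

## ---- Geometry Jacobians ---------------------------------------------

# Jacobians of the expanded (or asymmetric) site coordinates with respect
# to omega, evaluated at the crystal's current geometry (including any
# non-zero orientation increments, via the SO(3) left Jacobian).
#
# Returns list(frac, cart, Jf, Jx, M, dM) where Jf and Jx are arrays of
# dimension (n_sites, 3, n_omega) and dM is (3, 3, n_omega) with the cell
# blocks filled.
site_jacobians <- function(cr, expand = TRUE) {
  M <- cell_matrix(cr$lattice)
  Minv <- solve(M)
  dMfull <- cell_matrix_grad(cr$lattice)
  free_nm <- free_cell_params(cr$lattice$system)
  nx <- length(free_nm)
  nmol <- length(cr$molecules)
  nom <- nx + 6 * nmol
  ops <- if (expand) cr$ops else cr$ops[1]

  # dM/d(free param): chain through constrained parameters (e.g. cubic a
  # drives b and c too).
  dM <- array(0, c(3, 3, nom))
  for (i in seq_len(nx)) {
    dM[, , i] <- dM_free(cr$lattice$system, free_nm[i], dMfull)
  }

  nat <- vapply(cr$molecules, n_atoms, 0L)
  ntot <- sum(nat) * length(ops)
  Jf <- array(0, c(ntot, 3, nom))
  frac <- matrix(0, ntot, 3)
  typev <- character(ntot); chargev <- numeric(ntot)
  instv <- integer(ntot)
  inst <- 0L

  row0 <- 0L
  for (k in seq_along(ops)) {
    S <- ops[[k]]$R
    for (m in seq_len(nmol)) {
      mol <- cr$molecules[[m]]
      n <- nat[m]
      R <- mol_rotation(mol)
      Jl <- so3_left_jacobian(mol$rot_inc)
      v <- mol$local %*% t(R)                     # n x 3
      fmol <- sweep(v %*% t(Minv), 2, mol$center, "+")
      f <- apply_symop(ops[[k]], fmol)
      rows <- row0 + seq_len(n)
      # compact the instance: integer shift keeping the molecule whole
      f <- sweep(f, 2, floor(colMeans(f)))
      frac[rows, ] <- f
      inst <- inst + 1L
      typev[rows] <- mol$type
      chargev[rows] <- mol$charge
      instv[rows] <- inst
      # centers
      for (j in 1:3) {
        Jf[rows, , nx + 3 * (m - 1) + j] <-
          matrix(S[, j], n, 3, byrow = TRUE)
      }
      # orientations: d v_i / d eps_j = [Jl e_j]_x v_i
      SMinv <- S %*% Minv
      for (j in 1:3) {
        W <- skew(Jl[, j])
        dv <- v %*% t(W)                          # ([Jl e_j]_x v_i) rows
        Jf[rows, , nx + 3 * nmol + 3 * (m - 1) + j] <- dv %*% t(SMinv)
      }
      # cell parameters: d f = S dMinv v = -S Minv dM Minv v
      for (i in seq_len(nx)) {
        dMi <- dM[, , i]
        Jf[rows, , i] <- -(v %*% t(Minv)) %*% t(dMi) %*% t(Minv) %*% t(S)
      }
      row0 <- row0 + n
    }
  }
  # Cartesian: x = M f, dx = dM f + M df
  Jx <- array(0, c(ntot, 3, nom))
  for (o in seq_len(nom)) {
    Jx[, , o] <- Jf[, , o] %*% t(M)
    if (o <= nx) Jx[, , o] <- Jx[, , o] + frac %*% t(dM[, , o])
  }
  list(frac = frac, cart = frac %*% t(M), Jf = Jf, Jx = Jx, M = M, dM = dM,
       type = typev, charge = chargev, instance = instv)
}

# dM/d(free parameter), folding in system constraints (tetragonal b=a,
# hexagonal b=a, cubic b=c=a).
dM_free <- function(system, name, dMfull) {
  D <- dMfull[[name]]
  if (name == "a") {
    if (system %in% c("tetragonal", "hexagonal")) D <- D + dMfull$b
    if (system == "cubic") D <- D + dMfull$b + dMfull$c
  }
  D
}

## ---- Structural null modes ------------------------------------------

# Directions in omega space along which the lattice energy is exactly
# invariant: global fractional translations fixed by every operator's
# rotation part, and per-molecule rotations that map the (point or
# linear) molecule onto itself. Returns an n_omega x d matrix (possibly
# zero columns), orthonormal.
omega_null_modes <- function(cr) {
  nx <- n_free_cell(cr$lattice)
  nmol <- length(cr$molecules)
  nom <- nx + 6 * nmol
  cols <- list()
  # translations: intersection of ker(S_k - I)
  Kmat <- do.call(rbind, lapply(cr$ops, function(op) op$R - diag(3)))
  nsp <- nullspace(Kmat)
  if (ncol(nsp) > 0) {
    for (j in seq_len(ncol(nsp))) {
      v <- numeric(nom)
      for (m in seq_len(nmol)) v[nx + 3 * (m - 1) + 1:3] <- nsp[, j]
      cols[[length(cols) + 1]] <- v
    }
  }
  # rotational nulls: rank-deficient local coordinates
  for (m in seq_len(nmol)) {
    mol <- cr$molecules[[m]]
    sv <- svd(mol$local)
    rnk <- sum(sv$d > 1e-8 * max(sv$d, 1e-12))
    if (rnk >= 2) next
    R <- mol_rotation(mol)
    Jl <- so3_left_jacobian(mol$rot_inc)
    if (rnk == 0) {
      axes <- diag(3)
    } else {
      u <- R %*% sv$v[, 1]   # molecular axis in the Cartesian frame
      axes <- matrix(solve(Jl, u), ncol = 1)
    }
    for (j in seq_len(ncol(axes))) {
      v <- numeric(nom)
      v[nx + 3 * nmol + 3 * (m - 1) + 1:3] <- axes[, j]
      cols[[length(cols) + 1]] <- v
    }
  }
  if (length(cols) == 0) return(matrix(0, nom, 0))
  N <- do.call(cbind, cols)
  qr.Q(qr(N))[, seq_len(qr(N)$rank), drop = FALSE]
}

nullspace <- function(A) {
  s <- svd(A, nv = ncol(A))
  tol <- max(dim(A)) * max(s$d, 0) * 1e-12
  keep <- s$d <= tol
  if (length(s$d) < ncol(A))
    keep <- c(keep, rep(TRUE, ncol(A) - length(s$d)))
  s$v[, keep, drop = FALSE]
}

# Orthonormal basis of the complement of the null modes (the effective
# optimization subspace).
omega_free_basis <- function(cr) {
  N <- omega_null_modes(cr)
  nom <- omega_length(cr)
  if (ncol(N) == 0) return(diag(nom))
  P <- diag(nom) - N %*% t(N)
  e <- eigen(P, symmetric = TRUE)
  e$vectors[, e$values > 0.5, drop = FALSE]
}
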