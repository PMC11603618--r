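#' Envelope derivative of the optimal intermolecular energy
#'
#' At a converged lattice minimum the total derivative of `U_inter(
#' Omega*(p); p)` with respect to a repulsion/dispersion parameter
#' equals the partial derivative of the repulsion/dispersion energy
#' evaluated at the optimal geometry: the stationarity of the inner
#' minimization cancels the indirect dependence through `Omega*`. No
#' re-minimization is required.
#'
#' @param lm An `xtl_lmresult` with `status == "converged"`.
#' @param pots An `xtl_potentials`.
#' @param eopts [energy_options()].
#' @return Named vector `dU*/dp` over the free parameters.
#' @export
d_uinter_dp <- function(lm, pots, eopts = energy_options()) {
  if (lm$status != "converged")
    stop("stale derivative: lattice minimization did not converge",
         call. = FALSE)
  repdisp_energy(lm$crystal, pots, eopts, want_dp = TRUE)$dU_dp
}

#' Implicit derivative of the optimal geometry
#'
#' Differentiating the stationarity condition of the lattice
#' minimization gives the linear system
#' `H dOmega*/dp_j = - d2U_rd/dOmega dp_j` for each free parameter. The
#' system is solved in the subspace orthogonal to the structural null
#' modes (where `H` must be positive definite); along null modes the
#' minimizer position is arbitrary and the derivative is fixed to zero.
#'
#' @param H Hessian of `U_inter` w.r.t. Omega at the minimum.
#' @param cross Matrix of cross derivatives `d2U_rd/dOmega dp`
#'   (n_omega x n_free).
#' @param P Orthonormal basis of the non-null subspace (default: full
#'   space).
#' @return List with `dOmega_dp` (n_omega x n_free) and
#'   `solve_residual` (max relative residual of the linear solves).
#' @export
d_omega_dp <- function(H, cross, P = diag(nrow(H))) {
  Ht <- crossprod(P, H %*% P)
  Ht <- (Ht + t(Ht)) / 2
  ev <- eigen(Ht, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) <= 0)
    stop("sensitivity unavailable: Hessian not positive definite ",
         "in the reduced space (not a strict minimum)", call. = FALSE)
  b <- crossprod(P, cross)
  y <- solve(Ht, -b)
  x <- P %*% y
  resid <- Ht %*% y + b
  bn <- sqrt(colSums(b^2))
  rn <- sqrt(colSums(resid^2))
  rel <- ifelse(bn > 0, rn / bn, 0)
  list(dOmega_dp = x, solve_residual = max(c(rel, 0)))
}

# Full sensitivity block of one converged structure: dU*/dp, dOmega*/dp,
# the residual Jacobian rows and dMF/dp. All quantities are evaluated at
# the already-available optimal geometry; no lattice minimizations are
# performed here.
structure_sensitivity <- function(lm, entry, pots,
                                  eopts = energy_options(),
                                  denominator = "abs") {
  cr <- lm$crystal
  rep_ <- inter_energy(cr, pots, eopts, want = c("dp", "cross"))
  dU_dp <- rep_$dU_dp
  np <- length(dU_dp)
  dom <- d_omega_dp(lm$hess, rep_$cross, lm$free_basis)
  dOmega_dp <- dom$dOmega_dp

  nx <- n_free_cell(cr$lattice)
  ref_cell <- free_cell_values(entry$crystal$lattice)
  # cell residual rows
  Jcell <- dOmega_dp[seq_len(nx), , drop = FALSE] /
    (ref_cell * sqrt(nx))
  # coordinate residual rows: chain through the asymmetric-unit
  # fractional positions
  jac <- site_jacobians(cr, expand = FALSE)
  nat <- nrow(jac$frac)
  nom <- omega_length(cr)
  ny <- 3 * nat - 3
  dY_dom <- matrix(0, ny, nom)
  for (a in 2:nat) {
    for (ccomp in 1:3) {
      dY_dom[3 * (a - 2) + ccomp, ] <-
        jac$Jf[a, ccomp, ] - jac$Jf[1, ccomp, ]
    }
  }
  Jcoord <- (dY_dom %*% dOmega_dp) / sqrt(ny)
  # energy residual row
  den <- if (denominator == "abs") abs(entry$u_ref) else entry$u_ref
  Jen <- matrix(dU_dp / den, 1, np)

  jacobian <- rbind(Jcell, Jcoord, Jen)
  wjac <- rbind(sqrt(entry$w_g) * Jcell, sqrt(entry$w_g) * Jcoord,
                sqrt(entry$w_e) * Jen)

  geo <- structure_residuals(cr, entry, denominator)
  E <- energy_residual(lm$U_star, entry$u_ref, denominator)
  res <- c(geo$X, geo$Y, E)
  w <- c(rep(entry$w_g, length(geo$X) + length(geo$Y)), entry$w_e)
  dMF_dp <- as.numeric(crossprod(jacobian, w * res))

  list(dU_dp = dU_dp, dOmega_dp = dOmega_dp,
       solve_residual = dom$solve_residual,
       jacobian = jacobian, wjac = wjac,
       dMF_dp = stats::setNames(dMF_dp, names(dU_dp)))
}

#' Analytic gradient of the total merit function
#'
#' Sums the per-structure `dMF/dp` blocks over a training set, using
#' each structure's converged lattice-minimization result. Costs zero
#' additional lattice minimizations beyond the function evaluation's.
#'
#' @param tm Result of [total_merit()] (must be valid).
#' @param entries The training entries used for `tm`.
#' @param pots An `xtl_potentials`.
#' @param eopts [energy_options()].
#' @param denominator Energy-residual convention.
#' @return Named vector `dTMF/dp`.
#' @export
total_merit_gradient <- function(tm, entries, pots,
                                 eopts = energy_options(),
                                 denominator = "abs") {
  if (!tm$valid) stop("cannot differentiate an invalid TMF", call. = FALSE)
  g <- NULL
  for (i in seq_along(entries)) {
    sens <- structure_sensitivity(tm$results[[i]]$lm, entries[[i]], pots,
                                  eopts, denominator)
    g <- if (is.null(g)) sens$dMF_dp else g + sens$dMF_dp
  }
  g
}
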