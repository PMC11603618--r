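#' Lattice minimization options
#'
#' @param stage1_tol Infinity-norm gradient tolerance (scaled variables)
#'   handing over from the quasi-Newton stage to the Newton refinement.
#' @param stage2_tol Final infinity-norm gradient tolerance on scaled
#'   variables. The tight default supports iterating around the
#'   minimization in the parameter estimation.
#' @param maxit1,maxit2 Iteration caps for the two stages.
#' @param saddle_tol Most-negative allowed Hessian eigenvalue (scaled)
#'   at a converged point; below this the result is classified a saddle.
#' @param min_contact Collapse guard (Angstrom): trial geometries with
#'   an intermolecular contact below this are rejected by the line
#'   searches, insulating the minimization from the unphysical
#'   short-range turnover of the Buckingham potential. A minimization
#'   that terminates against this floor is reported as
#'   `overlap_failure`.
#' @param energy [energy_options()].
#' @return List of settings.
#' @export
latmin_options <- function(stage1_tol = 1e-5, stage2_tol = 1e-9,
                           maxit1 = 500, maxit2 = 100,
                           saddle_tol = -1e-8, min_contact = 1.0,
                           energy = energy_options()) {
  list(stage1_tol = stage1_tol, stage2_tol = stage2_tol,
       maxit1 = maxit1, maxit2 = maxit2, saddle_tol = saddle_tol,
       min_contact = min_contact, energy = energy)
}

# Package-level counter of lattice minimizations (used to demonstrate
# that analytic gradients add no minimizations).
.lm_counter <- new.env(parent = emptyenv())
.lm_counter$n <- 0L

#' Count / reset lattice-minimization invocations
#' @return `lm_call_count()` returns the number of [minimize_lattice()]
#'   calls since the last reset.
#' @export
lm_call_count <- function() .lm_counter$n

#' @rdname lm_call_count
#' @export
lm_call_reset <- function() { .lm_counter$n <- 0L; invisible(NULL) }

#' Minimize the intermolecular lattice energy over the rigid variables
#'
#' Two-stage local minimization of `U_inter` at fixed conformation and
#' fixed parameters: (1) L-BFGS quasi-Newton descent on scaled variables
#' to a loose gradient tolerance; (2) modified-Newton refinement with the
#' (eigenvalue-shifted) Hessian to a tight tolerance. Structural null
#' modes (global translations left free by the space group, rotations of
#' point-like or linear molecules) are projected out of the Newton step
#' and the curvature test. Saddle points and atomic-overlap collapses
#' are reported as failure statuses rather than errors.
#'
#' @param cr An `xtl_crystal` (with charges and atom types).
#' @param pots An `xtl_potentials`.
#' @param omega0 Optional starting variable vector (default: the
#'   crystal's current geometry).
#' @param opts [latmin_options()].
#' @return An object of class `xtl_lmresult`: list with `crystal` (the
#'   relaxed, rebased structure), `omega_star`, `U_star`, `U_elec`,
#'   `U_rd`, `status` (one of `"converged"`, `"saddle"`,
#'   `"not_converged"`, `"overlap_failure"`), `grad`, `grad_norm`
#'   (projected, scaled, infinity norm), `hess`, `free_basis`,
#'   `iterations`, `n_energy`.
#' @export
minimize_lattice <- function(cr, pots, omega0 = NULL,
                             opts = latmin_options()) {
  .lm_counter$n <- .lm_counter$n + 1L
  if (!is.null(omega0)) cr <- set_geometry(cr, omega0)
  s <- omega_scales(cr)
  eopts <- opts$energy
  nev <- 0L

  fail <- function(status, msg = NULL) {
    structure(list(crystal = cr, omega_star = omega_extract(cr),
                   U_star = NA_real_, U_elec = NA_real_, U_rd = NA_real_,
                   status = status, grad = NULL, grad_norm = NA_real_,
                   hess = NULL, free_basis = NULL,
                   iterations = c(stage1 = 0L, stage2 = 0L),
                   n_energy = nev, message = msg),
              class = "xtl_lmresult")
  }

  om0 <- omega_extract(cr)
  z0 <- om0 * s
  PEN <- 1e6   # rejection level for collapse-guarded trial geometries

  # Energy with collapse guard: geometries with an intermolecular
  # contact below min_contact (or any failure to evaluate) return a
  # large penalty so line searches back away from the unphysical
  # short-range well.
  guard_hits <- 0L
  fn <- function(z) {
    nev <<- nev + 1L
    out <- tryCatch({
      cr2 <- omega_apply(cr, z / s)
      rd <- repdisp_energy(cr2, pots, eopts)
      if (rd$minr < opts$min_contact) {
        guard_hits <<- guard_hits + 1L
        PEN + 1e3 * (opts$min_contact - rd$minr)
      } else rd$U + ewald_point_charge(cr2, eopts)$U
    }, error = function(e) { guard_hits <<- guard_hits + 1L; PEN + 1e3 })
    out
  }
  gr <- function(z) {
    g <- tryCatch(grad_at(cr, z / s, pots, eopts) / s,
                  error = function(e) NULL)
    if (is.null(g)) numeric(length(z)) else g
  }

  # ---- stage 1: quasi-Newton descent ---------------------------------
  # Warm starts already near a minimum skip straight to the Newton
  # refinement.
  g0 <- tryCatch(grad_at(cr, om0, pots, eopts) / s,
                 error = function(e) NULL)
  if (is.null(g0)) return(fail("overlap_failure", "gradient unavailable"))
  iter1 <- 0L
  if (max(abs(g0)) > 0.05) {
    st1 <- tryCatch(
      stats::optim(z0, fn, gr, method = "L-BFGS-B",
                   control = list(maxit = opts$maxit1, factr = 1e7,
                                  pgtol = opts$stage1_tol)),
      error = function(e) e)
    if (inherits(st1, "error"))
      return(fail("overlap_failure", conditionMessage(st1)))
    if (st1$value >= PEN)
      return(fail("overlap_failure", "minimization stuck in collapse guard"))
    cr <- set_geometry(cr, st1$par / s)
    iter1 <- st1$counts[1]
  }

  # ---- stage 2: modified Newton refinement ---------------------------
  iter2 <- 0L
  U <- NULL
  eval_guarded <- function(om_try) {
    tryCatch({
      cr2 <- omega_apply(cr, om_try)
      rd <- repdisp_energy(cr2, pots, eopts)
      if (rd$minr < opts$min_contact) {
        guard_hits <<- guard_hits + 1L
        Inf
      } else rd$U + ewald_point_charge(cr2, eopts)$U
    }, error = function(e) { guard_hits <<- guard_hits + 1L; Inf })
  }
  newton_thresh <- 0.05
  eig_cache <- NULL
  prev_gnorm <- Inf
  bad <- 0L
  for (it in seq_len(opts$maxit2)) {
    om <- omega_extract(cr)
    g <- tryCatch(grad_at(cr, om, pots, eopts),
                  xtl_overlap_error = function(e) e,
                  error = function(e) e)
    if (inherits(g, "condition"))
      return(fail("overlap_failure", conditionMessage(g)))
    P <- omega_free_basis(cr)
    gs <- g / s
    gproj <- crossprod(P, gs)
    gnorm <- max(abs(gproj))
    if (gnorm < opts$stage2_tol) break
    # divergence safeguard for the unconditioned Newton regime
    if (gnorm > prev_gnorm * 0.9) bad <- bad + 1L else bad <- 0L
    if (bad >= 4L) break
    prev_gnorm <- gnorm
    iter2 <- it
    # Hessian (recomputed unless already near the solution: the chart
    # drift of the orientation baseline is second order in the step)
    if (is.null(eig_cache) || gnorm >= 1e-4) {
      H <- energy_hessian(cr, pots, eopts)
      nev <- nev + 2L * length(om)
      Hs <- H / outer(s, s)
      Ht <- crossprod(P, Hs %*% P)
      eig_cache <- eigen((Ht + t(Ht)) / 2, symmetric = TRUE)
    }
    e <- eig_cache
    lam <- e$values
    tau <- max(1e-8, 1e-8 * max(abs(lam)))
    lam_sh <- pmax(lam, tau)
    dz <- -P %*% (e$vectors %*% (crossprod(e$vectors, gproj) / lam_sh))
    # cap the scaled step length
    dn <- sqrt(sum(dz^2))
    if (dn > 0.25) dz <- dz * (0.25 / dn)
    if (max(abs(gproj)) < newton_thresh) {
      # small-gradient regime: damped Newton on the gradient alone
      # (quadratic local convergence); an energy-decrease test here
      # would be defeated by the tiny cutoff-membership
      # discontinuities of the truncated lattice sums
      om_try <- om + as.numeric(dz) / s
      if (!is.finite(eval_guarded(om_try))) break
      nev <- nev + 1L
      cr <- set_geometry(cr, om_try)
      U <- NULL
    } else {
      if (is.null(U)) { U <- eval_guarded(om); nev <- nev + 1L }
      # Armijo backtracking on the (scaled-step) energy
      alpha <- 1; ok <- FALSE
      gd <- sum(gs * dz)
      for (ls in 1:30) {
        om_try <- om + alpha * as.numeric(dz) / s
        U_try <- eval_guarded(om_try)
        nev <- nev + 1L
        if (is.finite(U_try) && U_try <= U + 1e-4 * alpha * gd) {
          ok <- TRUE; break
        }
        alpha <- alpha / 2
      }
      if (!ok) {
        # energy noise can defeat Armijo even at moderate gradients;
        # fall back to the damped Newton step under the divergence
        # safeguard above
        om_try <- om + as.numeric(dz) / s
        if (!is.finite(eval_guarded(om_try))) break
        nev <- nev + 1L
      }
      cr <- set_geometry(cr, om_try)
      U <- NULL
    }
  }

  # ---- classification -------------------------------------------------
  om <- omega_extract(cr)
  cls <- tryCatch({
    g <- grad_at(cr, om, pots, eopts)
    rep_ <- inter_energy(cr, pots, eopts, want = "grad")
    rep_$hess <- energy_hessian(cr, pots, eopts, richardson = TRUE)
    list(g = g, rep_ = rep_)
  }, error = function(e) e)
  if (inherits(cls, "error"))
    return(fail("overlap_failure", conditionMessage(cls)))
  g <- cls$g; rep_ <- cls$rep_
  nev <- nev + 4L * length(om)
  P <- omega_free_basis(cr)
  gproj <- crossprod(P, g / s)
  gnorm <- max(abs(gproj))
  Ht <- crossprod(P, (rep_$hess / outer(s, s)) %*% P)
  lam <- eigen((Ht + t(Ht)) / 2, symmetric = TRUE, only.values = TRUE)$values
  status <- if (rep_$minr < opts$min_contact) "overlap_failure"
  else if (gnorm >= opts$stage2_tol) "not_converged"
  else if (min(lam) < opts$saddle_tol * max(1, max(abs(lam)))) "saddle"
  else "converged"
  # a stalled descent held back only by the collapse guard is a collapse
  if (status == "not_converged" && guard_hits > 0L) status <- "overlap_failure"

  structure(list(crystal = cr, omega_star = om, U_star = rep_$U_inter,
                 U_elec = rep_$U_elec, U_rd = rep_$U_rd,
                 status = status, grad = g, grad_norm = gnorm,
                 hess = rep_$hess, free_basis = P,
                 iterations = c(stage1 = iter1, stage2 = iter2),
                 n_energy = nev, message = NULL),
            class = "xtl_lmresult")
}

#' @export
print.xtl_lmresult <- function(x, ...) {
  cat(sprintf("<lattice minimization: status=%s U*=%.6f kJ/mol |grad|=%.2e>\n",
              x$status, x$U_star, x$grad_norm))
  invisible(x)
}
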