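#' Energy evaluation options
#'
#' @param cutoff Repulsion/dispersion atom-atom cutoff, Angstrom
#'   (default 15; no tail correction is applied).
#' @param taper Width (Angstrom) of the C2-smooth quintic switching
#'   region ending at the cutoff. A smooth cutoff keeps the energy,
#'   gradient and Hessian mutually consistent as atom pairs cross the
#'   cutoff; set 0 for a sharp truncation.
#' @param ewald_accuracy Target accuracy of the electrostatic sum,
#'   kJ/mol per molecule.
#' @param ewald_alpha Optional explicit Ewald splitting parameter
#'   (1/Angstrom); by default chosen from the cell volume. Real- and
#'   reciprocal-space cutoffs always adapt to alpha and the accuracy
#'   target, so the energy is invariant to alpha within the target.
#' @return A list of settings.
#' @export
energy_options <- function(cutoff = 15, taper = 2, ewald_accuracy = 1e-6,
                           ewald_alpha = NULL) {
  stopifnot(cutoff >= 8, taper >= 0, taper < cutoff)
  list(cutoff = cutoff, taper = taper, ewald_accuracy = ewald_accuracy,
       ewald_alpha = ewald_alpha)
}

ewald_settings <- function(lat, opts) {
  V <- cell_volume(lat)
  alpha <- if (!is.null(opts$ewald_alpha)) opts$ewald_alpha else
    (pi^3 / V^2)^(1 / 6) * 2
  # exp(-p) truncation level well below the accuracy target
  p <- max(25, -log(opts$ewald_accuracy * 1e-4))
  list(alpha = alpha, rcut = sqrt(p) / alpha, kcut = 2 * alpha * sqrt(p))
}

overlap_condition <- function(minr) {
  structure(class = c("xtl_overlap_error", "error", "condition"),
            list(message = sprintf(
                   "atomic overlap: interatomic distance %.3f A < 0.3 A",
                   minr),
                 call = NULL, minr = minr))
}

#' Repulsion/dispersion lattice energy
#'
#' Direct-space sum of the Buckingham potential over all unit-cell atom
#' pairs and periodic images within the cutoff, excluding intramolecular
#' pairs, normalized per mole of molecules (divided by Z).
#'
#' @param cr An `xtl_crystal` with atom types matching `pots$types`.
#' @param pots An `xtl_potentials`.
#' @param opts [energy_options()].
#' @param want_grad Compute the gradient w.r.t. the rigid variables.
#' @param want_dp Compute derivatives w.r.t. the free parameters (and,
#'   with `want_grad`, the Omega-parameter cross matrix).
#' @return List with `U` (kJ/mol), and when requested `grad`, `dU_dp`,
#'   `cross` (n_omega x n_free), `minr`.
#' @export
repdisp_energy <- function(cr, pots, opts = energy_options(),
                           want_grad = FALSE, want_dp = FALSE) {
  geo <- energy_geometry(cr, want_grad)
  typ <- match(geo$type, pots$types)
  if (anyNA(typ))
    stop("crystal contains atom types absent from the potential set: ",
         paste(unique(geo$type[is.na(typ)]), collapse = ", "), call. = FALSE)
  eff <- effective_params(pots)
  res <- repdisp_core(geo$cart, geo$M, as.integer(geo$instance),
                      as.integer(typ - 1L), eff$A, eff$B, eff$C,
                      opts$cutoff, opts$taper, crystal_Z(cr),
                      want_grad, want_dp, geo$Jx, geo$dM)
  if (isTRUE(res$overlap)) stop(overlap_condition(res$minr))
  out <- list(U = res$U, minr = res$minr)
  if (want_grad) out$grad <- as.numeric(res$grad)
  if (want_dp) {
    ch <- chain_to_free(pots, as.numeric(res$dU_dp),
                        if (want_grad) res$cross else NULL)
    out$dU_dp <- ch$dU
    if (want_grad) out$cross <- ch$cross
  }
  out
}

#' Point-charge Ewald electrostatic lattice energy
#'
#' Real-space, reciprocal-space, self and rigid intramolecular
#' correction terms, per mole of molecules, with tinfoil (conducting)
#' boundary conditions. The unit cell must be charge neutral.
#'
#' @inheritParams repdisp_energy
#' @return List with `U` (kJ/mol), component terms, and `grad` when
#'   requested.
#' @export
ewald_point_charge <- function(cr, opts = energy_options(),
                               want_grad = FALSE) {
  qtot <- sum(vapply(cr$molecules, function(m) sum(m$charge), 0)) *
    length(cr$ops)
  if (abs(qtot) > 1e-8)
    stop(sprintf("Ewald requires a neutral unit cell (net charge %.3e e)",
                 qtot), call. = FALSE)
  geo <- energy_geometry(cr, want_grad)
  ew <- ewald_settings(cr$lattice, opts)
  res <- ewald_core(geo$cart, geo$frac, geo$M, geo$charge,
                    as.integer(geo$instance), ew$alpha, ew$rcut, ew$kcut,
                    crystal_Z(cr), want_grad, geo$Jx, geo$Jf, geo$dM)
  out <- list(U = res$U, U_real = res$U_real, U_rec = res$U_rec,
              U_self = res$U_self, U_corr = res$U_corr)
  if (want_grad) out$grad <- as.numeric(res$grad)
  out
}

# Shared geometry assembly for the energy cores (unwrapped coordinates so
# every molecule instance stays contiguous).
energy_geometry <- function(cr, want_grad) {
  if (want_grad) {
    site_jacobians(cr, expand = TRUE)
  } else {
    st <- crystal_sites(cr, expand = TRUE, wrap = FALSE)
    M <- cell_matrix(cr$lattice)
    # compact each molecule instance by an integer lattice shift
    for (id in unique(st$instance)) {
      rows <- st$instance == id
      sh <- floor(colMeans(st$frac[rows, , drop = FALSE]))
      st$frac[rows, ] <- sweep(st$frac[rows, , drop = FALSE], 2, sh)
    }
    st$cart <- st$frac %*% t(M)
    list(frac = st$frac, cart = st$cart, M = M,
         Jf = array(0, c(nrow(st$frac), 3, 0)),
         Jx = array(0, c(nrow(st$frac), 3, 0)),
         dM = array(0, c(3, 3, 0)),
         type = st$type, charge = st$charge, instance = st$instance)
  }
}

#' Intermolecular lattice energy with derivatives
#'
#' `U_inter = U_elec + U_rd` per mole of molecules, with the requested
#' derivative blocks: the gradient and Hessian with respect to the
#' rigid-body variable vector, the derivatives of `U_rd` with respect to
#' the free potential parameters, and the Omega-parameter cross matrix.
#' The Hessian is obtained by central differencing of the analytic
#' gradient at fixed geometry (no lattice minimizations are involved)
#' and symmetrized.
#'
#' @param cr An `xtl_crystal` carrying charges and atom types.
#' @param pots An `xtl_potentials`.
#' @param opts [energy_options()].
#' @param want Character vector among `"grad"`, `"hess"`, `"dp"`,
#'   `"cross"`.
#' @return An object of class `xtl_energy_report`: list with `U_inter`,
#'   `U_elec`, `U_rd` and the requested blocks `grad`, `hess`, `dU_dp`,
#'   `cross`.
#' @export
inter_energy <- function(cr, pots, opts = energy_options(), want = "grad") {
  want_grad <- any(c("grad", "hess", "cross") %in% want)
  want_dp <- any(c("dp", "cross") %in% want)
  rd <- repdisp_energy(cr, pots, opts, want_grad = want_grad,
                       want_dp = want_dp)
  el <- ewald_point_charge(cr, opts, want_grad = want_grad)
  rep_ <- list(U_inter = rd$U + el$U, U_elec = el$U, U_rd = rd$U,
               minr = rd$minr)
  if (want_grad) rep_$grad <- rd$grad + el$grad
  if (want_dp) rep_$dU_dp <- rd$dU_dp
  if ("cross" %in% want) rep_$cross <- rd$cross
  if ("hess" %in% want) rep_$hess <- energy_hessian(cr, pots, opts)
  class(rep_) <- "xtl_energy_report"
  rep_
}

#' @export
print.xtl_energy_report <- function(x, ...) {
  cat(sprintf("<energy: U_inter=%.6f (U_elec=%.6f, U_rd=%.6f) kJ/mol>\n",
              x$U_inter, x$U_elec, x$U_rd))
  invisible(x)
}

# Central-difference Hessian of U_inter from the analytic gradient.
# Steps are scaled per component type; the result is symmetrized. With
# `richardson = TRUE` a two-step Richardson extrapolation removes the
# leading h^2 truncation term (used where the Hessian feeds the
# implicit-function sensitivities).
energy_hessian <- function(cr, pots, opts = energy_options(),
                           richardson = FALSE) {
  om0 <- omega_extract(cr)
  nom <- length(om0)
  s <- omega_scales(cr)
  col_fd <- function(i, h) {
    om <- om0; om[i] <- om0[i] + h
    gp <- grad_at(cr, om, pots, opts)
    om[i] <- om0[i] - h
    gm <- grad_at(cr, om, pots, opts)
    (gp - gm) / (2 * h)
  }
  H <- matrix(0, nom, nom)
  if (richardson) {
    h <- 2e-3 / s
    for (i in seq_len(nom))
      H[, i] <- (4 * col_fd(i, h[i] / 2) - col_fd(i, h[i])) / 3
  } else {
    h <- 1e-3 / s
    for (i in seq_len(nom)) H[, i] <- col_fd(i, h[i])
  }
  (H + t(H)) / 2
}

grad_at <- function(cr, omega, pots, opts) {
  cr2 <- omega_apply(cr, omega)
  rd <- repdisp_energy(cr2, pots, opts, want_grad = TRUE)
  el <- ewald_point_charge(cr2, opts, want_grad = TRUE)
  rd$grad + el$grad
}

energy_value_at <- function(cr, omega, pots, opts) {
  cr2 <- omega_apply(cr, omega)
  rd <- repdisp_energy(cr2, pots, opts)
  el <- ewald_point_charge(cr2, opts)
  rd$U + el$U
}
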