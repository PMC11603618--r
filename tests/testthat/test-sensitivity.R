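test_that("envelope derivative equals the parameter gradient at the optimum", {
  fix <- toy_fixture(2)
  e <- fix$entries[[1]]
  lm <- minimize_lattice(e$crystal, fix$pots, opts = fast_lm_opts())
  expect_equal(lm$status, "converged")
  denv <- d_uinter_dp(lm, fix$pots, fast_lm_opts()$energy)
  # definitional identity with the energy module's dU_rd/dp
  rd <- repdisp_energy(lm$crystal, fix$pots, fast_lm_opts()$energy,
                       want_dp = TRUE)
  expect_identical(unname(denv), unname(rd$dU_dp))

  # re-minimization finite differences over two decades of delta
  p0 <- get_params(fix$pots)
  j <- which.max(abs(denv))
  errs <- c()
  for (d_rel in c(1e-2, 1e-3, 1e-4)) {
    h <- d_rel * p0[j]
    pp <- p0; pp[j] <- p0[j] + h
    pm <- p0; pm[j] <- p0[j] - h
    lp <- minimize_lattice(lm$crystal, set_params(fix$pots, pp),
                           opts = fast_lm_opts())
    ln <- minimize_lattice(lm$crystal, set_params(fix$pots, pm),
                           opts = fast_lm_opts())
    fd <- (lp$U_star - ln$U_star) / (2 * h)
    errs <- c(errs, abs(denv[j] - fd) / abs(fd))
  }
  expect_true(all(errs < 1e-4))
  expect_lt(min(errs), 1e-6)

  # a non-converged minimization refuses to provide the derivative
  lm_bad <- lm; lm_bad$status <- "not_converged"
  expect_error(d_uinter_dp(lm_bad, fix$pots), "stale")
})

test_that("implicit geometry derivatives solve the optimality system", {
  fix <- toy_fixture(2)
  e <- fix$entries[[1]]
  opts <- fast_lm_opts()
  lm <- minimize_lattice(e$crystal, fix$pots, opts = opts)
  sens <- crystalfit:::structure_sensitivity(lm, e, fix$pots, opts$energy)
  expect_lt(sens$solve_residual, 1e-8)
  expect_true(all(is.finite(sens$dOmega_dp)))

  # columns match re-minimization finite differences
  p0 <- get_params(fix$pots)
  for (j in c(1, 4)) {
    h <- 3e-4 * p0[j]
    pp <- p0; pp[j] <- p0[j] + h
    pm <- p0; pm[j] <- p0[j] - h
    lp <- minimize_lattice(lm$crystal, set_params(fix$pots, pp), opts = opts)
    ln <- minimize_lattice(lm$crystal, set_params(fix$pots, pm), opts = opts)
    fd <- (omega_extract(lp$crystal) - omega_extract(ln$crystal)) / (2 * h)
    an <- sens$dOmega_dp[, j]
    # compare translation/cell components (orientation increments are
    # rebased to zero in the extracted vectors)
    rot <- grepl("\\.r[1-3]$", names(fd))
    expect_lt(max(abs(an[!rot] - fd[!rot])) / max(abs(fd[!rot])), 1e-4)
  }

  # an absent atom type has an exactly zero sensitivity column
  free <- array(FALSE, c(3, 3, 3)); free[, , 1] <- TRUE
  pots3 <- potential_set(c("X", "Y", "Z"),
                         A = matrix(c(fix$pots$A[1, 1], fix$pots$A[1, 2], 2e4,
                                      fix$pots$A[1, 2], fix$pots$A[2, 2], 2e4,
                                      2e4, 2e4, 2e4), 3),
                         B = matrix(3.6, 3, 3), C = matrix(0, 3, 3),
                         free = free)
  rep3 <- inter_energy(lm$crystal, pots3, opts$energy, want = c("dp", "cross"))
  zc <- grepl("Z", names(rep3$dU_dp))
  expect_true(all(rep3$cross[, zc] == 0))

  # indefinite Hessian is refused
  Hneg <- -diag(nrow(lm$hess))
  expect_error(d_omega_dp(Hneg, rep3$cross), "positive definite")
})

test_that("dTMF/dp matches end-to-end finite differences at zero LM cost", {
  fix <- toy_fixture(2)
  opts <- fast_lm_opts()
  p0 <- get_params(fix$pots) * c(1.08, 0.95, 1.03, 0.92, 1.05, 0.97)
  pots0 <- set_params(fix$pots, p0)

  lm_call_reset()
  tm <- total_merit(fix$entries, pots0, lm_opts = opts)
  calls_fn <- lm_call_count()
  expect_equal(calls_fn, length(fix$entries))
  g <- total_merit_gradient(tm, fix$entries, pots0, opts$energy)
  # the analytic gradient adds zero lattice minimizations
  expect_equal(lm_call_count(), calls_fn)

  fd <- numeric(length(p0))
  for (j in seq_along(p0)) {
    h <- 3e-4 * p0[j]
    pp <- p0; pp[j] <- p0[j] + h
    pm <- p0; pm[j] <- p0[j] - h
    fd[j] <- (total_merit(fix$entries, set_params(fix$pots, pp),
                          lm_opts = opts)$TMF -
                total_merit(fix$entries, set_params(fix$pots, pm),
                            lm_opts = opts)$TMF) / (2 * h)
  }
  expect_lt(max(abs(g - fd)) / max(abs(fd)), 1e-4)

  # at the generating parameters all residuals vanish, so dTMF/dp = 0
  tm0 <- total_merit(fix$entries, fix$pots, lm_opts = opts)
  g0 <- total_merit_gradient(tm0, fix$entries, fix$pots, opts$energy)
  expect_lt(max(abs(g0)), 1e-8)
})

test_that("zero-weight structures contribute nothing to the gradient", {
  fix <- toy_fixture(2)
  opts <- fast_lm_opts()
  e0 <- fix$entries[[1]]
  e0$w_g <- 0; e0$w_e <- 0
  p0 <- get_params(fix$pots) * 1.05
  pots0 <- set_params(fix$pots, p0)
  lm <- minimize_lattice(e0$crystal, pots0, opts = opts)
  sens <- crystalfit:::structure_sensitivity(lm, e0, pots0, opts$energy)
  expect_equal(unname(sens$dMF_dp), rep(0, length(p0)))
})
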