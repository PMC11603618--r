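test_that("buckingham_pair evaluates the exp-6 form", {
  expect_equal(buckingham_pair(2.5, 0, 3.6, 0), 0)
  # large-r limit approaches zero from below when C > 0
  expect_lt(buckingham_pair(30, 1e5, 3.6, 2000), 0)
  expect_gt(buckingham_pair(30, 1e5, 3.6, 2000), -1e-5)
  # frozen scalar oracle: 1e5*exp(-12.6) - 2000/3.5^6
  expect_equal(buckingham_pair(3.5, 1e5, 3.6, 2000),
               1e5 * exp(-12.6) - 2000 / 3.5^6, tolerance = 1e-12)
  expect_equal(round(buckingham_pair(3.5, 1e5, 3.6, 2000), 4), -0.7508)
  expect_error(buckingham_pair(0, 1, 1, 1), "positive")
})

test_that("combining rules: geometric A/C, harmonic B, with chain factors", {
  p <- c(100, 3, 2000)
  expect_equal(combine_cross(p, p), p)
  expect_equal(combine_cross(c(100, 3, 1), c(400, 6, 1))[1], 200)
  expect_equal(combine_cross(c(1, 3, 1), c(1, 6, 1))[2], 4)
  expect_error(combine_cross(c(1, 0, 1), c(1, 3, 1)), "positive")

  expect_equal(combine_chain_factor("A", 100, 100), 0.5)
  expect_equal(combine_chain_factor("A", 100, 400), 1)      # 0.5*sqrt(4)
  expect_equal(combine_chain_factor("B", 3, 6), 0.5 * (4 / 3)^2)
})

single_atom_cubic <- function(a, q = 0) {
  mol <- rigid_molecule("C", "X", matrix(0, 1, 3), q)
  crystal(lattice(a, a, a, system = "cubic"), sg_ops("P1"), list(mol),
          check = FALSE)
}

test_that("repulsion/dispersion sum matches a brute-force shell oracle", {
  pots0 <- potential_set("X", A = 0, B = 3.6, C = 0)
  cr <- single_atom_cubic(5)
  z <- repdisp_energy(cr, pots0, energy_options(cutoff = 12, taper = 0))
  expect_equal(z$U, 0)

  # pure dispersion on a single-atom cubic lattice vs direct image sum
  Cd <- 1000
  pots <- potential_set("X", A = 0, B = 3.6, C = Cd)
  a <- 4.2
  cr <- single_atom_cubic(a)
  cutoff <- 12
  val <- repdisp_energy(cr, pots, energy_options(cutoff = cutoff, taper = 0))$U
  nmax <- ceiling(cutoff / a)
  g <- expand.grid(n1 = -nmax:nmax, n2 = -nmax:nmax, n3 = -nmax:nmax)
  r <- a * sqrt(g$n1^2 + g$n2^2 + g$n3^2)
  r <- r[r > 0 & r <= cutoff]
  oracle <- 0.5 * sum(-Cd / r^6)
  expect_lt(abs(val - oracle) / abs(oracle), 1e-6)

  # exponential-only potential: doubling the cutoff changes nothing
  pots_e <- potential_set("X", A = 1e5, B = 3.6, C = 0)
  u1 <- repdisp_energy(cr, pots_e, energy_options(cutoff = 12))$U
  u2 <- repdisp_energy(cr, pots_e, energy_options(cutoff = 24))$U
  expect_lt(abs(u2 - u1), 1e-10)
})

test_that("atomic overlap raises the designed error", {
  mol1 <- rigid_molecule("C", "X", matrix(0, 1, 3), 0, center = c(0, 0, 0))
  mol2 <- rigid_molecule("C", "X", matrix(0, 1, 3), 0,
                         center = c(0.02, 0, 0))
  cr <- crystal(lattice(10, 10, 10, system = "cubic"), sg_ops("P1"),
                list(mol1, mol2), check = FALSE)
  pots <- potential_set("X", A = 1e5, B = 3.6, C = 100)
  expect_error(repdisp_energy(cr, pots, energy_options(cutoff = 12)),
               class = "xtl_overlap_error")
})

test_that("Ewald electrostatics reproduces the rock-salt Madelung sum", {
  # conventional NaCl cell: 8 ions as single-atom molecules
  a <- 5.64
  frac_na <- rbind(c(0, 0, 0), c(0.5, 0.5, 0), c(0.5, 0, 0.5),
                   c(0, 0.5, 0.5))
  frac_cl <- sweep(frac_na, 2, c(0.5, 0, 0), "+") %% 1
  mols <- c(lapply(seq_len(4), function(i)
              rigid_molecule("Na", "Na", matrix(0, 1, 3), +1,
                             center = frac_na[i, ])),
            lapply(seq_len(4), function(i)
              rigid_molecule("Cl", "Cl", matrix(0, 1, 3), -1,
                             center = frac_cl[i, ])))
  cr <- crystal(lattice(a, a, a, system = "cubic"), sg_ops("P1"), mols)
  ew <- ewald_point_charge(cr, energy_options())
  # Evjen oracle: direct sum over expanding cubes with fractional
  # surface weights, per ion
  evjen <- function(nshell) {
    r0 <- a / 2
    idx <- -nshell:nshell
    g <- expand.grid(i = idx, j = idx, k = idx)
    g <- g[!(g$i == 0 & g$j == 0 & g$k == 0), ]
    w <- (1 - 0.5 * (abs(g$i) == nshell)) *
         (1 - 0.5 * (abs(g$j) == nshell)) *
         (1 - 0.5 * (abs(g$k) == nshell))
    s <- (-1)^(abs(g$i) + abs(g$j) + abs(g$k))
    r <- r0 * sqrt(g$i^2 + g$j^2 + g$k^2)
    1389.35458 * sum(w * s / r) / 2   # per ion (half the pair energy)
  }
  oracle <- evjen(14)
  expect_lt(abs(ew$U - oracle) / abs(oracle), 1e-4)
  # and the implied Madelung constant
  alpha_M <- -ew$U * 2 * (a / 2) / 1389.35458
  expect_equal(alpha_M, 1.747565, tolerance = 2e-6)

  # invariance to the splitting parameter
  base <- ewald_settings(cr$lattice, energy_options())
  ew2 <- ewald_point_charge(cr, energy_options(ewald_alpha = base$alpha * 2))
  expect_lt(abs(ew2$U - ew$U), 1e-6)

  # all charges zero -> 0
  mols0 <- lapply(mols, function(m) { m$charge <- 0; m })
  cr0 <- crystal(cr$lattice, cr$ops, mols0)
  expect_equal(ewald_point_charge(cr0)$U, 0)
})

test_that("non-neutral cells are rejected by the Ewald sum", {
  mol <- rigid_molecule("Na", "Na", matrix(0, 1, 3), +1)
  cr <- crystal(lattice(8, 8, 8, system = "cubic"), sg_ops("P1"),
                list(mol), check = FALSE)
  expect_error(ewald_point_charge(cr), "neutral")
})

test_that("analytic gradient matches finite differences on a P1 dimer", {
  cr <- dimer_p1_crystal()
  pots <- toy_free_pots()
  eo <- energy_options(cutoff = 12)
  rep_ <- inter_energy(cr, pots, eo, want = c("grad", "dp", "cross"))
  om0 <- omega_extract(cr)
  fd <- numeric(length(om0))
  for (i in seq_along(om0)) {
    h <- 1e-5 * max(1, abs(om0[i]))
    op <- om0; op[i] <- om0[i] + h
    om <- om0; om[i] <- om0[i] - h
    fd[i] <- (crystalfit:::energy_value_at(cr, op, pots, eo) -
                crystalfit:::energy_value_at(cr, om, pots, eo)) / (2 * h)
  }
  expect_lt(max(abs(rep_$grad - fd)) / max(abs(fd)), 1e-6)
})

test_that("Hessian is symmetric and consistent with the gradient", {
  cr <- bent_p1bar_crystal()
  pots <- toy_free_pots()
  eo <- energy_options(cutoff = 12)
  rep_ <- inter_energy(cr, pots, eo, want = c("grad", "hess"))
  H <- rep_$hess
  expect_lt(max(abs(H - t(H))) / max(abs(H)), 1e-8)
  # directional FD of the analytic gradient at an independent step
  set.seed(3)
  om0 <- omega_extract(cr)
  for (k in 1:3) {
    v <- rnorm(length(om0)); v <- v / sqrt(sum(v^2))
    h <- 5e-4
    gp <- crystalfit:::grad_at(cr, om0 + h * v, pots, eo)
    gm <- crystalfit:::grad_at(cr, om0 - h * v, pots, eo)
    fdv <- (gp - gm) / (2 * h)
    expect_lt(max(abs(H %*% v - fdv)) / max(abs(fdv)), 1e-3)
  }
})

test_that("parameter derivatives: values, absent types, combining chain", {
  cr <- bent_p1bar_crystal()
  eo <- energy_options(cutoff = 12)
  # absent atom type contributes exactly zero derivative
  free <- array(FALSE, c(3, 3, 3)); free[, , 1] <- TRUE; free[, , 3] <- TRUE
  pots3 <- potential_set(c("X", "Y", "Z"),
                         A = matrix(2e4, 3, 3), B = matrix(3.6, 3, 3),
                         C = matrix(200, 3, 3), free = free)
  rd <- repdisp_energy(cr, pots3, eo, want_grad = FALSE, want_dp = TRUE)
  zcols <- grepl("Z", names(rd$dU_dp))
  expect_true(all(rd$dU_dp[zcols] == 0))
  expect_true(any(rd$dU_dp[!zcols] != 0))

  # explicit-mode dU/dp against finite differences
  pots <- toy_free_pots()
  rd <- repdisp_energy(cr, pots, eo, want_grad = TRUE, want_dp = TRUE)
  p0 <- get_params(pots)
  for (j in seq_along(p0)) {
    h <- 1e-5 * max(1, abs(p0[j]))
    pp <- p0; pp[j] <- p0[j] + h
    pm <- p0; pm[j] <- p0[j] - h
    fd <- (repdisp_energy(cr, set_params(pots, pp), eo)$U -
             repdisp_energy(cr, set_params(pots, pm), eo)$U) / (2 * h)
    expect_lt(abs(rd$dU_dp[j] - fd) / max(abs(fd), 1e-10), 1e-5)
  }

  # combining mode: chained homoatomic derivative vs FD under the rule
  potsc <- toy_potentials("combine")
  rdc <- repdisp_energy(cr, potsc, eo, want_dp = TRUE)
  pc <- get_params(potsc)
  for (j in seq_along(pc)) {
    h <- 1e-5 * max(1, abs(pc[j]))
    pp <- pc; pp[j] <- pc[j] + h
    pm <- pc; pm[j] <- pc[j] - h
    fd <- (repdisp_energy(cr, set_params(potsc, pp), eo)$U -
             repdisp_energy(cr, set_params(potsc, pm), eo)$U) / (2 * h)
    expect_lt(abs(rdc$dU_dp[j] - fd) / max(abs(fd), 1e-10), 1e-6)
  }

  # cross matrix vs FD of the gradient
  j <- 2
  h <- 1e-4 * p0[j]
  pp <- p0; pp[j] <- p0[j] + h
  pm <- p0; pm[j] <- p0[j] - h
  gp <- repdisp_energy(cr, set_params(pots, pp), eo, want_grad = TRUE)$grad
  gm <- repdisp_energy(cr, set_params(pots, pm), eo, want_grad = TRUE)$grad
  fdc <- (gp - gm) / (2 * h)
  expect_lt(max(abs(rd$cross[, j] - fdc)) / max(abs(fdc)), 1e-6)
})

test_that("energy is invariant to global translation and extensive", {
  cr <- dimer_p1_crystal()
  pots <- toy_free_pots()
  eo <- energy_options(cutoff = 12)
  u0 <- inter_energy(cr, pots, eo, want = character())$U_inter
  om <- omega_extract(cr)
  shift <- c(0.123, -0.215, 0.34)
  om[paste0("mol1.c", 1:3)] <- om[paste0("mol1.c", 1:3)] + shift
  om[paste0("mol2.c", 1:3)] <- om[paste0("mol2.c", 1:3)] + shift
  u1 <- inter_energy(omega_apply(cr, om), pots, eo, want = character())$U_inter
  expect_lt(abs(u1 - u0), 1e-10)

  # 2x1x1 supercell in P1 reproduces the per-molecule energy
  big_lat <- lattice(2 * cr$lattice$a, cr$lattice$b, cr$lattice$c,
                     cr$lattice$alpha, cr$lattice$beta, cr$lattice$gamma)
  # centers re-expressed in supercell fractional coordinates
  mols2 <- c(lapply(cr$molecules, function(m) {
    m$center[1] <- m$center[1] / 2; m
  }), lapply(cr$molecules, function(m) {
    m$center[1] <- m$center[1] / 2 + 0.5; m
  }))
  big <- crystal(big_lat, sg_ops("P1"), mols2)
  u2 <- inter_energy(big, pots, eo, want = character())$U_inter
  expect_lt(abs(u2 - u0) / abs(u0), 1e-8)
})
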