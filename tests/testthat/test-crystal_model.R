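test_that("cell_matrix reproduces simple cells and the triple-product volume", {
  expect_equal(cell_matrix(lattice(10, 10, 10, system = "cubic")),
               diag(c(10, 10, 10)))
  M <- cell_matrix(lattice(4, 5, 6, system = "orthorhombic"))
  expect_equal(M, diag(c(4, 5, 6)))
  expect_equal(det(M), 120)

  # triclinic volume against the scalar triple product of the columns
  lat <- lattice(5, 6, 7, 80, 85, 95)
  M <- cell_matrix(lat)
  a1 <- M[, 1]; a2 <- M[, 2]; a3 <- M[, 3]
  triple <- sum(a1 * c(a2[2] * a3[3] - a2[3] * a3[2],
                       a2[3] * a3[1] - a2[1] * a3[3],
                       a2[1] * a3[2] - a2[2] * a3[1]))
  expect_equal(cell_volume(lat), abs(triple), tolerance = 1e-12)

  # property: random valid lattices
  set.seed(11)
  for (i in 1:200) {
    lat <- lattice(runif(1, 3, 12), runif(1, 3, 12), runif(1, 3, 12),
                   runif(1, 70, 110), runif(1, 70, 110), runif(1, 70, 110))
    M <- cell_matrix(lat)
    expect_lt(abs(cell_volume(lat) - abs(det(M))) / cell_volume(lat), 1e-10)
    expect_equal(M[2, 1], 0)
    expect_equal(M[3, 1], 0)
    expect_equal(M[3, 2], 0)
  }
})

test_that("invalid lattices are rejected", {
  expect_error(lattice(-1, 5, 5), "length")
  expect_error(lattice(5, 5, 5, alpha = 190), "angles")
  # impossible angle combination gives a degenerate cell
  expect_error(lattice(5, 5, 5, 1, 1, 178), "invalid lattice")
})

test_that("analytic cell-matrix derivatives match finite differences", {
  lat <- lattice(6.2, 7.1, 8.3, 78, 88, 101)
  gr <- cell_matrix_grad(lat)
  for (nm in c("a", "b", "c", "alpha", "beta", "gamma")) {
    h <- 1e-6
    lp <- lat; lp[[nm]] <- lp[[nm]] + h
    lm_ <- lat; lm_[[nm]] <- lm_[[nm]] - h
    fd <- (cell_matrix(lp) - cell_matrix(lm_)) / (2 * h)
    expect_lt(max(abs(fd - gr[[nm]])), 1e-7)
  }
})

test_that("expand_symmetry enumerates unit-cell sites with wrapping", {
  # P1: output equals the asymmetric unit
  cr <- dimer_p1_crystal()
  st <- expand_symmetry(cr)
  expect_equal(nrow(st$frac), 4)
  expect_equal(st$op, rep(1L, 4))

  # P-1, one 3-atom molecule: 6 sites
  cr2 <- bent_p1bar_crystal()
  st2 <- expand_symmetry(cr2)
  expect_equal(nrow(st2$frac), 6)

  # P21 maps (0.1, 0.2, 0.3) to (0.9, 0.7, 0.7)
  op <- sg_ops("P21")[[2]]
  expect_equal(apply_symop(op, c(0.1, 0.2, 0.3)) %% 1, c(0.9, 0.7, 0.7))

  # count conservation for every fixture
  for (cr in list(dimer_p1_crystal(), bent_p1bar_crystal())) {
    st <- expand_symmetry(cr)
    natoms <- sum(vapply(cr$molecules, function(m) nrow(m$local), 0L))
    expect_equal(nrow(st$frac), length(cr$ops) * natoms)
  }
})

test_that("special positions are rejected", {
  mol <- rigid_molecule("C", "X", matrix(0, 1, 3), 0, center = c(0, 0, 0))
  lat <- lattice(8, 8, 8, system = "triclinic")
  cr <- crystal(lat, sg_ops("P-1"), list(mol), check = FALSE)
  expect_error(expand_symmetry(cr), "special position")
})

test_that("crystal invariants: neutrality and overlap", {
  loc <- rbind(c(0.6, 0, 0), c(-0.6, 0, 0))
  bad <- rigid_molecule(c("C", "N"), c("X", "Y"), loc, c(0.3, 0.0),
                        center = c(0.25, 0.25, 0.25))
  lat <- lattice(8, 8, 9, 85, 95, 100)
  expect_error(crystal(lat, sg_ops("P1"), list(bad)), "neutral")
})

test_that("set_geometry applies and regenerates constrained parameters", {
  cr <- bent_p1bar_crystal()
  om <- omega_extract(cr)
  expect_equal(length(om), n_free_cell(cr$lattice) + 6)
  cr2 <- set_geometry(cr, om)
  expect_equal(omega_extract(cr2), om)
  expect_equal(crystal_sites(cr2)$frac, crystal_sites(cr)$frac)

  # perturbing one free cell length changes exactly that lattice field
  om2 <- om; om2["cell.b"] <- om["cell.b"] + 0.1
  cr3 <- set_geometry(cr, om2)
  expect_equal(cr3$lattice$b, cr$lattice$b + 0.1)
  expect_equal(cr3$lattice$a, cr$lattice$a)
  expect_equal(cr3$lattice$gamma, cr$lattice$gamma)

  # monoclinic: constrained angles are regenerated
  mono <- lattice(6, 7, 8, 90, 101, 90, system = "monoclinic")
  crm <- crystal(mono, sg_ops("P21"),
                 list(rigid_molecule(c("C", "N"), c("X", "Y"),
                                     rbind(c(0.6, 0, 0), c(-0.6, 0, 0)),
                                     c(0.3, -0.3),
                                     center = c(0.2, 0.25, 0.3))))
  omm <- omega_extract(crm)
  expect_equal(names(omm)[1:4], c("cell.a", "cell.b", "cell.c", "cell.beta"))
  crm2 <- set_geometry(crm, omm + c(0.2, 0, 0, 1, rep(0, 6)))
  expect_equal(crm2$lattice$alpha, 90)
  expect_equal(crm2$lattice$gamma, 90)
  expect_equal(crm2$lattice$beta, crm$lattice$beta + 1)
})

test_that("an axis-angle increment rotates the molecular axis as expected", {
  loc <- rbind(c(0.6, 0, 0), c(-0.6, 0, 0))
  mol <- rigid_molecule(c("C", "N"), c("X", "Y"), loc, c(0.3, -0.3),
                        center = c(0.25, 0.25, 0.25))
  lat <- lattice(10, 10, 10, system = "cubic")
  cr <- crystal(lat, sg_ops("P1"), list(mol))
  om <- omega_extract(cr)
  om[paste0("mol1.r", 1:3)] <- c(0, 0, pi / 2)
  cr2 <- set_geometry(cr, om)
  st <- crystal_sites(cr2, wrap = FALSE)
  axis <- st$cart[1, ] - st$cart[2, ]
  # x-axis rotated to y
  expect_equal(as.numeric(axis), c(0, 1.2, 0), tolerance = 1e-12)
})

test_that("apply/extract round trip is exact for random variable vectors", {
  cr <- bent_p1bar_crystal()
  set.seed(4)
  for (i in 1:1000) {
    om <- omega_extract(cr)
    om <- om + c(runif(6, -0.05, 0.05), runif(3, -0.02, 0.02),
                 runif(3, -0.3, 0.3))
    cr2 <- omega_apply(cr, om)
    expect_lt(max(abs(omega_extract(cr2) - om)), 1e-12)
  }
})

test_that("degenerate cells raise an invalid-lattice error through omega", {
  cr <- bent_p1bar_crystal()
  om <- omega_extract(cr)
  om["cell.a"] <- 1e-9
  expect_error(omega_apply(cr, om), "invalid lattice")
})

test_that("ZYZ Euler export is consistent with the quaternion rotation", {
  set.seed(9)
  for (i in 1:50) {
    q <- quat_normalize(rnorm(4))
    e <- quat_to_euler_zyz(q)
    Rz <- function(t) matrix(c(cos(t), sin(t), 0, -sin(t), cos(t), 0,
                               0, 0, 1), 3, 3)
    Ry <- function(t) matrix(c(cos(t), 0, -sin(t), 0, 1, 0,
                               sin(t), 0, cos(t)), 3, 3)
    expect_lt(max(abs(Rz(e[1]) %*% Ry(e[2]) %*% Rz(e[3]) - quat_to_mat(q))),
              1e-10)
  }
})

test_that("structural null modes match the space group and molecule shape", {
  # P1: three global translations (plus none rotational for a bent molecule)
  expect_equal(ncol(omega_null_modes(dimer_p1_crystal())), 3 + 2)
  # the two extra modes above are the two diatomics' axial rotations
  # P-1 pins translations; bent molecule has no rotational null
  expect_equal(ncol(omega_null_modes(bent_p1bar_crystal())), 0)
  # P21 leaves translation along b free
  mono <- lattice(6, 7, 8, 90, 101, 90, system = "monoclinic")
  crm <- crystal(mono, sg_ops("P21"),
                 list(rigid_molecule(c("O", "H", "H"), c("X", "Y", "Y"),
                                     {
                                       l <- rbind(c(0, 0.4, 0),
                                                  c(0.95, -0.35, 0),
                                                  c(-0.95, -0.35, 0))
                                       sweep(l, 2, colMeans(l))
                                     },
                                     c(-0.5, 0.25, 0.25),
                                     center = c(0.2, 0.25, 0.3))))
  N <- omega_null_modes(crm)
  expect_equal(ncol(N), 1)
  # the mode lives on the center-y component
  nx <- n_free_cell(crm$lattice)
  expect_gt(abs(N[nx + 2, 1]), 0.99)
})
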