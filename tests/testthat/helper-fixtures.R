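# Shared fixtures, built in code and cached for the whole test run.

.fixture_env <- new.env(parent = emptyenv())

fast_lm_opts <- function() latmin_options(energy = energy_options(cutoff = 12))

# A small reference training set relaxed under the true toy parameters.
toy_fixture <- function(n = 2, seed = 7) {
  key <- sprintf("set_%d_%d", n, seed)
  if (is.null(.fixture_env[[key]])) {
    pots <- toy_potentials()
    entries <- generate_reference_set(default_toy_specs(n), pots, seed,
                                      lm_opts = fast_lm_opts())
    .fixture_env[[key]] <- list(pots = pots, entries = entries)
  }
  .fixture_env[[key]]
}

# A deterministic (no minimization) P-1 crystal with a bent triatomic.
bent_p1bar_crystal <- function() {
  loc <- rbind(c(0, 0.4, 0), c(0.95, -0.35, 0), c(-0.95, -0.35, 0))
  loc <- sweep(loc, 2, colMeans(loc))
  mol <- rigid_molecule(c("O", "H", "H"), c("X", "Y", "Y"), loc,
                        c(-0.5, 0.25, 0.25), center = c(0.25, 0.30, 0.40),
                        quat = quat_normalize(c(0.9, 0.2, -0.3, 0.1)))
  lat <- lattice(7.0, 7.5, 8.0, 80, 85, 95, system = "triclinic")
  crystal(lat, sg_ops("P-1"), list(mol), label = "bent-p1bar")
}

# A P1 "dimer" crystal: two diatomics in one cell (no symmetry).
dimer_p1_crystal <- function() {
  mk <- function(center, quat) {
    loc <- rbind(c(0.6, 0, 0), c(-0.6, 0, 0))
    rigid_molecule(c("C", "N"), c("X", "Y"), loc, c(0.3, -0.3),
                   center = center, quat = quat_normalize(quat))
  }
  lat <- lattice(7.5, 8.0, 8.5, 85, 95, 100, system = "triclinic")
  crystal(lat, sg_ops("P1"),
          list(mk(c(0.15, 0.20, 0.25), c(1, 0.3, 0.1, -0.2)),
               mk(c(0.60, 0.65, 0.70), c(0.8, -0.3, 0.4, 0.1))),
          label = "dimer-p1")
}

toy_free_pots <- function() toy_potentials("explicit")

expect_rel_equal <- function(x, y, tol, scale = max(abs(y), 1e-300)) {
  expect_lt(max(abs(x - y)) / scale, tol)
}
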