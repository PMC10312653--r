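test_that("analytic forces match finite differences of the potential", {
  for (mode in c("dimer", "tetramer")) {
    pp <- perturbed_protein(2, mode, seed = 7)
    res <- compute_potential_and_forces(pp$system, pp$ff)
    set.seed(11)
    sel <- sample(n_beads(pp$system), 6)
    fd <- fd_forces(pp$system, pp$ff, sel)
    rel <- abs(fd - res$forces[sel, ]) / pmax(1, abs(fd))
    expect_lt(max(rel), 1e-5)
  }
  # a two-chain interacting configuration (attractive pairs engaged)
  ff <- default_forcefield("dimer")
  single <- build_protein(make_coil_protein(2, "dimer"), ff)
  two <- pack_slab_box(single, copies = 2, box = c(10, 10, 12),
                       tolerance = 1.0, seed = 3)
  set.seed(8)
  two$coords <- two$coords + matrix(rnorm(3 * n_beads(two), sd = 0.01),
                                    ncol = 3)
  res <- compute_potential_and_forces(two, ff)
  sel <- sample(n_beads(two), 5)
  fd <- fd_forces(two, ff, sel)
  expect_lt(max(abs(fd - res$forces[sel, ]) / pmax(1, abs(fd))), 1e-5)
})

test_that("pair energetics honour the shifted cutoff and the interchain rule", {
  ff <- default_forcefield("dimer")
  box <- c(20, 20, 20)
  at <- function(r, chain, itype) {
    bare_system(matrix(c(5, 5, 5, 5 + r, 5, 5), ncol = 3, byrow = TRUE),
                box, chain = chain, itype = itype)
  }
  # attractive sticky pair exactly at the cutoff: zero energy
  s <- at(1.1, c(1L, 2L), c("C1", "C1"))
  expect_equal(compute_potential_and_forces(s, ff)$potential, 0)
  # just inside, the well is attractive and deep
  s <- at(2^(1 / 6) * ff$sigma, c(1L, 2L), c("C1", "C1"))
  e_inter <- compute_potential_and_forces(s, ff)$potential
  expect_lt(e_inter, -5)
  # the same pair on one chain is repulsive-only (intrachain excluded
  # from attraction): energy equals the inert-pair energy
  s_intra <- at(2^(1 / 6) * ff$sigma, c(1L, 1L), c("C1", "C1"))
  s_inert <- at(2^(1 / 6) * ff$sigma, c(1L, 2L), c("inert", "inert"))
  expect_equal(compute_potential_and_forces(s_intra, ff)$potential,
               compute_potential_and_forces(s_inert, ff)$potential)
  # different sticky types on different chains: repulsive-only
  s_ab <- at(2^(1 / 6) * ff$sigma, c(1L, 2L), c("C1", "C2"))
  expect_equal(compute_potential_and_forces(s_ab, ff)$potential,
               compute_potential_and_forces(s_inert, ff)$potential)
})

test_that("harmonic bond force is k*delta and excluded from nonbonded", {
  ff <- default_forcefield("dimer")
  r0 <- 0.38; k <- 8000; delta <- 0.013
  bonds <- data.frame(ai = 1L, aj = 2L, r0 = r0, kf = k)
  s <- bare_system(matrix(c(5, 5, 5, 5 + r0 + delta, 5, 5), ncol = 3,
                          byrow = TRUE), c(20, 20, 20), bonds = bonds)
  res <- compute_potential_and_forces(s, ff)
  expect_equal(res$potential, 0.5 * k * delta^2, tolerance = 1e-12)
  expect_equal(sqrt(sum(res$forces[1, ]^2)), k * delta, tolerance = 1e-9)
  # restoring direction
  expect_gt(res$forces[1, 1] * 0 + res$forces[2, 1] * -1, 0)
})

test_that("minimization reaches the analytic minimum and the force tolerance", {
  ff <- default_forcefield("dimer")
  bonds <- data.frame(ai = 1L, aj = 2L, r0 = 0.38, kf = 8000)
  s <- bare_system(matrix(c(5, 5, 5, 5.48, 5, 5), ncol = 3, byrow = TRUE),
                   c(20, 20, 20), bonds = bonds)
  m <- minimize(s, ff, force_tol = 1e-3)
  expect_equal(sqrt(sum((m$coords[2, ] - m$coords[1, ])^2)), 0.38,
               tolerance = 1e-4)
  # an already-minimal configuration converges immediately
  m2 <- minimize(m, ff, force_tol = 1e-3)
  expect_true(attr(m2, "converged"))
  expect_lte(attr(m2, "steps"), 1)
  # default tolerance contract on a protein
  pp <- perturbed_protein(2, "dimer", sd = 0.05, seed = 3)
  mp <- minimize(pp$system, pp$ff)
  expect_true(attr(mp, "converged"))
  expect_lt(attr(mp, "max_force"), 50)
})

test_that("Langevin runs are seed-deterministic and remove COM drift", {
  ff <- default_forcefield("dimer")
  pp <- perturbed_protein(2, "dimer", seed = 5)
  sys <- minimize(pp$system, ff)
  st <- integrator_settings(temperature = 293, seed = 17)
  t1 <- run_langevin(sys, ff, st, n_steps = 400, sample_interval = 100)
  t2 <- run_langevin(sys, ff, st, n_steps = 400, sample_interval = 100)
  expect_identical(t1$frames, t2$frames)
  t3 <- run_langevin(sys, ff, integrator_settings(temperature = 293,
                                                  seed = 18),
                     n_steps = 400, sample_interval = 100)
  expect_false(identical(t1$frames, t3$frames))
  # with removal every step, net momentum stays at numerical zero
  st1 <- integrator_settings(temperature = 293, seed = 7,
                             com_removal_interval = 1)
  tr <- run_langevin(sys, ff, st1, n_steps = 200, sample_interval = 200)
  v <- attr(tr, "final_velocities")
  p <- colSums(v * sys$beads$mass)
  thermal <- sqrt(sum(sys$beads$mass) * 0.0083144621 * 293)
  expect_lt(sqrt(sum(p^2)) / thermal, 1e-10)
})

test_that("velocity-Verlet limit conserves energy and minimum image holds", {
  ff <- default_forcefield("dimer")
  single <- build_protein(make_coil_protein(2, "dimer"), ff)
  two <- pack_slab_box(single, copies = 2, box = c(10, 10, 12),
                       tolerance = 1.0, seed = 3)
  two <- minimize(two, ff)
  # half the production step keeps the trajectory in the regime where
  # integration error (rather than the force discontinuity pairs see
  # when they cross the truncation cutoff) dominates
  st <- integrator_settings(friction = 0, temperature = 100, seed = 9,
                            dt = 0.0125)
  tr <- run_langevin(two, ff, st, n_steps = 1e4, sample_interval = 100)
  kB <- 0.0083144621
  etot <- tr$thermo$E_pot_kJmol +
    1.5 * n_beads(two) * kB * tr$thermo$T_K
  # drift relative to the system's kinetic-energy scale (the total can
  # sit near zero, which would make a ratio to E itself meaningless)
  scale <- 1.5 * n_beads(two) * kB * 100
  drift <- abs(etot[length(etot)] - etot[1]) / scale
  expect_lt(drift, 0.001)
  # energies invariant under whole-system translation across the boundary
  e0 <- compute_potential_and_forces(two, ff)$potential
  shifted <- two
  shifted$coords <- sweep(two$coords, 2, two$box, `+`)
  e1 <- compute_potential_and_forces(shifted, ff)$potential
  expect_equal(e0, e1, tolerance = 1e-10)
  part <- two
  part$coords[, 3] <- part$coords[, 3] + 0.4 * part$box[3]
  expect_equal(compute_potential_and_forces(part, ff)$potential, e0,
               tolerance = 1e-8)
})

test_that("staged z-compression hits the target and leaves no overlaps", {
  ff <- default_forcefield("dimer")
  single <- build_protein(make_coil_protein(2, "dimer"), ff)
  packed <- pack_slab_box(single, copies = 4, box = c(8, 8, 30),
                          tolerance = 1.0, seed = 4)
  packed <- minimize(packed, ff)
  comp <- compress_z(packed, ff, target_fraction = 0.15, n_stages = 8,
                     relax_steps = 300, seed = 2)
  expect_equal(comp$box[3], 0.15 * 30, tolerance = 1e-12)
  expect_equal(comp$box[1:2], packed$box[1:2])
  dmin <- coilslab:::cpp_min_interchain_dist(comp$coords, comp$box,
                                             comp$beads$chain,
                                             0.5 * ff$sigma)
  expect_true(!is.finite(dmin) || dmin >= 0.5 * ff$sigma)
  # dilute point count is conserved (volume scaling only moves beads)
  expect_equal(nrow(comp$coords), nrow(packed$coords))
})
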