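test_that("single-chain builder obeys chain combinatorics and sticky placement", {
  ff <- default_forcefield("dimer")
  spec <- make_coil_protein(2, "dimer")   # 32 / 25 / 32
  sys <- build_protein(spec, ff)
  expect_equal(n_beads(sys), 89)
  expect_equal(nrow(sys$bonds), 88)
  expect_equal(nrow(sys$angles), 87)
  expect_equal(nrow(sys$torsions), 86)
  # compact two-column face ({0,4}): 9 sticky beads per 32-residue coil
  expect_equal(sum(sys$beads$sticky & sys$beads$coil_id == 1), 9)
  expect_equal(sum(sys$beads$sticky & sys$beads$coil_id == 2), 9)
  # confining the columns to the coil core trims the outer heptads
  spec_core <- protein_spec("core", list(
    coil_segment(32, "C1", "dimer", sticky_core_fraction = 0.6)))
  expect_equal(sum(build_protein(spec_core, ff)$beads$sticky), 6)
  # heptad counting: an explicit two-position (a/d) pattern on a
  # 32-residue coil carries 10 sticky beads
  spec_ad <- protein_spec("ad", list(
    coil_segment(32, "C1", "dimer", sticky_pattern = c(0L, 3L),
                 sticky_core_fraction = 1)))
  sys_ad <- build_protein(spec_ad, ff)
  expect_equal(sum(sys_ad$beads$sticky), 10)
  # linker beads are inert
  expect_true(all(sys$beads$itype[sys$beads$kind == "linker"] == "inert"))
  # combinatorics for a bigger architecture
  spec4 <- make_coil_protein(4, "tetramer")
  sys4 <- build_protein(spec4, ff)
  n <- n_residues(spec4)
  expect_equal(c(n_beads(sys4), nrow(sys4$bonds), nrow(sys4$angles),
                 nrow(sys4$torsions)), c(n, n - 1, n - 2, n - 3))
})

test_that("initial helix matches the configured ideal geometry", {
  ff <- default_forcefield("dimer")
  spec <- protein_spec("coil32", list(coil_segment(32, "C1", "dimer")))
  sys <- build_protein(spec, ff)
  ete <- sqrt(sum((sys$coords[32, ] - sys$coords[1, ])[3]^2))
  expect_equal(ete, 31 * ff$helix$rise, tolerance = 1e-9)
  geom <- helix_internal_geometry(ff$helix)
  d12 <- sqrt(sum((sys$coords[2, ] - sys$coords[1, ])^2))
  expect_equal(d12, geom[["bond"]], tolerance = 1e-9)
  # bonded equilibria equal the helix internal coordinates for coil terms
  expect_equal(sys$bonds$r0[1], geom[["bond"]], tolerance = 1e-12)
  expect_equal(sys$angles$theta0[1], geom[["angle"]], tolerance = 1e-12)
  expect_equal(sys$torsions$phi0[1], geom[["torsion"]], tolerance = 1e-12)
})

test_that("terms spanning coil/linker junctions take the soft parameters", {
  ff <- default_forcefield("dimer")
  sys <- build_protein(make_coil_protein(2, "dimer"), ff)
  kf_coil <- ff$bonded$coil$bond[["k"]]
  kf_link <- ff$bonded$linker$bond[["k"]]
  # bond 32-33 crosses the first junction
  expect_equal(sys$bonds$kf[32], kf_link)
  expect_equal(sys$bonds$kf[31], kf_coil)
  expect_equal(sys$bonds$kf[57], kf_link)  # linker interior
  expect_equal(sys$bonds$kf[58], kf_coil)  # second coil start
})

test_that("packing arithmetic maximizes copies under the coil budget", {
  expect_equal(plan_packing(make_coil_protein(4), 450),
               list(copies = 112L, coils_placed = 448L,
                    n_coils_per_copy = 4L))
  expect_equal(plan_packing(make_coil_protein(2), 450)$coils_placed, 450L)
  expect_equal(plan_packing(make_coil_protein(3), 450)$coils_placed, 450L)
  # budget optimality over a range of architectures
  for (nc in 1:6) {
    pl <- plan_packing(make_coil_protein(nc), 450)
    expect_lte(pl$copies * nc, 450)
    expect_gt((pl$copies + 1) * nc, 450)
  }
})

test_that("packed boxes respect the tolerance and are seed-reproducible", {
  ff <- default_forcefield("dimer")
  single <- build_protein(make_coil_protein(2, "dimer"), ff)
  box <- c(12, 12, 30)
  p1 <- pack_slab_box(single, copies = 10, box = box, tolerance = 1.0,
                      seed = 5)
  expect_equal(length(unique(p1$beads$chain)), 10)
  dmin <- coilslab:::cpp_min_interchain_dist(p1$coords, p1$box,
                                             p1$beads$chain, 1.5)
  expect_gte(dmin, 1.0)
  p2 <- pack_slab_box(single, copies = 10, box = box, tolerance = 1.0,
                      seed = 5)
  expect_identical(p1$coords, p2$coords)
  p3 <- pack_slab_box(single, copies = 10, box = box, tolerance = 1.0,
                      seed = 6)
  expect_false(identical(p1$coords, p3$coords))
  # pool conformations are used round-robin
  pool <- list(single$coords, single$coords + 0.01)
  p4 <- pack_slab_box(single, pool, copies = 4, box = box, seed = 2)
  expect_equal(length(unique(p4$beads$chain)), 4)
  # an impossible packing errors with the achieved fraction
  expect_error(pack_slab_box(single, copies = 200, box = c(5, 5, 5),
                             tolerance = 1.0, seed = 1, max_attempts = 50),
               "packing fraction")
})
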