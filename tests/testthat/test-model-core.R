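test_that("multimer modes carry the framework's sticky strengths and valences", {
  dim_ <- multimer_mode("dimer")
  tet <- multimer_mode("tetramer")
  tri <- multimer_mode("trimer")
  expect_equal(dim_$epsilon_coil, 5.5)
  expect_equal(tet$epsilon_coil, 4.0)
  expect_equal(tri$epsilon_coil, 4.0)
  expect_equal(c(dim_$max_valence, tri$max_valence, tet$max_valence),
               c(2L, 3L, 4L))
  # faces: one per extra binding partner
  expect_equal(c(dim_$n_faces, tri$n_faces, tet$n_faces), c(1L, 2L, 3L))
  expect_error(multimer_mode("pentamer"), "valid modes")
})

test_that("default force field wires the coil/linker stiffness split and cutoff", {
  for (mode in c("dimer", "trimer", "tetramer")) {
    ff <- default_forcefield(mode)
    expect_equal(ff$cutoff, 1.1)
    expect_true(ff$shifted)
    b <- ff$bonded
    expect_equal(b$coil$angle[["k"]] / b$linker$angle[["k"]], 100)
    expect_equal(b$coil$bond[["k"]] / b$linker$bond[["k"]], 100)
    expect_equal(b$coil$torsion[["k"]] / b$linker$torsion[["k"]], 100)
    # equilibrium geometry identical between segment classes
    expect_equal(b$coil$angle[["theta0"]], b$linker$angle[["theta0"]])
  }
  expect_equal(default_forcefield("dimer")$mode$epsilon_coil, 5.5)
  expect_equal(default_forcefield("tetramer")$mode$epsilon_coil, 4.0)
})

test_that("shifted pair potential vanishes at the cutoff and is continuous", {
  ff <- default_forcefield("dimer")
  expect_equal(pair_potential(1.1, 5.5, ff = ff), 0)
  expect_equal(pair_potential(1.1 + 1e-9, 5.5, ff = ff), 0)
  # continuity approaching the cutoff from below
  eps <- 1e-7
  expect_lt(abs(pair_potential(1.1 - eps, 5.5, ff = ff)), 1e-5)
  # continuity on a fine grid inside the cutoff: jumps shrink with the
  # grid spacing (no discontinuity anywhere, including at the cutoff)
  r <- seq(0.44, 1.2, length.out = 1e5)
  v <- pair_potential(r, 5.5, ff = ff)
  expect_lt(max(abs(diff(v))), 0.05)
  # well depth scales with epsilon near the minimum
  rmin <- 2^(1 / 6) * ff$sigma
  expect_lt(pair_potential(rmin, 5.5, ff = ff), -5)
})

test_that("segment and protein spec invariants are enforced", {
  expect_error(coil_segment(5, "C1"), ">= 7")
  expect_error(coil_segment(32), "coil_type_id")
  expect_error(linker_segment(0), ">= 1")
  expect_error(protein_spec("x", list(linker_segment(10))),
               "at least one coil")
  spec <- make_coil_protein(3, "dimer")
  expect_equal(n_coils(spec), 3)
  expect_equal(n_linkers(spec), 2)
  expect_equal(n_residues(spec), 3 * 32 + 2 * 25)
  # maximally specific: every coil position its own type
  ids <- vapply(Filter(function(s) s$kind == "coil", spec$segments),
                `[[`, character(1), "coil_type_id")
  expect_equal(anyDuplicated(ids), 0L)
})

test_that("interaction table is symmetric, maximally specific and interchain-only", {
  ff <- default_forcefield("dimer")
  proteins <- list(make_coil_protein(2, "dimer"),
                   make_coil_protein(3, "dimer"))
  tab <- build_interaction_table(proteins, interaction_scheme(), ff)
  # symmetry in the type pair
  for (q in seq_len(nrow(tab))) {
    mirror <- tab[tab$type_i == tab$type_j[q] & tab$type_j == tab$type_i[q] &
                    tab$context == tab$context[q], ]
    expect_equal(mirror$class, tab$class[q])
    expect_equal(mirror$epsilon, tab$epsilon[q])
  }
  att <- tab[tab$class == "attractive", ]
  # attraction only interchain, only same sticky type
  expect_true(all(att$context == "interchain"))
  expect_true(all(att$type_i == att$type_j))
  expect_true(all(att$type_i != "inert"))
  expect_true(all(att$epsilon == 5.5))
  # specificity completeness: one attractive pair class per coil type
  n_types <- length(unique(c(
    vapply(Filter(function(s) s$kind == "coil", proteins[[1]]$segments),
           `[[`, character(1), "coil_type_id"),
    vapply(Filter(function(s) s$kind == "coil", proteins[[2]]$segments),
           `[[`, character(1), "coil_type_id"))))
  expect_equal(nrow(att), n_types)
  # linker/inert pairs repulsive-only everywhere
  inert <- tab[tab$type_i == "inert" | tab$type_j == "inert", ]
  expect_true(all(inert$class == "repulsive_only"))
  # missing type id rejected
  bad <- protein_spec("bad", list(structure(
    list(kind = "coil", length = 32L, coil_type_id = "",
         mode = multimer_mode("dimer"), sticky_pattern = c(0L, 3L)),
    class = c("coil_segment", "cc_segment"))))
  expect_error(build_interaction_table(bad, interaction_scheme(), ff),
               "coil_type_id")
})
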