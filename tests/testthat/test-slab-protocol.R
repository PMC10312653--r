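test_that("configuration selection samples the equilibrated portion reproducibly", {
  frames <- lapply(1:50, function(i) matrix(i, 4, 3))
  traj <- coilslab:::new_cc_trajectory(times = (0:49) * 1e4, frames = frames,
                                       box = c(10, 10, 10), thermo = NULL)
  sel <- select_configurations(traj, n = 5, t_equil = 1e5, seed = 3)
  expect_length(sel, 5)
  expect_true(all(attr(sel, "times") >= 1e5))
  expect_equal(anyDuplicated(vapply(sel, function(m) m[1, 1], numeric(1))),
               0L)
  sel2 <- select_configurations(traj, n = 5, t_equil = 1e5, seed = 3)
  expect_identical(sel, sel2)
  # exhaustive case returns everything
  all40 <- select_configurations(traj, n = 40, t_equil = 1e5, seed = 1)
  expect_setequal(attr(all40, "times"), (10:49) * 1e4)
  expect_error(select_configurations(traj, n = 41, t_equil = 1e5, seed = 1),
               "need 41")
})

test_that("equilibration detection matches the exhaustive-scan oracle", {
  # constant series equilibrates at the first frame
  s <- new_density_timeseries(0:49 * 100, rep(2, 50), rep(0.1, 50))
  expect_equal(detect_equilibration(s), 0)
  # persistent drift is never equilibrated
  s <- new_density_timeseries(0:49 * 100, 2 * (1 + 0.02 * (0:49)),
                              rep(0.1, 50))
  expect_true(is.na(detect_equilibration(s)))
  # step change then constant: t* at/after the step, equal to the oracle
  for (seed in 1:4) {
    s <- make_density_timeseries("step", n_samples = 80, step_at = 30,
                                 noise = 0.001, seed = seed)
    got <- detect_equilibration(s, window = 10, slope_tol = 0.02)
    want <- oracle_equilibration(s, window = 10, slope_tol = 0.02)
    expect_equal(as.numeric(got), as.numeric(want))
    expect_gte(got, s$times[30 - 10 + 1])
  }
  # stochastic stable/drift fixtures agree with the oracle too
  for (type in c("stable", "drift")) {
    s <- make_density_timeseries(type, n_samples = 60, seed = 11)
    expect_equal(as.numeric(detect_equilibration(s)),
                 as.numeric(oracle_equilibration(s, 10, 0.02)))
  }
  expect_error(detect_equilibration(
    new_density_timeseries(1:10, rep(1, 10), rep(1, 10)), window = 10),
    "two windows")
})

test_that("equilibration detection is monotone under appended stable data", {
  s <- make_density_timeseries("step", n_samples = 60, step_at = 25,
                               noise = 0.001, seed = 2)
  t1 <- detect_equilibration(s)
  longer <- new_density_timeseries(
    c(s$times, max(s$times) + (1:20) * 1000),
    c(s$center_density, rep(mean(tail(s$center_density, 10)), 20)),
    c(s$edge_density, rep(mean(tail(s$edge_density, 10)), 20)))
  t2 <- detect_equilibration(longer)
  expect_lte(t2, t1)
})

test_that("slab run bundles encode every stage setting for all runs", {
  ff <- default_forcefield("dimer")
  spec <- make_coil_protein(2, "dimer")
  single <- build_protein(spec, ff)
  packed <- pack_slab_box(single, copies = 3, box = c(10, 10, 20),
                          tolerance = 1.0, seed = 1)
  plan <- slab_run_plan(spec, seed = 5)
  d <- withr::local_tempdir()
  manifest <- prepare_slab_run(plan, packed, ff, d)
  dirs <- list.dirs(d, recursive = FALSE)
  expect_length(dirs, 4 * 3)  # 4 temperatures x 3 replicates
  expect_length(manifest$runs, 12)
  seeds <- vapply(manifest$runs, `[[`, integer(1), "seed")
  expect_equal(anyDuplicated(seeds), 0L)
  # NPT stage: 150 K for 200 ns at a 20 fs step
  p <- read_mdp(file.path(dirs[1], "npt.mdp"))
  expect_equal(as.numeric(p[["ref-t"]]), 150)
  expect_equal(as.numeric(p[["dt"]]), 0.02)
  expect_equal(as.numeric(p[["nsteps"]]) * as.numeric(p[["dt"]]), 2e5)
  # production: 20 us at 25 fs with rdd 1.6
  p <- read_mdp(file.path(dirs[1], "prod.mdp"))
  expect_equal(as.numeric(p[["dt"]]), 0.025)
  expect_equal(as.numeric(p[["nsteps"]]) * as.numeric(p[["dt"]]), 2e7)
  expect_equal(as.numeric(p[["rdd"]]), 1.6)
  # manifest is machine-readable and lists the files that exist
  m2 <- yaml::read_yaml(file.path(d, "manifest.yaml"))
  expect_equal(length(m2$runs), 12)
  expect_true(all(file.exists(file.path(d, m2$runs[[1]]$directory,
                                        m2$runs[[1]]$files))))
  # a mismatched system is rejected
  other <- build_protein(make_coil_protein(3, "dimer"), ff)
  expect_error(prepare_slab_run(plan, other, ff, d), "does not match")
})

test_that("expansion unwraps molecules and centres the slab", {
  ff <- default_forcefield("dimer")
  single <- build_protein(make_coil_protein(2, "dimer"), ff)
  packed <- pack_slab_box(single, copies = 6, box = c(8, 8, 30),
                          tolerance = 1.0, seed = 8)
  packed <- minimize(packed, ff)
  comp <- compress_z(packed, ff, target_fraction = 0.15, n_stages = 8,
                     relax_steps = 300, seed = 3)
  exp_sys <- expand_box_z(comp, new_z = 45)
  expect_equal(exp_sys$box[3], 45)
  # slab centred at z = Lz/2 within a bead diameter
  expect_lt(abs(mean(exp_sys$coords[, 3]) - 22.5), ff$sigma)
  # molecules whole: a split chain would show a bond on the scale of a
  # box length; thermal excursions of the soft linker bonds stay well
  # under 1.5 nm
  bl <- sqrt(rowSums((exp_sys$coords[exp_sys$bonds$ai, ] -
                        exp_sys$coords[exp_sys$bonds$aj, ])^2))
  expect_lt(max(bl), 1.5)
})

test_that("the miniature slab pipeline runs end to end and is analyzable", {
  ff <- default_forcefield("dimer")
  spec <- make_coil_protein(2, "dimer")
  plan <- slab_run_plan(spec, desk_scale = TRUE, seed = 1)
  plan$stages$single_molecule$prod_ps <- 1500
  plan$stages$npt$duration_ps <- 400
  plan$stages$nvt$duration_ps <- 300
  plan$stages$production$duration_ps <- 600
  res <- run_slab_pipeline(spec, ff, temperature = 253, plan = plan,
                           copies = 3, sample_ps = 100, seed = 21)
  expect_s3_class(res$trajectory, "cc_trajectory")
  expect_gte(n_frames(res$trajectory), 5)
  expect_equal(res$expanded$box[3], 45)
  pr <- density_profile(res$trajectory)
  expect_s3_class(pr, "density_profile")
  cs <- cluster_size_distribution(res$trajectory, every_ps = 100)
  expect_equal(sum(cs$prob), 1, tolerance = 1e-9)
  ts <- density_timeseries(res$trajectory)
  expect_length(ts$center_density, n_frames(res$trajectory))
})
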