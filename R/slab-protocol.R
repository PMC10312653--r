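# The slab phase-coexistence pipeline: single-molecule conformation
# generation, configuration selection, packing, compression, expansion,
# equilibration and production, plus density-stability equilibration
# detection.

#' Run a single-molecule simulation (minimize, equilibrate, produce)
#'
#' Follows the protocol's single-molecule stage: energy minimization,
#' NVT equilibration (500 ps at a 25 fs step by default, letting linkers
#' relax out of the initial helix), then NVT production at the same
#' temperature. One replicate per temperature.
#'
#' @param spec a [protein_spec()]
#' @param ff force field
#' @param temperature run temperature in K
#' @param equil_ps equilibration length in ps (default 500)
#' @param prod_ps production length in ps (paper scale is 5e6, i.e.
#'   5 us; desk-scale callers pass something smaller)
#' @param sample_ps interval between saved frames in ps
#' @param seed RNG seed
#' @return a `cc_trajectory` of the production run
#' @export
run_single_molecule <- function(spec, ff, temperature = 293,
                                equil_ps = 500, prod_ps = 5e4,
                                sample_ps = 100, seed = 1L) {
  sys <- build_protein(spec, ff)
  sys <- minimize(sys, ff)
  dt <- 0.025
  st <- integrator_settings(dt = dt, temperature = temperature, seed = seed)
  eq <- run_langevin(sys, ff, st, n_steps = round(equil_ps / dt),
                     sample_interval = round(equil_ps / dt))
  sys <- attr(eq, "final_system")
  st2 <- integrator_settings(dt = dt, temperature = temperature,
                             seed = seed + 1L)
  run_langevin(sys, ff, st2, n_steps = round(prod_ps / dt),
               sample_interval = max(1L, round(sample_ps / dt)),
               velocities = attr(eq, "final_velocities"))
}

#' Select conformations from the equilibrated part of a trajectory
#'
#' Uniform random sample of `n` distinct frames with time >= `t_equil`,
#' the configuration-pool step of the slab protocol (default: five
#' frames, equilibration assumed reached by 100 ns).
#'
#' @param traj a `cc_trajectory`
#' @param n number of conformations (default 5)
#' @param t_equil start of the equilibrated portion in ps (default 1e5)
#' @param seed RNG seed (selection is reproducible under it)
#' @return list of coordinate matrices; frame times as attribute `times`
#' @export
select_configurations <- function(traj, n = 5L, t_equil = 1e5, seed = 1L) {
  stopifnot(inherits(traj, "cc_trajectory"), n >= 1)
  ok <- which(traj$times >= t_equil)
  if (length(ok) < n)
    stop(sprintf("only %d frame(s) after t_equil = %g ps; need %d",
                 length(ok), t_equil, n), call. = FALSE)
  rng <- .with_seed(seed, sample(ok, n))
  out <- traj$frames[rng]
  attr(out, "times") <- traj$times[rng]
  out
}

# evaluate expr under a local RNG seed without touching the caller's
# RNG state
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

#' Slab run plan
#'
#' Collects every setting of the slab protocol: temperatures (default
#' 253, 273, 293, 313 K), three replicates, the packing budget (450
#' coils, 25 x 25 x 100 nm start box, 1.0 nm tolerance), the NPT slab
#' formation stage (200 ns, 20 fs, 150 K), expansion to a 150 nm
#' z-length, NVT equilibration (200 ns, 20 fs) and production (20 us,
#' 25 fs). `desk_scale` shrinks durations and box to a miniature that
#' the internal engine can run end to end; the file exporter always
#' writes the at-scale settings it is given.
#'
#' @param protein a [protein_spec()]
#' @param temperatures K (default `c(253, 273, 293, 313)`)
#' @param replicates per temperature (default 3)
#' @param coil_budget coils per box (default 450)
#' @param seed base seed; replicate seeds are derived deterministically
#' @param desk_scale use miniature desk-scale stage durations
#' @return object of class `slab_run_plan`
#' @export
slab_run_plan <- function(protein, temperatures = c(253, 273, 293, 313),
                          replicates = 3L, coil_budget = 450L, seed = 1L,
                          desk_scale = FALSE) {
  stopifnot(inherits(protein, "protein_spec"), replicates >= 1)
  stages <- if (desk_scale) {
    list(pack_box = c(8, 8, 30), final_z = 45,
         single_molecule = list(equil_ps = 500, prod_ps = 5000, dt = 0.025),
         npt = list(duration_ps = 1000, dt = 0.02, temperature = 150,
                    target_fraction = 0.15),
         nvt = list(duration_ps = 1000, dt = 0.02),
         production = list(duration_ps = 10000, dt = 0.025))
  } else {
    list(pack_box = c(25, 25, 100), final_z = 150,
         single_molecule = list(equil_ps = 500, prod_ps = 5e6, dt = 0.025),
         npt = list(duration_ps = 2e5, dt = 0.02, temperature = 150,
                    target_fraction = 0.15),
         nvt = list(duration_ps = 2e5, dt = 0.02),
         production = list(duration_ps = 2e7, dt = 0.025))
  }
  structure(list(protein = protein, temperatures = temperatures,
                 replicates = as.integer(replicates),
                 coil_budget = as.integer(coil_budget),
                 tolerance = 1.0, stages = stages, seed = as.integer(seed),
                 desk_scale = isTRUE(desk_scale)),
            class = "slab_run_plan")
}

# deterministic per-(temperature, replicate) seed, kept below 2^31
.plan_seed <- function(plan, t_index, replicate) {
  as.integer((plan$seed * 7919L + t_index * 104729L + replicate * 1299709L) %%
               .Machine$integer.max)
}

#' Export a complete slab run bundle
#'
#' Writes one directory per temperature x replicate containing the
#' packed starting coordinates, topology and the MDP files for every
#' stage (minimization; NPT at 150 K with the z-only Parrinello-Rahman
#' barostat at 1 bar, compressibility 3e-4 1/bar, 5 ps coupling; NVT at
#' the target temperature; production with `rdd = 1.6`), plus a
#' machine-readable YAML manifest listing every stage, seed and file.
#' Each replicate gets a distinct pseudo-random seed.
#'
#' @param plan a [slab_run_plan()]
#' @param packed a packed multi-chain `cc_system` consistent with the
#'   plan's protein
#' @param ff force field
#' @param dir output directory
#' @return invisibly, the manifest as a list (also written to
#'   `manifest.yaml`)
#' @export
prepare_slab_run <- function(plan, packed, ff, dir) {
  stopifnot(inherits(plan, "slab_run_plan"), inherits(packed, "cc_system"))
  nb_chain <- table(packed$beads$chain)
  if (length(unique(nb_chain)) != 1 ||
      as.integer(nb_chain[1]) != n_residues(plan$protein))
    stop("packed system does not match the plan's protein", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  runs <- list()
  for (ti in seq_along(plan$temperatures)) {
    tt <- plan$temperatures[ti]
    for (r in seq_len(plan$replicates)) {
      rdir <- file.path(dir, sprintf("T%03d_rep%d", tt, r))
      dir.create(rdir, showWarnings = FALSE)
      sd <- .plan_seed(plan, ti, r)
      write_gro(packed, file.path(rdir, "conf.gro"),
                title = sprintf("slab start %g K replicate %d", tt, r))
      write_top(packed, ff, file.path(rdir, "topol.top"))
      st <- plan$stages
      write_mdp(mdp_preset("min"), file.path(rdir, "min.mdp"))
      write_mdp(mdp_preset("npt", seed = sd,
                           nsteps = round(st$npt$duration_ps / st$npt$dt)),
                file.path(rdir, "npt.mdp"))
      write_mdp(mdp_preset("nvt", temperature = tt, seed = sd + 1L,
                           nsteps = round(st$nvt$duration_ps / st$nvt$dt)),
                file.path(rdir, "nvt.mdp"))
      write_mdp(mdp_preset("production", temperature = tt, seed = sd + 2L,
                           nsteps = round(st$production$duration_ps /
                                            st$production$dt)),
                file.path(rdir, "prod.mdp"))
      runs[[length(runs) + 1L]] <- list(
        temperature_K = tt, replicate = r, seed = sd,
        directory = basename(rdir),
        files = c("conf.gro", "topol.top", "min.mdp", "npt.mdp", "nvt.mdp",
                  "prod.mdp"),
        stages = list(
          minimize = list(force_tol_kJ_mol_nm = 50, step_nm = 0.002),
          npt = list(duration_ps = st$npt$duration_ps, dt_ps = st$npt$dt,
                     temperature_K = st$npt$temperature,
                     barostat = "Parrinello-Rahman semiisotropic z-only",
                     ref_p_bar = 1.0, compressibility_per_bar = 3e-4,
                     tau_p_ps = 5.0),
          expand = list(final_z_nm = plan$stages$final_z,
                        recenter = TRUE, unwrap = TRUE),
          nvt = list(duration_ps = st$nvt$duration_ps, dt_ps = st$nvt$dt,
                     temperature_K = tt),
          production = list(duration_ps = st$production$duration_ps,
                            dt_ps = st$production$dt, temperature_K = tt,
                            rdd_nm = 1.6)))
    }
  }
  manifest <- list(
    protein = plan$protein$name,
    coil_budget = plan$coil_budget,
    chains = length(unique(packed$beads$chain)),
    beads = n_beads(packed),
    box_nm = packed$box,
    tolerance_nm = plan$tolerance,
    desk_scale = plan$desk_scale,
    runs = runs)
  yaml::write_yaml(manifest, file.path(dir, "manifest.yaml"))
  invisible(manifest)
}

#' Unwrap molecules across periodic boundaries
#'
#' Walks each chain along its bond connectivity and places every bead at
#' the minimum-image position relative to its predecessor, so no
#' molecule is split across a boundary.
#'
#' @param system a `cc_system`
#' @return the system with whole molecules
#' @export
unwrap_molecules <- function(system) {
  x <- system$coords
  box <- system$box
  for (ch in unique(system$beads$chain)) {
    ix <- which(system$beads$chain == ch)
    for (q in seq_along(ix)[-1]) {
      d <- x[ix[q], ] - x[ix[q - 1L], ]
      d <- d - box * round(d / box)
      x[ix[q], ] <- x[ix[q - 1L], ] + d
    }
  }
  system$coords <- x
  system
}

#' Expand the box along z, keeping the slab centred
#'
#' Molecules are unwrapped first (so none is split by the expansion),
#' the slab's z centre of mass is found on the periodic circle, and the
#' whole configuration is shifted so the slab sits at the centre of the
#' new, longer box.
#'
#' @param system a `cc_system`
#' @param new_z new z-length in nm (default 150)
#' @return the expanded system
#' @export
expand_box_z <- function(system, new_z = 150) {
  stopifnot(new_z >= system$box[3])
  sys <- unwrap_molecules(system)
  lz <- sys$box[3]
  # slab centre via circular mean over the old periodic z
  th <- (sys$coords[, 3] %% lz) / lz * 2 * pi
  centre <- (atan2(mean(sin(th)), mean(cos(th))) / (2 * pi)) %% 1 * lz
  # wrap chain centres into the old box, then recentre at new_z / 2
  for (ch in unique(sys$beads$chain)) {
    ix <- which(sys$beads$chain == ch)
    com_z <- mean(sys$coords[ix, 3])
    shift <- ((com_z - centre) %% lz)
    if (shift > lz / 2) shift <- shift - lz
    sys$coords[ix, 3] <- sys$coords[ix, 3] - com_z + new_z / 2 + shift
  }
  sys$box[3] <- new_z
  sys
}

#' Centre/edge density time series of a trajectory
#'
#' Per-frame number density of the central window of the box and of the
#' two end windows combined — the two series whose simultaneous
#' stability defines slab equilibration.
#'
#' @param traj a `cc_trajectory`
#' @param centre_fraction fraction of the z-length forming the central
#'   window (default 1/15, i.e. 10 nm of a 150 nm box)
#' @param edge_fraction fraction of the z-length at *each* end (default
#'   7/30, mirroring the 35 nm edge windows of a 150 nm box)
#' @return object of class `density_timeseries` with `times`,
#'   `center_density`, `edge_density` (nm^-3)
#' @export
density_timeseries <- function(traj, centre_fraction = 1 / 15,
                               edge_fraction = 7 / 30) {
  box <- if (is.matrix(traj$box)) traj$box[1, ] else traj$box
  lz <- box[3]
  half_c <- centre_fraction * lz / 2
  ctr <- c(lz / 2 - half_c, lz / 2 + half_c)
  edge <- edge_fraction * lz
  v_ctr <- box[1] * box[2] * (ctr[2] - ctr[1])
  v_edge <- box[1] * box[2] * 2 * edge
  cd <- ed <- numeric(n_frames(traj))
  for (q in seq_along(traj$frames)) {
    z <- traj$frames[[q]][, 3] %% lz
    cd[q] <- sum(z >= ctr[1] & z < ctr[2]) / v_ctr
    ed[q] <- sum(z < edge | z >= lz - edge) / v_edge
  }
  new_density_timeseries(traj$times, cd, ed)
}

#' Construct a density time series
#' @param times sample times in ps
#' @param center_density,edge_density number densities in nm^-3
#' @export
new_density_timeseries <- function(times, center_density, edge_density) {
  stopifnot(length(times) == length(center_density),
            length(times) == length(edge_density),
            all(center_density >= 0), all(edge_density >= 0))
  structure(list(times = times, center_density = center_density,
                 edge_density = edge_density),
            class = "density_timeseries")
}

# fitted linear slope of y over 1..n (per sample)
.win_slope <- function(y) {
  n <- length(y)
  ix <- seq_len(n) - (n + 1) / 2
  sum(ix * (y - mean(y))) / sum(ix^2)
}

# relative change across one window: |slope| * (window-1) / |window mean|
.rel_window_change <- function(y) {
  mu <- abs(mean(y))
  if (mu < 1e-12) return(0) # an (almost) empty region is trivially stable
  abs(.win_slope(y)) * (length(y) - 1) / mu
}

#' Detect equilibration from centre/edge density stability
#'
#' The slab is considered equilibrated from the earliest time t* such
#' that over *every* subsequent sliding window both the centre and the
#' edge densities are stable — operationalized as the magnitude of the
#' fitted linear change across the window staying below `slope_tol`
#' (relative to the window mean). Downstream analyses should use only
#' t >= t*.
#'
#' @param series a [density_timeseries()]
#' @param window window length in samples (default 10)
#' @param slope_tol maximum relative change per window (default 0.02)
#' @return the equilibration start time in ps, or `NA` (with message
#'   `"not equilibrated"` as attribute) if no such time exists
#' @export
detect_equilibration <- function(series, window = 10L, slope_tol = 0.02) {
  stopifnot(inherits(series, "density_timeseries"), window >= 2)
  n <- length(series$times)
  if (n < 2 * window)
    stop("series shorter than two windows", call. = FALSE)
  n_win <- n - window + 1L
  ok <- logical(n_win)
  for (u in seq_len(n_win)) {
    ix <- u:(u + window - 1L)
    ok[u] <- .rel_window_change(series$center_density[ix]) < slope_tol &&
      .rel_window_change(series$edge_density[ix]) < slope_tol
  }
  bad <- which(!ok)
  start <- if (!length(bad)) 1L else max(bad) + 1L
  if (start > n_win) {
    out <- NA_real_
    attr(out, "status") <- "not equilibrated"
    return(out)
  }
  series$times[start]
}

#' Run the full slab pipeline at desk scale
#'
#' Executes every stage of the phase-coexistence protocol with the
#' internal engine: single-molecule production, configuration selection,
#' packing to the coil budget, minimization, staged z-compression
#' (NPT-analogue at 150 K), expansion with recentering, NVT temperature
#' equilibration and NVT production.
#'
#' @param spec a [protein_spec()]
#' @param ff force field
#' @param temperature production temperature in K
#' @param plan a desk-scale [slab_run_plan()]; `NULL` builds the default
#' @param copies number of chains (overrides the plan's coil budget when
#'   given)
#' @param sample_ps production frame interval in ps
#' @param seed RNG seed
#' @return list with the production `trajectory`, the final `system`,
#'   and the intermediate systems (`packed`, `compressed`, `expanded`)
#' @export
run_slab_pipeline <- function(spec, ff, temperature = 293, plan = NULL,
                              copies = NULL, sample_ps = 250, seed = 1L) {
  if (is.null(plan)) plan <- slab_run_plan(spec, desk_scale = TRUE,
                                           seed = seed)
  st <- plan$stages
  sm <- run_single_molecule(spec, ff, temperature = temperature,
                            equil_ps = st$single_molecule$equil_ps,
                            prod_ps = st$single_molecule$prod_ps,
                            sample_ps = st$single_molecule$prod_ps / 50,
                            seed = seed)
  pool <- select_configurations(sm, n = 5,
                                t_equil = st$single_molecule$prod_ps / 10,
                                seed = seed + 1L)
  single <- build_protein(spec, ff)
  packed <- pack_slab_box(single, pool, coil_budget = plan$coil_budget,
                          copies = copies, box = st$pack_box,
                          tolerance = plan$tolerance, seed = seed + 2L)
  packed <- minimize(packed, ff)
  compressed <- compress_z(packed, ff,
                           target_fraction = st$npt$target_fraction,
                           relax_steps = round(st$npt$duration_ps /
                                                 st$npt$dt / 10),
                           relax_temperature = st$npt$temperature,
                           dt = st$npt$dt, seed = seed + 3L)
  expanded <- expand_box_z(compressed, new_z = st$final_z)
  nvt <- run_langevin(expanded, ff,
                      integrator_settings(dt = st$nvt$dt,
                                          temperature = temperature,
                                          seed = seed + 4L),
                      n_steps = round(st$nvt$duration_ps / st$nvt$dt),
                      sample_interval = round(st$nvt$duration_ps /
                                                st$nvt$dt))
  eq_sys <- attr(nvt, "final_system")
  prod <- run_langevin(eq_sys, ff,
                       integrator_settings(dt = st$production$dt,
                                           temperature = temperature,
                                           seed = seed + 5L),
                       n_steps = round(st$production$duration_ps /
                                         st$production$dt),
                       sample_interval = max(1L, round(sample_ps /
                                                         st$production$dt)),
                       velocities = attr(nvt, "final_velocities"))
  list(trajectory = prod, system = attr(prod, "final_system"),
       packed = packed, compressed = compressed, expanded = expanded)
}
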