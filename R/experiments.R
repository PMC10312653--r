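# Desk-scale experiment presets: miniature versions of the study's two
# computational assays (multimerization capacity, slab coexistence) that
# the internal engine can run on one CPU in minutes. Box sizes and
# durations are the package's desk-scale defaults; the at-scale protocol
# is exported through prepare_slab_run() instead.

#' Desk-scale multimerization-capacity experiment
#'
#' Packs several copies of the 3-coil-2-linker protein with the chosen
#' multimer mode into a cubic box, minimizes, runs NVT Langevin dynamics
#' at 293 K and returns the multimer census averaged over the whole
#' production run — the census is a composition *over simulation time*,
#' so the association from the monomeric start is part of the average.
#'
#' @param mode multimer mode name or [multimer_mode()]
#' @param copies protein copies (default 10)
#' @param box_nm cubic box edge in nm (default 14)
#' @param prod_ps production length in ps (default 8000)
#' @param temperature K (default 293)
#' @param sample_ps frame interval in ps (default 100)
#' @param seed RNG seed
#' @return list with the `census` ([multimer_census()] result), the
#'   production `trajectory`, `max_multimer` (time-averaged largest coil
#'   component) and `max_cluster_fraction` (largest molecular cluster as
#'   a fraction of chains, last frame)
#' @export
multimer_census_experiment <- function(mode, copies = 10L, box_nm = 14,
                                       prod_ps = 8000, temperature = 293,
                                       sample_ps = 100, seed = 1L) {
  ff <- default_forcefield(mode)
  spec <- make_coil_protein(3, mode)
  single <- build_protein(spec, ff)
  packed <- pack_slab_box(single, copies = copies, box = rep(box_nm, 3),
                          tolerance = 1.0, seed = seed)
  packed <- minimize(packed, ff)
  dt <- 0.025
  traj <- run_langevin(packed, ff,
                       integrator_settings(temperature = temperature,
                                           seed = seed + 1L),
                       n_steps = round(prod_ps / dt),
                       sample_interval = round(sample_ps / dt))
  census <- multimer_census(traj)
  last <- traj$frames[[n_frames(traj)]]
  sizes <- molecule_clusters(last, traj$beads$chain, traj$box, cutoff = 0.9)
  list(census = census, trajectory = traj,
       max_multimer = mean(census$max_component),
       max_cluster_fraction = max(sizes) / copies)
}

#' Desk-scale slab coexistence experiment
#'
#' Runs the full miniature slab pipeline ([run_slab_pipeline()]) for a
#' protein at one temperature and reduces the production trajectory to
#' the coexistence observables: the z density profile, dense and dilute
#' densities (scaled analysis windows), their ratio, and the
#' cluster-size distribution.
#'
#' @param spec a [protein_spec()]
#' @param ff force field
#' @param temperature K
#' @param copies chain copies in the miniature box
#' @param prod_ps production length in ps
#' @param seed RNG seed
#' @return list with `profile`, `rho_dense`, `rho_dilute`, `ratio`,
#'   `clusters`, `verdict` and the pipeline `result`
#' @export
slab_coexistence_experiment <- function(spec, ff, temperature,
                                        copies = 6L, prod_ps = 4000,
                                        seed = 1L) {
  plan <- slab_run_plan(spec, desk_scale = TRUE, seed = seed)
  plan$stages$production$duration_ps <- prod_ps
  res <- run_slab_pipeline(spec, ff, temperature = temperature,
                           plan = plan, copies = copies,
                           sample_ps = 200, seed = seed)
  # analyse the latter half of the production run
  keep <- res$trajectory$times >= prod_ps / 2
  traj <- res$trajectory
  traj$frames <- traj$frames[keep]
  traj$times <- traj$times[keep]
  profile <- density_profile(traj)
  dd <- dense_dilute(profile)
  ratio <- if (dd["rho_dilute"] <= 0) Inf else
    unname(dd["rho_dense"] / dd["rho_dilute"])
  clusters <- cluster_size_distribution(traj, every_ps = 500)
  verdict <- call_llps(profile, clusters, n_proteins = copies)
  list(profile = profile, rho_dense = unname(dd["rho_dense"]),
       rho_dilute = unname(dd["rho_dilute"]), ratio = ratio,
       clusters = clusters, verdict = verdict, result = res)
}
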