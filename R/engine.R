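# R interface to the compiled Langevin dynamics engine.

# Map a cc_system + force field onto the flat argument list the compiled
# kernels take. Sticky interaction groups are integer-coded (0 = inert);
# attraction applies only to equal nonzero groups on different chains, so
# the maximally specific scheme and the interchain restriction are
# structural properties of the energy function. Nonbonded exclusions are
# the 1-2, 1-3 and 1-4 pairs spanned by the bonded terms.
.engine_args <- function(system, ff, fcap = 2000, skin = 0.3) {
  stopifnot(inherits(system, "cc_system"), inherits(ff, "cc_forcefield"))
  levels_sticky <- unique(system$beads$itype[system$beads$itype != "inert"])
  itype <- match(system$beads$itype, levels_sticky)
  itype[is.na(itype)] <- 0L
  ex <- rbind(
    cbind(system$bonds$ai, system$bonds$aj),
    if (nrow(system$angles)) cbind(system$angles$ai, system$angles$ak),
    if (nrow(system$torsions)) cbind(system$torsions$ai, system$torsions$al)
  )
  ex <- unique(ex)
  deg <- pi / 180
  list(
    itype = as.integer(itype),
    chain = as.integer(system$beads$chain),
    mass = as.numeric(system$beads$mass),
    eps_attr = ff$mode$epsilon_coil,
    eps_rep = ff$eps_rep,
    sigma = ff$sigma,
    cutoff = ff$cutoff,
    shifted = isTRUE(ff$shifted),
    fcap = fcap,
    skin = skin,
    bond_i = as.integer(system$bonds$ai), bond_j = as.integer(system$bonds$aj),
    bond_r0 = as.numeric(system$bonds$r0), bond_k = as.numeric(system$bonds$kf),
    angle_i = as.integer(system$angles$ai), angle_j = as.integer(system$angles$aj),
    angle_k = as.integer(system$angles$ak),
    angle_t0 = as.numeric(system$angles$theta0) * deg,
    angle_kf = as.numeric(system$angles$kf),
    tors_i = as.integer(system$torsions$ai), tors_j = as.integer(system$torsions$aj),
    tors_k = as.integer(system$torsions$ak), tors_l = as.integer(system$torsions$al),
    tors_p0 = as.numeric(system$torsions$phi0) * deg,
    tors_kf = as.numeric(system$torsions$kf),
    tors_m = as.integer(system$torsions$mult),
    excl_i = as.integer(ex[, 1]), excl_j = as.integer(ex[, 2])
  )
}

#' Potential energy and forces of a system
#'
#' Harmonic bonds and angles, periodic torsions, and
#' truncated-and-shifted Lennard-Jones over eligible nonbonded pairs
#' under minimum-image periodic boundaries. Forces are the exact negative
#' gradient of the potential (pair forces are finitely capped for
#' near-overlapping beads, with a warning).
#'
#' @param system a `cc_system`
#' @param ff a [default_forcefield()]
#' @param fcap cap on the nonbonded pair force magnitude, kJ/mol/nm.
#'   The default (2000) repels overlapping beads firmly while staying
#'   below the force needed to tear a bond apart, so capped-core
#'   penetrations created by box compression relax without breaking
#'   chains; the pair *energy* is never capped, so barriers remain
#'   intact for minimization.
#' @return list with `potential` (kJ/mol), `forces` (n x 3, kJ/mol/nm),
#'   per-term components and `max_force`
#' @export
compute_potential_and_forces <- function(system, ff, fcap = 2000) {
  res <- cpp_energy_forces(system$coords, system$box,
                           .engine_args(system, ff, fcap = fcap))
  if (res$n_capped > 0)
    warning(sprintf("%d near-overlapping pair force(s) capped at %g kJ/mol/nm",
                    res$n_capped, fcap))
  res
}

#' Steepest-descent energy minimization
#'
#' GROMACS-style steepest descent: the trial displacement scales the
#' force so the largest bead moves by the current step size, the step
#' grows on accepted moves and shrinks on rejected ones. Converges when
#' the maximum per-bead force drops below `force_tol`.
#'
#' @param system a `cc_system`
#' @param ff force field
#' @param force_tol convergence tolerance in kJ/mol/nm (default 50)
#' @param step initial step size in nm (default 0.002, i.e. 2 pm)
#' @param max_steps iteration cap
#' @return the system with minimized coordinates; attributes `converged`,
#'   `steps`, `max_force`, `potential`
#' @export
minimize <- function(system, ff, force_tol = 50, step = 0.002,
                     max_steps = 20000L) {
  stopifnot(force_tol > 0, step > 0)
  res <- cpp_minimize(system$coords, system$box, .engine_args(system, ff),
                      force_tol, step, as.integer(max_steps))
  if (!res$converged && res$max_force >= force_tol)
    warning(sprintf("minimization stopped after %d steps at max force %.3g kJ/mol/nm (tolerance %g)",
                    res$steps, res$max_force, force_tol))
  out <- system
  out$coords <- res$coords
  attr(out, "converged") <- res$converged
  attr(out, "steps") <- res$steps
  attr(out, "max_force") <- res$max_force
  attr(out, "potential") <- res$potential
  out
}

#' Langevin integrator settings
#'
#' Defaults follow the framework's common run parameters: 25 fs time
#' step, friction 0.2 / ps, centre-of-mass translational velocity removed
#' every 10 steps.
#'
#' @param dt time step in ps (default 0.025)
#' @param friction friction coefficient in 1/ps (default 0.2); 0 gives
#'   the deterministic velocity-Verlet limit (no thermostat)
#' @param temperature target temperature in K
#' @param com_removal_interval steps between COM velocity removals
#' @param seed integer RNG seed
#' @export
integrator_settings <- function(dt = 0.025, friction = 0.2,
                                temperature = 293,
                                com_removal_interval = 10L, seed = 1L) {
  stopifnot(dt > 0, friction >= 0, temperature >= 0,
            com_removal_interval >= 1)
  structure(list(dt = dt, friction = friction, temperature = temperature,
                 com_removal_interval = as.integer(com_removal_interval),
                 seed = as.integer(seed)),
            class = "integrator_settings")
}

#' Construct a trajectory object
#' @keywords internal
#' @noRd
new_cc_trajectory <- function(times, frames, box, thermo, beads = NULL) {
  stopifnot(length(times) == length(frames), !is.unsorted(times))
  structure(list(times = times, frames = frames, box = box, thermo = thermo,
                 beads = beads),
            class = "cc_trajectory")
}

#' @export
print.cc_trajectory <- function(x, ...) {
  cat(sprintf("cc_trajectory: %d frames, %d beads, t = %g..%g ps\n",
              length(x$frames),
              if (length(x$frames)) nrow(x$frames[[1]]) else 0,
              if (length(x$times)) min(x$times) else NA,
              if (length(x$times)) max(x$times) else NA))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `cc_trajectory`
#' @export
n_frames <- function(traj) length(traj$frames)

#' Run Langevin dynamics
#'
#' BAOAB-split Langevin integration in the NVT ensemble. Trajectories are
#' bit-reproducible for a given seed. With `friction = 0` the scheme
#' reduces to velocity Verlet (microcanonical).
#'
#' @param system a `cc_system` (minimized or otherwise non-overlapping)
#' @param ff force field
#' @param settings an [integrator_settings()]
#' @param n_steps number of integration steps
#' @param sample_interval steps between saved frames / thermo samples
#' @param velocities optional n x 3 starting velocities (nm/ps); `NULL`
#'   draws Maxwell-Boltzmann velocities at the target temperature
#' @return a `cc_trajectory`; attributes `final_system` and
#'   `final_velocities` allow continuation runs
#' @export
run_langevin <- function(system, ff, settings = integrator_settings(),
                         n_steps, sample_interval = 1000L,
                         velocities = NULL) {
  stopifnot(inherits(settings, "integrator_settings"), n_steps >= 1)
  res <- cpp_run_langevin(system$coords, system$box,
                          .engine_args(system, ff),
                          settings$dt, settings$friction,
                          settings$temperature,
                          settings$com_removal_interval,
                          as.integer(n_steps), as.integer(sample_interval),
                          settings$seed, velocities)
  ns <- res$n_samples
  if (res$blew_up) {
    ns <- max(0L, ns - 1L)
    warning("run aborted: non-finite coordinates/energy; returning last valid frames")
  }
  frames <- lapply(seq_len(ns), function(s) res$frames[, , s, drop = TRUE])
  thermo <- data.frame(time_ps = res$times[seq_len(ns)],
                       T_K = res$T_K[seq_len(ns)],
                       E_pot_kJmol = res$E_pot[seq_len(ns)])
  traj <- new_cc_trajectory(res$times[seq_len(ns)], frames, system$box,
                            thermo, beads = system$beads)
  final <- system
  final$coords <- res$coords
  attr(traj, "final_system") <- final
  attr(traj, "final_velocities") <- res$velocities
  traj
}

#' Staged z-compression of a simulation box
#'
#' Desk-scale stand-in for semi-isotropic NPT compression: the box
#' z-length and the molecule centres of mass are rescaled in stages (each
#' molecule moves rigidly, so bonds are untouched), with a short Langevin
#' relaxation at `relax_temperature` between stages and a final energy
#' minimization. Fails if beads persistently overlap below half a bead
#' diameter.
#'
#' @param system a multi-chain `cc_system`
#' @param ff force field
#' @param target_fraction final z-length as a fraction of the initial one
#'   (0 < f < 1); the slab protocol targets the 0.10-0.20 band
#' @param n_stages number of compression stages (default 10)
#' @param relax_steps Langevin steps per stage
#' @param relax_temperature relaxation temperature in K (default 150)
#' @param dt relaxation time step in ps (default 0.02)
#' @param seed RNG seed for the relaxation runs
#' @return compressed and relaxed `cc_system`
#' @export
compress_z <- function(system, ff, target_fraction, n_stages = 10L,
                       relax_steps = 2000L, relax_temperature = 150,
                       dt = 0.02, seed = 1L) {
  stopifnot(target_fraction > 0, target_fraction < 1, n_stages >= 1)
  z0 <- system$box[3]
  f_stage <- target_fraction^(1 / n_stages)
  sys <- system
  vel <- NULL
  for (s in seq_len(n_stages)) {
    new_z <- if (s == n_stages) z0 * target_fraction else sys$box[3] * f_stage
    scale <- new_z / sys$box[3]
    # rigid molecule moves: rescale chain centres of mass along z
    com_z <- tapply(sys$coords[, 3], sys$beads$chain, mean)
    shift <- (scale - 1) * com_z[as.character(sys$beads$chain)]
    sys$coords[, 3] <- sys$coords[, 3] + shift
    sys$box[3] <- new_z
    st <- integrator_settings(dt = dt, friction = 1.0,
                              temperature = relax_temperature,
                              seed = seed + s)
    traj <- run_langevin(sys, ff, st, n_steps = relax_steps,
                         sample_interval = relax_steps, velocities = vel)
    sys <- attr(traj, "final_system")
    vel <- attr(traj, "final_velocities")
  }
  # resolve any residual hard inter-chain overlaps (capped-core
  # penetrations during the squeeze) with gentle low-temperature
  # relaxation between minimizations before giving up; bonded intra-chain
  # neighbours are excluded from the nonbonded potential and legitimately
  # sit closer than half a bead diameter
  overlap <- function(s) {
    d <- cpp_min_interchain_dist(s$coords, s$box, s$beads$chain,
                                 0.5 * ff$sigma)
    is.finite(d) && d < 0.5 * ff$sigma
  }
  for (attempt in 1:4) {
    sys <- suppressWarnings(minimize(sys, ff))
    if (!overlap(sys)) break
    if (attempt == 4) {
      dmin <- cpp_min_interchain_dist(sys$coords, sys$box,
                                      sys$beads$chain, 0.5 * ff$sigma)
      stop(sprintf("compression left bead overlaps (min distance %.3f nm < %.3f nm); try more stages",
                   dmin, 0.5 * ff$sigma), call. = FALSE)
    }
    st <- integrator_settings(dt = dt / 4, friction = 2.0,
                              temperature = relax_temperature / 2,
                              seed = seed + 100L + attempt)
    traj <- run_langevin(sys, ff, st, n_steps = 2000,
                         sample_interval = 2000)
    sys <- attr(traj, "final_system")
  }
  sys
}
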