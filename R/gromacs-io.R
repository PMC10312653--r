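# GROMACS-dialect file writers/readers: GRO coordinates, TOP/ITP
# topology, MDP run settings, plus a PDB writer for visualization and a
# plain CSV thermodynamics writer. Units: nm, ps, kJ/mol, amu, K.

.gro_atom_names <- function(beads) {
  ifelse(beads$kind == "coil", "COI", "LNK")
}

#' Write a GRO coordinate file
#'
#' Fixed-column GROMACS coordinate format (positions in nm). Residue
#' numbers count beads within each chain; residue names mark coil (`COI`)
#' and linker (`LNK`) beads, atom names are `CA`.
#'
#' @param system a `cc_system`
#' @param file output path
#' @param title title line content
#' @param append append a frame (for multi-frame trajectories)
#' @export
write_gro <- function(system, file, title = "coilslab system",
                      append = FALSE) {
  stopifnot(inherits(system, "cc_system"))
  n <- n_beads(system)
  if (n == 0) stop("cannot write a system with zero beads", call. = FALSE)
  resname <- .gro_atom_names(system$beads)
  resnr <- sequence(rle(system$beads$chain)$lengths)
  lines <- c(
    title,
    sprintf("%5d", n),
    sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
            resnr %% 100000L, resname, "CA", seq_len(n) %% 100000L,
            system$coords[, 1], system$coords[, 2], system$coords[, 3]),
    sprintf("%10.5f%10.5f%10.5f", system$box[1], system$box[2], system$box[3])
  )
  con <- file(file, if (append) "a" else "w")
  on.exit(close(con))
  writeLines(lines, con)
  invisible(file)
}

#' Read a GRO coordinate file (single frame or trajectory)
#'
#' @param file path to a GRO file; multi-frame files (concatenated
#'   frames) are supported
#' @return for a single frame, a list with `coords`, `box`, `natoms`,
#'   `title`; for multiple frames a list of such frames
#' @export
read_gro <- function(file) {
  lines <- readLines(file)
  frames <- list()
  i <- 1L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    title <- lines[i]
    natoms <- as.integer(trimws(lines[i + 1L]))
    at <- lines[i + 2L + seq_len(natoms) - 1L]
    coords <- cbind(as.numeric(substr(at, 21, 28)),
                    as.numeric(substr(at, 29, 36)),
                    as.numeric(substr(at, 37, 44)))
    box <- as.numeric(strsplit(trimws(lines[i + 2L + natoms]), "\\s+")[[1]])[1:3]
    tm <- regmatches(title, regexec("t=\\s*([0-9.eE+-]+)", title))[[1]]
    frames[[length(frames) + 1L]] <-
      list(coords = coords, box = box, natoms = natoms, title = title,
           time = if (length(tm) == 2) as.numeric(tm[2]) else NA_real_)
    i <- i + 3L + natoms
  }
  if (length(frames) == 1) frames[[1]] else frames
}

#' Write a trajectory as a multi-frame GRO file
#'
#' @param traj a `cc_trajectory`
#' @param system a `cc_system` supplying bead metadata
#' @param file output path
#' @export
write_gro_trajectory <- function(traj, system, file) {
  stopifnot(inherits(traj, "cc_trajectory"))
  if (file.exists(file)) file.remove(file)
  for (q in seq_along(traj$frames)) {
    sys <- system
    sys$coords <- traj$frames[[q]]
    if (is.matrix(traj$box)) sys$box <- traj$box[q, ]
    write_gro(sys, file, title = sprintf("frame %d t= %.4f", q, traj$times[q]),
              append = TRUE)
  }
  invisible(file)
}

#' Read a multi-frame GRO file into a trajectory
#'
#' @param file path
#' @param beads optional bead metadata to attach
#' @export
read_gro_trajectory <- function(file, beads = NULL) {
  frames <- read_gro(file)
  if (!is.null(frames$coords)) frames <- list(frames)
  times <- vapply(frames, `[[`, numeric(1), "time")
  if (anyNA(times)) times <- seq_along(frames) - 1
  new_cc_trajectory(times, lapply(frames, `[[`, "coords"),
                    frames[[1]]$box, thermo = NULL, beads = beads)
}

# interaction-type names used in topologies: BB backbone, LNK linker,
# S<k> the k-th sticky coil type
.top_types <- function(system) {
  sticky_ids <- unique(system$beads$itype[system$beads$itype != "inert"])
  type_of <- ifelse(system$beads$itype != "inert",
                    paste0("S", match(system$beads$itype, sticky_ids)),
                    ifelse(system$beads$kind == "coil", "BB", "LNK"))
  list(type_of = type_of,
       names = c("BB", "LNK", paste0("S", seq_along(sticky_ids))),
       sticky_names = paste0("S", seq_along(sticky_ids)))
}

#' Write a GROMACS topology (TOP) file
#'
#' Emits `[ defaults ]` (LJ, sigma/epsilon combination rule),
#' `[ atomtypes ]` with the excluded-volume epsilon, `[ nonbond_params ]`
#' overrides carrying the sticky attraction for same-type pairs, one
#' `[ moleculetype ]` with atoms/bonds/angles/dihedrals, `[ exclusions ]`
#' suppressing intrachain sticky-sticky attraction, and `[ molecules ]`
#' with the chain count. All chains must be copies of the same molecule.
#'
#' Torsions are written as GROMACS proper dihedrals
#' \eqn{k(1+\cos(n\phi - \phi_s))} with \eqn{\phi_s = n\phi_0 + 180}, the
#' form equivalent to the engine's \eqn{k(1-\cos(n(\phi-\phi_0)))}.
#'
#' @param system a `cc_system`
#' @param ff force field
#' @param file output path
#' @param name molecule name
#' @export
write_top <- function(system, ff, file, name = "CCPROT") {
  stopifnot(inherits(system, "cc_system"), inherits(ff, "cc_forcefield"))
  chains <- system$beads$chain
  n_chain <- length(unique(chains))
  per <- table(chains)
  if (length(unique(per)) != 1)
    stop("write_top requires identical chains", call. = FALSE)
  nb <- as.integer(per[1])
  sel <- which(chains == chains[1])
  tt <- .top_types(system)
  type1 <- tt$type_of[sel]
  out <- c(
    "; coilslab topology",
    "[ defaults ]",
    "; nbfunc comb-rule gen-pairs fudgeLJ fudgeQQ",
    "1 2 no 1.0 1.0",
    "",
    "[ atomtypes ]",
    "; name mass charge ptype sigma epsilon",
    sprintf("%-6s %8.3f 0.000 A %8.4f %8.4f", tt$names, ff$mass, ff$sigma,
            ff$eps_rep),
    "",
    "[ nonbond_params ]",
    "; i j func sigma epsilon   (sticky same-type attraction)",
    sprintf("%-4s %-4s 1 %8.4f %8.4f", tt$sticky_names, tt$sticky_names,
            ff$sigma, ff$mode$epsilon_coil),
    "",
    "[ moleculetype ]",
    "; name nrexcl",
    sprintf("%s 3", name),
    "",
    "[ atoms ]",
    "; nr type resnr resname atom cgnr charge mass",
    sprintf("%5d %-5s %5d %-5s %-4s %5d 0.000 %8.3f",
            seq_len(nb), type1, seq_len(nb),
            .gro_atom_names(system$beads[sel, ]), "CA", seq_len(nb), ff$mass)
  )
  b <- system$bonds[system$bonds$ai %in% sel & system$bonds$aj %in% sel, ]
  out <- c(out, "", "[ bonds ]", "; ai aj func r0 k",
           sprintf("%5d %5d 1 %8.4f %10.2f", b$ai, b$aj, b$r0, b$kf))
  a <- system$angles[system$angles$ai %in% sel, ]
  out <- c(out, "", "[ angles ]", "; ai aj ak func theta0 k",
           sprintf("%5d %5d %5d 1 %8.3f %10.3f", a$ai, a$aj, a$ak,
                   a$theta0, a$kf))
  t <- system$torsions[system$torsions$ai %in% sel, ]
  phis <- t$mult * t$phi0 + 180
  phis <- ((phis + 180) %% 360) - 180
  out <- c(out, "", "[ dihedrals ]", "; ai aj ak al func phi_s k mult",
           sprintf("%5d %5d %5d %5d 1 %8.3f %10.4f %d", t$ai, t$aj, t$ak,
                   t$al, phis, t$kf, t$mult))
  # intrachain sticky-sticky same-type exclusions
  excl_lines <- character()
  for (sid in unique(type1[startsWith(type1, "S")])) {
    ix <- which(type1 == sid)
    if (length(ix) > 1) {
      for (q in seq_along(ix)[-length(ix)]) {
        excl_lines <- c(excl_lines,
                        paste(c(ix[q], ix[(q + 1):length(ix)]), collapse = " "))
      }
    }
  }
  if (length(excl_lines))
    out <- c(out, "", "[ exclusions ]", excl_lines)
  out <- c(out, "", "[ system ]", "coilslab slab system", "",
           "[ molecules ]", sprintf("%s %d", name, n_chain))
  writeLines(out, file)
  invisible(file)
}

#' Parse a coilslab-dialect topology file
#'
#' Reads back the term counts and molecule count written by
#' [write_top()] (only this package's dialect is supported).
#'
#' @param file path
#' @return list with `natoms`, `nbonds`, `nangles`, `ndihedrals`,
#'   `nmolecules`, `total_atoms`
#' @export
read_top <- function(file) {
  lines <- readLines(file)
  lines <- trimws(sub(";.*", "", lines))
  sec <- ""
  counts <- c(atoms = 0L, bonds = 0L, angles = 0L, dihedrals = 0L)
  nmol <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) next
    m <- regmatches(ln, regexec("^\\[\\s*(\\w+)\\s*\\]$", ln))[[1]]
    if (length(m) == 2) { sec <- m[2]; next }
    if (sec %in% names(counts)) counts[sec] <- counts[sec] + 1L
    if (sec == "molecules") {
      parts <- strsplit(ln, "\\s+")[[1]]
      nmol <- nmol + as.integer(parts[2])
    }
  }
  list(natoms = unname(counts["atoms"]), nbonds = unname(counts["bonds"]),
       nangles = unname(counts["angles"]),
       ndihedrals = unname(counts["dihedrals"]), nmolecules = nmol,
       total_atoms = unname(counts["atoms"]) * nmol)
}

#' Write a GROMACS MDP run-settings file
#'
#' @param params named list of mdp keys (underscores are written as
#'   hyphens, the GROMACS convention)
#' @param file output path
#' @export
write_mdp <- function(params, file) {
  keys <- gsub("_", "-", names(params))
  vals <- vapply(params, function(v)
    paste(vapply(v, function(x) format(x, scientific = FALSE, trim = TRUE),
                 character(1)), collapse = " "), character(1))
  writeLines(sprintf("%-28s = %s", keys, vals), file)
  invisible(file)
}

#' Read an MDP file into a named list
#' @param file path
#' @export
read_mdp <- function(file) {
  lines <- trimws(sub(";.*", "", readLines(file)))
  lines <- lines[nzchar(lines)]
  kv <- strsplit(lines, "\\s*=\\s*")
  out <- lapply(kv, `[`, 2)
  names(out) <- vapply(kv, `[`, character(1), 1)
  out
}

# shared run settings of the framework: sd (Langevin) integrator with
# inverse friction tau-t = 5 ps, shifted LJ cut off at 1.1 nm, strict
# Verlet buffer tolerance, COM motion removal every 10 steps
.mdp_common <- function(temperature, dt, nsteps, seed) {
  list(
    integrator = "sd",
    dt = dt,
    nsteps = format(nsteps, scientific = FALSE),
    cutoff_scheme = "Verlet",
    verlet_buffer_tolerance = "1e-7",
    nstlist = 10,
    rvdw = 1.1,
    vdw_modifier = "Potential-shift-Verlet",
    coulombtype = "Cut-off",
    rcoulomb = 1.1,
    pbc = "xyz",
    tc_grps = "System",
    tau_t = 5.0,           # inverse of the 0.2 / ps friction coefficient
    ref_t = temperature,
    ld_seed = seed,
    comm_mode = "Linear",
    nstcomm = 10,
    nstxout_compressed = 40000,
    nstenergy = 40000
  )
}

#' MDP presets for the slab protocol stages
#'
#' Returns the run-settings list for one stage of the phase-coexistence
#' pipeline: steepest-descent minimization (force tolerance 50 kJ/mol/nm,
#' step 2 pm), NPT slab formation (200 ns, 20 fs step, 150 K,
#' Parrinello-Rahman semi-isotropic z-only barostat at 1 bar,
#' compressibility 3e-4 1/bar, 5 ps coupling constant), NVT equilibration
#' (200 ns, 20 fs) and NVT production (20 us, 25 fs, rdd 1.6 nm).
#'
#' @param stage one of `"min"`, `"npt"`, `"nvt"`, `"production"`,
#'   `"single_molecule"`
#' @param temperature reference temperature in K (ignored for `min`)
#' @param seed Langevin seed written as `ld-seed`
#' @param nsteps override the stage's default step count (used by
#'   desk-scale plans)
#' @export
mdp_preset <- function(stage = c("min", "npt", "nvt", "production",
                                 "single_molecule"),
                       temperature = 293, seed = -1, nsteps = NULL) {
  stage <- match.arg(stage)
  if (stage == "min") {
    return(list(integrator = "steep", emtol = 50, emstep = 0.002,
                nsteps = 50000, cutoff_scheme = "Verlet", rvdw = 1.1,
                vdw_modifier = "Potential-shift-Verlet",
                coulombtype = "Cut-off", rcoulomb = 1.1, pbc = "xyz"))
  }
  out <- switch(stage,
    npt = {
      p <- .mdp_common(150, 0.020, if (is.null(nsteps)) 1e7 else nsteps, seed)
      c(p, list(pcoupl = "Parrinello-Rahman", pcoupltype = "semiisotropic",
                ref_p = c(1.0, 1.0), compressibility = c(0, 3e-4),
                tau_p = 5.0))
    },
    nvt = .mdp_common(temperature, 0.020,
                      if (is.null(nsteps)) 1e7 else nsteps, seed),
    production = c(.mdp_common(temperature, 0.025,
                               if (is.null(nsteps)) 8e8 else nsteps, seed),
                   list(rdd = 1.6)),
    single_molecule = .mdp_common(temperature, 0.025,
                                  if (is.null(nsteps)) 2e8 else nsteps, seed)
  )
  out
}

#' Write a PDB file for visualization
#'
#' Coordinates are converted from nm to Angstrom.
#'
#' @param system a `cc_system`
#' @param file output path
#' @export
write_pdb <- function(system, file) {
  n <- n_beads(system)
  resname <- .gro_atom_names(system$beads)
  chain_letter <- LETTERS[((system$beads$chain - 1L) %% 26L) + 1L]
  lines <- sprintf(
    "ATOM  %5d  CA  %-3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
    seq_len(n) %% 100000L, resname, chain_letter,
    sequence(rle(system$beads$chain)$lengths) %% 10000L,
    system$coords[, 1] * 10, system$coords[, 2] * 10, system$coords[, 3] * 10)
  writeLines(c(sprintf(
    "CRYST1%9.3f%9.3f%9.3f  90.00  90.00  90.00 P 1           1",
    system$box[1] * 10, system$box[2] * 10, system$box[3] * 10),
    lines, "END"), file)
  invisible(file)
}

#' Write the thermodynamic series of a trajectory as CSV
#'
#' Columns: `time_ps`, `T_K`, `E_pot_kJmol`.
#'
#' @param traj a `cc_trajectory` with a thermo table
#' @param file output path
#' @export
write_thermo_csv <- function(traj, file) {
  stopifnot(!is.null(traj$thermo))
  write.csv(traj$thermo, file, row.names = FALSE)
  invisible(file)
}

#' Export a complete GROMACS run file set
#'
#' Writes the coordinate file (`conf.gro`), topology (`topol.top`) and a
#' set of MDP files for the requested stages into `dir`. Re-importing
#' the exported files reproduces bead count, box and bonded-term counts
#' exactly.
#'
#' @param system a `cc_system`
#' @param ff force field
#' @param dir output directory (created if needed)
#' @param stages character vector of [mdp_preset()] stages
#' @param temperature reference temperature for thermostatted stages
#' @param seed `ld-seed` value
#' @return invisibly, the paths written
#' @export
export_gromacs <- function(system, ff, dir,
                           stages = c("min", "npt", "nvt", "production"),
                           temperature = 293, seed = -1) {
  if (n_beads(system) == 0) stop("system with zero beads", call. = FALSE)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create directory ", dir, call. = FALSE)
  paths <- c(
    gro = file.path(dir, "conf.gro"),
    top = file.path(dir, "topol.top")
  )
  write_gro(system, paths["gro"])
  write_top(system, ff, paths["top"])
  for (st in stages) {
    p <- file.path(dir, paste0(st, ".mdp"))
    write_mdp(mdp_preset(st, temperature = temperature, seed = seed), p)
    paths[st] <- p
  }
  invisible(paths)
}
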