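# shared builders for small test systems

# a bare cc_system from coordinates and minimal metadata, bypassing the
# protein builder (for hand-crafted nonbonded/bonded cases)
bare_system <- function(coords, box, chain = rep(1L, nrow(coords)),
                        itype = rep("inert", nrow(coords)),
                        sticky = itype != "inert",
                        coil_id = ifelse(sticky, 1L, 0L),
                        bonds = NULL, mass = 109) {
  n <- nrow(coords)
  beads <- data.frame(
    chain = as.integer(rep_len(chain, n)),
    segment = rep_len(1L, n),
    kind = rep_len(ifelse(itype == "inert", "linker", "coil"), n),
    coil_id = as.integer(rep_len(coil_id, n)),
    class = rep_len(ifelse(sticky, "coil_sticky", "linker_inert"), n),
    itype = rep_len(itype, n), sticky = rep_len(sticky, n),
    mass = rep_len(mass, n),
    stringsAsFactors = FALSE)
  empty_bonds <- data.frame(ai = integer(), aj = integer(),
                            r0 = numeric(), kf = numeric())
  empty_ang <- data.frame(ai = integer(), aj = integer(), ak = integer(),
                          theta0 = numeric(), kf = numeric())
  empty_tor <- data.frame(ai = integer(), aj = integer(), ak = integer(),
                          al = integer(), phi0 = numeric(), kf = numeric(),
                          mult = integer())
  sys <- list(coords = coords, box = box, beads = beads,
              bonds = if (is.null(bonds)) empty_bonds else bonds,
              angles = empty_ang, torsions = empty_tor, spec = NULL)
  class(sys) <- "cc_system"
  sys
}

# small randomly perturbed protein system for gradient checks
perturbed_protein <- function(n_coils = 2, mode = "dimer", sd = 0.02,
                              seed = 42) {
  ff <- default_forcefield(mode)
  sys <- build_protein(make_coil_protein(n_coils, mode), ff)
  set.seed(seed)
  sys$coords <- sys$coords + matrix(rnorm(3 * n_beads(sys), sd = sd),
                                    ncol = 3)
  list(system = sys, ff = ff)
}

# finite-difference gradient of the potential at selected beads
fd_forces <- function(system, ff, beads, h = 1e-6) {
  out <- matrix(NA_real_, length(beads), 3)
  for (q in seq_along(beads)) {
    i <- beads[q]
    for (k in 1:3) {
      cp <- system; cp$coords[i, k] <- cp$coords[i, k] + h
      cm <- system; cm$coords[i, k] <- cm$coords[i, k] - h
      out[q, k] <- -(compute_potential_and_forces(cp, ff)$potential -
                       compute_potential_and_forces(cm, ff)$potential) /
        (2 * h)
    }
  }
  out
}

# brute-force single-linkage molecular clustering oracle (O(n^2) pairs +
# union-find), minimum-image distances
oracle_clusters <- function(coords, chain_ids, box, cutoff) {
  chains <- sort(unique(chain_ids))
  parent <- seq_along(chains)
  find <- function(a) { while (parent[a] != a) a <- parent[a]; a }
  n <- nrow(coords)
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (chain_ids[i] == chain_ids[j]) next
    d <- coords[i, ] - coords[j, ]
    d <- d - box * round(d / box)
    if (sqrt(sum(d^2)) < cutoff) {
      a <- find(match(chain_ids[i], chains))
      b <- find(match(chain_ids[j], chains))
      if (a != b) parent[b] <- a
    }
  }
  roots <- vapply(seq_along(chains), find, integer(1))
  as.integer(table(roots))
}

# exhaustive-scan oracle for equilibration detection: literal double
# loop over every candidate start and every subsequent window
oracle_equilibration <- function(series, window, slope_tol) {
  n <- length(series$times)
  relchange <- function(y) {
    mu <- abs(mean(y))
    if (mu < 1e-12) return(0)
    ix <- seq_along(y) - (length(y) + 1) / 2
    slope <- sum(ix * (y - mean(y))) / sum(ix^2)
    abs(slope) * (length(y) - 1) / mu
  }
  for (s in 1:(n - window + 1)) {
    all_ok <- TRUE
    for (u in s:(n - window + 1)) {
      ix <- u:(u + window - 1)
      if (relchange(series$center_density[ix]) >= slope_tol ||
          relchange(series$edge_density[ix]) >= slope_tol) {
        all_ok <- FALSE
        break
      }
    }
    if (all_ok) return(series$times[s])
  }
  NA_real_
}
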