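# Trajectory analyses: density profiles along z, coexistence densities
# and binodals, molecular cluster-size distributions, coil-level multimer
# census, LLPS calls, and the validation metrics (Rg, RMSD, KDE+KL).

#' Number-density profile along the box z-axis
#'
#' Time-averaged number density (beads / nm^3) in slices along z
#' (default width 2 nm). Beads are wrapped into the box before slicing.
#' If the box length is not a multiple of the slice width the last slice
#' is truncated (its volume is reduced accordingly and the profile is
#' flagged).
#'
#' @param traj a `cc_trajectory` (equilibrated frames only; apply
#'   [detect_equilibration()] upstream)
#' @param slice_width slice thickness in nm (default 2)
#' @return object of class `density_profile` with `slice_centers`,
#'   `density` (nm^-3), `slice_volumes`, `slice_width`
#' @export
density_profile <- function(traj, slice_width = 2) {
  stopifnot(inherits(traj, "cc_trajectory"), n_frames(traj) >= 1,
            slice_width > 0)
  box <- if (is.matrix(traj$box)) traj$box[1, ] else traj$box
  lz <- box[3]
  n_full <- floor(lz / slice_width + 1e-9)
  edges <- seq(0, n_full * slice_width, by = slice_width)
  truncated <- (lz - n_full * slice_width) > 1e-9
  if (truncated) edges <- c(edges, lz)
  nsl <- length(edges) - 1L
  widths <- diff(edges)
  vols <- widths * box[1] * box[2]
  counts <- numeric(nsl)
  for (fr in traj$frames) {
    z <- fr[, 3] %% lz
    idx <- pmin(findInterval(z, edges, rightmost.closed = TRUE), nsl)
    counts <- counts + tabulate(idx, nbins = nsl)
  }
  dens <- counts / n_frames(traj) / vols
  structure(list(slice_centers = (head(edges, -1) + tail(edges, -1)) / 2,
                 density = dens, slice_volumes = vols,
                 slice_width = slice_width, box = box,
                 n_frames = n_frames(traj), truncated = truncated),
            class = "density_profile")
}

#' Average density profiles across replicates
#'
#' @param profiles list of [density_profile()] objects on identical
#'   slicing
#' @return `density_profile` with `density` (mean), `sd_density`
#'   (population standard deviation across replicates)
#' @export
average_profiles <- function(profiles) {
  stopifnot(length(profiles) >= 1)
  dmat <- vapply(profiles, `[[`, profiles[[1]]$density, "density")
  dmat <- matrix(dmat, ncol = length(profiles))
  out <- profiles[[1]]
  out$density <- rowMeans(dmat)
  out$sd_density <- apply(dmat, 1, .pop_sd)
  out$n_replicates <- length(profiles)
  out
}

# population (n-denominator) standard deviation, the convention used for
# triplicate means +/- sd
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Default coexistence analysis windows for a box length
#'
#' The 150-nm slab convention (dense region 70-80 nm, dilute regions
#' 1-35 and 115-150 nm) scaled proportionally to the actual box z-length.
#'
#' @param lz box z-length in nm
#' @export
default_coex_windows <- function(lz) {
  s <- lz / 150
  list(dense = c(70, 80) * s,
       dilute = list(c(1, 35) * s, c(115, 150) * s))
}

#' Dense- and dilute-phase densities from a profile
#'
#' Mean slice density over the central dense window and over the two
#' combined edge windows.
#'
#' @param profile a [density_profile()]
#' @param dense_window `c(lo, hi)` in nm; `NULL` uses the scaled 70-80 nm
#'   convention
#' @param dilute_windows list of `c(lo, hi)` windows; `NULL` uses the
#'   scaled 1-35 / 115-150 nm convention
#' @return named vector `c(rho_dense, rho_dilute)` in nm^-3
#' @export
dense_dilute <- function(profile, dense_window = NULL, dilute_windows = NULL) {
  stopifnot(inherits(profile, "density_profile"))
  lz <- profile$box[3]
  if (is.null(dense_window) || is.null(dilute_windows)) {
    w <- default_coex_windows(lz)
    if (is.null(dense_window)) dense_window <- w$dense
    if (is.null(dilute_windows)) dilute_windows <- w$dilute
  }
  all_w <- c(list(dense_window), dilute_windows)
  for (w in all_w)
    if (w[1] < 0 || w[2] > lz + 1e-9)
      stop("analysis window outside the box", call. = FALSE)
  zc <- profile$slice_centers
  in_win <- function(w) zc >= w[1] & zc <= w[2]
  dense_sel <- in_win(dense_window)
  dil_sel <- Reduce(`|`, lapply(dilute_windows, in_win))
  c(rho_dense = if (any(dense_sel)) mean(profile$density[dense_sel]) else 0,
    rho_dilute = if (any(dil_sel)) mean(profile$density[dil_sel]) else 0)
}

#' Build a binodal from replicate coexistence densities
#'
#' Per temperature, the dense and dilute branches are averaged over
#' replicates (mean, population sd). A temperature is flagged *melted*
#' when the dense and dilute mean +/- sd intervals overlap; melted points
#' are excluded from the binodal's points (they remain listed in
#' `$all_points`).
#'
#' @param data data.frame with columns `temperature`, `replicate`,
#'   `rho_dense`, `rho_dilute`
#' @return object of class `binodal` with `points` (non-melted only) and
#'   `all_points`
#' @export
build_binodal <- function(data) {
  stopifnot(all(c("temperature", "rho_dense", "rho_dilute") %in%
                  names(data)), nrow(data) >= 1)
  temps <- sort(unique(data$temperature))
  rows <- lapply(temps, function(tt) {
    d <- data[data$temperature == tt, ]
    dm <- mean(d$rho_dense); ds <- .pop_sd(d$rho_dense)
    gm <- mean(d$rho_dilute); gs <- .pop_sd(d$rho_dilute)
    melted <- (dm - ds) <= (gm + gs)
    data.frame(temperature = tt, rho_dense = dm, sd_dense = ds,
               rho_dilute = gm, sd_dilute = gs, melted = melted)
  })
  pts <- do.call(rbind, rows)
  structure(list(points = pts[!pts$melted, , drop = FALSE],
                 all_points = pts),
            class = "binodal")
}

#' @export
print.binodal <- function(x, ...) {
  cat("binodal:", nrow(x$points), "coexistence point(s),",
      sum(x$all_points$melted), "melted temperature(s) omitted\n")
  if (nrow(x$points)) print(x$points, row.names = FALSE)
  invisible(x)
}

#' Molecular clusters in one frame
#'
#' Two molecules are linked when *any* inter-molecular bead pair lies
#' within the cutoff (minimum-image distances); clusters are the
#' connected components (single linkage).
#'
#' @param coords n x 3 coordinates (nm)
#' @param chain_ids integer molecule labels per bead
#' @param box box lengths
#' @param cutoff linkage distance in nm (default 0.9)
#' @return integer vector of cluster sizes (in molecules), one entry per
#'   cluster
#' @export
molecule_clusters <- function(coords, chain_ids, box, cutoff = 0.9) {
  if (!nrow(coords)) stop("empty frame", call. = FALSE)
  chains <- sort(unique(chain_ids))
  g <- cpp_contact_graph(coords, box, as.integer(chain_ids),
                         as.integer(chain_ids), cutoff, FALSE)
  graph <- igraph::graph_from_data_frame(
    data.frame(from = match(g$gi, chains), to = match(g$gj, chains)),
    directed = FALSE,
    vertices = data.frame(name = seq_along(chains)))
  comp <- igraph::components(graph)
  as.integer(comp$csize)
}

#' Cluster-size distribution over a trajectory
#'
#' Frames are sampled every `every_ps` of the (equilibrated) trajectory;
#' per-frame cluster-size counts are accumulated and normalized to
#' probabilities over clusters (so `P(s)` is the probability that a
#' randomly chosen cluster has `s` molecules).
#'
#' @param traj a `cc_trajectory` whose `beads` carry chain ids
#' @param cutoff linkage cutoff in nm (default 0.9)
#' @param every_ps sampling interval in ps (default 1e4, i.e. 10 ns)
#' @return object of class `cluster_size_distribution` with `sizes`,
#'   `prob`, `max_size`, `n_frames`, `cutoff`
#' @export
cluster_size_distribution <- function(traj, cutoff = 0.9, every_ps = 1e4) {
  stopifnot(inherits(traj, "cc_trajectory"), !is.null(traj$beads))
  sel <- .sample_frame_indices(traj$times, every_ps)
  counts <- integer(0)
  mx <- 0L
  for (q in sel) {
    box <- if (is.matrix(traj$box)) traj$box[q, ] else traj$box
    sizes <- molecule_clusters(traj$frames[[q]], traj$beads$chain, box,
                               cutoff)
    mx <- max(mx, sizes)
    tb <- tabulate(sizes, nbins = max(sizes))
    if (length(tb) > length(counts))
      counts <- c(counts, integer(length(tb) - length(counts)))
    counts[seq_along(tb)] <- counts[seq_along(tb)] + tb
  }
  prob <- counts / sum(counts)
  keep <- prob > 0
  structure(list(sizes = which(keep), prob = prob[keep], max_size = mx,
                 n_frames = length(sel), cutoff = cutoff),
            class = "cluster_size_distribution")
}

# indices of frames spaced >= every_ps apart (always includes the first
# eligible frame)
.sample_frame_indices <- function(times, every_ps) {
  sel <- integer(0)
  last <- -Inf
  for (q in seq_along(times)) {
    if (times[q] - last >= every_ps - 1e-9) {
      sel <- c(sel, q)
      last <- times[q]
    }
  }
  if (!length(sel)) sel <- length(times)
  sel
}

#' Coil-level multimer census
#'
#' Two coil segments on different chains are *bound* when at least
#' `min_contacts` sticky-bead pairs lie within the cutoff. An n-mer is a
#' connected component of n coils; the census reports the fraction of
#' all coil instances found in monomers, dimers, trimers, tetramers and
#' anything larger, time-averaged with a population sd across the
#' sampled frames.
#'
#' @param traj a `cc_trajectory` with bead metadata (`coil_id`, `chain`,
#'   `sticky`)
#' @param cutoff contact distance in nm (default 0.9)
#' @param min_contacts sticky-bead pairs required to call a coil-coil
#'   bond (default 3)
#' @param every_ps frame sampling interval in ps (default 0: every frame)
#' @return object of class `multimer_composition`: `fractions` (named
#'   mean fractions of all coils, monomers included, summing to 1),
#'   `multimer_fractions` (the composition of the multimer species
#'   present: the same categories renormalized over bound coils only),
#'   `sd`, `per_frame` matrix
#' @export
multimer_census <- function(traj, cutoff = 0.9, min_contacts = 3,
                            every_ps = 0) {
  stopifnot(inherits(traj, "cc_trajectory"), !is.null(traj$beads))
  if (min_contacts < 1) stop("min_contacts must be >= 1", call. = FALSE)
  beads <- traj$beads
  n_coil <- max(beads$coil_id)
  stopifnot(n_coil >= 1)
  group <- ifelse(beads$sticky, beads$coil_id, 0L)
  sel <- if (every_ps > 0) .sample_frame_indices(traj$times, every_ps)
         else seq_along(traj$frames)
  cats <- c("monomer", "dimer", "trimer", "tetramer", "larger")
  per_frame <- matrix(0, nrow = length(sel), ncol = 5,
                      dimnames = list(NULL, cats))
  max_component <- numeric(length(sel))
  for (w in seq_along(sel)) {
    q <- sel[w]
    box <- if (is.matrix(traj$box)) traj$box[q, ] else traj$box
    g <- cpp_contact_graph(traj$frames[[q]], box, as.integer(group),
                           as.integer(beads$chain), cutoff, TRUE)
    keep <- g$count >= min_contacts
    graph <- igraph::graph_from_data_frame(
      data.frame(from = g$gi[keep], to = g$gj[keep]), directed = FALSE,
      vertices = data.frame(name = seq_len(n_coil)))
    sizes <- igraph::components(graph)$csize
    max_component[w] <- max(sizes)
    coil_weighted <- sizes # each component contributes `size` coils
    f <- vapply(1:4, function(s) sum(coil_weighted[sizes == s]), numeric(1))
    f <- c(f, sum(coil_weighted[sizes >= 5]))
    per_frame[w, ] <- f / n_coil
  }
  fractions <- colMeans(per_frame)
  bound <- sum(fractions[-1])
  structure(list(fractions = fractions,
                 sd = apply(per_frame, 2, .pop_sd),
                 # composition of the multimer species present: the same
                 # categories renormalized over bound coils only
                 multimer_fractions = if (bound > 0) fractions[-1] / bound
                                      else fractions[-1] * NA_real_,
                 per_frame = per_frame, max_component = max_component,
                 n_frames = length(sel),
                 cutoff = cutoff, min_contacts = min_contacts),
            class = "multimer_composition")
}

#' @export
print.multimer_composition <- function(x, ...) {
  cat("multimer census over", x$n_frames, "frames (fraction of coils):\n")
  print(round(rbind(mean = x$fractions, sd = x$sd), 3))
  invisible(x)
}

#' Call liquid-liquid phase separation
#'
#' LLPS is called when two markers are present simultaneously: a sharp
#' density transition along z (dense/dilute ratio at least
#' `density_ratio_min`) and a molecular cluster containing nearly all
#' proteins (largest observed cluster at least `cluster_fraction_min` of
#' `n_proteins`). A zero dilute density counts as an infinite ratio.
#'
#' @param profile a [density_profile()]
#' @param cluster_dist a [cluster_size_distribution()]
#' @param n_proteins number of protein chains in the simulation
#' @param density_ratio_min dense/dilute ratio threshold (default 10)
#' @param cluster_fraction_min largest-cluster fraction threshold
#'   (default 0.9)
#' @param dense_window,dilute_windows passed to [dense_dilute()]
#' @return list with `llps` (logical), `density_ratio`,
#'   `max_cluster_fraction`
#' @export
call_llps <- function(profile, cluster_dist, n_proteins,
                      density_ratio_min = 10, cluster_fraction_min = 0.9,
                      dense_window = NULL, dilute_windows = NULL) {
  dd <- dense_dilute(profile, dense_window, dilute_windows)
  ratio <- if (dd["rho_dilute"] <= 0) Inf else
    unname(dd["rho_dense"] / dd["rho_dilute"])
  frac <- cluster_dist$max_size / n_proteins
  list(llps = (ratio >= density_ratio_min) && (frac >= cluster_fraction_min),
       density_ratio = ratio, max_cluster_fraction = frac,
       rho_dense = unname(dd["rho_dense"]),
       rho_dilute = unname(dd["rho_dilute"]))
}

#' Radius of gyration
#'
#' Mass-weighted root-mean-square distance of the beads from their
#' centre of mass.
#'
#' @param coords n x 3 coordinates (nm)
#' @param masses bead masses; `NULL` for uniform
#' @return Rg in nm
#' @export
radius_of_gyration <- function(coords, masses = NULL) {
  coords <- rbind(coords)
  stopifnot(nrow(coords) >= 1)
  if (is.null(masses)) masses <- rep(1, nrow(coords))
  if (sum(masses) <= 0) stop("zero total mass", call. = FALSE)
  com <- colSums(coords * masses) / sum(masses)
  d2 <- rowSums(sweep(coords, 2, com)^2)
  sqrt(sum(masses * d2) / sum(masses))
}

#' Root-mean-square deviation, with optional optimal superposition
#'
#' With `fit = TRUE` the coordinates are first superposed on the
#' reference by the least-squares rigid-body transform (Kabsch
#' algorithm: centroid translation + optimal rotation from the SVD of
#' the covariance matrix).
#'
#' @param coords n x 3 coordinates
#' @param reference n x 3 reference coordinates
#' @param fit superpose before computing the deviation (default TRUE)
#' @return RMSD in nm
#' @export
rmsd <- function(coords, reference, fit = TRUE) {
  coords <- rbind(coords); reference <- rbind(reference)
  if (!all(dim(coords) == dim(reference)))
    stop("coordinate sets must have the same size", call. = FALSE)
  if (fit) {
    xc <- sweep(coords, 2, colMeans(coords))
    yc <- sweep(reference, 2, colMeans(reference))
    s <- svd(crossprod(xc, yc))
    d <- sign(det(s$v %*% t(s$u)))
    rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
    xc <- xc %*% t(rot)
    sqrt(mean(rowSums((xc - yc)^2)))
  } else {
    sqrt(mean(rowSums((coords - reference)^2)))
  }
}

#' Kullback-Leibler divergence between Gaussian KDEs of two samples
#'
#' Gaussian kernel density estimates are built for both samples
#' (bandwidth by Scott's rule, \eqn{h = \hat\sigma n^{-1/5}}, by
#' default) and \eqn{KL(p\|q) = \int p \log(p/q)} is evaluated by
#' trapezoidal quadrature on a shared grid spanning both samples plus a
#' 3-bandwidth margin. Where q underflows it is clamped to a small
#' floor (with a warning), so the divergence stays finite.
#'
#' @param sample_p,sample_q numeric samples
#' @param bandwidth `"scott"`, or a numeric bandwidth in data units
#' @param n_grid quadrature grid size (default 2048)
#' @param q_floor density floor for the q-clamp (default 1e-12)
#' @return divergence in nats (>= 0 up to quadrature error)
#' @export
kde_kl <- function(sample_p, sample_q, bandwidth = "scott", n_grid = 2048,
                   q_floor = 1e-12) {
  stopifnot(length(sample_p) >= 1, length(sample_q) >= 1)
  bw <- function(x) {
    if (is.numeric(bandwidth)) return(bandwidth)
    s <- stats::sd(x)
    if (!is.finite(s) || s == 0) s <- max(abs(x), 1e-8)
    s * length(x)^(-1 / 5)
  }
  hp <- bw(sample_p); hq <- bw(sample_q)
  lo <- min(sample_p, sample_q) - 3 * max(hp, hq)
  hi <- max(sample_p, sample_q) + 3 * max(hp, hq)
  grid <- seq(lo, hi, length.out = n_grid)
  kde <- function(x, h) {
    d <- vapply(grid, function(g) mean(dnorm(g, mean = x, sd = h)),
                numeric(1))
    d / .trapz(grid, d)
  }
  p <- kde(sample_p, hp)
  q <- kde(sample_q, hq)
  clamped <- q < q_floor & p > 0
  if (any(clamped))
    warning(sprintf("q underflowed on %d grid point(s); clamped to %g",
                    sum(clamped), q_floor))
  q <- pmax(q, q_floor)
  integrand <- ifelse(p > 0, p * log(p / q), 0)
  .trapz(grid, integrand)
}

.trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)
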