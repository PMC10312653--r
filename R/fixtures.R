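# Synthetic systems and trajectories with known ground truth, so every
# analysis and protocol operation is testable without running dynamics.

#' Synthetic slab trajectory with prescribed densities
#'
#' Places beads uniformly at a high density inside a z-window (the
#' "slab") and at a low density outside it, grouped into short straight
#' synthetic chains, over `n_frames` independent frames. The chain count
#' is fixed across frames (trajectory frames must share one bead count);
#' positions are redrawn every frame, so slice densities fluctuate like
#' counts in a real trajectory. The attached ground-truth record carries
#' the generating parameters.
#'
#' @param box box lengths in nm (default `c(25, 25, 150)`)
#' @param window slab z-window `c(lo, hi)` in nm (default `c(70, 80)`)
#' @param dense number density inside the window, nm^-3
#' @param dilute number density outside, nm^-3
#' @param n_frames frames to generate (default 50)
#' @param chain_size beads per synthetic chain (default 5)
#' @param seed RNG seed (fixture is bit-reproducible under it)
#' @return a `cc_trajectory`; `attr(, "ground_truth")` holds the record
#' @export
make_slab_fixture <- function(box = c(25, 25, 150), window = c(70, 80),
                              dense = 2.0, dilute = 0.02, n_frames = 50,
                              chain_size = 5L, seed = 1L) {
  stopifnot(dense >= dilute, dilute >= 0, window[1] < window[2],
            window[1] >= 0, window[2] <= box[3], chain_size >= 1)
  if (dense > 20)
    stop("requested dense density exceeds close packing", call. = FALSE)
  v_in <- box[1] * box[2] * (window[2] - window[1])
  v_out <- box[1] * box[2] * box[3] - v_in
  .with_seed(seed, {
    frames <- vector("list", n_frames)
    chain_ids_ref <- NULL
    n_in <- round(dense * v_in / chain_size) * chain_size
    n_out <- round(dilute * v_out / chain_size) * chain_size
    for (fr in seq_len(n_frames)) {
      place <- function(n, zlo, zhi, exclude = NULL) {
        if (n == 0) return(matrix(numeric(0), ncol = 3))
        n_ch <- n %/% chain_size
        # chain anchors; chain beads extend +x with tiny spacing
        anchors <- cbind(runif(n_ch, 0, box[1]), runif(n_ch, 0, box[2]),
                         runif(n_ch, zlo, zhi))
        if (!is.null(exclude)) { # resample anchors landing inside the slab
          bad <- anchors[, 3] >= exclude[1] & anchors[, 3] < exclude[2]
          while (any(bad)) {
            anchors[bad, 3] <- runif(sum(bad), zlo, zhi)
            bad <- anchors[, 3] >= exclude[1] & anchors[, 3] < exclude[2]
          }
        }
        do.call(rbind, lapply(seq_len(n_ch), function(c0) {
          sweep(cbind(0.08 * (seq_len(chain_size) - 1), 0, 0), 2,
                anchors[c0, ], `+`)
        }))
      }
      xin <- place(n_in, window[1], window[2])
      xout <- place(n_out, 0, box[3], exclude = window)
      frames[[fr]] <- rbind(xin, xout)
      if (fr == 1)
        chain_ids_ref <- rep(seq_len((n_in + n_out) %/% chain_size),
                             each = chain_size)
    }
    beads <- data.frame(chain = chain_ids_ref)
    traj <- new_cc_trajectory(times = (seq_len(n_frames) - 1) * 1e4,
                              frames = frames, box = box, thermo = NULL,
                              beads = beads)
    attr(traj, "ground_truth") <- list(dense = dense, dilute = dilute,
                                       window = window, box = box,
                                       chain_size = chain_size, seed = seed)
    traj
  })
}

#' Synthetic frame with an exact cluster composition
#'
#' Builds straight-rod chains arranged so that chains of the same
#' cluster have nearest-neighbour distances below the cutoff while
#' distinct clusters are separated by more than twice the cutoff;
#' [molecule_clusters()] recovers the composition exactly.
#'
#' @param composition named vector or list mapping cluster size ->
#'   number of clusters, e.g. `c("2" = 3)` for three dimers
#' @param cutoff linkage cutoff in nm (default 0.9)
#' @param box box lengths; `NULL` picks one large enough
#' @param chain_size beads per chain (default 5)
#' @return list with `coords`, `chain_ids`, `box` and the ground-truth
#'   `composition`
#' @export
make_cluster_fixture <- function(composition, cutoff = 0.9, box = NULL,
                                 chain_size = 5L) {
  sizes <- rep(as.integer(names(composition)), unlist(composition))
  if (!length(sizes)) stop("empty composition", call. = FALSE)
  gap <- 2.5 * cutoff            # inter-cluster clearance > 2 x cutoff
  d_link <- 0.8 * cutoff         # intra-cluster chain spacing < cutoff
  rod_len <- (chain_size - 1) * 0.3
  cell <- rod_len + max(sizes) * d_link + gap
  n_cl <- length(sizes)
  n_side <- ceiling(sqrt(n_cl))
  if (is.null(box)) {
    need <- n_side * cell + gap
    box <- c(need, need, cell + gap)
  }
  if (n_side * cell > box[1] + 1e-9 || n_side * cell > box[2] + 1e-9)
    stop("requested clusters do not fit the box with the required gaps",
         call. = FALSE)
  coords <- NULL
  chain_ids <- integer(0)
  ch <- 0L
  for (ci in seq_len(n_cl)) {
    gx <- ((ci - 1) %% n_side) * cell + gap / 2
    gy <- ((ci - 1) %/% n_side) * cell + gap / 2
    for (mi in seq_len(sizes[ci])) {
      ch <- ch + 1L
      rod <- cbind(0.3 * (seq_len(chain_size) - 1),
                   rep((mi - 1) * d_link, chain_size),
                   rep(0, chain_size))
      rod <- sweep(rod, 2, c(gx, gy, box[3] / 2), `+`)
      coords <- rbind(coords, rod)
      chain_ids <- c(chain_ids, rep(ch, chain_size))
    }
  }
  list(coords = coords, chain_ids = chain_ids, box = box,
       composition = composition, cutoff = cutoff)
}

#' Synthetic centre/edge density series with known equilibration
#'
#' Three profiles for exercising [detect_equilibration()]: `stable`
#' (constant mean plus small noise), `drift` (persistent linear trend)
#' and `step` (sharp level change at a known index, constant after).
#'
#' @param profile_type `"stable"`, `"drift"` or `"step"`
#' @param n_samples series length (default 100)
#' @param level base density in nm^-3
#' @param noise relative noise amplitude (default 0.002)
#' @param step_at sample index of the step change (for `"step"`)
#' @param drift_rate relative change per sample (for `"drift"`)
#' @param dt_ps sample spacing in ps
#' @param seed RNG seed
#' @return a [new_density_timeseries()]; ground truth as attribute
#' @export
make_density_timeseries <- function(profile_type = c("stable", "drift",
                                                     "step"),
                                    n_samples = 100L, level = 2.0,
                                    noise = 0.002, step_at = 40L,
                                    drift_rate = 0.01, dt_ps = 1000,
                                    seed = 1L) {
  profile_type <- match.arg(profile_type)
  .with_seed(seed, {
    t <- (seq_len(n_samples) - 1) * dt_ps
    base <- switch(profile_type,
      stable = rep(level, n_samples),
      drift = level * (1 + drift_rate * seq_len(n_samples)),
      step = c(rep(level * 2, step_at - 1),
               rep(level, n_samples - step_at + 1)))
    mk <- function() pmax(base * (1 + noise * rnorm(n_samples)), 0)
    out <- new_density_timeseries(t, mk(), mk())
    attr(out, "ground_truth") <- list(profile_type = profile_type,
                                      step_at = step_at, level = level,
                                      noise = noise, seed = seed)
    out
  })
}
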