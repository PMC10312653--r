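test_that("density profiles conserve bead counts and localize mass", {
  # all beads confined to a window: zero density elsewhere
  set.seed(4)
  frames <- lapply(1:5, function(i) {
    cbind(runif(200, 0, 25), runif(200, 0, 25), runif(200, 70, 80))
  })
  traj <- coilslab:::new_cc_trajectory((0:4) * 1e3, frames, c(25, 25, 150),
                                       NULL)
  pr <- density_profile(traj)
  inside <- pr$slice_centers > 70 & pr$slice_centers < 80
  expect_true(all(pr$density[!inside] == 0))
  expect_true(all(pr$density[inside] > 0))
  # conservation to 1e-9 relative
  tot <- sum(pr$density * pr$slice_volumes)
  expect_equal(tot, 200, tolerance = 1e-9)
  # uniform beads give a flat profile at N/V
  frames <- lapply(1:30, function(i)
    cbind(runif(3000, 0, 25), runif(3000, 0, 25), runif(3000, 0, 150)))
  traj <- coilslab:::new_cc_trajectory((0:29) * 1e3, frames,
                                       c(25, 25, 150), NULL)
  pr <- density_profile(traj)
  expect_equal(mean(pr$density), 3000 / (25 * 25 * 150), tolerance = 0.01)
  expect_lt(max(abs(pr$density - mean(pr$density))) / mean(pr$density), 0.2)
  # non-multiple box length: truncated last slice, still conservative
  traj2 <- traj
  traj2$box <- c(25, 25, 149)
  pr2 <- density_profile(traj2)
  expect_true(pr2$truncated)
  expect_equal(sum(pr2$density * pr2$slice_volumes), 3000, tolerance = 1e-9)
})

test_that("dense/dilute extraction uses the coexistence windows", {
  fx <- make_slab_fixture(dense = 2.0, dilute = 0.02, n_frames = 40,
                          seed = 9)
  pr <- density_profile(fx)
  dd <- dense_dilute(pr)
  expect_equal(unname(dd["rho_dense"]), 2.0, tolerance = 0.05)
  expect_equal(unname(dd["rho_dilute"]), 0.02, tolerance = 0.05)
  # uniform profile: both windows agree
  frames <- lapply(1:10, function(i)
    cbind(runif(2000, 0, 25), runif(2000, 0, 25), runif(2000, 0, 150)))
  traj <- coilslab:::new_cc_trajectory((0:9) * 1e3, frames, c(25, 25, 150),
                                       NULL)
  dd_u <- dense_dilute(density_profile(traj))
  expect_equal(unname(dd_u["rho_dense"]), unname(dd_u["rho_dilute"]),
               tolerance = 0.06)
  # empty box gives (0, 0)
  empty <- coilslab:::new_cc_trajectory(
    0, list(matrix(c(1, 1, 200), 1)), c(25, 25, 150), NULL)
  pr0 <- density_profile(empty)
  pr0$density[] <- 0
  expect_equal(unname(dense_dilute(pr0)), c(0, 0))
  expect_error(dense_dilute(pr, dense_window = c(100, 200)),
               "outside the box")
})

test_that("binodal construction averages replicates and drops melted points", {
  d <- data.frame(temperature = rep(c(253, 313), each = 3),
                  replicate = rep(1:3, 2),
                  rho_dense = c(5, 5, 5, 4.8, 5, 5.2),
                  rho_dilute = c(0.1, 0.1, 0.1, 4.0, 4.5, 5.0))
  b <- build_binodal(d)
  expect_equal(nrow(b$all_points), 2)
  # identical replicates at 253 K: sd 0, mean equals the value
  expect_equal(b$all_points$sd_dense[1], 0)
  expect_equal(b$all_points$rho_dense, c(5, 5))
  # overlapping intervals at 313 K: melted and omitted
  expect_equal(b$all_points$melted, c(FALSE, TRUE))
  expect_equal(b$points$temperature, 253)
  # overlap through the sd bands also melts
  d2 <- data.frame(temperature = rep(280, 3), replicate = 1:3,
                   rho_dense = c(4, 5, 6), rho_dilute = c(3.5, 4.5, 5.5))
  expect_true(build_binodal(d2)$all_points$melted)
})

test_that("molecular clustering equals the brute-force union-find oracle", {
  # hand-built cases
  box <- c(20, 20, 20)
  two <- rbind(c(1, 1, 1), c(1, 1, 1.5))   # 0.5 nm apart
  expect_equal(sort(molecule_clusters(two, c(1, 2), box, 0.9)), 2)
  apart <- rbind(c(1, 1, 1), c(1, 1, 2.0)) # exactly 1.0 nm
  expect_equal(sort(molecule_clusters(apart, c(1, 2), box, 0.9)), c(1, 1))
  # chain A-B close, B-C close, A-C far: one triple
  abc <- rbind(c(1, 1, 1), c(1, 1, 1.8), c(1, 1, 2.6))
  expect_equal(molecule_clusters(abc, c(1, 2, 3), box, 0.9), 3)
  # randomized systems with <= 12 chains, including cross-boundary pairs
  for (seed in 1:8) {
    set.seed(seed)
    n_ch <- sample(3:12, 1)
    coords <- NULL; chains <- integer(0)
    for (c0 in seq_len(n_ch)) {
      base <- runif(3, 0, 10)
      nb <- sample(2:5, 1)
      coords <- rbind(coords, sweep(matrix(rnorm(nb * 3, sd = 0.3),
                                           ncol = 3), 2, base, `+`))
      chains <- c(chains, rep(c0, nb))
    }
    box10 <- c(10, 10, 10)
    got <- sort(molecule_clusters(coords, chains, box10, 0.9))
    want <- sort(oracle_clusters(coords, chains, box10, 0.9))
    expect_equal(got, want)
  }
  expect_error(molecule_clusters(matrix(numeric(0), ncol = 3), integer(0),
                                 box, 0.9), "empty")
})

test_that("cluster-size distributions are normalized probabilities over clusters", {
  cf <- make_cluster_fixture(c("3" = 1, "1" = 2))
  sizes <- molecule_clusters(cf$coords, cf$chain_ids, cf$box, cf$cutoff)
  traj <- coilslab:::new_cc_trajectory(
    0, list(cf$coords), cf$box, NULL,
    beads = data.frame(chain = cf$chain_ids))
  dist <- cluster_size_distribution(traj, cutoff = cf$cutoff,
                                    every_ps = 1)
  expect_equal(sum(dist$prob), 1, tolerance = 1e-9)
  # cluster-count convention: P(3) = 1/3 with one triple and two singles
  expect_equal(dist$prob[dist$sizes == 3], 1 / 3)
  expect_equal(dist$prob[dist$sizes == 1], 2 / 3)
  expect_equal(dist$max_size, 3L)
})

test_that("multimer census classifies constructed bound coils", {
  box <- c(30, 30, 30)
  # two parallel sticky rods 0.5 nm apart: 5 contacts each -> dimers
  rod <- function(x0, y0, chain, coil) {
    list(coords = cbind(rep(x0, 5), rep(y0, 5), 5 + 0.3 * (0:4)),
         beads = data.frame(chain = rep(chain, 5), coil_id = rep(coil, 5),
                            sticky = rep(TRUE, 5)))
  }
  mk_traj <- function(rods) {
    coords <- do.call(rbind, lapply(rods, `[[`, "coords"))
    beads <- do.call(rbind, lapply(rods, `[[`, "beads"))
    beads$mass <- 109
    coilslab:::new_cc_trajectory(0, list(coords), box, NULL, beads = beads)
  }
  tr <- mk_traj(list(rod(5, 5, 1L, 1L), rod(5, 5.5, 2L, 2L)))
  mc <- multimer_census(tr, min_contacts = 3)
  expect_equal(unname(mc$fractions["dimer"]), 1)
  expect_equal(sum(mc$fractions), 1, tolerance = 1e-9)
  # three mutually bound coils -> all in trimers
  tr3 <- mk_traj(list(rod(5, 5, 1L, 1L), rod(5, 5.7, 2L, 2L),
                      rod(5.6, 5.35, 3L, 3L)))
  mc3 <- multimer_census(tr3, min_contacts = 3)
  expect_equal(unname(mc3$fractions["trimer"]), 1)
  # distant coils -> monomers
  trm <- mk_traj(list(rod(5, 5, 1L, 1L), rod(15, 15, 2L, 2L)))
  mcm <- multimer_census(trm, min_contacts = 3)
  expect_equal(unname(mcm$fractions["monomer"]), 1)
  # below min_contacts no bond is called: same-chain contacts never count
  tr_same <- mk_traj(list(rod(5, 5, 1L, 1L), rod(5, 5.5, 1L, 2L)))
  expect_equal(unname(multimer_census(tr_same)$fractions["monomer"]), 1)
  expect_error(multimer_census(tr, min_contacts = 0), "min_contacts")
})

test_that("LLPS calls require both density and cluster markers", {
  fx <- make_slab_fixture(dense = 2.0, dilute = 0.04, n_frames = 20,
                          chain_size = 5, seed = 13)
  pr <- density_profile(fx)
  n_prot <- length(unique(fx$beads$chain))
  # single giant cluster + sharp transition -> LLPS
  cl_all <- list(max_size = n_prot)
  class(cl_all) <- "cluster_size_distribution"
  v <- call_llps(pr, cl_all, n_prot)
  expect_true(v$llps)
  expect_gt(v$density_ratio, 10)
  # dense slab but fragmented clusters -> no LLPS
  cl_frag <- list(max_size = round(0.3 * n_prot))
  class(cl_frag) <- "cluster_size_distribution"
  expect_false(call_llps(pr, cl_frag, n_prot)$llps)
  # uniform gas -> no LLPS even with one big cluster
  fx_u <- make_slab_fixture(dense = 0.05, dilute = 0.05, n_frames = 20,
                            seed = 3)
  expect_false(call_llps(density_profile(fx_u), cl_all, n_prot)$llps)
  # zero dilute density handled as infinite ratio
  pr0 <- pr
  pr0$density[pr0$slice_centers < 65 | pr0$slice_centers > 85] <- 0
  expect_equal(call_llps(pr0, cl_all, n_prot)$density_ratio, Inf)
})

test_that("radius of gyration and RMSD match hand calculations", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1)), 0)
  two <- matrix(c(0, 0, 0, 2, 0, 0), ncol = 3, byrow = TRUE)
  expect_equal(radius_of_gyration(two), 1)
  # mass weighting: 3:1 masses put the COM at 0.5, Rg = sqrt(3)/2
  expect_equal(radius_of_gyration(two, masses = c(3, 1)),
               sqrt((3 * 0.25 + 1 * 2.25) / 4))
  set.seed(2)
  x <- matrix(rnorm(60), ncol = 3)
  expect_equal(radius_of_gyration(x + 5), radius_of_gyration(x))
  expect_error(radius_of_gyration(two, masses = c(0, 0)), "zero total mass")
  # RMSD cases
  expect_equal(rmsd(x, x), 0)
  expect_equal(rmsd(x + 3, x, fit = TRUE), 0, tolerance = 1e-10)
  shifted <- sweep(x, 2, c(0.7, 0, 0), `+`)
  expect_equal(rmsd(shifted, x, fit = FALSE), 0.7)
  # rotated copy superposes to zero
  th <- 0.6
  rot <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  expect_equal(rmsd(x %*% rot, x, fit = TRUE), 0, tolerance = 1e-10)
  expect_error(rmsd(x, x[1:10, ]), "same size")
})

test_that("KDE KL divergence reproduces Gaussian theory and asymmetry", {
  set.seed(5)
  p <- rnorm(3000)
  expect_equal(kde_kl(p, p), 0, tolerance = 0.02)
  q <- rnorm(3000, mean = 1)
  expect_equal(suppressWarnings(kde_kl(p, q)), 0.5, tolerance = 0.1)
  # asymmetry on skewed samples
  skew <- rexp(2000)
  sym <- rnorm(2000, mean = 1)
  expect_gt(abs(suppressWarnings(kde_kl(skew, sym)) -
                  suppressWarnings(kde_kl(sym, skew))), 0.05)
  # divergence is non-negative
  expect_gte(suppressWarnings(kde_kl(rnorm(500), rnorm(500, 3))), 0)
})
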