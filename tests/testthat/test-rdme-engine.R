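test_that("diffusion propensity follows 4nD/h^2 with per-direction nD/h^2", {
  expect_identical(diffusion_propensity(0, 10, 0.1), 0)
  expect_equal(diffusion_propensity(1, 10, 0.1), 4000)
  expect_equal(diffusion_propensity(3, 0.5, 0.25), 4 * 3 * 0.5 / 0.0625)
})

test_that("reaction propensity uses the mode-appropriate mesoscopic rate", {
  m <- build_ab_model(n0 = 5, k_d_micro = 10)
  h <- 0.025
  mp <- fig2_micro()
  occ <- c(A = 2, B = 5, C = 1)
  ## naive: k_micro nA nB / h^2
  expect_equal(reaction_propensity(m, "assoc", occ, h, "naive"),
               mp$k_micro * 10 / h^2, tolerance = 1e-6)
  ## kh: scalar k_h
  expect_equal(reaction_propensity(m, "assoc", occ, h, "kh"),
               k_h(h, mp) * 10 / h^2, tolerance = 1e-6)
  ## kc: occupancy-dependent at max(nA, nB) = 5
  expect_equal(reaction_propensity(m, "assoc", occ, h, "kc"),
               k_c(5, h, mp) * 10 / h^2, tolerance = 1e-6)
  ## zero when either reactant is absent
  expect_identical(reaction_propensity(m, "assoc", c(A = 0, B = 5, C = 0), h,
                                       "kc"), 0)
  ## dissociation is paired to the association mode
  expect_equal(reaction_propensity(m, "dissoc", occ, h, "kh"),
               k_h_d(10, k_h(h, mp), mp$k_micro) * 1, tolerance = 1e-6)
  expect_equal(reaction_propensity(m, "dissoc", occ, h, "kc"),
               k_c_d(10, k_c(5, h, mp), mp$k_micro) * 1, tolerance = 1e-6)
})

test_that("grid validation: L/h integrality and the kh-mode h_min bound", {
  m <- build_ab_model(n0 = 2)
  expect_error(simulate_rdme(m, L = 1, h = 0.03, mode = "naive", t_end = 1),
               "integer")
  expect_error(simulate_rdme(m, L = 1, h = 0.02, mode = "kh", t_end = 1),
               "h_min")
  ## kc mode has no such bound for h > rho
  expect_silent(simulate_rdme(m, L = 1, h = 0.02, mode = "kc", t_end = 0.01,
                              record_interval = Inf, seed = 1))
})

test_that("a single diffusing molecule occupies voxels uniformly in the long run", {
  m <- toy_diffusion_model(D = 1, n0 = 1)
  traj <- simulate_rdme(m, L = 2, h = 0.5, mode = "naive", t_end = 3000,
                        record_interval = 1, seed = 9,
                        record_occupancy = TRUE)
  counts <- rowSums(traj$occupancy["X", , -1])   # voxel visit counts
  expect_equal(sum(counts), 3000)
  chi2 <- sum((counts - mean(counts))^2 / mean(counts))
  ## 16 voxels, samples ~independent (mixing time << 1 s)
  expect_lt(chi2, qchisq(0.999, df = 15))
})

test_that("well-mixed limit: first-event time on a 1x1 grid is exponential with the Gillespie rate", {
  m <- build_ab_model(n0 = 1)
  h <- 1
  rate <- 0.25 / h^2   # naive k_micro nA nB / h^2
  traj <- simulate_rdme(m, L = 1, h = h, mode = "naive", t_end = 1e6,
                        record_interval = Inf, seed = 13, stop_species = "A",
                        replicates = 3000)
  tt <- traj$stop_times
  expect_true(all(is.finite(tt)))
  ks <- suppressWarnings(ks.test(tt, pexp, rate = rate))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(tt), 1 / rate, tolerance = 0.1)
})

test_that("species totals are conserved exactly and zero-reaction runs stay flat", {
  m <- toy_shuttle_model(n0 = 137)
  traj <- simulate_rdme(m, L = 2, h = 0.25, mode = "naive", t_end = 5,
                        record_interval = 0.5, seed = 21)
  tot <- traj$totals[, , 1]
  expect_true(all(tot[, "Mc"] + tot[, "Mm"] == 137))
  m0 <- toy_diffusion_model(n0 = 64)
  tr0 <- simulate_rdme(m0, L = 1, h = 0.25, mode = "naive", t_end = 2,
                       record_interval = 0.5, seed = 3)
  expect_true(all(tr0$totals[, "X", 1] == 64))
})

test_that("identical seed and configuration reproduce the trajectory exactly", {
  m <- build_ab_model(n0 = 5, k_d_micro = 10)
  a <- simulate_rdme(m, 1, 0.025, "kc", t_end = 5, record_interval = 0.5,
                     seed = 42)
  b <- simulate_rdme(m, 1, 0.025, "kc", t_end = 5, record_interval = 0.5,
                     seed = 42)
  expect_identical(a$totals, b$totals)
  expect_identical(a$events, b$events)
  d <- simulate_rdme(m, 1, 0.025, "kc", t_end = 5, record_interval = 0.5,
                     seed = 43)
  expect_false(identical(a$totals, d$totals))
})

test_that("two-molecule mean association time with k_h matches the closed forms", {
  ## moderate-replicate version of the construction identity, exercised
  ## through the full engine (the acceptance suite runs the 1e4 version)
  m <- build_ab_model(n0 = 1)
  L <- 0.2; h <- 0.025
  mp <- fig2_micro()
  traj <- simulate_rdme(m, L, h, mode = "kh", t_end = 1e9,
                        record_interval = Inf, seed = 7, stop_species = "A",
                        replicates = 3000)
  se <- sd(traj$stop_times) / sqrt(3000)
  expect_lt(abs(mean(traj$stop_times) - tau_micro(L / sqrt(pi), mp)), 3 * se)
})

test_that("reversible pair equilibrium matches the detailed-balance closed form", {
  ## K per voxel is k_meso/k_meso^d = k_micro/k_micro^d by the Eq-13 pairing,
  ## so the stationary bound fraction of one A-B pair is
  ## (1/k_d) / (1/k_d + L^2/k_micro)
  m <- build_ab_model(n0 = 1, k_d_micro = 10)
  L <- 0.2
  p_th <- (1 / 10) / (1 / 10 + L^2 / 0.25)
  ## replicate-level means give honest standard errors (within-run batch means
  ## underestimate the heavy-tailed rebinding autocorrelation)
  eq_mean <- function(mode, seed) {
    traj <- simulate_rdme(m, L, 0.025, mode = mode, t_end = 1200,
                          record_interval = 0.5, seed = seed, replicates = 8)
    apply(traj$totals[-(1:40), "C", ], 2, mean)
  }
  for (mode in c("kh", "kc")) {
    reps <- eq_mean(mode, seed = if (mode == "kh") 3 else 5)
    se <- sd(reps) / sqrt(length(reps))
    expect_lt(abs(mean(reps) - p_th), 3 * se)
  }
})

test_that("k_c-mode dissociation uses the occupancy of the forward reactants", {
  ## direct check through reaction_propensity at two occupancies
  m <- build_ab_model(n0 = 5, k_d_micro = 10)
  h <- 0.025
  mp <- fig2_micro()
  lo <- reaction_propensity(m, "dissoc", c(A = 1, B = 1, C = 1), h, "kc")
  hi <- reaction_propensity(m, "dissoc", c(A = 1, B = 6, C = 1), h, "kc")
  expect_equal(lo, k_c_d(10, k_c(1, h, mp), mp$k_micro), tolerance = 1e-6)
  expect_equal(hi, k_c_d(10, k_c(6, h, mp), mp$k_micro), tolerance = 1e-6)
  expect_gt(hi, lo)
  ## empty voxel floors the occupancy at 1
  none <- reaction_propensity(m, "dissoc", c(A = 0, B = 0, C = 2), h, "kc")
  expect_equal(none, 2 * k_c_d(10, k_c(1, h, mp), mp$k_micro),
               tolerance = 1e-6)
})

test_that("pseudo-coordinates fall inside occupied voxels", {
  m <- toy_diffusion_model(D = 0.5, n0 = 40)
  traj <- simulate_rdme(m, L = 2, h = 0.5, mode = "naive", t_end = 1,
                        record_interval = 1, seed = 2,
                        record_occupancy = TRUE)
  xy <- pseudo_coordinates(traj, 2, "X", seed = 1)
  expect_equal(nrow(xy), 40)
  expect_true(all(xy >= 0 & xy < 2))
  ## voxel histogram of pseudo-coordinates equals the occupancy
  vox <- floor(xy[, 1] / 0.5) + 4 * floor(xy[, 2] / 0.5)
  occ <- traj$occupancy["X", , 2]
  expect_equal(tabulate(vox + 1, nbins = 16), unname(occ))
})
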