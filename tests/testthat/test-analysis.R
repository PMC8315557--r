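## brute-force O(N^2) minimum-image pairwise histogram, independent of the
## compiled path
brute_hist <- function(x, y, L, breaks) {
  n <- length(x)
  d <- c()
  for (i in 1:(n - 1))
    for (j in (i + 1):n) {
      dx <- abs(x[i] - x[j]); dx <- min(dx, L - dx)
      dy <- abs(y[i] - y[j]); dy <- min(dy, L - dy)
      d <- c(d, sqrt(dx^2 + dy^2))
    }
  hist(d[d <= max(breaks)], breaks = breaks, plot = FALSE)$counts
}

test_that("pairwise distribution matches the brute-force oracle and the uniform law", {
  set.seed(101)
  L <- 4; n <- 100
  x <- runif(n, 0, L); y <- runif(n, 0, L)
  pd <- pairwise_distribution(x, y, L, dr = 0.1)
  breaks <- c(pd$r_lo, max(pd$r_hi))
  expect_equal(pd$count, brute_hist(x, y, L, breaks) * 2)
  ## P integrates to <= 1 over [0, L/2]
  expect_lte(sum(pd$P * (pd$r_hi - pd$r_lo)), 1 + 1e-12)
  ## uniform law P(r) ~ 2 pi r / A for r << L/2, averaged over many patterns
  set.seed(7)
  acc <- 0
  for (k in 1:40) {
    x <- runif(200, 0, L); y <- runif(200, 0, L)
    acc <- acc + pairwise_distribution(x, y, L, dr = 0.1)$P
  }
  Pbar <- acc / 40
  pd1 <- pairwise_distribution(x, y, L, dr = 0.1)
  small <- pd1$r < L / 4
  expect_equal(Pbar[small], 2 * pi * pd1$r[small] / L^2, tolerance = 0.06)
  ## two molecules at distance d: point mass in the containing bin
  pd2 <- pairwise_distribution(c(0, 0.42), c(0, 0), L = 4, dr = 0.05)
  expect_equal(sum(pd2$count), 2)
  expect_equal(pd2$count[pd2$r_lo < 0.42 & pd2$r_hi >= 0.42], 2)
  expect_error(pairwise_distribution(1, 1, L = 4), "at least 2")
})

test_that("H(r) is null for uniform patterns and peaks near the cluster scale", {
  L <- 8
  ## permutation-style null envelope from independent uniform patterns
  set.seed(11)
  Hs <- replicate(100, {
    x <- runif(400, 0, L); y <- runif(400, 0, L)
    H_of_r(x, y, L)$H
  })
  env <- apply(Hs, 1, quantile, probs = c(0.005, 0.995))
  x <- runif(400, 0, L); y <- runif(400, 0, L)
  H0 <- H_of_r(x, y, L)$H
  expect_gte(mean(H0 >= env[1, ] & H0 <= env[2, ]), 0.95)
  expect_lt(max(abs(H0)), 0.35)
  ## Gaussian cluster (sigma = 0.3, N = 500): strong positive H with argmax of
  ## order the cluster size; cross-checked against a 4x denser binning
  set.seed(12)
  cx <- (rnorm(500, 4, 0.3)) %% L; cy <- (rnorm(500, 4, 0.3)) %% L
  hc <- H_of_r(cx, cy, L)
  expect_gt(max(hc$H), 1)
  am <- hc$r[which.max(hc$H)]
  expect_gt(am, 0.2); expect_lt(am, 2)
  hfine <- H_of_r(cx, cy, L, dr = 0.0125)
  expect_lt(abs(hfine$r[which.max(hfine$H)] - am), 0.15)
  ## K is non-decreasing and bounded by 1
  expect_true(all(diff(hc$K) >= 0))
  expect_lte(max(hc$K), 1)
})

test_that("toroidal centroid wraps, is exact for points, and is translation-equivariant", {
  L <- 8
  ## cluster straddling the boundary centers at the origin, not at L/2
  set.seed(13)
  x <- (rnorm(300, 0, 0.2)) %% L; y <- (rnorm(300, 0, 0.2)) %% L
  ce <- centroid_torus(x, y, L)
  expect_lt(min(ce[1], L - ce[1]), 0.1)
  expect_lt(min(ce[2], L - ce[2]), 0.1)
  expect_equal(unname(centroid_torus(1.23, 4.56, L)), c(1.23, 4.56),
               ignore_attr = TRUE)
  ## translation equivariance for random shifts
  for (k in 1:5) {
    dx <- runif(1, 0, L); dy <- runif(1, 0, L)
    c2 <- centroid_torus((x + dx) %% L, (y + dy) %% L, L)
    expect_equal((ce[1] + dx) %% L, c2[[1]], tolerance = 1e-6)
    expect_equal((ce[2] + dy) %% L, c2[[2]], tolerance = 1e-6)
  }
  ## no directional concentration -> undefined centroid flag
  gx <- rep(seq(0.5, 7.5, 1), each = 8); gy <- rep(seq(0.5, 7.5, 1), 8)
  expect_warning(cc <- centroid_torus(gx, gy, L), "undefined")
  expect_true(anyNA(cc))
})

test_that("H statistics are invariant to global translation on the torus", {
  set.seed(14)
  L <- 6
  x <- (rnorm(200, 2, 0.5)) %% L; y <- (rnorm(200, 5, 0.5)) %% L
  h1 <- H_of_r(x, y, L)
  h2 <- H_of_r((x + 2.7) %% L, (y + 4.1) %% L, L)
  expect_equal(h1$H, h2$H, tolerance = 1e-12)
})

test_that("D_patch and beta are recovered from synthetic random walks", {
  ## pure Brownian centroid track: MSD = 4 D t, beta = 1
  set.seed(15)
  D <- 0.01   # um^2/min
  L <- 8; dts <- 60
  tracks <- lapply(1:12, function(k) {
    n <- 61
    dx <- rnorm(n - 1, 0, sqrt(2 * D)); dy <- rnorm(n - 1, 0, sqrt(2 * D))
    data.frame(time = (0:(n - 1)) * dts,
               x = (cumsum(c(4, dx))) %% L, y = (cumsum(c(4, dy))) %% L)
  })
  fit <- msd_and_dpatch(tracks, L = L, sample_dt = dts)
  expect_lt(abs(fit$D_patch - D), 2 * fit$D_se + 0.002)
  expect_gt(fit$beta, 0.9); expect_lt(fit$beta, 1.1)

  ## anomalous walk with beta = 0.85 via fractional Brownian motion
  ## (Cholesky of the fBm covariance; per-coordinate MSD = 2 D t^beta)
  set.seed(16)
  beta <- 0.85
  n <- 41; tt <- (1:n)   # minutes
  Hh <- beta / 2
  cv <- outer(tt, tt, function(a, b)
    D * (a^(2 * Hh) + b^(2 * Hh) - abs(a - b)^(2 * Hh)))
  Ch <- chol(cv + diag(1e-12, n))
  ## per-group estimates give an honest SE (pooled-pair OLS understates it);
  ## the elapsed-lag abscissa carries a ~+0.05 deterministic bias here
  betas <- vapply(1:8, function(g) {
    tracks2 <- lapply(1:5, function(k) {
      x <- c(4, 4 + as.vector(t(Ch) %*% rnorm(n)))
      y <- c(4, 4 + as.vector(t(Ch) %*% rnorm(n)))
      data.frame(time = (0:n) * 60, x = x %% L, y = y %% L)
    })
    msd_and_dpatch(tracks2, L = L, sample_dt = 60, fit_lags = 4:15)$beta
  }, 0)
  expect_lt(abs(mean(betas) - beta), 2 * sd(betas) / sqrt(8) + 0.06)

  ## static centroid with observation noise: baseline subtraction removes
  ## essentially all MSD; either too few positive lag points remain (fit
  ## error) or the fitted diffusivity is negligible against the noise scale
  set.seed(17)
  tracks3 <- lapply(1:5, function(k)
    data.frame(time = (0:60) * 60, x = 4 + rnorm(61, 0, 0.05),
               y = 4 + rnorm(61, 0, 0.05)))
  fit3 <- tryCatch(msd_and_dpatch(tracks3, L = L, sample_dt = 60),
                   error = function(e) e)
  if (inherits(fit3, "error")) {
    expect_match(conditionMessage(fit3), "usable|lag")
  } else {
    expect_lt(fit3$D_patch, 1e-3)
    expect_lt(max(abs(fit3$msd_adjusted), na.rm = TRUE), 0.2 * fit3$baseline)
  }
})

test_that("trajectory breaking discards jumps larger than max_jump", {
  L <- 20
  set.seed(21)
  ## two slow segments far apart joined by one 8-um jump
  seg1 <- cumsum(c(2, rnorm(14, 0, 0.05)))
  seg2 <- cumsum(c(10, rnorm(14, 0, 0.05)))
  tr <- data.frame(time = (0:29) * 60, x = c(seg1, seg2), y = rep(1, 30))
  fit <- msd_and_dpatch(tr, L = L, max_jump = 6, sample_dt = 60,
                        fit_lags = 2:5)
  ## with the jump discarded, no pooled MSD can reach the inter-segment scale
  expect_lt(max(fit$msd, na.rm = TRUE), 1)
  ## without breaking, the jump dominates the MSD at long lags
  fit_all <- msd_and_dpatch(tr, L = L, max_jump = 100, sample_dt = 60,
                            fit_lags = 2:5)
  expect_gt(max(fit_all$msd, na.rm = TRUE), 10)
})

test_that("CV_patch: zero for constant fields, 1/sqrt(mu) for Poisson counts, errors on empty", {
  const <- matrix(7, 25, 80)
  expect_equal(cv_patch(const), 0)
  set.seed(18)
  for (mu in c(4, 25)) {
    counts <- matrix(rpois(400 * 200, mu), 400, 200)
    expect_equal(cv_patch(counts), 1 / sqrt(mu), tolerance = 0.02)
  }
  expect_error(cv_patch(matrix(0, 4, 10)), "all-zero")
  expect_error(cv_patch(matrix(1, 4, 1)), "2 samples")
})

test_that("exponential dwell fits recover the time constant", {
  tt <- seq(0, 30, by = 0.5)
  y <- 400 * exp(-tt / 6)
  fit <- fit_exponential_decay(tt, y)
  expect_equal(fit$tau, 6, tolerance = 1e-6)
  ## noisy counts
  set.seed(19)
  yn <- rpois(length(tt), 400 * exp(-tt / 6))
  fitn <- fit_exponential_decay(tt, yn)
  expect_equal(fitn$tau, 6, tolerance = 0.1)
  ## a transient start is excluded by t_min
  y2 <- 200 * exp(-tt / 6) + 300 * exp(-tt / 0.5)
  fit2 <- fit_exponential_decay(tt, y2, t_min = 5)
  expect_equal(fit2$tau, 6, tolerance = 0.05)
  expect_error(fit_exponential_decay(tt, rev(y)), "decay")
})

test_that("tagged washout through the RDME recovers first-order detachment dwell times", {
  ## toy: membrane species M detaches at rate k to cytosolic U; tagging rule
  ## converts M -> M_tag whose detachment product is untagged U. Dwell = 1/k.
  k <- 0.4
  sp <- list(species_spec("M", "membrane", 0.01, carries = "m"),
             species_spec("U", "cytosol", 1))
  rx <- list(uni_reaction("M", "U", k, "mem_to_cyto", name = "det"))
  m <- rd_model(sp, rx, init = c(M = 500))
  mt <- tag_model(m, "m")
  nx <- 8L
  set.seed(22)
  state <- matrix(0L, 2, nx * nx,
                  dimnames = list(c("M", "U"), NULL))
  state["M", ] <- as.integer(rmultinom(1, 500, rep(1, nx * nx)))
  fit <- dwell_time(mt, state, L = 2, h = 0.25, center = c(1, 1),
                    radius = 2,   # whole domain tagged
                    mode = "naive", seed = 23, t_end = 12,
                    record_interval = 0.25)
  expect_equal(fit$tau, 1 / k, tolerance = 0.15)
  ## zero-rebinding control: single-molecule residence is exponential(k), so
  ## the Markov-chain closed form for the mean residence is 1/k; the fitted
  ## dwell above matches it because rebinding is disabled (U never returns)
  expect_equal(fit$tau, 1 / k, tolerance = 0.15)
})

test_that("polarization metric flags empty snapshots and tracks clustering", {
  ## synthetic trajectory object with particle positions
  L <- 8
  set.seed(20)
  mk <- function(n, sigma) {
    if (n == 0) return(data.frame(species = character(), x = numeric(),
                                  y = numeric()))
    data.frame(species = "Cdc42T", x = (rnorm(n, 4, sigma)) %% L,
               y = (rnorm(n, 4, sigma)) %% L)
  }
  traj <- structure(list(times = c(0, 1, 2),
                         positions = list(mk(0, 1), mk(300, 2.5), mk(300, 0.4)),
                         species = "Cdc42T",
                         meta = list(engine = "particle", L = L)),
                    class = c("pb_trajectory", "rd_trajectory"))
  pm <- polarization_metric(traj)
  expect_true(is.na(pm$H[1]))
  expect_gt(pm$H[3], pm$H[2])   # tighter cluster scores higher
})
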