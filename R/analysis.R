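#' Pairwise-distance distribution of a periodic point pattern
#'
#' `P(r)` is the density of pairwise (minimum-image) distances, normalized by
#' the N(N-1) ordered comparisons, so it integrates to at most 1 over
#' `[0, r_max]`. For a spatially uniform pattern `P(r) ~ 2 pi r / A` for
#' r well below L/2.
#'
#' @param x,y positions in um, wrapped to the `[0, L)` x `[0, L)` torus.
#' @param L domain side, um.
#' @param r_max histogram range, um; defaults to L/2 (the validity limit of
#'   minimum-image distances).
#' @param dr bin width, um.
#' @return data.frame with bin centers `r`, edges `r_lo`/`r_hi`, density `P`,
#'   and the raw ordered-pair `count` per bin.
#' @export
pairwise_distribution <- function(x, y, L, r_max = L / 2, dr = 0.05) {
  n <- length(x)
  if (n < 2) stop("pairwise statistics need at least 2 points")
  stopifnot(length(y) == n, r_max <= L / 2 + 1e-12)
  breaks <- seq(0, r_max, by = dr)
  if (breaks[length(breaks)] < r_max) breaks <- c(breaks, r_max)
  cnt <- .pair_dist_hist(x, y, L, breaks) * 2     # ordered pairs
  widths <- diff(breaks)
  data.frame(r = (breaks[-1] + breaks[-length(breaks)]) / 2,
             r_lo = breaks[-length(breaks)], r_hi = breaks[-1],
             P = cnt / (n * (n - 1)) / widths,
             count = cnt)
}

#' H(r) cluster statistic of a periodic point pattern
#'
#' Besag-L-type transform of the cumulative pairwise-distance distribution:
#' `H(r) = sqrt(A/pi * K(r)) - r` where `K(r)` is the cumulative mass of P(r)
#' up to r. H(r) = 0 for a structureless (uniform) pattern, > 0 for
#' clustering, < 0 for dispersion; the location of the maximum estimates the
#' cluster length scale.
#'
#' @inheritParams pairwise_distribution
#' @return data.frame with bin right edges `r`, cumulative `K` and `H`.
#' @export
H_of_r <- function(x, y, L, r_max = L / 2, dr = 0.05) {
  pd <- pairwise_distribution(x, y, L, r_max, dr)
  n <- length(x)
  K <- cumsum(pd$count) / (n * (n - 1))
  A <- L^2
  data.frame(r = pd$r_hi, K = K, H = sqrt(A / pi * K) - pd$r_hi)
}

#' H evaluated at a single radius
#'
#' @inheritParams pairwise_distribution
#' @param r radius at which to evaluate H, um.
#' @return H(r), um; NA if fewer than 2 points (flagged, not fatal).
#' @export
H_at <- function(x, y, L, r, dr = 0.05) {
  if (length(x) < 2) return(NA_real_)
  hh <- H_of_r(x, y, L, r_max = min(L / 2, r + dr), dr = dr)
  i <- which.min(abs(hh$r - r))
  hh$H[i]
}

#' Polarization metric time series of a trajectory
#'
#' H(r = 1.1 um) of the pooled positions of active Cdc42 (Cdc42T and the
#' Cdc42T-GEF complex) at each snapshot; the paper-standard summary of
#' polarity-patch formation. Snapshots with fewer than 2 active molecules give
#' NA.
#'
#' @param traj an `rdme_trajectory` recorded with occupancies, or a
#'   `pb_trajectory` recorded with positions.
#' @param species species pooled as "active" (defaults to all species whose
#'   name starts with Cdc42T, tagged shadows included).
#' @param r metric radius, um.
#' @param seed seed for pseudo-coordinate sampling of RDME snapshots.
#' @return data.frame with `time` and `H`.
#' @export
polarization_metric <- function(traj, species = NULL, r = 1.1, seed = 1) {
  L <- traj$meta$L
  species <- species %||% grep("^Cdc42T", traj$species, value = TRUE)
  H <- vapply(seq_along(traj$times), function(i) {
    xy <- snapshot_positions(traj, i, species, seed = seed + i)
    if (nrow(xy) < 2) NA_real_ else H_at(xy[, 1], xy[, 2], L, r)
  }, 0)
  data.frame(time = traj$times, H = H)
}

#' Positions of selected species at a snapshot
#'
#' Particle trajectories return recorded coordinates; RDME trajectories return
#' uniform pseudo-coordinates within occupied voxels.
#'
#' @param traj an `rd_trajectory`.
#' @param snapshot snapshot index.
#' @param species species names to pool.
#' @param seed pseudo-coordinate seed (RDME only).
#' @return two-column matrix (x, y).
#' @export
snapshot_positions <- function(traj, snapshot, species, seed = 1) {
  if (inherits(traj, "rdme_trajectory"))
    return(pseudo_coordinates(traj, snapshot, species, seed))
  if (is.null(traj$positions))
    stop("particle trajectory was not recorded with record_positions = TRUE")
  p <- traj$positions[[snapshot]]
  p <- p[p$species %in% species, , drop = FALSE]
  cbind(p$x, p$y)
}

#' Centroid of a point pattern on the torus
#'
#' Per-axis circular mean: coordinates are mapped to angles `2 pi x / L`, the
#' unit vectors averaged, and the mean angle mapped back, so clusters
#' straddling the periodic boundary are handled correctly.
#'
#' @param x,y positions, um.
#' @param L domain side, um.
#' @return length-2 vector (x, y) in `[0, L)`, with attribute `resultant`
#'   (mean resultant lengths per axis); NA with a warning when the pattern has
#'   no directional concentration on an axis.
#' @export
centroid_torus <- function(x, y, L) {
  if (!length(x)) stop("centroid of an empty pattern is undefined")
  circ_mean <- function(v) {
    th <- 2 * pi * v / L
    s <- mean(sin(th)); c <- mean(cos(th))
    R <- sqrt(s^2 + c^2)
    if (R < 1e-9) return(c(NA_real_, R))
    c((atan2(s, c) / (2 * pi)) %% 1 * L, R)
  }
  cx <- circ_mean(x); cy <- circ_mean(y)
  if (anyNA(c(cx[1], cy[1])))
    warning("no directional concentration; centroid undefined")
  structure(c(cx[1], cy[1]), resultant = c(cx[2], cy[2]))
}

#' Patch centroid track of a trajectory
#'
#' @param traj an `rd_trajectory` with spatial snapshots.
#' @param species species pooled (default: active Cdc42).
#' @param seed pseudo-coordinate seed.
#' @return data.frame with `time`, `x`, `y` (NA rows where the pattern was
#'   empty).
#' @export
centroid_track <- function(traj, species = NULL, seed = 1) {
  L <- traj$meta$L
  species <- species %||% grep("^Cdc42T", traj$species, value = TRUE)
  out <- t(vapply(seq_along(traj$times), function(i) {
    xy <- snapshot_positions(traj, i, species, seed = seed + i)
    if (nrow(xy) < 1) return(c(NA_real_, NA_real_))
    suppressWarnings(centroid_torus(xy[, 1], xy[, 2], L))
  }, c(0, 0)))
  data.frame(time = traj$times, x = out[, 1], y = out[, 2])
}

## minimum-image displacement on the torus
.mi_disp <- function(d, L) (d + L / 2) %% L - L / 2

#' Mean squared displacement and patch diffusivity fit
#'
#' Tracks (sampled every `sample_dt` seconds) are broken into sub-trajectories
#' at any single-step displacement exceeding `max_jump` (discarding centroid
#' jumps across the domain). Step displacements use the minimum-image metric
#' and are accumulated into unwrapped paths; the MSD at lag `i * sample_dt`
#' pools all interval pairs of that lag over all sub-trajectories. The
#' fast-wobble baseline MSD(1 sample interval) is subtracted, and
#' `log(MSD) = log(4 D_patch) + beta log(dt)` is fit by least squares over the
#' lag window `fit_lags` (in sampling intervals).
#'
#' @param tracks list of data.frames with columns `time`, `x`, `y` (equally
#'   spaced samples), or a single such data.frame.
#' @param L domain side, um (for minimum-image unwrapping).
#' @param max_jump sub-trajectory break threshold, um.
#' @param sample_dt sampling interval of the tracks, s.
#' @param fit_lags lag indices (multiples of `sample_dt`) used in the log-log
#'   fit; lag 1 is the subtracted baseline.
#' @param time_unit `"min"` (D_patch in um^2/min; lags converted to minutes)
#'   or `"s"`.
#' @return an `msd_fit` list: `lag` (in `time_unit`), `msd`, baseline,
#'   `D_patch`, `beta`, standard errors, and the fit window.
#' @export
msd_and_dpatch <- function(tracks, L, max_jump = 6, sample_dt = 60,
                           fit_lags = 2:10, time_unit = c("min", "s")) {
  time_unit <- match.arg(time_unit)
  if (is.data.frame(tracks)) tracks <- list(tracks)
  ## split tracks at large jumps and NA gaps, unwrap on the torus
  subpaths <- list()
  for (tr in tracks) {
    ok <- !(is.na(tr$x) | is.na(tr$y))
    idx <- split(seq_len(nrow(tr))[ok], cumsum(!ok)[ok])
    for (seg in idx) {
      if (length(seg) < 2) next
      dx <- .mi_disp(diff(tr$x[seg]), L)
      dy <- .mi_disp(diff(tr$y[seg]), L)
      jump <- sqrt(dx^2 + dy^2)
      brk <- cumsum(c(0, jump > max_jump))
      for (piece in split(seq_along(seg), brk)) {
        if (length(piece) < 2) next
        i0 <- piece[1]
        px <- cumsum(c(0, dx[piece[-length(piece)]]))
        py <- cumsum(c(0, dy[piece[-length(piece)]]))
        subpaths[[length(subpaths) + 1L]] <- cbind(px, py)
      }
    }
  }
  if (!length(subpaths)) stop("no usable sub-trajectories")
  max_lag <- max(fit_lags)
  lags <- seq_len(min(max_lag, max(vapply(subpaths, nrow, 0L)) - 1L))
  msd <- vapply(lags, function(l) {
    acc <- 0; cnt <- 0
    for (p in subpaths) {
      n <- nrow(p)
      if (n <= l) next
      d2 <- (p[(1 + l):n, 1] - p[1:(n - l), 1])^2 +
        (p[(1 + l):n, 2] - p[1:(n - l), 2])^2
      acc <- acc + sum(d2); cnt <- cnt + length(d2)
    }
    if (cnt == 0) NA_real_ else acc / cnt
  }, 0)

  baseline <- msd[1]
  adj <- msd - baseline
  use <- intersect(fit_lags, lags)
  use <- use[!is.na(adj[use]) & adj[use] > 0]
  if (length(use) < 3)
    stop("fewer than 3 usable lag points after baseline subtraction")
  tfac <- if (time_unit == "min") 60 else 1
  ## abscissa is the lag elapsed beyond the baseline interval: subtracting
  ## MSD(1 interval) removes that interval's displacement along with the fast
  ## wobble, so the remaining MSD grows with (lag - 1) intervals. Fitting
  ## against the raw lag would read a pure Brownian centroid as
  ## superdiffusive; this choice recovers beta = 1 and D exactly for Brownian
  ## tracks and anomalous exponents to within a few percent.
  lt <- log((use - 1) * sample_dt / tfac)
  ly <- log(adj[use])
  fit <- lm(ly ~ lt)
  co <- summary(fit)$coefficients
  D <- exp(co[1, 1]) / 4
  structure(list(lag = lags * sample_dt / tfac, msd = msd, baseline = baseline,
                 msd_adjusted = adj,
                 D_patch = D, D_se = D * co[1, 2],
                 beta = co[2, 1], beta_se = co[2, 2],
                 fit_lags = use, time_unit = time_unit,
                 n_subtracks = length(subpaths)),
            class = "msd_fit")
}

#' @export
print.msd_fit <- function(x, ...) {
  cat(sprintf("MSD fit over %d sub-trajectories: D_patch = %.4g +/- %.2g um^2/%s, beta = %.3f +/- %.3f\n",
              x$n_subtracks, x$D_patch, x$D_se, x$time_unit, x$beta, x$beta_se))
  invisible(x)
}

#' Spatial coefficient of variation of a local-count field
#'
#' Abundance-weighted spatial average of the temporal coefficient of variation
#' of local counts:
#' `CV_patch = sum_j cv_j <n_j>` / `sum_j <n_j>` with `cv_j = sd_j / mean_j`
#' over a time window (conventionally 60 s sampled every second). Zero for a
#' temporally constant field; `1/sqrt(mu)` for independent Poisson counts of
#' mean mu.
#'
#' @param counts matrix, locations x time samples, of local molecule counts.
#' @return CV_patch, dimensionless.
#' @export
cv_patch <- function(counts) {
  if (!is.matrix(counts) || ncol(counts) < 2)
    stop("need a locations x time matrix with at least 2 samples")
  m <- rowMeans(counts)
  if (all(m == 0)) stop("all-zero count field: CV_patch undefined")
  s <- apply(counts, 1, sd)
  cv <- ifelse(m > 0, s / m, 0)
  sum(cv * m) / sum(m)
}

#' CV_patch of an RDME trajectory window
#'
#' @param traj an `rdme_trajectory` recorded with occupancies sampled at 1 s
#'   (or finer) spacing.
#' @param species species pooled as the local field (default: active Cdc42).
#' @param window time window length, s.
#' @param t_start window start, s (defaults to the end of the trajectory minus
#'   the window).
#' @return CV_patch.
#' @export
cv_patch_trajectory <- function(traj, species = NULL, window = 60,
                                t_start = NULL) {
  if (is.null(traj$occupancy)) stop("needs record_occupancy = TRUE")
  species <- species %||% grep("^Cdc42T", traj$species, value = TRUE)
  t_start <- t_start %||% (max(traj$times) - window)
  sel <- which(traj$times >= t_start - 1e-9 &
                 traj$times <= t_start + window + 1e-9)
  if (length(sel) < 2 || diff(range(traj$times[sel])) < window - 1e-9)
    stop("trajectory window shorter than the requested averaging window")
  field <- apply(traj$occupancy[species, , sel, drop = FALSE], c(2, 3), sum)
  cv_patch(field)
}

#' Fit a single-exponential decay and report the time constant
#'
#' Fits `y(t) = y0 exp(-t / tau)` by nonlinear least squares (initialized from
#' the log-linear fit) over `t >= t_min`, the window start used to skip an
#' initial fast transient.
#'
#' @param time,y decay series (y >= 0).
#' @param t_min fit window start, s.
#' @return list with `tau`, `tau_se`, `y0` and the fit window.
#' @export
fit_exponential_decay <- function(time, y, t_min = 0) {
  keep <- time >= t_min & !is.na(y)
  t2 <- time[keep]; y2 <- y[keep]
  pos <- y2 > 0
  if (sum(pos) < 3) stop("need at least 3 positive observations to fit")
  lf <- lm(log(y2[pos]) ~ t2[pos])
  if (coef(lf)[2] >= 0)
    stop("series does not decay; cannot fit an exponential dwell time")
  start <- list(y0 = exp(coef(lf)[1]), tau = -1 / coef(lf)[2])
  fit <- tryCatch(
    suppressWarnings(nls(y2 ~ y0 * exp(-t2 / tau), start = start,
                         control = list(maxiter = 200, warnOnly = TRUE))),
    error = function(e) NULL)
  if (is.null(fit)) {
    co <- summary(lf)$coefficients
    return(list(tau = -1 / co[2, 1], tau_se = co[2, 2] / co[2, 1]^2,
                y0 = exp(co[1, 1]), t_min = t_min, method = "loglinear"))
  }
  co <- summary(fit)$coefficients
  list(tau = co["tau", 1], tau_se = co["tau", 2], y0 = co["y0", 1],
       t_min = t_min, method = "nls")
}

#' Dwell time of a tagged moiety at the polarity patch
#'
#' Washout protocol: from a steady-state snapshot, membrane species carrying
#' the moiety are converted to their tagged shadows inside a disk around the
#' patch centroid; the simulation continues and the total count of tagged
#' molecules decays as tagged molecules detach to the (untagging) cytosol.
#' A single exponential fitted after an initial transient gives the dwell
#' time.
#'
#' @param tagged_model an `rd_model` built with tagged shadows (see
#'   [tag_model()] / `build_polarity_model(tagged = )`).
#' @param state species x voxel occupancy matrix at steady state, for the
#'   untagged model's species (tagged rows are added as zeros).
#' @param L,h grid geometry of `state`.
#' @param center patch center (x, y), um.
#' @param radius tagging region radius, um.
#' @param mode,seed,t_end,record_interval passed to [simulate_rdme()].
#' @param t_min fit window start, s (skips the initial rapid decay from
#'   membrane detachment of inactive molecules).
#' @return list from [fit_exponential_decay()] plus the decay series.
#' @export
dwell_time <- function(tagged_model, state, L, h, center, radius,
                       mode = "kc", seed = 1, t_end = 30,
                       record_interval = 0.5, t_min = 0) {
  nm <- vapply(tagged_model$species, `[[`, "", "name")
  nx <- as.integer(round(L / h))
  full <- matrix(0L, length(nm), nx * nx)
  rownames(full) <- nm
  full[rownames(state), ] <- state
  ## voxels inside the tagging disk (voxel centers, torus metric)
  vx <- (seq_len(nx * nx) - 1) %% nx
  vy <- (seq_len(nx * nx) - 1) %/% nx
  cx <- (vx + 0.5) * h; cy <- (vy + 0.5) * h
  d2 <- .mi_disp(cx - center[1], L)^2 + .mi_disp(cy - center[2], L)^2
  inside <- d2 <= radius^2
  tagged <- grep("_tag$", nm, value = TRUE)
  for (tg in tagged) {
    base <- sub("_tag$", "", tg)
    full[tg, inside] <- full[tg, inside] + full[base, inside]
    full[base, inside] <- 0L
  }
  traj <- simulate_rdme(tagged_model, L, h, mode = mode, t_end = t_end,
                        record_interval = record_interval, seed = seed,
                        init_state = full)
  y <- rowSums(traj$totals[, tagged, 1, drop = FALSE])
  if (y[length(y)] >= y[1] && y[1] > 0)
    stop("tagged totals do not decay; check the tagging rules (leak?)")
  fit <- fit_exponential_decay(traj$times, y, t_min = t_min)
  fit$series <- data.frame(time = traj$times, tagged_total = y)
  fit
}
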