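#' Total diffusive jump propensity of a species in a voxel
#'
#' With n molecules of diffusion coefficient D in a voxel of side h, each of
#' the four neighbor directions has propensity `n D / h^2`; the total jump
#' propensity is `4 n D / h^2`.
#'
#' @param n molecule count (>= 0).
#' @param D diffusion coefficient, um^2/s.
#' @param h grid spacing, um.
#' @return total jump propensity, 1/s.
#' @export
diffusion_propensity <- function(n, D, h) {
  stopifnot(all(n >= 0), h > 0, D >= 0)
  4 * n * D / h^2
}

#' Reaction propensity in a voxel
#'
#' Bimolecular: `k_meso n_A n_B / h^2`, where k_meso is the naive k_micro, the
#' scale-dependent k_h, or the occupancy-dependent k_c(max(n_A, n_B)).
#' First-order: `k n`, with dissociation rates paired to the association mode.
#'
#' @param model an `rd_model`.
#' @param reaction reaction label.
#' @param occupancy named vector of per-species molecule counts in the voxel.
#' @param h grid spacing, um.
#' @param mode `"naive"`, `"kh"` or `"kc"`.
#' @return propensity, 1/s.
#' @export
reaction_propensity <- function(model, reaction, occupancy, h,
                                mode = c("kc", "kh", "naive")) {
  mode <- match.arg(mode)
  labels <- vapply(model$reactions, function(r) r$name %||% "", "")
  j <- match(reaction, labels)
  if (is.na(j)) stop("unknown reaction: ", reaction)
  r <- model$reactions[[j]]
  tab <- meso_rate_table(model, h, mode)
  if (r$type == "bi") {
    na <- occupancy[[r$ra]]; nb <- occupancy[[r$rb]]
    if (na == 0 || nb == 0) return(0)
    i <- match(r$name %||% "", tab$name)
    km <- switch(mode,
                 naive = r$k_micro,
                 kh = tab$k_meso[i],
                 kc = {
                   tb <- tab$kc_table[[i]]
                   n <- max(na, nb)
                   if (n > length(tb)) r$k_micro else tb[n]
                 })
    km * na * nb / h^2
  } else {
    n <- occupancy[[r$reactant]]
    if (n == 0) return(0)
    rate <- r$rate
    if (!is.null(r$dissociation_of) && mode != "naive") {
      i <- match(r$dissociation_of, tab$name)
      ratio <- if (mode == "kh") tab$ratio[i] else {
        fb <- model$reactions[[match(r$dissociation_of, labels)]]
        ne <- max(occupancy[[fb$ra]], occupancy[[fb$rb]], 1)
        tb <- tab$kc_table[[i]]
        if (tab$k_micro[i] == 0) 1
        else (if (ne > length(tb)) tab$k_micro[i] else tb[ne]) / tab$k_micro[i]
      }
      rate <- rate * ratio
    }
    rate * n
  }
}

## Build the flat reaction tables consumed by the NSM kernel.
compile_nsm <- function(model, h, mode) {
  nm <- vapply(model$species, `[[`, "", "name")
  sidx <- setNames(seq_along(nm) - 1L, nm)
  labels <- vapply(model$reactions, function(r) r$name %||% "", "")
  unis <- Filter(function(r) r$type == "uni", model$reactions)
  bis <- Filter(function(r) r$type == "bi", model$reactions)
  bi_labels <- vapply(bis, function(r) r$name %||% "", "")

  tab <- meso_rate_table(model, h, mode)

  pmat <- function(lst) {
    m <- matrix(-1L, length(lst), 2)
    for (i in seq_along(lst)) {
      p <- lst[[i]]
      if (length(p)) m[i, seq_along(p)] <- sidx[p]
    }
    m
  }

  u_rate <- vapply(unis, `[[`, 0, "rate")
  u_link <- rep(-1L, length(unis))
  for (i in seq_along(unis)) {
    d <- unis[[i]]$dissociation_of
    if (is.null(d)) next
    b <- match(d, bi_labels)
    if (mode == "kh") {
      u_rate[i] <- u_rate[i] * tab$ratio[b]       # k_h^d = k_d * k_h / k_micro
    } else if (mode == "kc") {
      u_link[i] <- b - 1L                          # occupancy-dependent k_c^d
    }
  }

  bi_rate <- switch(mode,
                    naive = tab$k_micro / h^2,
                    kh = tab$k_meso / h^2,
                    kc = rep(0, nrow(tab)))
  kc_tabs <- lapply(seq_len(nrow(tab)), function(i) {
    if (mode == "kc") tab$kc_table[[i]] / h^2 else numeric(0)
  })
  ratio_tabs <- lapply(seq_len(nrow(tab)), function(i) {
    if (mode == "kc" && tab$k_micro[i] > 0) tab$kc_table[[i]] / tab$k_micro[i]
    else 1
  })

  list(sidx = sidx,
       jump = vapply(model$species, `[[`, 0, "D") / h^2,
       u_reac = vapply(unis, function(r) sidx[[r$reactant]], 0L),
       u_rate = u_rate,
       u_prod = pmat(lapply(unis, `[[`, "products")),
       u_link = u_link,
       b_ra = vapply(bis, function(r) sidx[[r$ra]], 0L),
       b_rb = vapply(bis, function(r) sidx[[r$rb]], 0L),
       b_prod = pmat(lapply(bis, `[[`, "products")),
       bi_rate = bi_rate, kc_tabs = kc_tabs, ratio_tabs = ratio_tabs,
       rate_table = tab)
}

#' Simulate a model with the Next Subvolume Method
#'
#' Generates statistically exact realizations of the reaction-diffusion master
#' equation on an `L` x `L` periodic square discretized into voxels of side
#' `h`, using the selected mesoscopic rate mode for bimolecular reactions.
#'
#' @param model an `rd_model`.
#' @param L domain side, um; `L/h` must be an integer.
#' @param h grid spacing, um. In `"kh"` mode, h must satisfy the per-reaction
#'   lower bound [h_min()], otherwise an error reports the bound.
#' @param mode `"kc"` (occupancy-dependent rates), `"kh"` (scale-dependent
#'   scalar rates) or `"naive"` (k_micro used directly).
#' @param t_end simulated time horizon, s.
#' @param record_interval snapshot spacing, s (Inf to record only t = 0).
#' @param seed integer seed; identical seed + configuration gives an identical
#'   trajectory.
#' @param init_state optional integer matrix (species x voxel, voxels in
#'   row-major x-fastest order) to start from; by default the model's initial
#'   counts are placed in uniformly random voxels.
#' @param record_occupancy keep full per-voxel per-species counts at each
#'   snapshot (required for spatial statistics; `replicates` must be 1).
#' @param stop_species species name: stop a realization when its total count
#'   reaches zero and report the stopping time (used for first-passage
#'   measurements such as mean association times).
#' @param replicates number of independent realizations (independent RNG
#'   streams derived from `seed`).
#' @return an `rdme_trajectory` list: `times`, `totals` (time x species x
#'   replicate), optional `occupancy` (species x voxel x time), `stop_times`,
#'   `events`, and a `meta` block echoing the configuration and the mesoscopic
#'   rate table.
#' @export
simulate_rdme <- function(model, L, h, mode = c("kc", "kh", "naive"),
                          t_end, record_interval = t_end / 50, seed = 1,
                          init_state = NULL, record_occupancy = FALSE,
                          stop_species = NULL, replicates = 1) {
  mode <- match.arg(mode)
  nx <- L / h
  if (abs(nx - round(nx)) > 1e-9)
    stop("L/h must be an integer: the grid must tile the domain exactly")
  nx <- as.integer(round(nx))
  nm <- vapply(model$species, `[[`, "", "name")
  nspec <- length(nm)

  cm <- compile_nsm(model, h, mode)  # errors in kh mode when h < h_min

  if (is.null(init_state)) {
    occ0 <- matrix(0L, nspec, nx * nx)
    init_random <- TRUE
    init_total <- as.integer(model$init[nm])
  } else {
    if (!is.matrix(init_state) || nrow(init_state) != nspec ||
        ncol(init_state) != nx * nx)
      stop("init_state must be a species x voxel matrix matching the grid")
    occ0 <- matrix(as.integer(init_state), nspec)
    init_random <- FALSE
    init_total <- integer(nspec)
  }

  res <- .nsm_run(nx, h, nspec, cm$jump,
                  occ0, init_random, init_total,
                  as.integer(cm$u_reac), cm$u_rate, cm$u_prod,
                  as.integer(cm$u_link),
                  as.integer(cm$b_ra), as.integer(cm$b_rb), cm$b_prod,
                  cm$bi_rate, cm$kc_tabs, cm$ratio_tabs,
                  match(mode, c("naive", "kh", "kc")) - 1L,
                  t_end, record_interval, record_occupancy,
                  if (is.null(stop_species)) -1L else cm$sidx[[stop_species]],
                  as.integer(replicates),
                  as.double(seed), 0)

  totals <- res$totals
  dimnames(totals) <- list(NULL, nm, NULL)
  out <- list(times = res$times, totals = totals,
              stop_times = res$stop_times, events = res$events,
              species = nm,
              meta = list(engine = "rdme", L = L, h = h, nx = nx, mode = mode,
                          seed = seed, t_end = t_end,
                          record_interval = record_interval,
                          replicates = replicates,
                          rate_table = cm$rate_table))
  if (record_occupancy) {
    occ <- res$occupancy
    dim(occ) <- c(nspec, nx * nx, length(res$times))
    dimnames(occ) <- list(nm, NULL, NULL)
    out$occupancy <- occ
  }
  class(out) <- c("rdme_trajectory", "rd_trajectory")
  out
}

#' @export
print.rd_trajectory <- function(x, ...) {
  cat(sprintf("%s trajectory: %d species, %d snapshots, t in [0, %g] s\n",
              x$meta$engine, length(x$species), length(x$times),
              max(x$times)))
  fin <- final_totals(x)
  cat("final totals:", paste(sprintf("%s=%g", names(fin), fin),
                             collapse = ", "), "\n")
  invisible(x)
}

#' Species totals at the final snapshot (averaged over replicates)
#' @param traj an `rd_trajectory`.
#' @return named numeric vector.
#' @export
final_totals <- function(traj) {
  tt <- traj$totals
  nt <- dim(tt)[1]
  setNames(apply(tt[nt, , , drop = FALSE], 2, mean), traj$species)
}

#' Ensemble mean and standard deviation of species totals over replicates
#' @param traj an `rd_trajectory` run with `replicates > 1`.
#' @return list with `times`, `mean` and `sd` (time x species matrices) and
#'   `n` replicates.
#' @export
ensemble_stats <- function(traj) {
  tt <- traj$totals
  list(times = traj$times,
       mean = apply(tt, c(1, 2), mean),
       sd = apply(tt, c(1, 2), sd),
       n = dim(tt)[3])
}

#' Uniform pseudo-coordinates for molecules of an RDME snapshot
#'
#' Molecules are assigned positions sampled uniformly within their containing
#' voxel, which puts grid data on the same footing as particle positions for
#' the spatial statistics (H(r), centroid tracking).
#'
#' @param traj an `rdme_trajectory` recorded with `record_occupancy = TRUE`.
#' @param snapshot snapshot index (1-based).
#' @param species character vector of species to pool.
#' @param seed integer seed for the position sampling.
#' @return two-column matrix of (x, y) positions in um.
#' @export
pseudo_coordinates <- function(traj, snapshot, species, seed = 1) {
  if (is.null(traj$occupancy))
    stop("trajectory was not recorded with record_occupancy = TRUE")
  h <- traj$meta$h; nx <- traj$meta$nx
  occ <- traj$occupancy[species, , snapshot, drop = FALSE]
  counts <- colSums(occ)           # per voxel, pooled over species
  n <- sum(counts)
  if (n == 0) return(matrix(numeric(0), 0, 2))
  vox <- rep(seq_along(counts) - 1L, counts)
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed", .GlobalEnv)
    on.exit(if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv))
    set.seed(seed)
  }
  cbind((vox %% nx + runif(n)) * h,
        (vox %/% nx + runif(n)) * h)
}
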