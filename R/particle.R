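#' Time step for particle-based benchmark simulations
#'
#' Benchmarks of elementary reactions use `dt = (0.1 rho)^2 / (4 D_tot)`, so
#' the root-mean-square displacement per step is below a tenth of the reactive
#' radius; polarity-scale runs use `dt = rho^2 / (4 D_cyto)` (rms displacement
#' of the fastest, cytosolic, species equal to rho).
#'
#' @param rho reactive radius, um.
#' @param D_tot summed diffusion coefficient of a reactant pair, um^2/s.
#' @param D_cyto cytosolic diffusion coefficient, um^2/s.
#' @return time step, s.
#' @export
dt_benchmark <- function(rho, D_tot) (0.1 * rho)^2 / (4 * D_tot)

#' @rdname dt_benchmark
#' @export
dt_polarity <- function(rho, D_cyto) rho^2 / (4 * D_cyto)

## Flatten an rd_model into the tables consumed by the Brownian-dynamics
## kernel. lambda is recovered from k_micro via the 2D lambda-rho relation.
compile_pb <- function(model, epsilon_frac = 1e-3) {
  nm <- vapply(model$species, `[[`, "", "name")
  sidx <- setNames(seq_along(nm) - 1L, nm)
  unis <- Filter(function(r) r$type == "uni", model$reactions)
  bis <- Filter(function(r) r$type == "bi", model$reactions)
  bi_labels <- vapply(bis, function(r) r$name %||% "", "")

  pmat <- function(lst) {
    m <- matrix(-1L, max(1L, length(lst)), 2)
    for (i in seq_along(lst)) {
      p <- lst[[i]]
      if (length(p)) m[i, seq_along(p)] <- sidx[p]
    }
    m[seq_along(lst), , drop = FALSE]
  }

  u_sep <- vapply(unis, function(r) {
    if (length(r$products) < 2L) return(0)
    if (!is.null(r$product_sep)) return(r$product_sep)
    if (!is.null(r$dissociation_of)) {
      b <- bis[[match(r$dissociation_of, bi_labels)]]
      return(b$rho * (1 + epsilon_frac))
    }
    stop("two-product reaction '", r$name %||% "?",
         "' needs product_sep or a dissociation_of link")
  }, 0)

  list(sidx = sidx,
       sp_D = vapply(model$species, `[[`, 0, "D"),
       u_reac = vapply(unis, function(r) sidx[[r$reactant]], 0L),
       u_rate = vapply(unis, `[[`, 0, "rate"),
       u_prod = pmat(lapply(unis, `[[`, "products")),
       u_sep = u_sep,
       b_ra = vapply(bis, function(r) sidx[[r$ra]], 0L),
       b_rb = vapply(bis, function(r) sidx[[r$rb]], 0L),
       b_lambda = vapply(bis, function(r)
         if (r$k_micro > 0) lambda_from_kmicro_2d(r$k_micro, r$rho) else 0, 0),
       b_rho = vapply(bis, `[[`, 0, "rho"),
       b_prod = pmat(lapply(bis, `[[`, "products")),
       b_src = {
         m <- matrix(1L, max(1L, length(bis)), 2)
         for (i in seq_along(bis)) {
           s <- bis[[i]]$product_src
           m[i, seq_along(s)] <- s
         }
         m[seq_along(bis), , drop = FALSE]
       })
}

#' Simulate a model with 2D Brownian dynamics (lambda-rho reactions)
#'
#' Microscopic ground-truth engine: point molecules diffuse by Euler-Maruyama
#' steps on an `L` x `L` periodic square; bimolecular reactions fire with
#' probability `1 - exp(-lambda dt)` per step whenever two reactants are within
#' the reactive radius rho (one reaction per molecule per step, candidate
#' pairs processed in random order); first-order reactions fire with
#' probability `1 - exp(-k dt)` per molecule. Dissociation places one product
#' at the complex position and the other at distance `rho (1 + epsilon_frac)`
#' in a uniformly random direction.
#'
#' @param model an `rd_model`.
#' @param L domain side, um.
#' @param dt time step, s (see [dt_benchmark()]).
#' @param t_end simulated time, s.
#' @param record_interval snapshot spacing, s.
#' @param seed integer seed.
#' @param init optional data.frame with columns `species`, `x`, `y`; by default
#'   the model's initial counts are placed uniformly at random.
#' @param record_positions keep molecule positions at every snapshot
#'   (`replicates` must be 1).
#' @param stop_species species name: stop when its total hits zero.
#' @param replicates independent realizations (independent RNG streams).
#' @param epsilon_frac dissociation offset as a fraction of rho (small, > 0).
#' @param force_cell_list always use the cell-list neighbor search (testing
#'   hook; by default small systems use an all-pairs scan).
#' @return a `pb_trajectory` list: `times`, `totals` (time x species x
#'   replicate), optional `positions` (list of per-snapshot matrices with
#'   columns species/x/y), `stop_times`, and `meta`.
#' @export
simulate_particles <- function(model, L, dt, t_end,
                               record_interval = t_end / 50, seed = 1,
                               init = NULL, record_positions = FALSE,
                               stop_species = NULL, replicates = 1,
                               epsilon_frac = 1e-3, force_cell_list = FALSE) {
  nm <- vapply(model$species, `[[`, "", "name")
  cm <- compile_pb(model, epsilon_frac)
  if (is.null(init)) {
    init_random <- TRUE
    type0 <- integer(0); x0 <- numeric(0); y0 <- numeric(0)
    init_total <- as.integer(model$init[nm])
  } else {
    stopifnot(all(c("species", "x", "y") %in% names(init)))
    init_random <- FALSE
    type0 <- as.integer(cm$sidx[init$species])
    x0 <- init$x; y0 <- init$y
    init_total <- integer(length(nm))
  }
  res <- .pb_run(L, dt, t_end, record_interval, cm$sp_D,
                 type0, x0, y0, init_random, init_total,
                 as.integer(cm$u_reac), cm$u_rate, cm$u_prod, cm$u_sep,
                 as.integer(cm$b_ra), as.integer(cm$b_rb),
                 cm$b_lambda, cm$b_rho, cm$b_prod, cm$b_src,
                 record_positions,
                 if (is.null(stop_species)) -1L else cm$sidx[[stop_species]],
                 as.integer(replicates), as.double(seed), 0,
                 force_cell_list)
  totals <- res$totals
  dimnames(totals) <- list(NULL, nm, NULL)
  out <- list(times = res$times, totals = totals,
              stop_times = res$stop_times, species = nm,
              meta = list(engine = "particle", L = L, dt = dt,
                          t_end = t_end, record_interval = record_interval,
                          seed = seed, replicates = replicates,
                          epsilon_frac = epsilon_frac))
  if (record_positions) {
    out$positions <- lapply(res$positions, function(m) {
      data.frame(species = nm[m[, 1] + 1], x = m[, 2], y = m[, 3],
                 stringsAsFactors = FALSE)
    })
  }
  class(out) <- c("pb_trajectory", "rd_trajectory")
  out
}

#' Run a named benchmark scenario with both engines
#'
#' Ensemble comparison of the elementary association benchmarks: mean and
#' standard deviation of the total number of A molecules versus time, from the
#' particle engine and the RDME engine in a chosen rate mode.
#'
#' @param scenario one of `"low_irrev"`, `"low_rev"`, `"high_irrev"`,
#'   `"high_rev"` (low density: A = B = 5; high density: A = B = 5000, or as
#'   overridden).
#' @param engine `"particle"`, `"rdme"`.
#' @param mode RDME rate mode (ignored for the particle engine).
#' @param replicates ensemble size.
#' @param seed integer seed.
#' @param L domain side, um.
#' @param n0 initial copy number override (NULL for the scenario default).
#' @param t_end,record_interval time horizon and snapshot spacing, s.
#' @param h grid spacing for the RDME engine, um.
#' @return list with `times`, `mean`, `sd` for species A, plus the trajectory
#'   metadata.
#' @export
run_benchmark <- function(scenario = c("low_irrev", "low_rev", "high_irrev",
                                       "high_rev"),
                          engine = c("particle", "rdme"),
                          mode = "kc", replicates = 30, seed = 1,
                          L = 1, n0 = NULL, t_end = 20,
                          record_interval = t_end / 20, h = NULL) {
  scenario <- match.arg(scenario)
  engine <- match.arg(engine)
  low <- grepl("low", scenario)
  rev <- grepl("rev$", scenario) && !grepl("irrev", scenario)
  n0 <- n0 %||% if (low) 5 else 5000
  kd <- if (rev) 10 else 0
  model <- build_ab_model(n0 = n0, k_d_micro = kd)
  rho <- 0.005; D <- 0.0025
  if (engine == "particle") {
    traj <- simulate_particles(model, L, dt = dt_benchmark(rho, 2 * D),
                               t_end = t_end,
                               record_interval = record_interval,
                               seed = seed, replicates = replicates)
  } else {
    h <- h %||% (5 * rho)
    traj <- simulate_rdme(model, L, h, mode = mode, t_end = t_end,
                          record_interval = record_interval,
                          seed = seed, replicates = replicates)
  }
  st <- ensemble_stats(traj)
  list(times = st$times, mean = st$mean[, "A"], sd = st$sd[, "A"],
       n = st$n, meta = traj$meta)
}
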