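## Mesoscopic bimolecular rate constants for 2D RDME simulations.
##
## Microscopic picture: two molecules with summed diffusion coefficient D react
## at contact radius rho with intrinsic rate k_micro (Smoluchowski) or, in the
## lambda-rho picture used by the particle engine, with probability rate
## lambda = k_micro/(pi rho^2) whenever within rho. The scale-dependent rate
## k_h makes the RDME two-molecule mean association time match the microscopic
## one; the concentration-dependent rate k_c additionally accounts for the
## shortened mean free path at high local occupancy.

## constant from the pseudo-Green's function of the discrete 2D Laplacian on a
## square; appears in the mesoscopic mean association time
.C_MESO <- 0.1951

#' Geometric factor F(nu) of the microscopic mean association time
#'
#' `F(nu) = ln(1/nu)/(1-nu^2)^2 - (3-nu^2)/(4(1-nu^2))` with `nu = rho/R`, the
#' ratio of reactive radius to domain radius. Arises from the mean first
#' passage time to an absorbing disk at the center of a reflecting circular
#' domain. For small nu, `F(nu) ~ ln(1/nu) - 3/4`.
#'
#' @param nu dimensionless ratio in (0, 1); vectorized.
#' @return F(nu), dimensionless.
#' @export
F_nu <- function(nu) {
  if (any(!is.finite(nu)) || any(nu <= 0) || any(nu >= 1))
    stop("nu must lie strictly inside (0, 1)")
  log(1 / nu) / (1 - nu^2)^2 - (3 - nu^2) / (4 * (1 - nu^2))
}

#' Microscopic parameter bundle for one bimolecular reaction
#'
#' @param k_micro microscopic rate constant, um^2/s (> 0).
#' @param rho reactive radius, um (> 0).
#' @param D_tot sum of the two reactants' diffusion coefficients, um^2/s (> 0).
#' @param k_micro_d microscopic dissociation rate, 1/s (reversible reactions
#'   only).
#' @return a `micro_params` list; `alpha = k_micro / (2 pi D_tot)` is the
#'   dimensionless degree of diffusion control.
#' @export
micro_params <- function(k_micro, rho, D_tot, k_micro_d = NULL) {
  stopifnot(k_micro > 0, rho > 0, D_tot > 0)
  if (!is.null(k_micro_d)) stopifnot(k_micro_d > 0)
  structure(list(k_micro = k_micro, rho = rho, D_tot = D_tot,
                 k_micro_d = k_micro_d,
                 alpha = k_micro / (2 * pi * D_tot)),
            class = "micro_params")
}

#' Microscopic mean association time on a circular domain
#'
#' Mean time for two molecules (relative diffusion D_tot) to react on a disk of
#' radius R with reflecting boundary, one molecule held at the center:
#' `tau_micro = (pi R^2 / k_micro) (1 + alpha F(rho/R))`.
#'
#' @param R domain radius, um (> rho).
#' @param micro a [micro_params()] object.
#' @param asymptotic use the small-nu asymptotic `F(nu) = ln(1/nu) - 3/4`
#'   (the form under which the scale-dependent rate [k_h()] makes the
#'   mesoscopic time exactly equal to the microscopic one).
#' @return mean association time, s.
#' @export
tau_micro <- function(R, micro, asymptotic = FALSE) {
  if (any(R <= micro$rho)) stop("domain radius R must exceed rho")
  nu <- micro$rho / R
  Fv <- if (asymptotic) log(1 / nu) - 3 / 4 else F_nu(nu)
  (pi * R^2 / micro$k_micro) * (1 + micro$alpha * Fv)
}

#' Mesoscopic mean association time on a periodic square grid
#'
#' Mean association time of two molecules on an L x L domain discretized with
#' grid spacing h, reacting with mesoscopic rate k_meso:
#' `tau_meso = L^2/(2 pi D) log(L/h) + 0.1951 L^2/(4 D) + L^2/k_meso`.
#'
#' @param L domain side, um.
#' @param h grid spacing, um (0 < h <= L).
#' @param D_tot summed diffusion coefficient, um^2/s.
#' @param k_meso mesoscopic rate constant, um^2/s (> 0).
#' @return mean association time, s.
#' @export
tau_meso <- function(L, h, D_tot, k_meso) {
  if (any(h > L)) stop("grid spacing h cannot exceed the domain side L")
  stopifnot(h > 0, D_tot > 0, k_meso > 0)
  L^2 / (2 * pi * D_tot) * log(L / h) + .C_MESO * L^2 / (4 * D_tot) +
    L^2 / k_meso
}

#' Scale-dependent mesoscopic rate constant k_h
#'
#' The mesoscopic rate for which the RDME two-molecule mean association time
#' equals the microscopic one: `k_h = k_micro / (1 + (k_micro/D) G)` with
#' `G = log(h/(sqrt(pi) rho))/(2 pi) - (3/(2 pi) + 0.1951)/4`. Near the lower
#' grid bound [h_min()] the denominator approaches 0+ and k_h grows without
#' bound (it exceeds k_micro whenever G < 0); below the bound no k_h exists.
#'
#' @param h grid spacing, um.
#' @param micro a [micro_params()] object.
#' @return k_h, um^2/s.
#' @export
k_h <- function(h, micro) {
  G <- log(h / (sqrt(pi) * micro$rho)) / (2 * pi) -
    (3 / (2 * pi) + .C_MESO) / 4
  denom <- 1 + (micro$k_micro / micro$D_tot) * G
  if (any(denom <= 0)) {
    hm <- h_min(micro)
    stop(sprintf(paste0("grid too fine for k_h: h = %g um violates the lower ",
                        "bound h_min = %g um (= %.3f rho); no k_h reproduces ",
                        "the microscopic association time below this spacing"),
                 h[which(denom <= 0)[1]], hm, hm / micro$rho))
  }
  micro$k_micro / denom
}

#' Lower bound on the grid spacing for k_h
#'
#' `h_min = sqrt(pi) exp((3 + 2 * 0.1951 * pi)/4 - 2 pi D / k_micro) rho`.
#' For strongly diffusion-controlled reactions the bound saturates at
#' `sqrt(pi) e^{1.0565} rho ~ 5.1 rho`.
#'
#' @param micro a [micro_params()] object.
#' @return h_min, um.
#' @export
h_min <- function(micro) {
  sqrt(pi) * exp((3 + 2 * .C_MESO * pi) / 4 -
                   2 * pi * micro$D_tot / micro$k_micro) * micro$rho
}

#' Mesoscopic dissociation rate paired with k_h
#'
#' Matching mesoscopic and microscopic equilibrium occupancies of a reversible
#' pair gives `k_h^d = k_micro_d * k_h / k_micro`.
#'
#' @param k_micro_d microscopic dissociation rate, 1/s.
#' @param k_h_val mesoscopic association rate, um^2/s.
#' @param k_micro microscopic association rate, um^2/s.
#' @return k_h^d, 1/s.
#' @export
k_h_d <- function(k_micro_d, k_h_val, k_micro) {
  stopifnot(k_micro_d >= 0, k_h_val > 0, k_micro > 0)
  k_micro_d * k_h_val / k_micro
}

#' Concentration-dependent mesoscopic rate constant k_c
#'
#' Within a voxel of side h holding n = max(n_A, n_B) molecules of the more
#' abundant reactant, the mean free area per molecule is `A_c = h^2 / n`, and
#' k_c is the rate for which a molecule pair confined to a disk of equal area
#' (radius `R_c = h / sqrt(pi n)`) reproduces the microscopic mean association
#' time: `k_c = k_micro / (1 + alpha F(rho/R_c))`. In crowded voxels where
#' `R_c <= rho`, k_c is capped at k_micro. Always `0 < k_c <= k_micro`, and
#' k_c is non-decreasing in n.
#'
#' @param n occupancy of the more abundant reactant (integer >= 1; vectorized).
#' @param h grid spacing, um; must exceed rho for a physically meaningful
#'   discretization.
#' @param micro a [micro_params()] object.
#' @return k_c(n), um^2/s.
#' @export
k_c <- function(n, h, micro) {
  if (h <= micro$rho)
    stop("invalid grid: h must exceed the reactive radius rho")
  if (any(n < 1) || any(n != round(n))) stop("occupancy n must be integer >= 1")
  R_c <- h / sqrt(pi * n)
  out <- numeric(length(n))
  crowded <- R_c <= micro$rho
  out[crowded] <- micro$k_micro
  if (any(!crowded))
    out[!crowded] <- micro$k_micro /
      (1 + micro$alpha * F_nu(micro$rho / R_c[!crowded]))
  out
}

#' Mesoscopic dissociation rate paired with k_c
#'
#' `k_c^d(n) = k_micro_d * k_c(n) / k_micro`, the equilibrium-matching
#' dissociation rate for a pair diffusing on the mean free area A_c.
#'
#' @inheritParams k_h_d
#' @param k_c_val mesoscopic association rate(s) k_c(n), um^2/s.
#' @return k_c^d, 1/s (vectorized like `k_c_val`).
#' @export
k_c_d <- function(k_micro_d, k_c_val, k_micro) {
  stopifnot(k_micro_d >= 0, all(k_c_val > 0), k_micro > 0)
  k_micro_d * k_c_val / k_micro
}

#' Mesoscopic rate table for a model on a given grid
#'
#' Precomputes, for every bimolecular reaction of a model, the mesoscopic
#' association rate (scalar k_h, occupancy-indexed k_c lookup, or the naive
#' k_micro) and the matching dissociation scaling for linked first-order
#' reactions. The k_c lookup runs over n = 1 .. n_cap where n_cap is the first
#' occupancy at which the crowding cap k_c = k_micro applies.
#'
#' @param model an `rd_model`.
#' @param h grid spacing, um.
#' @param mode `"naive"`, `"kh"` or `"kc"`.
#' @return data.frame (one row per bimolecular reaction) with list-column
#'   `kc_table`; also usable as a diagnostic of the discretization.
#' @export
meso_rate_table <- function(model, h, mode = c("kc", "kh", "naive")) {
  mode <- match.arg(mode)
  Dmap <- setNames(vapply(model$species, `[[`, 0, "D"),
                   vapply(model$species, `[[`, "", "name"))
  bis <- Filter(function(r) r$type == "bi", model$reactions)
  rows <- lapply(bis, function(r) {
    if (r$k_micro == 0) {
      return(data.frame(name = r$name %||% "", k_micro = 0, rho = r$rho,
                        D_tot = Dmap[[r$ra]] + Dmap[[r$rb]], k_meso = 0,
                        ratio = 1, n_cap = 1L, stringsAsFactors = FALSE))
    }
    mp <- micro_params(r$k_micro, r$rho, Dmap[[r$ra]] + Dmap[[r$rb]])
    km <- switch(mode,
                 naive = r$k_micro,
                 kh = k_h(h, mp),
                 kc = NA_real_)
    n_cap <- if (mode == "kc") as.integer(ceiling(h^2 / (pi * r$rho^2))) else 1L
    data.frame(name = r$name %||% "", k_micro = r$k_micro, rho = r$rho,
               D_tot = mp$D_tot, k_meso = km,
               ratio = if (mode == "kc") NA_real_ else km / r$k_micro,
               n_cap = n_cap, stringsAsFactors = FALSE)
  })
  if (!length(rows)) {
    tab <- data.frame(name = character(), k_micro = numeric(),
                      rho = numeric(), D_tot = numeric(), k_meso = numeric(),
                      ratio = numeric(), n_cap = integer())
    tab$kc_table <- list()
    attr(tab, "mode") <- mode
    attr(tab, "h") <- h
    return(tab)
  }
  tab <- do.call(rbind, rows)
  tab$kc_table <- lapply(seq_along(bis), function(i) {
    r <- bis[[i]]
    if (mode != "kc" || r$k_micro == 0) return(numeric(0))
    mp <- micro_params(r$k_micro, r$rho, tab$D_tot[i])
    k_c(seq_len(tab$n_cap[i]), h, mp)
  })
  attr(tab, "mode") <- mode
  attr(tab, "h") <- h
  tab
}
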