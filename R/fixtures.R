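#' Built-in benchmark and polarity scenario factories
#'
#' Returns the exact model and simulation settings of the named scenario:
#' \describe{
#'   \item{fig2_low_irrev / fig2_low_rev}{A + B -> C (and reversible variant)
#'     with A = B = 5, C = 0 at t = 0, L = 1 um, lambda = 3183.1/s,
#'     rho = 0.005 um, D = 0.0025 um^2/s per species (degree of diffusion
#'     control lambda pi rho^2 / D_tot = 50).}
#'   \item{fig2_high_irrev / fig2_high_rev}{same reactions at high density,
#'     A = B = 5000.}
#'   \item{s1_sweep}{fixed abundances A = B = 2000 with the domain side L as
#'     an argument (0.4-6.4 um).}
#'   \item{polarity_base}{the Cdc42 polarity circuit, reference 2D parameters.}
#'   \item{polarity_updated}{the polarity circuit including the direct
#'     cytosolic Cdc42D recruitment reaction (R7).}
#'   \item{polarity_sweep}{polarity circuit with rate/abundance overrides.}
#' }
#'
#' @param name scenario name.
#' @param L domain side for `s1_sweep`, um.
#' @param k_d_micro microscopic dissociation rate for the reversible
#'   benchmarks, 1/s (10/s is the reference high-density value; 1/s the
#'   low-density reversible variant).
#' @param k_4a,gef_total polarity parameters (see [build_polarity_model()]).
#' @param ... further overrides passed to [build_polarity_model()].
#' @return list with `model` (an `rd_model`) and `config` (engine settings:
#'   `L`, `h`, `dt`, `rho`, recommended `t_end`).
#' @export
make_fixture <- function(name = c("fig2_low_irrev", "fig2_low_rev",
                                  "fig2_high_irrev", "fig2_high_rev",
                                  "s1_sweep", "polarity_base",
                                  "polarity_updated", "polarity_sweep"),
                         L = 1, k_d_micro = NULL, k_4a = 1, gef_total = 700,
                         ...) {
  name <- match.arg(name)
  rho <- if (grepl("^polarity", name)) 0.02 else 0.005
  if (grepl("^fig2|^s1", name)) {
    D <- 0.0025
    n0 <- switch(name, fig2_low_irrev = 5, fig2_low_rev = 5,
                 fig2_high_irrev = 5000, fig2_high_rev = 5000,
                 s1_sweep = 2000)
    rev <- grepl("rev$", name) && !grepl("irrev$", name)
    kd <- k_d_micro %||% (if (rev) 10 else 0)
    Ldom <- if (name == "s1_sweep") L else 1
    model <- build_ab_model(lambda = 3183.1, rho = rho, D = D, n0 = n0,
                            k_d_micro = kd)
    config <- list(L = Ldom, h = 5 * rho, dt = dt_benchmark(rho, 2 * D),
                   rho = rho, t_end = 20)
  } else {
    model <- build_polarity_model(
      k_4a = k_4a, gef_total = gef_total,
      include_reaction_7 = (name == "polarity_updated"), ...)
    config <- list(L = model$geometry$L, h = 5 * rho,
                   dt = dt_polarity(rho, 10), rho = rho, t_end = 300)
  }
  list(model = model, config = config)
}
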