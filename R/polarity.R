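#' Stochastic Cdc42 polarity model of budding yeast
#'
#' Builds the seven-reaction (optionally eight, with direct recruitment of
#' cytosolic Cdc42D by the Cdc42T-GEF complex) positive-feedback circuit of
#' Cdc42 polarity establishment, in the 2D microscopic parameterization:
#' membrane and cytosol are coincident periodic squares distinguished only by
#' the species diffusion coefficients.
#'
#' Species: GEFc, GEFm (the Cdc42 GEF, cytosolic/membrane), Cdc42Dc, Cdc42Dm
#' (inactive GDP-bound Cdc42), Cdc42T (active GTP-bound, membrane) and the
#' membrane complex Cdc42T.GEF that mediates positive feedback.
#'
#' @param k_4a microscopic rate constant (um^2/s) for membrane association of
#'   Cdc42T with GEFm; the admissible range is 0-2 um^2/s and no single default
#'   exists, so it must be supplied. A value of exactly 0 disables complex
#'   formation via this route and triggers a warning because a minimal rate of
#'   Cdc42 activation is required to start polarization.
#' @param gef_total total GEF molecules (15-700 in the reference
#'   parameterization).
#' @param cdc42_total total Cdc42 molecules.
#' @param include_reaction_7 add the direct recruitment reaction
#'   Cdc42T.GEF + Cdc42Dc -> Cdc42T.GEF + Cdc42T (the "updated model").
#' @param tagged `"none"`, `"cdc42"` or `"gef"`: mechanically add tagged shadow
#'   species for the membrane forms carrying that moiety. Tagged species have
#'   identical kinetics, except that detachment to the cytosol converts to the
#'   untagged cytosolic form; used for dwell-time washout measurements.
#' @param rates named list of rate-constant overrides
#'   (`k_1a`, `k_1b`, `k_2a`, `k_2b`, `k_3`, `k_4b`, `k_5a`, `k_5b`, `k_6`,
#'   `k_7`).
#' @param D_cyto,D_memb cytosolic and membrane diffusion coefficients, um^2/s.
#' @param rho reactive radius, um.
#' @param geometry geometry constants, see [rd_geometry()].
#' @return an `rd_model`.
#' @examples
#' m <- build_polarity_model(k_4a = 1)
#' sum(m$init[c("Cdc42Dc", "Cdc42Dm", "Cdc42T", "Cdc42T.GEF")])  # 5000
#' @export
build_polarity_model <- function(k_4a, gef_total = 700, cdc42_total = 5000,
                                 include_reaction_7 = FALSE,
                                 tagged = c("none", "cdc42", "gef"),
                                 rates = list(),
                                 D_cyto = 10, D_memb = 0.0045, rho = 0.02,
                                 geometry = rd_geometry()) {
  tagged <- match.arg(tagged)
  k <- list(k_1a = 0.1, k_1b = 10, k_2a = 0.032, k_2b = 0.63, k_3 = 0.07,
            k_4b = 10, k_5a = 4, k_5b = 6.5, k_6 = 0.2, k_7 = 0.5)
  unknown <- setdiff(names(rates), names(k))
  if (length(unknown)) stop("unknown rate override: ", paste(unknown, collapse = ", "))
  k[names(rates)] <- rates
  if (missing(k_4a)) stop("k_4a has no default (admissible range 0-2 um^2/s); supply it explicitly")
  if (k_4a == 0)
    warning("k_4a = 0: Cdc42T-GEF complex formation at the membrane is disabled")
  if (k$k_2a == 0)
    warning("k_2a = 0: a minimal value is required to start Cdc42 activation")

  species <- list(
    species_spec("GEFc",      "cytosol",  D_cyto, carries = "gef"),
    species_spec("GEFm",      "membrane", D_memb, carries = "gef"),
    species_spec("Cdc42Dc",   "cytosol",  D_cyto, carries = "cdc42"),
    species_spec("Cdc42Dm",   "membrane", D_memb, carries = "cdc42"),
    species_spec("Cdc42T",    "membrane", D_memb, carries = "cdc42"),
    species_spec("Cdc42T.GEF","membrane", D_memb, carries = c("cdc42", "gef"))
  )

  reactions <- list(
    uni_reaction("GEFc", "GEFm", k$k_1a, "cyto_to_mem", name = "R1a"),
    uni_reaction("GEFm", "GEFc", k$k_1b, "mem_to_cyto", name = "R1b"),
    ## GEFm + Cdc42Dm -> GEFm + Cdc42T: catalyst keeps its position/tag,
    ## the converted Cdc42 molecule keeps its own.
    bi_reaction("GEFm", "Cdc42Dm", c("GEFm", "Cdc42T"), k$k_2a, rho,
                "mem_bi", product_src = c(1L, 2L), name = "R2a"),
    uni_reaction("Cdc42T", "Cdc42Dm", k$k_2b, "mem_first_order", name = "R2b"),
    bi_reaction("Cdc42T.GEF", "Cdc42Dm", c("Cdc42T.GEF", "Cdc42T"), k$k_3, rho,
                "mem_bi", product_src = c(1L, 2L), name = "R3"),
    bi_reaction("Cdc42T", "GEFm", "Cdc42T.GEF", k_4a, rho,
                "mem_bi", product_src = 1L, name = "R4a", reverse = "R4b"),
    uni_reaction("Cdc42T.GEF", c("Cdc42T", "GEFm"), k$k_4b, "mem_first_order",
                 name = "R4b", dissociation_of = "R4a"),
    uni_reaction("Cdc42Dc", "Cdc42Dm", k$k_5a, "cyto_to_mem", name = "R5a"),
    uni_reaction("Cdc42Dm", "Cdc42Dc", k$k_5b, "mem_to_cyto", name = "R5b"),
    bi_reaction("Cdc42T", "GEFc", "Cdc42T.GEF", k$k_6, rho,
                "cyto_mem_bi", product_src = 1L, name = "R6")
  )
  if (include_reaction_7)
    reactions <- c(reactions, list(
      bi_reaction("Cdc42T.GEF", "Cdc42Dc", c("Cdc42T.GEF", "Cdc42T"), k$k_7, rho,
                  "cyto_mem_bi", product_src = c(1L, 2L), name = "R7")))

  model <- rd_model(species, reactions, geometry,
                    init = c(GEFc = gef_total, Cdc42Dc = cdc42_total))
  if (tagged != "none") model <- tag_model(model, moiety = tagged)
  model
}

#' Mechanically add tagged shadow species for a moiety
#'
#' Every membrane-bound species carrying the moiety gets a `_tag` shadow with
#' identical diffusion and kinetics. Reactions are rewritten for every
#' tagged/untagged combination of moiety-carrying reactants; each product
#' inherits its tag from the reactant it descends from (`product_src`). Because
#' cytosolic species have no shadows, detachment of a tagged membrane species
#' to the cytosol automatically produces the untagged cytosolic form -- the
#' washout rule used for dwell-time measurements.
#'
#' @param model an `rd_model`.
#' @param moiety moiety name to shadow (must appear in some species' `carries`).
#' @return an `rd_model` with shadow species (initial counts 0) and the
#'   generated reactions appended.
#' @export
tag_model <- function(model, moiety) {
  nm <- vapply(model$species, `[[`, "", "name")
  carriers <- vapply(model$species, function(s)
    moiety %in% s$carries && s$compartment == "membrane", TRUE)
  if (!any(carriers)) stop("no membrane species carries moiety '", moiety, "'")
  shadow_of <- setNames(ifelse(carriers, paste0(nm, "_tag"), NA_character_), nm)

  shadows <- lapply(model$species[carriers], function(s)
    species_spec(paste0(s$name, "_tag"), s$compartment, s$D, carries = s$carries))

  tag_name <- function(base, combo_id) paste0(base, "_tag", combo_id)

  new_reactions <- list()
  for (r in model$reactions) {
    reac <- if (r$type == "uni") r$reactant else c(r$ra, r$rb)
    taggable <- which(!is.na(shadow_of[reac]))
    if (!length(taggable)) next
    combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(taggable)))
    for (ci in seq_len(nrow(combos))) {
      sel <- unlist(combos[ci, ])
      if (!any(sel)) next  # base reaction already present
      treac <- reac
      treac[taggable[sel]] <- shadow_of[treac[taggable[sel]]]
      src <- if (r$type == "uni") rep(1L, length(r$products)) else r$product_src
      tprod <- r$products
      for (p in seq_along(tprod)) {
        from_tagged <- src[p] %in% taggable[sel]
        if (from_tagged && !is.na(shadow_of[tprod[p]]) &&
            moiety %in% model$species[[match(tprod[p], nm)]]$carries)
          tprod[p] <- shadow_of[tprod[p]]
      }
      combo_id <- paste(which(sel), collapse = "")
      lab <- if (is.null(r$name)) NULL else tag_name(r$name, combo_id)
      if (r$type == "uni") {
        new_reactions <- c(new_reactions, list(
          uni_reaction(treac[1], tprod, r$rate, r$class, name = lab,
                       dissociation_of = if (!is.null(r$dissociation_of))
                         tag_name(r$dissociation_of, combo_id) else NULL,
                       product_sep = r$product_sep)))
      } else {
        new_reactions <- c(new_reactions, list(
          bi_reaction(treac[1], treac[2], tprod, r$k_micro, r$rho, r$class,
                      product_src = r$product_src, name = lab,
                      reverse = if (!is.null(r$reverse))
                        tag_name(r$reverse, combo_id) else NULL)))
      }
    }
  }
  ## Drop dangling reverse/dissociation links: a generated tagged reaction may
  ## reference a partner combination that does not exist (e.g. the reverse of a
  ## tagged complex dissociation whose forward partner has a different combo
  ## id). Relink by matching reactant/product species instead.
  all_r <- c(model$reactions, new_reactions)
  labels <- vapply(all_r, function(r) r$name %||% "", "")
  for (i in seq_along(all_r)) {
    r <- all_r[[i]]
    if (r$type == "uni" && !is.null(r$dissociation_of) &&
        !(r$dissociation_of %in% labels)) {
      ## find a bi reaction whose single product is this reactant
      j <- which(vapply(all_r, function(q) q$type == "bi" &&
                          length(q$products) == 1L &&
                          q$products == r$reactant, TRUE))
      all_r[[i]]$dissociation_of <- if (length(j)) labels[j[1]] else NULL
    }
    if (r$type == "bi" && !is.null(r$reverse) && !(r$reverse %in% labels)) {
      j <- which(vapply(all_r, function(q) q$type == "uni" &&
                          length(q$products) == 2L &&
                          q$reactant %in% r$products, TRUE))
      all_r[[i]]$reverse <- if (length(j)) labels[j[1]] else NULL
    }
  }
  rd_model(c(model$species, shadows), all_r, model$geometry,
           init = model$init[model$init > 0])
}

#' Irreversible / reversible association benchmark model
#'
#' The prototypical diffusion-controlled reaction A + B -> C (optionally
#' reversible) on a periodic square membrane, parameterized by the lambda-rho
#' probability rate.
#'
#' @param lambda probability rate of reaction within rho, 1/s.
#' @param rho reactive radius, um.
#' @param D diffusion coefficient of each species, um^2/s (D_tot = 2 D).
#' @param n0 initial copy number of A and of B.
#' @param k_d_micro microscopic dissociation rate of C, 1/s; 0 for the
#'   irreversible reaction.
#' @return an `rd_model` with species A, B, C.
#' @export
build_ab_model <- function(lambda = 3183.1, rho = 0.005, D = 0.0025, n0 = 5,
                           k_d_micro = 0) {
  k_micro <- kmicro_from_lambda_2d(lambda, rho)
  species <- list(species_spec("A", "membrane", D, carries = "a"),
                  species_spec("B", "membrane", D, carries = "b"),
                  species_spec("C", "membrane", D, carries = c("a", "b")))
  fwd <- bi_reaction("A", "B", "C", k_micro, rho, "mem_bi", product_src = 1L,
                     name = "assoc",
                     reverse = if (k_d_micro > 0) "dissoc" else NULL)
  reactions <- list(fwd)
  if (k_d_micro > 0)
    reactions <- c(reactions, list(
      uni_reaction("C", c("A", "B"), k_d_micro, "mem_first_order",
                   name = "dissoc", dissociation_of = "assoc")))
  rd_model(species, reactions, init = c(A = n0, B = n0))
}
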