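#' @useDynLib mesosim, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rnorm runif sd setNames coef lm nls predict var
NULL

## Reaction class tags. Explicit per-reaction enum rather than inferred from
## product compartments (R-2a has a membrane product but is membrane-only).
REACTION_CLASSES <- c(
  "cyto_to_mem",     # first-order, cytosol -> membrane (R-1a, R-5a)
  "mem_to_cyto",     # first-order, membrane -> cytosol (R-1b, R-5b)
  "mem_first_order", # first-order, membrane-only (R-2b, R-4b)
  "mem_bi",          # second-order, both reactants at the membrane (R-2a, R-3, R-4a)
  "cyto_mem_bi"      # second-order, cytosolic species binds membrane species (R-6, R-7)
)

#' Define a molecular species
#'
#' @param name species identifier (unique within a model).
#' @param compartment `"membrane"` or `"cytosol"`. In the 2D representation the
#'   two compartments are coincident square domains; the compartment only
#'   determines which diffusion coefficient applies and how rates are converted
#'   between parameterizations.
#' @param D diffusion coefficient in um^2/s (> 0).
#' @param carries character vector of conserved moieties this species contains
#'   (e.g. `"cdc42"`, `"gef"`); used for conservation bookkeeping and for the
#'   mechanical construction of tagged shadow species.
#' @return a `species_spec` list.
#' @export
species_spec <- function(name, compartment = c("membrane", "cytosol"), D,
                         carries = character()) {
  compartment <- match.arg(compartment)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!is.numeric(D) || length(D) != 1L || !is.finite(D) || D < 0)
    stop("diffusion coefficient must be a finite non-negative number (um^2/s)")
  structure(list(name = name, compartment = compartment, D = D,
                 carries = carries),
            class = "species_spec")
}

#' Define a first-order reaction
#'
#' @param reactant species name.
#' @param products character vector of 0-2 product species names.
#' @param rate rate constant in 1/s (>= 0).
#' @param class reaction class tag, one of
#'   `"cyto_to_mem"`, `"mem_to_cyto"`, `"mem_first_order"`.
#' @param name optional reaction label.
#' @param dissociation_of label of the bimolecular reaction this reaction is the
#'   microscopic dissociation counterpart of (reversible pairs only). When set,
#'   the mesoscopic engines scale this rate by k_meso/k_micro of the forward
#'   reaction so that mesoscopic and microscopic equilibria agree.
#' @param product_sep for two-product dissociations in the particle engine, the
#'   separation distance placed between the products (defaults to rho + epsilon
#'   of the forward reaction when linked, otherwise must be supplied if the
#'   reaction has two products).
#' @return a `uni_reaction` list.
#' @export
uni_reaction <- function(reactant, products, rate,
                         class = c("mem_first_order", "cyto_to_mem", "mem_to_cyto"),
                         name = NULL, dissociation_of = NULL, product_sep = NULL) {
  class <- match.arg(class)
  if (!is.numeric(rate) || length(rate) != 1L || !is.finite(rate) || rate < 0)
    stop("rate constant must be finite and >= 0 (1/s)")
  if (length(products) > 2L) stop("at most two products are supported")
  structure(list(type = "uni", name = name, reactant = reactant,
                 products = as.character(products), rate = rate, class = class,
                 dissociation_of = dissociation_of, product_sep = product_sep),
            class = "rd_reaction")
}

#' Define a bimolecular reaction
#'
#' Microscopic parameterization follows the lambda-rho (Doi) picture: the two
#' reactants react with probability rate lambda whenever closer than the
#' reactive radius rho. The equivalent Smoluchowski-style microscopic rate
#' constant is `k_micro = lambda * pi * rho^2` in 2D.
#'
#' @param ra,rb reactant species names (distinct species).
#' @param products character vector of 1-2 product species names.
#' @param k_micro microscopic rate constant, um^2/s in the 2D parameterization.
#' @param rho reactive radius in um (> 0).
#' @param class `"mem_bi"` or `"cyto_mem_bi"`.
#' @param product_src integer vector (values 1 or 2), same length as
#'   `products`: which reactant each product inherits its position (particle
#'   engine) and its tagged-moiety status from. Catalytic conversions keep the
#'   catalyst and the converted molecule in place; association complexes are
#'   placed at the first-listed reactant.
#' @param name optional reaction label.
#' @param reverse label of the first-order reaction that reverses this one
#'   (dissociation), or NULL for irreversible reactions.
#' @return an `rd_reaction` list.
#' @export
bi_reaction <- function(ra, rb, products, k_micro, rho,
                        class = c("mem_bi", "cyto_mem_bi"),
                        product_src = seq_along(products), name = NULL,
                        reverse = NULL) {
  class <- match.arg(class)
  if (identical(ra, rb)) stop("same-species (A+A) reactions are not supported")
  if (!is.numeric(k_micro) || k_micro < 0 || !is.finite(k_micro))
    stop("k_micro must be finite and >= 0")
  if (!is.numeric(rho) || rho <= 0) stop("reactive radius rho must be > 0")
  if (length(products) < 1L || length(products) > 2L)
    stop("bimolecular reactions must have one or two products")
  if (length(product_src) != length(products) || !all(product_src %in% 1:2))
    stop("product_src must map each product to reactant 1 or 2")
  structure(list(type = "bi", name = name, ra = ra, rb = rb,
                 products = as.character(products),
                 k_micro = k_micro, rho = rho, class = class,
                 product_src = as.integer(product_src), reverse = reverse),
            class = "rd_reaction")
}

#' Geometry constants for the polarity system
#'
#' @param A_m membrane surface area, um^2. The 2D computational domain is the
#'   square with side `L = sqrt(A_m)`.
#' @param dz membrane thickness, um.
#' @param V_c cytosol volume, um^3.
#' @return list with `A_m`, `L`, `dz`, `V_c`, `V_m = A_m * dz` and
#'   `eta = V_m / V_c`.
#' @export
rd_geometry <- function(A_m = 64, dz = 0.0083, V_c = 48.144) {
  stopifnot(A_m > 0, dz > 0, V_c > 0)
  V_m <- A_m * dz
  list(A_m = A_m, L = sqrt(A_m), dz = dz, V_c = V_c, V_m = V_m,
       eta = V_m / V_c)
}

#' Assemble a reaction-diffusion model
#'
#' @param species list of [species_spec()] objects.
#' @param reactions list of reactions ([uni_reaction()] / [bi_reaction()]).
#' @param geometry output of [rd_geometry()] (or NULL for benchmark models that
#'   do not use the membrane/cytosol geometry).
#' @param init named integer vector of initial molecule counts per species
#'   (missing species start at 0). Initial placement is uniformly random over
#'   the domain unless an explicit state is supplied to the engines.
#' @return an object of class `rd_model`.
#' @export
rd_model <- function(species, reactions, geometry = NULL, init = integer()) {
  nm <- vapply(species, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("species names must be unique")
  refs <- unlist(lapply(reactions, function(r) {
    if (r$type == "uni") c(r$reactant, r$products) else c(r$ra, r$rb, r$products)
  }))
  bad <- setdiff(refs, nm)
  if (length(bad))
    stop("reactions reference undeclared species: ", paste(bad, collapse = ", "))
  if (length(init)) {
    if (is.null(names(init)) || !all(names(init) %in% nm))
      stop("init must be a named vector over declared species")
    if (any(init < 0) || any(init != round(init)))
      stop("initial counts must be non-negative integers")
  }
  counts <- setNames(integer(length(nm)), nm)
  counts[names(init)] <- as.integer(init)
  ## resolve reverse/dissociation links by label
  labels <- vapply(reactions, function(r) r$name %||% "", "")
  for (i in seq_along(reactions)) {
    r <- reactions[[i]]
    if (r$type == "uni" && !is.null(r$dissociation_of)) {
      j <- match(r$dissociation_of, labels)
      if (is.na(j) || reactions[[j]]$type != "bi")
        stop("dissociation_of must name a bimolecular reaction in the model")
    }
    if (r$type == "bi" && !is.null(r$reverse)) {
      j <- match(r$reverse, labels)
      if (is.na(j) || reactions[[j]]$type != "uni")
        stop("reverse must name a first-order reaction in the model")
    }
  }
  structure(list(species = species, reactions = reactions,
                 geometry = geometry, init = counts),
            class = "rd_model")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rd_model <- function(x, ...) {
  cat("Reaction-diffusion model:", length(x$species), "species,",
      length(x$reactions), "reactions\n")
  for (s in x$species)
    cat(sprintf("  %-16s %-9s D = %g um^2/s  n0 = %d\n", s$name,
                s$compartment, s$D, x$init[[s$name]]))
  for (r in x$reactions) {
    if (r$type == "uni")
      cat(sprintf("  [%s] %s -> %s  (k = %g /s, %s)\n", r$name %||% "-",
                  r$reactant, paste(r$products, collapse = " + "),
                  r$rate, r$class))
    else
      cat(sprintf("  [%s] %s + %s -> %s  (k_micro = %g, rho = %g um, %s)\n",
                  r$name %||% "-", r$ra, r$rb,
                  paste(r$products, collapse = " + "), r$k_micro, r$rho,
                  r$class))
  }
  invisible(x)
}

## ---- microscopic rate conversions -------------------------------------------

#' Convert between lambda and k_micro (2D membrane reactions)
#'
#' In 2D the probability rate lambda of the lambda-rho model and the
#' microscopic rate constant are related by `k_micro = lambda * pi * rho^2`,
#' i.e. the concentration of one molecule within the reactive disk is
#' `1 / (pi rho^2)`.
#'
#' @param k_micro microscopic rate constant, um^2/s.
#' @param lambda probability rate, 1/s.
#' @param rho reactive radius, um.
#' @return the converted rate.
#' @examples
#' lambda_from_kmicro_2d(0.25, 0.005)  # ~3183.1 /s
#' @export
lambda_from_kmicro_2d <- function(k_micro, rho) {
  if (any(rho <= 0)) stop("rho must be > 0")
  if (any(k_micro < 0)) stop("k_micro must be >= 0")
  k_micro / (pi * rho^2)
}

#' @rdname lambda_from_kmicro_2d
#' @export
kmicro_from_lambda_2d <- function(lambda, rho) {
  if (any(rho <= 0)) stop("rho must be > 0")
  lambda * pi * rho^2
}

#' Convert between lambda and k_micro for cytosol-to-membrane binding in 3D
#'
#' For a cytosolic molecule reacting with a membrane-bound one, the reactive
#' volume is the half sphere of radius rho above the membrane, so the
#' single-molecule concentration is `3 / (2 pi rho^3)` and
#' `lambda = 3 k_micro / (2 pi rho^3)`.
#'
#' @inheritParams lambda_from_kmicro_2d
#' @param k_micro microscopic rate constant, um^3/s.
#' @export
lambda_from_kmicro_3d_halfsphere <- function(k_micro, rho) {
  if (any(rho <= 0)) stop("rho must be > 0")
  if (any(k_micro < 0)) stop("k_micro must be >= 0")
  3 * k_micro / (2 * pi * rho^3)
}

#' @rdname lambda_from_kmicro_3d_halfsphere
#' @export
kmicro_from_lambda_3d_halfsphere <- function(lambda, rho) {
  if (any(rho <= 0)) stop("rho must be > 0")
  lambda * 2 * pi * rho^3 / 3
}

## ---- macroscopic <-> 2D <-> 3D scalings -------------------------------------

#' Scale macroscopic (3D volumetric) rate constants to the 2D representation
#'
#' The 2D model represents membrane and cytosol as coincident squares. Rates
#' from a volumetric macroscopic model are rescaled per reaction class:
#' cytosol-to-membrane first-order rates by eta = V_m/V_c; membrane bimolecular
#' rates by 1/dz; cytosol+membrane bimolecular rates by A_m/V_c;
#' membrane-only and membrane-to-cytosol first-order rates are unchanged (for
#' the latter the 1/eta scaling cancels against the eta factor carried by the
#' volumetric rate equations).
#'
#' @param rates data.frame with columns `value` and `class` (reaction class
#'   tags; see [uni_reaction()], [bi_reaction()]).
#' @param geometry output of [rd_geometry()].
#' @return the data.frame with a `value_2d` column appended.
#' @export
scale_macroscopic_to_2d <- function(rates, geometry) {
  if (!all(c("value", "class") %in% names(rates)))
    stop("rates must have columns 'value' and 'class'")
  if (!all(rates$class %in% REACTION_CLASSES))
    stop("untagged or unknown reaction class: ",
         paste(setdiff(rates$class, REACTION_CLASSES), collapse = ", "))
  fac <- c(cyto_to_mem = geometry$eta,
           mem_to_cyto = 1,
           mem_first_order = 1,
           mem_bi = 1 / geometry$dz,
           cyto_mem_bi = geometry$A_m / geometry$V_c)
  rates$value_2d <- rates$value * unname(fac[rates$class])
  rates
}

#' Convert 2D model rate constants to the 3D (spherical-cell) parameter set
#'
#' Reactions confined to the membrane keep their 2D rate constants. Reactions
#' in which a cytosolic species binds the membrane or a membrane-bound molecule
#' are multiplied by V_c/A_m, promoting their units by one length power
#' (1/s -> um/s, um^2/s -> um^3/s).
#'
#' @param model an `rd_model` (2D parameterization) or a data.frame with
#'   columns `name`, `value` and `class`.
#' @param geometry output of [rd_geometry()]; defaults to the model's geometry.
#' @return data.frame with columns `name`, `value_2d`, `value_3d`, `scaled`.
#' @export
convert_2d_to_3d <- function(model, geometry = NULL) {
  if (inherits(model, "rd_model")) {
    geometry <- geometry %||% model$geometry
    tab <- do.call(rbind, lapply(model$reactions, function(r) {
      data.frame(name = r$name %||% NA_character_,
                 value = if (r$type == "uni") r$rate else r$k_micro,
                 class = r$class, stringsAsFactors = FALSE)
    }))
  } else {
    tab <- model
    if (!all(c("name", "value", "class") %in% names(tab)))
      stop("need columns name, value, class")
  }
  if (is.null(geometry)) stop("geometry constants are required")
  scaled <- tab$class %in% c("cyto_to_mem", "cyto_mem_bi")
  data.frame(name = tab$name, value_2d = tab$value,
             value_3d = tab$value * ifelse(scaled, geometry$V_c / geometry$A_m, 1),
             scaled = scaled, stringsAsFactors = FALSE)
}

## ---- stoichiometry ----------------------------------------------------------

#' Stoichiometry matrix of a model
#'
#' @param model an `rd_model`.
#' @return integer matrix, species x reactions; entry (s, j) is the net change
#'   of species s when reaction j fires.
#' @export
stoichiometry_matrix <- function(model) {
  nm <- vapply(model$species, `[[`, "", "name")
  S <- matrix(0L, length(nm), length(model$reactions),
              dimnames = list(nm, vapply(model$reactions,
                                         function(r) r$name %||% "", "")))
  for (j in seq_along(model$reactions)) {
    r <- model$reactions[[j]]
    reac <- if (r$type == "uni") r$reactant else c(r$ra, r$rb)
    for (s in reac) S[s, j] <- S[s, j] - 1L
    for (s in r$products) S[s, j] <- S[s, j] + 1L
  }
  S
}

#' Conservation vectors for tagged moieties
#'
#' For each moiety (e.g. "cdc42", "gef") returns the 0/1 vector over species
#' counting how many copies of the moiety each species carries. For a closed
#' model these vectors annihilate the stoichiometry matrix.
#'
#' @param model an `rd_model`.
#' @return named list of numeric vectors over species.
#' @export
conservation_vectors <- function(model) {
  nm <- vapply(model$species, `[[`, "", "name")
  moieties <- unique(unlist(lapply(model$species, `[[`, "carries")))
  out <- lapply(moieties, function(m)
    setNames(vapply(model$species, function(s) as.numeric(m %in% s$carries), 0), nm))
  setNames(out, moieties)
}
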