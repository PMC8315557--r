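## Structured-text configuration: INI-style sections with key = value lines;
## reactions use a compact arrow syntax. Example:
##
##   [species]
##   A = membrane, D=0.0025
##   B = membrane, D=0.0025
##   C = membrane, D=0.0025
##   [reactions]
##   assoc:  A + B -> C : k_micro=0.25, rho=0.005, class=mem_bi, reverse=dissoc
##   dissoc: C -> A + B : k=10, class=mem_first_order, dissociation_of=assoc
##   [geometry]
##   A_m = 64
##   dz = 0.0083
##   V_c = 48.144
##   [initial]
##   A = 5
##   B = 5
##   [grid]
##   L = 1
##   h = 0.025
##   mode = kc
##   t_end = 20
##   record = 1
##   seed = 1

.parse_sections <- function(lines) {
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  sec <- NULL
  out <- list()
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      sec <- gsub("^\\[|\\]$", "", ln)
      out[[sec]] <- character()
    } else {
      if (is.null(sec)) stop("config line outside any [section]: ", ln)
      out[[sec]] <- c(out[[sec]], ln)
    }
  }
  out
}

.parse_kv <- function(lines) {
  kv <- list()
  for (ln in lines) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("expected 'key = value': ", ln)
    key <- trimws(m[2]); val <- trimws(m[3])
    num <- suppressWarnings(as.numeric(val))
    kv[[key]] <- if (is.na(num)) val else num
  }
  kv
}

.parse_opts <- function(txt) {
  if (!nzchar(trimws(txt))) return(list())
  .parse_kv(trimws(strsplit(txt, ",")[[1]]))
}

.parse_reaction <- function(ln) {
  m <- regmatches(ln, regexec("^(?:([A-Za-z0-9_.]+)\\s*:)?\\s*(.+?)->(.+?):(.*)$",
                              ln))[[1]]
  if (length(m) != 5) stop("malformed reaction line: ", ln)
  label <- if (nzchar(m[2])) m[2] else NULL
  lhs <- trimws(strsplit(m[3], "+", fixed = TRUE)[[1]])
  rhs <- trimws(strsplit(m[4], "+", fixed = TRUE)[[1]])
  rhs <- rhs[nzchar(rhs)]
  opts <- .parse_opts(m[5])
  if (length(lhs) == 1) {
    if (is.null(opts$k)) stop("first-order reaction needs k=: ", ln)
    if (is.null(opts$class)) stop("reaction needs class=: ", ln)
    uni_reaction(lhs, rhs, opts$k, opts$class, name = label,
                 dissociation_of = opts$dissociation_of,
                 product_sep = opts$product_sep)
  } else if (length(lhs) == 2) {
    if (is.null(opts$k_micro) || is.null(opts$rho) || is.null(opts$class))
      stop("bimolecular reaction needs k_micro=, rho=, class=: ", ln)
    src <- if (is.null(opts$product_src)) seq_along(rhs)
    else as.integer(strsplit(as.character(opts$product_src), "")[[1]])
    bi_reaction(lhs[1], lhs[2], rhs, opts$k_micro, opts$rho, opts$class,
                product_src = src, name = label, reverse = opts$reverse)
  } else stop("at most two reactants are supported: ", ln)
}

#' Load a model + simulation configuration from a structured text file
#'
#' Sections: `[species]` (name = compartment, D=...), `[reactions]`
#' (`label: A + B -> C : k_micro=..., rho=..., class=...`), optional
#' `[geometry]`, `[initial]`, and `[grid]` / `[particles]` engine settings.
#' Unknown keys and schema violations are rejected with the offending key
#' path.
#'
#' @param path file path.
#' @return list with `model` (an `rd_model`) and `config` (validated engine
#'   settings with defaults filled).
#' @export
load_config <- function(path) {
  secs <- .parse_sections(readLines(path, warn = FALSE))
  known <- c("species", "reactions", "geometry", "initial", "grid",
             "particles", "batch", "analysis")
  bad <- setdiff(names(secs), known)
  if (length(bad)) stop("unknown config section(s): ", paste(bad, collapse = ", "))
  if (is.null(secs$species)) stop("[species] section is required")

  species <- lapply(secs$species, function(ln) {
    m <- regmatches(ln, regexec("^([^=]+)=(.*)$", ln))[[1]]
    if (length(m) != 3) stop("malformed species line: ", ln)
    parts <- trimws(strsplit(m[3], ",")[[1]])
    opts <- .parse_kv(parts[-1])
    extra <- setdiff(names(opts), c("D", "carries"))
    if (length(extra)) stop("unknown species key(s) in [species] ", trimws(m[2]),
                            ": ", paste(extra, collapse = ", "))
    species_spec(trimws(m[2]), parts[1], opts$D,
                 carries = if (is.null(opts$carries)) character()
                 else strsplit(opts$carries, "\\|")[[1]])
  })
  reactions <- lapply(secs$reactions %||% character(), .parse_reaction)
  geometry <- if (!is.null(secs$geometry)) {
    g <- .parse_kv(secs$geometry)
    do.call(rd_geometry, g)
  } else NULL
  init <- if (!is.null(secs$initial)) {
    kv <- .parse_kv(secs$initial)
    setNames(as.integer(unlist(kv)), names(kv))
  } else integer()
  model <- rd_model(species, reactions, geometry, init)

  config <- list()
  if (!is.null(secs$grid)) {
    kv <- .parse_kv(secs$grid)
    allowed <- c("L", "h", "mode", "t_end", "record", "seed")
    bad <- setdiff(names(kv), allowed)
    if (length(bad)) stop("unknown [grid] key(s): ", paste(bad, collapse = ", "))
    if (is.null(kv$L) || is.null(kv$h)) stop("[grid] requires L and h")
    nx <- kv$L / kv$h
    if (abs(nx - round(nx)) > 1e-9)
      stop("[grid] L/h must be an integer (h must tile the domain)")
    kv$mode <- kv$mode %||% "kc"
    if (!kv$mode %in% c("naive", "kh", "kc"))
      stop("[grid] mode must be naive, kh or kc")
    if (kv$mode == "kh") {
      Dmap <- setNames(vapply(model$species, `[[`, 0, "D"),
                       vapply(model$species, `[[`, "", "name"))
      for (r in Filter(function(r) r$type == "bi" && r$k_micro > 0,
                       model$reactions)) {
        mp <- micro_params(r$k_micro, r$rho, Dmap[[r$ra]] + Dmap[[r$rb]])
        hm <- h_min(mp)
        if (kv$h < hm)
          stop(sprintf("[grid] h = %g um is below h_min = %g um (%.2f rho) for reaction %s",
                       kv$h, hm, hm / r$rho, r$name %||% "?"))
      }
    }
    kv$seed <- kv$seed %||% 1
    kv$record <- kv$record %||% ((kv$t_end %||% 1) / 50)
    config$grid <- kv
  }
  if (!is.null(secs$particles)) {
    kv <- .parse_kv(secs$particles)
    allowed <- c("L", "dt", "t_end", "record", "seed")
    bad <- setdiff(names(kv), allowed)
    if (length(bad)) stop("unknown [particles] key(s): ", paste(bad, collapse = ", "))
    config$particles <- kv
  }
  if (!is.null(secs$batch)) config$batch <- .parse_kv(secs$batch)
  list(model = model, config = config)
}

#' Run a seeded ensemble and aggregate it
#'
#' Runs `n_replicates` independent realizations (seeds derived from
#' `seed_base`), aggregates the per-species totals into ensemble mean and
#' standard deviation tables, and returns a manifest sufficient to re-run the
#' batch bit-for-bit.
#'
#' @param model an `rd_model`.
#' @param engine `"rdme"` or `"particle"`.
#' @param n_replicates ensemble size.
#' @param seed_base integer; replicate r uses stream `seed_base` + r.
#' @param out_dir optional directory: writes `totals_mean.tsv`,
#'   `totals_sd.tsv` and `manifest.txt`.
#' @param mode mesoscopic rate mode for the RDME engine (`"kc"`, `"kh"`,
#'   `"naive"`); an explicit formal so it cannot partially match `model`.
#' @param ... engine arguments (L, h, t_end, ... or L, dt, t_end, ...).
#' @return list with `times`, `mean`, `sd`, `n` and `manifest`.
#' @export
batch_run <- function(model, engine = c("rdme", "particle"), n_replicates,
                      seed_base = 1, out_dir = NULL, mode = "kc", ...) {
  engine <- match.arg(engine)
  t0 <- Sys.time()
  traj <- if (engine == "rdme")
    simulate_rdme(model, mode = mode, ..., seed = seed_base,
                  replicates = n_replicates)
  else
    simulate_particles(model, ..., seed = seed_base, replicates = n_replicates)
  st <- ensemble_stats(traj)
  manifest <- list(
    package_version = as.character(utils::packageVersion("mesosim")),
    engine = engine, n_replicates = n_replicates, seed_base = seed_base,
    config = traj$meta,
    started = format(t0, "%Y-%m-%d %H:%M:%S"),
    finished = format(Sys.time(), "%Y-%m-%d %H:%M:%S"))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    write_totals <- function(m, f) {
      df <- data.frame(time = st$times, m, check.names = FALSE)
      utils::write.table(df, file.path(out_dir, f), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    }
    write_totals(st$mean, "totals_mean.tsv")
    write_totals(st$sd, "totals_sd.tsv")
    writeLines(paste(names(unlist(manifest)), unlist(manifest), sep = " = "),
               file.path(out_dir, "manifest.txt"))
  }
  c(st, list(manifest = manifest))
}
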