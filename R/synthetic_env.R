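# Seeded generators for culture-style and ocean-style forcing scenarios.
# All generators are pure functions of (config, seed): the same inputs
# regenerate the same scenario bit for bit.

#' Factorial culture (chemostat) scenario grid
#'
#' Builds a factorial design over light x dilution (target growth) rate x
#' limitation regime, emulating the structure of laboratory compilations of
#' steady-state cultures. Optional multiplicative lognormal noise on the
#' medium concentrations emulates inter-study scatter (off by default).
#'
#' @param config list with `light` (vector, umol m^-2 s^-1), `growth_rate`
#'   (vector, d^-1), `limitation` (subset of `"N"`, `"P"`, `"replete"`),
#'   `medium` (named list of replete concentrations N/P/Fe, mmol m^-3) and
#'   `noise_sd` (lognormal sigma on concentrations; 0 disables noise).
#' @param seed integer RNG seed for the noise draws.
#' @return data.frame of class `culture_scenarios`, one row per scenario:
#'   `scenario_id`, `I`, `target_mu`, `limitation`, medium concentrations.
#' @export
make_culture_grid <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    light = c(50, 150, 400),
    growth_rate = seq(0.2, 1.1, by = 0.15),
    limitation = c("N", "P"),
    medium = list(N = 25, P = 1.6, Fe = 1e-3),
    noise_sd = 0), config)
  if (length(cfg$light) == 0 || length(cfg$growth_rate) == 0 ||
      length(cfg$limitation) == 0) {
    stop("make_culture_grid: empty design ranges (configuration error)")
  }
  if (!all(cfg$limitation %in% c("N", "P", "replete"))) {
    stop("make_culture_grid: limitation must be N, P or replete")
  }
  grid <- expand.grid(I = cfg$light, target_mu = cfg$growth_rate,
                      limitation = cfg$limitation,
                      stringsAsFactors = FALSE)
  grid$conc_N <- cfg$medium$N
  grid$conc_P <- cfg$medium$P
  grid$conc_Fe <- cfg$medium$Fe
  if (cfg$noise_sd > 0) {
    rng <- .seeded_rng(seed)
    for (col in c("conc_N", "conc_P", "conc_Fe")) {
      grid[[col]] <- grid[[col]] * exp(rng(nrow(grid)) * cfg$noise_sd)
    }
  }
  grid$scenario_id <- seq_len(nrow(grid))
  grid <- grid[, c("scenario_id", "I", "target_mu", "limitation",
                   "conc_N", "conc_P", "conc_Fe")]
  attr(grid, "seed") <- seed
  attr(grid, "config") <- cfg
  class(grid) <- c("culture_scenarios", "data.frame")
  grid
}

# local standard-normal stream that does not disturb the global RNG
.seeded_rng <- function(seed) {
  env <- new.env()
  env$state <- NULL
  function(n) {
    old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
            else suppressWarnings(rm(".Random.seed", envir = globalenv())))
    if (is.null(env$state)) set.seed(seed) else assign(".Random.seed", env$state, globalenv())
    x <- stats::rnorm(n)
    env$state <- get(".Random.seed", globalenv())
    x
  }
}

#' Emulate a steady-state chemostat culture
#'
#' For a designated limiting nutrient, solves for the medium concentration
#' at which the steady-state growth rate equals the target dilution rate
#' (bisection on the monotone concentration-to-growth map), all other
#' nutrients replete. For `"replete"` scenarios the medium is used as is.
#'
#' @param scenario one row of [make_culture_grid()] output (data.frame or
#'   list with `I`, `target_mu`, `limitation`, `conc_N`, `conc_P`,
#'   `conc_Fe`).
#' @param traits a [size_class_traits].
#' @return one-row data.frame: class label, realized `mu`, `I`,
#'   `limitation`, `NC` (N:C), `PC` (P:C), quotas and storage diagnostics.
#' @export
simulate_culture <- function(scenario, traits) {
  sc <- as.list(scenario)
  env_for <- function(conc_lim) {
    conc <- list(N = sc$conc_N, P = sc$conc_P, Fe = sc$conc_Fe)
    if (sc$limitation %in% c("N", "P")) conc[[sc$limitation]] <- conc_lim
    env_point(sc$I, conc$N, conc$P, conc$Fe)
  }
  if (sc$limitation == "replete") {
    ss <- steady_state(env_for(NA), traits)
  } else {
    hi <- if (sc$limitation == "N") sc$conc_N else sc$conc_P
    mu_at <- function(conc) steady_state(env_for(conc), traits)$mu
    mu_hi <- mu_at(hi)
    if (mu_hi < sc$target_mu) {
      # target growth not reachable even replete: report the replete culture
      ss <- steady_state(env_for(hi), traits)
    } else {
      root <- stats::uniroot(function(lc) mu_at(exp(lc)) - sc$target_mu,
                             lower = log(1e-7), upper = log(hi),
                             tol = 1e-10)
      ss <- steady_state(env_for(exp(root$root)), traits)
    }
  }
  data.frame(species = paste0(traits$label, "_analogue"),
             group = traits$label,
             mu = ss$mu, I = sc$I, limitation = sc$limitation,
             NC = ss$state$Q_N, PC = ss$state$Q_P,
             Q_Fe = ss$state$Q_Fe,
             sto_P = ss$storage$P, sto_N = ss$storage$N,
             limiter = ss$limiter)
}

#' Run a culture scenario grid for both size classes
#'
#' @param scenarios output of [make_culture_grid()].
#' @param traits trait list from [read_traits()].
#' @return data.frame with one row per scenario and class (the synthetic
#'   culture observation table used by the paired P-storage diagnostic).
#' @export
run_culture_grid <- function(scenarios, traits) {
  rows <- vector("list", 2L * nrow(scenarios))
  i <- 0L
  for (k in names(traits)) {
    for (r in seq_len(nrow(scenarios))) {
      i <- i + 1L
      row <- simulate_culture(scenarios[r, ], traits[[k]])
      row$scenario_id <- scenarios$scenario_id[r]
      row$target_mu <- scenarios$target_mu[r]
      rows[[i]] <- row
    }
  }
  do.call(rbind, rows)
}

#' Idealized meridional depth-latitude forcing scenario
#'
#' Generates light, nutrient restoring targets and mixing timescales on a
#' latitude x depth grid emulating the canonical zonal-mean regimes:
#' nutrient-rich, lower-light subpolar bands; oligotrophic subtropical gyres
#' with a deep nutricline; an equatorial upwelling band; an optional
#' hemispheric PO4 asymmetry (northern gyre more P-depleted); and an
#' optional Southern-Ocean low-iron (HNLC) band.
#'
#' @param config list; recognized fields (defaults in parentheses):
#'   `lat` (20 latitudes, -60..60), `depth` (10 levels, 5..275 m),
#'   `I0_min`/`I0_amp` (surface light 30 + 220 cos^2 lat),
#'   `k_attenuation` (0.03 m^-1), `N_deep` (25 mmol m^-3),
#'   `NP_supply` (16, deep N:P of the restoring targets),
#'   `Fe_deep` (8e-4 mmol m^-3), `po4_asymmetry` (0.35; 0 disables),
#'   `southern_fe_factor` (0.15; 1 disables), `tau_mix_base` (10 d),
#'   `tau_mix_gyre_extra` (30 d), `remin` (0.1 d^-1).
#' @param seed integer; recorded in the scenario (the default scenario is
#'   deterministic, the seed feeds any optional noise hooks).
#' @return object of class `grid_scenario`: `lat`, `depth`, per-cell forcing
#'   in `cells` (long data.frame), the resolved `config` and `seed`.
#' @export
make_meridional_grid <- function(config = list(), seed = 1L) {
  cfg <- utils::modifyList(list(
    lat = seq(-60, 60, length.out = 20),
    depth = seq(5, 275, by = 30),
    I0_min = 30, I0_amp = 220,
    k_attenuation = 0.03,
    N_deep = 25, NP_supply = 16, Fe_deep = 8e-4,
    po4_asymmetry = 0.35,
    southern_fe_factor = 0.15,
    tau_mix_base = 10, tau_mix_gyre_extra = 30,
    remin = 0.1), config)
  if (is.unsorted(cfg$lat) || is.unsorted(cfg$depth)) {
    stop("make_meridional_grid: lat and depth must be monotone increasing")
  }
  lat <- cfg$lat; depth <- cfg$depth
  grid <- expand.grid(lat = lat, depth = depth)
  rad <- grid$lat * pi / 180
  # subtropical-gyre weight: peaks near |lat| = 27.5, vanishing at the
  # equatorial band and poleward of ~45 degrees
  gyre <- exp(-((abs(grid$lat) - 27.5) / 11)^2)
  eq <- exp(-(grid$lat / 8)^2)
  I0 <- cfg$I0_min + cfg$I0_amp * cos(rad)^2
  grid$I <- light_at_depth(I0, grid$depth, cfg$k_attenuation)
  # nutricline depth: deep under the gyres, shallow at high latitude,
  # intermediate in the equatorial upwelling band
  z_nc <- 30 + 150 * gyre + 20 * eq
  nut_frac <- 1 / (1 + exp(-(grid$depth - z_nc) / 30))
  grid$target_N <- cfg$N_deep * nut_frac
  p_frac <- nut_frac
  if (cfg$po4_asymmetry > 0) {
    north_gyre <- gyre * (grid$lat > 0)
    p_frac <- p_frac * (1 - cfg$po4_asymmetry * north_gyre)
  }
  grid$target_P <- cfg$N_deep / cfg$NP_supply * p_frac
  fe_frac <- 0.2 + 0.8 * nut_frac
  fe_band <- grid$lat < -45
  fe_frac[fe_band] <- fe_frac[fe_band] * cfg$southern_fe_factor
  grid$target_Fe <- cfg$Fe_deep * fe_frac
  grid$tau_mix <- cfg$tau_mix_base + cfg$tau_mix_gyre_extra * gyre
  frc <- unlist(grid[c("I", "target_N", "target_P", "target_Fe", "tau_mix")])
  if (any(!is.finite(frc) | frc < 0)) {
    stop("make_meridional_grid: generated non-finite or negative forcing")
  }
  structure(list(lat = lat, depth = depth, cells = grid, remin = cfg$remin,
                 config = cfg, seed = seed,
                 config_hash = .config_hash(cfg)),
            class = "grid_scenario")
}

.config_hash <- function(cfg) {
  # cheap deterministic fingerprint of the resolved config
  cfg <- cfg[order(names(cfg))]
  s <- paste(deparse(cfg, control = "exact"), collapse = "")
  v <- utf8ToInt(s)
  sum(v * (seq_along(v) %% 97 + 1)) %% 2147483647
}

#' @export
print.grid_scenario <- function(x, ...) {
  cat("<grid_scenario>", length(x$lat), "lats x", length(x$depth),
      "depths; PO4 asymmetry:", x$config$po4_asymmetry,
      "; southern Fe factor:", x$config$southern_fe_factor, "\n")
  invisible(x)
}

#' Oligotrophic-to-eutrophic box forcing gradient
#'
#' A one-dimensional set of restoring boxes spanning oligotrophic (low
#' nutrient targets, high light) to eutrophic (high targets) conditions,
#' used for the ecological-selection check: the small-class biomass
#' fraction should fall monotonically along the gradient.
#'
#' @param n number of boxes.
#' @param N_range range of NO3 restoring targets, mmol m^-3.
#' @param I light (scalar or per box).
#' @param NP_supply N:P of the targets.
#' @param Fe target Fe (replete by default so selection is macronutrient
#'   driven).
#' @param tau_mix restoring timescale, d.
#' @return forcing list directly usable by [run_cells()].
#' @export
make_supply_gradient <- function(n = 16, N_range = c(0.05, 20), I = 200,
                                 NP_supply = 16, Fe = 2e-3, tau_mix = 10) {
  targets_N <- exp(seq(log(N_range[1]), log(N_range[2]), length.out = n))
  list(I = rep_len(I, n),
       restore = list(N = targets_N, P = targets_N / NP_supply,
                      Fe = rep_len(Fe, n)),
       tau_mix = tau_mix, remin = 0.1)
}

#' Read a culture observation table
#'
#' Validates a CSV of steady-state culture observations against the
#' documented schema (`species`, `group`, `mu`, `I`, `limitation`, `NC`,
#' `PC`). Ratio units are auto-detected: columns whose median exceeds 1 are
#' flagged as likely mmol/mol rather than mol/mol -- flagged for review,
#' never silently converted. Rows failing validation are reported in the
#' `problems` attribute, not dropped.
#'
#' @param path CSV file path.
#' @return data.frame of class `culture_table` with attributes `problems`
#'   (data.frame of row, column, reason) and `unit_flags` (character).
#' @export
lab_compilation_reader <- function(path) {
  if (!file.exists(path)) stop("lab_compilation_reader: file not found: ", path)
  mandatory <- c("species", "group", "mu", "I", "limitation", "NC", "PC")
  first <- readLines(path, n = 1L, warn = FALSE)
  if (length(first) == 0L || !nzchar(first)) {
    tab <- data.frame(species = character(), group = character(),
                      mu = numeric(), I = numeric(),
                      limitation = character(), NC = numeric(), PC = numeric())
    attr(tab, "problems") <- data.frame(row = integer(), column = character(),
                                        reason = character())
    attr(tab, "unit_flags") <- character()
    class(tab) <- c("culture_table", "data.frame")
    return(tab)
  }
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing <- setdiff(mandatory, names(tab))
  if (length(missing) > 0L) {
    stop("lab_compilation_reader: missing mandatory columns: ",
         paste(missing, collapse = ", "))
  }
  problems <- list()
  for (col in c("mu", "I", "NC", "PC")) {
    vals <- suppressWarnings(as.numeric(tab[[col]]))
    bad <- which(!is.finite(vals) | vals < 0)
    if (length(bad) > 0L) {
      problems[[length(problems) + 1L]] <-
        data.frame(row = bad, column = col, reason = "non-numeric or negative")
    }
    tab[[col]] <- vals
  }
  bad_lim <- which(!tab$limitation %in% c("N", "P", "replete"))
  if (length(bad_lim) > 0L) {
    problems[[length(problems) + 1L]] <-
      data.frame(row = bad_lim, column = "limitation",
                 reason = "unknown limitation regime")
  }
  unit_flags <- character()
  for (col in c("NC", "PC")) {
    med <- stats::median(tab[[col]], na.rm = TRUE)
    if (is.finite(med) && med > 1) {
      unit_flags <- c(unit_flags, sprintf(
        "%s: median %.3g > 1; values look like mmol/mol, review units", col, med))
    }
  }
  attr(tab, "problems") <- if (length(problems) > 0L) do.call(rbind, problems)
  else data.frame(row = integer(), column = character(), reason = character())
  attr(tab, "unit_flags") <- unit_flags
  class(tab) <- c("culture_table", "data.frame")
  tab
}
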