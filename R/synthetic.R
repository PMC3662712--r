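#' Define a synthetic climate scenario
#'
#' Describes two five-year periods of monthly climate on a rectangular
#' grid: a north-south mean-temperature gradient with a seasonal cycle, an
#' east-west precipitation gradient with a wet/dry season, cell-level
#' interannual noise, and additive between-period deltas. The default
#' deltas are calibrated to the magnitudes of observed change between the
#' two study periods of the source system (+0.9 degrees C mean annual
#' temperature, +5.2 mm annual precipitation); the spatial pattern is
#' synthetic.
#'
#' @param shape Grid dimensions `c(nrow, ncol)`.
#' @param cell_size,origin Grid geometry.
#' @param n_years Years per period (>= 1; default 5).
#' @param temp_base Domain-mean annual temperature at t1 (degrees C).
#' @param temp_ns_span Temperature difference from the warm (south, bottom)
#'   to the cold (north, top) edge, degrees C.
#' @param temp_seasonal_amplitude Half-range of the seasonal temperature
#'   cycle (degrees C); the annual range is twice this plus noise.
#' @param precip_monthly_base Domain-mean monthly precipitation (mm).
#' @param precip_ew_span Annual-precipitation difference across the
#'   east-west extent (mm).
#' @param precip_seasonal_amplitude Relative amplitude of the seasonal
#'   precipitation cycle (fraction of the monthly base).
#' @param temp_delta Warming applied to every month at t2 (degrees C).
#' @param precip_delta_annual Added annual precipitation at t2 (mm).
#' @param noise_sd_temp,noise_sd_precip Cell-level interannual monthly
#'   noise SD (degrees C / mm).
#' @param seed Integer seed.
#' @return Object of class `climate_scenario`.
#' @export
climate_scenario <- function(shape = c(60, 60), cell_size = 1, origin = c(0, 0),
                             n_years = 5L,
                             temp_base = 10.7, temp_ns_span = 16,
                             temp_seasonal_amplitude = 10,
                             precip_monthly_base = 63.6, precip_ew_span = 800,
                             precip_seasonal_amplitude = 0.5,
                             temp_delta = 0.9, precip_delta_annual = 5.2,
                             noise_sd_temp = 0.3, noise_sd_precip = 5,
                             seed = 1L) {
  if (any(shape <= 0)) stop("grid shape must be positive")
  if (n_years < 1L) stop("n_years must be >= 1")
  if (noise_sd_temp < 0 || noise_sd_precip < 0) stop("noise SD must be >= 0")
  structure(as.list(environment()), class = "climate_scenario")
}

#' Generate the t1/t2 climate stacks of a scenario
#'
#' Builds monthly temperature and precipitation grids for every year of
#' both periods, derives the seven variables per year with
#' [derive_climate_variables()], and averages years with [period_mean()].
#' With zero noise the per-cell t2 minus t1 mean annual temperature equals
#' `temp_delta` exactly; with noise, up to sampling error that shrinks with
#' cells times years.
#'
#' @param scenario A [climate_scenario()].
#' @return List with elements `t1` and `t2` ([climate_stack()]s on one
#'   geometry).
#' @export
make_climate <- function(scenario) {
  stopifnot(inherits(scenario, "climate_scenario"))
  sc <- scenario
  nr <- sc$shape[1]; nc <- sc$shape[2]
  ## spatial fields (row 1 = top = cold north edge)
  row_frac <- matrix((nr - seq_len(nr) + 0.5) / nr, nr, nc)       # 0 bottom..1 top
  col_frac <- matrix(rep((seq_len(nc) - 0.5) / nc, each = nr), nr, nc)
  t_annual <- sc$temp_base + sc$temp_ns_span * (0.5 - row_frac)
  p_monthly <- sc$precip_monthly_base +
    (sc$precip_ew_span / 12) * (col_frac - 0.5)
  season_t <- -cos(2 * pi * (1:12 - 1) / 12)        # coldest Jan, warmest Jul
  season_p <- sin(2 * pi * (1:12 - 1) / 12)

  one_period <- function(period, delta_t, delta_p_annual) {
    yearly <- lapply(seq_len(sc$n_years), function(yr) {
      ys <- fanout_seed(sc$seed, paste0("climate_", period), yr)
      months_t <- months_p <- vector("list", 12L)
      for (m in 1:12) {
        noise_t <- if (sc$noise_sd_temp > 0)
          with_seed(fanout_seed(ys, "temp", m),
                    matrix(stats::rnorm(nr * nc, 0, sc$noise_sd_temp), nr, nc))
          else 0
        noise_p <- if (sc$noise_sd_precip > 0)
          with_seed(fanout_seed(ys, "precip", m),
                    matrix(stats::rnorm(nr * nc, 0, sc$noise_sd_precip), nr, nc))
          else 0
        tm <- t_annual + sc$temp_seasonal_amplitude * season_t[m] +
          delta_t + noise_t
        pm <- pmax(p_monthly * (1 + sc$precip_seasonal_amplitude * season_p[m]) +
                     delta_p_annual / 12 + noise_p, 0)
        months_t[[m]] <- climate_grid(tm, "monthly_temp", sc$cell_size, sc$origin)
        months_p[[m]] <- climate_grid(pm, "monthly_precip", sc$cell_size, sc$origin)
      }
      derive_climate_variables(months_t, months_p, period = paste0(period, "_y", yr))
    })
    period_mean(yearly, period = period)
  }
  list(t1 = one_period("t1", 0, 0),
       t2 = one_period("t2", sc$temp_delta, sc$precip_delta_annual))
}

#' Define a virtual species
#'
#' A species with a known climate-suitability function: independent
#' Gaussian responses (each scaled to 1 at its optimum) on a subset of the
#' seven variables, multiplied per cell. Cells at or above
#' `suitability_cutoff` form the species' true envelope. Occupancy dynamics
#' between periods are governed by `persistence_probability` (chance an
#' occupied cell that loses suitability stays occupied at t2 - sink
#' populations persisting through apparent contraction) and
#' `dispersal_radius` (maximum distance, in cell units, from t1-occupied
#' cells at which newly suitable cells can be colonized; `Inf` = climate
#' tracking, `0` = complete dispersal limitation). Routes in occupied cells
#' are detected with probability `detection_probability` per survey year.
#'
#' @param responses Named list; each element `c(optimum =, breadth =)` for
#'   one of [climate_variables()]. Breadths must be positive.
#' @param suitability_cutoff True-envelope cutoff in `(0, 1)`.
#' @param detection_probability Per-year detection probability in `(0, 1]`.
#' @param persistence_probability Probability in `[0, 1]`.
#' @param dispersal_radius Non-negative, possibly `Inf` (cell units).
#' @param name Species label.
#' @param seed Integer seed for the species' stochastic occupancy draws.
#' @return Object of class `virtual_species`.
#' @export
virtual_species <- function(responses, suitability_cutoff = 0.5,
                            detection_probability = 1,
                            persistence_probability = 0,
                            dispersal_radius = Inf,
                            name = "virtual_sp", seed = 1L) {
  stopifnot(is.list(responses), length(responses) >= 1L)
  if (!all(names(responses) %in% climate_variables()))
    stop("responses must be named by climate variables")
  for (r in responses) {
    if (!all(c("optimum", "breadth") %in% names(r)) || r[["breadth"]] <= 0)
      stop("each response needs an optimum and a positive breadth")
  }
  stopifnot(suitability_cutoff > 0, suitability_cutoff < 1,
            detection_probability > 0, detection_probability <= 1,
            persistence_probability >= 0, persistence_probability <= 1,
            dispersal_radius >= 0)
  structure(list(responses = responses,
                 suitability_cutoff = suitability_cutoff,
                 detection_probability = detection_probability,
                 persistence_probability = persistence_probability,
                 dispersal_radius = dispersal_radius,
                 name = name, seed = seed),
            class = "virtual_species")
}

#' True suitability of a virtual species on a climate stack
#'
#' Per-cell product of the species' Gaussian responses,
#' `prod_v exp(-0.5 ((x_v - opt_v) / breadth_v)^2)`; equals 1 where every
#' variable sits at its optimum and decays monotonically with distance.
#'
#' @param species A [virtual_species()].
#' @param stack A [climate_stack()].
#' @return A [suitability_surface()].
#' @export
true_suitability <- function(species, stack) {
  stopifnot(inherits(species, "virtual_species"),
            inherits(stack, "climate_stack"))
  ref <- stack$grids[[1L]]
  s <- matrix(1, nrow(ref$values), ncol(ref$values))
  for (v in names(species$responses)) {
    r <- species$responses[[v]]
    s <- s * exp(-0.5 * ((stack$grids[[v]]$values - r[["optimum"]]) / r[["breadth"]])^2)
  }
  suitability_surface(s, ref, period = stack$period, algorithm = "truth")
}

#' Simulate survey routes
#'
#' Uniform random points over an extent, each with a unique id - the
#' synthetic analogue of survey routes represented by a single coordinate
#' pair.
#'
#' @param extent Named vector `c(xmin, xmax, ymin, ymax)` (as from
#'   `grid_extent`), or a [climate_grid()]/[climate_stack()] whose extent
#'   is used.
#' @param n_routes Number of routes (>= 1).
#' @param seed Integer seed.
#' @return Data frame with `route_id`, `x`, `y`.
#' @export
simulate_routes <- function(extent, n_routes = 600L, seed = 1L) {
  if (inherits(extent, "climate_stack")) extent <- grid_extent(extent$grids[[1L]])
  if (inherits(extent, "climate_grid")) extent <- grid_extent(extent)
  stopifnot(n_routes >= 1L, all(c("xmin", "xmax", "ymin", "ymax") %in% names(extent)))
  xy <- with_seed(seed, cbind(
    stats::runif(n_routes, extent[["xmin"]], extent[["xmax"]]),
    stats::runif(n_routes, extent[["ymin"]], extent[["ymax"]])))
  data.frame(route_id = sprintf("R%05d", seq_len(n_routes)),
             x = xy[, 1], y = xy[, 2])
}

## minimum distance (cell units) from each TRUE cell of `from` for the cells
## flagged in `targets`; brute force over occupied cells.
min_cell_distance <- function(targets, from) {
  out <- matrix(Inf, nrow(targets), ncol(targets))
  ti <- which(targets, arr.ind = TRUE)
  fi <- which(from, arr.ind = TRUE)
  if (nrow(ti) == 0L || nrow(fi) == 0L) return(out)
  for (k in seq_len(nrow(ti))) {
    d2 <- (fi[, 1] - ti[k, 1])^2 + (fi[, 2] - ti[k, 2])^2
    out[ti[k, 1], ti[k, 2]] <- sqrt(min(d2))
  }
  out
}

#' Simulate occurrence data for a virtual species
#'
#' Occupancy is cell-level: at t1 the species occupies its true t1
#' envelope; at t2 it occupies (a) stably suitable cells, (b) newly
#' suitable cells within `dispersal_radius` of any t1-occupied cell, and
#' (c) cells that lost suitability, each retained independently with
#' `persistence_probability`. Detection is route-level: a route in an
#' occupied cell is recorded as a presence if detected in at least one of
#' the five survey years (probability `1 - (1 - d)^5`), mirroring the
#' collapse of repeat observations into a single presence. Background
#' routes are sampled among routes without a recorded presence - by
#' default independently for each period, or reusing the t1 background set
#' if `reuse_t1_background`.
#'
#' @param species A [virtual_species()].
#' @param stacks List with `t1`, `t2` climate stacks.
#' @param routes Data frame from [simulate_routes()].
#' @param n_background Background routes per period.
#' @param n_survey_years Survey years collapsed per period (default 5).
#' @param reuse_t1_background Reuse the t1 background set at t2?
#' @param seed Integer seed.
#' @return List: `t1`/`t2` [occurrence_set()]s, `occupancy` (logical cell
#'   matrices per period), `true_envelopes`, `true_suitability` surfaces.
#' @export
simulate_occurrences <- function(species, stacks, routes, n_background = 200L,
                                 n_survey_years = 5L,
                                 reuse_t1_background = FALSE, seed = 1L) {
  suit <- lapply(stacks[c("t1", "t2")], function(s) true_suitability(species, s))
  env <- lapply(suit, function(s) !is.na(s$values) & s$values >= species$suitability_cutoff)

  occ1 <- env$t1
  expansion <- env$t2 & !env$t1
  contraction <- env$t1 & !env$t2
  colonized <- if (is.infinite(species$dispersal_radius)) expansion else {
    expansion & (min_cell_distance(expansion, occ1) <= species$dispersal_radius)
  }
  persisted <- contraction
  if (any(contraction)) {
    keep <- with_seed(fanout_seed(seed, "occupancy"),
                      stats::runif(sum(contraction)) < species$persistence_probability)
    persisted[contraction] <- keep
  }
  occ2 <- (env$t1 & env$t2) | colonized | persisted

  ref <- stacks$t1$grids[[1L]]
  rc <- point_cell(ref, routes$x, routes$y)
  in_grid <- !is.na(rc[, "row"])
  p_detect <- 1 - (1 - species$detection_probability)^n_survey_years

  period_set <- function(occ, period) {
    occupied_route <- rep(FALSE, nrow(routes))
    occupied_route[in_grid] <- occ[cbind(rc[in_grid, "row"], rc[in_grid, "col"])]
    detected <- with_seed(fanout_seed(seed, paste0("detection_", period)),
                          stats::runif(nrow(routes)) < p_detect)
    routes$route_id[occupied_route & detected]
  }
  pres1 <- period_set(occ1, "t1")
  pres2 <- period_set(occ2, "t2")
  bg1 <- sample_background(routes, pres1, n_background,
                           seed = fanout_seed(seed, "background_t1"))
  bg2 <- if (reuse_t1_background) setdiff(bg1, pres2) else
    sample_background(routes, pres2, n_background,
                      seed = fanout_seed(seed, "background_t2"))

  list(t1 = occurrence_set(species$name, "t1", pres1, bg1),
       t2 = occurrence_set(species$name, "t2", pres2, bg2),
       occupancy = list(t1 = occ1, t2 = occ2),
       true_envelopes = env,
       true_suitability = suit)
}

#' Named scenario presets
#'
#' Parameter bundles encoding the contrasts the validation framework is
#' meant to resolve:
#'
#' * `tracking` - species track climate perfectly (persistence 0,
#'   unlimited dispersal): the dynamic approach should win on sensitivity.
#' * `no_shift` - zero climate deltas and zero interannual noise, so the
#'   t1 and t2 climates are identical and dynamic and static maps
#'   coincide exactly.
#' * `persistence` - occupied cells that lose suitability persist with
#'   probability 0.9: hybrid sensitivity gains should grow with the
#'   proportion of presences in contraction areas.
#' * `dispersal_limited` - no colonization of newly suitable cells
#'   (radius 0, persistence 1): static specificity gains should grow with
#'   the proportion of absences in expansion areas.
#' * `generalist_vs_specialist` - response breadth and persistence vary
#'   jointly across species.
#'
#' Each preset returns the scenario, a list of virtual species whose
#' temperature/precipitation optima are spread across the climate gradient
#' (so per-species exposure to expansion and contraction varies), and the
#' sampling sizes (600 routes, 200 background routes per species at this
#' desk scale).
#'
#' @param name Preset name.
#' @param n_species Number of virtual species (default 12).
#' @param seed Integer master seed.
#' @return List: `scenario`, `species` (list), `n_routes`, `n_background`.
#' @export
scenario_presets <- function(name = c("tracking", "no_shift", "persistence",
                                      "dispersal_limited",
                                      "generalist_vs_specialist"),
                             n_species = 12L, seed = 42L) {
  name <- match.arg(name)
  base <- list(n_routes = 600L, n_background = 200L)
  sc <- switch(name,
    no_shift = climate_scenario(temp_delta = 0, precip_delta_annual = 0,
                                noise_sd_temp = 0, noise_sd_precip = 0,
                                seed = fanout_seed(seed, "scenario")),
    climate_scenario(seed = fanout_seed(seed, "scenario")))

  ## species optima spread across the realized climate gradient
  t_opts <- seq(5, 16, length.out = n_species)
  p_opts <- seq(500, 1050, length.out = n_species)
  p_opts <- p_opts[with_seed(fanout_seed(seed, "optima"), sample(n_species))]
  breadth_t <- switch(name,
    tracking = rep(2, n_species),
    no_shift = rep(2, n_species),
    persistence = seq(0.9, 1.8, length.out = n_species),
    dispersal_limited = seq(0.9, 1.8, length.out = n_species),
    generalist_vs_specialist = seq(0.8, 3, length.out = n_species))
  persist <- switch(name,
    tracking = rep(0, n_species),
    no_shift = rep(0, n_species),
    persistence = rep(0.9, n_species),
    dispersal_limited = rep(1, n_species),
    generalist_vs_specialist = seq(0, 0.9, length.out = n_species))
  radius <- switch(name,
    dispersal_limited = rep(0, n_species),
    rep(Inf, n_species))

  species <- lapply(seq_len(n_species), function(i) {
    virtual_species(
      responses = list(
        mean_annual_temp = c(optimum = t_opts[i], breadth = breadth_t[i]),
        annual_precip = c(optimum = p_opts[i], breadth = 250)),
      suitability_cutoff = 0.5,
      detection_probability = 1,
      persistence_probability = persist[i],
      dispersal_radius = radius[i],
      name = sprintf("vsp%02d", i),
      seed = fanout_seed(seed, "species", i))
  })
  c(list(name = name, scenario = sc, species = species), base)
}
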