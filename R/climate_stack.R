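#' Bundle the seven derived climate variables for one period
#'
#' A `climate_stack` holds exactly one [climate_grid()] per variable in
#' [climate_variables()], all on an identical geometry, labelled with the
#' period it describes (`"t1"`, `"t2"`, or an intermediate label such as a
#' single year).
#'
#' @param grids Named list of seven [climate_grid()] objects, names matching
#'   [climate_variables()].
#' @param period Period label.
#' @return An object of class `climate_stack`.
#' @export
climate_stack <- function(grids, period = "t1") {
  vars <- climate_variables()
  if (!setequal(names(grids), vars) || length(grids) != 7L)
    stop("a climate stack needs exactly the seven variables: ",
         paste(vars, collapse = ", "))
  grids <- grids[vars]
  ref <- grids[[1L]]
  for (g in grids) {
    if (!inherits(g, "climate_grid")) stop("all stack entries must be climate_grid objects")
    if (!same_geometry(g, ref)) stop("stack grids disagree in shape, origin or cell size")
  }
  structure(list(period = period, grids = grids), class = "climate_stack")
}

#' @export
print.climate_stack <- function(x, ...) {
  g <- x$grids[[1L]]
  cat(sprintf("<climate_stack> period %s: 7 variables on %d x %d cells (cell %g)\n",
              x$period, nrow(g$values), ncol(g$values), g$cell_size))
  invisible(x)
}

#' Derive the seven bioclimatic variables from monthly surfaces
#'
#' From 12 monthly mean-temperature grids and 12 monthly precipitation grids
#' (one calendar year, shared geometry) computes: annual precipitation (sum),
#' driest/wettest month precipitation (min/max over months), mean annual
#' temperature (mean of monthly means), maximum/minimum mean monthly
#' temperature (max/min over months), and temperature annual range
#' (max - min).
#'
#' @param monthly_mean_temp,monthly_precip Lists of 12 [climate_grid()].
#' @param period Label for the resulting stack (e.g. a year).
#' @return A [climate_stack()].
#' @export
derive_climate_variables <- function(monthly_mean_temp, monthly_precip,
                                     period = "year") {
  if (length(monthly_mean_temp) != 12L || length(monthly_precip) != 12L)
    stop("12 monthly grids are required for each of temperature and precipitation")
  ref <- monthly_mean_temp[[1L]]
  for (g in c(monthly_mean_temp, monthly_precip))
    if (!same_geometry(g, ref)) stop("monthly grids disagree in geometry")

  tarr <- simplify2array(lapply(monthly_mean_temp, function(g) g$values))
  parr <- simplify2array(lapply(monthly_precip, function(g) g$values))
  mk <- function(values, variable)
    climate_grid(values, variable, ref$cell_size, ref$origin)
  tmax <- apply(tarr, c(1, 2), max)
  tmin <- apply(tarr, c(1, 2), min)
  climate_stack(list(
    annual_precip        = mk(apply(parr, c(1, 2), sum),  "annual_precip"),
    driest_month_precip  = mk(apply(parr, c(1, 2), min),  "driest_month_precip"),
    wettest_month_precip = mk(apply(parr, c(1, 2), max),  "wettest_month_precip"),
    mean_annual_temp     = mk(apply(tarr, c(1, 2), mean), "mean_annual_temp"),
    temp_annual_range    = mk(tmax - tmin,                "temp_annual_range"),
    max_monthly_temp     = mk(tmax,                       "max_monthly_temp"),
    min_monthly_temp     = mk(tmin,                       "min_monthly_temp")
  ), period = period)
}

#' Average yearly stacks into a multi-year period mean
#'
#' Per-cell, per-variable arithmetic mean across years. Missingness is
#' propagated conservatively: a cell missing in any year is missing in the
#' output (in contrast to [aggregate_grid()], which averages the available
#' cells of a block; the asymmetry is deliberate - a coastal cell with one
#' bad year should not silently change its climatology).
#'
#' @param yearly_stacks List of [climate_stack()] objects on one geometry.
#' @param expected_years If given, must equal `length(yearly_stacks)`.
#' @param period Label for the resulting stack.
#' @return A [climate_stack()].
#' @export
period_mean <- function(yearly_stacks, expected_years = length(yearly_stacks),
                        period = "t1") {
  n <- length(yearly_stacks)
  if (n < 1L) stop("at least one yearly stack is required")
  if (expected_years != n)
    stop(sprintf("expected %d years but got %d stacks", expected_years, n))
  ref <- yearly_stacks[[1L]]$grids[[1L]]
  out <- lapply(climate_variables(), function(v) {
    mats <- lapply(yearly_stacks, function(s) {
      g <- s$grids[[v]]
      if (!same_geometry(g, ref)) stop("yearly stacks disagree in geometry")
      g$values
    })
    climate_grid(Reduce(`+`, mats) / n, v, ref$cell_size, ref$origin)
  })
  names(out) <- climate_variables()
  climate_stack(out, period = period)
}

#' Extract stack values at point locations
#'
#' Looks up the cell containing each point (cell-center registration,
#' half-open cell intervals, so edge points resolve deterministically) and
#' returns one row per point with the seven covariates. Points outside the
#' extent get `in_extent = FALSE`; rows with any missing covariate get
#' `complete = FALSE`. Neither is a hard failure - callers decide what to
#' drop.
#'
#' @param stack A [climate_stack()].
#' @param points Data frame with columns `x`, `y` (and optionally
#'   `route_id`, carried through).
#' @return Data frame: id/x/y columns, seven covariate columns, `in_extent`,
#'   `complete`.
#' @export
extract_at_points <- function(stack, points) {
  stopifnot(inherits(stack, "climate_stack"),
            is.data.frame(points), all(c("x", "y") %in% names(points)))
  ref <- stack$grids[[1L]]
  rc <- point_cell(ref, points$x, points$y)
  out <- data.frame(x = points$x, y = points$y)
  if ("route_id" %in% names(points))
    out <- cbind(route_id = points$route_id, out)
  for (v in climate_variables()) {
    m <- stack$grids[[v]]$values
    vals <- rep(NA_real_, nrow(rc))
    ok <- !is.na(rc[, "row"])
    vals[ok] <- m[cbind(rc[ok, "row"], rc[ok, "col"])]
    out[[v]] <- vals
  }
  out$in_extent <- !is.na(rc[, "row"])
  out$complete <- out$in_extent &
    stats::complete.cases(out[, climate_variables(), drop = FALSE])
  out
}
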