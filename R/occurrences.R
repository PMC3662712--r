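#' Collapse repeat observations into single presences per route
#'
#' A route counts as a presence if the focal species was recorded there in at
#' least one year of the window; repeat observations collapse to one.
#'
#' @param records Data frame with columns `route_id`, `species`, `year`.
#' @param species Focal species.
#' @param window Length-2 integer year range (inclusive).
#' @return Character vector of presence route ids (possibly empty).
#' @export
#' @examples
#' recs <- data.frame(route_id = c("A", "A", "B"), species = "sp",
#'                    year = c(1967, 1969, 1970))
#' collapse_presences(recs, "sp", c(1967, 1971))
collapse_presences <- function(records, species, window) {
  stopifnot(is.data.frame(records),
            all(c("route_id", "species", "year") %in% names(records)),
            length(window) == 2L)
  if (window[1] > window[2]) stop("empty year window")
  hit <- records$species == species &
    records$year >= window[1] & records$year <= window[2]
  sort(unique(as.character(records$route_id[hit])))
}

#' Sample background ("pseudo-absence") routes
#'
#' Draws `n` distinct routes uniformly without replacement from the routes at
#' which the focal species was never recorded in the window. Routes occupied
#' by *other* species still qualify; only the focal species excludes a route.
#'
#' @param routes Data frame of routes with a `route_id` column.
#' @param occupied Route ids occupied by the focal species.
#' @param n Number of background routes (the source study used 1000).
#' @param seed Integer seed; the same seed yields the same set.
#' @return Character vector of `n` background route ids.
#' @export
sample_background <- function(routes, occupied, n = 1000L, seed = 1L) {
  stopifnot(is.data.frame(routes), "route_id" %in% names(routes))
  pool <- setdiff(as.character(routes$route_id), as.character(occupied))
  if (length(pool) < n)
    stop(sprintf("cannot sample %d background routes: only %d unoccupied (short by %d)",
                 n, length(pool), n - length(pool)))
  sort(with_seed(seed, sample(pool, n)))
}

#' Assemble a presence/background set for one species and period
#'
#' @param species Species name.
#' @param period `"t1"` or `"t2"`.
#' @param presence_routes,background_routes Disjoint route-id sets.
#' @return An object of class `occurrence_set`.
#' @export
occurrence_set <- function(species, period, presence_routes, background_routes) {
  presence_routes <- as.character(presence_routes)
  background_routes <- as.character(background_routes)
  if (length(intersect(presence_routes, background_routes)) > 0L)
    stop("presence and background routes must be disjoint")
  structure(list(species = species, period = period,
                 presence_routes = presence_routes,
                 background_routes = background_routes,
                 n_background = length(background_routes)),
            class = "occurrence_set")
}

#' @export
print.occurrence_set <- function(x, ...) {
  cat(sprintf("<occurrence_set> %s @ %s: %d presences, %d background routes\n",
              x$species, x$period, length(x$presence_routes), x$n_background))
  invisible(x)
}

#' Build the labelled covariate matrix for model calibration
#'
#' Extracts the seven climate covariates at each presence and background
#' route; rows with incomplete covariates (missing cells or points outside
#' the extent) are dropped with a message stating the count.
#'
#' @param presences,background Route-id sets.
#' @param routes Data frame with `route_id`, `x`, `y`.
#' @param stack The period's [climate_stack()].
#' @return Data frame of class `cem_matrix`: `route_id`, `label`
#'   (factor `background`/`presence`), seven covariates. Carries the stack
#'   period as attribute `period`.
#' @export
build_model_matrix <- function(presences, background, routes, stack) {
  stopifnot(is.data.frame(routes), all(c("route_id", "x", "y") %in% names(routes)))
  ids <- c(as.character(presences), as.character(background))
  label <- factor(rep(c("presence", "background"),
                      c(length(presences), length(background))),
                  levels = c("background", "presence"))
  pos <- match(ids, as.character(routes$route_id))
  if (anyNA(pos)) stop("coordinates missing for route(s): ",
                       paste(utils::head(ids[is.na(pos)], 5), collapse = ", "))
  pts <- data.frame(route_id = ids, x = routes$x[pos], y = routes$y[pos])
  cov <- extract_at_points(stack, pts)
  keep <- cov$complete
  if (sum(!keep) > 0L)
    message(sum(!keep), " row(s) dropped for incomplete covariates")
  if (!any(keep)) stop("all rows have incomplete covariates")
  out <- data.frame(route_id = cov$route_id[keep], label = label[keep],
                    cov[keep, climate_variables(), drop = FALSE],
                    row.names = NULL)
  if (!all(c("presence", "background") %in% out$label))
    stop("model matrix needs at least one presence and one background row")
  attr(out, "period") <- stack$period
  class(out) <- c("cem_matrix", "data.frame")
  out
}
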