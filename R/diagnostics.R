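#' Proportions of t2 points in areas of range change
#'
#' Using the dynamic-approach range-change map, computes the proportion of
#' the species' t2 presences that fall on contraction cells (presences a
#' dynamic model must misclassify, and a hybrid model rescues) and the
#' proportion of t2 absences falling on expansion cells (absences a dynamic
#' model misclassifies relative to a static one).
#'
#' @param occ_t2 The species' t2 [occurrence_set()].
#' @param change A [classify_range_change()] map.
#' @param routes Data frame with `route_id`, `x`, `y`.
#' @return List with `prop_presences_in_contraction`,
#'   `prop_absences_in_expansion` and the backing counts.
#' @export
change_proportions <- function(occ_t2, change, routes) {
  cell_cat <- function(ids) {
    pos <- match(ids, as.character(routes$route_id))
    if (anyNA(pos)) stop("coordinates missing for route(s)")
    fake <- list(values = matrix(0, nrow(change$categories), ncol(change$categories)),
                 cell_size = change$cell_size, origin = change$origin)
    rc <- point_cell(fake, routes$x[pos], routes$y[pos])
    ok <- !is.na(rc[, "row"])
    cats <- rep(NA_character_, length(ids))
    cats[ok] <- change$categories[cbind(rc[ok, "row"], rc[ok, "col"])]
    cats[!is.na(cats) & cats != "missing"]
  }
  pc <- cell_cat(occ_t2$presence_routes)
  ac <- cell_cat(occ_t2$background_routes)
  if (length(pc) == 0L || length(ac) == 0L)
    stop("no usable t2 points on classified cells")
  list(species = occ_t2$species,
       prop_presences_in_contraction = mean(pc == "contraction"),
       prop_absences_in_expansion = mean(ac == "expansion"),
       n_presences = length(pc),
       n_presences_in_contraction = sum(pc == "contraction"),
       n_absences = length(ac),
       n_absences_in_expansion = sum(ac == "expansion"))
}

#' Simple linear regression with F test
#'
#' Ordinary least squares of `y` on `x` via [stats::lm()], reporting slope,
#' intercept, r-squared, the F statistic on (1, n-2) degrees of freedom and
#' its upper-tail p-value. An exact fit (zero residual sum of squares) is
#' reported with `perfect_fit = TRUE`, an infinite F and `p_value = NA`
#' rather than a spurious tiny p.
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, `x` not constant.
#' @return Object of class `cem_regression`.
#' @export
#' @examples
#' linear_regression(c(1, 2, 3), c(1, 3, 2)) # slope 0.5, r2 0.25, F 1/3
linear_regression <- function(x, y) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3L) stop("linear regression needs n >= 3")
  if (diff(range(x)) == 0) stop("constant x: regression undefined")
  fit <- stats::lm(y ~ x)
  ss_res <- sum(stats::residuals(fit)^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_reg <- ss_tot - ss_res
  perfect <- ss_res <= 1e-12 * max(ss_tot, 1)
  f <- if (perfect) Inf else ss_reg / (ss_res / (n - 2))
  structure(list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = if (ss_tot == 0) 1 else ss_reg / ss_tot,
    f_statistic = f,
    df = c(1L, n - 2L),
    p_value = if (perfect) NA_real_ else stats::pf(f, 1, n - 2, lower.tail = FALSE),
    n = n, perfect_fit = perfect),
    class = "cem_regression")
}

#' @export
print.cem_regression <- function(x, ...) {
  cat(sprintf("<cem_regression> slope %.4f, r2 %.3f, F(1,%d) = %s, p = %s%s\n",
              x$slope, x$r_squared, x$df[2],
              if (is.infinite(x$f_statistic)) "Inf" else sprintf("%.3f", x$f_statistic),
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3),
              if (x$perfect_fit) " [perfect fit]" else ""))
  invisible(x)
}

#' Load the packaged per-species summary tables
#'
#' The package ships, as plain CSV fixtures, the published per-species
#' evaluation statistics (12 resident North American breeding birds x 2
#' algorithms x 3 approaches: AUC static/dynamic, TSS, sensitivity and
#' specificity, each with SD) and the companion trait table (habitat niche
#' breadth as the number of land cover types used, and log body mass).
#'
#' @return Data frame.
#' @export
load_table1_fixture <- function() {
  path <- system.file("extdata", "table1_metrics.csv", package = "cemval",
                      mustWork = TRUE)
  utils::read.csv(path, check.names = TRUE, stringsAsFactors = FALSE)
}

#' @rdname load_table1_fixture
#' @export
load_table2_fixture <- function() {
  path <- system.file("extdata", "table2_traits.csv", package = "cemval",
                      mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

fixture_field <- function(table1, field) {
  if (!field %in% names(table1))
    stop("unknown metric field: ", field, " (available: ",
         paste(setdiff(names(table1), c("species", "common_name", "n_t1", "n_t2",
                                        "range_shift", "threshold_criterion",
                                        "algorithm")), collapse = ", "), ")")
  table1[[field]]
}

#' Summary statistics over the packaged evaluation table
#'
#' Arithmetic mean and SD (n-1) of one metric over the fixture rows,
#' optionally restricted to one algorithm; e.g. the mean dynamic AUC of the
#' 12 random-forest models, or hybrid sensitivity over all 24
#' species-by-algorithm values.
#'
#' @param table1 Fixture from [load_table1_fixture()].
#' @param field Metric column, e.g. `"auc_dynamic"`, `"sens_hybrid"`.
#' @param algorithm Optional `"rf"` or `"maxent"` filter.
#' @return List with `mean`, `sd`, `n`.
#' @export
summarize_fixture <- function(table1, field, algorithm = NULL) {
  rows <- if (is.null(algorithm)) table1 else table1[table1$algorithm == algorithm, ]
  v <- fixture_field(rows, field)
  list(mean = mean(v), sd = stats::sd(v), n = length(v))
}

#' Count species where the static AUC beats the dynamic AUC
#'
#' Number of species for which mean static AUC strictly exceeds mean
#' dynamic AUC for at least one of the two algorithms - range shifts not
#' unambiguously consistent with a climate-change model.
#'
#' @param table1 Fixture from [load_table1_fixture()].
#' @return Integer count.
#' @export
count_static_auc_exceeds <- function(table1) {
  sum(vapply(split(table1, table1$species),
             function(d) any(d$auc_static > d$auc_dynamic), logical(1)))
}

merge_traits <- function(table1, traits, algorithm) {
  rows <- table1[table1$algorithm == algorithm, ]
  m <- merge(rows, traits, by = "common_name")
  if (nrow(m) != nrow(rows))
    stop("unmatched species between metric table and trait table")
  m
}

#' Niche-breadth regression on hybrid-vs-dynamic sensitivity gains
#'
#' Regresses the per-species gain in sensitivity from the hybrid approach
#' over the dynamic approach on habitat niche breadth (number of land cover
#' types). Defaults to the maximum-entropy models, whose sensitivity was
#' the greater of the two algorithms; habitat generalists are expected to
#' show the larger gains (persistence in areas of apparent contraction).
#'
#' @param table1 Metric table ([load_table1_fixture()] or an equivalently
#'   shaped frame built from [evaluate_species()] output).
#' @param traits Trait table ([load_table2_fixture()]).
#' @param algorithm `"maxent"` (default) or `"rf"`.
#' @return A [linear_regression()] result.
#' @export
sensitivity_gain_vs_breadth <- function(table1, traits, algorithm = "maxent") {
  m <- merge_traits(table1, traits, algorithm)
  linear_regression(m$n_landcover_types, m$sens_hybrid - m$sens_dynamic)
}

#' Body-mass regression on static-vs-dynamic specificity gains
#'
#' Regresses the per-species gain in specificity from the static approach
#' over the dynamic approach on log body mass (a dispersal-ability proxy).
#' Defaults to the random-forest models, whose specificity was the greater;
#' the smallest-bodied (most dispersal-limited) species are expected to
#' show the larger gains, i.e. a negative slope.
#'
#' @inheritParams sensitivity_gain_vs_breadth
#' @param algorithm `"rf"` (default) or `"maxent"`.
#' @return A [linear_regression()] result.
#' @export
specificity_gain_vs_mass <- function(table1, traits, algorithm = "rf") {
  m <- merge_traits(table1, traits, algorithm)
  linear_regression(m$ln_mass, m$spec_static - m$spec_dynamic)
}

#' Regress per-species metric gains on range-change proportions
#'
#' `which = "sensitivity_contraction"` regresses hybrid-minus-dynamic
#' sensitivity gains on the proportion of t2 presences in areas of range
#' contraction; `which = "specificity_expansion"` regresses
#' static-minus-dynamic specificity gains on the proportion of t2 absences
#' in areas of range expansion.
#'
#' @param gains Data frame with columns `species` and `gain`.
#' @param proportions List of [change_proportions()] results (one per
#'   species).
#' @param which Which gain/proportion pairing to regress.
#' @return A [linear_regression()] result.
#' @export
gain_vs_change_regression <- function(gains, proportions,
                                      which = c("sensitivity_contraction",
                                                "specificity_expansion")) {
  which <- match.arg(which)
  prop_field <- if (which == "sensitivity_contraction")
    "prop_presences_in_contraction" else "prop_absences_in_expansion"
  props <- data.frame(
    species = vapply(proportions, `[[`, character(1), "species"),
    prop = vapply(proportions, `[[`, numeric(1), prop_field))
  m <- merge(gains, props, by = "species")
  if (nrow(m) != nrow(gains)) stop("unmatched species between gains and proportions")
  linear_regression(m$prop, m$gain)
}
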