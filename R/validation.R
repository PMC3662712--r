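#' Threshold a suitability surface into a binary envelope
#'
#' A cell is suitable iff its probability is greater than or equal to the
#' threshold (the `>=` convention is applied uniformly across the package);
#' missing cells stay missing.
#'
#' @param surface A [suitability_surface()].
#' @param threshold A [threshold_spec()] or a bare number in `(0, 1)`.
#' @param approach Tag for the resulting envelope.
#' @return Object of class `binary_envelope` (logical matrix + geometry).
#' @export
binarize <- function(surface, threshold, approach = paste0(surface$period, "_envelope")) {
  stopifnot(inherits(surface, "suitability_surface"))
  th <- if (inherits(threshold, "threshold_spec")) threshold$value else threshold
  stopifnot(is.numeric(th), length(th) == 1L)
  structure(list(cells = surface$values >= th,
                 cell_size = surface$cell_size, origin = surface$origin,
                 approach = approach, threshold = th),
            class = "binary_envelope")
}

#' @export
print.binary_envelope <- function(x, ...) {
  cat(sprintf("<binary_envelope> %s: %d/%d cells suitable (threshold %.4f)\n",
              x$approach, sum(x$cells, na.rm = TRUE), length(x$cells),
              x$threshold))
  invisible(x)
}

check_envelope_geometry <- function(a, b) {
  if (!identical(dim(a$cells), dim(b$cells)) ||
      abs(a$cell_size - b$cell_size) > 1e-9 ||
      any(abs(a$origin - b$origin) > 1e-9))
    stop("envelope geometries do not match")
}

#' Partition the grid into range-change categories
#'
#' Compares the t1 and t2 envelopes cell-by-cell: `expansion` = suitable
#' only at t2, `contraction` = suitable only at t1, `stable_suitable` =
#' suitable at both, `stable_unsuitable` = at neither, `missing` where
#' either envelope is missing. Categories are mutually exclusive and
#' exhaustive.
#'
#' @param env_t1,env_t2 [binarize()]d envelopes on one geometry.
#' @return Object of class `range_change_map` holding a character category
#'   matrix.
#' @export
classify_range_change <- function(env_t1, env_t2) {
  check_envelope_geometry(env_t1, env_t2)
  a <- env_t1$cells; b <- env_t2$cells
  cat_m <- matrix("missing", nrow(a), ncol(a))
  ok <- !is.na(a) & !is.na(b)
  cat_m[ok & a & b] <- "stable_suitable"
  cat_m[ok & !a & !b] <- "stable_unsuitable"
  cat_m[ok & !a & b] <- "expansion"
  cat_m[ok & a & !b] <- "contraction"
  structure(list(categories = cat_m, cell_size = env_t1$cell_size,
                 origin = env_t1$origin),
            class = "range_change_map")
}

#' @export
print.range_change_map <- function(x, ...) {
  tab <- table(factor(x$categories,
                      c("stable_suitable", "stable_unsuitable",
                        "expansion", "contraction", "missing")))
  cat("<range_change_map>\n")
  print(tab)
  invisible(x)
}

#' Build the prediction map for one validation approach
#'
#' * `dynamic`: the t2 envelope (the envelope both expands and contracts);
#' * `static`: the t1 envelope unchanged (null model of no climate-driven
#'   change);
#' * `hybrid`: the t1 envelope with areas of expansion appended, i.e. the
#'   set union of the two envelopes - contraction is *not* removed.
#'
#' @param approach `"dynamic"`, `"static"` or `"hybrid"`.
#' @param env_t1,env_t2 [binarize()]d envelopes on one geometry.
#' @return A `binary_envelope` tagged with the approach.
#' @export
prediction_map <- function(approach, env_t1, env_t2) {
  if (!approach %in% c("dynamic", "static", "hybrid"))
    stop("unknown approach: ", approach)
  check_envelope_geometry(env_t1, env_t2)
  cells <- switch(approach,
                  dynamic = env_t2$cells,
                  static = env_t1$cells,
                  hybrid = env_t1$cells | env_t2$cells)
  structure(list(cells = cells, cell_size = env_t1$cell_size,
                 origin = env_t1$origin, approach = approach,
                 threshold = env_t1$threshold),
            class = "binary_envelope")
}

## cell lookup for envelopes (same convention as climate grids)
envelope_cell_values <- function(envelope, x, y) {
  fake <- list(values = envelope$cells, cell_size = envelope$cell_size,
               origin = envelope$origin)
  rc <- point_cell(fake, x, y)
  out <- rep(NA, length(x))
  ok <- !is.na(rc[, "row"])
  out[ok] <- envelope$cells[cbind(rc[ok, "row"], rc[ok, "col"])]
  out
}

#' Confusion counts of a binary envelope against test points
#'
#' True positives are presences falling on suitable cells, false negatives
#' presences on unsuitable cells, and analogously for absences. Points on
#' missing cells (or outside the extent) are excluded with a message.
#'
#' @param envelope A `binary_envelope`.
#' @param presences,absences Data frames with `x`, `y`.
#' @return Named vector `c(tp, fp, fn, tn)`.
#' @export
confusion_counts <- function(envelope, presences, absences) {
  pv <- envelope_cell_values(envelope, presences$x, presences$y)
  av <- envelope_cell_values(envelope, absences$x, absences$y)
  dropped <- sum(is.na(pv)) + sum(is.na(av))
  if (dropped > 0L)
    message(dropped, " point(s) on missing cells excluded from confusion counts")
  pv <- pv[!is.na(pv)]; av <- av[!is.na(av)]
  if (length(pv) + length(av) == 0L) stop("no usable evaluation points")
  c(tp = sum(pv), fp = sum(av), fn = sum(!pv), tn = sum(!av))
}

#' Sensitivity, specificity and the true skill statistic
#'
#' Sensitivity is the proportion of correctly classified presences
#' (`tp / (tp + fn)`; 1 - omission), specificity the proportion of
#' correctly classified absences (`tn / (tn + fp)`; 1 - commission), and
#' TSS their sum minus one. The TSS as implemented ranges from -1 to 1
#' (the standard formula; see the methods vignette for a note on reported
#' ranges).
#'
#' @param counts Named confusion vector from [confusion_counts()].
#' @return A number.
#' @export
sensitivity <- function(counts) {
  d <- counts[["tp"]] + counts[["fn"]]
  if (d == 0) stop("sensitivity undefined: no presences")
  counts[["tp"]] / d
}

#' @rdname sensitivity
#' @export
specificity <- function(counts) {
  d <- counts[["tn"]] + counts[["fp"]]
  if (d == 0) stop("specificity undefined: no absences")
  counts[["tn"]] / d
}

#' @rdname sensitivity
#' @export
tss <- function(counts) sensitivity(counts) + specificity(counts) - 1

#' Rank-based AUC for presence vs background scores
#'
#' The probability that a randomly drawn presence scores higher than a
#' randomly drawn background point, ties counted one half (the rank-sum
#' definition; equal to the fraction of concordant score pairs).
#'
#' @param presence_scores,absence_scores Non-empty numeric vectors.
#' @return AUC in `[0, 1]`.
#' @export
#' @examples
#' auc(c(0.9, 0.6), c(0.3, 0.7)) # 0.75
auc <- function(presence_scores, absence_scores) {
  np <- length(presence_scores); na <- length(absence_scores)
  if (np == 0L || na == 0L) stop("auc needs non-empty score sets")
  r <- rank(c(presence_scores, absence_scores))
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * na)
}

#' Does the static model outperform the dynamic model in AUC?
#'
#' TRUE iff mean static AUC strictly exceeds mean dynamic AUC for at least
#' one of the two algorithms' evaluations of the species.
#'
#' @param summary_rf,summary_maxent `cem_evaluation` objects from
#'   [evaluate_species()] for the two algorithms.
#' @return Logical.
#' @export
static_exceeds_dynamic_auc <- function(summary_rf, summary_maxent) {
  one <- function(ev) {
    m <- ev$approaches$dynamic$mean
    m[["auc_static"]] > m[["auc_dynamic"]]
  }
  one(summary_rf) || one(summary_maxent)
}
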