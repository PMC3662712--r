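#' Cohen's kappa from a confusion table
#'
#' `kappa = (p_o - p_e) / (1 - p_e)` with observed agreement
#' `p_o = (tp + tn) / N` and chance agreement
#' `p_e = ((tp+fp)(tp+fn) + (fn+tn)(fp+tn)) / N^2`. Returns 0 when
#' `1 - p_e` is exactly zero (no information beyond chance).
#'
#' @param tp,fp,fn,tn Non-negative confusion counts.
#' @return Kappa in `[-1, 1]`.
#' @export
#' @examples
#' cohens_kappa(40, 10, 10, 40) # 0.6
cohens_kappa <- function(tp, fp, fn, tn) {
  counts <- c(tp, fp, fn, tn)
  if (any(counts < 0)) stop("confusion counts must be non-negative")
  n <- sum(counts)
  if (n == 0) stop("all confusion counts are zero")
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (1 - pe == 0) return(0)
  (po - pe) / (1 - pe)
}

#' Construct a threshold specification
#'
#' @param criterion `"max_kappa"` or `"prevalence"`.
#' @param value Threshold in `(0, 1)`.
#' @param provenance Optional list (seed, n_replicates, grid step, ...).
#' @return Object of class `threshold_spec`.
#' @export
threshold_spec <- function(criterion = c("max_kappa", "prevalence"),
                           value, provenance = list()) {
  criterion <- match.arg(criterion)
  if (!is.numeric(value) || length(value) != 1L || value <= 0 || value >= 1)
    stop("threshold value must lie strictly between 0 and 1")
  structure(list(criterion = criterion, value = value,
                 provenance = provenance),
            class = "threshold_spec")
}

#' @export
print.threshold_spec <- function(x, ...) {
  cat(sprintf("<threshold_spec> %s: %.5f\n", x$criterion, x$value))
  invisible(x)
}

## Mean kappa over a closed threshold grid for one scored test set.
## Exposed (internal) so the grid search can be oracle-tested on fixed
## scores without refitting models.
kappa_grid <- function(scores, labels, grid = seq(0.01, 0.99, by = 0.01)) {
  is_pres <- labels == "presence"
  vapply(grid, function(th) {
    pred <- scores >= th
    cohens_kappa(tp = sum(pred & is_pres), fp = sum(pred & !is_pres),
                 fn = sum(!pred & is_pres), tn = sum(!pred & !is_pres))
  }, numeric(1))
}

#' Threshold maximizing Cohen's kappa on calibration resamples
#'
#' Runs `n_replicates` model fits on random 75-25 training-testing
#' partitions of the calibration matrix, scores each held-out set at every
#' threshold on a closed 0.01-step grid from 0.01 to 0.99, averages kappa
#' per threshold across replicates, and returns the maximizing threshold.
#' Ties break toward the smallest threshold (stable under resampling
#' noise). A replicate whose test draw is single-class is re-drawn (at most
#' 10 times).
#'
#' @param matrix Calibration `cem_matrix` (period t1).
#' @param algorithm Backend passed to [cem()].
#' @param n_replicates Number of replicate fits (default 5).
#' @param split Training fraction (default 0.75).
#' @param grid Threshold grid.
#' @param seed Integer seed; results are reproducible under it.
#' @param ... Passed to [cem()] (e.g. `ntree`).
#' @return A [threshold_spec()] with criterion `"max_kappa"`.
#' @export
max_kappa_threshold <- function(matrix, algorithm = "rf", n_replicates = 5L,
                                split = 0.75, grid = seq(0.01, 0.99, by = 0.01),
                                seed = 1L, ...) {
  stopifnot(split > 0, split < 1)
  kap <- matrix(NA_real_, n_replicates, length(grid))
  for (r in seq_len(n_replicates)) {
    rseed <- fanout_seed(seed, "kappa_replicate", r)
    draw <- NULL
    for (attempt in 1:10) {
      idx <- with_seed(fanout_seed(rseed, "split", attempt),
                       stratified_sample(matrix$label, split))
      test <- matrix[-idx, , drop = FALSE]
      if (length(unique(test$label)) == 2L) { draw <- idx; break }
    }
    if (is.null(draw))
      stop("degenerate split: could not draw a two-class test set in 10 attempts")
    fit <- cem(matrix[draw, , drop = FALSE], algorithm = algorithm,
               seed = fanout_seed(rseed, "fit"), ...)
    test <- matrix[-draw, , drop = FALSE]
    kap[r, ] <- kappa_grid(predict(fit, test), test$label, grid)
  }
  mean_kap <- colMeans(kap)
  best <- grid[which.max(mean_kap)] # which.max -> first max -> smallest threshold
  threshold_spec("max_kappa", best,
                 provenance = list(seed = seed, n_replicates = n_replicates,
                                   split = split,
                                   grid_step = diff(grid[1:2]),
                                   mean_kappa = max(mean_kap)))
}

#' Prevalence-based threshold
#'
#' `n_presences / (n_presences + n_background)`; with the study's 1000
#' background points, a species with 73 calibration presences gets
#' 73/1073 ~ 0.068.
#'
#' @param n_presences Calibration presence count (>= 1).
#' @param n_background Background count (default 1000).
#' @return A [threshold_spec()] with criterion `"prevalence"`.
#' @export
prevalence_threshold <- function(n_presences, n_background = 1000L) {
  if (n_presences < 1L) stop("prevalence threshold needs at least one presence")
  threshold_spec("prevalence", n_presences / (n_presences + n_background),
                 provenance = list(n_presences = n_presences,
                                   n_background = n_background))
}

#' Choose the threshold criterion to report
#'
#' Given both candidate thresholds evaluated on the same t2 data, reports
#' the one yielding the greater model sensitivity; on an exact tie the
#' prevalence criterion wins (its lower threshold suits sensitivity-oriented
#' use).
#'
#' @param candidates List of two [threshold_spec()] objects (one per
#'   criterion).
#' @param t2_sensitivities Numeric vector of the matching t2 sensitivities.
#' @return The selected [threshold_spec()].
#' @export
select_reported_threshold <- function(candidates, t2_sensitivities) {
  stopifnot(length(candidates) == 2L, length(t2_sensitivities) == 2L)
  crit <- vapply(candidates, function(th) th$criterion, character(1))
  if (t2_sensitivities[1] == t2_sensitivities[2]) {
    candidates[[which(crit == "prevalence")[1]]]
  } else {
    candidates[[which.max(t2_sensitivities)]]
  }
}
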