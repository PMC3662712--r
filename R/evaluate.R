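#' Resampled temporal validation of one species
#'
#' The core validation loop. For each of `n_partitions` replicates:
#'
#' 1. refit the model on a stratified `train_fraction` subsample of the t1
#'    calibration matrix;
#' 2. project the refitted model onto the t1 and t2 climate stacks and
#'    binarize both with the *fixed* precomputed threshold;
#' 3. build the dynamic (t2), static (t1) and hybrid (union) prediction
#'    maps;
#' 4. score a stratified `test_fraction` subsample of the t2 evaluation
#'    points against all three maps (sensitivity, specificity, TSS), and
#'    compute AUC from the continuous t2-projected probabilities at those
#'    points (`auc_dynamic`) and from the t1-projected probabilities at the
#'    same points (`auc_static`).
#'
#' Both resampling knobs are independently configurable; each replicate
#' draws both a refit subsample and a test subsample, which is what gives
#' the replicate-to-replicate spread summarized as mean +/- SD. A replicate
#' whose test draw is single-class is re-drawn (at most 10 times). The whole
#' procedure is reproducible under `seed`.
#'
#' @param matrix_t1 Calibration `cem_matrix` from [build_model_matrix()].
#' @param occ_t2 The species' t2 [occurrence_set()].
#' @param routes Data frame with `route_id`, `x`, `y` (coordinates for the
#'   t2 routes).
#' @param stacks List with elements `t1` and `t2` ([climate_stack()]s).
#' @param algorithm Backend passed to [cem()].
#' @param threshold A [threshold_spec()] computed on t1 calibration data,
#'   applied unchanged to all three approaches.
#' @param n_partitions Number of replicates (the source study used 100).
#' @param train_fraction Fraction of t1 rows refit per replicate.
#' @param test_fraction Fraction of t2 points scored per replicate.
#' @param seed Integer seed.
#' @param ... Passed to [cem()].
#' @return Object of class `cem_evaluation`: per-approach replicate tables
#'   with per-metric mean and SD (n-1 denominator).
#' @export
evaluate_species <- function(matrix_t1, occ_t2, routes, stacks,
                             algorithm = "rf", threshold,
                             n_partitions = 100L, train_fraction = 0.75,
                             test_fraction = 0.25, seed = 1L, ...) {
  stopifnot(inherits(threshold, "threshold_spec") || is.numeric(threshold),
            all(c("t1", "t2") %in% names(stacks)))
  th <- if (inherits(threshold, "threshold_spec")) threshold$value else threshold

  ## t2 evaluation points -> cell indices (computed once)
  ref <- stacks$t2$grids[[1L]]
  lookup <- function(ids) {
    pos <- match(ids, as.character(routes$route_id))
    if (anyNA(pos)) stop("coordinates missing for t2 route(s)")
    rc <- point_cell(ref, routes$x[pos], routes$y[pos])
    ok <- !is.na(rc[, "row"])
    cbind(rc, idx = ifelse(ok, (rc[, "col"] - 1L) * nrow(ref$values) + rc[, "row"], NA))
  }
  p_idx <- lookup(occ_t2$presence_routes)[, "idx"]
  a_idx <- lookup(occ_t2$background_routes)[, "idx"]

  ## covariate tables per stack (computed once; complete cells only)
  tabs <- lapply(stacks[c("t1", "t2")], stack_cell_table)
  ok_cells <- lapply(tabs, stats::complete.cases)

  n0 <- length(p_idx) + length(a_idx)
  keep <- function(idx) idx[!is.na(idx) & ok_cells$t2[idx] & ok_cells$t1[idx]]
  p_idx <- keep(p_idx)
  a_idx <- keep(a_idx)
  drop_p <- n0 - length(p_idx) - length(a_idx)
  if (drop_p > 0L)
    message(drop_p, " t2 point(s) outside the extent or on missing cells excluded")
  if (length(p_idx) == 0L || length(a_idx) == 0L)
    stop("no usable t2 evaluation points on complete climate cells")

  approaches <- c("dynamic", "static", "hybrid")
  metric_names <- c("sensitivity", "specificity", "tss",
                    "auc_dynamic", "auc_static", "tp", "fp", "fn", "tn")
  reps <- lapply(approaches, function(a)
    matrix(NA_real_, n_partitions, length(metric_names),
           dimnames = list(NULL, metric_names)))
  names(reps) <- approaches

  for (r in seq_len(n_partitions)) {
    rseed <- fanout_seed(seed, "partition", r)
    ## refit subsample of t1
    tr_idx <- with_seed(fanout_seed(rseed, "train"),
                        stratified_sample(matrix_t1$label, train_fraction))
    fit <- cem(matrix_t1[tr_idx, , drop = FALSE], algorithm = algorithm,
               seed = fanout_seed(rseed, "fit"), ...)
    prob <- lapply(tabs, function(tab) {
      p <- rep(NA_real_, nrow(tab))
      ok <- stats::complete.cases(tab)
      p[ok] <- predict(fit, tab[ok, , drop = FALSE])
      p
    })
    suit1 <- prob$t1 >= th
    suit2 <- prob$t2 >= th
    maps <- list(dynamic = suit2, static = suit1, hybrid = suit1 | suit2)

    ## test subsample of t2 evaluation points
    sp <- sa <- NULL
    for (attempt in 1:10) {
      s <- fanout_seed(rseed, "test", attempt)
      sp_try <- with_seed(s, sample(seq_along(p_idx),
                                    max(1L, round(length(p_idx) * test_fraction))))
      sa_try <- with_seed(s + 1L, sample(seq_along(a_idx),
                                         max(1L, round(length(a_idx) * test_fraction))))
      if (length(sp_try) > 0L && length(sa_try) > 0L) { sp <- sp_try; sa <- sa_try; break }
    }
    if (is.null(sp)) stop("could not draw a two-class test set in 10 attempts")
    tp_cells <- p_idx[sp]; ta_cells <- a_idx[sa]

    auc_dyn <- auc(prob$t2[tp_cells], prob$t2[ta_cells])
    auc_sta <- auc(prob$t1[tp_cells], prob$t1[ta_cells])
    for (a in approaches) {
      m <- maps[[a]]
      cnt <- c(tp = sum(m[tp_cells]), fp = sum(m[ta_cells]),
               fn = sum(!m[tp_cells]), tn = sum(!m[ta_cells]))
      reps[[a]][r, ] <- c(sensitivity(cnt), specificity(cnt), tss(cnt),
                          auc_dyn, auc_sta, cnt)
    }
  }

  summaries <- lapply(reps, function(m) {
    df <- as.data.frame(m)
    list(replicates = df,
         mean = colMeans(df),
         sd = apply(df, 2L, stats::sd)) # n-1 denominator
  })
  structure(list(species = occ_t2$species, algorithm = algorithm,
                 threshold = threshold, n_partitions = n_partitions,
                 n_test_presences = length(p_idx),
                 n_test_absences = length(a_idx),
                 dropped_points = drop_p,
                 approaches = summaries),
            class = "cem_evaluation")
}

#' @export
print.cem_evaluation <- function(x, ...) {
  cat(sprintf("<cem_evaluation> %s (%s), %d replicates\n",
              x$species, x$algorithm, x$n_partitions))
  for (a in names(x$approaches)) {
    m <- x$approaches[[a]]$mean; s <- x$approaches[[a]]$sd
    cat(sprintf("  %-8s sens %.3f+/-%.3f  spec %.3f+/-%.3f  TSS %.3f  AUCdyn %.3f  AUCstat %.3f\n",
                a, m[["sensitivity"]], s[["sensitivity"]],
                m[["specificity"]], s[["specificity"]], m[["tss"]],
                m[["auc_dynamic"]], m[["auc_static"]]))
  }
  invisible(x)
}
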