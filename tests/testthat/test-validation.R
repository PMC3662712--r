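test_that("binarization uses the >= convention and propagates missingness", {
  g <- const_grid(0, 1, 3)
  surf <- suitability_surface(matrix(c(0.4, 0.5, 0.6), 1, 3), g)
  env <- binarize(surf, 0.5)
  expect_equal(as.vector(env$cells), c(FALSE, TRUE, TRUE))
  env_low <- binarize(surf, threshold_spec("prevalence", 0.1))
  expect_true(all(env_low$cells))
  surf_na <- suitability_surface(matrix(c(0.4, NA, 0.6), 1, 3), g)
  expect_true(is.na(binarize(surf_na, 0.5)$cells[1, 2]))
})

test_that("range change categories follow set algebra and tile the grid", {
  # cells: A=(1,1), B=(1,2), C=(1,3); t1={A,B}, t2={B,C}
  e1 <- toy_envelope(matrix(c(TRUE, TRUE, FALSE), 1, 3))
  e2 <- toy_envelope(matrix(c(FALSE, TRUE, TRUE), 1, 3))
  ch <- classify_range_change(e1, e2)
  expect_equal(as.vector(ch$categories),
               c("contraction", "stable_suitable", "expansion"))
  same <- classify_range_change(e1, e1)
  expect_false(any(same$categories %in% c("expansion", "contraction")))

  withr::local_seed(3)
  for (i in 1:10) {
    a <- matrix(sample(c(TRUE, FALSE, NA), 30, TRUE, c(.4, .4, .2)), 5, 6)
    b <- matrix(sample(c(TRUE, FALSE, NA), 30, TRUE, c(.4, .4, .2)), 5, 6)
    ch <- classify_range_change(toy_envelope(a), toy_envelope(b))
    tab <- table(factor(ch$categories,
                        c("stable_suitable", "stable_unsuitable",
                          "expansion", "contraction", "missing")))
    expect_equal(sum(tab), 30) # partition: counts sum to cell count
    expect_equal(unname(tab[["missing"]]), sum(is.na(a) | is.na(b)))
  }
  e_bad <- toy_envelope(matrix(TRUE, 2, 2))
  expect_error(classify_range_change(e1, e_bad), "geometr")
})

test_that("prediction maps encode the three approaches", {
  e1 <- toy_envelope(matrix(c(TRUE, TRUE, FALSE), 1, 3))
  e2 <- toy_envelope(matrix(c(FALSE, TRUE, TRUE), 1, 3))
  expect_equal(prediction_map("static", e1, e2)$cells, e1$cells)
  expect_equal(prediction_map("dynamic", e1, e2)$cells, e2$cells)
  expect_equal(as.vector(prediction_map("hybrid", e1, e2)$cells),
               c(TRUE, TRUE, TRUE))
  # t2 subset of t1 -> hybrid equals static
  e2sub <- toy_envelope(matrix(c(TRUE, FALSE, FALSE), 1, 3))
  expect_equal(prediction_map("hybrid", e1, e2sub)$cells,
               prediction_map("static", e1, e2sub)$cells)
  expect_error(prediction_map("blended", e1, e2), "unknown approach")
})

test_that("confusion counts classify points against envelope cells", {
  env <- toy_envelope(matrix(c(TRUE, FALSE), 1, 2)) # left suitable, right not
  pres <- data.frame(x = c(0.5, 0.5, 0.2), y = 0.5)     # all on suitable
  abs_ <- data.frame(x = c(1.5, 1.5), y = 0.5)          # all on unsuitable
  cnt <- confusion_counts(env, pres, abs_)
  expect_equal(cnt, c(tp = 3, fp = 0, fn = 0, tn = 2))
  # inverting the envelope swaps tp<->fn and tn<->fp
  inv <- toy_envelope(!env$cells)
  cnt_inv <- confusion_counts(inv, pres, abs_)
  expect_equal(unname(cnt_inv[c("fn", "tn", "tp", "fp")]), unname(cnt))
  # point on a missing cell is excluded with a message
  envna <- toy_envelope(matrix(c(TRUE, NA), 1, 2))
  expect_message(cnt2 <- confusion_counts(envna, pres, abs_), "excluded")
  expect_equal(sum(cnt2), 3)
  expect_error(suppressMessages(
    confusion_counts(envna, data.frame(x = 1.5, y = 0.5),
                     data.frame(x = 1.5, y = 0.5))), "no usable")
})

test_that("threshold metrics follow their definitions exactly", {
  cnt <- c(tp = 8, fp = 3, fn = 2, tn = 7)
  expect_equal(sensitivity(cnt), 0.8)
  expect_equal(specificity(cnt), 0.7)
  expect_equal(tss(cnt), 0.5)
  expect_equal(tss(c(tp = 5, fp = 0, fn = 0, tn = 5)), 1.0)
  expect_error(sensitivity(c(tp = 0, fp = 1, fn = 0, tn = 1)), "sensitivity")
  expect_error(specificity(c(tp = 1, fp = 0, fn = 1, tn = 0)), "specificity")
  withr::local_seed(2)
  for (i in 1:25) {
    cnt <- c(tp = sample(1:50, 1), fp = sample(1:50, 1),
             fn = sample(1:50, 1), tn = sample(1:50, 1))
    expect_identical(tss(cnt), sensitivity(cnt) + specificity(cnt) - 1)
  }
})

test_that("rank AUC equals all-pairs counting and survives monotone maps", {
  expect_equal(auc(c(0.9, 0.6), c(0.3, 0.7)), 0.75)
  expect_equal(auc(c(0.2, 0.8), c(0.2, 0.8)), 0.5)
  expect_equal(auc(c(0.9, 0.8), c(0.1, 0.2)), 1.0)
  expect_error(auc(numeric(0), 1), "non-empty")
  withr::local_seed(4)
  for (i in 1:50) {
    p <- round(runif(sample(2:20, 1)), 2) # rounding forces ties
    a <- round(runif(sample(2:20, 1)), 2)
    expect_equal(auc(p, a), auc_oracle(p, a), tolerance = 1e-12)
    expect_equal(auc(exp(3 * p), exp(3 * a)), auc(p, a), tolerance = 1e-12)
  }
})

test_that("a no-change world makes the three approaches coincide", {
  sc <- climate_scenario(shape = c(25, 25), n_years = 2,
                         temp_delta = 0, precip_delta_annual = 0,
                         noise_sd_temp = 0, noise_sd_precip = 0, seed = 31)
  st <- make_climate(sc)
  expect_identical(st$t1$grids$mean_annual_temp$values,
                   st$t2$grids$mean_annual_temp$values)
  r <- simulate_routes(st$t1, 250, seed = 32)
  sp <- virtual_species(list(mean_annual_temp = c(optimum = 10, breadth = 2.5)),
                        name = "sp", seed = 33)
  sim <- simulate_occurrences(sp, st, r, n_background = 80, seed = 34)
  m1 <- suppressMessages(build_model_matrix(sim$t1$presence_routes,
                                            sim$t1$background_routes, r, st$t1))
  th <- prevalence_threshold(sum(m1$label == "presence"), 80)
  ev <- suppressMessages(evaluate_species(m1, sim$t2, r, st, "rf", th,
                                          n_partitions = 4, seed = 35, ntree = 60))
  for (metric in c("sensitivity", "specificity", "tss")) {
    expect_equal(ev$approaches$dynamic$replicates[[metric]],
                 ev$approaches$static$replicates[[metric]])
    expect_equal(ev$approaches$dynamic$replicates[[metric]],
                 ev$approaches$hybrid$replicates[[metric]])
  }
  expect_equal(ev$approaches$dynamic$replicates$auc_dynamic,
               ev$approaches$dynamic$replicates$auc_static)
})

test_that("summary moments match recomputation from stored replicates", {
  out <- quick_species_eval(3, "rf", n_partitions = 5)
  skip_if(is.null(out), "degenerate draw")
  ev <- out$evaluation
  for (a in names(ev$approaches)) {
    df <- ev$approaches[[a]]$replicates
    expect_equal(ev$approaches[[a]]$mean, colMeans(df))
    expect_equal(ev$approaches[[a]]$sd, apply(df, 2, sd)) # n-1 denominator
  }
})

test_that("hybrid union-containment holds in every replicate", {
  out <- quick_species_eval(11, "maxent", n_partitions = 4, persistence = 0.7)
  skip_if(is.null(out), "degenerate draw")
  ap <- out$evaluation$approaches
  expect_true(all(ap$hybrid$replicates$sensitivity >=
                    pmax(ap$dynamic$replicates$sensitivity,
                         ap$static$replicates$sensitivity)))
  expect_true(all(ap$hybrid$replicates$specificity <=
                    pmin(ap$dynamic$replicates$specificity,
                         ap$static$replicates$specificity)))
})

test_that("the static-vs-dynamic AUC rule uses a strict comparison", {
  mk <- function(auc_s, auc_d) {
    structure(list(approaches = list(dynamic = list(
      mean = c(auc_static = auc_s, auc_dynamic = auc_d)))),
      class = "cem_evaluation")
  }
  # observed pairing for one of the study species: 0.943 static vs 0.927 dynamic
  expect_true(static_exceeds_dynamic_auc(mk(0.943, 0.927), mk(0.951, 0.944)))
  expect_false(static_exceeds_dynamic_auc(mk(0.80, 0.85), mk(0.82, 0.86)))
  expect_false(static_exceeds_dynamic_auc(mk(0.85, 0.85), mk(0.85, 0.85)))
})
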