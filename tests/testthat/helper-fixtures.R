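# Small programmatic fixtures shared across test files.

# Constant-valued grid
const_grid <- function(value, nr = 4, nc = 4, variable = "mean_annual_temp",
                       cell_size = 1, origin = c(0, 0)) {
  climate_grid(matrix(value, nr, nc), variable, cell_size, origin)
}

# Stack with per-variable constant values (optionally overridden matrices)
const_stack <- function(values = NULL, nr = 4, nc = 4, period = "t1",
                        cell_size = 1, origin = c(0, 0)) {
  defaults <- c(annual_precip = 800, driest_month_precip = 20,
                wettest_month_precip = 120, mean_annual_temp = 10,
                temp_annual_range = 20, max_monthly_temp = 25,
                min_monthly_temp = 5)
  grids <- lapply(climate_variables(), function(v) {
    val <- if (!is.null(values) && v %in% names(values)) values[[v]] else defaults[[v]]
    m <- if (is.matrix(val)) val else matrix(val, nr, nc)
    climate_grid(m, v, cell_size, origin)
  })
  names(grids) <- climate_variables()
  climate_stack(grids, period = period)
}

# Labelled covariate matrix with one informative variable (mean annual
# temperature); presences centred at +2, background at -2 when separable,
# both at 0 otherwise. Other variables are uninformative noise.
toy_matrix <- function(n_pres = 30, n_bg = 60, seed = 1, separable = TRUE) {
  withr::local_seed(seed)
  n <- n_pres + n_bg
  label <- factor(rep(c("presence", "background"), c(n_pres, n_bg)),
                  levels = c("background", "presence"))
  temp <- if (separable) c(rnorm(n_pres, 2, 0.5), rnorm(n_bg, -2, 0.5))
          else rnorm(n, 0, 1)
  out <- data.frame(route_id = sprintf("T%03d", seq_len(n)), label = label,
                    mean_annual_temp = temp)
  for (v in setdiff(climate_variables(), "mean_annual_temp"))
    out[[v]] <- rnorm(n)
  out
}

# Binary envelope on a unit grid from a logical matrix
toy_envelope <- function(cells, approach = "t1_envelope", threshold = 0.5) {
  structure(list(cells = cells, cell_size = 1, origin = c(0, 0),
                 approach = approach, threshold = threshold),
            class = "binary_envelope")
}

# Independent closed-form OLS oracle (normal equations), used to check
# linear_regression without going through lm().
ols_oracle <- function(x, y) {
  n <- length(x)
  sxx <- sum((x - mean(x))^2)
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2); ss_tot <- sum((y - mean(y))^2)
  f <- (ss_tot - ss_res) / (ss_res / (n - 2))
  list(slope = slope, intercept = intercept,
       r_squared = 1 - ss_res / ss_tot, f = f,
       p = pf(f, 1, n - 2, lower.tail = FALSE))
}

# All-pairs AUC oracle with half-credit ties
auc_oracle <- function(pres, abs) {
  tot <- 0
  for (p in pres) for (a in abs)
    tot <- tot + (p > a) + 0.5 * (p == a)
  tot / (length(pres) * length(abs))
}

# Direct kappa from scores/labels at one threshold (independent of the
# package's confusion helpers)
kappa_oracle <- function(scores, labels, th) {
  pred <- scores >= th
  pres <- labels == "presence"
  tp <- sum(pred & pres); fp <- sum(pred & !pres)
  fn <- sum(!pred & pres); tn <- sum(!pred & !pres)
  n <- tp + fp + fn + tn
  po <- (tp + tn) / n
  pe <- ((tp + fp) * (tp + fn) + (fn + tn) * (fp + tn)) / n^2
  if (1 - pe == 0) 0 else (po - pe) / (1 - pe)
}

# Small end-to-end synthetic species evaluation used by several tests
quick_species_eval <- function(seed, algorithm = "rf", n_partitions = 3,
                               shape = c(30, 30), n_routes = 250,
                               n_background = 80, persistence = 0,
                               radius = Inf, breadth = 2) {
  sc <- climate_scenario(shape = shape, n_years = 2, seed = fanout_seed(seed, "sc"))
  st <- make_climate(sc)
  r <- simulate_routes(st$t1, n_routes, seed = fanout_seed(seed, "routes"))
  sp <- virtual_species(
    responses = list(mean_annual_temp = c(optimum = 5 + (seed %% 7) * 1.5,
                                          breadth = breadth)),
    persistence_probability = persistence, dispersal_radius = radius,
    name = sprintf("sp%03d", seed), seed = fanout_seed(seed, "species"))
  sim <- simulate_occurrences(sp, st, r, n_background = n_background,
                              seed = fanout_seed(seed, "occ"))
  if (length(sim$t1$presence_routes) < 5 || length(sim$t2$presence_routes) < 5)
    return(NULL)
  m1 <- suppressMessages(build_model_matrix(sim$t1$presence_routes,
                                            sim$t1$background_routes, r, st$t1))
  th <- prevalence_threshold(sum(m1$label == "presence"), n_background)
  ev <- suppressMessages(evaluate_species(
    m1, sim$t2, r, st, algorithm = algorithm, threshold = th,
    n_partitions = n_partitions, seed = fanout_seed(seed, "eval"), ntree = 60))
  list(sim = sim, matrix = m1, threshold = th, evaluation = ev)
}
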