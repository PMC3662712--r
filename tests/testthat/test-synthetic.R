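test_that("climate generation honours deltas, noise and the seed", {
  sc0 <- climate_scenario(shape = c(10, 10), n_years = 2, temp_delta = 0,
                          precip_delta_annual = 0, noise_sd_temp = 0,
                          noise_sd_precip = 0, seed = 1)
  st0 <- make_climate(sc0)
  for (v in climate_variables())
    expect_identical(st0$t1$grids[[v]]$values, st0$t2$grids[[v]]$values)

  sc <- climate_scenario(shape = c(10, 10), n_years = 2, temp_delta = 0.9,
                         precip_delta_annual = 5.2, noise_sd_temp = 0,
                         noise_sd_precip = 0, seed = 1)
  st <- make_climate(sc)
  dT <- st$t2$grids$mean_annual_temp$values - st$t1$grids$mean_annual_temp$values
  expect_equal(as.vector(dT), rep(0.9, 100), tolerance = 1e-12)
  dP <- st$t2$grids$annual_precip$values - st$t1$grids$annual_precip$values
  expect_equal(as.vector(dP), rep(5.2, 100), tolerance = 1e-9)

  scn <- climate_scenario(shape = c(12, 12), n_years = 3, seed = 7)
  a <- make_climate(scn); b <- make_climate(scn)
  expect_identical(a$t1$grids$annual_precip$values, b$t1$grids$annual_precip$values)
  expect_identical(a$t2$grids$min_monthly_temp$values, b$t2$grids$min_monthly_temp$values)
  # noise really is interannual: mean warming close to the delta
  expect_equal(mean(a$t2$grids$mean_annual_temp$values -
                      a$t1$grids$mean_annual_temp$values), 0.9,
               tolerance = 0.05)
})

test_that("true suitability is a scaled product of Gaussian responses", {
  st <- const_stack(list(mean_annual_temp = matrix(c(10, 12, 14, 16), 2, 2)),
                    nr = 2, nc = 2)
  sp <- virtual_species(list(mean_annual_temp = c(optimum = 10, breadth = 2)))
  s <- true_suitability(sp, st)
  expect_equal(s$values[1, 1], 1.0)                      # at the optimum
  expect_equal(s$values[2, 1], exp(-0.5))                # one breadth away
  expect_equal(s$values[1, 2], exp(-2))                  # two breadths away
  # monotone decay with distance along the variable
  expect_true(all(diff(as.vector(s$values)) < 0))
  # responses on two variables multiply
  sp2 <- virtual_species(list(mean_annual_temp = c(optimum = 10, breadth = 2),
                              annual_precip = c(optimum = 700, breadth = 100)))
  s2 <- true_suitability(sp2, st)
  expect_equal(s2$values[1, 1], exp(-0.5 * 1^2)) # precip is constant 800
  expect_error(virtual_species(list(mean_annual_temp = c(optimum = 1, breadth = 0))),
               "positive breadth")
  expect_error(virtual_species(list(bogus_var = c(optimum = 1, breadth = 1))),
               "named by climate variables")
})

test_that("route simulation is uniform, unique and reproducible", {
  ext <- c(xmin = 0, xmax = 10, ymin = 0, ymax = 10)
  r <- simulate_routes(ext, 2000, seed = 13)
  expect_equal(anyDuplicated(r$route_id), 0L)
  expect_identical(r, simulate_routes(ext, 2000, seed = 13))
  # quadrant occupancy consistent with uniformity
  q <- table(r$x > 5, r$y > 5)
  expect_gt(chisq.test(q)$p.value, 0.001)
  expect_true(all(r$x >= 0 & r$x <= 10 & r$y >= 0 & r$y <= 10))
})

test_that("occupancy dynamics follow persistence and dispersal settings", {
  sc <- climate_scenario(shape = c(25, 25), n_years = 2, temp_delta = 1.5,
                         noise_sd_temp = 0, noise_sd_precip = 0, seed = 17)
  st <- make_climate(sc)
  r <- simulate_routes(st$t1, 400, seed = 18)
  base <- list(mean_annual_temp = c(optimum = 10, breadth = 2))

  # full persistence + unlimited dispersal + perfect detection:
  # t2 presences are exactly the routes inside the union of true envelopes
  sp_all <- virtual_species(base, persistence_probability = 1,
                            dispersal_radius = Inf, detection_probability = 1,
                            name = "all", seed = 19)
  sim <- simulate_occurrences(sp_all, st, r, n_background = 50, seed = 20)
  uni <- sim$true_envelopes$t1 | sim$true_envelopes$t2
  rc <- cemval:::point_cell(st$t1$grids[[1]], r$x, r$y)
  in_union <- uni[rc]
  expect_setequal(sim$t2$presence_routes, r$route_id[in_union])

  # zero persistence: no t2 presence on contraction cells
  sp_track <- virtual_species(base, persistence_probability = 0,
                              dispersal_radius = Inf, name = "track", seed = 19)
  sim2 <- simulate_occurrences(sp_track, st, r, n_background = 50, seed = 20)
  contraction <- sim2$true_envelopes$t1 & !sim2$true_envelopes$t2
  pos <- match(sim2$t2$presence_routes, r$route_id)
  expect_false(any(contraction[rc[pos, , drop = FALSE]]))

  # zero dispersal: no t2 presence on expansion cells
  sp_stuck <- virtual_species(base, persistence_probability = 1,
                              dispersal_radius = 0, name = "stuck", seed = 19)
  sim3 <- simulate_occurrences(sp_stuck, st, r, n_background = 50, seed = 20)
  expansion <- sim3$true_envelopes$t2 & !sim3$true_envelopes$t1
  pos3 <- match(sim3$t2$presence_routes, r$route_id)
  expect_false(any(expansion[rc[pos3, , drop = FALSE]]))
  # and its t2 occupancy never exceeds the t1 envelope
  expect_true(all(sim3$occupancy$t2 <= sim3$true_envelopes$t1))
})

test_that("imperfect detection thins presences at the collapsed-window rate", {
  sc <- climate_scenario(shape = c(20, 20), n_years = 1, noise_sd_temp = 0,
                         noise_sd_precip = 0, seed = 23)
  st <- make_climate(sc)
  r <- simulate_routes(st$t1, 1500, seed = 24)
  base <- list(mean_annual_temp = c(optimum = 10, breadth = 4))
  sp_full <- virtual_species(base, detection_probability = 1, name = "d1", seed = 25)
  sp_half <- virtual_species(base, detection_probability = 0.3, name = "d3", seed = 25)
  n_full <- length(simulate_occurrences(sp_full, st, r, 50, seed = 26)$t1$presence_routes)
  n_half <- length(simulate_occurrences(sp_half, st, r, 50, seed = 26)$t1$presence_routes)
  p5 <- 1 - (1 - 0.3)^5 # detected in >=1 of 5 years
  expect_equal(n_half / n_full, p5, tolerance = 0.1)
})

test_that("presets encode the intended scenario contrasts", {
  tr <- scenario_presets("tracking", seed = 1)
  expect_true(all(vapply(tr$species, function(s) s$persistence_probability, 1) == 0))
  expect_true(all(vapply(tr$species, function(s) s$dispersal_radius, 1) == Inf))
  pe <- scenario_presets("persistence", seed = 1)
  expect_true(all(vapply(pe$species, function(s) s$persistence_probability, 1) == 0.9))
  dl <- scenario_presets("dispersal_limited", seed = 1)
  expect_true(all(vapply(dl$species, function(s) s$dispersal_radius, 1) == 0))
  ns <- scenario_presets("no_shift", seed = 1)
  expect_equal(ns$scenario$temp_delta, 0)
  expect_equal(ns$scenario$noise_sd_temp, 0)
  gv <- scenario_presets("generalist_vs_specialist", seed = 1, n_species = 6)
  expect_length(gv$species, 6)
  expect_error(scenario_presets("bogus"), "arg")
  # identical seeds give identical presets
  expect_identical(scenario_presets("tracking", seed = 9),
                   scenario_presets("tracking", seed = 9))
})
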