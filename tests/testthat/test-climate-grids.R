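test_that("ASCII grid round trip preserves values, geometry and no-data cells", {
  f <- withr::local_tempfile(fileext = ".asc")
  writeLines(c("ncols 2", "nrows 2", "xllcorner 10", "yllcorner 20",
               "cellsize 4", "NODATA_value -9999",
               "1.5 -9999", "3 4"), f)
  g <- read_grid(f, "ascii_grid", variable = "mean_annual_temp")
  expect_equal(dim(g), c(2L, 2L))
  expect_true(is.na(g$values[1, 2]))
  expect_equal(g$values[2, ], c(3, 4))
  expect_equal(g$cell_size, 4)
  expect_equal(g$origin, c(10, 20))

  f2 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g, f2)
  g2 <- read_grid(f2, "ascii_grid", variable = "mean_annual_temp")
  expect_equal(g2$values, g$values)
  expect_equal(g2$origin, g$origin)
  expect_equal(g2$cell_size, g$cell_size)

  # bit-stable at the fixed write precision
  f3 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g2, f3)
  expect_identical(readLines(f2), readLines(f3))

  g3 <- const_grid(7, 3, 3)
  f4 <- withr::local_tempfile(fileext = ".asc")
  write_grid(g3, f4)
  expect_true(all(read_grid(f4, "ascii_grid")$values == 7))
})

test_that("grid constructor enforces its invariants", {
  expect_error(climate_grid(matrix(1, 2, 2), "not_a_variable"), "unknown")
  expect_error(climate_grid(matrix(1, 2, 2), "mean_annual_temp", cell_size = -1))
  expect_error(climate_grid(matrix(c(1, Inf, 2, 3), 2, 2), "mean_annual_temp"),
               "finite")
  expect_silent(climate_grid(matrix(1, 2, 2), "monthly_temp"))
})

test_that("seven variables derive correctly from monthly surfaces", {
  # constant months
  mt <- lapply(1:12, function(m) const_grid(10, 2, 2, "monthly_temp"))
  mp <- lapply(1:12, function(m) const_grid(10, 2, 2, "monthly_precip"))
  st <- derive_climate_variables(mt, mp)
  expect_equal(st$grids$annual_precip$values[1, 1], 120)
  expect_equal(st$grids$driest_month_precip$values[1, 1], 10)
  expect_equal(st$grids$wettest_month_precip$values[1, 1], 10)
  expect_equal(st$grids$mean_annual_temp$values[1, 1], 10)
  expect_equal(st$grids$max_monthly_temp$values[1, 1], 10)
  expect_equal(st$grids$min_monthly_temp$values[1, 1], 10)
  expect_equal(st$grids$temp_annual_range$values[1, 1], 0)

  # monthly temperatures 0..11 degrees
  mt2 <- lapply(0:11, function(m) const_grid(m, 2, 2, "monthly_temp"))
  st2 <- derive_climate_variables(mt2, mp)
  expect_equal(st2$grids$mean_annual_temp$values[1, 1], 5.5)
  expect_equal(st2$grids$max_monthly_temp$values[1, 1], 11)
  expect_equal(st2$grids$min_monthly_temp$values[1, 1], 0)
  expect_equal(st2$grids$temp_annual_range$values[1, 1], 11)

  expect_error(derive_climate_variables(mt[1:11], mp), "12 monthly")
  bad <- c(mt[1:11], list(const_grid(10, 3, 3, "monthly_temp")))
  expect_error(derive_climate_variables(bad, mp), "geometry")
})

test_that("derived variables satisfy range and ordering identities", {
  withr::local_seed(42)
  for (i in 1:5) {
    mt <- lapply(1:12, function(m)
      climate_grid(matrix(rnorm(9, 10, 8), 3, 3), "monthly_temp"))
    mp <- lapply(1:12, function(m)
      climate_grid(matrix(runif(9, 0, 200), 3, 3), "monthly_precip"))
    st <- derive_climate_variables(mt, mp)
    expect_equal(st$grids$temp_annual_range$values,
                 st$grids$max_monthly_temp$values - st$grids$min_monthly_temp$values)
    expect_true(all(st$grids$wettest_month_precip$values >=
                      st$grids$driest_month_precip$values))
  }
})

test_that("period averaging is exact, order-invariant and missing-conservative", {
  mk_year <- function(v) const_stack(list(mean_annual_temp = v), nr = 2, nc = 2)
  ident <- period_mean(replicate(5, mk_year(9.5), simplify = FALSE))
  expect_equal(ident$grids$mean_annual_temp$values, matrix(9.5, 2, 2))

  years <- lapply(1:5, function(v) mk_year(v))
  expect_equal(period_mean(years)$grids$mean_annual_temp$values, matrix(3, 2, 2))
  perm <- period_mean(years[c(4, 1, 5, 3, 2)])
  expect_equal(perm$grids$mean_annual_temp$values,
               period_mean(years)$grids$mean_annual_temp$values)

  # one year missing at a cell -> output missing there
  m <- matrix(2, 2, 2); m[1, 2] <- NA
  years[[3]] <- const_stack(list(mean_annual_temp = m), nr = 2, nc = 2)
  out <- period_mean(years)
  expect_true(is.na(out$grids$mean_annual_temp$values[1, 2]))
  expect_false(anyNA(out$grids$mean_annual_temp$values[2, ]))

  expect_error(period_mean(years, expected_years = 4), "expected 4")
})

test_that("block aggregation averages available cells and conserves full-block means", {
  g <- climate_grid(matrix(c(1, 3, 2, 4), 2, 2), "mean_annual_temp")
  a <- aggregate_grid(g, 2)
  expect_equal(a$values, matrix(2.5, 1, 1))
  expect_equal(a$cell_size, 2)

  expect_identical(aggregate_grid(g, 1), g)
  expect_error(aggregate_grid(g, 0), "positive")

  gm <- climate_grid(matrix(c(1, 3, NA, NA), 2, 2), "mean_annual_temp")
  expect_equal(aggregate_grid(gm, 2)$values[1, 1], 2)
  gall <- climate_grid(matrix(NA_real_, 2, 2), "mean_annual_temp")
  expect_true(is.na(aggregate_grid(gall, 2)$values[1, 1]))

  withr::local_seed(7)
  big <- climate_grid(matrix(rnorm(64), 8, 8), "mean_annual_temp")
  expect_equal(mean(aggregate_grid(big, 4)$values), mean(big$values))

  odd <- climate_grid(matrix(rnorm(35), 5, 7), "mean_annual_temp")
  expect_warning(at <- aggregate_grid(odd, 2), "truncating")
  expect_equal(dim(at$values), c(2L, 3L))
  # origin (bottom-left) preserved: truncation removes top rows / right cols
  expect_equal(at$origin, odd$origin)
  expect_equal(at$values[2, 1], mean(odd$values[4:5, 1:2]))
})

test_that("point extraction uses half-open cell intervals and flags bad points", {
  vals <- matrix(1:4, 2, 2) # [1,1]=1 top-left, [2,1]=2 bottom-left, ...
  st <- const_stack(list(mean_annual_temp = vals), nr = 2, nc = 2)
  pts <- data.frame(
    x = c(0.5, 1.5, 1.0, 0.5, 2.5, 0.5),
    y = c(1.5, 0.5, 0.5, 1.0, 0.5, 2.0))
  out <- extract_at_points(st, pts)
  expect_equal(out$mean_annual_temp[1], 1)  # center of top-left cell
  expect_equal(out$mean_annual_temp[2], 4)  # center of bottom-right cell
  # shared vertical edge x=1 -> right cell (half-open [left, right))
  expect_equal(out$mean_annual_temp[3], 4)
  # shared horizontal edge y=1 -> upper cell (bottom-inclusive)
  expect_equal(out$mean_annual_temp[4], 1)
  expect_false(out$in_extent[5]) # x outside
  expect_false(out$in_extent[6]) # y on the excluded top edge
  expect_false(out$complete[5])

  # missing covariate cell -> incomplete but in extent
  vna <- vals; vna[1, 1] <- NA
  st2 <- const_stack(list(mean_annual_temp = vna), nr = 2, nc = 2)
  out2 <- extract_at_points(st2, data.frame(x = 0.5, y = 1.5))
  expect_true(out2$in_extent[1])
  expect_false(out2$complete[1])
})

test_that("climate stacks reject incomplete or inconsistent variable sets", {
  st <- const_stack(nr = 2, nc = 2)
  expect_error(climate_stack(st$grids[1:6]), "seven variables")
  bad <- st$grids
  bad$mean_annual_temp <- const_grid(1, 3, 3)
  expect_error(climate_stack(bad), "disagree")
})
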