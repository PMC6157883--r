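test_that("density-table columns are normalized with mean 1 and the right variance", {
  tab <- test_density_table()
  integrals <- colSums(tab$density * tab$width)
  means <- colSums(tab$density * tab$width * tab$x)
  expect_true(all(integrals >= 0.99 & integrals <= 1.01))
  expect_true(all(means >= 0.97 & means <= 1.03))
  expect_true(all(tab$density >= 0))

  vars <- colSums(tab$density * tab$width * tab$x^2) - means^2
  theory <- (1 - tab$e) / (1 + tab$e)
  check <- tab$e >= 0.05 & tab$e < 1
  expect_true(all(abs(vars[check] / theory[check] - 1) < 0.05))
})

test_that("the unit-efficiency column is a point mass at x = 1", {
  tab <- test_density_table()
  col <- tab$density[, length(tab$e)]
  at_one <- which(tab$breaks[-length(tab$breaks)] <= 1 & tab$breaks[-1] >= 1)
  expect_equal(sum((col * tab$width)[at_one]), 1)
  expect_equal(sum((col * tab$width)[-at_one]), 0)
})

test_that("high-efficiency columns are bimodal with first-cycle-failure mass near 0.5", {
  tab <- test_density_table()
  col <- tab$density[, which.min(abs(tab$e - 0.9))]
  mass <- col * tab$width
  # families whose very first copy failed: about 1-E of them, about half size
  secondary <- sum(mass[tab$x >= 0.35 & tab$x <= 0.65])
  expect_gt(secondary, 0.06)
  expect_lt(secondary, 0.14)
  peak_near_half <- max(col[tab$x >= 0.4 & tab$x <= 0.6])
  trough <- min(col[tab$x >= 0.65 & tab$x <= 0.8])
  expect_gt(peak_near_half, trough)
})

test_that("family-size fluctuations decrease with efficiency", {
  tab <- test_density_table()
  means <- colSums(tab$density * tab$width * tab$x)
  vars <- colSums(tab$density * tab$width * tab$x^2) - means^2
  expect_true(all(diff(vars) < 0))
})

test_that("interpolation passes through grid nodes and truncates at the support end", {
  tab <- test_density_table()
  j <- which.min(abs(tab$e - 0.5))
  expect_equal(
    fsd_density(tab, tab$x[c(10, 50, 200)], 0.5),
    tab$density[c(10, 50, 200), j]
  )
  expect_equal(fsd_density(tab, max(tab$breaks) + 1, 0.5), 0)
  expect_error(fsd_density(tab, 1, 0.01), "outside")
  expect_error(fsd_density(tab, 1, 1.2), "outside")
})

test_that("off-grid interpolated distribution matches fresh Monte-Carlo draws", {
  tab <- test_density_table()
  e0 <- 0.33 # not a grid node
  col <- umicountr:::fsd_column(tab, e0)
  cdf <- c(0, cumsum(col * tab$width))
  cdf <- cdf / max(cdf)
  fresh <- simulate_normalized_family(1e5, e0, seed = 77)
  emp <- stats::ecdf(fresh)
  ks <- max(abs(cdf - emp(tab$breaks)))
  expect_lt(ks, 0.01)
})

test_that("table construction validates its inputs", {
  expect_error(build_density_table(c(0, 0.5)), "\\(0, 1\\]")
  expect_error(build_density_table(c(0.5, 0.2)), "increasing")
  expect_error(
    build_density_table(c(0.5, 1), replicates = 100),
    "at least 1e4"
  )
})

test_that("density tables round-trip through their file format losslessly", {
  tab <- build_density_table(c(0.4, 0.8), replicates = 1e4, seed = 5)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_density_table(tab, path)
  back <- read_density_table(path)
  expect_equal(back$e, tab$e)
  expect_equal(back$breaks, tab$breaks)
  expect_equal(back$x, tab$x)
  expect_equal(unname(back$density), unname(tab$density))
  expect_equal(back$replicates, tab$replicates)
  expect_equal(back$seed, tab$seed)
  expect_error(read_density_table(withr::local_tempfile(lines = "oops")), "not a")
})

test_that("table build is deterministic given a seed", {
  a <- build_density_table(c(0.3, 0.9), replicates = 1e4, seed = 123)
  b <- build_density_table(c(0.3, 0.9), replicates = 1e4, seed = 123)
  expect_identical(a$density, b$density)
})
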