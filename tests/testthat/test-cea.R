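test_that("average cost-effectiveness divides cost by effect", {
  expect_equal(cost_per_effect(100, 1), 100)
  expect_equal(round(cost_per_effect(976.26, 6.13), 2), 159.26)
  expect_equal(round(cost_per_effect(976.26, 4.97), 2), 196.43)
  expect_equal(round(cost_per_effect(372.83, 5.21), 2), 71.56)
  expect_equal(round(cost_per_effect(372.83, 3.44), 2), 108.38)
  expect_error(cost_per_effect(10, 0), "positive")
  expect_error(cost_per_effect(10, -1), "positive")
})

test_that("cost ratios compare the two arms' cost per effect", {
  expect_equal(round(cost_ratio(159.26, 71.56), 2), 2.23)
  expect_equal(round(cost_ratio(196.43, 108.38), 2), 1.81)
  expect_equal(cost_ratio(5, 5), 1)
  expect_error(cost_ratio(1, 0), "positive")
})

test_that("management cost totals treatment by stage plus screening", {
  tc <- c(I = 3290.34, II = 4771.01, III = 6031.88, IV = 6612.80)
  m_i <- management_cost("iFOBT", tc, c(I = 6, II = 17, III = 54, IV = 23),
                         37283.53)
  expect_equal(total_management_cost(m_i), 615948.66)
  m_g <- management_cost("genetic_testing", tc,
                         c(I = 10, II = 60, III = 25, IV = 5), 97626.33)
  expect_equal(total_management_cost(m_g), 600651.33)
  # zero patients, zero screening
  m0 <- management_cost("iFOBT", tc, c(I = 0, II = 0, III = 0, IV = 0), 0)
  expect_equal(total_management_cost(m0), 0)
  # a populated stage must have a cost
  expect_error(
    management_cost("iFOBT", tc[c("I", "II")], c(I = 1, III = 2), 0),
    "treatment cost missing")
})

test_that("the ICER chain on the bundled dataset shows dominance of genetic testing", {
  q_i <- stage_qalys(fx$stage_tables$iFOBT)
  q_g <- stage_qalys(fx$stage_tables$genetic_testing)
  res <- icer(total_management_cost(fx$management_costs$genetic_testing),
              total_management_cost(fx$management_costs$iFOBT),
              q_g$total_qaly, q_i$total_qaly)
  expect_equal(round(res$delta_cost, 2), -15297.33)
  expect_equal(round(res$delta_effect, 2), 152.96)
  expect_equal(round(res$icer, 2), -100.01)
  expect_identical(res$quadrant, "SE")
  expect_identical(res$dominance, "dominant")
})

test_that("ICER handles simple and degenerate sign patterns", {
  r <- icer(110, 100, 2, 1)
  expect_equal(r$icer, 10)
  expect_identical(r$quadrant, "NE")
  expect_identical(r$dominance, "trade_off")
  # equal costs, more effect: ratio 0 on the boundary
  r0 <- icer(50, 50, 2, 1)
  expect_equal(r0$icer, 0)
  expect_identical(r0$quadrant, "boundary")
  # zero incremental effect: undefined ratio, classification still reported
  rz <- icer(60, 50, 1, 1)
  expect_true(is.na(rz$icer))
  expect_identical(rz$quadrant, "boundary")
})

test_that("plane classification matches the exhaustive sign table", {
  # brute-force oracle over all 9 sign patterns of (delta_cost, delta_effect)
  signs <- c(-1, 0, 1)
  for (dc in signs) for (de in signs) {
    got <- classify_plane(dc, de)
    want_quadrant <-
      if (dc == 0 || de == 0) "boundary"
      else if (dc > 0 && de > 0) "NE"
      else if (dc < 0 && de > 0) "SE"
      else if (dc < 0 && de < 0) "SW"
      else "NW"
    want_dominance <- switch(want_quadrant, SE = "dominant",
                             NW = "dominated", "trade_off")
    expect_identical(got$quadrant, want_quadrant)
    expect_identical(got$dominance, want_dominance)
  }
})

test_that("swapping arms negates the deltas, keeps the ICER, mirrors the plane", {
  set.seed(99)
  mirror <- c(NE = "SW", SE = "NW", SW = "NE", NW = "SE")
  for (i in 1:25) {
    c1 <- runif(1, 0, 1e6); c2 <- runif(1, 0, 1e6)
    e1 <- runif(1, 0, 500); e2 <- runif(1, 0, 500)
    a <- icer(c1, c2, e1, e2)
    b <- icer(c2, c1, e2, e1)
    expect_equal(b$delta_cost, -a$delta_cost)
    expect_equal(b$delta_effect, -a$delta_effect)
    expect_equal(b$icer, a$icer, tolerance = 1e-12)
    expect_identical(b$quadrant, unname(mirror[a$quadrant]))
  }
})

test_that("GDP threshold bands classify ICERs and respect dominance", {
  gdp <- 11414
  expect_identical(classify_threshold(-100.01, "dominant", gdp),
                   "highly_cost_effective")
  expect_identical(classify_threshold(0.5 * gdp, "trade_off", gdp),
                   "highly_cost_effective")
  expect_identical(classify_threshold(2.5 * gdp, "trade_off", gdp),
                   "cost_effective")
  expect_identical(classify_threshold(4 * gdp, "trade_off", gdp),
                   "not_cost_effective")
  expect_identical(classify_threshold(0.1, "dominated", gdp),
                   "not_cost_effective")
  expect_error(classify_threshold(1, "trade_off", 0), "positive")
  # monotone non-increasing cost-effectiveness as ICER/GDP grows
  order_of <- c(highly_cost_effective = 3, cost_effective = 2,
                not_cost_effective = 1)
  ratios <- seq(0.1, 5, by = 0.1)
  classes <- order_of[vapply(ratios, function(r)
    classify_threshold(r * gdp, "trade_off", gdp), character(1))]
  expect_true(all(diff(classes) <= 0))
})
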