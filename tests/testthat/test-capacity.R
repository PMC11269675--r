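test_that("percentile scaling hits the documented endpoints and clamps", {
  x <- 0:100                       # Q5 = 5, Q95 = 95 by linear interpolation
  s <- percentile_scale(x)
  expect_equal(s[x == 5], 0)
  expect_equal(s[x == 95], 1)
  expect_equal(s[x == 50], 0.5)    # (50 - 5) / (95 - 5)
  expect_equal(s[x == 0], 0)       # clamped below Q5
  expect_equal(s[x == 100], 1)     # clamped above Q95
  expect_true(all(s >= 0 & s <= 1))
  inv <- percentile_scale(x, "lower_is_better")
  expect_equal(inv, 1 - s)
  expect_warning(d <- percentile_scale(rep(3, 10)), "degenerate")
  expect_equal(d, rep(0, 10))
  expect_error(percentile_scale(rep(NA_real_, 4)), "missing")
})

test_that("direction flags invert monotonically", {
  set.seed(11)
  x <- rnorm(40)
  i <- 17
  x2 <- x; x2[i] <- x2[i] + 0.5
  lo1 <- percentile_scale(x, "lower_is_better")[i]
  lo2 <- percentile_scale(x2, "lower_is_better")[i]
  expect_lte(lo2, lo1 + 1e-12)
  hi1 <- percentile_scale(x, "higher_is_better")[i]
  hi2 <- percentile_scale(x2, "higher_is_better")[i]
  expect_gte(hi2, hi1 - 1e-12)
})

test_that("indicator-table scaling respects per-column directions", {
  tab <- data.frame(region_id = c("A", "B", "C"),
                    good = c(1, 2, 3), bad = c(1, 2, 3))
  out <- scale_indicators(tab, c(good = "higher_is_better",
                                 bad = "lower_is_better"))
  expect_gt(out$good[3], out$good[1])
  expect_lt(out$bad[3], out$bad[1])
  expect_error(scale_indicators(tab, c(good = "higher_is_better")),
               "no direction")
})

test_that("capacity aggregation averages, reweights and rescales", {
  scaled <- data.frame(region_id = c("A", "B", "C"),
                       i1 = c(0.4, 0.0, 1.0), i2 = c(0.4, 0.2, 0.8),
                       i3 = c(0.4, 0.1, 0.9))
  eq <- aggregate_capacity(scaled, normalize = FALSE,
                           info = data.frame(indicator = c("i1", "i2", "i3"),
                                             dimension = "d"))
  expect_equal(eq$ac[1], 0.4)              # mean of a constant row
  # one-hot weights reproduce a single column (after rescale)
  oh <- aggregate_capacity(scaled, weights = c(i1 = 1, i2 = 0, i3 = 0),
                           info = data.frame(indicator = c("i1", "i2", "i3"),
                                             dimension = "d"))
  expect_equal(oh$ac, minmax_scale(scaled$i1))
  # two-point rescale
  two <- data.frame(region_id = c("A", "B"), i1 = c(0.3, 0.7))
  r <- aggregate_capacity(two, info = data.frame(indicator = "i1",
                                                 dimension = "d"))
  expect_equal(r$ac, c(0, 1))
  expect_error(aggregate_capacity(scaled, weights = c(1, 2)), "length")
  expect_error(aggregate_capacity(scaled, weights = c(i1 = 0, i2 = 0,
                                                      i3 = 0)), "zero")
})

test_that("equal-weight aggregation is invariant to indicator order", {
  scaled <- data.frame(region_id = c("A", "B", "C"),
                       i1 = c(0.1, 0.5, 0.9), i2 = c(0.7, 0.2, 0.4),
                       i3 = c(0.3, 0.8, 0.6))
  info <- data.frame(indicator = c("i1", "i2", "i3"), dimension = "d")
  a <- aggregate_capacity(scaled, info = info)
  b <- aggregate_capacity(scaled[, c("region_id", "i3", "i1", "i2")],
                          info = info)
  expect_equal(a$ac, b$ac)
})

test_that("AHP recovers weights exactly from consistent matrices", {
  for (n in c(3, 5, 15)) {
    set.seed(n)
    w <- rexp(n); w <- w / sum(w)
    A <- outer(w, w, `/`)
    r <- ahp_weights(A)
    expect_lt(max(abs(r$weights - w)), 1e-6)
    expect_lt(abs(r$cr), 1e-8)
    expect_equal(r$lambda_max, n, tolerance = 1e-8)
  }
  # the documented 3-weight example
  w <- c(0.5, 0.3, 0.2)
  r <- ahp_weights(outer(w, w, `/`))
  expect_equal(as.numeric(r$weights), w, tolerance = 1e-6)
})

test_that("AHP consistency ratio matches an independent eigendecomposition", {
  A <- matrix(c(1, 2, 5,
                1/2, 1, 3,
                1/5, 1/3, 1), 3, 3, byrow = TRUE)
  r <- ahp_weights(A)
  ev <- eigen(A)
  lambda_oracle <- max(Re(ev$values))
  v <- Re(ev$vectors[, which.max(Re(ev$values))])
  v <- v / sum(v)
  cr_oracle <- ((lambda_oracle - 3) / 2) / saaty_ri(3)
  expect_equal(r$lambda_max, lambda_oracle, tolerance = 1e-8)
  expect_equal(r$cr, cr_oracle, tolerance = 1e-8)
  expect_equal(as.numeric(r$weights), v, tolerance = 1e-8)
})

test_that("invalid pairwise matrices are rejected", {
  expect_error(ahp_weights(matrix(1, 2, 3)), "square")
  bad <- matrix(c(1, 2, 3, 1), 2, 2)          # not reciprocal
  expect_error(ahp_weights(bad), "reciprocal")
  neg <- matrix(c(1, -2, -1/2, 1), 2, 2)
  expect_error(ahp_weights(neg), "positive")
})

test_that("the consistency gate is strict at 10%", {
  expect_true(check_consistency(0.05))
  expect_true(check_consistency(0))
  expect_false(check_consistency(0.10))
  expect_false(check_consistency(0.2))
  expect_match(attr(check_consistency(0.2), "message"), "0.10")
})

test_that("weight concordance matches the rank-correlation oracle", {
  a <- c(0.5, 0.3, 0.2)
  expect_equal(weight_concordance(list(a, a))[1, 2], 1)
  expect_equal(weight_concordance(list(a, rev(a)))[1, 2], -1)
  set.seed(3)
  sets <- list(runif(6), runif(6), runif(6))
  M <- weight_concordance(sets)
  for (i in 1:2) for (j in (i + 1):3) {
    expect_equal(M[i, j], cor(rank(sets[[i]]), rank(sets[[j]])),
                 tolerance = 1e-12)
  }
  expect_error(weight_concordance(list(a)), ">= 2")
  expect_error(weight_concordance(list(a, c(1, 2))), "length")
})

test_that("synthetic expert matrices are reciprocal and near their true weights", {
  cfg <- small_config()
  ahp <- generate_ahp_matrices(cfg, n_experts = 3, perturb_sd = 0.05)
  for (e in 1:3) {
    A <- ahp$matrices[[e]]
    expect_lt(max(abs(A * t(A) - 1)), 1e-9)
    r <- ahp_weights(A)
    expect_true(check_consistency(r$cr))
    expect_gt(cor(as.numeric(r$weights), ahp$true_weights[e, ]), 0.95)
  }
})
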