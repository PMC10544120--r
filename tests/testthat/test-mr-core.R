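test_that("Wald ratio arithmetic, delta-method SE and guards", {
  w <- waldRatio(0.10, 0.01, 0.05, 0.01)
  expect_equal(w@theta, 0.5)
  expect_equal(w@seTheta, 0.1)
  expect_equal(w@oddsRatio, exp(0.5))
  expect_equal(w@ciLow, 0.5 - 1.959964 * 0.1)

  null <- waldRatio(0.10, 0.01, 0.00, 0.01)
  expect_equal(null@theta, 0)
  expect_equal(null@oddsRatio, 1)

  # second-order SE adds the exposure-uncertainty term
  w2 <- waldRatio(0.10, 0.01, 0.05, 0.01, secondOrder = TRUE)
  expect_equal(w2@seTheta, sqrt(0.01^2 / 0.1^2 + 0.05^2 * 0.01^2 / 0.1^4))
  expect_gt(w2@seTheta, w@seTheta)

  expect_error(waldRatio(0, 0.01, 0.05, 0.01), "betaExposure = 0")
})

test_that("IVW matches closed-form weighted sums and dispatches at J = 1", {
  h <- harmonizedSet(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.08), c(0.01, 0.02))
  e <- ivw(h, mode = "fixed")
  expect_equal(e@theta, 0.45)
  ora <- oracleIvwFixed(c(0.1, 0.2), c(0.05, 0.08), c(0.01, 0.02))
  expect_equal(e@seTheta, ora$se)

  # duplicated instrument halves the variance
  h2 <- harmonizedSet(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05), c(0.01, 0.01))
  e2 <- ivw(h2, mode = "fixed")
  expect_equal(e2@theta, 0.5)
  expect_equal(e2@seTheta, 0.1 / sqrt(2))

  h1 <- harmonizedSet(0.1, 0.01, 0.05, 0.01)
  single <- ivw(h1)
  ref <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(single@method, "wald_ratio")
  expect_equal(single@theta, ref@theta)
  expect_equal(single@seTheta, ref@seTheta)

  expect_error(ivw(harmonizedSet(c(0, 0), c(1, 1), c(0, 0), c(1, 1))),
               "zero")
})

test_that("random-effects IVW inflates the SE exactly when Q exceeds df", {
  # heterogeneous ratios: Q > J - 1, so inflation kicks in
  h <- harmonizedSet(c(1, 1), c(0.1, 0.1), c(0.4, 0.6), c(0.1, 0.1))
  fx <- ivw(h, mode = "fixed")
  re <- ivw(h, mode = "random")
  Q <- cochranQ(h)@Q
  expect_equal(re@seTheta, fx@seTheta * sqrt(Q / 1))
  expect_gte(re@seTheta, fx@seTheta)
  expect_equal(re@theta, fx@theta)

  # homogeneous ratios: Q <= J - 1, no inflation
  hHom <- harmonizedSet(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10),
                        c(0.01, 0.02))
  expect_equal(ivw(hHom, "random")@seTheta, ivw(hHom, "fixed")@seTheta)
})

test_that("IVW is invariant to per-SNP allele reorientation", {
  set.seed(21)
  for (i in 1:5) {
    J <- sample(3:8, 1)
    bx <- rnorm(J, 0.1, 0.05); by <- 0.4 * bx + rnorm(J, 0, 0.02)
    sey <- runif(J, 0.01, 0.05)
    flip <- sample(c(-1, 1), J, replace = TRUE)
    e1 <- ivw(harmonizedSet(bx, rep(0.01, J), by, sey), "fixed")
    e2 <- ivw(harmonizedSet(bx * flip, rep(0.01, J), by * flip, sey), "fixed")
    expect_equal(e2@theta, e1@theta, tolerance = 1e-12)
    expect_equal(e2@seTheta, e1@seTheta, tolerance = 1e-12)
  }
})

test_that("Cochran's Q matches the two-term hand computation", {
  hEq <- harmonizedSet(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.10),
                       c(0.01, 0.02))
  qEq <- cochranQ(hEq)
  expect_equal(qEq@Q, 0)
  expect_equal(qEq@pvalue, 1)

  # ratios 0.4 and 0.6 with ratio-SE 0.1 each: w = 100, pooled 0.5, Q = 2
  h <- harmonizedSet(c(1, 1), c(0.1, 0.1), c(0.4, 0.6), c(0.1, 0.1))
  q <- cochranQ(h)
  expect_equal(q@Q, 2)
  expect_equal(q@df, 1L)
  expect_equal(q@pvalue, pchisq(2, 1, lower.tail = FALSE))

  # quadratic growth as one ratio moves away from the pooled value
  qs <- vapply(c(0.6, 0.8, 1.0), function(r2)
    cochranQ(harmonizedSet(c(1, 1), c(0.1, 0.1), c(0.4, r2),
                           c(0.1, 0.1)))@Q, 0)
  expect_true(all(diff(qs) > 0))

  expect_error(cochranQ(harmonizedSet(0.1, 0.01, 0.05, 0.01)), "at least 2")
  expect_error(cochranQ(harmonizedSet(c(0, 0.1), c(1, 1), c(0, 0.1),
                                      c(1, 1))), "zero exposure")
})

test_that("MR-Egger interpolates exact lines and matches the WLS oracle", {
  bx <- c(0.1, 0.2, 0.3)
  by <- 0.01 + 0.5 * bx
  fit <- mrEgger(harmonizedSet(bx, rep(0.01, 3), by, rep(0.02, 3)))
  expect_equal(fit$pleiotropy@intercept, 0.01, tolerance = 1e-10)
  expect_equal(fit$estimate@theta, 0.5, tolerance = 1e-10)
  expect_equal(fit$estimate@method, "egger_slope")

  set.seed(33)
  for (i in 1:5) {
    J <- sample(5:12, 1)
    bx <- rnorm(J, 0.15, 0.08)
    by <- 0.02 + 0.4 * bx + rnorm(J, 0, 0.03)
    sey <- runif(J, 0.01, 0.06)
    fit <- mrEgger(harmonizedSet(bx, rep(0.01, J), by, sey))
    ora <- oracleEgger(bx, by, sey)
    expect_equal(fit$pleiotropy@intercept, ora$intercept, tolerance = 1e-10)
    expect_equal(fit$pleiotropy@seIntercept, ora$seIntercept, tolerance = 1e-10)
    expect_equal(fit$estimate@theta, ora$slope, tolerance = 1e-10)
    expect_equal(fit$estimate@seTheta, ora$seSlope, tolerance = 1e-10)
    expect_equal(fit$pleiotropy@pvalue,
                 2 * pt(-abs(ora$intercept / ora$seIntercept), ora$df),
                 tolerance = 1e-10)
  }
})

test_that("MR-Egger flags no pleiotropy for data through the origin", {
  set.seed(8)
  J <- 12
  bx <- runif(J, 0.05, 0.3)
  sey <- runif(J, 0.02, 0.05)
  by <- 0.5 * bx + rnorm(J, 0, sey)
  fit <- mrEgger(harmonizedSet(bx, rep(0.01, J), by, sey))
  expect_gt(fit$pleiotropy@pvalue, 0.05)
  expect_lt(abs(fit$pleiotropy@intercept), 0.05)
})

test_that("MR-Egger guards small and degenerate designs", {
  expect_error(mrEgger(harmonizedSet(c(0.1, 0.2), c(0.01, 0.01),
                                     c(0.05, 0.1), c(0.01, 0.01))),
               "at least 3")
  expect_error(mrEgger(harmonizedSet(rep(0.1, 4), rep(0.01, 4),
                                     c(0.04, 0.05, 0.06, 0.05),
                                     rep(0.01, 4))), "degenerate")
})

test_that("correlated-instrument GLS reduces to IVW at identity LD", {
  J <- 6
  set.seed(41)
  bx <- rnorm(J, 0.12, 0.04)
  by <- 0.3 * bx + rnorm(J, 0, 0.01)
  sey <- runif(J, 0.01, 0.03)
  idm <- diag(J); dimnames(idm) <- list(paste0("snp", 1:J), paste0("snp", 1:J))
  gls <- ivwCorrelated(harmonizedSet(bx, rep(0.01, J), by, sey, ld = idm))
  fx <- ivw(harmonizedSet(bx, rep(0.01, J), by, sey), "fixed")
  expect_equal(gls@theta, fx@theta, tolerance = 1e-12)
  expect_equal(gls@seTheta, fx@seTheta, tolerance = 1e-12)
})

test_that("GLS matches the explicit 2x2 matrix-inverse oracle", {
  bx <- c(0.1, 0.15); by <- c(0.05, 0.06); sey <- c(0.01, 0.02)
  rho <- matrix(c(1, 0.6, 0.6, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  gls <- ivwCorrelated(harmonizedSet(bx, c(0.01, 0.01), by, sey,
                                     variantIds = c("a", "b"), ld = rho))
  # explicit 2x2 inverse: Omega = D rho D
  O <- outer(sey, sey) * rho
  Oi <- matrix(c(O[2, 2], -O[1, 2], -O[2, 1], O[1, 1]), 2) /
    (O[1, 1] * O[2, 2] - O[1, 2] * O[2, 1])
  prec <- drop(t(bx) %*% Oi %*% bx)
  expect_equal(gls@theta, drop(t(bx) %*% Oi %*% by) / prec, tolerance = 1e-12)
  expect_equal(gls@seTheta, sqrt(1 / prec), tolerance = 1e-12)
})

test_that("a duplicated instrument at rho -> 1 adds no information", {
  rho <- matrix(c(1, 1 - 1e-12, 1 - 1e-12, 1), 2,
                dimnames = list(c("a", "b"), c("a", "b")))
  h <- harmonizedSet(c(0.1, 0.1), c(0.01, 0.01), c(0.05, 0.05),
                     c(0.01, 0.01), variantIds = c("a", "b"), ld = rho)
  gls <- ivwCorrelated(h)
  single <- waldRatio(0.1, 0.01, 0.05, 0.01)
  expect_equal(gls@seTheta, single@seTheta, tolerance = 1e-3)
  expect_error(ivwCorrelated(harmonizedSet(c(0.1, 0.1), c(0.01, 0.01),
                                           c(0.05, 0.05), c(0.01, 0.01))),
               "requires an LD matrix")
})

test_that("decrement rescaling negates, swaps bounds and guards reuse", {
  e <- ivw(harmonizedSet(c(0.1, 0.2), c(0.01, 0.01), c(0.05, 0.08),
                         c(0.01, 0.02)), "fixed")
  d <- rescalePerUnitDecrement(e, "1 mmol/L blood glucose")
  expect_equal(d@theta, -e@theta)
  expect_equal(d@ciLow, -e@ciHigh)
  expect_equal(d@ciHigh, -e@ciLow)
  expect_equal(d@oddsRatio, exp(-e@theta))
  expect_equal(d@pvalue, e@pvalue)
  expect_equal(d@scale, "per_unit_decrement")
  expect_equal(d@unitLabel, "1 mmol/L blood glucose")
  expect_error(rescalePerUnitDecrement(d), "already")

  # involution up to the guard: negating twice restores the numbers
  back <- rescalePerUnitDecrement(initialize(d, scale = "per_unit_increment"))
  expect_equal(back@theta, e@theta)
  expect_equal(back@ciLow, e@ciLow)
  expect_equal(back@oddsRatio, e@oddsRatio)

  # null effect maps to OR 1 on both scales
  null <- waldRatio(0.1, 0.01, 0, 0.01)
  expect_equal(rescalePerUnitDecrement(null)@oddsRatio, 1)
  # ln 2 per increment becomes OR 0.5 per decrement
  doubling <- waldRatio(1, 0.01, log(2), 0.01)
  expect_equal(rescalePerUnitDecrement(doubling)@oddsRatio, 0.5)
})

test_that("Bonferroni thresholds divide the family-wise level", {
  expect_equal(round(bonferroniThreshold(0.05, 3), 3), 0.017)
  expect_equal(bonferroniThreshold(0.05, 1), 0.05)
  expect_equal(bonferroniThreshold(0.10, 5), 0.02)
  expect_error(bonferroniThreshold(0, 3), "alpha")
  expect_error(bonferroniThreshold(0.05, 0), "m")
})
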