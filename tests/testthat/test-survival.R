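test_that("the Spearman filter drops redundant features deterministically", {
  set.seed(41)
  X <- matrix(rnorm(200 * 6), 200, 6,
              dimnames = list(NULL, paste0("f", 1:6)))
  X <- cbind(X, f1dup = X[, "f1"])          # rho = 1 with f1
  kept <- spearmanFilter(X, threshold = 0.9)
  expect_true("f1" %in% kept)
  expect_false("f1dup" %in% kept)

  # independent random columns all survive at 0.9
  X2 <- matrix(rnorm(200 * 30), 200, 30,
               dimnames = list(NULL, paste0("g", 1:30)))
  expect_length(spearmanFilter(X2, 0.9), 30L)

  # monotone transform is redundant under rank correlation
  X3 <- cbind(a = rnorm(100))
  X3 <- cbind(X3, b = exp(X3[, "a"]))
  expect_identical(spearmanFilter(X3, 0.9), "a")

  expect_identical(spearmanFilter(X2[, 1, drop = FALSE]), "g1")
  expect_warning(kc <- spearmanFilter(cbind(X2[, 1:2], const = 1)),
                 "constant")
  expect_identical(kc, c("g1", "g2"))
})

test_that("penalized Cox selects informative features with correct signs", {
  set.seed(42)
  n <- 150; p <- 12
  X <- matrix(rnorm(n * p), n, p, dimnames = list(NULL, paste0("f", 1:p)))
  lp <- X[, 1] - X[, 2]
  tt <- rexp(n, rate = 0.05 * exp(lp))
  cens <- runif(n, 0, quantile(tt, 0.95))
  ev <- as.integer(tt <= cens)
  fit <- fitPenalizedCox(X, pmin(tt, cens), ev, alphaGrid = c(0.5, 1),
                         seed = 7)
  expect_true(all(c("f1", "f2") %in% selectedFeatures(fit)))
  expect_gt(coef(fit)["f1"], 0)
  expect_lt(coef(fit)["f2"], 0)
  expect_true(fit@alpha %in% c(0.5, 1))

  # ridge keeps every coefficient nonzero
  fit0 <- fitPenalizedCox(X, pmin(tt, cens), ev, alphaGrid = 0, seed = 7)
  expect_length(selectedFeatures(fit0), p)
  expect_true(all(coef(fit0) != 0))

  expect_error(fitPenalizedCox(X, pmin(tt, cens), rep(0, n)), "no events")
  expect_error(fitPenalizedCox(X, rep(-1, n), ev), "positive")
})

test_that("the risk score is the linear combination of selected features", {
  X <- cbind(a = c(1, 2, 3, 4), b = c(0, 1, 0, 1))
  fit <- new("RampCoxFit", features = c("a", "b"),
             center = c(a = 2.5, b = 0.5), scale = c(a = 1, b = 1),
             selected = c("a", "b"), coefficients = c(a = 2, b = -1),
             alpha = 1, lambda = 0.1, threshold = 0,
             thresholdRule = "median", cvTable = data.frame())
  s <- rampScore(fit, X)
  expect_equal(s, 2 * (X[, "a"] - 2.5) - 1 * (X[, "b"] - 0.5))

  fit1 <- fit; fit1@selected <- "a"; fit1@coefficients <- c(a = 1)
  expect_equal(rampScore(fit1, X), X[, "a"] - 2.5, ignore_attr = TRUE)

  fit0 <- fit; fit0@selected <- character(0)
  fit0@coefficients <- setNames(numeric(0), character(0))
  expect_equal(rampScore(fit0, X), rep(0, 4))
  expect_error(rampScore(fit, X[, "a", drop = FALSE]), "absent")
})

test_that("dichotomization applies the frozen threshold monotonically", {
  s <- c(-2, -1, 0, 1, 2, 3)
  g <- dichotomize(s, median(s))
  expect_equal(as.vector(table(g)), c(3, 3))
  expect_identical(levels(g), c("low", "high"))
  expect_warning(dichotomize(rep(1, 5), 2), "single risk group")
  expect_warning(gShift <- dichotomize(s + 10, median(s)), "single")
  expect_true(all(gShift == "high"))
})

test_that("Kaplan-Meier estimates match the hand-computed product limit", {
  res <- kmLogrank(c(1, 2, 3), c(1, 1, 0), factor(rep("all", 3)))
  surv <- res$km$survival[match(c(1, 2), res$km$time)]
  expect_equal(surv, c(2 / 3, 1 / 3))
  expect_true(all(diff(res$km$survival) <= 1e-12))

  # identical groups: statistic 0, p = 1
  tt <- c(2, 4, 6, 8, 10); ev <- c(1, 0, 1, 1, 0)
  res2 <- kmLogrank(c(tt, tt), c(ev, ev), factor(rep(c("a", "b"), each = 5)))
  expect_equal(res2$chisq, 0, tolerance = 1e-12)
  expect_equal(res2$p, 1, tolerance = 1e-12)

  expect_error(kmLogrank(tt, ev, factor(rep("a", 5), levels = c("a", "b"))),
               "at least one subject")
})

test_that("the log-rank p agrees with a permutation oracle", {
  set.seed(43)
  n <- 60
  grp <- factor(rep(c("low", "high"), each = n / 2))
  tt <- rexp(n, rate = ifelse(grp == "high", 0.09, 0.04))
  cens <- runif(n, 0, 30)
  ev <- as.integer(tt <= cens)
  time <- pmin(tt, cens)
  res <- kmLogrank(time, ev, grp)
  obs <- logrankStat(time, ev, grp)
  expect_equal(res$chisq, obs, tolerance = 0.02)
  B <- 2000
  perm <- vapply(seq_len(B), function(i)
    logrankStat(time, ev, sample(grp)), numeric(1))
  pPerm <- (1 + sum(perm >= obs)) / (B + 1)
  mcSd <- sqrt(pPerm * (1 - pPerm) / B)
  expect_lt(abs(res$p - pPerm), 4 * mcSd + 0.01)
})

test_that("concordance equals exhaustive pair enumeration", {
  # perfectly ordered scores, no censoring
  tt <- c(8, 7, 6, 5, 4, 3, 2, 1)
  sc <- 1:8
  # perfect separation: coxph reports a divergent group coefficient, which
  # is expected on this fixture
  m <- suppressWarnings(
    survivalMetrics(tt, rep(1, 8), sc, dichotomize(sc, 4.5)))
  expect_equal(m$cindex, 1)
  mAnti <- suppressWarnings(
    survivalMetrics(tt, rep(1, 8), rev(sc), dichotomize(rev(sc), 4.5)))
  expect_equal(mAnti$cindex, 0)

  set.seed(44)
  tt2 <- sample(seq(1, 40, length.out = 8))
  ev2 <- c(1, 1, 0, 1, 0, 1, 1, 0)
  sc2 <- rnorm(8)
  m2 <- survivalMetrics(tt2, ev2, sc2, dichotomize(sc2, median(sc2)))
  expect_equal(m2$cindex, bruteCindex(tt2, ev2, sc2), tolerance = 1e-12)
})

test_that("hazard ratios come from the Efron Cox fit on the group indicator", {
  set.seed(45)
  n <- 80
  grp <- factor(rep(c("low", "high"), each = n / 2),
                levels = c("low", "high"))
  tt <- rexp(n, ifelse(grp == "high", 0.12, 0.04))
  ev <- rep(1L, n)
  sc <- as.numeric(grp == "high") + rnorm(n, sd = 0.1)
  m <- survivalMetrics(tt, ev, sc, grp)
  cx <- survival::coxph(survival::Surv(tt, ev) ~ I(grp == "high"),
                        ties = "efron")
  expect_equal(m$hr, exp(coef(cx))[[1]], tolerance = 1e-9)
  expect_lt(m$ci[1], m$hr)
  expect_gt(m$ci[2], m$hr)
  # a group without events leaves the HR undefined
  ev0 <- ifelse(grp == "high", 1L, 0L)
  m0 <- survivalMetrics(tt, ev0, sc, grp)
  expect_true(is.na(m0$hr))
})

test_that("association tests follow the McNemar and chi-square formulas", {
  # b = c: statistic 0, exact p = 1
  ramp <- factor(c(rep("high", 10), rep("low", 10)))
  chang <- factor(c(rep("high", 5), rep("low", 5), rep("high", 5),
                    rep("low", 5)))
  at <- associationTests(ramp, chang)
  expect_equal(at$mcnemar$statistic, 0)
  expect_equal(at$mcnemar$p, 1)

  # b = 10, c = 2 -> (b-c)^2/(b+c) = 64/12; exact binomial p (b+c < 25)
  ramp2 <- factor(c(rep("high", 12), rep("low", 12)),
                  levels = c("high", "low"))
  chang2 <- factor(c(rep("low", 10), rep("high", 2), rep("high", 2),
                     rep("low", 10)), levels = c("high", "low"))
  at2 <- associationTests(ramp2, chang2)
  expect_equal(at2$mcnemar$statistic, 64 / 12, tolerance = 1e-12)
  expect_true(at2$mcnemar$exact)
  expect_equal(at2$mcnemar$p, binom.test(10, 12, 0.5)$p.value)

  # independent simulated labels: chi-square p not extreme
  set.seed(46)
  a <- factor(sample(c("high", "low"), 500, replace = TRUE))
  b <- factor(sample(c("WNT", "SHH", "G3", "G4"), 500, replace = TRUE))
  at3 <- associationTests(a, b)
  expect_gt(at3$chisq$p, 0.01)
  expect_equal(at3$chisq$df, 3)
})
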