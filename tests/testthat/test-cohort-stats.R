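test_that("Mann-Whitney U matches the brute-force pairwise count", {
  r <- mannWhitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$U, 0)
  same <- mannWhitney(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p, 1, tolerance = 0.01)

  set.seed(19)
  for (i in 1:20) {
    a <- sample(1:6, 4, replace = TRUE)
    b <- sample(1:6, 4, replace = TRUE)
    wins <- sum(outer(a, b, `>`)) + 0.5 * sum(outer(a, b, `==`))
    expect_equal(mannWhitney(a, b)$U, wins)
  }
  expect_error(mannWhitney(numeric(0), 1:3), "empty")
})

test_that("Mann-Whitney is invariant to monotone transforms", {
  set.seed(23)
  a <- rnorm(12); b <- rnorm(10, 0.5)
  r1 <- mannWhitney(a, b)
  r2 <- mannWhitney(exp(a), exp(b))
  expect_equal(r1$U, r2$U)
  expect_equal(r1$p, r2$p)
  expect_equal(r1$U + mannWhitney(b, a)$U, 12 * 10)
})

test_that("Pearson chi-square on 2x2 tables without correction", {
  r <- chiSquare2x2(matrix(c(10, 7, 3, 17), 2))
  expect_equal(r$chi2, 7.7436, tolerance = 1e-4)
  expect_lt(abs(r$p - 0.0054), 1e-4)
  expect_equal(chiSquare2x2(matrix(5, 2, 2))$chi2, 0)
  expect_equal(chiSquare2x2(matrix(5, 2, 2))$p, 1)
  expect_equal(chiSquare2x2(matrix(c(2, 0, 0, 2), 2))$chi2, 4)
  expect_error(chiSquare2x2(matrix(c(1, 1, 0, 0), 2)), "margin")
})

test_that("Kaplan-Meier matches hand product-limit computations", {
  km <- kaplanMeier(c(1, 2, 3), c(1, 1, 1))
  expect_equal(km$surv, c(2 / 3, 1 / 3, 0))

  cen <- kaplanMeier(c(1, 2, 3), c(0, 0, 0))
  expect_true(all(cen$surv == 1))

  # 5 subjects: event 1, censored 2, event 3, censored 4, event 5
  km5 <- kaplanMeier(c(1, 2, 3, 4, 5), c(1, 0, 1, 0, 1))
  ev <- km5[km5$nEvent > 0, ]
  expect_equal(ev$surv, c(4 / 5, 4 / 5 * 2 / 3, 0))
})

test_that("KM without censoring equals one minus the empirical CDF", {
  set.seed(29)
  t <- round(rexp(40, 0.1) + 0.5, 1)
  km <- kaplanMeier(t, rep(1, 40))
  for (i in seq_len(nrow(km)))
    expect_equal(km$surv[i], mean(t > km$time[i]))
})

test_that("log-rank test behaves across null, separated and hand cases", {
  set.seed(31)
  tA <- rexp(20, 0.1)
  r0 <- logrank(tA, rep(1, 20), tA, rep(1, 20))
  expect_lt(r0$chi2, 1e-10)
  expect_equal(r0$p, 1, tolerance = 1e-6)

  sep <- logrank(1:20, rep(1, 20), 21:40, rep(1, 20))
  expect_lt(sep$p, 0.01)

  # symmetry in group order
  tB <- rexp(15, 0.2)
  eB <- rbinom(15, 1, 0.7); eA <- rbinom(20, 1, 0.7)
  expect_equal(logrank(tA, eA, tB, eB)$chi2,
               logrank(tB, eB, tA, eA)$chi2, tolerance = 1e-12)

  # direct O-E/V computation on a 6-subject example
  tm <- c(1, 2, 3, 4, 5, 6); ev <- c(1, 1, 0, 1, 1, 1)
  gr <- c(0, 1, 0, 1, 0, 1)
  o <- e <- v <- 0
  for (u in sort(unique(tm[ev == 1]))) {
    at <- tm >= u
    d <- sum(ev == 1 & tm == u)
    n <- sum(at); n1 <- sum(at & gr == 1)
    d1 <- sum(ev == 1 & tm == u & gr == 1)
    o <- o + d1; e <- e + d * n1 / n
    if (n > 1) v <- v + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  hand <- (o - e)^2 / v
  got <- logrank(tm[gr == 0], ev[gr == 0], tm[gr == 1], ev[gr == 1])
  expect_equal(got$chi2, hand, tolerance = 1e-10)

  expect_error(logrank(tA, rep(0, 20), tB, rep(0, 15)), "no events")
})

test_that("the cutpoint scan finds the separating threshold", {
  # survival perfectly separated at marker value 90
  set.seed(8)
  val <- c(runif(15, 50, 88), runif(15, 92, 100))
  tm <- c(rexp(15, 1 / 3) + 0.2, rexp(15, 1 / 60) + 10)
  ev <- rep(1, 30)
  cp <- optimalCutpoint(val, tm, ev, minGroupFrac = 0.1)
  expect_gt(cp$threshold, max(val[val < 90]))
  expect_lte(cp$threshold, min(val[val > 90]))
  expect_true(cp$pUncorrected)
  expect_error(optimalCutpoint(rep(5, 10), tm[1:10], ev[1:10]),
               "distinct")
})

test_that("the cutpoint scan is exhaustive (brute force, small cohorts)", {
  set.seed(37)
  for (rep in 1:5) {
    n <- sample(8:15, 1)
    val <- round(runif(n, 0, 100), 1)
    tm <- rexp(n, 0.1) + 0.1
    ev <- rbinom(n, 1, 0.8)
    if (sum(ev) == 0) ev[1] <- 1
    cp <- tryCatch(optimalCutpoint(val, tm, ev, minGroupFrac = 0.1),
                   error = function(e) NULL)
    if (is.null(cp)) next
    u <- sort(unique(val))
    thr <- (u[-length(u)] + u[-1]) / 2
    for (th in thr) {
      lo <- val <= th
      if (sum(lo) < 0.1 * n || sum(!lo) < 0.1 * n) next
      lr <- tryCatch(logrank(tm[lo], ev[lo], tm[!lo], ev[!lo]),
                     error = function(e) NULL)
      if (!is.null(lr)) expect_lte(lr$chi2, cp$chi2 + 1e-12)
    }
  }
})

test_that("the cohort summary reproduces the published medians", {
  co <- fetCohort()
  s <- idh1Summary(co)
  ttp <- s[s$variable == "ttp_min", ]
  expect_equal(ttp$median_all, 25)
  expect_equal(c(ttp$q25_all, ttp$q75_all), c(15, 45))
  sl <- s[s$variable == "slope_suv_h", ]
  expect_equal(sl$median_all, -0.08)
  expect_equal(c(sl$q25_all, sl$q75_all), c(-0.66, 0.34))
  tb <- s[s$variable == "tbr_mean", ]
  expect_equal(tb$median_all, 2.1)
  expect_true(all(s$p < 0.2))

  one <- co[5, ]
  s1 <- idh1Summary(one)
  expect_equal(s1[s1$variable == "ttp_min", "median_all"], one$ttp_min)
  expect_error(idh1Summary(co[, c("id", "idh1_mutant")]), "missing")
})
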