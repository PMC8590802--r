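test_that("residency filter drops sparse and dispersing individuals", {
  tel <- scape_points(id = paste0("f", 1:92),
                      x = runif(92, 0, 1000), y = runif(92, 0, 1000),
                      role = "telemetry",
                      individual_id = rep(c("a", "b", "c"), c(30, 31, 31)))
  out <- filter_individuals(tel, min_fixes = 30)
  # 30 fixes is not enough (>30 required); 31 is kept
  expect_setequal(unique(out$individual_id), c("b", "c"))
  rem <- attr(out, "removals")
  expect_equal(rem$individual_id, "a")

  # disperser exclusion plus count conservation
  out2 <- filter_individuals(tel, min_fixes = 30, exclude = "c")
  expect_equal(unique(out2$individual_id), "b")
  expect_equal(nrow(attr(out2, "removals")) +
                 length(unique(out2$individual_id)), 3L)

  # no-op when everything passes
  out3 <- filter_individuals(tel, min_fixes = 10)
  expect_equal(nrow(out3), 92L)
  expect_error(filter_individuals(tel, min_fixes = 1000), "no individuals")
})

test_that("KDE isopleth matches the analytic Gaussian contour", {
  # single fix with bandwidth h: the 95% isopleth of a symmetric bivariate
  # normal is a disc of radius sqrt(qchisq(.95, 2)) * h = 2.4477 h
  hr <- kde_home_range(data.frame(x = 0, y = 0), bandwidth = 100,
                       grid_n = 300)
  expect_equal(hr$area_km2, pi * (sqrt(qchisq(0.95, 2)) * 0.1)^2,
               tolerance = 0.01)
  # isopleth mass overshoots 0.95 by at most one cell's mass
  expect_gte(hr$iso_mass, 0.95)
  expect_lt(hr$iso_mass - 0.95, max(grid_values(hr$density)) *
              hr$mask$cellsize^2)

  set.seed(51)
  fx <- data.frame(x = rnorm(60, 0, 400), y = rnorm(60, 0, 250))
  h1 <- kde_home_range(fx)
  # translation invariance
  h2 <- kde_home_range(transform(fx, x = x + 1e4, y = y - 5e3))
  expect_equal(h1$area_km2, h2$area_km2, tolerance = 1e-12)
  # doubling coordinates quadruples area
  h4 <- kde_home_range(transform(fx, x = 2 * x, y = 2 * y))
  expect_equal(h4$area_km2 / h1$area_km2, 4, tolerance = 1e-6)

  expect_error(kde_home_range(data.frame(x = rep(1, 10), y = rep(2, 10))),
               "bandwidth")
})

test_that("Kruskal-Wallis wrapper reproduces rank arithmetic", {
  # hand computation: ranks {1,2,3} vs {4,5,6} -> H = 3.857 (df 1)
  kw <- kruskal_wallis(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
  expect_equal(kw$H, 12 / (6 * 7) * (36 / 3 + 225 / 3) - 3 * 7,
               tolerance = 1e-10)
  expect_equal(kw$H, 3.857, tolerance = 1e-3)
  expect_equal(kw$df, 1)

  # identical groups -> H = 0 (up to ties); monotone-transform invariance
  expect_lt(kruskal_wallis(c(1, 2, 3, 1, 2, 3),
                           rep(c("a", "b"), each = 3))$H, 1e-10)
  set.seed(52)
  v <- rnorm(20); gidx <- rep(c("a", "b"), 10)
  expect_equal(kruskal_wallis(v, gidx)$H, kruskal_wallis(exp(v), gidx)$H,
               tolerance = 1e-12)
  expect_error(kruskal_wallis(1:5, rep("a", 5)), "2 groups")
})

test_that("chi-square p agrees with a permutation oracle", {
  hrtab <- synthetic_homeranges()
  kw <- kruskal_wallis(hrtab$area_km2, hrtab$sex)
  r <- rank(hrtab$area_km2)
  n1 <- sum(hrtab$sex == "F"); n <- length(r)
  Hperm <- replicate(1e5, {
    rf <- sum(r[sample.int(n, n1)])
    12 / (n * (n + 1)) * (rf^2 / n1 + (sum(r) - rf)^2 / (n - n1)) -
      3 * (n + 1)
  })
  p_perm <- mean(Hperm >= kw$H - 1e-12)
  expect_equal(kw$p, p_perm, tolerance = 0.02)
})

test_that("availability samples stay inside the isopleth and match counts", {
  set.seed(53)
  fx <- data.frame(x = rnorm(80, 0, 300), y = rnorm(80, 0, 300))
  hr <- kde_home_range(fx)
  av <- sample_availability(hr, 80, seed = 4)
  expect_equal(nrow(av), 80L)
  expect_true(all(extract_at(hr$mask, av$x, av$y) == 1))
  av2 <- sample_availability(hr, 80, seed = 4)
  expect_identical(av$x, av2$x)
})

test_that("weighted RSF estimates respect the weighting algebra", {
  set.seed(54)
  n <- 400
  d <- data.frame(use = rep(c(1, 0), each = n / 2),
                  a = rnorm(n), b = rnorm(n),
                  individual_id = rep(c("i1", "i2", "i3", "i4"), n / 4))
  # equal weights reproduce the unweighted fit
  f_w <- selscape:::fit_rsf_data(d, c("a", "b"), rep(2, n),
                                 "exponential_RSF", "none")
  f_u <- selscape:::fit_rsf_data(d, c("a", "b"), rep(1, n),
                                 "exponential_RSF", "none")
  expect_equal(f_w$coef, f_u$coef, tolerance = 1e-10)

  # duplicating one individual's rows while halving its weights is a no-op
  pick <- d$individual_id == "i1"
  d2 <- rbind(d, d[pick, ])
  w2 <- c(ifelse(pick, 0.5, 1), rep(0.5, sum(pick)))
  f_dup <- selscape:::fit_rsf_data(d2, c("a", "b"), w2,
                                   "exponential_RSF", "none")
  expect_equal(f_dup$coef, f_u$coef, tolerance = 1e-8)

  # covariate identical at used and available points -> beta ~ 0
  d3 <- d; d3$a <- rep(rnorm(n / 2), 2)[order(rep(1:2, n / 2))]
  d3$a <- rnorm(n); d3$a[d3$use == 1] <- d3$a[d3$use == 0]
  f0 <- selscape:::fit_rsf_data(d3, "a", rep(1, n), "exponential_RSF", "none")
  expect_lt(abs(f0$coef["a"]), 3 * f0$se["a"])
})

test_that("distribution weighting balances individuals in the fit", {
  w <- small_world(nrow = 60, ncol = 60)
  tm <- names(w$stack$layers)[1]
  truth <- truth_model(setNames(1, tm), ind_beta = setNames(1, tm),
                       hr_sigma = 300)
  tel <- generate_telemetry(w$stack, truth, 5, c(40, 40, 40, 40, 200),
                            seed = 6)
  ids <- unique(tel$individual_id)
  avail <- do.call(rbind, lapply(ids, function(i) {
    fx <- tel[tel$individual_id == i, ]
    hr <- kde_home_range(fx, grid_n = 80)
    av <- sample_availability(hr, nrow(fx), seed = match(i, ids))
    av$id <- paste0(av$id, "_", i)
    av$individual_id <- i
    av
  }))
  fit <- fit_weighted_rsf(tel, avail, w$stack, terms = tm,
                          weighting = "distribution")
  expect_s3_class(fit, "rsf_fit")
  # every animal contributes equal total weight
  expect_equal(fit$weighting, "distribution")
  wts <- fit$fit$prior.weights
  byind <- tapply(wts, fit$fit$data$individual_id, sum)
  expect_equal(max(byind) / min(byind), 1, tolerance = 1e-9)
  # an individual lacking availability is an error
  expect_error(fit_weighted_rsf(tel, avail[avail$individual_id != ids[1], ],
                                w$stack, terms = tm), "lacking available")
})

test_that("CAIC prefers parsimony and exceeds AIC beyond n = 8", {
  expect_equal(caic(-50, 3, 100), 100 + 3 * (log(100) + 1))
  # equal LL: smaller k wins; equal k: larger LL wins
  f1 <- structure(list(LL = -50, k = 2, n = 100,
                       CAIC = caic(-50, 2, 100), form = "exponential_RSF"),
                  class = "rsf_fit")
  f2 <- structure(list(LL = -50, k = 4, n = 100,
                       CAIC = caic(-50, 4, 100), form = "logistic_RSPF"),
                  class = "rsf_fit")
  expect_equal(compare_forms(list(lean = f1, rich = f2))$choice, "lean")
  f3 <- structure(list(LL = -40, k = 2, n = 100,
                       CAIC = caic(-40, 2, 100), form = "logistic_RSPF"),
                  class = "rsf_fit")
  expect_equal(compare_forms(list(worse = f1, better = f3))$choice, "better")
  # CAIC > AIC whenever ln n + 1 > 2, i.e. n >= 8
  for (n in c(8, 20, 1000))
    expect_gt(caic(-50, 3, n), -2 * -50 + 2 * 3)
  f4 <- structure(list(LL = -40, k = 2, n = 50, CAIC = 1,
                       form = "exponential_RSF"), class = "rsf_fit")
  expect_error(compare_forms(list(a = f1, b = f4)), "same data")
})

test_that("RSS use curves are flat under the null and monotone under selection", {
  set.seed(55)
  n <- 300
  d <- data.frame(use = rep(c(1, 0), each = n / 2), a = rnorm(n))
  # beta = 0: fitted values constant
  d0 <- d; d0$a[d0$use == 1] <- d0$a[d0$use == 0]
  f0 <- selscape:::fit_rsf_data(d0, "a", rep(1, n), "exponential_RSF", "none")
  cv0 <- rss_use_curve(f0, d0[d0$use == 0, , drop = FALSE], "a")
  expect_lt(diff(range(cv0$fitted)), 0.1)

  # monotone positive selection -> nondecreasing smooth (50 random fits)
  bad <- 0
  for (r in 1:50) {
    a <- rnorm(n)
    b <- runif(1, 0.5, 2)
    use <- rbinom(n, 1, plogis(-0.5 + b * a))
    if (length(unique(use)) < 2) next
    dd <- data.frame(use = use, a = a)
    ff <- selscape:::fit_rsf_data(dd, "a", rep(1, n), "exponential_RSF",
                                  "none")
    cv <- rss_use_curve(ff, dd, "a")
    sm <- cv$smooth[!is.na(cv$smooth)]
    if (any(diff(sm) < -1e-6 * diff(range(sm)))) bad <- bad + 1
  }
  expect_equal(bad, 0)

  expect_error(rss_use_curve(f0, d0[0:3, ], "zz"), "absent")
})
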