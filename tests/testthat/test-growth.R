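# Brute-force oracle for window selection: enumerate every contiguous window,
# apply the same admissibility/ranking rule with plain lm() fits.
brute_force_window <- function(time, od, thr = 0.98, mp = 4L) {
  keep <- od > 0
  time <- time[keep]; lod <- log(od[keep])
  n <- length(time)
  cand <- expand.grid(i = 1:n, j = 1:n)
  cand <- cand[cand$j - cand$i + 1 >= mp, ]
  cand$r2 <- mapply(function(i, j) {
    summary(stats::lm(lod[i:j] ~ time[i:j]))$r.squared
  }, cand$i, cand$j)
  adm <- cand[cand$r2 >= thr, ]
  if (!nrow(adm)) return(NULL)
  adm <- adm[order(-adm$r2, -(adm$j - adm$i), adm$i), ]
  c(t_start = time[adm$i[1]], t_end = time[adm$j[1]])
}

test_that("exact exponential data recover mu to numerical tolerance", {
  s <- data.frame(time = 0:3, mean = 0.1 * 2^(0:3))
  fit <- fit_growth_rate(s, window = c(0, 3))
  expect_equal(fit$mu, log(2), tolerance = 1e-12)
  expect_equal(fit$r_squared, 1)
  # window choice is irrelevant on noise-free exponential data
  s10 <- data.frame(time = 0:10, mean = 0.05 * exp(0.69 * (0:10)))
  for (w in list(c(0, 10), c(2, 7), NULL)) {
    expect_equal(fit_growth_rate(s10, window = w)$mu, 0.69, tolerance = 1e-10)
  }
})

test_that("constant OD yields mu 0 and r_squared reported as 0", {
  s <- data.frame(time = 0:5, mean = rep(2, 6))
  fit <- suppressWarnings(fit_growth_rate(s))
  expect_equal(fit$mu, 0)
  expect_equal(fit$r_squared, 0)
  expect_true(fit$fallback)
})

test_that("auto window matches brute-force enumeration and excludes plateaus", {
  withr::local_seed(101)
  for (rep in 1:5) {
    mu <- runif(1, 0.3, 0.8)
    od <- pmin(0.2 * exp(mu * seq(0, 12, 0.5)), runif(1, 3, 6)) *
      (1 + rnorm(25, 0, 0.03))
    s <- data.frame(time = seq(0, 12, 0.5), mean = od)
    w <- auto_window(s)
    bf <- brute_force_window(s$time, s$mean)
    expect_equal(c(w$t_start, w$t_end), unname(bf), info = paste("rep", rep))
  }
  # noise-free plateau: chosen window stops before the cap
  s <- data.frame(time = 0:9, mean = pmin(0.1 * exp(0.5 * 0:9), 1.5))
  w <- auto_window(s)
  expect_lte(w$t_end, 5.5)
  expect_equal(fit_growth_rate(s)$mu, 0.5, tolerance = 1e-10)
})

test_that("short or degenerate series raise errors", {
  expect_error(auto_window(data.frame(time = 0:2, mean = c(1, 2, 4))),
               "at least 4")
  expect_error(fit_growth_rate(data.frame(time = 0:3, mean = c(1, 2, 0, 4)),
                               window = c(0, 3)), "negative OD")
  expect_error(fit_growth_rate(data.frame(time = 0:3, mean = c(1, 2, 4, 8)),
                               window = c(0, 0.5)), "fewer than 3")
})

test_that("od_final is the maximum of the mean series, not the endpoint", {
  od <- c(0.1, 0.4, 1.6, 4.8, 5.1, 4.9, 4.6)
  fit <- fit_growth_rate(data.frame(time = 0:6, mean = od), window = c(0, 3))
  expect_equal(fit$od_final, 5.1)
})

test_that("generating growth rate is recovered from noisy courses", {
  # single course at the reference condition
  tc <- simulate_growth_course(mu = 0.69, od0 = 0.25, od_max = 5.05,
                               noise_cv = 0.05, seed = 7)
  expect_lt(abs(fit_growth_rate(tc)$mu - 0.69), 0.05)
  # small-scale recovery sweep (the full 200-course sweep runs in acceptance)
  errs <- vapply(1:40, function(s) {
    tc <- simulate_growth_course(mu = 0.3, od0 = 0.25, od_max = 5.05,
                                 noise_cv = 0.05, seed = s)
    fit_growth_rate(tc)$mu - 0.3
  }, numeric(1))
  expect_lt(median(abs(errs)), 0.03)
})

test_that("per-replicate fits give a mu SEM consistent with the mean fit", {
  tc <- simulate_growth_course(mu = 0.69, od0 = 0.25, od_max = 5.05,
                               noise_cv = 0.05, seed = 3)
  pr <- fit_growth_rate_replicates(tc)
  expect_equal(nrow(pr), 3L)
  expect_lt(abs(attr(pr, "mu_mean") - 0.69), 0.1)
  expect_gt(attr(pr, "mu_sem"), 0)
})

test_that("growth_fit methods expose coefficients and predictions", {
  s <- data.frame(time = 0:5, mean = 0.2 * exp(0.4 * 0:5))
  fit <- fit_growth_rate(s)
  expect_equal(unname(coef(fit)), c(0.4, log(0.2)), tolerance = 1e-10)
  expect_equal(predict(fit, time = c(0, 5)), s$mean[c(1, 6)],
               tolerance = 1e-10)
  expect_output(print(fit), "mu")
  expect_named(summary(fit),
               c("mu", "od_final", "r_squared", "t_start", "t_end"))
})
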