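make_fake_fit <- function(chains, area_km2 = 1941, M = 50) {
  # minimal rtscr_fit shim holding given per-chain draw tables
  structure(list(model = "rtscr", chains = chains,
                 latent = vector("list", length(chains)),
                 area_km2 = area_km2, M = M,
                 n_id = 0, constraint_ok = TRUE),
            class = "rtscr_fit")
}

fake_chain <- function(n, lambda0, sigma, theta, psi, N, area = 1941) {
  data.frame(lambda0 = lambda0, sigma = sigma, theta = theta, psi = psi,
             N = N, D = 100 * N / area,
             iteration = seq_len(n), chain = 1)
}

test_that("summarize_fit computes density and moment summaries correctly", {
  # constant draws N = 25 over a 1941-km2 space: D = 1.288, rounding to 1.29
  ch <- replicate(2, fake_chain(50, 0.047, 3050, 0.87, 0.5, rep(25, 50)),
                  simplify = FALSE)
  s <- suppressWarnings(summarize_fit(make_fake_fit(ch)))
  expect_equal(s$table["D", "estimate"], 100 * 25 / 1941)
  expect_equal(round(s$table["D", "estimate"], 2), 1.29)
  expect_equal(s$table["D", "lower"], s$table["D", "upper"])  # degenerate CRI
  expect_equal(s$table["N", "cv"], 0)  # constant draws
  expect_equal(s$table["N", "estimate"], 25)

  # synthetic draw table with known moments
  set.seed(8)
  x <- rnorm(4000, 10, 2)
  ch2 <- list(fake_chain(2000, x[1:2000], 3000, 0.9, 0.5, 25),
              fake_chain(2000, x[2001:4000], 3000, 0.9, 0.5, 25))
  s2 <- suppressWarnings(summarize_fit(make_fake_fit(ch2)))
  expect_equal(s2$table["lambda0", "mean"], mean(x))
  expect_equal(s2$table["lambda0", "sd"], sd(x))
  expect_equal(s2$table["lambda0", "lower"],
               unname(quantile(x, 0.025)))
  expect_equal(s2$table["lambda0", "upper"],
               unname(quantile(x, 0.975)))
  expect_equal(s2$table["lambda0", "cv"], sd(x) / mean(x))
  # point estimate is the mean for detection parameters, the median for N, D
  expect_equal(s2$table["lambda0", "estimate"], mean(x))
  expect_equal(s2$table["N", "estimate"], 25)
  # CV of D is invariant to the area used
  s3 <- suppressWarnings(summarize_fit(make_fake_fit(ch2), area_km2 = 500))
  expect_equal(s3$table["D", "cv"], s2$table["D", "cv"])
})

test_that("Gelman-Rubin diagnostic matches a hand-computed value", {
  # 2 chains x 5 printed values, frozen arithmetic:
  # chain means 3, 5; W = (2.5 + 2.5)/2 = 2.5; B/n = var(c(3,5)) = 2
  # s2 = 4/5*2.5 + 2 = 4; Rhat = sqrt(3/2 * 4/2.5 - 4/10) = sqrt(2)
  c1 <- c(1, 2, 3, 4, 5)
  c2 <- c(3, 4, 5, 6, 7)
  expect_error(gelman_rubin(list(c1, c2)), "at least 10")
  c1 <- rep(c1, 2); c2 <- rep(c2, 2)  # n = 10, same means/variances? no:
  # recompute the frozen value for the replicated vectors directly
  n <- 10; W <- (var(c1) + var(c2)) / 2; B_n <- var(c(mean(c1), mean(c2)))
  expected <- sqrt(3 / 2 * ((n - 1) / n * W + B_n) / W - (n - 1) / (2 * n))
  expect_equal(gelman_rubin(list(c1, c2)), expected)

  # two long streams from the same normal: Rhat near 1
  set.seed(5)
  a <- rnorm(10000); b <- rnorm(10000)
  expect_lt(gelman_rubin(list(a, b)), 1.01)
  expect_gt(gelman_rubin(list(a, b)), 0.99)

  # well-separated chains: Rhat far above the 1.1 convergence rule
  expect_gt(gelman_rubin(list(a, b + 10)), 5)

  # agreement with the coda implementation on well-behaved chains
  skip_if_not_installed("coda")
  psrf <- unname(coda::gelman.diag(coda::mcmc.list(coda::mcmc(a),
                                                   coda::mcmc(b)),
                                   autoburnin = FALSE)$psrf[1, 1])
  expect_equal(gelman_rubin(list(a, b)), psrf, tolerance = 0.001)

  expect_error(gelman_rubin(list(a)), "two chains")
  expect_warning(r <- gelman_rubin(list(rep(1, 20), rep(1, 20))),
                 "undefined")
  expect_true(is.na(r))
})

test_that("home-range transform follows the bivariate-normal identity", {
  # point transform of sigma = 3.05 km: pi (2.447746 * 3.05)^2 km2 in ha
  hr <- home_range_from_sigma(3050)
  expect_equal(hr$mean, pi * (2.447746 * 3.05)^2 * 100)
  expect_equal(hr$mean, 17509.8, tolerance = 1e-4)
  # inverse identity: sigma = 1/(q sqrt(pi)) km gives exactly 1 km2 = 100 ha
  q <- 2.447746
  expect_equal(home_range_from_sigma(1000 / (q * sqrt(pi)))$mean, 100)
  # doubling sigma quadruples the area; transform strictly increasing
  expect_equal(home_range_from_sigma(2000)$mean,
               4 * home_range_from_sigma(1000)$mean)
  sig <- seq(500, 5000, by = 500)
  hrs <- vapply(sig, function(s) home_range_from_sigma(s)$mean, numeric(1))
  expect_true(all(diff(hrs) > 0))
  # posterior-mean transform on draws, with equal-tailed CRI
  set.seed(2)
  draws <- exp(rnorm(5000, log(3000), 0.1))
  hr2 <- home_range_from_sigma(draws)
  expect_equal(hr2$mean, mean(pi * (q * draws)^2 / 1e4))
  expect_equal(c(hr2$lower, hr2$upper),
               unname(quantile(pi * (q * draws)^2 / 1e4, c(0.025, 0.975))))
  expect_error(home_range_from_sigma(c(1000, -5)), "positive")
})

test_that("activity-center surface conserves posterior abundance", {
  qf <- quick_fit(seed = 601, n_iter = 3000, n_burnin = 1000, M = 40)
  surf <- activity_center_surface(qf$fit, cell_size = 2000)
  expect_true(all(surf$value >= 0))
  expect_equal(sum(surf$value), mean(posterior_draws(qf$fit)$N),
               tolerance = 1e-10)
  df <- as.data.frame(surf)
  expect_equal(sum(df$value), sum(surf$value))
  path <- tempfile(fileext = ".csv")
  write_ac_surface(surf, path)
  expect_equal(sum(read.csv(path)$value), sum(surf$value))
  expect_error(activity_center_surface(qf$fit, cell_size = 1e6),
               "larger than")
})

test_that("a flat posterior yields an approximately uniform surface", {
  # no data, rate pinned to zero: activity centers stay uniform
  traps <- tiny_traps(K = 2)
  ss <- build_state_space(traps, 4500)  # 10.0 x 10.0 km square
  cap <- capture_data(array(0L, c(0, 4, 2)), matrix(0L, 4, 2), character(0))
  ds <- scr_dataset(traps, cap, ss)
  # thinned enough that retained center positions are near-independent
  fit <- suppressWarnings(fit_rtscr(
    ds, config = mcmc_config(n_chains = 1, n_iter = 126000, n_burnin = 1000,
                             thin = 25, M = 2, seed = 31),
    fixed = list(lambda0 = 1e-12, sigma = 1000, theta = 0.5, psi = 1)))
  surf <- activity_center_surface(fit, cell_size = 2500)
  expect_equal(dim(surf$value), c(4, 4))
  # chi-square uniformity on the 16 cells at alpha = 0.01
  n_pts <- sum(surf$value) * surf$n_draws
  chi <- sum((surf$value * surf$n_draws - n_pts / 16)^2 / (n_pts / 16))
  expect_lt(chi, qchisq(0.99, df = 15))
})

test_that("MMDM averages per-individual maximum trap distances", {
  traps <- trap_array(c("A", "B", "C"),
                      rbind(c(0, 0), c(3000, 4000), c(100, 0)),
                      matrix(1, 3, 4))
  # 3-4-5 triangle: individual seen at (0,0) and (3000,4000) moved 5000 m
  y <- array(0L, c(2, 3, 4))
  y[1, 1, 1] <- 1L; y[1, 2, 3] <- 2L
  y[2, 3, 2] <- 1L
  cap <- capture_data(y, matrix(0L, 3, 4), c("JA", "JB"))
  mm <- mean_max_distance(cap, traps)
  expect_equal(mm$mmdm, 5000)
  expect_equal(mm$table$n_traps, c(2, 1))
  expect_true(is.na(mm$table$max_dist[2]))

  # all individuals single-trap: undefined
  y2 <- array(0L, c(1, 3, 4)); y2[1, 1, 1] <- 2L
  mm2 <- mean_max_distance(capture_data(y2, matrix(0L, 3, 4), "JA"), traps)
  expect_true(is.na(mm2$mmdm))
})

test_that("closure test matches the span-distribution oracle", {
  traps <- tiny_traps(K = 5)
  # 3 individuals x 5 occasions, binary histories built by hand
  y <- array(0L, c(3, 4, 5))
  y[1, 1, 1] <- 1L; y[1, 2, 2] <- 1L          # spans occasions 1-2, n=2
  y[2, 1, 1] <- 1L; y[2, 1, 5] <- 1L          # spans 1-5, n=2
  y[3, 2, 2] <- 1L; y[3, 3, 3] <- 1L; y[3, 4, 4] <- 1L  # spans 2-4, n=3
  cap <- capture_data(y, matrix(0L, 4, 5), c("A", "B", "C"))
  res <- closure_test(cap, traps)

  # oracle: enumerate the span distribution q = l - f for each (n, t = 5)
  span_pmf <- function(n, t) {
    q <- (n - 1):(t - 1)
    p <- (t - q) * choose(q - 1, n - 2) / choose(t, n)
    stopifnot(abs(sum(p) - 1) < 1e-12)
    list(q = q, p = p)
  }
  moments <- function(n, t) {
    d <- span_pmf(n, t)
    mu <- sum(d$q * d$p)
    c(mu = mu, v = sum((d$q - mu)^2 * d$p))
  }
  m2 <- moments(2, 5); m3 <- moments(3, 5)
  z_hand <- ((1 - m2["mu"]) + (4 - m2["mu"]) + (2 - m3["mu"])) /
    sqrt(2 * m2["v"] + m3["v"])
  expect_equal(res$statistic, unname(z_hand))
  expect_equal(res$p_value, unname(pnorm(z_hand)))
  expect_equal(res$n_individuals, 3)

  # all captures on one occasion: undefined
  y1 <- array(0L, c(2, 4, 5)); y1[1, 1, 3] <- 1L; y1[2, 2, 3] <- 2L
  expect_warning(
    r1 <- closure_test(capture_data(y1, matrix(0L, 4, 5), c("A", "B")),
                       traps),
    "undefined")
  expect_true(is.na(r1$statistic))
})

test_that("closure test p-values are calibrated under a closed population", {
  # simulated closed population: one-sided p approximately uniform, so the
  # rejection rate at alpha = 0.05 stays inside its binomial CI over reps
  set.seed(71)
  K <- 20; n_ind <- 12
  reps <- 200
  pvals <- vapply(seq_len(reps), function(r) {
    y <- array(0L, c(n_ind, 2, K))
    for (i in seq_len(n_ind)) {
      hits <- which(rbinom(K, 1, 0.25) == 1)
      if (length(hits) == 0) hits <- sample.int(K, 1)
      y[i, 1, hits] <- 1L
    }
    traps <- tiny_traps(K = K)
    yy <- array(0L, c(n_ind, 4, K)); yy[, 1, ] <- y[, 1, ]
    cl <- closure_test(capture_data(yy, matrix(0L, 4, K),
                                    sprintf("I%02d", seq_len(n_ind))),
                       traps)
    cl$p_value
  }, numeric(1))
  rej <- mean(pvals < 0.05)
  ci <- qbeta(c(0.005, 0.995), reps * 0.05 + 0.5, reps * 0.95 + 0.5)
  expect_gt(rej, ci[1] - 0.035)
  expect_lt(rej, ci[2] + 0.035)
  # and the p-values spread over (0, 1) rather than degenerate
  expect_gt(sd(pvals), 0.1)
})

test_that("model comparison reports CV changes in percent", {
  ch_a <- list(fake_chain(100, 0.05, rnorm(100, 3000, 600), 1, 0.5,
                          rpois(100, 25)))
  ch_b <- list(fake_chain(100, 0.05, rnorm(100, 3000, 570), 0.87, 0.5,
                          rpois(100, 25)))
  sa <- suppressWarnings(summarize_fit(make_fake_fit(ch_a)))
  sb <- suppressWarnings(summarize_fit(make_fake_fit(ch_b)))
  cmp <- compare_fits(sa, sb)
  expect_equal(cmp$parameter, c("N", "sigma", "D"))
  expect_equal(cmp$cv_change_pct,
               100 * (cmp$rtscr_cv - cmp$scr_cv) / cmp$scr_cv)
  # identical summaries: zero change everywhere
  cmp0 <- compare_fits(sa, sa)
  expect_true(all(cmp0$cv_change_pct == 0))
  # CV 0.20 -> 0.19 is a -5% change
  expect_equal(100 * (0.19 - 0.20) / 0.20, -5)
  sb2 <- sb; sb2$area_km2 <- 999
  expect_error(compare_fits(sa, sb2), "different state-space areas")
})
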