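# Likelihood arithmetic, sampler behaviour on tractable targets,
# diagnostics, and the posterior-update filter.

test_that("log-likelihood sums Gaussian residual terms exactly", {
  tr1 <- isolated_transport()
  p <- model_parameters("DIFF", rho = 0, u0 = 0.7, sigma = 1, seeds = "A")
  # one record equal to the trajectory: only the normalisation remains
  obs1 <- single_region_obs(0.7, 1)
  expect_equal(log_likelihood(p, tr1, obs1)$total, -0.5 * log(2 * pi),
               tolerance = 1e-10)
  # doubling sigma of a residual-free fit costs log 2 per record
  p2 <- model_parameters("DIFF", rho = 0, u0 = 0.7, sigma = 2, seeds = "A")
  obs3 <- single_region_obs(rep(0.7, 3), c(1, 2, 3))
  expect_equal(log_likelihood(p, tr1, obs3)$total -
                 log_likelihood(p2, tr1, obs3)$total,
               3 * log(2), tolerance = 1e-10)
  # hand-set residuals (0, 1, -2)
  obs_r <- single_region_obs(0.7 + c(0, 1, -2), c(1, 2, 3))
  ll <- log_likelihood(p, tr1, obs_r)
  expect_equal(ll$total, -3 * 0.5 * log(2 * pi) - 2.5, tolerance = 1e-10)
  expect_length(ll$pointwise, 3)
  # missing values are skipped
  obs_na <- single_region_obs(c(0.7, NA), c(1, 2))
  expect_equal(log_likelihood(p, tr1, obs_na)$total, -0.5 * log(2 * pi),
               tolerance = 1e-10)
})

test_that("posterior mean matches the conjugate closed form on a static toy", {
  # DIFF with rho ~= 0 on an isolated region: u(t) = u0, so observations
  # are Normal(u0, sigma^2) and the truncated-Normal prior on u0 is
  # effectively conjugate far from zero.
  tr1 <- isolated_transport()
  sig <- 0.3
  withr::with_seed(42, {
    y <- stats::rnorm(40, 2, sig)
  })
  obs <- single_region_obs(y, seq(0.1, 4, length.out = 40))
  pri <- list(rho = prior_truncnorm(0, 1e-6),   # pinned at ~0
              u0 = prior_normal(1, 1),
              sigma = prior_truncnorm(0, 1e-6 + sig))  # tight-ish scale
  # closed form with known sigma: posterior precision = n/sig^2 + 1
  post_prec <- length(y) / sig^2 + 1
  post_mean <- (sum(y) / sig^2 + 1) / post_prec
  fit <- suppressWarnings(
    fit_model("DIFF", tr1, obs, seeds = "A",
              priors = structure(pri, class = "prior_spec"),
              chains = 2, warmup = 1500, samples = 1500, rng_seed = 3))
  m <- posterior_matrix(fit)
  mc_se <- stats::sd(m[, "u0"]) / sqrt(200)  # conservative ESS
  expect_lt(abs(mean(m[, "u0"]) - post_mean), 3 * mc_se + 0.01)
  expect_lt(abs(mean(m[, "u0"]) - post_mean), 0.05)
  # MAP within 0.05 of the analytic posterior mode (= mean here)
  mp <- map_estimate(fit)
  expect_lt(abs(mp$u0 - post_mean), 0.05)
})

test_that("prior-only fits reproduce the prior", {
  tr1 <- isolated_transport()
  obs0 <- observation_set(
    data.frame(region = character(0), time = numeric(0),
               replicate = numeric(0), value = numeric(0)), "A")
  pri <- list(rho = prior_truncnorm(0.5, 0.2), u0 = prior_truncnorm(0, 1),
              sigma = prior_truncnorm(0, 0.5))
  fit <- suppressWarnings(
    fit_model("DIFF", tr1, obs0, seeds = "A",
              priors = structure(pri, class = "prior_spec"),
              chains = 2, warmup = 1000, samples = 2000, thin = 2,
              rng_seed = 8, init = "prior"))
  m <- posterior_matrix(fit)
  for (v in c("rho", "u0", "sigma")) {
    ks <- suppressWarnings(
      stats::ks.test(m[, v], function(q) prior_cdf(pri[[v]], q)))
    expect_lt(unname(ks$statistic), 0.05)
  }
  # truncated-support draws stay strictly positive
  expect_true(all(m > 0))
})

test_that("split R-hat separates mixed from non-mixed chains", {
  withr::with_seed(9, {
    mixed <- matrix(stats::rnorm(4000), 1000, 4)
    expect_lt(gelman_rubin(mixed), 1.01)
    stuck <- cbind(stats::rnorm(200, 0, 1e-3), 1 + stats::rnorm(200, 0, 1e-3))
    expect_gt(gelman_rubin(stuck), 10)
    # identical chains: no between-chain variance beyond the split halves,
    # so R-hat sits at 1 up to the finite-sample (n-1)/n correction
    same <- matrix(rep(stats::rnorm(100), 2), 100, 2)
    expect_lt(abs(gelman_rubin(same) - 1), 0.02)
  })
  expect_error(gelman_rubin(matrix(1:100, 100, 1)), "2 chains")
  expect_error(gelman_rubin(matrix(1:8, 4, 2)), "10 draws")
})

test_that("KS update filter controls type I error and detects updates", {
  pri <- prior_truncnorm(0, 0.5)
  withr::with_seed(13, {
    # draws from the prior itself: updated almost never at alpha = 0.001
    hits <- vapply(1:200, function(i) {
      posterior_updated(prior_sample(pri, 1000), pri)$updated
    }, TRUE)
    expect_lte(mean(hits), 0.01)
  })
  # point mass at the prior median
  med <- stats::qnorm(0.75) * 0.5
  pu <- posterior_updated(rep(med, 4000), pri)
  expect_true(pu$updated)
  expect_equal(pu$statistic, 0.5, tolerance = 1e-3)
  # gross shift
  expect_true(posterior_updated(prior_sample(pri, 1000) + 5 * 0.5,
                                pri)$updated)
})

test_that("truncated parameters are positive in every retained draw", {
  cg <- gen_connectome(5, rng_seed = 2)
  pg <- gen_pathology(cg, rng_seed = 3)
  fit <- suppressWarnings(
    fit_model("DIFF_RF", pg$transport, pg$obs, seeds = pg$true_params$seeds,
              priors = synthetic_priors("DIFF_RF", 10),
              chains = 2, warmup = 300, samples = 100, rng_seed = 4))
  expect_true(all(posterior_matrix(fit) > 0))
  expect_equal(dim(fit$loglik_pointwise),
               c(200, nrow(pg$obs)))
})

test_that("prior-predictive simulation from the study priors stays finite", {
  cg <- gen_connectome(6, rng_seed = 21)
  tr <- make_transport(cg, "retrograde")
  pri <- synthetic_priors("DIFF_RF", 12)
  withr::with_seed(77, {
    ok <- vapply(1:100, function(i) {
      p <- model_parameters("DIFF_RF",
        rho = prior_sample(pri$rho, 1), alpha = prior_sample(pri$alpha, 1),
        beta = prior_sample(pri$beta, 12), gamma = prior_sample(pri$gamma, 12),
        u0 = prior_sample(pri$u0, 1), sigma = prior_sample(pri$sigma, 1),
        seeds = "R01_ipsi")
      s <- tryCatch(simulate_pathology(p, tr, STUDY_TIMEPOINTS),
                    error = function(e) NULL, warning = function(w) NULL)
      !is.null(s) && all(is.finite(s$u))
    }, TRUE)
    expect_gte(mean(ok), 0.99)
  })
})
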