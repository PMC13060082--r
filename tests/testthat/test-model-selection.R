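# WAIC, information criteria, origin-constrained agreement, Delta tables.

test_that("WAIC matches direct arithmetic on degenerate and tiny cases", {
  # all samples give likelihood 0.5 for one observation
  ll <- matrix(log(0.5), nrow = 4, ncol = 1)
  w <- waic(ll)
  expect_equal(w$p_waic, 0)
  expect_equal(w$waic, -2 * log(0.5), tolerance = 1e-12)
  # two samples, loglik (-1, -3)
  w2 <- waic(matrix(c(-1, -3), 2, 1))
  expect_equal(w2$lppd, log((exp(-1) + exp(-3)) / 2), tolerance = 1e-12)
  expect_equal(w2$p_waic, 2)
  expect_equal(w2$waic, 7.1324, tolerance = 1e-4)
  expect_equal(w2$waic, -2 * (w2$lppd - w2$p_waic), tolerance = 1e-10)
  expect_error(waic(matrix(-1, 1, 3)), "2 posterior samples")
})

test_that("WAIC equals a naive double-loop oracle on random input", {
  withr::with_seed(31, {
    ll <- matrix(stats::rnorm(50 * 30, -2, 1), 50, 30)
    w <- waic(ll)
    lppd <- 0; pw <- 0
    for (j in 1:30) {
      lppd <- lppd + log(mean(exp(ll[, j])))
      pw <- pw + stats::var(ll[, j])
    }
    expect_equal(w$lppd, lppd, tolerance = 1e-10)
    expect_equal(w$p_waic, pw, tolerance = 1e-10)
    expect_equal(w$waic, -2 * (lppd - pw), tolerance = 1e-10)
  })
})

test_that("AIC/BIC/MSE follow their definitions", {
  z <- aic_bic_mse(-7, 0, 5, c(1, -1))
  expect_equal(z$aic, 14)
  expect_equal(z$bic, 14)
  expect_equal(z$mse, 1)
  z2 <- aic_bic_mse(-5, 3, 10, c(0.5, -0.5))
  expect_equal(z2$aic, 16)
  expect_equal(z2$bic, 3 * log(10) + 10, tolerance = 1e-10)
  expect_equal(n_free_params("DIFF", 20), 3)
  expect_equal(n_free_params("DIFF_R", 20), 24)
  expect_equal(n_free_params("DIFF_RF", 20), 44)
})

test_that("origin-constrained R2 matches hand arithmetic and its invariances", {
  r <- r2_origin(c(1, 2, 3), c(1, 2, 3))
  expect_equal(r$slope, 1)
  expect_equal(r$r2, 1)
  r2 <- r2_origin(c(1, 2, 3), c(1, 2, 2))
  expect_equal(r2$slope, 11 / 14, tolerance = 1e-10)
  expect_equal(r2$r2, 0.9603, tolerance = 1e-4)
  # invariant to common positive rescaling
  r3 <- r2_origin(7.3 * c(1, 2, 3), 7.3 * c(1, 2, 2))
  expect_equal(r3$r2, r2$r2, tolerance = 1e-12)
  # R2 equals the squared uncentered correlation (symmetric), while the
  # slope depends on which argument is the regressor
  r4 <- r2_origin(c(1, 2, 2), c(1, 2, 3))
  expect_equal(r4$r2, sum(c(1, 2, 3) * c(1, 2, 2))^2 / (14 * 9),
               tolerance = 1e-12)
  expect_false(isTRUE(all.equal(r2$slope, 1 / r4$slope)))
  expect_error(r2_origin(c(0, 0), c(1, 2)), "all-zero")
  # orthogonal noise around zero leaves R2 near zero
  withr::with_seed(5, {
    x <- stats::rnorm(500)
    y <- stats::rnorm(500, sd = 5)
    expect_lt(abs(r2_origin(x, y)$r2), 0.1)
  })
})

test_that("per-timepoint agreement applies the log-space drop rule", {
  conn <- toy_connectome(3)
  pred <- matrix(c(1, 2, 3, 2, 4, 6), 3, 2,
                 dimnames = list(conn$region_ids, NULL))
  obs <- observation_set(
    data.frame(region = rep(conn$region_ids, 2),
               time = rep(c(1, 2), each = 3), replicate = 1,
               value = c(1, 2, 3, 2, 4, 0)),
    conn$region_ids)
  pt <- per_timepoint_agreement(pred, obs)
  expect_equal(pt$r2[1], 1)
  expect_equal(pt$n_dropped, c(0, 0))
  lt <- per_timepoint_agreement(pred, obs, log_space = TRUE)
  expect_equal(lt$n_dropped, c(0, 1))
  expect_equal(lt$n_pairs, c(3, 2))
  # hand-check timepoint 2 in log space: pairs (log2,log2),(log4,log4)
  expect_equal(lt$r2[2], 1, tolerance = 1e-12)
  expect_message(
    per_timepoint_agreement(pred, observation_set(
      data.frame(region = "N1", time = c(1, 2), replicate = 1,
                 value = c(1, 1)), conn$region_ids)),
    "usable pair")
})

test_that("delta table subtracts minima and flags overlap via paired SE", {
  mk <- function(pw) {
    w <- waic(pw)
    list(waic = w, aic = w$waic + 1, bic = w$waic + 2, mse = 0.1)
  }
  withr::with_seed(17, {
    base <- matrix(stats::rnorm(40 * 25, -1, 0.3), 40, 25)
    m1 <- mk(base)
    m2 <- mk(base)                      # identical => overlap, delta 0
    m3 <- mk(base - 0.8)                # clearly worse
    dt <- delta_table(list(a = m1, b = m2, c = m3))
    expect_equal(dt$dwaic[dt$model == "a"], 0)
    expect_equal(dt$dwaic[dt$model == "b"], 0)
    expect_true(dt$overlaps_best[dt$model == "b"])
    expect_false(dt$overlaps_best[dt$model == "c"])
    # naive loop oracle for the paired SE of model c
    d <- m3$waic$pointwise - m1$waic$pointwise
    expect_equal(dt$dwaic_se[dt$model == "c"],
                 sqrt(length(d) * stats::var(d)), tolerance = 1e-10)
    expect_equal(dt$dwaic[dt$model == "c"],
                 m3$waic$waic - m1$waic$waic, tolerance = 1e-10)
  })
  expect_error(delta_table(list(a = mk(matrix(-1, 3, 4)))), "at least 2")
  expect_error(delta_table(list(a = mk(matrix(-1, 3, 4)),
                                b = mk(matrix(-1, 3, 5)))),
               "different observation counts")
})

test_that("leave-one-timepoint-out validates its holdout index", {
  conn <- toy_connectome(2)
  obs <- observation_set(
    data.frame(region = "N1", time = c(1, 2), replicate = 1,
               value = c(0.1, 0.2)), conn$region_ids)
  tr <- make_transport(conn, "retrograde")
  expect_error(leave_one_timepoint_out("DIFF", tr, obs, "N1"),
               "at least 3 timepoints")
  obs3 <- observation_set(
    data.frame(region = "N1", time = c(1, 2, 3), replicate = 1,
               value = c(0.1, 0.2, 0.3)), conn$region_ids)
  expect_error(leave_one_timepoint_out("DIFF", tr, obs3, "N1",
                                       holdout_index = 9),
               "out of range")
})
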