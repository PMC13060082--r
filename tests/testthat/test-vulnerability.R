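# Gene regressions, PCA axis, axis comparison, multiple testing.

test_that("standardization gives mean 0, sd 1 and is idempotent", {
  expect_equal(standardize(c(1, 2, 3)), c(-1, 0, 1))
  z <- standardize(stats::rnorm(50, 5, 3))
  expect_equal(standardize(z), z, tolerance = 1e-12)
  expect_error(standardize(rep(2, 10)), "constant")
})

test_that("region selection combines the beta sign and update rules", {
  expect_error(select_regions(c(-1, -2), c(1, 1), c(TRUE, TRUE),
                              c(TRUE, TRUE)),
               "no regions pass")
  b <- c(r1 = 0.5, r2 = -0.1)
  g <- c(r1 = 0.3, r2 = 0.3)
  expect_identical(select_regions(b, g, c(TRUE, TRUE), c(TRUE, TRUE)), "r1")
  # updated flags gate inclusion even for positive beta
  b2 <- c(r1 = 0.5, r2 = 0.4, r3 = 0.4)
  g2 <- c(r1 = 0.3, r2 = 0.3, r3 = 0.3)
  expect_identical(select_regions(b2, g2, c(TRUE, TRUE, FALSE),
                                  c(TRUE, FALSE, TRUE)), "r1")
})

test_that("selection recovers grown regions from simulated posteriors", {
  # grown regions: informative positive posteriors; silent regions keep
  # prior-like draws that the KS filter should not flag
  pri <- prior_truncnorm(0, 1)
  withr::with_seed(300, {
    hits <- vapply(1:10, function(rep) {
      grown <- c(rep(TRUE, 30), rep(FALSE, 10))
      nm <- sprintf("r%02d", 1:40)
      mean_b <- mean_g <- numeric(40)
      upd_b <- upd_g <- logical(40)
      for (i in 1:40) {
        db <- if (grown[i]) stats::rnorm(2000, 0.5 + 0.2 * stats::runif(1), 0.05)
          else prior_sample(pri, 2000)
        dg <- if (grown[i]) stats::rnorm(2000, 0.4, 0.05)
          else prior_sample(pri, 2000)
        mean_b[i] <- mean(db); mean_g[i] <- mean(dg)
        upd_b[i] <- posterior_updated(db, pri)$updated
        upd_g[i] <- posterior_updated(dg, pri)$updated
      }
      names(mean_b) <- names(mean_g) <- nm
      sel <- select_regions(mean_b, mean_g, upd_b, upd_g)
      identical(sort(sel), sort(nm[grown]))
    }, TRUE)
    expect_gte(mean(hits), 0.9)
  })
})

test_that("gene regressions recover exact and random coefficient structure", {
  withr::with_seed(60, {
    n <- 50
    zb <- standardize(stats::rnorm(n))
    zg <- standardize(stats::rnorm(n))
    expr <- cbind(g1 = zb, g2 = 2 * zg + 5,
                  g3 = stats::rnorm(n))
    co <- gene_regressions(expr, zb, zg)
    expect_equal(co$a[1], 1, tolerance = 1e-10)
    expect_equal(co$b[1], 0, tolerance = 1e-10)
    expect_equal(co$intercept[1], 0, tolerance = 1e-10)
    expect_equal(co$a[2], 0, tolerance = 1e-10)
    expect_equal(co$b[2], 2, tolerance = 1e-10)
    expect_equal(co$intercept[2], 5, tolerance = 1e-10)
    # normal-equations oracle on a random expression matrix
    G <- matrix(stats::rnorm(n * 20), n, 20,
                dimnames = list(NULL, paste0("g", 1:20)))
    co2 <- gene_regressions(G, zb, zg)
    X <- cbind(1, zb, zg)
    oracle <- solve(t(X) %*% X) %*% t(X) %*% G
    expect_equal(co2$intercept, unname(oracle[1, ]), tolerance = 1e-8)
    expect_equal(co2$a, unname(oracle[2, ]), tolerance = 1e-8)
    expect_equal(co2$b, unname(oracle[3, ]), tolerance = 1e-8)
    # per-gene lm cross-check on one gene
    lmfit <- stats::lm(G[, 7] ~ zb + zg)
    expect_equal(co2$a[7], unname(stats::coef(lmfit)[2]), tolerance = 1e-8)
    expect_error(gene_regressions(G, zb, zb + 1e-9 * zg), "collinear")
  })
})

test_that("PCA axis handles collinear, isotropic and planted clouds", {
  # points on the line b = 2a
  a <- c(-1, 0, 1, 2)
  ab <- cbind(a, 2 * a)
  ax <- extract_axis(ab)
  expect_equal(unname(ax$loadings), c(1, 2) / sqrt(5), tolerance = 1e-10)
  expect_equal(ax$variance_explained_pc1, 1)
  expect_gte(ax$loadings[2], 0)
  # isotropic cloud splits variance evenly
  withr::with_seed(61, {
    iso <- matrix(stats::rnorm(20000), 10000, 2)
    expect_lt(abs(extract_axis(iso)$variance_explained_pc1 - 0.5), 0.02)
  })
  # planted anisotropic direction is recovered
  withr::with_seed(62, {
    for (i in 1:10) {
      theta <- stats::runif(1, 0, pi)
      v <- c(cos(theta), sin(theta))
      zb <- standardize(stats::rnorm(40)); zg <- standardize(stats::rnorm(40))
      ge <- gen_expression(zb, zg, n_genes = 800, axis_direction = v,
                           anisotropy = 10, noise_sd = 1, rng_seed = i)
      co <- gene_regressions(ge$expr, zb, zg)
      ax <- extract_axis(co)
      cosv <- abs(sum(ax$loadings * v))
      expect_gte(cosv, 0.95)
    }
  })
  expect_error(extract_axis(cbind(1:2, 1:2)), "3 genes")
})

test_that("eta is invariant to affine rescaling of the raw parameters", {
  withr::with_seed(63, {
    beta <- stats::rnorm(30, 0.5, 0.2)
    gamma <- stats::rnorm(30, 0.4, 0.1)
    expr <- matrix(stats::rnorm(30 * 50), 30, 50)
    a1 <- extract_axis(gene_regressions(expr, standardize(beta),
                                        standardize(gamma)))
    a2 <- extract_axis(gene_regressions(expr, standardize(3 * beta - 7),
                                        standardize(0.1 * gamma + 2)))
    expect_equal(a1$eta, a2$eta, tolerance = 1e-10)
  })
})

test_that("axis comparison reproduces the printed-loadings arithmetic", {
  expect_equal(compare_axes(c(1, 0), c(1, 0))$cosine, 1)
  expect_equal(compare_axes(c(1, 0), c(0, 1))$angle_deg, 90)
  cmp <- compare_axes(c(-0.37, 0.93), c(-0.20, 0.98))
  expect_equal(cmp$cosine, 0.9843, tolerance = 1e-4)
  expect_equal(cmp$angle_deg, 10.2, tolerance = 0.05)
  # self-comparison with gene-level stats is a fixed point
  withr::with_seed(64, {
    zb <- standardize(stats::rnorm(20)); zg <- standardize(stats::rnorm(20))
    ge <- gen_expression(zb, zg, n_genes = 100, rng_seed = 5)
    ax <- extract_axis(gene_regressions(ge$expr, zb, zg))
    self <- compare_axes(ax, ax)
    expect_equal(self$cosine, 1)
    expect_equal(self$angle_deg, 0)
    expect_equal(self$gene_r, 1)
    expect_equal(self$ols_slope, 1, tolerance = 1e-10)
    expect_equal(self$sign_agreement, 1)
  })
})

test_that("Benjamini-Hochberg adjustment follows the step-up rule", {
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.04)),
               c(0.03, 0.03, 0.04))
  expect_equal(benjamini_hochberg(0.2), 0.2)
  expect_equal(benjamini_hochberg(rep(1, 5)), rep(1, 5))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
})
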