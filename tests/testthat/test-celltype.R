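# Cell-count estimation, CLR, Spearman, paired permutation test.

test_that("cluster cells are allocated proportionally and propagated", {
  clusters <- data.frame(cluster_id = "c1", size = 100, class = "dopaminergic")
  freqs <- data.frame(cluster_id = "c1", structure = c("A", "B"),
                      frequency = c(0.7, 0.3))
  counts <- estimate_regional_counts(clusters, freqs, character(0),
                                     c("A", "B"))
  expect_equal(counts["A", "dopaminergic"], 70)
  expect_equal(counts["B", "dopaminergic"], 30)
  # one-step propagation: child C credited to parent A
  freqs2 <- data.frame(cluster_id = "c1", structure = c("C", "B"),
                       frequency = c(0.7, 0.3))
  counts2 <- estimate_regional_counts(clusters, freqs2, c(C = "A"),
                                      c("A", "B"))
  expect_equal(counts2["A", "dopaminergic"], 70)
  # contributions that reach the root are dropped with a warning
  expect_warning(
    c3 <- estimate_regional_counts(clusters, freqs2, c(C = "X"),
                                   c("A", "B")),
    "dropped")
  expect_equal(attr(c3, "dropped_cells"), 70)
  expect_error(
    estimate_regional_counts(clusters, freqs2, c(C = "D", D = "C"),
                             c("A", "B")),
    "cycle")
  expect_error(
    estimate_regional_counts(data.frame(cluster_id = "c1", size = -5,
                                        class = "x"),
                             freqs, character(0), "A"),
    "nonnegative")
})

test_that("count totals are conserved through a 3-level ontology", {
  withr::with_seed(80, {
    clusters <- data.frame(cluster_id = paste0("c", 1:4),
                           size = c(120, 55, 200, 10),
                           class = c("glut", "gaba", "glut", "dopa"))
    structs <- c("R1", "R2", "R1_child", "R1_grandchild", "R2_child")
    onto <- c(R1_child = "R1", R1_grandchild = "R1_child", R2_child = "R2")
    freqs <- do.call(rbind, lapply(clusters$cluster_id, function(cid) {
      f <- stats::runif(length(structs))
      data.frame(cluster_id = cid, structure = structs,
                 frequency = f / sum(f))
    }))
    counts <- estimate_regional_counts(clusters, freqs, onto, c("R1", "R2"))
    expect_equal(sum(counts), sum(clusters$size), tolerance = 1e-9)
    # per-cell loop oracle
    oracle <- matrix(0, 2, 3, dimnames = list(c("R1", "R2"),
                                              sort(unique(clusters$class))))
    for (i in seq_len(nrow(freqs))) {
      cl <- clusters[clusters$cluster_id == freqs$cluster_id[i], ]
      s <- freqs$structure[i]
      while (!s %in% c("R1", "R2")) s <- onto[[s]]
      oracle[s, cl$class] <- oracle[s, cl$class] + cl$size * freqs$frequency[i]
    }
    expect_equal(unclass(counts), oracle, ignore_attr = TRUE,
                 tolerance = 1e-9)
  })
})

test_that("CLR transform matches hand arithmetic and sums to zero", {
  expect_equal(clr_transform(rep(0.25, 4)), rep(0, 4))
  v <- clr_transform(c(0.5, 0.25, 0.25))
  expect_equal(v, c(0.4621, -0.2310, -0.2310), tolerance = 1e-3)
  withr::with_seed(81, {
    m <- matrix(stats::rgamma(50 * 5, 2), 50, 5)
    m <- m / rowSums(m)
    cm <- clr_transform(m)
    expect_true(all(abs(rowSums(cm)) < 1e-10))
  })
  # zero handling via the half-minimum pseudocount
  w <- clr_transform(c(0.5, 0.5, 0))
  expect_length(w, 3)
  expect_equal(sum(w), 0, tolerance = 1e-10)
  expect_error(clr_transform(c(0, 0, 0)), "all-zero")
})

test_that("Spearman correlation equals rank-then-Pearson, with ties", {
  expect_equal(spearman_rho(1:10, (1:10)^3), 1)
  expect_equal(spearman_rho(c(1, 2, 3), c(3, 1, 2)), -0.5)
  withr::with_seed(82, {
    x <- sample(1:5, 30, replace = TRUE)   # heavy ties
    y <- sample(1:4, 30, replace = TRUE)
    # loop oracle: mid-ranks then Pearson
    mid_rank <- function(v) {
      r <- numeric(length(v))
      for (i in seq_along(v))
        r[i] <- sum(v < v[i]) + (sum(v == v[i]) + 1) / 2
      r
    }
    expect_equal(spearman_rho(x, y),
                 stats::cor(mid_rank(x), mid_rank(y)), tolerance = 1e-12)
    expect_equal(spearman_rho(x, y),
                 stats::cor(x, y, method = "spearman"), tolerance = 1e-12)
  })
  expect_error(spearman_rho(rep(1, 5), 1:5), "constant")
})

test_that("paired permutations keep hemispheres yoked and bound p-values", {
  withr::with_seed(83, {
    n <- 20
    base <- sprintf("R%02d", 1:n)
    eta <- stats::setNames(stats::rnorm(2 * n),
                           c(paste0(base, "_ipsi"), paste0(base, "_contra")))
    pred <- stats::setNames(stats::rnorm(n), base)
    # perfectly associated toy: monotone predictor
    eta2 <- stats::setNames(rep(pred, 2) + stats::rnorm(2 * n, 0, 1e-6),
                            names(eta))
    res <- paired_hemisphere_permutation(eta2, pred, n_perm = 500,
                                         rng_seed = 1)
    expect_equal(res$pval, 1 / 501, tolerance = 1e-12)
    expect_gt(res$rho, 0.99)
    # unpaired input is rejected without the flag
    eta_un <- eta[-1]
    expect_error(paired_hemisphere_permutation(eta_un, pred, n_perm = 10),
                 "unpaired")
    expect_silent(paired_hemisphere_permutation(eta_un, pred, n_perm = 10,
                                                rng_seed = 2,
                                                allow_unpaired = TRUE))
  })
})

test_that("paired permutation test has calibrated type I error", {
  withr::with_seed(84, {
    n <- 15
    base <- sprintf("R%02d", 1:n)
    labs <- c(paste0(base, "_ipsi"), paste0(base, "_contra"))
    rej <- vapply(1:400, function(i) {
      eta <- stats::setNames(stats::rnorm(2 * n), labs)
      pred <- stats::setNames(stats::rnorm(n), base)
      paired_hemisphere_permutation(eta, pred, n_perm = 200,
                                    rng_seed = i)$pval < 0.05
    }, TRUE)
    expect_lt(abs(mean(rej) - 0.05), 0.03)
  })
})

test_that("monoaminergic score averages the four named CLR components", {
  m <- matrix(stats::rnorm(12), 2, 6)
  colnames(m) <- c("glutamatergic", "GABAergic", "dopaminergic",
                   "noradrenergic", "serotonergic", "histaminergic")
  rownames(m) <- c("r1", "r2")
  sc <- monoaminergic_score(m)
  expect_equal(sc[["r1"]],
               mean(m["r1", c("dopaminergic", "noradrenergic",
                              "serotonergic", "histaminergic")]))
  # order invariance
  sc2 <- monoaminergic_score(m[, rev(colnames(m))])
  expect_equal(sc, sc2)
  # all four equal => score equals that value
  m2 <- m
  m2["r1", c("dopaminergic", "noradrenergic", "serotonergic",
             "histaminergic")] <- 0.7
  expect_equal(monoaminergic_score(m2)[["r1"]], 0.7)
  expect_error(monoaminergic_score(m[, 1:4]), "missing cell class")
})
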