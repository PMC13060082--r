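# Pre-ranked enrichment: running-sum score, permutation NES, categories.

# independent loop oracle: walk the full ranked list position by position
es_loop_oracle <- function(scores, set_genes, p = 1) {
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  r <- abs(scores[ord])^p
  hit <- genes %in% set_genes
  nr <- sum(r[hit])
  nmiss <- sum(!hit)
  run <- numeric(length(genes))
  cur <- 0
  for (i in seq_along(genes)) {
    cur <- cur + if (hit[i]) r[i] / nr else -1 / nmiss
    run[i] <- cur
  }
  if (max(run) >= -min(run)) max(run) else min(run)
}

test_that("enrichment score matches the hand-evaluated running sum", {
  scores <- c(gA = 0.9, gB = 0.5, gC = -0.2, gD = -0.8)
  res <- gsea_preranked(scores, list(top = c("gA", "gB")), n_perm = 50,
                        min_size = 2, max_size = 3, rng_seed = 1)
  expect_equal(res$es, 1.0, tolerance = 1e-12)
  # the running sum after each position is (0.6429, 1.0, 0.5, 0.0)
  expect_equal(es_loop_oracle(scores, c("gA", "gB")), 1.0)
  expect_equal(0.9 / 1.4, 0.6429, tolerance = 1e-4)
})

test_that("weight 0 reduces the score to the unweighted KS statistic", {
  withr::with_seed(71, {
    scores <- stats::setNames(stats::rnorm(30), paste0("g", 1:30))
    set <- sample(names(scores), 8)
    res <- gsea_preranked(scores, list(s = set), weight_p = 0, n_perm = 20,
                          min_size = 2, max_size = 20, rng_seed = 2)
    # classical KS: compare hit/miss empirical step functions
    expect_equal(res$es, es_loop_oracle(scores, set, p = 0),
                 tolerance = 1e-12)
  })
})

test_that("vectorised scores equal the loop oracle on 8-gene toys", {
  withr::with_seed(72, {
    for (i in 1:25) {
      scores <- stats::setNames(stats::rnorm(8), paste0("g", 1:8))
      k <- sample(2:5, 1)
      set <- sample(names(scores), k)
      res <- gsea_preranked(scores, list(s = set), n_perm = 10,
                            min_size = 2, max_size = 7, rng_seed = i)
      expect_equal(res$es, es_loop_oracle(scores, set), tolerance = 1e-12)
    }
  })
})

test_that("enrichment scores agree with an independent implementation", {
  skip_if_not_installed("fgsea")
  withr::with_seed(76, {
    for (i in 1:10) {
      scores <- stats::setNames(stats::rnorm(60), paste0("g", 1:60))
      set <- sample(names(scores), 12)
      es <- gsea_preranked(scores, list(s = set), n_perm = 5,
                           min_size = 2, max_size = 50, rng_seed = i)$es
      ord <- order(scores, decreasing = TRUE)
      ref <- fgsea::calcGseaStat(scores[ord],
                                 selectedStats = which(names(scores)[ord]
                                                       %in% set),
                                 gseaParam = 1)
      expect_equal(es, ref, tolerance = 1e-10)
    }
  })
})

test_that("degenerate collections are rejected", {
  scores <- stats::setNames(stats::rnorm(10), paste0("g", 1:10))
  expect_error(gsea_preranked(scores, list(all = names(scores)),
                              min_size = 2, max_size = 10),
               "entire ranked list")
  expect_error(gsea_preranked(scores, list(s = c("g1", "g2"))),
               "size bounds")
  expect_error(gsea_preranked(stats::rnorm(5), list(s = "g")), "named")
})

test_that("planted sets earn larger |NES| than random sets", {
  withr::with_seed(73, {
    wins <- vapply(1:20, function(i) {
      scores <- stats::setNames(sort(stats::rnorm(300), decreasing = TRUE),
                                paste0("g", 1:300))
      gs <- gen_genesets(names(scores), scores, n_sets = 12,
                         size_range = c(10, 25), n_planted = 4,
                         rng_seed = i)
      res <- gsea_preranked(scores, gs$sets, n_perm = 200, rng_seed = i)
      planted <- res$set %in% gs$planted
      mean(abs(res$nes[planted])) > mean(abs(res$nes[!planted]))
    }, TRUE)
    expect_gte(mean(wins), 0.9)
  })
})

test_that("permutation p-values are uniform under the null", {
  withr::with_seed(74, {
    scores <- stats::setNames(stats::rnorm(400), paste0("g", 1:400))
    sets <- lapply(1:200, function(i) sample(names(scores), 15))
    names(sets) <- paste0("s", 1:200)
    res <- gsea_preranked(scores, sets, n_perm = 1000, rng_seed = 9)
    ks <- suppressWarnings(stats::ks.test(res$pval, "punif"))
    expect_gt(ks$p.value, 0.05)
  })
})

test_that("category over-representation matches exact hypergeometrics", {
  # 2x2 table [[3,0],[0,3]]: two-sided p = 2/20
  cats <- stats::setNames(rep(c("m", "other"), each = 3), paste0("p", 1:6))
  sig <- stats::setNames(c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE),
                         paste0("p", 1:6))
  res <- category_enrichment(cats, sig)
  expect_equal(res$pval[res$category == "m"], 0.1, tolerance = 1e-10)
  expect_true(all(res$qval >= res$pval - 1e-12))
  # extreme case: all significant pathways concentrated in one category
  expect_equal(res$category[which.min(res$pval)], "m")
  expect_gt(res$log2_odds_ratio[res$category == "m"], 0)
})

test_that("category flags independent of category stay null-calibrated", {
  withr::with_seed(75, {
    rej <- vapply(1:200, function(i) {
      cats <- stats::setNames(sample(c("a", "b", "c"), 60, replace = TRUE),
                              paste0("p", 1:60))
      sig <- stats::setNames(stats::runif(60) < 0.2, names(cats))
      res <- suppressWarnings(category_enrichment(cats, sig))
      any(res$qval < 0.05)
    }, TRUE)
    expect_gte(mean(!rej), 0.94)
  })
})

test_that("keyword mapping assigns the five functional categories", {
  paths <- c("Oxidative phosphorylation", "Proteasome",
             "Synaptic vesicle cycle", "Parkinson disease",
             "Ribosome biogenesis")
  cats <- categorize_pathways(paths)
  expect_equal(unname(cats),
               c("metabolism", "protein_homeostasis", "synaptic_function",
                 "neurodegenerative_disease", "other"))
})
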