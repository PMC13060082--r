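# Pre-ranked gene set enrichment and category over-representation.

# Weighted Kolmogorov-Smirnov running-sum enrichment score from sorted hit
# positions. `w_all` holds |score|^p for the full ranked list; extrema of
# the running sum occur only at hit positions (maxima) and immediately
# before them (minima), so the score needs O(k) work.
es_from_positions <- function(pos, w_all, n_total) {
  k <- length(pos)
  pos <- sort(pos)
  w <- w_all[pos]
  nr <- sum(w)
  if (nr == 0) return(0)
  miss_unit <- 1 / (n_total - k)
  cum_hit <- cumsum(w) / nr
  miss_before <- (pos - seq_len(k)) * miss_unit
  val_after <- cum_hit - miss_before           # running sum just after hit j
  val_pre <- c(0, cum_hit[-k]) - miss_before   # just before hit j
  hi <- max(val_after)
  lo <- min(val_pre, 0)
  if (hi >= -lo) hi else lo
}

#' Pre-ranked gene set enrichment analysis
#'
#' Weighted Kolmogorov-Smirnov running-sum enrichment: walking down the
#' ranked list, hits increment the running sum by `|score|^weight_p`
#' (normalised by the in-set total) and misses decrement it by
#' `1/(N - N_hit)`. The enrichment score (ES) is the extremum of larger
#' absolute value (ties toward the positive extremum). Significance comes
#' from gene-label permutations: the normalised enrichment score (NES)
#' divides ES by the mean |permuted ES| of matching sign, and the
#' empirical p-value uses the add-one estimator over matching-sign
#' permutations. Benjamini-Hochberg FDR is applied across sets.
#'
#' @param scores Named numeric vector of per-gene ranking scores (e.g.
#'   correlation with the vulnerability axis); names are unique gene
#'   symbols.
#' @param gene_sets Named list of character vectors (e.g. from
#'   [read_gmt()]).
#' @param weight_p Weighting exponent (1 = classic weighted GSEA; 0 =
#'   unweighted KS statistic).
#' @param n_perm Number of gene-label permutations.
#' @param min_size,max_size Set-size bounds applied after intersecting
#'   each set with the ranked list.
#' @param rng_seed Optional seed for the permutations.
#' @return Data frame with columns `set`, `size`, `es`, `nes`, `pval`,
#'   `fdr`, `leading_edge` (slash-separated genes up to the ES extremum).
#' @export
gsea_preranked <- function(scores, gene_sets, weight_p = 1, n_perm = 1000,
                           min_size = 10, max_size = 500, rng_seed = NULL) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene symbols", call. = FALSE)
  if (any(!is.finite(scores)))
    stop("scores must be finite", call. = FALSE)
  ord <- order(scores, decreasing = TRUE)
  genes <- names(scores)[ord]
  r <- scores[ord]
  n <- length(genes)
  w_all <- abs(r)^weight_p
  sets <- lapply(gene_sets, function(s) which(genes %in% s))
  sizes <- lengths(sets)
  if (any(sizes == n))
    stop("gene set(s) covering the entire ranked list: ",
         paste(names(gene_sets)[sizes == n], collapse = ", "), call. = FALSE)
  keep <- sizes >= min_size & sizes <= max_size
  if (!any(keep))
    stop("no gene sets within the size bounds [", min_size, ", ",
         max_size, "]", call. = FALSE)
  sets <- sets[keep]
  sizes <- sizes[keep]
  with_seed(rng_seed, {
    # permutation null ES, shared across sets of equal size
    perm_by_size <- new.env(parent = emptyenv())
    null_es <- function(k) {
      key <- as.character(k)
      if (!is.null(perm_by_size[[key]])) return(perm_by_size[[key]])
      es <- vapply(seq_len(n_perm), function(i)
        es_from_positions(sample.int(n, k), w_all, n), 0)
      perm_by_size[[key]] <- es
      es
    }
    rows <- lapply(seq_along(sets), function(si) {
      pos <- sets[[si]]
      es <- es_from_positions(pos, w_all, n)
      perm <- null_es(sizes[si])
      same <- if (es >= 0) perm[perm >= 0] else perm[perm < 0]
      nes <- if (length(same) && mean(abs(same)) > 0)
        es / mean(abs(same)) else NA_real_
      p <- (1 + sum(abs(same) >= abs(es))) / (1 + length(same))
      # leading edge: hits at or before the ES extremum
      pos_s <- sort(pos)
      w <- w_all[pos_s]
      nr <- sum(w)
      cum_hit <- cumsum(w) / max(nr, .Machine$double.eps)
      miss_before <- (pos_s - seq_along(pos_s)) / (n - length(pos_s))
      run <- cum_hit - miss_before
      val_pre <- c(0, cum_hit[-length(pos_s)]) - miss_before
      le <- if (es >= 0) genes[pos_s[seq_len(which.max(run))]]
        else genes[pos_s[seq(which.min(val_pre), length(pos_s))]]
      data.frame(set = names(sets)[si], size = sizes[si], es = es,
                 nes = nes, pval = p,
                 leading_edge = paste(le, collapse = "/"),
                 stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, rows)
    out$fdr <- benjamini_hochberg(out$pval)
    out[c("set", "size", "es", "nes", "pval", "fdr", "leading_edge")]
  })
}

#' Default keyword map for pathway categories
#'
#' Editable keyword lists used to bin pathway names into the five broad
#' functional categories considered in the enrichment summary. Matching is
#' case-insensitive substring search; unmatched pathways fall into
#' `other`.
#'
#' @return Named list of character keyword vectors.
#' @export
default_category_keywords <- function() {
  list(
    metabolism = c("metabol", "oxidative phosphorylation", "glycolysis",
                   "citrate", "tca", "respirat", "fatty acid",
                   "pentose", "amino acid"),
    protein_homeostasis = c("proteasome", "ubiquitin", "autophagy",
                            "lysosome", "protein processing", "chaperone",
                            "protein export", "folding"),
    synaptic_function = c("synap", "neurotransmitter", "axon",
                          "neuroactive", "long-term potentiation",
                          "vesicle", "gaba", "glutamatergic",
                          "dopaminergic", "cholinergic", "serotonergic"),
    neurodegenerative_disease = c("parkinson", "alzheimer", "huntington",
                                  "prion", "amyotrophic",
                                  "neurodegeneration"))
}

#' Assign pathways to functional categories by keyword matching
#'
#' @param pathways Character vector of pathway names.
#' @param keywords Named list of keyword vectors (see
#'   [default_category_keywords()]); the first category whose keywords
#'   match wins, unmatched pathways get `"other"`.
#' @return Named character vector of categories.
#' @export
categorize_pathways <- function(pathways,
                                keywords = default_category_keywords()) {
  low <- tolower(pathways)
  out <- rep("other", length(pathways))
  for (cat in rev(names(keywords))) {
    hit <- Reduce(`|`, lapply(keywords[[cat]],
                              function(k) grepl(k, low, fixed = TRUE)),
                  accumulate = FALSE)
    out[hit] <- cat
  }
  names(out) <- pathways
  out
}

#' Category over-representation of significant pathways
#'
#' For each functional category, a two-sided Fisher exact test on the 2x2
#' table of significant-vs-not by in-category-vs-not, with
#' Benjamini-Hochberg correction across categories and a log2 odds ratio
#' (Haldane 0.5 correction when any cell is zero).
#'
#' @param categories Named character vector mapping pathway -> category
#'   (see [categorize_pathways()]).
#' @param significant Named logical vector (pathway -> enriched at the
#'   chosen FDR threshold), aligned by name with `categories`.
#' @return Data frame with columns `category`, `n_sig_in`, `n_in`,
#'   `log2_odds_ratio`, `pval`, `qval`.
#' @export
category_enrichment <- function(categories, significant) {
  common <- intersect(names(categories), names(significant))
  if (!length(common))
    stop("categories and significance flags share no pathways",
         call. = FALSE)
  categories <- categories[common]
  significant <- significant[common]
  cats <- unique(categories)
  rows <- lapply(cats, function(cc) {
    inc <- categories == cc
    if (!any(inc)) {
      warning("category '", cc, "' has no member pathways; skipped",
              call. = FALSE)
      return(NULL)
    }
    a <- sum(significant & inc); b <- sum(significant & !inc)
    c0 <- sum(!significant & inc); d <- sum(!significant & !inc)
    tab <- matrix(c(a, c0, b, d), 2)
    p <- stats::fisher.test(tab, alternative = "two.sided")$p.value
    if (any(tab == 0)) tab <- tab + 0.5
    lor <- log2((tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1]))
    data.frame(category = cc, n_sig_in = a, n_in = sum(inc),
               log2_odds_ratio = lor, pval = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$qval <- benjamini_hochberg(out$pval)
  out[order(out$pval), ]
}
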