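# Regional cell-type composition and compositional association tests.

MONOAMINERGIC_CLASSES <- c("dopaminergic", "noradrenergic", "serotonergic",
                           "histaminergic")

#' Estimate regional cell counts from cluster annotations
#'
#' Distributes the cells of each transcriptomic cluster across brain
#' structures according to its reported spatial frequencies, walks
#' contributions at structures outside the target region set up a
#' child-to-parent ontology until a target region is reached (dropping
#' them with a warning if the ontology root is reached first), and
#' aggregates counts by neurotransmitter class.
#'
#' @param clusters Data frame with columns `cluster_id`, `size` (cell
#'   count, >= 0), `class` (neurotransmitter class label).
#' @param frequencies Long data frame with columns `cluster_id`,
#'   `structure`, `frequency`; frequencies within a cluster must sum to
#'   at most 1 (the remainder is unmapped).
#' @param ontology Named character vector mapping child structure ->
#'   parent structure; must be acyclic.
#' @param target_regions Character vector of region labels to aggregate
#'   into.
#' @return Regions x classes count matrix with attribute `dropped_cells`.
#' @export
estimate_regional_counts <- function(clusters, frequencies, ontology,
                                     target_regions) {
  stopifnot(all(c("cluster_id", "size", "class") %in% names(clusters)),
            all(c("cluster_id", "structure", "frequency") %in%
                  names(frequencies)))
  if (any(clusters$size < 0))
    stop("cluster sizes must be nonnegative", call. = FALSE)
  fsum <- tapply(frequencies$frequency, frequencies$cluster_id, sum)
  if (any(fsum > 1 + 1e-8))
    stop("spatial frequencies exceed 1 for cluster(s): ",
         paste(names(fsum)[fsum > 1 + 1e-8], collapse = ", "),
         call. = FALSE)
  # resolve each structure to a target region (or NA at the root)
  resolve <- function(s) {
    seen <- character(0)
    while (!(s %in% target_regions)) {
      if (s %in% seen)
        stop("ontology contains a cycle through '", s, "'", call. = FALSE)
      seen <- c(seen, s)
      if (!s %in% names(ontology)) return(NA_character_)
      s <- unname(ontology[[s]])
    }
    s
  }
  structs <- unique(frequencies$structure)
  resolved <- vapply(structs, resolve, "")
  classes <- sort(unique(clusters$class))
  counts <- matrix(0, length(target_regions), length(classes),
                   dimnames = list(target_regions, classes))
  dropped <- 0
  cl_size <- stats::setNames(clusters$size, clusters$cluster_id)
  cl_class <- stats::setNames(clusters$class, clusters$cluster_id)
  for (i in seq_len(nrow(frequencies))) {
    cid <- as.character(frequencies$cluster_id[i])
    cells <- cl_size[[cid]] * frequencies$frequency[i]
    reg <- resolved[[as.character(frequencies$structure[i])]]
    if (is.na(reg)) {
      dropped <- dropped + cells
    } else {
      counts[reg, cl_class[[cid]]] <- counts[reg, cl_class[[cid]]] + cells
    }
  }
  if (dropped > 0)
    warning(sprintf("%.6g cells reached the ontology root and were dropped",
                    dropped), call. = FALSE)
  attr(counts, "dropped_cells") <- dropped
  counts
}

#' Regional composition from a count matrix
#'
#' @param counts Regions x classes nonnegative count matrix.
#' @return Row-normalised fraction matrix (class `celltype_composition`).
#' @export
composition_from_counts <- function(counts) {
  tot <- rowSums(counts)
  if (any(tot <= 0))
    stop("region(s) with zero total cells: ",
         paste(rownames(counts)[tot <= 0], collapse = ", "), call. = FALSE)
  structure(counts / tot, class = c("celltype_composition", "matrix"))
}

#' Centered log-ratio transform
#'
#' Maps compositional rows from the simplex to zero-sum real vectors:
#' `clr(x)_i = log(x_i / geometric_mean(x))`. When zeros are present, a
#' pseudocount (default: half the smallest nonzero fraction in the input)
#' is added and rows are renormalised first.
#'
#' @param fractions Matrix of row compositions, or a single numeric
#'   vector.
#' @param pseudocount Positive replacement added to all entries when
#'   zeros are present; `NULL` for the default rule.
#' @return CLR-transformed matrix (or vector); rows sum to zero.
#' @export
clr_transform <- function(fractions, pseudocount = NULL) {
  vec <- is.null(dim(fractions))
  x <- if (vec) matrix(fractions, nrow = 1) else as.matrix(fractions)
  if (any(x < 0)) stop("fractions must be nonnegative", call. = FALSE)
  if (any(rowSums(x) == 0)) stop("all-zero composition row", call. = FALSE)
  if (any(x == 0)) {
    pc <- pseudocount %||% (min(x[x > 0]) / 2)
    stopifnot(pc > 0)
    x <- x + pc
  }
  x <- x / rowSums(x)
  lx <- log(x)
  out <- lx - rowMeans(lx)
  if (vec) drop(out) else out
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (average ranks under ties).
#'
#' @param x,y Numeric vectors (length >= 3, non-constant).
#' @return Scalar rho.
#' @export
spearman_rho <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (length(unique(x)) < 2 || length(unique(y)) < 2)
    stop("Spearman correlation undefined for constant input", call. = FALSE)
  stats::cor(rank(x), rank(y))
}

#' Hemisphere-paired permutation test for regional associations
#'
#' Tests Spearman associations between a hemisphere-resolved regional
#' variable (e.g. the vulnerability axis eta) and region-level predictors
#' that are shared across hemispheres (e.g. CLR cell-type components from
#' a single-hemisphere atlas). Each permutation shuffles the region-level
#' predictor assignment; both hemispheres of a region always receive the
#' same shuffled value, preserving the within-region pairing. Empirical
#' p-values use the add-one estimator on `|rho|`; Benjamini-Hochberg
#' correction is applied across predictors.
#'
#' @param eta Named numeric vector over hemisphere-resolved regions
#'   (labels carry a `_ipsi`/`_contra` suffix).
#' @param predictors Matrix (regions x predictors) or named vector indexed
#'   by base region label.
#' @param n_perm Number of permutations.
#' @param rng_seed Optional seed.
#' @param allow_unpaired Permit base regions represented by a single
#'   hemisphere? Default `FALSE` (error).
#' @return Data frame with columns `predictor`, `rho`, `pval`, `qval`.
#' @export
paired_hemisphere_permutation <- function(eta, predictors, n_perm = 10000,
                                          rng_seed = NULL,
                                          allow_unpaired = FALSE) {
  if (is.null(names(eta)))
    stop("eta must be named by hemisphere-resolved region labels",
         call. = FALSE)
  pred <- if (is.null(dim(predictors)))
    matrix(predictors, ncol = 1,
           dimnames = list(names(predictors), "predictor"))
  else as.matrix(predictors)
  base <- base_region(names(eta))
  missing_pred <- setdiff(unique(base), rownames(pred))
  if (length(missing_pred))
    stop("no predictor values for region(s): ",
         paste(missing_pred, collapse = ", "), call. = FALSE)
  tab <- table(base)
  if (any(tab != 2) && !allow_unpaired)
    stop("unpaired hemisphere(s) for region(s): ",
         paste(names(tab)[tab != 2], collapse = ", "),
         "; set allow_unpaired = TRUE to proceed", call. = FALSE)
  regions <- unique(base)
  reg_ix <- match(base, regions)
  P <- pred[regions, , drop = FALSE]
  rho_obs <- vapply(seq_len(ncol(P)), function(j)
    spearman_rho(eta, P[reg_ix, j]), 0)
  with_seed(rng_seed, {
    exceed <- numeric(ncol(P))
    for (b in seq_len(n_perm)) {
      perm <- sample.int(length(regions))
      for (j in seq_len(ncol(P))) {
        rp <- spearman_rho(eta, P[perm, j][reg_ix])
        if (abs(rp) >= abs(rho_obs[j])) exceed[j] <- exceed[j] + 1
      }
    }
    p <- (1 + exceed) / (1 + n_perm)
    data.frame(predictor = colnames(P) %||% paste0("p", seq_len(ncol(P))),
               rho = rho_obs, pval = p, qval = benjamini_hochberg(p),
               row.names = NULL)
  })
}

#' Monoaminergic composition score
#'
#' Mean of the CLR-transformed fractions of the dopaminergic,
#' noradrenergic, serotonergic and histaminergic classes, per region.
#'
#' @param clr_matrix Regions x classes CLR matrix (from
#'   [clr_transform()]).
#' @param classes Names of the monoaminergic class columns.
#' @return Named per-region score vector.
#' @export
monoaminergic_score <- function(clr_matrix,
                                classes = MONOAMINERGIC_CLASSES) {
  missing_cls <- setdiff(classes, colnames(clr_matrix))
  if (length(missing_cls))
    stop("missing cell class(es): ", paste(missing_cls, collapse = ", "),
         call. = FALSE)
  rowMeans(clr_matrix[, classes, drop = FALSE])
}
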