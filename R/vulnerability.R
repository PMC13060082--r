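# Gene-parameter association, PCA vulnerability axis, enrichment.

#' Z-score a regional vector
#'
#' Centers to mean 0 and scales to sample standard deviation 1 (ddof = 1).
#'
#' @param values Numeric vector with at least 2 distinct values.
#' @return Standardised vector.
#' @export
standardize <- function(values) {
  if (length(unique(values[is.finite(values)])) < 2)
    stop("cannot standardize a (near-)constant vector", call. = FALSE)
  (values - mean(values)) / stats::sd(values)
}

#' Select regions for biological analyses
#'
#' Keeps regions with positive posterior-mean rise parameter whose rise and
#' fall posteriors were both updated from their priors (fall dynamics can
#' only manifest where growth occurs, and non-updated parameters carry no
#' regional information).
#'
#' @param post_beta Named numeric vector of posterior-mean rise parameters.
#' @param post_gamma Named numeric vector of posterior-mean fall parameters.
#' @param updated_beta,updated_gamma Logical vectors from the
#'   posterior-update filter, aligned with the parameter vectors.
#' @return Character vector (or integer indices when unnamed) of selected
#'   regions.
#' @export
select_regions <- function(post_beta, post_gamma, updated_beta,
                           updated_gamma) {
  stopifnot(length(post_beta) == length(post_gamma),
            length(post_beta) == length(updated_beta),
            length(post_beta) == length(updated_gamma))
  keep <- post_beta > 0 & updated_beta & updated_gamma
  if (!any(keep))
    stop("no regions pass the selection (beta > 0 and updated posteriors); ",
         "review the update-filter threshold", call. = FALSE)
  if (!is.null(names(post_beta))) names(post_beta)[keep] else which(keep)
}

#' Per-gene regressions on standardized rise and fall parameters
#'
#' Fits, for every gene, ordinary least squares of regional expression on
#' `z(beta)` and `z(gamma)` with an intercept, across hemisphere-resolved
#' regions. All genes share the design matrix, so a single QR factorisation
#' solves every regression.
#'
#' @param expr Regions x genes expression matrix (rows aligned with the
#'   parameter vectors).
#' @param z_beta,z_gamma Standardised regional parameters.
#' @param scale_expression Z-score each gene's expression first? Default
#'   `FALSE` (raw expression, intercept absorbs the gene mean).
#' @return Object of class `gene_coefficients`: data frame with columns
#'   `gene`, `intercept`, `a` (coefficient on `z(beta)`), `b` (coefficient
#'   on `z(gamma)`), `resid_sd`; carries the inputs as attributes for
#'   [extract_axis()].
#' @export
gene_regressions <- function(expr, z_beta, z_gamma,
                             scale_expression = FALSE) {
  expr <- as.matrix(expr)
  n <- nrow(expr)
  stopifnot(length(z_beta) == n, length(z_gamma) == n)
  if (n < 4)
    stop("need at least 4 regions for the gene regressions", call. = FALSE)
  if (abs(stats::cor(z_beta, z_gamma)) >= 0.999)
    stop("z(beta) and z(gamma) are collinear; regression is unidentified",
         call. = FALSE)
  if (scale_expression) expr <- apply(expr, 2, standardize)
  X <- cbind(intercept = 1, a = z_beta, b = z_gamma)
  qrX <- qr(X)
  coefs <- qr.coef(qrX, expr)            # 3 x genes
  fitted <- X %*% coefs
  rsd <- sqrt(colSums((expr - fitted)^2) / max(n - 3, 1))
  out <- data.frame(gene = colnames(expr) %||% paste0("g", seq_len(ncol(expr))),
                    intercept = coefs[1, ], a = coefs[2, ], b = coefs[3, ],
                    resid_sd = rsd, row.names = NULL)
  structure(out, class = c("gene_coefficients", "data.frame"),
            z_beta = z_beta, z_gamma = z_gamma, expr = expr)
}

#' Extract the PCA vulnerability axis
#'
#' Applies principal component analysis to the mean-centered (but not
#' variance-scaled) cloud of per-gene coefficient pairs `(a_g, b_g)`,
#' treating genes as observations. The first principal component's
#' loadings `(c1, c2)` are normalised to unit length and sign-flipped so
#' the fall loading `c2 >= 0`; the regional scalar axis is
#' `eta = c1 z(beta) + c2 z(gamma)`. Per-gene Pearson correlations of
#' expression with `eta` are attached when the coefficient object carries
#' its expression matrix.
#'
#' @param coeffs A `gene_coefficients` object (>= 3 genes), or a
#'   two-column matrix of coefficient pairs plus explicit `z_beta`,
#'   `z_gamma`.
#' @param z_beta,z_gamma Optional overrides of the standardized parameters
#'   stored on `coeffs`.
#' @return Object of class `vulnerability_axis`: list with `loadings`
#'   (`c(c1, c2)`), `variance_explained_pc1`, `eta` (named per region) and
#'   `gene_axis_corr` (named per gene, when expression is available).
#' @export
extract_axis <- function(coeffs, z_beta = NULL, z_gamma = NULL) {
  if (inherits(coeffs, "gene_coefficients")) {
    ab <- cbind(coeffs$a, coeffs$b)
    genes <- coeffs$gene
    z_beta <- z_beta %||% attr(coeffs, "z_beta")
    z_gamma <- z_gamma %||% attr(coeffs, "z_gamma")
    expr <- attr(coeffs, "expr")
  } else {
    ab <- as.matrix(coeffs)
    genes <- rownames(ab)
    expr <- NULL
  }
  if (nrow(ab) < 3)
    stop("need at least 3 genes for the PCA axis", call. = FALSE)
  centered <- scale(ab, center = TRUE, scale = FALSE)
  cv <- crossprod(centered) / (nrow(ab) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  v <- eg$vectors[, 1]
  v <- v / sqrt(sum(v^2))
  if (v[2] < 0 || (v[2] == 0 && v[1] < 0)) v <- -v
  ve <- eg$values[1] / sum(eg$values)
  eta <- NULL
  if (!is.null(z_beta) && !is.null(z_gamma)) {
    eta <- v[1] * z_beta + v[2] * z_gamma
    if (!is.null(expr) && !is.null(rownames(expr))) names(eta) <- rownames(expr)
  }
  gene_corr <- NULL
  if (!is.null(expr) && !is.null(eta)) {
    gene_corr <- as.vector(stats::cor(expr, eta))
    names(gene_corr) <- genes
  }
  structure(list(loadings = c(c1 = v[1], c2 = v[2]),
                 variance_explained_pc1 = ve,
                 eta = eta, gene_axis_corr = gene_corr),
            class = "vulnerability_axis")
}

#' @export
print.vulnerability_axis <- function(x, ...) {
  cat(sprintf("vulnerability axis: eta = %.3f z(beta) + %.3f z(gamma); PC1 %.1f%% of variance\n",
              x$loadings[1], x$loadings[2],
              100 * x$variance_explained_pc1))
  invisible(x)
}

#' Compare two vulnerability axes
#'
#' Computes the cosine similarity and angle between the PC1 loading
#' vectors and, when both axes carry per-gene correlations, the
#' gene-level concordance: Pearson correlation, with-intercept OLS slope
#' (axis B's correlations regressed on axis A's) and the fraction of
#' shared genes whose correlations agree in sign.
#'
#' @param axis_a,axis_b `vulnerability_axis` objects or length-2 loading
#'   vectors.
#' @return List with `cosine`, `angle_deg`, and (gene level, when
#'   available) `gene_r`, `ols_slope`, `sign_agreement`, `n_shared`.
#' @export
compare_axes <- function(axis_a, axis_b) {
  getl <- function(a) if (inherits(a, "vulnerability_axis")) a$loadings
    else as.numeric(a)
  va <- getl(axis_a); vb <- getl(axis_b)
  stopifnot(length(va) == 2, length(vb) == 2)
  cosine <- sum(va * vb) / sqrt(sum(va^2) * sum(vb^2))
  angle <- acos(pmin(pmax(cosine, -1), 1)) * 180 / pi
  out <- list(cosine = cosine, angle_deg = angle)
  ca <- if (inherits(axis_a, "vulnerability_axis")) axis_a$gene_axis_corr
  cb <- if (inherits(axis_b, "vulnerability_axis")) axis_b$gene_axis_corr
  if (!is.null(ca) && !is.null(cb)) {
    shared <- intersect(names(ca), names(cb))
    if (!length(shared))
      stop("axes share no genes", call. = FALSE)
    if (length(shared) >= 10) {
      x <- ca[shared]; y <- cb[shared]
      fit <- stats::lm(y ~ x)
      out$gene_r <- stats::cor(x, y)
      out$ols_slope <- unname(stats::coef(fit)[2])
      out$sign_agreement <- mean(sign(x) == sign(y))
      out$n_shared <- length(shared)
    }
  }
  out
}

#' Benjamini-Hochberg adjusted q-values
#'
#' Step-up FDR adjustment (wraps the standard implementation after input
#' validation).
#'
#' @param p Numeric p-values in `[0, 1]`.
#' @return Adjusted q-values, capped at 1.
#' @export
benjamini_hochberg <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  stats::p.adjust(p, method = "BH")
}
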