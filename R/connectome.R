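# Connectome container and transport operators.

#' Construct a connectome
#'
#' Wraps a directed, weighted region-by-region connectivity matrix. Entry
#' `W[i, j]` is the strength of the axonal projection from region `j` to
#' region `i`. Self-projections carry no transport, so the diagonal is
#' zeroed on construction.
#'
#' @param W Square nonnegative numeric matrix with identical row and column
#'   names (the region labels).
#' @param hemisphere Optional character vector of per-region hemisphere tags
#'   (`"ipsi"`/`"contra"`, or `"L"`/`"R"`). When `NULL`, tags are parsed
#'   from a `_ipsi`/`_contra` (or `_L`/`_R`) label suffix where present.
#' @param coords Optional numeric matrix (regions x 3) of region centroid
#'   coordinates, required for the Euclidean transport mode.
#' @return An object of class `connectome` with elements `W`, `region_ids`,
#'   `hemisphere` and `coords`.
#' @export
connectome <- function(W, hemisphere = NULL, coords = NULL) {
  assert_square_nonneg(W, "connectivity matrix")
  ids <- rownames(W)
  if (is.null(ids)) {
    ids <- sprintf("R%03d", seq_len(nrow(W)))
    dimnames(W) <- list(ids, ids)
  }
  if (anyDuplicated(ids))
    stop("duplicate region labels: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  if (!identical(rownames(W), colnames(W)))
    stop("row and column labels of W must match", call. = FALSE)
  diag(W) <- 0
  if (is.null(hemisphere)) hemisphere <- hemisphere_from_labels(ids)
  if (length(hemisphere) != length(ids))
    stop("hemisphere must have one tag per region", call. = FALSE)
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    if (nrow(coords) != length(ids) || ncol(coords) != 3)
      stop("coords must be a regions x 3 matrix", call. = FALSE)
    rownames(coords) <- ids
  }
  structure(list(W = W, region_ids = ids, hemisphere = hemisphere,
                 coords = coords),
            class = "connectome")
}

#' @export
print.connectome <- function(x, ...) {
  cat(sprintf("connectome: %d regions, %d directed edges\n",
              length(x$region_ids), sum(x$W > 0)))
  invisible(x)
}

#' Out-degree graph Laplacian
#'
#' Computes `L = -W + diag(out-strengths)` where the out-strength of region
#' `i` is the column sum `sum_k W[k, i]`. Column sums of `L` are zero, which
#' makes linear diffusion on `L` mass-conserving.
#'
#' @param W Square nonnegative connectivity matrix (diagonal is zeroed
#'   before the Laplacian is formed).
#' @return The Laplacian matrix, same dimnames as `W`.
#' @export
build_laplacian <- function(W) {
  assert_square_nonneg(W, "W")
  diag(W) <- 0
  L <- -W
  diag(L) <- diag(L) + colSums(W)
  L
}

#' Build a transport operator
#'
#' Maps a connectome to the graph Laplacian(s) implementing one of four
#' transport hypotheses. Retrograde transport (movement against the
#' projection direction) uses the transposed connectivity matrix;
#' anterograde uses the matrix as-is; bidirectional returns both Laplacians
#' so each can be paired with its own rate; Euclidean replaces connectivity
#' with a symmetric distance kernel over region centroids.
#'
#' @param conn A [connectome].
#' @param mode One of `"retrograde"`, `"anterograde"`, `"bidirectional"`,
#'   `"euclidean"`.
#' @param length_scale Optional positive length scale. When supplied in
#'   Euclidean mode the kernel is `exp(-d / length_scale)`; otherwise the
#'   inverse distance `1/d` is used.
#' @return An object of class `transport_operator` with elements `mode`,
#'   `L` (primary Laplacian) and `L2` (secondary Laplacian, bidirectional
#'   mode only).
#' @export
make_transport <- function(conn,
                           mode = c("retrograde", "anterograde",
                                    "bidirectional", "euclidean"),
                           length_scale = NULL) {
  stopifnot(inherits(conn, "connectome"))
  mode <- match.arg(mode)
  L2 <- NULL
  if (mode == "anterograde") {
    L <- build_laplacian(conn$W)
  } else if (mode == "retrograde") {
    L <- build_laplacian(t(conn$W))
  } else if (mode == "bidirectional") {
    L <- build_laplacian(t(conn$W))
    L2 <- build_laplacian(conn$W)
  } else {
    if (is.null(conn$coords))
      stop("euclidean transport requires region coordinates", call. = FALSE)
    D <- as.matrix(stats::dist(conn$coords))
    if (any(D[upper.tri(D)] == 0))
      stop("duplicate region centroids give an undefined distance kernel",
           call. = FALSE)
    if (is.null(length_scale)) {
      K <- 1 / D
    } else {
      stopifnot(length_scale > 0)
      K <- exp(-D / length_scale)
    }
    diag(K) <- 0
    dimnames(K) <- dimnames(conn$W)
    L <- build_laplacian(K)
  }
  structure(list(mode = mode, L = L, L2 = L2), class = "transport_operator")
}

#' Rewired-connectome null model
#'
#' Produces a connectome with the same regions, the same number of directed
#' edges and the same multiset of edge weights, with edge positions
#' randomised over off-diagonal cells. A degree-preserving variant swaps
#' edge targets pairwise, preserving in- and out-degree sequences.
#'
#' @param conn A [connectome].
#' @param rng_seed Integer seed; the result is deterministic given the seed.
#' @param method `"shuffle"` (weight-multiset shuffle, default) or
#'   `"degree_preserving"` (pairwise target swaps).
#' @return A rewired [connectome].
#' @export
rewire_null <- function(conn, rng_seed, method = c("shuffle",
                                                   "degree_preserving")) {
  stopifnot(inherits(conn, "connectome"))
  method <- match.arg(method)
  n <- length(conn$region_ids)
  if (n < 3) stop("rewiring needs at least 3 regions", call. = FALSE)
  W <- conn$W
  with_seed(rng_seed, {
    if (method == "shuffle") {
      off <- which(row(W) != col(W))
      nz <- off[W[off] > 0]
      wts <- W[nz]
      Wn <- matrix(0, n, n, dimnames = dimnames(W))
      pos <- sample(off, length(nz))
      Wn[pos] <- sample(wts)
    } else {
      Wn <- W
      edges <- which(Wn > 0, arr.ind = TRUE)
      k <- nrow(edges)
      for (s in seq_len(10 * k)) {
        ij <- sample.int(k, 2)
        e1 <- edges[ij[1], ]; e2 <- edges[ij[2], ]
        # swap targets of j->i edges: (i1,j1),(i2,j2) -> (i2,j1),(i1,j2)
        if (e1[1] == e2[1] || e1[2] == e2[2]) next
        if (e1[2] == e2[1] || e2[2] == e1[1]) next
        if (Wn[e2[1], e1[2]] > 0 || Wn[e1[1], e2[2]] > 0) next
        w1 <- Wn[e1[1], e1[2]]; w2 <- Wn[e2[1], e2[2]]
        Wn[e1[1], e1[2]] <- 0; Wn[e2[1], e2[2]] <- 0
        Wn[e2[1], e1[2]] <- w1; Wn[e1[1], e2[2]] <- w2
        edges[ij[1], 1] <- e2[1]; edges[ij[2], 1] <- e1[1]
      }
    }
    connectome(Wn, hemisphere = conn$hemisphere, coords = conn$coords)
  })
}

#' Randomised seed-region null model
#'
#' Draws a uniformly random region set of the same cardinality as the true
#' seed set, disjoint from it.
#'
#' @param conn A [connectome].
#' @param true_seeds Character vector of true seed region labels (or integer
#'   indices).
#' @param rng_seed Integer seed.
#' @return Character vector of randomised seed labels.
#' @export
random_seed_region <- function(conn, true_seeds, rng_seed) {
  stopifnot(inherits(conn, "connectome"), length(true_seeds) >= 1)
  ids <- conn$region_ids
  if (is.numeric(true_seeds)) true_seeds <- ids[true_seeds]
  if (!all(true_seeds %in% ids))
    stop("unknown seed region(s): ",
         paste(setdiff(true_seeds, ids), collapse = ", "), call. = FALSE)
  pool <- setdiff(ids, true_seeds)
  if (length(pool) < length(true_seeds))
    stop("too few non-seed regions to draw a disjoint seed set",
         call. = FALSE)
  with_seed(rng_seed, sample(pool, length(true_seeds)))
}
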