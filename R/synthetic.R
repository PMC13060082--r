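# Synthetic-study generator: connectome, pathology, expression, cell types,
# gene sets, and the assembled study object.

#' Experimental timepoint grid (months post-injection)
#'
#' @export
STUDY_TIMEPOINTS <- c(0.1, 0.2, 0.3, 0.5, 1, 3, 6, 9)

#' Generate a mirrored two-hemisphere synthetic connectome
#'
#' Directed weighted graph with identical intra-hemispheric wiring in the
#' two hemispheres (log-normal weights), sparse commissural connections,
#' a weak intra-hemispheric ring guaranteeing connectivity, and mirrored
#' 3-D region centroids for the Euclidean transport mode.
#'
#' @param n_per_hemi Regions per hemisphere (>= 5).
#' @param density Probability of each off-diagonal intra-hemispheric edge.
#' @param weight_scale Median edge weight.
#' @param commissural_prob Probability that a region projects to its
#'   mirror-image counterpart.
#' @param rng_seed Integer seed (bit-reproducible output).
#' @return A [connectome] with labels `R<k>_ipsi` / `R<k>_contra`.
#' @export
gen_connectome <- function(n_per_hemi = 20, density = 0.25,
                           weight_scale = 1, commissural_prob = 0.5,
                           rng_seed = 1) {
  stopifnot(n_per_hemi >= 5, density > 0, density <= 1)
  with_seed(rng_seed, {
    n <- n_per_hemi
    rw <- function(k) stats::rlnorm(k, log(weight_scale), 0.5)
    Wh <- matrix(0, n, n)
    off <- which(row(Wh) != col(Wh))
    picked <- off[stats::runif(length(off)) < density]
    Wh[picked] <- rw(length(picked))
    # intra-hemispheric ring keeps each hemisphere weakly connected
    for (i in seq_len(n)) {
      j <- if (i == n) 1 else i + 1
      if (Wh[j, i] == 0) Wh[j, i] <- rw(1)
    }
    N <- 2 * n
    W <- matrix(0, N, N)
    W[1:n, 1:n] <- Wh
    W[n + 1:n, n + 1:n] <- Wh
    # commissural edges between mirror-image regions (both directions)
    link <- stats::runif(n) < commissural_prob
    link[1] <- TRUE  # guarantees inter-hemispheric connectivity
    for (i in which(link)) {
      W[n + i, i] <- rw(1)
      W[i, n + i] <- rw(1)
    }
    ids <- c(sprintf("R%02d_ipsi", 1:n), sprintf("R%02d_contra", 1:n))
    dimnames(W) <- list(ids, ids)
    # scale to unit mean out-strength so transport and local growth act
    # on comparable timescales at unit rate parameters
    W <- W * (weight_scale / mean(colSums(W)))
    xyz <- cbind(stats::runif(n, 1, 10), stats::runif(n, 0, 10),
                 stats::runif(n, 0, 10))
    coords <- rbind(xyz, cbind(-xyz[, 1], xyz[, 2:3]))
    conn <- connectome(W, coords = coords)
    # top up connectivity if the construction ever leaves the graph split
    comp <- weak_components(conn$W)
    while (max(comp) > 1) {
      a <- which(comp == 1)[1]
      b <- which(comp != 1)[1]
      conn$W[b, a] <- rw(1)
      conn$W[a, b] <- rw(1)
      comp <- weak_components(conn$W)
    }
    conn
  })
}

# Connected-component labels of the undirected support of W.
weak_components <- function(W) {
  n <- nrow(W)
  adj <- (W > 0) | (t(W) > 0)
  comp <- integer(n)
  cur <- 0
  for (s in seq_len(n)) {
    if (comp[s] != 0) next
    cur <- cur + 1
    queue <- s
    comp[s] <- cur
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nb <- which(adj[v, ] & comp == 0)
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Generate a synthetic longitudinal pathology dataset
#'
#' Draws regional parameters (a configurable fraction of regions grow,
#' with positive fall rates where growth occurs; the rest are silent with
#' zero rise and fall), simulates the chosen model, and adds i.i.d.
#' Gaussian observation noise per replicate. Negative noisy values are
#' kept, matching the Gaussian likelihood, unless `clip_negative` is set.
#'
#' @param conn A [connectome].
#' @param model Generating model kind (default `"DIFF_RF"`).
#' @param timepoints Observation grid (months).
#' @param n_replicates Animals per timepoint.
#' @param sigma Observation noise sd.
#' @param seeds Seed region labels (default: first ipsilateral region).
#' @param rho,alpha,u0 Global parameters of the generating model.
#' @param grow_frac Fraction of regions with positive rise parameter.
#' @param beta_mean,beta_sd,gamma_mean,gamma_sd Location/spread of the
#'   regional parameters in growing regions (draws are magnitudes of
#'   Normal variates, hence positive).
#' @param transport_mode Transport hypothesis used for generation.
#' @param clip_negative Truncate noisy observations at zero?
#' @param rng_seed Integer seed.
#' @return List with `obs` ([observation_set]), `true_params`
#'   ([model_parameters]), `trajectories` (`trajectory_set`) and
#'   `transport`.
#' @export
gen_pathology <- function(conn, model = "DIFF_RF",
                          timepoints = STUDY_TIMEPOINTS, n_replicates = 3,
                          sigma = 0.02, seeds = NULL, rho = 1.2,
                          alpha = 3, u0 = 0.1, grow_frac = 0.75,
                          beta_mean = 0.7, beta_sd = 0.25,
                          gamma_mean = 0.5, gamma_sd = 0.25,
                          transport_mode = "retrograde",
                          clip_negative = FALSE, rng_seed = 1) {
  stopifnot(inherits(conn, "connectome"))
  model <- match.arg(model, MODEL_KINDS)
  seeds <- seeds %||% grep("_ipsi$", conn$region_ids, value = TRUE)[1]
  with_seed(rng_seed, {
    N <- length(conn$region_ids)
    grown <- stats::runif(N) < grow_frac
    grown[resolve_seeds(seeds, conn$region_ids)] <- TRUE
    beta <- gamma <- numeric(N)
    beta[grown] <- abs(stats::rnorm(sum(grown), beta_mean, beta_sd))
    gamma[grown] <- abs(stats::rnorm(sum(grown), gamma_mean, gamma_sd))
    params <- switch(model,
      DIFF = model_parameters("DIFF", rho = rho, u0 = u0, sigma = sigma,
                              seeds = seeds),
      DIFF_R = model_parameters("DIFF_R", rho = rho, alpha = alpha,
                                beta = beta, u0 = u0, sigma = sigma,
                                seeds = seeds),
      DIFF_RF = model_parameters("DIFF_RF", rho = rho, alpha = alpha,
                                 beta = beta, gamma = gamma, u0 = u0,
                                 sigma = sigma, seeds = seeds))
    transport <- make_transport(conn, transport_mode)
    traj <- simulate_pathology(params, transport, timepoints)
    recs <- expand.grid(region = conn$region_ids, time = timepoints,
                        replicate = seq_len(n_replicates),
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    mu <- traj$u[cbind(match(recs$region, conn$region_ids),
                       match(recs$time, timepoints))]
    y <- mu + stats::rnorm(nrow(recs), 0, sigma)
    if (clip_negative) y <- pmax(y, 0)
    recs$value <- y
    list(obs = observation_set(recs, conn$region_ids),
         true_params = params, trajectories = traj, transport = transport)
  })
}

#' Generate regional expression coupled to a planted axis
#'
#' Per-gene coefficient pairs `(a_g, b_g)` are drawn from a 2-D Gaussian
#' elongated along `axis_direction` (sd 1 along the axis, `1/anisotropy`
#' across it); expression is `intercept + a_g z(beta) + b_g z(gamma) +
#' noise`. The matrix covers one hemisphere; use
#' [duplicate_hemispheres()] to mirror it.
#'
#' @param z_beta,z_gamma Standardised regional parameters, named by base
#'   region.
#' @param n_genes Number of genes.
#' @param axis_direction Unit length-2 vector: the planted axis.
#' @param anisotropy Ratio of along-axis to across-axis coefficient sd
#'   (>= 1).
#' @param noise_sd Expression noise sd.
#' @param ab Optional n_genes x 2 matrix of exact coefficients (overrides
#'   the Gaussian draw).
#' @param rng_seed Integer seed.
#' @return List with `expr` (regions x genes), `ab` (planted
#'   coefficients) and `axis_direction`.
#' @export
gen_expression <- function(z_beta, z_gamma, n_genes = 2000,
                           axis_direction = c(-0.37, 0.93),
                           anisotropy = 10, noise_sd = 0.5, ab = NULL,
                           rng_seed = 1) {
  stopifnot(length(z_beta) == length(z_gamma), anisotropy >= 1)
  v <- axis_direction / sqrt(sum(axis_direction^2))
  u <- c(-v[2], v[1])
  with_seed(rng_seed, {
    if (is.null(ab)) {
      z1 <- stats::rnorm(n_genes)
      z2 <- stats::rnorm(n_genes, sd = 1 / anisotropy)
      ab <- cbind(a = z1 * v[1] + z2 * u[1], b = z1 * v[2] + z2 * u[2])
    } else {
      ab <- as.matrix(ab)
      n_genes <- nrow(ab)
    }
    icept <- stats::rnorm(n_genes, 5, 1)
    expr <- outer(z_beta, ab[, 1]) + outer(z_gamma, ab[, 2]) +
      matrix(icept, length(z_beta), n_genes, byrow = TRUE) +
      matrix(stats::rnorm(length(z_beta) * n_genes, 0, noise_sd),
             length(z_beta), n_genes)
    colnames(expr) <- sprintf("gene%04d", seq_len(n_genes))
    rownames(expr) <- names(z_beta)
    list(expr = expr, ab = ab, axis_direction = v)
  })
}

#' Duplicate a single-hemisphere matrix across hemispheres
#'
#' Assigns identical values to the left and right instances of each
#' region, so single-hemisphere molecular data can be compared with
#' hemisphere-specific parameter estimates.
#'
#' @param x Matrix with base-region row names.
#' @param suffixes Hemisphere suffixes appended to the row names.
#' @return Matrix with `2 * nrow(x)` rows.
#' @export
duplicate_hemispheres <- function(x, suffixes = c("ipsi", "contra")) {
  x <- as.matrix(x)
  out <- rbind(x, x)
  rownames(out) <- c(paste0(rownames(x), "_", suffixes[1]),
                     paste0(rownames(x), "_", suffixes[2]))
  out
}

#' Generate cell-type compositions coupled to the vulnerability axis
#'
#' Dirichlet-distributed per-region compositions whose monoaminergic
#' concentration parameters scale with `exp(coupling_strength *
#' z(eta))`; zero coupling gives an exchangeable null.
#'
#' @param eta Named per-region axis values.
#' @param concentration Named base Dirichlet concentrations per class.
#' @param coupling_strength Nonnegative coupling of the monoaminergic
#'   classes to the axis.
#' @param monoaminergic Which classes respond to the axis.
#' @param rng_seed Integer seed.
#' @return Regions x classes fraction matrix (rows sum to 1), class
#'   `celltype_composition`.
#' @export
gen_celltypes <- function(eta,
                          concentration = c(glutamatergic = 40,
                                            GABAergic = 25, other = 8,
                                            dopaminergic = 2,
                                            noradrenergic = 1,
                                            serotonergic = 1,
                                            histaminergic = 0.5),
                          coupling_strength = 3,
                          monoaminergic = MONOAMINERGIC_CLASSES,
                          rng_seed = 1) {
  stopifnot(coupling_strength >= 0, !is.null(names(eta)))
  z <- if (length(unique(eta)) > 1) standardize(eta) else eta * 0
  with_seed(rng_seed, {
    n <- length(eta)
    k <- length(concentration)
    out <- matrix(0, n, k, dimnames = list(names(eta), names(concentration)))
    mono <- names(concentration) %in% monoaminergic
    for (i in seq_len(n)) {
      conc <- concentration
      conc[mono] <- conc[mono] * exp(coupling_strength * z[i])
      g <- stats::rgamma(k, shape = conc, rate = 1)
      out[i, ] <- g / sum(g)
    }
    structure(out, class = c("celltype_composition", "matrix"))
  })
}

#' Generate cluster tables realising a target composition
#'
#' Builds a cluster annotation table (sizes, classes), per-structure
#' spatial frequencies, and a small ontology with child structures for
#' the first region, such that [estimate_regional_counts()] followed by
#' [composition_from_counts()] recovers the input composition.
#'
#' @param composition Regions x classes fraction matrix.
#' @param cells_per_region Expected total cells per region.
#' @param clusters_per_class Number of clusters per class.
#' @param rng_seed Integer seed.
#' @return List with `clusters`, `frequencies`, `ontology` and
#'   `target_regions`.
#' @export
gen_clusters <- function(composition, cells_per_region = 20000,
                         clusters_per_class = 3, rng_seed = 1) {
  with_seed(rng_seed, {
    regions <- rownames(composition)
    classes <- colnames(composition)
    totals <- round(cells_per_region *
                      stats::runif(length(regions), 0.5, 1.5))
    counts <- composition * totals
    clusters <- list(); freqs <- list()
    cid <- 0
    for (cl in classes) {
      class_counts <- counts[, cl]
      split_w <- stats::runif(clusters_per_class, 0.5, 1.5)
      split_w <- split_w / sum(split_w)
      for (s in seq_len(clusters_per_class)) {
        cid <- cid + 1
        ccount <- class_counts * split_w[s]
        size <- sum(ccount)
        if (size == 0) next
        clusters[[cid]] <- data.frame(cluster_id = sprintf("c%03d", cid),
                                      size = size, class = cl)
        freqs[[cid]] <- data.frame(cluster_id = sprintf("c%03d", cid),
                                   structure = regions,
                                   frequency = ccount / size)
      }
    }
    freq <- do.call(rbind, freqs)
    # report the first region's contributions at two child structures
    r1 <- regions[1]
    sub <- freq$structure == r1
    child <- ifelse(stats::runif(sum(sub)) < 0.5, paste0(r1, "_subA"),
                    paste0(r1, "_subB"))
    freq$structure[sub] <- child
    ontology <- stats::setNames(c(r1, r1),
                                c(paste0(r1, "_subA"), paste0(r1, "_subB")))
    list(clusters = do.call(rbind, clusters),
         frequencies = freq[freq$frequency > 0, ],
         ontology = ontology, target_regions = regions)
  })
}

#' Generate a gene-set collection with planted enrichment
#'
#' Random sets draw genes uniformly; planted sets sample genes with
#' probability proportional to `|score|^planted_bias`, concentrating on
#' genes aligned with the axis.
#'
#' @param genes Character vector of gene symbols.
#' @param gene_scores Per-gene axis scores (e.g. correlation with eta),
#'   aligned with `genes`.
#' @param n_sets Total number of sets.
#' @param size_range Inclusive set-size range.
#' @param n_planted Number of planted (axis-enriched) sets.
#' @param planted_bias Exponent of the sampling weight for planted sets.
#' @param rng_seed Integer seed.
#' @return List with `sets` (named list of gene vectors) and `planted`
#'   (names of the planted sets).
#' @export
gen_genesets <- function(genes, gene_scores, n_sets = 100,
                         size_range = c(10, 50), n_planted = 10,
                         planted_bias = 5, rng_seed = 1) {
  stopifnot(length(genes) == length(gene_scores),
            size_range[1] >= 2, size_range[2] <= length(genes),
            n_planted <= n_sets)
  with_seed(rng_seed, {
    w <- abs(gene_scores)
    w <- (w / max(w))^planted_bias
    sets <- vector("list", n_sets)
    names(sets) <- c(sprintf("planted_set_%02d", seq_len(n_planted)),
                     sprintf("random_set_%03d", seq_len(n_sets - n_planted)))
    for (i in seq_len(n_sets)) {
      k <- sample(seq(size_range[1], size_range[2]), 1)
      sets[[i]] <- if (i <= n_planted)
        sample(genes, k, prob = w) else sample(genes, k)
    }
    list(sets = sets, planted = names(sets)[seq_len(n_planted)])
  })
}

#' Assemble a complete synthetic study
#'
#' Generates every dataset the pipeline consumes — connectome,
#' longitudinal pathology, regional expression, cell-type composition
#' with cluster tables, and gene sets — with all couplings planted from
#' known ground truth and all randomness derived from one master seed.
#'
#' @param n_per_hemi Regions per hemisphere.
#' @param n_genes,n_sets Expression/gene-set sizes.
#' @param coupling_strength Monoaminergic coupling to the planted axis.
#' @param rng_seed Master seed; the whole study is bit-reproducible from
#'   it.
#' @param ... Passed to [gen_pathology()].
#' @return Object of class `synthetic_study`.
#' @export
synth_study <- function(n_per_hemi = 20, n_genes = 2000, n_sets = 100,
                        coupling_strength = 3, rng_seed = 1, ...) {
  sub <- with_seed(rng_seed, sample.int(10^8, 7))
  conn <- gen_connectome(n_per_hemi, rng_seed = sub[1])
  path <- gen_pathology(conn, rng_seed = sub[2], ...)
  tp <- path$true_params
  half <- seq_len(n_per_hemi)
  base_ids <- base_region(conn$region_ids)[half]
  # base-region parameter summaries (mean of the two hemispheres)
  bmean <- (tp$beta[half] + tp$beta[n_per_hemi + half]) / 2
  gmean <- (tp$gamma[half] + tp$gamma[n_per_hemi + half]) / 2
  zb <- stats::setNames(standardize(bmean), base_ids)
  zg <- stats::setNames(standardize(gmean), base_ids)
  exprs <- gen_expression(zb, zg, n_genes, rng_seed = sub[3])
  v <- exprs$axis_direction
  eta_true <- v[1] * zb + v[2] * zg
  cells <- gen_celltypes(eta_true, coupling_strength = coupling_strength,
                         rng_seed = sub[4])
  clus <- gen_clusters(cells, rng_seed = sub[5])
  gene_scores <- as.vector(stats::cor(exprs$expr, eta_true))
  sr <- c(min(10, max(2, n_genes %/% 5)), min(50, n_genes))
  gs <- gen_genesets(colnames(exprs$expr), gene_scores, n_sets = n_sets,
                     size_range = sr, n_planted = min(10, n_sets %/% 4),
                     rng_seed = sub[6])
  structure(list(
    connectome = conn, obs = path$obs, true_params = tp,
    trajectories = path$trajectories, transport = path$transport,
    expression = exprs$expr, celltypes = cells, clusters = clus,
    genesets = gs$sets,
    ground_truth = list(axis_direction = v, ab = exprs$ab,
                        eta = eta_true, z_beta = zb, z_gamma = zg,
                        planted_sets = gs$planted,
                        coupling_strength = coupling_strength,
                        gene_scores = gene_scores),
    rng_seed = rng_seed),
    class = "synthetic_study")
}
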