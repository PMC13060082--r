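# Readers and writers for the plain-text interchange formats.

#' Read / write a connectivity matrix
#'
#' CSV layout: header row, first column holds region labels, remaining
#' columns form the square numeric matrix. Hemisphere tags are parsed
#' from `_ipsi`/`_contra` label suffixes; coordinates can be supplied as
#' a separate CSV with columns `region,x,y,z`.
#'
#' @param path CSV file path.
#' @param coords_path Optional coordinates CSV.
#' @return A [connectome].
#' @export
read_connectivity <- function(path, coords_path = NULL) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate region labels in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M)) {
    badc <- names(df)[-1][!vapply(df[-1], is.numeric, TRUE)]
    stop("non-numeric connectivity column(s): ",
         paste(badc, collapse = ", "), call. = FALSE)
  }
  rownames(M) <- ids
  if (!identical(colnames(M), ids))
    stop("column labels do not match row labels in ", path, call. = FALSE)
  coords <- NULL
  if (!is.null(coords_path)) {
    cd <- utils::read.csv(coords_path)
    ix <- match(ids, cd$region)
    if (anyNA(ix))
      stop("coordinates missing for region(s): ",
           paste(ids[is.na(ix)], collapse = ", "), call. = FALSE)
    coords <- as.matrix(cd[ix, c("x", "y", "z")])
  }
  connectome(M, coords = coords)
}

#' @rdname read_connectivity
#' @param conn A [connectome].
#' @export
write_connectivity <- function(conn, path, coords_path = NULL) {
  df <- data.frame(region = conn$region_ids, conn$W, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  if (!is.null(coords_path) && !is.null(conn$coords)) {
    utils::write.csv(data.frame(region = conn$region_ids,
                                x = conn$coords[, 1], y = conn$coords[, 2],
                                z = conn$coords[, 3]),
                     coords_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read / write longitudinal observations
#'
#' Long CSV with columns `region,time_months,replicate,value`.
#'
#' @param path CSV file path.
#' @param region_ids Reference region labels for validation.
#' @return An [observation_set].
#' @export
read_observations <- function(path, region_ids) {
  df <- utils::read.csv(path)
  observation_set(df, region_ids)
}

#' @rdname read_observations
#' @param obs An [observation_set].
#' @export
write_observations <- function(obs, path) {
  df <- as.data.frame(obs)
  names(df)[names(df) == "time"] <- "time_months"
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read / write a regions-by-genes expression matrix
#'
#' CSV with header; first column = region labels, remaining columns =
#' genes.
#'
#' @param path CSV file path.
#' @return Numeric matrix, regions in rows.
#' @export
read_expression <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids))
    stop("duplicate region labels in ", path, call. = FALSE)
  M <- as.matrix(df[, -1, drop = FALSE])
  if (!is.numeric(M))
    stop("non-numeric expression values in ", path, call. = FALSE)
  rownames(M) <- ids
  M
}

#' @rdname read_expression
#' @param expr Regions x genes matrix.
#' @export
write_expression <- function(expr, path) {
  utils::write.csv(data.frame(region = rownames(expr), expr,
                              check.names = FALSE),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read / write cluster tables and the structure ontology
#'
#' The cluster table CSV has columns `cluster_id,size,class`; the
#' frequency CSV has `cluster_id,structure,frequency`; the ontology is a
#' JSON object mapping child structure to parent.
#'
#' @param cluster_path,freq_path,ontology_path File paths.
#' @return List with `clusters`, `frequencies`, `ontology`.
#' @export
read_clusters <- function(cluster_path, freq_path, ontology_path) {
  clusters <- utils::read.csv(cluster_path)
  frequencies <- utils::read.csv(freq_path)
  need1 <- c("cluster_id", "size", "class")
  need2 <- c("cluster_id", "structure", "frequency")
  if (!all(need1 %in% names(clusters)))
    stop("cluster table needs columns: ", paste(need1, collapse = ", "),
         call. = FALSE)
  if (!all(need2 %in% names(frequencies)))
    stop("frequency table needs columns: ", paste(need2, collapse = ", "),
         call. = FALSE)
  onto <- unlist(jsonlite::read_json(ontology_path))
  list(clusters = clusters, frequencies = frequencies, ontology = onto)
}

#' @rdname read_clusters
#' @param clus List as produced by [gen_clusters()].
#' @export
write_clusters <- function(clus, cluster_path, freq_path, ontology_path) {
  utils::write.csv(clus$clusters, cluster_path, row.names = FALSE)
  utils::write.csv(clus$frequencies, freq_path, row.names = FALSE)
  jsonlite::write_json(as.list(clus$ontology), ontology_path,
                       auto_unbox = TRUE)
  invisible(cluster_path)
}

#' Read / write gene-set collections (GMT)
#'
#' Tab-separated lines: set name, description, member genes. Sets smaller
#' than `min_size` after parsing are dropped with a warning.
#'
#' @param path GMT file path.
#' @param min_size Minimum retained set size.
#' @return Named list of character vectors.
#' @export
read_gmt <- function(path, min_size = 2) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3)
  if (length(bad))
    stop("malformed GMT line(s) (fewer than 3 fields) at line ",
         paste(bad, collapse = ", "), " of ", path, call. = FALSE)
  sets <- lapply(parts, function(p) unique(p[-(1:2)]))
  names(sets) <- vapply(parts, `[[`, "", 1)
  small <- lengths(sets) < min_size
  if (any(small)) {
    warning(sum(small), " gene set(s) below the minimum size ", min_size,
            " were dropped at load", call. = FALSE)
    sets <- sets[!small]
  }
  sets
}

#' @rdname read_gmt
#' @param sets Named list of gene vectors.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm)
    paste(c(nm, "na", sets[[nm]]), collapse = "\t"), "")
  writeLines(lines, path)
  invisible(path)
}

#' Write a complete synthetic study to a directory
#'
#' Emits connectivity, coordinates, observations, expression, cluster and
#' gene-set files plus a ground-truth JSON.
#'
#' @param study A `synthetic_study`.
#' @param dir Output directory (created if missing).
#' @return The directory path, invisibly.
#' @export
write_study <- function(study, dir) {
  stopifnot(inherits(study, "synthetic_study"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  fp <- function(f) file.path(dir, f)
  write_connectivity(study$connectome, fp("connectivity.csv"),
                     fp("coordinates.csv"))
  write_observations(study$obs, fp("observations.csv"))
  write_expression(study$expression, fp("expression.csv"))
  write_clusters(study$clusters, fp("clusters.csv"),
                 fp("cluster_frequencies.csv"), fp("ontology.json"))
  write_gmt(study$genesets, fp("genesets.gmt"))
  utils::write.csv(data.frame(region = rownames(study$celltypes),
                              study$celltypes, check.names = FALSE),
                   fp("celltype_fractions.csv"), row.names = FALSE)
  gt <- study$ground_truth
  tp <- study$true_params
  jsonlite::write_json(
    list(rng_seed = study$rng_seed,
         axis_direction = gt$axis_direction,
         planted_sets = gt$planted_sets,
         coupling_strength = gt$coupling_strength,
         eta = as.list(gt$eta),
         true_global = list(rho = tp$rho, alpha = tp$alpha, u0 = tp$u0,
                            sigma = tp$sigma),
         true_beta = stats::setNames(as.list(tp$beta),
                                     study$connectome$region_ids),
         true_gamma = stats::setNames(as.list(tp$gamma),
                                      study$connectome$region_ids),
         seeds = tp$seeds),
    fp("ground_truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
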