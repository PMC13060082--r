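# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores the caller's RNG state so seeded helpers do not
#' perturb enclosing simulations.
#' @noRd
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# Column variances with ddof = 1.
col_vars <- function(m) {
  n <- nrow(m)
  if (n < 2) stop("need at least 2 rows for a variance", call. = FALSE)
  mu <- colMeans(m)
  colSums((m - rep(mu, each = n))^2) / (n - 1)
}

assert_square_nonneg <- function(W, what = "W") {
  if (!is.matrix(W) || !is.numeric(W))
    stop(what, " must be a numeric matrix", call. = FALSE)
  if (nrow(W) != ncol(W))
    stop(what, " must be square (got ", nrow(W), "x", ncol(W), ")",
         call. = FALSE)
  if (any(!is.finite(W)))
    stop(what, " contains non-finite entries", call. = FALSE)
  if (any(W < 0))
    stop(what, " contains negative entries", call. = FALSE)
  invisible(W)
}

# Polynomial rolling hash of a character scalar (config fingerprints only;
# kept within double-precision exact-integer range).
fnv1a_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 0
  for (b in bytes) h <- (h * 131 + b) %% 2147483647
  sprintf("%08x", h)
}

rf_log <- function(stage, ...) {
  message(sprintf("[%s] %s", stage, paste0(...)))
}

# Strip a hemisphere suffix from region labels.
base_region <- function(labels) {
  sub("_(ipsi|contra|L|R)$", "", labels)
}

hemisphere_from_labels <- function(labels) {
  suf <- sub("^.*_(ipsi|contra|L|R)$", "\\1", labels)
  suf[!grepl("_(ipsi|contra|L|R)$", labels)] <- NA_character_
  map <- c(ipsi = "ipsi", contra = "contra", L = "ipsi", R = "contra")
  unname(map[suf])
}
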