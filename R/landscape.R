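# The 2-D sleep landscape: standardized 18-feature period vectors embedded
# with UMAP (via the umap-learn Python library, the reference
# implementation for this embedding) or PCA, then clustered with DBSCAN.
# Cluster indices from DBSCAN are arbitrary; characterize_clusters() maps
# them onto semantic cluster ids 0-4 by their dominant night composition.

#' Fit the sleep landscape
#'
#' Z-scores the period features (constant columns are dropped with a
#' warning), embeds to 2-D, clusters the embedding with DBSCAN, and
#' (optionally) assigns DBSCAN noise points to the nearest cluster
#' centroid so every period receives a phenotype.
#'
#' @param periods Period table from [assemble_periods()], or a numeric
#'   matrix of period features.
#' @param feature_cols Feature columns to use (default the 18-vector).
#' @param method `"umap"` (default; requires the `umap-learn` Python
#'   library on `PATH` via `python`) or `"pca"`.
#' @param n_neighbors,min_dist UMAP parameters (defaults 15 and 0.1, with
#'   2 output components).
#' @param eps,min_pts DBSCAN parameters in embedding units.
#' @param seed Integer seed for the embedding.
#' @param min_periods Minimum number of periods required.
#' @param assign_noise Assign noise points to nearest cluster centroid
#'   (default TRUE); if FALSE noise keeps cluster id -1.
#' @return A `sleep_landscape`: standardization constants, `embedding`
#'   (n x 2 matrix), `cluster` (integer ids, 0-based; -1 = unassigned
#'   noise), `was_noise`, and the parameters used.
#' @export
fit_landscape <- function(periods, feature_cols = PERIOD_FEATURES,
                          method = c("umap", "pca"),
                          n_neighbors = 15L, min_dist = 0.1,
                          eps = 0.5, min_pts = 15L, seed = 42L,
                          min_periods = 500L, assign_noise = TRUE) {
  method <- match.arg(method)
  x <- if (is.matrix(periods)) periods else
    as.matrix(as.data.table(periods)[, feature_cols, with = FALSE])
  if (nrow(x) < min_periods)
    stopf("landscape needs >= %d periods, got %d", min_periods, nrow(x))
  ctr <- colMeans(x)
  scl <- apply(x, 2, stats::sd)
  constant <- scl <= 0 | !is.finite(scl)
  if (any(constant)) {
    warnf("dropping constant feature column(s): %s",
          paste(colnames(x)[constant], collapse = ", "))
    x <- x[, !constant, drop = FALSE]
    ctr <- ctr[!constant]; scl <- scl[!constant]
  }
  z <- sweep(sweep(x, 2, ctr), 2, scl, "/")
  emb <- switch(method,
    umap = embed_umap(z, n_neighbors = n_neighbors, min_dist = min_dist,
                      seed = seed),
    pca  = {
      p <- stats::prcomp(z, center = FALSE, scale. = FALSE)
      p$x[, 1:2, drop = FALSE]
    })
  colnames(emb) <- c("x", "y")
  cl <- dbscan_cluster(emb, eps = eps, min_pts = min_pts)
  was_noise <- cl < 0L
  if (assign_noise && any(was_noise) && any(!was_noise))
    cl <- assign_noise_to_nearest(emb, cl)
  structure(
    list(center = ctr, scale = scl, dropped = names(constant)[constant],
         embedding = emb, cluster = cl, was_noise = was_noise,
         params = list(method = method, n_neighbors = n_neighbors,
                       min_dist = min_dist, n_components = 2L,
                       eps = eps, min_pts = min_pts, seed = seed,
                       assign_noise = assign_noise)),
    class = "sleep_landscape")
}

#' @export
print.sleep_landscape <- function(x, ...) {
  k <- sort(unique(x$cluster[x$cluster >= 0]))
  cat(sprintf("<sleep_landscape: %d periods, %s embedding, %d DBSCAN clusters (%d noise)>\n",
              nrow(x$embedding), x$params$method, length(k), sum(x$was_noise)))
  invisible(x)
}

#' 2-D UMAP embedding via the umap-learn Python library
#'
#' Runs the reference UMAP implementation in a Python subprocess through a
#' CSV handshake. Deterministic for a fixed seed on one platform;
#' cross-platform bit-identity of UMAP coordinates is not promised.
#'
#' @param x Numeric matrix (observations x features).
#' @param n_neighbors,min_dist,n_components UMAP parameters.
#' @param seed Integer random_state.
#' @param python Python executable (default `python` on PATH).
#' @return Numeric matrix (n x n_components).
#' @export
embed_umap <- function(x, n_neighbors = 15L, min_dist = 0.1,
                       n_components = 2L, seed = 42L,
                       python = Sys.which("python")) {
  if (!nzchar(python))
    stopf("no python executable found; use fit_landscape(method = 'pca')")
  script <- system.file("python", "umap_embed.py", package = "sleepscape")
  if (!nzchar(script)) stopf("umap_embed.py not found in the installed package")
  fin <- tempfile(fileext = ".csv"); fout <- tempfile(fileext = ".csv")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  fwrite(as.data.table(x), fin, col.names = FALSE)
  res <- suppressWarnings(system2(
    python, c(script, fin, fout, n_neighbors, min_dist, n_components, seed),
    stdout = TRUE, stderr = TRUE))
  status <- attr(res, "status") %||% 0L
  if (status != 0L || !file.exists(fout))
    stopf("umap-learn subprocess failed:\n%s", paste(res, collapse = "\n"))
  as.matrix(fread(fout, header = FALSE))
}

# ---- DBSCAN ---------------------------------------------------------------

#' DBSCAN clustering of a 2-D embedding
#'
#' Classic DBSCAN (core points have >= `min_pts` neighbours within `eps`,
#' neighbourhoods are epsilon-balls, counts include the point itself) with
#' a grid index over the plane for neighbour queries.
#'
#' @param x Numeric matrix with 2 columns.
#' @param eps Neighbourhood radius.
#' @param min_pts Minimum neighbourhood size for a core point.
#' @return Integer cluster ids, 0-based; -1 marks noise.
#' @export
dbscan_cluster <- function(x, eps = 0.5, min_pts = 15L) {
  stopifnot(is.matrix(x), ncol(x) == 2)
  n <- nrow(x)
  cx <- as.integer(floor(x[, 1] / eps)); cy <- as.integer(floor(x[, 2] / eps))
  key <- paste(cx, cy)
  index <- split(seq_len(n), key)
  eps2 <- eps^2
  region_query <- function(i) {
    ks <- paste(rep(cx[i] + (-1:1), each = 3), rep(cy[i] + (-1:1), 3))
    cand <- unlist(index[ks], use.names = FALSE)
    d2 <- (x[cand, 1] - x[i, 1])^2 + (x[cand, 2] - x[i, 2])^2
    cand[d2 <= eps2]
  }
  labels <- rep(-2L, n)  # -2 unvisited, -1 noise, >=0 cluster
  cl <- -1L
  for (i in seq_len(n)) {
    if (labels[i] != -2L) next
    nb <- region_query(i)
    if (length(nb) < min_pts) { labels[i] <- -1L; next }
    cl <- cl + 1L
    labels[i] <- cl
    queue <- setdiff(nb, i)
    while (length(queue)) {
      j <- queue[[1]]; queue <- queue[-1]
      if (labels[j] == -1L) labels[j] <- cl          # border point
      if (labels[j] != -2L) next
      labels[j] <- cl
      nb2 <- region_query(j)
      if (length(nb2) >= min_pts)
        queue <- c(queue, nb2[labels[nb2] == -2L])
    }
  }
  labels
}

assign_noise_to_nearest <- function(emb, cl) {
  ks <- sort(unique(cl[cl >= 0L]))
  centroids <- t(vapply(ks, function(k)
    colMeans(emb[cl == k, , drop = FALSE]), numeric(2)))
  noise <- which(cl < 0L)
  for (i in noise) {
    d2 <- (centroids[, 1] - emb[i, 1])^2 + (centroids[, 2] - emb[i, 2])^2
    cl[i] <- ks[which.min(d2)]
  }
  cl
}

# ---- silhouette -----------------------------------------------------------

#' Silhouette scores per point and per cluster
#'
#' For each point: `a` = mean distance to the other members of its own
#' cluster, `b` = mean distance to the members of the nearest other
#' cluster, score = (b - a) / max(a, b). Singleton clusters score 0.
#'
#' @param x Numeric matrix of coordinates (here, the 2-D embedding).
#' @param labels Cluster labels (any atomic type; >= 2 distinct required).
#' @return Named numeric vector of per-cluster mean silhouettes, with the
#'   per-point scores in attribute `"points"`.
#' @export
silhouette_by_cluster <- function(x, labels) {
  x <- as.matrix(x)
  ks <- sort(unique(labels))
  if (length(ks) < 2) stopf("silhouette needs >= 2 clusters")
  n <- nrow(x)
  # mean distance from every point to every cluster
  md <- matrix(NA_real_, n, length(ks))
  sizes <- integer(length(ks))
  for (j in seq_along(ks)) {
    members <- which(labels == ks[j])
    sizes[j] <- length(members)
    tot <- numeric(n)
    for (m in members)  # accumulate column-wise to avoid an n x n matrix
      tot <- tot + sqrt(rowSums(sweep(x, 2, x[m, ])^2))
    md[, j] <- tot / length(members)
  }
  scores <- numeric(n)
  for (i in seq_len(n)) {
    j <- match(labels[i], ks)
    if (sizes[j] == 1L) { scores[i] <- 0; next }
    a <- md[i, j] * sizes[j] / (sizes[j] - 1L)  # exclude self-distance 0
    b <- min(md[i, -j])
    scores[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  out <- vapply(ks, function(k) mean(scores[labels == k]), numeric(1))
  names(out) <- as.character(ks)
  attr(out, "points") <- scores
  out
}

# ---- cluster characterization ---------------------------------------------

#' Characterize DBSCAN clusters and map them to semantic ids
#'
#' Summarizes each DBSCAN cluster (feature means/SDs, night-composition
#' shares) and maps arbitrary DBSCAN indices onto the semantic cluster ids
#' 0-4 by each cluster's modal rule-based label (0: every night exactly
#' one long window; 1: some short-only night; 2: some long+short night;
#' 3: some multi-long night; 4: only very-short-sleep nights). An
#' ambiguous mapping (two DBSCAN clusters sharing a semantic id) is
#' reported with a warning and flagged.
#'
#' @param landscape A `sleep_landscape`.
#' @param periods The period table the landscape was fitted on (same row
#'   order).
#' @return List: `mapping` (data.table dbscan_id -> semantic id, modal
#'   share, size), `summary` (per-cluster feature means/SDs),
#'   `semantic` (per-period semantic cluster id), `ambiguous` (logical).
#' @export
characterize_clusters <- function(landscape, periods) {
  periods <- as.data.table(periods)
  stopifnot(nrow(periods) == nrow(landscape$embedding))
  rl <- rule_cluster(periods)
  cl <- landscape$cluster
  ks <- sort(unique(cl[cl >= 0L]))
  maps <- lapply(ks, function(k) {
    sel <- cl == k
    tab <- sort(table(rl[sel]), decreasing = TRUE)
    data.table(dbscan_id = k, semantic = as.integer(names(tab)[1]),
               modal_share = as.numeric(tab[1]) / sum(sel), n = sum(sel))
  })
  mapping <- rbindlist(maps)
  ambiguous <- anyDuplicated(mapping$semantic) > 0
  if (ambiguous)
    warnf("semantic mapping ambiguous: DBSCAN clusters share a dominant composition; override manually")
  summ <- periods[, c(list(n = .N),
                      lapply(.SD, mean), lapply(.SD, stats::sd)),
                  by = .(dbscan_id = cl), .SDcols = PERIOD_FEATURES]
  semantic <- mapping$semantic[match(cl, mapping$dbscan_id)]
  list(mapping = mapping, summary = summ, semantic = semantic,
       ambiguous = ambiguous)
}
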