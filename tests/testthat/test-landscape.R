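# Embedding, DBSCAN, silhouette, and semantic cluster mapping.

blob <- function(n, cx, cy, sd = 0.05, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  cbind(stats::rnorm(n, cx, sd), stats::rnorm(n, cy, sd))
}

test_that("dbscan finds separated blobs and marks stragglers as noise", {
  set.seed(1)
  x <- rbind(blob(40, 0, 0), blob(40, 5, 5), c(50, 50))
  cl <- dbscan_cluster(x, eps = 0.5, min_pts = 10)
  expect_equal(cl[81], -1L)
  expect_equal(length(unique(cl[1:40])), 1L)
  expect_equal(length(unique(cl[41:80])), 1L)
  expect_true(cl[1] != cl[41])
  expect_setequal(unique(cl), c(0L, 1L, -1L))
})

test_that("dbscan matches a naive quadratic implementation on random data", {
  naive_dbscan <- function(x, eps, min_pts) {
    d <- as.matrix(stats::dist(x))
    n <- nrow(x)
    lab <- rep(-2L, n); cl <- -1L
    for (i in seq_len(n)) {
      if (lab[i] != -2L) next
      nb <- which(d[i, ] <= eps)
      if (length(nb) < min_pts) { lab[i] <- -1L; next }
      cl <- cl + 1L; lab[i] <- cl
      queue <- setdiff(nb, i)
      while (length(queue)) {
        j <- queue[1]; queue <- queue[-1]
        if (lab[j] == -1L) lab[j] <- cl
        if (lab[j] != -2L) next
        lab[j] <- cl
        nb2 <- which(d[j, ] <= eps)
        if (length(nb2) >= min_pts) queue <- c(queue, nb2[lab[nb2] == -2L])
      }
    }
    lab
  }
  set.seed(23)
  for (r in 1:10) {
    x <- rbind(blob(30, 0, 0, 0.3), blob(30, 3, 0, 0.3), blob(15, 0, 3, 0.5))
    eps <- stats::runif(1, 0.2, 0.7)
    got <- dbscan_cluster(x, eps = eps, min_pts = 5)
    want <- naive_dbscan(x, eps = eps, min_pts = 5)
    # label ids may differ; partitions (incl. noise) must agree
    expect_true(all((got == -1L) == (want == -1L)))
    core <- got != -1L
    if (sum(core) > 1)
      expect_gt(oracle_ari(got[core], want[core]), 0.999)
  }
})

test_that("silhouette agrees with the textbook oracle to 1e-12", {
  set.seed(9)
  for (r in 1:100) {
    n <- sample(8:25, 1)
    x <- matrix(stats::rnorm(2 * n), ncol = 2)
    labels <- sample(0:2, n, replace = TRUE)
    if (length(unique(labels)) < 2) labels[1:2] <- 0:1
    got <- silhouette_by_cluster(x, labels)
    want <- oracle_silhouette(x, labels)
    expect_equal(attr(got, "points"), want, tolerance = 1e-12)
    for (k in unique(labels))
      expect_equal(got[[as.character(k)]], mean(want[labels == k]),
                   tolerance = 1e-12)
  }
})

test_that("silhouette limit cases: a = b scores 0; tight far clusters near 1", {
  # point 1: own-cluster partner at distance 2, other cluster at mean 2
  x <- matrix(c(0, 0, 0, 2, 2, 0, -2, 0), ncol = 2, byrow = TRUE)
  s <- attr(silhouette_by_cluster(x, c("A", "A", "B", "B")), "points")
  expect_equal(s[1], 0)
  # a = 0.2, b = 0.8 gives (b - a)/max = 0.75: collinear construction
  x2 <- matrix(c(0, 0, 0.2, 0, 0.7, 0, 0.9, 0), ncol = 2, byrow = TRUE)
  s2 <- attr(silhouette_by_cluster(x2, c(0, 0, 1, 1)), "points")
  expect_equal(s2[1], 0.75)
  # tight, far-apart clusters approach 1
  x3 <- rbind(blob(20, 0, 0, 1e-4, seed = 2), blob(20, 100, 0, 1e-4))
  s3 <- silhouette_by_cluster(x3, rep(0:1, each = 20))
  expect_true(all(s3 > 0.999))
  expect_error(silhouette_by_cluster(x3, rep(0, 40)), ">= 2 clusters")
})

test_that("standardization is applied and constant columns are dropped", {
  set.seed(4)
  x <- cbind(matrix(stats::rnorm(600 * 3, mean = c(5, -2, 0), sd = c(2, 1, 4)),
                    ncol = 3, byrow = TRUE), const = 1)
  colnames(x) <- c("f1", "f2", "f3", "const")
  expect_warning(ls <- fit_landscape(x, feature_cols = colnames(x),
                                     method = "pca", min_pts = 5),
                 "constant")
  expect_false("const" %in% names(ls$center))
  z <- sweep(sweep(x[, 1:3], 2, ls$center), 2, ls$scale, "/")
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, stats::sd) - 1) < 1e-9))
})

test_that("pca landscape is deterministic and maps duplicates identically", {
  set.seed(5)
  base <- rbind(matrix(stats::rnorm(300 * 4, 0), ncol = 4),
                matrix(stats::rnorm(300 * 4, 8), ncol = 4))
  colnames(base) <- paste0("f", 1:4)
  x <- base[rep(seq_len(nrow(base)), each = 2), ]  # duplicate every row
  l1 <- fit_landscape(x, feature_cols = colnames(x), method = "pca")
  l2 <- fit_landscape(x, feature_cols = colnames(x), method = "pca")
  expect_identical(l1$cluster, l2$cluster)
  expect_identical(l1$embedding, l2$embedding)
  odd <- seq(1, nrow(x), by = 2)
  expect_identical(l1$cluster[odd], l1$cluster[odd + 1L])
})

test_that("noise assignment gives every period a cluster", {
  set.seed(11)
  x <- rbind(blob(300, 0, 0, 0.2), blob(300, 6, 0, 0.2), c(3, 8))
  cl <- dbscan_cluster(x, eps = 0.5, min_pts = 10)
  expect_true(any(cl == -1L))
  ls <- fit_landscape(x, method = "pca", min_periods = 100, min_pts = 10)
  expect_true(all(ls$cluster >= 0L))
})

test_that("umap landscape recovers well-separated sd-0 archetypes", {
  cfg <- generator_config(
    archetypes = c("rec", "1-a", "c2", "c3", "c4"),
    transition_matrix = diag(5), n_individuals = 100, n_nights = 18,
    missing_night_prob = 0, sd_scale = 0, seed = 41)
  # sd-0 features are discrete (zero-variance columns, repeated rows);
  # suppress the expected constant-column / mapping warnings
  res <- suppressWarnings(run_pipeline(pipeline_config(
    generator = cfg, labeller = "landscape", embed_method = "umap",
    min_periods = 200, min_pts = 10)))
  labs <- truth_high_level(res)
  expect_gte(length(unique(res$landscape$cluster)), 2L)
  # high-level granularity: DBSCAN clusters mapped to semantic ids
  expect_gte(oracle_ari(res$periods$cluster, labs), 0.9)
  # fixed seed, fresh run: identical partition
  res2 <- suppressWarnings(run_pipeline(pipeline_config(
    generator = cfg, labeller = "landscape", embed_method = "umap",
    min_periods = 200, min_pts = 10)))
  expect_identical(res2$landscape$cluster, res$landscape$cluster)
})

test_that("semantic mapping is invariant to permuting DBSCAN label indices", {
  set.seed(12)
  cfg <- generator_config(archetypes = c("rec", "c2", "c3"),
                          transition_matrix = diag(3),
                          n_individuals = 40, n_nights = 12,
                          missing_night_prob = 0, sd_scale = 0, seed = 14)
  pop <- generate_population(cfg)
  nf <- compute_night_features(filter_nights(pop$nights))
  per <- assemble_periods(nf)
  # synthetic landscape: pretend clusters were found by rules
  rl <- rule_cluster(per$periods)
  fake <- structure(list(
    embedding = cbind(x = as.numeric(rl), y = 0 * as.numeric(rl)),
    cluster = as.integer(factor(rl)) - 1L,
    was_noise = rep(FALSE, nrow(per$periods)),
    params = list()), class = "sleep_landscape")
  ch1 <- characterize_clusters(fake, per$periods)
  perm <- c(2L, 0L, 1L)
  fake2 <- fake
  fake2$cluster <- perm[fake$cluster + 1L]
  ch2 <- characterize_clusters(fake2, per$periods)
  expect_identical(ch1$semantic, ch2$semantic)
})
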