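# Phenotyping stage: robust outlier exclusion, log transforms and
# standardization, k-means with many restarts, elbow-based selection of the
# cluster count, and canonical labeling of the three-cluster solution.

transformed_columns <- function(features) {
  stopifnot(all(c("avg_frequency", "duration", "amplitude", "n_cycles")
                %in% names(features)))
  if (any(features$amplitude <= 0) || any(features$n_cycles <= 0))
    stop("amplitude and n_cycles must be positive for the log transform",
         call. = FALSE)
  cbind(avg_frequency = features$avg_frequency,
        duration = features$duration,
        log_amplitude = log(features$amplitude),
        log_n_cycles = log(features$n_cycles))
}

#' Exclude events with extreme feature values
#'
#' Removes rows whose robust z-score (median/MAD) exceeds `threshold` on any
#' of the four transformed feature columns. Statistics are computed once on
#' the original table, so removal is order-independent. Columns with zero
#' MAD are skipped with a warning.
#'
#' @param features raw feature data frame with columns `avg_frequency`,
#'   `duration`, `amplitude`, `n_cycles`.
#' @param threshold robust z cutoff, default 3.5.
#' @return list: `features` (retained rows), `excluded` (integer row
#'   indices of the input that were removed).
#' @export
exclude_outliers <- function(features, threshold = 3.5) {
  if (nrow(features) < 10)
    stop("outlier screening needs at least 10 events", call. = FALSE)
  x <- transformed_columns(features)
  out <- rep(FALSE, nrow(x))
  for (j in seq_len(ncol(x))) {
    m <- median(x[, j])
    s <- mad(x[, j])
    if (s == 0) {
      warning("column ", colnames(x)[j], " has zero MAD; skipped in outlier screen")
      next
    }
    out <- out | abs(x[, j] - m) / s > threshold
  }
  if (all(out)) stop("outlier screen removed every event", call. = FALSE)
  list(features = features[!out, , drop = FALSE], excluded = which(out))
}

#' Transform and standardize the feature matrix
#'
#' Applies the natural log to amplitude and cycle count (their distributions
#' are right-skewed) and z-standardizes all four columns so each contributes
#' equally to the Euclidean distances used by k-means. Per-column means and
#' SDs are retained so the transform inverts exactly.
#'
#' @param features raw feature data frame.
#' @return an `hfo_feature_matrix`: standardized numeric matrix with columns
#'   `avg_frequency`, `duration`, `log_amplitude`, `log_n_cycles` and
#'   attributes `center` and `scale`.
#' @export
transform_and_standardize <- function(features) {
  x <- transformed_columns(features)
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  if (any(scl == 0)) stop("constant feature column cannot be standardized",
                          call. = FALSE)
  z <- sweep(sweep(x, 2, ctr, "-"), 2, scl, "/")
  structure(z, center = ctr, scale = scl, class = c("hfo_feature_matrix", "matrix"))
}

#' Invert the standardization (and logs) of a feature matrix
#'
#' @param z an `hfo_feature_matrix` (or any matrix in the standardized
#'   space, e.g. centroids).
#' @param ref the `hfo_feature_matrix` carrying the stored center/scale
#'   (defaults to `z` itself).
#' @return matrix on the raw feature scale with columns `avg_frequency`,
#'   `duration`, `amplitude`, `n_cycles`.
#' @export
invert_transform <- function(z, ref = z) {
  ctr <- attr(ref, "center"); scl <- attr(ref, "scale")
  x <- sweep(sweep(unclass(z), 2, scl, "*"), 2, ctr, "+")
  x[, 3] <- exp(x[, 3])
  x[, 4] <- exp(x[, 4])
  colnames(x) <- c("avg_frequency", "duration", "amplitude", "n_cycles")
  x
}

# k-means++ seeding: D^2-weighted sampling of initial centers.
kmeanspp_init <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(0, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- colSums((t(x) - centers[1, ])^2)
  for (i in seq_len(k - 1)) {
    p <- if (sum(d2) > 0) d2 / sum(d2) else rep(1 / n, n)
    centers[i + 1, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, colSums((t(x) - centers[i + 1, ])^2))
  }
  centers
}

#' Fit k-means with many restarts
#'
#' Runs Lloyd's algorithm from k-means++ initialisations `n_restarts` times
#' and keeps the solution with the smallest total within-cluster sum of
#' squares (WSS). Deterministic given `seed`. Restarts that collapse to an
#' empty cluster are re-drawn.
#'
#' @param z standardized `hfo_feature_matrix`.
#' @param k number of clusters (`k < nrow(z)`).
#' @param n_restarts number of random restarts, default 300.
#' @param seed integer seed.
#' @return an `hfo_cluster_model`: list with `k`, `centroids` (standardized),
#'   `centroids_raw` (back-transformed), `assignments`, `total_wss`,
#'   `n_restarts`, `seed`.
#' @export
kmeans_fit <- function(z, k, n_restarts = 300, seed = 1) {
  x <- unclass(z)
  if (k > nrow(x) || k < 1) stop("need 1 <= k <= n rows", call. = FALSE)
  if (k == nrow(x)) {
    # one point per cluster: WSS is exactly zero
    return(structure(list(
      k = k, centroids = x, centroids_raw = invert_transform(x, ref = z),
      assignments = seq_len(nrow(x)), total_wss = 0,
      n_restarts = n_restarts, seed = seed), class = "hfo_cluster_model"))
  }
  with_seed(seed, {
    best <- NULL
    r <- 0
    while (r < n_restarts) {
      init <- kmeanspp_init(x, k)
      fit <- tryCatch(
        kmeans(x, centers = init, iter.max = 100, algorithm = "Lloyd"),
        error = function(e) NULL, warning = function(w) NULL)
      if (is.null(fit) || any(fit$size == 0)) { r <- r + 1; next }
      if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
      r <- r + 1
    }
    if (is.null(best)) stop("k-means failed on every restart", call. = FALSE)
    structure(list(
      k = k,
      centroids = best$centers,
      centroids_raw = invert_transform(best$centers, ref = z),
      assignments = unname(best$cluster),
      total_wss = best$tot.withinss,
      n_restarts = n_restarts,
      seed = seed), class = "hfo_cluster_model")
  })
}

#' @export
print.hfo_cluster_model <- function(x, ...) {
  cat(sprintf("<hfo_cluster_model> k = %d, total WSS = %.3f (%d restarts)\n",
              x$k, x$total_wss, x$n_restarts))
  cat("Back-transformed centroids:\n")
  print(round(x$centroids_raw, 2))
  invisible(x)
}

#' Within-cluster sum-of-squares curve over candidate k
#'
#' @param z standardized `hfo_feature_matrix`.
#' @param k_max largest cluster count scanned, default 8.
#' @param n_restarts restarts per k.
#' @param seed integer seed.
#' @return named numeric vector: WSS for k = 1..k_max.
#' @export
wss_curve <- function(z, k_max = 8, n_restarts = 300, seed = 1) {
  vapply(seq_len(k_max), function(k)
    kmeans_fit(z, k, n_restarts = n_restarts,
               seed = derive_seed(seed, paste0("wss", k)))$total_wss,
    0)
}

#' Select the cluster count at the elbow of the WSS curve
#'
#' Picks the k maximising the perpendicular distance from the straight line
#' joining the curve's endpoints (the point where the rate of decrease
#' changes most sharply). Ties break toward smaller k; an exactly linear
#' curve returns the smallest interior k with a warning.
#'
#' @param wss named or plain numeric WSS vector over k = 1..k_max (length
#'   >= 4, non-increasing).
#' @return selected k (integer).
#' @export
select_k_elbow <- function(wss) {
  k <- seq_along(wss)
  if (length(wss) < 4) stop("elbow selection needs at least 4 k values", call. = FALSE)
  if (any(diff(wss) > 1e-8 * max(abs(wss))))
    stop("WSS curve must be non-increasing in k", call. = FALSE)
  x1 <- 1; y1 <- wss[1]; x2 <- length(wss); y2 <- wss[length(wss)]
  num <- abs((y2 - y1) * k - (x2 - x1) * wss + x2 * y1 - x1 * y2)
  d <- num / sqrt((y2 - y1)^2 + (x2 - x1)^2)
  interior <- d[-c(1, length(d))]
  if (max(interior) <= 1e-12 * max(abs(wss), 1)) {
    warning("WSS curve has no elbow (linear); returning smallest interior k")
    return(2L)
  }
  as.integer(which.max(d))            # which.max breaks ties toward smaller k
}

#' Relabel a three-cluster solution canonically
#'
#' Orders clusters 1..3 by ascending back-transformed duration centroid:
#' label 1 for the shortest-duration phenotype, 3 for the longest. Models
#' with k != 3 are returned unchanged with a warning.
#'
#' @param model an `hfo_cluster_model`.
#' @return the relabeled model.
#' @export
canonical_labels <- function(model) {
  if (model$k != 3) {
    warning("canonical labels are defined for k = 3; labels left as-is")
    return(model)
  }
  ord <- order(model$centroids_raw[, "duration"])
  relabel <- match(seq_len(3), ord)
  model$assignments <- relabel[model$assignments]
  model$centroids <- model$centroids[ord, , drop = FALSE]
  model$centroids_raw <- model$centroids_raw[ord, , drop = FALSE]
  rownames(model$centroids) <- rownames(model$centroids_raw) <- paste0("cluster", 1:3)
  model
}

#' Run the full phenotyping stage
#'
#' Outlier exclusion, transformation/standardization, WSS scan with elbow
#' selection (or a fixed k), the final k-means fit, and canonical labeling
#' when k = 3.
#'
#' @param features raw feature data frame.
#' @param k `"auto"` for elbow selection or an integer.
#' @param n_restarts k-means restarts, default 300.
#' @param seed integer seed.
#' @param k_max elbow scan range.
#' @return an `hfo_cluster_model` with extra elements `wss_curve`,
#'   `excluded` (outlier row indices) and `features` (retained rows with a
#'   `cluster` column).
#' @export
cluster_hfo <- function(features, k = "auto", n_restarts = 300, seed = 1,
                        k_max = 8) {
  scr <- exclude_outliers(features)
  z <- transform_and_standardize(scr$features)
  curve <- wss_curve(z, k_max = k_max, n_restarts = n_restarts, seed = seed)
  k_use <- if (identical(k, "auto")) select_k_elbow(curve) else as.integer(k)
  model <- kmeans_fit(z, k_use, n_restarts = n_restarts,
                      seed = derive_seed(seed, "final_fit"))
  if (k_use == 3) model <- canonical_labels(model)
  model$wss_curve <- curve
  model$excluded <- scr$excluded
  model$features <- cbind(scr$features, cluster = model$assignments)
  model
}

#' Plot the WSS elbow curve
#'
#' @param x an `hfo_cluster_model` from [cluster_hfo()].
#' @param ... passed to [graphics::plot()].
#' @export
plot.hfo_cluster_model <- function(x, ...) {
  if (is.null(x$wss_curve)) stop("model carries no WSS curve", call. = FALSE)
  graphics::plot(seq_along(x$wss_curve), x$wss_curve, type = "b",
                 xlab = "k", ylab = "total within-cluster SS", ...)
  graphics::abline(v = x$k, lty = 2)
  invisible(x)
}
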