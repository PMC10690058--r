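#' Haralick texture features
#'
#' Quantizes the image to `levels` grey levels over its own intensity
#' range, accumulates grey-level co-occurrence matrices at the given pixel
#' offsets, symmetrizes and normalizes each, computes the standard 13
#' Haralick statistics, and averages them over the offsets. Adding a
#' constant that does not change the quantization bins leaves the features
#' unchanged.
#'
#' @param pixels single-channel numeric matrix.
#' @param levels number of grey levels (>= 2, default 64).
#' @param offsets list of `c(drow, dcol)` offsets; default the four
#'   distance-1 directions `(0,1)`, `(1,0)`, `(1,1)`, `(1,-1)`.
#' @return Named numeric vector of 13 features.
#' @export
haralick_features <- function(pixels, levels = 64L,
                              offsets = list(c(0L, 1L), c(1L, 0L),
                                             c(1L, 1L), c(1L, -1L))) {
  stopifnot(is.matrix(pixels), is_count(levels, 2L))
  H <- nrow(pixels)
  W <- ncol(pixels)
  rng <- range(pixels)
  q <- if (rng[1L] == rng[2L]) matrix(1L, H, W)
  else matrix(pmin(as.integer(floor((pixels - rng[1L]) /
                                      (rng[2L] - rng[1L]) * levels)) + 1L,
                   levels), H, W)
  feats <- vapply(offsets, function(off) {
    dr <- off[1L]
    dc <- off[2L]
    if (abs(dr) >= H || abs(dc) >= W)
      stopf("image smaller than offset (%d, %d)", dr, dc)
    r0 <- max(1L, 1L - dr):min(H, H - dr)
    c0 <- max(1L, 1L - dc):min(W, W - dc)
    a <- q[r0, c0, drop = FALSE]
    b <- q[r0 + dr, c0 + dc, drop = FALSE]
    P <- matrix(0, levels, levels)
    tab <- table(factor(a, levels = seq_len(levels)),
                 factor(b, levels = seq_len(levels)))
    P <- P + tab + t(tab)  # symmetrize
    P <- P / sum(P)
    glcm_stats(P)
  }, numeric(13L))
  rowMeans(feats)
}

# The 13 classical statistics of a normalized, symmetric GLCM.
glcm_stats <- function(P) {
  G <- nrow(P)
  i <- matrix(seq_len(G), G, G)
  j <- t(i)
  px <- rowSums(P)
  mu <- sum(seq_len(G) * px)
  sg <- sqrt(sum((seq_len(G) - mu)^2 * px))
  eps <- 1e-12
  # distributions of i+j (2..2G) and |i-j| (0..G-1)
  pxy_sum <- vapply(2:(2L * G), function(k) sum(P[i + j == k]), numeric(1L))
  pxy_dif <- vapply(0:(G - 1L), function(k) sum(P[abs(i - j) == k]),
                    numeric(1L))
  asm <- sum(P^2)
  contrast <- sum((i - j)^2 * P)
  correlation <- if (sg < eps) 1 else sum((i - mu) * (j - mu) * P) / sg^2
  variance <- sum((i - mu)^2 * P)
  idm <- sum(P / (1 + (i - j)^2))
  sum_avg <- sum((2:(2L * G)) * pxy_sum)
  sum_ent <- -sum(pxy_sum * log(pxy_sum + eps))
  sum_var <- sum(((2:(2L * G)) - sum_avg)^2 * pxy_sum)
  entropy <- -sum(P * log(P + eps))
  dif_var <- {
    davg <- sum((0:(G - 1L)) * pxy_dif)
    sum(((0:(G - 1L)) - davg)^2 * pxy_dif)
  }
  dif_ent <- -sum(pxy_dif * log(pxy_dif + eps))
  hx <- -sum(px * log(px + eps))
  pipj <- outer(px, px)
  hxy1 <- -sum(P * log(pipj + eps))
  hxy2 <- -sum(pipj * log(pipj + eps))
  imc1 <- if (max(hx, eps) < eps) 0 else (entropy - hxy1) / max(hx, eps)
  imc2 <- sqrt(pmax(1 - exp(-2 * (hxy2 - entropy)), 0))
  c(angular_second_moment = asm, contrast = contrast,
    correlation = correlation, variance = variance,
    inverse_difference_moment = idm, sum_average = sum_avg,
    sum_variance = sum_var, sum_entropy = sum_ent, entropy = entropy,
    difference_variance = dif_var, difference_entropy = dif_ent,
    information_correlation_1 = imc1, information_correlation_2 = imc2)
}

#' Feature table of a dataset
#'
#' One row per image: either the flattened pixel vector or the Haralick
#' texture features, with `label` and `source_id` attached as attributes
#' for the supervised baselines.
#'
#' @param dataset an [img_dataset()].
#' @param type `"pixels"` or `"haralick"`.
#' @param ... passed to [haralick_features()].
#' @return A numeric matrix with attributes `label` and `source_id`.
#' @export
feature_table <- function(dataset, type = c("pixels", "haralick"), ...) {
  type <- match.arg(type)
  rows <- lapply(dataset$images, function(im) {
    switch(type, pixels = as.numeric(im$pixels),
           haralick = haralick_features(im$pixels, ...))
  })
  X <- do.call(rbind, rows)
  attr(X, "label") <- dataset_labels(dataset)
  attr(X, "source_id") <- dataset_ids(dataset)
  X
}

#' PCA reduction with a diminishing-returns component rule
#'
#' Principal components ordered by explained variance; the retained count
#' is the smallest `m` such that the variance explained by component
#' `m + 1` falls below `threshold` times that of component 1 (the spectrum
#' is returned so the choice can be audited).
#'
#' @param features numeric matrix, one row per observation.
#' @param threshold diminishing-returns fraction (default 0.1).
#' @param max_components cap on the retained count.
#' @return A list with `scores` (reduced matrix), `n_components`,
#'   `explained` (variance fractions summing to 1) and the `prcomp` fit.
#' @export
pca_reduce <- function(features, threshold = 0.1, max_components = Inf) {
  stopifnot(is.matrix(features), nrow(features) >= 2L)
  keep <- apply(features, 2L, function(col) var(col) > 0)
  if (!any(keep)) stopf("degenerate input: all features have zero variance")
  fit <- prcomp(features[, keep, drop = FALSE], center = TRUE, scale. = FALSE)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  m <- length(ev)
  for (cand in seq_len(length(ev) - 1L)) {
    if (ev[cand + 1L] < threshold * ev[1L]) {
      m <- cand
      break
    }
  }
  m <- as.integer(min(m, max_components))
  list(scores = fit$x[, seq_len(m), drop = FALSE], n_components = m,
       explained = ev, fit = fit)
}

#' k-means clustering with elbow selection of k
#'
#' Seeded k-means for `k = 1 .. k_max`; the chosen `k` is the smallest
#' value whose next increment reduces the within-cluster sum of squares by
#' less than `threshold` times the first increment's reduction.
#'
#' @param reduced numeric matrix (e.g. PCA scores).
#' @param k_max maximum k tried (>= 2).
#' @param seed integer seed.
#' @param threshold diminishing-returns fraction (default 0.1).
#' @param nstart restarts per k (default 10).
#' @return A list with `k`, `assignments` (for the chosen k), `wcss` (per
#'   k) and all `fits`.
#' @export
kmeans_elbow <- function(reduced, k_max = 10L, seed = 1L, threshold = 0.1,
                         nstart = 10L) {
  stopifnot(is.matrix(reduced), is_count(k_max, 2L))
  if (nrow(reduced) < k_max)
    stopf("fewer rows (%d) than k_max (%d)", nrow(reduced), k_max)
  fits <- with_seed(seed, lapply(seq_len(k_max), function(k)
    kmeans(reduced, centers = k, nstart = nstart, iter.max = 50L)))
  wcss <- vapply(fits, `[[`, numeric(1L), "tot.withinss")
  drops <- -diff(wcss)
  k <- k_max
  for (cand in seq_along(drops)) {
    if (drops[cand] < threshold * max(drops[1L], .Machine$double.eps)) {
      k <- cand
      break
    }
  }
  list(k = k, assignments = fits[[k]]$cluster, wcss = wcss, fits = fits)
}

#' Repeated-split evaluation of traditional supervised classifiers
#'
#' Fits `n_models` independent models per family -- random forest (RFC),
#' support vector machine (SVM) and k-nearest neighbours (KNN) -- each on
#' a fresh seeded train/validation split, and reports per-model and
#' aggregate validation accuracies. Splits are stratified draws without
#' replacement; `split` may be a ratio (e.g. 0.8) or fixed counts
#' `c(train, validation)` such as the 120/32 split used for a 152-image
#' dataset. Classifier hyperparameters are the library defaults (KNN uses
#' `knn_k` neighbours).
#'
#' @param features numeric matrix, one row per image.
#' @param labels character/factor labels, length `nrow(features)`.
#' @param n_models independent splits per family (default 10).
#' @param split ratio in (0,1) or integer `c(train, validation)` counts.
#' @param seed master seed.
#' @param knn_k neighbours for KNN (default 5).
#' @return An object of class `baseline_report`: per-family accuracy
#'   vectors plus mean/max summaries.
#' @export
supervised_baselines <- function(features, labels, n_models = 10L,
                                 split = 0.8, seed = 1L, knn_k = 5L) {
  stopifnot(is.matrix(features), nrow(features) == length(labels),
            is_count(n_models, 1L))
  labels <- factor(labels)
  if (nlevels(labels) != 2L) stopf("two-class labels required")
  n <- nrow(features)
  counts <- if (length(split) == 2L) as.integer(split)
  else c(round(split * n), n - round(split * n))
  if (sum(counts) > n) stopf("split counts exceed available rows")
  seeds <- derive_seeds(seed, n_models)
  splits <- lapply(seeds, function(s) with_seed(s, {
    repeat {
      # stratified: per-class train quota proportional to class size
      tr <- unlist(lapply(levels(labels), function(cl) {
        idx <- which(labels == cl)
        sample(idx, round(counts[1L] * length(idx) / n))
      }))
      extra <- counts[1L] - length(tr)
      pool <- setdiff(seq_len(n), tr)
      if (extra > 0L) tr <- c(tr, sample(pool, extra))
      if (extra < 0L) tr <- sample(tr, counts[1L])
      va <- sample(setdiff(seq_len(n), tr), counts[2L])
      if (nlevels(droplevels(labels[tr])) == 2L) return(list(tr = tr, va = va))
    }
  }))
  acc <- function(fit_predict) vapply(splits, function(sp) {
    pred <- fit_predict(features[sp$tr, , drop = FALSE], labels[sp$tr],
                        features[sp$va, , drop = FALSE])
    mean(pred == labels[sp$va])
  }, numeric(1L))
  rfc <- with_seed(seed, acc(function(xtr, ytr, xva)
    predict(randomForest::randomForest(xtr, ytr), xva)))
  svm <- acc(function(xtr, ytr, xva) {
    keep <- apply(xtr, 2L, function(col) var(col) > 0)
    predict(e1071::svm(xtr[, keep, drop = FALSE], ytr),
            xva[, keep, drop = FALSE])
  })
  knn <- with_seed(seed, acc(function(xtr, ytr, xva)
    class::knn(xtr, xva, ytr, k = knn_k)))
  fams <- list(rfc = rfc, svm = svm, knn = knn)
  structure(list(accuracies = fams,
                 mean_accuracy = vapply(fams, mean, numeric(1L)),
                 max_accuracy = vapply(fams, max, numeric(1L)),
                 n_models = n_models, split_counts = counts, seed = seed),
            class = "baseline_report")
}

#' @export
print.baseline_report <- function(x, ...) {
  cat(sprintf("<baseline_report: %d models per family, %d/%d splits>\n",
              x$n_models, x$split_counts[1L], x$split_counts[2L]))
  for (f in names(x$accuracies))
    cat(sprintf("  %-4s mean %.3f  max %.3f\n", toupper(f),
                x$mean_accuracy[[f]], x$max_accuracy[[f]]))
  invisible(x)
}
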