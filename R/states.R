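#' Fit the group-level connectivity state model
#'
#' Pools window features across subjects, centers them, projects onto the
#' top `n_components` principal axes (default 5), and clusters the projected
#' features with k-means (squared Euclidean distance, `n_replicates` seeded
#' restarts of the initial centroids, best within-cluster sum of squares
#' kept). Cluster names are assigned by centroid spectral profile via
#' [name_states()].
#'
#' @param features feature data frame from [connectivity_features()]
#'   (row-bound across subjects) or a windows x 140 matrix. Suppressed
#'   windows are excluded.
#' @param k number of clusters (default 5).
#' @param n_components retained principal components (default 5).
#' @param n_replicates k-means restarts (default 100).
#' @param seed integer seed.
#' @param f_grid frequency grid of the feature bins.
#' @return object of class `state_model`: `mean_vector`, `pca_basis`
#'   (n_components x 140, orthonormal rows), `explained_variance`,
#'   `centroids` (k x n_components), `k`, `state_names`, `f_grid`.
#' @export
fit_state_model <- function(features, k = 5, n_components = 5,
                            n_replicates = 100, seed = 1,
                            f_grid = spectral_config()$f_grid) {
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(X) < k)
    stopf("data error: %d windows for k = %d clusters", nrow(X), k)
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  basis <- t(pc$rotation[, seq_len(n_components), drop = FALSE])
  scores <- Xc %*% t(basis)
  ev <- pc$sdev^2 / sum(pc$sdev^2)
  set.seed(seed)
  km <- stats::kmeans(scores, centers = k, nstart = n_replicates,
                      iter.max = 200)
  model <- structure(list(mean_vector = mu, pca_basis = basis,
                          explained_variance = ev[seq_len(n_components)],
                          centroids = km$centers, k = k,
                          state_names = NULL, f_grid = f_grid,
                          inertia = km$tot.withinss),
                     class = "state_model")
  model$state_names <- name_states(model)
  model
}

#' @export
print.state_model <- function(x, ...) {
  cat(sprintf("<state_model> k = %d, %d PCs (%.1f%% variance), states: %s\n",
              x$k, nrow(x$pca_basis), 100 * sum(x$explained_variance),
              paste(x$state_names, collapse = ", ")))
  invisible(x)
}

#' Project features into a fitted model's PCA space
#' @param model a `state_model`.
#' @param X windows x 140 matrix.
#' @return windows x n_components score matrix.
#' @export
project_features <- function(model, X) {
  if (ncol(X) != length(model$mean_vector))
    stopf("shape error: %d feature columns, model expects %d",
          ncol(X), length(model$mean_vector))
  sweep(X, 2, model$mean_vector) %*% t(model$pca_basis)
}

#' Back-project centroids to the 140-bin feature space
#' @param model a `state_model`.
#' @return k x 140 matrix of centroid spectral profiles.
#' @export
backproject_centroids <- function(model) {
  sweep(model$centroids %*% model$pca_basis, 2, model$mean_vector, `+`)
}

#' Name clusters from their centroid spectral profiles
#'
#' Each centroid is back-projected to the 140-bin space and split into its
#' prefrontal-frontal and frontal-parietal halves; the half with the greater
#' mean fixes the region. The frequency band of the spectral peak of the
#' dominant half fixes the name per the state taxonomy (delta 0.5-4, theta
#' 4-8, alpha 8-13, beta 13-30 Hz): prefrontal-frontal delta is S3, alpha
#' S2, beta S1; frontal-parietal theta is S4, alpha S5. Name collisions
#' within a region are resolved by ordering the colliding centroids on the
#' spectral centroid of the dominant half (higher centroid takes the
#' higher-frequency name). All-zero centroids are labelled "unnamed".
#'
#' @param model a `state_model`.
#' @return character vector of length k, one name per cluster index.
#' @export
name_states <- function(model) {
  prof <- backproject_centroids(model)
  f <- model$f_grid
  nf <- length(f)
  bands <- list(delta = c(0.5, 4), theta = c(4, 8),
                alpha = c(8, 13), beta = c(13, 30))
  info <- lapply(seq_len(nrow(prof)), function(i) {
    v <- prof[i, ]
    if (all(abs(v) < 1e-12)) return(NULL)
    fpf <- v[seq_len(nf)]; fp <- v[nf + seq_len(nf)]
    dom <- if (mean(fpf) >= mean(fp)) "fpf" else "fp"
    h <- pmax(if (dom == "fpf") fpf else fp, 0)
    peak_f <- f[which.max(h)]
    band <- names(bands)[vapply(bands, function(b)
      peak_f >= b[1] && peak_f < b[2], logical(1))][1]
    cen <- if (sum(h) > 0) sum(f * h) / sum(h) else peak_f
    list(region = dom, band = band %||% NA_character_, centroid_f = cen)
  })
  names_out <- rep("unnamed", nrow(prof))
  candidate <- function(region, band) {
    if (is.na(band)) return(NA_character_)
    if (region == "fpf")
      switch(band, delta = "S3", alpha = "S2", beta = "S1", NA_character_)
    else
      switch(band, theta = "S4", alpha = "S5", NA_character_)
  }
  # within a region, centroids claim their band's name in ascending spectral
  # centroid order; a collision bumps the higher-frequency centroid to the
  # next free name up the region's frequency ladder (down if none above)
  for (region in c("fpf", "fp")) {
    ladder <- if (region == "fpf") c("S3", "S2", "S1") else c("S4", "S5")
    idx <- which(vapply(info, function(x)
      !is.null(x) && x$region == region, logical(1)))
    if (!length(idx)) next
    idx <- idx[order(vapply(info[idx], `[[`, numeric(1), "centroid_f"))]
    taken <- character()
    for (i in idx) {
      want <- candidate(region, info[[i]]$band)
      if (is.na(want)) next
      if (!(want %in% taken)) {
        names_out[i] <- want
      } else {
        pos <- match(want, ladder)
        above <- ladder[seq_along(ladder) > pos]
        below <- rev(ladder[seq_along(ladder) < pos])
        free <- c(setdiff(above, taken), setdiff(below, taken))
        if (length(free)) names_out[i] <- free[1]
      }
      if (names_out[i] != "unnamed") taken <- c(taken, names_out[i])
    }
  }
  names_out
}

#' Assign state labels to a subject's windows
#'
#' Non-suppressed windows are projected into the model's PCA space and
#' mapped to the nearest centroid (squared Euclidean; ties break to the
#' lowest cluster index). Suppressed windows are labelled "suppressed".
#'
#' @param model a fitted `state_model`.
#' @param features one subject's feature data frame (or matrix).
#' @return object of class `state_sequence`: data frame with `subject_id`,
#'   `window_index`, `t_center`, `label`.
#' @export
assign_states <- function(model, features) {
  if (is.matrix(features)) {
    feats <- features
    meta <- data.frame(subject_id = "unknown",
                       window_index = seq_len(nrow(features)),
                       t_center = NA_real_,
                       suppressed = FALSE)
  } else {
    feats <- feature_matrix(features, drop_suppressed = FALSE)
    meta <- features[c("subject_id", "window_index", "t_center", "suppressed")]
  }
  sc <- project_features(model, feats)
  d2 <- outer(rowSums(sc^2), rep(1, model$k)) -
    2 * sc %*% t(model$centroids) +
    outer(rep(1, nrow(sc)), rowSums(model$centroids^2))
  cl <- apply(d2, 1, which.min)            # which.min ties -> lowest index
  lab <- model$state_names[cl]
  lab[meta$suppressed] <- "suppressed"
  out <- data.frame(subject_id = meta$subject_id,
                    window_index = meta$window_index,
                    t_center = meta$t_center, label = lab)
  class(out) <- c("state_sequence", "data.frame")
  out
}

# all permutations of 1..k, cached (k <= 8 in practice)
all_perms <- function(k) {
  key <- sprintf("perms_%d", k)
  got <- .conndyn_cache[[key]]
  if (!is.null(got)) return(got)
  rec <- function(v) {
    if (length(v) == 1) return(matrix(v, 1, 1))
    do.call(rbind, lapply(seq_along(v), function(i)
      cbind(v[i], rec(v[-i]))))
  }
  P <- rec(seq_len(k))
  assign(key, P, envir = .conndyn_cache)
  P
}

# optimal label permutation (maximal agreement) mapping labels of b onto
# labels of a, by exhaustive search over the k! matchings
best_matching <- function(a, b, k) {
  C <- matrix(0, k, k)
  tab <- table(factor(a, levels = seq_len(k)), factor(b, levels = seq_len(k)))
  C[] <- as.numeric(tab)
  P <- all_perms(k)
  # agreement under permutation sigma (row p of P): sum_j C[sigma(j), j]
  idx <- P + rep((seq_len(k) - 1L) * k, each = nrow(P))
  agree <- rowSums(matrix(C[as.vector(idx)], nrow(P)))
  P[which.max(agree), ]
}

# minimal disagreement fraction between two k-labelings over all label
# permutations
min_disagreement <- function(a, b, k) {
  sigma <- best_matching(a, b, k)
  mean(a != sigma[b])
}

# worst-cluster disagreement: after optimal matching, the largest
# per-cluster fraction of b's members whose transferred a-label disagrees
worst_cluster_disagreement <- function(a, b, k) {
  sigma <- best_matching(a, b, k)
  worst <- 0
  for (j in seq_len(k)) {
    m <- b == j
    if (any(m)) worst <- max(worst, mean(a[m] != sigma[j]))
  }
  worst
}

#' Split-half stability index for cluster-number selection
#'
#' Quantifies the reproducibility of the k-clustering solution. For each
#' candidate k and each random split: cluster half A, transfer its labels to
#' half B by nearest centroid, cluster half B independently, match the two
#' labelings by the minimal-disagreement permutation (exhaustive over the k!
#' matchings), and score the split by the worst per-cluster disagreement:
#' the largest fraction, over B's clusters, of members whose transferred
#' label contradicts the matched label. A solution only counts as
#' reproducible when every cluster reproduces, so a single arbitrarily split
#' or re-merged cluster is penalized in full rather than averaged away.
#' Scores are normalized by the expected disagreement of random k-labelings
#' (1 - 1/k) and averaged over splits; lower is more stable, structureless
#' data scores near 1.
#'
#' @param features feature data frame or matrix (windows x 140).
#' @param k_candidates integer vector of candidate cluster counts (>= 2).
#' @param n_splits number of random splits.
#' @param seed integer seed.
#' @param n_components retained principal components.
#' @param n_replicates k-means restarts per half-fit.
#' @return named numeric vector of normalized instability per candidate k.
#' @seealso [select_n_states()] for the selection rule.
#' @export
stability_index <- function(features, k_candidates = 2:8, n_splits = 20,
                            seed = 1, n_components = 5, n_replicates = 10) {
  if (any(k_candidates < 2)) stopf("config error: candidate k must be >= 2")
  X <- if (is.matrix(features)) features else feature_matrix(features)
  if (nrow(X) < 2 * max(k_candidates))
    stopf("data error: need >= 2*max(k) windows")
  mu <- colMeans(X)
  Xc <- sweep(X, 2, mu)
  pc <- stats::prcomp(Xc, center = FALSE, scale. = FALSE)
  n_components <- min(n_components, ncol(pc$rotation))
  S <- Xc %*% pc$rotation[, seq_len(n_components), drop = FALSE]
  n <- nrow(S)
  out <- stats::setNames(numeric(length(k_candidates)),
                         as.character(k_candidates))
  for (ki in seq_along(k_candidates)) {
    k <- k_candidates[ki]
    vals <- numeric(n_splits)
    for (s in seq_len(n_splits)) {
      set.seed(derive_seed(seed, "stability", k, s))
      ia <- sample.int(n, floor(n / 2))
      A <- S[ia, , drop = FALSE]; B <- S[-ia, , drop = FALSE]
      km_a <- stats::kmeans(A, k, nstart = n_replicates, iter.max = 100)
      km_b <- stats::kmeans(B, k, nstart = n_replicates, iter.max = 100)
      d2 <- outer(rowSums(B^2), rep(1, k)) -
        2 * B %*% t(km_a$centers) +
        outer(rep(1, nrow(B)), rowSums(km_a$centers^2))
      transferred <- apply(d2, 1, which.min)
      vals[s] <- worst_cluster_disagreement(transferred, km_b$cluster, k) /
        (1 - 1 / k)
    }
    out[ki] <- mean(vals)
  }
  out
}

#' Select the number of connectivity states from the stability profile
#'
#' Merged coarsenings of well-separated states reproduce as reliably as the
#' states themselves, so the stable candidates form a contiguous run that
#' ends at the true granularity; instability jumps once clusters must be
#' split arbitrarily. The rule therefore takes the largest k of the
#' contiguous stable run (normalized instability at or below
#' `max_instability`) containing the instability argmin. Isolated stable
#' points beyond the first break are ignored: at large k, spurious clusters
#' can occasionally re-stabilize on incidental density ridges without being
#' part of the nested family. Falls back to the argmin when no candidate
#' qualifies.
#'
#' @param stability named vector from [stability_index()].
#' @param max_instability reproducibility bound (default 0.25, i.e. at
#'   least 75% of every cluster's members keep their matched label before
#'   chance normalization).
#' @return the selected k (integer).
#' @export
select_n_states <- function(stability, max_instability = 0.25) {
  ks <- as.integer(names(stability))
  ord <- order(ks)
  ks <- ks[ord]; stability <- stability[ord]
  ok <- stability <= max_instability
  if (!any(ok)) return(ks[which.min(stability)])
  i_min <- which.min(stability)
  run <- cumsum(!ok)            # constant within each contiguous ok-run
  in_run <- ok & run == run[i_min]
  max(ks[in_run])
}
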