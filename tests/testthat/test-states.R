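# feature-space blobs with a known assignment, planted directly in 140-d
make_blobs <- function(k, n_per, sep = 6, sd = 0.5, seed = 1) {
  set.seed(seed)
  centers <- matrix(0, k, 140)
  for (j in seq_len(k)) centers[j, ((j - 1) * 10 + 1):(j * 10)] <- sep
  X <- do.call(rbind, lapply(seq_len(k), function(j)
    sweep(matrix(rnorm(n_per * 140, sd = sd), n_per, 140), 2,
          centers[j, ], `+`)))
  list(X = X, labels = rep(seq_len(k), each = n_per))
}

test_that("two separable blobs are recovered exactly and deterministically", {
  b <- make_blobs(2, 60)
  m1 <- fit_state_model(b$X, k = 2, n_components = 3, seed = 4)
  m2 <- fit_state_model(b$X, k = 2, n_components = 3, seed = 4)
  expect_identical(m1$centroids, m2$centroids)
  lab <- assign_states(m1, b$X)$label
  expect_equal(length(unique(paste(lab, b$labels))), 2)
  expect_error(fit_state_model(b$X[1:3, ], k = 5), "data error")
})

test_that("PCA basis is orthonormal and centroid projection round-trips", {
  b <- make_blobs(3, 40, seed = 7)
  m <- fit_state_model(b$X, k = 3, n_components = 4, seed = 1)
  expect_equal(m$pca_basis %*% t(m$pca_basis), diag(4), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_true(all(diff(m$explained_variance) <= 1e-12))
  back <- backproject_centroids(m)
  again <- sweep(back, 2, m$mean_vector) %*% t(m$pca_basis)
  expect_equal(again, m$centroids, tolerance = 1e-8, ignore_attr = TRUE)
})

test_that("assignment maps centroid preimages to their cluster and breaks ties low", {
  m <- structure(list(mean_vector = rep(0, 4),
                      pca_basis = rbind(c(1, 0, 0, 0), c(0, 1, 0, 0)),
                      explained_variance = c(0.5, 0.3),
                      centroids = rbind(c(1, 0), c(-1, 0)), k = 2,
                      state_names = c("S4", "S2"),
                      f_grid = c(1, 2)),
                 class = "state_model")
  pre <- rbind(c(1, 0, 0, 0),    # exactly centroid 1
               c(0, 1, 0, 0))    # equidistant from both -> lowest index
  lab <- assign_states(m, pre)$label
  expect_identical(lab, c("S4", "S4"))
  expect_error(assign_states(m, matrix(0, 1, 3)), "shape error")
})

test_that("suppressed windows pass through assignment as 'suppressed'", {
  b <- make_blobs(2, 10, seed = 3)
  m <- fit_state_model(b$X, k = 2, n_components = 2, seed = 1)
  ft <- data.frame(subject_id = "s", window_index = 1:20,
                   t_center = seq(15, by = 10, length.out = 20),
                   suppressed = rep(c(TRUE, FALSE), 10))
  ft <- cbind(ft, as.data.frame(b$X))
  names(ft)[-(1:4)] <- c(paste0("fpf_", 1:70), paste0("fp_", 1:70))
  seq_out <- assign_states(m, ft)
  expect_identical(seq_out$label[ft$suppressed],
                   rep("suppressed", 10))
  expect_false(any(seq_out$label[!ft$suppressed] == "suppressed"))
})

test_that("centroid naming follows the region/band taxonomy", {
  f <- f_grid_default
  mk_profile <- function(fpf_band = NULL, fp_band = NULL, height = 0.5) {
    v <- numeric(140)
    if (!is.null(fpf_band))
      v[which(f >= fpf_band[1] & f <= fpf_band[2])] <- height
    if (!is.null(fp_band))
      v[70 + which(f >= fp_band[1] & f <= fp_band[2])] <- height
    v
  }
  profiles <- rbind(mk_profile(fpf_band = c(9, 11)),     # Fp-F alpha -> S2
                    mk_profile(fp_band = c(5, 7)),       # F-P theta  -> S4
                    mk_profile(fpf_band = c(1, 3)),      # Fp-F delta -> S3
                    mk_profile(fpf_band = c(14, 22)),    # Fp-F beta  -> S1
                    mk_profile(fp_band = c(9, 12)))      # F-P alpha  -> S5
  m <- structure(list(mean_vector = rep(0, 140),
                      pca_basis = diag(140)[1:140, ],    # identity basis
                      explained_variance = rep(0.2, 5),
                      centroids = profiles, k = 5,
                      state_names = NULL, f_grid = f),
                 class = "state_model")
  m$pca_basis <- diag(140)
  m$centroids <- profiles
  expect_identical(name_states(m), c("S2", "S4", "S3", "S1", "S5"))
  # collision: two Fp-F alpha-peaked centroids; the broader one reaching
  # into beta has the higher spectral centroid and takes S1
  m2 <- m
  m2$centroids <- rbind(mk_profile(fpf_band = c(8, 12)),
                        mk_profile(fpf_band = c(8, 20)),
                        mk_profile(fp_band = c(5, 7)),
                        mk_profile(fp_band = c(4, 12)),
                        mk_profile(fpf_band = c(1, 3)))
  m2$k <- 5
  expect_identical(name_states(m2), c("S2", "S1", "S4", "S5", "S3"))
  # all-zero centroid is unnamed
  m3 <- m
  m3$centroids <- rbind(profiles[1:2, ], 0)
  m3$k <- 3
  expect_identical(name_states(m3)[3], "unnamed")
})

test_that("stability profile identifies planted granularity and rejects noise", {
  b <- make_blobs(5, 60, seed = 11)
  st <- stability_index(b$X, 2:8, n_splits = 12, seed = 2,
                        n_components = 5, n_replicates = 10)
  expect_lt(st[["5"]], 0.1)
  expect_equal(select_n_states(st), 5)
  # instability jumps once clusters must be split arbitrarily
  expect_gt(min(st[c("6", "7", "8")]), 4 * st[["5"]])
  # over-splitting 2 blobs into 4 is less reproducible than k = 2
  b2 <- make_blobs(2, 80, seed = 13)
  st2 <- stability_index(b2$X, c(2, 4), n_splits = 12, seed = 3,
                         n_components = 2, n_replicates = 10)
  expect_lt(st2[["2"]], st2[["4"]])
  # structureless noise: nothing reproduces; chance-level instability
  set.seed(17)
  noise <- matrix(rnorm(250 * 140), 250, 140)
  stn <- stability_index(noise, c(2, 4, 6), n_splits = 12, seed = 5,
                         n_components = 5, n_replicates = 10)
  expect_gt(min(stn), 0.5)
  expect_error(stability_index(b$X, 1), "config error")
})

test_that("relabeling clusters leaves occupancy and global dynamics unchanged", {
  set.seed(23)
  lab <- sample(paste0("S", 1:5), 400, replace = TRUE)
  perm <- c(S1 = "S4", S2 = "S5", S3 = "S1", S4 = "S2", S5 = "S3")
  relab <- unname(perm[lab])
  occ1 <- sort(unname(occurrence_rate(lab)))
  occ2 <- sort(unname(occurrence_rate(relab)))
  expect_equal(occ1, occ2)
  expect_equal(global_transition_probability(lab),
               global_transition_probability(relab))
})
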