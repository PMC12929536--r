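test_that("k-means recovers well-separated descriptor blobs", {
  blobs <- generate_blob_profiles(n_per_blob = 80, separation = 12,
                                  noise_sd = 0.4, seed = 21)
  model <- fit_environment_model(blobs$profile, k = 8, seed = 5)
  for (state in c("native", "denatured")) {
    m <- model[[state]]
    truth <- sweep(sweep(blobs$centers[[state]], 2, m$center), 2, m$scale, "/")
    ## every true (standardized) blob mean has a fitted centroid nearby
    d <- apply(truth, 1, function(ctr) {
      min(sqrt(rowSums(sweep(m$centroids, 2, ctr)^2)))
    })
    expect_lt(max(d), 0.1)
  }
})

test_that("k = 1 yields the standardized origin and refits are identical", {
  prof <- random_profile(500, seed = 8)
  one <- fit_environment_model(prof, k = 1, seed = 2)
  expect_lt(max(abs(one$native$centroids)), 1e-10)
  a <- fit_environment_model(prof, k = 8, seed = 4)
  b <- fit_environment_model(prof, k = 8, seed = 4)
  expect_identical(a$native$centroids, b$native$centroids)
  expect_identical(a$denatured$centroids, b$denatured$centroids)
})

test_that("too few distinct points is an error", {
  prof <- random_profile(6, seed = 1)
  expect_error(fit_environment_model(prof, k = 8, seed = 1), "clusters")
  ## 20 rows but only 3 distinct descriptor vectors
  dup <- random_profile(3, seed = 2)
  dup <- dup[rep(1:3, length.out = 20), ]
  dup$pos <- 1:20
  expect_error(fit_environment_model(dup, k = 8, seed = 1), "distinct")
})

test_that("assignment picks the nearest centroid with low-index tie-break", {
  ## centroids of equal norm: +/- 3 along each standardized axis
  centroids <- rbind(3 * diag(4), -3 * diag(4))
  colnames(centroids) <- c("dG", "dH_ap", "dH_pol", "TdS_conf")
  m <- list(centroids = centroids,
            center = stats::setNames(rep(0, 4), colnames(centroids)),
            scale = stats::setNames(rep(1, 4), colnames(centroids)))
  model <- structure(list(k = 8L, seed = 1L, native = m, denatured = m),
                     class = "environment_model")
  prof <- random_profile(3, seed = 3)
  cols <- grep("_native$", names(prof))
  prof[1, cols] <- as.list(centroids[4, ])          # exactly centroid 3
  prof[2, cols] <- as.list((centroids[3, ] + centroids[6, ]) / 2)  # tie 2 vs 5
  enc <- assign_environments(prof, model)
  expect_equal(enc$env_native[1], 3L)
  expect_equal(enc$env_native[2], 2L)
})

test_that("encoding preserves length, range and is idempotent", {
  s <- test_setup()
  for (i in c(1, 5)) {
    enc1 <- assign_environments(s$profiles[[i]], s$model)
    enc2 <- assign_environments(s$profiles[[i]], s$model)
    expect_equal(nrow(enc1), nrow(s$profiles[[i]]))
    expect_true(all(enc1$env_native %in% 0:7))
    expect_true(all(enc1$env_denatured %in% 0:7))
    expect_identical(enc1, enc2)
  }
  ## across the whole training corpus every environment index is used
  expect_setequal(unique(s$corpus$env_native), 0:7)
  expect_setequal(unique(s$corpus$env_denatured), 0:7)
})

test_that("converged centroids are a fixed point of reassignment", {
  prof <- random_profile(400, seed = 13)
  model <- fit_environment_model(prof, k = 8, seed = 6)
  enc <- assign_environments(prof, model)
  X <- as.matrix(prof[, grep("_native$", names(prof))])
  m <- model$native
  Z <- sweep(sweep(X, 2, m$center), 2, m$scale, "/")
  means <- t(sapply(0:7, function(e) colMeans(Z[enc$env_native == e, , drop = FALSE])))
  expect_equal(unname(means), unname(m$centroids), tolerance = 1e-6)
})

test_that("environment models round-trip through JSON", {
  s <- test_setup()
  path <- withr::local_tempfile(fileext = ".json")
  write_environment_model(s$model, path)
  back <- read_environment_model(path)
  expect_equal(back$k, s$model$k)
  expect_equal(back$native$centroids, s$model$native$centroids,
               ignore_attr = TRUE)
  expect_equal(back$denatured$scale, s$model$denatured$scale,
               ignore_attr = TRUE)
  enc1 <- assign_environments(s$profiles[[2]], s$model)
  enc2 <- assign_environments(s$profiles[[2]], back)
  expect_identical(enc1$env_native, enc2$env_native)
})
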