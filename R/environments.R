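#' Fit the thermodynamic-environment model
#'
#' Clusters per-residue 4-D descriptor vectors, separately for the native
#' and denatured states, into `k` thermodynamic environments. Descriptors
#' are z-scored per dimension (training mean/SD) before clustering so no
#' single energetic component dominates the Euclidean metric. Clustering is
#' k-means with k-means++ seeding and multiple restarts; centroids are
#' stored in a canonical order (lexicographic by coordinate) so the
#' environment alphabet is reproducible for a fixed seed.
#'
#' @param profiles A `thermo_profile` tibble (rows may span many proteins)
#'   or a list of them.
#' @param k Number of environments per state (default 8).
#' @param seed Integer seed controlling the k-means initialisation.
#' @param n_restarts Number of k-means++ restarts (best total
#'   within-cluster sum of squares kept); capped at 100.
#' @return An `environment_model` object holding, per state, the k x 4
#'   centroid matrix in standardized space and the standardization
#'   constants.
#' @export
fit_environment_model <- function(profiles, k = 8L, seed = 1L,
                                  n_restarts = 10L) {
  profiles <- bind_profiles(profiles)
  n_restarts <- min(as.integer(n_restarts), 100L)
  model <- list(k = as.integer(k), seed = as.integer(seed))
  for (state in STATES) {
    X <- as.matrix(profiles[, paste(DESCRIPTORS, state, sep = "_")])
    if (nrow(X) < k) abort("Fewer residues than clusters")
    ctr <- colMeans(X)
    scl <- apply(X, 2L, sd)
    if (any(scl <= 0)) abort("Degenerate descriptor (zero SD) in training data")
    Z <- sweep(sweep(X, 2L, ctr), 2L, scl, "/")
    if (nrow(unique(Z)) < k) {
      abort("Fewer distinct descriptor vectors than clusters")
    }
    km <- withr::with_seed(seed, kmeans_pp(Z, k, n_restarts))
    ord <- do.call(order, as.data.frame(km$centers))
    centers <- km$centers[ord, , drop = FALSE]
    dimnames(centers) <- list(NULL, DESCRIPTORS)
    model[[state]] <- list(centroids = centers, center = ctr, scale = scl)
  }
  structure(model, class = "environment_model")
}

## k-means with k-means++ seeding and restarts; returns best stats::kmeans fit.
kmeans_pp <- function(Z, k, n_restarts) {
  best <- NULL
  for (r in seq_len(n_restarts)) {
    init <- kmeans_pp_centers(Z, k)
    fit <- suppressWarnings(
      kmeans(Z, centers = init, iter.max = 300L, algorithm = "Lloyd")
    )
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

kmeans_pp_centers <- function(Z, k) {
  n <- nrow(Z)
  centers <- matrix(NA_real_, k, ncol(Z))
  centers[1L, ] <- Z[sample.int(n, 1L), ]
  d2 <- colSums((t(Z) - centers[1L, ])^2)
  for (j in seq_len(k)[-1L]) {
    d2[d2 < 0] <- 0
    i <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j, ] <- Z[i, ]
    d2 <- pmin(d2, colSums((t(Z) - centers[j, ])^2))
  }
  centers
}

#' Encode a thermodynamic profile as environment strings
#'
#' Assigns every residue, independently for the native and denatured states,
#' to the nearest environment centroid (Euclidean distance in the model's
#' standardized descriptor space). Ties go to the lowest centroid index.
#' Environment indices run 0-7.
#'
#' @param profile A `thermo_profile` tibble (single protein or several).
#' @param model An `environment_model` from [fit_environment_model()].
#' @return An `encoded_profile` tibble with columns `id`, `pos`, `residue`,
#'   `env_native`, `env_denatured`.
#' @export
assign_environments <- function(profile, model) {
  stopifnot(inherits(model, "environment_model"))
  profile <- bind_profiles(profile)
  if (nrow(profile) == 0L) abort("Profile is empty")
  out <- tibble(id = profile$id, pos = profile$pos, residue = profile$residue)
  for (state in STATES) {
    X <- as.matrix(profile[, paste(DESCRIPTORS, state, sep = "_")])
    m <- model[[state]]
    Z <- sweep(sweep(X, 2L, m$center), 2L, m$scale, "/")
    out[[paste0("env_", state)]] <- nearest_centroid(Z, m$centroids)
  }
  class(out) <- c("encoded_profile", class(out))
  out
}

## 0-based index of nearest centroid; ties resolved to lowest index.
nearest_centroid <- function(Z, centroids) {
  ## squared distances via expansion; ties.method = "first" gives low index
  cross <- Z %*% t(centroids)
  d2 <- matrix(rowSums(centroids^2), nrow(Z), nrow(centroids),
               byrow = TRUE) - 2 * cross
  max.col(-d2, ties.method = "first") - 1L
}

#' Save / load an environment model
#'
#' JSON serialisation of centroids, standardization constants, `k` and the
#' fitting seed.
#'
#' @param model An `environment_model`.
#' @param path File path.
#' @export
write_environment_model <- function(model, path) {
  stopifnot(inherits(model, "environment_model"))
  payload <- list(k = model$k, seed = model$seed)
  for (state in STATES) {
    m <- model[[state]]
    payload[[state]] <- list(
      centroids = unname(apply(m$centroids, 1L, as.numeric, simplify = FALSE)),
      center = as.numeric(m$center),
      scale = as.numeric(m$scale)
    )
  }
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_environment_model
#' @export
read_environment_model <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- list(k = as.integer(payload$k), seed = as.integer(payload$seed))
  for (state in STATES) {
    p <- payload[[state]]
    cen <- if (is.matrix(p$centroids)) p$centroids else
      do.call(rbind, lapply(p$centroids, as.numeric))
    dimnames(cen) <- list(NULL, DESCRIPTORS)
    model[[state]] <- list(
      centroids = cen,
      center = setNames(as.numeric(p$center), DESCRIPTORS),
      scale = setNames(as.numeric(p$scale), DESCRIPTORS)
    )
  }
  structure(model, class = "environment_model")
}

#' @export
print.environment_model <- function(x, ...) {
  cat("Thermodynamic environment model\n")
  cat("  k =", x$k, "environments per state, seed =", x$seed, "\n")
  for (state in STATES) {
    cat("  ", state, "centroid spread (standardized):",
        format(round(range(x[[state]]$centroids), 2)), "\n")
  }
  invisible(x)
}

bind_profiles <- function(profiles) {
  if (is.data.frame(profiles)) return(profiles)
  dplyr::bind_rows(profiles)
}
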