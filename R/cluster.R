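#' Clustering parameters for trend analysis
#'
#' @param k Number of flat clusters (field defaults: 3 for the injury part,
#'   4 for the repair part of a 4-group ischaemia/repair design).
#' @param linkage Agglomeration method for hierarchical clustering
#'   (default `"average"`).
#' @param n_restarts Seeded K-means restarts; best inertia kept.
#' @param trend_tolerance Relative tolerance for [classify_trend()]
#'   (fraction of the profile range, default 0.05).
#' @param seed Integer seed for K-means restarts.
#' @return An object of class `clustering_params`.
#' @export
clustering_params <- function(k = 3L, linkage = "average", n_restarts = 10L,
                              trend_tolerance = 0.05, seed = NULL) {
  k <- as.integer(k)
  if (is.na(k) || k < 2L) stop_("k must be >= 2")
  if (trend_tolerance < 0) stop_("trend_tolerance must be >= 0")
  structure(list(k = k, linkage = linkage,
                 n_restarts = as.integer(n_restarts),
                 trend_tolerance = trend_tolerance, seed = seed),
            class = "clustering_params")
}

#' Pearson correlation distance between expression profiles
#'
#' d = 1 - Pearson r between row profiles, the shape-based distance
#' conventionally used to cluster expression trends: range [0, 2], 0 on the
#' diagonal, invariant to positive affine rescaling of a profile. Constant
#' profiles have undefined correlation; their distances are set to 1 with a
#' warning, and flagged in the `"constant"` attribute.
#'
#' @param profiles Numeric matrix, one row per protein, >= 3 columns.
#' @return A symmetric distance matrix with attribute `"constant"`.
#' @export
pearson_distance <- function(profiles) {
  if (!is.matrix(profiles) || nrow(profiles) < 2L)
    stop_("need a matrix of >= 2 profiles")
  if (ncol(profiles) < 3L) stop_("profiles need >= 3 points")
  constant <- apply(profiles, 1L, function(r) stats::sd(r) == 0)
  r <- suppressWarnings(stats::cor(t(profiles)))
  d <- 1 - r
  if (any(constant)) {
    warn_(sum(constant), " constant profile(s): distance set to 1")
    d[constant, ] <- 1
    d[, constant] <- 1
  }
  diag(d) <- 0
  d[d < 0] <- 0  # guard tiny negative rounding
  attr(d, "constant") <- constant
  d
}

#' Average-linkage hierarchical clustering of profiles
#'
#' Agglomerative clustering on a precomputed distance matrix, cut into `k`
#' flat clusters. Deterministic for a given input order ([stats::hclust()]
#' merges the lowest-index pair on ties).
#'
#' @param distances Symmetric distance matrix (e.g. [pearson_distance()]).
#' @param k Number of flat clusters.
#' @param linkage Agglomeration method.
#' @return List with the `hclust` tree (`tree`) and integer `clusters`.
#' @export
hierarchical_cluster <- function(distances, k, linkage = "average") {
  n <- nrow(distances)
  if (k > n) stop_("k (", k, ") exceeds the number of profiles (", n, ")")
  tree <- stats::hclust(stats::as.dist(distances), method = linkage)
  list(tree = tree, clusters = stats::cutree(tree, k = k))
}

#' Row-standardize profiles (z-profiles)
#'
#' Centres and scales each row to mean 0, SD 1 so Euclidean K-means becomes
#' shape-based. Constant rows cannot be standardized; they are returned as
#' all-zero rows and flagged.
#'
#' @param profiles Numeric matrix of row profiles.
#' @return Matrix of z-profiles with logical attribute `"constant"`.
#' @export
z_profiles <- function(profiles) {
  mu <- rowMeans(profiles)
  sdv <- apply(profiles, 1L, stats::sd)
  constant <- sdv == 0
  z <- (profiles - mu) / ifelse(constant, 1, sdv)
  z[constant, ] <- 0
  attr(z, "constant") <- constant
  z
}

#' K-means clustering of standardized trend profiles
#'
#' K-means on z-scored profiles with seeded random restarts, keeping the
#' lowest-inertia solution; labels are stable under the seed.
#'
#' @param profiles Numeric matrix, one row per protein.
#' @param params A [clustering_params()].
#' @return List with integer `labels`, `centers`, and total within-cluster
#'   `inertia`.
#' @export
kmeans_trends <- function(profiles, params = clustering_params()) {
  stopifnot(inherits(params, "clustering_params"))
  if (nrow(profiles) < params$k)
    stop_("need at least k = ", params$k, " profiles")
  z <- z_profiles(profiles)
  if (nrow(unique(as.data.frame(z))) < params$k)
    warn_("fewer distinct profiles than k; clusters may be degenerate")
  if (nrow(z) == params$k) {
    # one profile per cluster: the optimal partition is the singletons
    return(list(labels = stats::setNames(seq_len(params$k),
                                         rownames(profiles)),
                centers = z, inertia = 0))
  }
  fit <- with_seed(params$seed, {
    stats::kmeans(z, centers = params$k,
                  nstart = max(1L, params$n_restarts), iter.max = 50L)
  })
  list(labels = stats::setNames(fit$cluster, rownames(profiles)),
       centers = fit$centers, inertia = fit$tot.withinss)
}

#' Classify a three-group expression trend
#'
#' Rule-based labelling of a protein's mean profile over three ordered
#' groups. With consecutive differences d1, d2 and an absolute tolerance
#' eps = `tolerance` x range(means): both above eps gives `up`, both below
#' -eps gives `down`, rise then fall gives `up_down`, fall then rise gives
#' `down_up`, anything else `flat_mixed`. Constant profiles are
#' `flat_mixed` at any positive tolerance.
#'
#' @param means Numeric vector of exactly 3 ordered group means
#'   (log2 units).
#' @param tolerance Relative tolerance (fraction of the profile range,
#'   default 0.05).
#' @return One of `"up"`, `"down"`, `"up_down"`, `"down_up"`,
#'   `"flat_mixed"`.
#' @examples
#' classify_trend(c(1, 2, 3))            # "up"
#' classify_trend(c(0.749, 1.103, 1.018)) # "up_down"
#' @export
classify_trend <- function(means, tolerance = 0.05) {
  if (length(means) != 3L || !is.numeric(means))
    stop_("means must be a numeric vector of length 3")
  rng <- max(means) - min(means)
  if (rng == 0) return("flat_mixed")
  eps <- tolerance * rng
  d1 <- means[2] - means[1]
  d2 <- means[3] - means[2]
  if (d1 > eps && d2 > eps) return("up")
  if (d1 < -eps && d2 < -eps) return("down")
  if (d1 > eps && d2 < -eps) return("up_down")
  if (d1 < -eps && d2 > eps) return("down_up")
  "flat_mixed"
}

#' Trend profiles and labels for a set of proteins
#'
#' Builds the per-protein trend table over three ordered groups: raw group
#' means, z-profile, K-means cluster label and rule-based trend label.
#'
#' @param mean_matrix Numeric matrix of group means (rows proteins, 3
#'   ordered group columns), e.g. from [group_mean_matrix()].
#' @param params A [clustering_params()].
#' @param run_kmeans Logical; attach K-means labels (needs >= k rows).
#' @return Data frame with `accession`, the three group means,
#'   `kmeans_cluster` (NA when not run) and `trend_label`.
#' @export
trend_profiles <- function(mean_matrix, params = clustering_params(),
                           run_kmeans = TRUE) {
  if (ncol(mean_matrix) != 3L)
    stop_("trend profiles span exactly 3 ordered groups")
  labels <- apply(mean_matrix, 1L, classify_trend,
                  tolerance = params$trend_tolerance)
  km <- rep(NA_integer_, nrow(mean_matrix))
  if (run_kmeans && nrow(mean_matrix) >= params$k) {
    km <- kmeans_trends(mean_matrix, params)$labels
  }
  out <- data.frame(accession = rownames(mean_matrix),
                    mean_matrix, kmeans_cluster = unname(km),
                    trend_label = unname(labels),
                    stringsAsFactors = FALSE, row.names = NULL,
                    check.names = FALSE)
  out
}
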