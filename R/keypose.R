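#' Extract key poses from a sequence by k-means clustering
#'
#' The N posture features of one sequence are grouped into K clusters under
#' the squared-Euclidean objective
#'
#'     argmin_S  sum_j sum_{f in S_j} || f - C_j ||^2
#'
#' and the K centroids are taken as the sequence's key poses. Clustering is
#' run independently per sequence -- no dictionary shared across sequences
#' is learned -- which keeps the representation compact and training-free.
#'
#' The solver is Lloyd's algorithm with k-means++ seeding, `n_init`
#' restarts (best objective kept), an iteration cap and a relative
#' improvement tolerance. Frames equidistant from two centroids go to the
#' lower-indexed one; should a cluster empty out, the point currently
#' farthest from its centroid is reassigned to it and one refinement pass
#' follows, so the result always has exactly K non-empty clusters. The run
#' is deterministic given `seed` (the caller's RNG state is untouched).
#'
#' @param features Numeric `N x D` matrix of posture features (rows =
#'   frames, in temporal order).
#' @param K Number of key poses, `1 <= K <= N`. `K > N` is an error unless
#'   `clamp_k = TRUE`, which sets `K <- N` (useful when sweeping K over
#'   datasets whose shortest sequence is short).
#' @param seed Integer seed making the restarts reproducible.
#' @param n_init Number of k-means++ restarts.
#' @param max_iter Lloyd iteration cap per restart.
#' @param tol Relative objective-improvement tolerance for convergence.
#' @param clamp_k Clamp infeasible K to N instead of erroring.
#' @return An object of class `keypose_result`: list with `cluster_ids`
#'   (N integers in 1..K, temporal order), `centroids` (`K x D` matrix),
#'   `inertia` (the achieved objective value) and `K`.
#' @export
extract_key_poses <- function(features, K, seed = 1L, n_init = 10L,
                              max_iter = 300L, tol = 1e-6, clamp_k = FALSE) {
  features <- as.matrix(features)
  storage.mode(features) <- "double"
  N <- nrow(features)
  if (!all(is.finite(features))) stop("non-finite feature", call. = FALSE)
  K <- as.integer(K)
  if (K < 1L) stop("K must be >= 1", call. = FALSE)
  if (K > N) {
    if (!clamp_k)
      stop("infeasible K: K = ", K, " exceeds N = ", N,
           " frames (set clamp_k = TRUE to use K = N)", call. = FALSE)
    K <- N
  }
  best <- with_seed(seed, {
    b <- NULL
    for (r in seq_len(n_init)) {
      centers <- .kmeanspp_init(features, K)
      fit <- .lloyd(features, centers, max_iter = max_iter, tol = tol)
      if (is.null(b) || fit$inertia < b$inertia) b <- fit
    }
    b
  })
  structure(list(cluster_ids = best$assign, centroids = best$centers,
                 inertia = best$inertia, K = K),
            class = "keypose_result")
}

#' @export
print.keypose_result <- function(x, ...) {
  cat(sprintf("<keypose_result: K=%d, N=%d, inertia=%.6g>\n",
              x$K, length(x$cluster_ids), x$inertia))
  invisible(x)
}

# squared distances of all rows of X to each row of `centers` (N x K)
.sqdist_to_centers <- function(X, centers) {
  xs <- rowSums(X^2)
  cs <- rowSums(centers^2)
  outer(xs, cs, "+") - 2 * X %*% t(centers)
}

# k-means++ seeding: first center uniform, then D^2-weighted draws
.kmeanspp_init <- function(X, K) {
  N <- nrow(X)
  centers <- matrix(NA_real_, nrow = K, ncol = ncol(X))
  centers[1L, ] <- X[sample.int(N, 1L), ]
  if (K > 1L) {
    d2 <- pmax(.sqdist_to_centers(X, centers[1L, , drop = FALSE])[, 1L], 0)
    for (k in 2L:K) {
      if (sum(d2) <= 0) {
        idx <- sample.int(N, 1L)  # all points coincide with a center
      } else {
        idx <- sample.int(N, 1L, prob = d2)
      }
      centers[k, ] <- X[idx, ]
      d2 <- pmin(d2, pmax(.sqdist_to_centers(X, centers[k, , drop = FALSE])[, 1L], 0))
    }
  }
  centers
}

# Single-point improvement passes (Hartigan-style): move one frame to
# another cluster whenever that strictly lowers the objective, with exact
# size-weighted deltas. Escapes Lloyd-stable local optima; cannot empty a
# cluster. Returns possibly-updated (assign, centers) and whether it moved.
.hartigan_polish <- function(X, centers, assign, max_moves = 200L) {
  N <- nrow(X)
  K <- nrow(centers)
  moved <- FALSE
  for (mv in seq_len(max_moves)) {
    sizes <- tabulate(assign, nbins = K)
    d2 <- .sqdist_to_centers(X, centers)
    own <- d2[cbind(seq_len(N), assign)]
    remove_gain <- sizes[assign] / pmax(sizes[assign] - 1L, 1L) * own
    remove_gain[sizes[assign] <= 1L] <- -Inf  # moving would empty a cluster
    add_cost <- sweep(d2, 2L, sizes / (sizes + 1L), "*")
    delta <- add_cost - remove_gain
    delta[cbind(seq_len(N), assign)] <- 0
    best <- arrayInd(which.min(delta), dim(delta))
    i <- best[1L]; b <- best[2L]
    if (delta[i, b] >= -1e-12 * (1 + sum(own))) break
    a <- assign[i]
    centers[a, ] <- (centers[a, ] * sizes[a] - X[i, ]) / (sizes[a] - 1L)
    centers[b, ] <- (centers[b, ] * sizes[b] + X[i, ]) / (sizes[b] + 1L)
    assign[i] <- b
    moved <- TRUE
  }
  list(assign = assign, centers = centers, moved = moved)
}

# Lloyd iterations with lowest-index tie-break and empty-cluster repair,
# alternated with single-point polish passes until neither improves
.lloyd <- function(X, centers, max_iter, tol) {
  N <- nrow(X)
  K <- nrow(centers)
  assign <- integer(N)
  for (round in 1:5) {
    res <- .lloyd_core(X, centers, max_iter, tol)
    assign <- res$assign
    centers <- res$centers
    pol <- .hartigan_polish(X, centers, assign)
    if (!pol$moved) break
    assign <- pol$assign
    centers <- pol$centers
  }
  # final consistent assignment/objective (keeps clusters non-empty)
  d2 <- .sqdist_to_centers(X, centers)
  new_assign <- max.col(-d2, ties.method = "first")
  if (all(tabulate(new_assign, nbins = K) > 0L)) assign <- new_assign
  for (k in seq_len(K))
    centers[k, ] <- colMeans(X[assign == k, , drop = FALSE])
  inertia <- sum((X - centers[assign, , drop = FALSE])^2)
  list(assign = assign, centers = centers, inertia = inertia)
}

.lloyd_core <- function(X, centers, max_iter, tol) {
  N <- nrow(X)
  K <- nrow(centers)
  prev_obj <- Inf
  assign <- integer(N)
  for (it in seq_len(max_iter)) {
    d2 <- .sqdist_to_centers(X, centers)
    assign <- max.col(-d2, ties.method = "first")
    # repair empty clusters: farthest point from its centroid moves over
    repeat {
      sizes <- tabulate(assign, nbins = K)
      empty <- which(sizes == 0L)
      if (!length(empty)) break
      point_d2 <- d2[cbind(seq_len(N), assign)]
      movable <- which(sizes[assign] > 1L)
      far <- movable[which.max(point_d2[movable])]
      assign[far] <- empty[1L]
      d2[far, ] <- Inf  # pin it there for this pass
      d2[far, empty[1L]] <- 0
    }
    for (k in seq_len(K))
      centers[k, ] <- colMeans(X[assign == k, , drop = FALSE])
    obj <- sum((X - centers[assign, , drop = FALSE])^2)
    if (is.finite(prev_obj) &&
        prev_obj - obj <= tol * max(prev_obj, .Machine$double.eps)) break
    prev_obj <- obj
  }
  list(assign = assign, centers = centers)
}

#' Order cluster IDs by first temporal occurrence
#'
#' The clusters of a sequence are sorted by the frame index at which each
#' cluster first appears, restoring the temporal structure that the
#' (orderless) clustering discarded. For the cluster-ID sequence
#' `c(2,2,2,3,3,1,1,4,4,4)` the order is `c(2, 3, 1, 4)`.
#'
#' @param cluster_ids Integer vector of per-frame cluster IDs, temporal
#'   order.
#' @return The distinct cluster IDs in order of first occurrence.
#' @export
order_centroids <- function(cluster_ids) {
  if (!length(cluster_ids)) stop("empty cluster-ID sequence", call. = FALSE)
  unique(as.integer(cluster_ids))
}

#' Build the activity feature vector
#'
#' Concatenates a sequence's K centroid vectors in first-occurrence order
#' into the fixed-length descriptor used for classification. With P joints
#' the result has length `3 * K * (P - 1)`.
#'
#' @param result A [extract_key_poses()] result.
#' @return An object of class `activity_vector`: list with `values`
#'   (numeric vector of length `3K(P-1)`), `K`, and `order` (the
#'   first-occurrence permutation of 1..K).
#' @export
build_activity_vector <- function(result) {
  stopifnot(inherits(result, "keypose_result"))
  ord <- order_centroids(result$cluster_ids)
  values <- as.vector(t(result$centroids[ord, , drop = FALSE]))
  structure(list(values = values, K = result$K, order = ord),
            class = "activity_vector")
}

#' @export
print.activity_vector <- function(x, ...) {
  cat(sprintf("<activity_vector: K=%d, length=%d, order=[%s]>\n",
              x$K, length(x$values), paste(x$order, collapse = ",")))
  invisible(x)
}

#' Stack activity vectors into a classifier input matrix
#' @param vectors List of `activity_vector` objects of equal length.
#' @return Numeric matrix, one row per vector; row names from list names.
#' @export
stack_activity_vectors <- function(vectors) {
  vals <- lapply(vectors, function(v) {
    if (inherits(v, "activity_vector")) v$values else as.numeric(v)
  })
  lens <- lengths(vals)
  if (length(unique(lens)) != 1L)
    stop("activity vectors have differing lengths", call. = FALSE)
  m <- do.call(rbind, vals)
  rownames(m) <- names(vectors)
  m
}
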