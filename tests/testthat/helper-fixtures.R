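# shared fixtures: random-but-plausible frames, rotation matrices, and an
# exhaustive k-means oracle for tiny instances

# a jittered standing pose restricted to `joints`
random_frame <- function(joints = joint_scheme("J15")$members, sd = 0.05) {
  rest <- rest_skeleton()[joints, , drop = FALSE]
  rest + matrix(rnorm(length(rest), sd = sd), nrow = nrow(rest),
                dimnames = dimnames(rest))
}

# a short random sequence built from jittered frames
random_sequence <- function(n = 5, joints = joint_scheme("J15")$members,
                            id = "seq1", actor = "a1", label = "l1") {
  coords <- array(NA_real_, dim = c(n, length(joints), 3))
  for (i in seq_len(n)) coords[i, , ] <- random_frame(joints)
  skeleton_sequence(coords, joints, sequence_id = id, actor_id = actor,
                    label = label)
}

rotation_y <- function(theta) {
  matrix(c(cos(theta), 0, sin(theta),
           0, 1, 0,
           -sin(theta), 0, cos(theta)), 3, 3, byrow = TRUE)
}

# exhaustive k-means optimum: minimum of the squared-Euclidean objective
# over all assignments of N points to K clusters (label symmetry reduced
# by pinning point 1 to cluster 1); independent of the iterative solver
kmeans_bruteforce <- function(X, K) {
  X <- as.matrix(X)
  N <- nrow(X)
  # the objective as sum of squared deviations of one assignment (exact for
  # singleton clusters, unlike the fast difference form used in the search)
  direct_obj <- function(a) {
    obj <- 0
    for (k in unique(a)) {
      pts <- X[a == k, , drop = FALSE]
      obj <- obj + sum(sweep(pts, 2, colMeans(pts))^2)
    }
    obj
  }
  if (K == 1) return(direct_obj(rep(1L, N)))
  grid <- as.matrix(expand.grid(rep(list(seq_len(K)), N - 1)))
  xs2 <- sum(X^2)
  best <- Inf
  best_a <- NULL
  for (r in seq_len(nrow(grid))) {
    a <- c(1L, grid[r, ])
    s <- rowsum(X, a)
    n_k <- tabulate(a, nbins = K)[sort(unique(a))]
    obj <- xs2 - sum(rowSums(s^2) / n_k)
    if (obj < best) {
      best <- obj
      best_a <- a
    }
  }
  direct_obj(best_a)
}

# swap the left/right joint rows of a frame (the label permutation that
# mirroring applies), so isometry can be checked slot-by-slot
swap_lr_frame <- function(frame) {
  out <- frame
  base <- c("shoulder", "elbow", "wrist", "hand", "hip", "knee", "ankle", "foot")
  for (b in base) {
    l <- paste0("left_", b); r <- paste0("right_", b)
    if (all(c(l, r) %in% rownames(frame))) {
      out[l, ] <- frame[r, ]
      out[r, ] <- frame[l, ]
    }
  }
  out
}

# cheap deterministic string -> seed for per-sequence clustering in tests
hash_fixture <- function(id, salt = 0) {
  sum(utf8ToInt(id) * seq_along(utf8ToInt(id))) * 131 + salt
}

# Gaussian blob classes in D dims with centers `spread` apart
make_blobs <- function(n_per_class, centers, sd = 1) {
  X <- NULL
  y <- character(0)
  for (i in seq_len(nrow(centers))) {
    pts <- matrix(rnorm(n_per_class * ncol(centers), sd = sd),
                  nrow = n_per_class)
    pts <- sweep(pts, 2, centers[i, ], "+")
    X <- rbind(X, pts)
    y <- c(y, rep(paste0("class", i), n_per_class))
  }
  list(x = X, y = y)
}
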