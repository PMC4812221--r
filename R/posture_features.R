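#' Per-frame posture feature
#'
#' Converts one skeleton frame into a posture descriptor that is invariant
#' to where the person stands and to their build. With `J0` the torso joint
#' and `J2` the neck joint, every other joint `Ji` contributes the distance
#' vector
#'
#'     d_i = (J_i - J_0) / ||J_2 - J_0||
#'
#' and the feature is the concatenation `f = [d_1, ..., d_{P-1}]` over all
#' joints except the torso, in canonical joint order. Centering on the torso
#' removes the subject's position in the sensor's coverage area; dividing by
#' the neck--torso distance removes overall body size. The feature is *not*
#' rotation invariant -- facing direction is informative and is kept. No
#' temporal information enters: the descriptor is purely per-frame, which is
#' what makes the downstream activity representation independent of
#' movement speed.
#'
#' @param frame A `P x 3` matrix of joint coordinates with joint names as
#'   row names (as returned by [get_frame()]); must include `torso` and
#'   `neck`.
#' @param eps Degeneracy guard on the neck--torso distance, in meters. A
#'   frame whose neck and torso coincide to within `eps` signals corrupt
#'   tracking and raises an error. The default is far below sensor noise
#'   and only guards a true divide-by-zero.
#' @return Numeric vector of length `3 * (P - 1)`, dimensionless; names
#'   `<joint>.x/.y/.z` in canonical order with the torso excluded.
#' @examples
#' fr <- rbind(torso = c(0, 0, 0), neck = c(0, 1, 0), head = c(0, 1.2, 0))
#' compute_posture_feature(fr)
#' @export
compute_posture_feature <- function(frame, eps = 1e-9) {
  stopifnot(is.matrix(frame), ncol(frame) == 3L, !is.null(rownames(frame)))
  joints <- rownames(frame)
  if (!all(c("torso", "neck") %in% joints))
    stop("frame must contain 'torso' and 'neck' joints", call. = FALSE)
  torso <- frame["torso", ]
  neck <- frame["neck", ]
  denom <- sqrt(sum((neck - torso)^2))
  if (!is.finite(denom) || denom <= eps)
    stop("degenerate skeleton: neck-torso distance ", format(denom),
         " <= ", format(eps), call. = FALSE)
  keep <- setdiff(joints, "torso")
  d <- sweep(frame[keep, , drop = FALSE], 2L, torso) / denom
  out <- as.vector(t(d))
  names(out) <- paste(rep(keep, each = 3L), c("x", "y", "z"), sep = ".")
  out
}

#' Posture features for a whole sequence
#'
#' Applies [compute_posture_feature()] to every frame. A sequence of N
#' frames yields N feature vectors; frames are never silently dropped -- a
#' degenerate frame raises an error naming its index, so that callers can
#' pre-filter explicitly (silent dropping would change N and hence the
#' downstream clustering).
#'
#' @param seq A [skeleton_sequence()].
#' @param eps Passed to [compute_posture_feature()].
#' @return Numeric `N x 3(P-1)` matrix, one row per frame, in frame order.
#' @export
compute_sequence_features <- function(seq, eps = 1e-9) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  N <- n_frames(seq)
  P <- length(seq$joints)
  out <- matrix(NA_real_, nrow = N, ncol = 3L * (P - 1L))
  for (i in seq_len(N)) {
    f <- tryCatch(compute_posture_feature(get_frame(seq, i), eps = eps),
                  error = function(e)
                    stop("frame ", i, " of sequence '", seq$sequence_id,
                         "': ", conditionMessage(e), call. = FALSE))
    if (i == 1L) colnames(out) <- names(f)
    out[i, ] <- f
  }
  out
}
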