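#' Canonical skeleton joint vocabulary
#'
#' The package fixes a single 20-name joint vocabulary and ordering; every
#' sequence, feature vector and file format refers to joints by these names
#' in this order. Dataset-specific loaders are expected to map their native
#' joint layout onto this vocabulary.
#'
#' The order is: head, neck, torso, spine, then left/right pairs from the
#' shoulders down (shoulder, elbow, wrist, hand, hip, knee, ankle, foot).
#'
#' @return Character vector of the 20 canonical joint names, in canonical
#'   order.
#' @examples
#' canonical_joints()
#' @export
canonical_joints <- function() {
  c("head", "neck", "torso", "spine",
    "left_shoulder", "right_shoulder",
    "left_elbow", "right_elbow",
    "left_wrist", "right_wrist",
    "left_hand", "right_hand",
    "left_hip", "right_hip",
    "left_knee", "right_knee",
    "left_ankle", "right_ankle",
    "left_foot", "right_foot")
}

# left/right joint pairs, used by mirror_sequence() for label swapping
.lr_pairs <- function() {
  base <- c("shoulder", "elbow", "wrist", "hand", "hip", "knee", "ankle", "foot")
  data.frame(left = paste0("left_", base), right = paste0("right_", base),
             stringsAsFactors = FALSE)
}

#' Joint subset schemes
#'
#' Recognition accuracy is routinely evaluated on nested subsets of the
#' skeleton rather than all 20 joints. Four named schemes are provided:
#'
#' * `J7`: head, neck, torso, hands, feet (7 joints) -- the body extremes.
#' * `J11`: `J7` plus elbows and knees.
#' * `J15`: `J11` plus shoulders and hips -- the classic OpenNI 15-joint
#'   skeleton, the largest set available from 15-joint datasets.
#' * `J20`: the full canonical skeleton (adds spine, wrists, ankles),
#'   available only from 20-joint capture SDKs.
#'
#' Every scheme contains `torso` and `neck`, which the posture-feature
#' normalization requires, and is left/right symmetric.
#'
#' @param name One of `"J7"`, `"J11"`, `"J15"`, `"J20"`.
#' @return An object of class `joint_scheme`: a list with elements `name`
#'   and `members` (canonical joint names, in canonical order).
#' @examples
#' joint_scheme("J7")$members
#' @export
joint_scheme <- function(name = c("J7", "J11", "J15", "J20")) {
  name <- match.arg(name)
  members <- switch(name,
    J7  = c("head", "neck", "torso", "left_hand", "right_hand",
            "left_foot", "right_foot"),
    J11 = c("head", "neck", "torso", "left_elbow", "right_elbow",
            "left_hand", "right_hand", "left_knee", "right_knee",
            "left_foot", "right_foot"),
    J15 = c("head", "neck", "torso",
            "left_shoulder", "right_shoulder", "left_elbow", "right_elbow",
            "left_hand", "right_hand", "left_hip", "right_hip",
            "left_knee", "right_knee", "left_foot", "right_foot"),
    J20 = canonical_joints())
  # keep canonical ordering regardless of how the lists above are written
  members <- canonical_joints()[canonical_joints() %in% members]
  structure(list(name = name, members = members), class = "joint_scheme")
}

#' @export
print.joint_scheme <- function(x, ...) {
  cat("<joint_scheme ", x$name, ": ", length(x$members), " joints>\n", sep = "")
  invisible(x)
}

.as_scheme <- function(scheme) {
  if (inherits(scheme, "joint_scheme")) return(scheme)
  if (is.character(scheme) && length(scheme) == 1L) return(joint_scheme(scheme))
  stop("`scheme` must be a joint_scheme or one of \"J7\", \"J11\", \"J15\", \"J20\"",
       call. = FALSE)
}
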