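#' Canonical rest skeleton
#'
#' A fixed 20-joint standing pose (~1.75 m figure, meters; x = left/right,
#' y = up, z = depth) used as the base of the synthetic-activity generator.
#' The pose is arbitrary but frozen, so synthetic datasets are reproducible
#' across versions. The neck--torso distance is 0.40 m, comfortably away
#' from the posture-feature degeneracy guard.
#'
#' @return A `20 x 3` matrix, joints in canonical order as row names.
#' @export
rest_skeleton <- function() {
  m <- rbind(
    head           = c( 0.00, 1.70, 0.00),
    neck           = c( 0.00, 1.50, 0.00),
    torso          = c( 0.00, 1.10, 0.00),
    spine          = c( 0.00, 1.30, 0.00),
    left_shoulder  = c(-0.20, 1.45, 0.00),
    right_shoulder = c( 0.20, 1.45, 0.00),
    left_elbow     = c(-0.25, 1.20, 0.00),
    right_elbow    = c( 0.25, 1.20, 0.00),
    left_wrist     = c(-0.27, 0.98, 0.00),
    right_wrist    = c( 0.27, 0.98, 0.00),
    left_hand      = c(-0.28, 0.88, 0.00),
    right_hand     = c( 0.28, 0.88, 0.00),
    left_hip       = c(-0.12, 0.95, 0.00),
    right_hip      = c( 0.12, 0.95, 0.00),
    left_knee      = c(-0.14, 0.50, 0.00),
    right_knee     = c( 0.14, 0.50, 0.00),
    left_ankle     = c(-0.15, 0.08, 0.00),
    right_ankle    = c( 0.15, 0.08, 0.00),
    left_foot      = c(-0.16, 0.02, 0.12),
    right_foot     = c( 0.16, 0.02, 0.12)
  )
  colnames(m) <- c("x", "y", "z")
  m[canonical_joints(), ]
}

#' Configuration of the synthetic activity generator
#'
#' The generator emulates the statistical structure the recognition
#' pipeline assumes: an activity class is a short ordered tour of latent
#' key poses; an actor executes it at their own body scale, standing
#' anywhere on the floor, with per-frame sensor noise, variable sequence
#' length, and optionally mirrored (left-handed) execution.
#'
#' Defaults describe a small but realistic capture campaign: 3 activity
#' classes, 5 actors each repeating every activity 3 times, sequences of
#' 30--60 frames (2--4 s at 15 fps), 5 mm coordinate noise (typical RGBD
#' joint-tracking jitter), actor scales 0.9--1.1, a 3x3 m floor area, and
#' key poses separated by at least 0.3 m of joint displacement.
#'
#' @param n_classes Number of activity classes.
#' @param n_actors Number of actors.
#' @param repetitions_per_actor Executions of each class per actor.
#' @param key_poses_per_class Latent key poses per class (the true K).
#' @param frames_range Length-2 integer range of sequence lengths N.
#' @param noise_sigma Per-coordinate i.i.d. Gaussian noise SD, meters.
#' @param actor_scale_range Uniform range of actor body scale factors.
#' @param translation_range Side length (m) of the square floor area over
#'   which each sequence's torso anchor is placed uniformly.
#' @param left_handed_fraction Probability an actor is left-handed (all of
#'   that actor's sequences are sagittally mirrored).
#' @param pose_separation Minimum displacement (m) of at least one joint
#'   between consecutive key poses of a class.
#' @param interpolate Linearly interpolate between consecutive key poses
#'   (last 40% of each dwell); `FALSE` gives dwell-only sequences whose
#'   frames sit exactly on the key poses (useful for recovery analyses).
#' @param joints A [joint_scheme()] (or name) for the generated skeletons;
#'   default the full 20 joints.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of the configuration including the seed.
#' @return An object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_classes = 3L, n_actors = 5L,
                             repetitions_per_actor = 3L,
                             key_poses_per_class = 4L,
                             frames_range = c(30L, 60L),
                             noise_sigma = 0.005,
                             actor_scale_range = c(0.9, 1.1),
                             translation_range = 3,
                             left_handed_fraction = 0,
                             pose_separation = 0.3,
                             interpolate = TRUE,
                             joints = "J20",
                             seed = 1L) {
  stopifnot(n_classes >= 1L, n_actors >= 1L, repetitions_per_actor >= 1L,
            key_poses_per_class >= 1L, length(frames_range) == 2L,
            frames_range[1] >= key_poses_per_class,
            frames_range[1] <= frames_range[2],
            noise_sigma >= 0, actor_scale_range[1] > 0,
            actor_scale_range[1] <= actor_scale_range[2],
            translation_range >= 0,
            left_handed_fraction >= 0, left_handed_fraction <= 1,
            pose_separation > 0)
  structure(list(n_classes = as.integer(n_classes),
                 n_actors = as.integer(n_actors),
                 repetitions_per_actor = as.integer(repetitions_per_actor),
                 key_poses_per_class = as.integer(key_poses_per_class),
                 frames_range = as.integer(frames_range),
                 noise_sigma = noise_sigma,
                 actor_scale_range = actor_scale_range,
                 translation_range = translation_range,
                 left_handed_fraction = left_handed_fraction,
                 pose_separation = pose_separation,
                 interpolate = isTRUE(interpolate),
                 joints = .as_scheme(joints),
                 seed = as.integer(seed)),
            class = "synthetic_config")
}

# Latent class templates: each class is an ordered list of key poses
# (absolute P x 3 coordinates) plus dwell weights. Consecutive poses are
# rescaled, if needed, so that at least one joint moves >= pose_separation.
.make_class_templates <- function(config) {
  rest <- rest_skeleton()[config$joints$members, , drop = FALSE]
  P <- nrow(rest)
  # joints free to move between poses: everything but the normalization
  # anchors, so neck-torso stays rigid and features stay well-defined
  mobile <- setdiff(config$joints$members, c("torso", "neck"))
  templates <- vector("list", config$n_classes)
  for (c_i in seq_len(config$n_classes)) {
    Kt <- config$key_poses_per_class
    poses <- vector("list", Kt)
    prev <- rest
    for (j in seq_len(Kt)) {
      offs <- matrix(stats::rnorm(P * 3L, sd = config$pose_separation / 2),
                     nrow = P, dimnames = dimnames(rest))
      offs[c("torso", "neck"), ] <- 0
      pose <- rest + offs
      # enforce the separation floor against the previous pose
      disp <- sqrt(rowSums((pose - prev)^2))
      mx <- max(disp[mobile])
      if (mx < config$pose_separation) {
        fac <- config$pose_separation / max(mx, 1e-9)
        pose[mobile, ] <- prev[mobile, ] + fac * (pose[mobile, ] - prev[mobile, ])
      }
      poses[[j]] <- pose
      prev <- pose
    }
    g <- stats::rgamma(Kt, shape = 2)
    dwell <- 0.5 / Kt + 0.5 * g / sum(g)
    templates[[c_i]] <- list(key_poses = poses, dwell_weights = dwell)
  }
  templates
}

# one synthetic sequence: dwell/interpolate along the class's key poses,
# then scale, translate, optionally mirror, and add sensor noise
.synth_sequence <- function(template, config, scale_factor, translation,
                            lefty, N, joints, id, actor, label) {
  Kt <- length(template$key_poses)
  counts <- .dwell_counts(template$dwell_weights, N)
  P <- length(joints)
  coords <- array(NA_real_, dim = c(N, P, 3L))
  f <- 0L
  for (j in seq_len(Kt)) {
    nj <- counts[j]
    pose <- template$key_poses[[j]]
    if (config$interpolate && j < Kt) {
      n_dwell <- ceiling(0.6 * nj)
      n_interp <- nj - n_dwell
      for (t in seq_len(n_dwell)) coords[f + t, , ] <- pose
      nxt <- template$key_poses[[j + 1L]]
      for (t in seq_len(n_interp)) {
        a <- t / (n_interp + 1L)
        coords[f + n_dwell + t, , ] <- (1 - a) * pose + a * nxt
      }
    } else {
      for (t in seq_len(nj)) coords[f + t, , ] <- pose
    }
    f <- f + nj
  }
  coords <- coords * scale_factor
  coords[, , 1] <- coords[, , 1] + translation[1]
  coords[, , 3] <- coords[, , 3] + translation[2]
  s <- skeleton_sequence(coords, joints, sequence_id = id,
                         actor_id = actor, label = label)
  if (lefty) s <- mirror_sequence(s)
  if (config$noise_sigma > 0) {
    noisy <- s$coords + stats::rnorm(length(s$coords), sd = config$noise_sigma)
    s <- skeleton_sequence(noisy, joints, sequence_id = id,
                           actor_id = actor, label = label)
  }
  s
}

# integer frame allocation over poses: proportional to weights, >= 1 each
.dwell_counts <- function(weights, N) {
  Kt <- length(weights)
  counts <- diff(round(cumsum(c(0, weights)) * N))
  counts <- pmax(counts, 1L)
  while (sum(counts) > N) counts[which.max(counts)] <- counts[which.max(counts)] - 1L
  while (sum(counts) < N) counts[which.min(counts)] <- counts[which.min(counts)] + 1L
  as.integer(counts)
}

#' Generate a synthetic skeleton activity dataset in memory
#'
#' Draws class templates and per-sequence realizations according to the
#' configuration. Fully deterministic given the configuration (including
#' its seed).
#'
#' @param config A [synthetic_config()].
#' @return List with `sequences` (named list of `skeleton_sequence`),
#'   `manifest` (data frame with `sequence_id`, `actor_id`, `label`,
#'   `path` -- paths empty until written), and `templates` (the latent
#'   class templates: key poses and dwell weights).
#' @export
simulate_sequences <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  joints <- config$joints$members
  with_seed(config$seed, {
    templates <- .make_class_templates(config)
    scales <- stats::runif(config$n_actors, config$actor_scale_range[1],
                           config$actor_scale_range[2])
    lefty <- stats::runif(config$n_actors) < config$left_handed_fraction
    sequences <- list()
    rows <- list()
    for (a in seq_len(config$n_actors)) {
      actor <- sprintf("actor%02d", a)
      for (c_i in seq_len(config$n_classes)) {
        label <- sprintf("class%02d", c_i)
        for (r in seq_len(config$repetitions_per_actor)) {
          id <- sprintf("%s_%s_rep%02d", actor, label, r)
          n_choices <- seq.int(config$frames_range[1], config$frames_range[2])
          N <- n_choices[sample.int(length(n_choices), 1L)]
          translation <- stats::runif(2, -config$translation_range / 2,
                                      config$translation_range / 2)
          sequences[[id]] <- .synth_sequence(
            templates[[c_i]], config, scales[a], translation, lefty[a],
            N, joints, id, actor, label)
          rows[[id]] <- data.frame(sequence_id = id, actor_id = actor,
                                   label = label, path = "",
                                   stringsAsFactors = FALSE)
        }
      }
    }
    list(sequences = sequences, manifest = do.call(rbind, c(rows, list(make.row.names = FALSE))),
         templates = templates)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes one `skelcsv` file per sequence plus a `manifest.csv` into
#' `out_dir` and returns the manifest. Same configuration and seed give a
#' byte-identical dataset.
#'
#' @param config A [synthetic_config()].
#' @param out_dir Output directory (created if missing).
#' @return The manifest data frame, with `path` pointing at the written
#'   files; the latent `templates` are attached as an attribute.
#' @export
generate_dataset <- function(config, out_dir) {
  sim <- simulate_sequences(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(out_dir))
    stop("cannot create output directory: ", out_dir, call. = FALSE)
  man <- sim$manifest
  for (i in seq_len(nrow(man))) {
    fn <- file.path(out_dir, paste0(man$sequence_id[i], ".skelcsv"))
    write_sequence(sim$sequences[[man$sequence_id[i]]], fn)
    man$path[i] <- fn
  }
  # the stored manifest carries paths relative to its own location
  man_disk <- man
  man_disk$path <- basename(man_disk$path)
  write_manifest(man_disk, file.path(out_dir, "manifest.csv"))
  attr(man, "templates") <- sim$templates
  man
}

#' Change the execution speed of a sequence
#'
#' Monotone temporal resampling: the frame timeline is stretched or
#' compressed by `factor` while preserving the order in which poses are
#' visited. Integer factors >= 1 repeat every frame exactly `factor`
#' times; fractional surplus frames (or, for `factor < 1`, the frames
#' retained) are chosen by a seeded draw. The first frame is always kept.
#'
#' @param seq A `skeleton_sequence`.
#' @param factor Positive speed factor (2 = twice as many frames, i.e. the
#'   same motion performed half as fast).
#' @param seed Seed for the fractional-frame draw.
#' @return A `skeleton_sequence` with `max(1, round(N * factor))` frames.
#' @export
perturb_speed <- function(seq, factor, seed = 1L) {
  stopifnot(inherits(seq, "skeleton_sequence"), factor > 0)
  N <- n_frames(seq)
  M <- round(N * factor)
  if (M < 1L)
    stop("factor ", factor, " shrinks the sequence below one frame",
         call. = FALSE)
  if (M == N) return(seq)
  idx <- if (M > N) {
    base <- rep(seq_len(N), each = M %/% N)
    extra <- M - length(base)
    if (extra > 0) {
      dup <- with_seed(seed, sort(sample.int(N, extra)))
      sort(c(base, dup))
    } else base
  } else {
    keep <- with_seed(seed, sort(sample(2:N, M - 1L)))
    c(1L, keep)
  }
  skeleton_sequence(seq$coords[idx, , , drop = FALSE], seq$joints,
                    sequence_id = seq$sequence_id, actor_id = seq$actor_id,
                    label = seq$label)
}
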