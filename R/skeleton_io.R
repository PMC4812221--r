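#' Construct a skeleton sequence
#'
#' A skeleton sequence is the raw input of the recognition pipeline: an
#' ordered series of frames, each giving the 3D position (meters, sensor
#' coordinate frame) of the same set of joints, plus actor / activity-label
#' metadata.
#'
#' Coordinates are stored as an `N x P x 3` array (frames x joints x xyz)
#' with joint names from [canonical_joints()] on the second dimension.
#' Every sequence must contain the `torso` and `neck` joints (required by
#' the posture-feature normalization) and only finite coordinates.
#'
#' @param coords Numeric `N x P x 3` array, or an `N x 3P` matrix laid out
#'   as x,y,z per joint in joint order.
#' @param joints Character vector of P canonical joint names.
#' @param sequence_id,actor_id,label Metadata strings.
#' @return An object of class `skeleton_sequence` with elements `coords`
#'   (`N x P x 3` array), `joints`, `sequence_id`, `actor_id`, `label`.
#' @export
skeleton_sequence <- function(coords, joints, sequence_id = "seq",
                              actor_id = "actor", label = "unknown") {
  joints <- as.character(joints)
  if (anyDuplicated(joints))
    stop("duplicated joint names", call. = FALSE)
  unknown <- setdiff(joints, canonical_joints())
  if (length(unknown))
    stop("unknown joint name(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  if (!all(c("torso", "neck") %in% joints))
    stop("a skeleton sequence must contain the 'torso' and 'neck' joints",
         call. = FALSE)
  P <- length(joints)
  if (is.matrix(coords)) {
    if (ncol(coords) != 3L * P)
      stop("coordinate matrix must have 3 columns per joint", call. = FALSE)
    m <- coords
    coords <- array(NA_real_, dim = c(nrow(m), P, 3L))
    for (j in seq_len(P)) coords[, j, ] <- m[, (3L * j - 2L):(3L * j)]
  }
  if (!(is.array(coords) && length(dim(coords)) == 3L))
    stop("`coords` must be an N x P x 3 array or an N x 3P matrix",
         call. = FALSE)
  if (dim(coords)[2] != P || dim(coords)[3] != 3L)
    stop("`coords` must be N x ", P, " x 3", call. = FALSE)
  if (dim(coords)[1] < 1L)
    stop("a skeleton sequence needs at least one frame", call. = FALSE)
  if (!all(is.finite(coords)))
    stop("non-finite coordinate in skeleton sequence", call. = FALSE)
  dimnames(coords) <- list(NULL, joints, c("x", "y", "z"))
  structure(list(coords = coords, joints = joints,
                 sequence_id = as.character(sequence_id),
                 actor_id = as.character(actor_id),
                 label = as.character(label)),
            class = "skeleton_sequence")
}

#' @export
print.skeleton_sequence <- function(x, ...) {
  cat(sprintf("<skeleton_sequence %s: %d frames, %d joints, actor=%s, label=%s>\n",
              x$sequence_id, n_frames(x), length(x$joints), x$actor_id, x$label))
  invisible(x)
}

#' Number of frames in a sequence
#' @param seq A `skeleton_sequence`.
#' @return Integer frame count N.
#' @export
n_frames <- function(seq) dim(seq$coords)[1]

#' Extract one frame as a P x 3 joint-coordinate matrix
#' @param seq A `skeleton_sequence`.
#' @param i Frame index in 1..N.
#' @return Numeric `P x 3` matrix with joint names as row names.
#' @export
get_frame <- function(seq, i) {
  m <- seq$coords[i, , , drop = TRUE]
  if (length(seq$joints) == 1L) m <- matrix(m, nrow = 1L)
  dim(m) <- c(length(seq$joints), 3L)
  dimnames(m) <- list(seq$joints, c("x", "y", "z"))
  m
}

#' Read a skeleton sequence file
#'
#' The native dialect `"skelcsv"` is a plain-text format: a header line
#' `#joints=<comma-separated canonical names>` followed by one line per
#' frame holding `3 * P` comma-separated decimals (x,y,z per joint, in
#' header order). UTF-8, `.` decimal separator.
#'
#' @param path File to read.
#' @param dialect Format name; only `"skelcsv"` is built in.
#' @param sequence_id,actor_id,label Metadata attached to the returned
#'   sequence (the file itself carries only geometry).
#' @return A validated [skeleton_sequence()]; frame order as on disk.
#' @export
read_sequence <- function(path, dialect = "skelcsv", sequence_id = NULL,
                          actor_id = "actor", label = "unknown") {
  if (!identical(dialect, "skelcsv"))
    stop("unknown sequence dialect: ", dialect, call. = FALSE)
  if (!file.exists(path))
    stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines))
    stop("parse error in ", path, ": empty file", call. = FALSE)
  header <- lines[[1]]
  if (!startsWith(header, "#joints="))
    stop("parse error in ", path, " line 1: expected '#joints=' header",
         call. = FALSE)
  joints <- strsplit(sub("^#joints=", "", header), ",", fixed = TRUE)[[1]]
  joints <- trimws(joints)
  P <- length(joints)
  body <- lines[-1]
  if (!length(body))
    stop("parse error in ", path, ": no frame rows", call. = FALSE)
  rows <- strsplit(body, ",", fixed = TRUE)
  nf <- lengths(rows)
  bad <- which(nf != 3L * P)
  if (length(bad))
    stop("parse error in ", path, " line ", bad[1] + 1L, ": expected ",
         3L * P, " fields, found ", nf[bad[1]], call. = FALSE)
  vals <- suppressWarnings(as.numeric(unlist(rows)))
  unparsed <- is.na(vals) & !is.nan(vals)  # NaN/Inf parse fine; NA = garbage
  if (any(unparsed)) {
    bad_line <- which(vapply(rows, function(r) {
      v <- suppressWarnings(as.numeric(r))
      any(is.na(v) & !is.nan(v))
    }, logical(1)))[1]
    stop("parse error in ", path, " line ", bad_line + 1L,
         ": non-numeric field", call. = FALSE)
  }
  if (!all(is.finite(vals)))
    stop("validation error in ", path, ": non-finite coordinate",
         call. = FALSE)
  m <- matrix(vals, nrow = length(body), ncol = 3L * P, byrow = TRUE)
  coords <- array(NA_real_, dim = c(nrow(m), P, 3L))
  for (j in seq_len(P)) coords[, j, ] <- m[, (3L * j - 2L):(3L * j)]
  skeleton_sequence(coords, joints,
                    sequence_id = sequence_id %||%
                      sub("\\.[^.]*$", "", basename(path)),
                    actor_id = actor_id, label = label)
}

#' Write a skeleton sequence file
#'
#' Serializes to the native `"skelcsv"` dialect with full (17 significant
#' digit) precision so that `read_sequence(write_sequence(seq))` reproduces
#' `seq` exactly, and a second write is byte-identical.
#'
#' @param seq A valid [skeleton_sequence()].
#' @param path Destination file.
#' @return Invisibly, `path`.
#' @export
write_sequence <- function(seq, path) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  P <- length(seq$joints)
  N <- n_frames(seq)
  m <- matrix(NA_real_, nrow = N, ncol = 3L * P)
  for (j in seq_len(P)) m[, (3L * j - 2L):(3L * j)] <- seq$coords[, j, ]
  rows <- apply(m, 1L, function(r)
    paste(formatC(r, digits = 17, format = "g"), collapse = ","))
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(c(paste0("#joints=", paste(seq$joints, collapse = ",")), rows),
             con, sep = "\n")
  invisible(path)
}

#' Read / write a dataset manifest
#'
#' A manifest is a CSV with header `sequence_id,actor_id,label,path` listing
#' every sequence of a dataset. Paths are interpreted relative to the
#' manifest's own directory unless absolute.
#'
#' @param path Manifest CSV file.
#' @return A `data.frame` with columns `sequence_id`, `actor_id`, `label`,
#'   `path` (paths resolved against the manifest directory).
#' @export
read_manifest <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("sequence_id", "actor_id", "label", "path")
  if (!all(need %in% names(df)))
    stop("manifest must have columns ", paste(need, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(df$sequence_id))
    stop("duplicated sequence_id in manifest", call. = FALSE)
  rel <- !grepl("^(/|[A-Za-z]:)", df$path)
  df$path[rel] <- file.path(dirname(path), df$path[rel])
  df[, need]
}

#' @rdname read_manifest
#' @param manifest Data frame with the four manifest columns.
#' @export
write_manifest <- function(manifest, path) {
  need <- c("sequence_id", "actor_id", "label", "path")
  stopifnot(all(need %in% names(manifest)))
  utils::write.csv(manifest[, need], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Restrict a sequence to a joint subset
#'
#' @param seq A `skeleton_sequence`.
#' @param scheme A [joint_scheme()] (or its name). All scheme members must
#'   be present in `seq`; requesting e.g. `J20` from a 15-joint recording
#'   is an error, since the missing joints were never captured.
#' @return A `skeleton_sequence` holding exactly the scheme's joints, frame
#'   order unchanged.
#' @export
select_joints <- function(seq, scheme) {
  scheme <- .as_scheme(scheme)
  missing <- setdiff(scheme$members, seq$joints)
  if (length(missing))
    stop("unsupported scheme ", scheme$name, ": joint(s) not in sequence: ",
         paste(missing, collapse = ", "), call. = FALSE)
  keep <- match(scheme$members, seq$joints)
  skeleton_sequence(seq$coords[, keep, , drop = FALSE], scheme$members,
                    sequence_id = seq$sequence_id, actor_id = seq$actor_id,
                    label = seq$label)
}

#' Mirror a sequence across the body's sagittal plane
#'
#' Produces the left/right-swapped ("other-handed") version of an action,
#' used to augment training data when a dataset mixes left- and right-handed
#' executions. For each frame the sagittal plane is taken as the plane
#' through the torso joint whose normal is the left-shoulder to
#' right-shoulder direction of that frame; every joint is reflected across
#' it and left/right joint labels are swapped. This body-relative definition
#' works for arbitrarily rotated subjects.
#'
#' Mirroring is an involution (applying it twice restores the original to
#' numerical tolerance) and an isometry (all inter-joint distances are
#' preserved).
#'
#' @param seq A `skeleton_sequence` containing both shoulders and complete
#'   left/right joint pairs.
#' @return The mirrored `skeleton_sequence` (same id/actor/label, frame
#'   count and order unchanged).
#' @export
mirror_sequence <- function(seq) {
  stopifnot(inherits(seq, "skeleton_sequence"))
  if (!all(c("left_shoulder", "right_shoulder") %in% seq$joints))
    stop("cannot mirror: sequence lacks the shoulder joints that define the sagittal plane",
         call. = FALSE)
  pairs <- .lr_pairs()
  pairs <- pairs[pairs$left %in% seq$joints | pairs$right %in% seq$joints, ]
  incomplete <- !(pairs$left %in% seq$joints & pairs$right %in% seq$joints)
  if (any(incomplete))
    stop("cannot mirror: incomplete left/right pair(s): ",
         paste(pairs$left[incomplete], collapse = ", "), call. = FALSE)
  coords <- seq$coords
  N <- dim(coords)[1]
  t_i <- match("torso", seq$joints)
  ls_i <- match("left_shoulder", seq$joints)
  rs_i <- match("right_shoulder", seq$joints)
  for (f in seq_len(N)) {
    fr <- matrix(coords[f, , ], ncol = 3L)
    n <- fr[rs_i, ] - fr[ls_i, ]
    nn <- sqrt(sum(n^2))
    if (nn <= 1e-12)
      stop("cannot mirror frame ", f, ": coincident shoulders", call. = FALSE)
    n <- n / nn
    rel <- sweep(fr, 2L, fr[t_i, ])
    fr <- fr - 2 * (rel %*% n) %*% t(n)
    coords[f, , ] <- fr
  }
  # swap left/right labels by swapping the coordinate slots
  for (k in seq_len(nrow(pairs))) {
    li <- match(pairs$left[k], seq$joints)
    ri <- match(pairs$right[k], seq$joints)
    tmp <- coords[, li, , drop = FALSE]
    coords[, li, ] <- coords[, ri, ]
    coords[, ri, ] <- tmp
  }
  skeleton_sequence(coords, seq$joints, sequence_id = seq$sequence_id,
                    actor_id = seq$actor_id, label = seq$label)
}
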