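#' Specify an evaluation protocol
#'
#' Three protocol kinds cover the standard evaluation settings for
#' skeleton activity recognition:
#'
#' * `random_split`: per repetition, a class-stratified random split with a
#'   given training fraction. The named presets `"A"`, `"B"`, `"C"` use
#'   training fractions 1/3, 2/3 and 1/2 respectively.
#' * `new_person` (leave-one-actor-out): one fold per actor; all of that
#'   actor's sequences are tested on a model trained on everyone else.
#'   Repetitions rerun the folds with fresh clustering/CV seeds (the
#'   k-means stage is randomized).
#' * `loocv`: leave-one-sequence-out, one fold per sequence.
#'
#' @param kind `"random_split"`, `"new_person"`, `"loocv"`, or a preset
#'   `"A"`/`"B"`/`"C"` (random splits at the standard fractions).
#' @param train_fraction Training fraction in (0,1), random splits only.
#' @param repetitions Number of repetitions to average over.
#' @param k_values Integer vector of cluster counts K to sweep.
#' @param scheme A [joint_scheme()] (or name) applied to every sequence, or
#'   `NULL` to use each sequence's joints as stored.
#' @param mirror_augment Add a sagittally mirrored copy of every training
#'   sequence (same actor ID, so actor-disjoint folds stay leak-free);
#'   test folds are never augmented.
#' @param clamp_k Clamp K to a sequence's frame count when it exceeds it.
#' @param seed Master seed; every random choice of the protocol derives
#'   from it deterministically.
#' @return An object of class `protocol_spec`.
#' @export
protocol_spec <- function(kind = c("random_split", "new_person", "loocv",
                                   "A", "B", "C"),
                          train_fraction = NULL, repetitions = 1L,
                          k_values = 4L, scheme = NULL,
                          mirror_augment = FALSE, clamp_k = FALSE,
                          seed = 1L) {
  kind <- match.arg(kind)
  preset <- NULL
  if (kind %in% c("A", "B", "C")) {
    preset <- kind
    train_fraction <- switch(kind, A = 1 / 3, B = 2 / 3, C = 1 / 2)
    kind <- "random_split"
  }
  if (kind == "random_split") {
    if (is.null(train_fraction)) train_fraction <- 1 / 2
    stopifnot(train_fraction > 0, train_fraction < 1)
  } else {
    train_fraction <- NA_real_
  }
  if (!is.null(scheme)) scheme <- .as_scheme(scheme)
  stopifnot(repetitions >= 1L, all(k_values >= 1L))
  structure(list(kind = kind, preset = preset,
                 train_fraction = train_fraction,
                 repetitions = as.integer(repetitions),
                 k_values = as.integer(k_values), scheme = scheme,
                 mirror_augment = isTRUE(mirror_augment),
                 clamp_k = isTRUE(clamp_k), seed = as.integer(seed)),
            class = "protocol_spec")
}

#' Number of folds a protocol produces on a manifest
#' @param manifest Dataset manifest data frame.
#' @param spec A [protocol_spec()].
#' @return Integer fold count: 1 for random splits, one per actor for
#'   `new_person`, one per sequence for `loocv`.
#' @export
n_folds <- function(manifest, spec) {
  switch(spec$kind,
         random_split = 1L,
         new_person = length(unique(manifest$actor_id)),
         loocv = nrow(manifest))
}

#' Train/test split for one fold of a protocol
#'
#' Deterministic given `(spec$seed, repetition_index, fold_index)`. Random
#' splits are stratified per class (each class contributes
#' `round(train_fraction * n_class)` training sequences), which prevents a
#' class from disappearing from the training set at small fractions.
#'
#' @param manifest Dataset manifest data frame (`sequence_id`, `actor_id`,
#'   `label`, `path`).
#' @param spec A [protocol_spec()].
#' @param repetition_index Repetition number (1-based); reseeds random
#'   splits.
#' @param fold_index Fold number in `1..n_folds(manifest, spec)`.
#' @return List with character vectors `train` and `test` of sequence IDs
#'   (disjoint, covering the manifest).
#' @export
split_dataset <- function(manifest, spec, repetition_index = 1L,
                          fold_index = 1L) {
  stopifnot(inherits(spec, "protocol_spec"), nrow(manifest) >= 1L)
  ids <- manifest$sequence_id
  if (spec$kind == "random_split") {
    train <- character(0)
    split_seed <- hash_seed(spec$seed, "split", repetition_index)
    with_seed(split_seed, {
      for (cl in sort(unique(manifest$label))) {
        cl_ids <- ids[manifest$label == cl]
        n_tr <- round(spec$train_fraction * length(cl_ids))
        n_tr <- max(1L, min(length(cl_ids) - 1L, n_tr))
        train <- c(train, sample(cl_ids, n_tr))
      }
    })
    list(train = sort(train), test = sort(setdiff(ids, train)))
  } else if (spec$kind == "new_person") {
    actors <- sort(unique(manifest$actor_id))
    if (length(actors) < 2L)
      stop("new_person protocol needs at least two actors", call. = FALSE)
    if (fold_index < 1L || fold_index > length(actors))
      stop("fold_index out of range", call. = FALSE)
    held <- actors[fold_index]
    list(train = ids[manifest$actor_id != held],
         test = ids[manifest$actor_id == held])
  } else {  # loocv
    if (fold_index < 1L || fold_index > nrow(manifest))
      stop("fold_index out of range", call. = FALSE)
    list(train = ids[-fold_index], test = ids[fold_index])
  }
}

#' Precision, recall and accuracy from a confusion matrix
#'
#' With rows = true classes and columns = predicted classes:
#' `precision_c = confusion[c,c] / colSums(confusion)[c]`,
#' `recall_c = confusion[c,c] / rowSums(confusion)[c]`,
#' `accuracy = trace / total`. A zero denominator (class never predicted,
#' or absent from the test set) yields `NA` rather than 0, and `NA`s are
#' excluded from the macro (unweighted mean) averages; set
#' `undefined_as_zero = TRUE` for the zero convention instead.
#'
#' @param confusion Square non-negative integer matrix, true x predicted.
#' @param undefined_as_zero Count undefined per-class metrics as 0 in the
#'   macro averages.
#' @return List with `precision`, `recall` (named per-class vectors,
#'   possibly `NA`), `accuracy`, `macro_precision`, `macro_recall`.
#' @examples
#' compute_metrics(matrix(c(2, 1, 0, 1), 2, 2,
#'                        dimnames = list(c("a", "b"), c("a", "b"))))
#' @export
compute_metrics <- function(confusion, undefined_as_zero = FALSE) {
  confusion <- as.matrix(confusion)
  if (nrow(confusion) != ncol(confusion))
    stop("confusion matrix must be square", call. = FALSE)
  if (any(confusion < 0) || any(confusion != round(confusion)))
    stop("confusion matrix must hold non-negative counts", call. = FALSE)
  tp <- diag(confusion)
  col_tot <- colSums(confusion)
  row_tot <- rowSums(confusion)
  precision <- ifelse(col_tot > 0, tp / col_tot, NA_real_)
  recall <- ifelse(row_tot > 0, tp / row_tot, NA_real_)
  names(precision) <- names(recall) <- rownames(confusion)
  if (undefined_as_zero) {
    macro_p <- mean(ifelse(is.na(precision), 0, precision))
    macro_r <- mean(ifelse(is.na(recall), 0, recall))
  } else {
    macro_p <- mean(precision, na.rm = TRUE)
    macro_r <- mean(recall, na.rm = TRUE)
  }
  list(precision = precision, recall = recall,
       accuracy = sum(tp) / sum(confusion),
       macro_precision = macro_p, macro_recall = macro_r)
}

# Load every manifest sequence, apply the joint scheme, and return the
# per-sequence posture-feature matrices (plus mirrored copies if needed).
.load_features <- function(manifest, spec, sequences = NULL) {
  feats <- list()
  mirr <- list()
  for (i in seq_len(nrow(manifest))) {
    id <- manifest$sequence_id[i]
    s <- if (!is.null(sequences)) sequences[[id]] else
      read_sequence(manifest$path[i], sequence_id = id,
                    actor_id = manifest$actor_id[i],
                    label = manifest$label[i])
    if (!is.null(spec$scheme)) s <- select_joints(s, spec$scheme)
    feats[[id]] <- compute_sequence_features(s)
    if (spec$mirror_augment) {
      sm <- if (all(c("left_shoulder", "right_shoulder") %in% s$joints)) s else
        stop("mirror_augment requires shoulder joints; scheme ",
             spec$scheme$name %||% "?", " lacks them", call. = FALSE)
      mirr[[id]] <- compute_sequence_features(mirror_sequence(sm))
    }
  }
  list(features = feats, mirrored = mirr)
}

#' Run a full recognition experiment
#'
#' Executes the complete pipeline under a protocol: load sequences, select
#' joints, compute posture features, extract K key poses per sequence,
#' build activity vectors, train the one-vs-one SVM on each training fold
#' and predict its test fold. Per repetition, fold confusion matrices are
#' pooled; across repetitions, accuracy and per-class metrics are averaged
#' arithmetically (the pooled confusion counts are summed). Each
#' sequence's clustering seed derives deterministically from
#' `(spec$seed, sequence_id, repetition)`, so runs are reproducible while
#' sequences stay independent.
#'
#' When `spec$mirror_augment` is on, a mirrored copy of every *training*
#' sequence is added under the same actor ID; test folds always contain
#' only the natural recordings.
#'
#' @param manifest Dataset manifest data frame (see [read_manifest()]).
#' @param spec A [protocol_spec()].
#' @param grid A [hyper_grid()] for SVM model selection.
#' @param sequences Optional named list of pre-loaded `skeleton_sequence`
#'   objects keyed by `sequence_id` (skips file reads).
#' @return An object of class `har_experiment`: a list of
#'   `evaluation_report` objects, one per K in `spec$k_values`, named by K.
#'   Each report holds the summed `confusion`, averaged `accuracy`,
#'   `precision`/`recall` (per class and macro), and a `per_repetition`
#'   breakdown including the chosen `(C, gamma)` per fold.
#' @export
run_experiment <- function(manifest, spec, grid = hyper_grid(),
                           sequences = NULL) {
  stopifnot(inherits(spec, "protocol_spec"))
  classes <- sort(unique(manifest$label))
  loaded <- .load_features(manifest, spec, sequences)
  lens <- vapply(loaded$features, nrow, integer(1))
  reports <- list()

  for (K in spec$k_values) {
    if (!spec$clamp_k && any(lens < K)) {
      offenders <- names(lens)[lens < K]
      stop("infeasible K = ", K, " for sequence(s): ",
           paste(offenders, collapse = ", "),
           " (fewer frames than K; set clamp_k)", call. = FALSE)
    }
    conf_total <- matrix(0L, length(classes), length(classes),
                         dimnames = list(classes, classes))
    per_rep <- vector("list", spec$repetitions)

    for (rep_i in seq_len(spec$repetitions)) {
      # activity vectors for every sequence (and mirrored copy) at this K
      vec <- function(id, feats) {
        kp <- extract_key_poses(feats, K,
                                seed = hash_seed(spec$seed, id, rep_i),
                                clamp_k = spec$clamp_k)
        build_activity_vector(kp)$values
      }
      av <- lapply(names(loaded$features),
                   function(id) vec(id, loaded$features[[id]]))
      names(av) <- names(loaded$features)
      av_m <- if (spec$mirror_augment) {
        m <- lapply(names(loaded$mirrored),
                    function(id) vec(paste0(id, "#mirror"),
                                     loaded$mirrored[[id]]))
        names(m) <- names(loaded$mirrored)
        m
      } else NULL

      conf_rep <- matrix(0L, length(classes), length(classes),
                         dimnames = list(classes, classes))
      fold_info <- list()
      for (fold_i in seq_len(n_folds(manifest, spec))) {
        sp <- split_dataset(manifest, spec, rep_i, fold_i)
        tr_x <- do.call(rbind, av[sp$train])
        tr_y <- manifest$label[match(sp$train, manifest$sequence_id)]
        if (spec$mirror_augment) {
          tr_x <- rbind(tr_x, do.call(rbind, av_m[sp$train]))
          tr_y <- c(tr_y, tr_y)
        }
        model <- train_classifier(tr_x, tr_y, grid = grid,
                                  seed = hash_seed(spec$seed, "cv",
                                                   rep_i * 10000L + fold_i))
        te_x <- do.call(rbind, av[sp$test])
        truth <- manifest$label[match(sp$test, manifest$sequence_id)]
        pred <- predict(model, te_x)
        for (j in seq_along(truth))
          conf_rep[truth[j], pred[j]] <- conf_rep[truth[j], pred[j]] + 1L
        fold_info[[fold_i]] <- list(C = model$C, gamma = model$gamma,
                                    n_test = length(truth))
      }
      m <- compute_metrics(conf_rep)
      per_rep[[rep_i]] <- list(confusion = conf_rep, accuracy = m$accuracy,
                               precision = m$precision, recall = m$recall,
                               folds = fold_info)
      conf_total <- conf_total + conf_rep
    }

    acc <- mean(vapply(per_rep, `[[`, numeric(1), "accuracy"))
    prec <- rowMeans(vapply(per_rep, `[[`, numeric(length(classes)),
                            "precision"), na.rm = TRUE)
    rec <- rowMeans(vapply(per_rep, `[[`, numeric(length(classes)),
                           "recall"), na.rm = TRUE)
    reports[[as.character(K)]] <- structure(
      list(K = K, confusion = conf_total, accuracy = acc,
           precision = prec, recall = rec,
           macro_precision = mean(prec, na.rm = TRUE),
           macro_recall = mean(rec, na.rm = TRUE),
           per_repetition = per_rep, classes = classes,
           protocol = spec),
      class = "evaluation_report")
  }
  structure(reports, class = "har_experiment")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report: K=%d, accuracy=%.3f, macro P/R=%.3f/%.3f over %d repetition(s)>\n",
              x$K, x$accuracy, x$macro_precision, x$macro_recall,
              length(x$per_repetition)))
  invisible(x)
}

#' @export
print.har_experiment <- function(x, ...) {
  cat("<har_experiment>\n")
  for (r in x) print(r)
  invisible(x)
}
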