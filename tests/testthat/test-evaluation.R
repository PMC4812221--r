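make_manifest <- function(n_actors = 4, n_classes = 3, reps = 2) {
  g <- expand.grid(actor = sprintf("a%02d", seq_len(n_actors)),
                   label = sprintf("c%02d", seq_len(n_classes)),
                   rep = seq_len(reps), stringsAsFactors = FALSE)
  data.frame(sequence_id = sprintf("%s_%s_%d", g$actor, g$label, g$rep),
             actor_id = g$actor, label = g$label, path = "",
             stringsAsFactors = FALSE)
}

test_that("random splits are stratified, disjoint, covering, and seeded", {
  man <- make_manifest(n_actors = 3, n_classes = 3, reps = 3)  # 9 per class
  spec <- protocol_spec("A", seed = 42)
  sp <- split_dataset(man, spec, repetition_index = 1)
  expect_length(intersect(sp$train, sp$test), 0)
  expect_setequal(c(sp$train, sp$test), man$sequence_id)
  # one-third training, per class
  tr_lab <- man$label[match(sp$train, man$sequence_id)]
  expect_equal(unname(table(tr_lab)), rep(3L, 3), ignore_attr = TRUE)

  expect_identical(split_dataset(man, spec, 2), split_dataset(man, spec, 2))
  expect_false(identical(split_dataset(man, spec, 1)$train,
                         split_dataset(man, spec, 2)$train))

  # 18 sequences of one class at fraction 1/3: 6 train, 12 test
  man1 <- data.frame(sequence_id = sprintf("s%02d", 1:18),
                     actor_id = "a1", label = "only", path = "")
  sp1 <- split_dataset(man1, protocol_spec("A", seed = 1), 1)
  expect_length(sp1$train, 6)
  expect_length(sp1$test, 12)
})

test_that("experiment presets use the standard training fractions", {
  expect_equal(protocol_spec("A")$train_fraction, 1 / 3)
  expect_equal(protocol_spec("B")$train_fraction, 2 / 3)
  expect_equal(protocol_spec("C")$train_fraction, 1 / 2)
  expect_identical(protocol_spec("A")$kind, "random_split")
})

test_that("new-person folds hold out exactly one actor each", {
  man <- make_manifest(n_actors = 10)
  spec <- protocol_spec("new_person")
  expect_equal(n_folds(man, spec), 10)
  for (f in seq_len(10)) {
    sp <- split_dataset(man, spec, 1, f)
    te_actors <- unique(man$actor_id[match(sp$test, man$sequence_id)])
    tr_actors <- unique(man$actor_id[match(sp$train, man$sequence_id)])
    expect_length(te_actors, 1)
    expect_length(intersect(tr_actors, te_actors), 0)
    expect_setequal(c(sp$train, sp$test), man$sequence_id)
  }
  one <- make_manifest(n_actors = 1)
  expect_error(split_dataset(one, spec, 1, 1), "two actors")
})

test_that("loocv yields one singleton test fold per sequence", {
  man <- make_manifest(n_actors = 2, n_classes = 2, reps = 2)
  spec <- protocol_spec("loocv")
  expect_equal(n_folds(man, spec), nrow(man))
  seen <- character(0)
  for (f in seq_len(nrow(man))) {
    sp <- split_dataset(man, spec, 1, f)
    expect_length(sp$test, 1)
    expect_length(sp$train, nrow(man) - 1)
    seen <- c(seen, sp$test)
  }
  expect_setequal(seen, man$sequence_id)
})

test_that("metrics follow the precision/recall/accuracy definitions", {
  conf <- matrix(c(2, 1, 0, 1), 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  m <- compute_metrics(conf)
  expect_equal(unname(m$precision), c(2 / 3, 1))
  expect_equal(unname(m$recall), c(1, 1 / 2))
  expect_equal(m$accuracy, 3 / 4)

  ident <- diag(c(3, 4, 5))
  dimnames(ident) <- list(letters[1:3], letters[1:3])
  mi <- compute_metrics(ident)
  expect_equal(unname(mi$precision), rep(1, 3))
  expect_equal(unname(mi$recall), rep(1, 3))
  expect_equal(mi$accuracy, 1)

  # absent class: undefined marker excluded from the macro mean
  conf0 <- matrix(c(2, 0, 1, 0, 0, 0, 0, 0, 3), 3, 3, byrow = TRUE,
                  dimnames = list(letters[1:3], letters[1:3]))
  m0 <- compute_metrics(conf0)
  expect_true(is.na(m0$recall["b"]))
  expect_equal(m0$macro_recall, mean(c(2 / 3, 1)))
  mz <- compute_metrics(conf0, undefined_as_zero = TRUE)
  expect_equal(mz$macro_recall, mean(c(2 / 3, 0, 1)))

  expect_error(compute_metrics(matrix(0, 2, 3)), "square")
})

test_that("macro metrics are invariant under class relabeling", {
  set.seed(3)
  conf <- matrix(rpois(16, 3), 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  m <- compute_metrics(conf)
  perm <- c(3, 1, 4, 2)
  m_p <- compute_metrics(conf[perm, perm])
  expect_equal(m_p$macro_precision, m$macro_precision)
  expect_equal(m_p$macro_recall, m$macro_recall)
  expect_equal(unname(m_p$precision), unname(m$precision[perm]))
})

test_that("run_experiment bookkeeping: confusion totals, determinism, pooled accuracy", {
  cfg <- synthetic_config(n_actors = 3, repetitions_per_actor = 2,
                          frames_range = c(20L, 30L), seed = 5)
  sim <- simulate_sequences(cfg)
  grid <- hyper_grid(C_values = c(1, 32), gamma_values = c(0.001, 0.1))
  spec <- protocol_spec("new_person", k_values = 3, scheme = "J7", seed = 9)
  ex <- run_experiment(sim$manifest, spec, grid, sequences = sim$sequences)
  rep1 <- ex[["3"]][["per_repetition"]][[1]]
  expect_equal(sum(ex[["3"]]$confusion), nrow(sim$manifest))
  expect_equal(dim(ex[["3"]]$confusion), c(3, 3))
  # pooled accuracy equals the fold-size-weighted mean of fold accuracies
  expect_equal(rep1$accuracy,
               sum(diag(rep1$confusion)) / sum(rep1$confusion))

  ex2 <- run_experiment(sim$manifest, spec, grid, sequences = sim$sequences)
  expect_identical(ex[["3"]]$confusion, ex2[["3"]]$confusion)
  expect_equal(ex[["3"]]$accuracy, ex2[["3"]]$accuracy)
})

test_that("infeasible K is reported with the offending sequences", {
  cfg <- synthetic_config(n_actors = 2, repetitions_per_actor = 1,
                          frames_range = c(6L, 8L), seed = 2)
  sim <- simulate_sequences(cfg)
  spec <- protocol_spec("new_person", k_values = 50, scheme = "J7", seed = 1)
  expect_error(run_experiment(sim$manifest, spec, sequences = sim$sequences),
               "infeasible K")
})

test_that("mirror augmentation enlarges training only; test folds stay natural", {
  cfg <- synthetic_config(n_actors = 3, repetitions_per_actor = 2,
                          frames_range = c(15L, 20L), joints = "J15",
                          left_handed_fraction = 0.5, seed = 6)
  sim <- simulate_sequences(cfg)
  grid <- hyper_grid(C_values = 8, gamma_values = 0.01)
  spec <- protocol_spec("new_person", k_values = 3, scheme = "J15",
                        mirror_augment = TRUE, seed = 4)
  ex <- run_experiment(sim$manifest, spec, grid, sequences = sim$sequences)
  # every natural sequence predicted exactly once despite doubled training
  expect_equal(sum(ex[["3"]]$confusion), nrow(sim$manifest))
})
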