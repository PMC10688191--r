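# Small shared corpus for classifier tests (acceptance uses a larger one).
corpus_small <- gen_labeled_corpus(n_per_class = 60L, n_frames = 1200L,
                                   seed = 101L)
X_small <- corpus_small$features[dos_feature_names()]
y_small <- corpus_small$labels

test_that("switch_fit validates inputs and learns separable data", {
  expect_error(switch_fit(X_small, rep(1L, nrow(X_small)), "decision_tree"),
               "both classes")
  expect_error(switch_fit(X_small[1:10, ], y_small, "random_forest"),
               "differ in length")
  expect_error(switch_fit(X_small[, 1:5], y_small, "random_forest"),
               "missing")
  for (kind in c("random_forest", "gradient_boosted", "decision_tree")) {
    m <- switch_fit(X_small, y_small, kind, seed = 5L)
    expect_s3_class(m, "switch_model")
    expect_identical(m$manifest, dos_feature_names())
    train_acc <- mean(predict(m, X_small) == y_small)
    expect_gte(train_acc, 0.98)  # clear-margin corpus is nearly separable
    expect_true(all(predict(m, X_small) %in% c(0L, 1L)))
  }
  # contradictory duplicated labels cap training accuracy below 1
  Xc <- rbind(X_small[1:30, ], X_small[1:30, ])
  yc <- c(rep(0L, 30), rep(1L, 30))
  mc <- switch_fit(Xc, yc, "decision_tree", seed = 1L)
  expect_lt(mean(predict(mc, Xc) == yc), 1)
})

test_that("cross-validation is stratified, seeded and reproducible", {
  r1 <- cross_validate(X_small, y_small, "decision_tree", seed = 9L)
  r2 <- cross_validate(X_small, y_small, "decision_tree", seed = 9L)
  expect_identical(r1, r2)
  expect_identical(r1$n_folds, 5L)
  expect_length(r1$fold_accuracy, 5L)
  expect_equal(r1$mean_accuracy, mean(r1$fold_accuracy))
  expect_true(all(r1$fold_accuracy >= 0 & r1$fold_accuracy <= 1))
  few <- c(1:3, 61:63)  # three examples per class, fewer than n_folds
  expect_error(cross_validate(X_small[few, ], y_small[few],
                              "decision_tree", n_folds = 5L),
               "at least n_folds")
  # label shuffling collapses accuracy to the majority-class fraction
  set.seed(13)
  y_perm <- sample(y_small)
  r_perm <- cross_validate(X_small, y_perm, "decision_tree", seed = 9L)
  baseline <- max(mean(y_small == 0L), mean(y_small == 1L))
  expect_lt(abs(r_perm$mean_accuracy - baseline), 0.1)
})

test_that("model persistence round-trips predictions exactly", {
  set.seed(77)
  jitter_rows <- X_small[sample(nrow(X_small), 1000L, replace = TRUE), ]
  jitter_rows$sample_variance <-
    jitter_rows$sample_variance * stats::runif(1000L, 0.9, 1.1)
  for (kind in c("random_forest", "gradient_boosted", "decision_tree")) {
    m <- switch_fit(X_small, y_small, kind, seed = 3L)
    path <- tempfile(fileext = ".rds")
    save_model(m, path)
    m2 <- load_model(path)
    expect_identical(predict(m2, jitter_rows), predict(m, jitter_rows))
    unlink(path)
  }
})

test_that("forest accuracy is not materially below the single tree", {
  rf <- cross_validate(X_small, y_small, "random_forest", seed = 21L)
  dt <- cross_validate(X_small, y_small, "decision_tree", seed = 21L)
  expect_gte(rf$mean_accuracy, dt$mean_accuracy - 0.02)
})

test_that("residue rollup flags a residue iff any angle switches", {
  trips <- enumerate_triplets("ALA")
  none <- residue_rollup(trips, rep(0L, 10))
  expect_false(none$is_switch)
  expect_identical(none$n_switch, 0L)
  all_sw <- residue_rollup(trips, rep(1L, 10))
  expect_true(all_sw$is_switch)
  expect_identical(all_sw$n_switch, 10L)
  # A9-like: exactly the O-C-N and O-CA-N angles switch
  labels <- as.integer(trips$vertex %in% c("C", "CA") &
                       trips$atom_a == "N" & trips$atom_b == "O")
  roll <- residue_rollup(trips, labels)
  expect_true(roll$is_switch)
  expect_identical(roll$n_switch, 2L)
  expect_setequal(paste(roll$switch_triplets$atom_a,
                        roll$switch_triplets$vertex,
                        roll$switch_triplets$atom_b),
                  c("N C O", "N CA O"))
  expect_error(residue_rollup(trips, c(0L, 1L)), "one label per triplet")
})
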