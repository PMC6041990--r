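test_that("bootstrap draws keep the dataset size and a disjoint OOB set", {
  set.seed(1)
  bs <- draw_bootstrap(1)
  expect_equal(bs$in_bag, 1L)
  expect_equal(bs$oob, integer(0))
  for (n in c(5, 40, 200)) {
    bs <- draw_bootstrap(n)
    expect_length(bs$in_bag, n)
    expect_length(intersect(bs$oob, bs$in_bag), 0)
    expect_setequal(union(bs$oob, bs$in_bag), seq_len(n))
  }
})

test_that("unique in-bag fraction approaches the 1-(1-1/n)^n closed form", {
  n <- 500
  closed_form <- 1 - (1 - 1 / n)^n   # ~0.632 for large n
  set.seed(123)
  fracs <- replicate(2000, length(unique(draw_bootstrap(n)$in_bag)) / n)
  expect_equal(mean(fracs), closed_form, tolerance = 0.005)
})

test_that("under-sampling equalizes class counts at the minority count", {
  labels <- factor(c(rep("N", 50), rep("O", 30), rep("U", 10)),
                   levels = c("O", "U", "N"))
  set.seed(2)
  out <- undersample_to_minority(seq_along(labels), labels)
  expect_equal(as.vector(table(labels[out])), rep(10L, 3))
  balanced <- c(which(labels == "O")[1:10], which(labels == "U"),
                which(labels == "N")[1:10])
  expect_setequal(undersample_to_minority(balanced, labels), balanced)
})

test_that("under-sampling warns and proceeds when a class is absent", {
  labels <- factor(rep(c("O", "N"), each = 5), levels = c("O", "U", "N"))
  expect_warning(out <- undersample_to_minority(seq_len(10), labels), "U")
  expect_equal(as.vector(table(labels[out])[c("O", "N")]), c(5L, 5L))
})

test_that("gini impurity matches direct evaluation", {
  expect_equal(gini_impurity(c(5, 5)), 0.5)
  expect_equal(gini_impurity(c(10, 0)), 0)
  expect_equal(gini_impurity(c(35, 1)), 1 - (35 / 36)^2 - (1 / 36)^2)
  expect_error(gini_impurity(c(0, 0)), "all-zero")
})

test_that("best_split finds perfect separators and returns NULL on constants", {
  x <- cbind(f1 = c(0, 0, 1, 1), f2 = c(1, 1, 1, 1))
  y <- factor(c("O", "O", "N", "N"), levels = c("O", "U", "N"))
  sp <- best_split(x, y, candidates = 1:2)
  expect_equal(sp$feature, 1)
  expect_equal(sp$impurity, 0)
  expect_null(best_split(x[, 2, drop = FALSE] * 0 + 1, y, candidates = 1))
})

test_that("equal-impurity splits resolve to the lowest feature index", {
  # two identical perfect separators; brute-force both orderings
  base <- c(0, 0, 1, 1)
  y <- factor(c("O", "O", "N", "N"), levels = c("O", "U", "N"))
  for (ord in list(c(1, 2), c(2, 1))) {
    x <- cbind(a = base, b = base)
    sp <- best_split(x, y, candidates = ord)
    expect_equal(sp$feature, 1)
  }
})

test_that("a pure bootstrap yields a single-leaf tree", {
  m <- matrix(rbinom(40, 1, 0.5), 10, 4,
              dimnames = list(sprintf("g%d", 1:10), sprintf("f%d", 1:4)))
  ds <- annotation_dataset(m, rep("N", 10))
  model <- train_forest(ds, ntree = 1, mtry = 2, seed = 3)
  tr <- model$trees[[1]]
  expect_equal(sum(tr$is_leaf), 1)
  expect_equal(model$classes[tr$pred[1]], "N")
})

test_that("training is deterministic and early trees are seed-stable", {
  ds <- random_small_dataset(n = 40, J = 8, seed = 11)
  m1 <- train_forest(ds, ntree = 4, mtry = 3, undersample = TRUE, seed = 5)
  m2 <- train_forest(ds, ntree = 4, mtry = 3, undersample = TRUE, seed = 5)
  expect_identical(m1, m2)
  m3 <- train_forest(ds, ntree = 6, mtry = 3, undersample = TRUE, seed = 5)
  expect_identical(m1$trees[1:4], m3$trees[1:4])  # per-tree streams
})

test_that("every tree keeps OOB disjoint from its bootstrap and balanced in-bag", {
  ds <- random_small_dataset(n = 45, J = 8, seed = 13)
  model <- suppressWarnings(
    train_forest(ds, ntree = 5, mtry = 3, undersample = TRUE, seed = 7))
  expect_length(model$trees, 5)
  for (tr in model$trees) {
    expect_length(intersect(tr$oob, tr$in_bag), 0)
    counts <- table(ds$labels[tr$train_rows])
    counts <- counts[counts > 0]
    expect_true(all(counts == min(counts)))
    expect_true(all(tr$train_rows %in% tr$in_bag))
  }
})

test_that("instance routing partitions the data over the leaves", {
  ds <- random_small_dataset(n = 50, J = 10, seed = 17)
  model <- train_forest(ds, ntree = 3, mtry = 4, seed = 9)
  for (i in seq_along(model$trees)) {
    counts <- oob_leaf_statistics(model, ds, tree = i)
    expect_equal(sum(counts), length(model$trees[[i]]$oob))
  }
})

test_that("prediction is tree voting and probabilities sum to one", {
  ds <- random_small_dataset(n = 40, J = 8, seed = 19)
  model <- train_forest(ds, ntree = 7, mtry = 3, seed = 21)
  p <- predict(model, ds)
  expect_equal(rowSums(p), rep(1, nrow(ds$x)), ignore_attr = TRUE)
  expect_true(all(p * 7 == round(p * 7)))  # vote fractions
  cl <- predict(model, ds, type = "class")
  expect_equal(as.character(cl),
               colnames(p)[max.col(p, ties.method = "first")])
})

test_that("mtry larger than the feature count is rejected", {
  ds <- random_small_dataset(n = 20, J = 4, seed = 23)
  expect_error(train_forest(ds, ntree = 1, mtry = 99, seed = 1), "mtry")
})

test_that("forests round-trip exactly through JSON", {
  ds <- random_small_dataset(n = 35, J = 6, seed = 29)
  model <- train_forest(ds, ntree = 3, mtry = 3, undersample = TRUE, seed = 31)
  path <- withr::local_tempfile(fileext = ".json")
  write_forest_json(model, path)
  back <- read_forest_json(path)
  expect_identical(back$feature_ids, model$feature_ids)
  expect_identical(back$config, model$config)
  for (i in seq_along(model$trees)) {
    a <- model$trees[[i]]; b <- back$trees[[i]]
    for (fld in c("feature", "left", "right", "parent", "side",
                  "is_leaf", "pred", "in_bag", "train_rows", "oob")) {
      expect_identical(unname(b[[fld]]), unname(a[[fld]]), label = fld)
    }
    expect_equal(b$threshold, a$threshold)
    expect_equal(unname(b$counts), unname(a$counts))
  }
  # behavioural equivalence after the round trip
  expect_equal(predict(back, ds), predict(model, ds))
})
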