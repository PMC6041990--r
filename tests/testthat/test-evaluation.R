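test_that("auroc matches pair enumeration, perfect and all-tied cases", {
  expect_equal(auroc(c(0.1, 0.2, 0.8, 0.9), c(FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(auroc(rep(0.5, 6), c(TRUE, TRUE, FALSE, FALSE, TRUE, FALSE)), 0.5)
  # enumerate all four pos-neg pairs: (0.35>0.1) + (0.35<0.4=0) + 2 for 0.8
  expect_equal(auroc(c(0.1, 0.4, 0.35, 0.8), c(FALSE, FALSE, TRUE, TRUE)), 0.75)
  set.seed(5)
  for (i in 1:10) {
    s <- round(runif(12), 2)  # rounded scores force some ties
    p <- c(TRUE, FALSE, runif(10) > 0.5)
    expect_equal(auroc(s, p), oracle_auroc(s, p))
  }
  expect_error(auroc(1:3, c(TRUE, TRUE, TRUE)), "positive and one negative")
})

test_that("auroc is anti-symmetric and invariant under monotone transforms", {
  set.seed(7)
  for (i in 1:10) {
    s <- rnorm(20)
    p <- c(TRUE, FALSE, runif(18) > 0.4)
    expect_equal(auroc(s, p) + auroc(-s, p), 1)
    expect_equal(auroc(exp(s) + 3, p), auroc(s, p))
  }
})

test_that("weighted AUROC combines per-class values by instance counts", {
  expect_equal(weighted_auroc(c(0.7, 0.7, 0.7), c(1, 2, 3)), 0.7)
  expect_equal(weighted_auroc(c(0.6, 0.8), c(5, 5)), 0.7)
  # NA classes are dropped with weight renormalization
  expect_equal(weighted_auroc(c(0.6, NA, 0.8), c(1, 10, 1)), 0.7)
  expect_error(weighted_auroc(c(NA, NA), c(1, 1)), "no class")
})

test_that("weighted AUROC stays between the per-class extremes", {
  set.seed(11)
  for (i in 1:20) {
    a <- runif(3)
    w <- runif(3, 0.1, 5)
    v <- weighted_auroc(a, w)
    expect_gte(v, min(a) - 1e-12)
    expect_lte(v, max(a) + 1e-12)
  }
})

test_that("multiclass AUROC drops classes missing from a fold", {
  prob <- cbind(O = c(0.8, 0.7, 0.1, 0.2),
                U = c(0.1, 0.1, 0.1, 0.1),
                N = c(0.1, 0.2, 0.8, 0.7))
  res <- multiclass_auroc(prob, c("O", "O", "N", "N"))
  expect_true(is.na(res$per_class["U"]))
  expect_equal(unname(res$per_class["O"]), 1)
  expect_equal(res$weighted, 1)
})

test_that("mtry candidates follow the sqrt(J) multipliers", {
  g <- mtry_grid(7490)
  expect_equal(g$mtry[1], 43L)            # floor(0.5 * sqrt(7490))
  expect_equal(g$mtry, c(43L, 87L, 173L))
  expect_equal(mtry_grid(100)$mtry, c(5L, 10L, 20L))
  expect_true(all(diff(g$mtry) > 0))
  expect_equal(g$ntree, c(100L, 200L, 300L))
})

test_that("final parameters are the modal pair with deterministic ties", {
  sels <- c(rep(list(c(300, 43)), 6), rep(list(c(200, 43)), 4))
  expect_equal(select_final_params(sels), c(ntree = 300L, mtry = 43L))
  expect_equal(select_final_params(list(c(100, 7))), c(ntree = 100L, mtry = 7L))
  tie <- c(rep(list(c(300, 43)), 5), rep(list(c(100, 87)), 5))
  expect_equal(select_final_params(tie), c(ntree = 300L, mtry = 43L))
})

test_that("nested CV is reproducible and records folds x runs selections", {
  ds <- random_small_dataset(n = 60, J = 8, seed = 91)
  grid <- list(mtry = c(2L, 4L), ntree = c(5L, 10L))
  cv1 <- suppressWarnings(
    nested_cv(ds, grid = grid, outer_folds = 2, inner_folds = 2, runs = 1,
              undersample = TRUE, seed = 17))
  cv2 <- suppressWarnings(
    nested_cv(ds, grid = grid, outer_folds = 2, inner_folds = 2, runs = 1,
              undersample = TRUE, seed = 17))
  expect_equal(cv1$weighted_auroc, cv2$weighted_auroc)
  expect_identical(cv1$selected_params, cv2$selected_params)
  expect_equal(nrow(cv1$selected_params), 2)  # folds x runs
  expect_true(cv1$weighted_auroc >= 0 && cv1$weighted_auroc <= 1)
})

test_that("nested CV refuses classes smaller than the outer fold count", {
  m <- matrix(rbinom(200, 1, 0.4), 20, 10,
              dimnames = list(sprintf("g%d", 1:20), sprintf("f%d", 1:10)))
  ds <- annotation_dataset(m, c("O", rep("N", 10), rep("U", 9)))
  expect_error(nested_cv(ds, outer_folds = 5, runs = 1), "stratified")
})

test_that("label-permuted data scores near chance", {
  set.seed(23)
  aucs <- numeric(20)
  for (s in 1:20) {
    ds <- random_small_dataset(n = 90, J = 8, seed = 300 + s)
    # destroy any accidental signal by shuffling labels
    ds$labels <- sample(ds$labels)
    model <- suppressWarnings(
      train_forest(ds, ntree = 20, mtry = 3, undersample = TRUE,
                   seed = 300 + s))
    # held-out evaluation: score OOB-style via a fresh permuted copy
    eval_ds <- random_small_dataset(n = 90, J = 8, seed = 600 + s)
    eval_ds$labels <- sample(eval_ds$labels)
    aucs[s] <- multiclass_auroc(predict(model, eval_ds), eval_ds$labels)$weighted
  }
  expect_gte(mean(aucs), 0.45)
  expect_lte(mean(aucs), 0.55)
})
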