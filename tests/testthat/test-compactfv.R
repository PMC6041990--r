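test_that("the fixture tree exposes its rules with root-to-leaf conditions", {
  model <- worked_example_forest()
  rules <- enumerate_rules(model)
  expect_length(rules, 6)                    # one rule per leaf
  pos_rules <- rules_with_positive_value(model, "GO:0006887")
  n_rules <- Filter(function(r) r$predicted_class == "N", pos_rules)
  expect_length(n_rules, 3)
  covs <- sort(vapply(n_rules, function(r) sum(r$oob_class_counts), 1))
  expect_equal(covs, c(10, 36, 150))
  # deepest rule's conditions appear in root-to-leaf order
  r2 <- Filter(function(r) sum(r$oob_class_counts) == 150, n_rules)[[1]]
  expect_equal(r2$conditions$feature_id,
               c("GO:0043230", "GO:0006887", "GO:0043005", "GO:0042221"))
  expect_equal(r2$conditions$polarity,
               c("positive", "positive", "negative", "negative"))
})

test_that("rules with only a negative test of the feature are excluded", {
  model <- worked_example_forest()
  pos_rules <- rules_with_positive_value(model, "GO:0006887")
  for (r in pos_rules) {
    cond <- r$conditions
    expect_true(any(cond$feature_id == "GO:0006887" &
                      cond$polarity == "positive"))
  }
  # GO:0042221 appears only negatively on the relevant N-paths
  neg_only <- rules_with_positive_value(model, "GO:0042221")
  expect_length(Filter(function(r) r$predicted_class == "N", neg_only), 0)
})

test_that("positive-value scoring rejects the numeric total feature", {
  ds <- random_small_dataset(n = 30, J = 5, seed = 3, with_total = TRUE)
  model <- train_forest(ds, ntree = 2, mtry = 3, seed = 1)
  expect_error(rules_with_positive_value(model, "total"), "positive value")
})

test_that("features absent from every tree score an undefined precision", {
  model <- worked_example_forest()
  sc <- compact_fv(model)
  absent <- sc[sc$feature_id == "GO:0042221" & sc$class == "N", ]
  expect_equal(absent$cov, 0)
  expect_true(is.na(absent$prec))
  # undefined scores never enter a ranking
  expect_false("GO:0042221" %in% rank_for_class(sc, "N")$feature_id)
})

test_that("compact_fv matches the per-instance routing oracle exactly", {
  for (s in 1:12) {
    ds <- random_small_dataset(n = 20 + (s %% 4) * 10, J = 4 + s %% 9,
                               seed = 100 + s, with_total = s %% 2 == 0)
    model <- suppressWarnings(
      train_forest(ds, ntree = 1 + s %% 5, mtry = 2 + s %% 3,
                   undersample = s %% 3 == 0, seed = s))
    got <- compact_fv(model, ds)
    want <- oracle_compact_fv(model, ds)
    expect_identical(got$feature_id, want$feature_id)
    expect_identical(got$class, want$class)
    expect_identical(got$cov, want$cov)
    expect_identical(got$hits, want$hits)
    expect_identical(got$prec, want$prec)
  }
})

test_that("hits never exceed coverage and precision stays within [0, 1]", {
  ds <- random_small_dataset(n = 40, J = 9, seed = 41)
  model <- train_forest(ds, ntree = 6, mtry = 3, seed = 43)
  sc <- compact_fv(model, ds)
  expect_true(all(sc$hits <= sc$cov))
  expect_true(all(sc$prec[!is.na(sc$prec)] >= 0 & sc$prec[!is.na(sc$prec)] <= 1))
})

test_that("adding trees never decreases coverage", {
  ds <- random_small_dataset(n = 40, J = 8, seed = 47)
  m_small <- train_forest(ds, ntree = 3, mtry = 3, seed = 49)
  m_big <- train_forest(ds, ntree = 6, mtry = 3, seed = 49)
  cov_small <- compact_fv(m_small, ds)$cov
  cov_big <- compact_fv(m_big, ds)$cov
  expect_true(all(cov_big >= cov_small))
})

test_that("rankings order by precision, then coverage, then feature id", {
  sc <- data.frame(
    feature_id = c("GO:B", "GO:A", "GO:C", "GO:D", "GO:E"),
    class = "N",
    cov = c(100, 300, 300, 50, 0),
    hits = c(100, 300, 300, 10, 0),
    stringsAsFactors = FALSE
  )
  sc$prec <- ifelse(sc$cov > 0, sc$hits / sc$cov, NA_real_)
  r <- rank_for_class(sc, "N")
  expect_equal(r$feature_id, c("GO:A", "GO:C", "GO:B", "GO:D"))
  expect_equal(r$rank, 1:4)
  expect_equal(rank_for_class(sc, "N", top_k = 2)$feature_id, c("GO:A", "GO:C"))
  one <- rank_for_class(sc[sc$feature_id == "GO:D", ], "N")
  expect_equal(one$rank, 1L)
  empty <- rank_for_class(sc[sc$cov == 0, ], "N")
  expect_equal(nrow(empty), 0)
})

test_that("repeated builds average scores and reduce to one build at R = 1", {
  ds <- random_small_dataset(n = 40, J = 6, seed = 53)
  one <- compact_fv_repeats(ds, ntree = 3, mtry = 3, repeats = 1, seed = 55)
  direct <- compact_fv(
    train_forest(ds, ntree = 3, mtry = 3,
                 seed = compactfv:::derive_seed(55, 7919, 1)), ds)
  expect_equal(one$cov, direct$cov)
  expect_equal(one$hits, direct$hits)
  expect_equal(one$prec, direct$prec)
  avg <- compact_fv_repeats(ds, ntree = 3, mtry = 3, repeats = 4, seed = 55)
  expect_true(all(avg$n_defined <= 4))
  expect_true(all(avg$hits <= avg$cov))
})

test_that("ranking TSV writer emits the expected columns", {
  model <- worked_example_forest()
  sc <- compact_fv(model)
  r <- rank_for_class(sc, "N")
  path <- withr::local_tempfile(fileext = ".tsv")
  write_ranking_tsv(r, path)
  tab <- read.delim(path)
  expect_equal(names(tab)[1:4], c("rank", "feature_id", "feature_name", "class"))
  # precision order: 35/36 = 0.972, 180/186 = 0.968, 187/196 = 0.954
  expect_equal(tab$feature_id[1:3],
               c("GO:0043005", "GO:0043230", "GO:0006887"))
  expect_true(all(diff(tab$prec) <= 0))
})
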