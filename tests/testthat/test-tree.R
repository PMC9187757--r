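immobile_mbcr_tree <- function() {
  motion_tree(tree_split("mbcr", 118e-9,
                         tree_leaf("immobile"), tree_leaf("mobile")))
}

test_that("prediction descends by threshold with <= going left", {
  expect_equal(predict(motion_tree(tree_leaf("only")),
                       data.frame(x = c(1, 2, 3))),
               rep("only", 3))
  tree <- immobile_mbcr_tree()
  expect_equal(predict(tree, data.frame(mbcr = 50e-9)), "immobile")
  expect_equal(predict(tree, data.frame(mbcr = 300e-9)), "mobile")
  # a value exactly at the threshold goes left
  expect_equal(predict(tree, data.frame(mbcr = 118e-9)), "immobile")
  expect_error(predict(tree, data.frame(id = "t9", mbcr = NaN)), "t9.*mbcr")
  expect_error(predict(tree, data.frame(other = 1)), "mbcr")
})

test_that("training finds the exact midpoint split on separable data", {
  props <- tibble::tibble(id = as.character(1:4), v = c(1, 2, 9, 10))
  training <- tibble::tibble(id = props$id, label = c("A", "A", "B", "B"))
  tree <- train_tree(props, training)
  nd <- tidy(tree)
  expect_equal(tree$n_splits, 1)
  expect_equal(nd$threshold[nd$type == "split"], 5.5)
  expect_equal(resubstitution_loss(tree, props, training), 0)
})

test_that("Gini impurity is 0 for pure and 0.5 for balanced nodes", {
  expect_equal(trackpop:::gini(rep("a", 10)), 0)
  expect_equal(trackpop:::gini(rep(c("a", "b"), 5)), 0.5)
})

test_that("a split-free tree is the majority classifier", {
  props <- tibble::tibble(id = as.character(1:10), v = rnorm(10))
  training <- tibble::tibble(id = props$id,
                             label = rep(c("big", "small"), c(6, 4)))
  tree <- train_tree(props, training, max_splits = 0)
  expect_equal(tree$n_splits, 0)
  expect_equal(resubstitution_loss(tree, props, training), 0.4)
})

test_that("resubstitution loss is non-increasing in max_splits", {
  set.seed(19)
  n <- 60
  props <- tibble::tibble(id = as.character(1:n), u = rnorm(n), v = rnorm(n))
  training <- tibble::tibble(
    id = props$id,
    label = ifelse(props$u + 0.5 * props$v + rnorm(n, sd = 0.6) > 0, "up", "down")
  )
  losses <- vapply(0:6, function(k) {
    resubstitution_loss(train_tree(props, training, max_splits = k),
                        props, training)
  }, numeric(1))
  expect_true(all(diff(losses) <= 1e-12))
})

test_that("single-label training warns and yields a single leaf", {
  props <- tibble::tibble(id = c("a", "b"), v = c(1, 2))
  training <- tibble::tibble(id = c("a", "b"), label = c("x", "x"))
  expect_warning(tree <- train_tree(props, training), "single label")
  expect_equal(tree$n_splits, 0)
  expect_equal(predict(tree, data.frame(v = 99)), "x")
})

test_that("predictions are invariant under a consistent rescaling", {
  set.seed(3)
  props <- tibble::tibble(id = as.character(1:50), v = rnorm(50), w = rnorm(50))
  training <- tibble::tibble(id = props$id,
                             label = ifelse(props$v > 0.2, "hi", "lo"))
  tree <- train_tree(props, training, max_splits = 3)
  scale_node <- function(node, f) {
    if (!is.null(node$label)) return(node)
    tree_split(node$property,
               if (node$property == "v") node$threshold * f else node$threshold,
               scale_node(node$left, f), scale_node(node$right, f))
  }
  scaled_tree <- motion_tree(scale_node(tree$root, 1000))
  scaled_props <- dplyr::mutate(props, v = v * 1000)
  expect_equal(predict(scaled_tree, scaled_props), predict(tree, props))
})

test_that("training agrees with rpart on a well-separated fixture", {
  skip_if_not_installed("rpart")
  set.seed(8)
  n <- 90
  props <- tibble::tibble(
    id = as.character(1:n),
    mbcr = c(rnorm(n / 3, 5e-8, 1e-8), rnorm(n / 3, 4e-7, 8e-8),
             rnorm(n / 3, 4.5e-7, 8e-8)),
    asym = c(rnorm(n / 3, 1e-8, 5e-9), rnorm(n / 3, 5e-8, 2e-8),
             rnorm(n / 3, 3e-7, 5e-8))
  )
  training <- tibble::tibble(id = props$id,
                             label = rep(c("immobile", "mobile", "hybrid"), each = n / 3))
  tree <- train_tree(props, training, max_splits = 5)
  ours <- predict(tree, props)
  rp <- rpart::rpart(label ~ mbcr + asym,
                     data = dplyr::inner_join(training, props, by = "id"),
                     method = "class",
                     control = rpart::rpart.control(minsplit = 2, cp = 0,
                                                    maxdepth = 5))
  theirs <- as.character(predict(rp, props, type = "class"))
  # two greedy Gini learners should classify this separable set identically
  expect_gte(mean(ours == theirs), 0.97)
  expect_lte(resubstitution_loss(tree, props, training), 0.05)
})

test_that("trees round-trip through JSON with full precision", {
  set.seed(13)
  tree <- motion_tree(tree_split(
    "mbcr", 1.18e-7 * (1 + 1e-13),
    tree_leaf("immobile"),
    tree_split("mbcc_com", 5.4321098765432e-8,
               tree_split("n_points", 17.5, tree_leaf("mobile"), tree_leaf("hybrid")),
               tree_leaf("hybrid"))
  ))
  f <- withr::local_tempfile(fileext = ".json")
  write_tree(tree, f)
  back <- read_tree(f)
  expect_identical(back$root, tree$root)
  rows <- tibble::tibble(mbcr = runif(1000, 0, 3e-7),
                         mbcc_com = runif(1000, 0, 2e-7),
                         n_points = sample(5:60, 1000, replace = TRUE))
  expect_identical(predict(back, rows), predict(tree, rows))

  bad <- withr::local_tempfile(fileext = ".json")
  writeLines("", bad)
  expect_error(read_tree(bad), "malformed")
  writeLines('{"property": "x"}', bad)
  expect_error(read_tree(bad), "malformed")
})

test_that("classification partitions a simulated set and recovers ground truth", {
  cfg <- sim_config(n_walkers = 150, n_frames = 300, seed = 21)
  tracks <- filter_min_localizations(simulate_tracks(cfg), 5)
  truth_labels <- dplyr::distinct(tibble::as_tibble(tracks), id, label)
  props <- compute_properties(tracks)
  set.seed(77)
  train_ids <- sample(truth_labels$id, 100)
  training <- dplyr::filter(truth_labels, id %in% train_ids)
  tree <- train_tree(props, training, max_splits = 5)

  unlabelled <- dplyr::select(tibble::as_tibble(tracks), -label) |>
    track_set(dt = track_dt(tracks))
  classified <- classify_tracks(unlabelled, tree, props)
  got <- dplyr::distinct(tibble::as_tibble(classified), id, label)
  # partition: every trajectory gets exactly one label
  expect_setequal(got$id, truth_labels$id)
  expect_equal(sum(table(got$label)), nrow(truth_labels))

  cmp <- dplyr::inner_join(truth_labels, got, by = "id",
                           suffix = c("_true", "_pred"))
  mob <- dplyr::filter(cmp, label_true == "mobile")
  expect_gte(mean(mob$label_pred == "mobile"), 0.9)
  # immobile and mobile populations are separated by orders of magnitude in
  # bounding-circle radius, so cross-confusion stays below 1%
  imm_as_mob <- mean(cmp$label_pred[cmp$label_true == "immobile"] == "mobile")
  mob_as_imm <- mean(mob$label_pred == "immobile")
  expect_lt(imm_as_mob, 0.01)
  expect_lt(mob_as_imm, 0.01)
})
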