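test_that("gini impurity and decrease follow their definitions", {
  expect_identical(gini_impurity(c(10, 0, 0)), 0)
  expect_equal(gini_impurity(c(1, 1, 0)), 0.5)
  expect_equal(gini_impurity(c(2, 1, 1)), 0.625)
  expect_error(gini_impurity(c(0, 0, 0)), class = "parlourscore_argument_error")

  expect_equal(gini_decrease(c(4, 4, 0), c(4, 0, 0), c(0, 4, 0)), 0.5)
  expect_equal(gini_decrease(c(2, 2, 0), c(1, 1, 0), c(1, 1, 0)), 0)
  expect_error(gini_decrease(c(2, 2, 0), c(2, 2, 0), c(0, 0, 0)),
               class = "parlourscore_validation_error")
  expect_error(gini_decrease(c(2, 2, 0), c(2, 0, 0), c(1, 1, 0)),
               class = "parlourscore_validation_error")
})

test_that("best_split agrees with an exhaustive brute-force search", {
  # perfect separator
  d <- tibble::tibble(sw = rep(0:1, each = 4), awd = 0L, shh = 0L, oh = 0L)
  y <- ls_class3(rep(c(0L, 2L), each = 4))
  s <- best_split(d, y)
  expect_identical(s$feature, "sw")
  expect_equal(s$decrease, gini_impurity(c(4, 0, 4)))

  # all features constant -> no split
  d0 <- tibble::tibble(sw = 1L, awd = 1L, shh = 0L, oh = 0L)[rep(1, 6), ]
  expect_null(best_split(d0, ls_class3(rep(0:1, 3))))

  feats <- c("sw", "awd", "shh", "oh")
  for (seed in 1:40) {
    d <- random_obs(200, seed = seed)
    y <- ls_class3(d$ls)
    mine <- best_split(d, y, feats)
    oracle <- brute_force_split(d, y, feats)
    if (is.null(oracle)) {
      expect_null(mine)
    } else {
      expect_identical(mine$feature, oracle$feature)
      expect_equal(mine$decrease, oracle$decrease, tolerance = 1e-10)
    }
  }
})

test_that("split ties break in the fixed indicator order", {
  # two identical perfect separators: SW listed first wins
  d <- tibble::tibble(sw = rep(0:1, each = 4), awd = rep(0:1, each = 4),
                      shh = 0L, oh = 0L)
  s <- best_split(d, ls_class3(rep(c(0L, 2L), each = 4)))
  expect_identical(s$feature, "sw")
})

test_that("grown trees respect purity, depth and no-reuse invariants", {
  pure <- random_obs(30, seed = 21)
  pure$ls <- 1L
  tree <- grow_tree(pure)
  expect_true(tidy(tree)$leaf[1])
  expect_identical(as.character(predict(tree, pure)), rep("1", 30))

  for (seed in 22:31) {
    d <- random_obs(300, seed = seed)
    nodes <- tidy(grow_tree(d))
    expect_lte(max(nodes$depth), 4)
    # no feature reused on a path: each child's feature set strictly shrinks
    parent_feature <- nodes$split_feature[match(nodes$parent, nodes$node)]
    expect_true(all(is.na(parent_feature) |
                      nodes$split_feature != parent_feature |
                      is.na(nodes$split_feature)))
    # children's class counts sum to the parent's
    for (i in which(!nodes$leaf)) {
      kids <- nodes[which(nodes$parent == nodes$node[i]), ]
      expect_equal(colSums(kids[c("n_class0", "n_class1", "n_lame")]),
                   unlist(nodes[i, c("n_class0", "n_class1", "n_lame")]),
                   ignore_attr = TRUE)
    }
  }
})

test_that("a deterministic rule is learned exactly", {
  d <- deterministic_obs(600, seed = 33)
  tree <- grow_tree(d)
  expect_identical(as.character(predict(tree, d)), as.character(ls_class3(d$ls)))
})

test_that("the root split matches an independent CART implementation", {
  for (seed in c(2, 5, 9)) {
    d <- deterministic_obs(400, seed = seed)
    mine <- grow_tree(d)$root$split$feature
    ref <- rpart::rpart(
      ls_class3(ls) ~ sw + awd + shh + oh, data = d, method = "class",
      control = rpart::rpart.control(minsplit = 2, minbucket = 1, cp = 0,
                                     maxdepth = 1, xval = 0)
    )
    expect_identical(mine, as.character(ref$frame$var[1]))
  }
})

test_that("pruning enforces node size strictly greater than 20", {
  make <- function(n_per_arm) {
    tibble::tibble(sw = rep(0:1, each = n_per_arm), awd = 0L, shh = 0L, oh = 0L,
                   ls = rep(c(0L, 2L), each = n_per_arm))
  }
  pruned20 <- prune_tree(grow_tree(make(10)))  # 20 observations at the root
  expect_true(tidy(pruned20)$leaf[1])
  pruned21 <- prune_tree(grow_tree(make(11)))  # 22 observations: split kept
  expect_false(tidy(pruned21)$leaf[1])
})

test_that("pruning keeps a split whose decrease exactly meets the threshold", {
  d <- random_obs(400, seed = 35)
  tree <- grow_tree(d)
  dec <- tree$root$split$decrease
  kept <- prune_tree(tree, pruning_rule(min_gini_decrease = dec))
  expect_false(is.null(kept$root$split))  # "at least" is inclusive
  cut <- prune_tree(tree, pruning_rule(min_gini_decrease = dec + 1e-9))
  expect_true(is.null(cut$root$split))
})

test_that("pruned trees satisfy both criteria everywhere and pruning is idempotent", {
  rule <- pruning_rule()
  for (seed in 36:40) {
    d <- random_obs(1000, seed = seed)
    pruned <- prune_tree(grow_tree(d), rule)
    internal <- dplyr::filter(tidy(pruned), !leaf)
    expect_true(all(internal$n >= rule$min_node_size))
    expect_true(all(internal$decrease >= rule$min_gini_decrease))
    expect_identical(prune_tree(pruned, rule), pruned)
  }
})

test_that("prediction routes absent/present edges deterministically", {
  d <- tibble::tibble(sw = 0L, awd = 0L, shh = rep(0:1, each = 25), oh = 0L,
                      ls = rep(c(0L, 2L), each = 25))
  tree <- prune_tree(grow_tree(d))
  expect_identical(tree$root$split$feature, "shh")
  newd <- tibble::tibble(sw = c(1L, 0L), awd = 0L, shh = c(1L, 0L), oh = 1L)
  expect_identical(as.character(predict(tree, newd)), c(">=2", "0"))
  expect_error(predict(tree, tibble::tibble(sw = 1L, awd = NA, shh = 0L, oh = 0L)),
               class = "parlourscore_validation_error")
})

test_that("leaf ties resolve toward the lower class", {
  d <- tibble::tibble(sw = 0L, awd = 0L, shh = 0L, oh = 0L,
                      ls = rep(c(1L, 2L), 5))
  tree <- grow_tree(d)
  expect_identical(tree$root$prediction, "1")
})

test_that("stratified folds balance every class to within one observation", {
  y <- ls_class3(rep(c(0L, 0L, 1L, 1L), 2))
  folds <- stratified_kfold(y, k = 4, seed = 1)
  tab <- table(folds, y)
  expect_true(all(tab[, "0"] == 1L & tab[, "1"] == 1L))

  sim <- study_simulation(seed = 60)
  y <- ls_class3(sim$ls)
  folds <- stratified_kfold(y, k = 4, seed = 2)
  tab <- table(folds, y)
  expect_true(all(apply(tab, 2, function(cl) diff(range(cl)) <= 1L)))
  expect_true(all(abs(as.numeric(table(folds)) - nrow(sim) / 4) <= 3))

  expect_identical(folds, stratified_kfold(y, k = 4, seed = 2))
  expect_false(identical(folds, stratified_kfold(y, k = 4, seed = 3)))

  rare <- ls_class3(c(0L, 0L, 0L, 0L, 0L, 2L))
  expect_warning(stratified_kfold(rare, k = 4, seed = 1), "fewer than k")
})

test_that("cross-validation runs the grow-prune-evaluate protocol per fold", {
  d <- deterministic_obs(2000, seed = 44)
  cv <- cross_validate_select(d, seed = 44)
  expect_identical(nrow(cv$results), 4L)
  expect_true(all(cv$results$accuracy == 1))
  expect_identical(cv$best_fold, 1L)  # ties break to the lowest fold

  toy <- random_obs(10, seed = 45)
  suppressWarnings(cv2 <- cross_validate_select(toy, k = 2, seed = 45))
  expect_identical(nrow(cv2$results), 2L)
  expect_identical(length(cv2$confusions), 2L)
  expect_identical(cv2$results$n_train + cv2$results$n_test, rep(10L, 2))
})

test_that("the selected classifier beats the majority-class baseline on study-like herds", {
  sim <- study_simulation(seed = 70)
  cv <- cross_validate_select(sim, seed = 70)
  baseline <- max(table(ls_class3(sim$ls))) / nrow(sim)
  expect_gt(glance(cv)$best_accuracy, baseline)
  # fold sizes match the study protocol: held-out ~1030, training ~3095
  expect_true(all(abs(cv$results$n_test - 4125 / 4) <= 3))
  # qualitative tree structure: a cow without a swollen heel/hock is never
  # classified lame
  grid <- tidyr::crossing(sw = 0:1, awd = 0:1, shh = 0:1, oh = 0:1)
  pred <- predict(cv$tree, grid)
  expect_true(all(pred[grid$shh == 0L] != ">=2"))
})
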