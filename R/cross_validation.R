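#' Stratified k-fold assignment
#'
#' Assigns each observation to one of `k` folds so that the class composition
#' of every fold stays as close as possible to the full data set: within each
#' class, observations are shuffled (seeded) and dealt round-robin, so
#' per-class fold counts differ by at most one. A class with fewer members
#' than `k` is allowed (some folds then lack it) with a warning.
#'
#' @param class Factor (or vector) of class labels, one per observation.
#' @param k Number of folds, default 4.
#' @param seed Integer seed; the assignment is deterministic given it.
#' @return Integer vector of fold labels in `1:k`.
#' @export
#' @examples
#' table(stratified_kfold(ls_class3(rep(c(0, 0, 1, 1), 4)), k = 4, seed = 1))
stratified_kfold <- function(class, k = 4L, seed = 1L) {
  class <- as.factor(class)
  n <- length(class)
  if (n < k) {
    abort("Need at least `k` observations.", class = "parlourscore_argument_error")
  }
  small <- names(which(table(class) > 0 & table(class) < k))
  if (length(small)) {
    warn(paste0("Class(es) with fewer than k members: ",
                paste(small, collapse = ", "),
                "; some folds will lack them."))
  }
  folds <- integer(n)
  withr::with_seed(seed, {
    for (cl in levels(class)) {
      idx <- which(class == cl)
      idx <- idx[sample.int(length(idx))]
      folds[idx] <- ((seq_along(idx) - 1L) %% k) + 1L
    }
  })
  folds
}

#' Cross-validated tree selection
#'
#' The study's model-selection protocol: split the matched observations into
#' `k` stratified folds; for each fold, grow a tree to maximum depth on the
#' other `k - 1` folds, post-prune it, and evaluate it on the held-out fold;
#' keep the classifier with the highest held-out accuracy (ties broken by the
#' lowest fold index). All fold-level confusion matrices and accuracies are
#' retained alongside the selected classifier.
#'
#' @param data Matched observations with `ls` and the four indicator columns.
#' @param rule A [pruning_rule()].
#' @param k Number of folds, default 4.
#' @param seed Integer seed for the stratified split.
#' @param features Indicator columns, in tie-break order.
#' @return An `ips_cv` object: `tree` (the selected `lame_tree`),
#'   `best_fold`, `results` (per-fold tibble), `confusions` (list of
#'   [confusion_matrix3()]), `folds` (the assignment). [tidy()] returns the
#'   per-fold results, [glance()] a one-row summary.
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_cows = 400, n_visits = 4, seed = 5))
#' cv <- cross_validate_select(sim, seed = 5)
#' glance(cv)
cross_validate_select <- function(data, rule = pruning_rule(), k = 4L,
                                  seed = 1L, features = IPS_INDICATORS) {
  check_columns(data, c("ls", features), "data")
  class <- ls_class3(data$ls)
  folds <- stratified_kfold(class, k = k, seed = seed)
  fits <- purrr::map(seq_len(k), function(fold) {
    train <- folds != fold
    tree <- prune_tree(grow_tree(data[train, , drop = FALSE],
                                 class = class[train], features = features),
                       rule = rule)
    predicted <- predict(tree, data[!train, , drop = FALSE])
    cm <- confusion_matrix3(class[!train], predicted)
    list(tree = tree, cm = cm,
         result = tibble::tibble(fold = fold, n_train = sum(train),
                                 n_test = sum(!train), accuracy = accuracy(cm)))
  })
  results <- dplyr::bind_rows(purrr::map(fits, "result"))
  best <- which.max(results$accuracy)
  structure(
    list(tree = fits[[best]]$tree, best_fold = best, results = results,
         confusions = purrr::map(fits, "cm"), folds = folds, rule = rule,
         k = as.integer(k), seed = as.integer(seed)),
    class = "ips_cv"
  )
}

#' @export
print.ips_cv <- function(x, ...) {
  cat(x$k, "fold cross-validated tree selection\n")
  print(x$results)
  cat("Selected fold:", x$best_fold,
      sprintf("(held-out accuracy %.3f)\n", x$results$accuracy[x$best_fold]))
  invisible(x)
}

#' @describeIn cross_validate_select Per-fold training/test sizes and
#'   held-out accuracies.
#' @param x An `ips_cv` object.
#' @param ... Unused.
#' @method tidy ips_cv
#' @export
tidy.ips_cv <- function(x, ...) {
  x$results
}

#' @describeIn cross_validate_select One-row summary of the selection.
#' @method glance ips_cv
#' @export
glance.ips_cv <- function(x, ...) {
  tibble::tibble(
    k = x$k,
    best_fold = x$best_fold,
    best_accuracy = x$results$accuracy[x$best_fold],
    mean_accuracy = mean(x$results$accuracy)
  )
}
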