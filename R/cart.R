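# Decision-tree classifier over the four binary in-parlour indicators,
# predicting the three-class locomotion outcome {0, 1, >=2}. Splits maximise
# the decrease in Gini impurity; the tree is grown to maximum depth (pure
# node, or all four indicators used on the path, or no impurity-decreasing
# split) and then post-pruned by node size and realized impurity decrease.

#' Gini impurity of a class-count vector
#'
#' \eqn{1 - \sum_c p_c^2} over the class proportions at a node; 0 for a pure
#' node, at most 2/3 with three classes.
#'
#' @param class_counts Non-negative counts over the classes at a node; total
#'   must be positive.
#' @return Gini impurity in `[0, 2/3]` for three classes.
#' @export
#' @examples
#' gini_impurity(c(10, 0, 0))  # pure: 0
#' gini_impurity(c(1, 1, 0))   # 0.5
gini_impurity <- function(class_counts) {
  if (anyNA(class_counts) || any(class_counts < 0)) {
    abort("`class_counts` must be non-negative.", class = "parlourscore_argument_error")
  }
  n <- sum(class_counts)
  if (n == 0) {
    abort("`class_counts` must have a positive total.",
          class = "parlourscore_argument_error")
  }
  1 - sum((class_counts / n)^2)
}

#' Gini impurity decrease of a binary split
#'
#' Parent impurity minus the observation-weighted mean impurity of the two
#' branches; the split-selection criterion. Always non-negative; a split with
#' an empty branch is rejected.
#'
#' @param parent_counts Class counts at the node being split.
#' @param left_counts,right_counts Class counts of the two branches; must sum
#'   to `parent_counts` and each have at least one observation.
#' @return The impurity decrease (>= 0).
#' @export
#' @examples
#' gini_decrease(c(4, 4, 0), c(4, 0, 0), c(0, 4, 0))  # 0.5
gini_decrease <- function(parent_counts, left_counts, right_counts) {
  if (!all(left_counts + right_counts == parent_counts)) {
    abort("Branch counts must sum to the parent counts.",
          class = "parlourscore_validation_error")
  }
  n_l <- sum(left_counts)
  n_r <- sum(right_counts)
  if (n_l == 0 || n_r == 0) {
    abort("A split may not produce an empty branch.",
          class = "parlourscore_validation_error")
  }
  n <- n_l + n_r
  gini_impurity(parent_counts) -
    (n_l / n * gini_impurity(left_counts) + n_r / n * gini_impurity(right_counts))
}

class_count_vec <- function(y) {
  counts <- tabulate(as.integer(y), nbins = length(LS_CLASSES))
  setNames(counts, LS_CLASSES)
}

#' Best binary split at a node
#'
#' Evaluates every available binary feature and returns the one with maximal
#' Gini decrease. Ties are broken by the fixed indicator order SW, AWD, SHH,
#' OH; returns `NULL` if every candidate split has zero decrease or an empty
#' branch.
#'
#' @param data Observations at the node, with binary feature columns.
#' @param class Factor of node class labels (levels `"0"`, `"1"`, `">=2"`),
#'   same length as `nrow(data)`.
#' @param features Character vector of features still available on this path,
#'   in tie-break order.
#' @return `NULL`, or a list with `feature` and `decrease`.
#' @export
best_split <- function(data, class, features = IPS_INDICATORS) {
  parent <- class_count_vec(class)
  best <- NULL
  for (f in features) {
    x <- data[[f]]
    absent <- class_count_vec(class[x == 0L])
    present <- class_count_vec(class[x == 1L])
    if (sum(absent) == 0L || sum(present) == 0L) next
    dec <- gini_decrease(parent, absent, present)
    if (dec > 0 && (is.null(best) || dec > best$decrease)) {
      best <- list(feature = f, decrease = dec)
    }
  }
  best
}

new_node <- function(counts, depth) {
  list(
    n = sum(counts),
    counts = counts,
    gini = gini_impurity(counts),
    # majority class; ties resolved toward the lower class index
    prediction = LS_CLASSES[which.max(counts)],
    depth = depth,
    split = NULL,
    absent = NULL,
    present = NULL
  )
}

#' Grow a decision tree to maximum depth
#'
#' Recursive greedy growth: at each node the impurity-maximising split is
#' taken until the node is pure, all four indicators have been used on the
#' path, or no split decreases impurity. No indicator appears twice on a
#' root-to-leaf path, so depth is at most four. Prune afterwards with
#' [prune_tree()].
#'
#' @param data Training observations with the four indicator columns and,
#'   unless `class` is given, an `ls` column.
#' @param class Optional factor of outcome classes; defaults to
#'   `ls_class3(data$ls)`.
#' @param features Indicator columns to split on, in tie-break order.
#' @return A `lame_tree` object.
#' @export
#' @examples
#' sim <- simulate_herd(herd_config(n_cows = 300, n_visits = 3, seed = 11))
#' tree <- prune_tree(grow_tree(sim))
#' tree
grow_tree <- function(data, class = NULL, features = IPS_INDICATORS) {
  class <- class %||% ls_class3(data$ls)
  if (nrow(data) == 0L) {
    abort("Training data must be non-empty.", class = "parlourscore_validation_error")
  }
  stopifnot(length(class) == nrow(data))
  build <- function(rows, avail, depth) {
    y <- class[rows]
    node <- new_node(class_count_vec(y), depth)
    if (node$gini == 0 || length(avail) == 0L) {
      return(node)
    }
    s <- best_split(data[rows, , drop = FALSE], y, avail)
    if (is.null(s)) {
      return(node)
    }
    x <- data[[s$feature]][rows]
    node$split <- s
    node$absent <- build(rows[x == 0L], setdiff(avail, s$feature), depth + 1L)
    node$present <- build(rows[x == 1L], setdiff(avail, s$feature), depth + 1L)
    node
  }
  structure(
    list(root = build(seq_len(nrow(data)), features, 0L), features = features),
    class = "lame_tree"
  )
}

#' Pruning rule
#'
#' The two post-pruning criteria applied bottom-up by [prune_tree()]: an
#' internal node must hold at least `min_node_size` observations (default 21,
#' i.e. strictly more than 20) and its split must have decreased Gini impurity
#' by at least `min_gini_decrease` (default 0.005, chosen to balance accuracy
#' against tree complexity); otherwise it is collapsed to a leaf.
#'
#' @param min_node_size Minimum observations required to keep a split.
#' @param min_gini_decrease Minimum realized Gini decrease to keep a split.
#' @return A `pruning_rule` object.
#' @export
pruning_rule <- function(min_node_size = 21L, min_gini_decrease = 0.005) {
  if (min_node_size < 1 || min_gini_decrease <= 0) {
    abort("Pruning thresholds must be positive.", class = "parlourscore_argument_error")
  }
  structure(list(min_node_size = as.integer(min_node_size),
                 min_gini_decrease = as.numeric(min_gini_decrease)),
            class = "pruning_rule")
}

#' Post-prune a grown tree
#'
#' Bottom-up pruning: after pruning its children, any internal node that holds
#' fewer than `min_node_size` observations or whose split decreased impurity
#' by less than `min_gini_decrease` is collapsed to a leaf predicting its
#' majority class (ties toward the lower class). Idempotent; the result
#' satisfies both criteria at every remaining internal node.
#'
#' @param tree A `lame_tree` from [grow_tree()].
#' @param rule A [pruning_rule()].
#' @return The pruned `lame_tree`.
#' @export
prune_tree <- function(tree, rule = pruning_rule()) {
  stopifnot(inherits(tree, "lame_tree"), inherits(rule, "pruning_rule"))
  prune <- function(node) {
    if (is.null(node$split)) {
      return(node)
    }
    node$absent <- prune(node$absent)
    node$present <- prune(node$present)
    if (node$n < rule$min_node_size ||
        node$split$decrease < rule$min_gini_decrease) {
      node$split <- NULL
      node$absent <- NULL
      node$present <- NULL
    }
    node
  }
  tree$root <- prune(tree$root)
  tree
}

#' Predict locomotion score classes from a tree
#'
#' Routes each observation from the root: the absent branch when the node's
#' indicator is 0, the present branch when it is 1, down to a leaf whose
#' majority class is returned. Total and deterministic on complete
#' observations.
#'
#' @param object A `lame_tree`.
#' @param newdata Observations with the tree's indicator columns (0/1, no
#'   missing values).
#' @param ... Unused.
#' @return Factor of predicted classes with levels `"0"`, `"1"`, `">=2"`.
#' @export
predict.lame_tree <- function(object, newdata, ...) {
  flags <- as.matrix(newdata[object$features])
  if (anyNA(flags) || !all(flags %in% c(0L, 1L))) {
    abort("Indicator flags must be 0/1 with no missing values.",
          class = "parlourscore_validation_error")
  }
  out <- character(nrow(newdata))
  walk <- function(node, rows) {
    if (length(rows) == 0L) {
      return(invisible())
    }
    if (is.null(node$split)) {
      out[rows] <<- node$prediction
      return(invisible())
    }
    x <- flags[rows, node$split$feature]
    walk(node$absent, rows[x == 0L])
    walk(node$present, rows[x == 1L])
  }
  walk(object$root, seq_len(nrow(newdata)))
  factor(out, levels = LS_CLASSES)
}

#' @export
print.lame_tree <- function(x, ...) {
  cat("Decision tree over in-parlour indicators (n =", x$root$n, ")\n")
  show <- function(node, prefix, label) {
    header <- sprintf("%s%s n=%d gini=%.3f [%s]", prefix, label, node$n,
                      node$gini, paste(node$counts, collapse = "/"))
    if (is.null(node$split)) {
      cat(header, "-> predict", node$prediction, "\n")
    } else {
      cat(sprintf("%s split on %s (decrease %.4f)\n", header,
                  toupper(node$split$feature), node$split$decrease))
      show(node$absent, paste0(prefix, "  "),
           paste0(toupper(node$split$feature), "=absent:"))
      show(node$present, paste0(prefix, "  "),
           paste0(toupper(node$split$feature), "=present:"))
    }
  }
  show(x$root, "", "root:")
  invisible(x)
}

tree_nodes <- function(tree) {
  rows <- list()
  visit <- function(node, parent_id) {
    id <- length(rows) + 1L
    row <- tibble::tibble(
      id = id, parent = parent_id, depth = node$depth, n = node$n,
      n_class0 = node$counts[[1L]], n_class1 = node$counts[[2L]],
      n_lame = node$counts[[3L]], gini = node$gini,
      split_feature = if (is.null(node$split)) NA_character_ else node$split$feature,
      decrease = if (is.null(node$split)) NA_real_ else node$split$decrease,
      prediction = node$prediction, leaf = is.null(node$split)
    )
    rows[[id]] <<- dplyr::rename(row, node = "id")
    if (!is.null(node$split)) {
      visit(node$absent, id)
      visit(node$present, id)
    }
  }
  visit(tree$root, NA_integer_)
  dplyr::bind_rows(rows)
}

#' @describeIn grow_tree One row per node: counts, impurity, split feature and
#'   realized decrease, prediction.
#' @param x A `lame_tree`.
#' @param ... Unused.
#' @method tidy lame_tree
#' @export
tidy.lame_tree <- function(x, ...) {
  tree_nodes(x)
}

#' @describeIn grow_tree One-row summary: node/leaf counts and depth.
#' @method glance lame_tree
#' @export
glance.lame_tree <- function(x, ...) {
  info <- tree_nodes(x)
  tibble::tibble(
    n_train = x$root$n,
    nodes = nrow(info),
    leaves = sum(info$leaf),
    depth = max(info$depth)
  )
}

#' Export a tree as Graphviz DOT
#'
#' One box per node with its class counts; the edge to the absent branch is
#' green, to the present branch red.
#'
#' @param tree A `lame_tree`.
#' @return A single DOT-language string.
#' @export
tree_to_dot <- function(tree) {
  nodes <- tree_nodes(tree)
  decl <- purrr::pmap_chr(nodes, function(node, n, n_class0, n_class1, n_lame,
                                          gini, split_feature, prediction,
                                          leaf, ...) {
    label <- if (leaf) {
      sprintf("predict LS %s\\nn=%d (%d/%d/%d)", prediction, n,
              n_class0, n_class1, n_lame)
    } else {
      sprintf("%s?\\nn=%d (%d/%d/%d)\\ngini=%.3f", toupper(split_feature), n,
              n_class0, n_class1, n_lame, gini)
    }
    sprintf("  n%d [shape=box, label=\"%s\"];", node, label)
  })
  kids <- nodes[!is.na(nodes$parent), ]
  edges <- character(0)
  if (nrow(kids)) {
    first_child <- !duplicated(kids$parent)
    edges <- sprintf(
      "  n%d -> n%d [label=\"%s\", color=%s];",
      kids$parent, kids$node,
      ifelse(first_child, "absent", "present"),
      ifelse(first_child, "green", "red")
    )
  }
  paste(c("digraph lame_tree {", decl, edges, "}"), collapse = "\n")
}
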