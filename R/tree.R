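#' Hierarchical classification trees over trajectory properties
#'
#' A motion tree is a binary threshold tree: each internal node tests one
#' property against a threshold (`value <= threshold` descends left, `>`
#' descends right) and each leaf carries a population label such as
#' `"immobile"`, `"hybrid"` or `"mobile"`. Trees can be authored manually
#' with [tree_split()]/[tree_leaf()] or trained from a labelled training set
#' with [train_tree()].
#'
#' @param root a node built from [tree_split()] and [tree_leaf()].
#' @return an object of class `motion_tree`.
#' @examples
#' tree <- motion_tree(tree_split(
#'   "mbcr", 118e-9,
#'   tree_leaf("immobile"),
#'   tree_leaf("mobile")
#' ))
#' predict(tree, data.frame(mbcr = c(5e-8, 3e-7)))
#' @export
motion_tree <- function(root) {
  validate_node(root)
  structure(
    list(root = root,
         n_splits = count_splits(root),
         properties = node_properties(root),
         labels = sort(unique(node_labels(root)))),
    class = "motion_tree"
  )
}

#' @rdname motion_tree
#' @param property property name tested at the node.
#' @param threshold numeric threshold; `<=` goes left.
#' @param left,right child nodes.
#' @export
tree_split <- function(property, threshold, left, right) {
  stopifnot(is.character(property), length(property) == 1,
            is.numeric(threshold), length(threshold) == 1, is.finite(threshold))
  list(property = property, threshold = threshold, left = left, right = right)
}

#' @rdname motion_tree
#' @param label population label for the leaf.
#' @export
tree_leaf <- function(label) {
  stopifnot(is.character(label), length(label) == 1)
  list(label = label)
}

validate_node <- function(node) {
  if (!is.list(node)) stop("malformed tree node", call. = FALSE)
  if (!is.null(node$label)) return(invisible(TRUE))
  if (is.null(node$property) || is.null(node$threshold) ||
      is.null(node$left) || is.null(node$right)) {
    stop("internal node needs property, threshold, left and right", call. = FALSE)
  }
  validate_node(node$left)
  validate_node(node$right)
  invisible(TRUE)
}

count_splits <- function(node) {
  if (!is.null(node$label)) 0L
  else 1L + count_splits(node$left) + count_splits(node$right)
}

node_properties <- function(node) {
  if (!is.null(node$label)) character()
  else unique(c(node$property, node_properties(node$left), node_properties(node$right)))
}

node_labels <- function(node) {
  if (!is.null(node$label)) node$label
  else c(node_labels(node$left), node_labels(node$right))
}

#' Predict population labels from a motion tree
#'
#' Each row descends the tree from the root, going left when the tested
#' property is `<=` the node threshold. A non-finite value at a tested
#' property is an error naming the trajectory and the property, since the
#' branch taken would be arbitrary.
#'
#' @param object a [motion_tree()].
#' @param newdata data frame of property values; one row per trajectory.
#'   An `id` column, if present, is used in error messages.
#' @param ... unused.
#' @return character vector of labels, one per row.
#' @export
predict.motion_tree <- function(object, newdata, ...) {
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$properties, names(newdata))
  if (length(miss) > 0) {
    stop("property table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  ids <- if ("id" %in% names(newdata)) as.character(newdata$id) else
    as.character(seq_len(nrow(newdata)))
  vapply(seq_len(nrow(newdata)), function(i) {
    descend(object$root, newdata[i, , drop = FALSE], ids[i])
  }, character(1))
}

descend <- function(node, row, id) {
  while (is.null(node$label)) {
    v <- row[[node$property]]
    if (!is.finite(v)) {
      stop("cannot classify trajectory ", id, ": property `", node$property,
           "` is not finite", call. = FALSE)
    }
    node <- if (v <= node$threshold) node$left else node$right
  }
  node$label
}

#' Train a classification tree by greedy Gini induction
#'
#' CART-style best-first growth: at each step, the impure leaf whose best
#' (property, threshold) pair gives the largest decrease in total weighted
#' Gini impurity is split, with candidate thresholds at midpoints between
#' consecutive sorted distinct values. Growth stops when `max_splits`
#' internal nodes are reached, all leaves are pure, or no split reduces the
#' impurity. Leaves are labelled by majority class (ties broken towards the
#' lexicographically smallest label); equal-gain splits are broken by
#' property name, then by the smaller threshold, so training is fully
#' deterministic. Limiting the number of splits (default five) is the only
#' complexity control: no pruning, surrogate splits, or class weights.
#'
#' @param props property table from [compute_properties()]; must contain
#'   every training id. Only columns that are finite for all training rows
#'   are considered as split candidates.
#' @param training data frame with columns `id` and `label`.
#' @param max_splits maximum number of internal nodes.
#' @return a [motion_tree()].
#' @export
train_tree <- function(props, training, max_splits = 5) {
  stopifnot(all(c("id", "label") %in% names(training)), max_splits >= 0)
  training <- tibble::as_tibble(training)
  training$id <- as.character(training$id)
  missing_ids <- setdiff(training$id, as.character(props$id))
  if (length(missing_ids) > 0) {
    stop("training ids absent from property table: ",
         paste(utils::head(missing_ids, 3), collapse = ", "), call. = FALSE)
  }
  data <- join_training(training, props)
  labels <- as.character(data$label)
  if (length(unique(labels)) < 2) {
    warning("training set has a single label; returning a single-leaf tree",
            call. = FALSE)
    return(motion_tree(tree_leaf(unique(labels))))
  }
  cand <- setdiff(names(props)[vapply(props, is.numeric, logical(1))], "id")
  cand <- sort(cand[vapply(cand, function(cc) all(is.finite(data[[cc]])), logical(1))])
  if (length(cand) == 0) stop("no finite-valued candidate properties", call. = FALSE)

  x <- as.data.frame(data[cand])
  root <- grow_tree(x, labels, max_splits)
  motion_tree(root)
}

gini <- function(labels) {
  p <- table(labels) / length(labels)
  1 - sum(p^2)
}

majority_label <- function(labels) {
  tab <- table(labels)
  names(tab)[which.max(tab)]  # table names are sorted, so ties go to the smallest
}

# best (property, threshold) for one leaf; returns NULL if nothing reduces
# the node impurity
best_split <- function(x, labels) {
  n <- length(labels)
  parent <- gini(labels)
  best <- NULL
  for (prop in names(x)) {  # names(x) sorted by caller: lexicographic tie-break
    v <- x[[prop]]
    ord <- order(v)
    vs <- v[ord]
    ls <- labels[ord]
    distinct <- unique(vs)
    if (length(distinct) < 2) next
    thresholds <- (distinct[-length(distinct)] + distinct[-1]) / 2
    for (thr in thresholds) {
      left <- vs <= thr
      nl <- sum(left)
      imp <- (nl * gini(ls[left]) + (n - nl) * gini(ls[!left])) / n
      gain <- parent - imp
      if (gain > 1e-12 &&
          (is.null(best) || gain > best$gain + 1e-12)) {
        best <- list(property = prop, threshold = thr, gain = gain)
      }
    }
  }
  best
}

grow_tree <- function(x, labels, max_splits) {
  # leaves held in a list; each entry: row indices + cached best split
  leaves <- list(list(idx = seq_along(labels)))
  nodes <- list()  # flat store; node ids reference into it
  make_leaf_id <- function(entry) {
    nodes[[length(nodes) + 1]] <<- list(label = majority_label(labels[entry$idx]))
    length(nodes)
  }
  # iterative best-first growth on a working set of splittable leaves
  splits_done <- 0L
  # frontier entries: idx (rows), node_slot (position in parent to fill later)
  # Simpler: recursively collect; use a priority-driven loop on a frontier of
  # candidate leaves, then assemble the tree from the recorded splits.
  frontier <- list(list(idx = seq_along(labels), path = character()))
  decided <- list()  # path -> split or label
  while (TRUE) {
    # find best split across frontier leaves
    best_i <- 0L
    best_sp <- NULL
    if (splits_done < max_splits) {
      for (i in seq_along(frontier)) {
        entry <- frontier[[i]]
        if (length(unique(labels[entry$idx])) < 2) next
        sp <- entry$split %||% best_split(x[entry$idx, , drop = FALSE], labels[entry$idx])
        frontier[[i]]$split <- sp
        if (is.null(sp)) next
        # weighted gain over the whole training set
        wgain <- sp$gain * length(entry$idx)
        if (is.null(best_sp) || wgain > best_sp$wgain + 1e-12) {
          best_sp <- c(sp, list(wgain = wgain))
          best_i <- i
        }
      }
    }
    if (is.null(best_sp)) break
    entry <- frontier[[best_i]]
    decided[[paste0("/", paste(entry$path, collapse = "/"))]] <-
      list(property = best_sp$property, threshold = best_sp$threshold)
    go_left <- x[[best_sp$property]][entry$idx] <= best_sp$threshold
    frontier[[best_i]] <- NULL
    frontier <- c(frontier,
                  list(list(idx = entry$idx[go_left], path = c(entry$path, "L")),
                       list(idx = entry$idx[!go_left], path = c(entry$path, "R"))))
    splits_done <- splits_done + 1L
  }
  build <- function(path, idx) {
    key <- paste0("/", paste(path, collapse = "/"))
    if (!is.null(decided[[key]])) {
      sp <- decided[[key]]
      go_left <- x[[sp$property]][idx] <= sp$threshold
      tree_split(sp$property, sp$threshold,
                 build(c(path, "L"), idx[go_left]),
                 build(c(path, "R"), idx[!go_left]))
    } else {
      tree_leaf(majority_label(labels[idx]))
    }
  }
  build(character(), seq_along(labels))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Misclassification rate on the training set
#'
#' The resubstitution loss is the fraction of training trajectories whose
#' predicted label differs from the assigned label. With small training
#' sets it is the primary sanity check of a trained tree, alongside visual
#' inspection of the classified data set.
#'
#' @param tree a [motion_tree()].
#' @param props property table covering all training ids.
#' @param training data frame with columns `id` and `label`.
#' @return fraction in \[0, 1\].
#' @export
resubstitution_loss <- function(tree, props, training) {
  data <- join_training(training, props)
  if (nrow(data) < nrow(tibble::as_tibble(training))) {
    stop("training ids missing from property table", call. = FALSE)
  }
  pred <- predict(tree, data)
  mean(pred != data$label)
}

# training (id, label) joined to descriptors; any label column already in
# the property table (e.g. ground-truth annotation) is set aside
join_training <- function(training, props) {
  training <- tibble::as_tibble(training)[c("id", "label")]
  training$id <- as.character(training$id)
  props <- dplyr::mutate(tibble::as_tibble(props), id = as.character(.data$id))
  props$label <- NULL
  dplyr::inner_join(training, props, by = "id")
}

#' Classify every trajectory of a set
#'
#' Applies a motion tree to the property table and attaches the resulting
#' population label to each localization row of the track set. Every
#' trajectory receives exactly one label.
#'
#' @param tracks a [track_set()].
#' @param tree a [motion_tree()].
#' @param props property table covering every trajectory in `tracks`;
#'   computed with [compute_properties()] if omitted.
#' @param ... passed to [compute_properties()] when `props` is omitted.
#' @return `tracks` with a `label` column.
#' @export
classify_tracks <- function(tracks, tree, props = NULL, ...) {
  if (is.null(props)) props <- compute_properties(tracks, ...)
  ids <- unique(tibble::as_tibble(tracks)$id)
  miss <- setdiff(ids, as.character(props$id))
  if (length(miss) > 0) {
    stop("property table does not cover trajectory ", miss[1], call. = FALSE)
  }
  labs <- stats::setNames(predict(tree, props), as.character(props$id))
  out <- tibble::as_tibble(tracks)
  out$label <- unname(labs[out$id])
  new_track_set(out, dt = track_dt(tracks), pixel_size = track_pixel_size(tracks))
}

#' Save / load a motion tree as JSON
#'
#' Thresholds are written at full double precision, so a saved tree reloads
#' with bit-identical behaviour. The on-disk schema is the recursive node
#' form `{property, threshold, left, right}` / `{label}`, convenient for
#' authoring trees by hand.
#'
#' @param tree a [motion_tree()].
#' @param path JSON file path.
#' @return `write_tree` returns `path` invisibly; `read_tree` returns the
#'   tree.
#' @export
write_tree <- function(tree, path) {
  stopifnot(inherits(tree, "motion_tree"))
  # thresholds are emitted with 17 significant digits so the reload is
  # bit-identical; jsonlite handles the (lossless) string fields on re-read
  emit <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (!is.null(node$label)) {
      sprintf('%s{"label": %s}', pad, jsonlite::toJSON(node$label, auto_unbox = TRUE))
    } else {
      paste0(
        pad, "{\n",
        pad, sprintf('  "property": %s,\n',
                     jsonlite::toJSON(node$property, auto_unbox = TRUE)),
        pad, sprintf('  "threshold": %.17g,\n', node$threshold),
        pad, '  "left":\n', emit(node$left, indent + 1), ",\n",
        pad, '  "right":\n', emit(node$right, indent + 1), "\n",
        pad, "}"
      )
    }
  }
  writeLines(emit(tree$root, 0), path)
  invisible(path)
}

#' @rdname write_tree
#' @export
read_tree <- function(path) {
  node <- tryCatch(jsonlite::read_json(path, simplifyVector = FALSE),
                   error = function(e) stop("malformed tree file: ",
                                            conditionMessage(e), call. = FALSE))
  motion_tree(parse_node(node))
}

parse_node <- function(node) {
  if (!is.list(node)) stop("malformed tree file: node is not an object", call. = FALSE)
  if (!is.null(node$label)) return(tree_leaf(as.character(node$label)))
  if (is.null(node$property) || is.null(node$threshold) ||
      is.null(node$left) || is.null(node$right)) {
    stop("malformed tree file: internal node needs property, threshold, left, right",
         call. = FALSE)
  }
  tree_split(as.character(node$property), as.numeric(node$threshold),
             parse_node(node$left), parse_node(node$right))
}

#' @export
print.motion_tree <- function(x, ...) {
  cat(sprintf("# motion_tree: %d split(s), labels: %s\n",
              x$n_splits, paste(x$labels, collapse = ", ")))
  print_node(x$root, indent = 0)
  invisible(x)
}

print_node <- function(node, indent) {
  pad <- strrep("  ", indent)
  if (!is.null(node$label)) {
    cat(pad, "* ", node$label, "\n", sep = "")
  } else {
    cat(pad, node$property, " <= ", format(node$threshold, digits = 4), "\n", sep = "")
    print_node(node$left, indent + 1)
    print_node(node$right, indent + 1)
  }
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a motion tree into a node table
#'
#' @param x a [motion_tree()].
#' @param ... unused.
#' @return tibble with one row per node: `node` (path from the root, `""`
#'   for the root, then `L`/`R` steps), `depth`, `type`, `property`,
#'   `threshold`, `label`.
#' @export
tidy.motion_tree <- function(x, ...) {
  walk <- function(nd, path) {
    is_split <- is.null(nd$label)
    row <- tibble::tibble(
      node = paste(path, collapse = ""),
      depth = length(path),
      type = if (is_split) "split" else "leaf",
      property = nd$property %||% NA_character_,
      threshold = nd$threshold %||% NA_real_,
      label = nd$label %||% NA_character_
    )
    if (is_split) {
      row <- dplyr::bind_rows(row, walk(nd$left, c(path, "L")),
                              walk(nd$right, c(path, "R")))
    }
    row
  }
  walk(x$root, character())
}

#' @rdname tidy.motion_tree
#' @export
glance.motion_tree <- function(x, ...) {
  nd <- tidy(x)
  tibble::tibble(
    n_splits = x$n_splits,
    n_leaves = sum(nd$type == "leaf"),
    depth = max(nd$depth),
    n_labels = length(x$labels)
  )
}
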