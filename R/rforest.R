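# Random forest classifier with two split-rule types: a single feature
# compared to a threshold, or the difference of two features compared to a
# threshold (an oblique rule that can carve boundaries of the form
# f_i - f_j = t that axis-aligned trees approximate only with many splits).
# Trees are grown by maximizing entropy reduction over ~400 randomly proposed
# candidate rules per node; leaves store class generation probabilities and
# prediction averages them over the trees.

#' Shannon entropy of a label multiset, in bits
#'
#' @param labels Vector of class labels (any type; frequencies are used).
#' @return Entropy `-sum p log2 p` in bits.
#' @export
entropy_bits <- function(labels) {
  if (length(labels) == 0L) stop("empty label set")
  p <- table(labels) / length(labels)
  -sum(p * log2(p))
}

#' Forest training configuration
#'
#' Defaults follow the reference classifier: 100 trees of depth at most 50,
#' 400 candidate rules per node, and a stratified bootstrap of at most
#' 100,000 pixels per tree (full images pool tens of millions of pixels, so
#' a cap is required).
#'
#' @param n_trees Number of trees.
#' @param max_depth Maximum node depth (root = depth 0).
#' @param n_candidates Candidate rules evaluated per node.
#' @param per_tree_sample Bootstrap sample size cap per tree.
#' @param min_samples_leaf Minimum samples in each child of a split.
#' @param seed Integer seed; training is deterministic given the seed.
#' @return List of class `forest_config`.
#' @export
forest_config <- function(n_trees = 100L, max_depth = 50L, n_candidates = 400L,
                          per_tree_sample = 100000L, min_samples_leaf = 1L,
                          seed = 0L) {
  cfg <- list(n_trees = as.integer(n_trees), max_depth = as.integer(max_depth),
              n_candidates = as.integer(n_candidates),
              per_tree_sample = as.integer(per_tree_sample),
              min_samples_leaf = as.integer(min_samples_leaf),
              seed = as.integer(seed))
  if (any(unlist(cfg[1:5]) <= 0L) || cfg$max_depth < 0L) {
    stop("forest_config values must be positive")
  }
  class(cfg) <- "forest_config"
  cfg
}

#' Propose random candidate split rules for a node
#'
#' Each candidate is drawn independently: rule type uniform between single
#' and difference (single only when one feature exists), feature indices
#' uniform (a distinct pair for difference rules), and the threshold uniform
#' between the minimum and maximum of the rule's expression over the node's
#' samples. A degenerate node (all feature values constant) yields an empty
#' list.
#'
#' @param samples N x F feature matrix of the node's samples.
#' @param n_candidates Number of rules to propose.
#' @param seed Integer seed.
#' @return Data frame with columns `type` ("single"/"difference"), `i`, `j`
#'   (1-based feature indices; `j` is `NA` for single rules), `threshold`.
#' @export
propose_candidates <- function(samples, n_candidates = 400L, seed = 0L) {
  samples <- as.matrix(samples)
  if (nrow(samples) < 2L) stop("need at least 2 samples")
  res <- cpp_propose(samples, seq_len(nrow(samples)), as.integer(n_candidates),
                     as.double(seed))
  data.frame(type = c("single", "difference")[res$type + 1L],
             i = res$i, j = ifelse(res$type == 1L, res$j, NA_integer_),
             threshold = res$threshold, stringsAsFactors = FALSE)
}

candidates_to_cpp <- function(candidates) {
  type <- as.integer(candidates$type == "difference")
  list(type = type, i = as.integer(candidates$i),
       j = as.integer(ifelse(is.na(candidates$j), 1L, candidates$j)),
       threshold = as.numeric(candidates$threshold))
}

#' Best split among candidate rules
#'
#' Evaluates every candidate's entropy reduction (parent entropy minus the
#' size-weighted mean of child entropies) on the samples; samples with
#' expression value `<= threshold` go left. Returns `NULL` when no candidate
#' achieves strictly positive gain with two non-empty children; ties go to
#' the first proposed candidate.
#'
#' @param samples N x F feature matrix.
#' @param labels Integer class labels (codes in `classes`).
#' @param candidates Data frame from [propose_candidates()].
#' @param classes Class code vocabulary (default the codes present).
#' @param min_samples_leaf Minimum child size.
#' @return `NULL`, or a list with `rule` (one row of `candidates`) and
#'   `gain` in bits.
#' @export
best_split <- function(samples, labels, candidates, classes = sort(unique(labels)),
                       min_samples_leaf = 1L) {
  samples <- as.matrix(samples)
  y <- match(labels, classes) - 1L
  if (anyNA(y)) stop("labels outside the class vocabulary")
  if (nrow(candidates) == 0L) return(NULL)
  res <- cpp_best_split(samples, y, length(classes), seq_len(nrow(samples)),
                        candidates_to_cpp(candidates),
                        as.integer(min_samples_leaf))
  if (res$index == 0L) return(NULL)
  list(rule = candidates[res$index, , drop = FALSE], gain = res$gain)
}

#' Train a single decision tree
#'
#' Grows a tree from the root by repeatedly adding the best of
#' `n_candidates` randomly proposed rules; growth stops at a node when the
#' node is pure, the depth limit is reached, the node is degenerate, or no
#' candidate reduces the entropy, at which point a leaf holding the class
#' generation probabilities (class frequencies of the remaining training
#' data) is created.
#'
#' @param samples N x F feature matrix.
#' @param labels Class labels (codes in `classes`).
#' @param config A [forest_config()] (only `max_depth`, `n_candidates`,
#'   `min_samples_leaf` are used).
#' @param classes Class code vocabulary.
#' @param seed Integer seed.
#' @return A tree as a list of parallel node vectors (`type`, `i`, `j`,
#'   `threshold`, `gain`, `left`, `right`, `depth`, `probs`), class
#'   `hs_tree`; node 1 is the root, `type = -1` marks leaves.
#' @export
train_tree <- function(samples, labels, config = forest_config(),
                       classes = sort(unique(labels)), seed = config$seed) {
  samples <- as.matrix(samples)
  if (nrow(samples) == 0L) stop("empty training set")
  y <- match(labels, classes) - 1L
  if (anyNA(y)) stop("labels outside the class vocabulary")
  tr <- cpp_train_tree(samples, y, length(classes), config$max_depth,
                       config$n_candidates, config$min_samples_leaf,
                       as.double(seed))
  structure(tr, class = "hs_tree")
}

# pooled pixel matrix + labels from feature stacks and label maps,
# excluding ignore-labeled (255) and invalid-FFC pixels
pool_training_pixels <- function(features, labels, invalid = NULL) {
  if (inherits(features, "feature_stack")) features <- list(features)
  if (is.matrix(labels)) labels <- list(labels)
  stopifnot(length(features) == length(labels))
  xs <- vector("list", length(features))
  ys <- vector("list", length(features))
  for (i in seq_along(features)) {
    X <- feature_matrix(features[[i]])
    lab <- as.vector(labels[[i]])
    keep <- lab != 255L
    if (!is.null(invalid) && !is.null(invalid[[i]])) {
      keep <- keep & !as.vector(invalid[[i]])
    }
    xs[[i]] <- X[keep, , drop = FALSE]
    ys[[i]] <- lab[keep]
  }
  list(X = do.call(rbind, xs), y = unlist(ys))
}

#' Train a random forest
#'
#' Each tree receives its own seeded stratified bootstrap sample (with
#' replacement, per-class allocation proportional to class frequency, capped
#' at `per_tree_sample` pixels) from the pooled training pixels;
#' ignore-labeled (255) and invalid flat-field pixels are excluded.
#'
#' @param features A `feature_stack`, a list of them, or a plain N x F
#'   matrix.
#' @param labels Matching label map(s) (matrices of class codes), or a label
#'   vector when `features` is a matrix.
#' @param config A [forest_config()].
#' @param classes Class code vocabulary (default 0:3). Errors if any class is
#'   absent from the training data.
#' @param invalid Optional list of invalid-pixel masks matching `features`.
#' @return Object of class `hs_forest`: `trees`, `config`, `classes`,
#'   `feature_names`.
#' @export
train_forest <- function(features, labels, config = forest_config(),
                         classes = 0:3, invalid = NULL) {
  if (is.matrix(features) && !inherits(features, "feature_stack")) {
    X <- features
    y_codes <- as.integer(labels)
    feature_names <- colnames(features)
  } else {
    pooled <- pool_training_pixels(features, labels, invalid)
    X <- pooled$X
    y_codes <- as.integer(pooled$y)
    feature_names <- colnames(X)
  }
  missing_cls <- setdiff(classes, unique(y_codes))
  if (length(missing_cls)) {
    stop("class(es) absent from training data: ",
         paste(missing_cls, collapse = ", "))
  }
  y <- match(y_codes, classes) - 1L
  trees <- cpp_train_forest(X, y, length(classes), config$n_trees,
                            config$max_depth, config$n_candidates,
                            config$per_tree_sample, config$min_samples_leaf,
                            as.double(config$seed))
  structure(list(trees = trees, config = config, classes = as.integer(classes),
                 feature_names = feature_names),
            class = "hs_forest")
}

#' @export
print.hs_forest <- function(x, ...) {
  depths <- vapply(x$trees, function(t) max(t$depth), numeric(1))
  cat(sprintf("hs_forest: %d trees (max depth %d, mean %.1f), %d classes\n",
              length(x$trees), max(depths), mean(depths), length(x$classes)))
  invisible(x)
}

#' @export
summary.hs_forest <- function(object, ...) {
  nodes <- vapply(object$trees, function(t) length(t$type), numeric(1))
  leaves <- vapply(object$trees, function(t) sum(t$type == -1L), numeric(1))
  diffs <- vapply(object$trees, function(t) sum(t$type == 1L), numeric(1))
  singles <- vapply(object$trees, function(t) sum(t$type == 0L), numeric(1))
  out <- list(n_trees = length(object$trees), nodes = nodes, leaves = leaves,
              single_rules = singles, difference_rules = diffs,
              classes = object$classes)
  class(out) <- "summary.hs_forest"
  out
}

#' @export
print.summary.hs_forest <- function(x, ...) {
  cat(sprintf("hs_forest with %d trees\n", x$n_trees))
  cat(sprintf("  nodes/tree: median %g; leaves: median %g\n",
              median(x$nodes), median(x$leaves)))
  cat(sprintf("  split rules: %d single-feature, %d feature-difference\n",
              sum(x$single_rules), sum(x$difference_rules)))
  invisible(x)
}

#' Per-pixel class probabilities
#'
#' Averages the leaf generation probabilities of all trees.
#'
#' @param model An [train_forest()] model.
#' @param features `feature_stack` or N x F matrix (columns must match
#'   training).
#' @return N x K matrix of class probabilities (rows sum to 1), with class
#'   codes as column names.
#' @export
predict_proba <- function(model, features) {
  stopifnot(inherits(model, "hs_forest"))
  X <- if (inherits(features, "feature_stack")) feature_matrix(features)
       else as.matrix(features)
  if (!is.null(model$feature_names) && ncol(X) != length(model$feature_names)) {
    stop("feature count mismatch: model expects ",
         length(model$feature_names), ", got ", ncol(X))
  }
  p <- cpp_predict_proba(model$trees, X, length(model$classes))
  colnames(p) <- model$classes
  p
}

#' Predict class labels
#'
#' Argmax of [predict_proba()]; ties go to the lowest class code.
#'
#' @param object An [train_forest()] model.
#' @param features `feature_stack` or N x F matrix.
#' @param type `"class"` (default) or `"prob"`.
#' @param ... Unused.
#' @return Class codes (a matrix when `features` is a `feature_stack`), or
#'   the probability matrix when `type = "prob"`.
#' @export
predict.hs_forest <- function(object, features, type = c("class", "prob"), ...) {
  type <- match.arg(type)
  p <- predict_proba(object, features)
  if (type == "prob") return(p)
  cls <- object$classes[max.col(p, ties.method = "first")]
  if (inherits(features, "feature_stack")) {
    d <- dim(features$planes)
    cls <- matrix(as.integer(cls), d[1L], d[2L])
  }
  cls
}

# ---- JSON serialization (nested node records) ----

node_to_record <- function(tree, n) {
  if (tree$type[n] == -1L) {
    list(class_probs = as.numeric(tree$probs[n, ]))
  } else {
    list(rule_type = c("single", "difference")[tree$type[n] + 1L],
         i = tree$i[n],
         j = if (tree$type[n] == 1L) tree$j[n] else NULL,
         threshold = tree$threshold[n],
         left = node_to_record(tree, tree$left[n]),
         right = node_to_record(tree, tree$right[n]))
  }
}

record_to_node <- function(rec, buf, depth) {
  if (!is.null(rec$class_probs)) {
    buf$type <- c(buf$type, -1L)
    buf$i <- c(buf$i, 0L); buf$j <- c(buf$j, 0L)
    buf$threshold <- c(buf$threshold, NA_real_)
    buf$gain <- c(buf$gain, NA_real_)
    buf$left <- c(buf$left, 0L); buf$right <- c(buf$right, 0L)
    buf$depth <- c(buf$depth, depth)
    buf$probs <- rbind(buf$probs, as.numeric(rec$class_probs))
    buf$self <- length(buf$type)
    return(buf)
  }
  id <- length(buf$type) + 1L
  buf$type <- c(buf$type, as.integer(rec$rule_type == "difference"))
  buf$i <- c(buf$i, as.integer(rec$i))
  buf$j <- c(buf$j, if (is.null(rec$j)) 1L else as.integer(rec$j))
  buf$threshold <- c(buf$threshold, rec$threshold)
  buf$gain <- c(buf$gain, NA_real_)
  buf$left <- c(buf$left, 0L); buf$right <- c(buf$right, 0L)
  buf$depth <- c(buf$depth, depth)
  buf$probs <- rbind(buf$probs, rep(NA_real_, ncol(buf$probs)))
  buf <- record_to_node(rec$left, buf, depth + 1L)
  buf$left[id] <- buf$self
  buf <- record_to_node(rec$right, buf, depth + 1L)
  buf$right[id] <- buf$self
  buf$self <- id
  buf
}

#' Serialize / deserialize a forest model as JSON
#'
#' Trees are stored as nested node records: internal nodes carry
#' `rule_type`, `i`, `j`, `threshold`, `left`, `right`; leaves carry
#' `class_probs`.
#'
#' @param model An `hs_forest`.
#' @param path File path.
#' @return `write_forest` invisibly returns `path`; `read_forest` returns
#'   the model.
#' @export
write_forest <- function(model, path) {
  obj <- list(classes = model$classes,
              feature_names = model$feature_names,
              config = unclass(model$config),
              trees = lapply(model$trees, node_to_record, n = 1L))
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null"), path)
  invisible(path)
}

#' @rdname write_forest
#' @export
read_forest <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  K <- length(obj$classes)
  trees <- lapply(obj$trees, function(rec) {
    buf <- list(type = integer(0), i = integer(0), j = integer(0),
                threshold = numeric(0), gain = numeric(0),
                left = integer(0), right = integer(0), depth = integer(0),
                probs = matrix(numeric(0), 0, K), self = 0L)
    buf <- record_to_node(rec, buf, 0L)
    buf$self <- NULL
    buf
  })
  cfg <- obj$config
  config <- forest_config(cfg$n_trees, cfg$max_depth, cfg$n_candidates,
                          cfg$per_tree_sample, cfg$min_samples_leaf, cfg$seed)
  structure(list(trees = trees, config = config,
                 classes = as.integer(unlist(obj$classes)),
                 feature_names = if (is.null(obj$feature_names)) NULL
                                 else unlist(obj$feature_names)),
            class = "hs_forest")
}
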