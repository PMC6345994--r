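# Pixel-wise and object-wise evaluation metrics, the leave-one-out
# cross-validation driver, and end-to-end pipeline orchestration:
# FFC -> spectral k-means cluster image -> multi-scale features -> forest.

#' F-beta score
#'
#' `(1 + beta^2) * PRE * REC / (beta^2 * PRE + REC)`; beta = 0.5 weights
#' precision more, and F1 equals Dice's coefficient. Returns 0 when both
#' precision and recall are 0.
#'
#' @param precision,recall Values in `[0, 1]` (vectorized).
#' @param beta Positive weight.
#' @return F-beta score(s).
#' @export
f_beta <- function(precision, recall, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  num <- (1 + beta^2) * precision * recall
  den <- beta^2 * precision + recall
  ifelse(den == 0, 0, num / den)
}

#' Pixel-wise classification metrics
#'
#' Per-class confusion counts and precision/recall/F0.5/F1 over the evaluable
#' pixels (ignore-labeled pixels, and optionally invalid flat-field pixels,
#' are excluded). Precision is `TP/(TP+FP)` and recall `TP/(TP+FN)`, each 0
#' when its denominator is 0.
#'
#' @param pred,truth Label matrices of the same shape.
#' @param classes Class codes to report (default 0:3).
#' @param invalid Optional logical matrix of pixels to exclude.
#' @return Data frame with one row per class: `class`, `n_pixels` (truth
#'   pixels of the class), `tp`, `fp`, `fn`, `tn`, `precision`, `recall`,
#'   `f05`, `f1`.
#' @export
pixel_metrics <- function(pred, truth, classes = 0:3, invalid = NULL) {
  if (!identical(dim(pred), dim(truth))) stop("shape mismatch")
  keep <- truth != 255L & pred != 255L
  if (!is.null(invalid)) keep <- keep & !invalid
  if (!any(keep)) stop("no evaluable pixels")
  p <- pred[keep]; t <- truth[keep]
  n <- length(p)
  out <- lapply(classes, function(cl) {
    tp <- sum(p == cl & t == cl)
    fp <- sum(p == cl & t != cl)
    fn <- sum(p != cl & t == cl)
    tn <- n - tp - fp - fn
    pre <- if (tp + fp == 0) 0 else tp / (tp + fp)
    rec <- if (tp + fn == 0) 0 else tp / (tp + fn)
    data.frame(class = cl, n_pixels = tp + fn, tp = tp, fp = fp, fn = fn,
               tn = tn, precision = pre, recall = rec,
               f05 = f_beta(pre, rec, 0.5), f1 = f_beta(pre, rec, 1))
  })
  do.call(rbind, out)
}

#' Object-wise plurality classification
#'
#' Assigns each ground-truth object the modal predicted label over its
#' pixels (ties toward the lowest class code); an object is correctly
#' classified when this plurality label equals its true class.
#'
#' @param pred Predicted label matrix.
#' @param truth_objects List of objects (`id`, `class`, `pixels` linear
#'   indices), as in a scene's `truth$objects`.
#' @return Data frame with `id`, `true_class`, `plurality`, `correct`.
#' @export
object_classify <- function(pred, truth_objects) {
  if (length(truth_objects) == 0L) stop("no objects")
  rows <- lapply(truth_objects, function(o) {
    if (length(o$pixels) == 0L) stop("object with zero pixels")
    v <- pred[o$pixels]
    v <- v[v != 255L]
    if (length(v) == 0L) v <- 255L
    tab <- table(v)
    plur <- as.integer(names(tab)[which.max(tab)])  # ties: lowest code first
    data.frame(id = o$id, true_class = o$class, plurality = plur,
               correct = plur == o$class)
  })
  do.call(rbind, rows)
}

#' Object-wise precision and recall
#'
#' Per class c: recall = (true-c objects with plurality c) / (true-c
#' objects); precision = (true-c objects with plurality c) / (objects of any
#' true class with plurality c). Objects are defined on the ground truth
#' only. Classes absent from both truth and pluralities get `NA` metrics.
#'
#' @param object_df Result of [object_classify()].
#' @param classes Class codes to report (default the three cell classes
#'   1:3; the external region has no objects).
#' @return Data frame with `class`, `n_objects`, `precision`, `recall`,
#'   `f05`, `f1`.
#' @export
object_metrics <- function(object_df, classes = 1:3) {
  out <- lapply(classes, function(cl) {
    n_true <- sum(object_df$true_class == cl)
    n_plur <- sum(object_df$plurality == cl)
    n_cor <- sum(object_df$true_class == cl & object_df$plurality == cl)
    if (n_true == 0L && n_plur == 0L) {
      return(data.frame(class = cl, n_objects = 0L, precision = NA_real_,
                        recall = NA_real_, f05 = NA_real_, f1 = NA_real_))
    }
    pre <- if (n_plur == 0L) 0 else n_cor / n_plur
    rec <- if (n_true == 0L) 0 else n_cor / n_true
    data.frame(class = cl, n_objects = n_true, precision = pre, recall = rec,
               f05 = f_beta(pre, rec, 0.5), f1 = f_beta(pre, rec, 1))
  })
  do.call(rbind, out)
}

#' Leave-one-out cross-validation of the full pipeline
#'
#' For each fold, one scene is held out; the spectral k-means model is
#' fitted on the pooled flat-field-corrected pixels of the remaining scenes,
#' cluster images and multi-scale features are computed for every scene with
#' that fold's model, the forest is trained on the training scenes, and the
#' held-out scene is classified and scored pixel-wise and object-wise. Test
#' pixels never enter the fold's clustering or forest training.
#'
#' @param scenes List of `hs_scene` objects (or lists with `object`, `dark`,
#'   `flat` stacks and `truth`), length >= 2.
#' @param k Number of spectral clusters (default 32).
#' @param kmeans_iter Lloyd updates for the clustering model.
#' @param feat_config A [feature_config()].
#' @param forest_cfg A [forest_config()].
#' @param seed Base seed; per-fold seeds are derived from it.
#' @param kmeans_sample_cap Maximum number of training spectra used to fit
#'   the clustering model (uniform seeded subsample above the cap).
#' @param verbose Print per-fold progress.
#' @return Object of class `loo_report`: `folds` (per-fold pixel and object
#'   metric tables), `pixel` / `object` (per-class mean and s.d. over
#'   folds), `cell_average` (per-fold average over the three cell classes,
#'   excluding the external region, with mean and s.d.), `n_folds`.
#' @export
run_loo <- function(scenes, k = 32L, kmeans_iter = 30L,
                    feat_config = feature_config(),
                    forest_cfg = forest_config(), seed = 0L,
                    kmeans_sample_cap = 1000000L, verbose = FALSE) {
  n <- length(scenes)
  if (n < 2L) stop("need at least 2 scenes")
  corrected <- lapply(scenes, function(s) {
    flat_field_correct(s$object, s$dark, s$flat)
  })
  folds <- vector("list", n)
  for (fold in seq_len(n)) {
    train_idx <- setdiff(seq_len(n), fold)
    stopifnot(!(fold %in% train_idx))  # no fold contamination
    train_px <- do.call(rbind, lapply(corrected[train_idx], stack_pixels))
    if (nrow(train_px) > kmeans_sample_cap) {
      sel <- with_seed(seed + fold, sample.int(nrow(train_px), kmeans_sample_cap))
      train_px <- train_px[sel, , drop = FALSE]
    }
    km <- fit_kmeans(train_px, k = k, n_iter = kmeans_iter,
                     seed = seed + fold,
                     wavelengths = corrected[[fold]]$wavelengths)
    feats <- lapply(corrected, function(ffc) {
      extract_features(make_cluster_image(km, ffc), feat_config)
    })
    fcfg <- forest_cfg
    fcfg$seed <- as.integer(forest_cfg$seed + fold)
    forest <- train_forest(feats[train_idx],
                           lapply(scenes[train_idx], function(s) s$truth$labels),
                           config = fcfg, classes = 0:3,
                           invalid = lapply(corrected[train_idx],
                                            function(x) x$invalid))
    pred <- predict(forest, feats[[fold]])
    px <- pixel_metrics(pred, scenes[[fold]]$truth$labels,
                        invalid = corrected[[fold]]$invalid)
    ob <- object_metrics(object_classify(pred, scenes[[fold]]$truth$objects))
    folds[[fold]] <- list(pixel = px, object = ob)
    if (verbose) {
      message(sprintf("fold %d/%d: external recall %.3f, mean object recall %.3f",
                      fold, n, px$recall[px$class == 0], mean(ob$recall, na.rm = TRUE)))
    }
  }
  aggregate_loo(folds)
}

fold_stat <- function(folds, table, metric, cls) {
  vapply(folds, function(f) {
    tb <- f[[table]]
    tb[[metric]][tb$class == cls]
  }, numeric(1))
}

aggregate_loo <- function(folds) {
  metrics <- c("precision", "recall", "f05", "f1")
  agg <- function(table, classes) {
    do.call(rbind, lapply(classes, function(cl) {
      row <- data.frame(class = cl)
      for (m in metrics) {
        v <- fold_stat(folds, table, m, cl)
        row[[paste0(m, "_mean")]] <- mean(v, na.rm = TRUE)
        row[[paste0(m, "_sd")]] <- if (sum(!is.na(v)) > 1) sd(v, na.rm = TRUE) else 0
      }
      row
    }))
  }
  # per-fold average over the three cell classes (external excluded)
  cell_avg <- do.call(rbind, lapply(c("pixel", "object"), function(table) {
    do.call(rbind, lapply(metrics, function(m) {
      v <- vapply(folds, function(f) {
        tb <- f[[table]]
        mean(tb[[m]][tb$class %in% 1:3], na.rm = TRUE)
      }, numeric(1))
      data.frame(table = table, metric = m, mean = mean(v),
                 sd = if (length(v) > 1) sd(v) else 0)
    }))
  }))
  structure(list(folds = folds,
                 pixel = agg("pixel", 0:3),
                 object = agg("object", 1:3),
                 cell_average = cell_avg,
                 n_folds = length(folds)),
            class = "loo_report")
}

#' @export
print.loo_report <- function(x, ...) {
  cat(sprintf("loo_report over %d folds\n", x$n_folds))
  cat("pixel-wise (mean over folds):\n")
  print(x$pixel[, c("class", "precision_mean", "recall_mean", "f05_mean", "f1_mean")],
        row.names = FALSE, digits = 3)
  cat("object-wise (mean over folds):\n")
  print(x$object[, c("class", "precision_mean", "recall_mean", "f05_mean", "f1_mean")],
        row.names = FALSE, digits = 3)
  ca <- x$cell_average
  cat(sprintf("cell-class averages (excl. external): pixel F0.5 %.3f, object recall %.3f, object precision %.3f\n",
              ca$mean[ca$table == "pixel" & ca$metric == "f05"],
              ca$mean[ca$table == "object" & ca$metric == "recall"],
              ca$mean[ca$table == "object" & ca$metric == "precision"]))
  invisible(x)
}

#' Serialize / deserialize a LOO report as JSON
#'
#' @param report A `loo_report`.
#' @param path File path.
#' @return `write_loo_report` invisibly returns `path`; `read_loo_report`
#'   returns the report.
#' @export
write_loo_report <- function(report, path) {
  obj <- list(n_folds = report$n_folds,
              folds = lapply(report$folds, function(f)
                list(pixel = f$pixel, object = f$object)),
              pixel = report$pixel, object = report$object,
              cell_average = report$cell_average)
  writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17),
                              null = "null", dataframe = "columns"), path)
  invisible(path)
}

#' @rdname write_loo_report
#' @export
read_loo_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  df <- function(cols) {
    as.data.frame(lapply(cols, function(col) {
      unlist(lapply(col, function(v) if (is.null(v)) NA else v))
    }), stringsAsFactors = FALSE)
  }
  folds <- lapply(obj$folds, function(f) {
    list(pixel = df(f$pixel), object = df(f$object))
  })
  structure(list(folds = folds, pixel = df(obj$pixel), object = df(obj$object),
                 cell_average = df(obj$cell_average),
                 n_folds = obj$n_folds),
            class = "loo_report")
}
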