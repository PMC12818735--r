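#' Classifier specification for cross-age label transfer
#'
#' @param kind `"gradient_boosting"` (xgboost, the default),
#'   `"multinomial_logistic"` (ridge-penalized, glmnet), or
#'   `"nearest_centroid"` (fast deterministic baseline).
#' @param seed Integer seed; training and prediction are deterministic given
#'   it.
#' @param n_rounds Maximum boosting rounds; the actual number is chosen by
#'   `cv_folds`-fold cross-validation with early stopping.
#' @param regularization Ridge penalty (lambda) of the multinomial model.
#' @param cv_folds Cross-validation folds used to pick the boosting rounds.
#' @param max_depth,eta Tree depth and learning rate of the boosted trees.
#' @return A `classifier_spec` list.
#' @export
classifier_spec <- function(kind = c("gradient_boosting", "multinomial_logistic",
                                     "nearest_centroid"),
                            seed = 0, n_rounds = 30, regularization = 0.01,
                            cv_folds = 5, max_depth = 4, eta = 0.3) {
  kind <- match.arg(kind)
  structure(list(kind = kind, seed = as.integer(seed),
                 n_rounds = as.integer(n_rounds),
                 regularization = regularization,
                 cv_folds = as.integer(cv_folds),
                 max_depth = as.integer(max_depth), eta = eta),
            class = "classifier_spec")
}

#' Rand index between two partitions
#'
#' The pair-counting agreement `(a + b) / choose(n, 2)`, where `a` is the
#' number of element pairs co-clustered in both partitions and `b` the number
#' separated in both. Plain (unadjusted) Rand index: invariant to label
#' renaming, symmetric, in `[0, 1]`, and 1 exactly when the two label
#' vectors induce the same partition.
#'
#' @param a,b Label vectors of equal length >= 2 (any atomic type).
#' @return A single number in `[0, 1]`.
#' @export
rand_index <- function(a, b) {
  if (length(a) != length(b))
    stop("partitions must have equal length", call. = FALSE)
  if (length(a) < 2L)
    stop("partitions must contain at least 2 elements", call. = FALSE)
  ai <- match(a, unique(a)) - 1L
  bi <- match(b, unique(b)) - 1L
  ri_pair_cpp(ai, bi, max(ai) + 1L, max(bi) + 1L)
}

fit_predict <- function(x_train, y, x_test, spec) {
  labels <- levels(y)
  switch(spec$kind,
    gradient_boosting = {
      set.seed(spec$seed)
      params <- list(objective = "multi:softprob", num_class = length(labels),
                     max_depth = spec$max_depth, eta = spec$eta, nthread = 1,
                     seed = spec$seed)
      dtrain <- xgboost::xgb.DMatrix(x_train, label = as.integer(y) - 1L)
      cv <- xgboost::xgb.cv(params = params, data = dtrain,
                            nrounds = spec$n_rounds, nfold = spec$cv_folds,
                            early_stopping_rounds = 5, verbose = 0)
      best <- cv$early_stop$best_iteration
      if (is.null(best) || !length(best))
        best <- which.min(cv$evaluation_log$test_mlogloss_mean)
      fit <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = max(1L, best), verbose = 0)
      prob <- predict(fit, xgboost::xgb.DMatrix(x_test))  # n x num_class
      labels[max.col(prob, ties.method = "first")]
    },
    multinomial_logistic = {
      fit <- glmnet::glmnet(x_train, y, family = "multinomial", alpha = 0,
                            lambda = spec$regularization)
      as.character(predict(fit, x_test, type = "class")[, 1])
    },
    nearest_centroid = {
      cent <- vapply(labels, function(l)
        colMeans(x_train[y == l, , drop = FALSE]), numeric(ncol(x_train)))
      d2 <- outer(rowSums(x_test^2), rep(1, length(labels))) -
        2 * x_test %*% cent + outer(rep(1, nrow(x_test)), colSums(cent^2))
      labels[max.col(-d2, ties.method = "first")]
    })
}

#' Transfer subtype labels from one age to the next
#'
#' Trains the classifier on the normalized expression of the source (earlier)
#' age over the highly variable genes, then classifies every cell of the
#' target (later) age. The correspondence between true target labels and
#' transferred source labels is returned as a confusion matrix, the raw
#' material of the dynamic score and the Sankey map.
#'
#' @param source_norm,target_norm Normalized gene x cell expression matrices.
#' @param source_ann,target_ann Annotation data.frames (`cell_id`, `age`,
#'   `subtype`, `class`) matching the matrix columns.
#' @param spec A [classifier_spec()].
#' @param hvgs Feature genes; defaults to [select_hvgs()] on the source age
#'   (the training design). Genes absent from either matrix are dropped with
#'   a warning.
#' @return A `transfer_result` list: `source_age`, `target_age`, `predicted`
#'   and `true` label vectors (named by target cell id), and `confusion`
#'   (true target subtype x predicted source subtype cell counts).
#' @export
transfer_labels <- function(source_norm, source_ann, target_norm, target_ann,
                            spec = classifier_spec(), hvgs = NULL) {
  assert_count_matrix(source_norm, "source_norm")
  assert_count_matrix(target_norm, "target_norm")
  stopifnot(identical(colnames(source_norm), source_ann$cell_id),
            identical(colnames(target_norm), target_ann$cell_id))
  if (is.null(hvgs)) hvgs <- select_hvgs(source_norm)
  common <- intersect(intersect(hvgs, rownames(source_norm)), rownames(target_norm))
  if (length(common) < length(hvgs))
    warning(sprintf("%d of %d feature genes absent from source or target; using %d",
                    length(hvgs) - length(common), length(hvgs), length(common)),
            call. = FALSE)
  if (!length(common)) stop("no feature genes shared by source and target",
                            call. = FALSE)
  y <- factor(source_ann$subtype)
  if (nlevels(y) < 2L)
    stop("source age has a single subtype; nothing to learn", call. = FALSE)
  tab <- table(y)
  if (spec$kind == "gradient_boosting" && any(tab < spec$cv_folds))
    stop(sprintf("source subtype `%s` has %d cells, fewer than cv_folds = %d; use fewer folds",
                 names(tab)[which.min(tab)], min(tab), spec$cv_folds),
         call. = FALSE)
  x_train <- as.matrix(Matrix::t(source_norm[common, , drop = FALSE]))
  x_test <- as.matrix(Matrix::t(target_norm[common, , drop = FALSE]))
  predicted <- fit_predict(x_train, y, x_test, spec)
  names(predicted) <- target_ann$cell_id
  true <- stats::setNames(as.character(target_ann$subtype), target_ann$cell_id)
  confusion <- table(true = factor(true),
                     predicted = factor(predicted, levels = levels(y)))
  structure(list(source_age = as.character(unique(source_ann$age)),
                 target_age = as.character(unique(target_ann$age)),
                 predicted = predicted, true = true, confusion = confusion),
            class = "transfer_result")
}

#' Per-class dynamic scores across consecutive-age transfers
#'
#' For each age pair and each class, the target cells whose true class is
#' that class are restricted to, and the Rand index between their true
#' subtype partition and the partition induced by the transferred labels is
#' computed; the dynamic score is `1 - Rand index`, ranging from 0 (stable
#' transcriptomic identity across the pair) to 1 (complete reorganization).
#' Because the score compares partitions, it is invariant to renaming
#' subtypes between ages (an immature subtype relabelled with its mature name
#' scores identically). Per class, the mean and standard deviation across
#' pairs summarize the course, and classes are compared pairwise on their
#' per-pair scores.
#'
#' @param transfers List of [transfer_labels()] results over consecutive age
#'   pairs, in course order.
#' @param class_map Named character vector mapping subtype -> class.
#' @param comparison `"welch"` (two-sided Welch t-test on per-pair scores) or
#'   `"permutation"` (exact/two-sided Monte Carlo permutation of pair
#'   assignments).
#' @param n_perm Permutations when `comparison = "permutation"`.
#' @param seed Seed for the permutation test.
#' @return A `dynamics_result` list: `pairs` (per pair x class: `rand_index`,
#'   `dynamic_score`, `n_cells`, `missing` flag for classes with < 2 cells),
#'   `summary` (per class mean/sd across pairs), `comparisons` (class pairs
#'   with p-values).
#' @export
dynamic_scores <- function(transfers, class_map,
                           comparison = c("welch", "permutation"),
                           n_perm = 1000, seed = 0) {
  comparison <- match.arg(comparison)
  if (inherits(transfers, "transfer_result")) transfers <- list(transfers)
  rows <- list()
  for (tr in transfers) {
    pair <- paste0(tr$source_age, "-", tr$target_age)
    cls <- unname(class_map[tr$true])
    for (c in sort(unique(cls))) {
      idx <- which(cls == c)
      if (length(idx) < 2L) {
        rows[[length(rows) + 1L]] <- data.frame(
          pair = pair, class = c, n_cells = length(idx),
          rand_index = NA_real_, dynamic_score = NA_real_, missing = TRUE)
        next
      }
      ri <- rand_index(tr$true[idx], tr$predicted[idx])
      rows[[length(rows) + 1L]] <- data.frame(
        pair = pair, class = c, n_cells = length(idx),
        rand_index = ri, dynamic_score = 1 - ri, missing = FALSE)
    }
  }
  pairs <- do.call(rbind, rows)
  ok <- pairs[!pairs$missing, , drop = FALSE]
  classes <- sort(unique(pairs$class))
  summary <- do.call(rbind, lapply(classes, function(c) {
    s <- ok$dynamic_score[ok$class == c]
    data.frame(class = c, n_pairs = length(s),
               mean_score = if (length(s)) mean(s) else NA_real_,
               sd_score = if (length(s) > 1) stats::sd(s) else NA_real_)
  }))
  comp <- NULL
  if (length(classes) > 1L) {
    cmb <- utils::combn(classes, 2)
    comp <- do.call(rbind, lapply(seq_len(ncol(cmb)), function(i) {
      s1 <- ok$dynamic_score[ok$class == cmb[1, i]]
      s2 <- ok$dynamic_score[ok$class == cmb[2, i]]
      p <- compare_class_scores(s1, s2, comparison, n_perm, seed)
      data.frame(class_a = cmb[1, i], class_b = cmb[2, i],
                 mean_a = mean(s1), mean_b = mean(s2), p_value = p)
    }))
  }
  structure(list(pairs = pairs, summary = summary, comparisons = comp,
                 comparison = comparison),
            class = "dynamics_result")
}

compare_class_scores <- function(s1, s2, comparison, n_perm, seed) {
  if (length(s1) < 2L || length(s2) < 2L) return(NA_real_)
  if (comparison == "welch") {
    p <- tryCatch(stats::t.test(s1, s2)$p.value, error = function(e) NA_real_)
    return(p)
  }
  obs <- abs(mean(s1) - mean(s2))
  pooled <- c(s1, s2)
  n1 <- length(s1)
  set.seed(seed)
  more <- replicate(n_perm, {
    i <- sample.int(length(pooled), n1)
    abs(mean(pooled[i]) - mean(pooled[-i])) >= obs - 1e-12
  })
  (sum(more) + 1) / (n_perm + 1)
}

#' Sankey correspondence edges between consecutive ages
#'
#' One edge per (source subtype, target subtype) with `weight` = number of
#' target cells of that true subtype transferred to that source subtype, and
#' `similarity` = that count divided by the target subtype's size
#' (row-normalized confusion). With `floor = 0` the similarities of each
#' target subtype sum to 1.
#'
#' @param transfers List of [transfer_labels()] results (or a single one).
#' @param floor Edges with similarity below this are dropped (default 0.05,
#'   for readability of the diagram).
#' @return A data.frame with columns `source_age`, `target_age`,
#'   `source_subtype`, `target_subtype`, `weight`, `similarity`.
#' @export
sankey_edges <- function(transfers, floor = 0.05) {
  if (inherits(transfers, "transfer_result")) transfers <- list(transfers)
  out <- lapply(transfers, function(tr) {
    conf <- as.matrix(tr$confusion)
    sizes <- rowSums(conf)
    d <- expand.grid(target_subtype = rownames(conf),
                     source_subtype = colnames(conf),
                     stringsAsFactors = FALSE)
    d$weight <- as.vector(conf)
    d$similarity <- as.vector(conf / pmax(sizes, 1))
    d <- d[sizes[d$target_subtype] > 0, , drop = FALSE]
    d$source_age <- tr$source_age
    d$target_age <- tr$target_age
    d[, c("source_age", "target_age", "source_subtype", "target_subtype",
          "weight", "similarity")]
  })
  edges <- do.call(rbind, out)
  rownames(edges) <- NULL
  edges[edges$similarity >= floor | (floor == 0), , drop = FALSE]
}

#' @method print dynamics_result
#' @export
print.dynamics_result <- function(x, ...) {
  cat("Cross-age transcriptomic dynamics\n")
  cat(sprintf("  %d age pair(s), %d class(es)\n",
              length(unique(x$pairs$pair)), nrow(x$summary)))
  s <- x$summary[order(-x$summary$mean_score), ]
  for (i in seq_len(nrow(s)))
    cat(sprintf("  %-12s mean dynamic score %.3f (sd %s, %d pairs)\n",
                s$class[i], s$mean_score[i],
                ifelse(is.na(s$sd_score[i]), "NA", sprintf("%.3f", s$sd_score[i])),
                s$n_pairs[i]))
  invisible(x)
}
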