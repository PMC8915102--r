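#' Classifier specification with a hyperparameter grid
#'
#' Families and default lattices: SVM (kernel linear / gaussian /
#' polynomial degree 2, cost 0.1 / 1 / 10, gamma heuristic 1/p, 0.1, 1),
#' random forest (30 learning cycles), decision tree (Gini split criterion,
#' maximum splits 1 / 4 / 10) and LDA (linear or diagonal-linear
#' discriminant). The grid is searched by inner cross-validated accuracy;
#' ties break toward the first lattice point in declaration order.
#'
#' @param family one of `"svm"`, `"rf"`, `"dt"`, `"lda"`.
#' @param grid optional data frame of lattice points overriding the default.
#' @return a `classifier_spec`.
#' @export
classifier_spec <- function(family = c("svm", "rf", "dt", "lda"),
                            grid = NULL) {
  family <- match.arg(family)
  if (is.null(grid)) {
    grid <- switch(family,
      svm = rbind(
        expand.grid(kernel = "linear", cost = c(0.1, 1, 10), gamma = NA,
                    stringsAsFactors = FALSE),
        expand.grid(kernel = c("radial", "polynomial"), cost = c(0.1, 1, 10),
                    gamma = c(NA, 0.1, 1), stringsAsFactors = FALSE)),
      rf = data.frame(ntree = 30),
      dt = data.frame(max_splits = c(1, 4, 10)),
      lda = data.frame(type = c("linear", "diaglinear"),
                       stringsAsFactors = FALSE))
  }
  stopifnot(nrow(grid) >= 1)
  structure(list(family = family, grid = grid), class = "classifier_spec")
}

# Fit one lattice point. X standardized numeric matrix, y factor with levels
# c("benign", "malignant"). Returns an object usable by predict_scores().
fit_point <- function(family, point, X, y) {
  if (nlevels(droplevels(y)) < 2) stop("single-class training data")
  model <- switch(family,
    svm = {
      g <- if (is.na(point$gamma)) 1 / ncol(X) else point$gamma
      e1071::svm(X, y, kernel = point$kernel, cost = point$cost, gamma = g,
                 degree = 2, scale = FALSE, probability = FALSE)
    },
    rf = randomForest::randomForest(X, y, ntree = point$ntree),
    dt = fit_dt(X, y, point$max_splits),
    lda = if (point$type == "linear") MASS::lda(X, grouping = y)
          else fit_diaglda(X, y))
  list(family = family, type = if (family == "lda") point$type else NULL,
       model = model)
}

# Decision tree with Gini splitting, pruned back to at most max_splits splits
# using the complexity table.
fit_dt <- function(X, y, max_splits) {
  df <- data.frame(y = y, X, check.names = FALSE)
  fit <- rpart::rpart(y ~ ., df, method = "class",
                      parms = list(split = "gini"),
                      control = rpart::rpart.control(cp = 0, minsplit = 4,
                                                     xval = 0))
  cp <- fit$cptable
  ok <- cp[, "nsplit"] <= max_splits
  target <- max(cp[ok, "nsplit"])
  rpart::prune(fit, cp = cp[max(which(cp[, "nsplit"] == target)), "CP"] *
                 1.0000001)
}

# Diagonal-covariance LDA: class means with pooled per-feature variances.
fit_diaglda <- function(X, y) {
  lev <- levels(y)
  mu <- t(vapply(lev, function(g) colMeans(X[y == g, , drop = FALSE]),
                 numeric(ncol(X))))
  pooled <- colSums((X - mu[as.integer(y), , drop = FALSE])^2) /
    max(nrow(X) - length(lev), 1)
  pooled <- pmax(pooled, 1e-12)
  prior <- as.vector(table(y)) / length(y)
  list(levels = lev, mu = mu, var = pooled, prior = prior)
}

# Score = P(malignant) (or a monotone decision value); prediction at 0.5.
predict_scores <- function(fit, X) {
  lev <- c("benign", "malignant")
  switch(fit$family,
    svm = {
      pred <- stats::predict(fit$model, X, decision.values = TRUE)
      dv <- attr(pred, "decision.values")
      s <- as.vector(dv)
      # orient the decision value so larger = more malignant
      if (grepl("^malignant", colnames(dv)[1])) s <- -s
      list(score = -s, class = as.character(pred))
    },
    rf = {
      pr <- stats::predict(fit$model, X, type = "prob")[, "malignant"]
      list(score = pr, class = ifelse(pr > 0.5, "malignant", "benign"))
    },
    dt = {
      pr <- stats::predict(fit$model, data.frame(X, check.names = FALSE),
                           type = "prob")[, "malignant"]
      list(score = pr, class = ifelse(pr > 0.5, "malignant", "benign"))
    },
    lda = {
      if (fit$type == "linear") {
        pr <- stats::predict(fit$model, X)$posterior[, "malignant"]
      } else {
        m <- fit$model
        ll <- vapply(seq_along(m$levels), function(g)
          -0.5 * colSums((t(X) - m$mu[g, ])^2 / m$var) + log(m$prior[g]),
          numeric(nrow(X)))
        ll <- matrix(ll, nrow = nrow(X))
        pr <- 1 / (1 + exp(ll[, 1] - ll[, 2]))
      }
      list(score = pr, class = ifelse(pr > 0.5, "malignant", "benign"))
    })
}

#' Grid search over a classifier's hyperparameter lattice
#'
#' Inner stratified cross-validated accuracy selects the lattice point; ties
#' break toward the first point in declaration order. The winner is refit on
#' all the training data. A singleton lattice skips the inner loop.
#'
#' @param spec a [classifier_spec()].
#' @param X standardized training matrix.
#' @param y factor with levels benign / malignant.
#' @param inner_folds inner CV folds (default 5).
#' @return list with `fit` (refit winner) and `point` (chosen lattice row).
#' @export
grid_search <- function(spec, X, y, inner_folds = 5L) {
  if (nlevels(droplevels(y)) < 2) stop("single-class training data")
  grid <- spec$grid
  best <- 1L
  if (nrow(grid) > 1) {
    k <- min(inner_folds, min(table(y)))
    folds <- stratified_folds(as.integer(y), k)
    acc <- vapply(seq_len(nrow(grid)), function(g) {
      correct <- 0L
      for (f in seq_len(k)) {
        tr <- folds != f
        fit <- fit_point(spec$family, grid[g, , drop = FALSE],
                         X[tr, , drop = FALSE], droplevels(y[tr]))
        pr <- predict_scores(fit, X[!tr, , drop = FALSE])
        correct <- correct + sum(pr$class == as.character(y[!tr]))
      }
      correct / length(y)
    }, 0)
    best <- which.max(acc)                       # first max wins ties
  }
  list(fit = fit_point(spec$family, grid[best, , drop = FALSE], X, y),
       point = grid[best, , drop = FALSE])
}

#' ROC curve and AUC by threshold sweep
#'
#' Sweeps the unique score values from high to low; tied scores step
#' simultaneously. The area under the curve is the trapezoidal integral,
#' equal to the Mann-Whitney concordance probability.
#'
#' @param scores numeric vector, larger = more malignant.
#' @param labels vector with both classes present; positive class
#'   `"malignant"` (or 1).
#' @return a `roc_curve`: data frame `fpr`, `tpr`, plus attribute `auc`.
#' @export
roc_curve <- function(scores, labels) {
  pos <- labels == "malignant" | labels == 1
  if (!any(pos) || all(pos)) stop("both classes required for a ROC curve")
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- pos[ord]
  keep <- !duplicated(s, fromLast = TRUE)        # merge tied thresholds
  tpr <- c(0, cumsum(p)[keep] / sum(pos))
  fpr <- c(0, cumsum(!p)[keep] / sum(!pos))
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  structure(data.frame(fpr = fpr, tpr = tpr), auc = auc,
            class = c("roc_curve", "data.frame"))
}

#' Cross-validated evaluation of one classifier on one feature table
#'
#' Stratified 5-fold, 10-fold or leave-one-out cross-validation with
#' `repeats` repetitions (the LOO partition is fixed; repeats only capture
#' stochastic learners). Standardization parameters and, in strict mode, the
#' stepwise feature selection are fit on the training folds only. Held-out
#' predictions are pooled per repeat into confusion counts and a ROC curve;
#' the four metrics are reported as mean and SD over repeats, accuracy /
#' sensitivity / specificity in percent (malignant positive).
#'
#' @param table a `feature_table`.
#' @param spec a [classifier_spec()].
#' @param schema `"5fold"`, `"10fold"` or `"loo"`.
#' @param repeats repetitions (default 10).
#' @param seed RNG seed for fold assignment and stochastic learners.
#' @param folds optional fixed fold assignment (integer vector), overriding
#'   the schema's partition.
#' @param strict_selection optional significance threshold: when set, the
#'   stepwise selection is re-run inside every training fold (leakage-safe
#'   variant) instead of using the table as-is.
#' @return an `evaluation_report`.
#' @export
cross_validate <- function(table, spec, schema = c("5fold", "10fold", "loo"),
                           repeats = 10L, seed = 1L, folds = NULL,
                           strict_selection = NULL) {
  schema <- match.arg(schema)
  y <- factor(table$labels, levels = c("benign", "malignant"))
  n <- length(y)
  k <- switch(schema, "5fold" = 5L, "10fold" = 10L, "loo" = n)
  stopifnot(n >= k)
  set.seed(seed)
  loo_folds <- seq_len(n)
  per_rep <- vector("list", repeats)
  for (rep_i in seq_len(repeats)) {
    f <- if (!is.null(folds)) folds
         else if (schema == "loo") loo_folds
         else stratified_folds(as.integer(y), k)
    scores <- numeric(n); pred <- character(n)
    chosen <- list()
    for (fold in sort(unique(f))) {
      tr <- f != fold
      Xtr <- table$matrix[tr, , drop = FALSE]
      Xte <- table$matrix[!tr, , drop = FALSE]
      if (!is.null(strict_selection)) {
        sub <- structure(list(case_ids = table$case_ids[tr],
                              feature_names = table$feature_names,
                              matrix = Xtr, labels = table$labels[tr],
                              provenance = table$provenance),
                         class = "feature_table")
        sel <- stepwise_select(sub, strict_selection)
        keep <- match(sel$selected_names, table$feature_names)
        if (!length(keep)) keep <- seq_len(ncol(Xtr))   # fall back to all
        Xtr <- Xtr[, keep, drop = FALSE]
        Xte <- Xte[, keep, drop = FALSE]
      }
      mu <- colMeans(Xtr)
      sd_ <- apply(Xtr, 2, stats::sd)
      use <- sd_ > 0
      Xtr <- scale(Xtr[, use, drop = FALSE], mu[use], sd_[use])
      Xte <- scale(Xte[, use, drop = FALSE], mu[use], sd_[use])
      gs <- grid_search(spec, Xtr, droplevels(y[tr]))
      pr <- predict_scores(gs$fit, Xte)
      scores[!tr] <- pr$score
      pred[!tr] <- pr$class
      chosen[[length(chosen) + 1L]] <- gs$point
    }
    tp <- sum(pred == "malignant" & y == "malignant")
    tn <- sum(pred == "benign" & y == "benign")
    fp <- sum(pred == "malignant" & y == "benign")
    fn <- sum(pred == "benign" & y == "malignant")
    roc <- roc_curve(scores, as.character(y))
    per_rep[[rep_i]] <- list(
      confusion = c(TP = tp, TN = tn, FP = fp, FN = fn),
      accuracy = 100 * (tp + tn) / n,
      sensitivity = 100 * tp / (tp + fn),
      specificity = 100 * tn / (tn + fp),
      auc = attr(roc, "auc"),
      roc = roc, chosen = chosen)
  }
  metr <- function(nm) vapply(per_rep, `[[`, 0, nm)
  summ <- function(v) c(mean = mean(v), sd = if (repeats > 1) stats::sd(v) else 0)
  structure(list(
    schema = schema, family = spec$family, repeats = repeats,
    accuracy = summ(metr("accuracy")),
    sensitivity = summ(metr("sensitivity")),
    specificity = summ(metr("specificity")),
    auc = summ(metr("auc")),
    confusion = per_rep[[1]]$confusion,
    roc = per_rep[[1]]$roc,
    per_repeat = per_rep
  ), class = "evaluation_report")
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat(sprintf("<evaluation_report> %s, %s CV, %d repeats\n",
              toupper(x$family), x$schema, x$repeats))
  for (m in c("accuracy", "sensitivity", "specificity")) {
    cat(sprintf("  %-12s %6.2f%% +/- %.2f\n", m, x[[m]]["mean"],
                x[[m]]["sd"]))
  }
  cat(sprintf("  %-12s %6.4f  +/- %.4f\n", "AUC", x$auc["mean"],
              x$auc["sd"]))
  invisible(x)
}
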