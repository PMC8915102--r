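#' Bi-directional stepwise feature selection
#'
#' Starts from the empty model and alternates forward and backward phases on
#' a logistic regression of the binary label. The forward phase adds the
#' candidate with the smallest likelihood-ratio entry p-value if it is at or
#' below the significance threshold; the backward phase removes any included
#' feature whose removal p-value rises above the threshold (worst first).
#' Iteration stops when neither phase changes the model or after `max_steps`
#' actions. Features are z-scored internally; constant columns can never
#' enter. Ties on the p-value break toward the lowest column index, so the
#' procedure is deterministic.
#'
#' If a fit reaches quasi-perfect separation the deviance still converges
#' (toward 0) and the likelihood-ratio test remains usable; such steps are
#' flagged in the trace.
#'
#' @param table a `feature_table`.
#' @param threshold significance level ST in `(0, 1]` for both entry and
#'   removal (the two study settings are 0.05 and 0.1).
#' @param max_steps action cap (default twice the feature count).
#' @return a `selection_result`: `selected_names` (ordered), `trace`
#'   (data frame: step, action, feature, p_value, separation flag),
#'   `threshold`.
#' @export
stepwise_select <- function(table, threshold,
                            max_steps = 2L * length(table$feature_names)) {
  stopifnot(inherits(table, "feature_table"),
            threshold > 0, threshold <= 1)
  y <- as.integer(table$labels == "malignant")
  if (sum(y) < 2 || sum(1 - y) < 2)
    stop("need at least 2 cases per class")
  X <- scale(table$matrix)
  ok_col <- apply(is.finite(X), 2, all)          # constant columns -> NaN
  X[, !ok_col] <- 0
  nms <- table$feature_names
  p <- ncol(X)
  included <- integer(0)
  trace <- list()
  step <- 0L

  dev_of <- function(cols) {
    if (!length(cols)) {
      fit <- stats::glm.fit(matrix(1, length(y), 1), y,
                            family = stats::binomial())
    } else {
      fit <- suppressWarnings(
        stats::glm.fit(cbind(1, X[, cols, drop = FALSE]), y,
                       family = stats::binomial()))
    }
    list(dev = fit$deviance,
         sep = any(fit$fitted.values > 1 - 1e-8 | fit$fitted.values < 1e-8))
  }

  repeat {
    changed <- FALSE
    ## forward phase
    base <- dev_of(included)
    cand <- setdiff(which(ok_col), included)
    if (length(cand) && step < max_steps) {
      pv <- rep(NA_real_, length(cand))
      sep <- logical(length(cand))
      for (k in seq_along(cand)) {
        fit <- dev_of(c(included, cand[k]))
        lr <- max(base$dev - fit$dev, 0)
        pv[k] <- stats::pchisq(lr, df = 1, lower.tail = FALSE)
        sep[k] <- fit$sep
      }
      best <- which.min(pv)                      # ties -> lowest index
      if (pv[best] <= threshold) {
        included <- c(included, cand[best])
        step <- step + 1L
        trace[[step]] <- data.frame(step = step, action = "add",
                                    feature = nms[cand[best]],
                                    p_value = pv[best],
                                    separation = sep[best])
        changed <- TRUE
      }
    }
    ## backward phase: drop worst offenders until all significant
    repeat {
      if (length(included) == 0 || step >= max_steps) break
      full <- dev_of(included)
      pv <- vapply(seq_along(included), function(k) {
        red <- dev_of(included[-k])
        stats::pchisq(max(red$dev - full$dev, 0), df = 1, lower.tail = FALSE)
      }, 0)
      worst <- which.max(pv)
      if (pv[worst] > threshold) {
        step <- step + 1L
        trace[[step]] <- data.frame(step = step, action = "remove",
                                    feature = nms[included[worst]],
                                    p_value = pv[worst],
                                    separation = full$sep)
        included <- included[-worst]
        changed <- TRUE
      } else break
    }
    if (!changed || step >= max_steps) break
  }

  structure(list(
    selected_names = nms[included],
    trace = if (length(trace)) do.call(rbind, trace) else
      data.frame(step = integer(), action = character(),
                 feature = character(), p_value = numeric(),
                 separation = logical()),
    threshold = threshold
  ), class = "selection_result")
}

#' @export
print.selection_result <- function(x, ...) {
  cat("<selection_result> ST =", x$threshold, "->",
      length(x$selected_names), "features selected in",
      nrow(x$trace), "steps\n")
  invisible(x)
}

#' Persist a selection trace as JSON
#' @param result a `selection_result`.
#' @param path output path.
#' @export
write_selection <- function(result, path) {
  jsonlite::write_json(list(threshold = result$threshold,
                            selected = result$selected_names,
                            trace = result$trace),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
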