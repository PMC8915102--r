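#' Fuse functional, texture, shape and PSA features into one table
#'
#' Column-wise concatenation in the fixed order functional, texture, shape,
#' PSA; 122 + 58 + 85 + 1 = 266 columns under the default layouts. All inputs
#' must cover the identical case set; rows are aligned on the canonical
#' (sorted) case id order.
#'
#' @param functional,texture,shape numeric matrices (cases x features) with
#'   case ids as row names.
#' @param psa named numeric vector of PSA values (ng/mL), names = case ids.
#' @param labels named character vector, `"benign"` / `"malignant"`.
#' @return a `feature_table`: list with `case_ids`, `feature_names`,
#'   `matrix`, `labels`, `provenance`.
#' @export
integrate_features <- function(functional, texture, shape, psa, labels) {
  ids <- sort(rownames(functional))
  check <- function(x, what) {
    nm <- sort(if (is.matrix(x) || is.data.frame(x)) rownames(x) else names(x))
    if (!identical(nm, ids)) {
      bad <- c(setdiff(ids, nm), setdiff(nm, ids))
      stop("case sets differ for ", what, ": ",
           paste(utils::head(bad, 10), collapse = ", "))
    }
  }
  check(texture, "texture"); check(shape, "shape")
  check(psa, "psa"); check(labels, "labels")
  mat <- cbind(as.matrix(functional)[ids, , drop = FALSE],
               as.matrix(texture)[ids, , drop = FALSE],
               as.matrix(shape)[ids, , drop = FALSE],
               psa = unname(psa[ids]))
  if (anyNA(mat)) stop("feature table contains missing values")
  if (anyDuplicated(colnames(mat))) stop("feature names are not unique")
  prov <- c(rep("functional", ncol(functional)),
            rep("texture", ncol(texture)),
            rep("shape", ncol(shape)), "psa")
  structure(list(case_ids = ids, feature_names = colnames(mat),
                 matrix = mat, labels = unname(labels[ids]),
                 provenance = prov),
            class = "feature_table")
}

#' Extract the full fused feature table from a cohort
#'
#' Runs all three feature extractors on every case and fuses them with PSA.
#' The dataset-wide ADC range is estimated from the cohort itself unless a
#' previously persisted range is supplied.
#'
#' @param cohort list of `prostate_case` objects.
#' @param range optional `adc_range`; default: estimated from `cohort`.
#' @param layout a [functional_layout()].
#' @param ar an [ar_config()].
#' @param max_order SH expansion order.
#' @param max_vertices lesion mesh decimation target. The cohort-scale
#'   default (700) trades a little surface resolution for a large speed-up
#'   of the O(I^2) spherical relaxation and the nested SH fits; single-case
#'   analyses can raise it (the per-case functions default to 2000).
#' @param verbose print progress.
#' @return a `feature_table` (266 columns under the defaults).
#' @export
extract_feature_table <- function(cohort, range = NULL,
                                  layout = functional_layout(),
                                  ar = ar_config(), max_order = 85L,
                                  max_vertices = 700L,
                                  verbose = FALSE) {
  stopifnot(length(cohort) >= 1)
  if (is.null(range)) range <- estimate_global_range(cohort)
  ids <- vapply(cohort, `[[`, "", "case_id")
  fn <- t(vapply(cohort, functional_feature_vector,
                 FUN.VALUE = functional_feature_vector(cohort[[1]], range,
                                                       layout),
                 range = range, layout = layout))
  tx <- t(vapply(cohort, texture_feature_vector,
                 FUN.VALUE = texture_feature_vector(cohort[[1]])))
  sh <- matrix(NA_real_, length(cohort), max_order)
  for (i in seq_along(cohort)) {
    if (verbose) message("shape features: ", ids[i])
    sh[i, ] <- lesion_shape_features(cohort[[i]], config = ar,
                                     max_order = max_order,
                                     max_vertices = max_vertices)
  }
  colnames(sh) <- sprintf("sh_err_%02d", seq_len(max_order))
  rownames(fn) <- rownames(tx) <- rownames(sh) <- ids
  psa <- stats::setNames(vapply(cohort, `[[`, 0, "psa"), ids)
  labels <- stats::setNames(vapply(cohort, `[[`, "", "label"), ids)
  integrate_features(fn, tx, sh, psa, labels)
}

#' @export
print.feature_table <- function(x, ...) {
  cat("<feature_table>", length(x$case_ids), "cases x",
      length(x$feature_names), "features (",
      paste(table(x$provenance)[unique(x$provenance)],
            unique(x$provenance), collapse = " + "), ")\n")
  invisible(x)
}

#' Write / read a feature table as CSV
#'
#' @param table a `feature_table`.
#' @param path CSV path; the label is stored in a `label` column.
#' @export
write_feature_table <- function(table, path) {
  df <- data.frame(case_id = table$case_ids, label = table$labels,
                   table$matrix, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_table
#' @export
read_feature_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  mat <- as.matrix(df[, setdiff(names(df), c("case_id", "label")),
                      drop = FALSE])
  rownames(mat) <- df$case_id
  prov <- ifelse(grepl("^fn_", colnames(mat)), "functional",
          ifelse(grepl("^(fo_|glcm_|glrlm_)", colnames(mat)), "texture",
          ifelse(grepl("^sh_", colnames(mat)), "shape", "psa")))
  structure(list(case_ids = df$case_id, feature_names = colnames(mat),
                 matrix = mat, labels = df$label, provenance = prov),
            class = "feature_table")
}

#' Subset the columns of a feature table
#'
#' @param table a `feature_table`.
#' @param features character vector of feature names to keep.
#' @return a `feature_table` restricted to `features`.
#' @export
subset_features <- function(table, features) {
  stopifnot(all(features %in% table$feature_names))
  keep <- match(features, table$feature_names)
  structure(list(case_ids = table$case_ids, feature_names = features,
                 matrix = table$matrix[, keep, drop = FALSE],
                 labels = table$labels,
                 provenance = table$provenance[keep]),
            class = "feature_table")
}
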