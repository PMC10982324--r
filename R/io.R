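# File interfaces: the cohort CSV dialect, the JSON model file, and run
# configuration for the command-line wrapper.

#' Write a cohort to CSV
#'
#' One sample per row; feature columns first (original order), then the
#' reserved columns `label`, and `age`/`sex` when present. Missing entries
#' are written blank.
#'
#' @param cohort A [wdd_cohort()].
#' @param path Output file.
#' @export
write_cohort_csv <- function(cohort, path) {
  df <- as.data.frame(cohort$values, check.names = FALSE)
  df$label <- cohort$labels
  if (!is.null(cohort$age)) df$age <- cohort$age
  if (!is.null(cohort$sex)) df$sex <- cohort$sex
  utils::write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a cohort from CSV
#'
#' Expects a header row; the reserved columns are `label` (required, 0/1),
#' `age` and `sex` (optional). Every other column is a numeric feature,
#' order-preserving. Cells equal to a missing token (default blank or `NA`)
#' become missing entries.
#'
#' @param path CSV file.
#' @param missing_tokens Strings parsed as missing.
#' @return A [wdd_cohort()].
#' @export
read_cohort_csv <- function(path, missing_tokens = c("", "NA")) {
  df <- utils::read.csv(path, check.names = FALSE,
                        na.strings = missing_tokens,
                        stringsAsFactors = FALSE)
  if (!"label" %in% names(df)) stopf("missing required 'label' column")
  lab <- df$label
  bad <- which(!(lab %in% c(0, 1)) | is.na(lab))
  if (length(bad))
    stopf("invalid label value in row(s): %s (labels must be 0/1)",
          paste(utils::head(bad, 5), collapse = ", "))
  feat_cols <- setdiff(names(df), c("label", "age", "sex"))
  if (!length(feat_cols)) stopf("no feature columns found")
  for (cn in feat_cols) {
    col <- df[[cn]]
    if (!is.numeric(col)) {
      num <- suppressWarnings(as.numeric(col))
      bad <- which(!is.na(col) & is.na(num))
      if (length(bad))
        stopf("non-numeric value '%s' at row %d, column '%s'",
              col[bad[1]], bad[1], cn)
      df[[cn]] <- num
    }
  }
  wdd_cohort(as.matrix(df[, feat_cols, drop = FALSE]), as.integer(lab),
             age = if ("age" %in% names(df)) df$age else NULL,
             sex = if ("sex" %in% names(df)) df$sex else NULL,
             feature_names = feat_cols)
}

norm_to_list <- function(st) {
  if (is.null(st)) return(NULL)
  lapply(c("feature", "mu", "sigma", "q1", "q3", "lower_fence",
           "upper_fence", "kept"), function(f) st[[f]]) |>
    stats::setNames(c("feature", "mu", "sigma", "q1", "q3", "lower_fence",
                      "upper_fence", "kept"))
}

norm_from_list <- function(lst) {
  if (is.null(lst)) return(NULL)
  out <- data.frame(feature = unlist(lst$feature), mu = unlist(lst$mu),
                    sigma = unlist(lst$sigma), q1 = unlist(lst$q1),
                    q3 = unlist(lst$q3),
                    lower_fence = unlist(lst$lower_fence),
                    upper_fence = unlist(lst$upper_fence),
                    kept = unlist(lst$kept), stringsAsFactors = FALSE)
  class(out) <- c("wdd_norm", "data.frame")
  out
}

WDD_SCHEMA_VERSION <- "1.0"

#' Serialize a fitted WDD model to JSON
#'
#' The model file carries the variant, prototype, feature weights,
#' hyperparameters, decision threshold, feature names and the embedded
#' normalization statistics — everything needed for standalone prediction
#' with the missing-value-tolerant variants. KNN-variant files additionally
#' carry a flag that prediction-time missing values require an imputation
#' reference (the training matrix is not embedded in the file).
#'
#' @param model A fitted [wdd()] model.
#' @param path Output JSON file.
#' @export
write_model_json <- function(model, path) {
  stopifnot(inherits(model, "wdd"))
  obj <- list(
    schema_version = WDD_SCHEMA_VERSION,
    variant = model$variant,
    feature_names = model$feature_names,
    prototype = unname(model$prototype),
    weights = unname(model$weights),
    gamma = model$gamma, delta = model$delta, lambda = model$lambda,
    threshold = model$threshold, f = model$f,
    impute_k = model$control$impute_k,
    needs_imputation_reference = model$variant == "knn",
    norm = norm_to_list(model$norm),
    norm2 = norm_to_list(model$norm2))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", pretty = TRUE)
  invisible(path)
}

#' Load a WDD model from JSON
#'
#' @param path Model JSON file written by [write_model_json()].
#' @return A `wdd` model usable with [predict.wdd()]. KNN-variant models
#'   loaded from file refuse to predict samples with missing values (no
#'   imputation reference is stored in the file).
#' @export
read_model_json <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$schema_version, WDD_SCHEMA_VERSION))
    stopf("unknown model schema version: %s",
          obj$schema_version %||% "<absent>")
  fn <- unlist(obj$feature_names)
  model <- structure(list(
    variant = obj$variant,
    prototype = stats::setNames(unlist(obj$prototype), fn),
    weights = stats::setNames(unlist(obj$weights), fn),
    gamma = as.numeric(obj$gamma), delta = as.numeric(obj$delta),
    lambda = as.numeric(obj$lambda),
    threshold = as.numeric(obj$threshold), f = as.integer(obj$f),
    feature_names = fn,
    norm = norm_from_list(obj$norm),
    norm2 = norm_from_list(obj$norm2),
    control = wdd_control(impute_k = obj$impute_k %||% 15),
    impute_reference = NULL), class = "wdd")
  model
}

#' Read a run configuration (YAML or JSON)
#'
#' Validates the cross-field constraint that imputation is used exactly for
#' the KNN variant (the missing-value-tolerant variants never impute).
#'
#' @param path `.yaml`/`.yml` or `.json` file.
#' @return Named list of configuration values.
#' @export
read_run_config <- function(path) {
  cfg <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(cfg$impute) && !is.null(cfg$variant)) {
    if (isTRUE(cfg$impute) && cfg$variant != "knn")
      stopf("config error: impute = true is only valid with variant 'knn'")
    if (identical(cfg$impute, FALSE) && cfg$variant == "knn")
      stopf("config error: variant 'knn' requires impute = true")
  }
  cfg
}
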