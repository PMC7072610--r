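# Table readers/writers and the end-to-end analysis orchestration.

#' Read a sample-by-feature CSV table
#'
#' Expects a header row with `sample_id` as the first column and numeric
#' feature columns; empty cells become missing values (their count is
#' reported with a message). Duplicate sample ids and non-numeric cells are
#' errors.
#'
#' @param path CSV file path.
#' @return A tibble: `sample_id` (character) plus numeric feature columns.
#' @export
read_feature_table <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, na = c("", "NA"),
                        progress = FALSE)
  if (names(df)[1] != "sample_id") names(df)[1] <- "sample_id"
  df$sample_id <- as.character(df$sample_id)
  if (anyDuplicated(df$sample_id)) abort("duplicate sample_id values")
  feats <- setdiff(names(df), "sample_id")
  bad <- feats[!map_lgl(df[feats], is.numeric)]
  if (length(bad) > 0) {
    abort(sprintf("non-numeric feature column(s): %s",
                  paste(bad, collapse = ", ")))
  }
  n_missing <- sum(is.na(df[feats]))
  if (n_missing > 0) {
    inform(sprintf("%d missing value(s) in %s", n_missing, basename(path)))
  }
  df
}

#' Write a sample-by-feature table
#'
#' Inverse of [read_feature_table()]: comma-separated, UTF-8, header row,
#' missing values as empty cells (lossless round trip).
#'
#' @param x A tibble with a `sample_id` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path) {
  readr::write_csv(x, path, na = "")
  invisible(path)
}

#' Configuration for a full single-contrast analysis
#'
#' @param label Name of the metadata column defining the contrast.
#' @param positive Positive class label (the class sensitivity refers to).
#' @param n_pc Number of principal components, or `"auto"` to pick the
#'   smallest accuracy-maximizing count via [select_n_components()].
#' @param k kNN neighbor count.
#' @param n_perm Label permutations for the significance test.
#' @param candidates Candidate component counts when `n_pc = "auto"`.
#' @param fusion_pair Length-2 character vector of analyte names for the
#'   fusion model, or `NULL` to skip fusion.
#' @param fusion_method `"grid"` or `"lda"`.
#' @param top_loadings How many top-ranked loading bins to keep in the
#'   report.
#' @param seed Integer seed covering permutations (and any MCCV use).
#' @return A list of class `analysis_config`.
#' @export
analysis_config <- function(label, positive, n_pc = "auto", k = 5,
                            n_perm = 1000, candidates = 1:8,
                            fusion_pair = NULL, fusion_method = "grid",
                            top_loadings = 20, seed = 1) {
  if (!is.null(fusion_pair) && length(fusion_pair) != 2) {
    abort("`fusion_pair` must name exactly two analytes")
  }
  structure(
    list(label = label, positive = positive, n_pc = n_pc, k = k,
         n_perm = n_perm, candidates = candidates,
         fusion_pair = fusion_pair, fusion_method = fusion_method,
         top_loadings = top_loadings, seed = seed),
    class = "analysis_config"
  )
}

#' Run the full pipeline for one contrast
#'
#' Executes, for a single two-class contrast: total-integral normalization
#' of the binned matrix (if not already normalized), component selection
#' (optional), PCA-CA-kNN with LOOCV and the permutation significance test,
#' loading analysis of the first canonical component, univariate screening
#' of the analyte panel with BH correction, and (optionally) the
#' two-feature fusion model with its confusion summary.
#'
#' @param matrix A binned-matrix tibble (`sample_id` + bins), normalized or
#'   not.
#' @param meta Metadata tibble with `sample_id` and the contrast column.
#' @param config An [analysis_config()].
#' @param analytes Optional analyte tibble (`sample_id` + panel columns)
#'   for univariate screening and fusion.
#' @param out_dir Optional directory: when given, the report is written as
#'   `report.json` plus CSV tables, with the seed and config echoed.
#' @return A list of class `analysis_report` with elements `cv`,
#'   `permutation`, `loadings`, `markers` (or `NULL`), `fusion` (or
#'   `NULL`), `n_pc`, `config`.
#' @export
run_full_analysis <- function(matrix, meta, config, analytes = NULL,
                              out_dir = NULL) {
  stopifnot(inherits(config, "analysis_config"))
  stopifnot(config$label %in% names(meta))
  ids <- matrix$sample_id
  meta <- meta[match(ids, meta$sample_id), ]
  labels <- droplevels(factor(meta[[config$label]]))
  if (nlevels(labels) != 2) abort("contrast must have exactly two classes")
  if (any(table(labels) < 3)) {
    abort(sprintf("contrast class with < 3 samples in '%s'", config$label))
  }
  if (!config$positive %in% levels(labels)) {
    abort("positive class not present in the contrast column")
  }
  if (!is_normalized(matrix)) matrix <- total_integral_normalize(matrix)
  x <- as.matrix(matrix[feature_cols(matrix)])
  rownames(x) <- ids

  n_pc <- config$n_pc
  if (identical(n_pc, "auto")) {
    n_pc <- as.integer(select_n_components(
      x, labels, k = config$k,
      candidates = config$candidates[config$candidates <= min(nrow(x) - 2L, ncol(x))],
      positive = config$positive))
  }
  perm <- permutation_test(x, labels, n_pc = n_pc, k = config$k,
                           n_perm = config$n_perm, seed = config$seed,
                           positive = config$positive)
  model <- fit_pcaca_knn(x, labels, n_pc = n_pc, k = min(config$k, nrow(x)),
                         positive = config$positive)
  loadings <- loading_analysis(model, x, labels)

  markers <- NULL
  fusion <- NULL
  if (!is.null(analytes)) {
    markers <- screen_markers(analytes, meta, config$label, config$positive)
    if (!is.null(config$fusion_pair)) {
      missing_pair <- setdiff(config$fusion_pair, names(analytes))
      if (length(missing_pair) > 0) {
        abort(sprintf("fusion analyte(s) not in panel: %s",
                      paste(missing_pair, collapse = ", ")))
      }
      dat <- left_join(analytes, meta[c("sample_id", config$label)],
                       by = "sample_id")
      fusion_model <- fit_linear_combo(dat, config$fusion_pair,
                                       config$label, config$positive,
                                       method = config$fusion_method)
      scored <- score_linear_combo(fusion_model, dat)
      conf <- confusion(
        scored$pred[!is.na(scored$pred)],
        dat[[config$label]][!is.na(scored$pred)],
        config$positive
      )
      fusion <- list(model = fusion_model, scores = scored,
                     confusion = conf)
    }
  } else if (!is.null(config$fusion_pair)) {
    abort("fusion requested but no analyte panel supplied")
  }

  report <- structure(
    list(cv = perm$cv_report, permutation = perm, loadings = loadings,
         markers = markers, fusion = fusion, n_pc = n_pc, config = config),
    class = "analysis_report"
  )
  if (!is.null(out_dir)) write_analysis_report(report, out_dir)
  report
}

#' @export
print.analysis_report <- function(x, ...) {
  cat(sprintf("<analysis_report> contrast '%s' (positive = %s), n_pc = %d\n",
              x$config$label, x$config$positive, x$n_pc))
  print(x$cv)
  cat(sprintf("  permutation p = %.4g (%d permutations)\n",
              x$permutation$p_value, x$permutation$n_perm))
  if (!is.null(x$markers)) {
    cat(sprintf("  %d analytes screened; top: %s (q = %.3g)\n",
                nrow(x$markers), x$markers$feature[1], x$markers$q_value[1]))
  }
  if (!is.null(x$fusion)) print(x$fusion$model)
  invisible(x)
}

#' Write an analysis report bundle
#'
#' Serializes an [run_full_analysis()] report as `report.json` (metrics,
#' permutation summary, fusion model, seed and config echo, package
#' version) plus `loadings.csv`, `markers.csv` and `cv_predictions.csv`.
#'
#' @param report An `analysis_report`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_analysis_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(report$loadings, file.path(dir, "loadings.csv"), na = "")
  readr::write_csv(report$cv$per_sample, file.path(dir, "cv_predictions.csv"),
                   na = "")
  if (!is.null(report$markers)) {
    readr::write_csv(report$markers, file.path(dir, "markers.csv"), na = "")
  }
  js <- list(
    package_version = as.character(utils::packageVersion("immunometab")),
    config = unclass(report$config),
    n_pc = report$n_pc,
    cv = list(scheme = report$cv$scheme,
              sensitivity = report$cv$sensitivity,
              specificity = report$cv$specificity,
              accuracy = report$cv$accuracy,
              positive = report$cv$positive),
    permutation = list(observed_accuracy = report$permutation$observed_accuracy,
                       p_value = report$permutation$p_value,
                       n_perm = report$permutation$n_perm,
                       seed = report$permutation$seed),
    top_loadings = head(report$loadings, report$config$top_loadings)
  )
  if (!is.null(report$fusion)) {
    m <- report$fusion$model
    js$fusion <- list(features = m$features, weights = m$weights,
                      sign = m$sign, threshold = m$threshold,
                      method = m$method, auroc_resubstitution = m$auroc,
                      auroc_loocv = m$cv_auroc,
                      confusion = report$fusion$confusion)
  }
  jsonlite::write_json(js, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       dataframe = "rows")
  invisible(dir)
}
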