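# Reading and writing the plain-text artifacts: sample x feature tables
# (TSV/CSV), selection traces, IFS curves and metrics reports.

infer_sep <- function(path) {
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a feature matrix from TSV/CSV
#'
#' Canonical orientation is samples-as-rows with a header row and a label
#' column. GISTIC-style genes-as-rows tables (first column = gene ids,
#' remaining columns = samples) are supported via
#' `orientation = "genes"` together with an external label file holding
#' one label per sample in column order. The delimiter is inferred from
#' the extension (`.csv` comma, anything else tab).
#'
#' @param path Input file.
#' @param label_column Name of the label column (samples-as-rows only);
#'   default `"class"`.
#' @param orientation `"samples"` (default) or `"genes"`.
#' @param label_file Path to a text file with one label per line
#'   (required for `orientation = "genes"`).
#' @return A [feature_matrix()].
#' @export
read_matrix <- function(path, label_column = "class",
                        orientation = c("samples", "genes"),
                        label_file = NULL) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop("input file not found: ", path, call. = FALSE)
  }
  sep <- infer_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (orientation == "samples") {
    if (!(label_column %in% names(df))) {
      stop("label column '", label_column, "' not found in ", path,
           " (columns: ", paste(utils::head(names(df), 8), collapse = ", "),
           if (ncol(df) > 8) ", ..." else "", ")", call. = FALSE)
    }
    labels <- df[[label_column]]
    feats <- df[, setdiff(names(df), label_column), drop = FALSE]
    check_numeric_cells(feats, path)
    feature_matrix(as.matrix(feats), labels = labels,
                   feature_ids = names(feats))
  } else {
    if (is.null(label_file)) {
      stop("orientation = 'genes' requires 'label_file' (one label per ",
           "sample, in sample-column order)", call. = FALSE)
    }
    ids <- as.character(df[[1L]])
    feats <- df[, -1L, drop = FALSE]
    check_numeric_cells(feats, path)
    values <- t(as.matrix(feats))
    labels <- scan(label_file, what = character(), quiet = TRUE)
    if (length(labels) != nrow(values)) {
      stop("label file has ", length(labels), " labels but the matrix has ",
           nrow(values), " samples", call. = FALSE)
    }
    # keep numeric labels numeric so round-trips are faithful
    if (!anyNA(suppressWarnings(as.numeric(labels)))) {
      labels <- as.numeric(labels)
    }
    rownames(values) <- NULL
    feature_matrix(values, labels = labels, feature_ids = ids)
  }
}

check_numeric_cells <- function(df, path) {
  for (j in seq_along(df)) {
    if (!is.numeric(df[[j]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[j]]))))[1L]
      stop("non-numeric cell in ", path, " at row ",
           if (is.na(bad)) "?" else bad, ", column '", names(df)[j], "'",
           call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a feature matrix as TSV/CSV
#'
#' Samples-as-rows with the label in a final column, so that
#' `read_matrix(write_matrix(fm, path))` round-trips values, feature ids
#' and labels.
#'
#' @param fm A [feature_matrix()].
#' @param path Output file (`.csv` writes commas, anything else tabs).
#' @param label_column Name for the label column.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(fm, path, label_column = "class") {
  stopifnot(inherits(fm, "feature_matrix"))
  df <- as.data.frame(fm$values, check.names = FALSE)
  df[[label_column]] <- fm$labels
  utils::write.table(df, path, sep = infer_sep(path), quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

format_num <- function(x) {
  ifelse(is.na(x),
         "NA",
         trimws(formatC(signif(x, 6), format = "g", digits = 6)))
}

#' Write a selection trace as TSV
#'
#' Columns `rank`, `feature_id`, `score`, `relevance`, `redundancy`,
#' `interaction_factor`; numbers are formatted with 6 significant digits.
#'
#' @param trace A `selection_trace` from [cria_select()]/[greedy_select()].
#' @param path Output TSV file.
#' @return `path`, invisibly.
#' @export
write_trace <- function(trace, path) {
  stopifnot(inherits(trace, "selection_trace"))
  df <- as.data.frame(trace)
  for (col in c("score", "relevance", "redundancy", "interaction_factor")) {
    df[[col]] <- format_num(df[[col]])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a selection trace written by [write_trace()]
#'
#' @param path Trace TSV file.
#' @return A data frame with the trace columns (scores at the 6
#'   significant digits stored in the file).
#' @export
read_trace <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE,
                    colClasses = c(rank = "integer", feature_id = "character",
                                   score = "numeric", relevance = "numeric",
                                   redundancy = "numeric",
                                   interaction_factor = "numeric"))
}

#' Write an IFS curve (TSV + JSON summary)
#'
#' @param curve An `ifs_curve` from [ifs_curve()].
#' @param tsv_path Output TSV (`k`, `mean_accuracy`).
#' @param json_path Optional JSON summary (`optimal_k`,
#'   `accuracy_at_optimal`, classifier and protocol).
#' @return `tsv_path`, invisibly.
#' @export
write_ifs_curve <- function(curve, tsv_path, json_path = NULL) {
  stopifnot(inherits(curve, "ifs_curve"))
  df <- data.frame(k = curve$k, mean_accuracy = format_num(curve$accuracy))
  utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  if (!is.null(json_path)) {
    jsonlite::write_json(
      list(optimal_k = attr(curve, "optimal_k"),
           accuracy_at_optimal = attr(curve, "accuracy_at_optimal"),
           classifier = attr(curve, "classifier"),
           k_folds = attr(curve, "k_folds"),
           n_repeats = attr(curve, "n_repeats"),
           seed = attr(curve, "seed")),
      json_path, auto_unbox = TRUE, digits = NA)
  }
  invisible(tsv_path)
}

#' Write a metrics report as JSON
#'
#' @param report A `metrics_report` from [class_metrics()] or
#'   [cross_validate()].
#' @param path Output JSON file.
#' @return `path`, invisibly.
#' @export
write_metrics_report <- function(report, path) {
  stopifnot(inherits(report, "metrics_report"))
  out <- list(
    accuracy = report$accuracy,
    macro = list(precision = report$macro_precision,
                 recall = report$macro_recall,
                 f1 = report$macro_f1),
    per_class = report$per_class,
    confusion = list(classes = rownames(report$confusion),
                     counts = unclass(report$confusion)))
  if (!is.null(report$run_accuracies)) {
    out$runs <- list(accuracies = report$run_accuracies,
                     mean = report$mean_accuracy,
                     std = report$std_accuracy)
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows", matrix = "rowmajor")
  invisible(path)
}
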