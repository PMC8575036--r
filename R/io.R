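#' Read a design matrix
#'
#' Dense TSV/CSV files must carry a header row whose first field names the
#' sample-id column and whose remaining fields are unique variable ids;
#' each data row is a sample id followed by numeric values.  Parse errors
#' (ragged rows, non-numeric cells, duplicate ids) name the offending
#' line.  MatrixMarket coordinate files (`format = "mtx"`) are read with
#' [Matrix::readMM()] and take their ids from the sidecar text files
#' `<path>.rows` (sample ids) and `<path>.cols` (variable ids), one id per
#' line; explicit zeros are collapsed.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"tsv"`, `"csv"` or `"mtx"`.
#' @return list with `X` (matrix, sparse for mtx), `variable_ids`,
#'   `sample_ids`.
#' @export
read_design_matrix <- function(path, format = c("auto", "tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  if (format == "auto") {
    format <- switch(tolower(tools::file_ext(path)),
                     mtx = "mtx", csv = "csv", "tsv")
  }
  if (format == "mtx") {
    X <- as(Matrix::drop0(Matrix::readMM(path)), "CsparseMatrix")
    rows_f <- paste0(path, ".rows")
    cols_f <- paste0(path, ".cols")
    for (f in c(rows_f, cols_f)) {
      if (!file.exists(f)) {
        stop(sprintf("missing sidecar id file: %s", f), call. = FALSE)
      }
    }
    sample_ids <- readLines(rows_f)
    variable_ids <- readLines(cols_f)
    if (length(sample_ids) != nrow(X) || length(variable_ids) != ncol(X)) {
      stop("sidecar id counts do not match the matrix dimensions",
           call. = FALSE)
    }
    .check_ids(variable_ids, "variable")
    .check_ids(sample_ids, "sample")
    return(list(X = X, variable_ids = variable_ids, sample_ids = sample_ids))
  }

  sep <- if (format == "csv") "," else "\t"
  lines <- readLines(path)
  if (length(lines) < 2L) {
    stop("matrix file needs a header and at least one data row",
         call. = FALSE)
  }
  header <- strsplit(lines[1L], sep, fixed = TRUE)[[1L]]
  variable_ids <- header[-1L]
  .check_ids(variable_ids, "variable")
  p <- length(variable_ids)
  n <- length(lines) - 1L
  X <- matrix(NA_real_, n, p)
  sample_ids <- character(n)
  for (i in seq_len(n)) {
    f <- strsplit(lines[i + 1L], sep, fixed = TRUE)[[1L]]
    if (length(f) != p + 1L) {
      stop(sprintf("line %d: expected %d fields, found %d",
                   i + 1L, p + 1L, length(f)), call. = FALSE)
    }
    sample_ids[i] <- f[1L]
    v <- suppressWarnings(as.numeric(f[-1L]))
    if (anyNA(v)) {
      stop(sprintf("line %d: non-numeric value '%s'",
                   i + 1L, f[-1L][which(is.na(v))[1L]]), call. = FALSE)
    }
    X[i, ] <- v
  }
  .check_ids(sample_ids, "sample")
  list(X = X, variable_ids = variable_ids, sample_ids = sample_ids)
}

.check_ids <- function(ids, what) {
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate %s id: '%s'", what, ids[duplicated(ids)][1L]),
         call. = FALSE)
  }
  invisible(ids)
}

#' Write a design matrix
#'
#' Inverse of [read_design_matrix()]; `"mtx"` writes the MatrixMarket file
#' plus the `.rows`/`.cols` sidecar id files.
#'
#' @param X numeric matrix (dense or sparse).
#' @param variable_ids,sample_ids id vectors matching the dimensions.
#' @param path output path.
#' @param format `"tsv"`, `"csv"` or `"mtx"`.
#' @return `path`, invisibly.
#' @export
write_design_matrix <- function(X, variable_ids, sample_ids, path,
                                format = c("tsv", "csv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    Matrix::writeMM(as(as(Matrix::Matrix(X, sparse = TRUE), "generalMatrix"),
                       "CsparseMatrix"), path)
    writeLines(as.character(sample_ids), paste0(path, ".rows"))
    writeLines(as.character(variable_ids), paste0(path, ".cols"))
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(c("sample_id", variable_ids), collapse = sep), con)
  body <- apply(as.matrix(X), 1L, function(r)
    paste(sprintf("%.10g", r), collapse = sep))
  writeLines(paste(sample_ids, body, sep = sep), con)
  invisible(path)
}

#' Read and align an outcome file
#'
#' Logistic outcomes are TSV with header `sample_id<TAB>label`
#' (labels in \{0, 1\}); Cox outcomes have header
#' `sample_id<TAB>time<TAB>event` with strictly positive times and 0/1
#' event indicators.  `align_outcome()` joins by sample id so file row
#' order never matters; unmatched ids are an error.
#'
#' @param path outcome file path.
#' @param model `"logistic"` or `"cox"`.
#' @return data frame with `sample_id` plus `label` or `time`/`event`.
#' @export
read_outcome <- function(path, model = c("logistic", "cox")) {
  model <- match.arg(model)
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = c(sample_id = "character"),
                          check.names = FALSE)
  need <- if (model == "logistic") c("sample_id", "label")
          else c("sample_id", "time", "event")
  if (!all(need %in% names(df))) {
    stop(sprintf("outcome file must have columns: %s",
                 paste(need, collapse = ", ")), call. = FALSE)
  }
  .check_ids(df$sample_id, "sample")
  if (model == "logistic") {
    if (anyNA(df$label) || !all(df$label %in% c(0, 1))) {
      stop("labels must be 0/1", call. = FALSE)
    }
  } else {
    if (anyNA(df$time) || any(df$time <= 0)) {
      stop("times must be strictly positive", call. = FALSE)
    }
    if (anyNA(df$event) || !all(df$event %in% c(0, 1))) {
      stop("event indicators must be 0/1", call. = FALSE)
    }
  }
  df[need]
}

#' @rdname read_outcome
#' @param outcome data frame from `read_outcome()`.
#' @param sample_ids sample ids of the design matrix, in matrix row order.
#' @export
align_outcome <- function(outcome, sample_ids) {
  idx <- match(sample_ids, outcome$sample_id)
  if (anyNA(idx)) {
    stop(sprintf("sample '%s' has no outcome row",
                 sample_ids[which(is.na(idx))[1L]]), call. = FALSE)
  }
  extra <- setdiff(outcome$sample_id, sample_ids)
  if (length(extra)) {
    stop(sprintf("outcome sample '%s' is absent from the matrix", extra[1L]),
         call. = FALSE)
  }
  outcome[idx, , drop = FALSE]
}

#' Read a group-membership file
#'
#' Two-column TSV with header `variable_id<TAB>group_id`; a variable id
#' repeated under several group ids encodes overlap.
#'
#' @param path file path.
#' @return data frame with character columns `variable_id`, `group_id`.
#' @export
read_group_memberships <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: %s", path), call. = FALSE)
  }
  df <- utils::read.delim(path, colClasses = "character",
                          check.names = FALSE)
  if (!all(c("variable_id", "group_id") %in% names(df))) {
    stop("group file must have columns variable_id, group_id",
         call. = FALSE)
  }
  df[c("variable_id", "group_id")]
}

#' Column standardization
#'
#' Centers each column to mean zero and scales to unit standard deviation
#' with the population convention (divisor `n`).  Zero-variance columns
#' are centered only; their scale is recorded as 1 and a warning is
#' emitted.  Applying the transformation twice equals applying it once.
#'
#' @param X numeric matrix.
#' @param flag if `FALSE`, return `X` unchanged with centers 0, scales 1.
#' @return list with `X` (transformed), `centers`, `scales`.
#' @export
standardize_columns <- function(X, flag = TRUE) {
  X <- as.matrix(X)
  if (!flag) {
    return(list(X = X, centers = rep(0, ncol(X)), scales = rep(1, ncol(X))))
  }
  centers <- colMeans(X)
  Xc <- sweep(X, 2L, centers, "-")
  scales <- sqrt(colMeans(Xc^2))   # divisor n
  zero <- scales == 0
  if (any(zero)) {
    warning(sprintf("%d zero-variance column(s) centered but not scaled",
                    sum(zero)), call. = FALSE)
    scales[zero] <- 1
  }
  list(X = sweep(Xc, 2L, scales, "/"), centers = centers, scales = scales)
}

#' Write fitted coefficients / a path table
#'
#' `write_fit()` writes one row per latent coordinate — so a variable
#' shared by two groups appears once per group, and its latent entries sum
#' to the collapsed coefficient — with columns `variable_id`, `group_id`,
#' `latent_coefficient`, `collapsed_coefficient` (plus
#' `collapsed_original` when `beta_original` is supplied, i.e. when the
#' model was fitted on standardized columns).  `write_path()` writes one
#' row per penalty in grid order with the cross-validation summary columns
#' when present.  Floating-point values are printed with 10 significant
#' digits; row order is deterministic.
#'
#' @param fit a [fit_pgd()] result.
#' @param gs the [group_structure()] the fit used.
#' @param path output file path.
#' @param variable_ids optional variable ids (default `V1..Vp`).
#' @param beta_original optional coefficients back-transformed to the
#'   original column scale.
#' @return `path`, invisibly.
#' @export
write_fit <- function(fit, gs, path, variable_ids = NULL,
                      beta_original = NULL) {
  stopifnot(inherits(fit, "pgd_fit"), inherits(gs, "group_structure"))
  variable_ids <- variable_ids %||% paste0("V", seq_len(gs$p))
  vidx <- unlist(gs$groups, use.names = FALSE)
  df <- data.frame(
    variable_id = variable_ids[vidx],
    group_id = names(gs$groups)[gs$block],
    latent_coefficient = sprintf("%.10g", fit$gamma),
    collapsed_coefficient = sprintf("%.10g", fit$beta[vidx]),
    stringsAsFactors = FALSE)
  if (!is.null(beta_original)) {
    df$collapsed_original <- sprintf("%.10g", beta_original[vidx])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_fit
#' @param path_result an `"og_path"` from [fit_path()] or
#'   [cross_validate()].
#' @param file output file path.
#' @export
write_path <- function(path_result, file) {
  stopifnot(inherits(path_result, "og_path"))
  cv <- path_result$cv_table
  df <- data.frame(
    lambda = sprintf("%.10g", path_result$lambdas),
    metric_mean = if (is.null(cv)) NA else sprintf("%.10g", cv$metric_mean),
    metric_se = if (is.null(cv)) NA else sprintf("%.10g", cv$metric_se),
    n_groups_selected = path_result$n_groups_selected,
    n_nonzero = path_result$n_nonzero,
    stringsAsFactors = FALSE)
  utils::write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
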