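MODEL_FORMAT_VERSION <- "lucck-model/1"

# Doubles are serialized as %.17g strings: 17 significant digits are
# guaranteed to round-trip binary64 exactly through as.numeric().
num2str <- function(x) sprintf("%.17g", x)
str2num <- function(s) as.numeric(s)

#' Write a fitted model to JSON
#'
#' Serializes the full instance-based model — training matrix, labels,
#' per-feature statistics and kernel parameters, hyperparameters, and any
#' class weights — to a single JSON document. Floating-point values are
#' stored as 17-significant-digit decimal strings, so
#' `read_lucck(write_lucck(m, f))` reproduces `m` bit for bit.
#'
#' @param model A fitted [lucck] model.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_lucck <- function(model, path) {
  stopifnot(inherits(model, "lucck"))
  doc <- list(
    format = MODEL_FORMAT_VERSION,
    n_samples = nrow(model$x),
    n_features = ncol(model$x),
    feature_names = model$feature_names,
    levels = model$levels,
    class_ids = model$class_ids,
    x = apply(model$x, 2L, num2str, simplify = FALSE),
    stds = num2str(model$stds),
    lambdas = num2str(model$params$lambdas),
    alphas = num2str(model$alphas),
    thetas = num2str(model$params$thetas),
    constant = model$constant,
    capital_lambda = num2str(model$params$capital_lambda),
    capital_theta = num2str(model$params$capital_theta),
    std_convention = model$std_convention,
    class_weights = if (is.null(model$class_weights)) NULL
                    else num2str(model$class_weights))
  jsonlite::write_json(doc, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' Read a model written by [write_lucck]
#'
#' @param path Path to a model JSON file.
#' @return A [lucck] model object.
#' @export
read_lucck <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, MODEL_FORMAT_VERSION)) {
    stop(sprintf("unrecognized model format '%s' (expected '%s')",
                 doc$format %||% "<missing>", MODEL_FORMAT_VERSION))
  }
  X <- vapply(doc$x, str2num, numeric(doc$n_samples))
  dimnames(X) <- list(NULL, doc$feature_names)
  params <- kernel_params(str2num(doc$lambdas), str2num(doc$thetas),
                          str2num(doc$capital_lambda),
                          str2num(doc$capital_theta))
  structure(
    list(x = X,
         class_ids = as.integer(doc$class_ids),
         levels = doc$levels,
         class_sizes = tabulate(as.integer(doc$class_ids),
                                nbins = length(doc$levels)),
         params = params,
         alphas = str2num(doc$alphas),
         stds = str2num(doc$stds),
         constant = as.logical(doc$constant),
         std_convention = doc$std_convention,
         class_weights = if (is.null(doc$class_weights)) NULL
                         else str2num(doc$class_weights),
         feature_names = doc$feature_names),
    class = "lucck")
}

#' Read a feature table from CSV
#'
#' Expects a header row, one numeric feature column per feature, a label
#' column, and optionally a group column. Missing values anywhere in the
#' used columns are rejected with an error naming the columns.
#'
#' @param path CSV file path.
#' @param label Name of the label column.
#' @param group Optional name of the group/subject column.
#' @return List with `x` (numeric matrix), `labels`, `groups` (or NULL),
#'   and `feature_names`.
#' @export
read_feature_csv <- function(path, label, group = NULL) {
  df <- read.csv(path, check.names = FALSE)
  for (col in c(label, group)) {
    if (!col %in% names(df)) {
      stop(sprintf("column '%s' not found in %s", col, path))
    }
  }
  feat_cols <- setdiff(names(df), c(label, group))
  if (!length(feat_cols)) stop("no feature columns found")
  bad <- feat_cols[vapply(df[feat_cols],
                          function(v) anyNA(suppressWarnings(as.numeric(v))),
                          logical(1))]
  if (anyNA(df[[label]])) bad <- c(label, bad)
  if (length(bad)) {
    stop(sprintf("missing or non-numeric values in column(s): %s",
                 paste(bad, collapse = ", ")))
  }
  X <- as.matrix(as.data.frame(lapply(df[feat_cols], as.numeric)))
  colnames(X) <- feat_cols
  list(x = X, labels = df[[label]],
       groups = if (is.null(group)) NULL else df[[group]],
       feature_names = feat_cols)
}
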