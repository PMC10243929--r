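#' Construct a validated abundance matrix
#'
#' An abundance matrix is a non-negative numeric matrix of features (rows) by
#' samples (columns), with unique feature and sample identifiers stored as
#' dimnames. This is the canonical container for one modality's composition
#' profile (e.g. bacterial 16S, fungal ITS, or viral abundances).
#'
#' @param values Numeric matrix, features x samples, all entries >= 0.
#' @param feature_ids Character vector of unique row identifiers. Defaults to
#'   existing rownames.
#' @param sample_ids Character vector of unique column identifiers. Defaults to
#'   existing colnames.
#' @return A numeric matrix with class `c("abundance_matrix", "matrix", "array")`,
#'   rownames = feature ids, colnames = sample ids.
#' @export
abundance_matrix <- function(values,
                             feature_ids = rownames(values),
                             sample_ids = colnames(values)) {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(feature_ids) || is.null(sample_ids)) {
    stop("abundance_matrix requires feature and sample identifiers", call. = FALSE)
  }
  feature_ids <- as.character(feature_ids)
  sample_ids <- as.character(sample_ids)
  if (length(feature_ids) != nrow(values)) {
    stop("feature_ids length does not match the number of rows", call. = FALSE)
  }
  if (length(sample_ids) != ncol(values)) {
    stop("sample_ids length does not match the number of columns", call. = FALSE)
  }
  if (anyDuplicated(feature_ids)) {
    stop("duplicate feature identifiers: ",
         paste(unique(feature_ids[duplicated(feature_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(sample_ids)) {
    stop("duplicate sample identifiers: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "),
         call. = FALSE)
  }
  if (anyNA(values)) stop("abundance matrix contains missing values", call. = FALSE)
  if (any(values < 0)) {
    bad <- which(values < 0, arr.ind = TRUE)[1, ]
    stop(sprintf("negative abundance at feature '%s', sample '%s'",
                 feature_ids[bad[1]], sample_ids[bad[2]]), call. = FALSE)
  }
  if (nrow(values) < 2) stop("need at least 2 features", call. = FALSE)
  if (ncol(values) < 3) stop("need at least 3 samples", call. = FALSE)
  dimnames(values) <- list(feature_ids, sample_ids)
  class(values) <- c("abundance_matrix", "matrix", "array")
  values
}

#' Read an abundance table from delimited text
#'
#' Expects a header row of sample identifiers and a first column of feature
#' identifiers; the body must be non-negative numeric.
#'
#' @param path Path to a TSV/CSV file.
#' @param delimiter Field delimiter, default tab.
#' @return An [abundance_matrix()].
#' @export
read_abundance_table <- function(path, delimiter = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.table(path, sep = delimiter, header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE,
                          colClasses = "character", quote = "\"",
                          comment.char = "")
  if (ncol(df) < 2) stop("table must have a feature-id column plus sample columns",
                         call. = FALSE)
  feature_ids <- df[[1]]
  sample_ids <- colnames(df)[-1]
  body <- as.matrix(df[, -1, drop = FALSE])
  num <- suppressWarnings(matrix(as.numeric(body), nrow = nrow(body)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    stop(sprintf("malformed numeric value '%s' at feature '%s', sample '%s'",
                 body[bad[1], bad[2]], feature_ids[bad[1]], sample_ids[bad[2]]),
         call. = FALSE)
  }
  abundance_matrix(num, feature_ids, sample_ids)
}

#' Write an abundance table as delimited text
#'
#' Inverse of [read_abundance_table()]; round-trips values at full precision.
#'
#' @param x An [abundance_matrix()] (or plain matrix with dimnames).
#' @param path Output path.
#' @param delimiter Field delimiter, default tab.
#' @return `path`, invisibly.
#' @export
write_abundance_table <- function(x, path, delimiter = "\t") {
  df <- data.frame(feature_id = rownames(x), as.data.frame(unclass(x)),
                   check.names = FALSE)
  colnames(df)[1] <- "feature_id"
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     path, sep = delimiter, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Align modalities onto a shared sample set
#'
#' The model requires that all modalities are measured on the same samples.
#' Columns are reordered to the shared sample order (order of appearance in the
#' first modality); samples absent from any modality are dropped with a warning.
#'
#' @param tables List of 2 or 3 abundance matrices.
#' @param modality_names Optional names; defaults to names of `tables` or
#'   `modality1..M`.
#' @return A `multiomics_dataset`: a named list of abundance matrices sharing an
#'   identical, identically ordered sample-id set.
#' @export
align_modalities <- function(tables, modality_names = NULL) {
  if (!is.list(tables) || length(tables) < 2 || length(tables) > 3) {
    stop("need a list of 2 or 3 abundance matrices", call. = FALSE)
  }
  if (is.null(modality_names)) {
    modality_names <- names(tables)
    if (is.null(modality_names) || any(!nzchar(modality_names))) {
      modality_names <- paste0("modality", seq_along(tables))
    }
  }
  shared <- Reduce(intersect, lapply(tables, colnames))
  if (length(shared) < 3) {
    stop("modalities share fewer than 3 samples", call. = FALSE)
  }
  n_dropped <- sum(vapply(tables, function(t) sum(!colnames(t) %in% shared), 0L))
  if (n_dropped > 0) {
    warning(sprintf("dropping %d sample column(s) absent from some modality",
                    n_dropped), call. = FALSE)
  }
  out <- lapply(tables, function(t) {
    abundance_matrix(unclass(t)[, shared, drop = FALSE],
                     rownames(t), shared)
  })
  names(out) <- modality_names
  structure(out, class = "multiomics_dataset")
}

#' @export
print.multiomics_dataset <- function(x, ...) {
  cat(sprintf("multiomics_dataset: %d modalities, %d shared samples\n",
              length(x), ncol(x[[1]])))
  for (nm in names(x)) {
    cat(sprintf("  %s: %d features\n", nm, nrow(x[[nm]])))
  }
  invisible(x)
}

#' Normalize a composition profile
#'
#' Converts each sample (column) to relative abundance (columns sum to 1), with
#' an optional `log(1 + c*x)` transform applied afterwards. Columns with zero
#' total are left as zeros. This is the default preprocessing before kernel
#' affinity computation, following compositional microbiome convention.
#'
#' @param x Abundance matrix.
#' @param relative Divide each column by its sum (default TRUE).
#' @param log_c If non-NULL, apply `log1p(log_c * x)` after normalization.
#' @return Matrix of the same shape and dimnames.
#' @export
normalize_composition <- function(x, relative = TRUE, log_c = NULL) {
  v <- unclass(x)
  if (relative) {
    cs <- colSums(v)
    cs[cs == 0] <- 1
    v <- sweep(v, 2, cs, "/")
  }
  if (!is.null(log_c)) v <- log1p(log_c * v)
  v
}
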