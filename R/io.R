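#' Read and write expression matrices
#'
#' Expression files are TSV with the sample identifier in the first column
#' and gene identifiers in the header; values are non-negative TPM-like
#' numbers. Round trips preserve shape, names, and values to 6 significant
#' digits.
#'
#' @param path File path.
#' @return \code{read_expression}: a samples-by-genes numeric matrix with
#'   dimnames.
#' @export
read_expression <- function(path) {
  if (!file.exists(path)) stop("Expression file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", check.names = FALSE,
                          stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Expression file needs a sample column plus genes: ",
                          path, call. = FALSE)
  ids <- as.character(df[[1]])
  if (anyDuplicated(ids)) {
    stop("Duplicate sample identifiers at rows: ",
         paste(which(duplicated(ids)), collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(df[, -1, drop = FALSE])
  if (anyDuplicated(colnames(m))) stop("Duplicate gene identifiers", call. = FALSE)
  if (!is.numeric(m)) stop("Non-numeric expression values in ", path, call. = FALSE)
  if (nrow(m) == 0L) stop("Expression matrix is empty: ", path, call. = FALSE)
  rownames(m) <- ids
  m
}

#' @rdname read_expression
#' @param x Samples-by-genes matrix.
#' @export
write_expression <- function(x, path) {
  x <- as.matrix(x)
  if (nrow(x) == 0L || ncol(x) == 0L) stop("Refusing to write an empty matrix",
                                           call. = FALSE)
  df <- data.frame(sample = rownames(x) %||% paste0("sample", seq_len(nrow(x))),
                   signif(x, 6), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and write sample labels
#'
#' Label files are two-column TSV (sample identifier, class string) with a
#' header. Class strings must come from [binn_classes()] unless
#' \code{levels} says otherwise.
#'
#' @param path File path.
#' @param levels Allowed class strings (default [binn_classes()]).
#' @return \code{read_labels}: a named factor (names = sample ids).
#' @export
read_labels <- function(path, levels = binn_classes()) {
  if (!file.exists(path)) stop("Labels file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("Labels file needs two columns (sample, class)",
                          call. = FALSE)
  bad <- setdiff(unique(df[[2]]), levels)
  if (length(bad)) {
    stop("Unknown class string(s): ", paste(bad, collapse = ", "),
         "; allowed classes are: ", paste(levels, collapse = ", "),
         call. = FALSE)
  }
  stats::setNames(factor(df[[2]], levels = levels), df[[1]])
}

#' @rdname read_labels
#' @param y Class labels.
#' @param ids Sample identifiers.
#' @export
write_labels <- function(y, ids, path) {
  utils::write.table(data.frame(sample = ids, class = as.character(y)),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write an attribution result to CSV
#'
#' One file per method and class: rows are entities, columns are retained
#' sample identifiers, plus a final \code{mean_abs} summary column holding
#' the ranking score (mean absolute attribution).
#'
#' @param a An \code{attribution_result}.
#' @param path Output CSV path.
#' @param class Optional class restriction.
#' @return \code{path}, invisibly.
#' @export
write_attribution <- function(a, path, class = NULL) {
  stopifnot(inherits(a, "attribution_result"))
  scores <- a$scores
  if (!is.null(class)) {
    keep <- a$classes == class
    if (!any(keep)) stop("No retained samples of class ", class, call. = FALSE)
    scores <- scores[keep, , drop = FALSE]
  }
  out <- data.frame(entity = colnames(scores), t(scores),
                    mean_abs = colMeans(abs(scores)), check.names = FALSE)
  utils::write.csv(out, path, row.names = FALSE)
  invisible(path)
}

#' Read an attribution CSV back as a score matrix
#'
#' @param path CSV written by [write_attribution()].
#' @return Samples-by-entities matrix (the \code{mean_abs} column dropped).
#' @export
read_attribution <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  ent <- df$entity
  m <- as.matrix(df[, setdiff(names(df), c("entity", "mean_abs")), drop = FALSE])
  t(`rownames<-`(m, ent))
}

#' Write an overlap report to CSV
#'
#' @param report Data.frame from [topk_overlap()] (possibly row-bound over
#'   several comparisons with extra annotation columns).
#' @param path Output CSV path.
#' @return \code{path}, invisibly.
#' @export
write_overlap_report <- function(report, path) {
  utils::write.csv(report, path, row.names = FALSE)
  invisible(path)
}
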