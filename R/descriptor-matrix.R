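#' Descriptor matrix with aligned class labels
#'
#' The central container of the workflow: a numeric matrix of molecular
#' descriptors (compounds in rows, named descriptors in columns) together
#' with compound identifiers and, optionally, aligned binary class labels
#' (`"toxic"` / `"nontoxic"`; toxic is the positive class throughout).
#'
#' @param x Numeric matrix with column names (descriptor names).
#' @param labels Optional factor/character vector of class labels, one per
#'   row, with values in `c("toxic", "nontoxic")`.
#' @param compound_id Optional character vector of compound identifiers;
#'   defaults to row names of `x` or `cmpd_<i>`.
#' @return An object of class `descriptor_matrix`.
#' @examples
#' m <- matrix(rnorm(20), 5, 4, dimnames = list(NULL, paste0("d", 1:4)))
#' dm <- descriptor_matrix(m, labels = c("toxic", "toxic", "nontoxic",
#'                                       "toxic", "nontoxic"))
#' dim(dm)
#' @export
descriptor_matrix <- function(x, labels = NULL, compound_id = NULL) {
  if (!is.matrix(x) || !is.numeric(x))
    abort_config("descriptor_matrix: 'x' must be a numeric matrix")
  if (is.null(colnames(x)))
    abort_config("descriptor_matrix: descriptor columns must be named")
  if (is.null(compound_id)) {
    compound_id <- rownames(x) %||% sprintf("cmpd_%03d", seq_len(nrow(x)))
  }
  if (length(compound_id) != nrow(x))
    abort_config("descriptor_matrix: %d ids for %d rows",
                 length(compound_id), nrow(x))
  if (!is.null(labels)) {
    labels <- as.character(labels)
    if (length(labels) != nrow(x))
      abort_config("descriptor_matrix: %d labels for %d rows",
                   length(labels), nrow(x))
    bad <- setdiff(unique(labels), c("toxic", "nontoxic"))
    if (length(bad))
      abort_config("descriptor_matrix: unknown labels: %s",
                   paste(bad, collapse = ", "))
    labels <- factor(labels, levels = c("toxic", "nontoxic"))
  }
  rownames(x) <- NULL
  structure(list(x = x, labels = labels,
                 compound_id = as.character(compound_id)),
            class = "descriptor_matrix")
}

#' @export
dim.descriptor_matrix <- function(x) dim(x$x)

#' Subset a descriptor matrix
#'
#' `dm[i, j]` subsets compounds (rows) and/or descriptors (columns),
#' keeping labels and identifiers aligned.
#'
#' @param x A `descriptor_matrix`.
#' @param i Row (compound) index.
#' @param j Column (descriptor) index or names.
#' @param ... Ignored.
#' @return A `descriptor_matrix`.
#' @export
`[.descriptor_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$x))
  if (missing(j)) j <- seq_len(ncol(x$x))
  descriptor_matrix(x$x[i, j, drop = FALSE],
                    labels = if (!is.null(x$labels)) x$labels[i],
                    compound_id = x$compound_id[i])
}

#' @export
print.descriptor_matrix <- function(x, ...) {
  cat(sprintf("<descriptor_matrix> %d compounds x %d descriptors\n",
              nrow(x$x), ncol(x$x)))
  if (!is.null(x$labels)) {
    tab <- table(x$labels)
    cat(sprintf("labels: %d toxic, %d nontoxic\n",
                tab[["toxic"]], tab[["nontoxic"]]))
  }
  invisible(x)
}

#' Names of descriptors in a descriptor matrix
#' @param dm A `descriptor_matrix`.
#' @return Character vector of descriptor names.
#' @export
descriptor_names <- function(dm) colnames(dm$x)

#' Class counts of a labelled descriptor matrix
#' @param dm A `descriptor_matrix` with labels.
#' @return Named integer vector `c(toxic = , nontoxic = )`.
#' @export
class_counts <- function(dm) {
  if (is.null(dm$labels)) abort_config("class_counts: no labels attached")
  c(toxic = sum(dm$labels == "toxic"),
    nontoxic = sum(dm$labels == "nontoxic"))
}

#' Write / read a descriptor matrix as CSV
#'
#' The CSV has the compound identifier in the first column, one named
#' descriptor per further column, and (if present) a final `label` column.
#'
#' @param dm A `descriptor_matrix`.
#' @param path File path.
#' @return `read_descriptor_csv` returns a `descriptor_matrix`;
#'   `write_descriptor_csv` returns `path` invisibly.
#' @export
write_descriptor_csv <- function(dm, path) {
  df <- data.frame(compound_id = dm$compound_id, dm$x,
                   check.names = FALSE, stringsAsFactors = FALSE)
  if (!is.null(dm$labels)) df$label <- as.character(dm$labels)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_descriptor_csv
#' @export
read_descriptor_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  labels <- NULL
  if ("label" %in% names(df)) {
    labels <- df$label
    df$label <- NULL
  }
  ids <- df[[1L]]
  x <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(x) <- "double"
  descriptor_matrix(x, labels = labels, compound_id = ids)
}
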