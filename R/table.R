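#' Discrete data table with an explicit missing mask
#'
#' A \code{discrete_table} couples a data frame of category labels (character
#' columns; \code{NA} marks a missing cell) and numeric columns with its
#' \code{\link{cat_schema}}. Row identities are preserved through splitting
#' and reconstruction via the \code{row_ids} attribute.
#'
#' @param data A data frame. Categorical columns are coerced to character.
#' @param schema A \code{cat_schema} whose attributes match \code{names(data)}.
#' @param row_ids Integer row identities; defaults to \code{1:nrow(data)}.
#' @return A \code{discrete_table}.
#' @export
discrete_table <- function(data, schema, row_ids = NULL) {
  stopifnot(inherits(schema, "cat_schema"), is.data.frame(data))
  nm <- schema_names(schema)
  if (!identical(names(data), nm)) {
    stop("column names do not match schema attribute names")
  }
  kinds <- schema_kinds(schema)
  for (j in seq_along(nm)) {
    if (kinds[j] == "categorical") {
      col <- as.character(data[[j]])
      bad <- which(!is.na(col) & !col %in% schema_domain(schema, j))
      if (length(bad)) {
        stop(sprintf("value '%s' at row %d outside the domain of attribute %d (%s)",
                     col[bad[1]], bad[1], j, nm[j]))
      }
      data[[j]] <- col
    } else {
      data[[j]] <- as.numeric(data[[j]])
    }
  }
  ci <- class_attr(schema)
  if (ci > 0L && anyNA(data[[ci]])) {
    stop("the class column must not contain missing cells")
  }
  row_ids <- as.integer(row_ids %||% seq_len(nrow(data)))
  stopifnot(length(row_ids) == nrow(data), !anyDuplicated(row_ids))
  rownames(data) <- NULL
  structure(list(schema = schema, data = data, row_ids = row_ids),
            class = "discrete_table")
}

#' @export
print.discrete_table <- function(x, ...) {
  cat("<discrete_table> ", nrow(x$data), " rows x ", ncol(x$data),
      " attributes; ", sum(is.na(x$data)), " missing cells\n", sep = "")
  print(utils::head(x$data))
  invisible(x)
}

#' @export
dim.discrete_table <- function(x) dim(x$data)

n_rows <- function(table) nrow(table$data)

#' Missing mask of a table
#'
#' @param table A \code{discrete_table}.
#' @return Logical matrix, \code{TRUE} where a cell is missing.
#' @export
missing_mask <- function(table) {
  m <- is.na(as.matrix(table$data))
  dimnames(m) <- list(NULL, schema_names(table$schema))
  m
}

#' Read a discrete table from CSV
#'
#' Reads an RFC-4180 CSV with a header row. Cells equal to
#' \code{missing_sentinel} become missing. When \code{schema} is absent one is
#' inferred: every column categorical with a lexicographically sorted domain
#' of its observed values, last column taking the class role.
#'
#' @param path CSV file path.
#' @param schema Optional \code{cat_schema}.
#' @param missing_sentinel Sentinel string marking missing cells
#'   (default \code{"?"}).
#' @return A \code{discrete_table}.
#' @export
read_table <- function(path, schema = NULL, missing_sentinel = "?") {
  df <- utils::read.csv(path, colClasses = "character", check.names = FALSE,
                        stringsAsFactors = FALSE)
  for (j in seq_along(df)) df[[j]][df[[j]] == missing_sentinel] <- NA
  if (is.null(schema)) {
    attrs <- lapply(seq_along(df), function(j) {
      list(name = names(df)[j], kind = "categorical",
           domain = sort(unique(df[[j]][!is.na(df[[j]])])),
           role = if (j == ncol(df)) "class" else "feature")
    })
    schema <- cat_schema(attrs)
  } else {
    kinds <- schema_kinds(schema)
    for (j in seq_along(df)) {
      if (kinds[j] == "numeric") df[[j]] <- as.numeric(df[[j]])
    }
  }
  discrete_table(df, schema)
}

#' Write a discrete table to CSV
#'
#' Missing cells are serialized as the sentinel; \code{read_table} on the
#' result reproduces the table cell-for-cell.
#'
#' @inheritParams read_table
#' @param table A \code{discrete_table}.
#' @return \code{path}, invisibly.
#' @export
write_table <- function(table, path, missing_sentinel = "?") {
  df <- table$data
  for (j in seq_along(df)) {
    col <- as.character(df[[j]])
    col[is.na(col)] <- missing_sentinel
    df[[j]] <- col
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

subset_rows <- function(table, idx) {
  discrete_table(table$data[idx, , drop = FALSE], table$schema,
                 row_ids = table$row_ids[idx])
}

#' Split a table into complete and incomplete rows
#'
#' Partitions the rows into \code{Dcom} (no missing cells) and \code{Dmiss}
#' (at least one missing cell), preserving row identities.
#'
#' @param table A \code{discrete_table}.
#' @return A list with elements \code{dcom} and \code{dmiss}.
#' @export
split_by_completeness <- function(table) {
  any_miss <- rowSums(missing_mask(table)) > 0
  list(dcom = subset_rows(table, which(!any_miss)),
       dmiss = subset_rows(table, which(any_miss)))
}

#' Detect missing types
#'
#' A missing type is one distinct set of simultaneously missing attribute
#' indices; all incomplete rows sharing that set belong to the type. Types are
#' returned in lexicographic order of their attribute-index sets, so output is
#' deterministic.
#'
#' @param table A \code{discrete_table}.
#' @return A list of \code{missing_type} objects, each with fields
#'   \code{missing_attrs} (sorted integer attribute indices) and \code{rows}
#'   (integer row positions in \code{table}).
#' @export
detect_missing_types <- function(table) {
  m <- missing_mask(table)
  rows <- which(rowSums(m) > 0)
  if (length(rows) == 0L) return(list())
  keys <- vapply(rows, function(r) paste(which(m[r, ]), collapse = ","), "")
  groups <- split(rows, keys)
  types <- lapply(groups, function(rr) {
    structure(list(missing_attrs = unname(which(m[rr[1], ])),
                   rows = as.integer(rr)),
              class = "missing_type")
  })
  # order lexicographically on the integer index vectors, not on strings
  mats <- lapply(types, `[[`, "missing_attrs")
  maxlen <- max(lengths(mats))
  pad <- t(vapply(mats, function(v) c(v, rep(Inf, maxlen - length(v))),
                  numeric(maxlen)))
  if (maxlen == 1L) pad <- matrix(unlist(mats), ncol = 1)
  ord <- do.call(order, as.data.frame(pad))
  unname(types[ord])
}

#' Reconstruct a table from disjoint row partitions
#'
#' Inverse of \code{\link{split_by_completeness}}: merges two tables with
#' disjoint row identities back into one table in original row-id order.
#'
#' @param dcom,dmiss \code{discrete_table}s over the same schema with disjoint
#'   \code{row_ids}.
#' @return A single \code{discrete_table} ordered by row id.
#' @export
reconstruct <- function(dcom, dmiss) {
  if (!identical(schema_names(dcom$schema), schema_names(dmiss$schema))) {
    stop("schemas differ between the parts")
  }
  ids <- c(dcom$row_ids, dmiss$row_ids)
  if (anyDuplicated(ids)) stop("overlapping row identities in reconstruction")
  data <- rbind(dcom$data, dmiss$data)
  ord <- order(ids)
  discrete_table(data[ord, , drop = FALSE], dcom$schema, row_ids = ids[ord])
}
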