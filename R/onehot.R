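#' One-hot layout for a schema
#'
#' Assigns every attribute a contiguous block of encoded columns: one
#' indicator column per domain category for categorical attributes, a single
#' min-max scaled column for numeric attributes. Blocks follow schema
#' attribute order, so the layout is a fixed, reproducible coding space.
#'
#' Numeric scaling bounds are taken from the complete rows (\code{Dcom}) of
#' \code{table} when given; values outside the bounds clip to [0, 1].
#'
#' @param schema A \code{cat_schema}.
#' @param table Optional \code{discrete_table} used to derive numeric bounds.
#' @return A \code{onehot_layout} with per-attribute \code{offset} and
#'   \code{width} and the \code{total_width}.
#' @export
onehot_layout <- function(schema, table = NULL) {
  kinds <- schema_kinds(schema)
  widths <- vapply(seq_along(kinds), function(j) {
    if (kinds[j] == "categorical") length(schema_domain(schema, j)) else 1L
  }, integer(1))
  offsets <- cumsum(c(0L, widths[-length(widths)]))
  bounds <- vector("list", length(kinds))
  if (any(kinds == "numeric")) {
    if (is.null(table)) stop("a table is required to derive numeric bounds")
    dcom <- split_by_completeness(table)$dcom
    for (j in which(kinds == "numeric")) {
      v <- dcom$data[[j]]
      if (length(v) == 0L) stop("no complete rows to derive numeric bounds")
      bounds[[j]] <- range(v)
    }
  }
  structure(list(schema = schema, offsets = offsets, widths = widths,
                 bounds = bounds, total_width = sum(widths)),
            class = "onehot_layout")
}

# Encoded column indices of attribute j under the layout.
layout_block <- function(layout, j) {
  layout$offsets[j] + seq_len(layout$widths[j])
}

#' Encode table rows as a one-hot matrix
#'
#' Categorical cells become 0/1 indicator blocks (exactly one 1 per observed
#' cell); numeric cells are min-max scaled to [0, 1]. All encoded cells must
#' be observed: prefill first if needed.
#'
#' @param table A \code{discrete_table}.
#' @param layout A \code{onehot_layout} for the table's schema.
#' @param rows Row positions to encode (default all).
#' @param attrs Attribute indices to encode (default all); blocks of omitted
#'   attributes are dropped, remaining blocks keep their relative order.
#' @return Numeric matrix of size \code{length(rows)} x total block width.
#' @export
encode_one_hot <- function(table, layout, rows = seq_len(n_rows(table)),
                           attrs = seq_along(layout$widths)) {
  attrs <- sort(as.integer(attrs))
  kinds <- schema_kinds(table$schema)
  cols <- sum(layout$widths[attrs])
  out <- matrix(0, nrow = length(rows), ncol = cols)
  at <- 0L
  for (j in attrs) {
    w <- layout$widths[j]
    cell <- table$data[[j]][rows]
    miss <- which(is.na(cell))
    if (length(miss)) {
      stop(sprintf("missing cell at row %d, attribute %d (%s): encode requires observed cells",
                   rows[miss[1]], j, schema_names(table$schema)[j]))
    }
    if (kinds[j] == "categorical") {
      pos <- match(cell, schema_domain(table$schema, j))
      out[cbind(seq_along(rows), at + pos)] <- 1
    } else {
      b <- layout$bounds[[j]]
      v <- if (b[2] > b[1]) (cell - b[1]) / (b[2] - b[1]) else rep(0, length(cell))
      out[, at + 1L] <- pmin(pmax(v, 0), 1)
    }
    at <- at + w
  }
  out
}

#' Decode one-hot scores back to category labels
#'
#' Per attribute block the category at the maximum score is taken; ties break
#' to the lowest domain index. Only categorical attributes can be decoded.
#'
#' @param scores Numeric matrix whose columns are the concatenated blocks of
#'   \code{attrs} in layout order.
#' @param layout A \code{onehot_layout}.
#' @param attrs Categorical attribute indices matching the columns of
#'   \code{scores}.
#' @return Character matrix, one column per attribute in \code{attrs}.
#' @export
decode_one_hot <- function(scores, layout, attrs = seq_along(layout$widths)) {
  attrs <- sort(as.integer(attrs))
  kinds <- schema_kinds(layout$schema)
  if (any(kinds[attrs] != "categorical")) {
    stop("only categorical attributes can be decoded")
  }
  if (ncol(scores) != sum(layout$widths[attrs])) {
    stop(sprintf("score width %d does not match layout width %d",
                 ncol(scores), sum(layout$widths[attrs])))
  }
  out <- matrix(NA_character_, nrow = nrow(scores), ncol = length(attrs))
  colnames(out) <- schema_names(layout$schema)[attrs]
  at <- 0L
  for (i in seq_along(attrs)) {
    j <- attrs[i]
    w <- layout$widths[j]
    block <- scores[, at + seq_len(w), drop = FALSE]
    pick <- unname(apply(block, 1L, which.max))  # first maximum = lowest index
    out[, i] <- schema_domain(layout$schema, j)[pick]
    at <- at + w
  }
  out
}
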