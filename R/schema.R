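#' Categorical table schema
#'
#' A schema declares, for every attribute (column) of a discrete table, its
#' name, its kind (\code{"categorical"} or \code{"numeric"}), its ordered
#' category domain (categorical attributes only) and its role
#' (\code{"feature"} or \code{"class"}). The declared domain order is
#' canonical: it fixes one-hot positions and every deterministic tie-break in
#' the package.
#'
#' @param attributes A list, one element per attribute, each a list with
#'   entries \code{name}, \code{kind}, \code{domain} (categorical only) and
#'   \code{role}. \code{role} defaults to \code{"feature"}, \code{kind} to
#'   \code{"categorical"}.
#' @return An object of class \code{cat_schema}.
#' @examples
#' cat_schema(list(
#'   list(name = "lymphatics",
#'        domain = c("normal", "arched", "deformed", "displaced")),
#'   list(name = "outcome", domain = c("yes", "no"), role = "class")
#' ))
#' @export
cat_schema <- function(attributes) {
  stopifnot(is.list(attributes), length(attributes) > 0L)
  attrs <- lapply(attributes, function(a) {
    a$kind <- a$kind %||% "categorical"
    a$role <- a$role %||% "feature"
    if (!a$kind %in% c("categorical", "numeric")) {
      stop("attribute kind must be 'categorical' or 'numeric': ", a$name)
    }
    if (!a$role %in% c("feature", "class")) {
      stop("attribute role must be 'feature' or 'class': ", a$name)
    }
    if (is.null(a$name) || !nzchar(a$name)) stop("attribute names must be non-empty")
    if (a$kind == "categorical") {
      a$domain <- as.character(a$domain)
      if (length(a$domain) == 0L) stop("empty domain for attribute ", a$name)
      if (anyDuplicated(a$domain)) stop("duplicate domain labels for attribute ", a$name)
    } else {
      a$domain <- NULL
    }
    a[c("name", "kind", "domain", "role")]
  })
  nm <- vapply(attrs, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("attribute names must be unique")
  roles <- vapply(attrs, `[[`, "", "role")
  if (sum(roles == "class") > 1L) stop("at most one attribute may have role 'class'")
  structure(list(attributes = attrs), class = "cat_schema")
}

#' @export
print.cat_schema <- function(x, ...) {
  cat("<cat_schema> ", length(x$attributes), " attributes\n", sep = "")
  for (a in x$attributes) {
    dom <- if (a$kind == "categorical") {
      paste0(" {", paste(a$domain, collapse = ","), "}")
    } else ""
    cat("  ", a$name, " [", a$kind, "/", a$role, "]", dom, "\n", sep = "")
  }
  invisible(x)
}

schema_names <- function(schema) {
  vapply(schema$attributes, `[[`, "", "name")
}

schema_roles <- function(schema) {
  vapply(schema$attributes, `[[`, "", "role")
}

schema_kinds <- function(schema) {
  vapply(schema$attributes, `[[`, "", "kind")
}

# Index of the class attribute, or 0 when none is declared.
class_attr <- function(schema) {
  i <- which(schema_roles(schema) == "class")
  if (length(i)) i[1] else 0L
}

# Attributes eligible for amputation/imputation: categorical features.
eligible_attrs <- function(schema) {
  which(schema_kinds(schema) == "categorical" & schema_roles(schema) == "feature")
}

schema_domain <- function(schema, j) schema$attributes[[j]]$domain

#' Read or write a schema as JSON
#'
#' The JSON layout is
#' \code{{"attributes": [{"name", "kind", "domain", "role"}, ...],
#' "missing_sentinel": "?"}}.
#'
#' @param path File path.
#' @param schema A \code{cat_schema}.
#' @param missing_sentinel Sentinel string stored alongside the schema.
#' @return \code{read_schema} returns a list with elements \code{schema} and
#'   \code{missing_sentinel}; \code{write_schema} returns \code{path}
#'   invisibly.
#' @export
read_schema <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  attrs <- lapply(obj$attributes, function(a) {
    list(name = a$name, kind = a$kind %||% "categorical",
         domain = unlist(a$domain, use.names = FALSE),
         role = a$role %||% "feature")
  })
  list(schema = cat_schema(attrs),
       missing_sentinel = obj$missing_sentinel %||% "?")
}

#' @rdname read_schema
#' @export
write_schema <- function(schema, path, missing_sentinel = "?") {
  obj <- list(
    attributes = lapply(schema$attributes, function(a) {
      out <- list(name = a$name, kind = a$kind, role = a$role)
      if (a$kind == "categorical") out$domain <- as.list(a$domain)
      out
    }),
    missing_sentinel = missing_sentinel
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
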