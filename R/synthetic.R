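#' Latent-class synthetic categorical data
#'
#' Generates a complete discrete table with known inter-attribute dependence:
#' each row draws a latent class by the mixture weights, every attribute then
#' equals that class's modal category with probability \code{1 - noise} and
#' otherwise a uniform draw over the remaining categories. The class column
#' equals the latent class, so downstream classification accuracy is
#' meaningfully degraded by poor imputation. Mimics small UCI-style
#' categorical benchmark tables (a few hundred to a couple of thousand rows,
#' 4-18 mostly categorical attributes, 2-5 classes).
#'
#' @param n_rows Number of rows.
#' @param n_attrs Number of feature attributes.
#' @param domain_sizes Integer vector (recycled) of category counts per
#'   attribute.
#' @param n_classes Number of latent classes.
#' @param weights Mixture weights (default uniform); must sum to 1.
#' @param noise Corruption probability in [0, 1).
#' @param modal Optional n_classes x n_attrs integer matrix of modal category
#'   indices; by default drawn uniformly per (class, attribute) from the seed.
#' @param seed RNG seed.
#' @return A complete \code{discrete_table} whose last column \code{class} has
#'   the class role.
#' @export
gen_latent_class <- function(n_rows, n_attrs = 6L, domain_sizes = 4L,
                             n_classes = 4L, weights = NULL, noise = 0.1,
                             modal = NULL, seed = 1L) {
  stopifnot(n_rows >= 1, n_attrs >= 1, n_classes >= 2, noise >= 0, noise < 1)
  domain_sizes <- rep_len(as.integer(domain_sizes), n_attrs)
  weights <- weights %||% rep(1 / n_classes, n_classes)
  if (abs(sum(weights) - 1) > 1e-8) stop("mixture weights must sum to 1")
  attrs <- c(lapply(seq_len(n_attrs), function(j) {
    list(name = paste0("A", j), kind = "categorical",
         domain = paste0("a", j, "_", seq_len(domain_sizes[j])),
         role = "feature")
  }), list(list(name = "class", kind = "categorical",
                domain = paste0("c", seq_len(n_classes)), role = "class")))
  schema <- cat_schema(attrs)
  with_seed(seed, {
    if (is.null(modal)) {
      modal <- matrix(0L, n_classes, n_attrs)
      for (j in seq_len(n_attrs)) {
        modal[, j] <- sample.int(domain_sizes[j], n_classes, replace = TRUE)
      }
    }
    stopifnot(nrow(modal) == n_classes, ncol(modal) == n_attrs,
              all(modal >= 1), all(modal <= rep(domain_sizes, each = n_classes)))
    cls <- sample.int(n_classes, n_rows, replace = TRUE, prob = weights)
    df <- as.data.frame(lapply(seq_len(n_attrs), function(j) {
      dom <- schema_domain(schema, j)
      idx <- modal[cls, j]
      corrupt <- stats::runif(n_rows) < noise
      if (any(corrupt) && domain_sizes[j] > 1L) {
        idx[corrupt] <- vapply(which(corrupt), function(r) {
          sample(setdiff(seq_len(domain_sizes[j]), idx[r]), 1L)
        }, integer(1))
      }
      dom[idx]
    }))
    names(df) <- paste0("A", seq_len(n_attrs))
    df$class <- paste0("c", cls)
  })
  discrete_table(df, schema)
}

#' Functional-dependence synthetic data
#'
#' Generates a complete table where the second attribute is a (possibly
#' noisy) deterministic function of the first: \code{A1} is uniform over its
#' domain, \code{A2 = mapping[A1]} with probability \code{1 - noise} and a
#' uniform draw otherwise. A binary class label is the fixed rule "is A1 in
#' the first half of its domain". Useful for testing whether an imputer can
#' recover an exactly recoverable attribute.
#'
#' @param n_rows Number of rows.
#' @param domain_size Number of categories of \code{A1} (and of \code{A2}'s
#'   codomain).
#' @param mapping Integer vector of length \code{domain_size}: the category
#'   index of \code{A2} for each category of \code{A1}. Default identity.
#' @param noise Corruption probability in [0, 1).
#' @param seed RNG seed.
#' @return A complete \code{discrete_table} with attributes \code{A1},
#'   \code{A2} and a binary \code{class} column.
#' @export
gen_functional <- function(n_rows, domain_size = 4L, mapping = NULL,
                           noise = 0, seed = 1L) {
  stopifnot(n_rows >= 1, domain_size >= 2, noise >= 0, noise < 1)
  mapping <- as.integer(mapping %||% seq_len(domain_size))
  if (length(mapping) != domain_size || any(is.na(mapping)) ||
      any(mapping < 1) || any(mapping > domain_size)) {
    stop("mapping must assign every driver category a target category")
  }
  dom1 <- paste0("u", seq_len(domain_size))
  dom2 <- paste0("v", seq_len(domain_size))
  schema <- cat_schema(list(
    list(name = "A1", domain = dom1),
    list(name = "A2", domain = dom2),
    list(name = "class", domain = c("lo", "hi"), role = "class")
  ))
  with_seed(seed, {
    a1 <- sample.int(domain_size, n_rows, replace = TRUE)
    a2 <- mapping[a1]
    corrupt <- stats::runif(n_rows) < noise
    if (any(corrupt)) {
      a2[corrupt] <- sample.int(domain_size, sum(corrupt), replace = TRUE)
    }
    label <- ifelse(a1 <= domain_size / 2, "lo", "hi")
  })
  discrete_table(data.frame(A1 = dom1[a1], A2 = dom2[a2], class = label),
                 schema)
}
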