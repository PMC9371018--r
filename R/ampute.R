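#' Amputation configuration
#'
#' Describes how to delete cells from a complete table so the resulting
#' missingness follows one of the three canonical mechanisms:
#' \describe{
#'   \item{MCAR}{cells are removed uniformly at random;}
#'   \item{MAR}{removal probability depends on the observed value of a
#'     conditioning attribute;}
#'   \item{NMAR}{removal probability depends on the cell's own value.}
#' }
#' For MAR and NMAR a row is \code{dependence_odds} times more likely to lose
#' the cell when the driving value lies in the driver attribute's
#' high-frequency half (most frequent categories accumulating at least 50\%
#' of the mass).
#'
#' @param mechanism One of \code{"MCAR"}, \code{"MAR"}, \code{"NMAR"}.
#' @param rate Fraction of cells to delete per eligible attribute, in
#'   [0, 0.5]. Exactly \code{round(rate * n_rows)} cells are deleted per
#'   attribute.
#' @param dependence_odds Weight ratio (>= 1) planting the MAR/NMAR
#'   dependence; default 9.
#' @param conditioning Optional named integer map target attribute ->
#'   conditioning attribute (MAR only). Default: the next eligible attribute,
#'   cyclically.
#' @param targets Optional integer subset of eligible attribute indices to
#'   ampute; default all eligible (categorical feature) attributes.
#' @param seed RNG seed.
#' @return An \code{ampute_config}.
#' @export
ampute_config <- function(mechanism = c("MCAR", "MAR", "NMAR"), rate,
                          dependence_odds = 9, conditioning = NULL,
                          targets = NULL, seed = 1L) {
  mechanism <- match.arg(mechanism)
  if (!is.numeric(rate) || rate < 0 || rate > 0.5) {
    stop("rate must lie in [0, 0.5]")
  }
  if (dependence_odds < 1) stop("dependence_odds must be >= 1")
  structure(list(mechanism = mechanism, rate = rate,
                 dependence_odds = dependence_odds,
                 conditioning = conditioning, targets = targets, seed = seed),
            class = "ampute_config")
}

# Categories of attribute j covering >= 50% of observed mass, most frequent
# first (frequency ties break by domain order).
high_frequency_half <- function(table, j) {
  dom <- schema_domain(table$schema, j)
  counts <- table(factor(table$data[[j]], levels = dom))
  ord <- order(-as.integer(counts), seq_along(dom))
  cum <- cumsum(as.integer(counts)[ord])
  take <- seq_len(which(cum >= sum(counts) / 2)[1])
  dom[ord[take]]
}

# Default MAR conditioning: next eligible attribute, cyclically.
default_conditioning <- function(elig) {
  stats::setNames(elig[c(seq_along(elig)[-1], 1L)], elig)
}

#' Simulate missingness on a complete table
#'
#' Deletes exactly \code{round(rate * n_rows)} cells per target attribute
#' according to the configured mechanism. Cell selection is weighted sampling
#' without replacement; a row is never stripped of all its eligible
#' attributes. The class column and numeric attributes are never amputed.
#' Deterministic given the config seed.
#'
#' @param table A complete \code{discrete_table}.
#' @param config An \code{\link{ampute_config}}.
#' @return A \code{discrete_table} with the planted missing cells.
#' @export
ampute <- function(table, config) {
  if (any(missing_mask(table))) stop("ampute requires a complete table")
  elig <- eligible_attrs(table$schema)
  if (length(elig) < 2L) stop("at least 2 eligible attributes are required")
  targets <- as.integer(config$targets %||% elig)
  if (!all(targets %in% elig)) stop("targets must be eligible attributes")
  n <- n_rows(table)
  budget <- round(config$rate * n)
  if (budget == 0L) return(table)

  cond <- config$conditioning %||% default_conditioning(elig)
  mask <- matrix(FALSE, n, ncol(table$data))
  with_seed(config$seed, {
    for (j in targets) {
      w <- rep(1, n)
      if (config$mechanism == "MAR") {
        cj <- as.integer(cond[[as.character(j)]])
        if (is.na(cj) || cj == j) {
          stop("MAR conditioning attribute must exist and differ from the target")
        }
        hi <- high_frequency_half(table, cj)
        w[table$data[[cj]] %in% hi] <- config$dependence_odds
      } else if (config$mechanism == "NMAR") {
        hi <- high_frequency_half(table, j)
        w[table$data[[j]] %in% hi] <- config$dependence_odds
      }
      # protect rows that are already missing every other eligible attribute
      other <- setdiff(elig, j)
      doomed <- rowSums(mask[, other, drop = FALSE]) == length(other)
      w[doomed] <- 0
      if (sum(w > 0) < budget) {
        stop("row-protection left fewer candidate cells than the budget")
      }
      pick <- sample.int(n, budget, prob = w)
      mask[pick, j] <- TRUE
    }
  })
  data <- table$data
  for (j in targets) data[[j]][mask[, j]] <- NA
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Realized missing fractions
#'
#' @param table A \code{discrete_table}.
#' @return A list with \code{per_attribute} (named fractions over eligible
#'   attributes) and \code{overall} (fraction over all eligible cells).
#' @export
realized_missingness <- function(table) {
  elig <- eligible_attrs(table$schema)
  m <- missing_mask(table)[, elig, drop = FALSE]
  per <- colMeans(m)
  names(per) <- schema_names(table$schema)[elig]
  list(per_attribute = per, overall = mean(m))
}

#' Diagnose the planted missing mechanism
#'
#' For each amputed attribute, tests independence (chi-squared) between its
#' missingness indicator and the mechanism's driver values in the original
#' table: the conditioning attribute's values for MAR, the cell's own original
#' values for NMAR, and the default conditioning attribute's values for MCAR
#' (where no association should exist).
#'
#' @param original The complete \code{discrete_table} passed to
#'   \code{\link{ampute}}.
#' @param amputed The result of \code{ampute(original, config)}.
#' @param config The \code{\link{ampute_config}} used.
#' @return A data frame with one row per tested attribute: \code{attribute},
#'   \code{driver}, \code{statistic}, \code{df}, \code{p_value}. Degenerate
#'   contingency tables (a zero margin) yield \code{NA} statistics rather than
#'   an error.
#' @export
mechanism_diagnostic <- function(original, amputed, config) {
  elig <- eligible_attrs(original$schema)
  targets <- as.integer(config$targets %||% elig)
  cond <- config$conditioning %||% default_conditioning(elig)
  m <- missing_mask(amputed)
  out <- lapply(targets, function(j) {
    driver_attr <- switch(config$mechanism,
      NMAR = j,
      as.integer(cond[[as.character(j)]]))
    driver <- original$data[[driver_attr]]
    miss <- factor(m[, j], levels = c(FALSE, TRUE))
    tab <- table(miss, factor(driver, levels = schema_domain(original$schema, driver_attr)))
    tab <- tab[, colSums(tab) > 0, drop = FALSE]
    if (any(rowSums(tab) == 0) || ncol(tab) < 2L) {
      return(data.frame(attribute = j, driver = driver_attr,
                        statistic = NA_real_, df = NA_real_, p_value = NA_real_))
    }
    ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
    data.frame(attribute = j, driver = driver_attr,
               statistic = unname(ct$statistic), df = unname(ct$parameter),
               p_value = ct$p.value)
  })
  do.call(rbind, out)
}
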