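#' Hamming distance between two binary vectors
#'
#' Counts positions where the two equal-length 0/1 vectors differ. Over
#' one-hot encoded categorical attributes this is twice the number of
#' disagreeing attributes.
#'
#' @param a,b Equal-length 0/1 vectors.
#' @return Non-negative integer.
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b)) stop("hamming_distance: length mismatch")
  sum(a != b)
}

# Hamming distances from one encoded query row to every encoded donor row.
hamming_to_donors <- function(query, donors) {
  as.integer(colSums(abs(t(donors) - query)))
}

# Attributes usable for donor distances: categorical, any role (the class
# column is observed and informative), numeric excluded (binary metric).
distance_attrs <- function(schema) {
  which(schema_kinds(schema) == "categorical")
}

# Shared guard: every target attribute must have at least one observed value.
check_imputable <- function(table) {
  m <- missing_mask(table)
  for (j in which(colSums(m) > 0)) {
    if (all(m[, j])) {
      stop(sprintf("attribute %d (%s) has no observed values to impute from",
                   j, schema_names(table$schema)[j]))
    }
  }
  invisible(TRUE)
}

#' Mode imputation
#'
#' Every missing categorical cell is replaced by the most frequent observed
#' value of its attribute; frequency ties break to the earliest category in
#' domain order. Observed cells are never changed.
#'
#' @param table A \code{discrete_table}.
#' @return A complete \code{discrete_table}.
#' @export
impute_mode <- function(table) {
  check_imputable(table)
  data <- table$data
  m <- missing_mask(table)
  for (j in which(colSums(m) > 0)) {
    fill <- mode_value(data[[j]], schema_domain(table$schema, j))
    data[[j]][m[, j]] <- fill
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Frequency-weighted random imputation
#'
#' Each missing cell is drawn independently from the empirical distribution
#' of its attribute's observed values, so more frequent categories are more
#' likely to be chosen. Deterministic given the seed.
#'
#' @param table A \code{discrete_table}.
#' @param seed RNG seed.
#' @return A complete \code{discrete_table}.
#' @export
impute_random <- function(table, seed = 1L) {
  check_imputable(table)
  data <- table$data
  m <- missing_mask(table)
  with_seed(seed, {
    for (j in which(colSums(m) > 0)) {
      dom <- schema_domain(table$schema, j)
      counts <- table(factor(data[[j]], levels = dom))
      data[[j]][m[, j]] <- sample(dom, sum(m[, j]), replace = TRUE,
                                  prob = as.integer(counts))
    }
  })
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Hot-deck imputation
#'
#' For each incomplete row the donor is the complete row with the smallest
#' Hamming distance over the row's observed categorical attributes (one-hot
#' encoded); all missing cells are copied from that donor. Distance ties break
#' to the lowest donor row index.
#'
#' @param table A \code{discrete_table}.
#' @return A complete \code{discrete_table}.
#' @export
impute_hotdeck <- function(table) {
  impute_donor(table, k = 1L)
}

#' k-nearest-neighbour imputation
#'
#' For each incomplete row the \code{k} complete rows nearest by Hamming
#' distance (over observed categorical attributes, one-hot encoded) vote for
#' each missing cell with weight \code{1 / (1 + distance)}. Vote ties break
#' first to the category more frequent among the donors, then to domain
#' order. \code{k = 1} coincides with hot-deck.
#'
#' @param table A \code{discrete_table}.
#' @param k Number of donors (default 5); capped at the number of complete
#'   rows.
#' @return A complete \code{discrete_table}.
#' @export
impute_knn <- function(table, k = 5L) {
  impute_donor(table, k = as.integer(k))
}

impute_donor <- function(table, k) {
  stopifnot(k >= 1L)
  parts <- split_by_completeness(table)
  dcom <- parts$dcom
  if (n_rows(dcom) == 0L) stop("no complete rows available as donors")
  if (n_rows(parts$dmiss) == 0L) return(table)
  k <- min(k, n_rows(dcom))
  layout <- onehot_layout(table$schema, table)
  dattrs <- distance_attrs(table$schema)
  m <- missing_mask(table)
  data <- table$data
  miss_rows <- which(rowSums(m) > 0)
  donor_pos <- which(rowSums(missing_mask(table)) == 0)
  for (r in miss_rows) {
    obs <- intersect(dattrs, which(!m[r, ]))
    if (length(obs) == 0L) {
      d <- rep(0L, n_rows(dcom))
    } else {
      q <- encode_one_hot(table, layout, rows = r, attrs = obs)[1, ]
      D <- encode_one_hot(dcom, layout, rows = seq_len(n_rows(dcom)), attrs = obs)
      d <- hamming_to_donors(q, D)
    }
    ord <- order(d, seq_along(d))  # distance, then lowest donor index
    near <- ord[seq_len(k)]
    if (k == 1L) {
      donor <- near[1]
      for (j in which(m[r, ])) data[[j]][r] <- dcom$data[[j]][donor]
    } else {
      wts <- 1 / (1 + d[near])
      for (j in which(m[r, ])) {
        dom <- schema_domain(table$schema, j)
        vals <- factor(dcom$data[[j]][near], levels = dom)
        score <- tapply(wts, vals, sum, default = 0)
        freq <- as.integer(table(vals))
        best <- order(-score, -freq, seq_along(dom))[1]
        data[[j]][r] <- dom[best]
      }
    }
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Learner-backed imputation
#'
#' Treats imputation as classification: for every missing type \code{mt} and
#' every attribute \code{j} in it, a fresh learner is fitted on the complete
#' rows with one-hot features from the attributes outside \code{mt} and labels
#' from \code{j}, then predicts fills for the type's rows.
#'
#' @param table A \code{discrete_table}.
#' @param learner_factory A function returning a learner, i.e. a list with
#'   \code{fit(X, y) -> fitted} and \code{predict(fitted, X) -> labels} (see
#'   \code{\link{learner_rpart}}).
#' @return A complete \code{discrete_table}.
#' @export
impute_learner <- function(table, learner_factory) {
  parts <- split_by_completeness(table)
  dcom <- parts$dcom
  if (n_rows(dcom) == 0L) stop("no complete rows available for training")
  types <- detect_missing_types(table)
  if (length(types) == 0L) return(table)
  layout <- onehot_layout(table$schema, table)
  all_attrs <- seq_along(table$schema$attributes)
  data <- table$data
  for (mt in types) {
    inputs <- setdiff(all_attrs, mt$missing_attrs)
    Xtr <- encode_one_hot(dcom, layout, attrs = inputs)
    Xpred <- encode_one_hot(table, layout, rows = mt$rows, attrs = inputs)
    for (j in mt$missing_attrs) {
      y <- factor(dcom$data[[j]], levels = schema_domain(table$schema, j))
      learner <- learner_factory()
      fitted <- tryCatch(learner$fit(Xtr, y), error = function(e) {
        stop(sprintf("learner failed for missing type {%s}, attribute %d: %s",
                     paste(mt$missing_attrs, collapse = ","), j,
                     conditionMessage(e)))
      })
      pred <- as.character(learner$predict(fitted, Xpred))
      data[[j]][mt$rows] <- pred
    }
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Autoencoder imputation
#'
#' Trains a network with equal input and output width (the full one-hot
#' width) to reproduce the complete rows, mode-prefills the incomplete rows,
#' feeds them forward, and replaces only the originally missing blocks by the
#' decoded outputs. Observed cells are never altered.
#'
#' @param table A \code{discrete_table}.
#' @param config A \code{\link{train_config}}.
#' @return A complete \code{discrete_table}.
#' @export
impute_autoencoder <- function(table, config = train_config()) {
  parts <- split_by_completeness(table)
  dcom <- parts$dcom
  if (n_rows(parts$dmiss) == 0L) return(table)
  if (n_rows(dcom) == 0L) stop("no complete rows available for training")
  layout <- onehot_layout(table$schema, table)
  Xcom <- encode_one_hot(dcom, layout)
  fit <- train_mlp(Xcom, Xcom, config)
  prefilled <- impute_mode(table)
  m <- missing_mask(table)
  miss_rows <- which(rowSums(m) > 0)
  Xmiss <- encode_one_hot(prefilled, layout, rows = miss_rows)
  out <- forward(fit$model, Xmiss)$output
  data <- prefilled$data
  for (i in seq_along(miss_rows)) {
    r <- miss_rows[i]
    for (j in which(m[r, ])) {
      block <- out[i, layout_block(layout, j), drop = FALSE]
      data[[j]][r] <- decode_one_hot(block, layout, attrs = j)[1, 1]
    }
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Plain-MLP imputation (no momentum, no prefilling)
#'
#' The per-missing-type network procedure of \code{\link{impute_typed_mlp}}
#' with the momentum coefficient forced to 0 (plain mini-batch gradient
#' descent) and no prefilling: each type's model trains on the complete rows
#' only.
#'
#' @param table A \code{discrete_table}.
#' @param config A \code{\link{train_config}}; its \code{momentum} is ignored
#'   and treated as 0.
#' @return A complete \code{discrete_table}.
#' @export
impute_mlp <- function(table, config = train_config()) {
  config$momentum <- 0
  typed_mlp_impute(table, config, prefill_fn = NULL)
}
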