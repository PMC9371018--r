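# Fixture builders and independent oracles shared across the suite.
# Everything is generated in code under explicit seeds; no stored data files.

# A random categorical table: n_attrs feature columns with domain sizes drawn
# in dom_range, plus a class column. miss_frac of the feature cells are then
# punched out uniformly (never the class column).
random_table <- function(n_rows, n_attrs, dom_range = c(2L, 4L),
                         miss_frac = 0, seed = 1L) {
  set.seed(seed)
  sizes <- sample(dom_range[1]:dom_range[2], n_attrs, replace = TRUE)
  attrs <- c(lapply(seq_len(n_attrs), function(j) {
    list(name = paste0("A", j), domain = paste0("v", j, "_", seq_len(sizes[j])))
  }), list(list(name = "class", domain = c("y0", "y1"), role = "class")))
  schema <- cat_schema(attrs)
  df <- as.data.frame(lapply(seq_len(n_attrs), function(j) {
    sample(paste0("v", j, "_", seq_len(sizes[j])), n_rows, replace = TRUE)
  }))
  names(df) <- paste0("A", seq_len(n_attrs))
  df$class <- sample(c("y0", "y1"), n_rows, replace = TRUE)
  if (miss_frac > 0) {
    cells <- expand.grid(r = seq_len(n_rows), j = seq_len(n_attrs))
    hit <- cells[sample.int(nrow(cells), round(miss_frac * nrow(cells))), ]
    for (i in seq_len(nrow(hit))) df[hit$r[i], hit$j[i]] <- NA
  }
  discrete_table(df, schema)
}

# Central finite-difference gradients of bce_loss(forward(model, X), Y) for
# every parameter; the independent oracle for backprop.
fd_gradients <- function(model, X, Y, h = 1e-6) {
  loss_at <- function(m) bce_loss(forward(m, X)$output, Y)
  dW <- lapply(model$W, function(w) w * 0)
  db <- lapply(model$b, function(b) b * 0)
  for (l in seq_along(model$W)) {
    for (i in seq_along(model$W[[l]])) {
      mp <- model; mp$W[[l]][i] <- mp$W[[l]][i] + h
      mm <- model; mm$W[[l]][i] <- mm$W[[l]][i] - h
      dW[[l]][i] <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    }
    for (i in seq_along(model$b[[l]])) {
      mp <- model; mp$b[[l]][i] <- mp$b[[l]][i] + h
      mm <- model; mm$b[[l]][i] <- mm$b[[l]][i] - h
      db[[l]][i] <- (loss_at(mp) - loss_at(mm)) / (2 * h)
    }
  }
  list(dW = dW, db = db)
}

max_rel_grad_err <- function(analytic, numeric) {
  errs <- c()
  for (l in seq_along(analytic$dW)) {
    for (part in c("dW", "db")) {
      a <- analytic[[part]][[l]]; n <- numeric[[part]][[l]]
      errs <- c(errs, abs(a - n) / pmax(abs(n), 1e-6))
    }
  }
  max(errs)
}

# Brute-force donor search: for one incomplete row, Hamming distance to every
# complete row over the observed categorical attributes, counted attribute by
# attribute (x2 per disagreement in one-hot space).
oracle_hotdeck <- function(table) {
  parts <- split_by_completeness(table)
  dcom <- parts$dcom
  m <- missing_mask(table)
  data <- table$data
  cat_attrs <- which(vapply(table$schema$attributes, function(a)
    a$kind == "categorical", TRUE))
  for (r in which(rowSums(m) > 0)) {
    obs <- intersect(cat_attrs, which(!m[r, ]))
    d <- vapply(seq_len(nrow(dcom$data)), function(i) {
      2L * sum(vapply(obs, function(j)
        dcom$data[[j]][i] != data[[j]][r], TRUE))
    }, integer(1))
    donor <- which.min(d)  # first minimum = lowest index
    for (j in which(m[r, ])) data[[j]][r] <- dcom$data[[j]][donor]
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

oracle_knn <- function(table, k) {
  parts <- split_by_completeness(table)
  dcom <- parts$dcom
  k <- min(k, nrow(dcom$data))
  m <- missing_mask(table)
  data <- table$data
  cat_attrs <- which(vapply(table$schema$attributes, function(a)
    a$kind == "categorical", TRUE))
  for (r in which(rowSums(m) > 0)) {
    obs <- intersect(cat_attrs, which(!m[r, ]))
    d <- vapply(seq_len(nrow(dcom$data)), function(i) {
      2L * sum(vapply(obs, function(j)
        dcom$data[[j]][i] != data[[j]][r], TRUE))
    }, integer(1))
    near <- order(d, seq_along(d))[seq_len(k)]
    for (j in which(m[r, ])) {
      dom <- schema_dom(table, j)
      w <- vapply(dom, function(v)
        sum((1 / (1 + d[near]))[dcom$data[[j]][near] == v]), 0)
      f <- vapply(dom, function(v) sum(dcom$data[[j]][near] == v), 0)
      data[[j]][r] <- dom[order(-w, -f, seq_along(dom))[1]]
    }
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

schema_dom <- function(table, j) table$schema$attributes[[j]]$domain

oracle_mode <- function(table) {
  m <- missing_mask(table)
  data <- table$data
  for (j in which(colSums(m) > 0)) {
    dom <- schema_dom(table, j)
    counts <- vapply(dom, function(v) sum(data[[j]] == v, na.rm = TRUE), 0L)
    data[[j]][m[, j]] <- dom[which.max(counts)]
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

# Imputer closure contract: complete output, observed cells untouched, every
# fill inside its attribute's domain.
expect_valid_imputation <- function(imputed, original_with_missing) {
  m <- missing_mask(original_with_missing)
  expect_false(any(missing_mask(imputed)))
  obs <- as.matrix(original_with_missing$data)[!m]
  expect_identical(as.matrix(imputed$data)[!m], obs)
  for (j in seq_len(ncol(m))) {
    if (!any(m[, j])) next
    expect_true(all(imputed$data[[j]][m[, j]] %in% schema_dom(imputed, j)))
  }
}

# Stub learner that always predicts the training-set majority label;
# equivalent to mode imputation when used through impute_learner.
stub_majority_learner <- function() {
  function() list(
    fit = function(X, y) {
      tab <- table(y)
      list(label = names(tab)[which.max(tab)])
    },
    predict = function(fitted, X) rep(fitted$label, nrow(X)))
}
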