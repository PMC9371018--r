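#' Mechanism-aware prefilling
#'
#' Provisional imputation applied before network training so incomplete rows
#' can also serve as training inputs. Under MCAR the frequency-weighted
#' random imputer is used; under MAR and NMAR the mode imputer. The original
#' missing mask is returned untouched for later target bookkeeping.
#'
#' @param table A \code{discrete_table}.
#' @param mechanism One of \code{"MCAR"}, \code{"MAR"}, \code{"NMAR"}.
#' @param seed RNG seed (used by the MCAR random prefill).
#' @return List with \code{table} (complete) and \code{mask} (the original
#'   logical missing mask).
#' @export
prefill <- function(table, mechanism = c("MCAR", "MAR", "NMAR"), seed = 1L) {
  mechanism <- match.arg(mechanism)
  mask <- missing_mask(table)
  filled <- if (mechanism == "MCAR") impute_random(table, seed = seed)
            else impute_mode(table)
  list(table = filled, mask = mask)
}

# Shared engine behind the momentum-trained, prefilled imputer and the plain
# (beta = 0, no-prefill) baseline. `source` is the table rows are encoded
# from; `train_rows(mt)` selects each type's training rows.
typed_mlp_engine <- function(table, config, source, mask, train_rows_fn) {
  types <- detect_missing_types(table)
  layout <- onehot_layout(table$schema, table)
  all_attrs <- seq_along(table$schema$attributes)
  models <- vector("list", length(types))
  for (i in seq_along(types)) {
    mt <- types[[i]]
    inputs <- setdiff(all_attrs, mt$missing_attrs)
    rows <- train_rows_fn(mt)
    if (length(rows) == 0L) {
      stop(sprintf("no eligible training rows for missing type {%s}",
                   paste(mt$missing_attrs, collapse = ",")))
    }
    X <- encode_one_hot(source, layout, rows = rows, attrs = inputs)
    Y <- encode_one_hot(source, layout, rows = rows, attrs = mt$missing_attrs)
    cfg <- config
    cfg$seed <- derive_seed(config$seed, 100L + i)
    fit <- train_mlp(X, Y, cfg)
    stopifnot(fit$model$dims[1] == sum(layout$widths[inputs]),
              fit$model$dims[length(fit$model$dims)] ==
                sum(layout$widths[mt$missing_attrs]))
    models[[i]] <- list(type = mt, model = fit$model, input_attrs = inputs,
                        output_attrs = mt$missing_attrs,
                        loss_trace = fit$loss_trace)
  }
  structure(list(types = types, models = models, layout = layout,
                 source = source, mask = mask, config = config),
            class = "type_model_set")
}

#' Fit one network per missing type
#'
#' Detects the missing types of \code{table}, prefills it according to the
#' mechanism, and trains one momentum-optimized multilayer perceptron per
#' type: inputs are the one-hot blocks of the attributes outside the type,
#' targets the blocks of the attributes inside it. A row enters a type's
#' training set when its original mask does not intersect the type's missing
#' attributes, so targets are genuinely observed while inputs may contain
#' prefilled values — incomplete rows of other types still contribute
#' training signal.
#'
#' @param table A \code{discrete_table} with at least one missing cell and at
#'   least one complete row.
#' @param mechanism Missing mechanism tag driving the prefill strategy.
#' @param config A \code{\link{train_config}}.
#' @return A \code{type_model_set}: per missing type the trained model, its
#'   input/output attribute lists and loss trace, plus the shared layout,
#'   prefilled source table and original mask.
#' @export
fit_type_models <- function(table, mechanism = c("MCAR", "MAR", "NMAR"),
                            config = train_config()) {
  mechanism <- match.arg(mechanism)
  pre <- prefill(table, mechanism, seed = derive_seed(config$seed, 3L))
  mask <- pre$mask
  typed_mlp_engine(table, config, source = pre$table, mask = mask,
                   train_rows_fn = function(mt) {
                     hit <- rowSums(mask[, mt$missing_attrs, drop = FALSE]) > 0
                     which(!hit)
                   })
}

predict_type_fills <- function(fit, table) {
  data <- table$data
  mask <- fit$mask
  for (m in fit$models) {
    mt <- m$type
    X <- encode_one_hot(fit$source, fit$layout, rows = mt$rows,
                        attrs = m$input_attrs)
    out <- forward(m$model, X)$output
    labels <- decode_one_hot(out, fit$layout, attrs = m$output_attrs)
    for (ji in seq_along(m$output_attrs)) {
      j <- m$output_attrs[ji]
      data[[j]][mt$rows] <- labels[, ji]
    }
  }
  discrete_table(data, table$schema, row_ids = table$row_ids)
}

#' Per-missing-type MLP imputation with momentum and prefilling
#'
#' The package's headline imputer: missing types are detected, the table is
#' prefilled according to the stated mechanism (random fills under MCAR, mode
#' fills under MAR/NMAR), one multilayer perceptron is trained per type with
#' momentum gradient descent, and each incomplete row's missing cells are
#' replaced by the decoded outputs of its type's network. The complete and
#' imputed partitions are merged back in original row order.
#'
#' @param table A \code{discrete_table}.
#' @param mechanism The missing mechanism the data is assumed to follow
#'   (supplied by the user; it selects the prefill strategy).
#' @param config A \code{\link{train_config}}.
#' @return A complete \code{discrete_table} in the original row order.
#' @export
impute_typed_mlp <- function(table, mechanism = c("MCAR", "MAR", "NMAR"),
                             config = train_config()) {
  mechanism <- match.arg(mechanism)
  if (!any(missing_mask(table))) return(table)
  fit <- fit_type_models(table, mechanism, config)
  predict_type_fills(fit, table)
}

# Plain baseline: beta = 0, no prefilling, per-type training on the complete
# rows only. Prediction inputs of a type's rows are observed by definition of
# the type, so no prefill is needed there either.
typed_mlp_impute <- function(table, config, prefill_fn = NULL) {
  if (!any(missing_mask(table))) return(table)
  parts <- split_by_completeness(table)
  if (n_rows(parts$dcom) == 0L) stop("no complete rows available for training")
  mask <- missing_mask(table)
  dcom_rows <- which(rowSums(mask) == 0)
  # the mode-filled source is only a complete container for encoding: training
  # rows are complete and a type's prediction inputs exclude its own missing
  # attributes, so no mode fill is ever encoded for this baseline
  fit <- typed_mlp_engine(table, config, source = impute_mode(table),
                          mask = mask,
                          train_rows_fn = function(mt) dcom_rows)
  predict_type_fills(fit, table)
}
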