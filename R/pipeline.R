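#' Encode every site of a bundle into the feature matrix
#'
#' Convenience wrapper chaining [extract_windows()] and
#' [encode_features()] over an `acet_bundle` (in-memory or read from
#' disk). Encoders whose resources the bundle lacks must be excluded
#' explicitly.
#'
#' @param bundle an `acet_bundle` ([simulate_acetylome()], [read_bundle()]).
#' @param properties normalized property table; defaults to the bundled
#'   synthetic tables ([default_properties()]).
#' @inheritParams encode_features
#' @param flank window flank (default 9).
#' @param ... further arguments passed to [encode_features()].
#' @return the encoded feature tibble (id columns `protein_id`,
#'   `position`, `label` followed by the feature columns).
#' @export
encode_bundle <- function(bundle,
                          properties = default_properties(),
                          encoders = c("pcp", "pssm", "ac", "rc", "ss", "asa"),
                          flank = 9, ...) {
  stopifnot(inherits(bundle, "acet_bundle"))
  windows <- extract_windows(bundle$proteins, bundle$sites, flank = flank)
  encode_features(windows,
                  properties = properties,
                  pssms = bundle$pssms,
                  structure = bundle$structure,
                  encoders = encoders, ...)
}

#' Select SVM hyperparameters on a validation split
#'
#' Small grid search over the cost parameter and the RBF width, scoring
#' each candidate by validation MCC of the given model type. Mirrors the
#' standard practice of reserving a validation set for parameter
#' optimization; ties resolve to the earliest grid point
#' (`cost = costs[1]`, `gamma = 1/dim`).
#'
#' @param train,validation encoded feature tibbles (feature columns only,
#'   or with id columns which are dropped).
#' @param train_labels,validation_labels binary labels (0/1).
#' @param model which model the parameters are for: `"cascade"`,
#'   `"balanced"` (single balanced SVM) or `"all"` (single SVM on all
#'   rows).
#' @param costs candidate cost values (default `c(1, 8)`).
#' @param gamma_factors multipliers of the `1/dim` default width
#'   (default `c(1, 0.1, 0.01)`).
#' @inheritParams train_cascade
#' @return list with `cost`, `gamma` and the full `grid` tibble
#'   (`cost`, `gamma`, `mcc`).
#' @export
tune_svm_params <- function(train, train_labels,
                            validation, validation_labels,
                            model = c("cascade", "balanced", "all"),
                            costs = c(1, 8), gamma_factors = c(1, 0.1, 0.01),
                            q = 0.95, stop_frac = 0.05, seed = 1) {
  model <- match.arg(model)
  d <- ncol(.feature_matrix(train))
  grid <- tidyr::expand_grid(cost = costs, gamma = gamma_factors / d)
  grid$mcc <- purrr::map2_dbl(grid$cost, grid$gamma, function(C, g) {
    pred <- switch(model,
      cascade = {
        fit <- suppressWarnings(train_cascade(
          train, train_labels, q = q, stop_frac = stop_frac,
          cost = C, gamma = g, seed = seed))
        predict(fit, validation)$pred
      },
      balanced = {
        fit <- train_single_balanced(train, train_labels, cost = C,
                                     gamma = g, seed = seed)
        predict_scores(fit, validation)$pred
      },
      all = {
        fit <- train_single_all(train, train_labels, cost = C, gamma = g)
        predict_scores(fit, validation)$pred
      })
    classification_metrics(validation_labels, pred)$mcc
  })
  best <- which.max(grid$mcc)   # first maximum: earliest grid point on ties
  list(cost = grid$cost[best], gamma = grid$gamma[best], grid = grid)
}

#' Train the cascade and both single-SVM baselines on one feature set
#'
#' Used by the comparison experiment: fits the cascade, a single SVM on
#' the full (imbalanced) training data, and a single SVM on one balanced
#' subsample, then evaluates all three on a test set. When a validation
#' set is supplied, the cascade's and the balanced SVM's `(cost, gamma)`
#' are first optimized on it with [tune_svm_params()]; the all-data SVM
#' always keeps the given (default) parameters, because it stands for the
#' naive treatment of imbalanced data whose failure mode the comparison
#' demonstrates — tuning it away would change what is being compared.
#'
#' @param train,test encoded feature tibbles with a `label` column.
#' @param validation optional encoded feature tibble with a `label`
#'   column, used for per-model hyperparameter selection.
#' @inheritParams train_cascade
#' @return tibble with one row per model (`model`, then the
#'   [classification_metrics()] columns and the `cost`/`gamma` used).
#' @export
compare_classifiers <- function(train, test, validation = NULL,
                                q = 0.95, stop_frac = 0.05,
                                cost = 1, gamma = NULL, seed = 1) {
  stopifnot("label" %in% names(train), "label" %in% names(test))
  params <- list(cascade = list(cost = cost, gamma = gamma),
                 balanced = list(cost = cost, gamma = gamma),
                 all = list(cost = cost, gamma = gamma))
  if (!is.null(validation)) {
    stopifnot("label" %in% names(validation))
    for (m in c("cascade", "balanced")) {
      params[[m]] <- tune_svm_params(train, train$label,
                                     validation, validation$label,
                                     model = m, q = q,
                                     stop_frac = stop_frac, seed = seed)
    }
  }
  cascade <- suppressWarnings(train_cascade(
    train, train$label, q = q, stop_frac = stop_frac,
    cost = params$cascade$cost, gamma = params$cascade$gamma, seed = seed))
  single_all <- train_single_all(train, train$label,
                                 cost = params$all$cost,
                                 gamma = params$all$gamma)
  single_bal <- train_single_balanced(train, train$label,
                                      cost = params$balanced$cost,
                                      gamma = params$balanced$gamma,
                                      seed = seed)
  gdef <- 1 / ncol(.feature_matrix(test[, setdiff(names(test), "label")]))
  row <- function(metrics, name, prm) {
    dplyr::mutate(metrics, model = name, .before = 1) |>
      dplyr::mutate(cost = prm$cost,
                    gamma = if (is.null(prm$gamma)) gdef else prm$gamma)
  }
  dplyr::bind_rows(
    row(classification_metrics(test$label, predict(cascade, test)$pred),
        "cascade", params$cascade),
    row(classification_metrics(test$label,
                               predict_scores(single_all, test)$pred),
        "single_all", params$all),
    row(classification_metrics(test$label,
                               predict_scores(single_bal, test)$pred),
        "single_balanced", params$balanced)
  )
}
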