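## -- internal RBF-SVM scorer -------------------------------------------------
## Wraps e1071::svm so that higher decision values always mean "more
## positive", regardless of the factor-level order libsvm picked.
## The importFrom is load-bearing: it forces the e1071 namespace (and its
## predict.svm S3 registration) to load with this package, so models
## restored from an archive can predict in a fresh session.

#' @importFrom e1071 svm
NULL

## Feature blocks live on very different raw scales (PSSM integers vs.
## one-hot bits), which would make the RBF distance meaningless, so the
## scorer standardizes columns with training-set mean/SD (constant
## columns pass through) before fitting.
.fit_svm_scorer <- function(X, y, cost = 1, gamma = NULL, scale = TRUE) {
  X <- as.matrix(X)
  if (is.null(gamma)) gamma <- 1 / ncol(X)
  center <- scl <- NULL
  if (scale) {
    center <- colMeans(X)
    scl <- apply(X, 2, stats::sd)
    scl[scl == 0 | is.na(scl)] <- 1
    X <- sweep(sweep(X, 2, center), 2, scl, "/")
  }
  yf <- factor(y, levels = c(0, 1))
  fit <- tryCatch(
    e1071::svm(x = X, y = yf, kernel = "radial", cost = cost, gamma = gamma,
               scale = FALSE),
    error = function(e) stop("SVM training failed: ", conditionMessage(e),
                             call. = FALSE)
  )
  list(fit = fit, cols = colnames(X), center = center, scale = scl)
}

.svm_scores <- function(scorer, X) {
  X <- as.matrix(X)
  if (!is.null(scorer$cols)) {
    if (!all(scorer$cols %in% colnames(X))) {
      stop("newdata is missing feature column(s): ",
           paste(utils::head(setdiff(scorer$cols, colnames(X)), 5),
                 collapse = ", "), call. = FALSE)
    }
    X <- X[, scorer$cols, drop = FALSE]
  }
  if (!is.null(scorer$center)) {
    X <- sweep(sweep(X, 2, scorer$center), 2, scorer$scale, "/")
  }
  pred <- stats::predict(scorer$fit, X, decision.values = TRUE)
  dv <- attr(pred, "decision.values")
  ## column name "a/b": positive values favour class a
  flip <- if (sub("/.*", "", colnames(dv)[1]) == "1") 1 else -1
  as.numeric(dv[, 1]) * flip
}

#' Train one balanced SVM layer
#'
#' Fits a radial-basis SVM on a positive set and an equally sized negative
#' subset. Exposed mostly for testing and for custom cascade assembly;
#' [train_cascade()] calls it internally.
#'
#' @param pd data frame of positive feature rows.
#' @param nd data frame of negative feature rows, `nrow(nd) == nrow(pd)`.
#' @param cost SVM cost parameter C (default 1).
#' @param gamma RBF kernel width; default `1 / n_features`.
#' @param scale standardize columns to training mean/SD before fitting?
#'   default `TRUE` (feature blocks have very different raw scales;
#'   constant columns pass through unscaled).
#' @return a scorer object usable with [predict_scores()].
#' @export
train_balanced_layer <- function(pd, nd, cost = 1, gamma = NULL, scale = TRUE) {
  stopifnot(nrow(pd) == nrow(nd))
  scorer <- .fit_svm_scorer(rbind(as.matrix(pd), as.matrix(nd)),
                            c(rep(1L, nrow(pd)), rep(0L, nrow(nd))),
                            cost = cost, gamma = gamma, scale = scale)
  structure(list(scorer = scorer, threshold = 0), class = "svm_scorer")
}

#' Layer threshold from positive decision values
#'
#' Sorts the positive decision values in descending order and returns the
#' value at 1-based rank `ceiling(q * M)` where `M` is the number of
#' positives; at least `ceiling(q * M)` positives therefore score at or
#' above the threshold, i.e. at most a fraction `1 - q` of positives is
#' sacrificed per layer.
#'
#' @param pd_scores numeric decision values of the positive samples.
#' @param q positive-retention quantile (default 0.95).
#' @return the threshold, a single number.
#' @export
layer_threshold <- function(pd_scores, q = 0.95) {
  m <- length(pd_scores)
  if (m < 1) stop("empty positive score vector", call. = FALSE)
  stopifnot(q > 0, q <= 1)
  sort(pd_scores, decreasing = TRUE)[ceiling(q * m)]
}

#' Train a cascade of balanced SVM layers
#'
#' Resolves heavy negative:positive imbalance by training balanced layers
#' on the full positive set `PD` and a rotating negative subset `ND`:
#'
#' 1. `ND` starts as a uniform random subset of the total negatives `TND`
#'    with `|ND| = |PD| = M`; fit a balanced RBF SVM on `PD` and `ND`.
#' 2. Score `PD` and the surviving `TND` with the layer.
#' 3. The layer threshold `T_i` is the `ceiling(q * M)`-th largest
#'    positive decision value ([layer_threshold()]).
#' 4. Negatives scoring below `T_i` are confidently negative and are
#'    removed from `TND`; the pair `(S_i, T_i)` becomes layer `i`.
#' 5. The next `ND` is the `M` surviving negatives with the lowest
#'    decision values — the hardest negatives.
#' 6. Stop when a round removes fewer than `stop_frac * |TND_0|`
#'    negatives (the triggering layer is retained).
#'
#' Prediction ([predict.cascade_model()]) is the conjunction over layers.
#'
#' @param features data frame / tibble of numeric feature columns (id
#'   columns such as `protein_id`, `position`, `label` are dropped
#'   automatically if present).
#' @param labels binary vector, 1 = acetylated.
#' @param q positive-retention quantile per layer (default 0.95).
#' @param stop_frac stopping fraction of the original negative pool
#'   (default 0.05).
#' @inheritParams train_balanced_layer
#' @param seed integer seed for the initial negative draw.
#' @param max_layers safety cap on the number of layers (default 100).
#' @param layer_trainer optional injected scorer factory making the
#'   cascade classifier-agnostic: a function `(X, y)` (matrix, 0/1
#'   labels) returning a list with a `score` function mapping a matrix to
#'   numeric decision values, higher meaning more positive. Default: the
#'   balanced RBF SVM.
#' @return a `cascade_model` object; see [tidy.cascade_model()] for the
#'   per-layer training log.
#' @export
train_cascade <- function(features, labels, q = 0.95, stop_frac = 0.05,
                          cost = 1, gamma = NULL, seed = 1, max_layers = 100,
                          layer_trainer = NULL) {
  X <- .feature_matrix(features)
  stopifnot(nrow(X) == length(labels))
  pd_idx <- which(labels == 1)
  tnd_idx <- which(labels == 0)
  m <- length(pd_idx)
  if (m < 2) stop("need at least 2 positive samples", call. = FALSE)
  if (length(tnd_idx) < m) {
    stop("need at least as many negatives as positives", call. = FALSE)
  }
  tnd0 <- length(tnd_idx)
  pd <- X[pd_idx, , drop = FALSE]
  if (is.null(layer_trainer)) {
    layer_trainer <- function(Xtr, ytr) {
      scorer <- .fit_svm_scorer(Xtr, ytr, cost = cost, gamma = gamma)
      rm(Xtr, ytr)  # keep the closure environment (and archives) small
      list(score = function(Xn) .svm_scores(scorer, Xn))
    }
  }

  set.seed(seed)
  nd_idx <- sort(sample(tnd_idx, m))
  layers <- list()
  log <- list()
  surviving <- tnd_idx
  repeat {
    scorer <- layer_trainer(rbind(pd, X[nd_idx, , drop = FALSE]),
                            c(rep(1L, m), rep(0L, length(nd_idx))))
    pd_scores <- scorer$score(pd)
    tnd_scores <- scorer$score(X[surviving, , drop = FALSE])
    t_i <- layer_threshold(pd_scores, q)
    removed <- tnd_scores < t_i
    layers[[length(layers) + 1L]] <- list(scorer = scorer, threshold = t_i)
    log[[length(log) + 1L]] <- tibble::tibble(
      layer = length(layers),
      tnd_before = length(surviving),
      n_removed = sum(removed),
      tnd_after = length(surviving) - sum(removed),
      threshold = t_i,
      n_pos_below = sum(pd_scores < t_i)
    )
    keep_scores <- tnd_scores[!removed]
    surviving <- surviving[!removed]
    if (sum(removed) < stop_frac * tnd0) break
    if (length(layers) >= max_layers) {
      warning("cascade stopped at max_layers = ", max_layers)
      break
    }
    if (length(surviving) < m) {
      warning("fewer surviving negatives (", length(surviving),
              ") than positives (", m, "); cascade terminated")
      break
    }
    ## hardest negatives: lowest decision values, stable index tie-break
    nd_idx <- surviving[order(keep_scores, seq_along(keep_scores))[seq_len(m)]]
  }
  structure(list(
    layers = layers,
    feature_names = colnames(X),
    q = q, stop_frac = stop_frac, cost = cost,
    gamma = if (is.null(gamma)) 1 / ncol(X) else gamma,
    seed = seed,
    n_pos = m, n_neg = tnd0,
    log = dplyr::bind_rows(log)
  ), class = "cascade_model")
}

.feature_matrix <- function(features) {
  if (is.matrix(features)) return(features)
  drop_cols <- intersect(c("protein_id", "position", "label", "window"),
                         names(features))
  as.matrix(features[, setdiff(names(features), drop_cols), drop = FALSE])
}

#' @export
print.cascade_model <- function(x, ...) {
  cat("Cascade SVM model:", length(x$layers), "layer(s)\n")
  cat("  positives:", x$n_pos, " negatives:", x$n_neg,
      sprintf(" (%.1f:1)\n", x$n_neg / x$n_pos))
  cat("  q =", x$q, ", stop_frac =", x$stop_frac,
      ", cost =", x$cost, ", gamma =", signif(x$gamma, 3), "\n")
  cat("  negatives surviving all layers:",
      x$log$tnd_after[nrow(x$log)], "\n")
  invisible(x)
}

#' Predict acetylation labels with a cascade model
#'
#' A sample is positive only if its decision value reaches every layer's
#' threshold; it is classified negative at the first layer `i` with
#' `Dec_i < T_i` and is not scored by later layers.
#'
#' @param object a `cascade_model`.
#' @param newdata data frame with the model's feature columns (id columns
#'   are carried through to the output if present).
#' @param ... unused.
#' @return a tibble with `pred` (0/1) and `exit_layer` (the layer that
#'   rejected the sample; `NA` for predicted positives), preceded by any
#'   id columns of `newdata`.
#' @export
predict.cascade_model <- function(object, newdata, ...) {
  X <- .feature_matrix(newdata)
  missing <- setdiff(object$feature_names, colnames(X))
  if (length(missing) > 0) {
    stop("newdata lacks feature column(s): ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  X <- X[, object$feature_names, drop = FALSE]
  n <- nrow(X)
  alive <- rep(TRUE, n)
  exit_layer <- rep(NA_integer_, n)
  for (i in seq_along(object$layers)) {
    if (!any(alive)) break
    ly <- object$layers[[i]]
    sc <- ly$scorer$score(X[alive, , drop = FALSE])
    fail <- sc < ly$threshold
    exit_layer[which(alive)[fail]] <- i
    alive[which(alive)[fail]] <- FALSE
  }
  id <- if (is.data.frame(newdata)) {
    newdata[, intersect(c("protein_id", "position", "label"),
                        names(newdata)), drop = FALSE]
  } else NULL
  out <- tibble::tibble(pred = as.integer(alive), exit_layer = exit_layer)
  if (!is.null(id) && ncol(id) > 0) out <- dplyr::bind_cols(id, out)
  out
}

#' Decision values of one cascade layer
#'
#' Diagnostic accessor: raw decision values of layer `layer` for every row
#' of `newdata` (no short-circuiting).
#'
#' @inheritParams predict.cascade_model
#' @param layer 1-based layer index.
#' @return numeric vector of decision values.
#' @export
cascade_layer_scores <- function(object, newdata, layer = 1) {
  stopifnot(inherits(object, "cascade_model"),
            layer >= 1, layer <= length(object$layers))
  X <- .feature_matrix(newdata)[, object$feature_names, drop = FALSE]
  object$layers[[layer]]$scorer$score(X)
}

#' Baseline: a single SVM trained on all data
#'
#' With ~10:1 imbalance this baseline collapses towards the majority
#' class (near-zero sensitivity, near-perfect specificity); it is provided
#' for the comparison experiment against the cascade.
#'
#' @inheritParams train_cascade
#' @return an `svm_scorer` object (threshold 0).
#' @export
train_single_all <- function(features, labels, cost = 1, gamma = NULL) {
  X <- .feature_matrix(features)
  structure(list(scorer = .fit_svm_scorer(X, labels, cost = cost,
                                          gamma = gamma),
                 threshold = 0),
            class = "svm_scorer")
}

#' Baseline: a single SVM trained on one balanced subsample
#'
#' Uses all positives and a single seeded uniform subsample of negatives
#' of the same size.
#'
#' @inheritParams train_cascade
#' @return an `svm_scorer` object (threshold 0).
#' @export
train_single_balanced <- function(features, labels, cost = 1, gamma = NULL,
                                  seed = 1) {
  X <- .feature_matrix(features)
  pd_idx <- which(labels == 1)
  nd_pool <- which(labels == 0)
  m <- min(length(pd_idx), length(nd_pool))
  set.seed(seed)
  nd_idx <- if (length(nd_pool) > m) sort(sample(nd_pool, m)) else nd_pool
  pd_idx <- if (length(pd_idx) > m) sort(sample(pd_idx, m)) else pd_idx
  structure(list(scorer = .fit_svm_scorer(
    X[c(pd_idx, nd_idx), , drop = FALSE],
    c(rep(1L, length(pd_idx)), rep(0L, length(nd_idx))),
    cost = cost, gamma = gamma),
    threshold = 0), class = "svm_scorer")
}

#' Decision values and labels from a single-SVM baseline
#'
#' @param object an `svm_scorer` from [train_single_all()],
#'   [train_single_balanced()] or [train_balanced_layer()].
#' @param newdata data frame with the feature columns.
#' @return tibble `score`, `pred`.
#' @export
predict_scores <- function(object, newdata) {
  stopifnot(inherits(object, "svm_scorer"))
  sc <- .svm_scores(object$scorer, .feature_matrix(newdata))
  tibble::tibble(score = sc, pred = as.integer(sc >= object$threshold))
}

#' Save / load a cascade model archive
#'
#' The archive holds the layer SVMs and thresholds, feature names,
#' configuration and training log in one uncompressed RDS file; identical
#' training configuration and seed yield byte-identical archives.
#'
#' @param model a `cascade_model`.
#' @param path file path.
#' @return `path` (write) or the model (read).
#' @export
write_cascade <- function(model, path) {
  stopifnot(inherits(model, "cascade_model"))
  saveRDS(model, path, compress = FALSE)
  invisible(path)
}

#' @rdname write_cascade
#' @export
read_cascade <- function(path) {
  model <- readRDS(path)
  stopifnot(inherits(model, "cascade_model"))
  model
}
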