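#' Discretize a numeric column into three bins at mean +/- one SD
#'
#' The default discretization used before mutual-information estimation:
#' values below `mean - sd` code to -1, above `mean + sd` to +1, the rest
#' to 0. A constant column yields a single code.
#'
#' @param x numeric vector with finite values.
#' @return integer codes in `{-1, 0, 1}`.
#' @export
discretize_msd <- function(x) {
  stopifnot(all(is.finite(x)))
  s <- stats::sd(x)
  if (is.na(s) || s == 0) return(rep(0L, length(x)))
  m <- mean(x)
  ifelse(x < m - s, -1L, ifelse(x > m + s, 1L, 0L))
}

## mutual information (bits) between two small-integer code vectors
.mi <- function(a, b) {
  ja <- match(a, sort(unique(a)))
  jb <- match(b, sort(unique(b)))
  na <- max(ja); nb <- max(jb)
  joint <- tabulate((ja - 1L) * nb + jb, nbins = na * nb) / length(a)
  pa <- rowSums(matrix(joint, nrow = na, byrow = TRUE))
  pb <- colSums(matrix(joint, nrow = na, byrow = TRUE))
  ep <- outer(pa, pb)
  nz <- joint > 0
  sum(joint[nz] * log2(joint[nz] / as.vector(t(ep))[nz]))
}

#' Rank features by minimum-redundancy maximum-relevance (mRMR)
#'
#' Greedy forward ranking with the mutual-information difference (MID)
#' criterion: the first feature maximizes \eqn{I(f; y)}; each subsequent
#' feature maximizes \eqn{I(f; y) - \frac{1}{|S|}\sum_{g \in S} I(f; g)}
#' over the already-selected set \eqn{S}. Features are discretized with
#' [discretize_msd()] before MI estimation. Ties break towards the lower
#' column index, so the ranking is deterministic.
#'
#' @param features data frame / tibble of numeric feature columns.
#' @param labels binary vector (0/1), one per row.
#' @param k number of features to rank (default 300); clamped to the
#'   number of columns with a warning when larger.
#' @return tibble `rank`, `feature`, `score` (the criterion value at the
#'   step the feature was selected).
#' @export
mrmr_rank <- function(features, labels, k = 300) {
  stopifnot(nrow(features) == length(labels))
  if (min(table(labels)) < 2) {
    stop("need at least 2 samples per class", call. = FALSE)
  }
  p <- ncol(features)
  if (k > p) {
    warning("k = ", k, " exceeds feature count ", p, "; clamping")
    k <- p
  }
  disc <- lapply(features, discretize_msd)
  y <- as.integer(labels)
  rel <- vapply(disc, .mi, numeric(1), b = y)
  selected <- integer(0)
  scores <- numeric(0)
  red_sum <- numeric(p)      # sum of I(f; g) over selected g
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- if (step == 1) {
      rel[remaining]
    } else {
      rel[remaining] - red_sum[remaining] / length(selected)
    }
    pick <- remaining[which.max(crit)]
    selected <- c(selected, pick)
    scores <- c(scores, max(crit))
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
    add <- vapply(disc[remaining], .mi, numeric(1), b = disc[[pick]])
    red_sum[remaining] <- red_sum[remaining] + add
  }
  tibble::tibble(rank = seq_along(selected),
                 feature = names(features)[selected],
                 score = scores)
}

#' Rank features by Fisher score
#'
#' Alternative univariate ranker: \eqn{(\mu_1 - \mu_0)^2 /
#' (\sigma_1^2 + \sigma_0^2)} per feature, descending.
#'
#' @inheritParams mrmr_rank
#' @return tibble `rank`, `feature`, `score`.
#' @export
fisher_rank <- function(features, labels, k = 300) {
  stopifnot(nrow(features) == length(labels))
  k <- min(k, ncol(features))
  y <- as.integer(labels)
  sc <- vapply(features, function(f) {
    m1 <- mean(f[y == 1]); m0 <- mean(f[y == 0])
    v <- stats::var(f[y == 1]) + stats::var(f[y == 0])
    if (v == 0) return(0)
    (m1 - m0)^2 / v
  }, numeric(1))
  ord <- order(-sc, seq_along(sc))[seq_len(k)]
  tibble::tibble(rank = seq_len(k), feature = names(features)[ord],
                 score = sc[ord])
}

#' Incremental feature selection over a ranked list
#'
#' Adds ranked features one at a time, trains a classifier on the growing
#' prefix, and evaluates the Matthews correlation coefficient on the
#' validation set; the optimal subset is the prefix maximizing validation
#' MCC (smallest prefix on ties).
#'
#' @param ranked tibble from [mrmr_rank()] or [fisher_rank()], or a
#'   character vector of feature names in rank order.
#' @param train,validation data frames containing at least the ranked
#'   feature columns.
#' @param train_labels,validation_labels binary labels (0/1).
#' @param trainer function `(features_df, labels, seed) -> model` whose
#'   result works with `predict_scores()`; defaults to a single balanced
#'   RBF SVM ([train_single_balanced()]).
#' @param seed integer seed forwarded to the trainer.
#' @return an `ifs_curve` object: list with `curve` (tibble `n_features`,
#'   `mcc`), `n_selected`, `features` (the optimal subset, in rank order).
#' @export
ifs_select <- function(ranked, train, train_labels,
                       validation, validation_labels,
                       trainer = NULL, seed = 1) {
  feats <- if (is.character(ranked)) ranked else ranked$feature
  stopifnot(length(feats) > 0)
  if (length(unique(validation_labels)) < 2) {
    stop("validation set contains a single class; MCC is undefined",
         call. = FALSE)
  }
  if (is.null(trainer)) {
    trainer <- function(X, y, seed) train_single_balanced(X, y, seed = seed)
  }
  mccs <- vapply(seq_along(feats), function(s) {
    cols <- feats[seq_len(s)]
    fit <- trainer(train[, cols, drop = FALSE], train_labels, seed)
    pred <- predict_scores(fit, validation[, cols, drop = FALSE])
    classification_metrics(validation_labels, as.integer(pred$score >= fit$threshold))$mcc
  }, numeric(1))
  s_star <- which.max(mccs)   # first maximum = smallest subset on ties
  structure(list(
    curve = tibble::tibble(n_features = seq_along(feats), mcc = mccs),
    n_selected = s_star,
    features = feats[seq_len(s_star)]
  ), class = "ifs_curve")
}

#' @export
print.ifs_curve <- function(x, ...) {
  cat("Incremental feature selection curve\n")
  cat("  prefixes evaluated:", nrow(x$curve), "\n")
  cat("  selected subset:", x$n_selected, "features (validation MCC ",
      sprintf("%.4f", x$curve$mcc[x$n_selected]), ")\n", sep = "")
  invisible(x)
}
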