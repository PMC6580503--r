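#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Per-layer training log of a cascade model
#'
#' One row per layer: surviving negative-pool size before and after the
#' layer's pruning step, the number removed, the decision threshold, and
#' how many training positives fell below it.
#'
#' @param x a `cascade_model`.
#' @param ... unused.
#' @return a tibble with columns `layer`, `tnd_before`, `n_removed`,
#'   `tnd_after`, `threshold`, `n_pos_below`.
#' @method tidy cascade_model
#' @export
tidy.cascade_model <- function(x, ...) x$log

#' One-row summary of a cascade model
#'
#' @param x a `cascade_model`.
#' @param ... unused.
#' @return tibble `n_layers`, `n_pos`, `n_neg`, `n_neg_surviving`, `q`,
#'   `stop_frac`, `cost`, `gamma`, `seed`.
#' @method glance cascade_model
#' @export
glance.cascade_model <- function(x, ...) {
  tibble::tibble(
    n_layers = length(x$layers),
    n_pos = x$n_pos, n_neg = x$n_neg,
    n_neg_surviving = x$log$tnd_after[nrow(x$log)],
    q = x$q, stop_frac = x$stop_frac,
    cost = x$cost, gamma = x$gamma, seed = x$seed)
}

#' Tidy the incremental-selection curve
#'
#' @param x an `ifs_curve`.
#' @param ... unused.
#' @return tibble `n_features`, `mcc`, `selected` (logical flag on the
#'   chosen prefix size).
#' @method tidy ifs_curve
#' @export
tidy.ifs_curve <- function(x, ...) {
  dplyr::mutate(x$curve, selected = .data$n_features == x$n_selected)
}

#' One-row summary of an incremental selection run
#'
#' @param x an `ifs_curve`.
#' @param ... unused.
#' @return tibble `n_evaluated`, `n_selected`, `best_mcc`.
#' @method glance ifs_curve
#' @export
glance.ifs_curve <- function(x, ...) {
  tibble::tibble(n_evaluated = nrow(x$curve),
                 n_selected = x$n_selected,
                 best_mcc = x$curve$mcc[x$n_selected])
}

#' Plot an incremental-selection curve
#'
#' Validation MCC against prefix size, with the chosen subset marked.
#'
#' @param object an `ifs_curve`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot ifs_curve
#' @export
autoplot.ifs_curve <- function(object, ...) {
  ggplot2::ggplot(object$curve,
                  ggplot2::aes(x = .data$n_features, y = .data$mcc)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_vline(xintercept = object$n_selected,
                        linetype = "dashed", colour = "firebrick") +
    ggplot2::labs(x = "Number of top-ranked features",
                  y = "Validation MCC",
                  title = sprintf("Incremental feature selection (optimum: %d features)",
                                  object$n_selected)) +
    ggplot2::theme_minimal()
}

#' Plot the negative-pool shrinkage of a cascade model
#'
#' @param object a `cascade_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot cascade_model
#' @export
autoplot.cascade_model <- function(object, ...) {
  d <- object$log
  ggplot2::ggplot(d, ggplot2::aes(x = .data$layer, y = .data$tnd_after)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_hline(yintercept = object$n_pos, linetype = "dotted") +
    ggplot2::labs(x = "Cascade layer", y = "Surviving negatives",
                  title = "Negative pool pruned per cascade layer",
                  subtitle = "dotted line: positive-set size M") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot per-position property profiles
#'
#' @param profile output of [property_profile()].
#' @return a ggplot object (mean +/- SE per class, faceted by property).
#' @export
plot_property_profile <- function(profile) {
  ggplot2::ggplot(profile,
                  ggplot2::aes(x = .data$offset, y = .data$mean,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean - .data$se,
                                        ymax = .data$mean + .data$se),
                           width = 0.2, alpha = 0.6) +
    ggplot2::facet_wrap(~accession, scales = "free_y") +
    ggplot2::labs(x = "Window position relative to the lysine",
                  y = "Standardized property (mean ± SE)") +
    ggplot2::theme_minimal()
}

#' Plot per-class ASA histograms
#'
#' @param distribution output of [asa_distribution()].
#' @return a ggplot object.
#' @export
plot_asa_distribution <- function(distribution) {
  d <- dplyr::mutate(distribution,
                     bin = factor(ifelse(is.finite(.data$bin_hi),
                                         sprintf("%g-%g", .data$bin_lo, .data$bin_hi),
                                         sprintf(">%g", .data$bin_lo)),
                                  levels = unique(ifelse(is.finite(distribution$bin_hi),
                                                         sprintf("%g-%g", distribution$bin_lo, distribution$bin_hi),
                                                         sprintf(">%g", distribution$bin_lo)))))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$bin, y = .data$freq,
                                  fill = .data$class)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = "Accessible surface area (Å²)",
                  y = "Frequency") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
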