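## helpers: long per-position residue table from a windows tibble
.window_long <- function(windows) {
  len <- nchar(windows$window[1])
  flank <- (len - 1L) %/% 2L
  chars <- .char_matrix(windows$window)
  tibble::tibble(
    row = rep(seq_len(nrow(windows)), times = len),
    offset = rep(seq.int(-flank, flank), each = nrow(windows)),
    aa = as.vector(chars),
    label = rep(windows$label, times = len)
  )
}

.class_name <- function(label) ifelse(label == 1, "positive", "negative")

#' Per-position property profile of positive and negative windows
#'
#' Mean and standard error of a standardized physicochemical property at
#' each window position, separately per class. `'X'` positions (padding)
#' are excluded from the averages.
#'
#' @param windows tibble with `window` and `label` columns
#'   ([extract_windows()]).
#' @param norm_properties normalized property table
#'   ([normalize_properties()]); all accessions present are profiled.
#' @return tibble `accession`, `offset`, `class`, `mean`, `se`, `n`.
#' @export
property_profile <- function(windows, norm_properties) {
  long <- .window_long(windows) |> dplyr::filter(.data$aa != "X")
  props <- .prop_vectors(norm_properties)
  purrr::map_dfr(names(props), function(a) {
    long |>
      dplyr::mutate(value = unname(props[[a]][.data$aa]),
                    class = .class_name(.data$label)) |>
      dplyr::group_by(.data$offset, .data$class) |>
      dplyr::summarise(
        mean = mean(.data$value),
        se = if (dplyr::n() > 1) {
          stats::sd(.data$value) / sqrt(dplyr::n())
        } else 0,
        n = dplyr::n(), .groups = "drop") |>
      dplyr::mutate(accession = a, .before = 1)
  })
}

#' Per-position information entropy of positive and negative windows
#'
#' Shannon entropy (base 2) of the 20 amino-acid frequencies at each
#' window position and class, `'X'` excluded from the frequency
#' denominator. Lower entropy means stronger conservation; the maximum is
#' \eqn{\log_2 20 \approx 4.32} at uniform usage.
#'
#' @inheritParams property_profile
#' @return tibble `offset`, `class`, `entropy`, `n`.
#' @export
entropy_profile <- function(windows) {
  .window_long(windows) |>
    dplyr::filter(.data$aa != "X") |>
    dplyr::mutate(class = .class_name(.data$label)) |>
    dplyr::group_by(.data$offset, .data$class) |>
    dplyr::summarise(
      entropy = {
        f <- table(.data$aa) / dplyr::n()
        -sum(f * log2(f))
      },
      n = dplyr::n(), .groups = "drop")
}

#' Per-position composition bias between positive and negative windows
#'
#' For every window position and amino acid, the frequency difference
#' between the positive and negative class with a two-proportion z-test
#' (pooled standard error, two-sided). `'X'` is excluded from counts and
#' denominators. This is the numeric core of a two-sample logo; no
#' rendering is done.
#'
#' @inheritParams property_profile
#' @param alpha significance level for the `call` column (default 0.05).
#' @return tibble `offset`, `aa`, `freq_pos`, `freq_neg`, `diff`, `z`,
#'   `p_value`, `call` (`"enriched"` / `"depleted"` in positives, or
#'   `"ns"`).
#' @export
composition_bias <- function(windows, alpha = 0.05) {
  long <- .window_long(windows) |> dplyr::filter(.data$aa != "X")
  counts <- long |>
    dplyr::mutate(class = .class_name(.data$label)) |>
    dplyr::count(.data$offset, .data$class, .data$aa) |>
    tidyr::complete(offset = unique(long$offset),
                    class = c("positive", "negative"),
                    aa = AA20, fill = list(n = 0L))
  totals <- counts |>
    dplyr::group_by(.data$offset, .data$class) |>
    dplyr::summarise(total = sum(.data$n), .groups = "drop")
  counts |>
    dplyr::left_join(totals, by = c("offset", "class")) |>
    tidyr::pivot_wider(names_from = "class", values_from = c("n", "total")) |>
    dplyr::mutate(
      freq_pos = .data$n_positive / .data$total_positive,
      freq_neg = .data$n_negative / .data$total_negative,
      diff = .data$freq_pos - .data$freq_neg,
      z = {
        p_pool <- (.data$n_positive + .data$n_negative) /
          (.data$total_positive + .data$total_negative)
        se <- sqrt(p_pool * (1 - p_pool) *
                     (1 / .data$total_positive + 1 / .data$total_negative))
        ifelse(se > 0, .data$diff / se, 0)
      },
      p_value = 2 * stats::pnorm(-abs(.data$z)),
      call = dplyr::case_when(
        .data$p_value < alpha & .data$diff > 0 ~ "enriched",
        .data$p_value < alpha & .data$diff < 0 ~ "depleted",
        TRUE ~ "ns")
    ) |>
    dplyr::select("offset", "aa", "freq_pos", "freq_neg", "diff",
                  "z", "p_value", "call")
}

#' Secondary-structure state frequencies at site centers
#'
#' For each class, \eqn{F_i = N_i / N} over the seven DSSP states
#' (H, B, E, G, I, T, S), where `N` is the number of sites in the class;
#' coil takes the remaining mass.
#'
#' @param sites tibble `protein_id`, `position`, `label`.
#' @param structure tibble `protein_id`, `position`, `ss`, `asa`.
#' @return tibble `class`, `state`, `count`, `freq`.
#' @export
ss_frequency <- function(sites, structure) {
  dat <- sites |>
    dplyr::left_join(structure, by = c("protein_id", "position")) |>
    dplyr::mutate(class = .class_name(.data$label))
  if (anyNA(dat$ss)) {
    stop("structure annotation missing for ", sum(is.na(dat$ss)),
         " site(s)", call. = FALSE)
  }
  dat |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      cnt <- unname(vapply(SS7, function(s) sum(d$ss == s), integer(1)))
      tibble::tibble(state = SS7, count = cnt, freq = cnt / nrow(d))
    }) |>
    dplyr::ungroup()
}

#' Binned accessible-surface-area distribution per class
#'
#' Normalized histogram of the center-residue ASA per class, with fixed
#' bins of `bin_width` square Angstroms up to `max_asa` and one open-ended
#' final bin.
#'
#' @inheritParams ss_frequency
#' @param bin_width bin width in square Angstroms (default 10).
#' @param max_asa start of the open-ended last bin (default 150).
#' @return tibble `class`, `bin_lo`, `bin_hi` (`Inf` for the last bin),
#'   `count`, `freq`; frequencies sum to 1 within each class.
#' @export
asa_distribution <- function(sites, structure, bin_width = 10, max_asa = 150) {
  dat <- sites |>
    dplyr::left_join(structure, by = c("protein_id", "position")) |>
    dplyr::mutate(class = .class_name(.data$label))
  if (anyNA(dat$asa)) {
    stop("structure annotation missing for ", sum(is.na(dat$asa)),
         " site(s)", call. = FALSE)
  }
  lo <- c(seq(0, max_asa - bin_width, by = bin_width), max_asa)
  hi <- c(seq(bin_width, max_asa, by = bin_width), Inf)
  dat |>
    dplyr::group_by(.data$class) |>
    dplyr::group_modify(function(d, key) {
      counts <- vapply(seq_along(lo), function(i) {
        sum(d$asa >= lo[i] & d$asa < hi[i])
      }, integer(1))
      tibble::tibble(bin_lo = lo, bin_hi = hi, count = counts,
                     freq = counts / nrow(d))
    }) |>
    dplyr::ungroup()
}
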