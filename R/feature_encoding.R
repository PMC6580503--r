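#' Load amino-acid property tables from an AAindex1 flat file
#'
#' Parses the AAindex1 format: each record starts with `H <accession>`,
#' and the `I` line is followed by two rows of ten values in the standard
#' order (A R N D C Q E G H I / L K M F P S T W Y V).
#'
#' @param path path to an AAindex1-format file.
#' @param accessions character vector of accessions to load. If `NULL`,
#'   all records are loaded and records containing `NA` values are dropped
#'   with a message (indices with missing values cannot be normalized).
#'   Explicitly requesting a record with `NA` values is an error.
#' @return a tibble with columns `accession`, `aa`, `value`
#'   (20 rows per accession, alphabetical amino-acid order).
#' @export
load_aaindex <- function(path, accessions = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  h <- grep("^H ", lines)
  if (length(h) == 0) stop("no AAindex records found in ", path, call. = FALSE)
  acc_all <- sub("^H\\s+", "", lines[h])
  ## order of the two data rows in AAindex1
  row1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I")
  row2 <- c("L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  parse_record <- function(start) {
    i_line <- start + grep("^I ", lines[start:length(lines)])[1] - 1L
    if (is.na(i_line) || i_line + 2L > length(lines)) {
      stop("truncated AAindex record at line ", start, call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(unlist(
      strsplit(trimws(lines[c(i_line + 1L, i_line + 2L)]), "\\s+")
    )))
    if (length(vals) != 20) {
      stop("expected 20 values in AAindex record at line ", start,
           ", got ", length(vals), call. = FALSE)
    }
    stats::setNames(vals, c(row1, row2))[AA20]
  }
  if (is.null(accessions)) {
    keep <- acc_all
  } else {
    absent <- setdiff(accessions, acc_all)
    if (length(absent) > 0) {
      stop("accession(s) not found in ", path, ": ",
           paste(absent, collapse = ", "), call. = FALSE)
    }
    keep <- accessions
  }
  recs <- lapply(keep, function(a) parse_record(h[match(a, acc_all)]))
  has_na <- vapply(recs, anyNA, logical(1))
  if (any(has_na)) {
    if (is.null(accessions)) {
      message("dropping ", sum(has_na), " AAindex record(s) with NA values: ",
              paste(keep[has_na], collapse = ", "))
      recs <- recs[!has_na]
      keep <- keep[!has_na]
    } else {
      stop("AAindex record(s) contain NA values: ",
           paste(keep[has_na], collapse = ", "), call. = FALSE)
    }
  }
  tibble::tibble(
    accession = rep(keep, each = 20L),
    aa = rep(AA20, length(keep)),
    value = unlist(recs, use.names = FALSE)
  )
}

#' Standardize property tables to zero mean and unit standard deviation
#'
#' For property \eqn{j}, each raw value \eqn{P_{i,j}} becomes
#' \eqn{X_{i,j} = (P_{i,j} - \bar P_j) / S_j}, where the mean and the
#' (population) standard deviation are taken over the 20 amino acids.
#' The raw value of `'X'` (padding or ambiguity) is 0 by convention, so
#' after standardization `'X'` maps to \eqn{(0 - \bar P_j)/S_j}; this is
#' returned in the `x_value` column (constant within an accession).
#'
#' @param properties tibble `accession`, `aa`, `value` as returned by
#'   [load_aaindex()].
#' @param x_policy how to standardize the `'X'` symbol:
#'   `"raw-zero-normalized"` (default, the convention above) or `"z-zero"`
#'   (`'X'` maps to standardized 0).
#' @return the input with added columns `z` and `x_value`.
#' @export
normalize_properties <- function(properties,
                                 x_policy = c("raw-zero-normalized", "z-zero")) {
  x_policy <- match.arg(x_policy)
  out <- properties |>
    dplyr::group_by(.data$accession) |>
    dplyr::group_modify(function(d, key) {
      if (nrow(d) != 20) {
        stop("property ", key$accession, " has ", nrow(d),
             " values, expected 20", call. = FALSE)
      }
      m <- mean(d$value)
      s <- sqrt(mean((d$value - m)^2))
      if (s == 0) {
        stop("degenerate property ", key$accession,
             ": zero standard deviation", call. = FALSE)
      }
      d$z <- (d$value - m) / s
      d$x_value <- if (x_policy == "z-zero") 0 else (0 - m) / s
      d
    }) |>
    dplyr::ungroup()
  out
}

## named list: accession -> named numeric over AA20 + "X"
.prop_vectors <- function(norm_properties) {
  stopifnot(all(c("accession", "aa", "z", "x_value") %in% names(norm_properties)))
  split(norm_properties, norm_properties$accession)[
    unique(norm_properties$accession)] |>
    lapply(function(d) {
      v <- stats::setNames(d$z, d$aa)[AA20]
      c(v, X = d$x_value[1])
    })
}

#' Physicochemical property encoding of one peptide window
#'
#' One standardized property value per non-center window position, ordered
#' upstream to downstream, property-major. The center lysine is excluded
#' by default (it is constant across samples and carries no information);
#' set `include_center = TRUE` to keep it.
#'
#' @param window a peptide window string (odd length, center `'K'`).
#' @param norm_properties output of [normalize_properties()].
#' @param include_center keep the center position? default `FALSE`.
#' @return named numeric vector, `n_properties * (len - 1)` long by default.
#' @export
encode_pcp <- function(window, norm_properties, include_center = FALSE) {
  chars <- seq_to_chars(window)
  len <- length(chars)
  flank <- (len - 1L) %/% 2L
  offs <- seq.int(-flank, flank)
  if (!include_center) {
    keep <- offs != 0L
    chars <- chars[keep]
    offs <- offs[keep]
  }
  props <- .prop_vectors(norm_properties)
  unlist(lapply(names(props), function(a) {
    stats::setNames(props[[a]][chars], paste0("pcp_", a, "_", .off_lab(offs)))
  }))
}

.off_lab <- function(offs) {
  ifelse(offs < 0, paste0("m", -offs), ifelse(offs == 0, "c", paste0("p", offs)))
}

#' Auto-covariation encoding of one peptide window
#'
#' For property \eqn{j} and lag \eqn{g}, with \eqn{X_{i,j}} the
#' standardized property at window position \eqn{i} and \eqn{n} the window
#' length: \deqn{AC_{g,j} = \frac{1}{n-g} \sum_{i=1}^{n-g}
#' (X_{i,j} - \bar X_j)(X_{i+g,j} - \bar X_j)} where \eqn{\bar X_j} is the
#' within-window mean over all \eqn{n} positions. `'X'` contributes its
#' standardized value (see [normalize_properties()]).
#'
#' @inheritParams encode_pcp
#' @param lags integer lags, default `c(1, 2)`.
#' @return named numeric vector, property-major then lag.
#' @export
encode_ac <- function(window, norm_properties, lags = c(1, 2)) {
  chars <- seq_to_chars(window)
  n <- length(chars)
  if (any(lags >= n)) {
    stop("lag must be smaller than the window length (", n, ")", call. = FALSE)
  }
  props <- .prop_vectors(norm_properties)
  unlist(lapply(names(props), function(a) {
    x <- unname(props[[a]][chars])
    m <- mean(x)
    vals <- vapply(lags, function(g) {
      i <- seq_len(n - g)
      sum((x[i] - m) * (x[i + g] - m)) / (n - g)
    }, numeric(1))
    stats::setNames(vals, paste0("ac_", a, "_lag", lags))
  }))
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' Parses the `-out_ascii_pssm` dialect: a header line with two blocks of
#' the 20 amino-acid letters, then one row per residue holding the residue
#' index, the residue letter, 20 log-odds scores and 20 weighted
#' percentages. Only the log-odds block is retained.
#'
#' @param path path to the ASCII PSSM file.
#' @param sequence optional protein sequence; if given, the residue column
#'   is checked against it (a mismatch is a warning, not an error, since
#'   ambiguity letters are normalized to `'X'` on our side).
#' @return a tibble with `position`, `residue` and 20 score columns named
#'   by the header's amino-acid order.
#' @export
read_ascii_pssm <- function(path, sequence = NULL) {
  stopifnot(file.exists(path))
  lines <- readLines(path)
  hdr <- grep("^\\s*A\\s+R\\s+N\\s+D", lines)[1]
  if (is.na(hdr)) stop("no PSSM header line found in ", path, call. = FALSE)
  letters20 <- strsplit(trimws(lines[hdr]), "\\s+")[[1]][1:20]
  rows <- list()
  for (i in seq.int(hdr + 1L, length(lines))) {
    ln <- trimws(lines[i])
    if (ln == "" || !grepl("^[0-9]", ln)) break
    f <- strsplit(ln, "\\s+")[[1]]
    if (length(f) < 22) {
      stop("truncated PSSM row at line ", i, " of ", path, call. = FALSE)
    }
    rows[[length(rows) + 1L]] <- f[1:22]
  }
  if (length(rows) == 0) stop("no PSSM rows found in ", path, call. = FALSE)
  m <- do.call(rbind, rows)
  scores <- matrix(as.numeric(m[, 3:22]), nrow = nrow(m),
                   dimnames = list(NULL, letters20))
  if (anyNA(scores)) stop("non-numeric PSSM scores in ", path, call. = FALSE)
  out <- tibble::tibble(position = as.integer(m[, 1]), residue = m[, 2])
  out <- dplyr::bind_cols(out, tibble::as_tibble(scores))
  if (!is.null(sequence)) {
    obs <- normalize_sequence(paste(out$residue, collapse = ""))
    if (nchar(sequence) != nrow(out) || obs != sequence) {
      warning("PSSM residues in ", path,
              " do not match the provided sequence")
    }
  }
  out
}

#' Read all PSSM files from a directory
#'
#' Files are expected to be named `<protein_id>.pssm`.
#'
#' @param dir directory of ASCII PSSM files.
#' @return a named list of PSSM tibbles keyed by protein id.
#' @export
read_pssm_dir <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.pssm$", full.names = TRUE))
  out <- lapply(files, read_ascii_pssm)
  names(out) <- sub("\\.pssm$", "", basename(files))
  out
}

#' PSSM encoding of one peptide window
#'
#' 20 conservation scores per window position (position-major, columns in
#' the PSSM header order). Positions outside the protein (padding `'X'`)
#' contribute all-zero rows.
#'
#' @param pssm a PSSM tibble from [read_ascii_pssm()].
#' @param position 1-based center position of the window in the protein.
#' @param flank window flank size (window length `2 * flank + 1`).
#' @return named numeric vector of length `(2 * flank + 1) * 20`.
#' @export
encode_pssm <- function(pssm, position, flank = 9) {
  letters20 <- setdiff(names(pssm), c("position", "residue"))
  stopifnot(length(letters20) == 20)
  scores <- as.matrix(pssm[, letters20])
  offs <- seq.int(-flank, flank)
  pos <- position + offs
  out <- matrix(0, nrow = length(offs), ncol = 20)
  inb <- pos >= 1L & pos <= nrow(scores)
  out[inb, ] <- scores[pos[inb], , drop = FALSE]
  stats::setNames(as.vector(t(out)),
                  paste0("pssm_", rep(.off_lab(offs), each = 20), "_",
                         rep(letters20, length(offs))))
}

#' Residue composition of one peptide window
#'
#' Frequency of each of the 20 amino acids among the window's non-`'X'`
#' positions; `'X'` is excluded from both numerator and denominator so the
#' 20 frequencies sum to 1.
#'
#' @param window a peptide window string.
#' @return named numeric vector of length 20 (alphabetical order).
#' @export
encode_rc <- function(window) {
  chars <- seq_to_chars(window)
  chars <- chars[chars != "X"]
  counts <- vapply(AA20, function(a) sum(chars == a), numeric(1))
  stats::setNames(counts / length(chars), paste0("rc_", AA20))
}

#' One-hot secondary-structure encoding of one window
#'
#' Each position's DSSP state is expanded to a 7-bit one-hot code with bit
#' order S, T, I, G, E, B, H from most- to least-significant, so
#' `H -> 0000001`, `B -> 0000010`, ..., `S -> 1000000`. Coil (`'-'`, the
#' DSSP blank) and padding (`'X'`) map to the all-zero code.
#'
#' @param ss character vector of per-position state letters
#'   (length = window length), from `H,B,E,G,I,T,S,-,X`.
#' @return named numeric vector of length `7 * length(ss)`, position-major.
#' @export
encode_ss <- function(ss) {
  bad <- setdiff(unique(ss), c(SS7, "-", "X", ""))
  if (length(bad) > 0) {
    stop("unknown secondary-structure letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  n <- length(ss)
  flank <- (n - 1L) %/% 2L
  offs <- seq.int(-flank, flank)
  out <- matrix(0, nrow = n, ncol = 7,
                dimnames = list(NULL, SS_BIT_ORDER))
  hit <- match(ss, SS_BIT_ORDER)
  idx <- which(!is.na(hit))
  out[cbind(idx, hit[idx])] <- 1
  stats::setNames(as.vector(t(out)),
                  paste0("ss_", rep(.off_lab(offs), each = 7), "_",
                         rep(SS_BIT_ORDER, n)))
}

#' Accessible-surface-area encoding of one window
#'
#' Raw ASA values in square Angstroms, one per window position; `NA`
#' (padding or missing annotation) maps to 0.
#'
#' @param asa numeric vector of per-position ASA values (length = window
#'   length); `NA` for absent positions.
#' @return named numeric vector of the same length.
#' @export
encode_asa <- function(asa) {
  if (any(asa < 0, na.rm = TRUE)) {
    stop("negative ASA value", call. = FALSE)
  }
  n <- length(asa)
  flank <- (n - 1L) %/% 2L
  asa[is.na(asa)] <- 0
  stats::setNames(as.numeric(asa), paste0("asa_", .off_lab(seq.int(-flank, flank))))
}

## vectorized per-property z matrix for a character matrix of windows
.char_matrix <- function(windows) {
  n <- nchar(windows[1])
  matrix(unlist(strsplit(windows, "", fixed = TRUE)),
         ncol = n, byrow = TRUE)
}

#' Encode peptide windows into a named feature matrix
#'
#' Assembles the configured encoder blocks in the fixed order
#' PCP, PSSM, AC, RC, SS, ASA. With the default configuration
#' (4 properties, flank 9, lags 1 and 2) the feature space has
#' 72 + 380 + 8 + 20 + 133 + 19 = 632 columns. A registry mapping every
#' column to its (encoder, position/lag, property/letter) is attached as
#' the `"registry"` attribute (see [feature_registry()]).
#'
#' @param windows tibble from [extract_windows()] (columns `protein_id`,
#'   `position`, `window`, and optionally `label`).
#' @param properties normalized property table ([normalize_properties()]);
#'   required for the `pcp` and `ac` encoders.
#' @param pssms named list of PSSM tibbles keyed by protein id; required
#'   for the `pssm` encoder.
#' @param structure tibble `protein_id`, `position`, `ss`, `asa`; required
#'   for the `ss` and `asa` encoders.
#' @param encoders character subset of
#'   `c("pcp", "pssm", "ac", "rc", "ss", "asa")`, in any order; blocks are
#'   always assembled in the canonical order above.
#' @param lags lags for the auto-covariation block.
#' @param pcp_include_center include the (constant) center lysine in the
#'   PCP block? default `FALSE`.
#' @param missing_pssm what to do when a protein has no PSSM: `"error"`
#'   (default) or `"zero"` (all-zero block with a warning).
#' @return a tibble: the id columns of `windows` followed by the feature
#'   columns, with the registry attached as attribute `"registry"`.
#' @export
encode_features <- function(windows,
                            properties = NULL,
                            pssms = NULL,
                            structure = NULL,
                            encoders = c("pcp", "pssm", "ac", "rc", "ss", "asa"),
                            lags = c(1, 2),
                            pcp_include_center = FALSE,
                            missing_pssm = c("error", "zero")) {
  encoders <- match.arg(encoders, several.ok = TRUE)
  missing_pssm <- match.arg(missing_pssm)
  stopifnot(nrow(windows) > 0)
  len <- nchar(windows$window[1])
  stopifnot(all(nchar(windows$window) == len))
  flank <- (len - 1L) %/% 2L
  offs <- seq.int(-flank, flank)
  chars <- .char_matrix(windows$window)
  ns <- nrow(windows)

  need_props <- any(c("pcp", "ac") %in% encoders)
  if (need_props && is.null(properties)) {
    stop("encoders 'pcp'/'ac' require a normalized property table",
         call. = FALSE)
  }
  props <- if (need_props) .prop_vectors(properties) else NULL
  ## per-property standardized value matrix (samples x positions)
  zmats <- lapply(props, function(v) {
    matrix(v[chars], nrow = ns)
  })

  blocks <- list()
  registry <- list()

  if ("pcp" %in% encoders) {
    keep <- if (pcp_include_center) seq_along(offs) else which(offs != 0L)
    block <- do.call(cbind, lapply(names(zmats), function(a) {
      m <- zmats[[a]][, keep, drop = FALSE]
      colnames(m) <- paste0("pcp_", a, "_", .off_lab(offs[keep]))
      m
    }))
    blocks$pcp <- block
    registry$pcp <- tibble::tibble(
      column = colnames(block), encoder = "pcp",
      position = rep(as.character(offs[keep]), times = length(zmats)),
      detail = rep(names(zmats), each = length(keep)))
  }

  if ("pssm" %in% encoders) {
    if (is.null(pssms)) stop("encoder 'pssm' requires a PSSM list", call. = FALSE)
    absent <- setdiff(unique(windows$protein_id), names(pssms))
    if (length(absent) > 0) {
      if (missing_pssm == "error") {
        stop("no PSSM for protein(s): ",
             paste(utils::head(absent, 5), collapse = ", "), call. = FALSE)
      }
      warning("no PSSM for ", length(absent),
              " protein(s); using all-zero blocks")
    }
    letters20 <- NULL
    block <- matrix(0, nrow = ns, ncol = len * 20L)
    for (pid in unique(windows$protein_id)) {
      ridx <- which(windows$protein_id == pid)
      pm <- pssms[[pid]]
      if (is.null(pm)) next
      l20 <- setdiff(names(pm), c("position", "residue"))
      if (is.null(letters20)) letters20 <- l20
      scores <- as.matrix(pm[, l20])
      for (k in seq_along(offs)) {
        pos <- windows$position[ridx] + offs[k]
        inb <- pos >= 1L & pos <= nrow(scores)
        if (any(inb)) {
          block[ridx[inb], ((k - 1L) * 20L + 1L):(k * 20L)] <-
            scores[pos[inb], , drop = FALSE]
        }
      }
    }
    if (is.null(letters20)) letters20 <- c("A","R","N","D","C","Q","E","G","H",
                                           "I","L","K","M","F","P","S","T","W",
                                           "Y","V")
    colnames(block) <- paste0("pssm_", rep(.off_lab(offs), each = 20), "_",
                              rep(letters20, len))
    blocks$pssm <- block
    registry$pssm <- tibble::tibble(
      column = colnames(block), encoder = "pssm",
      position = rep(as.character(offs), each = 20),
      detail = rep(letters20, len))
  }

  if ("ac" %in% encoders) {
    block <- do.call(cbind, lapply(names(zmats), function(a) {
      x <- zmats[[a]]
      m <- rowMeans(x)
      cols <- vapply(lags, function(g) {
        i <- seq_len(len - g)
        rowSums((x[, i, drop = FALSE] - m) *
                  (x[, i + g, drop = FALSE] - m)) / (len - g)
      }, numeric(ns))
      cols <- matrix(cols, nrow = ns)
      colnames(cols) <- paste0("ac_", a, "_lag", lags)
      cols
    }))
    blocks$ac <- block
    registry$ac <- tibble::tibble(
      column = colnames(block), encoder = "ac",
      position = rep(as.character(lags), times = length(zmats)),
      detail = rep(names(zmats), each = length(lags)))
  }

  if ("rc" %in% encoders) {
    nonx <- rowSums(chars != "X")
    block <- vapply(AA20, function(a) rowSums(chars == a) / nonx, numeric(ns))
    block <- matrix(block, nrow = ns,
                    dimnames = list(NULL, paste0("rc_", AA20)))
    blocks$rc <- block
    registry$rc <- tibble::tibble(
      column = colnames(block), encoder = "rc",
      position = NA_character_, detail = AA20)
  }

  need_struct <- any(c("ss", "asa") %in% encoders)
  if (need_struct) {
    if (is.null(structure)) {
      stop("encoders 'ss'/'asa' require a structure annotation table",
           call. = FALSE)
    }
    key <- paste(structure$protein_id, structure$position)
    posm <- outer(windows$position, offs, `+`)
    hit <- matrix(match(paste(rep(windows$protein_id, length(offs)),
                              as.vector(posm)), key), nrow = ns)
  }

  if ("ss" %in% encoders) {
    ssm <- matrix("-", nrow = ns, ncol = len)
    found <- !is.na(hit)
    ssm[found] <- structure$ss[hit[found]]
    bad <- setdiff(unique(as.vector(ssm)), c(SS7, "-", "X", ""))
    if (length(bad) > 0) {
      stop("unknown secondary-structure letter(s): ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    block <- matrix(0, nrow = ns, ncol = len * 7L)
    for (k in seq_len(len)) {
      b <- match(ssm[, k], SS_BIT_ORDER)
      idx <- which(!is.na(b))
      block[cbind(idx, (k - 1L) * 7L + b[idx])] <- 1
    }
    colnames(block) <- paste0("ss_", rep(.off_lab(offs), each = 7), "_",
                              rep(SS_BIT_ORDER, len))
    blocks$ss <- block
    registry$ss <- tibble::tibble(
      column = colnames(block), encoder = "ss",
      position = rep(as.character(offs), each = 7),
      detail = rep(SS_BIT_ORDER, len))
  }

  if ("asa" %in% encoders) {
    block <- matrix(0, nrow = ns, ncol = len)
    found <- !is.na(hit)
    vals <- structure$asa[hit[found]]
    if (any(vals < 0, na.rm = TRUE)) stop("negative ASA value", call. = FALSE)
    vals[is.na(vals)] <- 0
    block[found] <- vals
    colnames(block) <- paste0("asa_", .off_lab(offs))
    blocks$asa <- block
    registry$asa <- tibble::tibble(
      column = colnames(block), encoder = "asa",
      position = as.character(offs), detail = NA_character_)
  }

  order_now <- intersect(c("pcp", "pssm", "ac", "rc", "ss", "asa"),
                         names(blocks))
  full <- do.call(cbind, blocks[order_now])
  if (anyNA(full)) stop("NaN/NA in assembled feature matrix", call. = FALSE)
  reg <- dplyr::bind_rows(registry[order_now])
  stopifnot(nrow(reg) == ncol(full), !anyDuplicated(reg$column))
  id_cols <- windows[, intersect(c("protein_id", "position", "label"),
                                 names(windows))]
  out <- dplyr::bind_cols(id_cols, tibble::as_tibble(full))
  attr(out, "registry") <- reg
  attr(out, "flank") <- flank
  message("assembled ", ncol(full), " feature columns for ", ns, " windows")
  out
}

#' Retrieve the feature registry of an encoded matrix
#'
#' @param features output of [encode_features()].
#' @return tibble `column`, `encoder`, `position`, `detail`.
#' @export
feature_registry <- function(features) {
  reg <- attr(features, "registry")
  if (is.null(reg)) stop("no feature registry attached", call. = FALSE)
  reg
}

#' Names of the feature columns of an encoded matrix
#' @param features output of [encode_features()].
#' @return character vector.
#' @export
feature_columns <- function(features) feature_registry(features)$column

#' Bundled synthetic amino-acid property tables
#'
#' Loads and standardizes the four synthetic AAindex-format property
#' tables shipped with the package (stand-ins for unfolding activation
#' energies at pH 7 and pH 9, backbone flexibility B-values, and
#' transmembrane-helix turn propensity; the numeric values are synthetic,
#' not the published indices — supply a real AAindex1 file to
#' [load_aaindex()] for genuine values).
#'
#' @inheritParams normalize_properties
#' @return a normalized property tibble.
#' @export
default_properties <- function(x_policy = "raw-zero-normalized") {
  path <- system.file("extdata", "aaindex1_synthetic.txt", package = "kascade")
  normalize_properties(load_aaindex(path), x_policy = x_policy)
}
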