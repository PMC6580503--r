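#' Read protein sequences from a FASTA file
#'
#' Sequences are upper-cased and non-standard letters (B, Z, J, U, O, `*`)
#' are normalized to `'X'`. Record order is preserved; the protein id is the
#' first whitespace-delimited token of the FASTA header.
#'
#' @param path path to a FASTA file.
#' @return a tibble with columns `protein_id` and `sequence`.
#' @examples
#' fa <- tempfile(fileext = ".fasta")
#' writeLines(c(">p1", "MKKT"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  stopifnot(file.exists(path))
  if (file.size(path) == 0) {
    warning("empty FASTA file: ", path)
    return(tibble::tibble(protein_id = character(), sequence = character()))
  }
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) stop("malformed FASTA in ", path, ": ",
                             conditionMessage(e), call. = FALSE)
  )
  ids <- sub("\\s.*$", "", names(set))
  if (anyDuplicated(ids)) {
    stop("duplicate protein ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  tibble::tibble(protein_id = ids,
                 sequence = unname(normalize_sequence(as.character(set))))
}

#' Write proteins to a FASTA file
#'
#' @param proteins tibble with `protein_id`, `sequence`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(proteins, path) {
  set <- Biostrings::BStringSet(proteins$sequence)
  names(set) <- proteins$protein_id
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Enumerate candidate lysine positions
#'
#' @param proteins tibble with `protein_id`, `sequence`.
#' @return tibble `protein_id`, `position` (1-based, ascending within each
#'   protein) for every `'K'` residue.
#' @export
enumerate_lysines <- function(proteins) {
  purrr::map2_dfr(proteins$protein_id, proteins$sequence, function(id, s) {
    pos <- stringr::str_locate_all(s, stringr::fixed("K"))[[1]][, 1]
    tibble::tibble(protein_id = rep(id, length(pos)), position = as.integer(pos))
  })
}

#' Extract a peptide window centered on a lysine
#'
#' Positions before the N-terminus or past the C-terminus are padded with
#' `'X'` so the window always has length `2 * flank + 1`.
#'
#' @param sequence a single protein sequence.
#' @param position 1-based position of the center residue (must be `'K'`).
#' @param flank number of residues on each side (default 9, window 19).
#' @return a character scalar of length `2 * flank + 1`.
#' @export
extract_window <- function(sequence, position, flank = 9) {
  n <- nchar(sequence)
  if (position < 1 || position > n) {
    stop("position ", position, " out of range [1, ", n, "]", call. = FALSE)
  }
  if (substr(sequence, position, position) != "K") {
    stop("residue at position ", position, " is '",
         substr(sequence, position, position), "', expected 'K'", call. = FALSE)
  }
  pad <- strrep("X", flank)
  substr(paste0(pad, sequence, pad), position, position + 2L * flank)
}

#' Extract peptide windows for a table of sites
#'
#' @param proteins tibble `protein_id`, `sequence`.
#' @param sites tibble `protein_id`, `position` and optionally `label`
#'   (1 = acetylated, 0 = not).
#' @inheritParams extract_window
#' @return `sites` with an added `window` column; `flank` is stored in the
#'   `"flank"` attribute.
#' @export
extract_windows <- function(proteins, sites, flank = 9) {
  missing <- setdiff(sites$protein_id, proteins$protein_id)
  if (length(missing) > 0) {
    stop("sites reference unknown protein ids: ",
         paste(utils::head(missing, 5), collapse = ", "), call. = FALSE)
  }
  dat <- dplyr::left_join(sites, proteins, by = "protein_id")
  pad <- strrep("X", flank)
  padded <- paste0(pad, dat$sequence, pad)
  centre <- substr(dat$sequence, dat$position, dat$position)
  if (any(centre != "K")) {
    bad <- which(centre != "K")
    stop("non-lysine residue at ", length(bad), " site(s), e.g. row ",
         bad[1], " (", dat$protein_id[bad[1]], ":", dat$position[bad[1]], ")",
         call. = FALSE)
  }
  out <- dat |>
    dplyr::mutate(window = substr(padded, .data$position,
                                  .data$position + 2L * flank)) |>
    dplyr::select(-"sequence")
  attr(out, "flank") <- flank
  out
}

#' Read a site annotation table
#'
#' Expects a tab-separated file with header columns `protein_id`,
#' `position` (1-based) and `label` (`1` acetylated, `0` not). Rows whose
#' position is out of range or does not fall on a lysine are rejected with
#' a warning reporting how many were dropped; unknown protein ids are an
#' error.
#'
#' @param path path to the TSV file.
#' @param proteins tibble `protein_id`, `sequence` used for validation.
#' @return a validated tibble `protein_id`, `position`, `label`.
#' @export
read_site_table <- function(path, proteins) {
  stopifnot(file.exists(path))
  sites <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    label = readr::col_integer()
  ), progress = FALSE)
  if (!all(sites$label %in% c(0L, 1L))) {
    stop("labels must be 0 or 1 in ", path, call. = FALSE)
  }
  unknown <- setdiff(sites$protein_id, proteins$protein_id)
  if (length(unknown) > 0) {
    stop("unknown protein ids in ", path, ": ",
         paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
  }
  seqs <- proteins$sequence[match(sites$protein_id, proteins$protein_id)]
  ok <- sites$position >= 1L & sites$position <= nchar(seqs) &
    substr(seqs, sites$position, sites$position) == "K"
  if (any(!ok)) {
    warning(sum(!ok), " site row(s) rejected (out of range or not a lysine), ",
            "e.g. row ", which(!ok)[1])
  }
  sites[ok, ]
}

#' Write a site table
#'
#' @param sites tibble `protein_id`, `position`, `label`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_site_table <- function(sites, path) {
  readr::write_tsv(sites, path, progress = FALSE)
  invisible(path)
}
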