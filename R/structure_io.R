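#' Read a per-residue structure annotation table
#'
#' Tab-separated with header `protein_id`, `position`, `ss`, `asa`:
#' the DSSP state letter (H, B, E, G, I, T, S; `-` for coil) and the
#' accessible surface area in square Angstroms for every residue.
#'
#' @param path path to the TSV file.
#' @return tibble `protein_id`, `position`, `ss`, `asa`.
#' @export
read_structure_table <- function(path) {
  stopifnot(file.exists(path))
  out <- readr::read_tsv(path, col_types = readr::cols(
    protein_id = readr::col_character(),
    position = readr::col_integer(),
    ss = readr::col_character(),
    asa = readr::col_double()
  ), progress = FALSE, na = "NA")
  bad <- setdiff(unique(out$ss), c(SS7, "-"))
  if (length(bad) > 0) {
    stop("unknown secondary-structure letter(s) in ", path, ": ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (any(out$asa < 0 | !is.finite(out$asa))) {
    stop("ASA values must be finite and non-negative in ", path, call. = FALSE)
  }
  out
}

#' Write a structure annotation table
#' @param structure tibble `protein_id`, `position`, `ss`, `asa`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_structure_table <- function(structure, path) {
  readr::write_tsv(structure, path, progress = FALSE)
  invisible(path)
}

#' Read per-residue annotations from a DSSP output file
#'
#' Minimal fixed-column parser for DSSP v2/v3 text output: rows after the
#' `#  RESIDUE AA STRUCTURE ...` header are read for residue number
#' (columns 6-10), amino acid (column 14), structure letter (column 17)
#' and ACC (columns 35-38). Chain-break rows (`!`) are skipped; a blank
#' structure column is mapped to `-` (coil).
#'
#' @param path path to a DSSP file.
#' @param protein_id id to assign; defaults to the file name stem.
#' @return tibble `protein_id`, `position`, `ss`, `asa`.
#' @export
read_dssp <- function(path, protein_id = NULL) {
  stopifnot(file.exists(path))
  if (is.null(protein_id)) {
    protein_id <- sub("\\.[^.]*$", "", basename(path))
  }
  lines <- readLines(path)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)[1]
  if (is.na(hdr)) stop("no DSSP residue header in ", path, call. = FALSE)
  body <- lines[seq.int(hdr + 1L, length(lines))]
  aa <- substr(body, 14, 14)
  keep <- aa != "!" & trimws(body) != ""
  body <- body[keep]
  ss <- substr(body, 17, 17)
  ss[ss == " "] <- "-"
  out <- tibble::tibble(
    protein_id = protein_id,
    position = as.integer(trimws(substr(body, 6, 10))),
    ss = ss,
    asa = as.numeric(trimws(substr(body, 35, 38)))
  )
  bad <- setdiff(unique(out$ss), c(SS7, "-"))
  if (length(bad) > 0) {
    stop("unknown DSSP structure letter(s): ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}
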