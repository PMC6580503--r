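## Shared fixtures, all built in code at test time.

AA20_T <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## an AAindex1-format fixture: two complete records plus one with NA
write_test_aaindex <- function(path = tempfile(fileext = ".txt")) {
  ## values listed in AAindex row order: A R N D C Q E G H I / L K M F P S T W Y V
  writeLines(c(
    "H TSTA000101",
    "D Test property one",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0     2.0     3.0     4.0     5.0     6.0     7.0     8.0     9.0    10.0",
    "    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//",
    "H TSTB000102",
    "D Test property two",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "    0.10   -0.20    0.35    0.40   -0.55    0.16    0.27   -0.38    0.49    0.52",
    "   -0.11    0.22   -0.33    0.44    0.15   -0.26    0.37    0.48   -0.59    0.60",
    "//",
    "H TSTC000103",
    "D Test property with a missing value",
    "I    A/L     R/K     N/M     D/F     C/P     Q/S     E/T     G/W     H/Y     I/V",
    "     1.0     2.0      NA     4.0     5.0     6.0     7.0     8.0     9.0    10.0",
    "    11.0    12.0    13.0    14.0    15.0    16.0    17.0    18.0    19.0    20.0",
    "//"), path)
  path
}

test_properties <- function(accessions = c("TSTA000101", "TSTB000102")) {
  normalize_properties(load_aaindex(write_test_aaindex(), accessions))
}

## a random peptide window with K at the center
random_window <- function(flank = 9, x_pad = 0) {
  chars <- sample(AA20_T, 2 * flank + 1, replace = TRUE)
  chars[flank + 1] <- "K"
  if (x_pad > 0) chars[seq_len(x_pad)] <- "X"
  paste(chars, collapse = "")
}

windows_tibble <- function(windows, labels) {
  tibble::tibble(protein_id = sprintf("w%03d", seq_along(windows)),
                 position = 10L, window = windows, label = as.integer(labels))
}

## independent double-loop auto-covariation oracle:
## AC_{g,j} = 1/(n-g) * sum_i (X_i - mean(X)) (X_{i+g} - mean(X))
ac_oracle <- function(window, norm_properties, lag) {
  props <- split(norm_properties, norm_properties$accession)
  vapply(unique(norm_properties$accession), function(a) {
    d <- props[[a]]
    lookup <- c(stats::setNames(d$z, d$aa), X = d$x_value[1])
    x <- unname(lookup[strsplit(window, "")[[1]]])
    n <- length(x)
    m <- sum(x) / n
    acc <- 0
    for (i in seq_len(n - lag)) {
      acc <- acc + (x[i] - m) * (x[i + lag] - m)
    }
    acc / (n - lag)
  }, numeric(1))
}

## small PSI-BLAST-style ASCII PSSM fixture where score(pos, col) is
## deterministic: score = (pos + col) %% 13 - 6
write_test_pssm <- function(sequence, path = tempfile(fileext = ".pssm")) {
  letters20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  hdr <- paste0("            ", paste(sprintf("%3s", letters20), collapse = ""),
                "  ", paste(sprintf("%3s", letters20), collapse = ""))
  chars <- strsplit(sequence, "")[[1]]
  rows <- vapply(seq_along(chars), function(i) {
    sc <- ((i + seq_len(20)) %% 13) - 6
    paste0(sprintf("%5d %s  ", i, chars[i]),
           paste(sprintf("%3d", sc), collapse = ""), "  ",
           paste(sprintf("%3d", rep(0, 20)), collapse = ""))
  }, character(1))
  writeLines(c("", "Last position-specific scoring matrix computed", hdr, rows,
               "", "                      K         Lambda"), path)
  path
}

expected_pssm_score <- function(pos, col) ((pos + col) %% 13) - 6

## tiny deterministic structure annotation for one protein
test_structure <- function(protein_id, length, ss = "H", asa = 50) {
  tibble::tibble(protein_id = protein_id, position = seq_len(length),
                 ss = rep_len(ss, length), asa = rep_len(asa, length))
}

small_bundle <- function(seed = 1, ...) {
  simulate_acetylome(sim_config(n_proteins = 60, n_pos = 30, n_neg = 300,
                                length_mean = 130, ...), seed = seed)
}

## brute-force mutual-information / greedy-MID oracles shared by the
## selection and acceptance tests
mi_oracle <- function(a, b) {
  tab <- table(a, b) / length(a)
  pa <- rowSums(tab); pb <- colSums(tab)
  s <- 0
  for (i in seq_along(pa)) for (j in seq_along(pb)) {
    if (tab[i, j] > 0) s <- s + tab[i, j] * log2(tab[i, j] / (pa[i] * pb[j]))
  }
  s
}

greedy_mid_oracle <- function(disc, y, k) {
  p <- length(disc)
  rel <- vapply(disc, mi_oracle, numeric(1), b = y)
  sel <- integer(0)
  remaining <- seq_len(p)
  for (step in seq_len(k)) {
    crit <- vapply(remaining, function(f) {
      if (length(sel) == 0) return(rel[f])
      rel[f] - mean(vapply(sel, function(g) mi_oracle(disc[[f]], disc[[g]]),
                           numeric(1)))
    }, numeric(1))
    pick <- remaining[which.max(crit)]
    sel <- c(sel, pick)
    remaining <- setdiff(remaining, pick)
    if (length(remaining) == 0) break
  }
  sel
}

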