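test_that("AAindex records load, reject NA, and error on unknown accessions", {
  path <- write_test_aaindex()
  props <- load_aaindex(path, c("TSTA000101", "TSTB000102"))
  expect_equal(nrow(props), 40)
  expect_equal(unique(table(props$accession)), 20L)
  ## values come back keyed by amino acid: A was listed first with 1.0
  expect_equal(props$value[props$accession == "TSTA000101" & props$aa == "A"], 1)
  expect_equal(props$value[props$accession == "TSTA000101" & props$aa == "V"], 20)
  expect_error(load_aaindex(path, "TSTC000103"), "NA")
  expect_error(load_aaindex(path, "NOPE000000"), "not found")
  expect_message(all_props <- load_aaindex(path), "dropping 1")
  expect_equal(unique(all_props$accession), c("TSTA000101", "TSTB000102"))
})

test_that("property standardization matches the population-SD hand computation", {
  path <- write_test_aaindex()
  norm <- normalize_properties(load_aaindex(path, "TSTA000101"))
  ## raw values are a permutation of 1..20 -> mean 10.5, population SD
  sd_pop <- sqrt(mean((1:20 - 10.5)^2))
  z_a <- (1 - 10.5) / sd_pop
  expect_equal(norm$z[norm$aa == "A"], z_a, tolerance = 1e-12)
  expect_equal(mean(norm$z), 0, tolerance = 1e-9)
  expect_equal(sqrt(mean(norm$z^2)), 1, tolerance = 1e-9)
  ## 'X' carries the standardized raw zero
  expect_equal(unique(norm$x_value), (0 - 10.5) / sd_pop, tolerance = 1e-12)
})

test_that("standardization is idempotent and rejects constant tables", {
  tbl <- tibble::tibble(accession = "Z", aa = AA20_T,
                        value = scale(1:20, scale = FALSE)[, 1] /
                          sqrt(mean((1:20 - 10.5)^2)))
  norm <- normalize_properties(tbl)
  expect_equal(norm$z, norm$value, tolerance = 1e-9)
  const <- tibble::tibble(accession = "C", aa = AA20_T, value = rep(5, 20))
  expect_error(normalize_properties(const), "degenerate")
})

test_that("z-zero policy maps X to zero instead of the standardized raw zero", {
  path <- write_test_aaindex()
  norm <- normalize_properties(load_aaindex(path, "TSTA000101"),
                               x_policy = "z-zero")
  expect_equal(unique(norm$x_value), 0)
})

test_that("PCP encoding excludes the center and handles X policy", {
  props <- test_properties()
  w <- random_window()
  v <- encode_pcp(w, props)
  expect_length(v, 2 * 18)
  ## center exclusion: changing nothing but the center leaves PCP unchanged
  expect_equal(encode_pcp(w, props),
               encode_pcp(w, props, include_center = FALSE))
  expect_length(encode_pcp(w, props, include_center = TRUE), 2 * 19)
  ## all-X flanks carry the per-property x_value
  wx <- paste0(strrep("X", 9), "K", strrep("X", 9))
  vx <- encode_pcp(wx, props)
  xvals <- unique(props[, c("accession", "x_value")])$x_value
  expect_equal(unname(vx), rep(xvals, each = 18))
})

test_that("auto-covariation matches the double-loop oracle and is zero for
           constant windows", {
  props <- test_properties()
  ## constant window: every deviation from the window mean vanishes
  wconst <- strrep("K", 19)
  expect_equal(unname(encode_ac(wconst, props)), rep(0, 4))
  ## dimension: 2 properties x 2 lags, property-major
  v <- encode_ac(random_window(), props)
  expect_length(v, 4)
  expect_equal(names(v)[1:2], c("ac_TSTA000101_lag1", "ac_TSTA000101_lag2"))
  set.seed(7)
  for (i in 1:50) {
    w <- random_window(x_pad = sample(0:5, 1))
    for (lag in c(1, 2)) {
      expect_equal(unname(encode_ac(w, props, lags = lag)),
                   unname(ac_oracle(w, props, lag)), tolerance = 1e-12)
    }
  }
  expect_error(encode_ac(random_window(), props, lags = 19), "lag")
})

test_that("ASCII PSSM files parse into position-by-letter scores", {
  seqs <- "MKTVRKAAKL"
  path <- write_test_pssm(seqs)
  pssm <- read_ascii_pssm(path, sequence = seqs)
  expect_equal(nrow(pssm), 10)
  expect_equal(names(pssm)[3:6], c("A", "R", "N", "D"))
  expect_equal(pssm$A, expected_pssm_score(1:10, 1))
  expect_equal(pssm$V, expected_pssm_score(1:10, 20))
  ## mismatching sequence is a warning, truncation an error
  expect_warning(read_ascii_pssm(path, sequence = "MKTVRKAAKV"), "match")
  lines <- readLines(path)
  bad <- tempfile()
  writeLines(c(lines[1:3], substr(lines[4], 1, 30)), bad)
  expect_error(read_ascii_pssm(bad), "truncated")
})

test_that("PSSM window encoding is 380-dim with zero padding rows", {
  seqs <- paste(rep("K", 30), collapse = "")
  pssm <- read_ascii_pssm(write_test_pssm(seqs))
  v <- encode_pssm(pssm, position = 15, flank = 9)
  expect_length(v, 380)
  ## window fully inside: every value recoverable by position arithmetic
  offs <- -9:9
  expect_equal(unname(v),
               as.vector(t(outer(15 + offs, 1:20, expected_pssm_score))))
  ## K at position 2: upstream offsets -9..-2 out of bounds -> 8*20 zeros
  v2 <- encode_pssm(pssm, position = 2, flank = 9)
  expect_equal(unname(v2[1:160]), rep(0, 160))
  expect_false(all(v2[161:180] == 0))
})

test_that("residue composition is X-free and sums to one", {
  v <- encode_rc(strrep("K", 19))
  expect_equal(unname(v[names(v) == "rc_K"]), 1)
  expect_equal(sum(v), 1)
  ## hand count: 9 upstream X, K, 9 A -> K 1/10, A 9/10
  v2 <- encode_rc(paste0(strrep("X", 9), "K", strrep("A", 9)))
  expect_equal(unname(v2["rc_K"]), 1 / 10)
  expect_equal(unname(v2["rc_A"]), 9 / 10)
  set.seed(1)
  for (i in 1:20) expect_equal(sum(encode_rc(random_window(x_pad = i %% 8))), 1,
                               tolerance = 1e-12)
})

test_that("secondary-structure one-hot uses the documented bit order", {
  ## all-helix window: 19 copies of 0000001 (H is the least-significant bit)
  v <- encode_ss(rep("H", 19))
  expect_length(v, 133)
  expect_equal(sum(v), 19)
  expect_equal(unname(v[7]), 1)    # 7th bit of position -9 is H
  expect_equal(unname(v[1:6]), rep(0, 6))
  ## S occupies the most-significant bit
  vs <- encode_ss(c("S", rep("-", 18)))
  expect_equal(unname(vs[1]), 1)
  expect_equal(sum(vs), 1)
  ## coil and padding are all-zero; exactly one bit per structured position
  expect_equal(sum(encode_ss(rep("-", 19))), 0)
  mixed <- c(rep("E", 5), rep("-", 5), rep("T", 5), rep("X", 4))
  vm <- matrix(encode_ss(mixed), ncol = 7, byrow = TRUE)
  expect_equal(rowSums(vm), c(rep(1, 5), rep(0, 5), rep(1, 5), rep(0, 4)))
  expect_error(encode_ss(c(rep("H", 18), "Q")), "unknown")
})

test_that("ASA encoding passes raw values through with absent -> 0", {
  expect_equal(unname(encode_asa(rep(NA_real_, 19))), rep(0, 19))
  expect_equal(unname(encode_asa(rep(100, 19))), rep(100, 19))
  expect_equal(unname(encode_asa(c(0:18))), as.numeric(0:18))
  expect_error(encode_asa(c(-1, rep(0, 18))), "negative")
})

test_that("assembly produces the documented 632-dimensional layout", {
  bundle <- small_bundle(seed = 11)
  feats <- suppressMessages(encode_bundle(bundle,
                                          properties = default_properties()))
  reg <- feature_registry(feats)
  expect_equal(nrow(reg), 632)
  expect_equal(length(feature_columns(feats)), 632)
  counts <- table(reg$encoder)[c("pcp", "pssm", "ac", "rc", "ss", "asa")]
  expect_equal(unname(as.integer(counts)), c(72, 380, 8, 20, 133, 19))
  ## block order is canonical and registry covers each column exactly once
  expect_equal(reg$column, feature_columns(feats))
  expect_false(anyDuplicated(reg$column) > 0)
  expect_false(anyNA(feats[, reg$column]))
})

test_that("sequence-only and single-encoder assemblies have the derived widths", {
  bundle <- small_bundle(seed = 12)
  wins <- extract_windows(bundle$proteins, bundle$sites)
  seq_only <- suppressMessages(encode_features(
    wins, properties = default_properties(), pssms = bundle$pssms,
    encoders = c("pcp", "pssm", "ac", "rc")))
  expect_length(feature_columns(seq_only), 72 + 380 + 8 + 20)
  rc_only <- suppressMessages(encode_features(wins, encoders = "rc"))
  expect_length(feature_columns(rc_only), 20)
})

test_that("vectorized assembly agrees with the per-window encoders", {
  bundle <- small_bundle(seed = 13)
  wins <- extract_windows(bundle$proteins, bundle$sites)[1:8, ]
  props <- default_properties()
  feats <- suppressMessages(encode_features(
    wins, properties = props, pssms = bundle$pssms,
    structure = bundle$structure))
  reg <- feature_registry(feats)
  for (i in seq_len(nrow(wins))) {
    w <- wins$window[i]
    pid <- wins$protein_id[i]
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "pcp"]]),
                 encode_pcp(w, props), tolerance = 1e-12)
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "ac"]]),
                 encode_ac(w, props), tolerance = 1e-12)
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "rc"]]),
                 encode_rc(w), tolerance = 1e-12)
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "pssm"]]),
                 encode_pssm(bundle$pssms[[pid]], wins$position[i]),
                 tolerance = 1e-12)
    st <- bundle$structure[bundle$structure$protein_id == pid, ]
    offs <- wins$position[i] + (-9:9)
    hit <- match(offs, st$position)
    ssv <- ifelse(is.na(hit), "-", st$ss[hit])
    asav <- ifelse(is.na(hit), NA_real_, st$asa[hit])
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "ss"]]),
                 encode_ss(ssv), tolerance = 1e-12)
    expect_equal(unlist(feats[i, reg$column[reg$encoder == "asa"]]),
                 encode_asa(asav), tolerance = 1e-12)
  }
})

test_that("encoding is a pure per-row function: permuting samples permutes rows", {
  bundle <- small_bundle(seed = 14)
  wins <- extract_windows(bundle$proteins, bundle$sites)[1:20, ]
  f1 <- suppressMessages(encode_features(wins, properties = default_properties(),
                                         encoders = c("pcp", "ac", "rc")))
  perm <- sample(nrow(wins))
  f2 <- suppressMessages(encode_features(wins[perm, ],
                                         properties = default_properties(),
                                         encoders = c("pcp", "ac", "rc")))
  expect_equal(as.data.frame(f2), as.data.frame(f1[perm, ]),
               ignore_attr = TRUE)
})

test_that("missing PSSMs are a configuration error unless zeros are requested", {
  bundle <- small_bundle(seed = 15)
  wins <- extract_windows(bundle$proteins, bundle$sites)[1:5, ]
  expect_error(suppressMessages(encode_features(
    wins, pssms = list(), encoders = "pssm")), "no PSSM")
  expect_warning(f <- suppressMessages(encode_features(
    wins, pssms = list(), encoders = "pssm", missing_pssm = "zero")),
    "all-zero")
  expect_true(all(as.matrix(f[, feature_columns(f)]) == 0))
})

test_that("DSSP files parse to the fallback annotation schema", {
  path <- tempfile(fileext = ".dssp")
  writeLines(c(
    "==== Secondary Structure Definition by the program DSSP ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N",
    "    1    1 A M              0   0  121      0, 0.0   2,-0.3",
    "    2    2 A K  H  >  S+    0   0   87      1,-0.2   4,-2.4",
    "    3    3 A T  E     -A    8   0A  13      2,-0.3   2,-0.2",
    "    4        !              0   0    0      0, 0.0   0, 0.0",
    "    5    5 A V  B     -B    7   0B   5      0,-0.1   0,-0.2"),
    path)
  ann <- read_dssp(path, protein_id = "p1")
  expect_equal(nrow(ann), 4)
  expect_equal(ann$ss, c("-", "H", "E", "B"))
  expect_equal(ann$asa, c(121, 87, 13, 5))
  expect_equal(ann$position, c(1L, 2L, 3L, 5L))
})
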