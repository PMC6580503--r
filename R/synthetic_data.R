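## Background amino-acid frequencies (approximate vertebrate proteome
## usage), in AA20 (alphabetical) order.
BG_FREQ <- c(A = 0.0826, C = 0.0137, D = 0.0546, E = 0.0674, F = 0.0386,
             G = 0.0708, H = 0.0227, I = 0.0593, K = 0.0582, L = 0.0966,
             M = 0.0242, N = 0.0406, P = 0.0472, Q = 0.0393, R = 0.0553,
             S = 0.0660, T = 0.0535, V = 0.0686, W = 0.0110, Y = 0.0292)

#' Configuration for the synthetic acetylome generator
#'
#' The defaults define the study conditions the rest of the package is
#' exercised under: a ~10:1 negative:positive site imbalance, lysine
#' enrichment immediately downstream of positive sites with serine
#' depletion at offsets +1..+4, strand-enriched / beta-bridge-free
#' positive centers, a high-ASA shift at positive centers, and stronger
#' downstream PSSM conservation around positive sites.
#'
#' @param n_proteins number of proteins (default 300).
#' @param length_mean,length_sd protein length distribution (normal,
#'   truncated at `length_min`).
#' @param length_min minimum protein length.
#' @param n_pos,n_neg positive / negative site counts (default 150 and
#'   1500, i.e. 10:1).
#' @param flank window flank (default 9; windows of 19).
#' @param k_enrich probability of lysine at offset +1 of a positive site
#'   (background is ~0.06; default 0.15).
#' @param s_deplete multiplicative down-weight of serine at offsets
#'   +1..+4 of positive sites (default 0.5).
#' @param ss_pos,ss_neg secondary-structure distributions over
#'   `c(H, B, E, G, I, T, S, "-")` at positive / negative site centers.
#'   The positive default has zero beta-bridge mass and enriched strand.
#' @param asa_pos_mean,asa_pos_sd normal ASA distribution at positive
#'   centers (truncated at 0; default mean 85, sd 35, shifting mass into
#'   the 60-150 range while keeping class overlap).
#' @param asa_neg_low_frac,asa_neg_low_rate,asa_neg_mean,asa_neg_sd
#'   negative-center ASA mixture: with probability `asa_neg_low_frac` an
#'   exponential with rate `asa_neg_low_rate` (buried, mass in 0-60),
#'   otherwise a truncated normal.
#' @param pssm_conservation,pssm_conservation_pos baseline and
#'   positive-downstream PSSM identity weight (0 = pure background,
#'   1 = fully conserved).
#' @param with_pssm,with_structure generate PSSMs / structure
#'   annotations? (default `TRUE`; switch off to speed up analyses that
#'   do not need them).
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_proteins = 300,
                       length_mean = 120, length_sd = 25, length_min = 40,
                       n_pos = 150, n_neg = 1500,
                       flank = 9,
                       k_enrich = 0.15, s_deplete = 0.5,
                       ss_pos = c(H = 0.25, B = 0.00, E = 0.22, G = 0.04,
                                  I = 0.01, T = 0.12, S = 0.10, "-" = 0.26),
                       ss_neg = c(H = 0.33, B = 0.02, E = 0.10, G = 0.04,
                                  I = 0.01, T = 0.12, S = 0.11, "-" = 0.27),
                       asa_pos_mean = 85, asa_pos_sd = 35,
                       asa_neg_low_frac = 0.45, asa_neg_low_rate = 1 / 22,
                       asa_neg_mean = 75, asa_neg_sd = 35,
                       pssm_conservation = 0.25,
                       pssm_conservation_pos = 0.45,
                       with_pssm = TRUE, with_structure = TRUE) {
  stopifnot(n_proteins > 0, n_pos > 0, n_neg > 0,
            abs(sum(ss_pos) - 1) < 1e-8, abs(sum(ss_neg) - 1) < 1e-8,
            k_enrich > 0, k_enrich < 1, s_deplete >= 0)
  structure(as.list(environment()), class = "sim_config")
}

.rtnorm <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  abs(x)  # reflect at 0; keeps the bulk where the mean puts it
}

.sample_aa <- function(n, weights) {
  sample(AA20, n, replace = TRUE, prob = weights)
}

#' Generate a synthetic acetylome bundle
#'
#' Draws protein sequences from background residue usage, selects positive
#' and negative lysine sites, plants the configured class-conditional
#' contrasts (sequence composition, secondary structure, ASA, PSSM
#' conservation), and returns everything in memory. Identical
#' `config`/`seed` give identical bundles. Use [write_bundle()] /
#' [read_bundle()] for the on-disk form.
#'
#' @param config a [sim_config()].
#' @param seed integer seed; the single source of randomness.
#' @return an `acet_bundle` list: `proteins`, `sites` (with planted
#'   labels), `structure` (or `NULL`), `pssms` (named list, or `NULL`),
#'   and `manifest` (every planted parameter plus the seed).
#' @export
simulate_acetylome <- function(config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(seed)
  cfg <- config

  lens <- pmax(cfg$length_min,
               round(stats::rnorm(cfg$n_proteins, cfg$length_mean,
                                  cfg$length_sd)))
  ids <- sprintf("SYNP%04d", seq_len(cfg$n_proteins))
  seqs <- vapply(lens, function(L) {
    paste(.sample_aa(L, BG_FREQ), collapse = "")
  }, character(1))
  proteins <- tibble::tibble(protein_id = ids, sequence = seqs)

  lys <- enumerate_lysines(proteins)
  n_sites <- cfg$n_pos + cfg$n_neg
  if (nrow(lys) < n_sites) {
    stop("infeasible site counts: ", n_sites, " sites requested but only ",
         nrow(lys), " lysines generated; reduce n_pos/n_neg or enlarge ",
         "the proteins", call. = FALSE)
  }
  pick <- sample(nrow(lys), n_sites)
  sites <- lys[pick, ]
  sites$label <- rep(c(1L, 0L), c(cfg$n_pos, cfg$n_neg))
  sites <- dplyr::arrange(sites, .data$protein_id, .data$position)

  ## plant sequence composition bias around positive sites; never touch a
  ## residue that is itself a selected site center
  centers <- paste(sites$protein_id, sites$position)
  seq_chars <- strsplit(stats::setNames(proteins$sequence,
                                        proteins$protein_id), "")
  w_enrich <- BG_FREQ
  w_enrich["K"] <- 0        # replaced by k_enrich below
  w_enrich["S"] <- w_enrich["S"] * cfg$s_deplete
  w_enrich <- w_enrich / sum(w_enrich) * (1 - cfg$k_enrich)
  w_enrich["K"] <- cfg$k_enrich
  w_dep <- BG_FREQ
  w_dep["S"] <- w_dep["S"] * cfg$s_deplete
  w_dep <- w_dep / sum(w_dep)

  pos_sites <- sites[sites$label == 1L, ]
  for (r in seq_len(nrow(pos_sites))) {
    pid <- pos_sites$protein_id[r]
    p <- pos_sites$position[r]
    L <- length(seq_chars[[pid]])
    for (off in 1:4) {
      tgt <- p + off
      if (tgt > L) next
      if (paste(pid, tgt) %in% centers) next
      w <- if (off == 1) w_enrich else w_dep
      seq_chars[[pid]][tgt] <- .sample_aa(1, w)
    }
  }
  proteins$sequence <- vapply(proteins$protein_id, function(pid) {
    paste(seq_chars[[pid]], collapse = "")
  }, character(1), USE.NAMES = FALSE)

  structure_tbl <- NULL
  if (cfg$with_structure) {
    per_prot <- lapply(seq_len(cfg$n_proteins), function(i) {
      L <- nchar(proteins$sequence[i])
      tibble::tibble(
        protein_id = ids[i],
        position = seq_len(L),
        ss = sample(names(cfg$ss_neg), L, replace = TRUE, prob = cfg$ss_neg),
        asa = round(ifelse(
          stats::runif(L) < cfg$asa_neg_low_frac,
          stats::rexp(L, cfg$asa_neg_low_rate),
          .rtnorm(L, cfg$asa_neg_mean, cfg$asa_neg_sd)), 1)
      )
    })
    structure_tbl <- dplyr::bind_rows(per_prot)
    ## overwrite positive centers with the positive-class distributions
    key <- paste(structure_tbl$protein_id, structure_tbl$position)
    pos_key <- paste(pos_sites$protein_id, pos_sites$position)
    idx <- match(pos_key, key)
    structure_tbl$ss[idx] <- sample(names(cfg$ss_pos), length(idx),
                                    replace = TRUE, prob = cfg$ss_pos)
    structure_tbl$asa[idx] <- round(.rtnorm(length(idx), cfg$asa_pos_mean,
                                            cfg$asa_pos_sd), 1)
  }

  pssms <- NULL
  if (cfg$with_pssm) {
    ## conservation weight per residue: baseline everywhere, elevated on
    ## the downstream flank of positive sites
    cons <- lapply(lens, function(L) rep(cfg$pssm_conservation, L))
    names(cons) <- ids
    for (r in seq_len(nrow(pos_sites))) {
      pid <- pos_sites$protein_id[r]
      p <- pos_sites$position[r]
      L <- length(cons[[pid]])
      hi <- seq.int(p + 1, min(p + cfg$flank, L))
      if (length(hi) > 0) cons[[pid]][hi] <- cfg$pssm_conservation_pos
    }
    pssms <- lapply(ids, function(pid) {
      s <- seq_to_chars(proteins$sequence[match(pid, ids)])
      .synthetic_pssm(pid, s, cons[[pid]])
    })
    names(pssms) <- ids
  }

  manifest <- c(unclass(cfg), list(seed = seed, n_lysines = nrow(lys)))
  manifest$ss_pos <- as.list(cfg$ss_pos)
  manifest$ss_neg <- as.list(cfg$ss_neg)
  structure(list(proteins = proteins, sites = sites,
                 structure = structure_tbl, pssms = pssms,
                 manifest = manifest),
            class = "acet_bundle")
}

## Dirichlet-perturbed background frequencies mixed with the identity of
## the observed residue, converted to integer half-bit log-odds
.synthetic_pssm <- function(protein_id, chars, conservation,
                            concentration = 30) {
  L <- length(chars)
  g <- matrix(stats::rgamma(L * 20, shape = rep(BG_FREQ * concentration,
                                                each = L)), nrow = L)
  probs <- g / rowSums(g)
  hit <- match(chars, AA20)
  ok <- !is.na(hit)
  onehot <- matrix(0, nrow = L, ncol = 20)
  onehot[cbind(which(ok), hit[ok])] <- 1
  w <- ifelse(ok, conservation, 0)
  probs <- probs * (1 - w) + onehot * w
  scores <- round(2 * log2((probs + 1e-4) /
                             matrix(BG_FREQ, L, 20, byrow = TRUE)))
  scores <- pmin(pmax(scores, -12), 12)
  colnames(scores) <- AA20
  ## emit columns in the PSI-BLAST header order
  psi_order <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  out <- tibble::tibble(position = seq_len(L),
                        residue = chars)
  dplyr::bind_cols(out, tibble::as_tibble(scores[, psi_order, drop = FALSE]))
}

#' @export
print.acet_bundle <- function(x, ...) {
  cat("Synthetic acetylome bundle:", nrow(x$proteins), "proteins,",
      sum(x$sites$label == 1), "positive /",
      sum(x$sites$label == 0), "negative sites\n")
  cat("  structure:", !is.null(x$structure),
      " pssms:", !is.null(x$pssms), "\n")
  invisible(x)
}

#' Split a bundle into train / validation / test by protein
#'
#' Proteins (and all their sites, structure rows and PSSMs) are assigned
#' whole to one split, so no protein leaks across splits.
#'
#' @param bundle an `acet_bundle`.
#' @param fractions named numeric vector summing to 1, e.g.
#'   `c(train = 0.7, validation = 0.15, test = 0.15)`.
#' @param seed integer seed for the protein permutation.
#' @return named list of `acet_bundle`s, one per fraction.
#' @export
split_bundle <- function(bundle,
                         fractions = c(train = 0.7, validation = 0.15,
                                       test = 0.15),
                         seed = 1) {
  stopifnot(inherits(bundle, "acet_bundle"), !is.null(names(fractions)))
  if (abs(sum(fractions) - 1) > 1e-8) {
    stop("split fractions must sum to 1", call. = FALSE)
  }
  ids <- bundle$proteins$protein_id
  set.seed(seed)
  perm <- sample(ids)
  sizes <- diff(round(cumsum(c(0, fractions)) * length(ids)))
  assignment <- rep(names(fractions), times = sizes)
  out <- lapply(names(fractions), function(nm) {
    keep <- perm[assignment == nm]
    structure(list(
      proteins = bundle$proteins[ids %in% keep, ],
      sites = bundle$sites[bundle$sites$protein_id %in% keep, ],
      structure = if (is.null(bundle$structure)) NULL else
        bundle$structure[bundle$structure$protein_id %in% keep, ],
      pssms = if (is.null(bundle$pssms)) NULL else
        bundle$pssms[intersect(names(bundle$pssms), keep)],
      manifest = c(bundle$manifest, list(split = nm))
    ), class = "acet_bundle")
  })
  names(out) <- names(fractions)
  out
}

#' Write a bundle to disk / read it back
#'
#' Layout: `proteins.fasta`, `sites.tsv`, `structure.tsv`,
#' `pssm/<protein_id>.pssm` (PSI-BLAST ASCII dialect) and `manifest.yml`.
#' All files are plain text and byte-stable for a fixed seed.
#'
#' @param bundle an `acet_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir` (write) or an `acet_bundle` (read).
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_fasta(bundle$proteins, file.path(dir, "proteins.fasta"))
  write_site_table(bundle$sites, file.path(dir, "sites.tsv"))
  if (!is.null(bundle$structure)) {
    write_structure_table(bundle$structure, file.path(dir, "structure.tsv"))
  }
  if (!is.null(bundle$pssms)) {
    pd <- file.path(dir, "pssm")
    dir.create(pd, showWarnings = FALSE)
    for (pid in names(bundle$pssms)) {
      write_ascii_pssm(bundle$pssms[[pid]], file.path(pd, paste0(pid, ".pssm")))
    }
  }
  yaml::write_yaml(bundle$manifest, file.path(dir, "manifest.yml"))
  invisible(dir)
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  proteins <- read_fasta(file.path(dir, "proteins.fasta"))
  sites <- read_site_table(file.path(dir, "sites.tsv"), proteins)
  spath <- file.path(dir, "structure.tsv")
  structure_tbl <- if (file.exists(spath)) read_structure_table(spath) else NULL
  pdir <- file.path(dir, "pssm")
  pssms <- if (dir.exists(pdir)) read_pssm_dir(pdir) else NULL
  mpath <- file.path(dir, "manifest.yml")
  manifest <- if (file.exists(mpath)) yaml::read_yaml(mpath) else list()
  structure(list(proteins = proteins, sites = sites,
                 structure = structure_tbl, pssms = pssms,
                 manifest = manifest),
            class = "acet_bundle")
}

#' Write a PSSM tibble in the PSI-BLAST ASCII dialect
#'
#' Emits the two-block header, per-residue rows with 20 log-odds scores
#' and 20 placeholder percentage columns, so files round-trip through
#' [read_ascii_pssm()].
#'
#' @param pssm tibble `position`, `residue`, 20 score columns.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_ascii_pssm <- function(pssm, path) {
  letters20 <- setdiff(names(pssm), c("position", "residue"))
  scores <- as.matrix(pssm[, letters20])
  hdr <- paste0("            ",
                paste(sprintf("%3s", letters20), collapse = " "), "  ",
                paste(sprintf("%3s", letters20), collapse = " "))
  rows <- vapply(seq_len(nrow(pssm)), function(i) {
    paste0(sprintf("%5d %s  ", pssm$position[i], pssm$residue[i]),
           paste(sprintf("%3d", scores[i, ]), collapse = " "), "  ",
           paste(sprintf("%3d", rep(0L, 20)), collapse = " "))
  }, character(1))
  writeLines(c("", "Last position-specific scoring matrix computed", hdr,
               rows, ""), path)
  invisible(path)
}

#' Planted-signal feature benchmark
#'
#' A small tabular generator, independent of the sequence pipeline, for
#' exercising feature selection: `n_signal` informative features shifted
#' by `effect` standard deviations in the positive class among `p - n_signal`
#' pure-noise features.
#'
#' @param n samples, split evenly between classes.
#' @param p total feature count (default 300).
#' @param n_signal number of informative features (default 5; they are
#'   the first `n_signal` columns, named `sig1..`).
#' @param effect class mean shift in SD units (default 1).
#' @param seed integer seed.
#' @return list with `features` (tibble `sig*`, `noise*`) and `labels`.
#' @export
simulate_feature_signal <- function(n = 400, p = 300, n_signal = 5,
                                    effect = 1, seed = 1) {
  stopifnot(p >= n_signal)
  set.seed(seed)
  labels <- rep(c(1L, 0L), length.out = n)
  X <- matrix(stats::rnorm(n * p), nrow = n)
  X[, seq_len(n_signal)] <- X[, seq_len(n_signal)] + labels * effect
  colnames(X) <- c(paste0("sig", seq_len(n_signal)),
                   paste0("noise", seq_len(p - n_signal)))
  list(features = tibble::as_tibble(X), labels = labels)
}
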