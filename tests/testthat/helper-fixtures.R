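# Shared fixtures, all built in code.

# Deterministic random DNA (independent of the global RNG stream).
rand_dna <- function(n, seed) {
  withr::with_seed(seed,
    paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = ""))
}

# Hand-built precursor fixture covering every assignment branch:
#  - let7a / let7f share an identical 5p mature sequence (composite naming)
#  - mir-134 has a unique loop region outside both mature windows (-pre)
#  - mir-127 carries its 3p mature at coordinates 57-78 exactly
#  - seq DUP occurs twice in mir-dup1 and once in mir-dup2 (3 loci)
#  - mir-mouse1 exists only in the mouse tier (cross-species fallback)
fixture_tiers <- function() {
  m_shared <- "TGAGGTAGTAGGTTGTATAGTT"                 # 22 nt shared 5p
  dup <- "ACGTGGCTTAGGCATCGATT"                        # 20 nt multi-locus
  loop134 <- "TTACGGCCATTGAACGGTCAAC"                  # 22 nt loop insert
  m_mouse <- "CCAGTCAGGATTACCAGAGTCG"                  # 22 nt mouse-only

  pad <- function(seed, n) rand_dna(n, seed)
  hp <- list()
  win <- list()

  # let-7a: 4 + 22 (5p) + 20 + 22 (3p) + 4 = 72 nt
  hp[["let-7a"]] <- paste0("AACC", m_shared, pad(11, 20), pad(12, 22), "GGTT")
  win[["let-7a"]] <- data.frame(
    precursor = "let-7a", mature_name = c("let-7a-5p", "let-7a-3p"),
    arm = c("5p", "3p"), start = c(5L, 47L), end = c(26L, 68L))

  hp[["let-7f"]] <- paste0("TTGG", m_shared, pad(13, 20), pad(14, 22), "CCAA")
  win[["let-7f"]] <- data.frame(
    precursor = "let-7f", mature_name = c("let-7f-5p", "let-7f-3p"),
    arm = c("5p", "3p"), start = c(5L, 47L), end = c(26L, 68L))

  # mir-134: windows 2-23 and 60-81; loop134 planted at 31-52
  hp[["mir-134"]] <- paste0("G", pad(15, 22), pad(16, 7), loop134,
                            pad(17, 7), pad(18, 22), "C")
  win[["mir-134"]] <- data.frame(
    precursor = "mir-134", mature_name = c("miR-134-5p", "miR-134-3p"),
    arm = c("5p", "3p"), start = c(2L, 60L), end = c(23L, 81L))

  # mir-127: 82 nt, 3p window at 57-78
  hp[["mir-127"]] <- paste0(pad(19, 1), pad(20, 22), pad(21, 33),
                            pad(22, 22), pad(23, 4))
  win[["mir-127"]] <- data.frame(
    precursor = "mir-127", mature_name = c("miR-127-5p", "miR-127-3p"),
    arm = c("5p", "3p"), start = c(2L, 57L), end = c(23L, 78L))

  # mir-dup1 holds DUP at 5-24 and 35-54; mir-dup2 holds it at 3-22
  hp[["mir-dup1"]] <- paste0("AATT", dup, pad(24, 10), dup, pad(25, 12))
  win[["mir-dup1"]] <- data.frame(
    precursor = "mir-dup1", mature_name = "miR-dup1-5p",
    arm = "5p", start = 5L, end = 24L)
  hp[["mir-dup2"]] <- paste0("GC", dup, pad(26, 40))
  win[["mir-dup2"]] <- data.frame(
    precursor = "mir-dup2", mature_name = "miR-dup2-5p",
    arm = "5p", start = 3L, end = 22L)

  # three plain rat hairpins
  for (i in 1:3) {
    nm <- sprintf("mir-r%d", i)
    hp[[nm]] <- paste0("A", pad(30 + i, 22), pad(40 + i, 20),
                       pad(50 + i, 22), "T")
    win[[nm]] <- data.frame(
      precursor = nm,
      mature_name = sprintf(c("miR-r%d-5p", "miR-r%d-3p"), i),
      arm = c("5p", "3p"), start = c(2L, 45L), end = c(23L, 66L))
  }

  rat <- precursor_set(unlist(hp), do.call(rbind, win), species = "rat")

  # mouse tier: one exclusive hairpin
  hp_m <- paste0("TT", m_mouse, pad(61, 20), pad(62, 22), "AA")
  mouse <- precursor_set(
    c("mir-mouse1" = hp_m),
    data.frame(precursor = "mir-mouse1", mature_name = "miR-mouse1-5p",
               arm = "5p", start = 3L, end = 24L),
    species = "mouse")

  list(rat = rat, mouse = mouse,
       seqs = list(shared = m_shared, dup = dup, loop134 = loop134,
                   mouse = m_mouse))
}

# Naive O(n * m) substring scan: the independent oracle for map_exact.
# Every window of every hairpin is extracted and compared; no index, no
# early exit.
brute_force_scan <- function(sequences, ps) {
  rows <- list()
  for (sq in sequences) {
    L <- nchar(sq)
    for (p in names(ps$sequences)) {
      s <- ps$sequences[[p]]
      n <- nchar(s)
      if (n < L) next
      starts <- seq_len(n - L + 1L)
      hit <- substring(s, starts, starts + L - 1L) == sq
      for (st in starts[hit]) {
        rows[[length(rows) + 1L]] <- data.frame(
          sequence = sq, precursor = p, start = st, end = st + L - 1L)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(sequence = character(0), precursor = character(0),
                      start = integer(0), end = integer(0)))
  }
  do.call(rbind, rows)
}

# Exhaustive loop-based evaluation of the expression-quorum rule: the
# independent oracle for classify_rule_based. Takes a plain matrix plus
# sample metadata and applies the thresholds literally, one cell at a time.
brute_force_rule <- function(counts, samples, thr = 1, quorum_frac = 0.8,
                             max_enriched = 5) {
  tissues <- unique(samples$tissue)
  labels <- character(nrow(counts))
  tissue_sets <- character(nrow(counts))
  for (i in seq_len(nrow(counts))) {
    expressed <- character(0)
    sex_hits <- character(0)
    for (t in tissues) {
      idx <- which(samples$tissue == t)
      n_over <- sum(counts[i, idx] > thr)
      if (n_over >= ceiling(quorum_frac * length(idx))) {
        expressed <- c(expressed, t)
      }
      sx <- samples$sex[idx]
      if (length(unique(sx)) == 2L) {
        over <- counts[i, idx] > thr
        mo <- sum(over & sx == "M")
        fo <- sum(over & sx == "F")
        nM <- sum(sx == "M"); nF <- sum(sx == "F")
        if ((mo >= ceiling(quorum_frac * nM) && fo == 0L) ||
            (fo >= ceiling(quorum_frac * nF) && mo == 0L)) {
          sex_hits <- c(sex_hits, t)
        }
      }
    }
    if (length(expressed) == 1L) {
      labels[i] <- "specific"; tissue_sets[i] <- expressed
    } else if (length(sex_hits) > 0L) {
      labels[i] <- "sex_specific"
      tissue_sets[i] <- paste(sort(sex_hits), collapse = ";")
    } else if (length(expressed) >= 2L && length(expressed) <= max_enriched) {
      labels[i] <- "enriched"
      tissue_sets[i] <- paste(sort(expressed), collapse = ";")
    } else {
      labels[i] <- "none"; tissue_sets[i] <- ""
    }
  }
  list(label = labels, tissues = tissue_sets)
}

# Random atlas_counts over a small tissue panel (mixed sexes) for
# property-style tests.
random_atlas <- function(n_mir, tissues, n_per_sex = 5L, lambda = 2,
                         seed = 1L) {
  organ_map <- stats::setNames(tissues, tissues)
  samples <- expand.grid(
    tissue = tissues,
    animal = c(sprintf("M%d", seq_len(n_per_sex)),
               sprintf("F%d", seq_len(n_per_sex))),
    stringsAsFactors = FALSE
  )
  samples$sex <- substr(samples$animal, 1, 1)
  samples$organ <- samples$tissue
  samples$sample <- sprintf("%s_%s", samples$tissue, samples$animal)
  m <- withr::with_seed(seed, matrix(
    rpois(n_mir * nrow(samples), lambda), n_mir, nrow(samples),
    dimnames = list(sprintf("m%03d", seq_len(n_mir)), samples$sample)
  ))
  atlas_counts(m, samples[, c("sample", "animal", "sex", "tissue", "organ")])
}

# Grid-search maximum-likelihood oracle for the two-component Poisson
# mixture (independent of the EM path).
grid_mixture_loglik <- function(y, lam_low_grid, lam_high_grid, pi_grid) {
  best <- -Inf
  for (ll in lam_low_grid) {
    dl <- dpois(y, ll)
    for (lh in lam_high_grid) {
      dh <- dpois(y, lh)
      for (p in pi_grid) {
        lik <- sum(log(p * dh + (1 - p) * dl))
        if (lik > best) best <- lik
      }
    }
  }
  best
}
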