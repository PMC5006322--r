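#' Generate a tiered toy precursor collection
#'
#' Builds random hairpins (60-90 nt) with annotated 5p and/or 3p mature
#' windows of 19-25 nt, organised as an ordered list of species tiers. The
#' first tier holds `n_precursors` hairpins; every later tier shares roughly
#' half of the first tier's hairpins and always contains at least one
#' tier-exclusive hairpin, mimicking conserved miRNAs that are annotated in
#' one species but not another.
#'
#' @param n_precursors hairpins in the first tier (>= 1).
#' @param species_tiers ordered character vector of species names, first =
#'   primary species.
#' @param seed integer seed; fixed seed gives identical records.
#' @return named list of `precursor_set`, one per tier, in tier order.
#' @export
#' @examples
#' tiers <- generate_precursor_set(5, c("rat", "mouse"), seed = 1)
#' tiers$rat
generate_precursor_set <- function(n_precursors, species_tiers, seed = 1L) {
  stopifnot_scalar_count(n_precursors, "n_precursors")
  if (length(species_tiers) < 1L) stop("need at least one tier", call. = FALSE)
  with_seed(seed, {
    make_hairpin <- function(name) {
      len <- sample(60:90, 1L)
      seq <- paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                   collapse = "")
      arms <- switch(sample(3L, 1L, prob = c(0.7, 0.15, 0.15)),
                     c("5p", "3p"), "5p", "3p")
      win <- list()
      if ("5p" %in% arms) {
        w <- sample(19:25, 1L)
        s <- sample(2:6, 1L)
        win[["5p"]] <- data.frame(
          precursor = name, mature_name = paste0(sub("^mir", "miR", name), "-5p"),
          arm = "5p", start = s, end = s + w - 1L
        )
      }
      if ("3p" %in% arms) {
        w <- sample(19:25, 1L)
        e <- len - sample(3:7, 1L)
        s <- e - w + 1L
        # guarantee no overlap with the 5p window
        if (!is.null(win[["5p"]]) && s <= win[["5p"]]$end) s <- win[["5p"]]$end + 2L
        if (e - s + 1L >= 19L && e <= len) {
          win[["3p"]] <- data.frame(
            precursor = name, mature_name = paste0(sub("^mir", "miR", name), "-3p"),
            arm = "3p", start = s, end = e
          )
        }
      }
      if (!length(win)) {  # fall back to a 5p window
        win[["5p"]] <- data.frame(
          precursor = name, mature_name = paste0(sub("^mir", "miR", name), "-5p"),
          arm = "5p", start = 2L, end = 23L
        )
      }
      list(seq = seq, windows = do.call(rbind, win))
    }

    n_tiers <- length(species_tiers)
    n_extra <- max(1L, ceiling(n_precursors / 5L))
    total <- n_precursors + (n_tiers - 1L) * n_extra
    names_all <- sprintf("mir-t%d", seq_len(total))
    hp <- lapply(names_all, make_hairpin)
    names(hp) <- names_all

    out <- vector("list", n_tiers)
    names(out) <- species_tiers
    idx_first <- seq_len(n_precursors)
    next_free <- n_precursors
    for (i in seq_len(n_tiers)) {
      if (i == 1L) {
        idx <- idx_first
      } else {
        shared <- sort(sample(idx_first, max(1L, floor(n_precursors / 2L))))
        excl <- next_free + seq_len(n_extra)
        next_free <- next_free + n_extra
        idx <- c(shared, excl)
      }
      seqs <- vapply(hp[idx], `[[`, character(1), "seq")
      names(seqs) <- names_all[idx]
      wins <- do.call(rbind, lapply(hp[idx], `[[`, "windows"))
      out[[i]] <- precursor_set(seqs, wins, species = species_tiers[i])
    }
    out
  })
}

#' Simulate small-RNA reads from mature arms with isomiR end variation
#'
#' Each read is a mature-window subsequence whose 5' and 3' ends are shifted
#' by offsets drawn from `isomir_profile`, followed by the 3' sequencing
#' adapter. Reads are uniform-quality; provenance (source precursor, mature
#' name, offsets) is recorded for truth checking.
#'
#' @param precursors a `precursor_set` (e.g. one tier of
#'   [generate_precursor_set()]).
#' @param isomir_profile data.frame with columns `offset5`, `offset3`,
#'   `prob`: the joint distribution of end shifts (0/0 = canonical mature).
#'   Positive `offset3` extends the 3' end; positive `offset5` trims the 5'
#'   end forward.
#' @param adapter 3' adapter appended to every read (default the common
#'   small-RNA adapter TGGAATTCTCGGGTGCCAAGG).
#' @param n_reads number of reads to draw.
#' @param seed integer seed.
#' @return data.frame with columns `sequence` (read with adapter), `insert`
#'   (the biological sequence), `precursor`, `mature_name`, `offset5`,
#'   `offset3`.
#' @export
generate_reads <- function(precursors,
                           isomir_profile = data.frame(offset5 = 0L,
                                                       offset3 = 0L,
                                                       prob = 1),
                           adapter = "TGGAATTCTCGGGTGCCAAGG",
                           n_reads = 1000L,
                           seed = 1L) {
  stopifnot(inherits(precursors, "precursor_set"))
  if (!nzchar(adapter)) stop("`adapter` must be non-empty", call. = FALSE)
  if (length(precursors$sequences) == 0L) {
    stop("empty precursor set", call. = FALSE)
  }
  stopifnot_scalar_count(n_reads, "n_reads", min = 0L)
  if (abs(sum(isomir_profile$prob) - 1) > 1e-8) {
    stop("isomiR profile probabilities must sum to 1", call. = FALSE)
  }
  win <- precursors$windows
  empty <- data.frame(sequence = character(0), insert = character(0),
                      precursor = character(0), mature_name = character(0),
                      offset5 = integer(0), offset3 = integer(0))
  if (n_reads == 0L) return(empty)
  with_seed(seed, {
    wi <- sample(nrow(win), n_reads, replace = TRUE)
    oi <- sample(nrow(isomir_profile), n_reads, replace = TRUE,
                 prob = isomir_profile$prob)
    s <- win$start[wi] + isomir_profile$offset5[oi]
    e <- win$end[wi] + isomir_profile$offset3[oi]
    len <- nchar(precursors$sequences)[win$precursor[wi]]
    if (any(s < 1L | e > len | s > e)) {
      stop("isomiR offsets push reads outside the hairpin", call. = FALSE)
    }
    ins <- substr(precursors$sequences[win$precursor[wi]], s, e)
    data.frame(
      sequence = paste0(ins, adapter),
      insert = unname(ins),
      precursor = win$precursor[wi],
      mature_name = win$mature_name[wi],
      offset5 = isomir_profile$offset5[oi],
      offset3 = isomir_profile$offset3[oi]
    )
  })
}

#' Simulate an atlas count matrix with planted truth
#'
#' Counts for each (miRNA, animal, tissue) cell are drawn from a Poisson
#' whose mean is `lambda_high * library_scale` when the tissue belongs to
#' the miRNA's planted enrichment set and `lambda_low * library_scale`
#' otherwise; a two-component Poisson world by construction. Sex-specific
#' miRNAs emit zeros in the opposite sex. Single-sex tissues (testis,
#' ovary, uterus in the default panel) are sampled only in the carrying
#' sex, so the default full design yields 215 samples.
#'
#' @param design an [atlas_design()].
#' @return list with elements `counts` (an `atlas_counts`) and `truth`
#'   (data.frame: mirna, label in specific/enriched/sex_specific/none,
#'   tissues, sex).
#' @export
generate_atlas_counts <- function(design) {
  stopifnot(inherits(design, "atlas_design"))
  tissues <- names(design$tissues)
  organs <- unname(design$tissues)
  nA <- design$n_animals_per_sex
  animals <- c(sprintf("M%d", seq_len(nA)), sprintf("F%d", seq_len(nA)))
  sexes <- rep(c("M", "F"), each = nA)
  sst <- single_sex_tissues()

  grid <- expand.grid(ti = seq_along(tissues), ai = seq_along(animals),
                      KEEP.OUT.ATTRS = FALSE)
  keep <- rep(TRUE, nrow(grid))
  for (j in seq_len(nrow(grid))) {
    tn <- tissues[grid$ti[j]]
    if (tn %in% names(sst) && sexes[grid$ai[j]] != sst[[tn]]) keep[j] <- FALSE
  }
  grid <- grid[keep, , drop = FALSE]
  samples <- data.frame(
    sample = sprintf("%s_%s", tissues[grid$ti], animals[grid$ai]),
    animal = animals[grid$ai],
    sex = sexes[grid$ai],
    tissue = tissues[grid$ti],
    organ = organs[grid$ti],
    stringsAsFactors = FALSE
  )
  ord <- order(match(samples$tissue, tissues), match(samples$animal, animals))
  samples <- samples[ord, , drop = FALSE]
  rownames(samples) <- NULL

  mirnas <- sprintf("mir_%03d", seq_len(design$n_mirnas))
  scale <- rep_len(design$library_scale, nrow(samples))

  cnt <- with_seed(design$seed, {
    m <- matrix(0, nrow = design$n_mirnas, ncol = nrow(samples),
                dimnames = list(mirnas, samples$sample))
    for (i in seq_len(design$n_mirnas)) {
      enr <- design$enrichment_patterns[[i]]
      lam <- ifelse(samples$tissue %in% enr,
                    design$lambda_high, design$lambda_low) * scale
      sx <- design$sex_pattern[i]
      if (!is.na(sx)) lam[samples$sex != sx] <- 0
      if (is.finite(design$dispersion_size)) {
        m[i, ] <- stats::rnbinom(nrow(samples), mu = lam,
                                 size = design$dispersion_size)
      } else {
        m[i, ] <- stats::rpois(nrow(samples), lam)
      }
    }
    m
  })

  truth <- truth_labels(design, mirnas)
  list(counts = atlas_counts(cnt, samples), truth = truth)
}

#' Recompute planted truth labels from an atlas design
#'
#' @param design an [atlas_design()].
#' @param mirnas miRNA ids to label (default `mir_001`...).
#' @return data.frame with mirna, label, tissues (";"-joined), sex.
#' @export
truth_labels <- function(design,
                         mirnas = sprintf("mir_%03d", seq_len(design$n_mirnas))) {
  lab <- character(design$n_mirnas)
  tset <- character(design$n_mirnas)
  for (i in seq_len(design$n_mirnas)) {
    enr <- design$enrichment_patterns[[i]]
    if (!is.na(design$sex_pattern[i])) {
      lab[i] <- "sex_specific"
    } else if (length(enr) == 0L) {
      lab[i] <- "none"
    } else if (length(enr) == 1L) {
      lab[i] <- "specific"
    } else {
      lab[i] <- "enriched"
    }
    tset[i] <- paste(sort(enr), collapse = ";")
  }
  data.frame(mirna = mirnas, label = lab, tissues = tset,
             sex = design$sex_pattern, stringsAsFactors = FALSE)
}

#' Simulate a serum qPCR time-course study with AR(1) noise
#'
#' Emits a well table with per-animal target and spike-in Ct values over a
#' group x timepoint grid, plus NTC / no-RT / water-extraction control
#' wells. Within-animal noise follows a stationary AR(1) process with
#' marginal standard deviation `sigma` and lag-1 correlation `rho`, so the
#' simulated log2 fold change of animal a at time t is
#' `true_log2fc[group, t] + e_at`.
#'
#' @param groups character vector of dose group names; the first is the
#'   reference (vehicle / pre-dose convention is set downstream).
#' @param timepoints numeric vector of sampling times (hours).
#' @param n_animals animals per group.
#' @param true_log2fc matrix `length(groups) x length(timepoints)` of true
#'   log2 fold changes (reference cells are usually 0).
#' @param rho AR(1) lag-1 correlation, |rho| < 1.
#' @param sigma marginal noise standard deviation (> 0).
#' @param target name of the measured miRNA.
#' @param spike spike-in oligo name (default "cel-miR-55-3p").
#' @param baseline_dct true target-minus-spike delta-Ct at fold change 1.
#' @param seed integer seed.
#' @return object of class `qpcr_study`: list with `wells` (data.frame:
#'   animal, group, timepoint, target, well_type, ct), `spike`, `target`,
#'   and `truth` (the true_log2fc matrix plus noise parameters).
#' @export
generate_qpcr_study <- function(groups = c("vehicle", "low", "high"),
                                timepoints = c(1, 4, 8, 24, 48),
                                n_animals = 6L,
                                true_log2fc = matrix(0, length(groups),
                                                     length(timepoints)),
                                rho = 0.5,
                                sigma = 0.5,
                                target = "miR-216a-5p",
                                spike = "cel-miR-55-3p",
                                baseline_dct = 8,
                                seed = 1L) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) || abs(rho) >= 1) {
    stop("`rho` must satisfy |rho| < 1", call. = FALSE)
  }
  if (!is.numeric(sigma) || sigma <= 0) stop("`sigma` must be > 0", call. = FALSE)
  stopifnot_scalar_count(n_animals, "n_animals")
  true_log2fc <- as.matrix(true_log2fc)
  if (!all(dim(true_log2fc) == c(length(groups), length(timepoints)))) {
    stop("`true_log2fc` must be groups x timepoints", call. = FALSE)
  }
  nT <- length(timepoints)
  with_seed(seed, {
    rows <- list()
    for (g in seq_along(groups)) {
      for (a in seq_len(n_animals)) {
        an <- sprintf("%s_a%d", groups[g], a)
        # stationary AR(1): marginal sd sigma, innovations sd sigma*sqrt(1-rho^2)
        e <- numeric(nT)
        e[1] <- stats::rnorm(1, 0, sigma)
        if (nT > 1L) {
          for (t in 2:nT) {
            e[t] <- rho * e[t - 1] + stats::rnorm(1, 0, sigma * sqrt(1 - rho^2))
          }
        }
        spike_ct <- 19 + stats::rnorm(nT, 0, 0.05)
        dct <- baseline_dct - (true_log2fc[g, ] + e)
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, group = groups[g], timepoint = timepoints,
          target = target, well_type = "sample", ct = spike_ct + dct
        )
        rows[[length(rows) + 1L]] <- data.frame(
          animal = an, group = groups[g], timepoint = timepoints,
          target = spike, well_type = "sample", ct = spike_ct
        )
      }
    }
    controls <- data.frame(
      animal = NA_character_, group = NA_character_, timepoint = NA_real_,
      target = c(target, target, spike),
      well_type = c("NTC", "noRT", "water"),
      ct = c(NA_real_, NA_real_, 19.2)
    )
    wells <- rbind(do.call(rbind, rows), controls)
    rownames(wells) <- NULL
    structure(
      list(wells = wells, spike = spike, target = target,
           truth = list(log2fc = true_log2fc, rho = rho, sigma = sigma,
                        groups = groups, timepoints = timepoints)),
      class = "qpcr_study"
    )
  })
}

#' @export
print.qpcr_study <- function(x, ...) {
  cat(sprintf("qpcr_study: target %s, spike %s, %d wells\n",
              x$target, x$spike, nrow(x$wells)))
  invisible(x)
}
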