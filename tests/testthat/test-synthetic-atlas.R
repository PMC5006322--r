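test_that("precursor generation is deterministic and well-formed", {
  a <- generate_precursor_set(1, "rat", seed = 7)
  b <- generate_precursor_set(1, "rat", seed = 7)
  expect_identical(a, b)
  ps <- a$rat
  expect_length(ps$sequences, 1L)
  len <- nchar(ps$sequences[[1]])
  expect_true(len >= 60 && len <= 90)
  w <- ps$windows
  expect_true(all(w$start >= 1 & w$end <= len))
  expect_true(all(w$end - w$start + 1 >= 19 & w$end - w$start + 1 <= 25))

  expect_error(generate_precursor_set(0, "rat"), "n_precursors")
})

test_that("later species tiers contain tier-exclusive precursors", {
  tiers <- generate_precursor_set(10, c("rat", "mouse"), seed = 1)
  excl <- setdiff(names(tiers$mouse$sequences), names(tiers$rat$sequences))
  expect_gte(length(excl), 1L)
  # shared precursors are identical hairpins across tiers
  shared <- intersect(names(tiers$mouse$sequences), names(tiers$rat$sequences))
  expect_identical(tiers$mouse$sequences[shared], tiers$rat$sequences[shared])
})

test_that("simulated reads are mature subsequences plus adapter", {
  tiers <- generate_precursor_set(6, "rat", seed = 5)
  ps <- tiers$rat
  rd <- generate_reads(ps, n_reads = 50, seed = 2)
  expect_equal(nrow(rd), 50L)
  # zero-offset profile: insert must equal the annotated mature sequence
  for (i in seq_len(nrow(rd))) {
    w <- ps$windows[ps$windows$mature_name == rd$mature_name[i], ]
    expect_identical(rd$insert[i],
                     substr(ps$sequences[[w$precursor]], w$start, w$end))
  }
  expect_true(all(endsWith(rd$sequence, "TGGAATTCTCGGGTGCCAAGG")))

  expect_equal(nrow(generate_reads(ps, n_reads = 0)), 0L)
  no_prec <- structure(
    list(sequences = character(0),
         windows = data.frame(precursor = character(0),
                              mature_name = character(0),
                              arm = character(0), start = integer(0),
                              end = integer(0)),
         species = "rat"),
    class = "precursor_set")
  expect_error(generate_reads(no_prec, n_reads = 1), "empty")
})

test_that("isomiR offset profile is honoured at the sampled rate", {
  tiers <- generate_precursor_set(6, "rat", seed = 5)
  prof <- data.frame(offset5 = c(0L, 0L), offset3 = c(0L, 2L),
                     prob = c(0.5, 0.5))
  rd <- generate_reads(tiers$rat, prof, n_reads = 1000, seed = 3)
  frac_ext <- mean(rd$offset3 == 2L)
  expect_lt(abs(frac_ext - 0.5), 0.05)
  ext <- rd[rd$offset3 == 2L, ][1, ]
  w <- tiers$rat$windows[tiers$rat$windows$mature_name == ext$mature_name, ]
  expect_identical(ext$insert,
                   substr(tiers$rat$sequences[[w$precursor]], w$start,
                          w$end + 2L))
})

test_that("atlas counts follow the planted two-component Poisson design", {
  pats <- c(list("liver"), rep(list(character(0)), 9))
  des <- atlas_design(10, enrichment_patterns = pats, lambda_high = 500,
                      lambda_low = 1, seed = 11)
  out <- generate_atlas_counts(des)
  out2 <- generate_atlas_counts(des)
  expect_identical(out$counts$counts, out2$counts$counts)

  ac <- out$counts
  expect_equal(ncol(ac$counts), 215L)  # 20 x 10 + 3 single-sex x 5
  liver <- ac$counts["mir_001", ac$samples$tissue == "liver"]
  expect_lt(abs(mean(liver) - 500), 3 * sqrt(500 / 10))
  expect_equal(out$truth$label[1], "specific")
  expect_equal(out$truth$tissues[1], "liver")
  expect_true(all(out$truth$label[-1] == "none"))
})

test_that("lambda_low = 0 silences all non-enriched cells exactly", {
  des <- atlas_design(4, enrichment_patterns = c(list("heart"),
                                                 rep(list(character(0)), 3)),
                      lambda_high = 100, lambda_low = 0, seed = 2)
  out <- generate_atlas_counts(des)
  ac <- out$counts
  expect_true(all(ac$counts[1, ac$samples$tissue != "heart"] == 0))
  expect_true(all(ac$counts[-1, ] == 0))
})

test_that("sex-specific miRNAs are silent in the opposite sex", {
  des <- atlas_design(2, sex_pattern = c("M", NA),
                      enrichment_patterns = list("liver", "liver"),
                      lambda_high = 50, lambda_low = 1, seed = 3)
  out <- generate_atlas_counts(des)
  ac <- out$counts
  expect_true(all(ac$counts[1, ac$samples$sex == "F"] == 0))
  expect_gt(sum(ac$counts[1, ac$samples$sex == "M"]), 0)
  expect_equal(out$truth$label, c("sex_specific", "specific"))
})

test_that("qPCR study noise has the requested AR(1) structure", {
  st0 <- generate_qpcr_study(groups = "g", timepoints = 1:8,
                             n_animals = 30, rho = 0,
                             true_log2fc = matrix(0, 1, 8),
                             sigma = 1, seed = 4)
  fc0 <- spike_normalized_fold_change(st0, reference = "predose")
  expect_lt(abs(mean(fc0$log2fc)), 3 * 1 / sqrt(nrow(fc0)))

  st <- generate_qpcr_study(groups = "g", timepoints = 1:8,
                            n_animals = 30, rho = 0.9,
                            true_log2fc = matrix(0, 1, 8),
                            sigma = 1, seed = 5)
  w <- st$wells
  tgt <- w[w$target == st$target & w$well_type == "sample", ]
  spk <- w[w$target == st$spike & w$well_type == "sample", ]
  e <- 8 - (tgt$ct - spk$ct)  # baseline_dct - dct recovers the noise
  by_an <- split(e, tgt$animal)
  pairs <- do.call(rbind, lapply(by_an, function(v) {
    cbind(v[-length(v)], v[-1])
  }))
  expect_lt(abs(cor(pairs[, 1], pairs[, 2]) - 0.9), 0.1)

  expect_identical(generate_qpcr_study(seed = 10)$wells,
                   generate_qpcr_study(seed = 10)$wells)
  expect_error(generate_qpcr_study(rho = 1), "rho")
})
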