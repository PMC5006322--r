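adapter <- "TGGAATTCTCGGGTGCCAAGG"

test_that("adapter trimming applies the prefix-match and length window", {
  r <- trim_adapter("ACGTACGTACGTACGTTGGAATTCXX", adapter,
                    min_len = 16, max_len = 35, match_prefix_len = 8)
  expect_true(r$keep)
  expect_identical(r$insert, "ACGTACGTACGTACGT")

  # 15-nt insert falls below the window
  r2 <- trim_adapter(paste0("ACGTACGTACGTACG", adapter), adapter)
  expect_false(r2$keep)
  expect_identical(r2$reason, "too_short")

  # no adapter: kept when within the window, dropped in strict mode
  free <- strrep("AC", 10)
  expect_true(trim_adapter(free, adapter)$keep)
  expect_false(trim_adapter(free, adapter, keep_untrimmed = FALSE)$keep)
  expect_false(trim_adapter(strrep("AC", 30), adapter)$keep)  # 60 nt > 35

  # ambiguous bases dropped only under the N-filtering profile
  rn <- paste0("ACGTNCGTACGTACGTA", adapter)
  expect_true(trim_adapter(rn, adapter)$keep)
  expect_false(trim_adapter(rn, adapter, drop_n = TRUE)$keep)

  # empty read discards without error
  expect_false(trim_adapter("", adapter)$keep)
  expect_error(trim_adapter("ACGT", adapter, match_prefix_len = 50),
               "prefix")
})

test_that("trimming profiles carry the documented windows", {
  expect_equal(trimming_profile("maastricht")[c("min_len", "max_len")],
               list(min_len = 16L, max_len = 35L))
  expect_equal(trimming_profile("niehs")[c("min_len", "max_len")],
               list(min_len = 14L, max_len = 24L))
  expect_true(trimming_profile("lilly")$drop_n)
  expect_equal(trimming_profile("lilly")$min_len, 17L)
})

test_that("read collapsing conserves counts and numbers ids uniquely", {
  col <- collapse_reads(c("ACGT", "ACGT", "ACGT", "AAAA"), "LIV")
  expect_identical(col$id, c("LIV_1_x3", "LIV_2_x1"))
  expect_identical(col$sequence, c("ACGT", "AAAA"))

  expect_equal(nrow(collapse_reads(character(0), "LIV")), 0L)
  expect_error(collapse_reads("ACGT", "L1V"), "alphabetic")

  reads <- withr::with_seed(42, sample(
    apply(matrix(sample(c("A", "C", "G", "T"), 20 * 300, TRUE), 300), 1,
          paste, collapse = ""),
    5000, replace = TRUE))
  col2 <- collapse_reads(reads, "RND")
  expect_equal(sum(col2$count), 5000L)
  expect_false(anyDuplicated(col2$sequence) > 0)
})

test_that("exact mapping equals the naive substring scan", {
  tiers <- fixture_tiers()
  queries <- withr::with_seed(7, c(
    tiers$seqs$shared, tiers$seqs$dup, tiers$seqs$loop134,
    replicate(60, paste(sample(c("A", "C", "G", "T"), 20, TRUE),
                        collapse = "")),
    # genuine substrings sampled from the fixture hairpins
    vapply(sample(names(tiers$rat$sequences), 20, TRUE), function(p) {
      s <- tiers$rat$sequences[[p]]
      st <- sample(nchar(s) - 21, 1)
      substr(s, st, st + 21)
    }, character(1))
  ))
  got <- map_exact(queries, tiers$rat)
  want <- brute_force_scan(unique(queries), tiers$rat)
  key <- function(d) sort(sprintf("%s|%s|%d|%d", d$sequence, d$precursor,
                                  d$start, d$end))
  expect_identical(key(got), key(want))

  # a sequence absent everywhere yields no rows
  expect_equal(nrow(map_exact(strrep("A", 25), tiers$rat)), 0L)
  # the planted multi-locus sequence has exactly 3 loci
  expect_equal(nrow(map_exact(tiers$seqs$dup, tiers$rat)), 3L)
})

test_that("isomiR assignment covers composite, -pre and coordinate naming", {
  tiers <- fixture_tiers()
  rat <- tiers$rat

  # shared 5p sequence -> composite name, invariant to locus order
  hits <- map_exact(tiers$seqs$shared, rat)
  a <- assign_isomir(hits, rat)
  expect_identical(a$assigned_mature, "let-7a-5p;let-7f-5p")
  a_rev <- assign_isomir(hits[rev(seq_len(nrow(hits))), ], rat)
  expect_identical(a_rev$assigned_mature, a$assigned_mature)

  # loop sequence outside both windows -> "<precursor>-pre"
  hits134 <- map_exact(tiers$seqs$loop134, rat)
  a134 <- assign_isomir(hits134, rat)
  expect_identical(a134$assigned_mature, "mir-134-pre")

  # exact 3p mature of mir-127 -> coordinate name with arm and 1-based ends
  m127 <- substr(rat$sequences[["mir-127"]], 57, 78)
  a127 <- assign_isomir(map_exact(m127, rat), rat)
  expect_identical(a127$isomir_name, "mir-127_3p_57_78")
  expect_identical(a127$assigned_mature, "miR-127-3p")

  expect_error(assign_isomir(map_exact("GGGGG", rat), rat), "locus")
})

test_that("an isomiR shifted within tolerance keeps its mature identity", {
  tiers <- fixture_tiers()
  rat <- tiers$rat
  # trim 2 nt off the 5' end of let-7a-5p (but keep it unique to let-7a
  # by adding 3' extension into the let-7a backbone)
  iso <- substr(rat$sequences[["let-7a"]], 7, 28)
  a <- assign_isomir(map_exact(iso, rat), rat)
  expect_true(grepl("let-7a-5p", a$assigned_mature))
  # a deep truncation far past the tolerance becomes a -pre call
  deep <- substr(rat$sequences[["let-7a"]], 13, 40)
  a2 <- assign_isomir(map_exact(deep, rat), rat)
  expect_identical(a2$assigned_mature, "let-7a-pre")
})

test_that("cross-species assignment uses the first tier that matches", {
  tiers <- fixture_tiers()
  reads <- c(rep(tiers$seqs$shared, 3), tiers$seqs$mouse, "GATTACAGATTACAGATTACA")
  col <- collapse_reads(reads, "XSP")
  res <- cross_species_assign(col, list(rat = tiers$rat, mouse = tiers$mouse))
  asg <- res$assignments
  expect_setequal(asg$species_tier[asg$sequence == tiers$seqs$shared], "rat")
  expect_setequal(asg$species_tier[asg$sequence == tiers$seqs$mouse], "mouse")
  expect_equal(res$unidentified$sequence, "GATTACAGATTACAGATTACA")

  # a sequence present in both tiers is claimed by the first
  both <- substr(tiers$rat$sequences[["let-7a"]], 5, 26)
  res2 <- cross_species_assign(collapse_reads(both, "TWO"),
                               list(rat = tiers$rat, mouse = tiers$rat))
  expect_true(all(res2$assignments$species_tier == "rat"))
})

test_that("multi-locus counts divide evenly and conserve totals", {
  tiers <- fixture_tiers()
  col <- collapse_reads(rep(tiers$seqs$dup, 12), "DUP")
  res <- cross_species_assign(col, list(rat = tiers$rat))
  expect_equal(nrow(res$assignments), 3L)
  div <- divide_multilocus_counts(res$assignments)
  expect_equal(div$count, rep(4, 3))
  expect_equal(sum(div$count), 12)

  # fractional shares are allowed
  fake <- res$assignments
  fake$count <- 10
  fake$n_loci <- 4L
  expect_equal(divide_multilocus_counts(fake)$count, rep(2.5, 3))

  # conservation over a random batch against all fixture hairpins
  reads <- withr::with_seed(3, {
    picks <- sample(names(tiers$rat$sequences), 400, TRUE)
    vapply(picks, function(p) {
      s <- tiers$rat$sequences[[p]]
      st <- sample(nchar(s) - 19, 1)
      substr(s, st, st + 19)
    }, character(1))
  })
  col2 <- collapse_reads(reads, "BAT")
  res2 <- cross_species_assign(col2, list(rat = tiers$rat))
  div2 <- divide_multilocus_counts(res2$assignments)
  assigned_total <- sum(div2$count)
  unidentified_total <- sum(res2$unidentified$count)
  expect_equal(assigned_total + unidentified_total, 400)
})

test_that("zero-offset synthetic reads are fully assigned to their truth", {
  tiers <- generate_precursor_set(8, "rat", seed = 21)
  rd <- generate_reads(tiers$rat, n_reads = 300, seed = 22)
  tr <- trim_adapter(rd$sequence, "TGGAATTCTCGGGTGCCAAGG")
  col <- collapse_reads(tr$insert[tr$keep], "RTR")
  res <- cross_species_assign(col, tiers)
  expect_equal(nrow(res$unidentified), 0L)
  asg <- res$assignments
  truth <- unique(rd[, c("insert", "mature_name")])
  for (i in seq_len(nrow(truth))) {
    got <- unique(asg$assigned_mature[asg$sequence == truth$insert[i]])
    expect_true(grepl(truth$mature_name[i], got, fixed = TRUE))
  }
})

test_that("isomiR percentages normalise within each parent", {
  tab <- data.frame(mature = c("a", "a", "b"),
                    isomir = c("a_1", "a_2", "b_1"),
                    count = c(75, 25, 40))
  out <- isomir_fraction_of_mature(tab)
  expect_equal(out$pct, c(75, 25, 100))

  rnd <- withr::with_seed(8, data.frame(
    mature = sample(letters[1:6], 60, TRUE),
    isomir = sprintf("iso%d", 1:60),
    count = rgamma(60, 2, 0.1)))
  o2 <- isomir_fraction_of_mature(rnd)
  sums <- tapply(o2$pct, o2$mature, sum)
  expect_true(all(abs(sums - 100) < 1e-9))

  z <- isomir_fraction_of_mature(data.frame(
    mature = "z", isomir = "z_1", count = 0))
  expect_true(is.na(z$pct))
  expect_true(z$undefined)
})
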