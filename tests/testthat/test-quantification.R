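test_that("tissue aggregation sums animals and organ aggregation takes max", {
  ac <- random_atlas(20, c("liver", "heart", "kidney"), seed = 5)
  tm <- aggregate_tissue(ac)
  # brute-force summation oracle
  for (t in colnames(tm)) {
    cols <- ac$samples$tissue == t
    for (i in seq_len(nrow(tm))) {
      expect_equal(tm[i, t], sum(ac$counts[i, cols]))
    }
  }

  brain <- matrix(c(120, 45, 300, 10), 1,
                  dimnames = list("m1", c("cerebrum", "cerebellum",
                                          "hippocampus", "brainstem")))
  om <- aggregate_organ(brain, default_organ_map())
  expect_equal(om[1, "brain"], 300)

  single <- matrix(5, 1, dimnames = list("m1", "liver"))
  expect_equal(aggregate_organ(single)[1, "liver"], 5)

  expect_error(aggregate_organ(matrix(1, 1, 1,
                                      dimnames = list("m", "nosuch"))),
               "organ map")
})

test_that("the default 23-tissue panel aggregates to 14 organs", {
  des <- atlas_design(5, lambda_high = 10, lambda_low = 1, seed = 1)
  atl <- generate_atlas_counts(des)
  tm <- aggregate_tissue(atl$counts)
  expect_equal(ncol(tm), 23L)
  om <- aggregate_organ(tm)
  expect_equal(ncol(om), 14L)
  expect_setequal(colnames(om), unique(unname(default_organ_map())))
  # max is idempotent: aggregating an organ-level matrix again is identity
  om2 <- aggregate_organ(om, setNames(colnames(om), colnames(om)))
  expect_equal(om2[, colnames(om)], om)
})

test_that("TMM factors track true depth and composition", {
  a <- withr::with_seed(1, rpois(500, 50))
  m <- cbind(A = a, B = 2L * a)
  rownames(m) <- sprintf("g%d", 1:500)
  f <- tmm_normalize(m, ref = "A")
  expect_lt(abs(f$factors[["B"]] / f$factors[["A"]] - 2), 1e-6)
  expect_equal(unname(f$factors[["A"]]), 1)
  expect_equal(f$norm[, "A"], f$norm[, "B"])

  # identical library -> factor exactly 1
  m2 <- cbind(A = a, B = a)
  expect_equal(unname(tmm_normalize(m2, ref = "A")$factors[["B"]]), 1)

  # scale consistency: multiplying a library by c multiplies its factor by
  # c -- exact for the unweighted trimmed mean, near-exact with the
  # inverse-variance weights (whose gene weights shift slightly with depth)
  m3 <- cbind(A = a, B = withr::with_seed(2, rpois(500, 50)))
  f3 <- tmm_normalize(m3, ref = "A", weighted = FALSE)$factors[["B"]]
  m4 <- m3; m4[, "B"] <- 3L * m4[, "B"]
  f4 <- tmm_normalize(m4, ref = "A", weighted = FALSE)$factors[["B"]]
  expect_lt(abs(f4 / f3 - 3), 1e-6)
  f3w <- tmm_normalize(m3, ref = "A")$factors[["B"]]
  f4w <- tmm_normalize(m4, ref = "A")$factors[["B"]]
  expect_lt(abs(f4w / f3w - 3), 0.03)

  expect_error(tmm_normalize(cbind(A = a, B = 0L * a)), "all-zero")
})

test_that("TMM recovers depth ratios under asymmetric DE and matches edgeR", {
  skip_if_not_installed("edgeR")
  base <- withr::with_seed(3, rpois(1000, rgamma(1000, 2, scale = 30)))
  depth <- 2.5
  b <- withr::with_seed(4, {
    mu <- base * depth
    de <- sample(1000, 50)        # 5% DE genes, 8-fold up in B
    mu[de] <- mu[de] * 8
    rpois(1000, mu)
  })
  m <- cbind(A = base, B = b)
  rownames(m) <- sprintf("g%d", 1:1000)
  fac <- tmm_normalize(m, ref = "A")$factors[["B"]]
  expect_lt(abs(fac / depth - 1), 0.05)

  ef <- edgeR::calcNormFactors(m, method = "TMM", refColumn = 1)
  # composition factors agree up to edgeR's geometric-mean rescaling
  ours <- tmm_normalize(m, ref = "A")
  comp_ours <- ours$factors[["B"]] * sum(m[, "A"]) / sum(m[, "B"])
  comp_edger <- ef[2] / ef[1]
  expect_lt(abs(comp_ours - comp_edger), 0.02)
})

test_that("low-count filtering keeps a miRNA iff any sample reaches 10", {
  m <- rbind(low = c(9, 9, 9), edge = c(10, 0, 0), high = c(50, 0, 2))
  colnames(m) <- c("s1", "s2", "s3")
  out <- filter_low_counts(m)
  expect_setequal(rownames(out), c("edge", "high"))

  rnd <- withr::with_seed(6, matrix(rpois(600, 6), 60))
  keep_oracle <- logical(60)
  for (i in 1:60) {
    keep_oracle[i] <- FALSE
    for (j in seq_len(ncol(rnd))) if (rnd[i, j] >= 10) keep_oracle[i] <- TRUE
  }
  expect_equal(nrow(filter_low_counts(rnd)), sum(keep_oracle))
})

test_that("TPM scaling, zero imputation and ceiling follow their rules", {
  m <- matrix(c(2, 3, 5), 3, 1, dimnames = list(c("a", "b", "c"), "s"))
  out <- tpm_normalize(m, impute_zero = FALSE, ceil = FALSE)
  expect_equal(unname(out[, 1]), c(200000, 300000, 500000))
  expect_equal(sum(out[, 1]), 1e6)

  mz <- matrix(c(0, 3, 5), 3, 1)
  imp <- tpm_normalize(mz, impute_zero = TRUE, ceil = FALSE)
  expect_equal(unname(imp[1, 1]), 1 / 9 * 1e6)  # zero imputed to 1.0 of 9

  mc <- matrix(c(1, 812999), 2, 1)
  expect_equal(unname(tpm_normalize(mc, impute_zero = FALSE)[1, 1]),
               ceiling(1 / 813000 * 1e6))  # 1.23 -> 2

  big <- withr::with_seed(7, matrix(rpois(300, 20), 30))
  cols <- tpm_normalize(big, impute_zero = FALSE, ceil = FALSE)
  expect_true(all(abs(colSums(cols) - 1e6) < 1e-6))

  expect_error(tpm_normalize(matrix(0, 2, 1), impute_zero = FALSE), "total")
})
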