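make_counts <- function(mat, tissues, n_per_sex = 5L) {
  samples <- expand.grid(
    animal = c(sprintf("M%d", 1:n_per_sex), sprintf("F%d", 1:n_per_sex)),
    tissue = tissues, stringsAsFactors = FALSE)
  samples$sex <- substr(samples$animal, 1, 1)
  samples$organ <- samples$tissue
  samples$sample <- sprintf("%s_%s", samples$tissue, samples$animal)
  colnames(mat) <- samples$sample
  atlas_counts(mat, samples[, c("sample", "animal", "sex", "tissue", "organ")])
}

test_that("quorum rule separates specific, enriched and sex-specific calls", {
  tissues <- c("liver", "kidney", "heart", "brainstem")
  m <- matrix(0L, 3, 40)
  # mir 1: count > 1 in 9/10 liver animals only -> specific(liver)
  m[1, 1:9] <- 5L
  # mir 2: quorum in liver, kidney, heart -> enriched
  m[2, c(1:8, 11:18, 21:28)] <- 7L
  # mir 3: liver expressed in 5/5 males, 0/5 females -> sex_specific
  m[3, 1:5] <- 9L
  ac <- make_counts(m, tissues)
  calls <- classify_rule_based(ac)
  expect_equal(calls$label, c("specific", "enriched", "sex_specific"))
  expect_equal(calls$tissues[1], "liver")
  expect_equal(calls$tissues[2], "heart;kidney;liver")
  expect_equal(calls$sex[3], "M")

  # a miRNA over quorum in more than enriched_max_tissues is none
  t6 <- c(tissues, "ileum", "cortex")
  m4 <- matrix(8L, 1, 60)
  expect_equal(classify_rule_based(make_counts(m4, t6))$label, "none")
})

test_that("quorum rule equals brute-force evaluation on random matrices", {
  tissues <- c("liver", "kidney", "heart", "cortex", "ileum", "cerebrum")
  for (rep in 1:25) {
    m <- withr::with_seed(100 + rep,
      matrix(rpois(30 * 60, sample(c(0.5, 2, 6), 1)), 30, 60))
    ac <- make_counts(m, tissues)
    got <- classify_rule_based(ac)
    want <- brute_force_rule(m, ac$samples)
    expect_identical(got$label, want$label)
    expect_identical(got$tissues, want$tissues)
  }
})

test_that("read-fraction classifier applies the 90/50 thresholds", {
  tm <- rbind(
    spec = c(liver = 960, kidney = 20, heart = 20),
    enr  = c(liver = 550, kidney = 250, heart = 200),
    none = c(liver = 400, kidney = 350, heart = 250),
    zero = c(liver = 0, kidney = 0, heart = 0))
  calls <- classify_percentage(tm)
  expect_equal(calls$label, c("specific", "enriched", "none", "none"))
  expect_equal(calls$tissues[1:2], c("liver", "liver"))
  expect_equal(calls$score[1], 96)
  expect_true(is.na(calls$score[4]))

  # every specific call would also pass the enriched threshold
  expect_true(all(calls$score[calls$label == "specific"] > 50))

  # grouped evaluation recognises signal split across one organ's tissues
  tmg <- matrix(c(250, 250, 250, 250, 4, 4), 1,
                dimnames = list("brainy", c("cerebrum", "cerebellum",
                                            "hippocampus", "brainstem",
                                            "liver", "heart")))
  grp <- classify_percentage(tmg, organ_map = default_organ_map())
  expect_equal(grp$label, "enriched")
  expect_equal(grp$tissues, "brainstem;cerebellum;cerebrum;hippocampus")
})

test_that("NMF candidates refine to tissue-level calls via the mixture", {
  pats <- c(list("liver", c("cerebrum", "cerebellum", "hippocampus",
                            "brainstem"), "heart"),
            rep(list(character(0)), 12))
  des <- atlas_design(15, enrichment_patterns = pats, lambda_high = 500,
                      lambda_low = 1, seed = 31)
  atl <- generate_atlas_counts(des)
  res <- classify_nmf_mixture(atl$counts, seed = 8)
  calls <- res$calls
  liver <- calls[calls$mirna == "mir_001", ]
  expect_equal(liver$label, "specific")
  expect_equal(liver$tissues, "liver")
  brain <- calls[calls$mirna == "mir_002", ]
  expect_equal(brain$label, "enriched")
  expect_equal(brain$tissues, "brainstem;cerebellum;cerebrum;hippocampus")
})

test_that("venn overlaps report every intersection", {
  v <- venn_compare(list(A = as.character(1:5), B = as.character(3:7),
                         C = as.character(5:9)))
  expect_equal(v$n[v$sets == "A;B;C"], 1L)
  expect_equal(v$members[v$sets == "A;B;C"], "5")
  expect_equal(v$n[v$sets == "A;B"], 3L)

  same <- venn_compare(list(x = letters[1:4], y = letters[1:4]))
  expect_true(all(same$n == 4L))

  sets <- withr::with_seed(9, list(
    A = sample(letters, 10), B = sample(letters, 12), C = sample(letters, 8)))
  v2 <- venn_compare(sets)
  n_of <- function(s) v2$n[v2$sets == s]
  expect_lte(n_of("A;B;C"), min(n_of("A;B"), n_of("A;C"), n_of("B;C")))
  expect_lte(n_of("A;B"), min(n_of("A"), n_of("B")))

  expect_error(venn_compare(list(A = "x")), "2 sets")
})
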