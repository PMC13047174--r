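test_that("shannon matches direct evaluation and its invariants", {
  expect_equal(shannon(c(5, 5, 5, 5)), log(4))
  expect_equal(shannon(c(7, 0, 0)), 0)
  expect_equal(shannon(c(1, 3)), -0.25 * log(0.25) - 0.75 * log(0.75))
  expect_error(shannon(c(0, 0)), "all-zero")

  # permutation-invariant, maximal at uniformity
  set.seed(1)
  for (i in 1:10) {
    x <- rpois(20, 10)
    x[1] <- x[1] + 1 # ensure non-uniform, positive total
    expect_equal(shannon(sample(x)), shannon(x))
    expect_lte(shannon(x), log(sum(x > 0)) + 1e-12)
  }
})

test_that("chao1 is the bias-corrected estimator and needs counts", {
  # S_obs = 10, F1 = 4, F2 = 2 -> 10 + 4*3/6 = 12
  expect_equal(chao1(c(rep(1, 4), rep(2, 2), rep(3, 4))), 12)
  # F2 = 0 stays defined: S_obs = 3, F1 = 2 -> 3 + 2*1/2 = 4
  expect_equal(chao1(c(1, 1, 5)), 4)
  # no singletons -> estimate equals observed richness
  expect_equal(chao1(c(4, 2, 9)), 3)
  expect_error(chao1(c(0.2, 0.8)), "integer")

  # Chao1 >= observed richness always
  set.seed(2)
  for (i in 1:20) {
    x <- rpois(30, 2)
    if (sum(x) == 0) next
    expect_gte(chao1(x), sum(x > 0))
  }
})

test_that("pairwise similarity metrics match set/formula arithmetic", {
  expect_equal(jaccard_index(c(1, 1, 1, 0), c(0, 2, 5, 3)), 0.5)
  expect_equal(jaccard_index(c(1, 0), c(0, 2)), 0)
  expect_equal(jaccard_index(c(3, 1), c(5, 9)), 1)
  expect_error(jaccard_index(c(0, 0), c(0, 0)), "undefined")

  expect_equal(bray_curtis(c(0.5, 0.5), c(1, 0)), 0.5)
  expect_equal(bray_curtis(c(0.3, 0.7), c(0.3, 0.7)), 0)
  expect_equal(bray_curtis(c(1, 0), c(0, 1)), 1)
  expect_error(bray_curtis(c(0, 0), c(0, 0)), "undefined")

  # symmetry and range on random vectors
  set.seed(3)
  for (i in 1:20) {
    a <- runif(10) * rbinom(10, 1, 0.7)
    b <- runif(10) * rbinom(10, 1, 0.7)
    if (sum(a) + sum(b) == 0) next
    if (any(a > 0 | b > 0)) {
      expect_equal(jaccard_index(a, b), jaccard_index(b, a))
      expect_true(jaccard_index(a, b) >= 0 && jaccard_index(a, b) <= 1)
    }
    expect_equal(bray_curtis(a, b), bray_curtis(b, a))
    expect_true(bray_curtis(a, b) >= 0 && bray_curtis(a, b) <= 1)
  }
})

test_that("rank tests reproduce exact enumeration p-values", {
  mw <- mann_whitney(c(1, 2), c(3, 4))
  expect_equal(mw$statistic, 0)
  expect_equal(mw$p_value, 1 / 3) # 2 of 6 label arrangements as extreme

  wsr <- wilcoxon_signed_rank(c(1, 2, 3), alternative = "greater")
  expect_equal(wsr$p_value, 1 / 8) # 1 of 2^3 sign assignments

  # mirrored pairs: two-sided signed-rank p = 1 by symmetry
  expect_equal(wilcoxon_signed_rank(c(-2, -1, 1, 2))$p_value, 1)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "zero")
  expect_error(mann_whitney(numeric(0), 1:3), "non-empty")
})

test_that("BH adjustment follows the step-up rule", {
  expect_equal(bh_fdr(0.04), 0.04)
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_fdr(c(1, 1, 1)), c(1, 1, 1))
  expect_error(bh_fdr(c(0.1, 1.2)), "\\[0, 1\\]")
})

test_that("alpha diversity joins metadata and respects counts mode", {
  meta <- make_meta(c("A", "B"), 2, c("g1", "g2"))
  ft <- make_counts(meta, 15, seed = 4)
  alpha <- alpha_diversity(ft, meta)
  expect_setequal(
    names(alpha),
    c("sample_id", "shannon", "chao1", "subject_id", "group", "timepoint")
  )
  expect_equal(nrow(alpha), 4)
  expect_equal(alpha$shannon[1], shannon(as.matrix(ft)[alpha$sample_id[1], ]))
  rel <- to_relative(ft)
  expect_error(alpha_diversity(rel), "counts")
})

test_that("endpoint differences detect a drifting group and only it", {
  make_alpha <- function(seed) {
    set.seed(seed)
    subjects <- c(paste0("d", 1:10), paste0("n", 1:10))
    groups <- rep(c("drift", "flat"), each = 10)
    base <- rnorm(20, 3, 0.3)
    last <- base + c(rep(1, 10), rep(0, 10)) + rnorm(20, 0, 0.2)
    data.frame(
      sample_id = c(paste0(subjects, "_1"), paste0(subjects, "_10")),
      subject_id = rep(subjects, 2),
      group = rep(groups, 2),
      timepoint = rep(c(1, 10), each = 20),
      shannon = c(base, last),
      stringsAsFactors = FALSE
    )
  }
  hits_drift <- hits_flat <- 0
  for (s in 1:10) {
    res <- paired_endpoint_difference(make_alpha(s), "shannon", 1, 10)
    w <- res[res$comparison == "within", ]
    hits_drift <- hits_drift + (w$p_value[w$group1 == "drift"] < 0.05)
    hits_flat <- hits_flat + (w$p_value[w$group1 == "flat"] < 0.05)
    expect_lt(res$p_value[res$comparison == "between"], 0.05)
  }
  expect_gte(hits_drift, 9) # a +1 nat drift is essentially always detected
  expect_lte(hits_flat, 2)
})

test_that("degenerate endpoint differences are reported as NA, not errors", {
  alpha <- data.frame(
    sample_id = paste0("s", 1:8),
    subject_id = rep(c("A", "B", "C", "D"), 2),
    group = "g",
    timepoint = rep(c(1, 10), each = 4),
    shannon = rep(c(1, 2, 3, 4), 2), # identical series at both endpoints
    stringsAsFactors = FALSE
  )
  res <- paired_endpoint_difference(alpha, "shannon", 1, 10)
  expect_true(is.na(res$p_value[res$comparison == "within"]))
})
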