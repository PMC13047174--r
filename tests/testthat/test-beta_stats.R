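test_that("distance matrices agree with the pairwise metric functions", {
  set.seed(11)
  v <- matrix(runif(18) * rbinom(18, 1, 0.8), 3, 6,
    dimnames = list(c("s1", "s2", "s3"), NULL)
  )
  ftab <- feature_table(v)
  dj <- as.matrix(distance_matrix(ftab, "jaccard"))
  db <- as.matrix(distance_matrix(ftab, "bray_curtis"))
  for (i in 1:2) {
    for (j in (i + 1):3) {
      expect_equal(dj[i, j], 1 - jaccard_index(v[i, ], v[j, ]))
      expect_equal(db[i, j], bray_curtis(v[i, ], v[j, ]))
    }
  }
  # duplicated rows sit at distance zero
  dup <- feature_table(rbind(a = v[1, ], b = v[1, ], c = v[2, ]))
  expect_equal(as.matrix(distance_matrix(dup, "bray_curtis"))["a", "b"], 0)
  expect_error(distance_matrix(feature_table(v[1, , drop = FALSE])), "2 rows")
})

test_that("pcoa reconstructs euclidean configurations and flags semimetrics", {
  set.seed(12)
  pts <- cbind(rnorm(8), rnorm(8))
  rownames(pts) <- paste0("s", 1:8)
  d <- stats::dist(pts)
  emb <- pcoa(d, n_axes = 2)
  rec <- stats::dist(as.matrix(emb$points[, c("PC1", "PC2")]))
  expect_equal(as.vector(rec), as.vector(d), tolerance = 1e-8)

  # points on a line: one informative axis, second eigenvalue ~ 0, and
  # asking for more axes than positive eigenvalues truncates with a warning
  line <- matrix(c(0, 1, 2, 3.5), ncol = 1, dimnames = list(paste0("p", 1:4)))
  expect_warning(emb_line <- pcoa(stats::dist(line), n_axes = 2), "positive eigenvalues")
  expect_lt(emb_line$eigenvalues[2] / emb_line$eigenvalues[1], 1e-10)
  expect_equal(
    as.vector(stats::dist(emb_line$points$PC1)),
    as.vector(stats::dist(line))
  )

  # a Bray-Curtis semimetric yields negative eigenvalues, reported unused
  comp <- feature_table(matrix(runif(40), 8, 5))
  emb_bc <- pcoa(distance_matrix(to_relative(comp), "bray_curtis"), n_axes = 2)
  expect_true(any(emb_bc$eigenvalues < 0))
  expect_true(all(emb_bc$prop_explained >= 0))
})

test_that("permanova matches the exhaustive relabeling oracle on small n", {
  brute_force_p <- function(d, labels) {
    d2 <- as.matrix(d)^2
    n <- nrow(d2)
    a <- length(unique(labels))
    sst <- sum(d2) / (2 * n)
    fstat <- function(lab) {
      ssw <- sum(vapply(split(seq_len(n), lab), function(ix) {
        sum(d2[ix, ix]) / (2 * length(ix))
      }, numeric(1)))
      ((sst - ssw) / (a - 1)) / (ssw / (n - a))
    }
    sizes <- table(labels)
    grid <- utils::combn(n, sizes[1])
    f_obs <- fstat(labels)
    f_all <- apply(grid, 2, function(ix) {
      lab <- rep(names(sizes)[2], n)
      lab[ix] <- names(sizes)[1]
      fstat(lab)
    })
    mean(f_all >= f_obs - 1e-12)
  }
  set.seed(13)
  for (sizes in list(c(3, 3), c(4, 4), c(3, 5))) {
    y <- matrix(runif(sum(sizes) * 4), sum(sizes), 4)
    d <- stats::dist(y)
    labels <- rep(c("g1", "g2"), sizes)
    ours <- permanova(d, labels, exact = TRUE)
    expect_equal(ours$p_value, brute_force_p(d, labels))
  }
})

test_that("permanova pseudo-F matches vegan's adonis2 and is seed-stable", {
  set.seed(14)
  v <- matrix(rpois(60, 20), 12, 5)
  labels <- rep(c("a", "b", "c"), each = 4)
  d <- distance_matrix(feature_table(v), "bray_curtis")
  pm <- permanova(d, labels, n_perm = 199, seed = 3)
  ad <- vegan::adonis2(d ~ labels, permutations = 199)
  expect_equal(pm$pseudo_F, ad$F[1])
  expect_equal(pm$df_between, ad$Df[1])
  expect_identical(pm$p_value, permanova(d, labels, n_perm = 199, seed = 3)$p_value)
  expect_true(pm$p_value >= 1 / 200 && pm$p_value <= 1)

  # perfectly separated groups reach the permutation floor once groups are
  # large enough that no random relabeling reproduces the split
  far <- feature_table(rbind(
    matrix(rnorm(50, 5, 0.01), 10), matrix(rnorm(50, 50, 0.01), 10)
  ))
  pm_far <- permanova(
    distance_matrix(far, "euclidean"), rep(c("x", "y"), each = 10),
    n_perm = 599, seed = 1
  )
  expect_equal(pm_far$p_value, 1 / 600)
  expect_error(permanova(d, c(rep("a", 11), "b"), 99), "single member")
})

test_that("consecutive stability respects adjacency and group structure", {
  meta <- data.frame(
    sample_id = c("A_1", "A_2", "A_4", "B_1", "B_3"),
    subject_id = c("A", "A", "A", "B", "B"),
    group = "g",
    timepoint = c(1, 2, 4, 1, 3),
    stringsAsFactors = FALSE
  )
  v <- matrix(rpois(25, 20), 5, 5, dimnames = list(meta$sample_id, NULL))
  v["A_2", ] <- v["A_1", ] # identical consecutive pair
  ft <- feature_table(v)
  expect_warning(cs <- consecutive_stability(ft, meta), "'B' has no adjacent")
  # a missing time point breaks adjacency: only T1-T2 remains for subject A
  expect_equal(cs$interval, "T1-T2")
  expect_equal(cs$jaccard, 1)

  disjoint <- feature_table(rbind(
    A_1 = c(5, 5, 0, 0), A_2 = c(0, 0, 5, 5)
  ))
  meta2 <- meta[1:2, ]
  expect_equal(consecutive_stability(disjoint, meta2)$jaccard, 0)
})

test_that("stability tests cover both families and skip sparse cells", {
  set.seed(15)
  series <- expand.grid(
    subject_id = paste0("s", 1:6), k = 1:3,
    stringsAsFactors = FALSE
  )
  series$group <- rep(c("g1", "g2"), 9)
  series$interval <- sprintf("T%d-T%d", series$k, series$k + 1)
  series$jaccard <- runif(nrow(series), 0.5, 0.9)
  res <- stability_tests(series)
  expect_equal(nrow(res$within), 2 * 3) # per group, all interval pairs
  expect_equal(nrow(res$between), 3) # per interval, one group pair
  expect_true(all(res$between$fdr_q >= res$between$p_value - 1e-12))

  single <- series[series$k == 1, ]
  res_single <- stability_tests(single)
  expect_null(res_single$within)
})

test_that("event comparisons need both sides and detect a configured event", {
  coh <- small_cohort(33, event = list(group = "toddler", prob = 1))
  ev <- event_split_compare(coh$taxa, coh$metadata, seed = 1)
  expect_lt(ev$permanova$p_value, 0.05)
  expect_lt(ev$alpha$p_value[ev$alpha$metric == "shannon"], 0.05)
  expect_equal(ev$n_subjects, 6)

  meta_one <- coh$metadata
  meta_one$event_status[meta_one$group == "toddler"] <- "before"
  expect_error(event_split_compare(coh$taxa, meta_one), ">= 3 needed")
  meta_none <- coh$metadata
  meta_none$event_status <- NULL
  expect_error(event_split_compare(coh$taxa, meta_none), "event_status")
})
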