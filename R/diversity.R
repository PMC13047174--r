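#' Shannon diversity (natural log)
#'
#' `H = -sum(p_i * ln(p_i))` over the positive entries of the relative
#' abundances of `x`. Reported in nats.
#'
#' @param x non-negative abundance vector with positive sum.
#' @return Shannon index in `[0, ln(k)]`.
#' @examples
#' shannon(c(5, 5, 5, 5)) # ln(4)
#' @export
shannon <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) stop("abundances must be non-negative and complete")
  if (sum(x) <= 0) stop("cannot compute Shannon diversity of an all-zero vector")
  unname(vegan::diversity(x, index = "shannon"))
}

#' Bias-corrected Chao1 richness estimate
#'
#' `S_obs + F1*(F1 - 1) / (2*(F2 + 1))`, with `F1`/`F2` the singleton and
#' doubleton counts; defined even when no doubletons are observed. Requires
#' integer counts (the estimator is undefined on relative abundances).
#'
#' @param x non-negative integer count vector.
#' @return Chao1 estimate (always `>=` observed richness).
#' @examples
#' chao1(c(1, 1, 1, 1, 2, 2, 3, 3, 3, 3)) # 10 + 4*3/6 = 12
#' @export
chao1 <- function(x) {
  x <- as.numeric(x)
  if (anyNA(x) || any(x < 0)) stop("counts must be non-negative and complete")
  if (any(abs(x - round(x)) > 1e-8)) {
    stop("Chao1 requires integer counts; it is undefined on relative abundances")
  }
  if (sum(x) <= 0) stop("cannot estimate richness of an all-zero vector")
  unname(vegan::estimateR(round(x))["S.chao1"])
}

#' Jaccard similarity of two samples
#'
#' Fraction of shared features: `|A intersect B| / |A union B|` with
#' presence defined as abundance strictly above `threshold`. Ranges from 0
#' (disjoint) to 1 (identical presence sets).
#'
#' @param a,b abundance vectors over the same feature space.
#' @param threshold presence threshold (default 0: any positive abundance).
#' @return Similarity in `[0, 1]`.
#' @examples
#' jaccard_index(c(1, 1, 1, 0), c(0, 2, 5, 3)) # {A,B,C} vs {B,C,D} -> 0.5
#' @export
jaccard_index <- function(a, b, threshold = 0) {
  if (length(a) != length(b)) stop("samples must share one feature space")
  pa <- a > threshold
  pb <- b > threshold
  uni <- sum(pa | pb)
  if (uni == 0) stop("both samples are empty; Jaccard similarity is undefined")
  sum(pa & pb) / uni
}

#' Bray-Curtis dissimilarity of two samples
#'
#' `sum(|a_i - b_i|) / sum(a_i + b_i)`, in `[0, 1]` for non-negative input.
#'
#' @param a,b non-negative abundance vectors over the same feature space.
#' @return Dissimilarity in `[0, 1]`.
#' @export
bray_curtis <- function(a, b) {
  if (length(a) != length(b)) stop("samples must share one feature space")
  tot <- sum(a + b)
  if (tot == 0) stop("both samples are all zero; Bray-Curtis is undefined")
  sum(abs(a - b)) / tot
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two independent samples. Exact p-values are used
#' for small tie-free samples, otherwise the normal approximation with tie
#' and continuity correction (the [stats::wilcox.test()] conventions).
#'
#' @param x,y numeric samples.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row data.frame with `method`, `statistic` (U), `p_value`,
#'   `n1`, `n2` and `alternative`.
#' @export
mann_whitney <- function(x, y, alternative = "two.sided") {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ht <- suppressWarnings(stats::wilcox.test(x, y, alternative = alternative))
  data.frame(
    method = "mann_whitney",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n1 = length(x), n2 = length(y),
    alternative = alternative,
    stringsAsFactors = FALSE
  )
}

#' Wilcoxon signed-rank test on paired differences
#'
#' Zero differences are dropped before testing, matching the classical
#' procedure; exact p-values for small tie-free samples, otherwise the
#' normal approximation.
#'
#' @param d vector of paired differences.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A one-row data.frame with `method`, `statistic` (W), `p_value`,
#'   `n` (non-zero differences) and `alternative`.
#' @export
wilcoxon_signed_rank <- function(d, alternative = "two.sided") {
  d <- d[!is.na(d)]
  d <- d[d != 0]
  if (!length(d)) {
    stop("all paired differences are zero; the signed-rank test is undefined")
  }
  ht <- suppressWarnings(stats::wilcox.test(d, alternative = alternative))
  data.frame(
    method = "wilcoxon_signed_rank",
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    n = length(d),
    alternative = alternative,
    stringsAsFactors = FALSE
  )
}

#' Benjamini-Hochberg false discovery rate adjustment
#'
#' @param p vector of p-values in `[0, 1]` (`NA`s passed through).
#' @return Vector of BH q-values.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Per-sample alpha diversity joined to metadata
#'
#' Shannon index (nats) and bias-corrected Chao1 per sample of a counts-mode
#' table, computed on raw counts by default; `rarefy = TRUE` rarefies every
#' sample to the minimum depth first (without replacement).
#'
#' @param x a counts-mode [feature_table].
#' @param meta optional metadata; when given, `subject_id`, `group` and
#'   `timepoint` are joined onto the result.
#' @param rarefy rarefy all samples to the minimum sample depth first.
#' @param seed optional seed for the rarefaction draw.
#' @return A data.frame with one row per sample: `sample_id`, `shannon`,
#'   `chao1` and, if `meta` is given, its grouping columns.
#' @export
alpha_diversity <- function(x, meta = NULL, rarefy = FALSE, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  if (x$mode != "counts") {
    stop("alpha diversity is computed on counts (Chao1 is undefined on relative data)")
  }
  v <- x$values
  if (rarefy) {
    if (!is.null(seed)) set.seed(seed)
    v <- vegan::rrarefy(round(v), min(rowSums(round(v))))
  }
  out <- data.frame(
    sample_id = rownames(v),
    shannon = apply(v, 1, shannon),
    chao1 = apply(v, 1, chao1),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  if (!is.null(meta)) {
    meta <- validate_metadata(meta, x)
    keep <- intersect(c("subject_id", "group", "timepoint", "age", "event_status"), names(meta))
    out <- cbind(out, meta[match(out$sample_id, meta$sample_id), keep, drop = FALSE])
    rownames(out) <- NULL
  }
  out
}

#' Paired endpoint change in alpha diversity, within and between groups
#'
#' For every subject present at both endpoints, computes the difference
#' `metric at t_last - metric at t_first`. Within each group the differences
#' are tested against zero (Wilcoxon signed-rank); between each pair of
#' groups the differences are compared (Mann-Whitney U). BH-FDR is applied
#' across the whole family of tests. Subjects missing either endpoint are
#' dropped with a warning; groups with fewer than two complete subjects are
#' skipped with a warning.
#'
#' @param alpha an [alpha_diversity()] result including `subject_id`,
#'   `group` and `timepoint`.
#' @param metric column of `alpha` to analyse (`"shannon"` or `"chao1"`).
#' @param t_first,t_last endpoint time points.
#' @return A data.frame of test results: `comparison` (`"within"` or
#'   `"between"`), `group1`, `group2` (`NA` for within), `n1`, `n2`,
#'   `mean_diff1`, `statistic`, `p_value`, `fdr_q`, `method`. Degenerate
#'   within-group tests (all differences zero) are reported with `NA`
#'   p-values.
#' @export
paired_endpoint_difference <- function(alpha, metric = "shannon",
                                       t_first = 1, t_last = 10) {
  stopifnot(metric %in% names(alpha))
  need <- c("subject_id", "group", "timepoint")
  if (!all(need %in% names(alpha))) {
    stop("alpha series must carry subject_id, group and timepoint; pass meta to alpha_diversity()")
  }
  first <- alpha[alpha$timepoint == t_first, ]
  last <- alpha[alpha$timepoint == t_last, ]
  subjects <- intersect(first$subject_id, last$subject_id)
  dropped <- setdiff(unique(alpha$subject_id), subjects)
  if (length(dropped)) {
    warning(sprintf(
      "%d subject(s) missing an endpoint dropped: %s",
      length(dropped), paste(utils::head(dropped, 5), collapse = ", ")
    ))
  }
  d <- data.frame(
    subject_id = subjects,
    group = first$group[match(subjects, first$subject_id)],
    diff = last[[metric]][match(subjects, last$subject_id)] -
      first[[metric]][match(subjects, first$subject_id)],
    stringsAsFactors = FALSE
  )
  rows <- list()
  for (g in unique(d$group)) {
    dg <- d$diff[d$group == g]
    if (length(dg) < 2) {
      warning(sprintf("group '%s' has < 2 complete subjects; skipped", g))
      next
    }
    res <- if (all(dg == 0)) {
      data.frame(
        method = "wilcoxon_signed_rank", statistic = NA_real_,
        p_value = NA_real_, n = length(dg),
        alternative = "two.sided", stringsAsFactors = FALSE
      )
    } else {
      wilcoxon_signed_rank(dg)
    }
    rows[[length(rows) + 1]] <- data.frame(
      comparison = "within", group1 = g, group2 = NA_character_,
      n1 = length(dg), n2 = NA_integer_, mean_diff1 = mean(dg),
      statistic = res$statistic, p_value = res$p_value,
      method = res$method, stringsAsFactors = FALSE
    )
  }
  groups <- unique(d$group)
  if (length(groups) > 1) {
    for (i in seq_len(length(groups) - 1)) {
      for (j in seq(i + 1, length(groups))) {
        d1 <- d$diff[d$group == groups[i]]
        d2 <- d$diff[d$group == groups[j]]
        if (length(d1) < 2 || length(d2) < 2) next
        res <- mann_whitney(d1, d2)
        rows[[length(rows) + 1]] <- data.frame(
          comparison = "between", group1 = groups[i], group2 = groups[j],
          n1 = length(d1), n2 = length(d2), mean_diff1 = mean(d1),
          statistic = res$statistic, p_value = res$p_value,
          method = res$method, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no group had enough complete subjects to test")
  out$fdr_q <- bh_fdr(out$p_value)
  out
}
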