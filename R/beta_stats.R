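#' Pairwise distance matrix of a feature table
#'
#' Jaccard similarity is converted to a distance (`1 - J`) on presence sets
#' (abundance strictly above `threshold`); Bray-Curtis acts on the
#' quantitative profiles; Euclidean uses [stats::dist()] and tolerates
#' missing entries (pairwise-complete, as needed for RSI profiles with
#' features absent from some units).
#'
#' @param x a [feature_table] or a numeric matrix with rows to compare.
#' @param metric `"jaccard"`, `"bray_curtis"` or `"euclidean"`.
#' @param threshold presence threshold for the Jaccard metric.
#' @return A [stats::dist] object with a `metric` attribute.
#' @export
distance_matrix <- function(x, metric = c("jaccard", "bray_curtis", "euclidean"),
                            threshold = 0) {
  metric <- match.arg(metric)
  v <- ft_matrix(x)
  if (nrow(v) < 2) stop("at least 2 rows are needed for a distance matrix")
  d <- switch(metric,
    jaccard = vegan::vegdist((v > threshold) * 1, method = "jaccard", binary = TRUE),
    bray_curtis = vegan::vegdist(v, method = "bray"),
    euclidean = stats::dist(v)
  )
  attr(d, "metric") <- metric
  d
}

#' Principal coordinates analysis
#'
#' Classical metric scaling of a distance matrix (Gower double-centering and
#' eigendecomposition). Axes are ordered by eigenvalue; coordinates are built
#' from positive eigenvalues only, and negative eigenvalues (present for
#' semimetrics such as Bray-Curtis) are reported but never used. Requesting
#' more axes than there are positive eigenvalues truncates with a warning.
#'
#' @param d a [stats::dist] (e.g. from [distance_matrix()]).
#' @param n_axes number of coordinate axes to return.
#' @param meta optional metadata; when given, `timepoint` (and `group`) are
#'   joined onto the coordinates so time can be used as an extra plotting
#'   axis.
#' @return A list of class `pcoa` with `points` (data.frame of `sample_id`
#'   and `PC*` columns, plus metadata columns if requested), `eigenvalues`,
#'   and `prop_explained` (relative to the positive eigenvalues).
#' @export
pcoa <- function(d, n_axes = 2, meta = NULL) {
  n <- attr(d, "Size")
  mds <- suppressWarnings(stats::cmdscale(d, k = n - 1, eig = TRUE))
  eig <- mds$eig
  npos <- sum(eig > sqrt(.Machine$double.eps))
  if (n_axes > npos) {
    warning(sprintf(
      "only %d positive eigenvalues; returning %d axes instead of %d",
      npos, npos, n_axes
    ))
    n_axes <- npos
  }
  pts <- mds$points[, seq_len(n_axes), drop = FALSE]
  colnames(pts) <- paste0("PC", seq_len(n_axes))
  out <- data.frame(sample_id = labels(d), pts, stringsAsFactors = FALSE)
  rownames(out) <- NULL
  if (!is.null(meta)) {
    keep <- intersect(c("subject_id", "group", "timepoint"), names(meta))
    out <- cbind(out, meta[match(out$sample_id, meta$sample_id), keep, drop = FALSE])
    rownames(out) <- NULL
  }
  structure(
    list(
      points = out,
      eigenvalues = eig,
      prop_explained = pmax(eig, 0) / sum(pmax(eig, 0))
    ),
    class = "pcoa"
  )
}

# internal: within-group sum of squares from a squared-distance matrix
ss_within <- function(d2, groups) {
  idx <- split(seq_len(nrow(d2)), groups)
  sum(vapply(idx, function(ix) sum(d2[ix, ix]) / (2 * length(ix)), numeric(1)))
}

# internal: all permutations of 1..n (for the exhaustive PERMANOVA)
all_perms <- function(n) {
  if (n == 1) {
    return(matrix(1L, 1, 1))
  }
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow(sub), n - 1))
  }))
}

#' Permutational multivariate analysis of variance (PERMANOVA)
#'
#' One-way PERMANOVA on a distance matrix: the pseudo-F statistic is built
#' from sums of squared inter-point distances
#' (`SS_total = sum_{i<j} d_ij^2 / n`, within-group terms analogously per
#' group), and its null distribution from random relabelings. The p-value
#' uses the `+1` convention (the observed statistic is counted among the
#' permutations), so it can never be 0 and lies in
#' `[1/(n_perm + 1), 1]`. With `exact = TRUE` all `n!` relabelings are
#' enumerated instead (feasible for small n) and the p-value is the exact
#' permutation tail probability.
#'
#' @param d a [stats::dist] object.
#' @param labels group label per row of `d`; at least 2 groups with at least
#'   2 members each.
#' @param n_perm number of random permutations (default 600).
#' @param seed optional integer seed for the permutation draw.
#' @param exact enumerate all label permutations instead of sampling.
#' @return A list of class `permanova`: `pseudo_F`, `p_value`, `n_perm`,
#'   `df_between`, `df_within`, `seed`, `exact`.
#' @export
permanova <- function(d, labels, n_perm = 600, seed = NULL, exact = FALSE) {
  labels <- as.factor(labels)
  n <- attr(d, "Size")
  if (length(labels) != n) stop("one label per distance-matrix row is required")
  sizes <- table(labels)
  if (length(sizes) < 2) stop("PERMANOVA needs at least 2 groups")
  if (any(sizes < 2)) {
    stop(sprintf(
      "group '%s' has a single member", names(sizes)[sizes < 2][1]
    ))
  }
  a <- length(sizes)
  d2 <- as.matrix(d)^2
  ss_t <- sum(d2) / (2 * n)
  f_of <- function(labs) {
    ss_w <- ss_within(d2, labs)
    ((ss_t - ss_w) / (a - 1)) / (ss_w / (n - a))
  }
  f_obs <- f_of(labels)
  if (exact) {
    perms <- all_perms(n)
    f_all <- apply(perms, 1, function(ix) f_of(labels[ix]))
    p <- mean(f_all >= f_obs - 1e-12)
    n_perm <- nrow(perms)
  } else {
    if (!is.null(seed)) set.seed(seed)
    f_perm <- replicate(n_perm, f_of(sample(labels)))
    p <- (1 + sum(f_perm >= f_obs)) / (n_perm + 1)
  }
  structure(
    list(
      pseudo_F = f_obs, p_value = p, n_perm = n_perm,
      df_between = a - 1, df_within = n - a,
      seed = seed, exact = exact
    ),
    class = "permanova"
  )
}

#' @export
print.permanova <- function(x, ...) {
  cat(sprintf(
    "<permanova> pseudo-F(%d, %d) = %.4g, p = %.4g (%s permutations)\n",
    x$df_between, x$df_within, x$pseudo_F, x$p_value,
    if (x$exact) sprintf("all %d", x$n_perm) else sprintf("%d random", x$n_perm)
  ))
  invisible(x)
}

#' Consecutive-pair Jaccard stability series
#'
#' For every subject and every pair of adjacent time points actually present
#' (a missing time point breaks adjacency rather than bridging to the next
#' available sample), computes the Jaccard similarity of the two samples.
#' Higher values mean a more stable community. Subjects without any adjacent
#' pair are dropped with a warning.
#'
#' @param x a [feature_table].
#' @param meta sample metadata covering `x`.
#' @param level label for the feature level analysed (e.g. `"taxonomic"` or
#'   `"functional"`), carried into the output.
#' @param threshold presence threshold for the Jaccard index.
#' @return A data.frame of class `stability_series`: `subject_id`, `group`,
#'   `interval` (`"T<k>-T<k+1>"`), `k`, `jaccard`, `level`.
#' @export
consecutive_stability <- function(x, meta, level = "taxonomic", threshold = 0) {
  stopifnot(inherits(x, "feature_table"))
  meta <- validate_metadata(meta, x)
  v <- ft_matrix(x)
  rows <- list()
  for (s in unique(meta$subject_id)) {
    ms <- meta[meta$subject_id == s, ]
    tps <- sort(ms$timepoint)
    found <- FALSE
    for (k in tps) {
      if (!((k + 1) %in% tps)) next
      id1 <- ms$sample_id[ms$timepoint == k]
      id2 <- ms$sample_id[ms$timepoint == k + 1]
      rows[[length(rows) + 1]] <- data.frame(
        subject_id = s, group = ms$group[1],
        interval = sprintf("T%d-T%d", k, k + 1), k = k,
        jaccard = jaccard_index(v[id1, ], v[id2, ], threshold),
        level = level, stringsAsFactors = FALSE
      )
      found <- TRUE
    }
    if (!found) {
      warning(sprintf("subject '%s' has no adjacent time-point pair; dropped", s))
    }
  }
  if (!length(rows)) stop("no subject contributed a consecutive pair")
  out <- do.call(rbind, rows)
  class(out) <- c("stability_series", class(out))
  out
}

#' Within- and between-group tests on a stability series
#'
#' Two families of Mann-Whitney U tests on the consecutive-pair Jaccard
#' values: (1) within each group, every pair of consecutive intervals is
#' compared; (2) for each interval, every pair of groups is compared. BH-FDR
#' is applied within each family. Comparisons with fewer than 2 observations
#' in a cell are skipped.
#'
#' @param series a [consecutive_stability()] data.frame.
#' @return A list with data.frames `within` (`group`, `interval1`,
#'   `interval2`, `n1`, `n2`, `statistic`, `p_value`, `fdr_q`) and `between`
#'   (`interval`, `group1`, `group2`, ...).
#' @export
stability_tests <- function(series) {
  stopifnot(all(c("subject_id", "group", "interval", "k", "jaccard") %in% names(series)))
  ks <- sort(unique(series$k))
  groups <- unique(series$group)
  within <- list()
  for (g in groups) {
    sg <- series[series$group == g, ]
    kg <- sort(unique(sg$k))
    if (length(kg) < 2) next
    for (i in seq_len(length(kg) - 1)) {
      for (j in seq(i + 1, length(kg))) {
        x1 <- sg$jaccard[sg$k == kg[i]]
        x2 <- sg$jaccard[sg$k == kg[j]]
        if (length(x1) < 2 || length(x2) < 2) next
        mw <- mann_whitney(x1, x2)
        within[[length(within) + 1]] <- data.frame(
          group = g,
          interval1 = sprintf("T%d-T%d", kg[i], kg[i] + 1),
          interval2 = sprintf("T%d-T%d", kg[j], kg[j] + 1),
          n1 = length(x1), n2 = length(x2),
          statistic = mw$statistic, p_value = mw$p_value,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  between <- list()
  if (length(groups) > 1) {
    for (k in ks) {
      sk <- series[series$k == k, ]
      for (i in seq_len(length(groups) - 1)) {
        for (j in seq(i + 1, length(groups))) {
          x1 <- sk$jaccard[sk$group == groups[i]]
          x2 <- sk$jaccard[sk$group == groups[j]]
          if (length(x1) < 2 || length(x2) < 2) next
          mw <- mann_whitney(x1, x2)
          between[[length(between) + 1]] <- data.frame(
            interval = sprintf("T%d-T%d", k, k + 1),
            group1 = groups[i], group2 = groups[j],
            n1 = length(x1), n2 = length(x2),
            statistic = mw$statistic, p_value = mw$p_value,
            stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  within <- if (length(within)) do.call(rbind, within) else NULL
  between <- if (length(between)) do.call(rbind, between) else NULL
  if (!is.null(within)) within$fdr_q <- bh_fdr(within$p_value)
  if (!is.null(between)) between$fdr_q <- bh_fdr(between$p_value)
  list(within = within, between = between)
}

#' Compare community composition and diversity before vs after an event
#'
#' Implements the developmental-event split (weaning/menarche analogs): each
#' subject's samples are aggregated to per-feature median relative
#' abundances before and after the event, a PERMANOVA tests the
#' before/after labels on the aggregated rows, and per-sample Shannon and
#' Chao1 values are compared between sides with Mann-Whitney U tests.
#'
#' @param x a counts-mode [feature_table].
#' @param meta metadata with an `event_status` column (`before`/`after`,
#'   `NA` for subjects without the event).
#' @param metric distance metric for the PERMANOVA (see [distance_matrix()]).
#' @param n_perm,seed passed to [permanova()].
#' @return A list with `permanova` (a [permanova()] result on the aggregated
#'   rows), `alpha` (a data.frame of Mann-Whitney results for `shannon` and
#'   `chao1`) and `n_subjects` (subjects contributing both sides).
#' @export
event_split_compare <- function(x, meta, metric = "bray_curtis",
                                n_perm = 600, seed = NULL) {
  stopifnot(inherits(x, "feature_table"))
  meta <- validate_metadata(meta, x)
  if (is.null(meta$event_status)) {
    stop("metadata has no event_status column")
  }
  me <- meta[!is.na(meta$event_status), ]
  both <- vapply(
    split(me$event_status, me$subject_id),
    function(s) length(unique(s)) == 2, logical(1)
  )
  if (sum(both) < 3) {
    stop(sprintf(
      "only %d subject(s) have samples on both sides of the event; >= 3 needed",
      sum(both)
    ))
  }
  me <- me[me$subject_id %in% names(both)[both], ]
  sub <- feature_table(ft_matrix(x)[me$sample_id, , drop = FALSE], mode = "counts")
  agg <- aggregate_median_by_subject(to_relative(sub), me, event = TRUE)
  info <- attr(agg, "info")
  pm <- permanova(distance_matrix(agg, metric), info$event_status,
    n_perm = n_perm, seed = seed
  )
  alpha <- alpha_diversity(sub, me)
  res <- lapply(c("shannon", "chao1"), function(metric_name) {
    mw <- mann_whitney(
      alpha[[metric_name]][alpha$event_status == "before"],
      alpha[[metric_name]][alpha$event_status == "after"]
    )
    data.frame(
      metric = metric_name, statistic = mw$statistic, p_value = mw$p_value,
      n_before = mw$n1, n_after = mw$n2, stringsAsFactors = FALSE
    )
  })
  list(
    permanova = pm,
    alpha = do.call(rbind, res),
    n_subjects = sum(both)
  )
}
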