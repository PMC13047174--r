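#' Rank features at every time point
#'
#' At each time point features are ranked by decreasing abundance, rank 1
#' being the most abundant. Ties (including all-zero time points) are broken
#' deterministically by ascending feature identifier, so a given series
#' always yields the same rank matrix.
#'
#' @param series timepoints x features abundance matrix (>= 2 of each).
#' @return An integer matrix of the same shape: a permutation of `1..N` per
#'   row.
#' @examples
#' rank_series(rbind(T1 = c(a = 0.5, b = 0.3, c = 0.2)))[1, ]
#' @export
rank_series <- function(series) {
  series <- as.matrix(series)
  if (ncol(series) < 2) stop("ranking needs at least 2 features")
  ids <- colnames(series)
  if (is.null(ids)) ids <- sprintf("feature%06d", seq_len(ncol(series)))
  out <- matrix(0L, nrow(series), ncol(series), dimnames = dimnames(series))
  for (t in seq_len(nrow(series))) {
    ord <- order(-series[t, ], ids)
    out[t, ord] <- seq_len(ncol(series))
  }
  out
}

#' Total rank hops of one feature's rank trajectory
#'
#' The sum of absolute rank changes between consecutive time points,
#' `D = sum(|rank_(k+1) - rank_k|)`; 0 for a feature whose rank never moves
#' and `(N - 1) * (t - 1)` for one oscillating between the extreme ranks.
#'
#' @param ranks integer rank trajectory of one feature (length `t >= 2`).
#' @return Non-negative integer `D`.
#' @examples
#' rank_hops(c(1, 2, 2)) # 1
#' @export
rank_hops <- function(ranks) {
  if (length(ranks) < 2) stop("a rank trajectory needs >= 2 time points")
  sum(abs(diff(as.numeric(ranks))))
}

#' Rank stability index
#'
#' `RSI = (1 - D / ((N - 1) * (t - 1)))^p`, where `D` is the feature's total
#' number of rank hops, `N` the number of ranked features and `t` the number
#' of time samples. RSI is strictly 1 for a feature whose rank never changes
#' and strictly 0 for one oscillating between the extreme ranks.
#'
#' @param D total rank hops (in `[0, (N-1)*(t-1)]`).
#' @param N number of ranked features (>= 2).
#' @param t number of time samples (>= 2).
#' @param p positive exponent (default 1).
#' @return RSI in `[0, 1]`.
#' @examples
#' rsi(1, N = 3, t = 3) # 0.75
#' @export
rsi <- function(D, N, t, p = 1) {
  if (N < 2 || t < 2) stop("RSI needs N >= 2 features and t >= 2 time samples")
  if (p <= 0) stop("exponent p must be positive")
  dmax <- (N - 1) * (t - 1)
  if (any(D < 0 | D > dmax)) {
    stop(sprintf("D must lie in [0, %d]", dmax))
  }
  (1 - D / dmax)^p
}

#' Per-feature rank stability profiles by subject or group
#'
#' For each scope unit (subject, or age group with samples pooled by mean
#' relative abundance per time point), features observed at least once in
#' the unit are ranked at every time point (absent-at-a-time-point features
#' enter at abundance 0 and tie at the bottom), rank hops are counted and
#' the RSI computed. Features never observed in a unit carry no dynamics and
#' are reported as `NA` for that unit. Units with fewer than 2 time points
#' are skipped with a warning.
#'
#' @param x a [feature_table].
#' @param meta sample metadata covering `x`.
#' @param scope `"subject"` or `"group"`.
#' @param p RSI exponent.
#' @return An object of class `rsi_profile`: list with `rsi` (units x
#'   features matrix, `NA` for features absent from a unit), `D` (matching
#'   rank-hop matrix), `info` (data.frame `unit`, `group`, `n_timepoints`,
#'   `n_features_ranked`) and `p`.
#' @export
rsi_profile <- function(x, meta, scope = c("subject", "group"), p = 1) {
  scope <- match.arg(scope)
  stopifnot(inherits(x, "feature_table"))
  meta <- validate_metadata(meta, x)
  rel <- to_relative(x)$values
  units <- if (scope == "subject") unique(meta$subject_id) else unique(meta$group)
  all_features <- colnames(rel)
  rsi_m <- matrix(NA_real_, length(units), length(all_features),
    dimnames = list(units, all_features)
  )
  d_m <- rsi_m
  info <- list()
  for (u in units) {
    mu <- meta[if (scope == "subject") meta$subject_id == u else meta$group == u, ]
    tps <- sort(unique(mu$timepoint))
    if (length(tps) < 2) {
      warning(sprintf("%s '%s' has < 2 time points; skipped", scope, u))
      next
    }
    series <- t(vapply(tps, function(tp) {
      ids <- mu$sample_id[mu$timepoint == tp]
      colMeans(rel[ids, , drop = FALSE])
    }, numeric(ncol(rel))))
    observed <- colSums(series) > 0
    if (sum(observed) < 2) {
      warning(sprintf("%s '%s' has < 2 observed features; skipped", scope, u))
      next
    }
    sub <- series[, observed, drop = FALSE]
    ranks <- rank_series(sub)
    D <- apply(ranks, 2, rank_hops)
    vals <- rsi(D, N = ncol(sub), t = length(tps), p = p)
    rsi_m[u, observed] <- vals
    d_m[u, observed] <- D
    info[[u]] <- data.frame(
      unit = u,
      group = mu$group[1],
      n_timepoints = length(tps),
      n_features_ranked = ncol(sub),
      stringsAsFactors = FALSE
    )
  }
  if (!length(info)) stop("no unit had enough time points for an RSI profile")
  keep <- names(info)
  structure(
    list(
      rsi = rsi_m[keep, , drop = FALSE],
      D = d_m[keep, , drop = FALSE],
      info = do.call(rbind, c(info, list(make.row.names = FALSE))),
      p = p
    ),
    class = "rsi_profile"
  )
}

#' @export
print.rsi_profile <- function(x, ...) {
  cat(sprintf(
    "<rsi_profile> %d units x %d features (p = %g); mean RSI %.3f\n",
    nrow(x$rsi), ncol(x$rsi), x$p, mean(x$rsi, na.rm = TRUE)
  ))
  invisible(x)
}
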