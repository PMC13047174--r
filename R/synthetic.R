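#' Simulate one subject's longitudinal counts under Taylor's law
#'
#' Generates a timepoints x features abundance series whose per-feature
#' temporal moments follow, in expectation, the power law
#' `sigma_i = V * mu_i^beta` on the relative-abundance scale.
#'
#' Mechanisms:
#' * `"bounded"` (default): per-feature baseline means drawn log-uniform over
#'   `baseline`, normalized to a composition; at each time point abundances
#'   are independent moment-matched scaled-Beta draws bounded at
#'   `bound_factor` times the mean-implied bound. When `depth` is given the
#'   latent target variance is reduced by the multinomial sampling variance
#'   `m(1-m)/depth`, so the realized mean-SD relation of the counts matches
#'   the target law; counts are then multinomial at `depth`.
#' * `"poisson"`: counts are independent Poisson draws with rates
#'   `depth * m_i`, so relative abundances fluctuate with
#'   `sigma = sqrt(mu/depth)`, i.e. scale index `beta = 1/2` (`V` is implied
#'   by the depth and the `V` argument is ignored).
#' * `"exponential"`: abundances are exponential draws with feature-specific
#'   means (`sigma = mu`, i.e. `beta = 1`, `V = 1`; `V` ignored). Baseline
#'   means are used unnormalized.
#'
#' @param n_features number of features (>= 20).
#' @param V target power-law amplitude (> 0); SD of a feature with relative
#'   abundance 1.
#' @param beta target scale index, in (0, 1.5].
#' @param n_timepoints number of time points (>= 3).
#' @param depth sequencing depth (reads per sample); `NULL` returns the
#'   latent abundances without count sampling (not allowed for `"poisson"`).
#' @param seed optional integer seed.
#' @param mechanism fluctuation mechanism, see Details.
#' @param baseline range (low, high) of the log-uniform baseline means.
#' @param bound_factor upper-bound multiplier of the scaled-Beta latent.
#' @return A `n_timepoints x n_features` numeric matrix (counts when `depth`
#'   is given, latent abundances otherwise), with `T*`/`F*` dimnames.
#' @examples
#' x <- simulate_taylor_subject(50, V = 0.2, beta = 0.75, seed = 1)
#' dim(x)
#' @export
simulate_taylor_subject <- function(n_features, V = 0.2, beta = 0.75,
                                    n_timepoints = 10, depth = 1e5,
                                    seed = NULL,
                                    mechanism = c("bounded", "poisson", "exponential"),
                                    baseline = c(1e-2, 1e-1),
                                    bound_factor = 4) {
  mechanism <- match.arg(mechanism)
  if (n_features < 20) stop("n_features must be >= 20")
  if (n_timepoints < 3) stop("n_timepoints must be >= 3")
  if (V <= 0) stop("V must be positive")
  if (beta <= 0 || beta > 1.5) stop("beta must be in (0, 1.5]")
  if (!is.null(depth) && depth < 1) stop("depth must be a positive count")
  if (is.null(depth) && mechanism == "poisson") {
    stop("the poisson mechanism needs a sequencing depth")
  }
  if (!is.null(seed)) set.seed(seed)

  m <- 10^stats::runif(n_features, log10(baseline[1]), log10(baseline[2]))
  out <- switch(mechanism,
    bounded = {
      m <- m / sum(m)
      X <- t(vapply(
        seq_len(n_timepoints),
        function(t) draw_bounded(m, V, beta, depth, bound_factor),
        numeric(n_features)
      ))
      if (is.null(depth)) {
        X
      } else {
        P <- X / rowSums(X)
        t(apply(P, 1, function(p) stats::rmultinom(1, depth, p)))
      }
    },
    poisson = {
      m <- m / sum(m)
      matrix(
        stats::rpois(n_timepoints * n_features, rep(m * depth, each = n_timepoints)),
        n_timepoints, n_features
      )
    },
    exponential = {
      X <- matrix(
        stats::rexp(n_timepoints * n_features, rate = rep(1 / m, each = n_timepoints)),
        n_timepoints, n_features
      )
      if (is.null(depth)) {
        X
      } else {
        P <- X / rowSums(X)
        t(apply(P, 1, function(p) stats::rmultinom(1, depth, p)))
      }
    }
  )
  dimnames(out) <- list(
    paste0("T", seq_len(n_timepoints)),
    sprintf("F%03d", seq_len(n_features))
  )
  out
}

# internal: one time point of moment-matched scaled-Beta abundances with
# target mean m and target SD V * m^beta; when depth is finite the
# multinomial sampling variance is subtracted from the latent target so the
# realized count moments match the law.
draw_bounded <- function(m, V, beta, depth, bound_factor) {
  sig <- V * m^beta
  sig2 <- sig^2
  if (!is.null(depth)) {
    sig2 <- pmax(sig2 - m * (1 - m) / depth, (0.05 * sig)^2)
  }
  bound <- m * (1 + sig2 / m^2) * bound_factor
  mu_b <- m / bound
  var_b <- sig2 / bound^2
  k <- mu_b * (1 - mu_b) / var_b - 1
  if (any(k <= 0)) {
    stop("infeasible (V, beta) target: latent variance exceeds the Beta bound")
  }
  bound * stats::rbeta(length(m), mu_b * k, (1 - mu_b) * k)
}

#' Random taxa-to-function redundancy map
#'
#' Builds a binary features x functions incidence matrix in which every taxon
#' maps to at least one function and the mean number of taxa per function
#' equals `redundancy` (exactly, when `n_functions * redundancy >=
#' n_features`). With `redundancy = 1` and `n_functions = n_features` the
#' result is a permutation matrix.
#'
#' @param n_features number of taxa (rows).
#' @param n_functions number of functions (columns).
#' @param redundancy target mean number of taxa contributing to a function
#'   (>= 1).
#' @param seed optional integer seed.
#' @return A binary `n_features x n_functions` matrix.
#' @export
redundancy_map <- function(n_features, n_functions, redundancy = 1, seed = NULL) {
  if (redundancy < 1) stop("redundancy must be >= 1")
  if (n_functions > n_features * redundancy) {
    stop(sprintf(
      "infeasible shape: %d functions cannot each draw from %d taxa at redundancy %g",
      n_functions, n_features, redundancy
    ))
  }
  if (!is.null(seed)) set.seed(seed)
  M <- matrix(0L, n_features, n_functions,
    dimnames = list(
      sprintf("F%03d", seq_len(n_features)),
      sprintf("fn%03d", seq_len(n_functions))
    )
  )
  # every taxon gets one function; cycling a shuffled function list keeps
  # column sums balanced
  assign_fun <- rep_len(sample.int(n_functions), n_features)
  M[cbind(seq_len(n_features), assign_fun)] <- 1L
  extra <- round(n_functions * redundancy) - n_features
  if (extra > 0) {
    zeros <- which(M == 0L)
    M[sample(zeros, min(extra, length(zeros)))] <- 1L
  }
  M
}

#' Configuration of a synthetic longitudinal cohort
#'
#' Defaults emulate a three-group cohort (12 toddlers, 13 adolescents, 35
#' adults) sampled at 10 time points at a depth of 100,000 reads per sample,
#' with toddlers the most volatile group. See the methods vignette for the
#' rationale behind each default.
#'
#' @param n_subjects named integer vector of subjects per group.
#' @param n_timepoints time points per subject.
#' @param n_features number of taxonomic features.
#' @param group_volatility named vector: target Taylor `V` per group.
#' @param group_beta named vector: target Taylor scale index per group.
#' @param baseline_log_sd SD of the log-normal baseline abundance profile;
#'   larger values give a longer rare tail and hence sparser presence.
#' @param subject_v_sd log-scale SD of subject-level variation around the
#'   group `V`.
#' @param subject_beta_sd SD of subject-level variation around the group
#'   scale index.
#' @param sequencing_depth reads per sample.
#' @param n_functions number of functional features.
#' @param redundancy mean taxa per function (see [redundancy_map()]).
#' @param bound_factor passed to the bounded fluctuation mechanism.
#' @param instability_window optional
#'   `list(group =, interval =, log_sd =)`: at the first time point of the
#'   given consecutive interval, subjects of `group` get their baseline
#'   perturbed by extra log-normal noise of SD `log_sd`, inflating local
#'   volatility there.
#' @param event optional `list(group =, prob =, effect =)`: subjects of
#'   `group` undergo a developmental event with probability `prob`, at a time
#'   drawn uniformly over interior time points; from the event on, the
#'   baseline is tempered (raising evenness and hence diversity) and mixed
#'   toward a cohort-level target profile with weight proportional to
#'   `effect`, emulating post-event convergence of the community.
#' @param seed optional integer seed.
#' @return A classed list of settings for [simulate_cohort()].
#' @export
synthetic_config <- function(n_subjects = c(toddler = 12, adolescent = 13, adult = 35),
                             n_timepoints = 10,
                             n_features = 200,
                             group_volatility = c(toddler = 0.4, adolescent = 0.2, adult = 0.2),
                             group_beta = c(toddler = 0.75, adolescent = 0.75, adult = 0.75),
                             baseline_log_sd = 2,
                             subject_v_sd = 0.15,
                             subject_beta_sd = 0.03,
                             sequencing_depth = 1e5,
                             n_functions = 50,
                             redundancy = 4,
                             bound_factor = 4,
                             instability_window = NULL,
                             event = NULL,
                             seed = NULL) {
  cfg <- list(
    n_subjects = unlist(n_subjects), n_timepoints = n_timepoints,
    n_features = n_features, group_volatility = unlist(group_volatility),
    group_beta = unlist(group_beta), baseline_log_sd = baseline_log_sd,
    subject_v_sd = subject_v_sd, subject_beta_sd = subject_beta_sd,
    sequencing_depth = sequencing_depth, n_functions = n_functions,
    redundancy = redundancy, bound_factor = bound_factor,
    instability_window = instability_window, event = event, seed = seed
  )
  if (any(cfg$n_subjects < 1) || cfg$n_timepoints < 3 || cfg$n_features < 20 ||
    cfg$sequencing_depth < 1 || cfg$n_functions < 1) {
    stop("all cohort sizes must be positive (and n_features >= 20, n_timepoints >= 3)")
  }
  if (is.null(names(cfg$n_subjects))) stop("n_subjects must be a named vector")
  groups <- names(cfg$n_subjects)
  if (!all(groups %in% names(cfg$group_volatility)) ||
    !all(groups %in% names(cfg$group_beta))) {
    stop("group_volatility and group_beta must name every group")
  }
  if (any(cfg$group_volatility <= 0)) stop("group volatilities must be positive")
  if (any(cfg$group_beta <= 0 | cfg$group_beta > 1.5)) {
    stop("group scale indices must be in (0, 1.5]")
  }
  if (cfg$redundancy < 1) stop("redundancy must be >= 1")
  if (!is.null(cfg$event)) {
    if (is.null(cfg$event$prob)) cfg$event$prob <- 0.75
    if (is.null(cfg$event$effect)) cfg$event$effect <- 1.5
    if (is.null(cfg$event$group) || !cfg$event$group %in% names(cfg$n_subjects)) {
      stop("event$group must name a cohort group")
    }
  }
  if (!is.null(cfg$instability_window)) {
    if (is.null(cfg$instability_window$log_sd)) cfg$instability_window$log_sd <- 2.5
    w <- cfg$instability_window
    if (is.null(w$group) || !w$group %in% names(cfg$n_subjects)) {
      stop("instability_window$group must name a cohort group")
    }
    if (is.null(w$interval) || w$interval < 1 || w$interval >= cfg$n_timepoints) {
      stop("instability_window$interval must index a consecutive interval")
    }
  }
  structure(cfg, class = "synthetic_config")
}

#' Simulate a longitudinal three-group cohort
#'
#' Draws a per-subject baseline composition (log-normal profile), subject
#' level Taylor parameters around the group targets, and a bounded-mechanism
#' abundance series per subject (see [simulate_taylor_subject()]); counts are
#' multinomial at the configured depth. The functional table is the exact
#' projection of the taxonomic counts through a [redundancy_map()]. Optional
#' instability windows and developmental events perturb the baseline locally
#' (see [synthetic_config()]).
#'
#' @param cfg a [synthetic_config()].
#' @return A list of class `microdyn_cohort` with elements `taxa` and
#'   `functions` (counts-mode [feature_table]s), `metadata` (a data.frame
#'   with `sample_id`, `subject_id`, `group`, `timepoint`, `age` in months
#'   and, when an event is configured, `event_status`), `map` (the redundancy
#'   matrix) and `config`.
#' @examples
#' cfg <- synthetic_config(
#'   n_subjects = c(toddler = 3, adult = 4),
#'   n_features = 40, sequencing_depth = 2000, n_functions = 10, seed = 1
#' )
#' coh <- simulate_cohort(cfg)
#' coh$taxa
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  nf <- cfg$n_features
  nt <- cfg$n_timepoints
  depth <- cfg$sequencing_depth
  map <- redundancy_map(nf, cfg$n_functions, cfg$redundancy)
  event_target <- if (!is.null(cfg$event)) {
    et <- stats::rlnorm(nf, 0, cfg$baseline_log_sd)
    et / sum(et)
  }
  age_base <- c(toddler = 20, adolescent = 143, adult = 499)

  counts <- list()
  meta <- list()
  for (g in names(cfg$n_subjects)) {
    for (s in seq_len(cfg$n_subjects[[g]])) {
      subj <- sprintf("%s%02d", substr(g, 1, 3), s)
      b <- stats::rlnorm(nf, 0, cfg$baseline_log_sd)
      b <- b / sum(b)
      Vs <- cfg$group_volatility[[g]] * stats::rlnorm(1, 0, cfg$subject_v_sd)
      Bs <- min(max(
        cfg$group_beta[[g]] + stats::rnorm(1, 0, cfg$subject_beta_sd),
        0.05
      ), 1.5)
      has_event <- !is.null(cfg$event) && g == cfg$event$group &&
        stats::runif(1) < cfg$event$prob
      event_time <- if (has_event) sample(3:(nt - 1), 1) else NA_integer_
      b_after <- if (has_event) {
        tempered <- b^(1 - 0.3 * cfg$event$effect) # flatter, hence more even
        tempered <- tempered / sum(tempered)
        w <- min(0.9, 0.4 * cfg$event$effect)
        ba <- (1 - w) * tempered + w * event_target
        ba / sum(ba)
      }
      win <- cfg$instability_window
      mat <- matrix(0, nt, nf)
      for (t in seq_len(nt)) {
        m_t <- b
        if (has_event && t >= event_time) m_t <- b_after
        if (!is.null(win) && g == win$group && t == win$interval) {
          m_t <- m_t * stats::rlnorm(nf, 0, win$log_sd)
          m_t <- m_t / sum(m_t)
        }
        x <- draw_bounded(m_t, Vs, Bs, depth, cfg$bound_factor)
        mat[t, ] <- stats::rmultinom(1, depth, x / sum(x))
      }
      rownames(mat) <- sprintf("%s_T%02d", subj, seq_len(nt))
      counts[[subj]] <- mat
      meta[[subj]] <- data.frame(
        sample_id = rownames(mat),
        subject_id = subj,
        group = g,
        timepoint = seq_len(nt),
        age = age_base[[g]] + (seq_len(nt) - 1) * 4,
        stringsAsFactors = FALSE
      )
      if (!is.null(cfg$event)) {
        meta[[subj]]$event_status <- if (has_event) {
          ifelse(seq_len(nt) < event_time, "before", "after")
        } else {
          NA_character_
        }
      }
    }
  }
  taxa <- do.call(rbind, counts)
  colnames(taxa) <- sprintf("F%03d", seq_len(nf))
  fun_counts <- taxa %*% map
  metadata <- do.call(rbind, meta)
  rownames(metadata) <- NULL
  structure(
    list(
      taxa = feature_table(taxa, mode = "counts"),
      functions = feature_table(fun_counts, mode = "counts"),
      metadata = metadata,
      map = map,
      config = cfg
    ),
    class = "microdyn_cohort"
  )
}

#' @export
print.microdyn_cohort <- function(x, ...) {
  cat(sprintf(
    "<microdyn_cohort> %d samples (%d subjects, %d time points), %d taxa, %d functions\n",
    nrow(as.matrix(x$taxa)), length(unique(x$metadata$subject_id)),
    x$config$n_timepoints, ncol(as.matrix(x$taxa)), ncol(as.matrix(x$functions))
  ))
  invisible(x)
}
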