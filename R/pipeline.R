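#' Run the full stability-analysis pipeline
#'
#' Wires the package's stages into one reproducible run: load (or simulate)
#' the cohort, per-sample alpha diversity, per-subject Taylor fits with
#' standardized coordinates, per-subject RSI profiles, the consecutive-pair
#' Jaccard stability series with its within/between-group tests, a PERMANOVA
#' on per-subject aggregated median profiles, and (when the metadata records
#' an event) the before/after-event comparison. Every artifact is listed in
#' a `manifest.json` together with the producing stage and the parameters
#' and seed of the run; outputs are deterministic given (inputs, seed).
#'
#' @param config a configuration list, or the path of a YAML file holding
#'   one. Recognised fields: `simulate` (arguments for [synthetic_config()];
#'   when present the cohort is simulated and written out), `table`,
#'   `metadata`, `func_table` (input paths, used when `simulate` is absent),
#'   `reference_group` (default `"adult"`), `p` (RSI exponent, default 1),
#'   `n_perm` (default 600), `seed` (default 1), `out_dir` (required).
#' @return Invisibly, the manifest list. On a stage failure the manifest is
#'   still written with the failure recorded, and the error is re-raised.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop(sprintf("config file not found: '%s'", config))
    config <- yaml::read_yaml(config)
  }
  out_dir <- config$out_dir
  if (is.null(out_dir)) stop("config must name an out_dir")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  n_perm <- if (is.null(config$n_perm)) 600L else as.integer(config$n_perm)
  p_exp <- if (is.null(config$p)) 1 else config$p
  ref_group <- if (is.null(config$reference_group)) "adult" else config$reference_group

  manifest <- list(
    seed = seed,
    parameters = list(n_perm = n_perm, p = p_exp, reference_group = ref_group),
    artifacts = list(), status = "running"
  )
  emit <- function(file, stage) {
    manifest$artifacts[[length(manifest$artifacts) + 1]] <<-
      list(file = file, stage = stage)
  }
  write_manifest <- function() {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
      auto_unbox = TRUE, pretty = TRUE, digits = NA
    )
  }

  run <- function() {
    if (!is.null(config$simulate)) {
      sim_args <- config$simulate
      # YAML maps arrive as lists; the generator wants named vectors
      for (fld in c("n_subjects", "group_volatility", "group_beta")) {
        if (is.list(sim_args[[fld]])) sim_args[[fld]] <- unlist(sim_args[[fld]])
      }
      if (is.null(sim_args$seed)) sim_args$seed <- seed
      cohort <- simulate_cohort(do.call(synthetic_config, sim_args))
      taxa <- cohort$taxa
      func <- cohort$functions
      meta <- cohort$metadata
      write_feature_table(taxa, file.path(out_dir, "taxa_counts.tsv"))
      write_feature_table(func, file.path(out_dir, "function_counts.tsv"))
      write_sample_metadata(meta, file.path(out_dir, "metadata.tsv"))
      emit("taxa_counts.tsv", "simulate")
      emit("function_counts.tsv", "simulate")
      emit("metadata.tsv", "simulate")
    } else {
      for (f in c(config$table, config$metadata, config$func_table)) {
        if (!file.exists(f)) stop(sprintf("input file not found: '%s'", f))
      }
      taxa <- read_feature_table(config$table)
      meta <- read_sample_metadata(config$metadata)
      func <- if (!is.null(config$func_table)) read_feature_table(config$func_table)
    }
    meta <- validate_metadata(meta, taxa)

    alpha <- alpha_diversity(taxa, meta)
    utils::write.table(alpha, file.path(out_dir, "alpha_diversity.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("alpha_diversity.tsv", "diversity")

    fits <- fit_taylor_subjects(taxa, meta)
    if (ref_group %in% fits$group && sum(fits$group == ref_group) >= 3) {
      fits <- standardize_params(fits, ref_group)
    }
    utils::write.table(fits, file.path(out_dir, "taylor_fits.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("taylor_fits.tsv", "taylor")

    prof <- rsi_profile(taxa, meta, scope = "subject", p = p_exp)
    rsi_long <- data.frame(
      unit = rep(rownames(prof$rsi), ncol(prof$rsi)),
      feature_id = rep(colnames(prof$rsi), each = nrow(prof$rsi)),
      rsi = as.vector(prof$rsi)
    )
    utils::write.table(rsi_long[!is.na(rsi_long$rsi), ],
      file.path(out_dir, "rsi_subject.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("rsi_subject.tsv", "rsi")

    tables <- list(taxonomic = taxa)
    if (!is.null(func)) tables$functional <- func
    series <- do.call(rbind, lapply(names(tables), function(lv) {
      consecutive_stability(tables[[lv]], meta, level = lv)
    }))
    utils::write.table(series, file.path(out_dir, "stability_series.tsv"),
      sep = "\t", quote = FALSE, row.names = FALSE
    )
    emit("stability_series.tsv", "stability")
    tests <- stability_tests(series[series$level == "taxonomic", ])
    for (fam in c("within", "between")) {
      if (is.null(tests[[fam]])) next
      fn <- sprintf("stability_tests_%s.tsv", fam)
      utils::write.table(tests[[fam]], file.path(out_dir, fn),
        sep = "\t", quote = FALSE, row.names = FALSE
      )
      emit(fn, "stability")
    }

    agg <- aggregate_median_by_subject(to_relative(taxa), meta)
    info <- attr(agg, "info")
    if (length(unique(info$group)) >= 2 && all(table(info$group) >= 2)) {
      pm <- permanova(distance_matrix(agg, "bray_curtis"), info$group,
        n_perm = n_perm, seed = seed
      )
      jsonlite::write_json(unclass(pm), file.path(out_dir, "permanova_group.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      emit("permanova_group.json", "permanova")
    }

    if (!is.null(meta$event_status) && any(!is.na(meta$event_status))) {
      ev <- event_split_compare(taxa, meta, n_perm = n_perm, seed = seed)
      jsonlite::write_json(
        list(
          permanova = unclass(ev$permanova), alpha = ev$alpha,
          n_subjects = ev$n_subjects
        ),
        file.path(out_dir, "event_comparison.json"),
        auto_unbox = TRUE, pretty = TRUE, digits = NA
      )
      emit("event_comparison.json", "event")
    }
  }

  status <- tryCatch(
    {
      run()
      "ok"
    },
    error = function(e) e
  )
  if (inherits(status, "error")) {
    manifest$status <- "failed"
    manifest$error <- conditionMessage(status)
    write_manifest()
    stop(status)
  }
  manifest$status <- "ok"
  write_manifest()
  invisible(manifest)
}
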