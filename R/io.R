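#' Read a feature table from delimited text
#'
#' Reads a tab-separated table with a header of identifiers and a first
#' column of identifiers. Lines starting with `#` are treated as comments,
#' except a BIOM-style `#OTU ID` header line, which is kept. The returned
#' table is always in counts mode and canonical samples x features
#' orientation.
#'
#' @param path path to a TSV file.
#' @param orientation `"samples_rows"` if samples are in rows (default) or
#'   `"features_rows"` if features are in rows (e.g. BIOM-style TSV exports).
#' @return A counts-mode [feature_table].
#' @export
read_feature_table <- function(path,
                               orientation = c("samples_rows", "features_rows")) {
  orientation <- match.arg(orientation)
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path))
  }
  lines <- readLines(path, encoding = "UTF-8")
  keep <- !startsWith(lines, "#") | startsWith(lines, "#OTU ID")
  lines <- lines[keep]
  if (length(lines) < 2) {
    stop(sprintf("'%s' has no data rows", path))
  }
  df <- utils::read.delim(
    text = lines, header = TRUE, sep = "\t",
    check.names = FALSE, colClasses = "character"
  )
  ids <- df[[1]]
  if (anyDuplicated(ids)) {
    stop(sprintf(
      "duplicated identifier '%s' in '%s'",
      ids[anyDuplicated(ids)], path
    ))
  }
  body <- df[, -1, drop = FALSE]
  m <- matrix(NA_real_, nrow(body), ncol(body),
    dimnames = list(ids, colnames(body))
  )
  for (j in seq_len(ncol(body))) {
    num <- suppressWarnings(as.numeric(body[[j]]))
    bad <- which(is.na(num) & !is.na(body[[j]]) & nzchar(body[[j]]))
    if (length(bad) || anyNA(body[[j]])) {
      i <- if (length(bad)) bad[1] else which(is.na(body[[j]]))[1]
      stop(sprintf(
        "malformed numeric value '%s' at row '%s', column '%s' of '%s'",
        body[[j]][i], ids[i], colnames(body)[j], path
      ))
    }
    m[, j] <- num
  }
  if (orientation == "features_rows") m <- t(m)
  feature_table(m, mode = "counts")
}

#' Write a feature table as tab-separated text
#'
#' Integer counts round-trip exactly through [read_feature_table()]. With
#' `orientation = "features_rows"` and `biom_style = TRUE` the header cell is
#' `#OTU ID` for interoperability with BIOM-style TSV consumers.
#'
#' @param x a [feature_table].
#' @param path output path.
#' @param orientation layout of the written file; see [read_feature_table()].
#' @param biom_style write a `#OTU ID` header (only with `"features_rows"`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(x, path,
                                orientation = c("samples_rows", "features_rows"),
                                biom_style = FALSE) {
  orientation <- match.arg(orientation)
  stopifnot(inherits(x, "feature_table"))
  m <- x$values
  if (orientation == "features_rows") m <- t(m)
  corner <- if (orientation == "samples_rows") {
    "sample_id"
  } else if (biom_style) "#OTU ID" else "feature_id"
  header <- paste(c(corner, colnames(m)), collapse = "\t")
  rows <- vapply(
    seq_len(nrow(m)),
    function(i) paste(c(rownames(m)[i], format(m[i, ], trim = TRUE, scientific = FALSE, digits = 15)), collapse = "\t"),
    character(1)
  )
  writeLines(c(header, rows), path, useBytes = TRUE)
  invisible(path)
}

#' Read a sample metadata table
#'
#' Expects tab-separated text with at least columns `sample_id`,
#' `subject_id`, `group` and `timepoint`; optional columns `age` and
#' `event_status` (`before`/`after`, `NA` for subjects without the event)
#' are carried through. `#` comment lines are ignored.
#'
#' @param path path to a TSV file.
#' @return A data.frame of per-sample metadata.
#' @export
read_sample_metadata <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path))
  }
  meta <- utils::read.delim(path,
    header = TRUE, sep = "\t", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE
  )
  validate_metadata(meta)
}

#' Write a sample metadata table
#' @param meta metadata data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sample_metadata <- function(meta, path) {
  utils::write.table(meta, path,
    sep = "\t", quote = FALSE,
    row.names = FALSE, na = "NA"
  )
  invisible(path)
}

#' Validate sample metadata, optionally against a feature table
#'
#' Enforces required columns, integer time points, and at most one sample per
#' (subject, timepoint). When `table` is given, every sample of the table must
#' have a metadata row.
#'
#' @param meta metadata data.frame.
#' @param table optional [feature_table] whose samples must be covered.
#' @return `meta` with `timepoint` coerced to integer.
#' @export
validate_metadata <- function(meta, table = NULL) {
  required <- c("sample_id", "subject_id", "group", "timepoint")
  missing_cols <- setdiff(required, names(meta))
  if (length(missing_cols)) {
    stop(
      "metadata lacks required column(s): ",
      paste(missing_cols, collapse = ", ")
    )
  }
  if (anyDuplicated(meta$sample_id)) {
    stop("duplicated sample_id in metadata")
  }
  tp <- meta$timepoint
  if (any(tp != as.integer(tp)) || any(tp < 1)) {
    stop("timepoint must be a positive integer")
  }
  meta$timepoint <- as.integer(tp)
  key <- paste(meta$subject_id, meta$timepoint)
  if (anyDuplicated(key)) {
    stop(sprintf(
      "duplicate (subject, timepoint) pair: %s",
      key[anyDuplicated(key)]
    ))
  }
  if (!is.null(table)) {
    absent <- setdiff(sample_ids(table), meta$sample_id)
    if (length(absent)) {
      stop(sprintf(
        "samples without metadata: %s",
        paste(utils::head(absent, 5), collapse = ", ")
      ))
    }
  }
  meta
}

#' Aggregate a relative table to per-subject medians
#'
#' Collapses all samples of a subject to the per-feature median of the
#' relative abundances, optionally split into before/after sides of a
#' developmental event (weaning or menarche analogs). Median rows generally
#' do not sum to 1, so aggregated rows are re-normalized; medians use the
#' midpoint convention for even sample counts.
#'
#' @param x a relative-mode [feature_table].
#' @param meta metadata covering the samples of `x`.
#' @param event if `TRUE`, aggregate separately before and after the event
#'   recorded in `meta$event_status`; subjects without an event status are
#'   dropped, and a subject with samples on only one side is an error.
#' @return A relative-mode [feature_table] with one row per subject (or per
#'   subject x side, named `<subject>.<side>`) and an `info` attribute: a
#'   data.frame with `row_id`, `subject_id`, `group` and (with `event`)
#'   `event_status`.
#' @export
aggregate_median_by_subject <- function(x, meta, event = FALSE) {
  stopifnot(inherits(x, "feature_table"))
  if (x$mode != "relative") {
    stop("aggregate_median_by_subject expects a relative-mode table; see to_relative()")
  }
  meta <- validate_metadata(meta, x)
  v <- x$values
  meta <- meta[match(rownames(v), meta$sample_id), ]
  if (event) {
    if (is.null(meta$event_status)) {
      stop("event aggregation requested but metadata has no event_status column")
    }
    keep <- !is.na(meta$event_status)
    meta <- meta[keep, , drop = FALSE]
    v <- v[keep, , drop = FALSE]
    split_key <- paste(meta$subject_id, meta$event_status, sep = ".")
    for (s in unique(meta$subject_id)) {
      sides <- unique(meta$event_status[meta$subject_id == s])
      if (length(sides) < 2) {
        stop(sprintf(
          "subject '%s' has samples only on the '%s' side of the event",
          s, sides
        ))
      }
    }
  } else {
    split_key <- meta$subject_id
  }
  if (!nrow(v)) {
    stop("no samples left to aggregate")
  }
  keys <- unique(split_key)
  agg <- t(vapply(
    keys,
    function(k) apply(v[split_key == k, , drop = FALSE], 2, stats::median),
    numeric(ncol(v))
  ))
  rs <- rowSums(agg)
  if (any(rs == 0)) {
    stop(sprintf("aggregated row '%s' is all zero", keys[which(rs == 0)[1]]))
  }
  agg <- agg / rs
  rownames(agg) <- keys
  out <- feature_table(agg, mode = "relative")
  first <- match(keys, split_key)
  info <- data.frame(
    row_id = keys,
    subject_id = meta$subject_id[first],
    group = meta$group[first],
    stringsAsFactors = FALSE
  )
  if (event) info$event_status <- meta$event_status[first]
  attr(out, "info") <- info
  out
}

#' Read a read-to-annotation mapping table
#'
#' A 5-column TSV relating each read to its sample, the ORF it maps to, the
#' function of that ORF and the taxonomic assignment of the read. Missing or
#' empty taxon labels are kept and later pooled under `"UNASSIGNED"`.
#'
#' @param path path to a TSV with columns `read_id`, `sample_id`, `orf_id`,
#'   `function_id`, `taxon_label`.
#' @return A data.frame with those five character columns.
#' @export
read_read_map <- function(path) {
  if (!file.exists(path)) {
    stop(sprintf("file not found: '%s'", path))
  }
  rm_df <- utils::read.delim(path,
    header = TRUE, sep = "\t", comment.char = "#",
    check.names = FALSE, stringsAsFactors = FALSE,
    colClasses = "character"
  )
  required <- c("read_id", "sample_id", "orf_id", "function_id", "taxon_label")
  if (!all(required %in% names(rm_df))) {
    stop(
      "read map lacks required column(s): ",
      paste(setdiff(required, names(rm_df)), collapse = ", ")
    )
  }
  key <- paste(rm_df$sample_id, rm_df$read_id)
  if (anyDuplicated(key)) {
    stop("read_id must be unique within a sample")
  }
  rm_df[required]
}

#' Per-ORF taxonomic contribution percentages
#'
#' For each ORF detected in a sample, computes the percentage of its mapping
#' reads contributed by each taxon. Reads without a taxonomic assignment are
#' pooled under the reserved label `"UNASSIGNED"` rather than dropped.
#'
#' @param rm a read map data.frame as returned by [read_read_map()].
#' @return A data.frame `(sample_id, orf_id, taxon_label, n_reads, percent)`;
#'   percentages sum to 100 within each (sample, ORF).
#' @examples
#' rm_df <- data.frame(
#'   read_id = paste0("r", 1:4), sample_id = "s1", orf_id = "orf1",
#'   function_id = "fn1", taxon_label = c("A", "A", "B", "B")
#' )
#' taxon_contribution(rm_df)
#' @export
taxon_contribution <- function(rm) {
  if (!nrow(rm)) {
    stop("read map is empty")
  }
  taxon <- rm$taxon_label
  taxon[is.na(taxon) | !nzchar(taxon)] <- "UNASSIGNED"
  counts <- stats::aggregate(
    list(n_reads = rm$read_id),
    by = list(
      sample_id = rm$sample_id, orf_id = rm$orf_id,
      taxon_label = taxon
    ),
    FUN = length
  )
  totals <- stats::aggregate(
    list(total = counts$n_reads),
    by = list(sample_id = counts$sample_id, orf_id = counts$orf_id),
    FUN = sum
  )
  out <- merge(counts, totals, by = c("sample_id", "orf_id"))
  out$percent <- 100 * out$n_reads / out$total
  out$total <- NULL
  out[order(out$sample_id, out$orf_id, -out$percent, out$taxon_label), ]
}
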