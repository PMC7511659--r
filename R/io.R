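#' Read a back-splice caller candidate table
#'
#' Reads a CIRI2-style tab-separated candidate table: one row per circRNA
#' candidate, identified either by a `circ_id` column (`chrom:start-end`) or
#' by `chrom`/`start`/`end` columns, plus one column of back-spliced junction
#' read counts per sample. All remaining columns are taken to be samples.
#' Duplicate rows for the same coordinates are merged by summing counts.
#'
#' @param path Path to the TSV file.
#' @param caller_name Name of the program that produced the table (e.g.
#'   `"CIRI2"`); recorded in the `callers` column.
#' @return A long tibble with columns `circ_id`, `sample_id`, `count`
#'   (non-negative integer) and `callers` (comma-separated caller names,
#'   constant within a `circ_id`).
#' @seealso [merge_caller_tables()], [intersect_callers()]
#' @export
read_caller_table <- function(path, caller_name) {
  stopifnot(is.character(caller_name), length(caller_name) == 1L)
  raw <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (nrow(raw) == 0L && ncol(raw) == 0L) abort("empty caller table")
  nm <- names(raw)
  if ("circ_id" %in% nm) {
    ids <- as.character(raw$circ_id)
    parse_circ_id(ids) # validates
    count_cols <- setdiff(nm, c("circ_id", "strand"))
  } else if (all(c("chrom", "start", "end") %in% nm)) {
    ids <- format_circ_id(as.character(raw$chrom), raw$start, raw$end)
    count_cols <- setdiff(nm, c("chrom", "start", "end", "strand"))
  } else {
    abort("caller table needs a 'circ_id' column or 'chrom'/'start'/'end' columns")
  }
  if (length(count_cols) == 0L) abort("caller table has no sample count columns")
  counts <- raw[count_cols]
  ok <- vapply(counts, function(v) {
    is.numeric(v) && !anyNA(v) && all(v >= 0) && all(v == round(v))
  }, logical(1))
  if (!any(ok)) abort("no valid count columns (non-negative integers) found")
  if (!all(ok)) {
    abort(paste0("count column '", count_cols[!ok][1L],
                 "' contains negative or non-integer values"))
  }
  long <- tibble(circ_id = ids) %>%
    dplyr::bind_cols(counts) %>%
    tidyr::pivot_longer(-"circ_id", names_to = "sample_id",
                        values_to = "count") %>%
    group_by(.data$circ_id, .data$sample_id) %>%
    summarise(count = sum(.data$count), .groups = "drop") %>%
    mutate(count = as.integer(.data$count), callers = caller_name) %>%
    arrange(.data$circ_id, .data$sample_id)
  long
}

#' Merge candidate tables from several callers
#'
#' Unifies candidates across callers by exact coordinate equality (no fuzzy
#' junction matching). For each (circRNA, sample) the merged count is the
#' maximum reported by any caller, and `callers` accumulates the set of
#' callers supporting the circRNA; both are symmetric in caller order.
#'
#' @param ... Long count tibbles as returned by [read_caller_table()].
#' @return A merged long count tibble.
#' @export
merge_caller_tables <- function(...) {
  tabs <- list(...)
  stopifnot(length(tabs) >= 1L)
  all_rows <- bind_rows(tabs) %>%
    tidyr::separate_longer_delim("callers", delim = ",")
  support <- all_rows %>%
    distinct(.data$circ_id, .data$callers) %>%
    group_by(.data$circ_id) %>%
    summarise(callers = paste(sort(unique(.data$callers)), collapse = ","),
              .groups = "drop")
  all_rows %>%
    group_by(.data$circ_id, .data$sample_id) %>%
    summarise(count = max(.data$count), .groups = "drop") %>%
    left_join(support, by = "circ_id") %>%
    arrange(.data$circ_id, .data$sample_id)
}

#' Read per-library composition statistics
#'
#' Reads the per-sample denominators used by the normalization methods:
#' total filtered reads, rRNA-mapped reads, chloroplast-mapped reads, raw
#' reads mapped to the endogenous marker gene (*ACT2*, AT3G18780), the total
#' back-spliced read sum, and the back-spliced sum excluding rRNA- and
#' chloroplast-derived circRNAs. Integrity constraints are verified on load.
#'
#' @param path Path to a TSV keyed by `sample_id` with columns
#'   `total_reads`, `rrna_reads`, `chloroplast_reads`, `marker_reads`,
#'   `backspliced_total`, `backspliced_excl`.
#' @return A validated tibble of library statistics.
#' @export
read_library_stats <- function(path) {
  stats <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  validate_library_stats(stats)
}

validate_library_stats <- function(stats) {
  need <- c("sample_id", "total_reads", "rrna_reads", "chloroplast_reads",
            "marker_reads", "backspliced_total", "backspliced_excl")
  miss <- setdiff(need, names(stats))
  if (length(miss)) abort(paste("library stats missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyDuplicated(stats$sample_id)) abort("duplicated sample_id in library stats")
  num <- stats[setdiff(need, "sample_id")]
  if (any(vapply(num, function(v) anyNA(v) || any(v < 0), logical(1)))) {
    abort("library stats contain negative or missing values")
  }
  bad <- stats$rrna_reads + stats$chloroplast_reads > stats$total_reads
  if (any(bad)) {
    abort(paste0("rRNA + chloroplast reads exceed total reads for sample '",
                 stats$sample_id[bad][1L], "'"))
  }
  bad <- stats$backspliced_excl > stats$backspliced_total
  if (any(bad)) {
    abort(paste0("backspliced_excl > backspliced_total for sample '",
                 stats$sample_id[bad][1L], "'"))
  }
  as_tibble(stats)
}

#' Read a ddPCR assay table
#'
#' Expects a TSV with one row per (target, organ, replicate) reaction,
#' carrying either raw droplet counts (`n_pos`, `n_total`) or pre-computed
#' `cp_per_ug`. Rows whose `target` equals the marker gene id (default
#' AT3G18780, *ACT2*) are tagged as reference-gene measurements.
#'
#' @param path Path to the TSV.
#' @param marker_id Gene id identifying marker (reference) rows.
#' @return A tibble with an added logical `is_marker` column.
#' @export
read_ddpcr_table <- function(path, marker_id = "AT3G18780") {
  d <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("target", "organ", "replicate")
  miss <- setdiff(need, names(d))
  if (length(miss)) abort(paste("ddPCR table missing columns:",
                                paste(miss, collapse = ", ")))
  if (!("cp_per_ug" %in% names(d)) && !all(c("n_pos", "n_total") %in% names(d))) {
    abort("ddPCR table needs either cp_per_ug or n_pos/n_total columns")
  }
  if (all(c("n_pos", "n_total") %in% names(d))) {
    if (any(d$n_pos < 0 | d$n_pos > d$n_total)) {
      abort("ddPCR droplet counts must satisfy 0 <= n_pos <= n_total")
    }
  }
  mutate(as_tibble(d), is_marker = .data$target == marker_id)
}

#' Write result tables and run metadata
#'
#' Writes each table as a deterministic TSV (floats rendered at a fixed
#' number of significant digits) plus a `run_metadata.yaml` file recording
#' method tags, scale constants, thresholds and the seed, so a run can be
#' reproduced byte for byte.
#'
#' @param tables Named list of data frames.
#' @param out_dir Output directory (created if needed).
#' @param digits Significant digits for numeric columns (default 4).
#' @param metadata Named list recorded in the metadata file.
#' @return Invisibly, the paths written.
#' @export
write_results <- function(tables, out_dir, digits = 4, metadata = list()) {
  stopifnot(is.list(tables))
  if (length(tables) && is.null(names(tables))) abort("tables must be named")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (nm in names(tables)) {
    tab <- as.data.frame(tables[[nm]])
    for (j in seq_along(tab)) {
      if (is.double(tab[[j]])) tab[[j]] <- signif(tab[[j]], digits)
    }
    p <- file.path(out_dir, paste0(nm, ".tsv"))
    readr::write_tsv(tab, p, progress = FALSE)
    paths <- c(paths, p)
  }
  meta_path <- file.path(out_dir, "run_metadata.yaml")
  meta <- c(list(package = "circquant", tables = names(tables),
                 digits = digits), metadata)
  yaml::write_yaml(meta, meta_path)
  invisible(c(paths, meta_path))
}

#' Export circRNA intervals as BED6
#'
#' CircRNA ids use 1-based fully closed coordinates; conversion to BED's
#' 0-based half-open convention happens only here, at the writer boundary.
#'
#' @param circ_id Character vector of `chrom:start-end` ids.
#' @param path Output file.
#' @param strand Strand per id (`"+"`, `"-"`, or `"unknown"`, written as
#'   `.`).
#' @return Invisibly, `path`.
#' @export
write_bed <- function(circ_id, path, strand = "unknown") {
  co <- parse_circ_id(unique(circ_id), strand = strand)
  bed <- data.frame(chrom = co$chrom,
                    start = format(co$start - 1, scientific = FALSE, trim = TRUE),
                    end = format(co$end, scientific = FALSE, trim = TRUE),
                    name = co$circ_id, score = 0L,
                    strand = ifelse(co$strand == "unknown", ".", co$strand))
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
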