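#' The six back-spliced count normalization methods
#'
#' @description
#' Back-spliced read counts can be scaled by six per-sample denominators:
#'
#' * `library_size` — total filtered reads `T_j` (the common convention in
#'   circRNA studies, and the one that correlates worst with ddPCR);
#' * `backspliced_sum` — total back-spliced reads `B_j`;
#' * `size_factor` — median-of-ratios size factor `f_j` computed on the
#'   back-spliced count matrix (see [compute_size_factors()]);
#' * `library_size_excl` — `T_j` minus rRNA- and chloroplast-mapped reads;
#' * `backspliced_sum_excl` — back-spliced reads excluding rRNA- and
#'   chloroplast-derived circRNAs;
#' * `marker_gene` — raw reads mapped to the endogenous marker *ACT2*
#'   (AT3G18780).
#'
#' All six are per-sample linear scalings, so within a sample they preserve
#' the rank order of circRNAs, and any correlation, fold change or class
#' assignment downstream is invariant to the `scale` constant.
#'
#' @return Character vector of the six method names.
#' @export
norm_methods <- function() {
  c("library_size", "backspliced_sum", "size_factor",
    "library_size_excl", "backspliced_sum_excl", "marker_gene")
}

#' Median-of-ratios size factors for a back-spliced count matrix
#'
#' Computes per-sample size factors by the median-of-ratios construction:
#' each circRNA's geometric mean across samples forms a reference
#' pseudo-sample, and a sample's factor is the median over circRNAs of the
#' ratio of its count to that reference. Only circRNAs with a nonzero count
#' in every sample (geometric mean > 0) are eligible — with sparse
#' back-spliced matrices this can leave no eligible rows, in which case an
#' error suggests the `backspliced_sum` method instead.
#'
#' @param counts Long count tibble (`circ_id`, `sample_id`, `count`).
#' @return Tibble with columns `sample_id`, `size_factor` (all positive).
#' @examples
#' counts <- tidyr::expand_grid(circ_id = c("1:1-10", "2:5-20"),
#'                              sample_id = c("s1", "s2"))
#' counts$count <- c(10L, 30L, 4L, 12L)
#' compute_size_factors(counts) # recovers the 1:3 depth ratio
#' @export
compute_size_factors <- function(counts) {
  wide <- counts_to_matrix(counts)
  if (ncol(wide) < 2L) abort("size factors need at least 2 samples")
  eligible <- rowSums(wide == 0) == 0L
  if (!any(eligible)) {
    abort(paste("no circRNA has nonzero counts in every sample;",
                "median-of-ratios is undefined on this sparse matrix -",
                "consider the 'backspliced_sum' method instead"))
  }
  m <- wide[eligible, , drop = FALSE]
  log_geo <- rowMeans(log(m))
  f <- apply(m, 2, function(col) median(exp(log(col) - log_geo)))
  tibble(sample_id = colnames(wide), size_factor = unname(f))
}

#' Normalize back-spliced read counts
#'
#' Scales raw back-spliced junction counts `c_ij` to `n_ij = c_ij * scale /
#' d_j`, where `d_j` is the per-sample denominator selected by `method` (see
#' [norm_methods()]). For `size_factor` the value is `c_ij / f_j` and
#' `scale` is ignored. Zero counts stay exactly zero under every method.
#'
#' @param counts Long count tibble (`circ_id`, `sample_id`, `count`).
#' @param stats Library statistics tibble (see [read_library_stats()]);
#'   not needed for `method = "size_factor"`.
#' @param method One of [norm_methods()].
#' @param scale Positive scale constant, default `1e6` (per-million
#'   convention). The multiplier behind any published normalized values is
#'   a reporting choice; every correlation-based result is invariant to it.
#' @return A long tibble `circ_id`, `sample_id`, `value`, plus `method` and
#'   `scale` columns recording how the values were produced.
#' @export
normalize_counts <- function(counts, stats = NULL,
                             method = c("library_size", "backspliced_sum",
                                        "size_factor", "library_size_excl",
                                        "backspliced_sum_excl", "marker_gene"),
                             scale = 1e6) {
  method <- match.arg(method)
  stopifnot(is.numeric(scale), length(scale) == 1L, scale > 0)
  check_counts(counts)
  if (method == "size_factor") {
    sf <- compute_size_factors(counts)
    denom <- setNames(sf$size_factor, sf$sample_id)
    eff_scale <- 1
  } else {
    if (is.null(stats)) abort("library stats are required for this method")
    stats <- validate_library_stats(stats)
    missing_s <- setdiff(unique(counts$sample_id), stats$sample_id)
    if (length(missing_s)) {
      abort(paste("no library stats for sample(s):",
                  paste(missing_s, collapse = ", ")))
    }
    denom_val <- switch(method,
      library_size = stats$total_reads,
      backspliced_sum = stats$backspliced_total,
      library_size_excl = stats$total_reads - stats$rrna_reads -
        stats$chloroplast_reads,
      backspliced_sum_excl = stats$backspliced_excl,
      marker_gene = stats$marker_reads)
    denom <- setNames(denom_val, stats$sample_id)
    eff_scale <- scale
  }
  used <- denom[unique(counts$sample_id)]
  if (any(used <= 0)) {
    bad <- names(used)[used <= 0][1L]
    abort(paste0("non-positive denominator for sample '", bad,
                 "' under method '", method, "'"))
  }
  counts %>%
    mutate(value = .data$count * eff_scale / unname(denom[.data$sample_id]),
           method = method, scale = scale) %>%
    select("circ_id", "sample_id", "value", "method", "scale")
}

#' Average normalized values over biological replicates
#'
#' Arithmetic mean (and sample standard deviation, `n - 1` denominator)
#' of normalized abundances over the replicates of each organ/sample type.
#'
#' @param norm Normalized tibble from [normalize_counts()].
#' @param samples Sample metadata tibble (`sample_id`, `organ`,
#'   `replicate`, optionally `protocol`).
#' @return Tibble `circ_id`, `organ`, `mean`, `sd`, `n_reps`, with the
#'   `method`/`scale` tags carried through. `sd` is 0 for one replicate.
#' @export
aggregate_replicates <- function(norm, samples) {
  stopifnot(all(c("circ_id", "sample_id", "value") %in% names(norm)),
            all(c("sample_id", "organ") %in% names(samples)))
  missing_s <- setdiff(unique(norm$sample_id), samples$sample_id)
  if (length(missing_s)) {
    abort(paste("samples without metadata:", paste(missing_s, collapse = ", ")))
  }
  norm %>%
    inner_join(samples[, c("sample_id", "organ")], by = "sample_id") %>%
    group_by(across(any_of(c("circ_id", "organ", "method", "scale")))) %>%
    summarise(mean = mean(.data$value),
              sd = if (n() > 1L) sd(.data$value) else 0,
              n_reps = n(), .groups = "drop")
}

check_counts <- function(counts) {
  need <- c("circ_id", "sample_id", "count")
  miss <- setdiff(need, names(counts))
  if (length(miss)) abort(paste("count table missing columns:",
                                paste(miss, collapse = ", ")))
  if (anyNA(counts$count) || any(counts$count < 0) ||
      any(counts$count != round(counts$count))) {
    abort("counts must be non-negative integers")
  }
  invisible(counts)
}

# long -> circ x sample matrix; absent pairs are zero
counts_to_matrix <- function(counts) {
  check_counts(counts)
  wide <- counts %>%
    select("circ_id", "sample_id", "count") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "count",
                       values_fill = 0L, values_fn = sum)
  m <- as.matrix(wide[-1])
  rownames(m) <- wide$circ_id
  m
}
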