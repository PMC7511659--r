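#' Minimum back-spliced read support filter
#'
#' A circRNA candidate is retained when its back-spliced reads, summed over
#' the replicates of at least one library type (organ x protocol group),
#' reach `k` (default 2, the standard "at least two back-spliced reads"
#' validity rule; thresholds are inclusive). With `per_replicate = TRUE`
#' the rule is applied to single libraries instead of pooled evidence.
#'
#' @param counts Long count tibble (`circ_id`, `sample_id`, `count`).
#' @param samples Optional sample metadata (`sample_id`, `organ`,
#'   optionally `protocol`); when omitted all samples form one library
#'   type.
#' @param k Minimum summed back-spliced reads (>= 1).
#' @param per_replicate Apply the threshold per library instead of per
#'   pooled library type.
#' @return List with `counts` (surviving rows) and `report` (a one-row
#'   filter report: `stage`, `n_in`, `n_out`, `removed` list-column).
#' @export
filter_min_support <- function(counts, samples = NULL, k = 2,
                               per_replicate = FALSE) {
  stopifnot(k >= 1)
  check_counts(counts)
  ids_in <- unique(counts$circ_id)
  grouped <- counts
  if (!is.null(samples)) {
    keys <- intersect(c("organ", "protocol"), names(samples))
    grouped <- counts %>%
      inner_join(samples[, c("sample_id", keys)], by = "sample_id")
  } else {
    keys <- character(0)
  }
  if (per_replicate) {
    support <- grouped %>%
      group_by(.data$circ_id) %>%
      summarise(max_support = max(.data$count), .groups = "drop")
  } else {
    support <- grouped %>%
      group_by(across(all_of(c("circ_id", keys)))) %>%
      summarise(pooled = sum(.data$count), .groups = "drop") %>%
      group_by(.data$circ_id) %>%
      summarise(max_support = max(.data$pooled), .groups = "drop")
  }
  keep <- support$circ_id[support$max_support >= k]
  out <- filter(counts, .data$circ_id %in% keep)
  list(counts = out,
       report = filter_report("min_support", ids_in, unique(out$circ_id)))
}

#' Two-caller confirmation filter
#'
#' Retains only candidates whose exact coordinates were also reported by a
#' confirmatory caller; counts are kept from the primary caller. The
#' confirmatory caller contributes an id set only — mirroring a workflow in
#' which one program quantifies and a second merely corroborates.
#'
#' @param counts Primary caller long count tibble.
#' @param confirm_ids Character vector of circRNA ids from the
#'   confirmatory caller.
#' @return List with `counts` and `report`; an empty intersection warns
#'   rather than errs.
#' @export
intersect_callers <- function(counts, confirm_ids) {
  check_counts(counts)
  ids_in <- unique(counts$circ_id)
  keep <- intersect(ids_in, confirm_ids)
  if (length(keep) == 0L) {
    warn("no candidate confirmed by the second caller: empty intersection")
  }
  out <- filter(counts, .data$circ_id %in% keep)
  list(counts = out, report = filter_report("caller_confirm", ids_in, keep))
}

filter_report <- function(stage, ids_in, ids_out) {
  removed <- setdiff(ids_in, ids_out)
  tibble(stage = stage, n_in = length(ids_in), n_out = length(ids_out),
         removed = list(removed))
}

#' Replicate reproducibility of circRNA detection
#'
#' Given the circRNA id sets detected in each biological replicate,
#' computes every exclusive Venn region (15 regions for 4 replicates) and
#' the fraction of the union detected in all replicates — the headline
#' measure of how reproducibly circRNAs form.
#'
#' @param sets Named list of character vectors (one per replicate, or any
#'   collection of sets).
#' @return A `circ_venn` object: list with `regions` (tibble `pattern`,
#'   `count`), `n_union`, `n_intersection`, `fraction_in_all`. Region
#'   counts always sum to the union size.
#' @export
replicate_reproducibility <- function(sets) {
  stopifnot(is.list(sets), length(sets) >= 2L)
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_along(sets))
  }
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets, use.names = FALSE))
  k <- length(sets)
  membership <- vapply(sets, function(s) universe %in% s,
                       logical(length(universe)))
  if (length(universe) == 1L) membership <- matrix(membership, nrow = 1L)
  pattern_of <- function(row) paste(names(sets)[row], collapse = "&")
  patterns <- apply(membership, 1L, pattern_of)
  # enumerate all 2^k - 1 regions so empty regions are reported as 0
  all_patterns <- unlist(lapply(seq_len(k), function(m) {
    combn(names(sets), m, FUN = paste, collapse = "&", simplify = TRUE)
  }))
  counts <- table(factor(patterns, levels = all_patterns))
  inter <- Reduce(intersect, sets)
  structure(
    list(regions = tibble(pattern = all_patterns,
                          count = as.integer(counts[all_patterns])),
         n_sets = k,
         n_union = length(universe),
         n_intersection = length(inter),
         fraction_in_all = if (length(universe)) {
           length(inter) / length(universe)
         } else NA_real_),
    class = "circ_venn")
}

#' @export
print.circ_venn <- function(x, ...) {
  cat("Exclusive overlap regions of", x$n_sets, "sets\n")
  cat("Union:", x$n_union, " In all sets:", x$n_intersection,
      sprintf(" (%.1f%%)\n", 100 * x$fraction_in_all))
  invisible(x)
}

#' @export
tidy.circ_venn <- function(x, ...) x$regions

#' Abundance detection filter
#'
#' A circRNA is considered quantifiable in an organ when its mean
#' normalized read value over that organ's replicates reaches `threshold`
#' (default 10 normalized reads, the value a ddPCR-anchored calibration
#' maps to the ddPCR limit of quantification). The union over organs
#' defines the analysis set. With `per_organ = FALSE` the grand mean over
#' all libraries is used instead.
#'
#' @param organ_means Aggregated tibble (`circ_id`, `organ`, `mean`), as
#'   from [aggregate_replicates()].
#' @param threshold Inclusive detection threshold on the mean.
#' @param per_organ Apply per organ (default) or to the grand mean.
#' @return List with `pass` (tibble `circ_id`, `organ` of passing pairs)
#'   and `union` (character vector, the analysis set).
#' @export
abundance_filter <- function(organ_means, threshold = 10, per_organ = TRUE) {
  stopifnot(all(c("circ_id", "organ", "mean") %in% names(organ_means)))
  if (per_organ) {
    pass <- organ_means %>%
      filter(.data$mean >= threshold) %>%
      select("circ_id", "organ")
  } else {
    passing_ids <- organ_means %>%
      group_by(.data$circ_id) %>%
      summarise(grand = mean(.data$mean), .groups = "drop") %>%
      filter(.data$grand >= threshold) %>%
      pull("circ_id")
    pass <- organ_means %>%
      filter(.data$circ_id %in% passing_ids) %>%
      select("circ_id", "organ")
  }
  list(pass = pass, union = unique(pass$circ_id))
}

#' Genome partition and organ overlap sets
#'
#' Splits the per-organ detection sets into nuclear and organellar
#' (chloroplast) partitions and derives, within each partition and overall:
#' the per-organ sets, the ubiquitous set (present in every organ), and
#' the organ-unique sets (present in exactly one organ, hence mutually
#' disjoint).
#'
#' @param pass Tibble (`circ_id`, `organ`) of detected pairs, as from
#'   [abundance_filter()].
#' @param organelles Chromosome names treated as organellar.
#' @return A `circ_overlap` object: named list of partitions (`all`,
#'   `nuclear`, `organellar`), each with `organ_sets`, `venn`
#'   (a `circ_venn`), `ubiquitous`, `unique_sets`.
#' @export
partition_and_overlap <- function(pass, organelles = organelle_chroms()) {
  stopifnot(all(c("circ_id", "organ") %in% names(pass)))
  pass <- distinct(as_tibble(pass), .data$circ_id, .data$organ)
  org_flag <- is_organelle(unique(pass$circ_id), organelles)
  organellar_ids <- unique(pass$circ_id)[org_flag]
  one_partition <- function(d) {
    organ_sets <- split(d$circ_id, d$organ)
    if (length(organ_sets) < 2L) {
      return(list(organ_sets = organ_sets, venn = NULL,
                  ubiquitous = if (length(organ_sets)) organ_sets[[1L]] else character(0),
                  unique_sets = organ_sets))
    }
    venn <- replicate_reproducibility(organ_sets)
    ubiquitous <- Reduce(intersect, organ_sets)
    unique_sets <- lapply(names(organ_sets), function(o) {
      setdiff(organ_sets[[o]],
              unlist(organ_sets[setdiff(names(organ_sets), o)],
                     use.names = FALSE))
    })
    names(unique_sets) <- names(organ_sets)
    list(organ_sets = organ_sets, venn = venn, ubiquitous = ubiquitous,
         unique_sets = unique_sets)
  }
  structure(
    list(all = one_partition(pass),
         nuclear = one_partition(filter(pass, !.data$circ_id %in% organellar_ids)),
         organellar = one_partition(filter(pass, .data$circ_id %in% organellar_ids))),
    class = "circ_overlap")
}

#' @export
print.circ_overlap <- function(x, ...) {
  for (p in names(x)) {
    part <- x[[p]]
    n <- length(unique(unlist(part$organ_sets, use.names = FALSE)))
    cat(sprintf("%-10s: %d circRNAs, %d ubiquitous, unique per organ: %s\n",
                p, n, length(part$ubiquitous),
                paste(vapply(part$unique_sets, length, integer(1)),
                      collapse = "/")))
  }
  invisible(x)
}
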