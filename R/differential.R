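#' Pairwise differential circRNA accumulation between two sample types
#'
#' For every circRNA, compares normalized abundances between the replicates
#' of two organs/sample types. The fold change is computed on replicate
#' means with a pseudocount (`log2((mean_A + pc) / (mean_B + pc))`), and the
#' p-value comes from a two-sided Welch (unequal-variance) t-test on
#' `log2(value + pc)` across replicates — a pragmatic choice at n = 4 that
#' is exact when replicate noise is log-normal. A call is significant when
#' `|log2FC| >= log2(fc_cutoff)` and `p <= alpha`; with fewer than two
#' replicates on either side the fold change is still reported but the
#' p-value is undefined and the call can never be significant. No
#' multiple-testing correction is applied by default (`p_adjust = "none"`);
#' Benjamini-Hochberg is available via `p_adjust = "BH"`.
#'
#' Missing (circRNA, sample) rows are treated as zero counts, so the input
#' need not be a complete grid.
#'
#' @param norm Long normalized tibble (`circ_id`, `sample_id`, `value`).
#' @param samples Sample metadata (`sample_id`, `organ`).
#' @param organ_a,organ_b The two sample types to compare (A vs B; positive
#'   `log2_fc` means higher in A).
#' @param fc_cutoff Fold-change cutoff (default 2, i.e. two-fold).
#' @param alpha Significance level (default 0.05).
#' @param pseudocount Added on the normalized scale before logs (default
#'   0.5) to keep fold changes finite and direction-correct at zeros.
#' @param analysis_set Optional character vector restricting the circRNAs
#'   tested (e.g. the abundance-filter union).
#' @param p_adjust Multiplicity correction passed to [stats::p.adjust()].
#' @return Tibble `circ_id`, `organ_a`, `organ_b`, `mean_a`, `mean_b`,
#'   `log2_fc`, `p_value`, `significant`.
#' @export
pairwise_diff <- function(norm, samples, organ_a, organ_b, fc_cutoff = 2,
                          alpha = 0.05, pseudocount = 0.5,
                          analysis_set = NULL, p_adjust = "none") {
  stopifnot(all(c("circ_id", "sample_id", "value") %in% names(norm)),
            all(c("sample_id", "organ") %in% names(samples)))
  pc <- pseudocount
  ids <- if (is.null(analysis_set)) unique(norm$circ_id) else analysis_set
  samp <- filter(samples, .data$organ %in% c(organ_a, organ_b))
  if (nrow(samp) == 0L) abort("no samples for the requested organs")
  grid <- tidyr::expand_grid(circ_id = ids, sample_id = samp$sample_id) %>%
    left_join(norm[, c("circ_id", "sample_id", "value")],
              by = c("circ_id", "sample_id")) %>%
    mutate(value = ifelse(is.na(.data$value), 0, .data$value)) %>%
    left_join(samp[, c("sample_id", "organ")], by = "sample_id")
  welch_log_p <- function(a, b) {
    if (length(a) < 2L || length(b) < 2L) return(NA_real_)
    la <- log2(a + pc); lb <- log2(b + pc)
    if (sd(la) == 0 && sd(lb) == 0) {
      return(if (isTRUE(all.equal(mean(la), mean(lb)))) 1 else 0)
    }
    tryCatch(t.test(la, lb, var.equal = FALSE)$p.value,
             error = function(e) NA_real_)
  }
  res <- grid %>%
    group_by(.data$circ_id) %>%
    summarise(
      mean_a = mean(.data$value[.data$organ == organ_a]),
      mean_b = mean(.data$value[.data$organ == organ_b]),
      p_value = welch_log_p(.data$value[.data$organ == organ_a],
                            .data$value[.data$organ == organ_b]),
      .groups = "drop") %>%
    mutate(organ_a = organ_a, organ_b = organ_b,
           log2_fc = log2((.data$mean_a + pc) / (.data$mean_b + pc)))
  res$p_value <- stats::p.adjust(res$p_value, method = p_adjust)
  res %>%
    mutate(significant = !is.na(.data$p_value) & .data$p_value <= alpha &
             abs(.data$log2_fc) >= log2(fc_cutoff)) %>%
    select("circ_id", "organ_a", "organ_b", "mean_a", "mean_b",
           "log2_fc", "p_value", "significant")
}

#' Differential accumulation over all organ pairs
#'
#' Runs [pairwise_diff()] for every unordered pair of sample types present
#' in `samples`.
#'
#' @inheritParams pairwise_diff
#' @return Row-bound tibble of all pairwise results.
#' @export
all_pairwise_diff <- function(norm, samples, fc_cutoff = 2, alpha = 0.05,
                              pseudocount = 0.5, analysis_set = NULL,
                              p_adjust = "none") {
  organs <- unique(samples$organ)
  if (length(organs) < 2L) abort("need at least two sample types")
  pairs <- utils::combn(organs, 2L, simplify = FALSE)
  bind_rows(lapply(pairs, function(p) {
    pairwise_diff(norm, samples, p[1L], p[2L], fc_cutoff, alpha,
                  pseudocount, analysis_set, p_adjust)
  }))
}

#' Count significant increases and decreases per organ pair
#'
#' @param results Tibble from [all_pairwise_diff()] (or a single
#'   [pairwise_diff()] result).
#' @return Tibble `organ_a`, `organ_b`, `n_up` (significantly higher in A),
#'   `n_down`. By antisymmetry, `n_up(A, B)` equals `n_down(B, A)`.
#' @export
count_diff_by_pair <- function(results) {
  results %>%
    group_by(.data$organ_a, .data$organ_b) %>%
    summarise(n_up = sum(.data$significant & .data$log2_fc > 0),
              n_down = sum(.data$significant & .data$log2_fc < 0),
              .groups = "drop")
}

#' Organ-specific circRNA calls
#'
#' A circRNA is called specific to (significantly increased in) an organ
#' when every pairwise comparison of that organ against the other sample
#' types is a significant increase.
#'
#' @param results Tibble from [all_pairwise_diff()].
#' @return Tibble `circ_id`, `organ` of organ-specific calls.
#' @export
organ_specific_calls <- function(results) {
  organs <- unique(c(results$organ_a, results$organ_b))
  directed <- bind_rows(
    results %>% select(organ = "organ_a", other = "organ_b",
                       "circ_id", "log2_fc", "significant"),
    results %>% mutate(log2_fc = -.data$log2_fc) %>%
      select(organ = "organ_b", other = "organ_a",
             "circ_id", "log2_fc", "significant"))
  directed %>%
    group_by(.data$circ_id, .data$organ) %>%
    summarise(specific = sum(.data$significant & .data$log2_fc > 0) ==
                (length(organs) - 1L) &&
                n() == (length(organs) - 1L),
              .groups = "drop") %>%
    filter(.data$specific) %>%
    select("circ_id", "organ")
}

#' Discrete abundance classes per organ
#'
#' Within each organ, detected circRNAs (mean > 0) are ranked in
#' descending abundance and split into `high` — the top `ceil(0.05 n)`;
#' `medium` — values strictly above the 80th percentile of the organ's
#' detected values but not `high`; `low` — the remaining detected; and
#' `not_detected` — absent or zero. Ties are broken by stable circRNA-id
#' order, so the partition is deterministic. Every circRNA receives exactly
#' one class in every organ of `organ_means`.
#'
#' @param organ_means Aggregated tibble (`circ_id`, `organ`, `mean`).
#' @return Tibble `circ_id`, `organ`, `class` (factor high/medium/low/
#'   not_detected); the full circRNA x organ grid.
#' @export
classify_abundance <- function(organ_means) {
  stopifnot(all(c("circ_id", "organ", "mean") %in% names(organ_means)))
  lv <- c("high", "medium", "low", "not_detected")
  grid <- tidyr::expand_grid(circ_id = unique(organ_means$circ_id),
                             organ = unique(organ_means$organ)) %>%
    left_join(organ_means[, c("circ_id", "organ", "mean")],
              by = c("circ_id", "organ")) %>%
    mutate(mean = ifelse(is.na(.data$mean), 0, .data$mean))
  classify_one <- function(d) {
    det <- d$mean > 0
    cls <- rep("not_detected", nrow(d))
    n_det <- sum(det)
    if (n_det > 0L) {
      vals <- d$mean[det]
      ord <- order(-vals, d$circ_id[det]) # stable tie-break by id
      n_high <- ceiling(0.05 * n_det)
      high_idx <- which(det)[ord[seq_len(n_high)]]
      q80 <- quantile(vals, 0.8, names = FALSE)
      # relative tolerance keeps "strictly above" scale-invariant when a
      # value coincides with the percentile
      cls[det] <- ifelse(d$mean[det] > q80 * (1 + 1e-9), "medium", "low")
      cls[high_idx] <- "high"
    }
    d$class <- factor(cls, levels = lv)
    d
  }
  grid %>%
    group_by(.data$organ) %>%
    dplyr::group_modify(~classify_one(.x)) %>%
    ungroup() %>%
    select("circ_id", "organ", "class")
}

#' Row ordering by hierarchical agglomerative clustering
#'
#' Orders circRNAs for heatmap display by average-linkage agglomerative
#' clustering of their per-organ profiles, using Euclidean distance on
#' `log2(value + 1)`. The leaf order is deterministic for a given input
#' order.
#'
#' @param organ_means Aggregated tibble (`circ_id`, `organ`, `mean`), or a
#'   numeric matrix with circRNA rownames.
#' @return Character vector: circRNA ids in dendrogram leaf order (a
#'   permutation of the input ids).
#' @export
cluster_order <- function(organ_means) {
  if (is.matrix(organ_means)) {
    m <- organ_means
  } else {
    stopifnot(all(c("circ_id", "organ", "mean") %in% names(organ_means)))
    wide <- organ_means %>%
      select("circ_id", "organ", "mean") %>%
      tidyr::pivot_wider(names_from = "organ", values_from = "mean",
                         values_fill = 0)
    m <- as.matrix(wide[-1])
    rownames(m) <- wide$circ_id
  }
  if (nrow(m) < 2L) abort("clustering needs at least 2 rows")
  hc <- hclust(dist(log2(m + 1)), method = "average")
  rownames(m)[hc$order]
}

#' Circular versus linear transcript accumulation
#'
#' Joins per-organ circRNA abundances with the normalized abundances of
#' their parent genes' linear transcripts and computes (i) Pearson
#' correlations between the two — overall and per organ, on the
#' `log2(value + 1)` scale on which abundance profiles are compared —
#' and (ii) circular:linear ratios with an enrichment flag marking
#' circRNAs whose abundance reaches `ratio_cutoff` times (default 1.5)
#' their linear counterpart in at least one sample type. Pairs with an
#' undetected linear partner are excluded from the correlation and counted
#' separately; intergenic circRNAs (no parent gene) are kept in the ratio
#' table with an absent linear value. Both inputs must declare the same
#' normalization `method`, since the ratios presuppose comparable units.
#'
#' @param circ_means Aggregated circRNA tibble (`circ_id`, `organ`,
#'   `mean`, `method`).
#' @param linear Linear-transcript tibble (`gene_id`, `organ`, `value`,
#'   `method`), on a comparable normalized scale.
#' @param mapping Tibble `circ_id`, `gene_id` (`NA` gene for intergenic).
#' @param ratio_cutoff Enrichment cutoff (default 1.5).
#' @return A `circ_linear` object: list with `pairs` (per circ x organ:
#'   circ/linear values, `ratio`, `enriched` per-circRNA flag),
#'   `correlations` (`stratum`, `r`, `n_pairs`), `n_undetected_linear`,
#'   `n_intergenic`.
#' @export
circ_linear_analysis <- function(circ_means, linear, mapping,
                                 ratio_cutoff = 1.5) {
  stopifnot(all(c("circ_id", "organ", "mean") %in% names(circ_means)),
            all(c("gene_id", "organ", "value") %in% names(linear)),
            all(c("circ_id", "gene_id") %in% names(mapping)))
  if ("method" %in% names(circ_means) && "method" %in% names(linear)) {
    mc <- unique(circ_means$method); ml <- unique(linear$method)
    if (length(mc) != 1L || length(ml) != 1L || mc != ml) {
      abort(paste0("circ and linear matrices must declare the same ",
                   "normalization method (got '",
                   paste(mc, collapse = ","), "' vs '",
                   paste(ml, collapse = ","), "')"))
    }
  }
  pairs <- circ_means %>%
    select("circ_id", "organ", circ = "mean") %>%
    left_join(mapping[, c("circ_id", "gene_id")], by = "circ_id") %>%
    left_join(linear %>% select("gene_id", "organ", linear = "value"),
              by = c("gene_id", "organ")) %>%
    mutate(ratio = ifelse(!is.na(.data$linear) & .data$linear > 0,
                          .data$circ / .data$linear, NA_real_))
  enr <- pairs %>%
    group_by(.data$circ_id) %>%
    summarise(enriched = any((!is.na(.data$linear) & .data$linear > 0 &
                                .data$circ >= ratio_cutoff * .data$linear) |
                               (!is.na(.data$linear) & .data$linear == 0 &
                                  .data$circ > 0)),
              .groups = "drop")
  pairs <- left_join(pairs, enr, by = "circ_id")
  usable <- filter(pairs, !is.na(.data$linear) & .data$linear > 0)
  cor_one <- function(d, stratum) {
    if (nrow(d) < 3L) {
      return(tibble(stratum = stratum, r = NA_real_, n_pairs = nrow(d)))
    }
    tibble(stratum = stratum,
           r = pearson(log2(d$circ + 1), log2(d$linear + 1)),
           n_pairs = nrow(d))
  }
  correlations <- bind_rows(
    cor_one(usable, "all"),
    bind_rows(lapply(unique(usable$organ),
                     function(o) cor_one(filter(usable, .data$organ == o), o))))
  structure(
    list(pairs = pairs, correlations = correlations,
         n_undetected_linear = nrow(filter(pairs, !is.na(.data$gene_id) &
                                             (is.na(.data$linear) |
                                                .data$linear == 0))),
         n_intergenic = length(unique(pairs$circ_id[is.na(pairs$gene_id)]))),
    class = "circ_linear")
}

#' @export
print.circ_linear <- function(x, ...) {
  cat("Circular vs linear accumulation:",
      length(unique(x$pairs$circ_id)), "circRNAs\n")
  print(x$correlations)
  cat("Enriched (circ >=1.5x linear in >=1 sample type):",
      sum(tapply(x$pairs$enriched, x$pairs$circ_id, any)), "\n")
  invisible(x)
}

#' @export
tidy.circ_linear <- function(x, ...) x$pairs

#' @export
glance.circ_linear <- function(x, ...) {
  tibble(r_all = x$correlations$r[x$correlations$stratum == "all"],
         n_pairs = x$correlations$n_pairs[x$correlations$stratum == "all"],
         n_undetected_linear = x$n_undetected_linear,
         n_intergenic = x$n_intergenic)
}
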