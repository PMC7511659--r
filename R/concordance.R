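#' Pearson product-moment correlation with domain checks
#'
#' The workflow ranks normalization methods by the Pearson correlation
#' between mean ddPCR quantities and mean normalized read values, computed
#' on the raw (untransformed) paired values. This wrapper enforces the
#' preconditions under which the coefficient is meaningful here.
#'
#' @param x,y Numeric vectors of equal length >= 3, neither constant.
#' @return The sample Pearson correlation coefficient.
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  if (length(x) < 3L) abort("need at least 3 paired values")
  if (anyNA(x) || anyNA(y)) abort("missing values in correlation input")
  if (sd(x) == 0 || sd(y) == 0) {
    abort("correlation undefined for a constant vector")
  }
  cor(x, y, method = "pearson")
}

#' Concordance of normalization methods with ddPCR
#'
#' For each normalization method, computes the Pearson correlation between
#' per-organ mean ddPCR abundances (cp/µg) and per-organ mean normalized
#' read values, both pooled over all (target, organ) pairs (`"all"`
#' stratum) and restricted to each organ. Cells are reported at 2 decimal
#' places; full precision is retained in the `r_full` column. Every cell is
#' invariant to the normalization scale constant and to any common
#' rescaling of the ddPCR units.
#'
#' @param ddpcr Tibble of ddPCR means: `target`, `organ`, `cp_per_ug`.
#' @param norm Tibble of per-organ normalized means: `circ_id`, `organ`,
#'   `mean`, `method` (several methods may be stacked).
#' @param pairing Tibble mapping `target` to `circ_id`, one row per target.
#' @return A `circ_concordance` tibble: `stratum`, `method`, `r` (2 dp),
#'   `r_full`, `n_pairs`. The paired values are attached for [autoplot()].
#' @export
concordance_table <- function(ddpcr, norm, pairing) {
  stopifnot(all(c("target", "organ", "cp_per_ug") %in% names(ddpcr)),
            all(c("circ_id", "organ", "mean", "method") %in% names(norm)),
            all(c("target", "circ_id") %in% names(pairing)))
  if (anyDuplicated(pairing$target)) {
    abort("pairing must map each target to exactly one circRNA")
  }
  orphans <- setdiff(unique(ddpcr$target), pairing$target)
  if (length(orphans)) {
    abort(paste("ddPCR target(s) with no paired circRNA:",
                paste(orphans, collapse = ", ")))
  }
  pairs <- ddpcr %>%
    inner_join(pairing, by = "target") %>%
    inner_join(norm, by = c("circ_id", "organ"),
               relationship = "many-to-many")
  if (nrow(pairs) == 0L) abort("no (target, organ) pairs after joining")
  per_stratum <- function(d, stratum) {
    d %>%
      group_by(.data$method) %>%
      summarise(r_full = pearson(.data$cp_per_ug, .data$mean),
                n_pairs = n(), .groups = "drop") %>%
      mutate(stratum = stratum, r = round(.data$r_full, 2))
  }
  out <- bind_rows(
    per_stratum(pairs, "all"),
    bind_rows(lapply(unique(pairs$organ),
                     function(o) per_stratum(filter(pairs, .data$organ == o), o)))
  ) %>%
    select("stratum", "method", "r", "r_full", "n_pairs")
  structure(out, pairs = pairs, class = c("circ_concordance", class(out)))
}

#' Concordance of the packaged benchmark table
#'
#' Runs [concordance_table()] on the packaged eight-circRNA ddPCR /
#' RNA-seq benchmark (see [benchmark_table()]), pairing each target with
#' itself and stacking the six normalization columns.
#'
#' @return A `circ_concordance` tibble (5 strata x 6 methods).
#' @examples
#' bc <- benchmark_concordance()
#' subset(bc, stratum == "all")
#' @export
benchmark_concordance <- function() {
  tab <- benchmark_table()
  norm <- tab %>%
    select("circ_id", "organ", all_of(norm_methods())) %>%
    tidyr::pivot_longer(all_of(norm_methods()), names_to = "method",
                        values_to = "mean")
  ddpcr <- tab %>%
    select(target = "circ_id", "organ", cp_per_ug = "ddpcr_cp_ug") %>%
    distinct()
  pairing <- distinct(tibble(target = tab$circ_id, circ_id = tab$circ_id))
  concordance_table(ddpcr, norm, pairing)
}

#' Calibrate the normalized-read detection threshold from the ddPCR LoQ
#'
#' Fits a zero-intercept least-squares line `normalized_reads = k * cp_per_ug`
#' through the (ddPCR, RNA-seq) pairs lying above the ddPCR limit of
#' quantification, and maps the LoQ through it. A zero intercept is forced
#' because a circRNA absent from the RNA (0 cp/µg) must yield 0 expected
#' reads. The resulting read threshold is rounded **up** at the resolution
#' of its second significant figure — conservative, so that the analysis
#' set never reaches below the quantifiable range, while an exact
#' proportionality stays exact (0.2 reads per cp/µg and an LoQ of 50 give
#' a threshold of exactly 10).
#'
#' @param pairs Tibble with columns `cp_per_ug` and `norm_reads` (per-organ
#'   means on both sides).
#' @param loq ddPCR limit of quantification in cp/µg, or a `circ_loq`
#'   object.
#' @return A `circ_calibration` object: list with `slope`, `loq_cp_per_ug`,
#'   `read_threshold`, `n_pairs`. `tidy()` returns the fitted pairs,
#'   `glance()` a one-row summary.
#' @examples
#' pairs <- tibble::tibble(cp_per_ug = c(60, 100, 200, 400),
#'                         norm_reads = 0.2 * c(60, 100, 200, 400))
#' calibrate_read_threshold(pairs, loq = 50) # threshold 10
#' @export
calibrate_read_threshold <- function(pairs, loq) {
  if (inherits(loq, "circ_loq")) loq <- loq$threshold_cp_per_ug
  stopifnot(is.numeric(loq), length(loq) == 1L, loq > 0,
            all(c("cp_per_ug", "norm_reads") %in% names(pairs)))
  use <- filter(as_tibble(pairs), .data$cp_per_ug >= loq)
  if (nrow(use) == 0L) abort("all pairs lie below the LoQ")
  if (nrow(use) < 4L) abort("need at least 4 pairs above the LoQ")
  k <- sum(use$cp_per_ug * use$norm_reads) / sum(use$cp_per_ug^2)
  if (k <= 0) abort("non-positive slope: no positive association, calibration invalid")
  structure(
    list(slope = k, loq_cp_per_ug = loq,
         read_threshold = ceiling_signif(k * loq, 2),
         n_pairs = nrow(use), pairs = use),
    class = "circ_calibration")
}

# round up to `digits` significant figures (1e-9 guard against float fuzz)
ceiling_signif <- function(x, digits = 1) {
  stopifnot(x > 0)
  p <- 10^(floor(log10(x)) - digits + 1)
  ceiling(x / p - 1e-9) * p
}

#' @export
print.circ_calibration <- function(x, ...) {
  cat("Read-threshold calibration (zero-intercept least squares)\n")
  cat(sprintf("  slope k      : %.4g normalized reads per cp/ug\n", x$slope))
  cat(sprintf("  ddPCR LoQ    : %g cp/ug\n", x$loq_cp_per_ug))
  cat(sprintf("  read threshold (k x LoQ, rounded up): %g\n", x$read_threshold))
  invisible(x)
}

#' @export
tidy.circ_calibration <- function(x, ...) {
  mutate(x$pairs, fitted = x$slope * .data$cp_per_ug,
         residual = .data$norm_reads - .data$fitted)
}

#' @export
glance.circ_calibration <- function(x, ...) {
  tibble(slope = x$slope, loq_cp_per_ug = x$loq_cp_per_ug,
         read_threshold = x$read_threshold, n_pairs = x$n_pairs)
}
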