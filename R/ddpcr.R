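#' Poisson occupancy estimate from droplet counts
#'
#' In droplet digital PCR the reaction is partitioned into ~15,000-20,000
#' droplets; target molecules distribute over droplets following a Poisson
#' law, so the mean number of copies per droplet is estimated from the
#' fraction of negative droplets: `lambda = -ln((n_total - n_pos) /
#' n_total)`.
#'
#' @param n_pos Positive droplets (vectorised).
#' @param n_total Total accepted droplets.
#' @return Estimated copies per droplet, strictly increasing in `n_pos`.
#' @examples
#' lambda_from_droplets(5000, 10000) # log(2)
#' @export
lambda_from_droplets <- function(n_pos, n_total) {
  if (any(n_total <= 0)) abort("n_total must be positive")
  if (any(n_pos < 0 | n_pos > n_total)) {
    abort("n_pos must satisfy 0 <= n_pos <= n_total")
  }
  if (any(n_pos == n_total)) {
    abort("all droplets positive: concentration above the dynamic range")
  }
  -log((n_total - n_pos) / n_total)
}

#' Convert droplet occupancy to copies per microgram of input RNA
#'
#' Chains the standard unit conversions: copies/droplet over the droplet
#' volume gives copies/µL of reaction; multiplied by the reaction volume and
#' divided by the RNA mass represented in one reaction it gives copies per
#' µg of input total RNA (cp/µg).
#'
#' @param lambda_ Copies per droplet (from [lambda_from_droplets()]).
#' @param droplet_volume_nl Droplet volume in nanolitres; default 0.85 (the
#'   QX200 droplet generation convention).
#' @param reaction_volume_ul Reaction volume in microlitres; default 20.
#' @param rna_mass_ug RNA mass represented in one reaction, in µg; default
#'   0.05 (1 µL of a 20 µL reverse-transcription reaction loaded with 1 µg
#'   of total RNA).
#' @return cp/µg, linear in `lambda_`.
#' @examples
#' copies_per_ug(0.00425) # 2000 cp/ug at the defaults
#' @export
copies_per_ug <- function(lambda_, droplet_volume_nl = 0.85,
                          reaction_volume_ul = 20, rna_mass_ug = 0.05) {
  if (droplet_volume_nl <= 0 || reaction_volume_ul <= 0 || rna_mass_ug <= 0) {
    abort("volumes and RNA mass must be positive")
  }
  if (any(lambda_ < 0)) abort("lambda must be non-negative")
  conc_per_ul <- lambda_ / (droplet_volume_nl * 1e-3)
  conc_per_ul * reaction_volume_ul / rna_mass_ug
}

#' Quantify a ddPCR assay table
#'
#' Applies [lambda_from_droplets()] and [copies_per_ug()] to every row that
#' carries droplet counts; rows with a pre-computed `cp_per_ug` are kept
#' as-is. Saturated wells (all droplets positive) raise an error.
#'
#' @param assay Tibble from [read_ddpcr_table()] (columns `target`,
#'   `organ`, `replicate`, `n_pos`/`n_total` or `cp_per_ug`, `is_marker`).
#' @inheritParams copies_per_ug
#' @return The assay tibble with `lambda`, `conc_per_ul` and `cp_per_ug`
#'   columns filled in.
#' @export
ddpcr_quantify <- function(assay, droplet_volume_nl = 0.85,
                           reaction_volume_ul = 20, rna_mass_ug = 0.05) {
  stopifnot(all(c("target", "organ", "replicate") %in% names(assay)))
  assay <- as_tibble(assay)
  if (all(c("n_pos", "n_total") %in% names(assay))) {
    assay$lambda <- lambda_from_droplets(assay$n_pos, assay$n_total)
    assay$conc_per_ul <- assay$lambda / (droplet_volume_nl * 1e-3)
    cp <- copies_per_ug(assay$lambda, droplet_volume_nl,
                        reaction_volume_ul, rna_mass_ug)
    if ("cp_per_ug" %in% names(assay)) {
      assay$cp_per_ug <- ifelse(is.na(assay$cp_per_ug), cp, assay$cp_per_ug)
    } else {
      assay$cp_per_ug <- cp
    }
  } else if (!("cp_per_ug" %in% names(assay))) {
    abort("assay has neither droplet counts nor cp_per_ug")
  }
  assay
}

#' Normalize target quantities to the marker gene
#'
#' Reference-gene normalization removes between-replicate differences in
#' reverse-transcription efficiency: within each biological replicate the
#' marker gene (*ACT2*) is measured in several technical repeats, and every
#' target's cp/µg is divided by the mean marker cp/µg of its replicate.
#' The result is invariant to any common rescaling of all cp/µg values.
#'
#' @param quant Quantified assay tibble (from [ddpcr_quantify()]) with an
#'   `is_marker` column.
#' @return The target rows with an added `rel_to_marker` column.
#' @export
marker_normalize <- function(quant) {
  stopifnot(all(c("target", "organ", "replicate", "cp_per_ug",
                  "is_marker") %in% names(quant)))
  markers <- filter(quant, .data$is_marker)
  if (nrow(markers) == 0L) abort("no marker rows in assay")
  ref <- markers %>%
    group_by(.data$organ, .data$replicate) %>%
    summarise(marker_cp = mean(.data$cp_per_ug), .groups = "drop")
  if (any(ref$marker_cp <= 0)) {
    abort("marker mean cp/ug is zero in at least one replicate")
  }
  targets <- filter(quant, !.data$is_marker)
  no_ref <- anti_join(targets, ref, by = c("organ", "replicate"))
  if (nrow(no_ref)) {
    abort(paste0("no marker measurement for replicate ", no_ref$replicate[1L],
                 " of ", no_ref$organ[1L]))
  }
  targets %>%
    left_join(ref, by = c("organ", "replicate")) %>%
    mutate(rel_to_marker = .data$cp_per_ug / .data$marker_cp) %>%
    select(-"marker_cp")
}

#' Limit of quantification from replicate dispersion
#'
#' A (target, sample type) measurement is flagged unreliable when its
#' sample standard deviation is at least as large as its mean (CV >= 1),
#' i.e. when replicate scatter is comparable to the signal itself; an
#' all-zero measurement is likewise unreliable (not detected). The limit of
#' quantification is the smallest mean observed for any target that is
#' never flagged in any sample type, snapped to one significant figure.
#'
#' @param measurements Tibble with columns `target`, `organ` (or any
#'   stratum label) and `cp_per_ug` at replicate level, or pre-aggregated
#'   columns `mean` and `sd`.
#' @return An object of class `circ_loq`: list with `threshold_cp_per_ug`,
#'   `rule`, and a `flags` tibble (`target`, `organ`, `mean`, `sd`, `cv`,
#'   `unreliable`). `tidy()` returns the flags; `glance()` the threshold.
#' @export
loq_from_replicates <- function(measurements) {
  m <- as_tibble(measurements)
  if (all(c("mean", "sd") %in% names(m))) {
    agg <- m
    if (!("organ" %in% names(agg))) agg$organ <- "all"
  } else {
    stopifnot(all(c("target", "organ", "cp_per_ug") %in% names(m)))
    agg <- m %>%
      group_by(.data$target, .data$organ) %>%
      summarise(mean = mean(.data$cp_per_ug),
                sd = if (n() > 1L) sd(.data$cp_per_ug) else NA_real_,
                n_reps = n(), .groups = "drop")
    if (any(agg$n_reps < 2L)) {
      abort("LoQ assessment needs >= 2 replicates per target and sample type")
    }
  }
  agg <- agg %>%
    mutate(cv = ifelse(.data$mean > 0, .data$sd / .data$mean, Inf),
           unreliable = .data$mean <= 0 | .data$sd >= .data$mean)
  reliable_targets <- agg %>%
    group_by(.data$target) %>%
    summarise(ok = !any(.data$unreliable), .groups = "drop") %>%
    filter(.data$ok) %>%
    pull("target")
  if (length(reliable_targets) == 0L) {
    abort("every target is unreliable: no quantifiable range")
  }
  thr_raw <- min(agg$mean[agg$target %in% reliable_targets])
  structure(
    list(threshold_cp_per_ug = signif(thr_raw, 1),
         threshold_unsnapped = thr_raw,
         rule = paste("unreliable when sample sd >= mean (CV >= 1) or not",
                      "detected; threshold = smallest mean of any target never",
                      "flagged in any sample type, one significant figure"),
         flags = agg),
    class = "circ_loq")
}

#' @export
print.circ_loq <- function(x, ...) {
  cat("Limit of quantification:", x$threshold_cp_per_ug, "cp/ug\n")
  cat("Rule:", x$rule, "\n")
  cat(sum(x$flags$unreliable), "of", nrow(x$flags),
      "(target, sample type) measurements flagged unreliable\n")
  invisible(x)
}

#' @export
tidy.circ_loq <- function(x, ...) x$flags

#' @export
glance.circ_loq <- function(x, ...) {
  tibble(threshold_cp_per_ug = x$threshold_cp_per_ug,
         n_measurements = nrow(x$flags),
         n_unreliable = sum(x$flags$unreliable))
}
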