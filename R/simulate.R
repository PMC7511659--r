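#' Configuration for the synthetic circRNA study generator
#'
#' Builds the parameter set describing a simulated four-organ, four-replicate
#' circRNA sequencing study with paired untreated (R-) and RNase R-treated
#' (R+) libraries, plus droplet-level ddPCR assays and linear-counterpart
#' abundances. Defaults emulate the design and the printed summary
#' statistics of a deep Arabidopsis circRNA survey: mean R- depth around 60M
#' read pairs and R+ around 43% of that; organ-dependent rRNA fractions
#' (fractions of a percent to several percent) and chloroplast fractions
#' (large in green tissue, small in roots); a small reproducible circRNA
#' fraction with the remainder forming stochastically in single replicates;
#' and R+ enrichment of circles with a per-species survival probability
#' modelling hydrolysis-then-digestion losses.
#'
#' @param seed Integer seed; identical configurations give identical
#'   outputs.
#' @param organs Sample types.
#' @param n_reps Biological replicates per organ per protocol.
#' @param n_circ Total circRNA species in the truth.
#' @param fraction_reproducible Share of species with persistent organ
#'   profiles; the rest appear in exactly one (organ, replicate).
#' @param n_planted_per_organ Number of reproducible species planted as
#'   organ-specific per organ.
#' @param planted_effect Multiplicative abundance factor in the planted
#'   organ.
#' @param planted_conc_meanlog,planted_conc_sdlog Log-normal law (cp/µg)
#'   for planted species' base concentration (kept high so planted species
#'   sit in the quantifiable range).
#' @param conc_meanlog,conc_sdlog Log-normal law for ordinary reproducible
#'   species (most circRNAs are rare).
#' @param organ_effect_sdlog Log-sd of per-organ factors for ordinary
#'   reproducible species (mild, sub-two-fold organ variation).
#' @param rep_noise_sdlog Biological replicate noise (log-sd) on
#'   concentrations, shared between the R- and R+ library of a replicate.
#' @param stochastic_conc_meanlog,stochastic_conc_sdlog Law for one-off
#'   stochastic species.
#' @param frac_organelle Fraction of species on the chloroplast genome.
#' @param frac_intergenic Fraction of species with no parent gene.
#' @param depth_range R- library size range (total filtered reads).
#' @param rrna_frac_rminus,rrna_frac_rplus Named per-organ ranges of the
#'   rRNA read fraction per protocol.
#' @param chloro_frac Named per-organ ranges of the chloroplast read
#'   fraction.
#' @param act2_frac Marker-gene (*ACT2*) share of non-rRNA non-chloroplast
#'   reads; `act2_noise_sdlog` its log-normal scatter.
#' @param act2_noise_sdlog See `act2_frac`.
#' @param reads_per_cp Expected back-spliced reads per (cp/µg x read of
#'   effective depth); calibrates counts so composition-corrected
#'   normalized reads are about 0.2 x cp/µg at the default scale.
#' @param rplus_depth_factor R+ depth relative to R-.
#' @param rplus_enrichment Per-molecule circRNA enrichment under RNase R.
#' @param rplus_survival Probability a circRNA species survives RNase R
#'   treatment; a failed species vanishes from every R+ replicate.
#' @param confirm_prob_reproducible,confirm_prob_stochastic Probability the
#'   confirmatory (second) caller also reports a species.
#' @param n_droplets,droplet_volume_nl,reaction_volume_ul,rna_mass_ug ddPCR
#'   partition geometry and loading (see [copies_per_ug()]).
#' @param ddpcr_bio_reps Biological replicates per ddPCR assay.
#' @param ddpcr_tech_reps Technical repeats for the marker gene.
#' @param ddpcr_bio_sdlog Biological log-sd of ddPCR concentrations
#'   (partition sampling adds the dominant low-concentration noise).
#' @param marker_cp Marker-gene concentration in cp/µg.
#' @param circ_linear_corr Log-scale correlation between circRNA and
#'   linear-counterpart abundances.
#' @param linear_meanlog,linear_sdlog Law of linear-counterpart
#'   abundances.
#' @return A validated `circ_sim_config` list.
#' @export
sim_config <- function(seed = 1,
                       organs = c("seedling", "root", "leaf", "flower"),
                       n_reps = 4,
                       n_circ = 2000,
                       fraction_reproducible = 0.05,
                       n_planted_per_organ = 2,
                       planted_effect = 8,
                       planted_conc_meanlog = log(100),
                       planted_conc_sdlog = 0.5,
                       conc_meanlog = log(0.025),
                       conc_sdlog = 2.5,
                       organ_effect_sdlog = 0.2,
                       rep_noise_sdlog = 0.3,
                       stochastic_conc_meanlog = log(0.3),
                       stochastic_conc_sdlog = 0.8,
                       frac_organelle = 0.05,
                       frac_intergenic = 0.1,
                       depth_range = c(5e7, 7e7),
                       rrna_frac_rminus = list(seedling = c(0.02, 0.04),
                                               root = c(0.005, 0.008),
                                               leaf = c(0.06, 0.0757),
                                               flower = c(0.03, 0.05)),
                       rrna_frac_rplus = list(seedling = c(0.01, 0.02),
                                              root = c(0.0027, 0.005),
                                              leaf = c(0.01, 0.02),
                                              flower = c(0.02, 0.0318)),
                       chloro_frac = list(seedling = c(0.25, 0.40),
                                          root = c(0.01, 0.03),
                                          leaf = c(0.20, 0.35),
                                          flower = c(0.05, 0.15)),
                       act2_frac = 5e-4,
                       act2_noise_sdlog = 0.05,
                       reads_per_cp = 2e-7,
                       rplus_depth_factor = 0.43,
                       rplus_enrichment = 10,
                       rplus_survival = 0.9,
                       confirm_prob_reproducible = 0.98,
                       confirm_prob_stochastic = 0.5,
                       n_droplets = 15000,
                       droplet_volume_nl = 0.85,
                       reaction_volume_ul = 20,
                       rna_mass_ug = 0.05,
                       ddpcr_bio_reps = 3,
                       ddpcr_tech_reps = 4,
                       ddpcr_bio_sdlog = 0.15,
                       marker_cp = 2e5,
                       circ_linear_corr = 0.46,
                       linear_meanlog = log(200),
                       linear_sdlog = 1.5) {
  cfg <- as.list(environment())
  fr <- c(cfg$fraction_reproducible, cfg$frac_organelle, cfg$frac_intergenic,
          cfg$rplus_survival, cfg$confirm_prob_reproducible,
          cfg$confirm_prob_stochastic)
  if (any(fr < 0 | fr > 1)) abort("all fractions must lie in [0, 1]")
  if (abs(cfg$circ_linear_corr) >= 1) abort("circ_linear_corr must be in (-1, 1)")
  n_repro <- round(cfg$fraction_reproducible * cfg$n_circ)
  if (cfg$n_planted_per_organ * length(cfg$organs) > n_repro) {
    abort("planted species exceed the reproducible fraction: infeasible config")
  }
  for (o in cfg$organs) {
    if (is.null(cfg$rrna_frac_rminus[[o]]) || is.null(cfg$chloro_frac[[o]]) ||
        is.null(cfg$rrna_frac_rplus[[o]])) {
      abort(paste0("missing composition range for organ '", o, "'"))
    }
  }
  structure(cfg, class = "circ_sim_config")
}

# evaluate code with a private, restored RNG state
with_sim_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate the ground-truth circRNA population
#'
#' Draws the simulated truth: circRNA coordinates (nuclear chromosomes 1-5
#' or the chloroplast genome), parent genes or intergenic status, persistent
#' per-organ concentrations (cp/µg) for reproducible species — including
#' planted organ-specific and, implicitly, ubiquitous ones — and single
#' (organ, replicate) events for stochastic species.
#'
#' @param config A [sim_config()] object.
#' @return A `circ_sim_truth` list: `circs` (per-species tibble with
#'   coordinates, parent gene, `reproducible`, `planted_organ`,
#'   `stochastic_organ`/`stochastic_rep`, `stochastic_conc`), `conc`
#'   (long tibble `circ_id`, `organ`, `conc` for reproducible species) and
#'   the `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "circ_sim_config"))
  with_sim_seed(config$seed, {
    n <- config$n_circ
    organs <- config$organs
    n_repro <- round(config$fraction_reproducible * n)
    n_planted <- config$n_planted_per_organ * length(organs)
    is_organellar <- runif(n) < config$frac_organelle
    chrom <- ifelse(is_organellar, "chloroplast",
                    as.character(sample(1:5, n, replace = TRUE)))
    start <- ifelse(is_organellar,
                    sample(1e3:1.5e5, n, replace = TRUE),
                    sample(1e4:3e7, n, replace = TRUE))
    width <- sample(150:2500, n, replace = TRUE)
    circ_id <- format_circ_id(chrom, start, start + width)
    while (anyDuplicated(circ_id)) { # regenerate collisions
      dup <- duplicated(circ_id)
      start[dup] <- start[dup] + sample(1:997, sum(dup), replace = TRUE)
      circ_id <- format_circ_id(chrom, start, start + width)
    }
    intergenic <- runif(n) < config$frac_intergenic
    gene_id <- ifelse(intergenic, NA_character_,
                      sprintf("AT%sG%05d",
                              ifelse(chrom == "chloroplast", "C", chrom),
                              sample(1:99999, n, replace = TRUE)))
    reproducible <- seq_len(n) <= n_repro
    planted_organ <- rep(NA_character_, n)
    if (n_planted > 0L) {
      planted_organ[seq_len(n_planted)] <-
        rep(organs, each = config$n_planted_per_organ)
    }
    base <- numeric(n)
    planted <- !is.na(planted_organ)
    base[planted] <- rlnorm(sum(planted), config$planted_conc_meanlog,
                            config$planted_conc_sdlog)
    ordinary <- reproducible & !planted
    base[ordinary] <- rlnorm(sum(ordinary), config$conc_meanlog,
                             config$conc_sdlog)
    conc <- tidyr::expand_grid(circ_id = circ_id[reproducible],
                               organ = organs)
    idx <- match(conc$circ_id, circ_id)
    conc$conc <- base[idx] * rlnorm(nrow(conc), 0, config$organ_effect_sdlog)
    po <- planted_organ[idx]
    conc$conc <- conc$conc *
      ifelse(!is.na(po) & po == conc$organ, config$planted_effect, 1)
    st <- !reproducible
    circs <- tibble(
      circ_id = circ_id, chrom = chrom, parent_gene = gene_id,
      reproducible = reproducible, planted_organ = planted_organ,
      stochastic_organ = ifelse(st, sample(organs, n, replace = TRUE),
                                NA_character_),
      stochastic_rep = ifelse(st, sample(config$n_reps, n, replace = TRUE),
                              NA_integer_),
      stochastic_conc = ifelse(st, rlnorm(n, config$stochastic_conc_meanlog,
                                          config$stochastic_conc_sdlog), NA_real_))
    structure(list(circs = circs, conc = conc, config = config),
              class = "circ_sim_truth")
  })
}

#' Simulate back-spliced RNA-seq counts and library statistics
#'
#' Realises library compositions and Poisson back-spliced counts for both
#' protocols. Expected counts are `concentration x effective depth x
#' reads_per_cp`, with shared biological replicate noise between the R- and
#' R+ libraries of a replicate. R+ libraries have reduced depth,
#' per-molecule circRNA enrichment, and per-species Bernoulli survival:
#' a species that fails survival (hydrolysis followed by exonucleolytic
#' digestion) is absent from all R+ replicates. Library statistics
#' (total/rRNA/chloroplast/marker reads, back-spliced sums with and without
#' organellar circRNAs) are realised from the configured composition
#' ranges. A confirmatory-caller id set is drawn alongside.
#'
#' @param truth A `circ_sim_truth` from [generate_truth()].
#' @return List with `counts` (long tibble over both protocols, zero rows
#'   included so the grid is complete), `samples` (metadata with
#'   `protocol` = `"R-"`/`"R+"`), `stats` (library statistics),
#'   `confirm_ids` (second-caller id set) and `survived` (named logical,
#'   R+ survival per species).
#' @export
simulate_rnaseq <- function(truth) {
  stopifnot(inherits(truth, "circ_sim_truth"))
  config <- truth$config
  with_sim_seed(config$seed + 1L, {
    organs <- config$organs
    reps <- seq_len(config$n_reps)
    circs <- truth$circs
    n <- nrow(circs)
    samples <- tidyr::expand_grid(protocol = c("R-", "R+"), organ = organs,
                                  replicate = reps) %>%
      mutate(sample_id = sprintf("%s_%s_rep%d",
                                 ifelse(.data$protocol == "R-", "Rm", "Rp"),
                                 .data$organ, .data$replicate))
    # library composition
    stats <- samples
    ns <- nrow(stats)
    stats$total_reads <- round(runif(ns, config$depth_range[1],
                                     config$depth_range[2]) *
                                 ifelse(stats$protocol == "R+",
                                        config$rplus_depth_factor, 1))
    rrna_f <- vapply(seq_len(ns), function(i) {
      rng <- if (stats$protocol[i] == "R-") {
        config$rrna_frac_rminus[[stats$organ[i]]]
      } else config$rrna_frac_rplus[[stats$organ[i]]]
      runif(1, rng[1], rng[2])
    }, numeric(1))
    chl_f <- vapply(seq_len(ns), function(i) {
      rng <- config$chloro_frac[[stats$organ[i]]]
      runif(1, rng[1], rng[2])
    }, numeric(1))
    stats$rrna_reads <- round(stats$total_reads * rrna_f)
    stats$chloroplast_reads <- round(stats$total_reads * chl_f)
    stats$marker_reads <- round((stats$total_reads - stats$rrna_reads -
                                   stats$chloroplast_reads) *
                                  config$act2_frac *
                                  rlnorm(ns, 0, config$act2_noise_sdlog))
    survived <- setNames(runif(n) < config$rplus_survival, circs$circ_id)
    # per-(species, organ, replicate) concentration incl. shared bio noise
    rep_grid <- tidyr::expand_grid(circ_id = circs$circ_id, organ = organs,
                                   replicate = reps) %>%
      left_join(truth$conc, by = c("circ_id", "organ")) %>%
      left_join(circs[, c("circ_id", "stochastic_organ", "stochastic_rep",
                          "stochastic_conc")], by = "circ_id") %>%
      mutate(conc = dplyr::case_when(
        !is.na(.data$conc) ~ .data$conc,
        !is.na(.data$stochastic_organ) &
          .data$stochastic_organ == .data$organ &
          .data$stochastic_rep == .data$replicate ~ .data$stochastic_conc,
        TRUE ~ 0),
        bio_factor = rlnorm(n(), 0, config$rep_noise_sdlog)) %>%
      select("circ_id", "organ", "replicate", "conc", "bio_factor")
    eff_depth <- setNames(stats$total_reads - stats$rrna_reads -
                            stats$chloroplast_reads, stats$sample_id)
    counts <- samples %>%
      inner_join(rep_grid, by = c("organ", "replicate"),
                 relationship = "many-to-many") %>%
      mutate(mu = .data$conc * .data$bio_factor *
               unname(eff_depth[.data$sample_id]) * config$reads_per_cp *
               ifelse(.data$protocol == "R+",
                      config$rplus_enrichment *
                        as.numeric(survived[.data$circ_id]), 1),
             count = rpois(n(), .data$mu)) %>%
      select("circ_id", "sample_id", "count")
    bs <- counts %>%
      mutate(organellar = .data$circ_id %in%
               circs$circ_id[circs$chrom %in% organelle_chroms()]) %>%
      group_by(.data$sample_id) %>%
      summarise(backspliced_total = sum(.data$count),
                backspliced_excl = sum(.data$count[!.data$organellar]),
                .groups = "drop")
    stats <- stats %>%
      left_join(bs, by = "sample_id") %>%
      select("sample_id", "total_reads", "rrna_reads", "chloroplast_reads",
             "marker_reads", "backspliced_total", "backspliced_excl")
    confirm_p <- ifelse(circs$reproducible, config$confirm_prob_reproducible,
                        config$confirm_prob_stochastic)
    confirm_ids <- circs$circ_id[runif(n) < confirm_p]
    list(counts = counts,
         samples = samples[, c("sample_id", "organ", "replicate", "protocol")],
         stats = validate_library_stats(stats),
         confirm_ids = confirm_ids,
         survived = survived)
  })
}

#' Simulate droplet-level ddPCR assays
#'
#' For each target and organ, draws biological replicates around the true
#' concentration (log-normal biological noise), converts cp/µg to expected
#' droplet occupancy by inverting [copies_per_ug()], and samples positive
#' droplets binomially — so the dominant noise at low concentrations is
#' partition sampling, which is what creates a limit of quantification.
#' Marker-gene (*ACT2*) assays with technical repeats are generated
#' alongside.
#'
#' @param truth A `circ_sim_truth`.
#' @param targets CircRNA ids to assay (must be reproducible species).
#' @return A ddPCR assay tibble (`target`, `organ`, `replicate`, `n_pos`,
#'   `n_total`, `is_marker`, `true_cp_per_ug`).
#' @export
simulate_ddpcr <- function(truth, targets) {
  stopifnot(inherits(truth, "circ_sim_truth"))
  config <- truth$config
  missing_t <- setdiff(targets, truth$conc$circ_id)
  if (length(missing_t)) {
    abort(paste("targets not in the reproducible truth:",
                paste(missing_t, collapse = ", ")))
  }
  with_sim_seed(config$seed + 2L, {
    lambda_per_cp <- config$rna_mass_ug / config$reaction_volume_ul *
      config$droplet_volume_nl * 1e-3
    draw <- function(target, organ, replicate, true_cp, is_marker) {
      cp <- true_cp * rlnorm(length(true_cp), 0, config$ddpcr_bio_sdlog)
      lam <- cp * lambda_per_cp
      p_pos <- 1 - exp(-lam)
      if (any(p_pos > 0.999)) {
        warn("ddPCR saturation: >99.9% positive droplets for some wells")
      }
      tibble(target = target, organ = organ, replicate = replicate,
             n_pos = rbinom(length(cp), config$n_droplets, p_pos),
             n_total = config$n_droplets, is_marker = is_marker,
             true_cp_per_ug = true_cp)
    }
    tgt <- tidyr::expand_grid(target = targets, organ = config$organs,
                              replicate = seq_len(config$ddpcr_bio_reps)) %>%
      left_join(truth$conc, by = c(target = "circ_id", organ = "organ"))
    out_t <- draw(tgt$target, tgt$organ, tgt$replicate, tgt$conc, FALSE)
    mk <- tidyr::expand_grid(organ = config$organs,
                             replicate = seq_len(config$ddpcr_bio_reps),
                             tech = seq_len(config$ddpcr_tech_reps))
    out_m <- draw("AT3G18780", mk$organ, mk$replicate,
                  rep(config$marker_cp, nrow(mk)), TRUE)
    bind_rows(out_t, out_m)
  })
}

#' Simulate linear-counterpart abundances
#'
#' Draws normalized linear-transcript abundances for every parent gene as a
#' bivariate log-normal with the configured log-scale correlation to the
#' circRNA truth (computed per organ). Intergenic circRNAs get no linear
#' partner.
#'
#' @param truth A `circ_sim_truth`.
#' @param method Normalization method tag recorded on the output, so it
#'   can be matched against a circRNA matrix in
#'   [circ_linear_analysis()].
#' @return List with `linear` (tibble `gene_id`, `organ`, `value`,
#'   `method`) and `mapping` (`circ_id`, `gene_id`).
#' @export
simulate_linear <- function(truth, method = "library_size_excl") {
  stopifnot(inherits(truth, "circ_sim_truth"))
  config <- truth$config
  with_sim_seed(config$seed + 3L, {
    rho <- config$circ_linear_corr
    mapping <- truth$circs %>%
      filter(.data$reproducible) %>%
      select("circ_id", gene_id = "parent_gene")
    mapped <- truth$conc %>%
      inner_join(filter(mapping, !is.na(.data$gene_id)), by = "circ_id")
    lin <- mapped %>%
      group_by(.data$organ) %>%
      mutate(z = if (n() > 1L && sd(log(.data$conc)) > 0) {
        (log(.data$conc) - mean(log(.data$conc))) / sd(log(.data$conc))
      } else 0) %>%
      ungroup() %>%
      mutate(value = exp(config$linear_meanlog + config$linear_sdlog *
                           (rho * .data$z +
                              sqrt(1 - rho^2) * rnorm(n()))),
             method = method) %>%
      select("gene_id", "organ", "value", "method")
    list(linear = lin, mapping = mapping)
  })
}
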