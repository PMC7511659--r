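test_that("identical configurations yield identical simulated datasets", {
  cfg <- sim_config(seed = 101, n_circ = 300)
  t1 <- generate_truth(cfg); t2 <- generate_truth(cfg)
  expect_identical(t1$circs, t2$circs)
  expect_identical(t1$conc, t2$conc)
  s1 <- simulate_rnaseq(t1); s2 <- simulate_rnaseq(t2)
  expect_identical(s1$counts, s2$counts)
  expect_identical(s1$stats, s2$stats)
  d1 <- simulate_ddpcr(t1, t1$conc$circ_id[1])
  d2 <- simulate_ddpcr(t2, t2$conc$circ_id[1])
  expect_identical(d1, d2)
  l1 <- simulate_linear(t1); l2 <- simulate_linear(t2)
  expect_identical(l1$linear, l2$linear)
  # a different seed changes the draw
  t3 <- generate_truth(sim_config(seed = 102, n_circ = 300))
  expect_false(identical(t1$circs$circ_id, t3$circs$circ_id))
})

test_that("infeasible configurations are rejected up front", {
  expect_error(sim_config(fraction_reproducible = 1.2), "fractions")
  expect_error(sim_config(n_circ = 100, fraction_reproducible = 0.01,
                          n_planted_per_organ = 5), "infeasible")
  expect_error(sim_config(circ_linear_corr = 1), "circ_linear_corr")
})

test_that("the reproducible fraction controls replicate persistence", {
  # fully reproducible truth: every species has organ concentrations
  cfg1 <- sim_config(seed = 5, n_circ = 100, fraction_reproducible = 1,
                     n_planted_per_organ = 0)
  tr1 <- generate_truth(cfg1)
  expect_true(all(tr1$circs$reproducible))
  expect_equal(nrow(tr1$conc), 100 * 4)
  expect_true(all(tr1$conc$conc > 0))

  # fully stochastic truth: each species appears in one (organ, replicate)
  cfg0 <- sim_config(seed = 5, n_circ = 100, fraction_reproducible = 0,
                     n_planted_per_organ = 0)
  tr0 <- generate_truth(cfg0)
  expect_false(any(tr0$circs$reproducible))
  expect_equal(nrow(tr0$conc), 0)
  sim0 <- simulate_rnaseq(tr0)
  det <- sim0$counts |>
    dplyr::filter(count > 0) |>
    dplyr::inner_join(sim0$samples, by = "sample_id") |>
    dplyr::filter(protocol == "R-")
  # no species detected in more than one replicate of any organ
  multi <- det |>
    dplyr::distinct(circ_id, organ, replicate) |>
    dplyr::count(circ_id, organ) |>
    dplyr::filter(n > 1)
  expect_equal(nrow(multi), 0L)
})

test_that("realized library statistics conserve read totals", {
  cfg <- sim_config(seed = 9, n_circ = 200)
  sim <- simulate_rnaseq(generate_truth(cfg))
  st <- sim$stats
  expect_true(all(st$rrna_reads + st$chloroplast_reads <= st$total_reads))
  expect_true(all(st$backspliced_excl <= st$backspliced_total))
  expect_true(all(st$marker_reads > 0))
  # R+ libraries are shallower by roughly the configured factor
  meta <- sim$samples
  depth <- tapply(st$total_reads,
                  meta$protocol[match(st$sample_id, meta$sample_id)], mean)
  expect_equal(unname(depth["R+"] / depth["R-"]), cfg$rplus_depth_factor,
               tolerance = 0.15)
})

test_that("RNase R treatment enriches survivors and deletes lost species", {
  cfg <- sim_config(seed = 13, n_circ = 1000, fraction_reproducible = 1,
                    n_planted_per_organ = 0, conc_meanlog = log(5),
                    conc_sdlog = 0.5, rplus_survival = 0.9)
  tr <- generate_truth(cfg)
  sim <- simulate_rnaseq(tr)
  meta <- sim$samples
  det <- sim$counts |>
    dplyr::filter(count > 0) |>
    dplyr::inner_join(meta, by = "sample_id")
  in_rm <- unique(det$circ_id[det$protocol == "R-"])
  in_rp <- unique(det$circ_id[det$protocol == "R+"])
  lost <- setdiff(in_rm, in_rp)
  # losses track the survival draw and a Binomial(1000, 0.1) count
  expect_true(all(!sim$survived[lost]))
  expect_gt(length(lost), 100 - 3 * sqrt(1000 * 0.1 * 0.9))
  expect_lt(length(lost), 100 + 3 * sqrt(1000 * 0.1 * 0.9))

  # expected enrichment for survivors: enrichment x depth factor
  cfg2 <- sim_config(seed = 14, n_circ = 400, fraction_reproducible = 1,
                     n_planted_per_organ = 0, conc_meanlog = log(20),
                     conc_sdlog = 0.3, rplus_survival = 1,
                     rplus_enrichment = 3, rplus_depth_factor = 0.5)
  sim2 <- simulate_rnaseq(generate_truth(cfg2))
  meta2 <- sim2$samples
  tot <- sim2$counts |>
    dplyr::inner_join(meta2, by = "sample_id") |>
    dplyr::group_by(protocol) |>
    dplyr::summarise(n = sum(count))
  ratio <- tot$n[tot$protocol == "R+"] / tot$n[tot$protocol == "R-"]
  expect_equal(ratio, 1.5, tolerance = 0.1)
})

test_that("zero concentrations produce zero counts and zero droplets", {
  cfg <- sim_config(seed = 3, n_circ = 50, fraction_reproducible = 1,
                    n_planted_per_organ = 0)
  tr <- generate_truth(cfg)
  tr$conc$conc <- 0
  sim <- simulate_rnaseq(tr)
  expect_true(all(sim$counts$count == 0))
  dd <- simulate_ddpcr(tr, tr$conc$circ_id[1])
  expect_true(all(dd$n_pos[!dd$is_marker] == 0))
})

test_that("simulated ddPCR assays round-trip the true concentration", {
  cfg <- sim_config(seed = 29, n_circ = 40, fraction_reproducible = 1,
                    n_planted_per_organ = 0, ddpcr_bio_reps = 200,
                    organ_effect_sdlog = 0, rep_noise_sdlog = 0)
  tr <- generate_truth(cfg)
  target <- tr$conc$circ_id[1]
  tr$conc$conc[tr$conc$circ_id == target] <- 2000
  dd <- simulate_ddpcr(tr, target)
  q <- ddpcr_quantify(dd[!dd$is_marker & dd$organ == "seedling", ])
  est <- mean(q$cp_per_ug)
  se <- sd(q$cp_per_ug) / sqrt(nrow(q))
  expect_lt(abs(est - 2000), 3 * se + 1e-9)
  # dispersion scale: CV at ~70 cp/ug is comparable to the benchmark rows
  tr$conc$conc[tr$conc$circ_id == target] <- 70
  q70 <- ddpcr_quantify(simulate_ddpcr(tr, target)) |>
    dplyr::filter(!is_marker, organ == "seedling")
  cv <- sd(q70$cp_per_ug) / mean(q70$cp_per_ug)
  expect_gt(cv, 0.4); expect_lt(cv, 0.8)
})

test_that("linear counterparts carry the configured log-scale correlation", {
  base <- sim_config(seed = 41, n_circ = 500, fraction_reproducible = 1,
                     n_planted_per_organ = 0, frac_intergenic = 0,
                     conc_sdlog = 1.5)
  # null correlation
  cfg0 <- base; cfg0$circ_linear_corr <- 0
  tr0 <- generate_truth(cfg0)
  l0 <- simulate_linear(tr0)
  j0 <- dplyr::inner_join(
    dplyr::inner_join(tr0$conc, l0$mapping, by = "circ_id"),
    l0$linear, by = c("gene_id", "organ"))
  r0 <- cor(log(j0$conc), log(j0$value))
  expect_lt(abs(r0), 0.2)
  # near-identity correlation
  cfg9 <- base; cfg9$circ_linear_corr <- 0.99
  l9 <- simulate_linear(generate_truth(cfg9))
  tr9 <- generate_truth(cfg9)
  j9 <- dplyr::inner_join(
    dplyr::inner_join(tr9$conc, l9$mapping, by = "circ_id"),
    l9$linear, by = c("gene_id", "organ"))
  expect_gt(cor(log(j9$conc), log(j9$value)), 0.9)
})

test_that("composition-aware normalizations beat library size on skewed organs", {
  # maximally unequal rRNA + chloroplast fractions across organs
  cfg <- sim_config(seed = 61, n_circ = 40, fraction_reproducible = 1,
                    n_planted_per_organ = 0, conc_meanlog = log(300),
                    conc_sdlog = 1, organ_effect_sdlog = 0.5,
                    rrna_frac_rminus = list(seedling = c(0.07, 0.0757),
                                            root = c(0.005, 0.006),
                                            leaf = c(0.07, 0.0757),
                                            flower = c(0.03, 0.04)),
                    chloro_frac = list(seedling = c(0.55, 0.60),
                                       root = c(0.005, 0.01),
                                       leaf = c(0.45, 0.55),
                                       flower = c(0.10, 0.15)))
  tr <- generate_truth(cfg)
  sim <- simulate_rnaseq(tr)
  meta <- dplyr::filter(sim$samples, protocol == "R-")
  counts <- dplyr::filter(sim$counts, sample_id %in% meta$sample_id)
  dd <- ddpcr_quantify(dplyr::filter(simulate_ddpcr(tr, tr$circs$circ_id),
                                     !is_marker)) |>
    dplyr::group_by(target, organ) |>
    dplyr::summarise(cp_per_ug = mean(cp_per_ug), .groups = "drop")
  pairing <- tibble::tibble(target = tr$circs$circ_id,
                            circ_id = tr$circs$circ_id)
  r_all <- sapply(norm_methods(), function(m) {
    norm <- normalize_counts(counts, sim$stats, m)
    means <- aggregate_replicates(norm, meta)
    ct <- concordance_table(dd, means, pairing)
    ct$r_full[ct$stratum == "all"]
  })
  for (m in setdiff(norm_methods(), "library_size")) {
    expect_gt(r_all[[m]], r_all[["library_size"]])
  }
})

test_that("default-like conditions reproduce the observed reproducibility band", {
  cfg <- sim_config(seed = 23, n_circ = 2000, fraction_reproducible = 0.05,
                    n_planted_per_organ = 0)
  sim <- simulate_rnaseq(generate_truth(cfg))
  det <- sim$counts |>
    dplyr::filter(count > 0) |>
    dplyr::inner_join(sim$samples, by = "sample_id") |>
    dplyr::filter(protocol == "R-")
  for (o in cfg$organs) {
    sets <- lapply(seq_len(cfg$n_reps), function(r) {
      unique(det$circ_id[det$organ == o & det$replicate == r])
    })
    names(sets) <- paste0("rep", seq_len(cfg$n_reps))
    frac <- replicate_reproducibility(sets)$fraction_in_all
    expect_gte(frac, 0.01)
    expect_lte(frac, 0.08)
  }
})
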