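make_two_organ_norm <- function(values_a, values_b, circ_id = "1:1-10",
                                organ_a = "root", organ_b = "seedling") {
  samples <- toy_samples(c(organ_a, organ_b),
                         n_reps = max(length(values_a), length(values_b)))
  norm <- tibble::tibble(
    circ_id = circ_id,
    sample_id = c(sprintf("%s_rep%d", organ_a, seq_along(values_a)),
                  sprintf("%s_rep%d", organ_b, seq_along(values_b))),
    value = c(values_a, values_b))
  list(norm = norm, samples = samples)
}

test_that("pairwise differential calls combine fold change and Welch p", {
  # identical replicates: zero fold change, never significant
  d <- make_two_organ_norm(c(5, 6, 7, 8), c(5, 6, 7, 8))
  res <- pairwise_diff(d$norm, d$samples, "root", "seedling")
  expect_equal(res$log2_fc, 0)
  expect_false(res$significant)

  # forced four-fold effect is significant
  set.seed(2)
  d2 <- make_two_organ_norm(c(100, 100, 100, 100),
                            25 + rnorm(4, 0, 1e-6))
  res2 <- pairwise_diff(d2$norm, d2$samples, "root", "seedling")
  expect_equal(res2$log2_fc, 2, tolerance = 0.05)
  expect_true(res2$significant)

  # single replicate: fold change reported, p undefined, not significant
  d3 <- make_two_organ_norm(c(100), c(25))
  res3 <- pairwise_diff(d3$norm, d3$samples, "root", "seedling")
  expect_true(is.na(res3$p_value))
  expect_false(res3$significant)
  expect_gt(res3$log2_fc, 1.9)

  # missing (circRNA, sample) rows count as zeros
  d4 <- make_two_organ_norm(c(10, 10, 10, 10), c(4))
  norm4 <- d4$norm[-(6:8), ] # only one seedling row present
  res4 <- pairwise_diff(norm4, d4$samples, "root", "seedling")
  expect_equal(res4$mean_b, 1)
})

test_that("pairwise results are antisymmetric in the organ order", {
  set.seed(14)
  for (i in 1:25) {
    n_circ <- 6
    ids <- sprintf("1:%d-%d", 1:n_circ * 10, 1:n_circ * 10 + 5)
    samples <- toy_samples(c("leaf", "flower"), n_reps = 4)
    norm <- tidyr::expand_grid(circ_id = ids,
                               sample_id = samples$sample_id) |>
      dplyr::mutate(value = rlnorm(dplyr::n(), 3, 1))
    ab <- pairwise_diff(norm, samples, "leaf", "flower")
    ba <- pairwise_diff(norm, samples, "flower", "leaf")
    expect_equal(ab$log2_fc, -ba$log2_fc)
    expect_equal(ab$p_value, ba$p_value)
    expect_equal(ab$significant, ba$significant)
    # up counts mirror down counts
    ca <- count_diff_by_pair(ab); cb <- count_diff_by_pair(ba)
    expect_equal(ca$n_up, cb$n_down)
    expect_equal(ca$n_down, cb$n_up)
  }
})

test_that("per-pair counts recover a planted direction split", {
  # 16 circRNAs four-fold up in root, 5 down, 9 null
  ids <- sprintf("2:%d-%d", 1:30 * 100, 1:30 * 100 + 50)
  samples <- toy_samples(c("root", "seedling"), n_reps = 4)
  set.seed(77)
  norm <- tidyr::expand_grid(circ_id = ids, sample_id = samples$sample_id) |>
    dplyr::left_join(samples, by = "sample_id") |>
    dplyr::mutate(base = dplyr::case_when(
      circ_id %in% ids[1:16] & organ == "root" ~ 400,
      circ_id %in% ids[17:21] & organ == "seedling" ~ 400,
      TRUE ~ 100),
      value = base * rlnorm(dplyr::n(), 0, 0.1)) |>
    dplyr::select(circ_id, sample_id, value)
  res <- pairwise_diff(norm, samples, "root", "seedling")
  counts <- count_diff_by_pair(res)
  expect_equal(counts$n_up, 16L)
  expect_equal(counts$n_down, 5L)
  expect_setequal(organ_specific_calls(res)$circ_id[
    organ_specific_calls(res)$organ == "root"], ids[1:16])
})

test_that("abundance classes follow the 5% / 80th-percentile partition", {
  # 20 equally spaced values: 1 high, 3 medium, 16 low
  means <- tibble::tibble(circ_id = sprintf("1:%d-%d", 1:20 * 10, 1:20 * 10 + 5),
                          organ = "root", mean = as.numeric(1:20))
  cls <- classify_abundance(means)
  tab <- table(cls$class)
  expect_equal(as.integer(tab[c("high", "medium", "low", "not_detected")]),
               c(1L, 3L, 16L, 0L))
  expect_equal(as.character(cls$class[which.max(means$mean)]), "high")

  # identical values: deterministic ceil(0.05 n) high via id tie-break
  means2 <- means; means2$mean <- 7
  cls2 <- classify_abundance(means2)
  expect_equal(sum(cls2$class == "high"), 1L)
  expect_equal(as.character(cls2$class[order(cls2$circ_id)][1]), "high")
  expect_identical(cls2, classify_abundance(means2))

  # absence in one organ is not_detected there regardless of others
  means3 <- dplyr::bind_rows(means,
                             tibble::tibble(circ_id = "1:10-15",
                                            organ = "leaf", mean = 50))
  cls3 <- classify_abundance(means3)
  expect_equal(as.character(cls3$class[cls3$organ == "leaf" &
                                         cls3$circ_id == "1:20-25"]),
               "not_detected")
})

test_that("class partition counts hold over random abundance profiles", {
  set.seed(55)
  for (i in 1:50) {
    n <- sample(5:200, 1)
    n_zero <- sample(0:min(5, n - 1), 1)
    vals <- c(rlnorm(n - n_zero, 2, 1.5), rep(0, n_zero))
    means <- tibble::tibble(
      circ_id = sprintf("1:%d-%d", seq_len(n) * 10, seq_len(n) * 10 + 5),
      organ = "x", mean = sample(vals))
    cls <- classify_abundance(means)
    n_det <- n - n_zero
    expect_equal(sum(cls$class %in% c("high", "medium", "low")), n_det)
    expect_equal(sum(cls$class == "high"), ceiling(0.05 * n_det))
    expect_equal(sum(cls$class == "not_detected"), n_zero)
  }
})

test_that("clustered row order is a permutation with expected structure", {
  # identical rows end up adjacent
  m <- rbind(c(5, 5, 50), c(80, 2, 1), c(5, 5, 50), c(79, 2, 2))
  rownames(m) <- sprintf("1:%d-%d", 1:4 * 10, 1:4 * 10 + 5)
  ord <- cluster_order(m)
  expect_setequal(ord, rownames(m))
  pos <- match(rownames(m)[c(1, 3)], ord)
  expect_equal(abs(diff(pos)), 1)

  # two well-separated blocks stay contiguous
  set.seed(3)
  blocks <- rbind(matrix(rlnorm(15, log(1000), 0.1), 5, 3),
                  matrix(rlnorm(15, log(2), 0.1), 5, 3))
  rownames(blocks) <- sprintf("2:%d-%d", 1:10 * 10, 1:10 * 10 + 5)
  ordb <- cluster_order(blocks)
  top <- match(rownames(blocks)[1:5], ordb)
  expect_true(max(top) - min(top) == 4)

  expect_error(cluster_order(blocks[1, , drop = FALSE]), "at least 2")
})

test_that("average-linkage agglomeration matches a brute-force oracle", {
  set.seed(19)
  m <- matrix(rlnorm(18, 3, 1.2), 6, 3)
  rownames(m) <- sprintf("1:%d-%d", 1:6 * 10, 1:6 * 10 + 5)
  lm <- log2(m + 1)
  hc <- hclust(dist(lm), method = "average")
  expect_identical(hclust_merge_sets(hc), bf_average_linkage(lm))
  # and the package's ordering is consistent with that tree
  expect_equal(cluster_order(m), rownames(m)[hc$order])
})

test_that("circular/linear comparison computes ratios, flags and correlations", {
  organs <- c("seedling", "root", "leaf")
  circ <- tidyr::expand_grid(circ_id = c("1:1-10", "2:1-10", "3:1-10"),
                             organ = organs) |>
    dplyr::mutate(mean = c(10, 20, 30, 3, 0, 0, 5, 6, 7),
                  method = "library_size_excl")
  mapping <- tibble::tibble(circ_id = c("1:1-10", "2:1-10", "3:1-10"),
                            gene_id = c("AT1G00001", "AT2G00002", NA))
  # linear = circ exactly for gene 1; gene 2 mostly higher; gene 3 intergenic
  linear <- tidyr::expand_grid(gene_id = c("AT1G00001", "AT2G00002"),
                               organ = organs) |>
    dplyr::mutate(value = c(10, 20, 30, 1, 10, 10),
                  method = "library_size_excl")
  res <- circ_linear_analysis(circ, linear, mapping)
  pairs <- tidy(res)
  # ratio defined only where linear > 0
  expect_true(all(is.na(pairs$ratio[is.na(pairs$gene_id)])))
  expect_equal(pairs$ratio[pairs$circ_id == "1:1-10" &
                             pairs$organ == "seedling"], 1)
  # enrichment: circ 3 vs linear 1 in seedling -> 3 >= 1.5 * 1
  expect_true(all(pairs$enriched[pairs$circ_id == "2:1-10"]))
  expect_false(any(pairs$enriched[pairs$circ_id == "1:1-10"]))
  expect_equal(res$n_intergenic, 1L)

  # identical profiles give r = 1
  ident <- circ_linear_analysis(
    dplyr::filter(circ, circ_id == "1:1-10"),
    dplyr::filter(linear, gene_id == "AT1G00001"),
    mapping[1, ])
  expect_equal(ident$correlations$r[ident$correlations$stratum == "all"], 1)

  # mismatched normalization tags refuse to compare
  bad <- dplyr::mutate(linear, method = "library_size")
  expect_error(circ_linear_analysis(circ, bad, mapping), "same")
})
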