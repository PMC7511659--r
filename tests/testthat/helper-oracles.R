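# Independent brute-force oracles and tiny fixture builders used across the
# suite. These deliberately avoid the package's own code paths.

# Pearson r via the raw sum formula
bf_pearson <- function(x, y) {
  n <- length(x)
  num <- n * sum(x * y) - sum(x) * sum(y)
  den <- sqrt((n * sum(x^2) - sum(x)^2) * (n * sum(y^2) - sum(y)^2))
  num / den
}

# median-of-ratios size factors by direct enumeration
bf_size_factors <- function(m) {
  g <- apply(m, 1, function(r) if (any(r == 0)) 0 else exp(mean(log(r))))
  keep <- g > 0
  if (!any(keep)) stop("no eligible rows")
  apply(m[keep, , drop = FALSE], 2, function(col) median(col / g[keep]))
}

# exclusive Venn region counts by direct membership enumeration
bf_venn_regions <- function(sets) {
  universe <- unique(unlist(sets))
  pat <- vapply(universe, function(el) {
    paste(names(sets)[vapply(sets, function(s) el %in% s, logical(1))],
          collapse = "&")
  }, character(1))
  table(pat)
}

# naive average-linkage (UPGMA on raw pairwise distances) agglomeration:
# returns the sequence of merged member sets, each sorted
bf_average_linkage <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  merges <- list()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          dd <- mean(d[clusters[[i]], clusters[[j]]])
          if (dd < best_d) { best_d <- dd; best <- c(i, j) }
        }
      }
    }
    merged <- sort(c(clusters[[best[1]]], clusters[[best[2]]]))
    merges[[length(merges) + 1L]] <- merged
    clusters[[best[1]]] <- merged
    clusters[[best[2]]] <- NULL
  }
  merges
}

# merged member sets from an hclust merge matrix, in merge order
hclust_merge_sets <- function(hc) {
  sets <- list()
  for (k in seq_len(nrow(hc$merge))) {
    members <- function(v) {
      if (v < 0) -v else sets[[v]]
    }
    sets[[k]] <- sort(c(members(hc$merge[k, 1]), members(hc$merge[k, 2])))
  }
  sets
}

# small long-format count table: matrix in, tibble out
toy_counts <- function(m, samples = NULL) {
  if (is.null(rownames(m))) {
    rownames(m) <- sprintf("1:%d-%d", seq_len(nrow(m)) * 100,
                           seq_len(nrow(m)) * 100 + 50)
  }
  if (is.null(colnames(m))) colnames(m) <- paste0("s", seq_len(ncol(m)))
  tibble::as_tibble(as.data.frame.table(m, stringsAsFactors = FALSE)) |>
    stats::setNames(c("circ_id", "sample_id", "count")) |>
    dplyr::mutate(count = as.integer(count))
}

toy_samples <- function(organs, n_reps = 4, protocol = "R-") {
  tidyr::expand_grid(organ = organs, replicate = seq_len(n_reps)) |>
    dplyr::mutate(sample_id = sprintf("%s_rep%d", organ, replicate),
                  protocol = protocol)
}

toy_stats <- function(sample_id, total = 1e6, rrna = 0, chloro = 0,
                      marker = 1000, bs = 500, bsx = NULL) {
  n <- length(sample_id)
  tibble::tibble(sample_id = sample_id,
                 total_reads = rep_len(total, n),
                 rrna_reads = rep_len(rrna, n),
                 chloroplast_reads = rep_len(chloro, n),
                 marker_reads = rep_len(marker, n),
                 backspliced_total = rep_len(bs, n),
                 backspliced_excl = rep_len(if (is.null(bsx)) bs else bsx, n))
}
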