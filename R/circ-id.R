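#' Parse circRNA identifiers of the form "chrom:start-end"
#'
#' CircRNA candidates are identified by the genomic interval between their
#' back-splice acceptor and donor, written `chrom:start-end` with 1-based,
#' fully closed coordinates (e.g. `"5:1106879-1107381"`). Nuclear chromosomes
#' are `"1"`..`"5"`; organellar candidates carry the organelle name as the
#' chromosome.
#'
#' @param x Character vector of identifiers.
#' @param strand Optional strand for each id, one of `"+"`, `"-"`,
#'   `"unknown"`. Strand is carried through the workflow but never used in
#'   any computation (back-splice quantification is strand-agnostic).
#'
#' @return A tibble with columns `circ_id`, `chrom`, `start`, `end`,
#'   `strand`. `format_circ_id()` is its inverse on the coordinate columns.
#' @examples
#' parse_circ_id("5:1106879-1107381")
#' @export
parse_circ_id <- function(x, strand = "unknown") {
  stopifnot(is.character(x), length(x) >= 1L)
  m <- regmatches(x, regexec("^([^:]+):([0-9]+)-([0-9]+)$", x))
  bad <- vapply(m, length, integer(1)) != 4L
  if (any(bad)) {
    abort(paste0("malformed circRNA id: '", x[bad][1L],
                 "' (expected \"chrom:start-end\")"))
  }
  chrom <- vapply(m, `[`, character(1), 2L)
  start <- as.numeric(vapply(m, `[`, character(1), 3L))
  end <- as.numeric(vapply(m, `[`, character(1), 4L))
  if (any(start > end)) {
    i <- which(start > end)[1L]
    abort(paste0("invalid interval in '", x[i], "': start ", start[i],
                 " > end ", end[i]))
  }
  strand <- rep_len(strand, length(x))
  if (!all(strand %in% c("+", "-", "unknown"))) {
    abort("strand must be one of '+', '-', 'unknown'")
  }
  tibble(circ_id = x, chrom = chrom, start = start, end = end,
         strand = strand)
}

#' @param chrom,start,end Coordinate vectors (1-based, closed interval).
#' @rdname parse_circ_id
#' @export
format_circ_id <- function(chrom, start, end) {
  stopifnot(all(start <= end))
  paste0(chrom, ":", format(start, scientific = FALSE, trim = TRUE),
         "-", format(end, scientific = FALSE, trim = TRUE))
}

#' Default organelle chromosome names
#'
#' Chloroplast-derived circRNAs are recognised by chromosome-name membership
#' in this set; extend it for other assemblies.
#' @return Character vector of chromosome names treated as organellar.
#' @export
organelle_chroms <- function() c("chloroplast", "Pt", "ChrC")

#' Classify circRNA ids as nuclear or organellar
#'
#' @param circ_id Character vector of `chrom:start-end` ids.
#' @param organelles Chromosome names counted as organellar.
#' @return Logical vector, `TRUE` for chloroplast/organellar ids.
#' @export
is_organelle <- function(circ_id, organelles = organelle_chroms()) {
  parse_circ_id(circ_id)$chrom %in% organelles
}
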