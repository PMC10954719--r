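#' @importFrom rlang %||% .data
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   left_join bind_rows n desc across
#' @importFrom stats rnbinom rpois rbinom runif rgeom predict quantile median
#'   p.adjust sd var pt
#' @importFrom utils head tail
NULL

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

# Derive a reproducible 32-bit substream seed from a global seed and a
# stage label, so pipeline stages can be rerun in isolation.
stage_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((abs(seed) * 7919 + h * 104729 + 17) %% 2147483647)
}

# run code under a temporary RNG seed without touching the caller's stream
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# reverse complement in DNA space (T alphabet)
revcomp_dna <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# extract a genomic window as transcript-oriented RNA (U alphabet);
# genome is a named character vector of DNA sequences, 0-based half-open
# coordinates
extract_rna <- function(genome, chrom, start, end, strand) {
  stopifnot(chrom %in% names(genome), start >= 0)
  chrom_seq <- genome[[chrom]]
  stopifnot(end <= nchar(chrom_seq))
  s <- substr(chrom_seq, start + 1, end)
  if (strand == "-") s <- revcomp_dna(s)
  chartr("T", "U", s)
}

# empty BED6 tibble
empty_bed6 <- function() {
  tibble::tibble(chrom = character(), start = integer(), end = integer(),
                 name = character(), score = numeric(), strand = character())
}

assert_bed6 <- function(x) {
  need <- c("chrom", "start", "end", "name", "score", "strand")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("BED6 table is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(x) && !all(x$strand %in% c("+", "-")))
    stop("BED6 strand must be '+' or '-'", call. = FALSE)
  invisible(x)
}
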