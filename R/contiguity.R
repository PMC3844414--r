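# Contiguity statistics: N(x), NG(x), NG graphs, cumulative length plots and
# the gene-sized scaffold metric. All operate on plain numeric length sets so
# they apply equally to scaffolds, contigs or alignment lengths.

as_lengths <- function(lengths) {
  if (is.data.frame(lengths)) lengths <- lengths$length
  lengths <- as.numeric(lengths)
  if (any(is.na(lengths)) || any(lengths <= 0)) {
    abort("lengths must be positive and non-missing")
  }
  sort(lengths, decreasing = TRUE)
}

#' N(x) length of a length set
#'
#' Sums sequence lengths longest-first and returns the length of the first
#' sequence at which the cumulative sum reaches `x`% of the total. Ties are
#' inclusive: a cumulative sum exactly at the threshold qualifies.
#'
#' @param lengths Numeric vector of sequence lengths (any order), or a data
#'   frame with a `length` column.
#' @param x Percentage threshold in (0, 100]; 50 gives the classic N50.
#' @return The N(x) length in bases.
#' @examples
#' nx(c(8, 5, 4, 3), 50)  # 5: cumulative 8 (40%), 13 (65%)
#' @export
nx <- function(lengths, x = 50) {
  stopifnot(x > 0, x <= 100)
  ls <- as_lengths(lengths)
  if (length(ls) == 0) abort("empty length set")
  ls[which(cumsum(ls) >= x / 100 * sum(ls))[1]]
}

#' NG(x) length of a length set against a genome size
#'
#' As [nx()], but the threshold is `x`% of the estimated genome size rather
#' than of the total assembly size. Returns 0 when the assembly never
#' reaches the threshold (the NG graph "touches the x-axis").
#'
#' @inheritParams nx
#' @param genome_size Estimated genome size in bases.
#' @return The NG(x) length in bases (0 if unreached).
#' @examples
#' ngx(c(8, 5, 4, 3), 50, genome_size = 30)  # 4: need 15; cumulative 8, 13, 17
#' @export
ngx <- function(lengths, x = 50, genome_size) {
  stopifnot(x > 0, x <= 100, genome_size > 0)
  ls <- as_lengths(lengths)
  if (length(ls) == 0) return(0)
  i <- which(cumsum(ls) >= x / 100 * genome_size)[1]
  if (is.na(i)) 0 else ls[i]
}

#' NG graph series
#'
#' NG(x) at every integer threshold x = 1..100, the series plotted in NG
#' graphs. The first point equals the longest sequence whenever that
#' sequence is at least 1% of the genome size, and trailing points are 0
#' when the assembly is smaller than the genome.
#'
#' @inheritParams ngx
#' @param label Optional series label carried into the output.
#' @return Tibble with columns `label`, `x`, `ng_length`.
#' @export
ng_graph <- function(lengths, genome_size, label = "assembly") {
  stopifnot(genome_size > 0)
  ls <- as_lengths(lengths)
  cum <- cumsum(ls)
  ng <- vapply(1:100, function(x) {
    i <- which(cum >= x / 100 * genome_size)[1]
    if (is.na(i)) 0 else ls[i]
  }, numeric(1))
  tibble(label = label, x = 1:100, ng_length = ng)
}

#' Gene-sized scaffold content
#'
#' Total length in sequences at least `threshold` bases long (25 Kbp, the
#' length of an average vertebrate gene, by default), together with the
#' ranking key metric: the absolute difference between that amount and the
#' expected genome size (lower is better).
#'
#' @inheritParams ngx
#' @param threshold Minimum sequence length in bases.
#' @return One-row tibble with `amount`, `pct_genome`, `key_metric`.
#' @export
gene_sized_amount <- function(lengths, genome_size,
                              threshold = asmqc_defaults$gene_size) {
  stopifnot(threshold > 0, genome_size > 0)
  if (is.data.frame(lengths)) lengths <- lengths$length
  amount <- sum(lengths[lengths >= threshold])
  tibble(amount = amount,
         pct_genome = 100 * amount / genome_size,
         key_metric = abs(amount - genome_size))
}

#' Cumulative length series
#'
#' The series behind cumulative length plots: lengths sorted longest-first
#' with their running total.
#'
#' @inheritParams nx
#' @param label Optional series label carried into the output.
#' @return Tibble with columns `label`, `rank`, `length`, `cumulative`.
#' @export
cumulative_length_series <- function(lengths, label = "assembly") {
  if (is.data.frame(lengths)) lengths <- lengths$length
  if (length(lengths) == 0) {
    return(tibble(label = character(), rank = integer(),
                  length = numeric(), cumulative = numeric()))
  }
  ls <- as_lengths(lengths)
  tibble(label = label, rank = seq_along(ls), length = ls, cumulative = cumsum(ls))
}
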