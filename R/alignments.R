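# Alignment ingestion. Scaffold-to-reference local alignments are held as a
# tibble with 0-based half-open intervals on both coordinate systems:
#   scaffold_id, scaffold_len, s_start, s_end, ref_id, r_start, r_end,
#   strand, identity (percent, NA when unknown), length (reference bases).
# Reference intervals are always forward-strand; `strand` records the
# orientation of the scaffold relative to the reference.

aln_columns <- c("scaffold_id", "scaffold_len", "s_start", "s_end",
                 "ref_id", "r_start", "r_end", "strand", "identity", "length")

#' Build an alignment table
#'
#' Constructor/validator for the alignment tibble used by the coverage and
#' validation metrics. Intervals are 0-based half-open; `length` (reference
#' bases spanned) is derived.
#'
#' @param scaffold_id,ref_id Sequence identifiers.
#' @param s_start,s_end Query interval on the scaffold.
#' @param r_start,r_end Interval on the reference (forward strand).
#' @param strand `"+"` or `"-"`.
#' @param identity Percent identity in `[0, 100]`, `NA` when unknown.
#' @param scaffold_len Full scaffold length, used by length filters.
#' @return Alignment tibble.
#' @export
alignments <- function(scaffold_id, ref_id, r_start, r_end,
                       s_start = 0L, s_end = r_end - r_start,
                       strand = "+", identity = NA_real_,
                       scaffold_len = NA_integer_) {
  out <- tibble(
    scaffold_id = as.character(scaffold_id),
    scaffold_len = as.integer(scaffold_len),
    s_start = as.integer(s_start), s_end = as.integer(s_end),
    ref_id = as.character(ref_id),
    r_start = as.integer(r_start), r_end = as.integer(r_end),
    strand = strand, identity = as.numeric(identity)
  )
  if (any(out$r_end <= out$r_start) || any(out$s_end <= out$s_start)) {
    abort("alignment intervals must have positive length")
  }
  if (any(!is.na(out$identity) & (out$identity < 0 | out$identity > 100))) {
    abort("identity must be within [0, 100]")
  }
  if (!all(out$strand %in% c("+", "-"))) abort("strand must be '+' or '-'")
  out$length <- out$r_end - out$r_start
  out[aln_columns]
}

empty_alignments <- function() {
  alignments(character(), character(), integer(), integer())[0, ]
}

#' Read scaffold-to-reference alignments
#'
#' Reads local alignments from SAM or PAF into the package's alignment
#' tibble. Unmapped SAM records are skipped; coordinates are normalised to
#' 0-based half-open with reference intervals on the forward strand. SAM
#' identity is `(aligned bases - NM) / aligned bases` when the NM tag is
#' present, otherwise `NA`; PAF identity is `matches / alignment length`.
#'
#' @param path Path to the alignment file.
#' @param format `"sam"` or `"paf"` (default guessed from the extension).
#' @return Alignment tibble (see [alignments()]).
#' @export
read_alignments <- function(path, format = c("auto", "sam", "paf")) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.sam$", path, ignore.case = TRUE)) "sam" else "paf"
  }
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  switch(format, sam = read_sam_alignments(path), paf = read_paf_alignments(path))
}

read_sam_alignments <- function(path) {
  bam <- Rsamtools::asBam(path, tempfile(), overwrite = TRUE,
                          indexDestination = FALSE)
  on.exit(unlink(bam), add = TRUE)
  param <- Rsamtools::ScanBamParam(
    what = c("qname", "flag"), tag = "NM",
    flag = Rsamtools::scanBamFlag(isUnmappedQuery = FALSE)
  )
  ga <- GenomicAlignments::readGAlignments(bam, param = param, use.names = FALSE)
  if (length(ga) == 0) return(empty_alignments())
  cig <- GenomicAlignments::cigar(ga)
  ops <- GenomicAlignments::cigarOpTable(cig)
  aligned <- ops[, "M"] + ops[, "="] + ops[, "X"]
  nm <- S4Vectors::mcols(ga)$NM
  identity <- ifelse(is.na(nm), NA_real_, 100 * (aligned - nm) / aligned)
  qlen <- GenomicAlignments::cigarWidthAlongQuerySpace(cig,
                                                       after.soft.clipping = FALSE)
  left_clip <- as.integer(sub("^([0-9]+)S.*", "\\1",
                              ifelse(grepl("^[0-9]+S", cig), cig, "0S")))
  right_clip <- as.integer(sub(".*[^0-9]([0-9]+)S$", "\\1",
                               ifelse(grepl("[0-9]+S$", cig), cig, "x0S")))
  qwidth <- GenomicAlignments::cigarWidthAlongQuerySpace(cig,
                                                         after.soft.clipping = TRUE)
  minus <- as.logical(S4Vectors::decode(GenomicAlignments::strand(ga)) == "-")
  # aligned query interval in read orientation, then flipped for minus strand
  qs <- left_clip
  qe <- left_clip + qwidth
  s_start <- ifelse(minus, qlen - qe, qs)
  s_end <- ifelse(minus, qlen - qs, qe)
  alignments(
    scaffold_id = S4Vectors::mcols(ga)$qname,
    scaffold_len = qlen,
    s_start = s_start, s_end = s_end,
    ref_id = as.character(S4Vectors::decode(GenomicAlignments::seqnames(ga))),
    r_start = GenomicAlignments::start(ga) - 1L,
    r_end = GenomicAlignments::end(ga),
    strand = ifelse(minus, "-", "+"),
    identity = identity
  )
}

read_paf_alignments <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) return(empty_alignments())
  fields <- stringr::str_split(lines, "\t")
  bad <- which(vapply(fields, length, integer(1)) < 12)
  if (length(bad) > 0) {
    abort(sprintf("malformed PAF record at line %d (fewer than 12 fields)", bad[1]))
  }
  m <- t(vapply(fields, function(f) f[1:12], character(12)))
  num <- suppressWarnings(apply(m[, c(2:4, 7:11), drop = FALSE], 2, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (any(is.na(num))) {
    abort(sprintf("malformed PAF record at line %d (non-numeric coordinate)",
                  which(rowSums(is.na(num)) > 0)[1]))
  }
  alnlen <- num[, 8]
  matches <- num[, 7]
  alignments(
    scaffold_id = m[, 1], scaffold_len = num[, 1],
    s_start = num[, 2], s_end = num[, 3],
    ref_id = m[, 6], r_start = num[, 5], r_end = num[, 6],
    strand = m[, 5],
    identity = ifelse(alnlen > 0, 100 * matches / alnlen, NA_real_)
  )
}

#' Read BLAST tabular (outfmt 6) tag matches
#'
#' Ingests `blastn -outfmt 6` output (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore) as tag-to-scaffold
#' matches for the tag-pair analysis, keeping hits with at least
#' `min_aligned` aligned bases.
#'
#' @param path Path to the tabular file.
#' @param min_aligned Minimum aligned length per hit (default 95).
#' @return Tibble with `tag_id`, `scaffold_id`, `position` (0-based scaffold
#'   coordinate of the tag start), `strand`, `aligned`, `identity`.
#' @export
read_blast_tags <- function(path, min_aligned = asmqc_defaults$tag_min_aligned) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  tb <- readr::read_tsv(path, col_names = cols, show_col_types = FALSE)
  tb |>
    filter(.data$length >= min_aligned) |>
    mutate(
      strand = ifelse(.data$send >= .data$sstart, "+", "-"),
      # 0-based position of the tag's first base on the scaffold forward strand
      position = as.integer(
        ifelse(.data$send >= .data$sstart,
               .data$sstart - .data$qstart,
               .data$send - .data$qstart)
      )
    ) |>
    select(tag_id = "qseqid", scaffold_id = "sseqid", "position",
           "strand", aligned = "length", identity = "pident")
}

#' Filter alignments by identity and length thresholds
#'
#' Applies the benchmark's alignment stringency: minimum percent identity
#' (alignments with unknown identity are dropped whenever the identity
#' threshold is positive), minimum scaffold length, and minimum alignment
#' length on the reference.
#'
#' @param alns Alignment tibble.
#' @param min_identity Minimum percent identity (default 98).
#' @param min_scaffold_len Minimum scaffold length (default 200).
#' @param min_aln_len Minimum alignment length in reference bases.
#' @return Filtered alignment tibble.
#' @export
filter_alignments <- function(alns,
                              min_identity = asmqc_defaults$min_identity,
                              min_scaffold_len = asmqc_defaults$min_scaffold_len,
                              min_aln_len = 0) {
  stopifnot(min_identity >= 0, min_scaffold_len >= 0, min_aln_len >= 0)
  keep <- alns$length >= min_aln_len
  if (min_scaffold_len > 0) {
    keep <- keep & !is.na(alns$scaffold_len) & alns$scaffold_len >= min_scaffold_len
  }
  if (min_identity > 0) {
    keep <- keep & !is.na(alns$identity) & alns$identity >= min_identity
  }
  alns[keep, , drop = FALSE]
}
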