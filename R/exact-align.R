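# Bundled naive aligner for synthetic data.
#
# A seed-and-extend exact matcher: non-overlapping k-mer seeds from each
# query contig are located in the reference (Aho-Corasick via
# Biostrings::matchPDict), then extended maximally in both directions while
# bases match exactly. On synthetic assemblies whose pieces are exact
# substrings of the generated genome this recovers the provenance
# alignments precisely, which is what makes the analytic ground-truth
# predictions checkable. It is an oracle for synthetic data only, not a
# general-purpose aligner.

#' Exact seed-and-extend alignment of an assembly to a reference
#'
#' Finds all maximal exact matches of at least `min_len` bases between the
#' contigs of `asm` (scaffolds split at N-runs of `gap_min` or more) and
#' the reference sequences, on both strands.
#'
#' @param asm Query `asmqc_assembly` (or tibble with `id`, `seq`).
#' @param ref Reference `asmqc_assembly` (or tibble with `id`, `seq`).
#' @param seed_len Seed k-mer length; alignments shorter than
#'   `2 * seed_len - 1` may be missed.
#' @param min_len Minimum reported alignment length.
#' @param gap_min N-run length splitting scaffolds into contigs.
#' @return Alignment tibble (see [alignments()]) with scaffold-orientation
#'   query intervals and 100% identity.
#' @export
align_exact <- function(asm, ref, seed_len = 16L, min_len = 50L,
                        gap_min = asmqc_defaults$gap_min) {
  contigs <- split_scaffolds(asm, gap_min = gap_min)
  if (nrow(contigs) == 0) return(empty_alignments())
  scaffold_len <- setNames(asm$length, asm$id)
  ref_raw <- lapply(setNames(ref$seq, ref$id), charToRaw)
  ref_dna <- lapply(setNames(ref$seq, ref$id), Biostrings::DNAString)

  hits <- list()
  for (ci in seq_len(nrow(contigs))) {
    cseq <- contigs$seq[ci]
    for (str in c("+", "-")) {
      qseq <- if (str == "+") cseq else revcomp(cseq)
      h <- align_one_query(qseq, ref_raw, ref_dna, seed_len, min_len)
      if (is.null(h) || nrow(h) == 0) next
      clen <- nchar(cseq)
      # map query coordinates back to the forward-strand scaffold
      if (str == "-") {
        tmp <- h$q_start
        h$q_start <- clen - h$q_end
        h$q_end <- clen - tmp
      }
      h$q_start <- h$q_start + contigs$start[ci]
      h$q_end <- h$q_end + contigs$start[ci]
      h$scaffold_id <- contigs$scaffold_id[ci]
      h$strand <- str
      hits[[length(hits) + 1L]] <- h
    }
  }
  if (length(hits) == 0) return(empty_alignments())
  h <- bind_rows(hits) |>
    distinct(.data$scaffold_id, .data$ref_id, .data$strand,
             .data$q_start, .data$r_start, .data$r_end)
  alignments(
    scaffold_id = h$scaffold_id,
    scaffold_len = scaffold_len[h$scaffold_id],
    s_start = h$q_start, s_end = h$q_start + (h$r_end - h$r_start),
    ref_id = h$ref_id, r_start = h$r_start, r_end = h$r_end,
    strand = h$strand, identity = 100
  )
}

# Maximal exact extensions of seed hits of one oriented query against all
# reference sequences. Coordinates are 0-based half-open.
align_one_query <- function(qseq, ref_raw, ref_dna, seed_len, min_len) {
  qlen <- nchar(qseq)
  if (qlen < seed_len) return(NULL)
  offs <- seq.int(0L, qlen - seed_len, by = seed_len)
  seeds <- stringr::str_sub(qseq, offs + 1L, offs + seed_len)
  ok <- !stringr::str_detect(seeds, "[^ACGT]")
  offs <- offs[ok]; seeds <- seeds[ok]
  if (length(seeds) == 0) return(NULL)
  pd <- Biostrings::PDict(Biostrings::DNAStringSet(seeds))
  qr <- charToRaw(qseq)

  out <- list()
  for (rid in names(ref_dna)) {
    mi <- Biostrings::matchPDict(pd, ref_dna[[rid]])
    starts <- Biostrings::startIndex(mi)
    n_hits <- lengths(starts)
    if (sum(n_hits) == 0) next
    q0 <- rep.int(offs, n_hits)
    r0 <- unlist(starts, use.names = FALSE) - 1L
    # process per diagonal so seeds inside an already-extended alignment
    # are skipped
    o <- order(r0 - q0, q0)
    q0 <- q0[o]; r0 <- r0[o]
    diag <- r0 - q0
    rr <- ref_raw[[rid]]
    rlen <- length(rr)
    prev_diag <- NA_integer_; prev_end <- -1L
    for (k in seq_along(q0)) {
      if (!is.na(prev_diag) && diag[k] == prev_diag && q0[k] < prev_end) next
      ext <- extend_exact(qr, rr, q0[k], r0[k], seed_len, qlen, rlen)
      prev_diag <- diag[k]; prev_end <- ext$q_end
      if (ext$q_end - ext$q_start >= min_len) {
        out[[length(out) + 1L]] <- tibble(
          ref_id = rid, q_start = ext$q_start, q_end = ext$q_end,
          r_start = ext$r_start, r_end = ext$r_start + (ext$q_end - ext$q_start)
        )
      }
    }
  }
  if (length(out) == 0) NULL else bind_rows(out)
}

# Longest common extension around a seed match; raw-vector comparison.
extend_exact <- function(qr, rr, q0, r0, seed_len, qlen, rlen) {
  w <- min(q0, r0)
  ext_left <- 0L
  if (w > 0) {
    a <- qr[q0:(q0 - w + 1L)]
    b <- rr[r0:(r0 - w + 1L)]
    neq <- which(a != b)
    ext_left <- if (length(neq) == 0) w else neq[1] - 1L
  }
  qe <- q0 + seed_len; re <- r0 + seed_len    # 0-based exclusive seed ends
  w2 <- min(qlen - qe, rlen - re)
  ext_right <- 0L
  if (w2 > 0) {
    a <- qr[(qe + 1L):(qe + w2)]
    b <- rr[(re + 1L):(re + w2)]
    neq <- which(a != b)
    ext_right <- if (length(neq) == 0) w2 else neq[1] - 1L
  }
  list(q_start = q0 - ext_left, q_end = qe + ext_right,
       r_start = r0 - ext_left)
}

revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}
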