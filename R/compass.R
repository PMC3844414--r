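# Alignment-based validation metrics over four length sets: scaffold
# lengths (S), reference lengths (R), alignment lengths on the reference
# (A) and coverage-island lengths (C). The four ratios are
#   coverage     = sum(C) / sum(R)
#   validity     = sum(A) / sum(S)
#   multiplicity = sum(A) / sum(C)
#   parsimony    = sum(S) / sum(C)  ( = multiplicity / validity )

#' Coverage islands
#'
#' Merges alignment footprints on each reference sequence into maximal
#' disjoint intervals of continuous coverage ("coverage islands").
#' Overlapping and abutting footprints merge.
#'
#' @param alns Alignment tibble (see [alignments()]).
#' @return Tibble with `ref_id`, `start`, `end`, `length`, one row per island.
#' @examples
#' a <- alignments(c("s1", "s2"), "ref", r_start = c(0, 40), r_end = c(50, 90))
#' coverage_islands(a)
#' @export
coverage_islands <- function(alns) {
  if (nrow(alns) == 0) {
    return(tibble(ref_id = character(), start = integer(),
                  end = integer(), length = integer()))
  }
  alns |>
    group_by(.data$ref_id) |>
    dplyr::reframe({
      merged <- IRanges::reduce(IRanges::IRanges(start = .data$r_start + 1L,
                                                 end = .data$r_end))
      tibble(start = IRanges::start(merged) - 1L, end = IRanges::end(merged))
    }) |>
    mutate(length = .data$end - .data$start) |>
    arrange(.data$ref_id, .data$start)
}

#' Coverage, validity, multiplicity and parsimony of an assembly
#'
#' Computes the four alignment-based validation metrics from the scaffold
#' length set, the reference length set and a set of scaffold-to-reference
#' alignments. Alignment lengths are measured in reference coordinates and
#' summed as-is (overlaps are not de-overlapped), so multiplicity above 1
#' indicates repeat expansion or spurious duplication and below 1 repeat
#' collapse.
#'
#' @param asm_lengths Scaffold lengths: numeric vector, or an
#'   `asmqc_assembly`/data frame with a `length` column.
#' @param ref_lengths Reference lengths, same conventions.
#' @param alns Alignment tibble; every `ref_id`/`scaffold_id` must appear in
#'   the corresponding length set when those are named or tabular.
#' @param label Assembly label for reporting.
#' @return Object of class `compass_result`: sums `sum_s`, `sum_r`, `sum_a`,
#'   `sum_c` and the four ratios. Use [tidy()] for a one-row tibble.
#' @examples
#' a <- alignments(c("s1", "s2"), "ref", r_start = c(0, 0), r_end = c(100, 100),
#'                 scaffold_len = 100)
#' compass(c(s1 = 100, s2 = 100), c(ref = 100), a)
#' @export
compass <- function(asm_lengths, ref_lengths, alns, label = "assembly") {
  asm_ls <- named_lengths(asm_lengths)
  ref_ls <- named_lengths(ref_lengths)
  if (!is.null(names(ref_ls)) && nrow(alns) > 0) {
    unknown <- setdiff(unique(alns$ref_id), names(ref_ls))
    if (length(unknown) > 0) {
      abort(paste0("alignment references unknown reference sequence(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  if (!is.null(names(asm_ls)) && nrow(alns) > 0) {
    unknown <- setdiff(unique(alns$scaffold_id), names(asm_ls))
    if (length(unknown) > 0) {
      abort(paste0("alignment references unknown scaffold(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  islands <- coverage_islands(alns)
  sum_s <- sum(asm_ls); sum_r <- sum(ref_ls)
  sum_a <- sum(alns$length); sum_c <- sum(islands$length)
  structure(list(
    label = label,
    sum_s = sum_s, sum_r = sum_r, sum_a = sum_a, sum_c = sum_c,
    coverage = sum_c / sum_r,
    validity = sum_a / sum_s,
    multiplicity = if (sum_c > 0) sum_a / sum_c else NA_real_,
    parsimony = if (sum_c > 0) sum_s / sum_c else NA_real_,
    islands = islands
  ), class = "compass_result")
}

named_lengths <- function(x) {
  if (is.data.frame(x)) {
    ls <- x$length
    names(ls) <- if ("id" %in% names(x)) x$id else x$scaffold_id
    ls
  } else {
    x
  }
}

#' @export
print.compass_result <- function(x, ...) {
  cat(sprintf(paste0(
    "<compass_result '%s'>\n",
    "  sums: S=%s R=%s A=%s C=%s\n",
    "  coverage=%.4f validity=%.4f multiplicity=%.4f parsimony=%.4f\n"),
    x$label,
    format(x$sum_s, big.mark = ","), format(x$sum_r, big.mark = ","),
    format(x$sum_a, big.mark = ","), format(x$sum_c, big.mark = ","),
    x$coverage, x$validity, x$multiplicity, x$parsimony))
  invisible(x)
}

#' @rdname compass
#' @param x A `compass_result`.
#' @param ... Unused.
#' @method tidy compass_result
#' @export
tidy.compass_result <- function(x, ...) {
  tibble(label = x$label,
         sum_s = x$sum_s, sum_r = x$sum_r, sum_a = x$sum_a, sum_c = x$sum_c,
         coverage = x$coverage, validity = x$validity,
         multiplicity = x$multiplicity, parsimony = x$parsimony)
}

#' @rdname compass
#' @method glance compass_result
#' @export
glance.compass_result <- function(x, ...) {
  tidy(x)[, c("label", "coverage", "validity", "multiplicity", "parsimony")]
}

#' Derive validated regions of trusted reference sequences
#'
#' Given alignments of scaffolds (from any number of assemblies) onto
#' fosmid-like trusted sequences, keeps alignments of at least
#' `min_aln_len` reference bases, unions their footprints per fosmid, and
#' returns each maximal interval as a validated region with its sequence.
#'
#' @param fosmids `asmqc_assembly` (or tibble with `id`, `seq`) of trusted
#'   sequences.
#' @param alns Alignment tibble with the fosmids as references (pool the
#'   alignments of all assemblies before calling).
#' @param min_aln_len Minimum supporting alignment length (default 1000).
#' @return Tibble with `vfr_id` (`"<fosmid_id>:<start>-<end>"`, 0-based
#'   half-open), `fosmid_id`, `start`, `end`, `length`, `seq`.
#' @export
derive_vfrs <- function(fosmids, alns,
                        min_aln_len = asmqc_defaults$vfr_min_aln) {
  qual <- alns[alns$length >= min_aln_len, , drop = FALSE]
  islands <- coverage_islands(qual)
  if (nrow(islands) == 0) {
    return(tibble(vfr_id = character(), fosmid_id = character(),
                  start = integer(), end = integer(),
                  length = integer(), seq = character()))
  }
  islands |>
    rename(fosmid_id = "ref_id") |>
    left_join(tibble(fosmid_id = fosmids$id, fosmid_seq = fosmids$seq),
              by = "fosmid_id") |>
    mutate(
      vfr_id = sprintf("%s:%d-%d", .data$fosmid_id, .data$start, .data$end),
      seq = stringr::str_sub(.data$fosmid_seq, .data$start + 1L, .data$end)
    ) |>
    select("vfr_id", "fosmid_id", "start", "end", "length", "seq")
}

#' Summarise a validated-region set
#'
#' Counts of validated regions, their total length, and the number of
#' non-overlapping fragments of `fragment_len` they yield.
#'
#' @param vfrs Tibble from [derive_vfrs()], or an `asmqc_assembly` read from
#'   a validated-region FASTA file.
#' @param fragment_len Fragment length in nt (default 1000).
#' @return One-row tibble with `n_vfr`, `total_length`, `n_fragments`.
#' @export
vfr_summary <- function(vfrs, fragment_len = asmqc_defaults$fragment_len) {
  lens <- if ("length" %in% names(vfrs)) vfrs$length else nchar(vfrs$seq)
  tibble(n_vfr = nrow(vfrs),
         total_length = sum(lens),
         n_fragments = sum(lens %/% fragment_len))
}

#' Cumulative length series of alignment lengths
#'
#' [cumulative_length_series()] applied to the multiset of alignment
#' lengths (reference bases), the series shown in alignment cumulative
#' length plots.
#'
#' @param alns Alignment tibble.
#' @param label Series label.
#' @return Tibble with `label`, `rank`, `length`, `cumulative`.
#' @export
alignment_clp <- function(alns, label = "assembly") {
  cumulative_length_series(alns$length, label = label)
}
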