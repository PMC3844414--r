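# Short-range accuracy via tag pairs from validated-region fragments.
#
# Each validated region is cut into non-overlapping 1,000 nt fragments; a
# pair of 100 nt tags is taken from the ends of each fragment, mapped
# against an assembly, and the pairs are classified:
#   a) tags matching anywhere          b) tags matching exactly one scaffold
#   c) pairs sharing a scaffold        d) pairs uniquely on the same scaffold
#   e) pairs in d at the expected distance (900 +/- 2 nt, same strand)
# Summary score = c * (e / d), the number of co-locating pairs weighted by
# the fraction of uniquely placed pairs at the correct distance.

#' Fragment validated regions
#'
#' Cuts each validated region into non-overlapping fragments of
#' `fragment_len` nt starting at position 0; a trailing remainder shorter
#' than `fragment_len` is discarded.
#'
#' @param vfrs Tibble with `vfr_id` (or `id`) and `seq` columns, e.g. from
#'   [derive_vfrs()] or a validated-region FASTA via [read_assembly_fasta()].
#' @param fragment_len Fragment length in nt (default 1000).
#' @return Tibble with `vfr_id`, `frag_index` (1-based), `start`, `end`
#'   (0-based half-open within the region) and `seq`.
#' @export
fragment_vfrs <- function(vfrs, fragment_len = asmqc_defaults$fragment_len) {
  ids <- if ("vfr_id" %in% names(vfrs)) vfrs$vfr_id else vfrs$id
  purrr::map2(ids, vfrs$seq, function(id, seq) {
    n <- nchar(seq) %/% fragment_len
    if (n == 0) return(NULL)
    starts <- (seq_len(n) - 1L) * fragment_len
    tibble(vfr_id = id, frag_index = seq_len(n),
           start = starts, end = starts + fragment_len,
           seq = stringr::str_sub(seq, starts + 1L, starts + fragment_len))
  }) |>
    bind_rows()
}

#' Extract tag pairs from fragments
#'
#' Takes a `tag_len` nt tag from each end of every fragment. For the
#' default sizes the expected distance between the start coordinates of the
#' two tags of a pair is 900 nt.
#'
#' @param fragments Tibble from [fragment_vfrs()].
#' @param tag_len Tag length in nt (default 100).
#' @return Tibble with one row per tag: `vfr_id`, `frag_index`, `side`
#'   (`"L"`/`"R"`), `tag_id` (`"<vfr_id>.<frag_index>.<side>"`), `offset`
#'   within the fragment, `expected_distance`, `seq`.
#' @export
extract_tags <- function(fragments, tag_len = asmqc_defaults$tag_len) {
  if (nrow(fragments) == 0) {
    return(tibble(vfr_id = character(), frag_index = integer(),
                  side = character(), tag_id = character(),
                  offset = integer(), expected_distance = integer(),
                  seq = character()))
  }
  frag_len <- unique(nchar(fragments$seq))
  stopifnot(length(frag_len) == 1, frag_len >= 2 * tag_len)
  expected <- frag_len - tag_len
  bind_rows(
    fragments |>
      mutate(side = "L", offset = 0L,
             seq = stringr::str_sub(.data$seq, 1L, tag_len)),
    fragments |>
      mutate(side = "R", offset = as.integer(expected),
             seq = stringr::str_sub(.data$seq, expected + 1L, frag_len))
  ) |>
    mutate(tag_id = paste(.data$vfr_id, .data$frag_index, .data$side, sep = "."),
           expected_distance = as.integer(expected)) |>
    select("vfr_id", "frag_index", "side", "tag_id", "offset",
           "expected_distance", "seq") |>
    arrange(.data$vfr_id, .data$frag_index, .data$side)
}

#' Map tags against an assembly
#'
#' The bundled matching backend: a tag matches a scaffold wherever a
#' full-length, indel-free alignment leaves at least `min_aligned` of its
#' `tag_len` bases identical (i.e. at most `tag_len - min_aligned`
#' mismatches), on either strand. For real data an external aligner's
#' tabular output can be ingested with [read_blast_tags()] instead; both
#' feed [classify_pairs()].
#'
#' @param tags Tibble from [extract_tags()].
#' @param asm Target `asmqc_assembly`.
#' @param min_aligned Minimum matching bases per tag (default 95).
#' @return Tibble with one row per match: `tag_id`, `scaffold_id`,
#'   `position` (0-based scaffold coordinate of the leftmost matched base),
#'   `strand`.
#' @export
map_tags <- function(tags, asm, min_aligned = asmqc_defaults$tag_min_aligned) {
  if (nrow(tags) == 0 || nrow(asm) == 0) {
    return(tibble(tag_id = character(), scaffold_id = character(),
                  position = integer(), strand = character()))
  }
  subject <- Biostrings::DNAStringSet(setNames(asm$seq, asm$id))
  tag_len <- unique(nchar(tags$seq))
  stopifnot(length(tag_len) == 1)
  max_mm <- tag_len - min_aligned
  stopifnot(max_mm >= 0)
  hits_for <- function(pattern, strand) {
    m <- Biostrings::vmatchPattern(pattern, subject, max.mismatch = max_mm,
                                   fixed = TRUE)
    st <- Biostrings::startIndex(m)
    n <- lengths(st)
    if (sum(n) == 0) return(NULL)
    tibble(scaffold_id = rep.int(names(subject), n),
           position = unlist(st, use.names = FALSE) - 1L,
           strand = strand)
  }
  out <- purrr::map(seq_len(nrow(tags)), function(i) {
    pat <- Biostrings::DNAString(tags$seq[i])
    h <- bind_rows(
      hits_for(pat, "+"),
      hits_for(Biostrings::reverseComplement(pat), "-")
    )
    if (nrow(h) == 0) return(NULL)
    h$tag_id <- tags$tag_id[i]
    h
  }) |>
    bind_rows()
  if (nrow(out) == 0) {
    return(tibble(tag_id = character(), scaffold_id = character(),
                  position = integer(), strand = character()))
  }
  select(out, "tag_id", "scaffold_id", "position", "strand")
}

#' Tag-pair summary score
#'
#' The product of the number of pairs co-locating on one scaffold and the
#' fraction of uniquely placed pairs at the expected distance:
#' `c * (e / d)`, defined as 0 when `d` is 0.
#'
#' @param c_pairs,d_pairs,e_pairs Category counts (see [classify_pairs()]).
#' @return Numeric score.
#' @examples
#' tag_summary_score(910, 1000, 918)  # 910 * 0.918
#' @export
tag_summary_score <- function(c_pairs, d_pairs, e_pairs) {
  if (d_pairs == 0) return(0)
  c_pairs * (e_pairs / d_pairs)
}

#' Classify tag pairs and score an assembly
#'
#' Computes the five tag-mapping categories and the summary score from
#' per-tag match lists. A tag is "unique" when it has exactly one match
#' position in exactly one scaffold; pairs whose tags multi-map within one
#' scaffold count toward `c` but not `d`. Category `e` additionally
#' requires both tags on the same strand with the absolute difference of
#' their start coordinates within `tolerance` of `expected_distance`.
#'
#' @param matches Match tibble from [map_tags()] or [read_blast_tags()].
#' @param tags Tag tibble from [extract_tags()] (defines the full pair set).
#' @param expected_distance Expected start-coordinate distance (default 900).
#' @param tolerance Allowed deviation in nt (default 2).
#' @param label Assembly label for reporting.
#' @return Object of class `tag_pair_report` with counts `a`, `b`, `c`,
#'   `d`, `e`, `n_pairs`, `n_tags` and `summary_score`; see [tidy()].
#' @export
classify_pairs <- function(matches, tags,
                           expected_distance = NULL,
                           tolerance = asmqc_defaults$tag_tolerance,
                           label = "assembly") {
  if (is.null(expected_distance)) {
    expected_distance <- if ("expected_distance" %in% names(tags) && nrow(tags) > 0) {
      tags$expected_distance[1]
    } else {
      asmqc_defaults$tag_distance
    }
  }
  pair_keys <- unique(tags[, c("vfr_id", "frag_index")])
  n_pairs <- nrow(pair_keys)
  n_tags <- nrow(tags)

  per_tag <- matches |>
    group_by(.data$tag_id) |>
    summarise(n_scaffolds = dplyr::n_distinct(.data$scaffold_id),
              n_positions = n(),
              scaffold = .data$scaffold_id[1],
              position = .data$position[1],
              strand = .data$strand[1],
              scaffolds = list(unique(.data$scaffold_id)),
              .groups = "drop")

  tag_tbl <- tags |>
    select("vfr_id", "frag_index", "side", "tag_id") |>
    left_join(per_tag, by = "tag_id") |>
    mutate(matched = !is.na(.data$n_scaffolds),
           unique = .data$matched & .data$n_scaffolds == 1 & .data$n_positions == 1)

  a <- sum(tag_tbl$matched)
  b <- sum(tag_tbl$matched & tag_tbl$n_scaffolds == 1)

  wide <- tag_tbl |>
    tidyr::pivot_wider(id_cols = c("vfr_id", "frag_index"),
                       names_from = "side",
                       values_from = c("matched", "unique", "scaffold",
                                       "position", "strand", "scaffolds"))
  share <- purrr::map2_lgl(wide$scaffolds_L, wide$scaffolds_R, function(l, r) {
    !is.null(l) && !is.null(r) && length(intersect(l, r)) > 0
  })
  c_pairs <- sum(share)
  d_sel <- !is.na(wide$unique_L) & !is.na(wide$unique_R) &
    wide$unique_L & wide$unique_R &
    wide$scaffold_L == wide$scaffold_R
  d_pairs <- sum(d_sel)
  e_sel <- d_sel &
    wide$strand_L == wide$strand_R &
    abs(abs(wide$position_L - wide$position_R) - expected_distance) <= tolerance
  e_pairs <- sum(e_sel)

  structure(list(
    label = label,
    a = a, b = b, c = c_pairs, d = d_pairs, e = e_pairs,
    n_pairs = n_pairs, n_tags = n_tags,
    expected_distance = expected_distance, tolerance = tolerance,
    summary_score = tag_summary_score(c_pairs, d_pairs, e_pairs)
  ), class = "tag_pair_report")
}

#' @export
print.tag_pair_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<tag_pair_report '%s'> %d pairs (%d tags)\n",
    "  a=%d b=%d c=%d d=%d e=%d\n  summary score = %.2f (max %d)\n"),
    x$label, x$n_pairs, x$n_tags, x$a, x$b, x$c, x$d, x$e,
    x$summary_score, x$n_pairs))
  invisible(x)
}

#' @rdname classify_pairs
#' @param x A `tag_pair_report`.
#' @param ... Unused.
#' @method tidy tag_pair_report
#' @export
tidy.tag_pair_report <- function(x, ...) {
  tibble(label = x$label, a = x$a, b = x$b, c = x$c, d = x$d, e = x$e,
         n_pairs = x$n_pairs, n_tags = x$n_tags,
         summary_score = x$summary_score)
}

#' @rdname classify_pairs
#' @method glance tag_pair_report
#' @export
glance.tag_pair_report <- function(x, ...) {
  tibble(label = x$label, summary_score = x$summary_score,
         max_score = x$n_pairs)
}

#' Full tag-pair accuracy pipeline
#'
#' Convenience wrapper: fragments the validated regions, extracts tag
#' pairs, maps them against the assembly with the bundled matcher and
#' classifies the pairs. Run it on contig sequences instead of scaffolds by
#' passing a contig table rebuilt into an assembly.
#'
#' @inheritParams fragment_vfrs
#' @inheritParams map_tags
#' @inheritParams classify_pairs
#' @param tag_len Tag length in nt.
#' @return A `tag_pair_report`.
#' @export
vfr_tag_report <- function(vfrs, asm,
                           fragment_len = asmqc_defaults$fragment_len,
                           tag_len = asmqc_defaults$tag_len,
                           min_aligned = asmqc_defaults$tag_min_aligned,
                           tolerance = asmqc_defaults$tag_tolerance,
                           label = attr(asm, "label")) {
  tags <- extract_tags(fragment_vfrs(vfrs, fragment_len), tag_len)
  matches <- map_tags(tags, asm, min_aligned)
  classify_pairs(matches, tags, tolerance = tolerance,
                 label = if (is.null(label)) "assembly" else label)
}

#' Write tag sequences to FASTA
#'
#' @param tags Tibble from [extract_tags()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_tag_fasta <- function(tags, path) {
  ss <- Biostrings::DNAStringSet(setNames(tags$seq, tags$tag_id))
  Biostrings::writeXStringSet(ss, path, width = 60L)
  invisible(path)
}
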