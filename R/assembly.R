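# Assembly container and basic descriptive statistics.
#
# An assembly is a tibble of scaffold records (id, seq, length) carrying the
# assembly label, a species tag and an optional genome-size estimate as
# attributes, so it pipes through dplyr verbs while staying a first-class
# object for the sequence-level operations.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "N",
                 "R", "Y", "S", "W", "K", "M", "B", "D", "H", "V")

new_assembly <- function(records, label = "assembly", species = NA_character_,
                         genome_size = NA_real_) {
  out <- tibble::new_tibble(records,
                            class = "asmqc_assembly",
                            nrow = nrow(records))
  attr(out, "label") <- label
  attr(out, "species") <- species
  attr(out, "genome_size") <- genome_size
  out
}

#' Construct an assembly from named sequences
#'
#' Builds the scaffold table used throughout the package from a named
#' character vector of IUPAC DNA sequences. Scaffold identifiers must be
#' unique and non-empty, and every sequence must be non-empty.
#'
#' @param seqs Named character vector of scaffold sequences.
#' @param label Assembly label (e.g. a team code).
#' @param species Free-text species tag.
#' @param genome_size Estimated genome size in bases, if known.
#' @return A tibble of class `asmqc_assembly` with columns `id`, `seq`,
#'   `length`, carrying `label`, `species` and `genome_size` as attributes.
#' @examples
#' asm <- assembly(c(s1 = "ACGT", s2 = "NNNNA"), label = "demo")
#' asm$length
#' @export
assembly <- function(seqs, label = "assembly", species = NA_character_,
                     genome_size = NA_real_) {
  ids <- names(seqs)
  if (is.null(ids) || any(!nzchar(ids))) {
    abort("every scaffold must have a non-empty identifier")
  }
  validate_scaffolds(ids, unname(seqs))
  new_assembly(
    tibble(id = ids, seq = toupper(unname(seqs)),
           length = unname(nchar(seqs))),
    label = label, species = species, genome_size = genome_size
  )
}

validate_scaffolds <- function(ids, seqs) {
  dup <- ids[duplicated(ids)]
  if (length(dup) > 0) {
    abort(paste0("duplicate FASTA header(s): ", paste(unique(dup), collapse = ", ")))
  }
  if (any(nchar(seqs) == 0)) {
    abort(paste0("empty sequence for entry: ",
                 paste(ids[nchar(seqs) == 0], collapse = ", ")))
  }
  bad <- stringr::str_locate(toupper(seqs),
                             paste0("[^", paste(IUPAC_CHARS, collapse = ""), "]"))[, 1]
  if (any(!is.na(bad))) {
    i <- which(!is.na(bad))[1]
    abort(sprintf("non-IUPAC character in '%s' at position %d", ids[i], bad[i]))
  }
  invisible(TRUE)
}

#' @export
print.asmqc_assembly <- function(x, ...) {
  cat(sprintf("<assembly '%s'> %d scaffold(s), %s bp total\n",
              attr(x, "label"), nrow(x),
              format(sum(x$length), big.mark = ",")))
  NextMethod()
}

#' Read an assembly from a FASTA file
#'
#' Reads a (optionally gzip-compressed) FASTA file of scaffold sequences,
#' preserving entry order and sequence case. Duplicate headers, empty
#' sequences and non-IUPAC characters are hard errors; downstream
#' comparisons are case-insensitive.
#'
#' @param path Path to a FASTA file.
#' @inheritParams assembly
#' @return An `asmqc_assembly` tibble; zero-row if the file has no entries.
#' @export
read_assembly_fasta <- function(path, label = NULL, species = NA_character_,
                                genome_size = NA_real_) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  if (is.null(label)) label <- sub("\\.(fa|fasta|fna)(\\.gz)?$", "", basename(path))
  ss <- Biostrings::readBStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- as.character(ss)
  if (length(seqs) > 0) validate_scaffolds(ids, seqs)
  new_assembly(
    tibble(id = unname(ids), seq = unname(toupper(seqs)),
           length = unname(nchar(seqs))),
    label = label, species = species, genome_size = genome_size
  )
}

#' Write an assembly to a FASTA file
#'
#' @param asm An `asmqc_assembly`.
#' @param path Output path.
#' @param width Line-wrap width in columns.
#' @return `path`, invisibly.
#' @export
write_assembly_fasta <- function(asm, path, width = 60L) {
  ss <- Biostrings::BStringSet(setNames(asm$seq, asm$id))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' Split scaffolds into contigs at long N-runs
#'
#' Removes every maximal run of `gap_min` or more consecutive `N` characters
#' (case-insensitive) and returns the remaining gap-free-by-construction
#' segments as contigs. N-runs shorter than `gap_min` stay inside contigs;
#' ambiguity codes other than N never trigger a split. Intervals are
#' 0-based half-open on the parent scaffold.
#'
#' @param asm An `asmqc_assembly`.
#' @param gap_min Minimum N-run length that constitutes a gap (default 25).
#' @return Tibble with columns `scaffold_id`, `contig_id`, `start`, `end`,
#'   `length`, `seq`.
#' @examples
#' asm <- assembly(c(s1 = paste0(strrep("A", 4), strrep("N", 25), "GGG")))
#' split_scaffolds(asm)[, c("start", "end", "length")]
#' @export
split_scaffolds <- function(asm, gap_min = asmqc_defaults$gap_min) {
  stopifnot(gap_min >= 1)
  pieces <- purrr::map2(asm$id, asm$seq, function(id, seq) {
    gaps <- stringr::str_locate_all(seq, paste0("N{", gap_min, ",}"))[[1]]
    len <- nchar(seq)
    if (nrow(gaps) == 0) {
      starts <- 0L; ends <- len
    } else {
      # contigs are the complement of the gap runs within [0, len)
      starts <- c(0L, gaps[, 2])          # gap ends are 1-based inclusive == 0-based exclusive
      ends <- c(gaps[, 1] - 1L, len)      # gap starts 1-based -> 0-based
      keep <- starts < ends
      starts <- starts[keep]; ends <- ends[keep]
    }
    if (length(starts) == 0) return(NULL)
    tibble(
      scaffold_id = id,
      start = as.integer(starts),
      end = as.integer(ends),
      seq = stringr::str_sub(seq, starts + 1L, ends)
    )
  })
  out <- bind_rows(pieces)
  if (nrow(out) == 0) {
    return(tibble(scaffold_id = character(), contig_id = character(),
                  start = integer(), end = integer(),
                  length = integer(), seq = character()))
  }
  out |>
    group_by(.data$scaffold_id) |>
    mutate(contig_id = paste0(.data$scaffold_id, ".", row_number())) |>
    ungroup() |>
    mutate(length = .data$end - .data$start) |>
    select("scaffold_id", "contig_id", "start", "end", "length", "seq")
}

#' Assembly size inclusion filter
#'
#' Benchmarking practice excludes assemblies whose total size is less than a
#' quarter of the expected genome size. The boundary is inclusive: exactly
#' 25% passes.
#'
#' @param asm An `asmqc_assembly`.
#' @param genome_size Expected genome size in bases.
#' @param min_fraction Minimum total-size/genome-size ratio (default 0.25).
#' @return One-row tibble with `label`, `total`, `genome_size`, `ratio`, `pass`.
#' @export
assembly_size_filter <- function(asm, genome_size = attr(asm, "genome_size"),
                                 min_fraction = asmqc_defaults$size_filter) {
  stopifnot(is.numeric(genome_size), genome_size > 0)
  total <- sum(asm$length)
  tibble(
    label = attr(asm, "label"),
    total = total,
    genome_size = genome_size,
    ratio = total / genome_size,
    pass = total / genome_size >= min_fraction
  )
}

length_summary <- function(lengths, n_count, prefix,
                           thresholds = c(1e3, 1e4, 25e3, 1e5, 1e6)) {
  out <- tibble(
    count = length(lengths),
    total = sum(lengths),
    longest = if (length(lengths)) max(lengths) else 0,
    mean = if (length(lengths)) mean(lengths) else NA_real_,
    n50 = if (length(lengths)) nx(lengths, 50) else NA_real_,
    pct_n = if (sum(lengths) > 0) 100 * n_count / sum(lengths) else NA_real_
  )
  for (t in thresholds) {
    out[[paste0("count_ge_", format(t, scientific = FALSE, trim = TRUE))]] <-
      sum(lengths >= t)
  }
  names(out) <- paste0(prefix, "_", names(out))
  out
}

#' Basic descriptive statistics for an assembly
#'
#' Computes counts, total and longest lengths, mean, N50, percent N and
#' counts above standard length thresholds, for both the scaffold and the
#' contig length sets. When a genome size is available, NG50s and the
#' gene-sized scaffold metric are included.
#'
#' @param asm An `asmqc_assembly`.
#' @param contigs Contig table from [split_scaffolds()]; computed if missing.
#' @param genome_size Estimated genome size (defaults to the assembly attribute).
#' @param gene_size Average gene length used for the gene-sized metric.
#' @return One-row tibble keyed by `label`.
#' @export
assembly_stats <- function(asm, contigs = NULL,
                           genome_size = attr(asm, "genome_size"),
                           gene_size = asmqc_defaults$gene_size) {
  if (is.null(contigs)) contigs <- split_scaffolds(asm)
  n_total <- sum(stringr::str_count(asm$seq, "N"))
  out <- dplyr::bind_cols(
    tibble(label = attr(asm, "label"), species = attr(asm, "species")),
    length_summary(asm$length, n_total, "scaffold"),
    length_summary(contigs$length,
                   sum(stringr::str_count(contigs$seq, "N")), "contig")
  )
  if (!is.na(genome_size)) {
    gs <- gene_sized_amount(asm$length, genome_size, threshold = gene_size)
    out$scaffold_ng50 <- ngx(asm$length, 50, genome_size)
    out$contig_ng50 <- if (nrow(contigs)) ngx(contigs$length, 50, genome_size) else 0
    out$gene_sized_amount <- gs$amount
    out$gene_sized_absdiff <- gs$key_metric
  }
  out
}
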