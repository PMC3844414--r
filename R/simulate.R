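# Synthetic genomes and corrupted assemblies with analytically known ground
# truth. All randomness flows from one explicit seed through a private RNG
# stream; the global random state is never touched.

with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1) abort("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

#' Generate a random genome with planted repeats
#'
#' Uniform random DNA of the requested length, optionally with exact copies
#' of planted repeat units overwritten at recorded, non-overlapping
#' positions. Exact copies keep alignment behaviour analytically
#' predictable. Fully reproducible from the seed.
#'
#' @param length Genome length in bases.
#' @param seed Integer seed; the only source of randomness.
#' @param repeat_spec Optional tibble/data frame with columns `unit_length`
#'   and `copies`, one row per repeat family.
#' @param label Sequence identifier.
#' @return A one-record `asmqc_assembly`; planted repeat positions are in
#'   the `"repeats"` attribute (`family`, `copy`, `start`, `end`).
#' @export
generate_genome <- function(length, seed, repeat_spec = NULL, label = "genome") {
  stopifnot(length >= 1)
  with_seed(seed, {
    seq <- random_dna(length)
    rep_tbl <- tibble(family = integer(), copy = integer(),
                      start = integer(), end = integer())
    if (!is.null(repeat_spec) && nrow(repeat_spec) > 0) {
      if (sum(repeat_spec$unit_length * repeat_spec$copies) > length) {
        abort("genome too short for the requested repeat content")
      }
      occupied <- IRanges::IRanges()
      for (fam in seq_len(nrow(repeat_spec))) {
        ul <- repeat_spec$unit_length[fam]
        unit <- random_dna(ul)
        placed <- 0L
        tries <- 0L
        while (placed < repeat_spec$copies[fam]) {
          tries <- tries + 1L
          if (tries > 1000L) abort("could not place repeats without overlap")
          s <- sample.int(length - ul + 1L, 1L) - 1L
          iv <- IRanges::IRanges(start = s + 1L, width = ul)
          if (length(IRanges::findOverlaps(iv, occupied)) > 0) next
          occupied <- c(occupied, iv)
          stringr::str_sub(seq, s + 1L, s + ul) <- unit
          placed <- placed + 1L
          rep_tbl <- bind_rows(rep_tbl,
                               tibble(family = fam, copy = placed,
                                      start = s, end = s + ul))
        }
      }
    }
    g <- assembly(setNames(seq, label), label = label, genome_size = length)
    attr(g, "repeats") <- rep_tbl
    g
  })
}

#' Corruption-plan operations
#'
#' Constructors for the ordered operations of a corruption plan:
#' `op_fragment()` splits the genome tiling at the given positions;
#' `op_insert_gap()` inserts a run of Ns at a genome position (emulating a
#' scaffolding gap); `op_duplicate()` appends extra copies of a genome
#' interval as standalone scaffolds (spurious duplication / repeat
#' expansion); `op_chimera()` appends one scaffold concatenating intervals
#' from distant loci (a chimeric join); `op_collapse_repeat()` deletes all
#' but the first planted copy of a repeat family (repeat collapse);
#' `op_substitute()` applies random base substitutions at the given rate.
#' All intervals are 0-based half-open genome coordinates.
#'
#' @param breakpoints Integer genome positions at which to split.
#' @param position Genome position for the gap.
#' @param n_run_length Number of Ns to insert.
#' @param start,end Interval to duplicate.
#' @param copies Number of extra copies.
#' @param intervals Two-column matrix or data frame of (start, end) rows.
#' @param family Planted repeat family index.
#' @param rate Per-base substitution probability.
#' @return An op object for [corruption_plan()].
#' @name corruption_ops
NULL

op <- function(type, ...) structure(list(type = type, ...), class = "asmqc_op")

#' @rdname corruption_ops
#' @export
op_fragment <- function(breakpoints) op("fragment", breakpoints = sort(unique(as.integer(breakpoints))))

#' @rdname corruption_ops
#' @export
op_insert_gap <- function(position, n_run_length = 100L) {
  op("insert_gap", position = as.integer(position),
     n_run_length = as.integer(n_run_length))
}

#' @rdname corruption_ops
#' @export
op_duplicate <- function(start, end, copies = 1L) {
  stopifnot(end > start, copies >= 1)
  op("duplicate", start = as.integer(start), end = as.integer(end),
     copies = as.integer(copies))
}

#' @rdname corruption_ops
#' @export
op_chimera <- function(intervals) {
  intervals <- as.data.frame(intervals)
  names(intervals) <- c("start", "end")
  stopifnot(all(intervals$end > intervals$start))
  op("chimera", intervals = intervals)
}

#' @rdname corruption_ops
#' @export
op_collapse_repeat <- function(family = 1L) op("collapse_repeat", family = as.integer(family))

#' @rdname corruption_ops
#' @export
op_substitute <- function(rate) {
  stopifnot(rate >= 0, rate <= 1)
  op("substitute", rate = rate)
}

#' Build a corruption plan
#'
#' An ordered list of corruption operations plus the seed that makes any
#' stochastic op (substitutions) reproducible.
#'
#' @param ... Op objects from the `op_*()` constructors.
#' @param seed Integer seed.
#' @return A `corruption_plan`.
#' @export
corruption_plan <- function(..., seed = 1L) {
  ops <- list(...)
  stopifnot(all(vapply(ops, inherits, logical(1), "asmqc_op")))
  structure(list(ops = ops, seed = as.integer(seed)), class = "corruption_plan")
}

#' Apply a corruption plan to a genome
#'
#' Produces a corrupted "assembly" from a genome, together with the
#' provenance (truth) alignments of every assembled piece back to the
#' genome and the compass metrics those alignments imply. When the plan
#' contains no `collapse_repeat` or `substitute` op and the genome is
#' repeat-free, the expected metrics are exact for any aligner that
#' recovers maximal exact matches (see [align_exact()]): duplicated bases
#' inflate the alignment sum but not the covered sum, inserted gap Ns
#' inflate only the scaffold sum, and fragmentation changes nothing.
#'
#' @param genome One-record `asmqc_assembly` from [generate_genome()].
#' @param plan A [corruption_plan()].
#' @return A `synthetic_truth` list: `genome`, `assembly`, `plan`,
#'   `truth_alignments` (alignment tibble), `expected` (one-row tibble of
#'   compass sums/ratios), and `exact` (whether the prediction is analytic).
#' @export
corrupt_assembly <- function(genome, plan) {
  stopifnot(inherits(plan, "corruption_plan"), nrow(genome) == 1)
  gseq <- genome$seq[1]
  G <- genome$length[1]
  rep_tbl <- attr(genome, "repeats")
  if (is.null(rep_tbl)) rep_tbl <- tibble(family = integer(), copy = integer(),
                                          start = integer(), end = integer())

  # pieces tiling (part of) the genome; gaps: per-piece inserted N-runs
  pieces <- tibble(start = 0L, end = G)
  gaps <- tibble(at = integer(), n = integer())
  dups <- tibble(start = integer(), end = integer(), copies = integer())
  chimeras <- list()
  sub_rate <- 0
  has_collapse <- FALSE

  split_at <- function(pieces, pos) {
    hit <- which(pieces$start < pos & pos < pieces$end)
    if (length(hit) == 0) return(pieces)
    p <- pieces[hit, ]
    bind_rows(pieces[-hit, ],
              tibble(start = c(p$start, pos), end = c(pos, p$end))) |>
      arrange(.data$start)
  }
  delete_interval <- function(pieces, s, e) {
    out <- list()
    for (i in seq_len(nrow(pieces))) {
      ps <- pieces$start[i]; pe <- pieces$end[i]
      if (pe <= s || ps >= e) { out[[length(out) + 1]] <- tibble(start = ps, end = pe); next }
      if (ps < s) out[[length(out) + 1]] <- tibble(start = ps, end = s)
      if (pe > e) out[[length(out) + 1]] <- tibble(start = e, end = pe)
    }
    bind_rows(out) |> arrange(.data$start)
  }

  for (o in plan$ops) {
    switch(o$type,
      fragment = {
        for (bp in o$breakpoints) pieces <- split_at(pieces, bp)
      },
      insert_gap = {
        hit <- which(pieces$start < o$position & o$position < pieces$end)
        if (length(hit) == 0) abort("gap position does not fall inside a piece")
        gaps <- bind_rows(gaps, tibble(at = o$position, n = o$n_run_length))
      },
      duplicate = {
        stopifnot(o$end <= G)
        dups <- bind_rows(dups, tibble(start = o$start, end = o$end,
                                       copies = o$copies))
      },
      chimera = {
        stopifnot(all(o$intervals$end <= G))
        chimeras[[length(chimeras) + 1]] <- o$intervals
      },
      collapse_repeat = {
        has_collapse <- TRUE
        fam <- rep_tbl[rep_tbl$family == o$family, ]
        if (nrow(fam) < 2) abort("repeat family has fewer than 2 planted copies")
        for (i in 2:nrow(fam)) pieces <- delete_interval(pieces, fam$start[i], fam$end[i])
      },
      substitute = {
        sub_rate <- sub_rate + o$rate
      },
      abort(paste0("unknown op type: ", o$type))
    )
  }

  # assemble scaffolds + provenance alignments
  scaffolds <- character()
  truth <- list()
  add_aln <- function(scaffold_id, s_start, g_start, g_end) {
    truth[[length(truth) + 1]] <<- tibble(
      scaffold_id = scaffold_id, s_start = as.integer(s_start),
      s_end = as.integer(s_start + (g_end - g_start)),
      r_start = as.integer(g_start), r_end = as.integer(g_end)
    )
  }
  for (i in seq_len(nrow(pieces))) {
    id <- sprintf("piece_%03d", i)
    ps <- pieces$start[i]; pe <- pieces$end[i]
    g <- gaps[gaps$at > ps & gaps$at < pe, ] |> arrange(.data$at)
    segs_start <- c(ps, g$at); segs_end <- c(g$at, pe)
    seq_parts <- character(); offset <- 0L
    for (k in seq_along(segs_start)) {
      seg <- stringr::str_sub(gseq, segs_start[k] + 1L, segs_end[k])
      seq_parts <- c(seq_parts, seg)
      add_aln(id, offset, segs_start[k], segs_end[k])
      offset <- offset + nchar(seg)
      if (k <= nrow(g)) {
        seq_parts <- c(seq_parts, strrep("N", g$n[k]))
        offset <- offset + g$n[k]
      }
    }
    scaffolds[id] <- paste(seq_parts, collapse = "")
  }
  if (nrow(dups) > 0) {
    for (i in seq_len(nrow(dups))) {
      for (cp in seq_len(dups$copies[i])) {
        id <- sprintf("dup_%03d_%d", i, cp)
        scaffolds[id] <- stringr::str_sub(gseq, dups$start[i] + 1L, dups$end[i])
        add_aln(id, 0L, dups$start[i], dups$end[i])
      }
    }
  }
  for (i in seq_along(chimeras)) {
    id <- sprintf("chimera_%03d", i)
    iv <- chimeras[[i]]
    parts <- stringr::str_sub(gseq, iv$start + 1L, iv$end)
    offset <- 0L
    for (k in seq_len(nrow(iv))) {
      add_aln(id, offset, iv$start[k], iv$end[k])
      offset <- offset + (iv$end[k] - iv$start[k])
    }
    scaffolds[id] <- paste(parts, collapse = "")
  }

  if (sub_rate > 0) {
    scaffolds <- with_seed(plan$seed, {
      vapply(scaffolds, function(s) {
        n <- nchar(s)
        hit <- which(runif(n) < sub_rate)
        if (length(hit) == 0) return(s)
        ch <- stringr::str_sub(s, hit, hit)
        repl <- vapply(ch, function(b) {
          if (b == "N") "N" else sample(setdiff(c("A", "C", "G", "T"), b), 1)
        }, character(1))
        for (j in seq_along(hit)) stringr::str_sub(s, hit[j], hit[j]) <- repl[j]
        s
      }, character(1))
    })
  }

  asm <- assembly(scaffolds, label = paste0(attr(genome, "label"), "_corrupt"),
                  genome_size = G)
  truth_tbl <- bind_rows(truth)
  truth_tbl <- extend_truth(truth_tbl, scaffolds, gseq, G)
  truth_aln <- alignments(
    scaffold_id = truth_tbl$scaffold_id,
    scaffold_len = asm$length[match(truth_tbl$scaffold_id, asm$id)],
    s_start = truth_tbl$s_start, s_end = truth_tbl$s_end,
    ref_id = genome$id[1], r_start = truth_tbl$r_start,
    r_end = truth_tbl$r_end, strand = "+", identity = 100
  )
  expected <- tidy(compass(asm, genome, truth_aln,
                           label = attr(asm, "label")))
  structure(list(
    genome = genome, assembly = asm, plan = plan,
    truth_alignments = truth_aln, expected = expected,
    exact = !has_collapse && sub_rate == 0 && nrow(rep_tbl) == 0
  ), class = "synthetic_truth")
}

# Truth alignments carry maximal-exact-match semantics: at a chimeric
# junction the flanking bases can match the reference continuation by
# chance, and any maximal-extension aligner will include them, so the
# provenance intervals are extended until the first mismatch or boundary.
extend_truth <- function(truth_tbl, scaffolds, gseq, G) {
  if (nrow(truth_tbl) == 0) return(truth_tbl)
  for (i in seq_len(nrow(truth_tbl))) {
    sid <- truth_tbl$scaffold_id[i]
    slen <- nchar(scaffolds[[sid]])
    # rightwards
    while (truth_tbl$s_end[i] < slen && truth_tbl$r_end[i] < G &&
           substr(scaffolds[[sid]], truth_tbl$s_end[i] + 1L,
                  truth_tbl$s_end[i] + 1L) ==
           substr(gseq, truth_tbl$r_end[i] + 1L, truth_tbl$r_end[i] + 1L)) {
      truth_tbl$s_end[i] <- truth_tbl$s_end[i] + 1L
      truth_tbl$r_end[i] <- truth_tbl$r_end[i] + 1L
    }
    # leftwards
    while (truth_tbl$s_start[i] > 0L && truth_tbl$r_start[i] > 0L &&
           substr(scaffolds[[sid]], truth_tbl$s_start[i],
                  truth_tbl$s_start[i]) ==
           substr(gseq, truth_tbl$r_start[i], truth_tbl$r_start[i])) {
      truth_tbl$s_start[i] <- truth_tbl$s_start[i] - 1L
      truth_tbl$r_start[i] <- truth_tbl$r_start[i] - 1L
    }
  }
  truth_tbl
}

#' Sample fosmid-like subsequences from a genome
#'
#' Draws `n` subsequences of fosmid-insert size (uniform in
#' `length_range`) at reproducible random positions.
#'
#' @param genome One-record `asmqc_assembly`.
#' @param n Number of fosmids.
#' @param seed Integer seed.
#' @param length_range Insert length range in bases (default 35-40 Kbp).
#' @return An `asmqc_assembly` of fosmid records with extra columns
#'   `src_start`, `src_end` recording the source interval.
#' @export
sample_fosmids <- function(genome, n, seed,
                           length_range = c(35000L, 40000L)) {
  stopifnot(nrow(genome) == 1, n >= 0)
  G <- genome$length[1]
  stopifnot(max(length_range) < G)
  if (n == 0) {
    out <- assembly(character(0) |> setNames(character(0)))[0, ]
    out$src_start <- integer(); out$src_end <- integer()
    return(out)
  }
  with_seed(seed, {
    lens <- sample.int(diff(range(length_range)) + 1L, n, replace = TRUE) +
      min(length_range) - 1L
    starts <- vapply(lens, function(l) sample.int(G - l + 1L, 1L) - 1L, integer(1))
    seqs <- stringr::str_sub(genome$seq[1], starts + 1L, starts + lens)
    names(seqs) <- sprintf("fosmid_%03d", seq_len(n))
    out <- assembly(seqs, label = paste0(attr(genome, "label"), "_fosmids"))
    out$src_start <- as.integer(starts)
    out$src_end <- as.integer(starts + lens)
    out
  })
}

#' Generate a random corruption plan
#'
#' Draws a plan of fragmentation, gap-insertion, duplication and chimera
#' ops whose expected compass metrics are analytically exact on a
#' repeat-free genome, for ground-truth recovery checks.
#'
#' @param genome_length Genome length the plan targets.
#' @param seed Integer seed.
#' @param min_piece Minimum spacing between breakpoints/segment bounds.
#' @return A `corruption_plan`.
#' @export
random_plan <- function(genome_length, seed, min_piece = 500L) {
  with_seed(seed, {
    grid <- seq(min_piece, genome_length - min_piece, by = min_piece)
    n_bp <- sample(1:5, 1)
    bps <- sort(sample(grid, min(n_bp, length(grid))))
    ops <- list(op_fragment(bps))
    if (runif(1) < 0.7) {
      pos <- sample(setdiff(grid, bps), 1)
      ops <- c(ops, list(op_insert_gap(pos, sample(25:200, 1))))
    }
    if (runif(1) < 0.8) {
      s <- sample(grid[grid < genome_length - 2 * min_piece], 1)
      ops <- c(ops, list(op_duplicate(s, s + sample(min_piece:(2 * min_piece), 1),
                                      copies = sample(1:3, 1))))
    }
    if (runif(1) < 0.5) {
      s1 <- sample(grid[grid < genome_length / 2 - min_piece], 1)
      s2 <- sample(grid[grid > genome_length / 2], 1)
      ops <- c(ops, list(op_chimera(rbind(
        c(s1, s1 + min_piece), c(s2, min(s2 + min_piece, genome_length))
      ))))
    }
    do.call(corruption_plan, c(ops, list(seed = seed)))
  })
}

#' Write a synthetic fixture to disk
#'
#' Writes genome, assembly and (optionally) fosmid FASTA files plus a truth
#' JSON (plan summary and expected metrics) for a `synthetic_truth`.
#'
#' @param truth A `synthetic_truth` from [corrupt_assembly()].
#' @param dir Output directory (created if needed).
#' @param fosmids Optional fosmid set from [sample_fosmids()].
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(truth, dir, fosmids = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_assembly_fasta(truth$genome, file.path(dir, "genome.fa"))
  write_assembly_fasta(truth$assembly, file.path(dir, "assembly.fa"))
  if (!is.null(fosmids)) {
    write_assembly_fasta(fosmids, file.path(dir, "fosmids.fa"))
  }
  ops <- lapply(truth$plan$ops, function(o) o[setdiff(names(o), "class")])
  jsonlite::write_json(
    list(seed = truth$plan$seed, ops = ops,
         exact = truth$exact, expected = truth$expected),
    file.path(dir, "truth.json"),
    auto_unbox = TRUE, pretty = TRUE, digits = NA
  )
  invisible(dir)
}
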