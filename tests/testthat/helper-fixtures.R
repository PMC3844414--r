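# Shared fixtures and independent oracles, built in code at test time.

tmp_fasta <- function(seqs, dir = tempdir()) {
  path <- tempfile(tmpdir = dir, fileext = ".fa")
  writeLines(unlist(purrr::map2(names(seqs), seqs, function(id, s) c(paste0(">", id), s))),
             path)
  path
}

# brute-force N(x)/NG(x): walk the sorted lengths and accumulate
oracle_nx <- function(lengths, x, denom = sum(lengths)) {
  ls <- sort(lengths, decreasing = TRUE)
  threshold <- x / 100 * denom
  acc <- 0
  for (l in ls) {
    acc <- acc + l
    if (acc >= threshold) return(l)
  }
  0
}

# brute-force coverage islands via a per-base boolean array
oracle_islands_total <- function(alns, ref_len) {
  totals <- 0L
  for (rid in unique(alns$ref_id)) {
    covered <- logical(ref_len)
    sub <- alns[alns$ref_id == rid, ]
    for (i in seq_len(nrow(sub))) {
      covered[(sub$r_start[i] + 1):sub$r_end[i]] <- TRUE
    }
    totals <- totals + sum(covered)
  }
  totals
}

oracle_island_count <- function(alns, ref_len) {
  n <- 0L
  for (rid in unique(alns$ref_id)) {
    covered <- logical(ref_len)
    sub <- alns[alns$ref_id == rid, ]
    for (i in seq_len(nrow(sub))) {
      covered[(sub$r_start[i] + 1):sub$r_end[i]] <- TRUE
    }
    runs <- rle(covered)
    n <- n + sum(runs$values)
  }
  n
}

random_alignment_set <- function(n_aln, n_ref = 3, ref_len = 1000) {
  st <- sample.int(ref_len - 20, n_aln, replace = TRUE) - 1L
  alignments(
    scaffold_id = paste0("s", sample.int(5, n_aln, replace = TRUE)),
    ref_id = paste0("r", sample.int(n_ref, n_aln, replace = TRUE)),
    r_start = st,
    r_end = st + sample.int(15, n_aln, replace = TRUE),
    scaffold_len = 500L,
    identity = 100
  )
}

cli_path <- function() system.file("cli", "asmqc.R", package = "asmqc")
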