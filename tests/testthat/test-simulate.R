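test_that("genome generation is seed-deterministic with planted repeats", {
  g1 <- generate_genome(5000, seed = 5)
  g2 <- generate_genome(5000, seed = 5)
  expect_identical(g1$seq, g2$seq)
  expect_equal(g1$length, 5000L)
  expect_false(identical(generate_genome(5000, seed = 6)$seq, g1$seq))
  spec <- tibble::tibble(unit_length = 300, copies = 4)
  gr <- generate_genome(20000, seed = 7, repeat_spec = spec)
  reps <- attr(gr, "repeats")
  expect_equal(nrow(reps), 4)
  units <- substring(gr$seq, reps$start + 1, reps$end)
  expect_equal(length(unique(units)), 1)  # exact copies
  expect_gte(stringr::str_count(gr$seq, stringr::fixed(units[1])), 4)
})

test_that("an empty plan reproduces the genome with unit metrics", {
  g <- generate_genome(8000, seed = 9)
  tr <- corrupt_assembly(g, corruption_plan(seed = 9))
  expect_equal(nrow(tr$assembly), 1)
  expect_equal(tr$assembly$seq, g$seq)
  expect_equal(unlist(tr$expected[c("coverage", "validity",
                                    "multiplicity", "parsimony")]),
               c(coverage = 1, validity = 1, multiplicity = 1, parsimony = 1))
  expect_true(tr$exact)
})

test_that("plan operations shift the expected sums analytically", {
  g <- generate_genome(100000, seed = 10)
  # duplication: one extra 10 kb copy on a 100 kb genome -> multiplicity 1.1
  tr <- corrupt_assembly(g, corruption_plan(op_duplicate(0, 10000), seed = 1))
  expect_equal(tr$expected$multiplicity, 1.1)
  expect_equal(tr$expected$coverage, 1)
  # gap insertion inflates scaffolds but not alignments
  trg <- corrupt_assembly(g, corruption_plan(op_insert_gap(50000, 200), seed = 1))
  expect_equal(trg$expected$sum_s, 100200)
  expect_equal(trg$expected$sum_a, 100000)
  expect_equal(trg$expected$validity, 100000 / 100200)
  # fragmentation alone changes nothing
  trf <- corrupt_assembly(g, corruption_plan(op_fragment(c(30000, 60000)),
                                             seed = 1))
  expect_equal(nrow(trf$assembly), 3)
  expect_equal(trf$expected$multiplicity, 1)
  # chimera adds alignable sequence from two loci
  trc <- corrupt_assembly(g, corruption_plan(
    op_chimera(rbind(c(0, 2000), c(80000, 82000))), seed = 1))
  expect_equal(trc$expected$sum_a, 104000)
  expect_equal(trc$expected$multiplicity, 1.04)
})

test_that("the exact aligner recovers plan-predicted metrics", {
  g <- generate_genome(30000, seed = 11)
  plan <- corruption_plan(
    op_fragment(c(9000, 21000)),
    op_insert_gap(4000, 60),
    op_duplicate(12000, 13500, copies = 2),
    op_chimera(rbind(c(500, 1400), c(25000, 25900))),
    seed = 11
  )
  tr <- corrupt_assembly(g, plan)
  al <- align_exact(tr$assembly, g)
  obs <- compass(tr$assembly, g, al)
  expect_equal(obs$multiplicity, tr$expected$multiplicity, tolerance = 1e-9)
  expect_equal(obs$sum_a, tr$expected$sum_a)
  expect_equal(obs$sum_c, tr$expected$sum_c)
})

test_that("the exact aligner reports minus-strand matches in scaffold coordinates", {
  g <- generate_genome(5000, seed = 12)
  piece <- substring(g$seq, 1001, 3000)
  rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(piece)))
  asm <- assembly(c(flipped = rc))
  al <- align_exact(asm, g)
  expect_equal(nrow(al), 1)
  expect_equal(al$strand, "-")
  expect_equal(c(al$r_start, al$r_end), c(1000L, 3000L))
  expect_equal(c(al$s_start, al$s_end), c(0L, 2000L))
})

test_that("repeat collapse shrinks the assembly relative to the covered reference", {
  spec <- tibble::tibble(unit_length = 2000, copies = 3)
  g <- generate_genome(60000, seed = 13, repeat_spec = spec)
  tr <- corrupt_assembly(g, corruption_plan(op_collapse_repeat(1), seed = 13))
  expect_false(tr$exact)
  al <- align_exact(tr$assembly, g)
  obs <- compass(tr$assembly, g, al)
  # the remaining copy aligns to all three repeat loci: coverage stays 1
  expect_equal(obs$coverage, 1, tolerance = 1e-6)
  # but 4 kb of assembly was deleted, so parsimony (cost) drops below 1
  expect_lt(obs$parsimony, 1)
  expect_equal(obs$sum_s, 56000)
})

test_that("substitutions erode tag matching only gently at low rates", {
  g <- generate_genome(20000, seed = 14)
  tr <- corrupt_assembly(g, corruption_plan(op_substitute(0.005), seed = 14))
  expect_false(identical(tr$assembly$seq, g$seq))
  rep <- vfr_tag_report(tibble::tibble(vfr_id = "v", seq = g$seq), tr$assembly)
  # P(tag survives) = P(Binom(100, .005) <= 5) ~ 0.9999; 20 fragments
  expect_gte(rep$summary_score, 0.9 * rep$n_pairs)
  expect_equal(rep$n_pairs, 20)
})

test_that("fragmentation-only assemblies have the planned N50", {
  g <- generate_genome(25000, seed = 15)
  bps <- c(4000, 7000, 15000, 21000)
  tr <- corrupt_assembly(g, corruption_plan(op_fragment(bps), seed = 15))
  planned <- diff(c(0, bps, 25000))
  expect_equal(nx(tr$assembly$length, 50), oracle_nx(planned, 50))
  expect_setequal(tr$assembly$length, planned)
})

test_that("fosmid sampling is reproducible and traceable to source intervals", {
  g <- generate_genome(120000, seed = 16)
  f1 <- sample_fosmids(g, 3, seed = 17)
  f2 <- sample_fosmids(g, 3, seed = 17)
  expect_identical(f1$seq, f2$seq)
  expect_true(all(f1$length >= 35000 & f1$length <= 40000))
  expect_equal(substring(g$seq, f1$src_start + 1, f1$src_end), f1$seq)
  expect_equal(nrow(sample_fosmids(g, 0, seed = 1)), 0)
})

test_that("a fosmid from a faithful assembly validates end to end", {
  g <- generate_genome(120000, seed = 18)
  fos <- sample_fosmids(g, 1, seed = 19)
  asm <- assembly(setNames(g$seq, "s1"), label = "perfect")
  al <- align_exact(asm, fos, min_len = 1000)
  vfrs <- derive_vfrs(fos, al)
  expect_equal(nrow(vfrs), 1)
  expect_equal(vfrs$length, fos$length)
  expect_equal(vfrs$seq, fos$seq)
})

test_that("fixtures write deterministically and round-trip", {
  g <- generate_genome(10000, seed = 20)
  tr <- corrupt_assembly(g, random_plan(10000, seed = 20))
  d1 <- file.path(tempdir(), "fix_a"); d2 <- file.path(tempdir(), "fix_b")
  write_fixture(tr, d1); write_fixture(tr, d2)
  expect_identical(readLines(file.path(d1, "assembly.fa")),
                   readLines(file.path(d2, "assembly.fa")))
  truth <- jsonlite::read_json(file.path(d1, "truth.json"))
  expect_equal(truth$seed, 20)
  back <- read_assembly_fasta(file.path(d1, "genome.fa"))
  expect_equal(back$seq, g$seq)
})
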