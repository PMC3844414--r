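demo_dirs <- function(metrics, lower = character()) {
  setNames(ifelse(metrics %in% lower, "lower_better", "higher_better"), metrics)
}

test_that("z-scores use the sample sd and respect metric direction", {
  tbl <- tibble::tibble(assembly = c("a", "b", "c"), m1 = c(10, 20, 30))
  z <- zscore_rank(tbl, demo_dirs("m1"))
  expect_equal(sort(z$m1), c(-1, 0, 1))   # sd = 10 with n-1 denominator
  expect_equal(z$assembly[1], "c")
  # lower_better negates
  tbl2 <- tibble::tibble(assembly = c("a", "b"), m = c(5, 15))
  z2 <- zscore_rank(tbl2, demo_dirs("m", lower = "m"))
  expect_equal(z2$m[z2$assembly == "a"], sqrt(2) / 2, tolerance = 1e-12)
  expect_equal(z2$m[z2$assembly == "b"], -sqrt(2) / 2, tolerance = 1e-12)
  # population sd option scales accordingly
  zp <- zscore_rank(tbl, demo_dirs("m1"), sd_type = "population")
  expect_equal(sort(zp$m1), c(-1, 0, 1) * sqrt(3 / 2), tolerance = 1e-12)
})

test_that("per-metric z columns sum to zero and missing values contribute zero", {
  set.seed(81)
  tbl <- tibble::tibble(assembly = letters[1:6],
                        m1 = rnorm(6), m2 = runif(6) * 100, m3 = rnorm(6))
  tbl$m2[3] <- NA
  z <- zscore_rank(tbl, demo_dirs(c("m1", "m2", "m3")))
  expect_equal(sum(z$m1), 0, tolerance = 1e-12)
  expect_equal(sum(z$m2), 0, tolerance = 1e-12)
  expect_equal(z$m2[z$assembly == "c"], 0)
  expect_equal(z$sum_z, z$m1 + z$m2 + z$m3)
})

test_that("a zero-spread metric warns and contributes nothing", {
  tbl <- tibble::tibble(assembly = c("a", "b"), m1 = c(1, 1), m2 = c(0, 10))
  expect_warning(z <- zscore_rank(tbl, demo_dirs(c("m1", "m2"))), "zero spread")
  expect_equal(z$m1, c(0, 0))
})

test_that("z-score ranking is invariant to affine rescaling and direction flips", {
  set.seed(82)
  tbl <- tibble::tibble(assembly = letters[1:5], m1 = rnorm(5), m2 = rnorm(5))
  dirs <- demo_dirs(c("m1", "m2"))
  base <- zscore_rank(tbl, dirs)
  scaled <- dplyr::mutate(tbl, m1 = 3.7 * m1 + 11)
  expect_equal(zscore_rank(scaled, dirs)$sum_z, base$sum_z, tolerance = 1e-12)
  flipped <- dplyr::mutate(tbl, m2 = -m2)
  dirs_f <- demo_dirs(c("m1", "m2"), lower = "m2")
  expect_equal(zscore_rank(flipped, dirs_f)$sum_z, base$sum_z, tolerance = 1e-12)
})

test_that("leave-one-out bounds bracket and reduce to halves for twin metrics", {
  set.seed(83)
  tbl <- tibble::tibble(assembly = letters[1:4], m1 = rnorm(4), m2 = rnorm(4),
                        m3 = rnorm(4))
  lb <- loo_bounds(tbl, demo_dirs(c("m1", "m2", "m3")))
  expect_true(all(lb$min_sum <= lb$max_sum))
  # each bound is reachable by deleting one metric
  z <- zscore_rank(tbl, demo_dirs(c("m1", "m2", "m3")))
  z <- z[match(lb$assembly, z$assembly), ]
  loo_sums <- cbind(z$sum_z - z$m1, z$sum_z - z$m2, z$sum_z - z$m3)
  expect_equal(lb$min_sum, apply(loo_sums, 1, min))
  expect_equal(lb$max_sum, apply(loo_sums, 1, max))
  # two identical metrics: either deletion leaves half the sum
  twin <- tibble::tibble(assembly = letters[1:4], m1 = tbl$m1, m2 = tbl$m1)
  lt <- loo_bounds(twin, demo_dirs(c("m1", "m2")))
  expect_equal(lt$min_sum, lt$max_sum)
  expect_equal(lt$min_sum, lt$sum_z / 2, tolerance = 1e-12)
  # a single metric cannot be deleted
  expect_error(loo_bounds(tbl[c("assembly", "m1")], demo_dirs("m1")),
               "at least 2 metrics")
})

test_that("perfectly correlated metrics give zero-width bounds after halving", {
  tbl <- tibble::tibble(assembly = letters[1:4],
                        m1 = c(1, 2, 3, 4), m2 = c(10, 20, 30, 40))
  lb <- loo_bounds(tbl, demo_dirs(c("m1", "m2")))
  expect_equal(lb$max_sum - lb$min_sum, rep(0, 4), tolerance = 1e-12)
})

test_that("average ranks use direction, midranks for ties, and skip missing", {
  tbl <- tibble::tibble(assembly = c("a", "b", "c"), m = c(3, 1, 2))
  ar <- average_rank(tbl, demo_dirs("m"))
  expect_equal(ar$avg_rank[match(c("a", "b", "c"), ar$assembly)], c(1, 3, 2))
  tie <- tibble::tibble(assembly = c("a", "b", "c"), m = c(5, 5, 1))
  art <- average_rank(tie, demo_dirs("m"))
  expect_equal(art$avg_rank[match(c("a", "b", "c"), art$assembly)], c(1.5, 1.5, 3))
  # missing values excluded from that metric
  tbl2 <- tibble::tibble(assembly = c("a", "b", "c"),
                         m1 = c(3, 1, 2), m2 = c(NA, 10, 20))
  ar2 <- average_rank(tbl2, demo_dirs(c("m1", "m2")))
  expect_equal(ar2$n_metrics[match("a", ar2$assembly)], 1)
})

test_that("metric correlations recover exact linear relations", {
  tbl <- tibble::tibble(assembly = c("a", "b", "c"),
                        m1 = c(1, 2, 3), m2 = c(2, 4, 6), m3 = c(3, 2, 1))
  mc <- metric_correlations(tbl)
  r12 <- mc$r[mc$metric1 == "m1" & mc$metric2 == "m2"]
  r13 <- mc$r[mc$metric1 == "m1" & mc$metric2 == "m3"]
  expect_equal(r12, 1)
  expect_equal(r13, -1)
  # too few complete pairs -> missing
  tbl$m2[1:2] <- NA
  mc2 <- metric_correlations(tbl)
  expect_true(is.na(mc2$r[mc2$metric1 == "m1" & mc2$metric2 == "m2"]))
})

test_that("the paired-read summary score normalises within species", {
  tbl <- tibble::tibble(assembly = c("x", "y"),
                        error_free_bases = c(100, 50),
                        original_n50 = c(20, 10),
                        broken_n50 = c(10, 10))
  sc <- reapr_summary(tbl)
  expect_equal(sc$reapr_score, c(1, 1))
  # a single assembly self-normalises to 1
  expect_equal(reapr_summary(tbl[1, ])$reapr_score, 1)
  # scale invariance
  doubled <- dplyr::mutate(tbl, dplyr::across(-assembly, ~ .x * 2))
  expect_equal(reapr_summary(doubled)$reapr_score, sc$reapr_score)
  # broken N50 cannot exceed the original
  bad <- dplyr::mutate(tbl, broken_n50 = c(30, 10))
  expect_error(reapr_summary(bad), "exceed")
  zero <- dplyr::mutate(tbl, error_free_bases = 0)
  expect_error(reapr_summary(zero), "positive maximum")
})

test_that("the registry declares the ten key metrics and round-trips as JSON", {
  reg <- key_metric_registry()
  expect_equal(nrow(reg), 10)
  expect_equal(sum(reg$direction == "lower_better"), 1)
  expect_equal(reg$metric[reg$direction == "lower_better"], "gene_sized_absdiff")
  expect_setequal(reg$metric[reg$external],
                  c("cegma_core_genes", "optmap_level1", "optmap_level123"))
  dirs <- registry_directions()
  path <- tempfile(fileext = ".json")
  jsonlite::write_json(as.list(dirs), path, auto_unbox = TRUE)
  expect_equal(unlist(jsonlite::read_json(path)), dirs)
})

test_that("metric tables round-trip through CSV with a directions sidecar", {
  tbl <- tibble::tibble(assembly = c("a", "b", "c"),
                        ng50_scaffold = c(1e6, 2e6, NA),
                        reapr_score = c(0.5, 1, 0.25))
  path <- tempfile(fileext = ".csv")
  write_metric_table(tbl, path)
  back <- read_metric_table(path)
  expect_equal(tibble::as_tibble(back), tbl, ignore_attr = TRUE)
  expect_equal(attr(back, "directions"),
               registry_directions()[c("ng50_scaffold", "reapr_score")])
  # master export keeps registry column order and blanks missing metrics
  out <- tempfile(fileext = ".csv")
  master <- export_master_table(tbl, out)
  expect_equal(names(master), c("assembly", key_metric_registry()$metric))
  expect_true(all(is.na(master$cegma_core_genes)))
  line1 <- readLines(out)[2]
  expect_false(grepl("\\.$", line1))  # missing written as empty, not "."
  # re-export of unchanged results is byte-identical
  out2 <- tempfile(fileext = ".csv")
  export_master_table(tbl, out2)
  expect_identical(readLines(out), readLines(out2))
})

test_that("rank_assemblies combines z-scores, bounds and average ranks", {
  set.seed(84)
  tbl <- tibble::tibble(assembly = letters[1:5],
                        m1 = rnorm(5), m2 = rnorm(5), m3 = rnorm(5))
  res <- rank_assemblies(tbl, demo_dirs(c("m1", "m2", "m3")))
  expect_equal(res$rank, 1:5)
  expect_true(all(diff(res$sum_z) <= 0))
  expect_true(all(res$min_sum <= res$max_sum))
})
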