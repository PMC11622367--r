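mk_summary <- function(unmod, areas, n_fpop, positions) {
  forms <- if (length(areas) == 0) NULL else
    data.frame(form_key = paste0("SEQ|f", seq_along(areas)), area = areas,
               n_fpop = n_fpop, positions = positions, stringsAsFactors = FALSE)
  area_summary(unmod, forms, sequence = "AAAAMAAAWKAA")
}

test_that("peptide EOM is the modified share of the total area", {
  expect_equal(peptide_eom(mk_summary(75, 25, 1L, "5")), 0.25)
  expect_equal(peptide_eom(mk_summary(100, numeric(0), integer(0), character(0))), 0)
  # two modified forms: 50 / (50 + 50)
  expect_equal(peptide_eom(mk_summary(50, c(30, 20), c(1L, 1L), c("5", "5"))), 0.5)
  # other-class-only form joins the denominator but never the numerator
  expect_equal(peptide_eom(mk_summary(50, c(30, 20), c(1L, 0L), c("5", ""))),
               30 / 100)
  expect_error(peptide_eom(mk_summary(NA, 25, 1L, "5")), "contract")
  expect_error(peptide_eom(mk_summary(0, 25, 1L, "5")), "contract")
})

test_that("residue EOM supports both denominator readings", {
  s <- mk_summary(70, 30, 1L, "5")
  expect_equal(residue_eom(s, 5, "literal"), 0.3)
  expect_equal(residue_eom(s, 5, "all_forms"), 0.3)  # single-residue case agrees
  s2 <- mk_summary(60, c(30, 10), c(1L, 1L), c("5", "9"))
  expect_equal(residue_eom(s2, 5, "all_forms"), 30 / 100)
  expect_equal(residue_eom(s2, 5, "literal"), 30 / 90)
  expect_equal(residue_eom(s2, 3, "literal"), 0)  # residue with no modified form
})

test_that("APO weights forms by their event count", {
  # single mono-oxidized form collapses APO to the peptide EOM
  s1 <- mk_summary(75, 25, 1L, "5")
  expect_equal(apo(s1), peptide_eom(s1))
  # one triply modified form: numerator multiplied by 3
  s3 <- mk_summary(70, 30, 3L, "5,9,12")
  expect_equal(apo(s3), 0.9)
  expect_equal(peptide_eom(s3), 0.3)
  expect_equal(apo(mk_summary(100, numeric(0), integer(0), character(0))), 0)
})

test_that("replicate aggregation matches closed forms in both mean modes", {
  out <- aggregate_replicates(c(0.2, 0.2, 0.2))
  expect_equal(out$mean, 0.2)
  expect_equal(out$mean, aggregate_replicates(c(0.2, 0.2, 0.2), "geometric")$mean)

  expect_equal(aggregate_replicates(c(0.1, 0.4))$mean, 0.25)
  expect_equal(aggregate_replicates(c(0.1, 0.4), "geometric")$mean, 0.2)
  expect_equal(aggregate_replicates(c(0.1, 0.4))$sd, stats::sd(c(0.1, 0.4)))

  single <- aggregate_replicates(0.3)
  expect_equal(single$mean, 0.3)
  expect_equal(single$sd, 0)
  expect_true("low_n" %in% single$flags)

  withzero <- aggregate_replicates(c(0, 0.4), "geometric")
  expect_equal(withzero$mean, 0)
  expect_true("geomean_zero" %in% withzero$flags)
  expect_error(aggregate_replicates(numeric(0)), "empty")
})

test_that("control subtraction reports, clips and flags correctly", {
  expect_equal(subtract_control(0.30, 0.05)$net, 0.25)

  clipped <- subtract_control(0.05, 0.08, clip_negative = TRUE)
  expect_equal(clipped$net, 0)
  expect_match(clipped$flags, "clipped_negative:-0.03", fixed = TRUE)

  unclipped <- subtract_control(0.05, 0.08)
  expect_equal(unclipped$net, -0.03)
  expect_true("negative_net" %in% unclipped$flags)

  noctrl <- subtract_control(0.30, NA_real_)
  expect_equal(noctrl$net, 0.30)
  expect_true("no_control" %in% noctrl$flags)
})

test_that("condition comparison is a guarded Welch t-test", {
  same <- compare_conditions(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(same$delta, 0)
  expect_equal(same$p, 1)

  # degenerate zero-variance lists: variance floor keeps the test defined
  far <- compare_conditions(c(0.1, 0.1, 0.1), c(0.4, 0.4, 0.4))
  expect_equal(far$delta, -0.3)
  expect_lt(far$p, 1e-6)

  skipped <- compare_conditions(0.1, c(0.2, 0.3))
  expect_true(is.na(skipped$p))
  expect_equal(skipped$flags, "skipped_low_n")

  # agrees with stats::t.test away from the degenerate case
  set.seed(21)
  for (i in 1:10) {
    a <- runif(5); b <- runif(6)
    ours <- compare_conditions(a, b)
    ref <- stats::t.test(a, b)
    expect_equal(ours$t, unname(ref$statistic), tolerance = 1e-10)
    expect_equal(ours$p, ref$p.value, tolerance = 1e-10)
  }
})

test_that("area summation groups by file/protein/peptide/form over charges", {
  rec <- annotate_forms(suppressWarnings(
    attach_sample_map(tiny_psm(), tiny_sample_map("A"), "exact")),
    "generic")$records
  sa <- summarize_areas(rec)
  unmod <- sa$areas[sa$areas$form_key == "AAAAMK|unmod", ]
  expect_equal(unmod$area, 1000)  # z=2 600 + z=3 400

  # missing abundance is skipped and counted, never treated as zero
  rec$abundance[1] <- NA
  expect_warning(sa2 <- summarize_areas(rec), "missing abundance")
  expect_equal(sa2$areas$area[sa2$areas$form_key == "AAAAMK|unmod"], 400)
  expect_equal(sa2$audit$stage, "missing_abundance")

  # random table: group sums equal independent brute-force accumulation
  set.seed(31)
  exp <- generate_experiment(small_config())
  ann <- attach_sample_map(exp$psm, exp$sample_map, "exact")
  rec <- annotate_forms(ann, "generic")$records[sample(1:500, 50), ]
  sa3 <- summarize_areas(rec)$areas
  for (i in sample(nrow(sa3), 10)) {
    g <- sa3[i, ]
    brute <- 0
    for (j in seq_len(nrow(rec)))
      if (rec$spectrum_file[j] == g$file && rec$accession[j] == g$protein &&
          rec$sequence[j] == g$sequence && rec$form_key[j] == g$form_key)
        brute <- brute + rec$abundance[j]
    expect_equal(g$area, brute)
  }
})
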