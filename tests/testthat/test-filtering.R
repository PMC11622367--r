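annotated <- function(psm, sm) {
  ann <- suppressWarnings(attach_sample_map(psm, sm, "exact"))
  annotate_forms(ann, "generic")$records
}

test_that("node duplicates are removed deterministically and idempotently", {
  psm <- tiny_psm()
  # the same unmodified peptide reported by 5 nodes in one file
  dup <- psm[rep(1, 5), ]
  dup$search_node <- paste0("n", 1:5)
  dup$abundance <- c(600, 600, 500, 600, 100)
  rec <- annotate_forms(rbind(dup, psm[-1, ]), "generic")$records
  dd <- deduplicate_nodes(rec)
  expect_equal(sum(dd$records$sequence == "AAAAMK" &
                   dd$records$form_key == "AAAAMK|unmod" &
                   dd$records$charge == 2L), 1L)
  expect_equal(sum(dd$audit$rows_removed), 4L)
  # survivor is the max-abundance copy (ties -> first)
  expect_equal(dd$records$abundance[dd$records$form_key == "AAAAMK|unmod" &
                                    dd$records$charge == 2L], 600)

  # idempotence and identity on duplicate-free input
  again <- deduplicate_nodes(dd$records)
  expect_identical(again$records, dd$records)
  expect_equal(nrow(again$audit), 0L)

  # the set of distinct (file, sequence, form) triples is preserved
  key <- function(r) unique(paste(r$spectrum_file, r$sequence, r$form_key))
  expect_setequal(key(dd$records), key(rec))
})

test_that("different charge states are never collapsed by deduplication", {
  rec <- annotate_forms(tiny_psm(), "generic")$records
  dd <- deduplicate_nodes(rec)
  expect_equal(nrow(dd$records), nrow(rec))  # z=2 and z=3 unmod both kept
})

test_that("peptides without unmodified area are excluded per file", {
  psm <- tiny_psm()
  sm <- tiny_sample_map("A", reps = 1)
  rec <- annotated(psm, sm)
  areas <- summarize_areas(deduplicate_nodes(rec)$records)$areas
  # P2/CCWNK has only an unmodified form: kept, EOM 0
  fm <- filter_missing_unmodified(areas)
  expect_true(any(fm$areas$sequence == "CCWNK"))

  # modified form with no unmodified observation: excluded and audited
  psm2 <- psm[psm$modifications_raw != "", ]
  rec2 <- annotated(psm2, sm)
  areas2 <- summarize_areas(deduplicate_nodes(rec2)$records)$areas
  fm2 <- filter_missing_unmodified(areas2)
  expect_false(any(fm2$areas$sequence == "AAAAMK"))
  expect_equal(fm2$audit$stage, "missing_unmodified")
  # conservation: rows in = rows kept + rows audited
  expect_equal(nrow(areas2), nrow(fm2$areas) + sum(fm2$audit$rows_removed))
})

test_that("an unmodified area of exactly zero is treated as missing", {
  areas <- data.frame(file = "f1", condition = "A", replicate = 1L,
                      treatment = "laser", protein = "P1", sequence = "AMK",
                      form_key = c("AMK|unmod", "AMK|2:Oxidation"),
                      area = c(0, 500), n_fpop = c(0L, 1L),
                      positions = c("", "2"), protein_start = NA_integer_,
                      stringsAsFactors = FALSE)
  fm <- filter_missing_unmodified(areas)
  expect_equal(nrow(fm$areas), 0L)
  expect_equal(sum(fm$audit$rows_removed), 2L)
})

test_that("replicate support requires modified evidence in enough laser replicates", {
  per_rep <- data.frame(condition = "A", protein = "P1", target = "PEPK",
                        treatment = "laser", replicate = 1:4,
                        eom = c(0.2, 0, 0, 0),
                        evidence = c(TRUE, FALSE, FALSE, FALSE),
                        stringsAsFactors = FALSE)
  # seen in 1 of 4 replicates, threshold 3 -> dropped
  out <- filter_replicate_support(per_rep, 3L)
  expect_equal(nrow(out$per_rep), 0L)
  expect_match(out$audit$reason, "1 laser replicate")

  # seen in 3 of 3, threshold 3 -> kept (boundary inclusive)
  per3 <- per_rep[1:3, ]; per3$evidence <- TRUE
  expect_equal(nrow(filter_replicate_support(per3, 3L)$per_rep), 3L)

  # threshold 1 reproduces unfiltered behavior
  expect_equal(nrow(filter_replicate_support(per_rep, 1L)$per_rep), 4L)
  expect_error(filter_replicate_support(per_rep, 0L), ">= 1")

  # control rows ride along with their target but contribute no evidence
  withc <- rbind(per_rep, within(per_rep, treatment <- "control"))
  withc$evidence[withc$treatment == "laser"] <- TRUE
  expect_equal(nrow(filter_replicate_support(withc, 3L)$per_rep), 8L)
})

test_that("differential analysis keeps only proteins common to all conditions", {
  out <- filter_common_proteins(list(A = c("P1", "P2"), B = c("P2", "P3")))
  expect_equal(out$proteins, "P2")
  expect_equal(nrow(out$audit), 2L)

  ident <- filter_common_proteins(list(A = c("P1", "P2"), B = c("P1", "P2")))
  expect_equal(ident$proteins, c("P1", "P2"))
  expect_equal(nrow(ident$audit), 0L)

  expect_error(filter_common_proteins(list(A = "P1")), "at least 2")

  # 3 conditions vs brute-force set algebra on random sets
  set.seed(9)
  for (i in 1:10) {
    sets <- lapply(1:3, function(j) sample(sprintf("P%02d", 1:20), 12))
    names(sets) <- c("A", "B", "C")
    brute <- sort(Filter(function(p) all(vapply(sets, function(s) p %in% s,
                                                logical(1))),
                         unique(unlist(sets))))
    expect_equal(filter_common_proteins(sets)$proteins, brute)
  }
})

test_that("the full filter chain conserves rows and is idempotent", {
  cfg <- small_config(dup_injection_rate = 0.4, dropout_rate = 0.1)
  exp <- generate_experiment(cfg)
  ann <- attach_sample_map(exp$psm, exp$sample_map, "exact")
  rec <- annotate_forms(ann, "generic")$records
  dd <- deduplicate_nodes(rec)
  expect_equal(nrow(rec), nrow(dd$records) + sum(dd$audit$rows_removed))
  dd2 <- deduplicate_nodes(dd$records)
  expect_identical(dd2$records, dd$records)

  areas <- summarize_areas(dd$records)$areas
  fm <- filter_missing_unmodified(areas)
  expect_equal(nrow(areas), nrow(fm$areas) + sum(fm$audit$rows_removed))
  fm2 <- filter_missing_unmodified(fm$areas)
  expect_identical(fm2$areas, fm$areas)
  expect_equal(nrow(fm2$audit), 0L)
})
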