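canonical_tsv <- function(df) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

test_that("tables are read with columns and row order preserved", {
  df <- data.frame("Master Protein Accessions" = c("P1", "P2", "P1"),
                   "Sequence" = c("PEPK", "AAAR", "PEPK"),
                   "Modifications" = c("", "", ""),
                   "Precursor Abundance" = c("100", "200", "300"),
                   "Spectrum File" = "f1.raw", "Extra" = "x",
                   check.names = FALSE)
  rows <- read_psm_table(canonical_tsv(df))
  expect_equal(nrow(rows), 3L)
  expect_true("Extra" %in% names(rows))  # passthrough, mapping happens later
  expect_equal(rows$Sequence, df$Sequence)

  empty <- df[0, ]
  expect_error(read_psm_table(canonical_tsv(empty)), "empty table")
  expect_error(read_psm_table("no/such/file.tsv"), "no such file")
})

test_that("column mapping parses abundance and enforces the schema", {
  rows <- data.frame("Annotated Sequence" = "PEPTIDE", "Acc" = "P1",
                     "Mods" = "", "Abundance" = "1,000", "File" = "a.raw",
                     check.names = FALSE)
  mapping <- c("Acc" = "accession", "Annotated Sequence" = "sequence",
               "Mods" = "modifications_raw", "Abundance" = "abundance",
               "File" = "spectrum_file")
  rec <- apply_column_mapping(rows, mapping)
  expect_equal(rec$sequence, "PEPTIDE")
  expect_equal(rec$abundance, 1000)      # thousands separator tolerated
  expect_false("Abundance" %in% names(rec))

  # blank abundance is missing, never zero
  rows$Abundance <- ""
  expect_true(is.na(apply_column_mapping(rows, mapping)$abundance))

  expect_error(apply_column_mapping(rows, mapping[-3]),
               "modifications_raw")
  expect_error(apply_column_mapping(rows, c(mapping, "Nope" = "charge"))
               , NA)  # absent optional source columns are tolerated
  bad <- mapping; names(bad)[4] <- "NoSuchColumn"
  expect_error(apply_column_mapping(rows, bad), "NoSuchColumn")
})

test_that("sample-map annotation classifies every file exactly once", {
  rec <- data.frame(accession = "P1", sequence = "PEPK",
                    modifications_raw = "", abundance = 1,
                    spectrum_file = c("s1_L.raw", "s1_C.raw"),
                    stringsAsFactors = FALSE)
  sm <- data.frame(file_pattern = c("_L", "_C"), condition = "A",
                   replicate = 1L, treatment = c("laser", "control"))
  ann <- attach_sample_map(rec, sm, match_mode = "substring")
  expect_equal(nrow(ann), nrow(rec))  # never alters record count
  expect_equal(ann$treatment, c("laser", "control"))

  # a file matching rules with different assignments is fatal
  sm2 <- data.frame(file_pattern = c("s1", "_C"), condition = "A",
                    replicate = c(1L, 2L), treatment = c("laser", "control"))
  expect_error(attach_sample_map(rec, sm2, "substring"), "different assignments")

  # unmatched file is fatal and names the file
  expect_error(attach_sample_map(rec, sm[1, ], "substring"), "s1_C.raw")
})

test_that("a laser-only sample map warns that controls are absent", {
  cfg <- small_config()
  sm <- tiny_sample_map(conditions = c("A", "B"), reps = 3)
  rec <- data.frame(accession = "P1", sequence = "PEPK",
                    modifications_raw = "", abundance = 1,
                    spectrum_file = sm$file_pattern, stringsAsFactors = FALSE)
  expect_warning(attach_sample_map(rec, sm, "exact"), "no control files")
})

test_that("TMT channel expansion fans rows out per mapped channel", {
  set.seed(5)
  n <- 10
  rows <- data.frame(Acc = "P1", Seq = "PEPK", Mods = "", File = "f1.raw",
                     stringsAsFactors = FALSE)
  rows <- rows[rep(1, n), ]
  channels <- sprintf("TMT%d", 1:6)
  for (ch in channels) rows[[ch]] <- round(runif(n, 10, 100), 2)
  mapping <- c(Acc = "accession", Seq = "sequence",
               Mods = "modifications_raw", File = "spectrum_file")
  cmap <- data.frame(file_pattern = channels,
                     condition = rep(c("A", "B"), each = 3),
                     replicate = rep(1:3, 2), treatment = "laser")
  rec <- expand_tmt_channels(rows, cmap, mapping)
  expect_equal(nrow(rec), n * 6L)
  expect_setequal(unique(rec$spectrum_file), paste0("f1.raw::", channels))
  # brute-force column sums
  expect_equal(sum(rec$abundance), sum(sapply(channels, function(ch) sum(rows[[ch]]))))

  rows$TMT1[1] <- ""
  rec <- expand_tmt_channels(rows, cmap, mapping)
  expect_equal(sum(is.na(rec$abundance)), 1L)
  expect_error(expand_tmt_channels(rows[, -5], cmap, mapping), "TMT1")
})

test_that("read -> map -> write -> re-read is the identity on the five columns", {
  exp <- generate_experiment(small_config())
  path <- withr::local_tempfile(fileext = ".tsv")
  df <- exp$psm[1:50, ]
  names(df)[1:5] <- c("Master Protein Accessions", "Sequence", "Modifications",
                      "Precursor Abundance", "Spectrum File")
  utils::write.table(data.frame(lapply(df, function(x)
    if (is.double(x)) sprintf("%.17g", x) else x), check.names = FALSE),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  rec <- apply_column_mapping(read_psm_table(path), default_column_mapping("pd"))
  expect_equal(rec$accession, df[["Master Protein Accessions"]])
  expect_equal(rec$sequence, df[["Sequence"]])
  expect_equal(rec$modifications_raw, df[["Modifications"]])
  expect_equal(rec$abundance, df[["Precursor Abundance"]])
  expect_equal(rec$spectrum_file, df[["Spectrum File"]])
})
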