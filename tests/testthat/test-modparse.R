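test_that("each dialect grammar parses localized events", {
  expect_equal(nrow(parse_modifications("", "PEPTIDE", "generic")), 0L)
  expect_equal(nrow(parse_modifications(NA, "PEPTIDE", "pd")), 0L)

  ev <- parse_modifications("5M(15.9949)", "AAAAMK", "fragpipe")
  expect_equal(ev$position, 5L)
  expect_equal(ev$residue, "M")
  expect_equal(ev$mass_delta, 15.9949)

  # hand-parsed PD token: count prefix, shared name, bracketed site list
  ev <- parse_modifications("2xOxidation [M5; W9]", "AAAAMAAAWK", "pd")
  expect_equal(ev$position, c(5L, 9L))
  expect_equal(ev$residue, c("M", "W"))
  expect_equal(ev$name, rep("Oxidation", 2))

  ev <- parse_modifications("1xOxidation [M5]; 1xCarbamidomethyl [C2]",
                            "ACAAMK", "pd")
  expect_equal(ev$position, c(2L, 5L))
  expect_equal(ev$name, c("Carbamidomethyl", "Oxidation"))

  ev <- parse_modifications("5:M:Oxidation:15.9949; 0:-:Acetyl:42.0106",
                            "AAAAMK", "generic")
  expect_equal(ev$position, c(0L, 5L))
  expect_equal(ev$residue, c("", "M"))

  ev <- parse_modifications("N-term(42.0106), 5M(15.9949)", "AAAAMK", "fragpipe")
  expect_equal(ev$position, c(0L, 5L))
})

test_that("inconsistent residue tokens raise a quarantineable parse error", {
  expect_error(parse_modifications("5W(15.9949)", "AAAAMK", "fragpipe"),
               class = "fpopquant_parse_error")
  expect_error(parse_modifications("1xOxidation [M9]", "AAAAMK", "pd"),
               class = "fpopquant_parse_error")
  expect_error(parse_modifications("2xOxidation [M5]", "AAAAMK", "pd"),
               class = "fpopquant_parse_error")
  expect_error(parse_modifications("gibberish", "AAAAMK", "generic"),
               class = "fpopquant_parse_error")
})

test_that("generic serialize/parse round trip is the identity", {
  set.seed(11)
  for (i in 1:20) {
    seqchr <- paste(sample(LETTERS[1:20], 10, replace = TRUE), collapse = "")
    k <- sample(0:3, 1)
    pos <- sort(sample(1:10, k))
    ev <- data.frame(position = pos,
                     residue = substring(seqchr, pos, pos),
                     name = sample(c("Oxidation", "Dioxidation"), k, replace = TRUE),
                     mass_delta = round(runif(k, 1, 60), 4),
                     stringsAsFactors = FALSE)
    s <- serialize_modifications(ev, "generic")
    back <- parse_modifications(s, seqchr, "generic")
    expect_equal(back$position, ev$position)
    expect_equal(back$name, ev$name)
    expect_equal(back$mass_delta, ev$mass_delta)
  }
})

test_that("classification follows the catalog and is order-invariant", {
  cat <- fpop_catalog()
  ev <- data.frame(position = c(5L, 2L, 0L, 7L),
                   residue = c("M", "C", "", "W"),
                   name = NA_character_,
                   mass_delta = c(15.9949, 57.0215, 42.0106, 3.9949),
                   stringsAsFactors = FALSE)
  cl <- classify_events(ev, cat)
  expect_equal(cl$mod_class, c("fpop", "fixed", "other", "fpop"))
  expect_equal(cl$name, c("Oxidation", "Carbamidomethyl", "Acetyl",
                          "Trp->Kynurenine"))

  # permuting catalog rows never changes the classification
  set.seed(3)
  for (i in 1:5) {
    cl2 <- classify_events(ev, cat[sample(nrow(cat)), ])
    expect_identical(cl2$mod_class, cl$mod_class)
    expect_identical(cl2$name, cl$name)
  }
})

test_that("uncatalogued and N-terminal events are classed other", {
  # acetyl mass on an internal residue: not in catalog for that site
  ev <- data.frame(position = 3L, residue = "A", name = NA_character_,
                   mass_delta = 42.0106, stringsAsFactors = FALSE)
  expect_equal(classify_events(ev, fpop_catalog())$mod_class, "other")
  # N-terminal +16 never counts as FPOP (no Nterm entry at that mass)
  ev <- data.frame(position = 0L, residue = "", name = NA_character_,
                   mass_delta = 15.9949, stringsAsFactors = FALSE)
  expect_equal(classify_events(ev, fpop_catalog())$mod_class, "other")
})

test_that("count_fpop_mods counts only FPOP events", {
  mk <- function(classes) data.frame(position = seq_along(classes),
                                     residue = rep("A", length(classes)),
                                     name = rep("x", length(classes)),
                                     mass_delta = rep(1, length(classes)),
                                     mod_class = classes,
                                     stringsAsFactors = FALSE)
  expect_equal(count_fpop_mods(mk(character(0))), 0L)
  expect_equal(count_fpop_mods(mk(c("fpop", "fixed"))), 1L)
  expect_equal(count_fpop_mods(mk(c("fpop", "fpop", "fpop"))), 3L)
  expect_lte(count_fpop_mods(mk(c("fpop", "other"))), 2L)
})

test_that("form keys canonicalize event order and ignore fixed mods", {
  seqchr <- "ACAAMAAAWK"
  ev1 <- classify_events(parse_modifications(
    "5:M:Oxidation:15.9949; 9:W:Oxidation:15.9949", seqchr, "generic"))
  ev2 <- classify_events(parse_modifications(
    "9:W:Oxidation:15.9949; 5:M:Oxidation:15.9949", seqchr, "generic"))
  expect_identical(form_key(seqchr, ev1), form_key(seqchr, ev2))

  with_cam <- classify_events(parse_modifications(
    "5:M:Oxidation:15.9949; 2:C:Carbamidomethyl:57.0215", seqchr, "generic"))
  without <- classify_events(parse_modifications(
    "5:M:Oxidation:15.9949", seqchr, "generic"))
  expect_identical(form_key(seqchr, with_cam), form_key(seqchr, without))
  expect_identical(form_key("PEPTIDE", classify_events(
    parse_modifications("", "PEPTIDE", "generic"))), "PEPTIDE|unmod")
})

test_that("catalogs can be round-tripped through TSV and are validated", {
  path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(fpop_catalog(), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  expect_equal(read_catalog(path), fpop_catalog())
  bad <- data.frame(name = c("a", "b"), mass_delta = c(10, 10.001),
                    class = c("fpop", "fixed"), residues = "")
  expect_error(validate <- classify_events(
    data.frame(position = 1L, residue = "A", name = NA, mass_delta = 10),
    bad), "overlap")
})
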