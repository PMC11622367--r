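# Independent brute-force oracles and fixture builders. These re-derive
# every ratio by explicit loops over forms, independently of the package's
# vectorized implementations.

oracle_peptide_eom <- function(s) {
  num <- 0; den <- s$unmod_area
  for (i in seq_len(nrow(s$forms))) {
    den <- den + s$forms$area[i]
    if (s$forms$n_fpop[i] > 0) num <- num + s$forms$area[i]
  }
  num / den
}

oracle_residue_eom <- function(s, pos, mode) {
  num <- 0; all_forms <- 0
  for (i in seq_len(nrow(s$forms))) {
    all_forms <- all_forms + s$forms$area[i]
    ps <- as.integer(strsplit(s$forms$positions[i], ",")[[1]])
    if (length(ps) > 0 && pos %in% ps) num <- num + s$forms$area[i]
  }
  den <- if (mode == "literal") num + s$unmod_area else s$unmod_area + all_forms
  if (den == 0) 0 else num / den
}

oracle_apo <- function(s) {
  num <- 0; den <- s$unmod_area
  for (i in seq_len(nrow(s$forms))) {
    den <- den + s$forms$area[i]
    num <- num + s$forms$n_fpop[i] * s$forms$area[i]
  }
  num / den
}

# Random area summary: 12-residue peptide, 0-5 FPOP forms at distinct
# position sets (n_fpop = number of sites), plus optionally one
# other-class-only form (n_fpop = 0, no positions).
random_summary <- function(max_forms = 5, with_other = TRUE,
                           seq_len_pep = 12) {
  sequence <- paste(sample(LETTERS[1:20], seq_len_pep, replace = TRUE),
                    collapse = "")
  nf <- sample(0:max_forms, 1)
  forms <- NULL
  if (nf > 0) {
    rows <- lapply(seq_len(nf), function(i) {
      k <- sample(1:3, 1)
      pos <- sort(sample(seq_len(seq_len_pep), k))
      data.frame(form_key = paste0(sequence, "|f", i),
                 area = stats::runif(1, 0, 1000),
                 n_fpop = k, positions = paste(pos, collapse = ","),
                 stringsAsFactors = FALSE)
    })
    forms <- do.call(rbind, rows)
  }
  if (with_other && stats::runif(1) < 0.3) {
    other <- data.frame(form_key = paste0(sequence, "|other"),
                        area = stats::runif(1, 0, 500),
                        n_fpop = 0L, positions = "", stringsAsFactors = FALSE)
    forms <- rbind(forms, other)
  }
  area_summary(unmod_area = stats::runif(1, 1, 2000), forms = forms,
               sequence = sequence)
}

# small deterministic synthetic experiment for pipeline-level tests
small_config <- function(...) {
  defaults <- list(n_proteins = 5L, peptides_per_protein = 3L,
                   replicates_per_condition = 4L, control_replicates = 3L,
                   sigma = 0.15, seed = 42L)
  do.call(synth_config, utils::modifyList(defaults, list(...)))
}

# canonical 5-column test table
tiny_psm <- function() {
  data.frame(
    accession = c("P1", "P1", "P1", "P2"),
    sequence = c("AAAAMK", "AAAAMK", "AAAAMK", "CCWNK"),
    modifications_raw = c("", "5:M:Oxidation:15.9949", "", ""),
    abundance = c(600, 200, 400, 100),
    spectrum_file = c("A_R1_L.raw", "A_R1_L.raw", "A_R1_L.raw", "A_R1_L.raw"),
    charge = c(2L, 2L, 3L, 2L),
    search_node = c("n1", "n1", "n1", "n1"),
    stringsAsFactors = FALSE)
}

tiny_sample_map <- function(conditions = "A", reps = 1, with_control = FALSE) {
  rows <- expand.grid(replicate = seq_len(reps),
                      treatment = if (with_control) c("laser", "control") else "laser",
                      condition = conditions, stringsAsFactors = FALSE)
  rows$file_pattern <- sprintf("%s_R%d_%s.raw", rows$condition, rows$replicate,
                               ifelse(rows$treatment == "laser", "L", "C"))
  rows[, c("file_pattern", "condition", "replicate", "treatment")]
}
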