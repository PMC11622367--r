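# Reading heterogeneous PSM exports and mapping them to the canonical
# five-column schema: accession, sequence, modifications_raw, abundance,
# spectrum_file (plus optional charge, search_node, scan, protein_start).

CANONICAL <- c("accession", "sequence", "modifications_raw",
               "abundance", "spectrum_file")
OPTIONAL_CANONICAL <- c("charge", "search_node", "scan", "protein_start")

#' Read a PSM table from disk
#'
#' Reads a search-engine export with all source column names preserved and
#' every cell as trimmed character data; no interpretation happens here
#' (see [apply_column_mapping()]).
#'
#' @param path Path to the table.
#' @param dialect File format. `"auto"` (default) picks from the extension:
#'   `.tsv`/`.txt` tab-separated, `.csv` comma-separated, `.xlsx`/`.xls`
#'   spreadsheet. `"pd_export"` and `"fragpipe_psm"` are aliases kept for
#'   explicitness (spreadsheet and TSV respectively).
#' @param sheet Sheet number for spreadsheet input (default first).
#' @return A character `data.frame`, one row per PSM, source column names
#'   preserved, row order preserved.
#' @export
read_psm_table <- function(path,
                           dialect = c("auto", "generic_tsv", "generic_csv",
                                       "spreadsheet", "pd_export",
                                       "fragpipe_psm"),
                           sheet = 1) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("cannot read PSM table: no such file '", path, "'")
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext,
      tsv = "generic_tsv", txt = "generic_tsv", tab = "generic_tsv",
      csv = "generic_csv", xlsx = "spreadsheet", xls = "spreadsheet",
      stop("cannot auto-detect dialect from extension '.", ext,
           "'; pass dialect explicitly"))
  }
  if (dialect == "pd_export") dialect <- "spreadsheet"
  if (dialect == "fragpipe_psm") dialect <- "generic_tsv"
  rows <- switch(dialect,
    generic_tsv = utils::read.delim(path, colClasses = "character",
                                    check.names = FALSE, na.strings = NULL),
    generic_csv = utils::read.csv(path, colClasses = "character",
                                  check.names = FALSE, na.strings = NULL),
    spreadsheet = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading spreadsheets requires the 'readxl' package")
      x <- readxl::read_excel(path, sheet = sheet, col_types = "text")
      x <- as.data.frame(x, check.names = FALSE, stringsAsFactors = FALSE)
      x[] <- lapply(x, function(col) ifelse(is.na(col), "", col))
      x
    })
  if (nrow(rows) == 0L) stop("empty table: '", path, "' has headers but no data rows")
  rows[] <- lapply(rows, trimws)
  rows
}

#' Default column mappings for known search-engine exports
#'
#' @param dialect `"generic"`/`"pd"` (Proteome Discoverer consensus export
#'   names) or `"fragpipe"` (psm.tsv names).
#' @return Named character vector mapping source column name to canonical
#'   name; pass to [apply_column_mapping()] (override entries as needed).
#' @export
default_column_mapping <- function(dialect = c("generic", "pd", "fragpipe")) {
  dialect <- match.arg(dialect)
  if (dialect == "fragpipe") {
    c("Protein" = "accession",
      "Peptide" = "sequence",
      "Assigned Modifications" = "modifications_raw",
      "Intensity" = "abundance",
      "Spectrum File" = "spectrum_file",
      "Charge" = "charge")
  } else {
    c("Master Protein Accessions" = "accession",
      "Sequence" = "sequence",
      "Modifications" = "modifications_raw",
      "Precursor Abundance" = "abundance",
      "Spectrum File" = "spectrum_file",
      "Charge" = "charge",
      "Search Node" = "search_node")
  }
}

#' Map source columns onto the canonical PSM schema
#'
#' @param rows Raw row `data.frame` from [read_psm_table()].
#' @param mapping Named character vector `source_name = canonical_name`
#'   covering each of `accession`, `sequence`, `modifications_raw`,
#'   `abundance`, `spectrum_file` exactly once; optional targets `charge`,
#'   `search_node`, `scan`, `protein_start`.
#' @return A `data.frame` of canonical PSM records. Abundance is parsed as
#'   numeric with thousands separators tolerated; blank cells become `NA`
#'   (missing is distinct from zero and never imputed). Unmapped source
#'   columns are dropped.
#' @export
apply_column_mapping <- function(rows, mapping) {
  targets <- unname(mapping)
  bad <- setdiff(targets, c(CANONICAL, OPTIONAL_CANONICAL))
  if (length(bad) > 0L)
    stop("unknown canonical target(s) in mapping: ", paste(bad, collapse = ", "))
  dup <- targets[duplicated(targets)]
  if (length(dup) > 0L)
    stop("canonical target(s) mapped more than once: ", paste(unique(dup), collapse = ", "))
  # tolerate mapping entries whose optional source column is absent
  present <- names(mapping) %in% names(rows)
  missing_required <- setdiff(CANONICAL, targets[present])
  if (length(missing_required) > 0L) {
    absent_src <- names(mapping)[!present & targets %in% CANONICAL]
    if (length(absent_src) > 0L)
      stop("mapped column(s) absent from data: ", paste(absent_src, collapse = ", "))
    stop("column mapping does not cover canonical column(s): ",
         paste(missing_required, collapse = ", "))
  }
  mapping <- mapping[present]
  out <- rows[, names(mapping), drop = FALSE]
  names(out) <- unname(mapping)
  out$abundance <- parse_abundance(out$abundance)
  if ("charge" %in% names(out))
    out$charge <- suppressWarnings(as.integer(gsub("[^0-9-]", "", out$charge)))
  if ("protein_start" %in% names(out))
    out$protein_start <- suppressWarnings(as.integer(out$protein_start))
  if (any(!nzchar(out$sequence)))
    stop("empty peptide sequence in row(s) ",
         paste(utils::head(which(!nzchar(out$sequence)), 5), collapse = ", "))
  if (any(!nzchar(out$spectrum_file)))
    stop("empty spectrum file in row(s) ",
         paste(utils::head(which(!nzchar(out$spectrum_file)), 5), collapse = ", "))
  rownames(out) <- NULL
  out
}

parse_abundance <- function(x) {
  x <- gsub(",", "", trimws(as.character(x)), fixed = TRUE)
  out <- suppressWarnings(as.numeric(x))
  bad <- nzchar(x) & !tolower(x) %in% c("na", "nan") & is.na(out)
  if (any(bad))
    warning(sum(bad), " abundance value(s) could not be parsed and were set to missing")
  neg <- !is.na(out) & out < 0
  if (any(neg)) stop("negative abundance value(s) found")
  out
}

#' Read a sample map from a TSV file
#'
#' @param path TSV with columns `file_pattern`, `condition`, `replicate`,
#'   `treatment` (`laser` or `control`).
#' @return A validated sample-map `data.frame`.
#' @export
read_sample_map <- function(path) {
  sm <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  validate_sample_map(sm)
}

validate_sample_map <- function(sample_map) {
  req <- c("file_pattern", "condition", "replicate", "treatment")
  miss <- setdiff(req, names(sample_map))
  if (length(miss) > 0L)
    stop("sample map is missing column(s): ", paste(miss, collapse = ", "))
  sample_map$replicate <- as.integer(sample_map$replicate)
  if (anyNA(sample_map$replicate) || any(sample_map$replicate < 1L))
    stop("sample map replicate must be a positive integer")
  if (!all(sample_map$treatment %in% c("laser", "control")))
    stop("sample map treatment must be 'laser' or 'control'")
  if (anyDuplicated(sample_map$file_pattern))
    stop("sample map file_pattern values must be unique")
  sample_map
}

#' Annotate PSM records with condition, replicate and treatment
#'
#' Each distinct spectrum file must match exactly one sample-map entry;
#' an unmatched file or a file matching two entries is a fatal error.
#' If no control files match at all, a warning is emitted and downstream
#' control subtraction treats the background as zero (records get the
#' `no_control` flag).
#'
#' @param records Canonical PSM `data.frame` from [apply_column_mapping()].
#' @param sample_map Sample-map `data.frame` (columns `file_pattern`,
#'   `condition`, `replicate`, `treatment`) or path readable by
#'   [read_sample_map()].
#' @param match_mode How `file_pattern` is matched against spectrum file
#'   names: `"exact"`, `"substring"` (fixed substring) or `"regex"`.
#' @return `records` with `condition`, `replicate`, `treatment` columns
#'   appended; record count unchanged.
#' @export
attach_sample_map <- function(records, sample_map,
                              match_mode = c("exact", "substring", "regex")) {
  match_mode <- match.arg(match_mode)
  if (is.character(sample_map) && length(sample_map) == 1L)
    sample_map <- read_sample_map(sample_map)
  sample_map <- validate_sample_map(sample_map)
  files <- unique(records$spectrum_file)
  hit <- matrix(FALSE, length(files), nrow(sample_map))
  for (j in seq_len(nrow(sample_map))) {
    pat <- sample_map$file_pattern[j]
    hit[, j] <- switch(match_mode,
      exact = files == pat,
      substring = grepl(pat, files, fixed = TRUE),
      regex = grepl(pat, files))
  }
  nhit <- rowSums(hit)
  if (any(nhit == 0L))
    stop("spectrum file(s) unmatched by the sample map: ",
         paste(files[nhit == 0L], collapse = ", "))
  amb <- which(nhit > 1L)
  for (i in amb) {
    triples <- unique(sample_map[hit[i, ], c("condition", "replicate", "treatment")])
    if (nrow(triples) > 1L)
      stop("spectrum file '", files[i],
           "' matches sample-map entries with different assignments")
  }
  entry <- apply(hit, 1, function(h) which(h)[1])
  idx <- entry[match(records$spectrum_file, files)]
  records$condition <- sample_map$condition[idx]
  records$replicate <- sample_map$replicate[idx]
  records$treatment <- sample_map$treatment[idx]
  if (!any(records$treatment == "control"))
    warning("no control files matched; control subtraction will treat background as zero")
  records
}

#' Expand TMT reporter channels into per-channel PSM records
#'
#' For isobaric-tag data the reporter intensity of each mapped channel is
#' used as the precursor abundance: every input row fans out into one
#' record per channel, with `spectrum_file` set to
#' `"<sourcefile>::<channel>"` so the channel identity travels through the
#' pipeline unchanged.
#'
#' @param rows Raw row `data.frame` from [read_psm_table()].
#' @param channel_map Sample-map `data.frame` whose `file_pattern` values
#'   are reporter-channel column names present in `rows`.
#' @param mapping Column mapping (as in [apply_column_mapping()]) covering
#'   the non-abundance canonical columns of `rows`.
#' @return Canonical PSM `data.frame` with `nrow(rows) * nrow(channel_map)`
#'   records; blank channel values become missing abundance.
#' @export
expand_tmt_channels <- function(rows, channel_map, mapping) {
  channel_map <- validate_sample_map(channel_map)
  absent <- setdiff(channel_map$file_pattern, names(rows))
  if (length(absent) > 0L)
    stop("reporter channel column(s) absent from data: ",
         paste(absent, collapse = ", "))
  mapping <- mapping[unname(mapping) != "abundance"]
  if (!"abundance" %in% unname(mapping)) {
    # abundance comes from the channels; satisfy the base mapping with a stub
    rows[[".tmt_abundance_stub"]] <- ""
    mapping <- c(mapping, ".tmt_abundance_stub" = "abundance")
  }
  base <- apply_column_mapping(rows, mapping)
  out <- lapply(seq_len(nrow(channel_map)), function(j) {
    ch <- channel_map$file_pattern[j]
    rec <- base
    rec$abundance <- parse_abundance(rows[[ch]])
    rec$spectrum_file <- paste0(rec$spectrum_file, "::", ch)
    rec
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
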