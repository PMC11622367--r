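# Modification catalog: maps modification names / mass deltas to a class
# (fpop, fixed, other) used throughout quantitation.

#' Default modification catalog
#'
#' The shipped catalog covers the canonical hydroxyl-radical oxidation series
#' (+15.9949, +31.9898, +47.9847 Da) plus common side-chain FPOP products,
#' carbamidomethylation of Cys as a fixed modification, and N-terminal
#' acetylation as a non-FPOP search artifact. Extend or replace it with
#' [read_catalog()].
#'
#' @details Columns: `name` (modification name), `mass_delta` (Da),
#'   `class` (`"fpop"`, `"fixed"` or `"other"`), `residues` (string of
#'   1-letter codes the entry is restricted to; `""` means any residue;
#'   `"Nterm"` permits peptide N-terminus matches at position 0).
#'   N-terminal events (position 0) only ever match entries whose `residues`
#'   explicitly contain `"Nterm"`.
#'
#' @return A `data.frame` with columns `name`, `mass_delta`, `class`,
#'   `residues`.
#' @seealso [read_catalog()], [classify_events()]
#' @export
#' @examples
#' fpop_catalog()
fpop_catalog <- function() {
  cat <- data.frame(
    name = c("Oxidation", "Dioxidation", "Trioxidation", "Carbonyl",
             "Trp->Kynurenine", "His->Asn", "His->Asp",
             "Carbamidomethyl", "Acetyl"),
    mass_delta = c(15.9949, 31.9898, 47.9847, 13.9793,
                   3.9949, -23.0159, -22.0320,
                   57.0215, 42.0106),
    class = c("fpop", "fpop", "fpop", "fpop",
              "fpop", "fpop", "fpop",
              "fixed", "other"),
    residues = c("", "", "", "",
                 "W", "H", "H",
                 "C", "Nterm"),
    stringsAsFactors = FALSE
  )
  validate_catalog(cat)
  cat
}

#' Read a modification catalog from a TSV file
#'
#' @param path Path to a tab-separated file with columns `name`,
#'   `mass_delta`, `class` and optionally `residues`.
#' @return A validated catalog `data.frame` (see [fpop_catalog()]).
#' @export
read_catalog <- function(path) {
  cat <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE, colClasses = "character")
  req <- c("name", "mass_delta", "class")
  miss <- setdiff(req, names(cat))
  if (length(miss) > 0L)
    stop("catalog file is missing column(s): ", paste(miss, collapse = ", "))
  if (!"residues" %in% names(cat)) cat$residues <- ""
  cat$mass_delta <- as.numeric(cat$mass_delta)
  cat$residues[is.na(cat$residues)] <- ""
  cat <- cat[, c("name", "mass_delta", "class", "residues")]
  validate_catalog(cat)
  cat
}

validate_catalog <- function(cat, mass_tol = 0.01) {
  if (nrow(cat) == 0L) stop("catalog is empty")
  if (!all(cat$class %in% c("fpop", "fixed", "other")))
    stop("catalog class must be one of fpop, fixed, other")
  if (anyNA(cat$mass_delta)) stop("catalog mass_delta must be numeric")
  if (anyDuplicated(tolower(cat$name)))
    stop("catalog names must be unique")
  # no mass window may span two classes (restricted to overlapping residue sets)
  n <- nrow(cat)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) for (j in seq(i + 1L, n)) {
      if (abs(cat$mass_delta[i] - cat$mass_delta[j]) <= 2 * mass_tol &&
          cat$class[i] != cat$class[j] &&
          residues_overlap(cat$residues[i], cat$residues[j]))
        stop("catalog mass windows of '", cat$name[i], "' and '",
             cat$name[j], "' overlap with different classes")
    }
  }
  invisible(cat)
}

residues_overlap <- function(a, b) {
  if (a == "" || b == "") return(TRUE)
  any(strsplit(a, "")[[1]] %in% strsplit(b, "")[[1]])
}
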