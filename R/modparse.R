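# Parsing of modification annotation strings into localized events.
#
# Three dialects are supported:
#   pd       "1xOxidation [M5]; 2xOxidation [M5; W9]"  (Proteome Discoverer)
#   fragpipe "5M(15.9949), 9W(15.9949)"                (FragPipe psm.tsv)
#   generic  "5:M:Oxidation:15.9949; 9:W:Oxidation:15.9949"
# Positions are 1-based within the peptide; position 0 denotes the peptide
# N-terminus. PD tokens carry no mass delta (NA until classified).

empty_events <- function() {
  data.frame(position = integer(0), residue = character(0),
             name = character(0), mass_delta = numeric(0),
             stringsAsFactors = FALSE)
}

parse_error <- function(msg) {
  stop(structure(class = c("fpopquant_parse_error", "error", "condition"),
                 list(message = msg, call = NULL)))
}

check_event_residue <- function(position, residue, sequence, token) {
  if (position > nchar(sequence))
    parse_error(sprintf("modification token '%s' places position %d beyond peptide '%s'",
                        token, position, sequence))
  if (position >= 1L) {
    actual <- substr(sequence, position, position)
    if (nzchar(residue) && actual != residue)
      parse_error(sprintf(
        "modification token '%s' names residue %s at position %d but peptide '%s' has %s",
        token, residue, position, sequence, actual))
  }
}

#' Parse a modification annotation string into localized events
#'
#' @param modifications_raw Annotation string in the source dialect; `""` or
#'   `NA` denotes an unmodified peptide.
#' @param sequence Peptide sequence (uppercase 1-letter codes) the
#'   annotations refer to.
#' @param dialect One of `"generic"`, `"pd"`, `"fragpipe"`.
#' @return A `data.frame` of events with columns `position` (1-based; 0 =
#'   peptide N-terminus), `residue`, `name` (`NA` for fragpipe until
#'   classified), `mass_delta` (Da; `NA` for pd until classified), ordered
#'   by position then name.
#' @seealso [classify_events()], [serialize_modifications()]
#' @export
#' @examples
#' parse_modifications("5M(15.9949)", "AAAAMK", "fragpipe")
#' parse_modifications("2xOxidation [M5; W9]", "AAAAMAAAWK", "pd")
parse_modifications <- function(modifications_raw, sequence,
                                dialect = c("generic", "pd", "fragpipe")) {
  dialect <- match.arg(dialect)
  if (is.na(modifications_raw) || !nzchar(trimws(modifications_raw)))
    return(empty_events())
  s <- trimws(modifications_raw)
  ev <- switch(dialect,
    generic = parse_generic(s, sequence),
    pd = parse_pd(s, sequence),
    fragpipe = parse_fragpipe(s, sequence))
  ev[order(ev$position, ev$name, method = "radix"), , drop = FALSE]
}

parse_generic <- function(s, sequence) {
  toks <- trimws(strsplit(s, ";", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  out <- lapply(toks, function(tok) {
    parts <- strsplit(tok, ":", fixed = TRUE)[[1]]
    if (length(parts) != 4L)
      parse_error(sprintf("cannot parse generic modification token '%s'", tok))
    pos <- suppressWarnings(as.integer(parts[1]))
    delta <- suppressWarnings(as.numeric(parts[4]))
    if (is.na(pos) || pos < 0L || is.na(delta))
      parse_error(sprintf("cannot parse generic modification token '%s'", tok))
    res <- if (parts[2] == "-") "" else parts[2]
    check_event_residue(pos, res, sequence, tok)
    data.frame(position = pos, residue = res, name = parts[3],
               mass_delta = delta, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(empty_events())))
}

parse_pd <- function(s, sequence) {
  m <- gregexpr("(\\d+)x([^\\[;]+?)\\s*\\[([^]]*)\\]", s, perl = TRUE)[[1]]
  if (m[1] == -1L)
    parse_error(sprintf("cannot parse PD modification string '%s'", s))
  toks <- regmatches(s, list(m))[[1]]
  covered <- sum(attr(m, "match.length"))
  leftover <- gsub("[;[:space:]]", "", gsub("(\\d+)x([^\\[;]+?)\\s*\\[([^]]*)\\]", "", s, perl = TRUE))
  if (nzchar(leftover))
    parse_error(sprintf("unrecognized text '%s' in PD modification string '%s'", leftover, s))
  out <- lapply(toks, function(tok) {
    n <- as.integer(sub("^(\\d+)x.*$", "\\1", tok))
    name <- trimws(sub("^\\d+x([^\\[]+?)\\s*\\[.*$", "\\1", tok, perl = TRUE))
    sites <- trimws(strsplit(sub("^.*\\[([^]]*)\\]$", "\\1", tok), ";")[[1]])
    sites <- sites[nzchar(sites)]
    if (length(sites) != n)
      parse_error(sprintf("PD token '%s' announces %d site(s) but lists %d", tok, n, length(sites)))
    rows <- lapply(sites, function(site) {
      if (toupper(site) %in% c("N-TERM", "N-TERMINUS")) {
        pos <- 0L; res <- ""
      } else if (grepl("^[A-Z]\\d+$", site)) {
        pos <- as.integer(sub("^[A-Z]", "", site))
        res <- substr(site, 1, 1)
      } else parse_error(sprintf("cannot parse PD site '%s' in token '%s'", site, tok))
      check_event_residue(pos, res, sequence, tok)
      data.frame(position = pos, residue = res, name = name,
                 mass_delta = NA_real_, stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  })
  do.call(rbind, c(out, list(empty_events())))
}

parse_fragpipe <- function(s, sequence) {
  toks <- trimws(strsplit(s, ",", fixed = TRUE)[[1]])
  toks <- toks[nzchar(toks)]
  out <- lapply(toks, function(tok) {
    if (grepl("^N-term\\(([-0-9.]+)\\)$", tok, ignore.case = TRUE)) {
      pos <- 0L; res <- ""
      delta <- as.numeric(sub("^N-term\\(([-0-9.]+)\\)$", "\\1", tok, ignore.case = TRUE))
    } else if (grepl("^(\\d+)([A-Z])\\(([-0-9.]+)\\)$", tok)) {
      pos <- as.integer(sub("^(\\d+)[A-Z]\\(.*$", "\\1", tok))
      res <- sub("^\\d+([A-Z])\\(.*$", "\\1", tok)
      delta <- as.numeric(sub("^\\d+[A-Z]\\(([-0-9.]+)\\)$", "\\1", tok))
    } else parse_error(sprintf("cannot parse FragPipe modification token '%s'", tok))
    check_event_residue(pos, res, sequence, tok)
    data.frame(position = pos, residue = res, name = NA_character_,
               mass_delta = delta, stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(empty_events())))
}

#' Serialize modification events back to an annotation string
#'
#' Inverse of [parse_modifications()] for round-tripping and for emitting
#' synthetic tables in each search-engine dialect.
#'
#' @param events Event `data.frame` as returned by [parse_modifications()]
#'   (names required for `pd`/`generic`, mass deltas for `fragpipe`/`generic`).
#' @inheritParams parse_modifications
#' @return A single annotation string; `""` for an empty event set.
#' @export
serialize_modifications <- function(events,
                                    dialect = c("generic", "pd", "fragpipe")) {
  dialect <- match.arg(dialect)
  if (is.null(events) || nrow(events) == 0L) return("")
  ev <- events[order(events$position, events$name, method = "radix"), , drop = FALSE]
  switch(dialect,
    generic = paste(sprintf("%d:%s:%s:%.4f", ev$position,
                            ifelse(nzchar(ev$residue), ev$residue, "-"),
                            ev$name, ev$mass_delta), collapse = "; "),
    fragpipe = paste(ifelse(ev$position == 0L,
                            sprintf("N-term(%.4f)", ev$mass_delta),
                            sprintf("%d%s(%.4f)", ev$position, ev$residue,
                                    ev$mass_delta)), collapse = ", "),
    pd = {
      toks <- vapply(split(seq_len(nrow(ev)), ev$name), function(idx) {
        sub <- ev[idx, , drop = FALSE]
        sites <- ifelse(sub$position == 0L, "N-Term",
                        paste0(sub$residue, sub$position))
        sprintf("%dx%s [%s]", nrow(sub), sub$name[1],
                paste(sites, collapse = "; "))
      }, character(1))
      paste(toks, collapse = "; ")
    })
}

#' Classify modification events against a catalog
#'
#' Each event is matched to a catalog entry first by name (case-insensitive,
#' honoring the entry's residue restriction), then by mass delta within
#' `mass_tol`; unmatched events are classed `"other"`. N-terminal events
#' (position 0) only match entries whose residue restriction explicitly
#' contains `"Nterm"`, so e.g. N-terminal acetylation never counts as an
#' FPOP oxidation. Classification is a pure function of the catalog:
#' reordering catalog rows never changes the result (mass ties resolve by
#' smallest mass difference, then alphabetical name).
#'
#' @param events Event `data.frame` from [parse_modifications()].
#' @param catalog Catalog `data.frame` (see [fpop_catalog()]).
#' @param mass_tol Mass-match tolerance in Da (default 0.01, matching the
#'   4-decimal precision search engines report).
#' @return `events` with columns `mod_class` set and `name`/`mass_delta`
#'   filled in from the matched catalog entry where they were missing.
#' @export
#' @examples
#' ev <- parse_modifications("5M(15.9949)", "AAAAMK", "fragpipe")
#' classify_events(ev, fpop_catalog())
classify_events <- function(events, catalog = fpop_catalog(), mass_tol = 0.01) {
  validate_catalog(cat = catalog, mass_tol = mass_tol)
  if (nrow(events) == 0L) {
    events$mod_class <- character(0)
    return(events)
  }
  events$mod_class <- NA_character_
  for (i in seq_len(nrow(events))) {
    compat <- catalog_compatible(catalog, events$residue[i], events$position[i])
    hit <- NA_integer_
    if (!is.na(events$name[i])) {
      byname <- which(compat & tolower(catalog$name) == tolower(events$name[i]))
      if (length(byname) > 0L) hit <- byname[1]
    }
    if (is.na(hit) && !is.na(events$mass_delta[i])) {
      d <- abs(catalog$mass_delta - events$mass_delta[i])
      cand <- which(compat & d <= mass_tol)
      if (length(cand) > 0L) {
        cand <- cand[order(d[cand], catalog$name[cand], method = "radix")]
        hit <- cand[1]
      }
    }
    if (is.na(hit)) {
      events$mod_class[i] <- "other"
      if (is.na(events$name[i]))
        events$name[i] <- sprintf("%+.4f", events$mass_delta[i])
    } else {
      events$mod_class[i] <- catalog$class[hit]
      if (is.na(events$name[i])) events$name[i] <- catalog$name[hit]
      if (is.na(events$mass_delta[i])) events$mass_delta[i] <- catalog$mass_delta[hit]
    }
  }
  events
}

catalog_compatible <- function(catalog, residue, position) {
  vapply(catalog$residues, function(r) {
    if (position == 0L) return(grepl("Nterm", r, fixed = TRUE))
    if (r == "" ) return(TRUE)
    nzchar(residue) && grepl(residue, gsub("Nterm", "", r, fixed = TRUE), fixed = TRUE)
  }, logical(1), USE.NAMES = FALSE)
}

#' Count FPOP modification events
#'
#' @param events Classified event `data.frame` (see [classify_events()]).
#' @return Number of events with `mod_class == "fpop"`; fixed and other
#'   events do not count.
#' @export
count_fpop_mods <- function(events) {
  if (nrow(events) == 0L) return(0L)
  sum(events$mod_class == "fpop")
}

#' Canonical modified-form key
#'
#' Identifies a peptide form by its FPOP (and other-class) events only, so
#' that e.g. the carbamidomethylated and plain carriers of the same
#' oxidation state share a key and their areas are summed together. Fixed
#' modifications are excluded; "other"-class events are retained because
#' they are distinct molecular species that belong in the denominator.
#'
#' @param sequence Peptide sequence.
#' @param events Classified event `data.frame`.
#' @return A deterministic string key; `"<sequence>|unmod"` when no
#'   FPOP/other events are present.
#' @export
#' @examples
#' ev <- classify_events(parse_modifications("5M(15.9949)", "AAAAMK", "fragpipe"))
#' form_key("AAAAMK", ev)
form_key <- function(sequence, events) {
  keep <- events[events$mod_class %in% c("fpop", "other"), , drop = FALSE]
  if (nrow(keep) == 0L) return(paste0(sequence, "|unmod"))
  keep <- keep[order(keep$position, keep$name, method = "radix"), , drop = FALSE]
  paste0(sequence, "|", paste(sprintf("%d:%s", keep$position, keep$name),
                              collapse = "+"))
}
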