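# Fidelity filters. Every removed row is accounted for in exactly one
# audit entry so that rows_in = rows_out + sum(rows_removed).

empty_audit <- function() {
  data.frame(stage = character(0), file = character(0), protein = character(0),
             sequence = character(0), form = character(0), reason = character(0),
             rows_removed = integer(0), stringsAsFactors = FALSE)
}

audit_entry <- function(stage, file = "", protein = "", sequence = "",
                        form = "", reason = "", rows_removed = 1L) {
  data.frame(stage = stage, file = file, protein = protein,
             sequence = sequence, form = form, reason = reason,
             rows_removed = as.integer(rows_removed), stringsAsFactors = FALSE)
}

bind_audits <- function(...) {
  out <- do.call(rbind, c(list(empty_audit()), Filter(Negate(is.null), list(...))))
  rownames(out) <- NULL
  out
}

#' Remove search-node duplicate PSM rows
#'
#' Multilevel search workflows split modification types across nodes, so
#' the same (file, peptide, form, charge) identification — most often the
#' unmodified peptide — can be reported once per node. Counting those
#' duplicates inflates the denominator of the EOM ratio, so within each
#' (spectrum_file, sequence, form_key, charge, scan-if-present) group
#' exactly one record survives.
#'
#' @param records Canonical PSM `data.frame` carrying a `form_key` column
#'   (see [annotate_forms()]).
#' @param policy Survivor choice: `"max"` (highest abundance, ties broken
#'   by input order; missing abundance sorts last) or `"first"` (input
#'   order). Both are deterministic and idempotent.
#' @return List with `records` (survivors, input order preserved) and
#'   `audit` (one entry per duplicated group).
#' @export
deduplicate_nodes <- function(records, policy = c("max", "first")) {
  policy <- match.arg(policy)
  if (!"form_key" %in% names(records))
    stop("records must carry form keys; run annotate_forms() first")
  n <- nrow(records)
  charge <- if ("charge" %in% names(records)) records$charge else rep(NA, n)
  scan <- if ("scan" %in% names(records)) records$scan else rep(NA, n)
  key <- paste(records$spectrum_file, records$sequence, records$form_key,
               ifelse(is.na(charge), ".", charge),
               ifelse(is.na(scan), ".", scan), sep = "\r")
  keep <- logical(n)
  audits <- list()
  for (idx in split(seq_len(n), factor(key, levels = unique(key)))) {
    if (length(idx) == 1L) { keep[idx] <- TRUE; next }
    surv <- if (policy == "first") idx[1] else {
      ab <- records$abundance[idx]
      ab[is.na(ab)] <- -Inf
      idx[which.max(ab)]  # which.max takes the first of ties
    }
    keep[surv] <- TRUE
    audits[[length(audits) + 1L]] <- audit_entry(
      stage = "node_duplicates",
      file = records$spectrum_file[idx[1]],
      protein = records$accession[idx[1]],
      sequence = records$sequence[idx[1]],
      form = records$form_key[idx[1]],
      reason = sprintf("%d duplicate row(s) removed (policy=%s)",
                       length(idx) - 1L, policy),
      rows_removed = length(idx) - 1L)
  }
  list(records = records[keep, , drop = FALSE],
       audit = do.call(bind_audits, audits))
}

#' Exclude peptides with no unmodified-form area
#'
#' A modified-form area without an observed unmodified peptide in the same
#' file cannot yield a defensible EOM (legacy spreadsheet pipelines would
#' still report one). The exclusion is per spectrum file, so one bad
#' replicate does not remove the peptide everywhere.
#'
#' @param areas Long area table from [summarize_areas()].
#' @return List with `areas` (kept rows) and `audit`.
#' @export
filter_missing_unmodified <- function(areas) {
  key <- paste(areas$file, areas$protein, areas$sequence, sep = "\r")
  keep <- logical(nrow(areas))
  audits <- list()
  for (idx in split(seq_len(nrow(areas)), factor(key, levels = unique(key)))) {
    g <- areas[idx, , drop = FALSE]
    unmod <- g$area[g$form_key == paste0(g$sequence[1], "|unmod")]
    if (length(unmod) == 1L && !is.na(unmod) && unmod > 0) {
      keep[idx] <- TRUE
    } else {
      audits[[length(audits) + 1L]] <- audit_entry(
        stage = "missing_unmodified", file = g$file[1], protein = g$protein[1],
        sequence = g$sequence[1],
        reason = "no unmodified-form area in this file",
        rows_removed = length(idx))
    }
  }
  list(areas = areas[keep, , drop = FALSE],
       audit = do.call(bind_audits, audits))
}

#' Require modified-area evidence in enough replicates
#'
#' A target (peptide or residue) is only reported for a condition when its
#' modified area is observed in at least `min_mod_replicates` laser
#' replicates. The default of 3 is the literal reading of requiring "more
#' than two" supporting replicates; labs running n = 3 designs may lower
#' it (the audit records the threshold used). Control files are not
#' subject to this filter.
#'
#' @param per_rep Per-replicate table with columns `condition`, `protein`,
#'   `target`, `treatment`, `evidence` (logical: nonzero modified area) and
#'   one row per replicate observation.
#' @param min_mod_replicates Minimum number of laser replicates with
#'   modified-area evidence (>= 1; 1 reproduces unfiltered behavior).
#' @return List with `per_rep` (kept rows) and `audit`.
#' @export
filter_replicate_support <- function(per_rep, min_mod_replicates = 3L) {
  if (min_mod_replicates < 1L) stop("min_mod_replicates must be >= 1")
  key <- paste(per_rep$condition, per_rep$protein, per_rep$target, sep = "\r")
  keep <- logical(nrow(per_rep))
  audits <- list()
  for (idx in split(seq_len(nrow(per_rep)), factor(key, levels = unique(key)))) {
    g <- per_rep[idx, , drop = FALSE]
    laser <- g$treatment == "laser"
    n_evid <- sum(g$evidence[laser])
    if (n_evid >= min_mod_replicates) {
      keep[idx] <- TRUE
    } else {
      audits[[length(audits) + 1L]] <- audit_entry(
        stage = "replicate_support", file = "", protein = g$protein[1],
        sequence = g$target[1],
        reason = sprintf("modified area in %d laser replicate(s) < threshold %d",
                         n_evid, min_mod_replicates),
        rows_removed = length(idx))
    }
  }
  list(per_rep = per_rep[keep, , drop = FALSE],
       audit = do.call(bind_audits, audits))
}

#' Restrict differential analysis to proteins seen in every condition
#'
#' @param sets_by_condition Named list mapping condition label to the
#'   character vector of quantifiable protein accessions.
#' @return List with `proteins` (the intersection) and `audit` (one entry
#'   per dropped protein).
#' @export
filter_common_proteins <- function(sets_by_condition) {
  if (length(sets_by_condition) < 2L)
    stop("differential mode requires at least 2 conditions")
  sets_by_condition <- lapply(sets_by_condition, unique)
  common <- Reduce(intersect, sets_by_condition)
  dropped <- setdiff(unique(unlist(sets_by_condition)), common)
  audits <- lapply(dropped, function(p) {
    absent <- names(sets_by_condition)[!vapply(sets_by_condition,
                                               function(s) p %in% s, logical(1))]
    audit_entry(stage = "common_proteins", protein = p,
                reason = paste0("not quantifiable in condition(s): ",
                                paste(absent, collapse = ", ")),
                rows_removed = 0L)
  })
  list(proteins = sort(common), audit = do.call(bind_audits, audits))
}
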