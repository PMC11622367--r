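#' @export
print.fpop_eom <- function(x, ...) {
  cat("FPOP extent-of-modification results\n")
  cat(sprintf("  conditions: %s\n", paste(x$config$conditions, collapse = ", ")))
  cat(sprintf("  peptide targets: %d   residue targets: %d\n",
              nrow(x$peptide), nrow(x$residue)))
  cat(sprintf("  rows: %d in -> %d after parsing -> %d after deduplication\n",
              x$log[["records_in"]], x$log[["after_parse"]],
              x$log[["after_dedup"]]))
  cat(sprintf("  filter audit entries: %d (%s)\n", nrow(x$audit),
              if (nrow(x$audit)) paste(names(table(x$audit$stage)),
                                       collapse = ", ") else "none"))
  if (nrow(x$comparisons) > 0L)
    cat(sprintf("  condition comparisons: %d (Welch)\n", nrow(x$comparisons)))
  invisible(x)
}

#' Summarize an fpop_eom object
#'
#' @param object An `fpop_eom` object from [fpop_quantify()].
#' @param ... Unused.
#' @return Invisibly, a list with per-condition target counts and net-EOM
#'   five-number summaries.
#' @export
summary.fpop_eom <- function(object, ...) {
  print(object)
  out <- list()
  for (cc in object$config$conditions) {
    pep <- object$peptide[object$peptide$condition == cc, , drop = FALSE]
    res <- object$residue[object$residue$condition == cc, , drop = FALSE]
    cat(sprintf("\ncondition %s: %d peptides (net EOM median %.4f), %d residues\n",
                cc, nrow(pep), stats::median(pep$net_eom), nrow(res)))
    out[[cc]] <- list(n_peptides = nrow(pep), n_residues = nrow(res),
                      net_eom = summary(pep$net_eom))
  }
  invisible(out)
}

# %.17g survives a write/read round trip of doubles exactly.
format_numeric_cols <- function(df) {
  for (nm in names(df)) {
    if (is.double(df[[nm]])) {
      v <- df[[nm]]
      df[[nm]] <- ifelse(is.na(v), "NA", sprintf("%.17g", v))
    }
  }
  df
}

write_tsv <- function(df, path) {
  utils::write.table(format_numeric_cols(df), path, sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "NA")
}

#' Read back a result TSV written by write_results
#'
#' @param path Path to a TSV written by [write_results()].
#' @return A `data.frame` with numeric columns restored.
#' @export
read_results_tsv <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                          colClasses = "character")
  for (nm in names(df)) {
    v <- df[[nm]]
    nonmiss <- !(v %in% c("NA", ""))
    if (!any(nonmiss)) next
    num <- suppressWarnings(as.numeric(v[nonmiss]))
    if (!anyNA(num)) {
      full <- rep(NA_real_, length(v))
      full[nonmiss] <- num
      df[[nm]] <- full
    }
  }
  int_cols <- intersect(c("n", "position", "replicate", "rows_removed"),
                        names(df))
  for (nm in int_cols)
    if (is.numeric(df[[nm]])) df[[nm]] <- as.integer(df[[nm]])
  df
}

#' Write result tables to a directory
#'
#' Writes `peptide_eom.tsv`, `residue_eom.tsv`, `comparisons.tsv`,
#' `filter_audit.tsv`, `venn_membership.tsv` and `run_config.txt` with a
#' deterministic row and column order. Numeric cells are written with 17
#' significant digits so a round trip through [read_results_tsv()]
#' reproduces the in-memory values exactly. An empty result set produces
#' headers-only files with a warning.
#'
#' @param x An `fpop_eom` object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_results <- function(x, out_dir) {
  stopifnot(inherits(x, "fpop_eom"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!dir.exists(out_dir)) stop("cannot create output directory '", out_dir, "'")
  if (nrow(x$peptide) == 0L)
    warning("empty result set; writing headers-only tables")
  paths <- c(peptide = file.path(out_dir, "peptide_eom.tsv"),
             residue = file.path(out_dir, "residue_eom.tsv"),
             comparisons = file.path(out_dir, "comparisons.tsv"),
             audit = file.path(out_dir, "filter_audit.tsv"),
             venn = file.path(out_dir, "venn_membership.tsv"),
             config = file.path(out_dir, "run_config.txt"))
  pep <- x$peptide
  pep_cols <- intersect(c("condition", "protein", "sequence", "n", "mean_eom",
                          "sd_eom", "control_mean", "net_eom", "apo",
                          "p_value", "flags"), names(pep))
  write_tsv(pep[, pep_cols, drop = FALSE], paths[["peptide"]])
  res <- x$residue
  keep <- intersect(c("condition", "protein", "sequence", "target", "position",
                      "n", "mean_eom", "sd_eom", "control_mean", "net_eom",
                      "p_value", "flags"), names(res))
  write_tsv(res[, keep, drop = FALSE], paths[["residue"]])
  write_tsv(x$comparisons, paths[["comparisons"]])
  write_tsv(x$audit, paths[["audit"]])
  write_tsv(venn_membership(x), paths[["venn"]])
  cfg <- x$config
  cfg$conditions <- paste(cfg$conditions, collapse = ",")
  writeLines(sprintf("%s\t%s", names(cfg),
                     vapply(cfg, function(v) paste(format(v), collapse = ","),
                            character(1))),
             paths[["config"]])
  invisible(paths)
}

#' Per-condition modified-protein membership (Venn input)
#'
#' @param x An `fpop_eom` object.
#' @param level `"peptide"` (protein sets) or `"residue"` (residue-id sets).
#' @return `data.frame` with one row per id: membership flag per condition
#'   and the Venn region label.
#' @export
venn_membership <- function(x, level = c("peptide", "residue")) {
  level <- match.arg(level)
  tab <- x[[level]]
  conds <- x$config$conditions
  ids <- if (level == "peptide") tab$protein
         else paste(tab$protein, tab$target, sep = ":")
  sets <- lapply(conds, function(cc) unique(ids[tab$condition == cc]))
  names(sets) <- conds
  all_ids <- sort(unique(unlist(sets)))
  out <- data.frame(id = all_ids, stringsAsFactors = FALSE)
  for (cc in conds)
    out[[cc]] <- all_ids %in% sets[[cc]]
  out$region <- apply(out[, conds, drop = FALSE], 1, function(m)
    paste(conds[as.logical(m)], collapse = "&"))
  out
}
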