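# End-to-end quantitation: annotated PSM records -> filtered, control-
# subtracted, replicate-averaged EOM at peptide and residue level.

#' Parse, classify and key the modifications of each PSM record
#'
#' @param records Canonical PSM `data.frame` (see [apply_column_mapping()]).
#' @param dialect Modification-string dialect (see [parse_modifications()]).
#' @param catalog Modification catalog (see [fpop_catalog()]).
#' @param mass_tol Catalog mass-match tolerance in Da.
#' @return List with `records` (columns `form_key`, `n_fpop`, `fpop_positions`
#'   appended; rows whose annotation failed to parse are quarantined) and
#'   `audit` (one entry per quarantined annotation).
#' @export
annotate_forms <- function(records, dialect = c("generic", "pd", "fragpipe"),
                           catalog = fpop_catalog(), mass_tol = 0.01) {
  dialect <- match.arg(dialect)
  mods <- ifelse(is.na(records$modifications_raw), "", records$modifications_raw)
  ukey <- paste(records$sequence, mods, sep = "\r")
  uniq <- !duplicated(ukey)
  info <- new.env(parent = emptyenv())
  audits <- list()
  for (i in which(uniq)) {
    res <- tryCatch({
      ev <- parse_modifications(mods[i], records$sequence[i], dialect)
      ev <- classify_events(ev, catalog, mass_tol)
      fp <- ev[ev$mod_class == "fpop", , drop = FALSE]
      list(ok = TRUE, key = form_key(records$sequence[i], ev),
           n = count_fpop_mods(ev),
           pos = paste(sort(unique(fp$position)), collapse = ","))
    }, fpopquant_parse_error = function(e) list(ok = FALSE, msg = conditionMessage(e)))
    assign(ukey[i], res, envir = info)
  }
  got <- lapply(ukey, get, envir = info)
  ok <- vapply(got, `[[`, logical(1), "ok")
  if (any(!ok)) {
    bad <- which(!ok & uniq)
    audits <- lapply(bad, function(i) {
      nrows <- sum(ukey == ukey[i])
      audit_entry(stage = "parse_error", protein = records$accession[i],
                  sequence = records$sequence[i], form = mods[i],
                  reason = got[[i]]$msg, rows_removed = nrows)
    })
  }
  out <- records[ok, , drop = FALSE]
  out$form_key <- vapply(got[ok], `[[`, character(1), "key")
  out$n_fpop <- vapply(got[ok], `[[`, integer(1), "n")
  out$fpop_positions <- vapply(got[ok], `[[`, character(1), "pos")
  list(records = out, audit = do.call(bind_audits, audits))
}

#' Sum PSM abundances into per-peptide form areas
#'
#' Groups deduplicated, annotated records by (spectrum file, protein,
#' peptide, form) and sums abundance over charge states within each file
#' (never across files). Records with missing abundance are skipped and
#' counted. Forms with no FPOP and no other-class modifications are the
#' unmodified form (`<sequence>|unmod`).
#'
#' @param records Deduplicated, annotated PSM `data.frame` carrying
#'   `condition`, `replicate`, `treatment`, `form_key`, `n_fpop`,
#'   `fpop_positions`.
#' @return List with `areas` (long `data.frame`: `file`, `condition`,
#'   `replicate`, `treatment`, `protein`, `sequence`, `form_key`, `area`,
#'   `n_fpop`, `positions`, `protein_start`) and `audit`.
#' @export
summarize_areas <- function(records) {
  audits <- list()
  drop <- is.na(records$abundance)
  if (any(drop)) {
    warning(sum(drop), " record(s) with missing abundance excluded from area sums")
    audits[[1]] <- audit_entry(stage = "missing_abundance",
                               reason = "abundance missing; excluded from area sums",
                               rows_removed = sum(drop))
    records <- records[!drop, , drop = FALSE]
  }
  ps <- if ("protein_start" %in% names(records)) records$protein_start
        else rep(NA_integer_, nrow(records))
  key <- paste(records$spectrum_file, records$accession, records$sequence,
               records$form_key, sep = "\r")
  idx1 <- !duplicated(key)
  area <- as.numeric(tapply(records$abundance, factor(key, levels = key[idx1]), sum))
  areas <- data.frame(
    file = records$spectrum_file[idx1],
    condition = records$condition[idx1],
    replicate = records$replicate[idx1],
    treatment = records$treatment[idx1],
    protein = records$accession[idx1],
    sequence = records$sequence[idx1],
    form_key = records$form_key[idx1],
    area = area,
    n_fpop = records$n_fpop[idx1],
    positions = records$fpop_positions[idx1],
    protein_start = ps[idx1],
    stringsAsFactors = FALSE)
  rownames(areas) <- NULL
  list(areas = areas, audit = do.call(bind_audits, audits))
}

# One area_summary object per (file, protein, sequence) group.
split_area_summaries <- function(areas) {
  key <- paste(areas$file, areas$protein, areas$sequence, sep = "\r")
  lapply(split(seq_len(nrow(areas)), factor(key, levels = unique(key))),
         function(idx) {
    g <- areas[idx, , drop = FALSE]
    unmod_key <- paste0(g$sequence[1], "|unmod")
    is_unmod <- g$form_key == unmod_key
    unmod <- if (any(is_unmod)) sum(g$area[is_unmod]) else NA_real_
    forms <- g[!is_unmod, c("form_key", "area", "n_fpop", "positions"),
               drop = FALSE]
    area_summary(unmod_area = unmod, forms = forms, file = g$file[1],
                 condition = g$condition[1], replicate = g$replicate[1],
                 treatment = g$treatment[1], protein = g$protein[1],
                 sequence = g$sequence[1])
  })
}

#' Quantify the extent of modification from annotated PSM records
#'
#' Runs the full pipeline: modification parsing and classification,
#' search-node deduplication, charge-state area summation, the
#' missing-unmodified and replicate-support filters, per-replicate EOM and
#' APO at peptide and residue level, replicate averaging, pooled control
#' subtraction and (for multi-condition runs) Welch comparisons restricted
#' to proteins quantifiable in every condition.
#'
#' @param psm Canonical PSM `data.frame` from [apply_column_mapping()] (or
#'   [generate_experiment()]).
#' @param sample_map Sample map `data.frame` or TSV path (see
#'   [attach_sample_map()]).
#' @param dialect Modification-string dialect of `psm$modifications_raw`.
#' @param catalog Modification catalog.
#' @param mass_tol Catalog mass tolerance (Da).
#' @param match_mode Sample-map matching mode.
#' @param min_mod_replicates Replicate-support threshold (default 3: the
#'   modified area must be seen in more than two laser replicates).
#' @param dedup_policy Duplicate-survivor policy (see [deduplicate_nodes()]).
#' @param mean_mode Replicate averaging: `"arithmetic"` (default) or
#'   `"geometric"` (legacy spreadsheet compatibility).
#' @param denominator_mode Residue-level denominator (see [residue_eom()]).
#' @param clip_negative Clip negative net EOM to zero?
#' @param differential Compare conditions when 2 or more are present?
#' @param bh_adjust Benjamini-Hochberg adjust p-values across targets?
#' @return An object of class `"fpop_eom"`: a list with `peptide` and
#'   `residue` result tables (condition, protein, target, n, mean/sd EOM,
#'   control mean, net EOM, APO, p-value, flags), `comparisons`, `audit`,
#'   `config` and `log` (row counts per stage). See [write_results()],
#'   [plot.fpop_eom()].
#' @export
fpop_quantify <- function(psm, sample_map,
                          dialect = c("generic", "pd", "fragpipe"),
                          catalog = fpop_catalog(), mass_tol = 0.01,
                          match_mode = c("exact", "substring", "regex"),
                          min_mod_replicates = 3L,
                          dedup_policy = c("max", "first"),
                          mean_mode = c("arithmetic", "geometric"),
                          denominator_mode = c("literal", "all_forms"),
                          clip_negative = FALSE, differential = TRUE,
                          bh_adjust = TRUE) {
  dialect <- match.arg(dialect)
  match_mode <- match.arg(match_mode)
  dedup_policy <- match.arg(dedup_policy)
  mean_mode <- match.arg(mean_mode)
  denominator_mode <- match.arg(denominator_mode)
  logv <- c(records_in = nrow(psm))

  ann <- attach_sample_map(psm, sample_map, match_mode)
  af <- annotate_forms(ann, dialect, catalog, mass_tol)
  logv["after_parse"] <- nrow(af$records)
  dd <- deduplicate_nodes(af$records, dedup_policy)
  logv["after_dedup"] <- nrow(dd$records)
  sa <- summarize_areas(dd$records)
  fm <- filter_missing_unmodified(sa$areas)
  logv["area_rows_kept"] <- nrow(fm$areas)
  audit <- bind_audits(af$audit, dd$audit, sa$audit, fm$audit)

  summaries <- split_area_summaries(fm$areas)

  # per-replicate peptide values
  pep_rep <- do.call(rbind, lapply(summaries, function(s) {
    num <- sum(s$forms$area[s$forms$n_fpop > 0L])
    data.frame(condition = s$condition, protein = s$protein,
               target = s$sequence, treatment = s$treatment,
               replicate = s$replicate, file = s$file,
               eom = peptide_eom(s), apo = apo(s),
               evidence = num > 0, stringsAsFactors = FALSE)
  }))
  if (is.null(pep_rep)) pep_rep <- data.frame()

  # residue target list: every FPOP-modified position seen for a peptide
  res_targets <- residue_target_table(fm$areas)
  res_rep <- residue_per_replicate(summaries, res_targets, denominator_mode)

  # replicate-support filter (laser evidence) at both levels
  frs_p <- filter_replicate_support(pep_rep, min_mod_replicates)
  frs_r <- filter_replicate_support(res_rep, min_mod_replicates)
  audit <- bind_audits(audit, frs_p$audit, frs_r$audit)

  peptide <- aggregate_level(frs_p$per_rep, mean_mode, clip_negative,
                             has_apo = TRUE)
  residue <- aggregate_level(frs_r$per_rep, mean_mode, clip_negative,
                             has_apo = FALSE)
  residue <- merge(residue,
                   unique(res_targets[, c("protein", "target", "sequence",
                                          "position", "residue_id")]),
                   by = c("protein", "target"), all.x = TRUE, sort = FALSE)

  conditions <- sort(unique(ann$condition))
  comparisons <- data.frame()
  if (differential && length(conditions) >= 2L) {
    sets <- lapply(conditions, function(cc)
      unique(peptide$protein[peptide$condition == cc]))
    names(sets) <- conditions
    fc <- filter_common_proteins(sets)
    audit <- bind_audits(audit, fc$audit)
    comparisons <- rbind(
      compare_level(frs_p$per_rep, peptide, fc$proteins, "peptide", bh_adjust),
      compare_level(frs_r$per_rep, residue, fc$proteins, "residue", bh_adjust))
  }

  peptide <- attach_pvalues(peptide, comparisons, "peptide", conditions)
  residue <- attach_pvalues(residue, comparisons, "residue", conditions)
  peptide$sequence <- peptide$target
  peptide <- sort_results(peptide)
  residue <- sort_results(residue)
  logv["peptide_targets"] <- nrow(peptide)
  logv["residue_targets"] <- nrow(residue)

  structure(list(
    peptide = peptide, residue = residue, comparisons = comparisons,
    audit = audit, log = logv,
    config = list(dialect = dialect, mass_tol = mass_tol,
                  match_mode = match_mode,
                  min_mod_replicates = as.integer(min_mod_replicates),
                  dedup_policy = dedup_policy, mean_mode = mean_mode,
                  denominator_mode = denominator_mode,
                  clip_negative = clip_negative, differential = differential,
                  bh_adjust = bh_adjust, conditions = conditions)),
    class = "fpop_eom")
}

residue_target_table <- function(areas) {
  mod <- areas[areas$n_fpop > 0L & nzchar(areas$positions), , drop = FALSE]
  if (nrow(mod) == 0L)
    return(data.frame(protein = character(0), sequence = character(0),
                      position = integer(0), residue_id = character(0),
                      target = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(mod)), function(i) {
    pos <- parse_positions(mod$positions[i])
    data.frame(protein = mod$protein[i], sequence = mod$sequence[i],
               position = pos, protein_start = mod$protein_start[i],
               stringsAsFactors = FALSE)
  })
  tt <- unique(do.call(rbind, rows))
  letter <- substr(tt$sequence, tt$position, tt$position)
  tt$residue_id <- ifelse(!is.na(tt$protein_start),
                          paste0(letter, tt$protein_start + tt$position - 1L),
                          paste0(letter, tt$position, "@", tt$sequence))
  tt$target <- tt$residue_id
  tt[, c("protein", "sequence", "position", "residue_id", "target")]
}

residue_per_replicate <- function(summaries, res_targets, denominator_mode) {
  if (nrow(res_targets) == 0L || length(summaries) == 0L)
    return(data.frame(condition = character(0), protein = character(0),
                      target = character(0), treatment = character(0),
                      replicate = integer(0), file = character(0),
                      eom = numeric(0), evidence = logical(0),
                      stringsAsFactors = FALSE))
  out <- lapply(summaries, function(s) {
    tt <- res_targets[res_targets$protein == s$protein &
                      res_targets$sequence == s$sequence, , drop = FALSE]
    if (nrow(tt) == 0L) return(NULL)
    eoms <- vapply(tt$position, function(p)
      residue_eom(s, p, denominator_mode), numeric(1))
    evid <- vapply(tt$position, function(p) {
      hits <- vapply(s$forms$positions, function(ps)
        p %in% parse_positions(ps), logical(1), USE.NAMES = FALSE)
      sum(s$forms$area[hits]) > 0
    }, logical(1))
    data.frame(condition = s$condition, protein = s$protein,
               target = tt$target, treatment = s$treatment,
               replicate = s$replicate, file = s$file, eom = eoms,
               evidence = evid, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), out), list(NULL)))
  rownames(out) <- NULL
  out
}

aggregate_level <- function(per_rep, mean_mode, clip_negative, has_apo) {
  cols <- c("condition", "protein", "target", "n", "mean_eom", "sd_eom",
            "control_mean", "net_eom", if (has_apo) "apo", "flags")
  if (is.null(per_rep) || nrow(per_rep) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols),
                         stringsAsFactors = FALSE)
    return(out)
  }
  key <- paste(per_rep$condition, per_rep$protein, per_rep$target, sep = "\r")
  rows <- lapply(split(seq_len(nrow(per_rep)),
                       factor(key, levels = unique(key))), function(idx) {
    g <- per_rep[idx, , drop = FALSE]
    laser <- g[g$treatment == "laser", , drop = FALSE]
    ctrl <- g[g$treatment == "control", , drop = FALSE]
    if (nrow(laser) == 0L) return(NULL)
    agg <- aggregate_replicates(laser$eom, mean_mode)
    cm <- if (nrow(ctrl) > 0L) aggregate_replicates(ctrl$eom, mean_mode)$mean
          else NA_real_
    sub <- subtract_control(agg$mean, cm, clip_negative)
    flags <- sort(unique(c(agg$flags, sub$flags)))
    df <- data.frame(condition = g$condition[1], protein = g$protein[1],
                     target = g$target[1], n = agg$n, mean_eom = agg$mean,
                     sd_eom = agg$sd, control_mean = sub$control_mean,
                     net_eom = sub$net, stringsAsFactors = FALSE)
    if (has_apo) df$apo <- mean(laser$apo)
    df$flags <- paste(flags, collapse = ",")
    df
  })
  out <- do.call(rbind, c(Filter(Negate(is.null), rows), list(NULL)))
  rownames(out) <- NULL
  out
}

compare_level <- function(per_rep, agg, common_proteins, level, bh_adjust) {
  empty <- data.frame(level = character(0), condition_a = character(0),
                      condition_b = character(0), protein = character(0),
                      target = character(0), delta = numeric(0),
                      t = numeric(0), df = numeric(0), p_value = numeric(0),
                      p_adj = numeric(0), flags = character(0),
                      stringsAsFactors = FALSE)
  if (is.null(per_rep) || nrow(per_rep) == 0L || nrow(agg) == 0L) return(empty)
  agg <- agg[agg$protein %in% common_proteins, , drop = FALSE]
  conds <- sort(unique(agg$condition))
  if (length(conds) < 2L) return(empty)
  laser <- per_rep[per_rep$treatment == "laser", , drop = FALSE]
  cmeans <- setNames(agg$control_mean,
                     paste(agg$condition, agg$protein, agg$target, sep = "\r"))
  rows <- list()
  for (i in seq_len(length(conds) - 1L)) for (j in seq(i + 1L, length(conds))) {
    ca <- conds[i]; cb <- conds[j]
    ta <- unique(agg[agg$condition == ca, c("protein", "target")])
    tb <- unique(agg[agg$condition == cb, c("protein", "target")])
    shared <- merge(ta, tb)
    if (nrow(shared) == 0L) next
    for (k in seq_len(nrow(shared))) {
      pr <- shared$protein[k]; tg <- shared$target[k]
      a <- laser$eom[laser$condition == ca & laser$protein == pr &
                     laser$target == tg] -
           cmeans[[paste(ca, pr, tg, sep = "\r")]]
      b <- laser$eom[laser$condition == cb & laser$protein == pr &
                     laser$target == tg] -
           cmeans[[paste(cb, pr, tg, sep = "\r")]]
      cmp <- compare_conditions(a, b)
      rows[[length(rows) + 1L]] <- data.frame(
        level = level, condition_a = ca, condition_b = cb, protein = pr,
        target = tg, delta = cmp$delta, t = cmp$t, df = cmp$df,
        p_value = cmp$p, p_adj = NA_real_,
        flags = paste(cmp$flags, collapse = ","), stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, c(rows, list(empty)))
  if (nrow(out) > 0L && bh_adjust) {
    key <- paste(out$condition_a, out$condition_b)
    for (kk in unique(key))
      out$p_adj[key == kk] <- stats::p.adjust(out$p_value[key == kk],
                                              method = "BH")
  }
  out <- out[order(out$condition_a, out$condition_b, out$protein, out$target,
                   method = "radix"), , drop = FALSE]
  rownames(out) <- NULL
  out
}

attach_pvalues <- function(agg, comparisons, level, conditions) {
  agg$p_value <- rep(NA_real_, nrow(agg))
  if (nrow(agg) == 0L || nrow(comparisons) == 0L || length(conditions) != 2L)
    return(agg)
  cmp <- comparisons[comparisons$level == level, , drop = FALSE]
  key <- paste(agg$protein, agg$target, sep = "\r")
  idx <- match(key, paste(cmp$protein, cmp$target, sep = "\r"))
  agg$p_value <- cmp$p_value[idx]
  agg
}

sort_results <- function(df) {
  if (nrow(df) == 0L) return(df)
  ord <- order(df$condition, df$protein, df$target, method = "radix")
  out <- df[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
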