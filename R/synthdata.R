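# Synthetic multi-condition, multi-replicate PSM tables with known
# ground-truth modification fractions, including the corruption modes the
# fidelity filters target (node duplicates, replicate dropout).

#' Configuration for a synthetic FPOP experiment
#'
#' Defaults describe a typical cell-scale FPOP design: 100 peptides over 20
#' proteins, two conditions with 4 laser replicates and 4 no-laser controls
#' each, per-peptide true modified fraction drawn uniformly from
#' \[0.05, 0.5\], 2% background oxidation in controls, lognormal peptide
#' abundances with sigma = 0.2 of replicate scatter, and two charge states
#' per form.
#'
#' @param n_proteins,peptides_per_protein Experiment size.
#' @param conditions Condition labels.
#' @param replicates_per_condition Laser replicates per condition.
#' @param control_replicates No-laser control replicates per condition.
#' @param eom_range Range the true per-peptide modified fraction p is drawn
#'   from (uniform).
#' @param control_background Background modified fraction p0 in controls;
#'   must not exceed `min(eom_range)` unless
#'   `allow_background_above_p = TRUE`.
#' @param log_mu Mean of log total peptide area (arbitrary intensity units).
#' @param sigma Lognormal scatter applied both to the per-file total area
#'   draw and, independently, to every XIC component (form x charge), in
#'   mean-preserving form; `sigma = 0` gives exact, noise-free areas.
#' @param charge_states Number of charge states each form's area is split
#'   across (random proportions).
#' @param multi_mod_fraction Share of the modified area carried by a single
#'   2-3-site form (the rest goes to 1-site forms).
#' @param dup_injection_rate Probability a PSM row is duplicated under a
#'   fake search-node id (emulates multilevel-search duplicates).
#' @param dropout_rate Probability a laser replicate lacks a peptide's
#'   modified forms entirely.
#' @param oxidizable Residues eligible for oxidation (the commonly searched
#'   MFHILVWY set).
#' @param allow_background_above_p Permit p0 above the p range.
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return A validated list of class `"synth_config"`.
#' @export
synth_config <- function(n_proteins = 20L, peptides_per_protein = 5L,
                         conditions = c("A", "B"),
                         replicates_per_condition = 4L,
                         control_replicates = 4L,
                         eom_range = c(0.05, 0.5),
                         control_background = 0.02,
                         log_mu = log(1e6), sigma = 0.2,
                         charge_states = 2L, multi_mod_fraction = 0.2,
                         dup_injection_rate = 0, dropout_rate = 0,
                         oxidizable = "MFHILVWY",
                         allow_background_above_p = FALSE, seed = 1L) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              peptides_per_protein = as.integer(peptides_per_protein),
              conditions = as.character(conditions),
              replicates_per_condition = as.integer(replicates_per_condition),
              control_replicates = as.integer(control_replicates),
              eom_range = as.numeric(eom_range),
              control_background = control_background,
              log_mu = log_mu, sigma = sigma,
              charge_states = as.integer(charge_states),
              multi_mod_fraction = multi_mod_fraction,
              dup_injection_rate = dup_injection_rate,
              dropout_rate = dropout_rate, oxidizable = oxidizable,
              allow_background_above_p = isTRUE(allow_background_above_p),
              seed = as.integer(seed))
  probs <- c(cfg$multi_mod_fraction, cfg$dup_injection_rate, cfg$dropout_rate,
             cfg$control_background, cfg$eom_range)
  if (any(probs < 0 | probs > 1))
    stop("all probabilities and fractions must lie in [0, 1]")
  if (cfg$eom_range[1] > cfg$eom_range[2]) stop("eom_range must be increasing")
  if (cfg$control_background > cfg$eom_range[1] && !cfg$allow_background_above_p)
    stop("control_background exceeds min(eom_range); ",
         "set allow_background_above_p = TRUE to override")
  if (cfg$n_proteins < 1L || cfg$peptides_per_protein < 1L ||
      cfg$replicates_per_condition < 1L || cfg$charge_states < 1L ||
      cfg$sigma < 0 || length(cfg$conditions) < 1L)
    stop("invalid synthetic-experiment configuration")
  structure(cfg, class = "synth_config")
}

AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

make_peptide_sequences <- function(n, oxidizable) {
  ox <- strsplit(oxidizable, "")[[1]]
  non_ox <- setdiff(AA20, c(ox, "K", "R"))
  out <- character(n)
  for (i in seq_len(n)) {
    repeat {
      len <- sample(10:16, 1)
      s <- sample(non_ox, len - 1L, replace = TRUE)
      n_ox_here <- sample(3:min(5, len - 2L), 1)
      pos <- sample(seq_len(len - 1L), n_ox_here)
      s[pos] <- sample(ox, n_ox_here, replace = TRUE)
      s <- c(s, sample(c("K", "R"), 1))  # tryptic-like terminus
      seqchr <- paste(s, collapse = "")
      if (!seqchr %in% out) break
    }
    out[i] <- seqchr
  }
  out
}

# per-peptide modified-form layout: 1-site forms plus one optional
# 2-3-site form carrying multi_mod_fraction of the modified area
make_forms <- function(sequence, oxidizable, multi_mod_fraction) {
  ox <- strsplit(oxidizable, "")[[1]]
  pos_all <- which(strsplit(sequence, "")[[1]] %in% ox)
  ns <- min(3L, length(pos_all))
  single_pos <- sort(sample(pos_all, ns))
  w <- stats::runif(ns); w <- w / sum(w)
  forms <- data.frame(positions = as.character(single_pos),
                      share = (1 - multi_mod_fraction) * w,
                      k = 1L, stringsAsFactors = FALSE)
  if (multi_mod_fraction > 0 && length(pos_all) >= 2L) {
    km <- min(3L, length(pos_all))
    multi_pos <- sort(sample(pos_all, km))
    forms <- rbind(forms, data.frame(
      positions = paste(multi_pos, collapse = ","),
      share = multi_mod_fraction, k = km, stringsAsFactors = FALSE))
  } else if (multi_mod_fraction > 0) {
    # too few oxidizable residues for a multi form: fold into singles
    forms$share <- forms$share / sum(forms$share)
  }
  forms$mods <- vapply(strsplit(forms$positions, ","), function(p)
    paste(sprintf("%s:%s:Oxidation:15.9949", p,
                  substring(sequence, as.integer(p), as.integer(p))),
          collapse = "; "), character(1))
  forms
}

#' Generate a synthetic FPOP experiment with known ground truth
#'
#' For every (condition, replicate, treatment) spectrum file, each
#' peptide's total area is drawn lognormally; the modified share (true
#' fraction p for laser files, background p0 for controls) is split among
#' 1-3-site oxidized forms and across charge states with random
#' proportions, and every XIC component receives independent
#' mean-preserving lognormal noise. Node duplicates and modified-form
#' dropout are applied as separate post-processing passes with their own
#' derived seeds, so changing their rates never perturbs the core data.
#'
#' @param config A [synth_config()].
#' @return List with `psm` (canonical PSM `data.frame`, generic
#'   modification dialect), `sample_map`, and `truth` (list of `peptide`
#'   ground truth with per-peptide p/p0/APO factor, `residue` with
#'   per-residue area shares, and `file_totals` with drawn and realized
#'   per-file totals before dropout).
#' @export
generate_experiment <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  cfg <- config
  set.seed(cfg$seed)

  npep <- cfg$n_proteins * cfg$peptides_per_protein
  protein <- sprintf("PROT%03d", rep(seq_len(cfg$n_proteins),
                                     each = cfg$peptides_per_protein))
  sequence <- make_peptide_sequences(npep, cfg$oxidizable)
  p <- stats::runif(npep, cfg$eom_range[1], cfg$eom_range[2])
  forms <- lapply(sequence, make_forms, oxidizable = cfg$oxidizable,
                  multi_mod_fraction = cfg$multi_mod_fraction)

  truth_pep <- data.frame(protein = protein, sequence = sequence, p = p,
                          p0 = cfg$control_background,
                          apo_factor = vapply(forms, function(f)
                            sum(f$share * f$k), numeric(1)),
                          stringsAsFactors = FALSE)
  truth_res <- do.call(rbind, lapply(seq_len(npep), function(i) {
    f <- forms[[i]]
    pos <- lapply(strsplit(f$positions, ","), as.integer)
    all_pos <- sort(unique(unlist(pos)))
    share <- vapply(all_pos, function(pp)
      sum(f$share[vapply(pos, function(v) pp %in% v, logical(1))]), numeric(1))
    data.frame(protein = protein[i], sequence = sequence[i],
               position = all_pos,
               residue = substring(sequence[i], all_pos, all_pos),
               share = share, stringsAsFactors = FALSE)
  }))

  files <- expand.grid(replicate = seq_len(max(cfg$replicates_per_condition,
                                               cfg$control_replicates)),
                       treatment = c("laser", "control"),
                       condition = cfg$conditions,
                       stringsAsFactors = FALSE)
  files <- files[(files$treatment == "laser" &
                  files$replicate <= cfg$replicates_per_condition) |
                 (files$treatment == "control" &
                  files$replicate <= cfg$control_replicates), , drop = FALSE]
  files <- files[order(files$condition, files$treatment, files$replicate), ,
                 drop = FALSE]
  files$file <- sprintf("%s_R%d_%s.raw", files$condition, files$replicate,
                        ifelse(files$treatment == "laser", "L", "C"))
  if (cfg$control_replicates == 0L)
    files <- files[files$treatment == "laser", , drop = FALSE]

  charges <- seq(2L, length.out = cfg$charge_states)
  rows <- vector("list", nrow(files))
  totals <- vector("list", nrow(files))
  for (fi in seq_len(nrow(files))) {
    fr <- files[fi, ]
    A <- exp(stats::rnorm(npep, cfg$log_mu, cfg$sigma))
    frac <- if (fr$treatment == "laser") p else rep(cfg$control_background, npep)
    pep_rows <- vector("list", npep)
    realized <- numeric(npep)
    for (i in seq_len(npep)) {
      f <- forms[[i]]
      comp_share <- c(1 - frac[i], frac[i] * f$share)        # unmod + forms
      comp_mods <- c("", f$mods)
      nz <- length(charges)
      cw <- matrix(stats::runif(length(comp_share) * nz), ncol = nz)
      cw <- cw / rowSums(cw)
      noise <- matrix(exp(stats::rnorm(length(comp_share) * nz,
                                       -cfg$sigma^2 / 2, cfg$sigma)),
                      ncol = nz)
      ab <- A[i] * comp_share * cw * noise
      realized[i] <- sum(ab)
      pep_rows[[i]] <- data.frame(
        accession = protein[i], sequence = sequence[i],
        modifications_raw = rep(comp_mods, times = nz),
        abundance = as.vector(ab),
        spectrum_file = fr$file,
        charge = rep(charges, each = length(comp_share)),
        search_node = "n1", stringsAsFactors = FALSE)
    }
    rows[[fi]] <- do.call(rbind, pep_rows)
    totals[[fi]] <- data.frame(file = fr$file, protein = protein,
                               sequence = sequence, drawn_area = A,
                               realized_area = realized,
                               stringsAsFactors = FALSE)
  }
  psm <- do.call(rbind, rows)
  rownames(psm) <- NULL

  # dropout pass: a laser replicate loses a peptide's modified forms
  if (cfg$dropout_rate > 0) {
    set.seed(cfg$seed + 1L)
    laser_files <- files$file[files$treatment == "laser"]
    combos <- expand.grid(file = laser_files, sequence = sequence,
                          stringsAsFactors = FALSE)
    drop <- combos[stats::runif(nrow(combos)) < cfg$dropout_rate, , drop = FALSE]
    if (nrow(drop) > 0L) {
      kill <- paste(psm$spectrum_file, psm$sequence) %in%
        paste(drop$file, drop$sequence) & nzchar(psm$modifications_raw)
      psm <- psm[!kill, , drop = FALSE]
    }
  }

  # duplicate-injection pass: fake second search node
  if (cfg$dup_injection_rate > 0) {
    set.seed(cfg$seed + 2L)
    dup <- stats::runif(nrow(psm)) < cfg$dup_injection_rate
    if (any(dup)) {
      extra <- psm[dup, , drop = FALSE]
      extra$search_node <- "n2_dup"
      psm <- rbind(psm, extra)
    }
  }
  rownames(psm) <- NULL

  sample_map <- data.frame(file_pattern = files$file,
                           condition = files$condition,
                           replicate = files$replicate,
                           treatment = files$treatment,
                           stringsAsFactors = FALSE)
  rownames(sample_map) <- NULL
  list(psm = psm, sample_map = sample_map,
       truth = list(peptide = truth_pep, residue = truth_res,
                    file_totals = do.call(rbind, totals)))
}

#' Write a synthetic experiment to disk in a search-engine dialect
#'
#' Emits the PSM table with dialect-correct column names and
#' modification-string grammar (so the IO and parsing layers are exercised
#' end to end), plus `sample_map.tsv` and the ground-truth tables.
#'
#' @param experiment Result of [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @param dialect `"generic_tsv"`, `"pd_like"` or `"fragpipe_like"`.
#' @return Invisibly, a named vector of the paths written (`psm`,
#'   `sample_map`, `truth_peptide`, `truth_residue`).
#' @export
emit_dialect <- function(experiment, dir,
                         dialect = c("generic_tsv", "pd_like", "fragpipe_like")) {
  dialect <- match.arg(dialect)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  psm <- experiment$psm
  mods <- psm$modifications_raw
  if (dialect != "generic_tsv") {
    target <- if (dialect == "pd_like") "pd" else "fragpipe"
    umods <- unique(paste(psm$sequence, mods, sep = "\r"))
    conv <- vapply(umods, function(u) {
      parts <- strsplit(u, "\r", fixed = TRUE)[[1]]
      m <- if (length(parts) < 2L) "" else parts[2]
      serialize_modifications(parse_modifications(m, parts[1], "generic"),
                              target)
    }, character(1))
    mods <- unname(conv[match(paste(psm$sequence, mods, sep = "\r"), umods)])
  }
  out <- if (dialect == "fragpipe_like") {
    data.frame("Protein" = psm$accession, "Peptide" = psm$sequence,
               "Assigned Modifications" = mods,
               "Intensity" = psm$abundance,
               "Spectrum File" = psm$spectrum_file, "Charge" = psm$charge,
               check.names = FALSE, stringsAsFactors = FALSE)
  } else {
    data.frame("Master Protein Accessions" = psm$accession,
               "Sequence" = psm$sequence, "Modifications" = mods,
               "Precursor Abundance" = psm$abundance,
               "Spectrum File" = psm$spectrum_file, "Charge" = psm$charge,
               "Search Node" = psm$search_node,
               check.names = FALSE, stringsAsFactors = FALSE)
  }
  paths <- c(psm = file.path(dir, "psm_table.tsv"),
             sample_map = file.path(dir, "sample_map.tsv"),
             truth_peptide = file.path(dir, "ground_truth_peptide.tsv"),
             truth_residue = file.path(dir, "ground_truth_residue.tsv"))
  write_tsv(out, paths[["psm"]])
  write_tsv(experiment$sample_map, paths[["sample_map"]])
  write_tsv(experiment$truth$peptide, paths[["truth_peptide"]])
  write_tsv(experiment$truth$residue, paths[["truth_residue"]])
  invisible(paths)
}
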