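# Publication-style outputs: per-target bar graphs, grouped condition
# bars, and 2-3-set Venn diagrams. Each function returns (invisibly) the
# computed geometry so tests assert on data, not rendered pixels; passing
# `file=` additionally renders to png/svg/pdf.

open_device <- function(file, format = c("png", "svg", "pdf"),
                        width = 7, height = 5) {
  format <- match.arg(format)
  switch(format,
    png = grDevices::png(file, width = width, height = height,
                         units = "in", res = 150),
    svg = grDevices::svg(file, width = width, height = height),
    pdf = grDevices::pdf(file, width = width, height = height))
}

unique_labels <- function(x) {
  if (!anyDuplicated(x)) return(x)
  make.unique(x, sep = "#")
}

#' Bar graph of net EOM per target
#'
#' One bar per peptide or residue target, height = control-subtracted mean
#' EOM, with optional standard-deviation error bars.
#'
#' @param results A peptide- or residue-level result `data.frame` (one
#'   condition) with columns `target`, `net_eom`, `sd_eom`.
#' @param error_bar `"sd"` (default) or `"none"`.
#' @param main Plot title.
#' @param file Optional output path; rendered when given.
#' @param format Image format for `file`.
#' @return Invisibly, a list with `labels`, `heights`, `errors` as drawn;
#'   `NULL` (with a warning, no file) for an empty table.
#' @export
plot_bars <- function(results, error_bar = c("sd", "none"),
                      main = "Extent of Modification", file = NULL,
                      format = c("png", "svg", "pdf")) {
  error_bar <- match.arg(error_bar)
  if (is.null(results) || nrow(results) == 0L) {
    warning("no targets to plot")
    return(invisible(NULL))
  }
  labels <- unique_labels(as.character(results$target))
  heights <- results$net_eom
  errors <- if (error_bar == "sd") results$sd_eom else rep(NA_real_, nrow(results))
  geom <- list(labels = labels, heights = heights, errors = errors)
  draw <- function() {
    op <- graphics::par(mar = c(9, 4, 3, 1))
    on.exit(graphics::par(op))
    mids <- graphics::barplot(heights, names.arg = labels, las = 2,
                              col = "steelblue", main = main,
                              ylab = "Extent of Modification",
                              cex.names = 0.7,
                              ylim = range(0, heights + ifelse(is.na(errors), 0, errors),
                                           heights, na.rm = TRUE) * 1.08)
    if (error_bar == "sd") {
      up <- heights + errors; dn <- heights - errors
      ok <- !is.na(errors) & errors > 0
      if (any(ok))
        graphics::arrows(mids[ok], dn[ok], mids[ok], up[ok], angle = 90,
                         code = 3, length = 0.03)
    }
  }
  if (!is.null(file)) {
    open_device(file, format)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else if (interactive()) draw()
  invisible(geom)
}

#' Grouped bar graph comparing conditions
#'
#' Adjacent bars per condition for each target shared between conditions,
#' with significance markers (`*`) on targets whose Welch comparison
#' p-value is below `alpha`.
#'
#' @param results Multi-condition result `data.frame` with columns
#'   `condition`, `target`, `net_eom`, `sd_eom`, `p_value`.
#' @param condition_order Order of conditions within each group (default:
#'   sorted unique conditions present).
#' @param alpha Significance threshold for markers.
#' @inheritParams plot_bars
#' @return Invisibly, a list with the height matrix (`conditions x
#'   targets`), error matrix, and `significant` logical per target; `NULL`
#'   (warning) when no target is shared between conditions.
#' @export
plot_grouped_bars <- function(results, condition_order = NULL, alpha = 0.05,
                              error_bar = c("sd", "none"),
                              main = "Extent of Modification by Condition",
                              file = NULL, format = c("png", "svg", "pdf")) {
  error_bar <- match.arg(error_bar)
  conds <- if (is.null(condition_order)) sort(unique(results$condition))
           else condition_order
  if (length(conds) < 2L) stop("grouped bars need at least 2 conditions")
  counts <- table(unique(results[, c("condition", "target")])$target)
  shared <- names(counts)[counts == length(conds)]
  shared <- shared[order(match(shared, results$target))]  # input order
  if (length(shared) == 0L) {
    warning("no targets shared between conditions")
    return(invisible(NULL))
  }
  h <- matrix(NA_real_, length(conds), length(shared),
              dimnames = list(conds, shared))
  e <- h
  sig <- setNames(rep(FALSE, length(shared)), shared)
  for (cc in conds) {
    sub <- results[results$condition == cc, , drop = FALSE]
    idx <- match(shared, sub$target)
    h[cc, ] <- sub$net_eom[idx]
    e[cc, ] <- sub$sd_eom[idx]
    if ("p_value" %in% names(sub))
      sig <- sig | (!is.na(sub$p_value[idx]) & sub$p_value[idx] < alpha)
  }
  geom <- list(heights = h, errors = e, significant = sig,
               conditions = conds)
  draw <- function() {
    op <- graphics::par(mar = c(9, 4, 3, 1))
    on.exit(graphics::par(op))
    shades <- grDevices::gray.colors(length(conds), start = 0.25, end = 0.75)
    top <- max(h + ifelse(is.na(e), 0, e), 0, na.rm = TRUE)
    mids <- graphics::barplot(h, beside = TRUE, names.arg = colnames(h),
                              las = 2, col = shades, main = main,
                              ylab = "Extent of Modification", cex.names = 0.7,
                              ylim = c(min(h, 0, na.rm = TRUE), top * 1.15),
                              legend.text = conds,
                              args.legend = list(x = "topright", bty = "n"))
    if (error_bar == "sd") {
      ok <- !is.na(e) & e > 0
      if (any(ok))
        graphics::arrows(mids[ok], (h - e)[ok], mids[ok], (h + e)[ok],
                         angle = 90, code = 3, length = 0.03)
    }
    if (any(sig))
      graphics::text(colMeans(mids)[sig],
                     apply(h + ifelse(is.na(e), 0, e), 2, max)[sig] + top * 0.05,
                     "*", cex = 1.4)
  }
  if (!is.null(file)) {
    open_device(file, format)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else if (interactive()) draw()
  invisible(geom)
}

#' Region counts for 2 or 3 labeled sets
#'
#' @param sets Named list of 2 or 3 character vectors.
#' @return List with `counts` (named by region label, e.g. `"A"`, `"A&B"`)
#'   and `membership` (`data.frame`: every id with its region).
#' @export
venn_regions <- function(sets) {
  if (length(sets) < 2L || length(sets) > 3L)
    stop("Venn diagrams support 2 or 3 sets")
  if (is.null(names(sets)) || any(!nzchar(names(sets))))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  labs <- names(sets)
  ids <- sort(unique(unlist(sets)))
  inset <- vapply(sets, function(s) ids %in% s, logical(length(ids)))
  if (length(ids) == 1L) inset <- matrix(inset, nrow = 1, dimnames = list(NULL, labs))
  region <- apply(inset, 1, function(m) paste(labs[m], collapse = "&"))
  # all 2^k - 1 region labels, fixed order
  combos <- unlist(lapply(seq_along(labs), function(k)
    utils::combn(labs, k, paste, collapse = "&", simplify = FALSE)),
    use.names = FALSE)
  counts <- setNames(integer(length(combos)), combos)
  tb <- table(region)
  counts[names(tb)] <- as.integer(tb)
  list(counts = counts,
       membership = data.frame(id = ids, region = region,
                               stringsAsFactors = FALSE))
}

#' Venn diagram of 2 or 3 sets
#'
#' Draws proportional circles with region counts computed by exact set
#' algebra (see [venn_regions()]).
#'
#' @inheritParams venn_regions
#' @inheritParams plot_bars
#' @return Invisibly, the [venn_regions()] list.
#' @export
plot_venn <- function(sets, main = "Shared modified proteins", file = NULL,
                      format = c("png", "svg", "pdf")) {
  reg <- venn_regions(sets)
  labs <- names(sets)
  k <- length(labs)
  centers <- if (k == 2L) cbind(x = c(-0.5, 0.5), y = c(0, 0))
             else cbind(x = c(-0.5, 0.5, 0), y = c(0.35, 0.35, -0.5))
  # region label positions (fixed layout)
  region_xy <- if (k == 2L) {
    rbind(c(-0.9, 0), c(0.9, 0), c(0, 0))
  } else {
    rbind(c(-0.9, 0.55), c(0.9, 0.55), c(0, -0.95),
          c(0, 0.65), c(-0.55, -0.2), c(0.55, -0.2), c(0, 0.05))
  }
  draw <- function() {
    op <- graphics::par(mar = c(1, 1, 3, 1))
    on.exit(graphics::par(op))
    graphics::plot(NA, xlim = c(-2, 2), ylim = c(-2, 2), axes = FALSE,
                   xlab = "", ylab = "", main = main, asp = 1)
    cols <- grDevices::adjustcolor(c("steelblue", "indianred", "seagreen")[1:k],
                                   alpha.f = 0.4)
    graphics::symbols(centers[, "x"], centers[, "y"],
                      circles = rep(1.05, k), inches = FALSE, add = TRUE,
                      bg = cols, fg = "grey30")
    graphics::text(region_xy[, 1], region_xy[, 2], reg$counts)
    lab_xy <- centers * 1.9
    graphics::text(lab_xy[, "x"], lab_xy[, "y"], labs, font = 2)
  }
  if (!is.null(file)) {
    open_device(file, format)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else if (interactive()) draw()
  invisible(reg)
}

#' Volcano plot of condition comparisons
#'
#' Net-EOM difference against -log10 p for every compared target; off the
#' default output set but handy for proteome-wide runs.
#'
#' @param comparisons The `comparisons` table of an `fpop_eom` object.
#' @param alpha Significance threshold line.
#' @inheritParams plot_bars
#' @return Invisibly, a `data.frame` with `delta` and `neg_log10_p`.
#' @export
plot_volcano <- function(comparisons, alpha = 0.05, main = "Volcano",
                         file = NULL, format = c("png", "svg", "pdf")) {
  ok <- !is.na(comparisons$p_value)
  df <- data.frame(target = comparisons$target[ok],
                   delta = comparisons$delta[ok],
                   neg_log10_p = -log10(comparisons$p_value[ok]))
  draw <- function() {
    graphics::plot(df$delta, df$neg_log10_p, pch = 19,
                   col = ifelse(df$neg_log10_p > -log10(alpha), "red3", "grey40"),
                   xlab = expression(Delta ~ "net EOM"),
                   ylab = expression(-log[10] ~ p), main = main)
    graphics::abline(h = -log10(alpha), lty = 2)
  }
  if (!is.null(file)) {
    open_device(file, format)
    on.exit(grDevices::dev.off(), add = TRUE)
    draw()
  } else if (interactive()) draw()
  invisible(df)
}

#' Plot method for fpop_eom objects
#'
#' @param x An `fpop_eom` object.
#' @param kind `"bar"`, `"grouped_bar"`, `"venn"` or `"volcano"`.
#' @param level `"peptide"` or `"residue"`.
#' @param condition Condition to plot for `kind = "bar"` (default first).
#' @param ... Passed to the underlying plot function ([plot_bars()],
#'   [plot_grouped_bars()], [plot_venn()], [plot_volcano()]).
#' @return Invisibly, the underlying plot geometry.
#' @export
plot.fpop_eom <- function(x, kind = c("bar", "grouped_bar", "venn", "volcano"),
                          level = c("peptide", "residue"),
                          condition = NULL, ...) {
  kind <- match.arg(kind)
  level <- match.arg(level)
  tab <- x[[level]]
  if (kind == "bar") {
    cc <- if (is.null(condition)) x$config$conditions[1] else condition
    plot_bars(tab[tab$condition == cc, , drop = FALSE], ...)
  } else if (kind == "grouped_bar") {
    plot_grouped_bars(tab, ...)
  } else if (kind == "venn") {
    memb <- venn_membership(x, level)
    conds <- x$config$conditions
    sets <- lapply(conds, function(cc) memb$id[memb[[cc]]])
    names(sets) <- conds
    plot_venn(sets, ...)
  } else {
    cmp <- x$comparisons[x$comparisons$level == level, , drop = FALSE]
    plot_volcano(cmp, ...)
  }
}
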