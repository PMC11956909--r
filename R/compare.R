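# Two-group comparison of per-subject regional densities (e.g. male vs
# female), one test per (region, cell type), with Benjamini-Hochberg false
# discovery rate control across all tests jointly.

#' Compare per-region, per-cell-type densities between two groups
#'
#' Runs Welch's two-sample t test (default) or the Mann-Whitney U test on the
#' per-subject densities of every (region, cell type) cell, then applies
#' Benjamini-Hochberg correction across all tested rows jointly. Rows where
#' either group has fewer than two subjects are flagged `untested` and get NA
#' statistics. Effects are reported as the ratio of group means (group1 /
#' group2), mirroring "more cells in group 1" phrasing.
#'
#' @param rdm a `region_density_matrix` whose subjects carry group labels, or
#'   a long data.frame with columns `region_id`, `cell_type`, `subject_id`,
#'   `group`, `density`.
#' @param groups optional character length-2 selecting and ordering the two
#'   group labels; default: the two labels present.
#' @param alpha FDR level used to flag discoveries (q <= alpha).
#' @param test `"welch"` or `"wilcoxon"`.
#' @return A `comparison_table` data.frame: region_id, cell_type, mean_1,
#'   mean_2, effect_ratio, statistic, p, q, significant, untested; attribute
#'   `groups`.
#' @export
compare_groups <- function(rdm, groups = NULL, alpha = 0.05,
                           test = c("welch", "wilcoxon")) {
  test <- match.arg(test)
  stopifnot(alpha > 0, alpha < 1)
  long <- if (inherits(rdm, "region_density_matrix")) rdm_to_long(rdm) else rdm
  need <- c("region_id", "cell_type", "subject_id", "group", "density")
  if (!all(need %in% names(long)))
    stop("need columns: ", paste(need, collapse = ", "), call. = FALSE)
  if (is.null(groups)) {
    groups <- sort(unique(long$group))
    if (length(groups) != 2)
      stop("exactly two group labels required; found: ",
           paste(groups, collapse = ", "), call. = FALSE)
  }
  long <- long[long$group %in% groups, ]
  cells <- unique(long[c("region_id", "cell_type")])
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- long[long$region_id == cells$region_id[i] &
                long$cell_type == cells$cell_type[i], ]
    x <- sub$density[sub$group == groups[1]]
    y <- sub$density[sub$group == groups[2]]
    untested <- length(x) < 2 || length(y) < 2
    if (untested) {
      stat <- p <- NA_real_
    } else if (stats::var(x) == 0 && stats::var(y) == 0) {
      # degenerate constant samples: t.test would error; identical means are
      # no evidence of a difference, distinct constant means are a sure one
      if (mean(x) == mean(y)) { stat <- 0; p <- 1 }
      else { stat <- sign(mean(x) - mean(y)) * Inf; p <- 0 }
    } else if (test == "welch") {
      ht <- stats::t.test(x, y, var.equal = FALSE)
      stat <- unname(ht$statistic); p <- ht$p.value
    } else {
      ht <- suppressWarnings(stats::wilcox.test(x, y, exact = FALSE))
      stat <- unname(ht$statistic); p <- ht$p.value
    }
    m1 <- mean(x); m2 <- mean(y)
    data.frame(region_id = cells$region_id[i], cell_type = cells$cell_type[i],
               mean_1 = m1, mean_2 = m2,
               effect_ratio = if (m2 > 0) m1 / m2 else NA_real_,
               statistic = stat, p = p, untested = untested)
  })
  out <- do.call(rbind, rows)
  out$q <- NA_real_
  tested <- !out$untested
  out$q[tested] <- stats::p.adjust(out$p[tested], method = "BH")
  out$significant <- !is.na(out$q) & out$q <= alpha
  structure(out, groups = groups, alpha = alpha, test = test,
            class = c("comparison_table", "data.frame"))
}

rdm_to_long <- function(rdm) {
  dn <- dimnames(rdm$density)
  long <- expand.grid(region_id = dn$region, cell_type = dn$cell_type,
                      subject_id = dn$subject, stringsAsFactors = FALSE)
  long$density <- as.numeric(rdm$density)
  long$group <- unname(rdm$subjects[long$subject_id])
  long$region_id <- as.integer(long$region_id)
  long
}

#' @export
print.comparison_table <- function(x, ...) {
  g <- attr(x, "groups")
  cat(sprintf("comparison_table: %s vs %s, %d cells tested, %d significant at q <= %.2f (%s)\n",
              g[1], g[2], sum(!x$untested), sum(x$significant),
              attr(x, "alpha"), attr(x, "test")))
  invisible(x)
}
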