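#' Mean-plot data for significant metabolites
#'
#' For every metabolite with at least one significant pairwise difference,
#' collects the material of a group mean plot: arithmetic group means of the
#' normalized values, 95% confidence half-widths
#' \eqn{t_{0.975,\nu} \sqrt{MSE/n_g}} from the same one-way ANOVA that fed
#' Tukey's test, the compact-letter labels, and the k x k fold-change matrix
#' (cell in row i, column j compares group i against the group in column j).
#'
#' @param object A `"metabnorm"` object.
#' @param cmp A [compare_groups()] result.
#' @param conf_level Confidence level of the interval bars.
#' @return Named list, one entry per significant metabolite:
#'   `means`, `ci_halfwidth`, `n`, `letters`, `fc_matrix`.
#' @export
build_mean_plot_data <- function(object, cmp, conf_level = 0.95) {
  stopifnot(inherits(object, "metabnorm"),
            inherits(cmp, "metab_comparisons"))
  out <- list()
  for (m in cmp$significant_metabolites) {
    tk <- cmp$anova[[m]]
    if (is.null(tk)) next
    means <- attr(tk, "means")
    n_g <- attr(tk, "n")
    nu <- attr(tk, "df")
    hw <- stats::qt(1 - (1 - conf_level) / 2, nu) *
      sqrt(attr(tk, "MSE") / n_g)
    out[[m]] <- list(means = means,
                     ci_halfwidth = stats::setNames(hw, names(means)),
                     n = n_g,
                     letters = cmp$letters[[m]],
                     fc_matrix = fold_change_matrix(
                       object$fits[[m]]$group_means[names(means)],
                       object$spec$transform))
  }
  out
}

#' Pre/post-normalization confounder plot data
#'
#' For every (metabolite, declared confounder) pair, pairs the transformed
#' raw values with the normalized values against the confounder: grouped
#' box-plot data for categorical confounders (fixed factors and random
#' block factors), scatter data for continuous ones.  Visual verification
#' that normalization removed the confounder's effect.
#'
#' @param object A `"metabnorm"` object.
#' @return List, one entry per metabolite x confounder: `metabolite`,
#'   `confounder`, `kind` (`"continuous"` or `"categorical"`), and a data
#'   frame `data` with columns `x`, `pre`, `post`.
#' @export
build_confounder_plots <- function(object) {
  stopifnot(inherits(object, "metabnorm"))
  spec <- object$spec
  confs <- c(spec$fixed_continuous, spec$fixed_factors, spec$random_factors)
  kinds <- rep(c("continuous", "categorical"),
               c(length(spec$fixed_continuous),
                 length(spec$fixed_factors) + length(spec$random_factors)))
  out <- list()
  for (m in names(object$fits)) {
    for (ci in seq_along(confs)) {
      v <- confs[ci]
      out[[paste(m, v, sep = ".")]] <- list(
        metabolite = m, confounder = v, kind = kinds[ci],
        data = data.frame(x = object$table$data[[v]],
                          pre = object$transformed$data[[m]],
                          post = object$normalized[[m]]))
    }
  }
  out
}

#' Mean-centered heatmap with dendrograms
#'
#' Mean-centers every normalized metabolite column (over its non-missing
#' values) and clusters rows (samples) and columns (metabolites)
#' hierarchically with Euclidean distance and complete linkage.  Missing
#' cells are excluded from the distances (pairwise-complete, via
#' [stats::dist()]'s rescaled sums) and stay blank in the drawn heatmap.
#'
#' @param object A `"metabnorm"` object, or a numeric samples x metabolites
#'   matrix of normalized values.
#' @return List of class `"metab_heatmap"`: `matrix` (centered values),
#'   `row_hclust`, `col_hclust`.
#' @export
build_heatmap <- function(object) {
  if (inherits(object, "metabnorm")) {
    mat <- as.matrix(object$normalized[names(object$fits)])
    rownames(mat) <- paste(
      as.character(object$table$data[[object$table$sample_col]]),
      as.character(object$normalized[[object$spec$group_col]]), sep = " / ")
  } else mat <- as.matrix(object)
  if (nrow(mat) < 2L || ncol(mat) < 2L)
    stop("report error: heatmap needs at least 2 samples and 2 metabolites",
         call. = FALSE)
  if (any(colSums(!is.na(mat)) == 0L))
    stop("report error: all-missing metabolite column", call. = FALSE)
  centered <- scale(mat, center = TRUE, scale = FALSE)
  attr(centered, "scaled:center") <- NULL
  row_h <- stats::hclust(stats::dist(centered), method = "complete")
  col_h <- stats::hclust(stats::dist(t(centered)), method = "complete")
  structure(list(matrix = centered, row_hclust = row_h, col_hclust = col_h),
            class = "metab_heatmap")
}

#' @export
plot.metab_heatmap <- function(x, ...) {
  pal <- grDevices::colorRampPalette(c("#2166AC", "#F7F7F7", "#B2182B"))(101)
  stats::heatmap(x$matrix,
                 Rowv = stats::as.dendrogram(x$row_hclust),
                 Colv = stats::as.dendrogram(x$col_hclust),
                 scale = "none", col = pal,
                 margins = c(8, 8), ...)
  invisible(x)
}

#' Pathway-mapping export of significant results
#'
#' One row per significant (metabolite, comparison): metabolite name,
#' comparison label, fold-change, a direction colour token (`red` up,
#' `blue` down, `grey` for fold-change 1), a dot-size value scaled by
#' `|log2 FC|`, and the chosen p- or q-value.  The column layout targets
#' spreadsheet upload into a pathway-visualization service and is
#' provisional: the exact upload schema of such services is not fixed, so
#' adjust columns downstream if a service rejects the file.
#'
#' @param cmp A [compare_groups()] result (screening already applied).
#' @param value_kind Which value to carry: `"p"` or `"q"`.
#' @return Data frame with columns `metabolite`, `comparison`,
#'   `fold_change`, `color`, `dot_size`, `value` (header only when nothing
#'   is significant).
#' @export
export_pathway_projector <- function(cmp, value_kind = c("p", "q")) {
  stopifnot(inherits(cmp, "metab_comparisons"))
  value_kind <- match.arg(value_kind)
  r <- cmp$results[cmp$results$significant, , drop = FALSE]
  fc <- r$fold_change
  data.frame(metabolite = r$metabolite,
             comparison = r$comparison,
             fold_change = fc,
             color = ifelse(is.na(fc) | fc == 1, "grey",
                            ifelse(fc > 1, "red", "blue")),
             dot_size = abs(log2(fc)),
             value = if (value_kind == "p") r$tukey_p else r$q_value,
             stringsAsFactors = FALSE)
}

# --- PDF renderers -----------------------------------------------------

.draw_mean_plots <- function(mean_data, transform) {
  if (!length(mean_data)) {
    graphics::plot.new()
    graphics::text(0.5, 0.5, "No significant metabolites")
    return(invisible())
  }
  for (m in names(mean_data)) {
    d <- mean_data[[m]]
    k <- length(d$means)
    ylim <- range(c(d$means - d$ci_halfwidth, d$means + d$ci_halfwidth))
    pad <- 0.35 * diff(ylim)
    graphics::plot(seq_len(k), d$means, xaxt = "n", xlim = c(0.5, k + 0.5),
                   ylim = c(ylim[1] - pad * (1 + k / 2), ylim[2] + pad),
                   xlab = "", ylab = "Normalized mean (log2 scale)",
                   main = m, pch = 16, cex = 1.3)
    graphics::axis(1, at = seq_len(k), labels = names(d$means))
    graphics::arrows(seq_len(k), d$means - d$ci_halfwidth,
                     seq_len(k), d$means + d$ci_halfwidth,
                     angle = 90, code = 3, length = 0.06)
    graphics::text(seq_len(k), d$means + d$ci_halfwidth,
                   labels = d$letters[names(d$means)], pos = 3, font = 2)
    # fold-change matrix below: row i = comparisons with column group j
    y0 <- ylim[1] - pad
    for (i in seq_len(k))
      graphics::text(seq_len(k), y0 - (i - 1) * pad / 2,
                     labels = sprintf("%.3f", d$fc_matrix[i, ]),
                     cex = 0.7, col = "grey25")
  }
  invisible()
}

.draw_confounder_plots <- function(plots) {
  for (p in plots) {
    d <- p$data
    keep <- !is.na(d$x)
    d <- d[keep, , drop = FALSE]
    graphics::par(mfrow = c(1, 2))
    for (phase in c("pre", "post")) {
      y <- d[[phase]]
      ttl <- paste0(p$metabolite, " vs ", p$confounder, " (", phase,
                    "-normalization)")
      if (p$kind == "continuous") {
        graphics::plot(d$x, y, xlab = p$confounder, ylab = "log2 signal",
                       main = ttl, pch = 16, cex.main = 0.8)
        ok <- !is.na(y)
        if (sum(ok) > 2)
          graphics::abline(stats::lm(y ~ d$x), col = "red3", lty = 2)
      } else {
        graphics::boxplot(y ~ factor(d$x), xlab = p$confounder,
                          ylab = "log2 signal", main = ttl, cex.main = 0.8)
      }
    }
    graphics::par(mfrow = c(1, 1))
  }
  invisible()
}
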