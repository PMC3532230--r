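#' Shapiro-Wilk normality test of residuals
#'
#' Thin, validating wrapper around [stats::shapiro.test()], applied to the
#' conditional residuals of a metabolite fit (pooled across groups).
#'
#' @param residuals Numeric vector, 3 to 5000 non-missing values, not all
#'   identical.
#' @return List with `W` and `p`.
#' @export
test_normality <- function(residuals) {
  x <- residuals[!is.na(residuals)]
  if (length(x) < 3L || length(x) > 5000L)
    stop("diagnostic error: Shapiro-Wilk requires 3..5000 observations",
         call. = FALSE)
  if (max(x) - min(x) < .Machine$double.eps * 100)
    stop("diagnostic error: residuals are constant", call. = FALSE)
  sw <- stats::shapiro.test(x)
  list(W = unname(sw$statistic), p = unname(sw$p.value))
}

#' Brown-Forsythe test of equal group variances
#'
#' Levene-type test computed as a one-way ANOVA on absolute deviations from
#' the group center (median by default — the Brown-Forsythe variant — or the
#' mean), applied to normalized values by treatment group.  Implemented with
#' [car::leveneTest()].
#'
#' @param values Numeric vector of normalized values (may contain `NA`).
#' @param groups Group labels, same length as `values`.
#' @param center `"median"` (default) or `"mean"`.
#' @return List with `stat` (the F-type statistic) and `p`.
#' @export
test_equal_variance <- function(values, groups, center = c("median", "mean")) {
  center <- match.arg(center)
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]
  g <- factor(as.character(groups)[keep])
  if (nlevels(g) < 2L)
    stop("diagnostic error: need at least 2 groups", call. = FALSE)
  if (any(table(g) < 2L))
    stop("diagnostic error: group(s) with fewer than 2 usable values",
         call. = FALSE)
  lt <- car::leveneTest(v, g, center = if (center == "median") stats::median
                                       else mean)
  list(stat = lt[1L, "F value"], p = lt[1L, "Pr(>F)"])
}

#' Assumption diagnostics for every fitted metabolite
#'
#' Runs the Shapiro-Wilk test on each metabolite's conditional residuals and
#' the Brown-Forsythe test on its normalized values by treatment group, and
#' flags violations at p < 0.05.  Metabolites whose diagnostics cannot be
#' computed (constant residuals, a group too small) get `NA` statistics and
#' `NA` flags.
#'
#' @param object A `"metabnorm"` object.
#' @param alpha Flagging threshold, default 0.05.
#' @param center Group center for the Brown-Forsythe test.
#' @return Data frame with one row per fitted metabolite: `metabolite`,
#'   `shapiro_W`, `shapiro_p`, `levene_stat`, `levene_p`, `overall_mean`,
#'   `normality_violation`, `variance_violation`.
#' @export
diagnose <- function(object, alpha = 0.05, center = c("median", "mean")) {
  stopifnot(inherits(object, "metabnorm"))
  center <- match.arg(center)
  grp <- object$normalized[[object$spec$group_col]]
  rows <- lapply(names(object$fits), function(m) {
    f <- object$fits[[m]]
    sw <- tryCatch(test_normality(f$residuals),
                   error = function(e) list(W = NA_real_, p = NA_real_))
    lv <- tryCatch(test_equal_variance(object$normalized[[m]], grp, center),
                   error = function(e) list(stat = NA_real_, p = NA_real_))
    data.frame(metabolite = m,
               shapiro_W = sw$W, shapiro_p = sw$p,
               levene_stat = lv$stat, levene_p = lv$p,
               overall_mean = mean(object$transformed$data[[m]], na.rm = TRUE),
               normality_violation = sw$p < alpha,
               variance_violation = lv$p < alpha,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Residual-vs-mean plot data
#'
#' One point per (sample, metabolite): x = the metabolite's overall mean
#' transformed signal across all samples, y = the sample's conditional
#' residual.  Basis of the residual-error plots in the output suite.
#'
#' @param object A `"metabnorm"` object.
#' @return Data frame with columns `metabolite`, `sample_id`, `mean`,
#'   `residual`.
#' @export
residual_vs_mean_data <- function(object) {
  stopifnot(inherits(object, "metabnorm"))
  ids <- as.character(object$table$data[[object$table$sample_col]])
  rows <- lapply(names(object$fits), function(m) {
    f <- object$fits[[m]]
    data.frame(metabolite = m,
               sample_id = ids[f$used],
               mean = mean(object$transformed$data[[m]], na.rm = TRUE),
               residual = f$residuals,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
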