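#' Normalize a metabolite table by per-metabolite linear (mixed) modelling
#'
#' The central fitting function.  For every metabolite column the transformed
#' signal is modelled as treatment-group effect plus declared fixed-effect
#' covariates and random-effect block factors; the normalized value of each
#' sample is then reconstructed as
#'
#' \deqn{n_i = e_i + m_{g(i)}}
#'
#' the conditional residual plus the adjusted mean of the sample's treatment
#' group.  This removes the estimated effects of quantity, internal standard,
#' run day and any other declared confounder while retaining group structure.
#' Metabolites whose model cannot be fitted (too few observations, residual
#' degrees of freedom below 1, zero residual variance) are skipped with a
#' warning and listed in the result, never silently dropped.
#'
#' @param table A [metabolite_table()] (or a data frame in the documented
#'   wide layout, which is validated first).
#' @param spec A [model_spec()]; defaults to the spec attached to `table`.
#' @return An object of class `"metabnorm"` with components
#'   \describe{
#'     \item{normalized}{data frame: sample id, group, covariate and
#'       replicate columns followed by the normalized metabolite columns on
#'       the transformed scale; missingness pattern identical to the input.}
#'     \item{averaged}{normalized data with technical replicates averaged
#'       (equal to `normalized` when no replicate column is declared).}
#'     \item{fits}{named list of [fit_metabolite_model()] results.}
#'     \item{skipped}{named character vector of skipped metabolites and the
#'       reason each failed.}
#'     \item{table}{the validated input table (raw scale).}
#'     \item{transformed}{the transformed input table.}
#'     \item{spec}{the model specification.}
#'   }
#' @examples
#' sim <- simulate_dataset(simulation_spec(n_metabolites = 3, seed = 7))
#' fit <- metabnorm(sim$table)
#' fit
#' head(group_means(fit))
#' @export
metabnorm <- function(table, spec = NULL) {
  if (is.data.frame(table)) {
    if (is.null(spec)) stop("a model_spec is required with a raw data frame",
                            call. = FALSE)
    table <- metabolite_table(table, spec)
  }
  stopifnot(inherits(table, "metabolite_table"))
  if (is.null(spec)) spec <- table$spec
  res <- normalize_table(table, spec)
  out <- structure(c(res, list(table = table, spec = spec,
                               call = match.call())),
                   class = "metabnorm")
  out$averaged <- average_technical_replicates(out)
  out
}

#' Normalize all metabolites of a table
#'
#' Workhorse behind [metabnorm()]: applies the declared transform, fits every
#' metabolite independently with [fit_metabolite_model()], and reconstructs
#' normalized values with [normalize_metabolite()].
#'
#' @inheritParams metabnorm
#' @return List with `normalized` (data frame), `transformed`
#'   (`metabolite_table`), `fits` (list) and `skipped` (named character).
#' @export
normalize_table <- function(table, spec = table$spec) {
  stopifnot(inherits(table, "metabolite_table"))
  trans <- transform_signals(table, spec$transform)
  meta_cols <- c(table$sample_col, spec$group_col, spec$replicate_col,
                 spec$fixed_continuous, spec$fixed_factors,
                 spec$random_factors)
  norm <- trans$data[meta_cols]
  fits <- list()
  skipped <- character()
  for (m in table$metabolites) {
    y <- trans$data[[m]]
    fit <- tryCatch(fit_metabolite_model(y, trans, spec, metabolite = m),
                    error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      skipped[m] <- fit
      warning("metabolite '", m, "' skipped: ", fit, call. = FALSE)
      next
    }
    if (stats::var(fit$residuals) < 1e-12) {
      skipped[m] <- "degenerate fit: zero residual variance"
      warning("metabolite '", m, "' skipped: zero residual variance",
              call. = FALSE)
      next
    }
    fits[[m]] <- fit
    norm[[m]] <- normalize_metabolite(fit)
  }
  if (!length(fits))
    stop("pipeline error: every metabolite failed to fit", call. = FALSE)
  list(normalized = norm, transformed = trans, fits = fits, skipped = skipped)
}

#' Reconstruct normalized values from a fitted model
#'
#' Normalized value = conditional residual + adjusted group mean.  Samples
#' whose signal (or any model covariate) was missing stay missing.
#'
#' @param fit A `"metab_fit"` from [fit_metabolite_model()].
#' @return Numeric vector aligned with the rows of the original table.
#' @export
normalize_metabolite <- function(fit) {
  stopifnot(inherits(fit, "metab_fit"))
  out <- rep(NA_real_, length(fit$used))
  out[fit$used] <- fit$residuals +
    unname(fit$group_means[as.character(fit$group)])
  out
}

#' Average technical replicates of normalized data
#'
#' Collapses the normalized table to one row per biological unit (level of
#' the declared replicate column): each metabolite value becomes the
#' arithmetic mean of its non-missing replicate values; a unit whose values
#' are all missing stays missing.  With no replicate column declared the
#' normalized table is returned unchanged.
#'
#' @param object A `"metabnorm"` object, or a normalized data frame (then
#'   `replicate_col`, `group_col` and `metabolites` must be given).
#' @param replicate_col,group_col,metabolites Column roles when `object` is
#'   a plain data frame.
#' @return Data frame of averaged normalized values.
#' @export
average_technical_replicates <- function(object, replicate_col = NULL,
                                         group_col = NULL,
                                         metabolites = NULL) {
  if (inherits(object, "metabnorm")) {
    df <- object$normalized
    replicate_col <- object$spec$replicate_col
    group_col <- object$spec$group_col
    metabolites <- names(object$fits)
  } else df <- object
  if (is.null(replicate_col)) return(df)
  stopifnot(replicate_col %in% names(df), group_col %in% names(df))
  key <- as.character(df[[replicate_col]])
  gprr <- tapply(as.character(df[[group_col]]), key,
                 function(g) length(unique(g)))
  if (any(gprr > 1L))
    stop("validation error: replicate set(s) spanning multiple treatment ",
         "groups: ", paste(names(gprr)[gprr > 1L], collapse = ", "),
         call. = FALSE)
  units <- unique(key)
  idx <- match(units, key)
  keep <- setdiff(names(df), metabolites)
  out <- df[idx, keep, drop = FALSE]
  rownames(out) <- NULL
  for (m in intersect(metabolites, names(df))) {
    v <- tapply(df[[m]], key, function(x)
      if (all(is.na(x))) NA_real_ else mean(x, na.rm = TRUE))
    out[[m]] <- as.numeric(v[units])
  }
  out
}

#' @export
print.metabnorm <- function(x, ...) {
  cat("metabnorm fit:", length(x$fits), "metabolites normalized,",
      length(x$skipped), "skipped\n")
  print(x$spec)
  cat("  samples:", nrow(x$normalized), "\n")
  if (length(x$skipped))
    cat("  skipped:", paste(names(x$skipped), collapse = ", "), "\n")
  invisible(x)
}

#' Summarize a metabnorm fit
#'
#' Prints the assumption diagnostics (Shapiro-Wilk on conditional residuals,
#' Brown-Forsythe on normalized values by treatment group) for every fitted
#' metabolite, mirroring the console summary a bench scientist checks before
#' trusting downstream comparisons.
#'
#' @param object A `"metabnorm"` object.
#' @param ... Unused.
#' @return Invisibly, the [diagnose()] data frame.
#' @export
summary.metabnorm <- function(object, ...) {
  d <- diagnose(object)
  cat("Per-metabolite normalization:", length(object$fits), "fitted,",
      length(object$skipped), "skipped\n\n")
  cat("Assumption diagnostics (flags at p < 0.05):\n")
  show <- d
  for (cc in c("shapiro_W", "shapiro_p", "levene_stat", "levene_p",
               "overall_mean"))
    show[[cc]] <- signif(show[[cc]], 4)
  print(show, row.names = FALSE)
  nv <- sum(d$normality_violation, na.rm = TRUE)
  vv <- sum(d$variance_violation, na.rm = TRUE)
  cat("\n", nv, " metabolite(s) flagged for non-normal residuals; ",
      vv, " flagged for unequal group variances\n", sep = "")
  invisible(d)
}

#' @export
residuals.metabnorm <- function(object, ...) {
  out <- matrix(NA_real_, nrow(object$normalized), length(object$fits),
                dimnames = list(
                  as.character(object$normalized[[object$table$sample_col]]),
                  names(object$fits)))
  for (m in names(object$fits)) {
    f <- object$fits[[m]]
    out[f$used, m] <- f$residuals
  }
  out
}

#' @export
fitted.metabnorm <- function(object, ...) {
  out <- matrix(NA_real_, nrow(object$normalized), length(object$fits),
                dimnames = list(
                  as.character(object$normalized[[object$table$sample_col]]),
                  names(object$fits)))
  for (m in names(object$fits)) {
    f <- object$fits[[m]]
    out[f$used, m] <- f$fitted
  }
  out
}

#' @export
coef.metabnorm <- function(object, ...) {
  cf <- lapply(object$fits, `[[`, "coefficients")
  nm <- unique(unlist(lapply(cf, names)))
  out <- matrix(NA_real_, length(cf), length(nm),
                dimnames = list(names(cf), nm))
  for (m in names(cf)) out[m, names(cf[[m]])] <- cf[[m]]
  out
}

#' @export
group_means.metabnorm <- function(fit, ...) {
  t(vapply(fit$fits, `[[`, fit$fits[[1L]]$group_means, "group_means"))
}

#' Residual-vs-mean plot of a metabnorm fit
#'
#' Plots every conditional residual against its metabolite's overall mean
#' transformed signal — the standard check that the transform stabilized the
#' variance across the abundance range.
#'
#' @param x A `"metabnorm"` object.
#' @param label Logical: label each metabolite's points at its mean abundance
#'   (the expanded variant of the plot).
#' @param ... Passed to [graphics::plot()].
#' @export
plot.metabnorm <- function(x, label = FALSE, ...) {
  d <- residual_vs_mean_data(x)
  graphics::plot(d$mean, d$residual,
                 xlab = "Overall mean transformed signal",
                 ylab = "Conditional residual",
                 pch = 16, col = "#00000066",
                 xlim = if (label) range(d$mean) + c(0, 0.12 * diff(range(d$mean)))
                        else NULL, ...)
  graphics::abline(h = 0, lty = 2, col = "grey40")
  if (label) {
    lab <- unique(d[c("metabolite", "mean")])
    graphics::text(lab$mean, max(d$residual), labels = lab$metabolite,
                   srt = 90, adj = c(1, 0.5), cex = 0.6, col = "grey30")
  }
  invisible(d)
}
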