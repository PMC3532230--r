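#' Fit the normalization model for one metabolite
#'
#' Fits, on the transformed scale, a fixed linear model (least squares, via
#' [stats::lm()]) when no random factors are declared, or a linear mixed
#' model (REML, via [lme4::lmer()]) with one independent random intercept
#' per declared random factor:
#'
#' \deqn{y = \mu + Group + \sum_j \beta_j x_j + \sum_f factor_f +
#'       \sum_r b_r + e}
#'
#' Residuals are conditional: observed value minus fixed-effect prediction
#' minus predicted random intercepts (BLUPs).  A random variance estimated
#' at the zero boundary is retained as zero, in which case the fit
#' degenerates to the fixed-effect fit.
#'
#' @param y Numeric vector of transformed signals (may contain `NA`), one
#'   value per row of `table`.
#' @param table A [metabolite_table()] supplying group and covariates.
#' @param spec A [model_spec()]; defaults to the table's spec.
#' @param metabolite Optional metabolite name stored in the result.
#' @return An object of class `"metab_fit"` with elements `mu`,
#'   `group_effects`, `betas`, `fixed_factor_effects`, `random_variances`
#'   (per random factor plus `sigma2_e`), `blups`, `residuals` and `fitted`
#'   (aligned with the used rows), `group_means` (adjusted means, `NA` for
#'   group levels with no usable observations), `used` (logical row index),
#'   and `n_used`.
#' @seealso [group_means()], [normalize_metabolite()]
#' @export
fit_metabolite_model <- function(y, table, spec = table$spec,
                                 metabolite = NA_character_) {
  stopifnot(inherits(table, "metabolite_table"), inherits(spec, "model_spec"))
  df <- table$data
  stopifnot(length(y) == nrow(df))
  all_levels <- sort(unique(as.character(df[[spec$group_col]])))

  used <- !is.na(y)
  for (v in spec$fixed_continuous) used <- used & !is.na(df[[v]])
  for (v in c(spec$fixed_factors, spec$random_factors))
    used <- used & !is.na(df[[v]])
  n <- sum(used)
  if (n < 3L)
    stop("fit error: fewer than 3 usable observations", call. = FALSE)

  d <- data.frame(.y = y[used])
  grp_chr <- as.character(df[[spec$group_col]])[used]
  counts <- table(grp_chr)
  if (any(counts < 2L))
    stop("fit error: group level(s) with a single usable observation: ",
         paste(names(counts)[counts < 2L], collapse = ", "), call. = FALSE)
  present <- intersect(all_levels, names(counts))
  d$.group <- factor(grp_chr, levels = present)
  for (v in spec$fixed_continuous) d[[v]] <- df[[v]][used]
  for (v in spec$fixed_factors) {
    f <- factor(as.character(df[[v]])[used])
    if (nlevels(f) < 2L)
      stop("fit error: fixed factor '", v,
           "' has a single level among usable rows", call. = FALSE)
    d[[v]] <- f
  }
  for (v in spec$random_factors) {
    f <- factor(as.character(df[[v]])[used])
    if (nlevels(f) < 2L)
      stop("fit error: random factor '", v,
           "' has a single level among usable rows", call. = FALSE)
    d[[v]] <- f
  }

  fixed_terms <- c(if (nlevels(d$.group) > 1L) ".group",
                   spec$fixed_continuous, spec$fixed_factors)
  rhs_fixed <- if (length(fixed_terms)) paste(fixed_terms, collapse = " + ")
               else "1"
  fixed_formula <- stats::as.formula(paste(".y ~", rhs_fixed))

  X <- stats::model.matrix(fixed_formula, d)
  p <- qr(X)$rank
  if (n - p - length(spec$random_factors) < 1L)
    stop("fit error: residual degrees of freedom < 1 (n = ", n,
         ", fixed parameters = ", p, ")", call. = FALSE)

  if (!length(spec$random_factors)) {
    fit <- stats::lm(fixed_formula, data = d)
    beta <- stats::coef(fit)
    if (anyNA(beta))
      stop("fit error: model is over-parameterized (rank-deficient design)",
           call. = FALSE)
    res <- unname(stats::residuals(fit))
    fitv <- unname(stats::fitted(fit))
    sigma2_e <- sum(res^2) / (n - p)
    rand_var <- c(sigma2_e = sigma2_e)
    blups <- list()
  } else {
    rnd <- paste(sprintf("(1 | %s)", spec$random_factors), collapse = " + ")
    mixed_formula <- stats::as.formula(paste(".y ~", rhs_fixed, "+", rnd))
    fit <- tryCatch(
      suppressMessages(suppressWarnings(
        lme4::lmer(mixed_formula, data = d, REML = TRUE,
                   control = lme4::lmerControl(
                     check.conv.singular = "ignore",
                     calc.derivs = FALSE)))),
      error = function(e)
        stop("fit error: mixed model did not converge (",
             conditionMessage(e), ")", call. = FALSE))
    beta <- lme4::fixef(fit)
    vc <- as.data.frame(lme4::VarCorr(fit))
    rand_var <- stats::setNames(vc$vcov[match(spec$random_factors, vc$grp)],
                                spec$random_factors)
    rand_var <- c(rand_var, sigma2_e = vc$vcov[vc$grp == "Residual"])
    blups <- lapply(lme4::ranef(fit), function(r)
      stats::setNames(r[["(Intercept)"]], rownames(r)))
    res <- unname(stats::residuals(fit))   # conditional residuals
    fitv <- unname(stats::fitted(fit))     # includes BLUPs
  }

  gm <- .adjusted_means(X, beta, d$.group, all_levels)

  structure(list(
    metabolite = metabolite,
    mu = unname(beta["(Intercept)"]),
    group_effects = .coef_by_term(X, beta, ".group"),
    betas = stats::setNames(
      unname(beta[match(spec$fixed_continuous, names(beta))]),
      spec$fixed_continuous),
    fixed_factor_effects = lapply(
      stats::setNames(spec$fixed_factors, spec$fixed_factors),
      function(v) .coef_by_term(X, beta, v)),
    random_variances = rand_var,
    blups = blups,
    residuals = res,
    fitted = fitv,
    group_means = gm,
    group = d$.group,
    used = used,
    n_used = n,
    sigma2_e = unname(rand_var["sigma2_e"]),
    coefficients = beta),
    class = "metab_fit")
}

# Coefficients of the model-matrix columns generated by one factor term
# (treatment contrasts: one column per non-reference level).
.coef_by_term <- function(X, beta, term) {
  cols <- setdiff(colnames(X)[startsWith(colnames(X), term)], "(Intercept)")
  stats::setNames(unname(beta[cols]), substring(cols, nchar(term) + 1L))
}

# Adjusted (least-squares) means: prediction for each group at the global
# mean of every continuous covariate, averaging fixed factors over their
# observed level proportions, random effects at zero.
.adjusted_means <- function(X, beta, group, all_levels) {
  xbar <- colMeans(X)
  gcols <- startsWith(colnames(X), ".group")
  present <- levels(group)
  out <- stats::setNames(rep(NA_real_, length(all_levels)), all_levels)
  for (g in present) {
    x <- xbar
    if (any(gcols))
      x[gcols] <- as.numeric(colnames(X)[gcols] == paste0(".group", g))
    out[g] <- sum(x * beta)
  }
  out
}

#' Adjusted group means of a fit
#'
#' The adjusted (least-squares) mean of group *g* is the model prediction
#' for that group at the global mean of every continuous covariate, with
#' fixed factors averaged over their observed level proportions and random
#' effects at their mean of zero.  Group levels with no usable observations
#' get `NA` and are skipped in pairwise comparisons.
#'
#' @param fit A `"metab_fit"` or `"metabnorm"` object.
#' @param ... Unused.
#' @return Named numeric vector (one per group level) for a `metab_fit`;
#'   a metabolites x groups matrix for a `metabnorm` object.
#' @export
group_means <- function(fit, ...) UseMethod("group_means")

#' @export
group_means.metab_fit <- function(fit, ...) fit$group_means

#' @export
print.metab_fit <- function(x, ...) {
  cat("Per-metabolite normalization fit",
      if (!is.na(x$metabolite)) paste0("(", x$metabolite, ")"), "\n")
  cat("  n used:", x$n_used, "\n")
  cat("  adjusted group means:\n")
  print(round(x$group_means, 4))
  if (length(x$random_variances) > 1L) {
    cat("  variance components:\n")
    print(round(x$random_variances, 5))
  } else {
    cat("  residual variance:", signif(x$sigma2_e, 5), "\n")
  }
  invisible(x)
}
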