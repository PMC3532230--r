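#' Declare the per-metabolite normalization model
#'
#' A model specification names the treatment factor and assigns every
#' confounding variable a role: continuous fixed-effect covariates enter as
#' regression slopes, categorical fixed-effect covariates as factor effects,
#' and block factors (e.g. run day, strain) as independent random intercepts.
#'
#' @param group_col Name of the treatment-group column.
#' @param fixed_continuous Character vector of continuous covariate columns
#'   entering the model as regression slopes (e.g. tissue quantity, internal
#'   standard signal).
#' @param fixed_factors Character vector of categorical covariate columns
#'   entering as fixed factors.
#' @param random_factors Character vector of categorical columns entering as
#'   random intercepts (variance components), e.g. run day.
#' @param transform Signal transform applied before modelling: `"log2"`
#'   (default; requires strictly positive signals) or `"none"`.
#' @param replicate_col Optional name of a column identifying technical
#'   replicate sets; replicates are averaged after normalization.
#' @return An object of class `"model_spec"`.
#' @examples
#' model_spec("Group", fixed_continuous = c("Quantity", "IS"),
#'            random_factors = "Day")
#' @export
model_spec <- function(group_col,
                       fixed_continuous = character(),
                       fixed_factors = character(),
                       random_factors = character(),
                       transform = c("log2", "none"),
                       replicate_col = NULL) {
  transform <- match.arg(transform)
  stopifnot(is.character(group_col), length(group_col) == 1L)
  fixed_continuous <- as.character(fixed_continuous)
  fixed_factors <- as.character(fixed_factors)
  random_factors <- as.character(random_factors)
  covs <- c(fixed_continuous, fixed_factors, random_factors)
  if (anyDuplicated(covs))
    stop("covariate roles must be disjoint: ",
         paste(unique(covs[duplicated(covs)]), collapse = ", "), call. = FALSE)
  if (group_col %in% covs)
    stop("group column '", group_col, "' cannot also be a covariate", call. = FALSE)
  if (!is.null(replicate_col)) {
    stopifnot(is.character(replicate_col), length(replicate_col) == 1L)
    if (replicate_col %in% c(group_col, covs))
      stop("replicate column '", replicate_col,
           "' cannot double as group or covariate", call. = FALSE)
  }
  structure(list(group_col = group_col,
                 fixed_continuous = fixed_continuous,
                 fixed_factors = fixed_factors,
                 random_factors = random_factors,
                 transform = transform,
                 replicate_col = replicate_col),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat("Normalization model specification\n")
  cat("  group factor   :", x$group_col, "\n")
  fmt <- function(v) if (length(v)) paste(v, collapse = ", ") else "(none)"
  cat("  fixed slopes   :", fmt(x$fixed_continuous), "\n")
  cat("  fixed factors  :", fmt(x$fixed_factors), "\n")
  cat("  random factors :", fmt(x$random_factors), "\n")
  cat("  transform      :", x$transform, "\n")
  if (!is.null(x$replicate_col))
    cat("  replicates     :", x$replicate_col, "\n")
  invisible(x)
}

#' Significance screening configuration
#'
#' Controls how metabolites are flagged as significantly different between
#' treatment groups: by Tukey HSD p-value, Storey q-value, mean fold-change,
#' or a combination of p- or q-value with fold-change (logical AND).  The
#' fold-change threshold is applied two-sidedly as `max(FC, 1/FC)`.
#'
#' @param criterion One of `"p"`, `"q"`, `"fc"`, `"p_and_fc"`, `"q_and_fc"`.
#' @param alpha Significance cutoff for p- or q-values, in (0, 1).
#' @param fc_threshold Minimum fold-change, `>= 1`.
#' @return An object of class `"screen_config"`.
#' @export
screen_config <- function(criterion = c("p", "q", "fc", "p_and_fc", "q_and_fc"),
                          alpha = 0.05, fc_threshold = 1) {
  criterion <- match.arg(criterion)
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) ||
      alpha <= 0 || alpha >= 1)
    stop("alpha must lie in (0, 1)", call. = FALSE)
  if (!is.numeric(fc_threshold) || length(fc_threshold) != 1L ||
      is.na(fc_threshold) || fc_threshold < 1)
    stop("fc_threshold must be >= 1", call. = FALSE)
  structure(list(criterion = criterion, alpha = alpha,
                 fc_threshold = fc_threshold),
            class = "screen_config")
}

#' Construct and validate a metabolite table
#'
#' A metabolite table is a wide-format data frame whose first column holds
#' sample identifiers, followed by the treatment-group column and every
#' covariate column named in the model specification; all remaining columns
#' are metabolite signals (positive ion counts, or `NA` for signals set to
#' missing because the metabolite was not detected — zeros are rejected).
#'
#' @param df A data frame in the layout above.
#' @param spec A [model_spec()] naming the group and covariate columns.
#' @return An object of class `"metabolite_table"`: a list with elements
#'   `data` (the validated data frame), `sample_col`, `metabolites`
#'   (character vector of metabolite column names), and `spec`.
#' @export
metabolite_table <- function(df, spec) {
  stopifnot(is.data.frame(df), inherits(spec, "model_spec"))
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  declared <- c(spec$group_col, spec$fixed_continuous, spec$fixed_factors,
                spec$random_factors, spec$replicate_col)
  missing_cols <- setdiff(declared, names(df))
  if (length(missing_cols))
    stop("schema error: declared column(s) not in table: ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  sample_col <- names(df)[1L]
  if (sample_col %in% declared)
    stop("schema error: first column must be the sample identifier, not '",
         sample_col, "'", call. = FALSE)
  metabolites <- setdiff(names(df), c(sample_col, declared))
  if (!length(metabolites))
    stop("validation error: no metabolite columns found", call. = FALSE)

  ids <- as.character(df[[sample_col]])
  if (anyNA(ids) || any(!nzchar(ids)))
    stop("validation error: missing sample identifiers", call. = FALSE)
  rep_key <- if (is.null(spec$replicate_col)) rep("", nrow(df))
             else as.character(df[[spec$replicate_col]])
  if (anyDuplicated(paste(rep_key, ids, sep = "\r")))
    stop("validation error: duplicated sample identifiers within a ",
         "technical-replicate set", call. = FALSE)

  grp <- df[[spec$group_col]]
  if (anyNA(grp))
    stop("validation error: missing values in group column '",
         spec$group_col, "'", call. = FALSE)
  if (length(unique(as.character(grp))) < 2L)
    stop("validation error: group column '", spec$group_col,
         "' has fewer than 2 levels", call. = FALSE)

  for (v in spec$fixed_continuous) {
    val <- df[[v]]
    if (is.character(val)) val <- utils::type.convert(val, as.is = TRUE)
    if (!is.numeric(val))
      stop("validation error: continuous covariate '", v,
           "' is not numeric", call. = FALSE)
    df[[v]] <- val
  }
  for (v in c(spec$fixed_factors, spec$random_factors)) {
    lev <- unique(as.character(df[[v]][!is.na(df[[v]])]))
    if (length(lev) < 2L)
      stop("validation error: categorical covariate '", v,
           "' has fewer than 2 levels", call. = FALSE)
  }

  for (m in metabolites) {
    val <- df[[m]]
    if (!is.numeric(val)) {
      num <- suppressWarnings(as.numeric(as.character(val)))
      bad <- which(is.na(num) & !is.na(val) & as.character(val) != "NA")
      if (length(bad))
        stop("validation error: non-numeric signal in metabolite '", m,
             "', sample '", ids[bad[1L]], "'", call. = FALSE)
      val <- num
    }
    nonpos <- which(!is.na(val) & val <= 0)
    if (length(nonpos))
      stop("validation error: non-positive signal (", val[nonpos[1L]],
           ") in metabolite '", m, "', sample '", ids[nonpos[1L]],
           "' (undetected signals must be NA, not zero)", call. = FALSE)
    df[[m]] <- val
  }

  structure(list(data = df, sample_col = sample_col,
                 metabolites = metabolites, spec = spec),
            class = "metabolite_table")
}

#' Read a metabolite table from a CSV file
#'
#' Reads a wide-format CSV (first column sample identifiers, then group and
#' covariate columns as declared in `spec`, remaining columns metabolite
#' signals) and validates it.  The literal token `"NA"` and empty cells are
#' treated as missing.
#'
#' @param path Path to the CSV file.
#' @param spec A [model_spec()].
#' @return A [metabolite_table()].
#' @export
read_metabolite_table <- function(path, spec) {
  if (!file.exists(path))
    stop("input file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE,
                        na.strings = c("NA", ""))
  metabolite_table(df, spec)
}

#' @export
print.metabolite_table <- function(x, ...) {
  cat("Metabolite table:", nrow(x$data), "samples x",
      length(x$metabolites), "metabolites\n")
  grp <- table(x$data[[x$spec$group_col]])
  cat("  groups:", paste(sprintf("%s (n=%d)", names(grp), as.integer(grp)),
                         collapse = ", "), "\n")
  nmiss <- sum(is.na(as.matrix(x$data[x$metabolites])))
  cat("  missing signal cells:", nmiss, "\n")
  invisible(x)
}

#' Transform metabolite signals
#'
#' Applies the declared signal transform (elementwise `log2`, or identity)
#' to every metabolite column.  Missing values propagate.  Under `log2`
#' every non-missing signal must be strictly positive.
#'
#' @param table A [metabolite_table()].
#' @param transform `"log2"` or `"none"`; defaults to the table's spec.
#' @return A `metabolite_table` with transformed signal columns and
#'   attribute `transform` recording the transform applied.
#' @export
transform_signals <- function(table, transform = table$spec$transform) {
  stopifnot(inherits(table, "metabolite_table"))
  transform <- match.arg(transform, c("log2", "none"))
  if (transform == "log2") {
    ids <- as.character(table$data[[table$sample_col]])
    for (m in table$metabolites) {
      val <- table$data[[m]]
      bad <- which(!is.na(val) & val <= 0)
      if (length(bad))
        stop("validation error: cannot log2-transform non-positive signal in ",
             "metabolite '", m, "', sample '", ids[bad[1L]], "'", call. = FALSE)
      table$data[[m]] <- log2(val)
    }
  }
  attr(table, "transform") <- transform
  table
}
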