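#' Build run configuration from CLI-style arguments
#'
#' Turns a flat named list of option values (as collected from command-line
#' flags or a `key: value` config file) into a validated [model_spec()],
#' [screen_config()] and output directory.  Defaults: `transform = "log2"`,
#' `criterion = "p"`, `alpha = 0.05`, `fc_threshold = 1`, `outdir =
#' "metabnorm_out"`.  Comma-separated values are accepted for the list-valued
#' keys (`fixed`, `fixed_factors`, `random`).
#'
#' @param args Named list; recognized keys: `group_col`, `fixed`,
#'   `fixed_factors`, `random`, `transform`, `criterion`, `alpha`,
#'   `fc_threshold`, `replicate_col`, `outdir`.
#' @return List with `spec`, `screen`, `outdir`.
#' @export
parse_run_config <- function(args = list()) {
  get <- function(key, default = NULL) {
    v <- args[[key]]
    if (is.null(v) || (length(v) == 1L && is.na(v))) default else v
  }
  split_csv <- function(v) {
    if (is.null(v)) return(character())
    v <- unlist(strsplit(as.character(v), ",", fixed = TRUE))
    trimws(v[nzchar(trimws(v))])
  }
  group_col <- get("group_col", "Group")
  spec <- model_spec(
    group_col = as.character(group_col),
    fixed_continuous = split_csv(get("fixed")),
    fixed_factors = split_csv(get("fixed_factors")),
    random_factors = split_csv(get("random")),
    transform = match.arg(as.character(get("transform", "log2")),
                          c("log2", "none")),
    replicate_col = if (is.null(get("replicate_col"))) NULL
                    else as.character(get("replicate_col")))
  criterion <- as.character(get("criterion", "p"))
  if (!criterion %in% c("p", "q", "fc", "p_and_fc", "q_and_fc"))
    stop("unknown screening criterion: '", criterion, "'", call. = FALSE)
  screen <- screen_config(criterion = criterion,
                          alpha = as.numeric(get("alpha", 0.05)),
                          fc_threshold = as.numeric(get("fc_threshold", 1)))
  list(spec = spec, screen = screen,
       outdir = as.character(get("outdir", "metabnorm_out")))
}

#' Read a `key: value` run-configuration file
#'
#' Plain-text alternative to command-line flags: one `key: value` pair per
#' line, `#` comments and blank lines ignored.  Keys mirror the flags
#' accepted by [parse_run_config()].
#'
#' @param path Path to the config file.
#' @return Named list of raw values, suitable for [parse_run_config()].
#' @export
read_run_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  out <- list()
  for (ln in lines) {
    hit <- regexpr(":", ln, fixed = TRUE)
    if (hit < 1L)
      stop("config error: expected 'key: value', got '", ln, "'",
           call. = FALSE)
    key <- trimws(substr(ln, 1L, hit - 1L))
    out[[key]] <- trimws(substring(ln, hit + 1L))
  }
  out
}

# CSV writer used for every exported table: full double precision
# (15 significant digits), "." decimal, no row names -- byte-stable across
# identical runs.
.write_csv <- function(df, path) {
  utils::write.csv(df, path, row.names = FALSE, na = "NA",
                   fileEncoding = "UTF-8", quote = TRUE)
  path
}

# metabolite x pair matrix -> exported data frame with a Metabolite column
.matrix_df <- function(mat) {
  cbind(data.frame(Metabolite = rownames(mat), stringsAsFactors = FALSE),
        as.data.frame(mat, check.names = FALSE))
}

#' Write the full output suite of a run
#'
#' Emits every artifact of a normalization-plus-inference run into `outdir`:
#' normalized data and its replicate-averaged version; the residual-vs-mean
#' plot (standard and expanded/labelled); mean plots for significant
#' metabolites (PDF figure plus a CSV of the plot data); Tukey p-value,
#' q-value and fold-change tables (metabolites x all pairwise comparisons);
#' pre/post-normalization confounder plots; the mean-centered heatmap with
#' dendrograms; and the pathway-mapping spreadsheet.  With no significant
#' metabolites the mean-plot and pathway files are still written (header
#' only / placeholder page) and a message is logged.
#'
#' @param object A `"metabnorm"` object.
#' @param cmp The matching [compare_groups()] result.
#' @param outdir Output directory (created if needed).
#' @param value_kind p- or q-values in the pathway export.
#' @return Invisibly, a named character vector of written file paths.
#' @export
write_output_suite <- function(object, cmp, outdir,
                               value_kind = c("p", "q")) {
  stopifnot(inherits(object, "metabnorm"),
            inherits(cmp, "metab_comparisons"))
  value_kind <- match.arg(value_kind)
  if (!dir.exists(outdir) &&
      !dir.create(outdir, recursive = TRUE, showWarnings = FALSE))
    stop("I/O error: cannot create output directory '", outdir, "'",
         call. = FALSE)
  if (file.access(outdir, mode = 2L) != 0L)
    stop("I/O error: output directory '", outdir, "' is not writable",
         call. = FALSE)
  paths <- character()
  pt <- function(name) file.path(outdir, name)

  paths["normalized"] <- .write_csv(object$normalized, pt("normalized_data.csv"))
  paths["normalized_averaged"] <-
    .write_csv(object$averaged, pt("normalized_data_replicate_averaged.csv"))

  grDevices::pdf(pt("residuals_vs_mean.pdf"), width = 7, height = 5.5)
  plot(object, label = FALSE)
  grDevices::dev.off()
  paths["residuals_vs_mean"] <- pt("residuals_vs_mean.pdf")

  grDevices::pdf(pt("residuals_vs_mean_labeled.pdf"), width = 11, height = 7)
  plot(object, label = TRUE)
  grDevices::dev.off()
  paths["residuals_vs_mean_labeled"] <- pt("residuals_vs_mean_labeled.pdf")

  mean_data <- build_mean_plot_data(object, cmp)
  if (!length(mean_data))
    message("no significant metabolites: mean-plot and pathway exports ",
            "written with header/placeholder only")
  grDevices::pdf(pt("mean_plots.pdf"), width = 6, height = 6)
  .draw_mean_plots(mean_data, object$spec$transform)
  grDevices::dev.off()
  paths["mean_plots_pdf"] <- pt("mean_plots.pdf")

  md_rows <- lapply(names(mean_data), function(m) {
    d <- mean_data[[m]]
    data.frame(Metabolite = m, Group = names(d$means),
               Mean = as.numeric(d$means),
               CI_halfwidth = as.numeric(d$ci_halfwidth),
               N = as.integer(d$n), Letters = unname(d$letters[names(d$means)]),
               stringsAsFactors = FALSE)
  })
  md <- if (length(md_rows)) do.call(rbind, md_rows)
        else data.frame(Metabolite = character(), Group = character(),
                        Mean = numeric(), CI_halfwidth = numeric(),
                        N = integer(), Letters = character())
  paths["mean_plots_csv"] <- .write_csv(md, pt("mean_plots.csv"))

  paths["tukey_p"] <- .write_csv(.matrix_df(.results_matrix(cmp, "tukey_p")),
                                 pt("tukey_pvalues.csv"))
  paths["q_values"] <- .write_csv(.matrix_df(.results_matrix(cmp, "q_value")),
                                  pt("qvalues.csv"))
  paths["fold_changes"] <-
    .write_csv(.matrix_df(.results_matrix(cmp, "fold_change")),
               pt("fold_changes.csv"))

  grDevices::pdf(pt("confounder_plots.pdf"), width = 9, height = 4.5)
  .draw_confounder_plots(build_confounder_plots(object))
  grDevices::dev.off()
  paths["confounder_plots"] <- pt("confounder_plots.pdf")

  hm <- tryCatch(build_heatmap(object), error = function(e) e)
  grDevices::pdf(pt("heatmap.pdf"), width = 8, height = 8)
  if (inherits(hm, "error")) {
    warning("heatmap skipped: ", conditionMessage(hm), call. = FALSE)
    graphics::plot.new()
    graphics::text(0.5, 0.5, paste("Heatmap skipped:", conditionMessage(hm)))
  } else plot(hm)
  grDevices::dev.off()
  paths["heatmap"] <- pt("heatmap.pdf")

  paths["pathway"] <- .write_csv(export_pathway_projector(cmp, value_kind),
                                 pt("pathway_projector.csv"))
  invisible(paths)
}

#' Run the whole normalization and inference pipeline
#'
#' Reads (or accepts) a metabolite table, normalizes it, prints the
#' assumption diagnostics, performs pairwise inference and screening, and
#' writes the complete output suite.
#'
#' @param input Path to a wide-format CSV, a data frame, or a
#'   [metabolite_table()].
#' @param spec A [model_spec()] (required unless `input` is already a
#'   `metabolite_table`).
#' @param screen A [screen_config()].
#' @param outdir Output directory; `NULL` skips file output.
#' @param quiet Suppress the console diagnostics summary.
#' @return List with `fit` (`"metabnorm"`), `comparisons`
#'   (`"metab_comparisons"`), `diagnostics` (data frame), and `files`
#'   (named paths, when written).
#' @export
run_pipeline <- function(input, spec = NULL, screen = screen_config(),
                         outdir = NULL, quiet = FALSE) {
  table <- if (inherits(input, "metabolite_table")) input
           else if (is.data.frame(input)) metabolite_table(input, spec)
           else read_metabolite_table(input, spec)
  fit <- metabnorm(table)
  diag <- diagnose(fit)
  if (!quiet) summary(fit)
  cmp <- compare_groups(fit, screen)
  if (!quiet) print(cmp)
  files <- if (!is.null(outdir)) write_output_suite(fit, cmp, outdir)
  list(fit = fit, comparisons = cmp, diagnostics = diag, files = files)
}
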