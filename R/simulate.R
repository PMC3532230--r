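#' Specify a synthetic metabolomic dataset
#'
#' Describes a generative model matching the normalization model: per-sample
#' log2 signal = baseline + group effect + covariate slopes + block offsets
#' + Gaussian noise, exported on the raw (ion-count) scale as
#' `2^(log2 signal)`, with independent missingness.  Defaults emulate a
#' three-group LC-MS adipose experiment measured over several run days with
#' a tissue-quantity covariate.
#'
#' @param n_per_group Samples per treatment group.
#' @param groups Treatment group labels (k >= 2).
#' @param n_metabolites Number of metabolite columns.
#' @param log2_group_effects True group effects on the log2 scale: a
#'   metabolites x groups matrix, a length-k vector recycled across
#'   metabolites, or `NULL` for no group effect.
#' @param covariate_slopes Named numeric vector: true slope per continuous
#'   covariate (log2 signal units per covariate unit), shared across
#'   metabolites.
#' @param covariate_distributions Named list: `c(mean, sd)` per continuous
#'   covariate; covariates are drawn once per sample and shared across
#'   metabolites.
#' @param block_factors Named list: each entry `list(levels = L, sd = s)`
#'   gives a block factor whose L levels are assigned cyclically to samples
#'   and whose level offsets are drawn from `N(0, s^2)`.
#' @param residual_sd Residual SD on the log2 scale.
#' @param mu Baseline log2 signal (20 corresponds to about 1e6 ion counts).
#' @param missing_rate Probability a cell is set missing, in \[0, 1).
#' @param seed Integer seed; the draw order is blocks, covariates, noise,
#'   missingness, so adding metabolites does not perturb earlier draws.
#' @return An object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_per_group = 8,
                            groups = c("Control", "Fast", "InsNeut"),
                            n_metabolites = 14,
                            log2_group_effects = NULL,
                            covariate_slopes = c(Quantity = 0.02),
                            covariate_distributions =
                              list(Quantity = c(mean = 50, sd = 10)),
                            block_factors =
                              list(Day = list(levels = 3, sd = 0.5)),
                            residual_sd = 0.25,
                            mu = 20,
                            missing_rate = 0.02,
                            seed = 1L) {
  groups <- as.character(groups)
  if (length(groups) < 2L || anyDuplicated(groups))
    stop("groups must be >= 2 unique labels", call. = FALSE)
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must lie in [0, 1)", call. = FALSE)
  if (residual_sd < 0) stop("residual_sd must be >= 0", call. = FALSE)
  k <- length(groups)
  eff <- log2_group_effects
  if (is.null(eff)) eff <- matrix(0, n_metabolites, k)
  if (is.vector(eff))
    eff <- matrix(eff, n_metabolites, k, byrow = TRUE)
  stopifnot(nrow(eff) == n_metabolites, ncol(eff) == k)
  dimnames(eff) <- list(sprintf("Met%02d", seq_len(n_metabolites)), groups)
  if (!setequal(names(covariate_slopes), names(covariate_distributions)))
    stop("covariate_slopes and covariate_distributions must name the same ",
         "covariates (use slope 0 for a null covariate)", call. = FALSE)
  if (length(block_factors) && is.null(names(block_factors)))
    stop("block_factors must be a named list", call. = FALSE)
  for (b in block_factors)
    if (b$sd < 0) stop("block factor sd must be >= 0", call. = FALSE)
  structure(list(n_per_group = n_per_group, groups = groups,
                 n_metabolites = n_metabolites, log2_group_effects = eff,
                 covariate_slopes = covariate_slopes,
                 covariate_distributions = covariate_distributions,
                 block_factors = block_factors, residual_sd = residual_sd,
                 mu = mu, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

#' Generate a synthetic metabolite table with known effects
#'
#' Draws a dataset from the generative model of [simulation_spec()] and
#' returns it in the exact wide input layout (sample id, group, covariate
#' and block columns, then metabolite columns, raw ion-count scale) along
#' with a truth record of every drawn effect.
#'
#' @param spec A [simulation_spec()].
#' @param seed Overrides `spec$seed` when given.
#' @return List with
#'   \describe{
#'     \item{table}{a [metabolite_table()] (its attached [model_spec()]
#'       declares every simulated covariate in its true role).}
#'     \item{truth}{list: `mu`, `group_effects` (metabolites x groups),
#'       `covariate_slopes`, `covariates` (drawn per-sample values),
#'       `block_offsets` (drawn per-level offsets), `block_assignment`,
#'       `residual_sd`, `noise` (matrix), `missing` (logical matrix),
#'       `log2_expected` (noise-free log2 signal matrix).}
#'   }
#' @export
simulate_dataset <- function(spec, seed = spec$seed) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(seed)
  k <- length(spec$groups)
  n <- spec$n_per_group * k
  m <- spec$n_metabolites
  group <- rep(spec$groups, each = spec$n_per_group)
  ids <- sprintf("S%03d", seq_len(n))

  # 1. block offsets (one draw per level, in declaration order)
  block_offsets <- lapply(spec$block_factors, function(b)
    stats::setNames(stats::rnorm(b$levels, 0, b$sd),
                    paste0("L", seq_len(b$levels))))
  block_assignment <- lapply(spec$block_factors, function(b)
    paste0("L", rep_len(seq_len(b$levels), n)))

  # 2. continuous covariates (one draw per sample, shared across metabolites)
  covariates <- lapply(spec$covariate_distributions, function(d)
    stats::rnorm(n, d[["mean"]], d[["sd"]]))

  # 3. residual noise, metabolite by metabolite
  noise <- matrix(0, n, m)
  for (j in seq_len(m)) noise[, j] <- stats::rnorm(n, 0, spec$residual_sd)

  # 4. missingness
  miss <- matrix(stats::runif(n * m) < spec$missing_rate, n, m)

  gidx <- match(group, spec$groups)
  expected <- matrix(spec$mu, n, m)
  for (j in seq_len(m))
    expected[, j] <- expected[, j] + spec$log2_group_effects[j, gidx]
  for (v in names(spec$covariate_slopes))
    expected <- expected + spec$covariate_slopes[[v]] * covariates[[v]]
  for (b in names(spec$block_factors))
    expected <- expected +
      block_offsets[[b]][block_assignment[[b]]]
  log2sig <- expected + noise

  df <- data.frame(Sample = ids, Group = group, stringsAsFactors = FALSE)
  for (v in names(covariates)) df[[v]] <- covariates[[v]]
  for (b in names(spec$block_factors)) df[[b]] <- block_assignment[[b]]
  met_names <- rownames(spec$log2_group_effects)
  for (j in seq_len(m)) {
    sig <- 2^log2sig[, j]
    sig[miss[, j]] <- NA_real_
    df[[met_names[j]]] <- sig
  }
  mspec <- model_spec("Group",
                      fixed_continuous = names(spec$covariate_slopes),
                      random_factors = names(spec$block_factors),
                      transform = "log2")
  dimnames(noise) <- dimnames(miss) <- dimnames(log2sig) <-
    dimnames(expected) <- list(ids, met_names)
  list(table = metabolite_table(df, mspec),
       truth = list(mu = spec$mu,
                    group_effects = spec$log2_group_effects,
                    covariate_slopes = spec$covariate_slopes,
                    covariates = covariates,
                    block_offsets = block_offsets,
                    block_assignment = block_assignment,
                    residual_sd = spec$residual_sd,
                    noise = noise,
                    missing = miss,
                    log2_expected = expected))
}
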