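#' Tukey HSD pairwise comparisons
#'
#' All-pairs comparison of group means of (normalized) values via the
#' Studentized-range distribution.  A one-way ANOVA on the values gives the
#' pooled mean square error with \eqn{\nu = N - k} degrees of freedom; for a
#' pair (a, b) the observed statistic is the Tukey-Kramer form
#' \deqn{q_{obs} = \frac{|\bar m_b - \bar m_a|}
#'   {\sqrt{(MSE/2)(1/n_a + 1/n_b)}}}
#' and \eqn{p = 1 - F_q(q_{obs}; k, \nu)} with \eqn{F_q} the
#' Studentized-range CDF.  Pairs are labelled `"B-A"` (second level minus
#' first, levels in lexicographic order).
#'
#' @param values Numeric vector (missing values dropped).
#' @param groups Group labels, same length as `values`.
#' @param alpha Level of the simultaneous confidence intervals.
#' @return Data frame with one row per pair: `comparison`, `diff`
#'   (mean of the second-named level minus the first), `se`, `p`, `lwr`,
#'   `upr`; attributes `means`, `n`, `MSE`, `df`.
#' @export
tukey_hsd <- function(values, groups, alpha = 0.05) {
  keep <- !is.na(values) & !is.na(groups)
  v <- values[keep]
  g <- factor(as.character(groups)[keep])
  k <- nlevels(g)
  if (k < 2L)
    stop("inference error: need at least 2 groups", call. = FALSE)
  n_g <- tabulate(g)
  N <- length(v)
  nu <- N - k
  if (nu < 1L)
    stop("inference error: residual degrees of freedom < 1", call. = FALSE)
  m_g <- tapply(v, g, mean)
  mse <- sum((v - m_g[as.integer(g)])^2) / nu
  if (mse <= 0)
    stop("inference error: zero within-group variance", call. = FALSE)
  lev <- levels(g)
  pr <- utils::combn(k, 2L)
  qcrit <- stats::qtukey(1 - alpha, k, nu)
  rows <- apply(pr, 2L, function(ab) {
    a <- ab[1L]; b <- ab[2L]
    se <- sqrt((mse / 2) * (1 / n_g[a] + 1 / n_g[b]))
    diff <- m_g[b] - m_g[a]
    q_obs <- abs(diff) / se
    data.frame(comparison = paste0(lev[b], "-", lev[a]),
               group1 = lev[a], group2 = lev[b],
               diff = unname(diff), se = se,
               p = stats::ptukey(q_obs, k, nu, lower.tail = FALSE),
               lwr = unname(diff) - qcrit * se,
               upr = unname(diff) + qcrit * se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "means") <- m_g
  attr(out, "n") <- stats::setNames(n_g, lev)
  attr(out, "MSE") <- mse
  attr(out, "df") <- nu
  out
}

#' Storey q-values
#'
#' Estimates the proportion of true null hypotheses \eqn{\hat\pi_0} from the
#' p-value distribution and converts each p-value into a q-value (estimated
#' per-test false discovery rate).  \eqn{\hat\pi_0(\lambda) =
#' \#\{p_i > \lambda\} / (m (1-\lambda))} is evaluated on
#' \eqn{\lambda \in \{0.05, 0.10, \ldots, 0.95\}}, smoothed by a cubic
#' smoothing spline with 3 effective degrees of freedom, and
#' \eqn{\hat\pi_0} is the fitted value at \eqn{\lambda = 0.95}, capped at 1
#' and floored at 0.  For fewer than 100 p-values \eqn{\hat\pi_0 = 1}
#' (the Benjamini-Hochberg reduction) for stability.  q-values are made
#' monotone from the largest p downwards.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\] (`NA` allowed and
#'   returned as `NA`).
#' @param pi0 Optional fixed \eqn{\pi_0} overriding estimation; `pi0 = 1`
#'   yields Benjamini-Hochberg adjusted p-values exactly.
#' @return Numeric vector of q-values in input order, with attribute `pi0`.
#' @export
storey_qvalues <- function(pvals, pi0 = NULL) {
  ok <- !is.na(pvals)
  p <- pvals[ok]
  m <- length(p)
  if (m < 1L)
    stop("validation error: no p-values supplied", call. = FALSE)
  if (any(p < 0 | p > 1))
    stop("validation error: p-values must lie in [0, 1]", call. = FALSE)
  if (is.null(pi0)) {
    if (m < 100L) {
      pi0 <- 1
    } else {
      lambda <- seq(0.05, 0.95, by = 0.05)
      pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                      numeric(1L))
      sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
      pi0 <- stats::predict(sp, x = 0.95)$y
      pi0 <- max(min(pi0, 1), 0)
    }
  }
  o <- order(p, decreasing = TRUE)
  q_sorted <- numeric(m)
  q_sorted[1L] <- min(pi0 * p[o[1L]], 1)
  if (m > 1L) for (i in 2:m) {
    rank_i <- m - i + 1L
    q_sorted[i] <- min(pi0 * m * p[o[i]] / rank_i, q_sorted[i - 1L])
  }
  q <- numeric(m)
  q[o] <- q_sorted
  out <- rep(NA_real_, length(pvals))
  out[ok] <- q
  attr(out, "pi0") <- pi0
  out
}

#' Pairwise fold-change matrix from group means
#'
#' Under the log2 transform the fold-change between groups a and b is
#' \eqn{FC(a, b) = 2^{m_a - m_b}} (ratio of geometric means on the raw
#' scale); with no transform it is the plain ratio \eqn{m_a / m_b}
#' (undefined, `NA`, when \eqn{m_b = 0}).  Cell (i, j) of the returned
#' matrix compares the group in row i against the group in column j.
#'
#' @param means Named numeric vector of per-group adjusted means on the
#'   analysis scale.
#' @param transform `"log2"` or `"none"`.
#' @return k x k numeric matrix with unit diagonal and
#'   `FC[i, j] * FC[j, i] == 1`.
#' @export
fold_change_matrix <- function(means, transform = c("log2", "none")) {
  transform <- match.arg(transform)
  k <- length(means)
  out <- matrix(NA_real_, k, k, dimnames = list(names(means), names(means)))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (is.na(means[i]) || is.na(means[j])) next
    out[i, j] <- if (transform == "log2") 2^(means[i] - means[j])
                 else if (means[j] == 0) NA_real_ else means[i] / means[j]
  }
  out
}

#' Compact letter display for pairwise significance
#'
#' Insert-and-absorb algorithm: start with a single column holding every
#' group; for each significantly different pair, split every column that
#' still contains both; delete columns whose group set is contained in
#' another's; assign letters a, b, c, ... to the surviving columns in order
#' of their smallest group index.  Two groups share at least one letter if
#' and only if they are not significantly different.
#'
#' @param significant k x k logical matrix (symmetric, `FALSE` diagonal):
#'   `TRUE` where the pair differs significantly.
#' @param groups Group labels in display order; defaults to the matrix
#'   dimnames.
#' @return Named character vector: letter string per group.
#' @export
compact_letter_display <- function(significant, groups = rownames(significant)) {
  significant <- as.matrix(significant)
  k <- nrow(significant)
  if (is.null(groups)) groups <- as.character(seq_len(k))
  stopifnot(ncol(significant) == k, length(groups) == k)
  if (any(diag(significant)))
    stop("significance matrix must have a FALSE diagonal", call. = FALSE)
  if (!isTRUE(all(significant == t(significant))))
    stop("significance matrix must be symmetric", call. = FALSE)

  cols <- list(seq_len(k))
  pairs <- which(upper.tri(significant) & significant, arr.ind = TRUE)
  for (r in seq_len(nrow(pairs))) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    new_cols <- list()
    for (cl in cols) {
      if (i %in% cl && j %in% cl) {
        new_cols <- c(new_cols, list(setdiff(cl, i)), list(setdiff(cl, j)))
      } else new_cols <- c(new_cols, list(cl))
    }
    # absorb: drop any column whose set is a subset of another column's
    keep <- rep(TRUE, length(new_cols))
    for (a in seq_along(new_cols)) {
      if (!keep[a]) next
      for (b in seq_along(new_cols)) {
        if (a == b || !keep[b]) next
        if (all(new_cols[[a]] %in% new_cols[[b]]) &&
            !(length(new_cols[[a]]) == length(new_cols[[b]]) && a < b)) {
          keep[a] <- FALSE
          break
        }
      }
    }
    cols <- new_cols[keep]
  }
  # order columns by smallest group index, ties broken by the next members
  key <- vapply(cols, function(cl)
    paste(sprintf("%06d", sort(cl)), collapse = ""), character(1L))
  cols <- cols[order(key)]
  letters_pool <- c(letters, paste0(rep(letters, each = 26), letters))
  out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(cols))
    out[cols[[ci]]] <- paste0(out[cols[[ci]]], letters_pool[ci])
  out
}

#' Screen comparison results for significant metabolites
#'
#' Applies the configured criterion to every (metabolite, pair) entry:
#' `p` -> `tukey_p < alpha`; `q` -> `q_value < alpha`; `fc` ->
#' `max(FC, 1/FC) >= fc_threshold`; combined criteria are the logical AND.
#' A metabolite is significant when any of its pairs passes.
#'
#' @param results The comparison data frame of a
#'   [compare_groups()] result (columns `metabolite`, `comparison`,
#'   `fold_change`, `tukey_p`, `q_value`), or the `"metab_comparisons"`
#'   object itself.
#' @param cfg A [screen_config()].
#' @return List with `results` (the data frame plus a logical `significant`
#'   column) and `significant_metabolites` (character vector).
#' @export
screen_metabolites <- function(results, cfg = screen_config()) {
  if (inherits(results, "metab_comparisons")) results <- results$results
  stopifnot(is.data.frame(results), inherits(cfg, "screen_config"))
  p_pass <- results$tukey_p < cfg$alpha
  q_pass <- results$q_value < cfg$alpha
  fc_two <- pmax(results$fold_change, 1 / results$fold_change)
  fc_pass <- fc_two >= cfg$fc_threshold
  sig <- switch(cfg$criterion,
                p = p_pass,
                q = q_pass,
                fc = fc_pass,
                p_and_fc = p_pass & fc_pass,
                q_and_fc = q_pass & fc_pass)
  sig[is.na(sig)] <- FALSE
  results$significant <- sig
  list(results = results,
       significant_metabolites = unique(results$metabolite[sig]))
}

#' Pairwise treatment comparisons on normalized data
#'
#' Runs Tukey HSD on every fitted metabolite's normalized values, pools all
#' p-values into one Storey q-value computation, derives fold-changes from
#' the back-transformed adjusted group means, builds a compact letter
#' display per metabolite at `cfg$alpha`, and screens for significance under
#' the configured criterion.
#'
#' @param object A `"metabnorm"` object.
#' @param cfg A [screen_config()].
#' @return An object of class `"metab_comparisons"`: list with
#'   \describe{
#'     \item{results}{long data frame, one row per metabolite x ordered
#'       pair: `metabolite`, `comparison`, `diff` (adjusted-mean difference
#'       on the transformed scale), `fold_change`, `tukey_p`, `q_value`,
#'       `significant`.}
#'     \item{letters}{named list: per metabolite, group -> letter string.}
#'     \item{anova}{named list of per-metabolite Tukey tables (with
#'       `means`, `n`, `MSE`, `df` attributes) reused by the mean plots.}
#'     \item{significant_metabolites}{character vector.}
#'     \item{pairs}{character vector of comparison labels (column order of
#'       the exported matrices).}
#'     \item{pi0}{estimated proportion of true nulls.}
#'     \item{failed}{named character vector of metabolites whose inference
#'       failed, with reasons.}
#'   }
#' @examples
#' sim <- simulate_dataset(simulation_spec(n_metabolites = 3, seed = 7))
#' cmp <- compare_groups(metabnorm(sim$table))
#' head(cmp$results)
#' @export
compare_groups <- function(object, cfg = screen_config()) {
  stopifnot(inherits(object, "metabnorm"), inherits(cfg, "screen_config"))
  grp <- object$normalized[[object$spec$group_col]]
  all_levels <- sort(unique(as.character(grp)))
  pr <- utils::combn(all_levels, 2L)
  pair_labels <- apply(pr, 2L, function(ab) paste0(ab[2L], "-", ab[1L]))

  rows <- list()
  anovas <- list()
  letters_by_m <- list()
  failed <- character()
  for (m in names(object$fits)) {
    fit <- object$fits[[m]]
    tk <- tryCatch(tukey_hsd(object$normalized[[m]], grp, alpha = cfg$alpha),
                   error = function(e) conditionMessage(e))
    if (is.character(tk)) {
      failed[m] <- tk
      rows[[m]] <- data.frame(metabolite = m, comparison = pair_labels,
                              diff = NA_real_, fold_change = NA_real_,
                              tukey_p = NA_real_, stringsAsFactors = FALSE)
      next
    }
    anovas[[m]] <- tk
    gm <- fit$group_means
    fc <- fold_change_matrix(gm, object$spec$transform)
    d <- data.frame(metabolite = m, comparison = pair_labels,
                    diff = NA_real_, fold_change = NA_real_,
                    tukey_p = NA_real_, stringsAsFactors = FALSE)
    for (ci in seq_len(ncol(pr))) {
      a <- pr[1L, ci]; b <- pr[2L, ci]
      if (!is.na(gm[a]) && !is.na(gm[b])) {
        d$diff[ci] <- gm[b] - gm[a]
        d$fold_change[ci] <- fc[b, a]
      }
      hit <- match(pair_labels[ci], tk$comparison)
      if (!is.na(hit)) d$tukey_p[ci] <- tk$p[hit]
    }
    rows[[m]] <- d

    lev <- names(attr(tk, "means"))
    sig <- matrix(FALSE, length(lev), length(lev),
                  dimnames = list(lev, lev))
    for (ri in seq_len(nrow(tk))) {
      if (tk$p[ri] < cfg$alpha)
        sig[tk$group1[ri], tk$group2[ri]] <-
          sig[tk$group2[ri], tk$group1[ri]] <- TRUE
    }
    letters_by_m[[m]] <- compact_letter_display(sig)
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  q <- storey_qvalues(results$tukey_p)
  results$q_value <- as.numeric(q)
  scr <- screen_metabolites(results, cfg)

  structure(list(results = scr$results,
                 letters = letters_by_m,
                 anova = anovas,
                 significant_metabolites = scr$significant_metabolites,
                 pairs = pair_labels,
                 group_levels = all_levels,
                 pi0 = attr(q, "pi0"),
                 screen = cfg,
                 transform = object$spec$transform,
                 failed = failed),
            class = "metab_comparisons")
}

#' @export
print.metab_comparisons <- function(x, ...) {
  n_m <- length(unique(x$results$metabolite))
  cat("Pairwise treatment comparisons:", n_m, "metabolites x",
      length(x$pairs), "pairs\n")
  cat("  screen:", x$screen$criterion, "at alpha =", x$screen$alpha,
      if (x$screen$fc_threshold > 1)
        paste0(", fold-change >= ", x$screen$fc_threshold), "\n")
  cat("  estimated pi0:", signif(x$pi0, 4), "\n")
  cat("  significant metabolites (", length(x$significant_metabolites),
      "): ", paste(x$significant_metabolites, collapse = ", "), "\n", sep = "")
  if (length(x$failed))
    cat("  inference failed for:", paste(names(x$failed), collapse = ", "),
        "\n")
  invisible(x)
}

# Wide metabolite x pair matrix of one results column.
.results_matrix <- function(cmp, col) {
  mets <- unique(cmp$results$metabolite)
  out <- matrix(NA_real_, length(mets), length(cmp$pairs),
                dimnames = list(mets, cmp$pairs))
  idx <- cbind(match(cmp$results$metabolite, mets),
               match(cmp$results$comparison, cmp$pairs))
  out[idx] <- cmp$results[[col]]
  out
}
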