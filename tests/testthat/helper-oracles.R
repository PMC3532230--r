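# Independent oracles used across the suite.  Each re-derives a quantity by
# a different route than the implementation (quadrature, brute force, direct
# linear algebra, or an external reference implementation).

# Studentized-range CDF by nested quadrature: P(Q <= q) for k means and
# df error degrees of freedom, integrating over the scaled chi distribution
# of the pooled SD and the range distribution of k standard normals.
ptukey_oracle <- function(q, k, df) {
  inner <- function(wi)
    k * stats::integrate(function(z)
      stats::dnorm(z) * pmax(stats::pnorm(z) - stats::pnorm(z - q * wi), 0)^(k - 1),
      -Inf, Inf, rel.tol = 1e-10)$value
  f_w <- function(w)
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(w) - df * w^2 / 2)
  stats::integrate(function(w) f_w(w) * vapply(w, inner, numeric(1)),
                   0, Inf, rel.tol = 1e-9)$value
}

# Brute-force compact letter display: the letter columns are exactly the
# maximal cliques of the "not significantly different" graph, found by
# exhaustive subset enumeration (k <= 5), ordered by smallest member.
cld_oracle <- function(significant, groups = rownames(significant)) {
  k <- nrow(significant)
  if (is.null(groups)) groups <- as.character(seq_len(k))
  compat <- !significant
  subsets <- lapply(seq_len(2^k - 1), function(mask)
    which(bitwAnd(mask, 2^(seq_len(k) - 1)) > 0))
  is_clique <- vapply(subsets, function(s) {
    if (length(s) < 2) return(TRUE)
    all(compat[s, s][upper.tri(diag(length(s)))])
  }, logical(1))
  cliques <- subsets[is_clique]
  maximal <- cliques[vapply(seq_along(cliques), function(i) {
    !any(vapply(cliques, function(o)
      length(o) > length(cliques[[i]]) && all(cliques[[i]] %in% o),
      logical(1)))
  }, logical(1))]
  key <- vapply(maximal, function(cl)
    paste(sprintf("%06d", sort(cl)), collapse = ""), character(1))
  maximal <- maximal[order(key)]
  out <- stats::setNames(rep("", k), groups)
  for (ci in seq_along(maximal))
    out[maximal[[ci]]] <- paste0(out[maximal[[ci]]], letters[ci])
  out
}

# Shapiro-Wilk reference values from an independent implementation
# (scipy.stats.shapiro via the system python).
shapiro_reference <- function(x) {
  f <- tempfile(fileext = ".txt")
  on.exit(unlink(f))
  writeLines(format(x, digits = 17), f)
  out <- system2("python", c("-c", shQuote(paste0(
    "import sys, scipy.stats as st; ",
    "x=[float(l) for l in open(sys.argv[1])]; W,p=st.shapiro(x); ",
    "print(repr(float(W))); print(repr(float(p)))")), f), stdout = TRUE)
  list(W = as.numeric(out[1]), p = as.numeric(out[2]))
}

# One-dimensional REML profile over the variance ratio phi = sigma_b^2 /
# sigma_e^2 for a single random intercept factor, by direct grid search on
# the restricted log-likelihood.
reml_profile_oracle <- function(y, X, z,
                                grid = c(0, exp(seq(log(1e-6), log(1e4),
                                                    length.out = 1500)))) {
  Z <- stats::model.matrix(~ z - 1)
  n <- length(y)
  p <- qr(X)$rank
  crit <- vapply(grid, function(phi) {
    V <- diag(n) + phi * tcrossprod(Z)
    Vi <- solve(V)
    XtVi <- crossprod(X, Vi)
    A <- XtVi %*% X
    B <- solve(A, XtVi %*% y)
    r <- y - X %*% B
    s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
    as.numeric(determinant(V)$modulus) +
      as.numeric(determinant(A)$modulus) + (n - p) * log(s2)
  }, numeric(1))
  phi <- grid[which.min(crit)]
  V <- diag(n) + phi * tcrossprod(Z)
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  B <- solve(XtVi %*% X, XtVi %*% y)
  r <- y - X %*% B
  s2 <- as.numeric(crossprod(r, Vi %*% r)) / (n - p)
  c(sigma_b2 = phi * s2, sigma_e2 = s2)
}

# Levene/Brown-Forsythe by hand: one-way ANOVA on absolute deviations from
# the group center.
levene_oracle <- function(values, groups, center = stats::median) {
  keep <- !is.na(values)
  v <- values[keep]
  g <- factor(groups[keep])
  dev <- abs(v - tapply(v, g, center)[as.integer(g)])
  a <- stats::anova(stats::lm(dev ~ g))
  list(stat = a[1, "F value"], p = a[1, "Pr(>F)"])
}

# Small balanced toy table: 2 groups, 1-2 metabolites, optional covariate.
toy_table <- function(values = c(8, 16, 32, 64), groups = c("A", "A", "B", "B"),
                      quantity = NULL, extra = list()) {
  df <- data.frame(Sample = sprintf("s%d", seq_along(values)),
                   Group = groups, stringsAsFactors = FALSE)
  fixed <- character()
  if (!is.null(quantity)) {
    df$Quantity <- quantity
    fixed <- "Quantity"
  }
  for (nm in names(extra)) df[[nm]] <- extra[[nm]]
  df$Met1 <- values
  metabolite_table(df, model_spec("Group", fixed_continuous = fixed))
}
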