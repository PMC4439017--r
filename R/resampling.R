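# One-way pseudo-F machinery. The F-ratio itself is ordinary
# between/within mean squares; "pseudo" refers to its null distribution
# being generated by label permutation rather than a parametric F.

# Fast one-way pseudo-F given integer group codes and precomputed totals.
.at_pseudo_f <- function(y, g_int, counts, sst, grand_sq_over_n) {
  sums <- rowsum(y, g_int, reorder = TRUE)
  ssb <- sum(sums^2 / counts) - grand_sq_over_n
  ssw <- sst - ssb
  k <- length(counts)
  n <- sum(counts)
  (ssb / (k - 1)) / (ssw / (n - k))
}

# Collapse record-level data to per-unit means when an id vector is given.
.at_collapse_units <- function(values, groups, ids) {
  if (is.null(ids)) {
    return(list(values = as.numeric(values), groups = as.character(groups)))
  }
  .at_assert(length(ids) == length(values), "design",
             "ids must match values in length")
  ids <- as.character(ids)
  gmap <- tapply(as.character(groups), ids, unique)
  if (any(lengths(gmap) != 1L))
    .at_stop("design", "unit(s) assigned to more than one group: %s",
             paste(names(gmap)[lengths(gmap) != 1L], collapse = ", "))
  m <- tapply(as.numeric(values), ids, mean)
  list(values = as.numeric(m), groups = as.character(unlist(gmap[names(m)])))
}

#' One-way permutation ANOVA (pseudo-F test)
#'
#' Tests a group effect on a numeric trait with a randomization approach:
#' the observed pseudo-F (between/within mean-square ratio) is compared to
#' its distribution under random reassignment of group labels across
#' analysis units. The p-value uses the add-one rule
#' `p = (1 + #permuted >= observed) / (1 + n_perm)`, so `p` lies in (0, 1]
#' and ties count against the null. Suitable for traits with outliers or
#' non-normal errors where a parametric F would be unreliable.
#'
#' @param values Numeric response, one per record.
#' @param groups Group labels, one per record (>= 2 groups, >= 2 units per
#'   group).
#' @param ids Optional unit identifiers. When supplied, records are first
#'   averaged within units (e.g. per-individual means) and labels are
#'   permuted across units, respecting repeated measures; when `NULL`
#'   each record is its own unit.
#' @param n_perm Number of random permutations (default 9999).
#' @param seed Optional RNG seed for reproducibility.
#' @return An object of class `perm_test`: `statistic_name`, `observed`,
#'   `df` (between, within), `p_value`, `n_perm_used`, `n_units`.
#' @export
#' @examples
#' permutation_anova(c(1, 2, 101, 102), c("a", "a", "b", "b"),
#'                   n_perm = 999, seed = 1)
permutation_anova <- function(values, groups, ids = NULL, n_perm = 9999,
                              seed = NULL) {
  .at_assert(is.numeric(n_perm) && n_perm >= 1, "parameter",
             "n_perm must be >= 1")
  u <- .at_collapse_units(values, groups, ids)
  y <- u$values
  g <- factor(u$groups)
  .at_assert(nlevels(g) >= 2L, "design", "need at least 2 groups")
  counts <- as.numeric(table(g))
  if (any(counts < 2L))
    .at_stop("design", "group(s) with fewer than 2 units: %s",
             paste(levels(g)[counts < 2], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)

  g_int <- as.integer(g)
  n <- length(y)
  grand_sq_over_n <- sum(y)^2 / n
  sst <- sum(y^2) - grand_sq_over_n
  if (sst <= 0) {
    # all units identical: no variance to explain
    return(structure(list(statistic_name = "pseudo-F", observed = NaN,
                          df = c(between = nlevels(g) - 1L,
                                 within = n - nlevels(g)),
                          p_value = 1, n_perm_used = 0L, n_units = n),
                     class = "perm_test"))
  }
  obs <- .at_pseudo_f(y, g_int, counts, sst, grand_sq_over_n)
  tol <- sqrt(.Machine$double.eps)
  hits <- 0L
  for (b in seq_len(n_perm)) {
    f <- .at_pseudo_f(y[sample.int(n)], g_int, counts, sst, grand_sq_over_n)
    if (f >= obs - tol) hits <- hits + 1L
  }
  structure(list(statistic_name = "pseudo-F", observed = obs,
                 df = c(between = nlevels(g) - 1L, within = n - nlevels(g)),
                 p_value = (1 + hits) / (1 + n_perm),
                 n_perm_used = as.integer(n_perm), n_units = n),
            class = "perm_test")
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("%s(%d,%d) = %.4g, P = %.4g (%d permutations, %d units)\n",
              x$statistic_name, x$df[1L], x$df[2L], x$observed, x$p_value,
              x$n_perm_used, x$n_units))
  invisible(x)
}

# Type-II sums of squares for a two-factor layout via model-matrix fits.
.at_factorial_f <- function(y, Xa, Xb, Xab, Xfull, dfs) {
  dev <- function(X) sum(.lm.fit(X, y)$residuals^2)
  d_a <- dev(Xa)      # y ~ A
  d_b <- dev(Xb)      # y ~ B
  d_ab <- dev(Xab)    # y ~ A + B
  d_full <- dev(Xfull)
  mse <- d_full / dfs[["resid"]]
  c(A = ((d_b - d_ab) / dfs[["A"]]) / mse,
    B = ((d_a - d_ab) / dfs[["B"]]) / mse,
    AB = ((d_ab - d_full) / dfs[["AB"]]) / mse)
}

#' Two-factor permutation ANOVA with interaction
#'
#' Pseudo-F tests for the two main effects and their interaction in a
#' crossed design. Each main effect is tested by restricted permutation:
#' response values are shuffled only within levels of the other factor, so
#' the other factor's structure is preserved under the null. The
#' interaction is tested by residual (Freedman-Lane-style) permutation:
#' residuals from the additive main-effects fit are permuted and added back
#' to its fitted values before recomputing the interaction pseudo-F.
#' Sums of squares are Type II, so results do not depend on factor order
#' in mildly unbalanced designs.
#'
#' @param values Numeric response, one per record.
#' @param factor_a,factor_b Crossed factor labels (every cell must be
#'   non-empty). If `factor_b` has a single level the call degenerates to
#'   [permutation_anova()] on `factor_a`.
#' @param n_perm Permutations per term (default 9999).
#' @param seed Optional RNG seed.
#' @return A list of `perm_test` objects: `$factor_a`, `$factor_b`,
#'   `$interaction` (the latter `NULL` in the degenerate single-factor
#'   case, where `$factor_a` holds the one-way result).
#' @export
factorial_permutation <- function(values, factor_a, factor_b, n_perm = 9999,
                                  seed = NULL) {
  a <- factor(factor_a)
  b <- factor(factor_b)
  if (nlevels(b) < 2L) {
    return(list(factor_a = permutation_anova(values, a, n_perm = n_perm,
                                             seed = seed),
                factor_b = NULL, interaction = NULL))
  }
  if (nlevels(a) < 2L) {
    return(list(factor_a = NULL,
                factor_b = permutation_anova(values, b, n_perm = n_perm,
                                             seed = seed),
                interaction = NULL))
  }
  tab <- table(a, b)
  if (any(tab == 0L))
    .at_stop("design", "empty cell(s) in the crossed design: %s",
             paste(utils::head(outer(rownames(tab), colnames(tab), paste,
                                     sep = ":")[tab == 0L], 5L),
                   collapse = ", "))
  y <- as.numeric(values)
  n <- length(y)
  if (!is.null(seed)) set.seed(seed)

  Xa <- stats::model.matrix(~a)
  Xb <- stats::model.matrix(~b)
  Xab <- stats::model.matrix(~a + b)
  Xfull <- stats::model.matrix(~a * b)
  dfs <- c(A = nlevels(a) - 1L, B = nlevels(b) - 1L,
           AB = (nlevels(a) - 1L) * (nlevels(b) - 1L),
           resid = n - nlevels(a) * nlevels(b))
  .at_assert(dfs["resid"] > 0, "design",
             "no residual degrees of freedom (need replication within cells)")
  obs <- .at_factorial_f(y, Xa, Xb, Xab, Xfull, dfs)
  tol <- sqrt(.Machine$double.eps)

  # restricted permutation indices: shuffle within strata
  perm_within <- function(strata) {
    idx <- seq_len(n)
    for (lv in split(idx, strata)) idx[lv] <- lv[sample.int(length(lv))]
    idx
  }
  fit_ab <- .lm.fit(Xab, y)
  fitted_ab <- y - fit_ab$residuals
  res_ab <- fit_ab$residuals

  hits <- c(A = 0L, B = 0L, AB = 0L)
  for (i in seq_len(n_perm)) {
    fA <- .at_factorial_f(y[perm_within(b)], Xa, Xb, Xab, Xfull, dfs)["A"]
    fB <- .at_factorial_f(y[perm_within(a)], Xa, Xb, Xab, Xfull, dfs)["B"]
    ystar <- fitted_ab + res_ab[sample.int(n)]
    fAB <- .at_factorial_f(ystar, Xa, Xb, Xab, Xfull, dfs)["AB"]
    if (fA >= obs["A"] - tol) hits["A"] <- hits["A"] + 1L
    if (fB >= obs["B"] - tol) hits["B"] <- hits["B"] + 1L
    if (fAB >= obs["AB"] - tol) hits["AB"] <- hits["AB"] + 1L
  }
  mk <- function(term, df1) {
    structure(list(statistic_name = "pseudo-F", observed = unname(obs[term]),
                   df = c(between = unname(df1),
                          within = unname(dfs["resid"])),
                   p_value = (1 + unname(hits[term])) / (1 + n_perm),
                   n_perm_used = as.integer(n_perm), n_units = n),
              class = "perm_test")
  }
  list(factor_a = mk("A", dfs["A"]), factor_b = mk("B", dfs["B"]),
       interaction = mk("AB", dfs["AB"]))
}

#' Non-parametric bootstrap confidence interval
#'
#' Percentile bootstrap: the statistic is recomputed on `n_boot` resamples
#' (with replacement, same size as the input) and the CI is read off the
#' empirical quantiles of the resampled distribution.
#'
#' @param values Numeric sample (>= 2 values).
#' @param statistic Function of a numeric vector (default `mean`).
#' @param n_boot Number of bootstrap replicates (default 9999).
#' @param level Confidence level (default 0.95).
#' @param seed Optional RNG seed.
#' @return An object of class `bootstrap_ci`: `point`, `lower`, `upper`,
#'   `n_boot`, `level`.
#' @export
bootstrap_ci <- function(values, statistic = mean, n_boot = 9999,
                         level = 0.95, seed = NULL) {
  values <- as.numeric(values)
  .at_assert(length(values) >= 2L, "sample_size",
             "need at least 2 values for a bootstrap CI")
  .at_assert(level > 0 && level < 1, "parameter", "level must be in (0, 1)")
  if (!is.null(seed)) set.seed(seed)
  n <- length(values)
  if (identical(statistic, mean)) {
    # vectorized fast path for the common case
    draws <- matrix(values[sample.int(n, n * n_boot, replace = TRUE)],
                    nrow = n_boot)
    stats_boot <- rowMeans(draws)
  } else {
    stats_boot <- vapply(seq_len(n_boot), function(i)
      statistic(values[sample.int(n, n, replace = TRUE)]), numeric(1))
  }
  alpha <- (1 - level) / 2
  q <- stats::quantile(stats_boot, c(alpha, 1 - alpha), type = 7,
                       names = FALSE)
  structure(list(point = statistic(values), lower = q[1L], upper = q[2L],
                 n_boot = as.integer(n_boot), level = level),
            class = "bootstrap_ci")
}

#' @export
print.bootstrap_ci <- function(x, ...) {
  cat(sprintf("%.4g, %d%% CI [%.4g, %.4g] (%d bootstrap replicates)\n",
              x$point, round(100 * x$level), x$lower, x$upper, x$n_boot))
  invisible(x)
}

#' Variance explained by individual identity
#'
#' One-way decomposition of record-level variation: the percentage of the
#' total sum of squares attributable to between-individual differences,
#' `100 * SS_between / SS_total`. Used to quantify how repeatable a
#' thermoregulatory trait is across repeated measures of the same animals.
#'
#' @param values Numeric response, one per record.
#' @param individual_ids Individual labels, one per record (>= 2
#'   individuals).
#' @return A list: `pct_between_individuals`, `ss_between`, `ss_total`,
#'   `undefined` (`TRUE` when `ss_total = 0`).
#' @export
variance_explained <- function(values, individual_ids) {
  y <- as.numeric(values)
  id <- as.character(individual_ids)
  .at_assert(length(y) == length(id), "design",
             "values and ids must have equal length")
  .at_assert(length(unique(id)) >= 2L, "design",
             "need at least 2 individuals")
  grand <- mean(y)
  sst <- sum((y - grand)^2)
  means <- tapply(y, id, mean)
  counts <- tapply(y, id, length)
  ssb <- sum(counts * (means - grand)^2)
  if (sst <= 0) {
    return(list(pct_between_individuals = NA_real_, ss_between = 0,
                ss_total = 0, undefined = TRUE))
  }
  list(pct_between_individuals = 100 * ssb / sst, ss_between = ssb,
       ss_total = sst, undefined = FALSE)
}
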