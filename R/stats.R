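# Group-comparison decision tree: normality-routed parametric/nonparametric
# tests with Bonferroni-corrected post hoc comparisons, reported as
# mean +/- SEM with the route recorded.

#' Decide the parametric/nonparametric route for one sample
#'
#' For n <= 30 the Shapiro-Wilk test at `alpha` decides the route. For
#' n > 30 the route is parametric unless the sample shows extreme shape
#' (|skewness| or |excess kurtosis| beyond the declared thresholds, an
#' automated stand-in for visual Q-Q/histogram inspection under the central
#' limit theorem). Diagnostics are always returned so the route is auditable.
#'
#' @param x numeric sample (n >= 3).
#' @param alpha Shapiro-Wilk significance level.
#' @param skew_max,kurt_max shape thresholds for the large-sample branch.
#' @return list with `route` ("parametric"/"nonparametric"), `branch`
#'   ("shapiro"/"moments") and `diagnostics` (n, shapiro_p, skewness,
#'   excess_kurtosis).
#' @export
assess_normality <- function(x, alpha = 0.05, skew_max = 2, kurt_max = 4) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3) stop("need at least 3 observations to assess normality")
  skew <- e1071::skewness(x, type = 2)
  kurt <- e1071::kurtosis(x, type = 2)
  if (n <= 30) {
    p <- if (stats::sd(x) == 0) 0 else stats::shapiro.test(x)$p.value
    route <- if (p < alpha) "nonparametric" else "parametric"
    branch <- "shapiro"
  } else {
    ok <- is.finite(skew) && is.finite(kurt) &&
      abs(skew) < skew_max && abs(kurt) < kurt_max
    route <- if (ok) "parametric" else "nonparametric"
    p <- NA_real_
    branch <- "moments"
  }
  list(route = route, branch = branch,
       diagnostics = list(n = n, shapiro_p = p, skewness = skew,
                          excess_kurtosis = kurt))
}

#' Compare two groups (Welch's t or Mann-Whitney U)
#'
#' The route (parametric -> Welch's unequal-variance t test; nonparametric ->
#' Mann-Whitney U) is taken from `route`, or decided from the data: the
#' nonparametric route is used when either group fails [assess_normality()].
#' Means +/- SEM are reported either way. Two identical zero-variance groups
#' are reported as p = 1 with a degeneracy flag rather than an error.
#'
#' @param a,b numeric samples (n >= 3 each).
#' @param route `NULL` (decide from data), "parametric" or "nonparametric".
#' @param labels length-2 group labels.
#' @return An object of class `group_comparison`: list with test name,
#'   statistic, p-value, group summaries, route and flags.
#' @export
compare_two_groups <- function(a, b, route = NULL,
                               labels = c("group1", "group2")) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (length(a) < 3 || length(b) < 3) stop("both groups need n >= 3")
  routes <- NULL
  if (is.null(route)) {
    ra <- assess_normality(a); rb <- assess_normality(b)
    routes <- list(ra, rb)
    route <- if (ra$route == "nonparametric" || rb$route == "nonparametric")
      "nonparametric" else "parametric"
  }
  route <- match.arg(route, c("parametric", "nonparametric"))
  degenerate <- stats::sd(a) == 0 && stats::sd(b) == 0 &&
    length(a) == length(b) && all(sort(a) == sort(b))
  if (degenerate) {
    test <- if (route == "parametric") "Welch t" else "Mann-Whitney U"
    stat <- 0; p <- 1
  } else if (route == "parametric") {
    tt <- stats::t.test(a, b, var.equal = FALSE)
    test <- "Welch t"; stat <- unname(tt$statistic); p <- tt$p.value
  } else {
    wt <- suppressWarnings(stats::wilcox.test(a, b, exact = FALSE))
    test <- "Mann-Whitney U"; stat <- unname(wt$statistic); p <- wt$p.value
  }
  structure(list(
    test = test, statistic = stat, p_value = p, route = route,
    routes = routes, degenerate = degenerate,
    groups = data.frame(group = labels, n = c(length(a), length(b)),
                        mean = c(mean(a), mean(b)), sem = c(sem(a), sem(b))),
    direction = labels[if (mean(a) >= mean(b)) 1 else 2]),
    class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  g <- x$groups
  cat(sprintf("%s: %s %.3g +/- %.3g (n=%d) vs %s %.3g +/- %.3g (n=%d)\n",
              x$test, g$group[1], g$mean[1], g$sem[1], g$n[1],
              g$group[2], g$mean[2], g$sem[2], g$n[2]))
  cat(sprintf("  statistic = %.4g, p = %.4g, route = %s%s\n",
              x$statistic, x$p_value, x$route,
              if (isTRUE(x$degenerate)) " [degenerate]" else ""))
  invisible(x)
}

# Dunn's rank-based multiple comparison test (two-sided z approximation with
# tie correction); p-values are returned raw, adjustment is applied by the
# caller.
dunn_pairwise <- function(values, groups) {
  groups <- factor(groups)
  N <- length(values)
  r <- rank(values)
  Rbar <- tapply(r, groups, mean)
  ni <- tabulate(groups)
  ties <- table(values)
  tiecor <- sum(ties^3 - ties) / (12 * (N - 1))
  lev <- levels(groups)
  out <- list()
  for (i in seq_along(lev)[-length(lev)]) for (j in (i + 1):length(lev)) {
    se <- sqrt((N * (N + 1) / 12 - tiecor) * (1 / ni[i] + 1 / ni[j]))
    z <- (Rbar[i] - Rbar[j]) / se
    out[[length(out) + 1L]] <- data.frame(
      group1 = lev[i], group2 = lev[j], statistic = unname(z),
      p_raw = 2 * stats::pnorm(-abs(z)))
  }
  do.call(rbind, out)
}

# Conover's post hoc test after Friedman (balanced complete blocks);
# two-sided t approximation with (b-1)(k-1) degrees of freedom.
conover_pairwise <- function(mat) {
  b <- nrow(mat); k <- ncol(mat)
  R <- t(apply(mat, 1, rank))
  Rj <- colSums(R)
  A <- sum(R^2)
  B <- sum(Rj^2) / b
  dfree <- (b - 1) * (k - 1)
  denom <- sqrt(2 * b * (A - B) / dfree)
  lev <- colnames(mat) %||% paste0("g", seq_len(k))
  out <- list()
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    tstat <- if (denom == 0) 0 else (Rj[i] - Rj[j]) / denom
    out[[length(out) + 1L]] <- data.frame(
      group1 = lev[i], group2 = lev[j], statistic = unname(tstat),
      p_raw = if (denom == 0) 1 else 2 * stats::pt(-abs(tstat), dfree))
  }
  do.call(rbind, out)
}

#' Compare three or more groups with Bonferroni-corrected post hoc tests
#'
#' Parametric route: one-way ANOVA followed by Bonferroni-adjusted pairwise
#' Welch t tests. Nonparametric route: Kruskal-Wallis followed by Dunn's
#' multiple comparison test with Bonferroni correction. Paired designs
#' (`paired = TRUE`; samples are matched complete blocks): Friedman test
#' followed by Conover's test with Bonferroni correction. The route is
#' decided as in [compare_two_groups()] when `NULL`.
#'
#' @param samples named list of numeric vectors (>= 3 groups); for paired
#'   designs all groups must have equal length (blocks in common order).
#' @param route `NULL`, "parametric" or "nonparametric".
#' @param paired logical; use the Friedman/Conover branch.
#' @return list with `omnibus` (test, statistic, p_value, route), `pairwise`
#'   (data.frame with raw and Bonferroni-adjusted p-values), `groups`
#'   (mean +/- SEM table).
#' @export
compare_multi_groups <- function(samples, route = NULL, paired = FALSE) {
  stopifnot(is.list(samples), length(samples) >= 3)
  if (is.null(names(samples)) || any(names(samples) == ""))
    names(samples) <- paste0("group", seq_along(samples))
  samples <- lapply(samples, function(v) v[!is.na(v)])
  ns <- lengths(samples)
  if (any(ns < 3)) stop("every group needs n >= 3")
  labels <- names(samples)
  values <- unlist(samples, use.names = FALSE)
  groups <- factor(rep(labels, ns), levels = labels)
  gtab <- data.frame(group = labels, n = ns,
                     mean = vapply(samples, mean, numeric(1)),
                     sem = vapply(samples, sem, numeric(1)))
  if (is.null(route)) {
    rts <- vapply(samples, function(v) assess_normality(v)$route, character(1))
    route <- if (any(rts == "nonparametric")) "nonparametric" else "parametric"
  }
  route <- match.arg(route, c("parametric", "nonparametric"))
  if (paired) {
    if (length(unique(ns)) != 1)
      stop("paired comparison needs equal group sizes (complete blocks)")
    mat <- do.call(cbind, samples)
    fr <- stats::friedman.test(mat)
    pw <- conover_pairwise(mat)
    omni <- list(test = "Friedman", statistic = unname(fr$statistic),
                 p_value = fr$p.value, route = "nonparametric")
  } else if (route == "parametric") {
    fit <- stats::aov(values ~ groups)
    s <- summary(fit)[[1]]
    omni <- list(test = "one-way ANOVA", statistic = s$`F value`[1],
                 p_value = s$`Pr(>F)`[1], route = route)
    pw <- list()
    for (i in seq_along(labels)[-length(labels)]) for (j in (i + 1):length(labels)) {
      a <- samples[[i]]; b <- samples[[j]]
      if (stats::sd(a) == 0 && stats::sd(b) == 0 && all(sort(a) == sort(b)) &&
          length(a) == length(b)) {
        pw[[length(pw) + 1L]] <- data.frame(group1 = labels[i], group2 = labels[j],
                                            statistic = 0, p_raw = 1)
      } else {
        tt <- stats::t.test(a, b, var.equal = FALSE)
        pw[[length(pw) + 1L]] <- data.frame(group1 = labels[i], group2 = labels[j],
                                            statistic = unname(tt$statistic),
                                            p_raw = tt$p.value)
      }
    }
    pw <- do.call(rbind, pw)
  } else {
    kw <- stats::kruskal.test(values, groups)
    omni <- list(test = "Kruskal-Wallis", statistic = unname(kw$statistic),
                 p_value = kw$p.value, route = route)
    pw <- dunn_pairwise(values, groups)
  }
  pw$p_adjusted <- pmin(1, pw$p_raw * nrow(pw))  # Bonferroni
  rownames(pw) <- NULL
  list(omnibus = omni, pairwise = pw, groups = gtab)
}
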