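#' Two-group functional ANOVA with pointwise F-ratio
#'
#' Fits, at every grid point t, the model
#' \deqn{f_i(t) = \mu(t) + \alpha_{g(i)}(t) + \epsilon_i(t)}
#' for two groups (exoskeleton on / off) under the identifiability constraint
#' \eqn{\alpha_1(t) + \alpha_2(t) = 0}, enforced exactly by reparameterizing
#' \eqn{\alpha_2 = -\alpha_1} (design matrix columns 1 and +/-1). With a
#' balanced design the least-squares solution is \eqn{\mu(t)} = grand mean
#' and \eqn{\alpha_1(t)} = half the group-mean difference. The error curves
#' are
#' \deqn{SSE(t) = \sum_i (f_i - \mu - \alpha_{g(i)})^2, \quad
#'       SSY(t) = \sum_i (f_i - \mu)^2}
#' and the F-ratio curve
#' \deqn{F(t) = \frac{(SSY(t) - SSE(t)) / df_{error}}{SSE(t) / df_{regression}}}
#' with \eqn{df_{error} = 1} and \eqn{df_{regression} = n - 2} (18 for the
#' canonical 10-subject, two-condition design of 20 curves). The F-criterion
#' is the upper-alpha quantile of F(1, n - 2) — 4.41 at alpha = 0.05 with 18
#' denominator degrees of freedom.
#'
#' @param sample an `fd_sample` (ideally registered), or a curves x points
#'   matrix already on the evaluation grid.
#' @param groups factor/character of length n_curves with exactly two levels
#'   and equal group sizes; the FIRST level is group 1 (reported in
#'   `alpha[1, ]`).
#' @param grid evaluation grid (default: the sample's argvals, or 0..100 for
#'   matrices with 101 columns).
#' @param alpha significance level for the F-criterion (default 0.05).
#' @return object of class `fanova_result` with `mu`, `alpha` (2 x grid,
#'   rows sum to 0), `sse`, `ssy`, `f`, `f_crit`, `df_error`,
#'   `df_regression`, `intervals` (significant intervals data.frame),
#'   `grid`, `groups` (level names).
#' @export
fanova <- function(sample, groups, grid = NULL, alpha = 0.05) {
  if (inherits(sample, "fd_sample")) {
    if (is.null(grid)) grid <- sample$argvals
    Y <- eval_fd(sample, grid)
  } else {
    Y <- as.matrix(sample)
    if (is.null(grid)) grid <- seq(0, 100, length.out = ncol(Y))
  }
  groups <- factor(groups)
  if (nlevels(groups) != 2)
    stop("unsupported design: exactly two groups required")
  n1 <- sum(groups == levels(groups)[1])
  n2 <- sum(groups == levels(groups)[2])
  if (n1 != n2)
    stop("unsupported design: groups must have equal numbers of curves")
  n <- n1 + n2
  if (nrow(Y) != n) stop("group labels must match the number of curves")
  # reparameterized design: f = mu + s * alpha1, s = +1 group 1, -1 group 2
  s <- ifelse(groups == levels(groups)[1], 1, -1)
  mu <- colMeans(Y)
  alpha1 <- colMeans(Y * s)          # balanced: (mean1 - mean2)/2
  fit <- outer(rep(1, n), mu) + outer(s, alpha1)
  sse <- colSums((Y - fit)^2)
  ssy <- colSums(sweep(Y, 2, mu)^2)
  res <- structure(list(mu = mu,
                        alpha = rbind(alpha1, -alpha1),
                        sse = sse, ssy = ssy,
                        df_error = 1, df_regression = n - 2,
                        grid = grid, groups = levels(groups),
                        alpha_level = alpha, n_curves = n),
                   class = "fanova_result")
  res$f <- f_curve(res)
  # with one curve per group there are no error degrees of freedom: nothing
  # can reach significance
  res$f_crit <- if (res$df_regression >= 1) {
    f_criterion(alpha, res$df_error, res$df_regression)
  } else Inf
  res$intervals <- significant_intervals(res$f, res$f_crit, grid)
  res
}

#' Pointwise F-ratio curve from FANOVA error curves
#'
#' \eqn{F(t) = [(SSY(t) - SSE(t)) / df_{error}] / [SSE(t) / df_{regression}]}.
#' Grid points with SSE(t) = 0 return `Inf` and are flagged via the
#' `degenerate` attribute.
#'
#' @param result a `fanova_result` (or any list with `sse`, `ssy`,
#'   `df_error`, `df_regression`).
#' @return numeric F-ratio series (>= 0 up to roundoff).
#' @export
f_curve <- function(result) {
  num <- (result$ssy - result$sse) / result$df_error
  den <- result$sse / result$df_regression
  # SSE = 0 with group differences is a perfect-separation degeneracy (F Inf);
  # SSE = SSY = 0 means no variation at all, so F = 0
  f <- ifelse(result$sse == 0, ifelse(result$ssy <= 1e-300, 0, Inf), num / den)
  f <- pmax(f, 0)
  attr(f, "degenerate") <- result$sse == 0
  f
}

#' F-criterion: upper-alpha quantile of the F distribution
#'
#' With alpha = 0.05, df1 = 1, df2 = 18 this is 4.41 (2 dp), the threshold a
#' pointwise F-ratio must exceed for the group difference at that time point
#' to be significant.
#'
#' @param alpha significance level in (0, 1).
#' @param df1 numerator degrees of freedom.
#' @param df2 denominator degrees of freedom.
#' @return the quantile.
#' @export
f_criterion <- function(alpha = 0.05, df1 = 1, df2 = 18) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  qf(1 - alpha, df1, df2)
}

#' Maximal runs of grid points with F above the criterion
#'
#' @param f F-ratio series on a uniform grid.
#' @param f_crit scalar threshold.
#' @param grid the normalized-time grid (same length as `f`).
#' @return data.frame with `start` and `end` (grid units, run endpoints
#'   inclusive); zero rows when nothing is significant.
#' @export
significant_intervals <- function(f, f_crit, grid = seq(0, 100, length.out = length(f))) {
  above <- as.vector(f) > f_crit
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  data.frame(start = grid[starts[keep]], end = grid[ends[keep]])
}

#' Peak values of biomechanical series, whole-trial and per phase
#'
#' The peak of each variable is the maximum absolute value (angular velocity
#' and acceleration swing negative during lowering, so magnitude is the
#' comparable quantity), reported with its normalized time. Ties take the
#' first grid point.
#'
#' @param series named list of numeric series on a common normalized grid
#'   (e.g., `list(Fc = ..., theta = ...)`), or a single numeric series.
#' @param phases a `phase_segmentation` (or NULL for whole-trial only).
#' @param grid the normalized-time grid.
#' @return data.frame with `variable`, `phase` ("all", "flexion", "lifting",
#'   "laying"), `peak` (signed value at the absolute peak), `t_peak`.
#' @export
peak_extract <- function(series, phases = NULL,
                         grid = seq(0, 100, length.out = length(series[[1]]))) {
  if (is.numeric(series)) series <- list(value = series)
  one <- function(v, idx, phase, name) {
    j <- idx[which.max(abs(v[idx]))]
    data.frame(variable = name, phase = phase, peak = v[j], t_peak = grid[j])
  }
  out <- list()
  for (name in names(series)) {
    v <- series[[name]]
    out[[length(out) + 1]] <- one(v, seq_along(v), "all", name)
    if (!is.null(phases)) {
      b <- phases$boundaries * (grid[length(grid)] - grid[1]) + grid[1]
      cuts <- list(flexion = grid <= b[1],
                   lifting = grid > b[1] & grid <= b[2],
                   laying = grid > b[2])
      for (ph in names(cuts)) {
        idx <- which(cuts[[ph]])
        if (length(idx)) out[[length(out) + 1]] <- one(v, idx, ph, name)
      }
    }
  }
  do.call(rbind, out)
}

#' Paired t-test on per-subject peak values
#'
#' Classical two-sided paired t-test on the differences x - y. Degenerate
#' zero-variance differences return t = 0, p = 1 (all-zero differences) or
#' p = 0 with a flag (constant nonzero difference).
#'
#' @param x,y paired numeric vectors (same subjects, two conditions).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `p`, `mean_diff`, `significant`, `degenerate`.
#' @export
paired_ttest <- function(x, y, alpha = 0.05) {
  n <- length(x)
  if (length(y) != n || n < 2) stop("need paired vectors of equal length >= 2")
  d <- x - y
  if (sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, p = 1, mean_diff = 0, significant = FALSE,
                  degenerate = TRUE))
    }
    return(list(t = sign(mean(d)) * Inf, p = 0, mean_diff = mean(d),
                significant = TRUE, degenerate = TRUE))
  }
  tt <- t.test(x, y, paired = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value,
       mean_diff = unname(tt$estimate), significant = tt$p.value < alpha,
       degenerate = FALSE)
}

#' @export
print.fanova_result <- function(x, ...) {
  cat(sprintf("<fanova_result> %d curves, groups %s vs %s | F-crit(%g; %d, %d) = %.2f\n",
              x$n_curves, x$groups[1], x$groups[2], x$alpha_level,
              x$df_error, x$df_regression, x$f_crit))
  cat(sprintf("  max F = %.2f; %d significant interval(s)\n",
              max(x$f), nrow(x$intervals)))
  invisible(x)
}

#' Export a FANOVA result as tidy CSV curves
#'
#' Columns `t_norm, mu, alpha_g1, sse, ssy, f`.
#'
#' @param result a `fanova_result`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_fanova_csv <- function(result, path) {
  df <- data.frame(t_norm = result$grid, mu = result$mu,
                   alpha_g1 = result$alpha[1, ], sse = result$sse,
                   ssy = result$ssy, f = as.numeric(result$f))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
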