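#' Concordance regression of predicted on observed cumulative incidence
#'
#' Fits `predicted = b0 + b1 * observed + e` by ordinary least squares.
#' Perfect external concordance corresponds to intercept 0, slope 1 and
#' R-squared 1. Standard errors use the Huber-White sandwich estimator;
#' clustering by source study accounts for serial dependence when several
#' endpoints come from one study, with the CR1 small-sample factor
#' `G/(G-1) * (n-1)/(n-k)`. With `cluster = "none"` every point is its own
#' cluster and the factor reduces to the usual HC1 `n/(n-k)`.
#'
#' @param points A `validation_points` data.frame (columns `observed`,
#'   `predicted`, and `study_id` when clustering by study).
#' @param include_intercept Fit the intercept (default) or force the line
#'   through the origin. The no-intercept slope solves the normal equation
#'   `sum(X*Y)/sum(X^2)`; its R-squared is uncentered and reported as such.
#' @param cluster `"study_id"` (default) or `"none"`.
#' @return An object of class `concordance_fit` with elements `intercept`,
#'   `slope`, `r_squared`, `robust_se_intercept`, `robust_se_slope`,
#'   `n_points`, `n_clusters`, `include_intercept`, `r_squared_uncentered`
#'   (no-intercept fits only) and the underlying `lm` fit.
#' @export
fit_concordance <- function(points, include_intercept = TRUE,
                            cluster = c("study_id", "none")) {
  cluster <- match.arg(cluster)
  n <- nrow(points)
  if (n < 3) stop("need at least 3 validation points")
  if (length(unique(points$observed)) < 2) {
    stop("observed values are degenerate (fewer than 2 distinct X)")
  }
  fm <- if (include_intercept) predicted ~ observed else predicted ~ observed - 1
  fit <- stats::lm(fm, data = points)
  beta <- stats::coef(fit)
  k <- length(beta)

  cl <- if (cluster == "study_id") {
    if (is.null(points$study_id)) stop("clustering needs a study_id column")
    as.character(points$study_id)
  } else {
    as.character(seq_len(n))
  }
  X <- stats::model.matrix(fit)
  u <- stats::residuals(fit)
  G <- length(unique(cl))
  # CR1 sandwich: bread = (X'X)^-1, meat = sum_g s_g s_g'
  scores <- rowsum(X * u, cl)
  meat <- crossprod(as.matrix(scores))
  bread <- solve(crossprod(X))
  adj <- (G / (G - 1)) * ((n - 1) / (n - k))
  V <- adj * bread %*% meat %*% bread
  se <- sqrt(diag(V))

  r2 <- if (include_intercept) {
    summary(fit)$r.squared
  } else {
    NA_real_
  }
  r2u <- if (!include_intercept) {
    1 - sum(u^2) / sum(points$predicted^2)
  } else {
    NA_real_
  }
  structure(
    list(
      intercept = if (include_intercept) unname(beta["(Intercept)"]) else 0,
      slope = unname(beta["observed"]),
      r_squared = r2,
      r_squared_uncentered = r2u,
      robust_se_intercept = if (include_intercept)
        unname(se["(Intercept)"]) else NA_real_,
      robust_se_slope = unname(se["observed"]),
      n_points = n, n_clusters = G,
      include_intercept = include_intercept,
      cluster = cluster, vcov = V, lm_fit = fit
    ),
    class = "concordance_fit"
  )
}

#' @export
print.concordance_fit <- function(x, ...) {
  cat("Concordance regression (predicted on observed)\n")
  if (x$include_intercept) {
    cat(sprintf("  intercept: %8.4f (robust SE %.4f)\n",
                x$intercept, x$robust_se_intercept))
  } else {
    cat("  intercept: constrained to 0\n")
  }
  cat(sprintf("  slope:     %8.4f (robust SE %.4f)\n",
              x$slope, x$robust_se_slope))
  if (x$include_intercept) {
    cat(sprintf("  R-squared: %8.4f\n", x$r_squared))
  } else {
    cat(sprintf("  R-squared (uncentered): %8.4f\n", x$r_squared_uncentered))
  }
  cat(sprintf("  n = %d points in %d cluster(s)\n", x$n_points, x$n_clusters))
  invisible(x)
}

#' Concordance fit on a subset of validation points
#'
#' Convenience wrapper: filter by dependency label or outcome category,
#' then fit. `selector = "all"` is identical to [fit_concordance()] on the
#' full set.
#'
#' @inheritParams fit_concordance
#' @param selector One of `"all"`, `"dependent"`, `"independent"`,
#'   `"microvascular"`, `"macrovascular"`, `"mortality"`.
#' @return A `concordance_fit`.
#' @export
subset_fit <- function(points, selector = c("all", "dependent",
                                            "independent", "microvascular",
                                            "macrovascular", "mortality"),
                       include_intercept = TRUE,
                       cluster = c("study_id", "none")) {
  selector <- match.arg(selector)
  sub <- if (selector == "all") {
    points
  } else if (selector %in% c("dependent", "independent")) {
    points[points$dependency == selector, , drop = FALSE]
  } else {
    points[points$category == selector, , drop = FALSE]
  }
  if (!nrow(sub)) stop("selector '", selector, "' matches no points")
  fit_concordance(sub, include_intercept = include_intercept,
                  cluster = cluster)
}

#' Scatterplot of predicted versus observed with identity and fitted lines
#'
#' Draws the standard external-validation scatter on the \[0,1\] x \[0,1\]
#' square: the 45-degree identity line (perfect concordance), the
#' best-fitting regression line, and per-study symbols/colours.
#'
#' @param points A `validation_points` data.frame.
#' @param fit Optional `concordance_fit` to draw; fitted on the fly when
#'   `NULL`.
#' @param file Optional output path (png/pdf, via [ggplot2::ggsave()]).
#' @param title Plot title.
#' @return List with `plot` (the ggplot object), `summary` (one-row
#'   data.frame with the fit statistics and n), and `file` (or `NULL`).
#' @export
scatter_report <- function(points, fit = NULL, file = NULL,
                           title = "Predicted vs. observed cumulative incidence") {
  if (!nrow(points)) stop("no validation points to plot")
  if (is.null(fit)) fit <- fit_concordance(points)
  summ <- data.frame(
    n = fit$n_points, n_clusters = fit$n_clusters,
    intercept = fit$intercept, slope = fit$slope,
    r_squared = if (fit$include_intercept) fit$r_squared
                else fit$r_squared_uncentered,
    robust_se_slope = fit$robust_se_slope
  )
  p <- ggplot2::ggplot(points,
                       ggplot2::aes(x = .data$observed, y = .data$predicted,
                                    colour = .data$study_id,
                                    shape = .data$study_id)) +
    ggplot2::geom_abline(intercept = 0, slope = 1, colour = "black") +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "grey40", linetype = "dashed") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_shape_manual(
      values = rep(c(16, 17, 15, 18, 3, 4, 8), length.out =
                     length(unique(points$study_id)))) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(x = "Observed cumulative incidence",
                  y = "Predicted cumulative incidence",
                  title = title,
                  subtitle = sprintf("slope %.3f, intercept %.3f, n = %d",
                                     fit$slope, fit$intercept,
                                     fit$n_points)) +
    ggplot2::theme_bw()
  if (!is.null(file)) {
    ggplot2::ggsave(file, p, width = 6, height = 5, dpi = 150)
  }
  list(plot = p, summary = summ, file = file)
}
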