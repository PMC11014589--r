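# S3 methods for "conservation_fit" objects.

ci_lookup <- function(object, statistic, level) {
  ci <- object$ci
  if (is.null(ci)) return(NULL)
  row <- ci[ci$statistic == statistic & abs(ci$level - level) < 1e-9, ]
  if (nrow(row) == 0L) return(NULL)
  c(row$lower, row$upper)
}

fmt_ci <- function(bounds, digits = 2) {
  if (is.null(bounds)) return("")
  sprintf(" [%.*f, %.*f]", digits, bounds[1], digits, bounds[2])
}

#' @export
print.conservation_fit <- function(x, digits = 2, ...) {
  cat(sprintf("Cortical conservation fit: lambda = k * A  (map %s, n = %d)\n",
              x$map, x$n))
  cat(sprintf("  k  = %.*f letters/mm^2%s\n", digits, x$k,
              fmt_ci(ci_lookup(x, "k", 0.68), digits)))
  if (!is.na(x$c)) {
    cat(sprintf("  c  = %.*f mm%s\n", digits, x$c,
                fmt_ci(ci_lookup(x, "c", 0.68), digits)))
  }
  if (!is.na(x$r_squared)) {
    cat(sprintf("  R2 = %.*f%s\n", digits, x$r_squared,
                fmt_ci(ci_lookup(x, "r_squared", 0.68), digits)))
  }
  if (!is.na(x$r)) {
    cat(sprintf("  r  = %.*f%s\n", digits, x$r,
                fmt_ci(ci_lookup(x, "r", 0.68), digits)))
  }
  if (x$n_boot > 0) {
    cat(sprintf("  (68%% percentile bootstrap, %d resamples%s)\n", x$n_boot,
                if (!is.null(x$seed)) sprintf(", seed %d", x$seed) else ""))
  }
  invisible(x)
}

#' @export
summary.conservation_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.conservation_fit")
}

#' @export
print.summary.conservation_fit <- function(x, digits = 3, ...) {
  fit <- x$fit
  print(fit, digits = digits)
  cat(sprintf("  area per letter: %.3f mm^2\n", 1 / fit$k))
  if (!is.null(fit$ci)) {
    cat("\nBootstrap percentile intervals:\n")
    ci <- fit$ci
    ci$level <- sprintf("%d%%", round(ci$level * 100))
    print(ci, digits = digits, row.names = FALSE)
    if (fit$boot_dropped > 0) {
      cat(sprintf("  %d degenerate resamples dropped\n", fit$boot_dropped))
    }
  }
  res <- stats::residuals(fit)
  cat(sprintf("\nResiduals (letters): min %.1f, median %.1f, max %.1f\n",
              min(res), stats::median(res), max(res)))
  invisible(x)
}

#' @export
coef.conservation_fit <- function(object, ...) {
  c(k = object$k)
}

#' @export
fitted.conservation_fit <- function(object, ...) {
  object$k * object$data$area
}

#' @export
residuals.conservation_fit <- function(object, ...) {
  object$data$lambda - stats::fitted(object)
}

#' Predict letter counts from map areas under conservation
#'
#' @param object A [fit_conservation()] object.
#' @param newdata Either a numeric vector of areas (mm^2) or a data
#'   frame with the fitted map's area column; omitted, the fitted
#'   areas are used.
#' @param ... Unused.
#' @return Predicted lambda values, `k * A`.
#' @export
predict.conservation_fit <- function(object, newdata = NULL, ...) {
  area <- if (is.null(newdata)) {
    object$data$area
  } else if (is.data.frame(newdata)) {
    if (!object$map %in% names(newdata)) {
      stop(sprintf("'newdata' lacks the fitted map column '%s'", object$map))
    }
    newdata[[object$map]]
  } else {
    as.numeric(newdata)
  }
  object$k * area
}

#' Confidence intervals for conservation-fit statistics
#'
#' @param object A [fit_conservation()] object fit with `n_boot > 0`.
#' @param parm Statistics to report (default all four).
#' @param level Confidence level; must be one of the levels the fit
#'   was bootstrapped at.
#' @param ... Unused.
#' @return A matrix with one row per statistic, columns `lower` and
#'   `upper`.
#' @export
confint.conservation_fit <- function(object,
                                     parm = c("k", "c", "r", "r_squared"),
                                     level = 0.68, ...) {
  if (is.null(object$ci)) {
    stop("fit has no bootstrap intervals; refit with n_boot > 0")
  }
  parm <- match.arg(parm, several.ok = TRUE)
  rows <- lapply(parm, function(p) {
    b <- ci_lookup(object, p, level)
    if (is.null(b)) stop(sprintf("no %.0f%% interval stored", level * 100))
    b
  })
  out <- do.call(rbind, rows)
  dimnames(out) <- list(parm, c("lower", "upper"))
  out
}

#' Scatter plot of a conservation fit
#'
#' Plots per-observer letter count against map area, the through-origin
#' conservation line, and the 1-SD and 2-SD covariance ellipses (drawn
#' in standardized coordinates and mapped back to the data units).
#'
#' @param x A [fit_conservation()] object.
#' @param ellipses Draw covariance ellipses (default TRUE; needs at
#'   least 3 observers).
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.conservation_fit <- function(x, ellipses = TRUE, ...) {
  dat <- x$data
  graphics::plot(
    dat$area, dat$lambda,
    xlab = sprintf("%s surface area A (mm^2)", x$map),
    ylab = expression(lambda ~ "(letters)"),
    xlim = c(0, max(dat$area) * 1.1), ylim = c(0, max(dat$lambda) * 1.1),
    pch = 19, col = grDevices::adjustcolor("steelblue", 0.8), ...
  )
  graphics::abline(0, x$k, lty = 2)
  if (ellipses && !is.null(x$ellipse)) {
    th <- seq(0, 2 * pi, length.out = 181)
    e <- x$ellipse
    for (n_sd in 1:2) {
      # unit-circle parametrisation rotated to the ellipse axes, then
      # scaled back from standardized to data coordinates
      u <- n_sd * (e$axes[1] * cos(th) * cos(e$angle) -
                     e$axes[2] * sin(th) * sin(e$angle))
      v <- n_sd * (e$axes[1] * cos(th) * sin(e$angle) +
                     e$axes[2] * sin(th) * cos(e$angle))
      graphics::lines(e$center[1] + u * e$sd[1], e$center[2] + v * e$sd[2],
                      col = grDevices::adjustcolor("tomato", 0.7))
    }
  }
  invisible(x)
}
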