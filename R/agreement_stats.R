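#' Linear agreement between estimated and reference displacement
#'
#' Ordinary least squares of estimated on reference; perfect agreement
#' is slope 1, intercept 0, R-squared 1.
#'
#' @param estimated,reference Paired displacement series (mm), equal
#'   length >= 3, finite.
#' @return A list with `slope`, `intercept`, `r_squared`, `n`.
#' @export
linear_agreement <- function(estimated, reference) {
  stopifnot(length(estimated) == length(reference), length(estimated) >= 3,
            all(is.finite(estimated)), all(is.finite(reference)))
  if (sd(reference) == 0) {
    stop("reference series is constant; slope undefined", call. = FALSE)
  }
  fit <- lm(estimated ~ reference)
  # R^2 = 1 - SSR/SST (== squared Pearson correlation for simple OLS)
  sst <- sum((estimated - mean(estimated))^2)
  ssr <- sum(fit$residuals^2)
  list(slope = unname(coef(fit)[2]),
       intercept = unname(coef(fit)[1]),
       r_squared = if (sst > 0) 1 - ssr / sst else as.numeric(ssr == 0),
       n = length(estimated))
}

#' Bland-Altman agreement analysis
#'
#' Plots-in-numbers form of the method-comparison analysis: differences
#' (estimated - reference) against means of the pair.  In `"constant"`
#' mode the bias is the mean difference and the 95% limits of agreement
#' are bias +/- 1.96 * SD(differences).  When the difference scatter is
#' visibly not constant across the displacement range, `"regression"`
#' mode fits the bias as a straight line in the pair mean and draws the
#' limits at bias(x) +/- 1.96 * SD(residuals).  Sample standard
#' deviations (n - 1) are used throughout.
#'
#' @param estimated,reference Paired series (mm), equal length >= 3.
#' @param bias_model `"regression"` or `"constant"`.
#' @return An `agreement_report`: `n`, `bias_model`, `bias_intercept`,
#'   `bias_slope` (0 in constant mode), `loa_halfwidth`
#'   (1.96 * residual SD, mm), plus the scatter regression `slope`,
#'   `intercept` and `r_squared` from [linear_agreement()].
#' @export
bland_altman <- function(estimated, reference,
                         bias_model = c("regression", "constant")) {
  bias_model <- match.arg(bias_model)
  stopifnot(length(estimated) == length(reference), length(estimated) >= 3,
            all(is.finite(estimated)), all(is.finite(reference)))
  d <- estimated - reference
  m <- (estimated + reference) / 2
  if (bias_model == "constant" || sd(m) == 0) {
    bias_intercept <- mean(d)
    bias_slope <- 0
    resid <- d - bias_intercept
  } else {
    fit <- lm(d ~ m)
    bias_intercept <- unname(coef(fit)[1])
    bias_slope <- unname(coef(fit)[2])
    resid <- unname(fit$residuals)
  }
  la <- linear_agreement(estimated, reference)
  structure(list(n = length(d),
                 bias_model = bias_model,
                 bias_intercept = bias_intercept,
                 bias_slope = bias_slope,
                 loa_halfwidth = 1.96 * sd(resid),
                 slope = la$slope,
                 intercept = la$intercept,
                 r_squared = la$r_squared),
            class = "agreement_report")
}

#' Serialize / restore an agreement report as JSON
#'
#' @param report An `agreement_report`.
#' @param path Output path.
#' @return The path (write) or the report (read).
#' @export
write_agreement_report <- function(report, path) {
  payload <- c(list(schema = "ettnir-agreement/1"), unclass(report))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_agreement_report
#' @export
read_agreement_report <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (is.null(p$schema) || p$schema != "ettnir-agreement/1") {
    stop("unrecognized agreement report schema", call. = FALSE)
  }
  p$schema <- NULL
  structure(p, class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d, bias model: %s)\n", x$n, x$bias_model))
  cat(sprintf("  scatter OLS: slope %.4f, intercept %.4f mm, R^2 %.4f\n",
              x$slope, x$intercept, x$r_squared))
  cat(sprintf("  bias: %.4f %+.4f * mean (mm); LoA half-width %.4f mm\n",
              x$bias_intercept, x$bias_slope, x$loa_halfwidth))
  invisible(x)
}

#' Cycle-wise interpolation summary
#'
#' Re-grids repeated sweep cycles onto a uniform displacement grid via
#' per-cycle linear interpolation, then reports the cross-cycle mean and
#' the 1.96 * SD band at each grid point (the shaded-band summary used
#' for sweep measurements).  Within a cycle, frames at the same
#' commanded plateau are averaged first, the cycle is split into its
#' monotone passes, each pass is interpolated onto the grid, and the
#' passes of a cycle are averaged into one per-cycle curve.
#'
#' @param values Measured quantity per frame (voltage, ratio or
#'   estimate).
#' @param truth Reference displacement per frame (mm).
#' @param cycle Cycle label per frame.
#' @param grid_interval Grid spacing (mm), > 0.
#' @return A `cycle_summary` data frame with `grid`, `mean`, `band`
#'   (1.96 * SD; `NA` with a warning when only one cycle is available)
#'   and attribute `n_cycles`.
#' @export
summarize_cycles <- function(values, truth, cycle, grid_interval = 1) {
  stopifnot(grid_interval > 0, length(values) == length(truth),
            length(values) == length(cycle))
  grid <- seq(ceiling(min(truth) / grid_interval) * grid_interval,
              floor(max(truth) / grid_interval) * grid_interval,
              by = grid_interval)
  cycles <- unique(cycle)
  percyc <- sapply(cycles, function(cy) {
    sel <- cycle == cy
    v <- values[sel]; tr <- truth[sel]
    # collapse plateaus: consecutive runs of equal truth
    runs <- cumsum(c(TRUE, diff(tr) != 0))
    dk <- tapply(tr, runs, mean)
    vk <- tapply(v, runs, mean)
    if (length(dk) < 2) stop("cycle shorter than one grid step", call. = FALSE)
    dir <- sign(diff(dk))
    seg <- cumsum(c(TRUE, diff(dir) != 0))
    segid <- c(seg, seg[length(seg)]) # point i belongs to segment of step i
    passes <- sapply(unique(segid), function(sg) {
      idx <- which(segid == sg)
      if (length(idx) < 2) return(rep(NA_real_, length(grid)))
      approx(dk[idx], vk[idx], xout = grid, rule = 1)$y
    })
    rowMeans(passes, na.rm = TRUE)
  })
  if (is.null(dim(percyc))) percyc <- matrix(percyc, ncol = length(cycles))
  mean_curve <- rowMeans(percyc, na.rm = TRUE)
  if (length(cycles) < 2) {
    warning("single cycle: SD band undefined")
    band <- rep(NA_real_, length(grid))
  } else {
    band <- 1.96 * apply(percyc, 1, sd, na.rm = TRUE)
  }
  structure(data.frame(grid = grid, mean = mean_curve, band = band),
            n_cycles = length(cycles),
            class = c("cycle_summary", "data.frame"))
}
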