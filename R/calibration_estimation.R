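#' Voltage ratios used for displacement estimation
#'
#' Computes r12 = VP1/VP2 and r32 = VP3/VP2.  VP2 must clear a signal
#' floor: a collapsed P2 signal means the fiber has decoupled from the
#' tissue or the tube is far outside the working range, and the ratios
#' would blow up.
#'
#' @param frame A list/one-row data frame with `vp1`, `vp2`, `vp3`, or a
#'   numeric vector of the five voltages.
#' @param floor Minimum acceptable VP2 (V).
#' @return A list with `r12` and `r32`.
#' @export
compute_ratios <- function(frame, floor = 0.02) {
  v <- if (is.numeric(frame)) {
    list(vp1 = frame[1], vp2 = frame[2], vp3 = frame[3])
  } else {
    frame
  }
  if (!is.finite(v$vp2) || v$vp2 <= floor) {
    stop("low-signal: VP2 <= floor (", floor, " V)", call. = FALSE)
  }
  list(r12 = v$vp1 / v$vp2, r32 = v$vp3 / v$vp2)
}

#' Calibration measurement set
#'
#' Exactly five records at the commanded displacements -10, -5, 0, +5,
#' +10 mm, each carrying the dwell-averaged ratio pair.
#'
#' @param displacement Commanded displacements (mm).
#' @param r12,r32 Dwell-averaged ratios at each displacement.
#' @return A `calibration_set` data frame sorted by displacement.
#' @export
calibration_set <- function(displacement, r12, r32) {
  required <- c(-10, -5, 0, 5, 10)
  if (length(displacement) != 5L || !setequal(displacement, required) ||
      anyDuplicated(displacement)) {
    stop("calibration requires exactly the displacements -10, -5, 0, +5, +10 mm",
         call. = FALSE)
  }
  if (!all(is.finite(r12)) || !all(is.finite(r32))) {
    stop("non-finite calibration ratios", call. = FALSE)
  }
  ord <- order(displacement)
  structure(data.frame(displacement = displacement[ord],
                       r12 = r12[ord], r32 = r32[ord]),
            class = c("calibration_set", "data.frame"))
}

# Quadratic through three (d, r) nodes; coefficients c(c0, c1, c2) for
# r = c0 + c1*d + c2*d^2.
interp_quadratic <- function(d, r) {
  as.numeric(solve(cbind(1, d, d^2), r))
}

eval_quadratic <- function(coefs, d) {
  coefs[1] + coefs[2] * d + coefs[3] * d^2
}

quadratic_monotone <- function(coefs, range) {
  if (abs(coefs[3]) < 1e-14) return(TRUE)
  vertex <- -coefs[2] / (2 * coefs[3])
  !(vertex > range[1] && vertex < range[2])
}

#' Fit the four-branch quadratic calibration model
#'
#' Each branch is the quadratic through its three calibration nodes:
#' `f12_high` and `f32_low` interpolate r12 and r32 at -10, -5, 0 mm
#' (the negative, pulled-out half-range); `f32_high` and `f12_low`
#' interpolate r32 and r12 at 0, +5, +10 mm (the positive, pushed-in
#' half-range).  "High" branches carry the larger, better-SNR ratio in
#' their half-range and dominate the weighted estimate.  Branches whose
#' vertex falls inside their half-range are flagged non-monotone.
#'
#' @param cal A [calibration_set()].
#' @param weight_w Fusion weight for the high-signal branch, in \[0, 1\].
#' @return A `calibration_model` list with the four coefficient triples,
#'   the d = 0 baselines, the weight, the valid range and monotonicity
#'   flags.
#' @export
fit_calibration <- function(cal, weight_w = 0.95) {
  if (!inherits(cal, "calibration_set")) {
    cal <- calibration_set(cal$displacement, cal$r12, cal$r32)
  }
  stopifnot(weight_w >= 0, weight_w <= 1)
  neg <- cal$displacement <= 0
  pos <- cal$displacement >= 0
  model <- list(
    f12_high = interp_quadratic(cal$displacement[neg], cal$r12[neg]),
    f32_low  = interp_quadratic(cal$displacement[neg], cal$r32[neg]),
    f32_high = interp_quadratic(cal$displacement[pos], cal$r32[pos]),
    f12_low  = interp_quadratic(cal$displacement[pos], cal$r12[pos]),
    r12_zero = cal$r12[cal$displacement == 0],
    r32_zero = cal$r32[cal$displacement == 0],
    weight_w = weight_w,
    valid_range = c(-10, 10),
    nodes = as.data.frame(cal)
  )
  model$monotone <- c(
    f12_high = quadratic_monotone(model$f12_high, c(-10, 0)),
    f32_low  = quadratic_monotone(model$f32_low, c(-10, 0)),
    f32_high = quadratic_monotone(model$f32_high, c(0, 10)),
    f12_low  = quadratic_monotone(model$f12_low, c(0, 10))
  )
  class(model) <- "calibration_model"
  if (!all(model$monotone)) {
    warning("non-monotone calibration branch(es): ",
            paste(names(model$monotone)[!model$monotone], collapse = ", "))
  }
  model
}

#' Classify the displacement direction
#'
#' The rule compares r12 to its d = 0 baseline: r12/r12(0) > 1 means the
#' light spot moved toward P1, i.e. the tube moved outward (negative
#' displacement); < 1 means inward (positive).  An optional deadband
#' returns "zero" for ratios within `1 +/- deadband`.
#'
#' @param ratios A list with `r12` (and `r32`), e.g. from
#'   [compute_ratios()].
#' @param model A `calibration_model`.
#' @param deadband Relative deadband around 1 (default 0, the strict
#'   rule).
#' @return `"negative"`, `"positive"` or `"zero"`.
#' @export
classify_direction <- function(ratios, model, deadband = 0) {
  rel <- ratios$r12 / model$r12_zero
  if (rel > 1 + deadband) "negative"
  else if (rel < 1 - deadband) "positive"
  else "zero"
}

#' Invert one calibration branch
#'
#' Solves f(d) = ratio on the branch's half-range.  Ratios beyond the
#' fitted curve's reach clamp to the appropriate range end and set the
#' `clamped` flag (extrapolating beyond the calibration range is what
#' produces outliers past +/-11 mm).
#'
#' @param quadratic Coefficient triple c(c0, c1, c2).
#' @param ratio_value Observed ratio.
#' @param applicable_range Half-range c(lo, hi) (mm).
#' @return A list with `d` (mm) and `clamped` (logical).
#' @export
invert_branch <- function(quadratic, ratio_value, applicable_range) {
  lo <- applicable_range[1]; hi <- applicable_range[2]
  c2 <- quadratic[3]; c1 <- quadratic[2]; c0 <- quadratic[1] - ratio_value
  tol <- 1e-9 * max(1, abs(lo), abs(hi))
  if (abs(c2) < 1e-14) {
    if (abs(c1) < 1e-14) stop("degenerate calibration branch", call. = FALSE)
    d <- -c0 / c1
    if (d < lo - tol) return(list(d = lo, clamped = TRUE))
    if (d > hi + tol) return(list(d = hi, clamped = TRUE))
    return(list(d = min(hi, max(lo, d)), clamped = FALSE))
  }
  disc <- c1^2 - 4 * c2 * c0
  if (disc < 0) {
    # ratio beyond the fitted extremum: clamp to the vertex-side range end
    vertex <- -c1 / (2 * c2)
    d <- if (abs(vertex - lo) < abs(vertex - hi)) lo else hi
    return(list(d = d, clamped = TRUE))
  }
  roots <- (-c1 + c(-1, 1) * sqrt(disc)) / (2 * c2)
  inside <- roots >= lo - tol & roots <= hi + tol
  if (sum(inside) == 2L && diff(range(roots)) > 2 * tol) {
    stop("both quadratic roots fall in the applicable range; ",
         "branch is not monotone there", call. = FALSE)
  }
  if (any(inside)) {
    d <- roots[inside][1]
    return(list(d = min(hi, max(lo, d)), clamped = FALSE))
  }
  # real roots, all outside: clamp to the nearest range end
  nearest <- roots[which.min(pmin(abs(roots - lo), abs(roots - hi)))]
  list(d = if (abs(nearest - lo) < abs(nearest - hi)) lo else hi,
       clamped = TRUE)
}

#' Estimate tube displacement from a ratio pair
#'
#' Direction is classified first; the matching half-range is then
#' inverted twice, once through the high-signal branch (the larger,
#' more reliable ratio) and once through the low-signal branch, and the
#' two estimates are fused as
#' \deqn{d_{final} = w \cdot d_{high} + (1 - w) \cdot d_{low}.}
#'
#' @param ratios A list with `r12`, `r32`.
#' @param model A `calibration_model`.
#' @param deadband Passed to [classify_direction()].
#' @return A `displacement_estimate` list: `d_final`, `d_high`, `d_low`,
#'   `direction`, `clamped`.
#' @export
estimate_displacement <- function(ratios, model, deadband = 0) {
  direction <- classify_direction(ratios, model, deadband)
  w <- model$weight_w
  if (direction == "zero") {
    est <- list(d_final = 0, d_high = 0, d_low = 0,
                direction = "zero", clamped = FALSE)
  } else if (direction == "negative") {
    hi <- invert_branch(model$f12_high, ratios$r12, c(-10, 0))
    lo <- invert_branch(model$f32_low, ratios$r32, c(-10, 0))
    est <- list(d_final = w * hi$d + (1 - w) * lo$d,
                d_high = hi$d, d_low = lo$d,
                direction = "negative", clamped = hi$clamped || lo$clamped)
  } else {
    hi <- invert_branch(model$f32_high, ratios$r32, c(0, 10))
    lo <- invert_branch(model$f12_low, ratios$r12, c(0, 10))
    est <- list(d_final = w * hi$d + (1 - w) * lo$d,
                d_high = hi$d, d_low = lo$d,
                direction = "positive", clamped = hi$clamped || lo$clamped)
  }
  class(est) <- "displacement_estimate"
  est
}

#' Rotation alert from the perpendicular sensors
#'
#' Compares VP4/VP2 and VP5/VP2 to their calibration-time baselines and
#' flags the frame when either deviates by more than `threshold`
#' (fractional).  A large deviation means the side-firing tip has
#' rotated away from the board.
#'
#' @param frame Voltages (list with `vp2`, `vp4`, `vp5`, or length-5
#'   numeric).
#' @param baselines Length-2 vector: calibration-time VP4/VP2 and
#'   VP5/VP2.
#' @param threshold Fractional deviation triggering the alert.
#' @param floor VP2 signal floor (V).
#' @return A `rotation_alert` list: `ratio_p4`, `ratio_p5`, `threshold`,
#'   `flagged`.
#' @export
rotation_alert <- function(frame, baselines, threshold = 0.30, floor = 0.02) {
  v <- if (is.numeric(frame)) {
    list(vp2 = frame[2], vp4 = frame[4], vp5 = frame[5])
  } else frame
  if (!is.finite(v$vp2) || v$vp2 <= floor) {
    stop("low-signal: VP2 <= floor", call. = FALSE)
  }
  r4 <- v$vp4 / v$vp2
  r5 <- v$vp5 / v$vp2
  dev <- c(abs(r4 / baselines[1] - 1), abs(r5 / baselines[2] - 1))
  structure(list(ratio_p4 = r4, ratio_p5 = r5, threshold = threshold,
                 flagged = any(dev > threshold)),
            class = "rotation_alert")
}

#' Track a whole voltage series
#'
#' Applies ratio computation, direction classification and branch
#' inversion frame by frame.  Frames whose VP2 falls below the signal
#' floor yield `NA` estimates with a reason; other frames are
#' unaffected.
#'
#' @param series Voltage series data frame (`vp1`..`vp5`, optionally
#'   `ref_mm`).
#' @param model A `calibration_model`.
#' @param floor VP2 signal floor (V).
#' @param deadband Direction deadband.
#' @param rotation_baselines Optional length-2 baselines for the
#'   rotation alert; `NULL` skips it.
#' @param rotation_threshold Alert threshold.
#' @return A data frame with `d_final`, `d_high`, `d_low`, `direction`,
#'   `clamped`, `reason` (NA unless the frame was rejected) and, when
#'   requested, `rotation_flag`; `ref_mm` is carried through when
#'   present.
#' @export
track_series <- function(series, model, floor = 0.02, deadband = 0,
                         rotation_baselines = NULL, rotation_threshold = 0.30) {
  n <- nrow(series)
  out <- data.frame(d_final = rep(NA_real_, n), d_high = NA_real_,
                    d_low = NA_real_, direction = NA_character_,
                    clamped = NA, reason = NA_character_,
                    stringsAsFactors = FALSE)
  if (!is.null(rotation_baselines)) out$rotation_flag <- NA
  for (i in seq_len(n)) {
    vp2 <- series$vp2[i]
    if (!is.finite(vp2) || vp2 <= floor) {
      out$reason[i] <- "low_signal"
      next
    }
    ratios <- list(r12 = series$vp1[i] / vp2, r32 = series$vp3[i] / vp2)
    est <- estimate_displacement(ratios, model, deadband)
    out$d_final[i] <- est$d_final
    out$d_high[i] <- est$d_high
    out$d_low[i] <- est$d_low
    out$direction[i] <- est$direction
    out$clamped[i] <- est$clamped
    if (!is.null(rotation_baselines)) {
      out$rotation_flag[i] <- rotation_alert(
        list(vp2 = vp2, vp4 = series$vp4[i], vp5 = series$vp5[i]),
        rotation_baselines, rotation_threshold, floor)$flagged
    }
  }
  if (!is.null(series$ref_mm)) out$ref_mm <- series$ref_mm
  if (!is.null(series$cycle)) out$cycle <- series$cycle
  if (!is.null(series$time)) out$time <- series$time
  out
}

#' Serialize / restore a calibration model as JSON
#'
#' Full-precision round trip: reading back the file reproduces every
#' coefficient bit-exactly.
#'
#' @param model A `calibration_model`.
#' @param path Output path (`.json`).
#' @return `write_calibration_model` returns `path` invisibly;
#'   `read_calibration_model` returns the model.
#' @export
write_calibration_model <- function(model, path) {
  payload <- list(
    schema = "ettnir-calibration/1",
    displacements_mm = model$nodes$displacement,
    r12 = model$nodes$r12,
    r32 = model$nodes$r32,
    f12_high = model$f12_high, f32_low = model$f32_low,
    f32_high = model$f32_high, f12_low = model$f12_low,
    r12_zero = model$r12_zero, r32_zero = model$r32_zero,
    weight_w = model$weight_w,
    valid_range = model$valid_range,
    monotone = as.list(model$monotone),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_calibration_model
#' @export
read_calibration_model <- function(path) {
  p <- jsonlite::fromJSON(path)
  if (is.null(p$schema) || p$schema != "ettnir-calibration/1") {
    stop("unrecognized calibration file schema", call. = FALSE)
  }
  model <- list(f12_high = p$f12_high, f32_low = p$f32_low,
                f32_high = p$f32_high, f12_low = p$f12_low,
                r12_zero = p$r12_zero, r32_zero = p$r32_zero,
                weight_w = p$weight_w, valid_range = p$valid_range,
                nodes = data.frame(displacement = p$displacements_mm,
                                   r12 = p$r12, r32 = p$r32),
                monotone = unlist(p$monotone))
  class(model) <- "calibration_model"
  model
}

#' @export
print.calibration_model <- function(x, ...) {
  cat("Four-branch quadratic calibration model\n")
  cat(sprintf("  baselines r12(0) = %.4f, r32(0) = %.4f; w = %.2f\n",
              x$r12_zero, x$r32_zero, x$weight_w))
  for (b in c("f12_high", "f32_low", "f32_high", "f12_low")) {
    cf <- x[[b]]
    cat(sprintf("  %-8s r = %+.5g %+.5g d %+.5g d^2  [monotone: %s]\n",
                b, cf[1], cf[2], cf[3], x$monotone[[b]]))
  }
  invisible(x)
}
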