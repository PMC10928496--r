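#' Define a single optical tissue layer
#'
#' A layer is described by its thickness and the four optical properties
#' that govern near-infrared transport: the absorption coefficient
#' \eqn{\mu_a}, the scattering coefficient \eqn{\mu_s}, the scattering
#' anisotropy \eqn{g} (mean cosine of the single-scattering deflection),
#' and the refractive index \eqn{n}.
#'
#' @param name Layer label.
#' @param thickness_mm Layer thickness in mm; must be positive.
#' @param mu_a Absorption coefficient in 1/cm; non-negative.
#' @param mu_s Scattering coefficient in 1/cm; non-negative.
#' @param g Scattering anisotropy, strictly inside (-1, 1).
#' @param n Refractive index, at least 1.
#' @return A one-row data frame with the validated fields.
#' @export
tissue_layer <- function(name, thickness_mm, mu_a, mu_s, g, n) {
  chk <- function(ok, field, msg) {
    if (!isTRUE(ok)) {
      stop(sprintf("layer '%s', field '%s': %s", name, field, msg), call. = FALSE)
    }
  }
  chk(is.character(name) && length(name) == 1L, "name", "must be a single string")
  chk(is.finite(thickness_mm) && thickness_mm > 0, "thickness_mm", "must be > 0")
  chk(is.finite(mu_a) && mu_a >= 0, "mu_a", "must be >= 0")
  chk(is.finite(mu_s) && mu_s >= 0, "mu_s", "must be >= 0")
  chk(is.finite(g) && abs(g) < 1, "g", "must satisfy |g| < 1")
  chk(is.finite(n) && n >= 1, "n", "must be >= 1")
  data.frame(name = name, thickness_mm = thickness_mm, mu_a = mu_a,
             mu_s = mu_s, g = g, n = n, stringsAsFactors = FALSE)
}

#' Assemble an ordered tissue stack
#'
#' Layers are ordered from the tracheal lumen side (where the side-firing
#' fiber sits) to the skin side (where the detector board sits).
#'
#' @param layers A data frame with columns `name`, `thickness_mm`, `mu_a`,
#'   `mu_s`, `g`, `n`, or a list of such one-row frames / lists.
#' @return An object of class `tissue_stack`: the layer table with a
#'   `total_thickness` attribute (mm).
#' @export
#' @examples
#' stack <- default_tissue_stack()
#' attr(stack, "total_thickness") # 16 mm
build_tissue_stack <- function(layers) {
  if (is.data.frame(layers)) {
    rows <- lapply(seq_len(nrow(layers)), function(i) as.list(layers[i, ]))
  } else if (is.list(layers)) {
    rows <- lapply(layers, as.list)
  } else {
    stop("layers must be a data frame or a list of layer records", call. = FALSE)
  }
  if (length(rows) < 1L) stop("a tissue stack needs at least one layer", call. = FALSE)
  validated <- do.call(rbind, lapply(rows, function(r) {
    tissue_layer(as.character(r$name), as.numeric(r$thickness_mm),
                 as.numeric(r$mu_a), as.numeric(r$mu_s),
                 as.numeric(r$g), as.numeric(r$n))
  }))
  structure(validated,
            total_thickness = sum(validated$thickness_mm),
            class = c("tissue_stack", "data.frame"))
}

#' Default five-layer tracheal tissue stack
#'
#' The reference anterior neck model used throughout the package: mucosal/
#' submucosal/glandular tissue, tracheal cartilage, adipose-rich soft
#' tissue, muscle-rich soft tissue and skin, ordered from the lumen
#' outward, 16 mm thick in total.  Coefficients are in 1/cm, thicknesses
#' in mm.
#'
#' @return A `tissue_stack`.
#' @export
default_tissue_stack <- function() {
  build_tissue_stack(data.frame(
    name = c("mucosa", "cartilage", "adipose", "muscle", "skin"),
    thickness_mm = c(1.5, 1.0, 6.5, 6.5, 0.5),
    mu_a = c(0.70, 1.00, 0.22, 0.35, 1.80),
    mu_s = c(173, 100, 119, 83, 408),
    g = c(0.95, 0.92, 0.79, 0.90, 0.95),
    n = c(1.40, 1.45, 1.40, 1.40, 1.36),
    stringsAsFactors = FALSE
  ))
}

#' Read / write a tissue stack file
#'
#' Stack files are YAML or JSON lists of records with keys `name`,
#' `thickness_mm`, `mu_a_per_cm`, `mu_s_per_cm`, `g`, `n`.  A packaged
#' default (`system.file("extdata", "tissue_stack_default.yaml",
#' package = "ettnir")`) reproduces the reference five-layer model.
#'
#' @param path File path; format chosen by extension (`.yaml`/`.yml` or
#'   `.json`).
#' @return `read_tissue_stack` returns a `tissue_stack`;
#'   `write_tissue_stack` returns `path` invisibly.
#' @export
read_tissue_stack <- function(path) {
  if (!file.exists(path)) stop("stack file not found: ", path, call. = FALSE)
  recs <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  } else {
    # keep the bare key "n" a string (YAML 1.1 would read it as a boolean)
    yaml::read_yaml(path, handlers = list("bool#yes" = identity,
                                          "bool#no" = identity))
  }
  build_tissue_stack(lapply(recs, function(r) {
    list(name = r$name, thickness_mm = r$thickness_mm,
         mu_a = r$mu_a_per_cm, mu_s = r$mu_s_per_cm, g = r$g, n = r$n)
  }))
}

#' @rdname read_tissue_stack
#' @param stack A `tissue_stack`.
#' @export
write_tissue_stack <- function(stack, path) {
  recs <- lapply(seq_len(nrow(stack)), function(i) {
    list(name = stack$name[i], thickness_mm = stack$thickness_mm[i],
         mu_a_per_cm = stack$mu_a[i], mu_s_per_cm = stack$mu_s[i],
         g = stack$g[i], n = stack$n[i])
  })
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = I(17))
  } else {
    yaml::write_yaml(recs, path)
  }
  invisible(path)
}

#' Describe the photon source
#'
#' The source models the side-firing fiber tip pressed against the lumen
#' wall: a surface emitter with either a Lambertian ("cosine") angular
#' lobe or an idealized pencil beam, optionally tilted to emulate tube
#' rotation.
#'
#' @param lateral_position Lateral position of the tip on the lumen
#'   surface (mm).
#' @param angular_model `"cosine_lobe"` (default) or `"pencil"`.
#' @param tilt_angle Lobe tilt in degrees, within \[-90, 90\].
#' @param n_packets Number of photon packets to launch.
#' @param seed Integer seed; fixes the run exactly.
#' @return A `source_spec` list.
#' @export
source_spec <- function(lateral_position = 0, angular_model = c("cosine_lobe", "pencil"),
                        tilt_angle = 0, n_packets = 2e6, seed = 1L) {
  angular_model <- match.arg(angular_model)
  stopifnot(n_packets >= 1, tilt_angle >= -90, tilt_angle <= 90)
  structure(list(lateral_position = lateral_position,
                 angular_model = angular_model,
                 tilt_angle = tilt_angle,
                 n_packets = as.double(n_packets),
                 seed = as.integer(seed)),
            class = "source_spec")
}

#' Sample the Henyey-Greenstein deflection cosine
#'
#' Inverse-CDF sampling of \eqn{\cos\theta} for the 3D Henyey-Greenstein
#' phase function with anisotropy `g`; `g = 0` reduces to the isotropic
#' \eqn{2u - 1}.  Vectorized over `u`.
#'
#' @param g Anisotropy, |g| < 1.
#' @param u Uniform variates in \[0, 1).
#' @return Deflection cosines in \[-1, 1\].
#' @export
sample_hg_cosine <- function(g, u) {
  stopifnot(abs(g) < 1)
  if (abs(g) < 1e-12) return(2 * u - 1)
  t <- (1 - g^2) / (1 - g + 2 * g * u)
  pmin(1, pmax(-1, (1 + g^2 - t^2) / (2 * g)))
}

#' Unpolarized Fresnel reflection at a refractive-index step
#'
#' @param n_from,n_to Refractive indices on the incident and transmitted
#'   sides (both >= 1).
#' @param cos_incident Direction cosine with respect to the interface
#'   normal, |cos| <= 1.
#' @return A list with `reflect_probability` (in \[0, 1\]; 1 beyond the
#'   critical angle) and `cos_refracted` (|cos| of the transmitted ray;
#'   `NA` under total internal reflection).
#' @export
fresnel_interface <- function(n_from, n_to, cos_incident) {
  stopifnot(n_from >= 1, n_to >= 1, abs(cos_incident) <= 1)
  ci <- abs(cos_incident)
  if (n_from == n_to) {
    return(list(reflect_probability = 0, cos_refracted = cos_incident))
  }
  st2 <- (n_from / n_to)^2 * (1 - ci^2)
  if (st2 >= 1) {
    return(list(reflect_probability = 1, cos_refracted = NA_real_))
  }
  ct <- sqrt(1 - st2)
  rs <- (n_from * ci - n_to * ct) / (n_from * ci + n_to * ct)
  rp <- (n_from * ct - n_to * ci) / (n_from * ct + n_to * ci)
  list(reflect_probability = 0.5 * (rs^2 + rp^2),
       cos_refracted = sign(cos_incident) * ct)
}

#' Run the layered-slab Monte Carlo transport
#'
#' Transports photon packets from the lumen-surface source through the
#' stack and tallies the diffusely transmitted light leaving the skin
#' surface, binned laterally.  `"planar2D"` confines positions and
#' directions to the x-z plane (planar transport with the symmetrized
#' planar Henyey-Greenstein density); `"slab3D"` is full 3D transport
#' and additionally returns the 2D skin exitance map needed for the
#' off-axis rotation sensors.
#'
#' Both outer media default to air (n = 1) with Fresnel escape; packets
#' wandering beyond `domain_halfwidth` laterally are tallied as lateral
#' escape.  Launched power is normalized to 1 W.
#'
#' @param stack A `tissue_stack`.
#' @param source A `source_spec`.
#' @param dimensionality `"planar2D"` or `"slab3D"`.
#' @param bin_width Lateral bin width, mm.
#' @param domain_halfwidth Lateral half-width of the simulated domain, mm.
#' @param y_halfwidth Half-width of the y-binning range for the 3D map, mm.
#' @param strip_halfwidth 3D only: half-width of the y-strip pooled into
#'   the 1D profile, mm (pooling trades y-resolution for photon
#'   statistics).
#' @param n_outer Length-2 vector: refractive index of the outer medium on
#'   the lumen and skin sides.
#' @return A list with `profile` (an `exitance_profile`) and `tally`
#'   (a `transport_tally`).
#' @export
run_mc <- function(stack, source, dimensionality = c("planar2D", "slab3D"),
                   bin_width = 0.5, domain_halfwidth = 40, y_halfwidth = 8,
                   strip_halfwidth = 2, n_outer = c(1, 1)) {
  if (!inherits(stack, "tissue_stack")) stack <- build_tissue_stack(stack)
  dimensionality <- match.arg(dimensionality)
  stopifnot(bin_width > 0, domain_halfwidth > 0, length(n_outer) == 2)
  if (source$n_packets < 1e4) {
    warning("n_packets < 1e4: exitance profile will be very noisy")
  }
  lay <- as.matrix(stack[, c("thickness_mm", "mu_a", "mu_s", "g", "n")])
  storage.mode(lay) <- "double"
  amod <- if (source$angular_model == "cosine_lobe") 0L else 1L
  tilt <- source$tilt_angle * pi / 180
  set.seed(source$seed)
  if (dimensionality == "planar2D") {
    raw <- .mc_run_2d(lay, source$n_packets, source$lateral_position,
                      amod, tilt, bin_width, domain_halfwidth,
                      n_outer[1], n_outer[2])
    nb <- length(raw$bins)
    centers <- -domain_halfwidth + (seq_len(nb) - 0.5) * bin_width
    intensity <- raw$bins / raw$launched
    y_map <- NULL; y_centers <- NULL
  } else {
    raw <- .mc_run_3d(lay, source$n_packets, source$lateral_position,
                      amod, tilt, bin_width, domain_halfwidth, y_halfwidth,
                      n_outer[1], n_outer[2])
    nbx <- nrow(raw$bins); nby <- ncol(raw$bins)
    centers <- -domain_halfwidth + (seq_len(nbx) - 0.5) * bin_width
    y_centers <- -y_halfwidth + (seq_len(nby) - 0.5) * bin_width
    y_map <- raw$bins / raw$launched
    # 1D profile: power within the central y-strip, per x-bin
    js <- which(abs(y_centers) <= strip_halfwidth)
    intensity <- rowSums(y_map[, js, drop = FALSE])
  }
  profile <- structure(list(bin_centers = centers,
                            intensity = intensity,
                            bin_width = bin_width,
                            dimensionality = dimensionality,
                            smoothing_window = 1L,
                            y_map = y_map,
                            y_centers = y_centers,
                            n_packets = raw$launched,
                            seed = source$seed),
                       class = "exitance_profile")
  tally <- structure(list(launched_weight = 1,
                          absorbed_weight = raw$absorbed / raw$launched,
                          skin_exitance_weight = raw$skin / raw$launched,
                          lumen_reflectance_weight = raw$lumen / raw$launched,
                          lateral_escape_weight = raw$lateral / raw$launched),
                     class = "transport_tally")
  list(profile = profile, tally = tally)
}

#' Build an exitance profile from bins
#'
#' Constructor used by the generator and tests; `run_mc()` builds its own.
#'
#' @param bin_centers Strictly increasing, uniformly spaced centers (mm).
#' @param intensity Non-negative power per bin (W).
#' @param bin_width Bin width (mm); inferred from the centers if missing.
#' @param dimensionality `"planar2D"` or `"slab3D"`.
#' @return An `exitance_profile`.
#' @export
exitance_profile <- function(bin_centers, intensity, bin_width = NULL,
                             dimensionality = "planar2D") {
  stopifnot(length(bin_centers) == length(intensity), all(intensity >= 0),
            all(diff(bin_centers) > 0))
  if (is.null(bin_width)) bin_width <- diff(bin_centers)[1]
  structure(list(bin_centers = as.numeric(bin_centers),
                 intensity = as.numeric(intensity),
                 bin_width = bin_width,
                 dimensionality = dimensionality,
                 smoothing_window = 1L,
                 y_map = NULL, y_centers = NULL,
                 n_packets = NA_real_, seed = NA_integer_),
            class = "exitance_profile")
}

#' Smooth an exitance profile with a centered moving average
#'
#' Interior points use the full window; edges fall back to the available
#' shorter window.  For an even window of width w the offsets are
#' `-floor((w-1)/2) .. +ceiling((w-1)/2)`.
#'
#' @param profile An `exitance_profile`.
#' @param window Window length in bins (>= 1, <= number of bins).
#' @return The smoothed `exitance_profile`, with `smoothing_window` set.
#' @export
smooth_profile <- function(profile, window = 6L) {
  stopifnot(inherits(profile, "exitance_profile"))
  n <- length(profile$intensity)
  window <- as.integer(window)
  if (window < 1L) stop("window must be >= 1", call. = FALSE)
  if (window > n) stop("window exceeds the number of bins", call. = FALSE)
  lo <- floor((window - 1) / 2)
  hi <- ceiling((window - 1) / 2)
  avg <- function(y) {
    vapply(seq_len(n), function(i) {
      mean(y[max(1L, i - lo):min(n, i + hi)])
    }, numeric(1))
  }
  out <- profile
  out$intensity <- avg(profile$intensity)
  if (!is.null(profile$y_map)) {
    out$y_map <- apply(profile$y_map, 2, avg) # smooth along x per y-column
  }
  out$smoothing_window <- window
  out
}

#' Half-intensity half-width of an exitance profile
#'
#' Locates the profile peak and the lateral offsets, left and right of it,
#' at which the linearly interpolated intensity first falls to half the
#' peak value; returns the mean of the two offsets.
#'
#' @param profile An `exitance_profile` (smooth it first for Monte Carlo
#'   output).
#' @return Half-width in mm.
#' @export
half_intensity_halfwidth <- function(profile) {
  stopifnot(inherits(profile, "exitance_profile"))
  x <- profile$bin_centers
  y <- profile$intensity
  ipk <- which.max(y)
  if (ipk == 1L || ipk == length(y)) {
    stop("profile peak sits on the domain edge; enlarge the domain", call. = FALSE)
  }
  half <- y[ipk] / 2
  cross <- function(idx) {
    # first index along idx where y drops below half, interpolated
    for (k in seq_along(idx)[-1]) {
      i1 <- idx[k - 1]; i2 <- idx[k]
      if (y[i2] <= half && y[i1] > half) {
        frac <- (y[i1] - half) / (y[i1] - y[i2])
        return(abs((x[i1] + frac * (x[i2] - x[i1])) - x[ipk]))
      }
    }
    NA_real_
  }
  right <- cross(ipk:length(y))
  left <- cross(ipk:1)
  if (is.na(right) || is.na(left)) {
    stop("no half-intensity crossing found on both sides of the peak", call. = FALSE)
  }
  mean(c(left, right))
}

#' Simulated voltage-ratio curves versus tube displacement
#'
#' Samples an exitance profile at the three axial sensor positions for a
#' grid of tube displacements and returns the two working ratios
#' r12 = I(P1)/I(P2) and r32 = I(P3)/I(P2).  Displacing the tube by d
#' moves the light spot to lateral position d (positive d = tube pushed
#' inward = spot moves toward P3).
#'
#' @param stack A `tissue_stack`; ignored when `profile` is supplied.
#' @param source A `source_spec`; ignored when `profile` is supplied.
#' @param geometry A [sensor_geometry()].
#' @param displacements Displacement grid (mm).
#' @param dimensionality Passed to [run_mc()] when a run is needed.
#' @param profile Optional precomputed `exitance_profile` (smoothed or
#'   raw); avoids re-running the transport.
#' @param smoothing_window Moving-average window applied when the profile
#'   is computed here.
#' @param ... Further arguments to [run_mc()].
#' @return A data frame with columns `d`, `r12`, `r32`.
#' @export
simulate_ratio_curves <- function(stack, source, geometry, displacements,
                                  dimensionality = "planar2D", profile = NULL,
                                  smoothing_window = 6L, ...) {
  if (is.null(profile)) {
    profile <- run_mc(stack, source, dimensionality = dimensionality, ...)$profile
    profile <- smooth_profile(profile, smoothing_window)
  }
  rows <- lapply(displacements, function(d) {
    I <- sensor_intensities(profile, geometry, d)
    data.frame(d = d, r12 = I[1] / I[2], r32 = I[3] / I[2])
  })
  do.call(rbind, rows)
}

#' @export
print.tissue_stack <- function(x, ...) {
  cat("Tissue stack (lumen -> skin), total thickness",
      attr(x, "total_thickness"), "mm\n")
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' @export
print.transport_tally <- function(x, ...) {
  cat(sprintf(paste0("Transport tally (fractions of 1 W launched)\n",
                     "  absorbed: %.4f  skin exitance: %.4f\n",
                     "  lumen reflectance: %.4f  lateral escape: %.4f\n"),
              x$absorbed_weight, x$skin_exitance_weight,
              x$lumen_reflectance_weight, x$lateral_escape_weight))
  invisible(x)
}
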