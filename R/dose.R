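# Simplified heterogeneity-aware photon dose engine: primary-photon
# exponential attenuation along Siddon radiological paths, inverse-square
# fall-off, and a Gaussian-smoothed square aperture.  Deliberately not a
# convolution/superposition algorithm: it is deterministic, desk-scale,
# and sensitive to electron-density errors, which is the quantity the
# pseudo-CT verification has to expose.

#' Convert Hounsfield units to relative electron density
#'
#' Piecewise-linear calibration through (-1000 HU, 0.0), (0 HU, 1.0),
#' (1500 HU, 1.85), clamped outside that range.
#'
#' @param hu numeric vector of finite HU; out-of-scan sentinel values (NA)
#'   are an error - the volume must be corrected first.
#' @return relative electron density (water = 1).
#' @export
hu_to_density <- function(hu) {
  if (anyNA(hu))
    stop("sentinel (NA) HU cannot be converted; correct the volume first",
         call. = FALSE)
  lo <- pmax(pmin(hu, 1500), -1000)
  ifelse(lo <= 0, 1 + lo / 1000, 1 + lo * (0.85 / 1500))
}

density_volume <- function(ct) {
  stopifnot(ct$modality == "CT")
  d <- ct
  d$data <- array(hu_to_density(ct$data), dim = dim(ct$data))
  d
}

#' Radiological (water-equivalent) path length
#'
#' Exact Siddon-style line integral of relative electron density over the
#' voxels traversed by the segment from `src` to `dst`; density outside
#' the grid counts as 0.
#'
#' @param density [image_volume()] of relative electron density.
#' @param src,dst physical endpoints, mm (length-3).
#' @return water-equivalent depth in cm.
#' @export
radiological_path <- function(density, src, dst) {
  src <- as.numeric(src); dst <- as.numeric(dst)
  if (sqrt(sum((dst - src)^2)) < 1e-9)
    stop("degenerate zero-length ray", call. = FALSE)
  if (anyNA(density$data))
    stop("density volume contains sentinel voxels", call. = FALSE)
  wepl_mm <- .ray_wepl_cpp(as.numeric(density$data),
                           as.integer(dim(density$data)),
                           density$spacing, density$origin,
                           density$direction, src, dst)
  wepl_mm / 10
}

#' Treatment beam specification
#'
#' Beam geometry follows the usual couch/gantry convention for a
#' supine patient in LPS coordinates: the source sits at
#' `isocenter + SAD * u(gantry, couch)` with
#' `u = (sin g cos c, -cos g, sin g sin c)`, so gantry 0 is an anterior
#' beam, couch 0 keeps the beam in the axial plane, and a non-zero couch
#' angle tips a lateral beam towards the vertex.
#'
#' @param gantry_deg,couch_deg beam angles in degrees.
#' @param isocenter_mm physical isocenter, mm.
#' @param sad_mm source-axis distance, default 1000 mm.
#' @param field_mm square field side at the isocenter plane, mm.
#' @param weight non-negative relative beam weight.
#' @param mu_cm attenuation coefficient per cm water, default 0.05
#'   (a 6 MV-like primary beam magnitude).
#' @param penumbra_sigma_mm Gaussian penumbra sigma, default 3 mm.
#' @return a `beam_spec`.
#' @export
beam_spec <- function(gantry_deg, couch_deg = 0,
                      isocenter_mm = c(0, 0, 0), sad_mm = 1000,
                      field_mm = 40, weight = 1, mu_cm = 0.05,
                      penumbra_sigma_mm = 3) {
  if (weight < 0) stop("beam weight must be >= 0", call. = FALSE)
  if (field_mm <= 0) stop("field side must be positive", call. = FALSE)
  if (mu_cm <= 0) stop("attenuation coefficient must be positive",
                       call. = FALSE)
  structure(list(gantry_deg = gantry_deg, couch_deg = couch_deg,
                 isocenter_mm = as.numeric(isocenter_mm),
                 sad_mm = sad_mm, field_mm = field_mm, weight = weight,
                 mu_cm = mu_cm, penumbra_sigma_mm = penumbra_sigma_mm),
            class = "beam_spec")
}

beam_source_unit <- function(beam) {
  g <- beam$gantry_deg * pi / 180
  c_ <- beam$couch_deg * pi / 180
  c(sin(g) * cos(c_), -cos(g), sin(g) * sin(c_))
}

beam_frame <- function(beam) {
  u <- beam_source_unit(beam)
  src <- beam$isocenter_mm + beam$sad_mm * u
  e3 <- -u                      # beam travel direction (source -> iso)
  ref <- if (abs(e3[3]) < 0.9) c(0, 0, 1) else c(0, 1, 0)
  e1 <- ref - sum(ref * e3) * e3
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(e3[2] * e1[3] - e3[3] * e1[2],
          e3[3] * e1[1] - e3[1] * e1[3],
          e3[1] * e1[2] - e3[2] * e1[1])
  list(src = src, e1 = e1, e2 = e2, e3 = e3)
}

#' Dose of a single beam on a density grid
#'
#' `D(p) = weight * exp(-mu * d_eff(p)) * (SAD / r(p))^2 * f_lateral(p)`
#' with `d_eff` the radiological path from the source, `r` the source
#' distance and `f_lateral` a Gaussian-smoothed square aperture projected
#' to the isocenter plane.
#'
#' @param density relative electron density [image_volume()].
#' @param beam a [beam_spec()].
#' @param inverse_square,penumbra logical switches, both on by default
#'   (useful off for closed-form checks).
#' @return dose [image_volume()] (modality DOSE), same grid as `density`.
#' @export
compute_beam_dose <- function(density, beam, inverse_square = TRUE,
                              penumbra = TRUE) {
  if (anyNA(density$data))
    stop("density volume contains sentinel voxels", call. = FALSE)
  fr <- beam_frame(beam)
  dose <- .beam_dose_cpp(as.numeric(density$data),
                         as.integer(dim(density$data)),
                         density$spacing, density$origin,
                         density$direction, fr$src, fr$e1, fr$e2, fr$e3,
                         beam$sad_mm, beam$field_mm / 2,
                         beam$penumbra_sigma_mm, beam$mu_cm / 10,
                         beam$weight, inverse_square, penumbra)
  image_volume(array(dose, dim = dim(density$data)), density$spacing,
               density$origin, density$direction, modality = "DOSE")
}

#' Construct a 5-beam plan avoiding the unscanned region
#'
#' Four coplanar beams (couch 0) plus one non-coplanar beam aimed from the
#' vertex side, isocenter at the PTV centroid, field side covering the PTV
#' with a margin.  Any candidate beam whose entry ray (source to
#' isocenter) crosses the unscanned region is rotated in gantry, in 5
#' degree steps alternating around the nominal angle, to the nearest
#' admissible angle.
#'
#' @param ptv PTV [binary_mask()].
#' @param unscanned unscanned-region [binary_mask()] on the same grid (may
#'   be empty).
#' @param config list: `gantry_deg` (4 coplanar angles), `noncoplanar`
#'   (list with `gantry_deg`, `couch_deg`), `sad_mm`, `mu_cm`,
#'   `penumbra_sigma_mm`, `field_margin_mm`, `prescription` label.
#' @return an `rt_plan`: list of 5 [beam_spec()]s plus normalization state.
#' @export
make_plan <- function(ptv, unscanned = NULL, config = list()) {
  cfg <- modifyList(list(gantry_deg = c(40, 115, 245, 320),
                         noncoplanar = list(gantry_deg = 90,
                                            couch_deg = 75),
                         sad_mm = 1000, mu_cm = 0.05,
                         penumbra_sigma_mm = 3, field_margin_mm = 3),
                    config)
  on <- which(ptv$data > 0)
  if (length(on) == 0) stop("empty PTV", call. = FALSE)
  d <- dim(ptv$data)
  idx <- cbind((on - 1) %% d[1],
               ((on - 1) %/% d[1]) %% d[2],
               (on - 1) %/% (d[1] * d[2]))
  pts <- index_to_physical(ptv, idx)
  iso <- colMeans(pts)
  half_extent <- max(sqrt(rowSums(sweep(pts, 2, iso)^2)))
  field <- 2 * (half_extent + cfg$field_margin_mm)

  mk <- function(g, c_) beam_spec(g, c_, iso, cfg$sad_mm, field, 1,
                                  cfg$mu_cm, cfg$penumbra_sigma_mm)
  angles <- c(cfg$gantry_deg, cfg$noncoplanar$gantry_deg)
  couch <- c(rep(0, length(cfg$gantry_deg)), cfg$noncoplanar$couch_deg)
  beams <- vector("list", length(angles))
  for (b in seq_along(angles)) {
    beams[[b]] <- admissible_beam(mk, angles[b], couch[b], unscanned)
  }
  structure(list(beams = beams, isocenter_mm = iso,
                 normalization = NULL, weights = rep(1, length(beams))),
            class = "rt_plan")
}

# entry ray (source -> isocenter) must not cross the unscanned mask
beam_enters_unscanned <- function(beam, unscanned) {
  if (is.null(unscanned) || !any(unscanned$data > 0)) return(FALSE)
  fr <- beam_frame(beam)
  mask_density <- unscanned
  mask_density$modality <- "CT"
  path <- .ray_wepl_cpp(as.numeric(unscanned$data),
                        as.integer(dim(unscanned$data)),
                        unscanned$spacing, unscanned$origin,
                        unscanned$direction, fr$src, beam$isocenter_mm)
  path > 1e-6
}

admissible_beam <- function(mk, gantry, couch, unscanned) {
  for (step in 0:36) {
    for (sgn in if (step == 0) 1 else c(1, -1)) {
      cand <- mk((gantry + sgn * 5 * step) %% 360, couch)
      if (!beam_enters_unscanned(cand, unscanned)) return(cand)
    }
  }
  stop("planning error: no admissible beam angle avoids the unscanned region",
       call. = FALSE)
}

#' @export
print.rt_plan <- function(x, ...) {
  cat(sprintf("<rt_plan> %d beams, isocenter (%.1f, %.1f, %.1f) mm\n",
              length(x$beams), x$isocenter_mm[1], x$isocenter_mm[2],
              x$isocenter_mm[3]))
  for (b in x$beams)
    cat(sprintf("  gantry %5.1f  couch %5.1f  field %.0f mm  weight %.3f\n",
                b$gantry_deg, b$couch_deg, b$field_mm, b$weight))
  if (!is.null(x$normalization))
    cat(sprintf("  normalization factor %.5f (D95 = 100%%)\n",
                x$normalization))
  invisible(x)
}

# dose level such that exactly ceil(0.95 n) PTV voxels are at or above it
d95_level <- function(dose_ptv) {
  n <- length(dose_ptv)
  k <- ceiling(0.95 * n)
  sort(dose_ptv, decreasing = TRUE)[k]
}

#' Compute the plan dose on a CT, optimizing weights and normalizing
#'
#' Per-beam doses are computed once; beam weights are then adjusted by a
#' bounded multiplicative loop (at most 50 iterations) pushing the maximum
#' PTV dose to at most 110% of prescription, and a final global
#' normalization sets D95(PTV) = 100% exactly.  The returned plan carries
#' the optimized weights and the frozen normalization factor so the same
#' plan can be recomputed unchanged on another CT
#' (see [recompute_plan_dose()]).
#'
#' @param ct corrected, sentinel-free CT [image_volume()].
#' @param plan an `rt_plan` from [make_plan()].
#' @param ptv PTV [binary_mask()] on the same grid.
#' @return list with `dose` (a DOSE [image_volume()], % of prescription)
#'   and `plan` (the plan with final weights and normalization).
#' @export
compute_plan_dose <- function(ct, plan, ptv) {
  stop_grid_mismatch(ct, ptv, "ct and ptv")
  dens <- density_volume(ct)
  per_beam <- lapply(plan$beams, function(b) {
    b$weight <- 1
    compute_beam_dose(dens, b)$data
  })
  in_ptv <- ptv$data > 0
  if (!any(vapply(per_beam, function(db) any(db[in_ptv] > 1e-9),
                  logical(1))))
    stop("planning error: PTV outside all fields", call. = FALSE)

  w <- plan$weights
  w <- w / mean(w)
  for (iter in 1:50) {
    total <- Reduce(`+`, Map(`*`, per_beam, w))
    dptv <- total[in_ptv]
    scale <- 100 / d95_level(dptv)
    mx <- max(dptv) * scale
    if (mx <= 110 + 1e-9) break
    hot <- which.max(dptv)
    shares <- vapply(seq_along(w),
                     function(b) w[b] * per_beam[[b]][in_ptv][hot],
                     numeric(1))
    shares <- shares / sum(shares)
    w <- w * (110 / mx)^shares
    w <- w / mean(w)
  }
  total <- Reduce(`+`, Map(`*`, per_beam, w))
  norm <- 100 / d95_level(total[in_ptv])
  out <- image_volume(total * norm, ct$spacing, ct$origin, ct$direction,
                      "DOSE")
  plan$weights <- w
  plan$normalization <- norm
  for (b in seq_along(plan$beams)) plan$beams[[b]]$weight <- w[b]
  list(dose = out, plan = plan)
}

#' Recompute a frozen plan on another CT
#'
#' Uses the plan's stored beam weights and normalization factor unchanged
#' (no re-optimization, no re-normalization): the verification-plan
#' contract.
#'
#' @param ct sentinel-free CT [image_volume()] on the planning grid.
#' @param plan an `rt_plan` that has been through [compute_plan_dose()].
#' @return dose [image_volume()], % of prescription.
#' @export
recompute_plan_dose <- function(ct, plan) {
  if (is.null(plan$normalization))
    stop("plan has not been normalized yet; run compute_plan_dose first",
         call. = FALSE)
  dens <- density_volume(ct)
  total <- Reduce(`+`, lapply(plan$beams, function(b) {
    compute_beam_dose(dens, b)$data
  }))
  image_volume(total * plan$normalization, ct$spacing, ct$origin,
               ct$direction, "DOSE")
}
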