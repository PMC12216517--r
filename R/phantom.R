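#' Specification of a hollow-tube phantom
#'
#' Describes a synthetic hollow tube standing in for the rectal wall/lumen:
#' a bright annular wall around a dark lumen, embedded in an intermediate
#' background, with optional planted wall displacement of known amplitude and
#' direction (the analytic ground truth for the deformation descriptors).
#'
#' Deformation semantics: `"inward_radial"` moves the entire wall toward the
#' lumen centerline by `amplitude` mm (tumor regressing / intruding inward),
#' `"outward_radial"` moves it away from the centerline (growth into
#' surrounding fat), `"mixed"` alternates inward/outward across angular
#' sectors, `"none"` plants a zero field. `angular_extent` (radians, centered
#' at angle 0) and `axial_extent` (fraction of sections, centered) restrict
#' where the deformation applies; within that support the amplitude is
#' constant so the planted magnitude is exactly `amplitude`.
#'
#' @param shape voxel grid, default `c(96, 96, 24)`.
#' @param spacing mm per voxel, default the working resolution
#'   `c(0.781, 0.781, 4)`.
#' @param inner_radius,outer_radius lumen and wall outer radii in mm (at the
#'   tube's mid-length).
#' @param taper amplitude of the mid-length wall-thickness bump (mm; the
#'   thickness grows by `taper / 4` at the tube center, at constant
#'   mid-radius). The bump anchors axial correspondence during registration
#'   and places the largest-wall-area section mid-tube, where planted
#'   deformations are centered.
#' @param curvature amplitude (mm) of a sinusoidal centerline bow in x.
#' @param deformation one of `"none"`, `"inward_radial"`, `"outward_radial"`,
#'   `"mixed"` (half the circumference pushed outward, the opposite half
#'   inward: a one-sided bulge with luminal intrusion opposite).
#' @param amplitude planted displacement in mm.
#' @param angular_extent angular support of the deformation in radians
#'   (`2 * pi` = whole circumference).
#' @param axial_extent fraction of the tube length affected, in (0, 1].
#' @param noise_sd additive Gaussian intensity noise SD.
#' @param heterogeneity amplitude of smooth lesion-like intensity texture
#'   inside the wall.
#' @param seed integer seed controlling noise and texture.
#' @return a `phantom_spec` list.
#' @export
tube_phantom_spec <- function(shape = c(96, 96, 24),
                              spacing = c(0.781, 0.781, 4),
                              inner_radius = 8, outer_radius = 12,
                              taper = 4, curvature = 0,
                              deformation = c("none", "inward_radial",
                                              "outward_radial", "mixed"),
                              amplitude = 0, angular_extent = 2 * pi,
                              axial_extent = 1, noise_sd = 0.05,
                              heterogeneity = 0, seed = 1L) {
  deformation <- match.arg(deformation)
  if (!(outer_radius > inner_radius && inner_radius > 0))
    stop("need outer_radius > inner_radius > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  if (deformation %in% c("inward_radial", "mixed") &&
      amplitude >= inner_radius - abs(taper) / 2)
    stop("inward amplitude would collapse the wall through the centerline")
  structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                 inner_radius = inner_radius, outer_radius = outer_radius,
                 taper = taper, curvature = curvature,
                 deformation = deformation,
                 amplitude = amplitude, angular_extent = angular_extent,
                 axial_extent = axial_extent, noise_sd = noise_sd,
                 heterogeneity = heterogeneity, seed = as.integer(seed)),
            class = "phantom_spec")
}

# smooth [0,1] ramp used at deformation support edges (measure-zero effect
# when extents are full)
taper01 <- function(u) ifelse(u <= 0, 0, ifelse(u >= 1, 1, u * u * (3 - 2 * u)))

# planted radial displacement (mm, signed: negative = inward) at angle phi,
# section fraction fz
planted_amplitude <- function(spec, phi, fz) {
  if (spec$deformation == "none" || spec$amplitude == 0)
    return(rep(0, length(phi)))
  half_ang <- spec$angular_extent / 2
  dphi <- abs(((phi + pi) %% (2 * pi)) - pi)
  in_ang <- dphi <= half_ang
  half_ax <- spec$axial_extent / 2
  in_ax <- abs(fz - 0.5) <= half_ax
  a <- ifelse(in_ang & in_ax, spec$amplitude, 0)
  sgn <- switch(spec$deformation,
                inward_radial = rep(-1, length(phi)),
                outward_radial = rep(1, length(phi)),
                mixed = ifelse(sin(phi) >= 0, 1, -1))
  a * sgn
}

#' Generate a hollow-tube phantom with analytic deformation ground truth
#'
#' Builds the deformed patient image and mask plus the exact planted
#' [deformation_field()] on the canonical (undeformed) grid: at every
#' canonical wall voxel the ground-truth vector is the displacement that
#' carried that material point into the deformed tube, so its norm and its
#' angle to the lumen centroid are exactly computable.
#'
#' @param spec a [tube_phantom_spec()].
#' @return list with `volume`, `mask` (both deformed), `field` (ground truth
#'   on the canonical grid), and `canonical` (undeformed volume + mask).
#' @export
make_tube <- function(spec) {
  d <- spec$shape
  sp <- spec$spacing
  origin <- c(0, 0, 0)
  # physical coordinate grids
  xs <- (seq_len(d[1]) - 1) * sp[1]
  ys <- (seq_len(d[2]) - 1) * sp[2]
  zs <- (seq_len(d[3]) - 1) * sp[3]
  cx0 <- mean(range(xs))
  cy0 <- mean(range(ys))
  fz <- if (d[3] > 1) (seq_len(d[3]) - 1) / (d[3] - 1) else 0.5

  set.seed(spec$seed)
  het_phase <- runif(2, 0, 2 * pi)

  build <- function(deformed) {
    vox <- array(0.45, dim = d)
    lab <- array(LABEL_BACKGROUND, dim = d)
    for (k in seq_len(d[3])) {
      cx <- cx0 + spec$curvature * sin(pi * fz[k])
      dx <- outer(xs - cx, rep(1, d[2]))
      dy <- outer(rep(1, d[1]), ys - cy0)
      r <- sqrt(dx^2 + dy^2)
      phi <- atan2(dy, dx)
      a <- if (deformed)
        matrix(planted_amplitude(spec, as.vector(phi), fz[k]), d[1], d[2])
      else matrix(0, d[1], d[2])
      # wall thickness peaks at mid-length at constant mid-radius: anchors
      # axial correspondence (a z-shift misplaces the bump) without being
      # expressible as a radial displacement, and keeps the largest-wall-area
      # section at the tube center where planted deformations live
      tap <- spec$taper * (0.5 - abs(fz[k] - 0.5)) / 2
      rin <- spec$inner_radius - tap + a
      rout <- spec$outer_radius + tap + a
      wall <- r >= rin & r < rout
      lumen <- r < rin
      sl <- matrix(0.45, d[1], d[2])
      sl[lumen] <- 0.1
      wallint <- 1.0
      if (spec$heterogeneity > 0) {
        tex <- spec$heterogeneity *
          sin(2 * phi + het_phase[1]) * cos(2 * pi * (r / spec$outer_radius) +
                                            het_phase[2])
        sl[wall] <- wallint + tex[wall]
      } else sl[wall] <- wallint
      vox[, , k] <- sl
      lk <- matrix(LABEL_BACKGROUND, d[1], d[2])
      lk[wall] <- LABEL_WALL
      lk[lumen] <- LABEL_LUMEN
      lab[, , k] <- lk
    }
    if (spec$noise_sd > 0)
      vox <- vox + array(rnorm(prod(d), 0, spec$noise_sd), dim = d)
    list(volume = image_volume(vox, sp, origin),
         mask = annotation_mask(lab, sp, origin))
  }

  set.seed(spec$seed)
  canonical <- build(deformed = FALSE)
  set.seed(spec$seed + 1L)
  deformed <- build(deformed = TRUE)

  # exact ground-truth field at canonical wall voxels
  vecs <- array(0, dim = c(d, 3))
  roi <- canonical$mask$labels == LABEL_WALL
  idx <- which_voxels(roi)
  if (nrow(idx) > 0) {
    cxk <- cx0 + spec$curvature * sin(pi * fz[idx[, 3]])
    px <- xs[idx[, 1]] - cxk
    py <- ys[idx[, 2]] - cy0
    phi <- atan2(py, px)
    a <- planted_amplitude(spec, phi, fz[idx[, 3]])
    ux <- a * cos(phi)
    uy <- a * sin(phi)
    vecs[cbind(idx, 1)] <- ux
    vecs[cbind(idx, 2)] <- uy
  }
  field <- deformation_field(vecs, roi = roi, spacing = sp, origin = origin)
  list(volume = deformed$volume, mask = deformed$mask, field = field,
       canonical = canonical)
}

#' Generate a labeled phantom cohort
#'
#' Emits a cohort of tube phantoms with per-subject geometric jitter and a
#' planted class contrast: "responder" phantoms get low-amplitude inward-only
#' wall displacement (regressed tumors resemble the non-diseased tube), while
#' "non-responder" phantoms get high-amplitude mixed inward/outward
#' displacement (variable structural change in both directions).
#'
#' Default effect sizes: responders 0.8 mm inward (SD 0.3), non-responders
#' 4 mm mixed (SD 1), against an 8/12 mm lumen/wall geometry — sub-voxel
#' change versus wall-thickness-scale change.
#'
#' @param n cohort size (>= 2).
#' @param class_mix responder fraction in (0, 1); the study composition is
#'   0.36.
#' @param seed integer seed.
#' @param responder_amplitude,nonresponder_amplitude mean planted amplitudes
#'   (mm).
#' @param noise_sd,heterogeneity passed to [tube_phantom_spec()].
#' @param shape,spacing grid geometry.
#' @return list with `specs` (list of [tube_phantom_spec()]) and `manifest`
#'   (data.frame of id, label and acquisition metadata).
#' @export
make_cohort <- function(n, class_mix = 0.36, seed = 1L,
                        responder_amplitude = 0.8,
                        nonresponder_amplitude = 4,
                        noise_sd = 0.05, heterogeneity = 0.25,
                        shape = c(96, 96, 24),
                        spacing = c(0.781, 0.781, 4)) {
  if (n < 2) stop("cohort size must be >= 2")
  if (class_mix <= 0 || class_mix >= 1) stop("class_mix must be in (0, 1)")
  set.seed(seed)
  n_resp <- max(1L, min(n - 1L, as.integer(round(n * class_mix))))
  label <- c(rep("responder", n_resp), rep("non-responder", n - n_resp))
  specs <- vector("list", n)
  for (i in seq_len(n)) {
    resp <- label[i] == "responder"
    rin <- runif(1, 7, 9)
    amp <- if (resp) max(0.2, rnorm(1, responder_amplitude, 0.3))
           else max(1.5, min(rin - 3, rnorm(1, nonresponder_amplitude, 1)))
    rout <- rin + runif(1, 3.5, 4.5)
    het <- if (resp) heterogeneity * runif(1, 0.2, 0.6)
           else heterogeneity * runif(1, 0.8, 1.6)
    specs[[i]] <- tube_phantom_spec(
      shape = shape, spacing = spacing, inner_radius = rin,
      outer_radius = rout, curvature = runif(1, 0, 2),
      deformation = if (resp) "inward_radial" else "mixed",
      amplitude = amp, angular_extent = 2 * pi,
      axial_extent = runif(1, 0.7, 1), noise_sd = noise_sd,
      heterogeneity = het, seed = seed * 1000L + i)
  }
  manifest <- data.frame(
    id = sprintf("P%03d", seq_len(n)),
    label = label,
    institution = sample(c("inst1", "inst2"), n, replace = TRUE),
    scanner = sample(c("vendorA", "vendorB"), n, replace = TRUE),
    sex = sample(c("male", "female"), n, replace = TRUE, prob = c(0.6, 0.4)),
    field_strength = sample(c("1.5T", "3T"), n, replace = TRUE),
    annotation = sample(c("manual", "automated"), n, replace = TRUE,
                        prob = c(0.75, 0.25)),
    ctnm = ifelse(label == "responder",
                  sample(2:3, n, replace = TRUE),
                  sample(3:4, n, replace = TRUE)),
    stringsAsFactors = FALSE)
  list(specs = specs, manifest = manifest)
}

#' Generate synthetic immune-cell count tables
#'
#' Emulates a multiplex-immunohistology cell-count table (CD8+ T cells, CD4+
#' T cells, regulatory T cells, macrophages) whose columns are monotone
#' functions of chosen feature columns plus noise, so planted radiomic-biology
#' correlations are recoverable by [spearman_fdr_map()].
#'
#' @param features data.frame/matrix of radiomic features (rows = patients).
#' @param coupling numeric matrix (cell types x features) of target Spearman
#'   strengths in `[-1, 1]`; 0 plants independence.
#' @param seed integer seed.
#' @return data.frame of normalized cell counts, one row per patient.
#' @export
make_cell_counts <- function(features,
                             coupling = matrix(0, 4, ncol(features)),
                             seed = 1L) {
  features <- as.matrix(features)
  n <- nrow(features)
  cells <- c("CD8", "CD4", "Treg", "macrophage")
  if (nrow(coupling) != length(cells) || ncol(coupling) != ncol(features))
    stop("coupling must be 4 x ncol(features)")
  set.seed(seed)
  z <- scale(features)
  z[!is.finite(z)] <- 0
  out <- matrix(0, n, length(cells), dimnames = list(NULL, cells))
  for (ci in seq_along(cells)) {
    signal <- as.vector(z %*% coupling[ci, ])
    s2 <- sum(coupling[ci, ]^2)
    noise_sd <- if (s2 >= 1) 0.05 else sqrt(1 - s2)
    raw <- signal + rnorm(n, 0, noise_sd)
    out[, ci] <- exp(raw)                     # monotone, count-like, positive
  }
  as.data.frame(sweep(out, 2, colSums(out), "/") * 100)  # normalized counts
}
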