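# Synthetic CT phantoms with ground truth. Geometry is specified in
# continuous 1-based voxel coordinates (centres of voxels are at integer
# positions); HU classes follow typical CT values: background air -1000,
# soft tissue ~40, trabecular/cortical bone ~1200, metal implants ~3200,
# decompositional gas ~-800, table shell ~300.

#' Phantom specification
#'
#' Parametric description of a synthetic CT volume: background air, an
#' ellipsoidal soft-tissue body optionally enclosing gas pockets, bones and
#' metal objects, optional gas channels (used to model an open airway that
#' connects interior gas to the outside), and an optional scanner table —
#' an arc-shaped shell below the body whose interior is either hollow
#' (air-filled, watertight, unreachable from the volume corners) or solid.
#'
#' Coordinates and radii are in voxel units. Objects are painted in the
#' order background, table, body, bones, metal, gas; later classes
#' overwrite earlier ones. Optional Gaussian HU noise (clipped at three
#' standard deviations) may be added; the spec is rejected if the noise
#' could move any painted class across a default decision threshold
#' (-200, -220 or +2800 HU), so ground-truth masks stay exact.
#'
#' @param shape Integer length-3 volume dimensions (x, y, z voxels).
#' @param spacing Numeric length-3 voxel spacing in mm.
#' @param background_hu Background air HU.
#' @param body `list(center, radii, hu)` for the body ellipsoid, or `NULL`.
#' @param bones List of `list(type = "sphere"|"cylinder_z", center, radius,
#'   hu, zrange)` elements (`zrange` for cylinders).
#' @param metal_objects,gas_pockets Lists of spheres
#'   (`list(center, radius, hu)`); must lie strictly inside the body.
#' @param gas_channels List of z-aligned cylinders
#'   (`list(center_xy, radius, zrange, hu)`); may pierce the body surface.
#' @param table `NULL` or `list(center_xy, r_in, r_out, wall,
#'   arc_half_deg, cavity_half_deg, shell_hu, cavity_hu, hollow)`.
#' @param noise_sd Gaussian noise standard deviation in HU (0 = none).
#' @param rng_seed Integer seed making the noise reproducible.
#' @return An object of class `phantom_spec`.
#' @export
phantom_spec <- function(shape,
                         spacing = c(1, 1, 1),
                         background_hu = -1000,
                         body = NULL,
                         bones = list(),
                         metal_objects = list(),
                         gas_pockets = list(),
                         gas_channels = list(),
                         table = NULL,
                         noise_sd = 0,
                         rng_seed = 1L) {
  spec <- structure(
    list(shape = as.integer(shape), spacing = as.double(spacing),
         background_hu = as.double(background_hu), body = body,
         bones = bones, metal_objects = metal_objects,
         gas_pockets = gas_pockets, gas_channels = gas_channels,
         table = table, noise_sd = as.double(noise_sd),
         rng_seed = as.integer(rng_seed)),
    class = "phantom_spec"
  )
  validate_phantom_spec(spec)
}

spec_error <- function(...) stop("invalid phantom spec: ", ..., call. = FALSE)

validate_phantom_spec <- function(spec) {
  d <- spec$shape
  if (length(d) != 3L || any(d < 2L))
    spec_error("`shape` must be 3 dimensions of at least 2 voxels")
  if (any(spec$spacing <= 0))
    spec_error("`spacing` must be strictly positive")
  if (spec$noise_sd < 0)
    spec_error("`noise_sd` must be non-negative")
  in_bounds <- function(lo, hi, what) {
    if (any(lo < 1) || any(hi > d))
      spec_error(what, " extends outside the volume bounds")
  }
  if (!is.null(spec$body)) {
    b <- spec$body
    in_bounds(b$center - b$radii, b$center + b$radii, "body ellipsoid")
  }
  for (s in c(spec$metal_objects, spec$gas_pockets)) {
    in_bounds(s$center - s$radius, s$center + s$radius, "sphere")
    if (is.null(spec$body))
      spec_error("gas pockets and metal objects require a body")
    b <- spec$body
    rel <- sqrt(sum(((s$center - b$center) / b$radii)^2))
    if (rel + s$radius / min(b$radii) > 0.97)
      spec_error("gas pockets and metal objects must lie strictly inside ",
                 "the body ellipsoid")
  }
  for (cyl in spec$gas_channels)
    in_bounds(c(cyl$center_xy - cyl$radius, min(cyl$zrange)),
              c(cyl$center_xy + cyl$radius, max(cyl$zrange)), "gas channel")
  if (!is.null(spec$table)) {
    tb <- spec$table
    if (tb$r_in >= tb$r_out) spec_error("table needs r_in < r_out")
    if (isTRUE(tb$hollow)) {
      if (tb$r_out - tb$r_in <= 2 * tb$wall)
        spec_error("hollow table shell leaves no room for a cavity")
      if (tb$cavity_half_deg >= tb$arc_half_deg)
        spec_error("table cavity arc must be narrower than the shell arc")
    }
    reach <- tb$r_out * sin(tb$arc_half_deg * pi / 180)
    in_bounds(c(tb$center_xy[1] - reach, tb$center_xy[2], 1),
              c(tb$center_xy[1] + reach, tb$center_xy[2] + tb$r_out, 1),
              "table arc")
  }
  spec
}

# voxel-centre coordinate grids
coord_grids <- function(d) {
  list(
    x = array(seq_len(d[1]), d),
    y = array(rep(seq_len(d[2]), each = d[1]), d),
    z = array(rep(seq_len(d[3]), each = d[1] * d[2]), d)
  )
}

CLASS_BACKGROUND <- 0L
CLASS_TABLE_SHELL <- 1L
CLASS_TABLE_CAVITY <- 2L
CLASS_BODY <- 3L
CLASS_BONE <- 4L
CLASS_METAL <- 5L
CLASS_GAS <- 6L

#' Generate a phantom volume with ground truth
#'
#' Renders a [phantom_spec()] into a [ct_volume()] plus ground-truth masks:
#' `exterior_air_mask` (background air and the hollow table cavity),
#' `interior_gas_mask` (gas pockets and channels) and `metal_mask`. The
#' masks are pairwise disjoint by construction. With the same spec
#' (including `rng_seed`) the output is bit-identical across calls.
#'
#' @param spec A [phantom_spec()].
#' @return A list with elements `volume` ([ct_volume()]), `truth` (list of
#'   the three logical mask arrays) and `labels` (integer class array:
#'   0 background, 1 table shell, 2 table cavity, 3 body, 4 bone, 5 metal,
#'   6 gas).
#' @export
generate_phantom <- function(spec) {
  spec <- validate_phantom_spec(spec)
  d <- spec$shape
  g <- coord_grids(d)
  cls <- array(CLASS_BACKGROUND, d)
  hu <- array(spec$background_hu, d)

  paint <- function(mask, class_id, value) {
    cls[mask] <<- class_id
    hu[mask] <<- value
  }

  if (!is.null(spec$table)) {
    tb <- spec$table
    dx <- g$x - tb$center_xy[1]
    dy <- g$y - tb$center_xy[2]
    r <- sqrt(dx^2 + dy^2)
    phi <- atan2(abs(dx), dy) * 180 / pi    # angle from the posterior axis
    band <- r >= tb$r_in & r <= tb$r_out & phi <= tb$arc_half_deg
    shell_hu <- if (is.null(tb$shell_hu)) 300 else tb$shell_hu
    if (isTRUE(tb$hollow)) {
      cavity <- r >= tb$r_in + tb$wall & r <= tb$r_out - tb$wall &
        phi <= tb$cavity_half_deg
      cavity_hu <- if (is.null(tb$cavity_hu)) -1000 else tb$cavity_hu
      paint(band & !cavity, CLASS_TABLE_SHELL, shell_hu)
      paint(band & cavity, CLASS_TABLE_CAVITY, cavity_hu)
    } else {
      paint(band, CLASS_TABLE_SHELL, shell_hu)
    }
  }

  if (!is.null(spec$body)) {
    b <- spec$body
    inside <- ((g$x - b$center[1]) / b$radii[1])^2 +
      ((g$y - b$center[2]) / b$radii[2])^2 +
      ((g$z - b$center[3]) / b$radii[3])^2 <= 1
    paint(inside, CLASS_BODY, if (is.null(b$hu)) 40 else b$hu)
  }

  sphere_mask <- function(s)
    (g$x - s$center[1])^2 + (g$y - s$center[2])^2 +
      (g$z - s$center[3])^2 <= s$radius^2

  for (bn in spec$bones) {
    type <- if (is.null(bn$type)) "sphere" else bn$type
    m <- switch(type,
      sphere = sphere_mask(bn),
      cylinder_z = (g$x - bn$center[1])^2 + (g$y - bn$center[2])^2 <=
        bn$radius^2 & g$z >= min(bn$zrange) & g$z <= max(bn$zrange),
      spec_error("unknown bone type: ", type)
    )
    paint(m, CLASS_BONE, if (is.null(bn$hu)) 1200 else bn$hu)
  }
  for (mt in spec$metal_objects)
    paint(sphere_mask(mt), CLASS_METAL, if (is.null(mt$hu)) 3200 else mt$hu)
  for (gp in spec$gas_pockets)
    paint(sphere_mask(gp), CLASS_GAS, if (is.null(gp$hu)) -800 else gp$hu)
  for (ch in spec$gas_channels) {
    m <- (g$x - ch$center_xy[1])^2 + (g$y - ch$center_xy[2])^2 <=
      ch$radius^2 & g$z >= min(ch$zrange) & g$z <= max(ch$zrange)
    paint(m, CLASS_GAS, if (is.null(ch$hu)) -800 else ch$hu)
  }

  # the hollow cavity must be watertight: no face contact with background
  cavity <- cls == CLASS_TABLE_CAVITY
  if (any(cavity) &&
      any(cavity & neighbours_face(cls == CLASS_BACKGROUND)))
    spec_error("table cavity is face-connected to background air")

  if (spec$noise_sd > 0) {
    thresholds <- c(-200, -220, 2800)
    margin <- min(vapply(unique(as.vector(hu)),
                         function(v) min(abs(v - thresholds)), numeric(1)))
    if (3 * spec$noise_sd >= margin)
      spec_error("noise_sd too large: 3*sd must stay below the minimum ",
                 "distance (", margin, " HU) of any class to a threshold")
    noise <- with_fixed_seed(spec$rng_seed,
                             stats::rnorm(length(hu), 0, spec$noise_sd))
    noise <- pmin(pmax(noise, -3 * spec$noise_sd), 3 * spec$noise_sd)
    hu <- hu + array(noise, d)
  }

  list(
    volume = ct_volume(hu, spacing = spec$spacing),
    truth = list(
      exterior_air_mask = cls == CLASS_BACKGROUND | cls == CLASS_TABLE_CAVITY,
      interior_gas_mask = cls == CLASS_GAS,
      metal_mask = cls == CLASS_METAL
    ),
    labels = cls
  )
}

#' Standard phantom fixtures
#'
#' A named set of small (44 x 52 x 28 voxel, isotropic 1 mm) phantom
#' specifications exercising every behaviour of the pipeline:
#'
#' * `body_only`: plain soft-tissue ellipsoid with a bone column.
#' * `body_with_gas`: two gas pockets fully enclosed by the body — the
#'   canonical "blue" case.
#' * `body_with_metal`: a metal sphere (and bone) inside the body — the
#'   canonical "red" case.
#' * `body_with_hollow_table`: body, gas pocket and a hollow air-filled
#'   table arc whose cavity cannot be reached from the volume corners;
#'   discriminates table seeding on from off.
#' * `body_with_solid_table`: same arc without a cavity; table-seed scans
#'   must come back empty.
#' * `open_airway`: a gas pocket connected to the outside air by a channel,
#'   reproducing the known failure mode in which corner-seeded growing
#'   removes ventilated airways from the gas visualization.
#'
#' @param gas_hu HU painted into gas pockets (default -800); exposed so
#'   threshold sweeps can vary it.
#' @return Named list of [phantom_spec()]s.
#' @export
standard_fixtures <- function(gas_hu = -800) {
  shape <- c(44L, 52L, 28L)
  body <- list(center = c(22, 24, 14), radii = c(14, 12, 10), hu = 40)
  bone <- list(type = "cylinder_z", center = c(22, 24), radius = 2.5,
               zrange = c(8, 20), hu = 1200)
  pocket_a <- list(center = c(16, 22, 14), radius = 3, hu = gas_hu)
  pocket_b <- list(center = c(27, 27, 17), radius = 2, hu = gas_hu)
  metal <- list(center = c(26, 24, 14), radius = 2, hu = 3200)
  table_hollow <- list(center_xy = c(22, 28), r_in = 15, r_out = 22,
                       wall = 2, arc_half_deg = 50, cavity_half_deg = 35,
                       shell_hu = 300, cavity_hu = -1000, hollow = TRUE)
  table_solid <- modifyList(table_hollow, list(hollow = FALSE))
  list(
    body_only = phantom_spec(shape, body = body, bones = list(bone)),
    body_with_gas = phantom_spec(shape, body = body, bones = list(bone),
                                 gas_pockets = list(pocket_a, pocket_b)),
    body_with_metal = phantom_spec(shape, body = body, bones = list(bone),
                                   metal_objects = list(metal)),
    body_with_hollow_table = phantom_spec(shape, body = body,
                                          gas_pockets = list(pocket_a),
                                          table = table_hollow),
    body_with_solid_table = phantom_spec(shape, body = body,
                                         gas_pockets = list(pocket_a),
                                         table = table_solid),
    open_airway = phantom_spec(
      shape, body = body,
      gas_pockets = list(pocket_a),
      gas_channels = list(list(center_xy = c(16, 22), radius = 1.5,
                               zrange = c(14, 28), hu = gas_hu))
    )
  )
}
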