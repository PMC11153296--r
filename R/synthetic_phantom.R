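# Ellipsoid membership on the phantom grid: semi-axes in mm.
ellipsoid_mask <- function(xc, yc, zc, centre, semi) {
  dx2 <- ((xc - centre[1]) / semi[1])^2
  dy2 <- ((yc - centre[2]) / semi[2])^2
  dz2 <- ((zc - centre[3]) / semi[3])^2
  outer(outer(dx2, dy2, "+"), dz2, "+") <= 1
}

# Solve an ellipsoid's uniform scale s from its volume and axis ratios.
semi_from_volume <- function(vol_mm3, ratios) {
  s <- (vol_mm3 / (4 / 3 * pi * prod(ratios)))^(1 / 3)
  s * ratios
}

#' Generate a voxel body phantom for one participant
#'
#' Builds an organ-labelled body (head + torso + legs, with brain, heart,
#' liver, pancreas, bladder, leg muscles, an abdominal adipose depot and a
#' residual lean core as ellipsoids) on a regular grid, then derives Dixon
#' water and fat signal images from per-organ fat fractions (subcutaneous
#' and abdominal adipose 0.90 by default; liver and pancreas at the
#' participant's sampled fat percentages; lean organs low). Organ sizes
#' scale with the participant's weight so the ground-truth whole-body and
#' adipose volumes match the sampled body composition.
#'
#' @param participant a `participant_record`.
#' @param vox_mm voxel size, mm (default 4).
#' @param ff_sd per-voxel Gaussian noise SD on the fat fraction
#'   (default: configured `ff_sd`, 0).
#' @param seed integer seed (used only when `ff_sd > 0`).
#' @return List of class `body_phantom`: `water`, `fat` ([voxel_image()]s),
#'   `labels` (integer [voxel_image()], 0 = background, with a `levels`
#'   attribute), and `ground_truth` (analytic organ volumes in litres,
#'   per-label fat fractions, adipose/body volume targets).
#' @export
generate_body_phantom <- function(participant, vox_mm = 4,
                                  ff_sd = participant$config$noise_params$ff_sd,
                                  seed = NULL) {
  stopifnot(inherits(participant, "participant_record"))
  cfg <- participant$config
  if (is.null(seed)) seed <- cfg$seed
  v <- participant$vars
  vol <- participant$volumes_l # litres
  H <- participant$height * 1000
  body_mm3 <- participant$truth$body_volume_l * 1e6
  adipose_mm3 <- participant$truth$adipose_volume_l * 1e6

  head_r <- 95
  head_c <- c(0, 0, H - head_r)
  head_vol <- 4 / 3 * pi * head_r^3
  # legs end where the torso begins (0.40 H), so the body parts are disjoint
  leg_r <- 80
  leg_hz <- 0.20 * H
  leg_cz <- 0.20 * H
  leg_vol <- 2 * 4 / 3 * pi * leg_r^2 * leg_hz
  torso_vol <- body_mm3 - head_vol - leg_vol
  if (torso_vol <= 0) stop("body too small for the phantom template", call. = FALSE)
  torso_cz <- 0.22 * H
  torso_zc <- 0.62 * H
  a_x <- sqrt(1.5 * torso_vol / (4 / 3 * pi * torso_cz))
  a_y <- a_x / 1.5

  xr <- max(a_x, 85 + leg_r, head_r) + 2 * vox_mm
  yr <- max(a_y, leg_r, head_r) + 2 * vox_mm
  xc <- seq(-xr + vox_mm / 2, xr, by = vox_mm)
  yc <- seq(-yr + vox_mm / 2, yr, by = vox_mm)
  zc <- seq(vox_mm / 2, H, by = vox_mm)

  torso <- ellipsoid_mask(xc, yc, zc, c(0, 0, torso_zc), c(a_x, a_y, torso_cz))
  head <- ellipsoid_mask(xc, yc, zc, head_c, rep(head_r, 3))
  leg_l <- ellipsoid_mask(xc, yc, zc, c(-85, 0, leg_cz), c(leg_r, leg_r, leg_hz))
  leg_r_m <- ellipsoid_mask(xc, yc, zc, c(85, 0, leg_cz), c(leg_r, leg_r, leg_hz))
  body <- torso | head | leg_l | leg_r_m

  w3 <- (v[["weight"]] / 110.6)^(1 / 3)
  leg_musc_c <- vol[["leg_muscle"]] / 2 * 1e6 / (4 / 3 * pi * 62^2)
  organs <- list(
    brain = ellipsoid_mask(xc, yc, zc, head_c,
                           semi_from_volume(vol[["brain"]] * 1e6, c(1, 1, 1))),
    heart = ellipsoid_mask(xc, yc, zc, c(40, 0, torso_zc + 0.55 * torso_cz),
                           semi_from_volume(vol[["heart"]] * 1e6, c(1, 1, 1))),
    liver = ellipsoid_mask(xc, yc, zc, c(-70 * w3, 20, torso_zc + 0.13 * torso_cz),
                           semi_from_volume(vol[["liver"]] * 1e6, c(2.1, 1.33, 1))),
    pancreas = ellipsoid_mask(xc, yc, zc, c(30, 45, torso_zc - 0.18 * torso_cz),
                              semi_from_volume(vol[["pancreas"]] * 1e6, c(2.5, 1, 0.8))),
    bladder = ellipsoid_mask(xc, yc, zc, c(0, 10, torso_zc - 0.8 * torso_cz),
                             semi_from_volume(vol[["bladder"]] * 1e6, c(1, 1, 1))),
    abd_adipose = ellipsoid_mask(xc, yc, zc, c(0, -30, torso_zc - 0.42 * torso_cz),
                                 semi_from_volume(vol[["abd_adipose"]] * 1e6,
                                                  c(2.5, 1.25, 0.8))),
    leg_muscle = ellipsoid_mask(xc, yc, zc, c(-85, 0, leg_cz), c(62, 62, leg_musc_c)) |
      ellipsoid_mask(xc, yc, zc, c(85, 0, leg_cz), c(62, 62, leg_musc_c))
  )
  overlap <- Reduce(`+`, lapply(organs, function(m) m * 1L))
  if (any(overlap > 1L)) stop("overlapping organ labels", call. = FALSE)
  if (any(Reduce(`|`, organs) & !body)) {
    stop("organ extends outside the body", call. = FALSE)
  }

  # residual lean core: a scaled copy of the torso, sized by bisection so the
  # non-organ lean volume hits its target
  dx2 <- (xc / a_x)^2; dy2 <- (yc / a_y)^2; dz2 <- ((zc - torso_zc) / torso_cz)^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  taken <- Reduce(`|`, organs)
  vox_ml <- vox_mm^3 / 1000
  target_n <- vol[["lean_other"]] * 1e6 / vox_mm^3
  lo <- 0; hi <- 1
  for (i in 1:40) {
    f <- (lo + hi) / 2
    n <- sum(r2 <= f^2 & !taken)
    if (n < target_n) lo <- f else hi <- f
  }
  lean_other <- r2 <= ((lo + hi) / 2)^2 & !taken

  levels <- c("brain", "heart", "liver", "pancreas", "bladder",
              "abd_adipose", "leg_muscle", "lean_other", "sat")
  lab <- array(0L, dim(body))
  for (i in seq_along(organs)) lab[organs[[i]]] <- i
  lab[lean_other] <- 8L
  lab[body & lab == 0L] <- 9L

  ff_by_label <- c(
    brain = 0.05, heart = 0.05,
    liver = v[["liver_fat_pct"]] / 100,
    pancreas = v[["pancreas_fat_pct"]] / 100,
    bladder = 0, abd_adipose = 0.90, leg_muscle = 0.05,
    lean_other = 0.10, sat = 0.90
  )
  ff <- array(0, dim(body))
  for (i in seq_along(levels)) ff[lab == i] <- ff_by_label[[levels[i]]]
  if (ff_sd > 0) {
    with_seed(derive_seed(seed, "phantom", participant$id, participant$timepoint), {
      noise <- array(stats::rnorm(length(ff), 0, ff_sd), dim(ff))
      ff <- pmin(pmax(ff + noise, 0), 1)
    })
  }
  total <- ifelse(lab > 0L, 100, 0)
  fat <- voxel_image(ff * total, vox_mm)
  water <- voxel_image((1 - ff) * total, vox_mm)
  labels <- voxel_image(lab, vox_mm)
  attr(labels, "levels") <- levels

  measured <- vapply(seq_along(levels), function(i) sum(lab == i) * vox_ml / 1000,
                     numeric(1))
  names(measured) <- levels
  structure(
    list(
      water = water, fat = fat, labels = labels,
      ground_truth = list(
        organ_volumes_l = vol,
        voxel_volumes_l = measured,
        body_volume_l = participant$truth$body_volume_l,
        adipose_volume_l = participant$truth$adipose_volume_l,
        fat_fraction_by_label = ff_by_label
      )
    ),
    class = "body_phantom"
  )
}

#' Logical mask for one phantom label
#'
#' @param phantom a [generate_body_phantom()] result.
#' @param label label name (see `attr(phantom$labels, "levels")`).
#' @return Logical [voxel_image()].
#' @export
phantom_mask <- function(phantom, label) {
  levels <- attr(phantom$labels, "levels")
  i <- match(label, levels)
  if (is.na(i)) stop("unknown label: ", label, call. = FALSE)
  voxel_image(array(phantom$labels$data == i, dim(phantom$labels$data)),
              phantom$labels$vox_mm)
}
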