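# Spherical construction of a modified 10-20 montage. Positions are defined
# by inclination from the vertex and azimuth from the nose (left positive),
# with intermediate row electrodes placed on great-circle arcs between the
# midline and the outer ring, then projected stereographically to 2-D.

sph2cart <- function(inc, az) {
  inc <- inc * pi / 180
  az <- az * pi / 180
  c(sin(inc) * sin(az), sin(inc) * cos(az), cos(inc))
}

slerp <- function(a, b, f) {
  w <- acos(max(-1, min(1, sum(a * b))))
  if (w < 1e-12) return(a)
  (sin((1 - f) * w) * a + sin(f * w) * b) / sin(w)
}

cart2incaz <- function(v) {
  c(acos(max(-1, min(1, v[3]))) * 180 / pi, atan2(v[1], v[2]) * 180 / pi)
}

#' Bundled EEG sensor layout (modified 10-20, 56 channels)
#'
#' A 56-channel montage on the extended 10-20 system: the classic 10-20 core
#' (including the inferior temporal ring FT9/FT10, TP9/TP10), frontal and
#' parieto-occipital extensions, but without the 10-10 intermediates
#' (C5/C6, FT7/FT8, TP7/TP8, CP3/CP4, ...), as on common research caps.
#' Positions are returned as a stereographic 2-D projection of the spherical
#' electrode coordinates (vertex at the origin, nose towards +y, radius
#' `tan(inclination / 2)` in head-radius units).
#'
#' @return A `sensor_layout` tibble with columns `channel`, `x`, `y`,
#'   `inclination`, `azimuth`.
#' @export
sensor_layout_1020 <- function() {
  pos <- list()
  add <- function(name, inc, az) pos[[name]] <<- c(inc, az)
  add("Fpz", 90, 0); add("AFz", 67.5, 0); add("Fz", 45, 0); add("FCz", 22.5, 0)
  add("Cz", 0, 0); add("Pz", 45, 180); add("Oz", 90, 180); add("Iz", 105, 180)
  for (side in c(1, -1)) { # 1 = left (odd), -1 = right (even)
    add(if (side == 1) "Fp1" else "Fp2", 90, side * 18)
    add(if (side == 1) "AF7" else "AF8", 90, side * 36)
    add(if (side == 1) "F7" else "F8", 90, side * 54)
    add(if (side == 1) "T7" else "T8", 90, side * 90)
    add(if (side == 1) "P7" else "P8", 90, side * 126)
    add(if (side == 1) "PO7" else "PO8", 90, side * 144)
    add(if (side == 1) "O1" else "O2", 90, side * 162)
    add(if (side == 1) "F9" else "F10", 105, side * 54)
    add(if (side == 1) "FT9" else "FT10", 105, side * 72)
    add(if (side == 1) "TP9" else "TP10", 105, side * 108)
    add(if (side == 1) "P9" else "P10", 105, side * 126)
    add(if (side == 1) "PO9" else "PO10", 105, side * 144)
    add(if (side == 1) "O9" else "O10", 105, side * 162)
  }
  # row arcs: midline anchor -> ring anchor, channels at fractional arc
  rowarc <- function(mid, ring_inc, ring_az, side, specs) {
    a <- sph2cart(pos[[mid]][1], pos[[mid]][2])
    b <- sph2cart(ring_inc, side * ring_az)
    for (nm in names(specs)) {
      ia <- cart2incaz(slerp(a, b, specs[[nm]]))
      add(nm, ia[1], ia[2])
    }
  }
  for (side in c(1, -1)) {
    o <- function(odd, even) if (side == 1) odd else even
    rowarc("AFz", 90, 36, side, stats::setNames(list(0.5), o("AF3", "AF4")))
    rowarc("Fz", 90, 54, side,
           stats::setNames(list(0.25, 0.5), c(o("F1", "F2"), o("F3", "F4"))))
    rowarc("FCz", 90, 72, side,
           stats::setNames(list(0.25, 0.75), c(o("FC1", "FC2"), o("FC5", "FC6"))))
    rowarc("Cz", 90, 90, side,
           stats::setNames(list(0.25, 0.5), c(o("C1", "C2"), o("C3", "C4"))))
    rowarc("Pz", 90, 90 + 36, side,
           stats::setNames(list(0.5), o("P3", "P4")))
    # CP and PO rows: anchored at the virtual (unpopulated) CPz/POz midline
    # points so row geometry matches the 10-10 construction
    cpz <- sph2cart(22.5, 180)
    b <- sph2cart(90, side * 108)
    for (spec in list(list("CP1", "CP2", 0.25), list("CP5", "CP6", 0.75))) {
      nm <- if (side == 1) spec[[1]] else spec[[2]]
      ia <- cart2incaz(slerp(cpz, b, spec[[3]]))
      add(nm, ia[1], ia[2])
    }
    poz <- sph2cart(67.5, 180)
    ia <- cart2incaz(slerp(poz, sph2cart(90, side * 144), 0.5))
    add(o("PO3", "PO4"), ia[1], ia[2])
  }
  nm <- names(pos)
  inc <- vapply(pos, `[`, numeric(1), 1)
  az <- vapply(pos, `[`, numeric(1), 2)
  r <- tan(inc * pi / 360)
  out <- tibble::tibble(
    channel = nm,
    x = -r * sin(az * pi / 180), # right positive
    y = r * cos(az * pi / 180), # front positive
    inclination = inc, azimuth = az
  )
  class(out) <- c("sensor_layout", class(out))
  out
}

#' Select a sensor cluster around centroid electrodes
#'
#' Returns the union, over centroid electrodes, of all channels whose 2-D
#' projected distance from the centroid is at most `radius` (centroids
#' included). With the bundled layout and the preset radii this reproduces
#' the canonical temporal (12-channel) and centroparietal (6-channel)
#' clusters used in sensor-space decoding.
#'
#' @param layout A [sensor_layout_1020()]-style tibble (`channel`, `x`, `y`).
#' @param centroids Character vector of centroid channel names.
#' @param radius Neighborhood radius in layout units (head radii).
#' @return Character vector of channel names (layout order).
#' @export
select_sensor_cluster <- function(layout, centroids, radius) {
  missing <- setdiff(centroids, layout$channel)
  if (length(missing)) {
    abort(paste("unknown centroid electrode(s):", paste(missing, collapse = ", ")))
  }
  keep <- rep(FALSE, nrow(layout))
  for (ctr in centroids) {
    i <- match(ctr, layout$channel)
    d <- sqrt((layout$x - layout$x[i])^2 + (layout$y - layout$y[i])^2)
    keep <- keep | d <= radius + 1e-12
  }
  layout$channel[keep]
}

#' Preset sensor clusters
#'
#' The two hypothesis-driven sensor subsets used in sensor-space decoding:
#' a bilateral temporal cluster around T7/T8 and a centroparietal cluster
#' around Pz, with neighborhood radii (0.60 and 0.43 head radii) chosen so
#' the selection yields the canonical 12- and 6-channel sets on the bundled
#' montage.
#'
#' @param layout A sensor layout tibble; defaults to [sensor_layout_1020()].
#' @return Named list with `temporal` and `centroparietal` channel vectors;
#'   attribute `radii` records the radii used.
#' @export
preset_sensor_clusters <- function(layout = sensor_layout_1020()) {
  out <- list(
    temporal = select_sensor_cluster(layout, c("T7", "T8"), 0.60),
    centroparietal = select_sensor_cluster(layout, "Pz", 0.43)
  )
  attr(out, "radii") <- c(temporal = 0.60, centroparietal = 0.43)
  out
}
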