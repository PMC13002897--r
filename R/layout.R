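#' Probe layout objects
#'
#' A `probe_layout` describes the on-shank geometry of a multifunctional
#' neural probe: recording electrode sites, nanophotonic emitter sites, and
#' the microfluidic outlet, all in a common (axial, lateral) coordinate frame
#' measured in micrometres from the shank tip. Geometry drives every
#' distance-dependent effect in the package: photostimulation gain falls off
#' with electrode-emitter distance, and the epileptiform component falls off
#' with distance from the outlet (the injection site).
#'
#' @param electrodes tibble with columns `electrode_id`, `axial_um`,
#'   `lateral_um` (and optionally `site`).
#' @param emitters tibble with columns `emitter_id`, `axial_um`, `lateral_um`.
#' @param outlet length-2 numeric `c(axial_um, lateral_um)`.
#' @param shank_length_um total shank length.
#' @param in_brain_depth_um insertion depth; electrodes with
#'   `axial_um < in_brain_depth_um` are considered inside the brain.
#'
#' @return An object of class `probe_layout`.
#' @export
probe_layout <- function(electrodes, emitters, outlet,
                         shank_length_um = 3900,
                         in_brain_depth_um = 1400) {
  electrodes <- tibble::as_tibble(electrodes)
  emitters <- tibble::as_tibble(emitters)
  req_e <- c("electrode_id", "axial_um", "lateral_um")
  req_m <- c("emitter_id", "axial_um", "lateral_um")
  if (!all(req_e %in% names(electrodes))) {
    abort("`electrodes` needs columns electrode_id, axial_um, lateral_um",
          class = "probeseize_invalid_layout")
  }
  if (!all(req_m %in% names(emitters))) {
    abort("`emitters` needs columns emitter_id, axial_um, lateral_um",
          class = "probeseize_invalid_layout")
  }
  coords <- c(electrodes$axial_um, electrodes$lateral_um,
              emitters$axial_um, emitters$lateral_um, outlet)
  if (!all(is.finite(coords)) || any(coords < 0)) {
    abort("layout coordinates must be finite and non-negative",
          class = "probeseize_invalid_layout")
  }
  structure(
    list(
      electrodes = electrodes,
      emitters = emitters,
      outlet = c(axial_um = unname(outlet[1]), lateral_um = unname(outlet[2])),
      shank_length_um = shank_length_um,
      in_brain_depth_um = in_brain_depth_um
    ),
    class = "probe_layout"
  )
}

#' Default probe layout
#'
#' The stock geometry: 16 recording electrodes staggered alongside 16 grating
#' emitters on a 55-um longitudinal pitch, two additional electrodes near the
#' shank tip (18 electrodes in total), and the microfluidic outlet in the
#' middle of the array, about 0.9 mm from the tip. Axial coordinates are
#' measured from the shank tip.
#'
#' @param in_brain_depth_um insertion depth; default 1400 um puts the whole
#'   array and the tip electrodes in the brain.
#' @return A [probe_layout()].
#' @examples
#' lay <- default_layout()
#' nrow(lay$electrodes) # 18
#' @export
default_layout <- function(in_brain_depth_um = 1400) {
  pitch <- 55
  n <- 16
  emitter_axial <- 487.5 + pitch * (seq_len(n) - 1)   # centered at 900 um
  emitters <- tibble::tibble(
    emitter_id = seq_len(n),
    axial_um = emitter_axial,
    lateral_um = rep(c(35, 75), length.out = n)
  )
  array_electrodes <- tibble::tibble(
    electrode_id = seq_len(n),
    axial_um = 460 + pitch * (seq_len(n) - 1),
    lateral_um = rep(c(20, 60), length.out = n),
    site = "array"
  )
  tip_electrodes <- tibble::tibble(
    electrode_id = c(17L, 18L),
    axial_um = c(50, 105),
    lateral_um = c(40, 40),
    site = "tip"
  )
  probe_layout(
    electrodes = dplyr::bind_rows(array_electrodes, tip_electrodes),
    emitters = emitters,
    outlet = c(897, 50),
    shank_length_um = 3900,
    in_brain_depth_um = in_brain_depth_um
  )
}

#' @export
print.probe_layout <- function(x, ...) {
  cat(sprintf(
    "<probe_layout> %d electrodes, %d emitters, outlet at %.1f um (axial)\n",
    nrow(x$electrodes), nrow(x$emitters), x$outlet[["axial_um"]]
  ))
  invisible(x)
}

#' Electrodes considered inside the brain
#'
#' @param layout a [probe_layout()].
#' @return integer electrode ids with axial position above the tip but below
#'   the insertion depth.
#' @export
in_brain_electrodes <- function(layout) {
  stopifnot(inherits(layout, "probe_layout"))
  layout$electrodes$electrode_id[layout$electrodes$axial_um < layout$in_brain_depth_um]
}

layout_electrode <- function(layout, electrode_id) {
  i <- match(electrode_id, layout$electrodes$electrode_id)
  if (anyNA(i)) {
    abort(sprintf("unknown electrode id(s): %s",
                  paste(electrode_id[is.na(i)], collapse = ", ")),
          class = "probeseize_unknown_electrode")
  }
  layout$electrodes[i, ]
}

layout_emitter <- function(layout, emitter_id) {
  i <- match(emitter_id, layout$emitters$emitter_id)
  if (anyNA(i)) {
    abort(sprintf("unknown emitter id(s): %s",
                  paste(emitter_id[is.na(i)], collapse = ", ")),
          class = "probeseize_unknown_emitter")
  }
  layout$emitters[i, ]
}

#' Euclidean electrode-emitter distance
#'
#' @param layout a [probe_layout()].
#' @param electrode_id,emitter_id ids (vectorized, recycled).
#' @return distance in micrometres.
#' @export
electrode_emitter_distance <- function(layout, electrode_id, emitter_id) {
  e <- layout_electrode(layout, electrode_id)
  m <- layout_emitter(layout, emitter_id)
  sqrt((e$axial_um - m$axial_um)^2 + (e$lateral_um - m$lateral_um)^2)
}

#' Electrode distance to the microfluidic outlet
#'
#' @inheritParams electrode_emitter_distance
#' @return distance in micrometres.
#' @export
electrode_outlet_distance <- function(layout, electrode_id) {
  e <- layout_electrode(layout, electrode_id)
  sqrt((e$axial_um - layout$outlet[["axial_um"]])^2 +
         (e$lateral_um - layout$outlet[["lateral_um"]])^2)
}

electrode_pair_distance <- function(layout, id_a, id_b) {
  a <- layout_electrode(layout, id_a)
  b <- layout_electrode(layout, id_b)
  sqrt((a$axial_um - b$axial_um)^2 + (a$lateral_um - b$lateral_um)^2)
}

#' Write / read a probe layout as JSON
#'
#' @param layout a [probe_layout()].
#' @param path file path.
#' @return `read_layout` returns a [probe_layout()]; `write_layout` the path,
#'   invisibly.
#' @export
write_layout <- function(layout, path) {
  obj <- list(
    electrodes = layout$electrodes,
    emitters = layout$emitters,
    outlet = as.list(layout$outlet),
    shank_length_um = layout$shank_length_um,
    in_brain_depth_um = layout$in_brain_depth_um
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  if (!file.exists(path)) {
    abort(sprintf("layout file not found: %s", path),
          class = "probeseize_missing_file")
  }
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  probe_layout(
    electrodes = obj$electrodes,
    emitters = obj$emitters,
    outlet = c(obj$outlet$axial_um, obj$outlet$lateral_um),
    shank_length_um = obj$shank_length_um,
    in_brain_depth_um = obj$in_brain_depth_um
  )
}
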