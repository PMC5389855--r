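#' Describe one spectral/lifetime acquisition channel
#'
#' A channel is identified by its short name, excitation wavelength, emission
#' band and fluorescence-lifetime gate. Lifetime gating is an acquisition
#' property: stacks arrive already gated, and the gate here is metadata that
#' travels with the data so that channel identity never depends on plane order
#' in a file.
#'
#' @param name Short identifier, e.g. `"405"`, `"488"`, `"AF"`. Must be unique
#'   within one acquisition.
#' @param excitation_nm Excitation wavelength in nm (positive integer).
#' @param emission_band_nm Length-2 numeric `(low, high)` emission band in nm,
#'   strictly ordered.
#' @param lifetime_gate_ns Length-2 numeric `(low, high)` photon-arrival gate
#'   in ns, nonnegative and strictly ordered.
#' @return An object of class `channel_spec`.
#' @seealso [hyper_channels()] for the standard three-channel HyPer layout.
#' @export
#' @examples
#' channel_spec("405", 405, c(500, 550), c(1.5, 5.5))
channel_spec <- function(name, excitation_nm, emission_band_nm, lifetime_gate_ns) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  if (!(length(excitation_nm) == 1L && excitation_nm > 0)) {
    abort("`excitation_nm` must be a single positive number.")
  }
  if (length(emission_band_nm) != 2L || !all(emission_band_nm > 0) ||
      emission_band_nm[1] >= emission_band_nm[2]) {
    abort("`emission_band_nm` must be two positive values with low < high.")
  }
  if (length(lifetime_gate_ns) != 2L || any(lifetime_gate_ns < 0) ||
      lifetime_gate_ns[1] >= lifetime_gate_ns[2]) {
    abort("`lifetime_gate_ns` must be two nonnegative values with low < high.")
  }
  structure(
    list(
      name = name,
      excitation_nm = as.numeric(excitation_nm),
      emission_band_nm = as.numeric(emission_band_nm),
      lifetime_gate_ns = as.numeric(lifetime_gate_ns)
    ),
    class = "channel_spec"
  )
}

#' @export
print.channel_spec <- function(x, ...) {
  cat(sprintf(
    "<channel_spec> %s: %dex %d-%dem, gate %.1f-%.1f ns\n",
    x$name, x$excitation_nm, x$emission_band_nm[1], x$emission_band_nm[2],
    x$lifetime_gate_ns[1], x$lifetime_gate_ns[2]
  ))
  invisible(x)
}

#' The standard three-channel lifetime-gated HyPer acquisition
#'
#' Two short-gate sensor channels (405 ex and 488 ex, both 500-550 nm
#' emission, 1.5-5.5 ns) and one long-gate, blue-shifted autofluorescence
#' channel (405 ex, 450-470 nm, 7-11.5 ns) containing no sensor signal.
#'
#' @return Named list of three [channel_spec()] objects: `"405"`, `"488"`,
#'   `"AF"`.
#' @export
hyper_channels <- function() {
  list(
    "405" = channel_spec("405", 405, c(500, 550), c(1.5, 5.5)),
    "488" = channel_spec("488", 488, c(500, 550), c(1.5, 5.5)),
    "AF"  = channel_spec("AF", 405, c(450, 470), c(7, 11.5))
  )
}

#' One subject's intensity volume in one channel
#'
#' Wraps a 3-D nonnegative array of voxel intensities with acquisition
#' metadata. The axis order is fixed package-wide as `(z, y, x)`:
#' `voxels[k, , ]` is the k-th optical section as a `(y, x)` matrix. z indices
#' are 1-based (R convention); pixel-plane `(x, y)` coordinates used for ROIs
#' are 0-based pixel centers.
#'
#' @param voxels 3-D numeric array, all values finite and >= 0, dims
#'   `(z, y, x)`. A 2-D matrix is promoted to a single-slice stack.
#' @param channel A [channel_spec()].
#' @param subject_id,group,experiment_id Identifying labels (strings).
#' @param z_step_um Axial step between sections in micrometres.
#' @return An object of class `channel_stack`.
#' @export
channel_stack <- function(voxels, channel, subject_id = "subject",
                          group = "", experiment_id = "",
                          z_step_um = 0.34) {
  if (is.matrix(voxels)) {
    voxels <- array(voxels, dim = c(1L, nrow(voxels), ncol(voxels)))
  }
  if (!(is.array(voxels) && length(dim(voxels)) == 3L)) {
    abort("`voxels` must be a 3-D array with dims (z, y, x).")
  }
  storage.mode(voxels) <- "double"
  if (!all(is.finite(voxels))) abort("voxel values must all be finite.")
  if (any(voxels < 0)) abort("voxel values must all be >= 0.")
  if (!inherits(channel, "channel_spec")) abort("`channel` must be a channel_spec.")
  if (!(is.numeric(z_step_um) && length(z_step_um) == 1L && z_step_um > 0)) {
    abort("`z_step_um` must be a single positive number.")
  }
  structure(
    list(
      voxels = voxels, channel = channel,
      subject_id = as.character(subject_id), group = as.character(group),
      experiment_id = as.character(experiment_id),
      z_step_um = as.numeric(z_step_um)
    ),
    class = "channel_stack"
  )
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$voxels)
  cat(sprintf(
    "<channel_stack> subject %s%s, channel %s, %d x %d x %d (z,y,x), dz %.2f um\n",
    x$subject_id, if (nzchar(x$group)) paste0(" [", x$group, "]") else "",
    x$channel$name, d[1], d[2], d[3], x$z_step_um
  ))
  invisible(x)
}

#' @export
dim.channel_stack <- function(x) dim(x$voxels)

# internal: accept channel_stack or bare array, return the 3-D voxel array
as_voxels <- function(x, arg = "stack") {
  if (inherits(x, "channel_stack")) return(x$voxels)
  if (is.matrix(x)) return(array(x, dim = c(1L, nrow(x), ncol(x))))
  if (is.array(x) && length(dim(x)) == 3L) {
    storage.mode(x) <- "double"
    return(x)
  }
  abort(sprintf("`%s` must be a channel_stack or a 2-D/3-D numeric array.", arg))
}

# internal: carry metadata from a template stack onto new voxels
rewrap_stack <- function(template, voxels) {
  if (inherits(template, "channel_stack")) {
    out <- template
    out$voxels <- voxels
    out
  } else if (is.matrix(template)) {
    voxels[1, , ]
  } else {
    voxels
  }
}
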