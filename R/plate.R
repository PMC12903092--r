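# Plate geometry for multiwell MEA plates.

#' Multiwell MEA plate layout
#'
#' Describes the geometry of a multiwell MEA plate. The default matches a
#' 48-well plate in which each well carries 16 extracellular electrodes
#' embedded in a 4 x 4 grid (50 um diameter, 350 um pitch).
#'
#' @param n_wells Number of wells on the plate.
#' @param n_rows,n_cols Electrode grid dimensions within a well.
#' @param electrode_spacing Center-to-center electrode pitch, micrometers.
#' @param electrode_diameter Electrode diameter, micrometers.
#' @return An object of class `plate_layout`.
#' @examples
#' layout <- plate_layout()
#' electrode_ids(layout)
#' @export
plate_layout <- function(n_wells = 48, n_rows = 4, n_cols = 4,
                         electrode_spacing = 350, electrode_diameter = 50) {
  stopifnot(n_wells >= 1, n_rows >= 1, n_cols >= 1)
  structure(
    list(
      n_wells = as.integer(n_wells),
      n_rows = as.integer(n_rows),
      n_cols = as.integer(n_cols),
      electrodes_per_well = as.integer(n_rows * n_cols),
      electrode_spacing = electrode_spacing,
      electrode_diameter = electrode_diameter
    ),
    class = "plate_layout"
  )
}

#' Electrode identifiers of a plate layout
#'
#' Electrodes are named `"R{row}C{col}"` within a well, in row-major order.
#'
#' @param layout A [plate_layout()].
#' @return Character vector of unique electrode ids.
#' @export
electrode_ids <- function(layout = plate_layout()) {
  grid <- expand.grid(col = seq_len(layout$n_cols), row = seq_len(layout$n_rows))
  sprintf("R%dC%d", grid$row, grid$col)
}

#' Well identifiers of a plate layout
#'
#' Wells are labelled `"A1"`, `"A2"`, ... across 8 columns per row letter,
#' matching the vendor convention for 48-well plates (`A1`..`F8`).
#'
#' @param layout A [plate_layout()].
#' @return Character vector of well ids, length `n_wells`.
#' @export
well_ids <- function(layout = plate_layout()) {
  n_cols <- 8
  n_rows <- ceiling(layout$n_wells / n_cols)
  grid <- expand.grid(col = seq_len(n_cols), row = LETTERS[seq_len(n_rows)])
  paste0(grid$row, grid$col)[seq_len(layout$n_wells)]
}

#' @export
print.plate_layout <- function(x, ...) {
  cat(sprintf(
    "MEA plate layout: %d wells, %d electrodes/well (%dx%d grid, %g um pitch)\n",
    x$n_wells, x$electrodes_per_well, x$n_rows, x$n_cols, x$electrode_spacing
  ))
  invisible(x)
}
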