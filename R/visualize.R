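#' Capture intermediate feature maps
#'
#' Runs one forward pass in evaluation mode with read-only hooks on the
#' requested units and returns their activations; the pass is identical to a
#' plain prediction, so capturing never changes any output. Unit names follow
#' the graph's labels, e.g. `msf.conv1x1`, `msf.conv3x3`, `msf.conv5x5`,
#' `msf.conv7x7`, `msf.out`, `mlf1.conv1` .. `mlf3.out`, `rs1.s1.out`,
#' `head.conv`. The `msf.convKxK` units are the per-path outputs entering the
#' fusion sum (the 1x1 unit is taken after its max-pool), so `msf.out` equals
#' their element-wise sum exactly.
#'
#' @param model a `dcfcnn_model`.
#' @param image one preprocessed H x W x C image (see [preprocess()]).
#' @param units character vector of unit names.
#' @return named list of `feature_map_stack` objects, each with `unit` and
#'   `maps` (H' x W' x channels array).
#' @export
extract_feature_maps <- function(model, image, units) {
  valid <- unlist(lapply(model$graph$nodes, function(n) n$unit))
  valid <- sort(unique(valid[!is.na(valid)]))
  unknown <- setdiff(units, valid)
  if (length(unknown) > 0) {
    stop_config("unknown unit(s) %s; valid units: %s",
                paste(unknown, collapse = ", "),
                paste(valid, collapse = ", "),
                subclass = "fusenet_unknown_unit")
  }
  x <- as_batch(list(image))
  fwd <- nn_forward(model, x, train = FALSE, capture = units)
  lapply(setNames(units, units), function(u) {
    a <- fwd$captured[[u]]   # (C, H, W, 1)
    d <- dim(a)
    structure(list(unit = u,
                   maps = aperm(array(a, d[1:3]), c(2, 3, 1))),
              class = "feature_map_stack")
  })
}

#' Render a feature-map stack as a tiled grayscale grid
#'
#' Each channel map is min-max normalized to \[0, 255\] independently (a
#' constant map renders mid-gray) and the maps are tiled row-major into
#' `ceiling(n_channels / columns)` rows. Optionally written as a PNG.
#'
#' @param stack a `feature_map_stack` from [extract_feature_maps()].
#' @param columns tiles per row.
#' @param file optional PNG output path.
#' @param global_scale normalize all maps with one shared min/max instead of
#'   per map.
#' @return the grid as a numeric matrix in \[0, 1\], invisibly.
#' @export
render_grid <- function(stack, columns = 8, file = NULL,
                        global_scale = FALSE) {
  stopifnot(inherits(stack, "feature_map_stack"))
  maps <- stack$maps
  d <- dim(maps)
  n <- d[3]
  if (n == 0) stop_data("empty feature-map stack")
  rows <- ceiling(n / columns)
  grid <- matrix(0, rows * d[1], columns * d[2])
  if (global_scale) {
    lo <- min(maps); hi <- max(maps)
  }
  for (i in seq_len(n)) {
    m <- maps[, , i]
    if (!global_scale) {
      lo <- min(m); hi <- max(m)
    }
    norm <- if (hi > lo) (m - lo) / (hi - lo) else
      matrix(0.5, d[1], d[2])  # defined behavior for zero range
    r0 <- ((i - 1) %/% columns) * d[1]
    c0 <- ((i - 1) %% columns) * d[2]
    grid[r0 + seq_len(d[1]), c0 + seq_len(d[2])] <- norm
  }
  if (!is.null(file)) png::writePNG(grid, file)
  invisible(grid)
}
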