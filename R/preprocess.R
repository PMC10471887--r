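#' Preprocessing configuration
#'
#' The chain is: scale the short image edge to `short_edge` (the long edge
#' scales by the same factor, truncated to an integer), center-crop a
#' `crop_size` x `crop_size` window, divide by 255 and standardize each
#' channel. The four standard resize-crop strategies are 256-224, 384-336,
#' 512-448 and 640-560; the default is 512-448, which is the configuration
#' whose layer table the architecture reproduces.
#'
#' @param short_edge target length in pixels of the short image edge.
#' @param crop_size side of the square center crop; must not exceed
#'   `short_edge`.
#' @param channel_mean,channel_std per-channel statistics applied after
#'   scaling pixel values to \[0, 1\]. The intended use is to compute them
#'   from the training split of the active dataset (see [channel_stats()]);
#'   the defaults (0 and 1) leave values on the \[0, 1\] scale.
#' @param interpolation only `"bilinear"` is supported.
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(short_edge = 512, crop_size = 448,
                              channel_mean = c(0, 0, 0),
                              channel_std = c(1, 1, 1),
                              interpolation = "bilinear") {
  if (crop_size > short_edge) {
    stop_config("crop_size (%d) must not exceed short_edge (%d)",
                crop_size, short_edge)
  }
  if (short_edge < 1 || crop_size < 1) {
    stop_config("short_edge and crop_size must be positive")
  }
  channel_mean <- rep_len(as.numeric(channel_mean), 3)
  channel_std <- rep_len(as.numeric(channel_std), 3)
  if (any(channel_std <= 0)) {
    stop_config("channel_std components must be strictly positive")
  }
  interpolation <- match.arg(interpolation, "bilinear")
  structure(list(short_edge = as.integer(short_edge),
                 crop_size = as.integer(crop_size),
                 channel_mean = channel_mean, channel_std = channel_std,
                 interpolation = interpolation),
            class = "preprocess_config")
}

check_rgb <- function(image) {
  d <- dim(image)
  if (length(d) != 3 || d[3] != 3) {
    stop_data("expected an H x W x 3 image array, got dimensions [%s]",
              paste(d, collapse = ", "),
              subclass = "fusenet_not_rgb")
  }
  invisible(d)
}

#' Resize so that the short edge reaches a target length
#'
#' Aspect ratio is preserved up to integer truncation: the long edge becomes
#' `floor(long * target / short)`. Resizing 2304 x 1728 to a short edge of
#' 512 therefore yields 682 x 512 (truncation, not rounding). Bilinear
#' interpolation; a no-op (bit-identical) when the short edge already equals
#' the target.
#'
#' @param image H x W x 3 numeric array.
#' @param target short-edge length in pixels.
#' @return resized H' x W' x 3 array with `min(H', W') == target`.
#' @export
resize_short_edge <- function(image, target) {
  d <- check_rgb(image)
  h <- d[1]; w <- d[2]
  if (target < 1) stop_config("target short edge must be positive")
  if (min(h, w) == target) return(image)
  if (h <= w) {
    nh <- as.integer(target)
    nw <- as.integer(floor(w * target / h))
  } else {
    nw <- as.integer(target)
    nh <- as.integer(floor(h * target / w))
  }
  # EBImage stores spatial axes as (x, y); our arrays are (row, col), so the
  # first array dimension maps onto EBImage's "w" argument. resize() is
  # separable, so the relabelling is immaterial.
  img <- EBImage::Image(image, colormode = "Color")
  out <- EBImage::resize(img, w = nh, h = nw, filter = "bilinear",
                         antialias = FALSE)
  array(EBImage::imageData(out), c(nh, nw, 3))
}

#' Center crop to a square window
#'
#' Rows `floor((H - size)/2) .. floor((H - size)/2) + size - 1` are kept (same
#' rule for columns); indices are 0-based half-open in that formula, origin at
#' the top-left. No padding: a crop larger than the image is an error.
#'
#' @param image H x W x 3 numeric array.
#' @param size crop side in pixels.
#' @return size x size x 3 array.
#' @export
center_crop <- function(image, size) {
  d <- check_rgb(image)
  h <- d[1]; w <- d[2]
  if (size > h || size > w) {
    stop_data("crop size %d exceeds image dimensions %d x %d (no padding)",
              size, h, w, subclass = "fusenet_crop_too_large")
  }
  oy <- floor((h - size) / 2)
  ox <- floor((w - size) / 2)
  image[(oy + 1):(oy + size), (ox + 1):(ox + size), , drop = FALSE]
}

#' Scale to \[0, 1\] and standardize per channel
#'
#' Each pixel becomes `(p/255 - mean_c) / std_c` on its channel `c`.
#'
#' @param image H x W x 3 array of 8-bit values in \[0, 255\].
#' @param cfg a [preprocess_config()].
#' @return real-valued array of the same dimensions.
#' @export
normalize_standardize <- function(image, cfg = preprocess_config()) {
  check_rgb(image)
  out <- image / 255
  for (c in 1:3) {
    out[, , c] <- (out[, , c] - cfg$channel_mean[c]) / cfg$channel_std[c]
  }
  out
}

#' Full preprocessing chain
#'
#' Composition of [resize_short_edge()], [center_crop()] and
#' [normalize_standardize()]; the output is `crop_size` x `crop_size` x 3.
#'
#' @inheritParams normalize_standardize
#' @export
preprocess <- function(image, cfg = preprocess_config()) {
  x <- resize_short_edge(image, cfg$short_edge)
  x <- center_crop(x, cfg$crop_size)
  normalize_standardize(x, cfg)
}

#' Per-channel mean and standard deviation of an image set
#'
#' Statistics are pooled over all pixels of all images on the \[0, 1\] scale,
#' ready to be passed to [preprocess_config()] as `channel_mean` /
#' `channel_std`. Typically computed on the training split of each fold.
#'
#' @param images list of H x W x 3 arrays with values in \[0, 255\].
#' @return list with elements `mean` and `std` (length-3 numerics).
#' @export
channel_stats <- function(images) {
  stopifnot(length(images) > 0)
  ch <- lapply(1:3, function(c) {
    unlist(lapply(images, function(im) as.numeric(im[, , c]) / 255))
  })
  m <- vapply(ch, mean, 0)
  s <- vapply(ch, sd, 0)
  s[s < 1e-8] <- 1e-8
  list(mean = m, std = s)
}
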