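#' Scene categories and the label merge rule
#'
#' Histology scenes come in three categories: `no_cancer` (benign tissue
#' only), `partial_cancer` (a scene partially covered by a cancer region) and
#' `full_cancer` (a scene filled by the cancer region). For binary
#' classification the two cancer-bearing categories are merged into a single
#' `malignant` class and `no_cancer` maps to `benign`.
#'
#' @param category character vector of scene categories.
#' @return character vector of labels, `"benign"` or `"malignant"`.
#' @examples
#' merge_labels(c("no_cancer", "partial_cancer", "full_cancer"))
#' @export
merge_labels <- function(category) {
  check_category(category)
  ifelse(category == "no_cancer", "benign", "malignant")
}

scene_categories <- c("no_cancer", "partial_cancer", "full_cancer")

check_category <- function(category) {
  bad <- setdiff(unique(category), scene_categories)
  if (length(bad) > 0) {
    stop_config("unknown scene category: %s (expected one of %s)",
                paste(bad, collapse = ", "),
                paste(scene_categories, collapse = ", "),
                subclass = "fusenet_invalid_category")
  }
  invisible(category)
}

#' Configuration for the synthetic histology generator
#'
#' The defaults emulate the composition of the real scene collection the
#' model targets: 690 scenes partially containing cancer (125 patients),
#' 48 scenes filled with cancer (14 patients) and 142 scenes with no cancer
#' (35 patients) - 880 scenes in all. The default image size is 576 x 432,
#' one quarter of the native 2304 x 1728 scene resolution, to keep generation
#' fast; pass the full size explicitly when needed.
#'
#' @param n_no_cancer,n_partial,n_full per-category scene counts.
#' @param image_height,image_width image dimensions in pixels.
#' @param n_patients named integer vector of patient counts per category.
#' @param separability real in \[0, 1\]; scales the stain-contrast difference
#'   between benign and malignant scenes. At 0 the categories are drawn from
#'   identical blob parameters; at 1 the cancer-cluster tint is at full
#'   strength.
#' @param seed integer seed; every scene derives its own RNG stream from
#'   `(seed, scene_id)` so generation order never changes content.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_no_cancer = 142, n_partial = 690, n_full = 48,
                         image_height = 432, image_width = 576,
                         n_patients = c(no_cancer = 35, partial_cancer = 125,
                                        full_cancer = 14),
                         separability = 0.9, seed = 1L) {
  counts <- c(n_no_cancer, n_partial, n_full)
  if (any(counts < 0) || any(counts != round(counts))) {
    stop_config("scene counts must be non-negative integers")
  }
  if (separability < 0 || separability > 1) {
    stop_config("separability must lie in [0, 1], got %g", separability)
  }
  if (image_height < 8 || image_width < 8) {
    stop_config("image dimensions must be at least 8 x 8")
  }
  np <- n_patients[scene_categories]
  np[is.na(np)] <- 1L
  np <- pmax(1L, as.integer(np))
  names(np) <- scene_categories
  structure(list(n_no_cancer = as.integer(n_no_cancer),
                 n_partial = as.integer(n_partial),
                 n_full = as.integer(n_full),
                 image_height = as.integer(image_height),
                 image_width = as.integer(image_width),
                 n_patients = np,
                 separability = separability,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Multi-octave value noise in [0, 1]: coarse uniform grids, bilinearly
# upsampled and summed with halving amplitudes. Drawn from the current RNG.
value_noise <- function(h, w, octaves = 4, base_cells = 6) {
  acc <- matrix(0, h, w)
  amp <- 1
  total <- 0
  for (o in seq_len(octaves)) {
    cells <- base_cells * 2^(o - 1)
    gh <- cells; gw <- cells
    grid <- matrix(runif((gh + 1) * (gw + 1), -0.5, 0.5), gh + 1, gw + 1)
    ry <- (seq_len(h) - 1) / max(h - 1, 1) * gh
    rx <- (seq_len(w) - 1) / max(w - 1, 1) * gw
    i0 <- pmin(floor(ry), gh - 1); fy <- ry - i0
    j0 <- pmin(floor(rx), gw - 1); fx <- rx - j0
    top <- grid[i0 + 1, j0 + 1, drop = FALSE] * (1 - fy) +
      grid[i0 + 2, j0 + 1, drop = FALSE] * fy
    bot <- grid[i0 + 1, j0 + 2, drop = FALSE] * (1 - fy) +
      grid[i0 + 2, j0 + 2, drop = FALSE] * fy
    layer <- sweep(top, 2, 1 - fx, "*") + sweep(bot, 2, fx, "*")
    acc <- acc + amp * layer
    total <- total + amp
    amp <- amp / 2
  }
  pmin(pmax(0.5 + acc / total * 1.6, 0), 1)
}

# Accumulate anti-aliased elliptical blobs into coverage mask m (max compositing).
# blobs: data.frame(cy, cx, ry, rx, theta) in pixel units.
paint_blobs <- function(m, blobs, alpha = 1) {
  h <- nrow(m); w <- ncol(m)
  for (i in seq_len(nrow(blobs))) {
    b <- blobs[i, ]
    r <- max(b$ry, b$rx)
    y0 <- max(1, floor(b$cy - r - 2)); y1 <- min(h, ceiling(b$cy + r + 2))
    x0 <- max(1, floor(b$cx - r - 2)); x1 <- min(w, ceiling(b$cx + r + 2))
    if (y0 > y1 || x0 > x1) next
    ys <- y0:y1; xs <- x0:x1
    dy <- ys - b$cy; dx <- xs - b$cx
    ct <- cos(b$theta); st <- sin(b$theta)
    u <- outer(dy * ct, dx * st, "+") / b$ry
    v <- outer(-dy * st, dx * ct, "+") / b$rx
    d <- sqrt(u^2 + v^2)
    edge <- 1.5 / min(b$ry, b$rx)  # ~1.5 px anti-aliased rim
    a <- pmin(pmax((1 - d) / edge, 0), 1) * alpha
    m[ys, xs] <- pmax(m[ys, xs], a)
  }
  m
}

random_blobs <- function(n, h, w, r_lo, r_hi, in_disc = NULL) {
  if (n == 0) {
    return(data.frame(cy = numeric(0), cx = numeric(0), ry = numeric(0),
                      rx = numeric(0), theta = numeric(0)))
  }
  if (is.null(in_disc)) {
    cy <- runif(n, 1, h); cx <- runif(n, 1, w)
  } else {
    rr <- in_disc$R * sqrt(runif(n))
    th <- runif(n, 0, 2 * pi)
    cy <- pmin(pmax(in_disc$cy + rr * sin(th), 1), h)
    cx <- pmin(pmax(in_disc$cx + rr * cos(th), 1), w)
  }
  r <- runif(n, r_lo, r_hi)
  ecc <- runif(n, 0.7, 1)
  data.frame(cy = cy, cx = cx, ry = r, rx = r * ecc,
             theta = runif(n, 0, pi))
}

#' Generate one synthetic histology scene
#'
#' Produces an 8-bit RGB image with an eosin-like pink textured background and
#' hematoxylin-like purple blobs. `no_cancer` scenes carry only sparse,
#' low-contrast round blobs; `partial_cancer` scenes add one dense
#' high-contrast cluster covering 20-60% of the area; `full_cancer` scenes are
#' covered at least 90% by the dense cluster. The tint strength of the cancer
#' cluster scales linearly with `cfg$separability`, so at separability 0 all
#' three categories are drawn from identical blob parameters.
#'
#' @param category one of `"no_cancer"`, `"partial_cancer"`, `"full_cancer"`.
#' @param cfg a [synth_config()].
#' @param seed integer RNG stream for this scene (derived from the dataset
#'   seed and scene id by [build_manifest()]).
#' @param scene_id,patient_id identifiers stored on the sample.
#' @return an `image_sample`: list with `pixels` (H x W x 3 integer array in
#'   \[0, 255\]), `label`, `category`, `patient_id`, `scene_id`.
#' @export
generate_scene <- function(category, cfg = synth_config(), seed = cfg$seed,
                           scene_id = category, patient_id = "P000") {
  stopifnot(length(category) == 1)
  check_category(category)
  h <- cfg$image_height; w <- cfg$image_width
  s <- cfg$separability
  mind <- min(h, w)
  px <- with_seed(seed, {
    t <- value_noise(h, w)
    base <- c(0.92, 0.72, 0.80)      # eosin pink
    amp <- c(0.08, 0.12, 0.08)
    img <- array(0, c(h, w, 3))
    for (c in 1:3) img[, , c] <- base[c] + (t - 0.5) * amp[c]

    # neutral sparse blobs, present in every category
    sparse <- random_blobs(12, h, w, 0.020 * mind, 0.045 * mind)
    m_sparse <- paint_blobs(matrix(0, h, w), sparse)
    purple <- c(0.45, 0.30, 0.62)
    a0 <- 0.25
    for (c in 1:3) {
      img[, , c] <- img[, , c] * (1 - a0 * m_sparse) + purple[c] * a0 * m_sparse
    }

    # category-specific dense cluster, tinted in proportion to separability
    if (category != "no_cancer") {
      r_lo <- 0.030 * mind; r_hi <- 0.060 * mind
      rbar2 <- mean(c(r_lo, r_hi))^2
      if (category == "partial_cancer") {
        f <- runif(1, 0.2, 0.6)
        R <- sqrt(f * h * w / pi)
        cy <- runif(1, 0.35 * h, 0.65 * h)
        cx <- runif(1, 0.35 * w, 0.65 * w)
        n <- ceiling(2.5 * R^2 / rbar2)
        dense <- random_blobs(n, h, w, r_lo, r_hi,
                              in_disc = list(cy = cy, cx = cx, R = R))
      } else {
        n <- ceiling(3.0 * h * w / (pi * rbar2))
        dense <- random_blobs(n, h, w, r_lo, r_hi)
      }
      m_dense <- paint_blobs(matrix(0, h, w), dense)
      a1 <- 0.85 * s
      for (c in 1:3) {
        img[, , c] <- img[, , c] * (1 - a1 * m_dense) + purple[c] * a1 * m_dense
      }
    }
    array(as.integer(round(pmin(pmax(img, 0), 1) * 255)), c(h, w, 3))
  })
  structure(list(pixels = px,
                 label = merge_labels(category),
                 category = category,
                 patient_id = patient_id,
                 scene_id = scene_id),
            class = "image_sample")
}

#' Build a dataset manifest with the requested category composition
#'
#' Scenes are listed per category (no_cancer, partial_cancer, full_cancer) and
#' patients are assigned round-robin within each category, so no patient ever
#' spans two categories. Labels follow [merge_labels()]. Pixel data are not
#' materialized; use [load_scene()] or [simulate_dataset()].
#'
#' @param cfg a [synth_config()].
#' @return a `dataset_manifest`: list with `samples` (data.frame with columns
#'   scene_id, patient_id, category, label, seed, path), `counts`, `seed` and
#'   the generating `config`.
#' @examples
#' m <- build_manifest(synth_config(n_no_cancer = 3, n_partial = 2, n_full = 1))
#' table(m$samples$label)
#' @export
build_manifest <- function(cfg = synth_config()) {
  stopifnot(inherits(cfg, "synth_config"))
  counts <- c(no_cancer = cfg$n_no_cancer,
              partial_cancer = cfg$n_partial,
              full_cancer = cfg$n_full)
  rows <- lapply(scene_categories, function(cat) {
    n <- counts[[cat]]
    if (n == 0) return(NULL)
    code <- c(no_cancer = "nc", partial_cancer = "pc", full_cancer = "fc")[[cat]]
    ids <- sprintf("%s%04d", code, seq_len(n))
    np <- cfg$n_patients[[cat]]
    patients <- sprintf("P_%s_%03d", code, ((seq_len(n) - 1) %% np) + 1)
    data.frame(scene_id = ids, patient_id = patients, category = cat,
               label = merge_labels(cat),
               seed = vapply(ids, function(id) derive_seed(cfg$seed, id), 0L),
               path = NA_character_, stringsAsFactors = FALSE)
  })
  samples <- do.call(rbind, rows)
  if (is.null(samples)) {
    samples <- data.frame(scene_id = character(0), patient_id = character(0),
                          category = character(0), label = character(0),
                          seed = integer(0), path = character(0),
                          stringsAsFactors = FALSE)
  }
  rownames(samples) <- NULL
  structure(list(samples = samples, counts = counts, seed = cfg$seed,
                 config = cfg),
            class = "dataset_manifest")
}

#' @export
print.dataset_manifest <- function(x, ...) {
  cat(sprintf("dataset_manifest: %d scenes (%d benign / %d malignant), seed %d\n",
              nrow(x$samples), sum(x$samples$label == "benign"),
              sum(x$samples$label == "malignant"), x$seed))
  print(x$counts)
  invisible(x)
}

#' Materialize one scene of a manifest
#'
#' Reads the PNG if the manifest row carries a path, otherwise regenerates the
#' scene from its per-scene RNG stream (both routes yield identical pixels).
#'
#' @param manifest a `dataset_manifest`.
#' @param scene_id scene identifier or integer row index.
#' @return an `image_sample`.
#' @export
load_scene <- function(manifest, scene_id) {
  s <- manifest$samples
  i <- if (is.numeric(scene_id)) scene_id else match(scene_id, s$scene_id)
  if (is.na(i) || i < 1 || i > nrow(s)) {
    stop_data("scene '%s' is not in the manifest", as.character(scene_id))
  }
  row <- s[i, ]
  if (!is.na(row$path) && file.exists(row$path)) {
    px <- png::readPNG(row$path)
    px <- array(as.integer(round(px * 255)), dim(px))
    structure(list(pixels = px, label = row$label, category = row$category,
                   patient_id = row$patient_id, scene_id = row$scene_id),
              class = "image_sample")
  } else {
    generate_scene(row$category, manifest$config, seed = row$seed,
                   scene_id = row$scene_id, patient_id = row$patient_id)
  }
}

#' Generate a dataset on disk
#'
#' Writes one PNG per scene plus `manifest.csv` (columns scene_id, patient_id,
#' category, label, path). Regenerating with the same config reproduces
#' byte-identical files in identical order.
#'
#' @param cfg a [synth_config()].
#' @param dir output directory (created if missing).
#' @return the `dataset_manifest`, with `path` filled in, invisibly.
#' @export
simulate_dataset <- function(cfg, dir) {
  manifest <- build_manifest(cfg)
  img_dir <- file.path(dir, "images")
  dir.create(img_dir, recursive = TRUE, showWarnings = FALSE)
  s <- manifest$samples
  for (i in seq_len(nrow(s))) {
    sc <- generate_scene(s$category[i], cfg, seed = s$seed[i],
                         scene_id = s$scene_id[i], patient_id = s$patient_id[i])
    p <- file.path(img_dir, paste0(s$scene_id[i], ".png"))
    png::writePNG(sc$pixels / 255, p)
    s$path[i] <- p
  }
  manifest$samples <- s
  write_manifest(manifest, file.path(dir, "manifest.csv"))
  invisible(manifest)
}

#' @rdname simulate_dataset
#' @param manifest a `dataset_manifest`.
#' @param file CSV path.
#' @export
write_manifest <- function(manifest, file) {
  write.csv(manifest$samples[, c("scene_id", "patient_id", "category",
                                 "label", "seed", "path")],
            file, row.names = FALSE)
  invisible(file)
}

#' Read a manifest CSV written by [write_manifest()]
#'
#' @param file CSV path.
#' @param cfg optional [synth_config()] enabling regeneration of scenes that
#'   have no stored PNG.
#' @return a `dataset_manifest`.
#' @export
read_manifest <- function(file, cfg = NULL) {
  s <- read.csv(file, stringsAsFactors = FALSE)
  need <- c("scene_id", "patient_id", "category", "label")
  if (!all(need %in% names(s))) {
    stop_data("manifest CSV must have columns %s", paste(need, collapse = ", "))
  }
  if (is.null(s$seed)) s$seed <- NA_integer_
  if (is.null(s$path)) s$path <- NA_character_
  check_category(s$category)
  counts <- vapply(scene_categories, function(cat) sum(s$category == cat), 0L)
  structure(list(samples = s, counts = counts,
                 seed = if (is.null(cfg)) NA_integer_ else cfg$seed,
                 config = cfg),
            class = "dataset_manifest")
}
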