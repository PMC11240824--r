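#' RGB core image
#'
#' Thin container for one tissue-microarray core: an `H x W x 3` numeric
#' array with intensities in `[0, 1]`, plus patient/core identifiers and a
#' compartment variant tag.
#'
#' @param pixels Numeric array `H x W x 3` with values in `[0, 1]`.
#' @param patient_id,core_id Identifiers.
#' @param variant One of "original", "epithelium", "stroma".
#' @return Object of class `core_image`.
#' @export
core_image <- function(pixels, patient_id, core_id,
                       variant = c("original", "epithelium", "stroma")) {
  variant <- match.arg(variant)
  d <- dim(pixels)
  if (length(d) != 3 || d[3] != 3) stop("pixels must be an H x W x 3 array")
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 1) {
    stop("pixel intensities must lie in [0, 1]")
  }
  structure(list(pixels = pixels, patient_id = patient_id,
                 core_id = core_id, variant = variant),
            class = "core_image")
}

#' @export
print.core_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<core_image %s (%s) %dx%d variant=%s>\n",
              x$core_id, x$patient_id, d[1], d[2], x$variant))
  invisible(x)
}

# mask label codes
MASK_BACKGROUND <- 0L
MASK_EPITHELIUM <- 1L
MASK_STROMA <- 2L

#' Three-class tissue segmentation mask
#'
#' Integer matrix over `{0 = background, 1 = epithelium, 2 = stroma}`.
#' Adipocyte regions are, by convention, folded into background.
#'
#' @param labels Integer matrix with values in `{0, 1, 2}`.
#' @return Object of class `segmentation_mask`.
#' @export
segmentation_mask <- function(labels) {
  if (!is.matrix(labels)) stop("labels must be a matrix")
  labels <- matrix(as.integer(labels), nrow(labels), ncol(labels))
  if (!all(labels %in% c(MASK_BACKGROUND, MASK_EPITHELIUM, MASK_STROMA))) {
    stop("unknown mask labels: allowed codes are 0 (background), ",
         "1 (epithelium), 2 (stroma)")
  }
  structure(list(labels = labels), class = "segmentation_mask")
}

#' Read / write core images and masks as PNG
#'
#' Masks are stored as single-channel PNGs with grey levels 0, 1/2, 1
#' encoding background, epithelium, stroma.
#'
#' @param path File path.
#' @param patient_id,core_id,variant Metadata attached on read.
#' @return `read_core_image` returns a [core_image()]; `read_mask` a
#'   [segmentation_mask()].
#' @export
read_core_image <- function(path, patient_id = NA_character_,
                            core_id = NA_character_, variant = "original") {
  px <- png::readPNG(path)
  if (length(dim(px)) == 2) px <- array(rep(px, 3), c(dim(px), 3))
  if (dim(px)[3] == 4) px <- px[, , 1:3]  # drop alpha
  core_image(px, patient_id, core_id, variant)
}

#' @rdname read_core_image
#' @param image A [core_image()].
#' @export
write_core_image <- function(image, path) {
  png::writePNG(image$pixels, path)
  invisible(path)
}

#' @rdname read_core_image
#' @export
read_mask <- function(path) {
  g <- png::readPNG(path)
  if (length(dim(g)) == 3) g <- g[, , 1]
  segmentation_mask(round(g * 2))
}

#' @rdname read_core_image
#' @param mask A [segmentation_mask()].
#' @export
write_mask <- function(mask, path) {
  png::writePNG(mask$labels / 2, path)
  invisible(path)
}

# optical density of an H x W x 3 pixel array, as an N x 3 matrix
optical_density <- function(px) {
  -log(pmax(matrix(px, prod(dim(px)[1:2]), 3), 1 / 255))
}

# Macenko-style stain basis estimation: SVD plane of tissue OD + robust
# angular extremes. Returns a 3 x 2 matrix (hematoxylin, eosin columns).
estimate_stain_basis <- function(px, beta = 0.15, alpha = 0.01) {
  od <- optical_density(px)
  tissue <- rowSums(od) > beta
  if (sum(tissue) < 10) return(NULL)
  odt <- od[tissue, , drop = FALSE]
  v <- eigen(stats::cov(odt), symmetric = TRUE)$vectors[, 1:2]
  proj <- odt %*% v
  # orient the plane basis so projections are mostly positive
  for (j in 1:2) if (stats::median(proj[, j]) < 0) {
    v[, j] <- -v[, j]; proj[, j] <- -proj[, j]
  }
  phi <- atan2(proj[, 2], proj[, 1])
  q <- stats::quantile(phi, c(alpha, 1 - alpha), names = FALSE)
  s1 <- v %*% c(cos(q[1]), sin(q[1]))
  s2 <- v %*% c(cos(q[2]), sin(q[2]))
  if (any(s1 < 0)) s1 <- abs(s1)
  if (any(s2 < 0)) s2 <- abs(s2)
  s1 <- s1 / sqrt(sum(s1^2))
  s2 <- s2 / sqrt(sum(s2^2))
  # hematoxylin has the larger red-channel optical density
  if (s1[1] >= s2[1]) cbind(s1, s2) else cbind(s2, s1)
}

# non-negative least-squares-ish concentrations for stain basis S (3 x 2)
stain_concentrations <- function(od, S) {
  C <- od %*% S %*% solve(crossprod(S))  # N x 2, unconstrained LS
  C[C < 0] <- 0
  C
}

#' Reference-based stain normalization
#'
#' Macenko-style normalization: both images are decomposed into optical
#' density, a two-stain (hematoxylin/eosin) basis is estimated for each via
#' the SVD plane of tissue pixels and robust angular extremes, and the
#' source concentrations are rescaled so their 99th percentiles match the
#' reference's. The image is reconstructed with the reference stain basis,
#' so its stain-channel statistics match the reference while white
#' background stays white (zero optical density maps to zero
#' concentration).
#'
#' @param image Source [core_image()].
#' @param reference Reference [core_image()] containing tissue.
#' @param beta Optical-density sum below which a pixel counts as
#'   background for basis estimation.
#' @return Normalized [core_image()] (unchanged, with a warning, if the
#'   source contains no tissue to estimate stains from).
#' @export
normalize_stain <- function(image, reference, beta = 0.15) {
  stopifnot(inherits(image, "core_image"), inherits(reference, "core_image"))
  S_src <- estimate_stain_basis(image$pixels, beta = beta)
  if (is.null(S_src)) {
    warning("no tissue found in source image; returned unchanged")
    return(image)
  }
  S_ref <- estimate_stain_basis(reference$pixels, beta = beta)
  if (is.null(S_ref)) stop("reference image contains no tissue")

  od_src <- optical_density(image$pixels)
  od_ref <- optical_density(reference$pixels)
  C_src <- stain_concentrations(od_src, S_src)
  C_ref <- stain_concentrations(od_ref, S_ref)
  p99 <- function(x) stats::quantile(x[x > 0], 0.99, names = FALSE)
  for (j in 1:2) {
    sc_src <- p99(C_src[, j])
    sc_ref <- p99(C_ref[, j])
    if (is.finite(sc_src) && sc_src > 0 && is.finite(sc_ref)) {
      C_src[, j] <- C_src[, j] * (sc_ref / sc_src)
    }
  }
  out <- exp(-(C_src %*% t(S_ref)))
  out[out > 1] <- 1
  d <- dim(image$pixels)
  core_image(array(out, d), image$patient_id, image$core_id, image$variant)
}

#' Segment a core into epithelium, stroma and background
#'
#' The default classifier deconvolves the image against the canonical H&E
#' stain basis and thresholds: pixels with total optical density below
#' `od_threshold` are background; remaining pixels are epithelium when the
#' hematoxylin concentration exceeds the eosin concentration and stroma
#' otherwise. A pluggable `classifier` function (taking the image,
#' returning an H x W label matrix over `{0, 1, 2}`) can replace the
#' heuristic, e.g. to consume externally produced masks.
#'
#' @param image A [core_image()] (normalized upstream).
#' @param classifier Optional function `image -> label matrix`.
#' @param od_threshold Background optical-density-sum threshold.
#' @return A [segmentation_mask()] covering every pixel.
#' @export
segment_tissue <- function(image, classifier = NULL, od_threshold = 0.15) {
  stopifnot(inherits(image, "core_image"))
  d <- dim(image$pixels)
  if (!is.null(classifier)) {
    lab <- classifier(image)
    if (inherits(lab, "segmentation_mask")) lab <- lab$labels
    if (!is.matrix(lab) || !all(dim(lab) == d[1:2])) {
      stop("external classifier returned a mask of the wrong shape")
    }
    return(segmentation_mask(lab))
  }
  od <- optical_density(image$pixels)
  C <- stain_concentrations(od, he_stain_matrix())
  lab <- matrix(MASK_BACKGROUND, d[1], d[2])
  tissue <- rowSums(od) >= od_threshold
  lab[tissue & (C[, 1] > C[, 2])] <- MASK_EPITHELIUM
  lab[tissue & (C[, 1] <= C[, 2])] <- MASK_STROMA
  segmentation_mask(lab)
}

#' Build the three compartment variants of a core
#'
#' Returns the original image with background removed, an epithelium-only
#' image, and a stroma-only image; non-retained pixels are set to white.
#'
#' @param image A [core_image()] with `variant == "original"`.
#' @param mask Its [segmentation_mask()].
#' @return Named list of three [core_image()]s
#'   (`original`, `epithelium`, `stroma`).
#' @export
make_variants <- function(image, mask) {
  stopifnot(inherits(image, "core_image"), inherits(mask, "segmentation_mask"))
  d <- dim(image$pixels)
  if (!all(dim(mask$labels) == d[1:2])) stop("mask shape does not match image")
  keep_white <- function(keep) {
    px <- image$pixels
    drop <- !keep
    for (b in 1:3) {
      ch <- px[, , b]
      ch[drop] <- 1
      px[, , b] <- ch
    }
    px
  }
  lab <- mask$labels
  list(
    original = core_image(keep_white(lab != MASK_BACKGROUND),
                          image$patient_id, image$core_id, "original"),
    epithelium = core_image(keep_white(lab == MASK_EPITHELIUM),
                            image$patient_id, image$core_id, "epithelium"),
    stroma = core_image(keep_white(lab == MASK_STROMA),
                        image$patient_id, image$core_id, "stroma")
  )
}

#' Non-overlapping tile grid origins
#'
#' 0-based, row-major, top-left origins of the square tiles fitting inside
#' an `h x w` image; right/bottom remainders smaller than `patch_size` are
#' discarded rather than padded.
#'
#' @param h,w Image height and width in pixels.
#' @param patch_size Tile side length.
#' @return data.frame with columns `row0`, `col0` (possibly 0 rows).
#' @export
tile_grid <- function(h, w, patch_size = 200) {
  nr <- h %/% patch_size
  nc <- w %/% patch_size
  if (nr == 0 || nc == 0) {
    return(data.frame(row0 = integer(0), col0 = integer(0)))
  }
  g <- expand.grid(col0 = (seq_len(nc) - 1L) * patch_size,
                   row0 = (seq_len(nr) - 1L) * patch_size)
  data.frame(row0 = g$row0, col0 = g$col0)
}

#' Split a core into 200x200 patches
#'
#' Tiles the image on a non-overlapping grid from the top-left corner and
#' attaches each patch's background fraction, computed from the
#' segmentation mask restricted to the tile (background is the
#' segmentation class, not raw whiteness).
#'
#' @param image A [core_image()].
#' @param mask Matching [segmentation_mask()] (optional; without it the
#'   background fraction falls back to the near-white pixel fraction).
#' @param patch_size Tile side length (default 200).
#' @return List of `core_patch` objects (empty, with a warning, when the
#'   image is smaller than one patch).
#' @export
tile_patches <- function(image, mask = NULL, patch_size = 200) {
  stopifnot(inherits(image, "core_image"))
  d <- dim(image$pixels)
  grid <- tile_grid(d[1], d[2], patch_size)
  if (nrow(grid) == 0) {
    warning("image (", d[1], "x", d[2], ") smaller than one patch; no tiles")
    return(list())
  }
  if (!is.null(mask)) {
    stopifnot(inherits(mask, "segmentation_mask"))
    if (!all(dim(mask$labels) == d[1:2])) stop("mask shape does not match image")
  }
  lapply(seq_len(nrow(grid)), function(i) {
    rr <- grid$row0[i] + seq_len(patch_size)
    cc <- grid$col0[i] + seq_len(patch_size)
    px <- image$pixels[rr, cc, , drop = FALSE]
    bg <- if (!is.null(mask)) {
      mean(mask$labels[rr, cc] == MASK_BACKGROUND)
    } else {
      mean(apply(px, c(1, 2), min) > 0.95)
    }
    structure(list(patient_id = image$patient_id, core_id = image$core_id,
                   variant = image$variant,
                   row0 = grid$row0[i], col0 = grid$col0[i], pixels = px,
                   background_fraction = bg, artifact_flags = character(0)),
              class = "core_patch")
  })
}

#' Default artifact-detector thresholds
#'
#' Engineering defaults: a bubble is a large connected near-uniform
#' low-saturation non-white region; blur is a low variance-of-Laplacian
#' focus measure; overexposure is a dominant near-saturated brightness
#' fraction.
#'
#' @return Named list of thresholds.
#' @export
artifact_thresholds <- function() {
  list(bubble_sat = 0.10, bubble_value = 0.95, bubble_frac = 0.40,
       bubble_sd = 0.06, blur_var = 1e-3, over_value = 0.98, over_frac = 0.90)
}

# flags for one patch: subset of {"bubble", "blur", "overexposed"}
detect_artifacts <- function(patch, th = artifact_thresholds()) {
  px <- patch$pixels[, , , drop = TRUE]
  mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
  mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
  sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
  gray <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
  flags <- character(0)

  grey_region <- sat < th$bubble_sat & mx < th$bubble_value
  if (mean(grey_region) > th$bubble_frac &&
      stats::sd(gray[grey_region]) < th$bubble_sd) {
    flags <- c(flags, "bubble")
  }
  n <- nrow(gray)
  if (n > 2) {
    core <- gray[2:(n - 1), 2:(n - 1)]
    lap <- 4 * core - gray[1:(n - 2), 2:(n - 1)] - gray[3:n, 2:(n - 1)] -
      gray[2:(n - 1), 1:(n - 2)] - gray[2:(n - 1), 3:n]
    if (stats::var(as.vector(lap)) < th$blur_var) flags <- c(flags, "blur")
  }
  if (mean(gray > th$over_value) > th$over_frac &&
      patch$background_fraction < 0.5) {
    flags <- c(flags, "overexposed")
  }
  flags
}

#' Filter patches on background fraction and artifacts
#'
#' Removes patches with *more than* `bg_threshold` background (strict
#' inequality: a patch at exactly the threshold is kept) and patches with
#' any detected artifact. Detector flags are recorded on every patch; the
#' full kept/dropped manifest is attached as the `"manifest"` attribute.
#'
#' @param patches List of `core_patch` from [tile_patches()].
#' @param bg_threshold Background fraction above which a patch is dropped
#'   (default 0.90).
#' @param thresholds Detector thresholds, see [artifact_thresholds()].
#' @return List of kept patches, with attribute `manifest` (data.frame:
#'   core_id, row0, col0, background_fraction, flags, kept).
#' @export
filter_patches <- function(patches, bg_threshold = 0.90,
                           thresholds = artifact_thresholds()) {
  if (length(patches) == 0) {
    out <- list()
    attr(out, "manifest") <- data.frame(core_id = character(0),
                                        row0 = integer(0), col0 = integer(0),
                                        background_fraction = numeric(0),
                                        flags = character(0), kept = logical(0))
    return(out)
  }
  patches <- lapply(patches, function(p) {
    p$artifact_flags <- detect_artifacts(p, thresholds)
    p
  })
  kept <- vapply(patches, function(p) {
    p$background_fraction <= bg_threshold && length(p$artifact_flags) == 0
  }, logical(1))
  manifest <- data.frame(
    core_id = vapply(patches, `[[`, character(1), "core_id"),
    row0 = vapply(patches, `[[`, numeric(1), "row0"),
    col0 = vapply(patches, `[[`, numeric(1), "col0"),
    background_fraction = vapply(patches, `[[`, numeric(1),
                                 "background_fraction"),
    flags = vapply(patches, function(p) paste(p$artifact_flags, collapse = ";"),
                   character(1)),
    kept = kept, stringsAsFactors = FALSE)
  out <- patches[kept]
  attr(out, "manifest") <- manifest
  out
}
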