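#' @title Tiling, optical density and Macenko stain normalization
#' @name preprocess
NULL

#' Preprocessing configuration
#'
#' @param tile_size_px Tile side in pixels; whole-slide practice uses 1000,
#'   synthetic tests use smaller tiles (default 1000).
#' @param background_saturation_threshold HSV saturation below which a pixel
#'   counts as background (default 0.05).
#' @param background_tile_fraction A tile is flagged non-tissue when at least
#'   this fraction of its pixels are background (default 0.75).
#' @param od_beta Optical-density floor; pixels with any channel below it are
#'   treated as transparent and dropped from stain estimation (default 0.15).
#' @param alpha_percentile Robust percentile (in (0, 50)) of the projected
#'   angle distribution used to pick the extreme stain directions (default 1).
#' @param i0 Per-channel illuminant intensity (default 255).
#' @return A `preprocess_config` list.
#' @export
preprocess_config <- function(tile_size_px = 1000,
                              background_saturation_threshold = 0.05,
                              background_tile_fraction = 0.75,
                              od_beta = 0.15, alpha_percentile = 1,
                              i0 = c(255, 255, 255)) {
  stopifnot(tile_size_px >= 1,
            background_saturation_threshold >= 0,
            background_saturation_threshold <= 1,
            background_tile_fraction >= 0, background_tile_fraction <= 1,
            od_beta > 0, alpha_percentile > 0, alpha_percentile < 50,
            all(i0 > 0))
  if (length(i0) == 1) i0 <- rep(i0, 3)
  structure(list(tile_size_px = tile_size_px,
                 background_saturation_threshold = background_saturation_threshold,
                 background_tile_fraction = background_tile_fraction,
                 od_beta = od_beta, alpha_percentile = alpha_percentile,
                 i0 = i0), class = "preprocess_config")
}

#' Tile an image into non-overlapping fixed-size patches
#'
#' Cuts the image into a grid of `tile_size_px` squares; partial edge tiles
#' are discarded (fixed-size backbone contract). Each tile is flagged
#' `is_tissue = FALSE` when at least `background_tile_fraction` of its pixels
#' have HSV saturation below `background_saturation_threshold`.
#'
#' @param image h x w x 3 RGB array with values in \[0, 255\].
#' @param config A [preprocess_config()].
#' @param slide_id Identifier stored on each tile.
#' @return List of `tile_patch` objects (fields `slide_id`, `grid_row`,
#'   `grid_col`, `pixels`, `is_tissue`), in row-major grid order; empty list
#'   when the image is smaller than one tile.
#' @export
tile_slide <- function(image, config = preprocess_config(),
                       slide_id = "slide") {
  stopifnot(length(dim(image)) == 3, dim(image)[3] >= 3)
  ts <- config$tile_size_px
  nr <- dim(image)[1] %/% ts
  nc <- dim(image)[2] %/% ts
  if (nr == 0 || nc == 0) return(list())
  tiles <- vector("list", nr * nc)
  k <- 0
  for (r in seq_len(nr)) {
    for (cc in seq_len(nc)) {
      px <- image[((r - 1) * ts + 1):(r * ts), ((cc - 1) * ts + 1):(cc * ts),
                  1:3, drop = FALSE]
      mx <- pmax(px[, , 1], px[, , 2], px[, , 3])
      mn <- pmin(px[, , 1], px[, , 2], px[, , 3])
      sat <- ifelse(mx > 0, (mx - mn) / mx, 0)
      bg_frac <- mean(sat < config$background_saturation_threshold)
      k <- k + 1
      tiles[[k]] <- structure(
        list(slide_id = slide_id, grid_row = r - 1L, grid_col = cc - 1L,
             pixels = px, is_tissue = bg_frac < config$background_tile_fraction),
        class = "tile_patch")
    }
  }
  tiles
}

#' Optical density transform and its inverse
#'
#' `OD = -log10((pixels + 1) / (I0 + 1))`, a strictly decreasing bijection of
#' pixel intensity; the +1 offset keeps 0-valued pixels finite. Stains mix
#' linearly in OD space.
#'
#' @param pixels Numeric array/matrix of RGB values in \[0, 255\]; for arrays
#'   the last dimension must be the 3 channels.
#' @param i0 Per-channel illuminant (length 3 or scalar).
#' @return Array of the same shape (nonnegative OD, or pixels in \[0, 255\]).
#' @export
rgb_to_od <- function(pixels, i0 = c(255, 255, 255)) {
  if (length(i0) == 1) i0 <- rep(i0, 3)
  d <- dim(pixels)
  if (is.null(d)) return(-log10((pixels + 1) / (i0[1] + 1)))
  i0v <- i0[slice.index(pixels, length(d))]
  od <- -log10((pixels + 1) / (i0v + 1))
  od[od < 0] <- 0
  od
}

#' @rdname rgb_to_od
#' @param od Nonnegative optical-density values.
#' @export
od_to_rgb <- function(od, i0 = c(255, 255, 255)) {
  if (length(i0) == 1) i0 <- rep(i0, 3)
  d <- dim(od)
  i0v <- if (is.null(d)) i0[1] else i0[slice.index(od, length(d))]
  px <- (i0v + 1) * 10^(-od) - 1
  px[px < 0] <- 0; px[px > 255] <- 255
  px
}

# n x 3 OD pixel matrix from an h x w x 3 image
od_pixel_matrix <- function(image, i0) {
  od <- rgb_to_od(image, i0)
  cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
}

# Exact nonnegative least squares for the 2-column stain system, vectorized:
# solve min ||od - M c||^2 s.t. c >= 0 for every row of `od` (n x 3).
nnls_two_stain <- function(od, m) {
  gram <- crossprod(m)            # 2 x 2
  rhs <- od %*% m                 # n x 2
  det <- gram[1, 1] * gram[2, 2] - gram[1, 2]^2
  c1 <- (rhs[, 1] * gram[2, 2] - rhs[, 2] * gram[1, 2]) / det
  c2 <- (rhs[, 2] * gram[1, 1] - rhs[, 1] * gram[1, 2]) / det
  neg <- c1 < 0 | c2 < 0
  if (any(neg)) {
    # clamp each variable in turn, keep the better residual
    a1 <- pmax(rhs[neg, 1] / gram[1, 1], 0) # c2 = 0
    a2 <- pmax(rhs[neg, 2] / gram[2, 2], 0) # c1 = 0
    r1 <- -2 * a1 * rhs[neg, 1] + a1^2 * gram[1, 1]
    r2 <- -2 * a2 * rhs[neg, 2] + a2^2 * gram[2, 2]
    use1 <- r1 <= r2
    c1[neg] <- ifelse(use1, a1, 0)
    c2[neg] <- ifelse(use1, 0, a2)
  }
  cbind(c1, c2)
}

#' Estimate a stain profile by the Macenko method
#'
#' Filters out transparent pixels (any channel OD below `od_beta`), takes the
#' SVD of the remaining OD cloud, projects pixels onto the plane of the top
#' two right singular vectors, and back-projects the directions at the
#' `alpha_percentile` and `100 - alpha_percentile` of the projected angle
#' distribution as the two stain vectors. Vectors are sign-corrected to be
#' nonnegative, unit-normalized, and ordered with hematoxylin first
#' (convention: hematoxylin is the column with the larger blue-channel OD
#' component). Robust per-stain maxima are the 99th percentile of the
#' nonnegative deconvolution concentrations.
#'
#' @param od_pixels n x 3 matrix of OD pixels, or an h x w x 3 RGB image in
#'   \[0, 255\] (converted internally).
#' @param config A [preprocess_config()].
#' @return A `stain_profile`: list with `stain_vectors` (3 x 2, columns
#'   hematoxylin then eosin) and `max_concentrations` (length 2).
#' @export
estimate_stain_profile <- function(od_pixels, config = preprocess_config()) {
  if (length(dim(od_pixels)) == 3)
    od_pixels <- od_pixel_matrix(od_pixels, config$i0)
  keep <- od_pixels[, 1] >= config$od_beta &
    od_pixels[, 2] >= config$od_beta & od_pixels[, 3] >= config$od_beta
  od <- od_pixels[keep, , drop = FALSE]
  if (nrow(od) < 2) stop("insufficient stain signal: fewer than 2 usable pixels")
  sv <- svd(od, nu = 0, nv = 3)
  if (sv$d[2] < 1e-8 * sv$d[1])
    stop("insufficient stain signal: rank-deficient OD cloud")
  v <- sv$v[, 1:2]
  # orient the plane basis so projections land in a consistent half-plane
  if (sum(v[, 1]) < 0) v[, 1] <- -v[, 1]
  proj <- od %*% v
  phi <- atan2(proj[, 2], proj[, 1])
  a <- config$alpha_percentile / 100
  lo <- quantile(phi, a, names = FALSE)
  hi <- quantile(phi, 1 - a, names = FALSE)
  dirs <- cbind(v %*% c(cos(lo), sin(lo)), v %*% c(cos(hi), sin(hi)))
  # sign-correct each direction to the nonnegative orthant
  for (j in 1:2) {
    if (sum(dirs[, j]) < 0) dirs[, j] <- -dirs[, j]
    dirs[, j] <- pmax(dirs[, j], 0)
    dirs[, j] <- dirs[, j] / sqrt(sum(dirs[, j]^2))
  }
  # hematoxylin convention: larger blue-channel OD component first
  if (dirs[3, 1] < dirs[3, 2]) dirs <- dirs[, 2:1]
  conc <- nnls_two_stain(od, dirs)
  maxc <- c(quantile(conc[, 1], 0.99, names = FALSE),
            quantile(conc[, 2], 0.99, names = FALSE))
  structure(list(stain_vectors = dirs, max_concentrations = maxc),
            class = "stain_profile")
}

#' Normalize a tile to a reference stain profile
#'
#' Deconvolves the tile's OD with the source stain vectors (nonnegative least
#' squares per pixel), rescales each stain concentration by
#' `reference$max_concentrations / source$max_concentrations`, re-composes
#' with the reference stain vectors and inverts the OD transform. Background
#' (non-tissue) tiles are returned unchanged with a `normalize_skipped`
#' attribute and a warning.
#'
#' @param tile A `tile_patch` from [tile_slide()].
#' @param source Stain profile of the tile's slide.
#' @param reference Target stain profile.
#' @param config A [preprocess_config()] (supplies the illuminant).
#' @return The normalized `tile_patch` (pixels clamped to \[0, 255\]).
#' @export
normalize_tile <- function(tile, source, reference,
                           config = preprocess_config()) {
  stopifnot(inherits(tile, "tile_patch"))
  if (!isTRUE(tile$is_tissue)) {
    warning("background-only tile returned unchanged")
    attr(tile, "normalize_skipped") <- TRUE
    return(tile)
  }
  d <- dim(tile$pixels)
  od <- od_pixel_matrix(tile$pixels, config$i0)
  conc <- nnls_two_stain(od, source$stain_vectors)
  scale <- reference$max_concentrations / source$max_concentrations
  conc <- sweep(conc, 2, scale, "*")
  od_new <- conc %*% t(reference$stain_vectors)
  px <- od_to_rgb(array(od_new, c(d[1] * d[2], 1, 3)), config$i0)
  tile$pixels <- array(px, d)
  tile
}

#' Serialize / load a stain profile as JSON
#' @param profile A `stain_profile`.
#' @param path JSON file path.
#' @return The path (write) or the `stain_profile` (read).
#' @export
write_stain_profile <- function(profile, path) {
  jsonlite::write_json(list(stain_vectors = profile$stain_vectors,
                            max_concentrations = profile$max_concentrations),
                       path, digits = NA)
  invisible(path)
}

#' @rdname write_stain_profile
#' @export
read_stain_profile <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(stain_vectors = matrix(unlist(x$stain_vectors), nrow = 3),
                 max_concentrations = as.numeric(x$max_concentrations)),
            class = "stain_profile")
}

#' The shipped default reference stain profile
#'
#' Standard H&E stain vectors ([default_stain_matrix()]) with unit robust
#' maxima; used when no cohort reference slide is designated.
#' @return A `stain_profile`.
#' @export
default_stain_profile <- function() {
  structure(list(stain_vectors = default_stain_matrix(),
                 max_concentrations = c(1, 1)), class = "stain_profile")
}
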