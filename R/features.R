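#' @title Tile feature extraction through a pluggable convolutional backbone
#' @name features
NULL

#' Describe a feature-extraction backbone
#'
#' The backbone is an interface: any frozen map from a fixed-size RGB tile to
#' a `d`-vector. Two deterministic backbones ship with the package, both
#' fixed-seed random convolutional feature extractors (random filter banks,
#' ReLU, global mean/sd pooling of the response maps, then a fixed random
#' affine projection to `d`):
#' \describe{
#'   \item{`default`}{`d = 2048`, 24 filters, input side 64 — the production
#'     contract dimensionality; a pretrained extractor with the same signature
#'     can be plugged in through this interface.}
#'   \item{`tiny`}{`d = 16`, 8 filters, input side 32 — runs the whole
#'     pipeline on CPU in seconds; used throughout the tests.}
#' }
#' No training ever occurs here; the backbone is frozen.
#'
#' @param name `"default"`, `"tiny"`, or a custom label (then supply
#'   `output_dim`, `n_filters`, `input_side`).
#' @param output_dim,n_filters,input_side Override the preset dimensions.
#' @param seed Seed fixing the filter bank and projection (default 42).
#' @return A `backbone_spec` with fields `name`, `output_dim`, `weights_id`,
#'   `deterministic`.
#' @export
backbone_spec <- function(name = "default", output_dim = NULL,
                          n_filters = NULL, input_side = NULL, seed = 42) {
  preset <- switch(name,
    default = list(d = 2048, f = 24, side = 64),
    tiny = list(d = 16, f = 8, side = 32),
    list(d = output_dim, f = n_filters %||% 8, side = input_side %||% 32))
  d <- output_dim %||% preset$d
  if (is.null(d) || d < 1) stop("output_dim must be >= 1")
  structure(list(name = name, output_dim = d,
                 n_filters = n_filters %||% preset$f,
                 input_side = input_side %||% preset$side,
                 seed = seed,
                 weights_id = sprintf("%s-seed%d", name, seed),
                 deterministic = TRUE),
            class = "backbone_spec")
}

# Fixed random filter bank + projection for a backbone (memoised per spec).
backbone_weights <- function(spec) {
  key <- sprintf("%s-%d-%d-%d", spec$weights_id, spec$output_dim,
                 spec$n_filters, spec$input_side)
  cache <- .moma_backbone_cache
  if (!is.null(cache[[key]])) return(cache[[key]])
  w <- with_seed(spec$seed, {
    filters <- lapply(seq_len(spec$n_filters), function(i) {
      k <- matrix(rnorm(9), 3, 3)
      k - mean(k) # zero-mean filters respond to texture, not brightness
    })
    # raw stats: per-channel mean/sd (6) + per-filter mean/sd on gray (2f)
    n_stats <- 6 + 2 * spec$n_filters
    proj <- matrix(rnorm(n_stats * spec$output_dim, sd = 1 / sqrt(n_stats)),
                   n_stats, spec$output_dim)
    bias <- rnorm(spec$output_dim, sd = 0.01)
    list(filters = filters, proj = proj, bias = bias)
  })
  assign(key, w, envir = cache)
  w
}

.moma_backbone_cache <- new.env(parent = emptyenv())

# d-vector for one tile's pixel array
backbone_forward_one <- function(pixels, spec, w) {
  x <- pixels / 255
  side <- spec$input_side
  if (dim(x)[1] != side || dim(x)[2] != side)
    x <- EBImage::resize(x, side, side) # bilinear
  gray <- (x[, , 1] + x[, , 2] + x[, , 3]) / 3
  stats <- c(mean(x[, , 1]), mean(x[, , 2]), mean(x[, , 3]),
             sd(as.vector(x[, , 1])), sd(as.vector(x[, , 2])),
             sd(as.vector(x[, , 3])))
  for (k in w$filters) {
    r <- EBImage::filter2(gray, k)
    r[r < 0] <- 0 # ReLU
    stats <- c(stats, mean(r), sd(as.vector(r)))
  }
  as.vector(stats %*% w$proj) + w$bias
}

#' Extract a feature bag from a slide's tissue tiles
#'
#' Applies the frozen backbone to each tile, one feature row per tile in input
#' order. Deterministic: repeated calls are bit-identical, and permuting the
#' tiles permutes the rows identically.
#'
#' @param tiles List of `tile_patch` objects (tissue tiles of one slide).
#' @param backbone A [backbone_spec()].
#' @return A `feature_bag`: list with `slide_id`, `features`
#'   (n_tiles x d matrix) and `tile_ids` (character, `r<row>_c<col>`).
#' @export
extract_features <- function(tiles, backbone = backbone_spec("tiny")) {
  tiles <- Filter(function(t) isTRUE(t$is_tissue), tiles)
  if (length(tiles) == 0)
    stop("empty bag: a slide must contribute at least one tissue tile")
  sz <- vapply(tiles, function(t) dim(t$pixels)[1], numeric(1))
  if (length(unique(sz)) > 1) stop("all tiles must have the same size")
  w <- backbone_weights(backbone)
  feats <- t(vapply(tiles, function(t) backbone_forward_one(t$pixels, backbone, w),
                    numeric(backbone$output_dim)))
  if (backbone$output_dim == 1) feats <- matrix(feats, ncol = 1)
  ids <- vapply(tiles, function(t) sprintf("r%d_c%d", t$grid_row, t$grid_col),
                character(1))
  if (anyDuplicated(ids)) stop("tile ids must be unique within a bag")
  structure(list(slide_id = tiles[[1]]$slide_id, features = feats,
                 tile_ids = ids), class = "feature_bag")
}

#' Write / read a feature bag as CSV
#'
#' One file per slide: first column `tile_id`, remaining columns the feature
#' matrix.
#' @param bag A `feature_bag`.
#' @param path CSV path.
#' @return The path (write) or the `feature_bag` (read; slide id taken from
#'   the file name unless a `slide_id` column is present).
#' @export
write_feature_bag <- function(bag, path) {
  df <- data.frame(slide_id = bag$slide_id, tile_id = bag$tile_ids,
                   bag$features, check.names = FALSE)
  colnames(df) <- c("slide_id", "tile_id",
                    paste0("f", seq_len(ncol(bag$features))))
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_feature_bag
#' @export
read_feature_bag <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  structure(list(slide_id = df$slide_id[1],
                 features = unname(as.matrix(df[, -(1:2), drop = FALSE])),
                 tile_ids = df$tile_id), class = "feature_bag")
}

#' Fit / apply a per-dimension feature standardizer
#'
#' Backbone statistics carry large common offsets across tiles; z-scoring each
#' feature dimension on the training set (mean 0, sd 1) puts tile-to-tile
#' contrast on a common scale for clustering and the MIL model. Fit on
#' training bags only; apply to every bag.
#'
#' @param bags List of training `feature_bag`s.
#' @return A `feature_scaler` with `center` and `scale` vectors.
#' @export
fit_feature_scaler <- function(bags) {
  x <- do.call(rbind, lapply(bags, function(b) b$features))
  ctr <- colMeans(x)
  scl <- apply(x, 2, sd)
  scl[scl < 1e-8] <- 1
  structure(list(center = ctr, scale = scl), class = "feature_scaler")
}

#' @rdname fit_feature_scaler
#' @param bag A `feature_bag`.
#' @param scaler A `feature_scaler`.
#' @return The bag with standardized features.
#' @export
scale_bag <- function(bag, scaler) {
  bag$features <- sweep(sweep(bag$features, 2, scaler$center), 2,
                        scaler$scale, "/")
  bag
}
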