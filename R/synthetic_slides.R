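#' @title Synthetic H&E-like slides, concept textures and survival cohorts
#' @description Generators for fully synthetic study material: procedural
#'   two-stain slides composed in optical density from a known stain matrix,
#'   seven separable pathology "concept" textures, and right-censored Weibull
#'   survival cohorts with known covariate effects. Every downstream module is
#'   exercised against these generators, so their contracts (determinism,
#'   separability, planted ground truth) are part of the tested surface.
#' @name synthetic_slides
NULL

#' The seven pathology concepts
#'
#' Tissue concepts used by the texture generator and the concept classifier:
#' tumor epithelium (TUM), cancer-associated stroma (STR), lymphocytes (LYM),
#' smooth muscle (MUS), mucus (MUC), adipose tissue (ADI) and debris (DEB).
#'
#' @return Character vector of the seven concept codes, in integer-code order
#'   (mask code = position; 0 is background).
#' @export
concept_names <- function() c("TUM", "STR", "LYM", "MUS", "MUC", "ADI", "DEB")

#' Default H&E stain matrix
#'
#' Column-unit optical-density vectors for hematoxylin (first column) and
#' eosin (second column), the standard reference values used in stain
#' deconvolution. Used as the default forward-model matrix for synthesis and
#' as the shipped normalization reference.
#'
#' @return 3 x 2 matrix with unit-norm nonnegative columns.
#' @export
default_stain_matrix <- function() {
  m <- cbind(h = c(0.65, 0.70, 0.29), e = c(0.07, 0.99, 0.11))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}

## --- low-level pattern primitives -----------------------------------------

# 0/1 matrix with n random disks of radius in [rmin, rmax]; uses ambient RNG
disk_mask <- function(nr, nc, n, rmin, rmax) {
  m <- matrix(0, nr, nc)
  if (n < 1) return(m)
  cy <- runif(n, 1, nr); cx <- runif(n, 1, nc); r <- runif(n, rmin, rmax)
  ys <- row(m); xs <- col(m)
  for (i in seq_len(n)) {
    m[(ys - cy[i])^2 + (xs - cx[i])^2 <= r[i]^2] <- 1
  }
  m
}

# smooth [0,1] field from a few random Gaussian bumps; uses ambient RNG
blob_field <- function(nr, nc, n_blobs, width) {
  f <- matrix(0, nr, nc)
  cy <- runif(n_blobs, 1, nr); cx <- runif(n_blobs, 1, nc)
  ys <- row(f); xs <- col(f)
  for (i in seq_len(n_blobs)) {
    f <- f + exp(-((ys - cy[i])^2 + (xs - cx[i])^2) / (2 * width^2))
  }
  f <- f / max(f)
  f
}

# Per-concept hematoxylin/eosin concentration maps (OD-concentration units).
# Recipes are procedural and chosen so that (a) distinct concepts separate
# linearly in simple filter statistics, and (b) LYM contains pure-hematoxylin
# pixels and STR pure-eosin pixels, giving the Macenko estimator clean angle
# extremes on rendered slides. Uses the ambient RNG.
concept_concentrations <- function(concept, nr, nc = nr) {
  z <- matrix(0, nr, nc)
  s <- min(nr, nc)
  switch(concept,
    TUM = { # large nuclei dots, eosinophilic cytoplasm
      dots <- disk_mask(nr, nc, round(nr * nc / 260), s / 20, s / 13)
      list(h = 0.15 + 1.0 * dots, e = 0.45 + 0.08 * blob_field(nr, nc, 4, s / 3) - 0.45 * dots)
    },
    STR = { # fine diagonal collagen stripes, pure eosin
      ph <- runif(1, 0, 2 * pi)
      w <- 0.5 + 0.5 * sin(2 * pi * (row(z) + col(z)) / (s / 8) + ph)
      list(h = z, e = 0.85 * w)
    },
    LYM = { # dense small pure-hematoxylin dots
      dots <- disk_mask(nr, nc, round(nr * nc / 55), s / 55, s / 34)
      list(h = 0.08 + 1.25 * dots, e = 0.12 * (1 - dots))
    },
    MUS = { # coarse horizontal fibres, strong eosin
      ph <- runif(1, 0, 2 * pi)
      w <- 0.5 + 0.5 * sin(2 * pi * row(z) / (s / 3.2) + ph)
      list(h = matrix(0.25, nr, nc), e = 0.95 * w)
    },
    MUC = { # pale smooth mucin pools: low concentration, low variance
      f <- blob_field(nr, nc, 3, s / 2.5)
      list(h = 0.10 * f, e = 0.28 * f)
    },
    ADI = { # near-white circular fat vacuoles with thin eosin membranes
      n_cells <- sample(2:4, 1)
      cy <- runif(n_cells, nr * 0.2, nr * 0.8); cx <- runif(n_cells, nc * 0.2, nc * 0.8)
      r <- runif(n_cells, s / 6, s / 4.2)
      h <- matrix(0.10, nr, nc); e <- matrix(0.35, nr, nc)
      ys <- row(z); xs <- col(z)
      for (i in seq_len(n_cells)) {
        d2 <- (ys - cy[i])^2 + (xs - cx[i])^2
        inside <- d2 <= (r[i] - 1.5)^2
        ring <- d2 <= (r[i] + 1.5)^2 & !inside
        h[inside] <- 0.01; e[inside] <- 0.01; e[ring] <- 0.7
      }
      list(h = h, e = e)
    },
    DEB = { # coarse blocky high-variance speckle in both stains
      b <- max(2, round(s / 14))
      br <- ceiling(nr / b); bc <- ceiling(nc / b)
      uh <- matrix(runif(br * bc, 0, 1.0), br, bc)
      ue <- matrix(runif(br * bc, 0, 1.0), br, bc)
      idx <- cbind(rep(ceiling(seq_len(nr) / b), nc),
                   rep(ceiling(seq_len(nc) / b), each = nr))
      list(h = matrix(uh[idx], nr, nc), e = matrix(ue[idx], nr, nc))
    },
    stop("unknown concept id: ", concept)
  )
}

# Forward optical-density model: concentrations -> 8-bit RGB.
# od: h x w x 3 nonnegative array; returns values in [0, 255].
od_compose_rgb <- function(ch, ce, stain_matrix, noise_sd = 0, i0 = 255) {
  nr <- nrow(ch); nc <- ncol(ch)
  conc <- rbind(as.vector(ch), as.vector(ce)) # 2 x npix
  od <- stain_matrix %*% conc                 # 3 x npix
  if (noise_sd > 0) od <- od + matrix(rnorm(length(od), 0, noise_sd), nrow(od))
  od[od < 0] <- 0
  px <- (i0 + 1) * 10^(-od) - 1
  px[px < 0] <- 0; px[px > 255] <- 255
  array(c(matrix(px[1, ], nr, nc), matrix(px[2, ], nr, nc), matrix(px[3, ], nr, nc)),
        dim = c(nr, nc, 3))
}

#' Generate a procedural concept texture patch
#'
#' Produces a deterministic RGB patch for one of the seven pathology concepts.
#' Textures are procedural (dots, stripes, blobs, speckle) rather than
#' photorealistic: each concept has a distinct dot density, stripe frequency or
#' blob size so that concepts are linearly separable in simple filter
#' statistics, which is what the downstream concept classifier relies on.
#'
#' @param concept_id One of [concept_names()].
#' @param size Patch side in pixels (>= 32).
#' @param seed Integer seed; the same (concept, size, seed) gives a
#'   bit-identical patch.
#' @param stain_matrix 3 x 2 stain matrix used to compose RGB from the two
#'   concentration maps; defaults to [default_stain_matrix()].
#' @param noise_sd Gaussian noise, in optical-density units, added to the
#'   composed image (default 0).
#' @return `size` x `size` x 3 numeric array with values in \[0, 255\].
#' @export
make_concept_texture <- function(concept_id, size, seed,
                                 stain_matrix = default_stain_matrix(),
                                 noise_sd = 0) {
  if (!concept_id %in% concept_names())
    stop("unknown concept id: ", concept_id)
  if (size < 32) stop("size must be >= 32")
  with_seed(seed, {
    cc <- concept_concentrations(concept_id, size, size)
    od_compose_rgb(cc$h, cc$e, stain_matrix, noise_sd = noise_sd)
  })
}

## --- slide specification and rendering ------------------------------------

#' Construct a synthetic slide specification
#'
#' @param width_px,height_px Slide dimensions in pixels.
#' @param concept_layout data.frame with columns `row0`, `col0`, `row1`,
#'   `col1` (1-based inclusive pixel bounds) and `concept` (a code from
#'   [concept_names()]); may have zero rows.
#' @param stain_matrix 3 x 2 matrix of optical-density stain vectors; columns
#'   must be unit-norm and nonnegative.
#' @param noise_sd Gaussian optical-density noise level (>= 0).
#' @param background_fraction Fraction in \[0, 1\] of each region's pixels
#'   knocked back to bare background; 1 renders the pure illuminant.
#' @return A `slide_spec` object.
#' @export
slide_spec <- function(width_px, height_px, concept_layout = NULL,
                       stain_matrix = default_stain_matrix(),
                       noise_sd = 0, background_fraction = 0) {
  stopifnot(width_px >= 1, height_px >= 1, noise_sd >= 0,
            background_fraction >= 0, background_fraction <= 1)
  if (is.null(concept_layout))
    concept_layout <- data.frame(row0 = integer(), col0 = integer(),
                                 row1 = integer(), col1 = integer(),
                                 concept = character())
  stopifnot(all(c("row0", "col0", "row1", "col1", "concept") %in%
                  names(concept_layout)))
  if (!all(abs(sqrt(colSums(stain_matrix^2)) - 1) < 1e-6))
    stop("stain_matrix columns must have unit Euclidean norm")
  if (any(stain_matrix < 0)) stop("stain_matrix entries must be nonnegative")
  if (nrow(concept_layout) > 0) {
    ok <- concept_layout$row0 >= 1 & concept_layout$col0 >= 1 &
      concept_layout$row1 <= height_px & concept_layout$col1 <= width_px &
      concept_layout$row0 <= concept_layout$row1 &
      concept_layout$col0 <= concept_layout$col1
    if (!all(ok)) stop("concept_layout regions must lie within slide bounds")
    if (!all(concept_layout$concept %in% concept_names()))
      stop("unknown concept id in layout")
  }
  structure(list(width_px = width_px, height_px = height_px,
                 concept_layout = concept_layout, stain_matrix = stain_matrix,
                 noise_sd = noise_sd,
                 background_fraction = background_fraction),
            class = "slide_spec")
}

#' Render a synthetic slide from a specification
#'
#' The image is the inverse optical-density transform of
#' `stain_matrix %*% concentration_maps` plus Gaussian OD noise. The returned
#' mask labels every pixel with the integer code of its concept (position in
#' [concept_names()]) or 0 for background, and depends only on the layout,
#' never on the seed.
#'
#' @param spec A [slide_spec()].
#' @param seed Integer seed controlling textures, knockout and noise.
#' @return List with `image` (h x w x 3, values in \[0, 255\]) and `mask`
#'   (h x w integer matrix of concept codes).
#' @export
render_slide <- function(spec, seed) {
  stopifnot(inherits(spec, "slide_spec"))
  h <- spec$height_px; w <- spec$width_px
  ch <- matrix(0, h, w); ce <- matrix(0, h, w)
  mask <- matrix(0L, h, w)
  img <- with_seed(seed, {
    lay <- spec$concept_layout
    if (nrow(lay) > 0 && spec$background_fraction < 1) {
      for (i in seq_len(nrow(lay))) {
        rr <- lay$row0[i]:lay$row1[i]; cc <- lay$col0[i]:lay$col1[i]
        tex <- concept_concentrations(lay$concept[i], length(rr), length(cc))
        if (spec$background_fraction > 0) {
          knock <- matrix(runif(length(rr) * length(cc)) <
                            spec$background_fraction, length(rr))
          tex$h[knock] <- 0; tex$e[knock] <- 0
        }
        ch[rr, cc] <- tex$h; ce[rr, cc] <- tex$e
        mask[rr, cc] <- match(lay$concept[i], concept_names())
      }
    } else if (nrow(lay) > 0) {
      for (i in seq_len(nrow(lay)))
        mask[lay$row0[i]:lay$row1[i], lay$col0[i]:lay$col1[i]] <-
          match(lay$concept[i], concept_names())
    }
    od_compose_rgb(ch, ce, spec$stain_matrix, noise_sd = spec$noise_sd)
  })
  list(image = img, mask = mask)
}

## --- survival cohort simulation -------------------------------------------

#' Simulate a right-censored Weibull survival cohort
#'
#' Covariates are drawn i.i.d. standard normal; event times follow a Weibull
#' distribution with shape `kappa` and per-subject scale
#' `lambda0 * exp(coef . x)` (accelerated failure time form). Censoring times
#' are uniform on (0, q), with q calibrated by bisection so that the expected
#' censoring fraction matches `censor_rate`.
#'
#' @param n Number of subjects (>= 1).
#' @param coef Numeric vector of covariate effects on log-scale.
#' @param lambda0 Baseline Weibull scale (> 0).
#' @param kappa Weibull shape (> 0).
#' @param censor_rate Target censoring fraction in \[0, 1).
#' @param seed Integer seed; identical seeds give identical cohorts.
#' @return data.frame manifest with columns `slide_id`, `path`, `label`,
#'   `time`, `event`, `partition` and covariate columns `x1..xp`.
#' @export
simulate_survival_cohort <- function(n, coef, lambda0, kappa, censor_rate,
                                     seed) {
  stopifnot(n >= 1, lambda0 > 0, kappa > 0)
  if (censor_rate >= 1 || censor_rate < 0)
    stop("censor_rate must be in [0, 1)")
  with_seed(seed, {
    p <- length(coef)
    x <- matrix(rnorm(n * p), n, p)
    lp <- as.vector(x %*% coef)
    tt <- rweibull(n, shape = kappa, scale = lambda0 * exp(lp))
    if (censor_rate == 0) {
      time <- tt; event <- rep(1L, n)
    } else {
      # P(C < T) for C ~ U(0, q) equals mean(pmin(T, q) / q), decreasing in q
      f <- function(q) mean(pmin(tt, q) / q) - censor_rate
      lo <- min(tt) * 1e-6; hi <- max(tt) * 1e6
      q <- stats::uniroot(f, c(lo, hi), tol = 1e-9)$root
      cens <- runif(n, 0, q)
      event <- as.integer(tt <= cens)
      time <- pmin(tt, cens)
    }
    out <- data.frame(slide_id = sprintf("s%04d", seq_len(n)),
                      path = NA_character_, label = NA_character_,
                      time = time, event = event,
                      partition = NA_character_)
    colnames(x) <- paste0("x", seq_len(p))
    cbind(out, as.data.frame(x))
  })
}

## --- planted-label classification cohort ----------------------------------

#' Simulate a planted-signal classification cohort
#'
#' Generates `n_slides` synthetic slides on a grid of `grid` x `grid` square
#' regions of `tile_px` pixels; each region receives a random non-tumor
#' concept (or background). A slide's binary label is a deterministic function
#' of its layout: positive iff it carries at least `m_tumor` tumor (TUM)
#' regions. Positive slides receive between `m_tumor` and `m_tumor + 3` tumor
#' regions; negative slides carry none. Attention pooling is a weighted mean
#' and therefore count-invariant, so the planted weak-label signal is the
#' presence of tumor texture, not its count.
#'
#' @param n_slides Number of slides (default 60, balanced classes).
#' @param grid Regions per side (default 6).
#' @param tile_px Region (= tile) side in pixels (default 32).
#' @param m_tumor Minimum tumor-region count defining a positive slide
#'   (default 3).
#' @param noise_sd Optical-density noise of the renders (default 0.01).
#' @param stain_matrix Stain matrix for all slides.
#' @param seed Integer seed.
#' @return List with `slides` (list of `render_slide` outputs), `specs`,
#'   `manifest` (slide_id, label, n_tumor, partition), and `tumor_tiles`
#'   (per-slide logical grid flagging tumor regions, in row-major tile order).
#' @export
simulate_planted_cohort <- function(n_slides = 60, grid = 6, tile_px = 32,
                                    m_tumor = 3, noise_sd = 0.01,
                                    stain_matrix = default_stain_matrix(),
                                    seed = 1) {
  side <- grid * tile_px
  other <- setdiff(concept_names(), "TUM")
  labels <- rep(c(1L, 0L), length.out = n_slides)
  with_seed(seed, {
    labels <- sample(labels)
    slides <- vector("list", n_slides)
    specs <- vector("list", n_slides)
    tumor_tiles <- vector("list", n_slides)
    n_tum <- integer(n_slides)
    seeds <- sample.int(.Machine$integer.max, n_slides)
    for (s in seq_len(n_slides)) {
      k <- if (labels[s] == 1)
        min(sample(m_tumor:(m_tumor + 3), 1), grid * grid) else 0L
      n_tum[s] <- k
      cells <- expand.grid(gr = seq_len(grid), gc = seq_len(grid))
      tum_idx <- sample(nrow(cells), k)
      concept <- rep(NA_character_, nrow(cells))
      concept[tum_idx] <- "TUM"
      rest <- setdiff(seq_len(nrow(cells)), tum_idx)
      filled <- rest[runif(length(rest)) < 0.9]
      concept[filled] <- sample(other, length(filled), replace = TRUE)
      keep <- !is.na(concept)
      lay <- data.frame(
        row0 = (cells$gr[keep] - 1) * tile_px + 1,
        col0 = (cells$gc[keep] - 1) * tile_px + 1,
        row1 = cells$gr[keep] * tile_px,
        col1 = cells$gc[keep] * tile_px,
        concept = concept[keep])
      sp <- slide_spec(side, side, lay, stain_matrix = stain_matrix,
                       noise_sd = noise_sd)
      specs[[s]] <- sp
      slides[[s]] <- render_slide(sp, seeds[s])
      # flags in tile-grid order (row-major), matching tile_slide() output
      flags <- logical(grid * grid)
      flags[(cells$gr[tum_idx] - 1) * grid + cells$gc[tum_idx]] <- TRUE
      tumor_tiles[[s]] <- flags
    }
    manifest <- data.frame(slide_id = sprintf("slide%03d", seq_len(n_slides)),
                           label = labels, n_tumor = n_tum,
                           partition = NA_character_)
    list(slides = slides, specs = specs, manifest = manifest,
         tumor_tiles = tumor_tiles, grid = grid, tile_px = tile_px)
  })
}

## --- cohort I/O -------------------------------------------------------------

#' Write a rendered slide, its mask and a JSON sidecar
#'
#' @param render Output of [render_slide()].
#' @param path Output image path (`.png` or `.tif`/`.tiff`).
#' @param spec,seed If supplied, a JSON sidecar `<path>.json` records the
#'   generating specification and seed.
#' @return `path`, invisibly.
#' @export
write_slide <- function(render, path, spec = NULL, seed = NULL) {
  img <- render$image / 255
  if (grepl("\\.tiff?$", path, ignore.case = TRUE)) {
    tiff::writeTIFF(img, path)
  } else {
    png::writePNG(img, path)
  }
  mask_path <- sub("\\.(png|tiff?)$", "_mask.png", path, ignore.case = TRUE)
  png::writePNG(render$mask / 255, mask_path)
  if (!is.null(spec)) {
    side <- list(width_px = spec$width_px, height_px = spec$height_px,
                 concept_layout = spec$concept_layout,
                 stain_matrix = spec$stain_matrix,
                 noise_sd = spec$noise_sd,
                 background_fraction = spec$background_fraction,
                 seed = seed)
    jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                         digits = NA)
  }
  invisible(path)
}

#' Read a slide image (PNG or TIFF) as a 0-255 RGB array
#' @param path Image path.
#' @return h x w x 3 numeric array in \[0, 255\].
#' @export
read_slide <- function(path) {
  img <- if (grepl("\\.tiff?$", path, ignore.case = TRUE))
    tiff::readTIFF(path) else png::readPNG(path)
  if (length(dim(img)) == 2) img <- array(rep(img, 3), c(dim(img), 3))
  img[, , 1:3, drop = FALSE] * 255
}

#' Write / read a cohort manifest CSV
#'
#' Manifests have the header columns `slide_id`, `path`, `label`, `time`,
#' `event`, `partition`; additional columns (covariates, planted ground truth)
#' are preserved.
#'
#' @param manifest data.frame manifest.
#' @param path CSV path.
#' @return The path (write) or the manifest data.frame (read).
#' @export
write_manifest <- function(manifest, path) {
  write.csv(manifest, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- read.csv(path, stringsAsFactors = FALSE)
  if (anyDuplicated(m$slide_id)) stop("slide ids must be unique")
  m
}

#' Stain-estimation fixture slide
#'
#' A two-region slide (a lymphocyte field, which contains pure-hematoxylin
#' pixels, and a stroma field, which contains pure-eosin pixels) rendered from
#' a planted stain matrix. Because the Macenko estimator drops pixels with any
#' OD channel below its `od_beta` floor, recovery to high precision requires
#' stain vectors bounded away from zero; `fixture_stain_matrix()` provides two
#' such matrices.
#'
#' @param stain_matrix Planted 3 x 2 stain matrix.
#' @param noise_sd Optical-density noise (default 0).
#' @param seed Integer seed.
#' @param side Slide side in pixels (default 128).
#' @return A [render_slide()] result; the planted matrix is attached as
#'   attribute `stain_matrix`.
#' @export
simulate_stain_fixture <- function(stain_matrix = fixture_stain_matrix(1),
                                   noise_sd = 0, seed = 1, side = 128) {
  half <- side %/% 2
  lay <- data.frame(row0 = c(1, half + 1), col0 = c(1, 1),
                    row1 = c(half, side), col1 = c(side, side),
                    concept = c("LYM", "STR"))
  sp <- slide_spec(side, side, lay, stain_matrix = stain_matrix,
                   noise_sd = noise_sd)
  out <- render_slide(sp, seed)
  attr(out, "stain_matrix") <- stain_matrix
  out
}

#' @rdname simulate_stain_fixture
#' @param which 1 or 2: two distinct unit-column stain matrices whose entries
#'   all exceed 0.25.
#' @export
fixture_stain_matrix <- function(which = 1) {
  m <- if (which == 1)
    cbind(h = c(0.65, 0.70, 0.29), e = c(0.30, 0.90, 0.22))
  else
    cbind(h = c(0.55, 0.66, 0.50), e = c(0.40, 0.85, 0.30))
  sweep(m, 2, sqrt(colSums(m^2)), "/")
}
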