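test_that("tiling produces the exact non-overlapping grid", {
  cfg <- preprocess_config(tile_size_px = 100)
  img <- array(runif(300 * 200 * 3, 0, 255), c(200, 300, 3))
  tiles <- tile_slide(img, cfg)
  expect_length(tiles, 6) # 2 x 3 grid
  coords <- t(vapply(tiles, function(t) c(t$grid_row, t$grid_col), numeric(2)))
  expect_false(any(duplicated(coords)))
  # edge remainder dropped
  img2 <- array(runif(199 * 100 * 3, 0, 255), c(199, 100, 3))
  expect_length(tile_slide(img2, preprocess_config(tile_size_px = 100)), 1)
  # smaller than one tile -> empty list, not an error
  expect_length(tile_slide(img2, preprocess_config(tile_size_px = 500)), 0)
})

test_that("all-white image yields background tiles only", {
  img <- array(255, c(128, 128, 3))
  tiles <- tile_slide(img, preprocess_config(tile_size_px = 64))
  expect_true(all(!vapply(tiles, function(t) t$is_tissue, logical(1))))
})

test_that("optical density transform is the stated bijection", {
  i0 <- c(255, 255, 255)
  px <- array(255, c(4, 4, 3))
  expect_true(all(rgb_to_od(px, i0) == 0))
  # (v + 1) / (I0 + 1) = 0.1  ->  OD = 1
  v <- 0.1 * 256 - 1
  expect_equal(rgb_to_od(array(v, c(1, 1, 3)), i0)[1], 1)
  x <- array(runif(10 * 10 * 3, 0, 255), c(10, 10, 3))
  expect_lt(max(abs(od_to_rgb(rgb_to_od(x, i0), i0) - x)), 1)
  # order-reversing
  od <- rgb_to_od(array(c(10, 200), c(2, 1, 3)), i0)
  expect_true(od[1, 1, 1] > od[2, 1, 1])
})

test_that("Macenko estimation recovers a planted stain matrix", {
  for (which in 1:2) {
    fx <- simulate_stain_fixture(fixture_stain_matrix(which), noise_sd = 0,
                                 seed = 1)
    prof <- estimate_stain_profile(fx$image, preprocess_config())
    planted <- attr(fx, "stain_matrix")
    for (j in 1:2) {
      expect_gte(abs(sum(prof$stain_vectors[, j] * planted[, j])), 0.999)
      expect_equal(sum(prof$stain_vectors[, j]^2), 1, tolerance = 1e-9)
    }
    expect_true(all(prof$stain_vectors >= 0))
    # hematoxylin convention: first column has the larger blue component
    expect_gte(prof$stain_vectors[3, 1], prof$stain_vectors[3, 2])
    expect_true(all(prof$max_concentrations > 0))
  }
})

test_that("degenerate OD clouds raise the insufficient-signal error", {
  # single stain direction -> rank deficient
  h <- default_stain_matrix()[, 1]
  od <- outer(seq(0.3, 1.5, length.out = 500), h)
  expect_error(estimate_stain_profile(od), "rank-deficient")
  expect_error(estimate_stain_profile(od * 0 + 0.01), "fewer than 2")
})

test_that("alpha percentile is insensitive on a clean two-stain mixture", {
  fx <- simulate_stain_fixture(fixture_stain_matrix(1), noise_sd = 0, seed = 2)
  p1 <- estimate_stain_profile(fx$image, preprocess_config(alpha_percentile = 1))
  p5 <- estimate_stain_profile(fx$image, preprocess_config(alpha_percentile = 5))
  for (j in 1:2)
    expect_gte(abs(sum(p1$stain_vectors[, j] * p5$stain_vectors[, j])), 0.999)
})

test_that("normalization to the source profile is the identity", {
  fx <- simulate_stain_fixture(fixture_stain_matrix(1), noise_sd = 0, seed = 3)
  cfg <- preprocess_config(tile_size_px = 64)
  prof <- estimate_stain_profile(fx$image, cfg)
  tiles <- Filter(function(t) t$is_tissue, tile_slide(fx$image, cfg))
  tn <- normalize_tile(tiles[[1]], prof, prof, cfg)
  expect_lt(max(abs(tn$pixels - tiles[[1]]$pixels)), 1)
})

test_that("normalization is idempotent within 2 intensity levels", {
  fx <- simulate_stain_fixture(fixture_stain_matrix(2), noise_sd = 0.01,
                               seed = 4)
  cfg <- preprocess_config(tile_size_px = 64)
  src <- estimate_stain_profile(fx$image, cfg)
  # the fixed-point check re-estimates the reference from the first output,
  # which is itself a stain recovery; like the recovery fixtures, the
  # reference must have no channel below the od_beta transparency floor
  # (classic eosin's 0.07 red is unrecoverable by construction of the filter)
  ref <- structure(list(stain_vectors = fixture_stain_matrix(1),
                        max_concentrations = c(1, 1)),
                   class = "stain_profile")
  tiles <- Filter(function(t) t$is_tissue, tile_slide(fx$image, cfg))
  y1 <- lapply(tiles, normalize_tile, source = src, reference = ref,
               config = cfg)
  # the re-estimation profile comes from the whole normalized slide, as a
  # cohort pipeline would compute it
  od1 <- do.call(rbind, lapply(y1, function(t) {
    od <- rgb_to_od(t$pixels)
    cbind(as.vector(od[, , 1]), as.vector(od[, , 2]), as.vector(od[, , 3]))
  }))
  r2 <- estimate_stain_profile(od1, cfg)
  for (k in seq_along(y1)) {
    y2 <- normalize_tile(y1[[k]], r2, r2, cfg)
    expect_lt(mean(abs(y2$pixels - y1[[k]]$pixels)), 2)
  }
})

test_that("normalization collapses stain variation between renderings", {
  # identical layout and seed, two different stain matrices -> identical
  # concentration maps; after normalization to one reference the images agree
  cfg <- preprocess_config(tile_size_px = 64)
  ref <- default_stain_profile()
  out <- lapply(1:2, function(w) {
    fx <- simulate_stain_fixture(fixture_stain_matrix(w), noise_sd = 0,
                                 seed = 5)
    prof <- estimate_stain_profile(fx$image, cfg)
    tiles <- Filter(function(t) t$is_tissue, tile_slide(fx$image, cfg))
    lapply(tiles, function(t) normalize_tile(t, prof, ref, cfg)$pixels)
  })
  for (k in seq_along(out[[1]])) {
    for (ch in 1:3)
      expect_lt(mean(abs(out[[1]][[k]][, , ch] - out[[2]][[k]][, , ch])), 2)
  }
})

test_that("background tiles are skipped with a warning", {
  cfg <- preprocess_config(tile_size_px = 32)
  tiles <- tile_slide(array(255, c(32, 32, 3)), cfg)
  expect_warning(out <- normalize_tile(tiles[[1]], default_stain_profile(),
                                       default_stain_profile(), cfg),
                 "background")
  expect_true(attr(out, "normalize_skipped"))
  expect_identical(out$pixels, tiles[[1]]$pixels)
})

test_that("stain profiles round-trip through JSON", {
  prof <- default_stain_profile()
  f <- withr::local_tempfile(fileext = ".json")
  write_stain_profile(prof, f)
  p2 <- read_stain_profile(f)
  expect_equal(p2$stain_vectors, unname(prof$stain_vectors))
  expect_equal(p2$max_concentrations, prof$max_concentrations)
})
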