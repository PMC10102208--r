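test_that("concept textures are deterministic and validated", {
  a <- make_concept_texture("LYM", 64, seed = 7)
  b <- make_concept_texture("LYM", 64, seed = 7)
  expect_identical(a, b)
  expect_false(identical(a, make_concept_texture("LYM", 64, seed = 8)))
  expect_error(make_concept_texture("nucleus", 64, 1), "unknown concept")
  expect_error(make_concept_texture("TUM", 16, 1), ">= 32")
  expect_true(all(a >= 0 & a <= 255))
})

test_that("adipose texture contains a near-white circular blob", {
  for (seed in 1:5) {
    p <- make_concept_texture("ADI", 32, seed)
    bright <- p[, , 1] > 235 & p[, , 2] > 235 & p[, , 3] > 235
    expect_gt(mean(bright), 0.03)
  }
})

test_that("concept textures separate linearly in simple filter statistics", {
  # oracle features deliberately independent of the package's backbone:
  # channel means/variances and an edge-density statistic
  simple_stats <- function(p) {
    g <- (p[, , 1] + p[, , 2] + p[, , 3]) / 3 / 255
    e <- mean(abs(diff(g)) > 0.05)
    c(apply(p, 3, mean), apply(p, 3, function(ch) var(as.vector(ch))),
      edge = e)
  }
  feats <- list(); ys <- character(0)
  for (co in concept_names()) for (i in 1:100) {
    feats[[length(feats) + 1]] <-
      simple_stats(make_concept_texture(co, 32, i * 31 + match(co, concept_names())))
    ys <- c(ys, co)
  }
  x <- do.call(rbind, feats)
  tr <- rep(rep(c(TRUE, FALSE), c(70, 30)), length(concept_names()))
  df <- data.frame(y = factor(ys), x)
  fit <- nnet::multinom(y ~ ., df[tr, ], trace = FALSE, maxit = 300)
  acc <- mean(predict(fit, df[!tr, ]) == df$y[!tr])
  expect_gte(acc, 0.99)
})

test_that("render_slide follows the forward optical-density model", {
  lay <- data.frame(row0 = 1, col0 = 1, row1 = 40, col1 = 40,
                    concept = "STR")
  sp <- slide_spec(80, 80, lay, noise_sd = 0)
  r <- render_slide(sp, seed = 1)
  # background pixels are the pure illuminant
  expect_true(all(abs(r$image[41:80, , ] - 255) < 1e-9))
  sp_bg <- slide_spec(80, 80, lay, noise_sd = 0, background_fraction = 1)
  r_bg <- render_slide(sp_bg, seed = 1)
  expect_true(all(abs(r_bg$image - 255) < 1e-9))
  # stroma is pure eosin: nonzero-OD pixels are proportional to stain column 2
  od <- rgb_to_od(r$image)
  str_px <- cbind(as.vector(od[1:40, 1:40, 1]), as.vector(od[1:40, 1:40, 2]),
                  as.vector(od[1:40, 1:40, 3]))
  str_px <- str_px[rowSums(str_px) > 0.2, ]
  e <- default_stain_matrix()[, 2]
  cosines <- (str_px %*% e) / sqrt(rowSums(str_px^2))
  expect_true(all(cosines > 1 - 1e-6))
  # mask from layout only
  expect_equal(unique(as.vector(r$mask[1:40, 1:40])),
               match("STR", concept_names()))
  expect_equal(unique(as.vector(r$mask[41:80, ])), 0L)
})

test_that("render_slide: same spec, different seeds -> same mask, different noise", {
  lay <- data.frame(row0 = 1, col0 = 1, row1 = 64, col1 = 64,
                    concept = "DEB")
  sp <- slide_spec(64, 64, lay, noise_sd = 0.05)
  r1 <- render_slide(sp, seed = 1)
  r2 <- render_slide(sp, seed = 2)
  expect_identical(r1$mask, r2$mask)
  expect_false(identical(r1$image, r2$image))
  expect_identical(render_slide(sp, seed = 1)$image, r1$image)
})

test_that("slide_spec validates stain matrix and region bounds", {
  bad <- default_stain_matrix() * 2
  expect_error(slide_spec(64, 64, stain_matrix = bad), "unit")
  lay <- data.frame(row0 = 1, col0 = 1, row1 = 100, col1 = 10,
                    concept = "TUM")
  expect_error(slide_spec(64, 64, lay), "bounds")
})

test_that("survival cohort simulation matches the Weibull model", {
  man <- simulate_survival_cohort(10000, coef = 0, lambda0 = 2, kappa = 1,
                                  censor_rate = 0, seed = 4)
  expect_true(mean(man$time) > 1.9 && mean(man$time) < 2.1)
  expect_true(all(man$event == 1))
  man2 <- simulate_survival_cohort(10000, coef = 0, lambda0 = 2, kappa = 1,
                                   censor_rate = 0, seed = 4)
  expect_identical(man, man2)
  expect_error(simulate_survival_cohort(10, 0, 1, 1, censor_rate = 1, seed = 1),
               "censor_rate")
})

test_that("empirical censoring fraction tracks the target rate", {
  for (rate in c(0.2, 0.5)) {
    man <- simulate_survival_cohort(2000, coef = c(0.8), lambda0 = 1.5,
                                    kappa = 1.3, censor_rate = rate, seed = 9)
    expect_lt(abs(mean(man$event == 0) - rate), 0.05)
  }
})

test_that("planted cohort labels are a deterministic function of the layout", {
  co <- simulate_planted_cohort(n_slides = 12, seed = 3)
  expect_identical(co$manifest$label, as.integer(co$manifest$n_tumor >= 3))
  expect_identical(co$manifest$label,
                   vapply(co$tumor_tiles, function(f) as.integer(sum(f) >= 3),
                          integer(1)))
  co2 <- simulate_planted_cohort(n_slides = 12, seed = 3)
  expect_identical(co$manifest, co2$manifest)
  expect_identical(co$slides[[1]]$image, co2$slides[[1]]$image)
})

test_that("slide and manifest round-trip through disk formats", {
  co <- simulate_planted_cohort(n_slides = 2, grid = 2, seed = 1)
  d <- withr::local_tempdir()
  p <- file.path(d, "s1.png")
  write_slide(co$slides[[1]], p, spec = co$specs[[1]], seed = 1)
  img <- read_slide(p)
  expect_equal(dim(img), dim(co$slides[[1]]$image))
  expect_lt(max(abs(img - co$slides[[1]]$image)), 1) # 8-bit quantization
  expect_true(file.exists(file.path(d, "s1_mask.png")))
  expect_true(file.exists(paste0(p, ".json")))
  tp <- file.path(d, "s1.tif")
  write_slide(co$slides[[1]], tp)
  expect_lt(max(abs(read_slide(tp) - co$slides[[1]]$image)), 1)
  mf <- file.path(d, "m.csv")
  write_manifest(co$manifest, mf)
  expect_equal(read_manifest(mf)$slide_id, co$manifest$slide_id)
  dup <- rbind(co$manifest, co$manifest)
  write_manifest(dup, mf)
  expect_error(read_manifest(mf), "unique")
})
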