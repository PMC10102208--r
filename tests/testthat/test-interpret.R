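test_that("a constant predictor yields zero importance everywhere", {
  set.seed(50)
  m <- tiny_model()
  m$params$head$W[] <- 0 # head ignores the embedding
  bag <- structure(list(slide_id = "s",
                        features = matrix(rnorm(6 * 8), 6, 8),
                        tile_ids = sprintf("r0_c%d", 0:5)),
                   class = "feature_bag")
  asg <- structure(list(slide_id = "s", tile_ids = bag$tile_ids,
                        cluster_id = rep(0L, 6)),
                   class = "cluster_assignment")
  imp <- occlusion_importance(m, bag, asg)
  expect_equal(imp$importance, rep(0, 6))
  expect_equal(imp$importance_norm, rep(0, 6))
  expect_equal(imp$grid_col, 0:5)
})

test_that("occlusion matches the analytic delta of a linear-logit surrogate", {
  set.seed(51)
  d <- 5; n <- 9
  w <- rnorm(d); b <- 0.3
  bag <- structure(list(slide_id = "s", features = matrix(rnorm(n * d), n, d),
                        tile_ids = sprintf("r0_c%d", seq_len(n) - 1)),
                   class = "feature_bag")
  surrogate <- list(w = w, b = b)
  fwd <- function(model, bg, cl) {
    p <- 1 / (1 + exp(-(mean(bg$features %*% model$w) + model$b)))
    list(class_probabilities = c(1 - p, p))
  }
  imp <- occlusion_importance(surrogate, bag, rep(0L, n), target_class = 2,
                              forward_fn = fwd, n_classes = 2)
  contrib <- as.vector(bag$features %*% w)
  p_full <- 1 / (1 + exp(-(mean(contrib) + b)))
  analytic <- vapply(seq_len(n), function(i) {
    p_occ <- 1 / (1 + exp(-(mean(contrib[-i]) + b)))
    p_full - p_occ
  }, numeric(1))
  expect_lt(max(abs(imp$importance - analytic)), 1e-6)
  # additive-logit completeness: importance ordering = contribution ordering
  expect_identical(order(imp$importance), order(contrib))
})

test_that("single-tile slides fall back to the uniform prior", {
  set.seed(52)
  m <- tiny_model()
  bag <- structure(list(slide_id = "s", features = matrix(rnorm(8), 1, 8),
                        tile_ids = "r0_c0"), class = "feature_bag")
  fw <- mil_forward(m, bag, 0L)
  imp <- occlusion_importance(m, bag, 0L, target_class = 2)
  expect_equal(imp$importance, fw$class_probabilities[2] - 0.5)
})

test_that("concept classifier separates textures and is seed-deterministic", {
  tr_p <- list(); tr_y <- character(0)
  te_p <- list(); te_y <- character(0)
  for (co in concept_names()) {
    k <- match(co, concept_names())
    for (i in 1:40) {
      tr_p[[length(tr_p) + 1]] <- make_concept_texture(co, 32, i * 7 + k)
      tr_y <- c(tr_y, co)
    }
    for (i in 1:15) {
      te_p[[length(te_p) + 1]] <- make_concept_texture(co, 32, 9e5 + i * 13 + k)
      te_y <- c(te_y, co)
    }
  }
  m1 <- train_concept_classifier(tr_p, tr_y, seed = 1,
                                 val_patches = te_p, val_labels = te_y)
  expect_gte(m1$val_accuracy, 0.99)
  m2 <- train_concept_classifier(tr_p, tr_y, seed = 1)
  expect_identical(predict_concepts(m1, te_p)$concept,
                   predict_concepts(m2, te_p)$concept)
  expect_error(train_concept_classifier(tr_p[1:3], rep("TUM", 3), 1),
               "2 concepts")
  expect_error(train_concept_classifier(tr_p[1:2], c("TUM", "weird"), 1),
               "unknown")
})

test_that("concept scores scale the maximum to 100 over selected regions", {
  map <- data.frame(importance = c(0.8, 0.8, 0.1),
                    importance_norm = c(1, 1, 0))
  onehot <- function(i) { v <- rep(0, 7); v[i] <- 1; v }
  probs <- rbind(onehot(1), onehot(2), onehot(3))
  colnames(probs) <- concept_names()
  cs <- concept_scores(map, probs, threshold = 0.7, scale = "raw")
  expect_equal(unname(cs["TUM"]), 100)
  expect_equal(unname(cs["STR"]), 100) # equal raw scores both scale to 100
  expect_equal(unname(cs["LYM"]), 0)
  # single selected region
  cs1 <- concept_scores(data.frame(importance = 0.9, importance_norm = 1),
                        matrix(onehot(1), 1, dimnames = list(NULL, concept_names())))
  expect_equal(unname(cs1["TUM"]), 100)
  expect_true(all(cs1[-1] == 0))
  # empty selection -> zeros with warning
  expect_warning(cs0 <- concept_scores(map, probs, threshold = 1.01),
                 "no region")
  expect_true(all(cs0 == 0))
  # invariance to region enumeration order
  ord <- c(3, 1, 2)
  cs_perm <- concept_scores(map[ord, ], probs[ord, ], scale = "raw")
  expect_equal(cs_perm, cs)
})

test_that("heatmap rendering is neutral at zero and deterministic", {
  set.seed(53)
  img <- array(runif(64 * 64 * 3, 0, 255), c(64, 64, 3))
  map <- data.frame(slide_id = "s", tile_id = sprintf("r%d_c%d",
                                                      rep(0:1, each = 2),
                                                      rep(0:1, 2)),
                    grid_row = rep(0:1, each = 2), grid_col = rep(0:1, 2),
                    importance = rep(0, 4), importance_norm = rep(0, 4))
  out <- render_heatmap(map, img, tile_px = 32, alpha = 0.4)
  blend <- 0.6 * img / 255 + 0.4 * 1 # neutral color is white
  expect_lt(max(abs(out[, 1:64, ] - blend)), 0.01)
  # monotone importance -> monotone red minus blue along the color map
  map$importance <- c(-0.8, -0.2, 0.3, 0.9)
  out2 <- render_heatmap(map, img, tile_px = 32, alpha = 1)
  rb <- vapply(seq_len(4), function(i) {
    rr <- map$grid_row[i] * 32 + 16; cc <- map$grid_col[i] * 32 + 16
    out2[rr, cc, 1] - out2[rr, cc, 3]
  }, numeric(1))
  expect_true(all(diff(rb) > 0))
  expect_error(render_heatmap(map, img[1:40, , ], 32), "align")
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  render_heatmap(map, img, 32, path = f1)
  render_heatmap(map, img, 32, path = f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})
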