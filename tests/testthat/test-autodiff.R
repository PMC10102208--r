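# The reverse-mode engine is the substrate of every trainable component;
# verify its gradients against central finite differences.

ad <- function(name) get(name, envir = asNamespace("moma"))

fd_check <- function(build, x0, eps = 1e-6, tol = 1e-5) {
  # build(tape, xnode) -> scalar node; returns max relative gradient error
  tape <- ad("ad_tape")()
  xn <- ad("ad_input")(tape, x0)
  loss <- build(tape, xn)
  ad("ad_backward")(tape, loss)
  g <- xn$grad
  err <- 0
  for (k in seq_along(x0)) {
    xp <- x0; xp[k] <- xp[k] + eps
    xm <- x0; xm[k] <- xm[k] - eps
    tp <- ad("ad_tape")(); lp <- build(tp, ad("ad_input")(tp, xp))
    tm <- ad("ad_tape")(); lm <- build(tm, ad("ad_input")(tm, xm))
    fd <- (lp$value[1, 1] - lm$value[1, 1]) / (2 * eps)
    err <- max(err, abs(fd - g[k]) / max(1, abs(fd)))
  }
  err
}

test_that("elementwise and reduction ops backpropagate correctly", {
  set.seed(1)
  x0 <- matrix(rnorm(12), 3, 4)
  expect_lt(fd_check(function(tp, x) {
    s <- ad("ad_sigmoid")(tp, ad("ad_tanh")(tp, x))
    ad("ad_sum")(tp, ad("ad_hadamard")(tp, s, s))
  }, x0), 1e-5)
  expect_lt(fd_check(function(tp, x) {
    ad("ad_mean")(tp, ad("ad_softplus")(tp, ad("ad_scale")(tp, x, 1.7)))
  }, x0), 1e-5)
  expect_lt(fd_check(function(tp, x) {
    ad("ad_sum")(tp, ad("ad_log")(tp, ad("ad_exp")(tp, x)))
  }, x0), 1e-5)
  expect_lt(fd_check(function(tp, x) {
    ad("ad_sum")(tp, ad("ad_relu")(tp, ad("ad_shift")(tp, x, 0.3)))
  }, x0), 1e-4) # relu kinks excluded by shift w.h.p.
})

test_that("matrix ops, softmax and layer norm backpropagate correctly", {
  set.seed(2)
  x0 <- matrix(rnorm(12), 3, 4)
  w <- matrix(rnorm(8), 4, 2)
  expect_lt(fd_check(function(tp, x) {
    wn <- ad("ad_input")(tp, w)
    ad("ad_sum")(tp, ad("ad_softmax_rows")(tp, ad("ad_matmul")(tp, x, wn)))
  }, x0), 1e-5)
  g <- matrix(rnorm(4), 1, 4); b <- matrix(rnorm(4), 1, 4)
  m <- matrix(rnorm(12), 3, 4)
  expect_lt(fd_check(function(tp, x) {
    y <- ad("ad_layernorm")(tp, x, ad("ad_input")(tp, g),
                            ad("ad_input")(tp, b))
    ad("ad_sum")(tp, ad("ad_hadamard")(tp, y, ad("ad_input")(tp, m)))
  }, x0), 1e-4)
  expect_lt(fd_check(function(tp, x) {
    xt <- ad("ad_t")(tp, x)
    ad("ad_sum")(tp, ad("ad_matmul")(tp, xt, x))
  }, x0), 1e-5)
})

test_that("row selection, binding and bias ops backpropagate correctly", {
  set.seed(3)
  x0 <- matrix(rnorm(20), 5, 4)
  b <- matrix(rnorm(4), 1, 4)
  expect_lt(fd_check(function(tp, x) {
    a <- ad("ad_rows")(tp, x, c(1, 3, 3, 5)) # duplicated index
    bb <- ad("ad_rows")(tp, x, c(2, 4, 1, 2))
    ad("ad_sum")(tp, ad("ad_hadamard")(tp,
      ad("ad_rbind")(tp, list(a, bb)),
      ad("ad_rbind")(tp, list(bb, a))))
  }, x0), 1e-5)
  expect_lt(fd_check(function(tp, x) {
    y <- ad("ad_add_bias")(tp, x, ad("ad_input")(tp, b))
    z <- ad("ad_cbind")(tp, list(y, x))
    ad("ad_mean")(tp, ad("ad_hadamard")(tp, z, z))
  }, x0), 1e-5)
})

test_that("the full MIL loss gradient matches finite differences", {
  set.seed(4)
  cfg <- mil_config_tiny()
  model <- mil_model_init(cfg, input_dim = 6, seed = 5)
  x <- matrix(rnorm(10 * 6), 10, 6)
  cl <- sample(0:2, 10, replace = TRUE)
  tc <- train_config("classification", epochs = 1, seed = 1)
  w <- c(1.4, 0.8)
  loss_at <- function(params) {
    m <- model; m$params <- params
    fw <- mil_forward(m, x, cl)
    suppressMessages(moma:::mil_loss_nodes(fw, 2, w, cfg, tc))$total$value[1, 1]
  }
  fw <- mil_forward(model, x, cl)
  ln <- suppressMessages(moma:::mil_loss_nodes(fw, 2, w, cfg, tc))
  moma:::ad_backward(fw$nodes$tape, ln$total)
  grads <- moma:::param_grads(fw$nodes$params)
  modify <- function(params, path, delta, i, j) {
    ref <- params
    walk <- function(lst, p) {
      if (length(p) == 1) {
        lst[[p[[1]]]][i, j] <- lst[[p[[1]]]][i, j] + delta
        return(lst)
      }
      lst[[p[[1]]]] <- walk(lst[[p[[1]]]], p[-1]); lst
    }
    walk(ref, path)
  }
  eps <- 1e-6
  paths <- list(list("reduce", "W"), list("layers", 1L, "heads", 1L, "Wk"),
                list("layers", 1L, "W2"), list("tile_att", "V"),
                list("cluster_att", "U"), list("head", "W"))
  for (pt in paths) {
    g <- grads; p <- model$params
    for (k in pt) { g <- g[[k]]; p <- p[[k]] }
    i <- 1 + (nchar(paste(unlist(pt), collapse = "")) %% nrow(p))
    j <- ncol(p)
    fd <- (loss_at(modify(model$params, pt, eps, i, j)) -
             loss_at(modify(model$params, pt, -eps, i, j))) / (2 * eps)
    expect_lt(abs(fd - g[i, j]) / max(1e-6, abs(fd)), 1e-4)
  }
})
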