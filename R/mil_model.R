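#' @title Cluster-structured attention-MIL transformer
#' @description The weakly supervised slide-level predictor. Tile features are
#'   reduced by a learned affine map, tiles of each microenvironment cluster
#'   form a token sequence passed through a transformer encoder, gated
#'   attention pools tokens to a cluster vector and cluster vectors to the
#'   slide embedding, and an affine + softmax head produces class
#'   probabilities. Tiles are an unordered set, so no positional encodings are
#'   used; the full forward pass is permutation-invariant at the slide level.
#' @name mil_model
NULL

#' Model configuration
#'
#' Defaults follow the production architecture: 512-dimensional reduced
#' features, transformer encoder layers with 512 hidden neurons, 8 heads and a
#' 2048-neuron multi-layer perceptron, dropout 0.1. The residual wiring
#' requires `transformer_hidden == reduced_dim`. A `tiny` preset
#' (16/16/2/32, 1 layer) runs the whole pipeline on CPU in seconds and is used
#' by the tests.
#'
#' @param reduced_dim Per-tile reduced feature dimension (default 512).
#' @param transformer_hidden Transformer token width (must equal
#'   `reduced_dim`; default 512).
#' @param n_heads Attention heads (must divide `transformer_hidden`;
#'   default 8).
#' @param mlp_dim Transformer MLP width (default 2048).
#' @param n_layers Encoder depth (default 2).
#' @param dropout Dropout rate in \[0, 1) (default 0.1).
#' @param n_classes Number of slide-level classes (default 2).
#' @param attention `"gated"` (two-branch tanh/sigmoid, the default) or
#'   `"simple"` (tanh branch only).
#' @param attention_dim Width of the attention branches (default
#'   `reduced_dim`).
#' @return A `mil_config` list.
#' @export
mil_config <- function(reduced_dim = 512, transformer_hidden = 512,
                       n_heads = 8, mlp_dim = 2048, n_layers = 2,
                       dropout = 0.1, n_classes = 2,
                       attention = c("gated", "simple"),
                       attention_dim = reduced_dim) {
  attention <- match.arg(attention)
  stopifnot(reduced_dim >= 1, mlp_dim >= 1, n_layers >= 1, n_classes >= 2,
            dropout >= 0, dropout < 1, attention_dim >= 1)
  if (transformer_hidden != reduced_dim)
    stop("transformer_hidden must equal reduced_dim (residual wiring)")
  if (transformer_hidden %% n_heads != 0)
    stop("n_heads must divide transformer_hidden")
  structure(list(reduced_dim = reduced_dim,
                 transformer_hidden = transformer_hidden, n_heads = n_heads,
                 mlp_dim = mlp_dim, n_layers = n_layers, dropout = dropout,
                 n_classes = n_classes, attention = attention,
                 attention_dim = attention_dim), class = "mil_config")
}

#' @rdname mil_config
#' @export
mil_config_tiny <- function(n_classes = 2) {
  mil_config(reduced_dim = 16, transformer_hidden = 16, n_heads = 2,
             mlp_dim = 32, n_layers = 1, dropout = 0.1,
             n_classes = n_classes)
}

glorot <- function(nr, nc) {
  matrix(runif(nr * nc, -1, 1) * sqrt(6 / (nr + nc)), nr, nc)
}

#' Initialize model parameters
#'
#' Glorot-uniform weights, zero biases, unit layer-norm gains, drawn under a
#' fixed seed.
#'
#' @param config A [mil_config()].
#' @param input_dim Backbone feature dimension d.
#' @param seed Integer seed.
#' @return A `mil_model`: list with `params`, `config`, `input_dim`, `seed`.
#' @export
mil_model_init <- function(config, input_dim, seed = 1) {
  d <- config$reduced_dim
  dh <- d %/% config$n_heads
  da <- config$attention_dim
  params <- with_seed(seed, {
    layers <- lapply(seq_len(config$n_layers), function(l) {
      heads <- lapply(seq_len(config$n_heads), function(h)
        list(Wq = glorot(d, dh), Wk = glorot(d, dh), Wv = glorot(d, dh)))
      list(heads = heads, Wo = glorot(d, d), bo = matrix(0, 1, d),
           ln1g = matrix(1, 1, d), ln1b = matrix(0, 1, d),
           W1 = glorot(d, config$mlp_dim), b1 = matrix(0, 1, config$mlp_dim),
           W2 = glorot(config$mlp_dim, d), b2 = matrix(0, 1, d),
           ln2g = matrix(1, 1, d), ln2b = matrix(0, 1, d))
    })
    att <- function() list(V = glorot(d, da), U = glorot(d, da),
                           w = glorot(da, 1))
    list(reduce = list(W = glorot(input_dim, d), b = matrix(0, 1, d)),
         layers = layers, tile_att = att(), cluster_att = att(),
         head = list(W = glorot(d, config$n_classes),
                     b = matrix(0, 1, config$n_classes)))
  })
  structure(list(params = params, config = config, input_dim = input_dim,
                 seed = seed), class = "mil_model")
}

# Recursively wrap a parameter structure (nested lists of matrices) as tape
# inputs; returns the same structure of nodes.
param_nodes <- function(tape, params) {
  if (is.matrix(params)) return(ad_input(tape, params))
  lapply(params, function(p) param_nodes(tape, p))
}

# Recursively collect gradients from a node structure (NULL grads -> zeros)
param_grads <- function(pnodes) {
  if (is.environment(pnodes)) {
    g <- pnodes$grad
    if (is.null(g)) g <- matrix(0, nrow(pnodes$value), ncol(pnodes$value))
    return(g)
  }
  lapply(pnodes, param_grads)
}

# Elementwise map over two parallel parameter structures
param_map2 <- function(a, b, f) {
  if (is.matrix(a)) return(f(a, b))
  Map(function(x, y) param_map2(x, y, f), a, b)
}

dropout_mask <- function(nr, nc, p) {
  matrix((runif(nr * nc) >= p) / (1 - p), nr, nc)
}

# one transformer encoder layer on token node TT (n x d)
encoder_layer <- function(tape, TT, lp, config, train) {
  dh <- config$transformer_hidden %/% config$n_heads
  heads <- lapply(lp$heads, function(hp) {
    q <- ad_matmul(tape, TT, hp$Wq)
    k <- ad_matmul(tape, TT, hp$Wk)
    v <- ad_matmul(tape, TT, hp$Wv)
    a <- ad_softmax_rows(tape, ad_scale(tape,
           ad_matmul(tape, q, ad_t(tape, k)), 1 / sqrt(dh)))
    ad_matmul(tape, a, v)
  })
  o <- ad_add_bias(tape, ad_matmul(tape, ad_cbind(tape, heads), lp$Wo), lp$bo)
  if (train && config$dropout > 0)
    o <- ad_mul_const(tape, o,
                      dropout_mask(nrow(o$value), ncol(o$value), config$dropout))
  t1 <- ad_layernorm(tape, ad_add(tape, TT, o), lp$ln1g, lp$ln1b)
  m <- ad_add_bias(tape,
         ad_matmul(tape,
           ad_relu(tape, ad_add_bias(tape, ad_matmul(tape, t1, lp$W1), lp$b1)),
           lp$W2), lp$b2)
  if (train && config$dropout > 0)
    m <- ad_mul_const(tape, m,
                      dropout_mask(nrow(m$value), ncol(m$value), config$dropout))
  ad_layernorm(tape, ad_add(tape, t1, m), lp$ln2g, lp$ln2b)
}

# gated (or simple tanh) attention scores over rows of TT: returns n x 1 node
attention_scores <- function(tape, TT, ap, config) {
  br <- ad_tanh(tape, ad_matmul(tape, TT, ap$V))
  if (config$attention == "gated")
    br <- ad_hadamard(tape, br, ad_sigmoid(tape, ad_matmul(tape, TT, ap$U)))
  ad_matmul(tape, br, ap$w)
}

#' Full slide-level forward pass
#'
#' Reduces the bag, encodes each nonempty cluster's tiles with the transformer,
#' pools tokens to cluster vectors and cluster vectors to the slide embedding
#' with gated attention, and classifies the embedding. The reported per-tile
#' attention is the within-cluster weight multiplied by the cluster's weight,
#' so it sums to 1 over the whole pooled set. `instance_scores` are the
#' classification head's logits applied per tile to the post-transformer
#' tokens (used by the instance loss).
#'
#' @param model A `mil_model`.
#' @param bag A `feature_bag` (or plain feature matrix).
#' @param assignment A `cluster_assignment` (or integer vector of cluster ids
#'   aligned to the bag rows).
#' @param train Logical; enables dropout (uses the ambient RNG). Eval mode
#'   (`FALSE`, default) is deterministic.
#' @return A `slide_forward` list: `class_probabilities`, `cluster_attention`
#'   (named by cluster id), `tile_attention` (bag order), `slide_embedding`,
#'   `instance_scores` (n_tiles x n_classes, bag order), `clusters`
#'   (cluster ids in stream order), plus tape internals (`nodes`) used by the
#'   training loop.
#' @export
mil_forward <- function(model, bag, assignment, train = FALSE) {
  x <- if (inherits(bag, "feature_bag")) bag$features else bag
  cl <- if (inherits(assignment, "cluster_assignment"))
    assignment$cluster_id else assignment
  stopifnot(nrow(x) >= 1, length(cl) == nrow(x))
  if (ncol(x) != model$input_dim) stop("feature dimension mismatch")
  config <- model$config
  tape <- ad_tape()
  pn <- param_nodes(tape, model$params)
  xn <- ad_input(tape, x)
  hh <- ad_add_bias(tape, ad_matmul(tape, xn, pn$reduce$W), pn$reduce$b)
  clusters <- sort(unique(cl))
  n <- nrow(x)
  cluster_vecs <- list()
  token_nodes <- list()
  within_w <- list()
  idx_by_cluster <- list()
  for (ci in seq_along(clusters)) {
    idx <- which(cl == clusters[ci])
    tt <- ad_rows(tape, hh, idx)
    for (l in seq_len(config$n_layers))
      tt <- encoder_layer(tape, tt, pn$layers[[l]], config, train)
    s <- attention_scores(tape, tt, pn$tile_att, config)
    a <- ad_softmax_rows(tape, ad_t(tape, s)) # 1 x n_c
    cluster_vecs[[ci]] <- ad_matmul(tape, a, tt) # 1 x d
    token_nodes[[ci]] <- tt
    within_w[[ci]] <- as.vector(a$value)
    idx_by_cluster[[ci]] <- idx
  }
  zz <- ad_rbind(tape, cluster_vecs) # m x d
  gs <- attention_scores(tape, zz, pn$cluster_att, config)
  ga <- ad_softmax_rows(tape, ad_t(tape, gs)) # 1 x m
  emb <- ad_matmul(tape, ga, zz)               # 1 x d
  logits <- ad_add_bias(tape, ad_matmul(tape, emb, pn$head$W), pn$head$b)
  prob <- ad_softmax_rows(tape, logits)
  # per-tile instance logits, scattered back to bag order
  inst <- matrix(NA_real_, n, config$n_classes)
  inst_nodes <- vector("list", length(clusters))
  for (ci in seq_along(clusters)) {
    sn <- ad_add_bias(tape, ad_matmul(tape, token_nodes[[ci]], pn$head$W),
                      pn$head$b)
    inst_nodes[[ci]] <- sn
    inst[idx_by_cluster[[ci]], ] <- sn$value
  }
  tile_att <- numeric(n)
  gav <- as.vector(ga$value)
  for (ci in seq_along(clusters))
    tile_att[idx_by_cluster[[ci]]] <- within_w[[ci]] * gav[ci]
  structure(list(
    class_probabilities = as.vector(prob$value),
    cluster_attention = setNames(gav, clusters),
    tile_attention = tile_att,
    slide_embedding = as.vector(emb$value),
    instance_scores = inst,
    clusters = clusters,
    nodes = list(tape = tape, params = pn, prob = prob, logits = logits,
                 emb = emb, instance = inst_nodes,
                 idx_by_cluster = idx_by_cluster)),
    class = "slide_forward")
}

#' Reduce a bag to the model's working dimension
#'
#' The learned affine map shared across tiles (evaluation mode).
#'
#' @param bag A `feature_bag` or feature matrix.
#' @param model A `mil_model`.
#' @return n_tiles x `reduced_dim` matrix, rows in input order.
#' @export
reduce_features <- function(bag, model) {
  x <- if (inherits(bag, "feature_bag")) bag$features else bag
  if (ncol(x) != model$input_dim) stop("feature dimension mismatch")
  sweep(x %*% model$params$reduce$W, 2, as.vector(model$params$reduce$b), "+")
}

#' Classify a slide embedding
#'
#' Affine head plus softmax; output lies on the probability simplex.
#'
#' @param slide_embedding Numeric vector of length `reduced_dim`.
#' @param model A `mil_model` (its classification head is used).
#' @return Probability vector of length `n_classes`.
#' @export
classify <- function(slide_embedding, model) {
  if (length(slide_embedding) != model$config$reduced_dim)
    stop("embedding dimension mismatch")
  z <- as.vector(slide_embedding %*% model$params$head$W) +
    as.vector(model$params$head$b)
  z <- z - max(z)
  exp(z) / sum(exp(z))
}

#' Serialize / load a model checkpoint as JSON
#'
#' Parameters, architecture configuration and input dimension in one JSON
#' document (text-only checkpoint).
#' @param model A `mil_model`.
#' @param path JSON path.
#' @return The path (write) or the `mil_model` (read).
#' @export
write_checkpoint <- function(model, path) {
  ser <- function(p) if (is.matrix(p))
    list(.mat = TRUE, nr = nrow(p), data = as.vector(p)) else lapply(p, ser)
  jsonlite::write_json(list(params = ser(model$params),
                            config = unclass(model$config),
                            input_dim = model$input_dim, seed = model$seed),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = FALSE)
  de <- function(p) {
    if (is.list(p) && isTRUE(p[[".mat"]]))
      return(matrix(as.numeric(unlist(p$data)), nrow = p$nr[[1]]))
    lapply(p, de)
  }
  cfg <- lapply(x$config, function(v) unlist(v))
  config <- mil_config(reduced_dim = cfg$reduced_dim,
                       transformer_hidden = cfg$transformer_hidden,
                       n_heads = cfg$n_heads, mlp_dim = cfg$mlp_dim,
                       n_layers = cfg$n_layers, dropout = cfg$dropout,
                       n_classes = cfg$n_classes, attention = cfg$attention,
                       attention_dim = cfg$attention_dim)
  structure(list(params = de(x$params), config = config,
                 input_dim = x$input_dim, seed = x$seed),
            class = "mil_model")
}
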