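# Internal layer-graph builder shared by the two backbones and the assembled
# ensemble. A graph is an ordered list of layer descriptors consumed by the
# C++ engine plus bookkeeping: per-node output shapes (H, W, C) and the
# shape/fan-in of every learnable parameter (used for seeded initialization).

.ngNew <- function(inputShape = c(224L, 224L, 3L)) {
  g <- new.env(parent = emptyenv())
  g$layers <- list(list(type = "input", in_ = integer(0)))
  g$shape <- list(as.integer(inputShape))
  g$paramInfo <- list()
  g
}

.ngShape <- function(g, id) g$shape[[id]]

.ngConvOut <- function(n, k, s, p) as.integer((n + 2L * p - k) %/% s + 1L)

.ngAdd <- function(g, type, in_, prefix = NULL, k = 0L, s = 1L, p = 0L,
                   cout = NULL) {
  sh <- g$shape[[in_[1L]]]
  out <- switch(type,
    conv = {
      stopifnot(!is.null(prefix), !is.null(cout))
      g$paramInfo[[length(g$paramInfo) + 1L]] <- list(
        name = paste0(prefix, ".W"), kind = "conv",
        dim = c(cout, k * k * sh[3L]), fanin = k * k * sh[3L])
      c(.ngConvOut(sh[1L], k, s, p), .ngConvOut(sh[2L], k, s, p), cout)
    },
    bn = {
      g$paramInfo[[length(g$paramInfo) + 1L]] <- list(
        name = paste0(prefix, ".gamma"), kind = "bn_gamma", dim = sh[3L])
      g$paramInfo[[length(g$paramInfo) + 1L]] <- list(
        name = paste0(prefix, ".beta"), kind = "bn_beta", dim = sh[3L])
      sh
    },
    relu = sh,
    maxpool = c(.ngConvOut(sh[1L], k, s, p), .ngConvOut(sh[2L], k, s, p),
                sh[3L]),
    avgpool = c(.ngConvOut(sh[1L], k, s, p), .ngConvOut(sh[2L], k, s, p),
                sh[3L]),
    add = sh,
    concat = {
      sh2 <- g$shape[[in_[2L]]]
      c(sh[1L], sh[2L], sh[3L] + sh2[3L])
    },
    dense = {
      stopifnot(!is.null(prefix), !is.null(cout))
      din <- prod(sh)
      g$paramInfo[[length(g$paramInfo) + 1L]] <- list(
        name = paste0(prefix, ".W"), kind = "dense_W", dim = c(cout, din),
        fanin = din)
      g$paramInfo[[length(g$paramInfo) + 1L]] <- list(
        name = paste0(prefix, ".b"), kind = "dense_b", dim = cout)
      c(1L, 1L, cout)
    },
    stop("unknown layer type: ", type)
  )
  g$layers[[length(g$layers) + 1L]] <- list(
    type = type, in_ = as.integer(in_), prefix = prefix,
    k = as.integer(k), s = as.integer(s), p = as.integer(p))
  g$shape[[length(g$layers)]] <- as.integer(out)
  length(g$layers)
}

# Layer list in the form the C++ engine expects.
.ngCompile <- function(g) {
  lapply(g$layers, function(l) {
    out <- list(type = l$type, `in` = l$in_, k = l$k, s = l$s, p = l$p)
    if (!is.null(l$prefix)) out$prefix <- l$prefix
    out
  })
}

# Seeded initialization: He-normal convolution kernels, identity batch-norm
# affine terms, small gaussian dense weights, zero biases. Draw order follows
# graph construction order, so a (graph, seed) pair fixes every parameter.
.ngInitParams <- function(g, seed) {
  params <- vector("list", length(g$paramInfo))
  names(params) <- vapply(g$paramInfo, `[[`, "", "name")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())),
          add = TRUE)
  set.seed(seed)
  for (i in seq_along(g$paramInfo)) {
    pi <- g$paramInfo[[i]]
    params[[i]] <- switch(pi$kind,
      conv = matrix(stats::rnorm(prod(pi$dim), sd = sqrt(2 / pi$fanin)),
                    pi$dim[1L], pi$dim[2L]),
      bn_gamma = rep(1, pi$dim),
      bn_beta = rep(0, pi$dim),
      dense_W = matrix(stats::rnorm(prod(pi$dim), sd = 0.01),
                       pi$dim[1L], pi$dim[2L]),
      dense_b = rep(0, pi$dim))
  }
  params
}

# ---- architecture builders ------------------------------------------------

# Modified ResNet-50: standard bottleneck layout truncated after the global
# average pool, so the output is the 2048-d feature vector f1.
.buildResNet50Graph <- function(prefix = "rn") {
  g <- .ngNew()
  id <- .ngAdd(g, "conv", 1L, paste0(prefix, ".conv1"), k = 7L, s = 2L,
               p = 3L, cout = 64L)
  stageConv1 <- id
  id <- .ngAdd(g, "bn", id, paste0(prefix, ".bn1"))
  id <- .ngAdd(g, "relu", id)
  id <- .ngAdd(g, "maxpool", id, k = 3L, s = 2L, p = 1L)
  stagePool <- id
  stages <- integer(4)
  widths <- c(64L, 128L, 256L, 512L)
  blocks <- c(3L, 4L, 6L, 3L)
  strides <- c(1L, 2L, 2L, 2L)
  for (st in 1:4) {
    for (b in seq_len(blocks[st])) {
      pre <- sprintf("%s.s%d.b%d", prefix, st, b)
      s <- if (b == 1L) strides[st] else 1L
      cin <- .ngShape(g, id)[3L]
      w <- widths[st]
      a <- .ngAdd(g, "conv", id, paste0(pre, ".c1"), k = 1L, cout = w)
      a <- .ngAdd(g, "bn", a, paste0(pre, ".n1"))
      a <- .ngAdd(g, "relu", a)
      a <- .ngAdd(g, "conv", a, paste0(pre, ".c2"), k = 3L, s = s, p = 1L,
                  cout = w)
      a <- .ngAdd(g, "bn", a, paste0(pre, ".n2"))
      a <- .ngAdd(g, "relu", a)
      a <- .ngAdd(g, "conv", a, paste0(pre, ".c3"), k = 1L, cout = 4L * w)
      a <- .ngAdd(g, "bn", a, paste0(pre, ".n3"))
      sc <- id
      if (s != 1L || cin != 4L * w) {
        sc <- .ngAdd(g, "conv", id, paste0(pre, ".sc"), k = 1L, s = s,
                     cout = 4L * w)
        sc <- .ngAdd(g, "bn", sc, paste0(pre, ".nsc"))
      }
      id <- .ngAdd(g, "add", c(a, sc))
      id <- .ngAdd(g, "relu", id)
    }
    stages[st] <- id
  }
  id <- .ngAdd(g, "avgpool", id, k = 7L, s = 7L)
  stageNodes <- c("Conv 1" = stageConv1, "Max Pooling" = stagePool,
                  "Conv 2_x" = stages[1], "Conv 3_x" = stages[2],
                  "Conv 4_x" = stages[3], "Conv 5_x" = stages[4],
                  "Average Pooling" = id)
  list(graph = g, final = id, stageNodes = stageNodes)
}

# Modified DenseNet-201: growth rate 32, block sizes 6/12/48/32, halving
# transitions, truncated after the global average pool (1920-d feature f2).
.buildDenseNet201Graph <- function(prefix = "dn") {
  g <- .ngNew()
  growth <- 32L
  id <- .ngAdd(g, "conv", 1L, paste0(prefix, ".conv1"), k = 7L, s = 2L,
               p = 3L, cout = 64L)
  stageConv1 <- id
  id <- .ngAdd(g, "bn", id, paste0(prefix, ".bn1"))
  id <- .ngAdd(g, "relu", id)
  id <- .ngAdd(g, "maxpool", id, k = 3L, s = 2L, p = 1L)
  stagePool <- id
  blocks <- c(6L, 12L, 48L, 32L)
  stageNodes <- c("Conv 1" = stageConv1, "Max Pooling" = stagePool)
  for (bl in 1:4) {
    for (ly in seq_len(blocks[bl])) {
      pre <- sprintf("%s.d%d.l%d", prefix, bl, ly)
      a <- .ngAdd(g, "bn", id, paste0(pre, ".n1"))
      a <- .ngAdd(g, "relu", a)
      a <- .ngAdd(g, "conv", a, paste0(pre, ".c1"), k = 1L,
                  cout = 4L * growth)
      a <- .ngAdd(g, "bn", a, paste0(pre, ".n2"))
      a <- .ngAdd(g, "relu", a)
      a <- .ngAdd(g, "conv", a, paste0(pre, ".c2"), k = 3L, p = 1L,
                  cout = growth)
      id <- .ngAdd(g, "concat", c(id, a))
    }
    stageNodes[sprintf("DenseBlock_%d", bl)] <- id
    if (bl < 4L) {
      pre <- sprintf("%s.t%d", prefix, bl)
      cin <- .ngShape(g, id)[3L]
      id <- .ngAdd(g, "bn", id, paste0(pre, ".n"))
      id <- .ngAdd(g, "relu", id)
      id <- .ngAdd(g, "conv", id, paste0(pre, ".c"), k = 1L,
                   cout = cin %/% 2L)
      id <- .ngAdd(g, "avgpool", id, k = 2L, s = 2L)
      stageNodes[sprintf("Transition_%d", bl)] <- id
    }
  }
  id <- .ngAdd(g, "bn", id, paste0(prefix, ".bnF"))
  id <- .ngAdd(g, "relu", id)
  id <- .ngAdd(g, "avgpool", id, k = 7L, s = 7L)
  stageNodes["Average Pooling"] <- id
  list(graph = g, final = id, stageNodes = stageNodes)
}
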