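#' Hourglass network configuration
#'
#' Architecture hyperparameters of the single-stack 3D hourglass. The
#' defaults reproduce the production configuration: a stem convolution with
#' 256 features, kernel 7, stride 2; residual blocks with 64, 64, and 128
#' features and kernels 1, 1, 3; group normalization with 8 groups; 46
#' output channels (one per clinical landmark); 4 pooling levels. Toy
#' configurations (e.g. `stem_features = 8`, `depth = 2`) train in seconds
#' on the phantom benchmark.
#'
#' @param in_channels input channels (1 for CBCT intensity).
#' @param out_channels output channels, one heatmap per landmark.
#' @param stem_features,stem_kernel,stem_stride stem convolution block.
#' @param block_features,block_kernels the three convolutions of every
#'   residual block; the third entry is the block's output width.
#' @param gn_groups group-normalization groups; must divide every
#'   normalized feature count.
#' @param depth number of pooling levels in the hourglass.
#' @param seed integer seed for parameter initialization.
#' @return An object of class `network_config`.
#' @export
network_config <- function(in_channels = 1L, out_channels = 46L,
                           stem_features = 256L, stem_kernel = 7L,
                           stem_stride = 2L,
                           block_features = c(64L, 64L, 128L),
                           block_kernels = c(1L, 1L, 3L),
                           gn_groups = 8L, depth = 4L, seed = 1L) {
  cfg <- list(in_channels = as.integer(in_channels),
              out_channels = as.integer(out_channels),
              stem_features = as.integer(stem_features),
              stem_kernel = as.integer(stem_kernel),
              stem_stride = as.integer(stem_stride),
              block_features = as.integer(block_features),
              block_kernels = as.integer(block_kernels),
              gn_groups = as.integer(gn_groups),
              depth = as.integer(depth),
              seed = as.integer(seed))
  with(cfg, {
    stopifnot(in_channels >= 1, out_channels >= 1, stem_features >= 1,
              length(block_features) == 3L, length(block_kernels) == 3L,
              depth >= 1, gn_groups >= 1, stem_stride >= 1)
    if (any(block_kernels %% 2L == 0L) || stem_kernel %% 2L == 0L)
      stop("kernel sizes must be odd (same-padding)", call. = FALSE)
  })
  for (f in c(cfg$stem_features, cfg$block_features))
    if (f %% cfg$gn_groups != 0L)
      stop("feature count ", f, " not divisible by gn_groups = ",
           cfg$gn_groups, call. = FALSE)
  structure(cfg, class = "network_config")
}

# --- parameter initialization --------------------------------------------

init_conv <- function(k, cin, cout) {
  fan_in <- k^3 * cin
  list(w = array(rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
                 c(k, k, k, cin, cout)),
       b = numeric(cout), k = k, cin = cin, cout = cout)
}

init_gn <- function(c) list(gamma = rep(1, c), beta = numeric(c))

init_resblock <- function(cin, feats, kerns, gn_groups) {
  bl <- list(conv1 = init_conv(kerns[1], cin, feats[1]),
             gn1 = init_gn(feats[1]),
             conv2 = init_conv(kerns[2], feats[1], feats[2]),
             gn2 = init_gn(feats[2]),
             conv3 = init_conv(kerns[3], feats[2], feats[3]),
             gn3 = init_gn(feats[3]))
  if (cin != feats[3]) bl$proj <- init_conv(1L, cin, feats[3])
  bl
}

#' Build a seeded hourglass network
#'
#' Instantiates the architecture: stem convolution (group norm + ReLU),
#' a residual block adapting stem features to the block width, a contracting
#' pathway of `depth` residual blocks each followed by 2x2x2 max pooling,
#' an expanding pathway of trilinear upsamplings each followed by a residual
#' block, skip connections summed elementwise at equal resolutions, and a
#' final 1x1x1 convolution with sigmoid (no normalization). Each residual
#' block applies conv-GN-ReLU, conv-GN-ReLU, conv-GN, adds the (possibly
#' 1x1x1-projected) shortcut, then a final ReLU. Initialization is fan-in
#' scaled Gaussian, fully determined by `config$seed`.
#'
#' @param config a [network_config()].
#' @return An object of class `ceph_network` with fields `config` and
#'   `params` (a nested list of numeric arrays).
#' @export
build_network <- function(config) {
  stopifnot(inherits(config, "network_config"))
  old <- get0(".Random.seed", globalenv(), ifnotfound = NULL)
  on.exit(restore_seed(old))
  set.seed(config$seed)
  width <- config$block_features[3]
  params <- list(
    stem = c(init_conv(config$stem_kernel, config$in_channels,
                       config$stem_features),
             init_gn(config$stem_features)),
    pre = init_resblock(config$stem_features, config$block_features,
                        config$block_kernels, config$gn_groups))
  for (l in seq_len(config$depth)) {
    params[[paste0("down", l)]] <-
      init_resblock(width, config$block_features, config$block_kernels,
                    config$gn_groups)
    params[[paste0("up", l)]] <-
      init_resblock(width, config$block_features, config$block_kernels,
                    config$gn_groups)
  }
  # Small-scale head initialization: output logits start near zero so the
  # sigmoid activations begin around 0.5, well inside (0, 1) and away from
  # the saturated ends regardless of depth.
  params$head <- init_conv(1L, width, config$out_channels)
  params$head$w <- params$head$w * (1e-3 / sqrt(2 / width))
  structure(list(config = config, params = params), class = "ceph_network")
}

restore_seed <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", globalenv()))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Number of trainable parameters
#' @param net a [build_network()] result.
#' @return Integer count of scalar parameters.
#' @export
n_parameters <- function(net) {
  n <- 0L
  walk <- function(x) {
    for (nm in names(x)) {
      if (nm %in% c("w", "b", "gamma", "beta")) n <<- n + length(x[[nm]])
      else if (is.list(x[[nm]])) walk(x[[nm]])
    }
  }
  walk(net$params)
  n
}

# --- layer forward/backward ----------------------------------------------

conv_fw <- function(x, p, stride = 1L, keep = FALSE) {
  pad <- (p$k - 1L) %/% 2L
  r <- .cpp_conv3d_forward(x, dim(x), p$w, p$b, p$k, stride, pad, keep)
  list(out = r$out,
       cache = if (keep) list(col = r$col, xdim = dim(x),
                              odim = dim(r$out), stride = stride, pad = pad))
}

conv_bw <- function(cache, p, gout) {
  r <- .cpp_conv3d_backward(cache$col, p$w, cache$xdim, gout, cache$odim,
                            p$k, cache$stride, cache$pad)
  list(gx = r$gx, grads = list(w = r$gw, b = r$gb))
}

gn_fw <- function(x, p, groups, keep = FALSE) {
  r <- .cpp_groupnorm_forward(x, dim(x), p$gamma, p$beta, groups, 1e-5)
  list(out = r$out,
       cache = if (keep) list(xhat = r$xhat, invstd = r$invstd,
                              xdim = dim(x)))
}

gn_bw <- function(cache, p, groups, gout) {
  r <- .cpp_groupnorm_backward(gout, cache$xhat, cache$invstd, p$gamma,
                               cache$xdim, groups)
  list(gx = r$gx, grads = list(gamma = r$ggamma, beta = r$gbeta))
}

relu_fw <- function(x) {
  out <- .cpp_relu_forward(x)
  dim(out) <- dim(x)
  out
}

relu_bw <- function(out, gout) {
  g <- .cpp_relu_backward(out, gout)
  dim(g) <- dim(gout)
  g
}

cgr_fw <- function(x, conv, gn, groups, stride = 1L, keep = FALSE) {
  a <- conv_fw(x, conv, stride, keep)
  b <- gn_fw(a$out, gn, groups, keep)
  out <- relu_fw(b$out)
  list(out = out,
       cache = if (keep) list(conv = a$cache, gn = b$cache, relu = out))
}

cgr_bw <- function(cache, conv, gn, groups, gout) {
  g <- relu_bw(cache$relu, gout)
  gb <- gn_bw(cache$gn, gn, groups, g)
  gc <- conv_bw(cache$conv, conv, gb$gx)
  list(gx = gc$gx, gconv = gc$grads, ggn = gb$grads)
}

resblock_fw <- function(x, pr, groups, keep = FALSE) {
  a <- cgr_fw(x, pr$conv1, pr$gn1, groups, 1L, keep)
  b <- cgr_fw(a$out, pr$conv2, pr$gn2, groups, 1L, keep)
  c3 <- conv_fw(b$out, pr$conv3, 1L, keep)
  g3 <- gn_fw(c3$out, pr$gn3, groups, keep)
  if (is.null(pr$proj)) {
    short <- x
    pc <- NULL
  } else {
    pc <- conv_fw(x, pr$proj, 1L, keep)
    short <- pc$out
  }
  out <- relu_fw(g3$out + short)
  list(out = out,
       cache = if (keep) list(a = a$cache, b = b$cache, c3 = c3$cache,
                              g3 = g3$cache, proj = pc$cache, relu = out))
}

resblock_bw <- function(cache, pr, groups, gout) {
  g <- relu_bw(cache$relu, gout)
  grads <- list()
  gg3 <- gn_bw(cache$g3, pr$gn3, groups, g)
  grads$gn3 <- gg3$grads
  gc3 <- conv_bw(cache$c3, pr$conv3, gg3$gx)
  grads$conv3 <- gc3$grads
  bb <- cgr_bw(cache$b, pr$conv2, pr$gn2, groups, gc3$gx)
  grads$conv2 <- bb$gconv; grads$gn2 <- bb$ggn
  aa <- cgr_bw(cache$a, pr$conv1, pr$gn1, groups, bb$gx)
  grads$conv1 <- aa$gconv; grads$gn1 <- aa$ggn
  gx <- aa$gx
  if (is.null(pr$proj)) {
    gx <- gx + g
  } else {
    gp <- conv_bw(cache$proj, pr$proj, g)
    grads$proj <- gp$grads
    gx <- gx + gp$gx
  }
  list(gx = gx, grads = grads)
}

# --- full network --------------------------------------------------------

check_input_size <- function(net, d) {
  minsz <- 2L^net$config$depth * net$config$stem_stride
  if (any(d < minsz))
    stop("input of size ", paste(d, collapse = "x"),
         " too small for depth ", net$config$depth,
         "; every dimension must be at least ", minsz, call. = FALSE)
}

net_forward <- function(net, x, keep = FALSE) {
  cfg <- net$config
  p <- net$params
  if (length(dim(x)) == 3L) dim(x) <- c(dim(x), 1L)
  check_input_size(net, dim(x)[1:3])
  cache <- list()
  s <- cgr_fw(x, p$stem[c("w", "b", "k", "cin", "cout")],
              p$stem[c("gamma", "beta")], cfg$gn_groups, cfg$stem_stride,
              keep)
  cache$stem <- s$cache
  pre <- resblock_fw(s$out, p$pre, cfg$gn_groups, keep)
  cache$pre <- pre$cache
  h <- pre$out
  skips <- vector("list", cfg$depth)
  skipdims <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    r <- resblock_fw(h, p[[paste0("down", l)]], cfg$gn_groups, keep)
    cache[[paste0("down", l)]] <- r$cache
    skips[[l]] <- r$out
    skipdims[[l]] <- dim(r$out)
    pl <- .cpp_maxpool3d_forward(r$out, dim(r$out))
    cache[[paste0("pool", l)]] <- list(argmax = pl$argmax,
                                       xdim = dim(r$out))
    h <- pl$out
  }
  for (l in rev(seq_len(cfg$depth))) {
    cache[[paste0("updim", l)]] <- dim(h)
    u <- .cpp_upsample3d_forward(h, dim(h), skipdims[[l]][1:3])
    h <- u + skips[[l]]
    r <- resblock_fw(h, p[[paste0("up", l)]], cfg$gn_groups, keep)
    cache[[paste0("up", l)]] <- r$cache
    h <- r$out
  }
  hd <- conv_fw(h, p$head, 1L, keep)
  cache$head <- hd$cache
  logits <- hd$out
  out <- 1 / (1 + exp(-logits))
  list(out = out, logits = logits, cache = if (keep) cache)
}

# Backward pass mirroring net_forward: the expanding path is unwound first
# (up1 was applied last); skip-branch gradients are held until the
# contracting path is unwound, because each down-block output feeds both its
# skip connection and, through pooling, all deeper levels.
net_backprop <- function(net, cache, gout_logits) {
  cfg <- net$config
  p <- net$params
  grads <- list()
  hb <- conv_bw(cache$head, p$head, gout_logits)
  grads$head <- hb$grads
  g <- hb$gx
  gskips <- vector("list", cfg$depth)
  for (l in seq_len(cfg$depth)) {
    rb <- resblock_bw(cache[[paste0("up", l)]], p[[paste0("up", l)]],
                      cfg$gn_groups, g)
    grads[[paste0("up", l)]] <- rb$grads
    gskips[[l]] <- rb$gx # gradient of (upsample(h) + skip_l), both branches
    g <- .cpp_upsample3d_backward(rb$gx, dim(rb$gx),
                                  cache[[paste0("updim", l)]])
  }
  # g now holds the gradient at the bottleneck (output of pool_depth)
  for (l in rev(seq_len(cfg$depth))) {
    pl <- cache[[paste0("pool", l)]]
    gs <- .cpp_maxpool3d_backward(g, pl$argmax, pl$xdim) + gskips[[l]]
    db <- resblock_bw(cache[[paste0("down", l)]], p[[paste0("down", l)]],
                      cfg$gn_groups, gs)
    grads[[paste0("down", l)]] <- db$grads
    g <- db$gx
  }
  pb <- resblock_bw(cache$pre, p$pre, cfg$gn_groups, g)
  grads$pre <- pb$grads
  sb <- cgr_bw(cache$stem, p$stem[c("w", "b", "k", "cin", "cout")],
               p$stem[c("gamma", "beta")], cfg$gn_groups, pb$gx)
  grads$stem <- c(sb$gconv, sb$ggn)
  grads
}

#' Run the network on a single-channel 3D grid
#'
#' Pure function of the parameters and input: produces one activation grid
#' per output channel at half the input resolution (the stem stride), all
#' values strictly in (0, 1).
#'
#' @param net a [build_network()] result.
#' @param input 3D numeric array (or 4D with one trailing channel).
#' @return 4D array `(x, y, z, out_channels)` of sigmoid activations.
#' @export
network_forward <- function(net, input) {
  net_forward(net, input, keep = FALSE)$out
}

#' Output-grid geometry for a given input volume
#'
#' The network halves resolution in the stem (stride 2 with same-padding),
#' so output voxel `o` sits at input voxel `stem_stride * o`: the output
#' grid keeps the input origin and direction with spacing multiplied by the
#' stem stride.
#'
#' @param net a [build_network()] result.
#' @param vol the input [volume()].
#' @return A [grid_geometry()] for the network output.
#' @export
output_geometry <- function(net, vol) {
  s <- net$config$stem_stride
  din <- dim(vol$data)
  grid_geometry(ceiling(din / s), spacing = vol$spacing * s,
                origin = vol$origin, direction = vol$direction)
}
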