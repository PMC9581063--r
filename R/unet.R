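# The five-composite-layer 3D U-Net.
#
# Layer plan (channels for base width c): two down-sampling composite layers
# (1 -> c -> c, then c -> 2c -> 2c), a bottleneck (2c -> 4c -> 4c), and two
# up-sampling composite layers mirrored through skip connections
# (concat 4c -> 2c -> 2c, concat 2c -> c -> c), with a final 1-voxel
# convolution to the 3 classes (background, helix, sheet). Each composite
# layer is two conv(3^3) + batch-norm + ReLU blocks; consecutive layers are
# joined by dropout followed by 2x max pooling (down path) or a 2^3/stride-2
# transposed convolution (up path). The network is end-to-end convolutional:
# output dimensions equal input dimensions for any input divisible by 4.

#' Network configuration
#'
#' @param base_channels channel width of the first composite layer; widths
#'   double per level (c, 2c, 4c at the bottleneck). Default 64 for the
#'   full-size model; desk-scale experiments use 8.
#' @param dropout_rate dropout fraction applied between composite layers.
#' @param seed seed for weight initialization.
#' @return A `unet_config` list (`num_classes` is fixed at 3, `depth` at 5).
#' @export
unet_config <- function(base_channels = 64L, dropout_rate = 0.1, seed = 1L) {
  base_channels <- as.integer(base_channels)
  if (is.na(base_channels) || base_channels < 1L)
    stop("`base_channels` must be >= 1")
  if (dropout_rate < 0 || dropout_rate >= 1)
    stop("`dropout_rate` must be in [0, 1)")
  structure(list(base_channels = base_channels, dropout_rate = dropout_rate,
                 num_classes = 3L, depth = 5L, seed = as.integer(seed)),
            class = "unet_config")
}

unet_channel_plan <- function(c1) {
  c2 <- 2L * c1; cb <- 4L * c1
  list(
    conv = list(  # name, cin, cout
      enc1.conv1 = c(1L, c1),  enc1.conv2 = c(c1, c1),
      enc2.conv1 = c(c1, c2),  enc2.conv2 = c(c2, c2),
      bott.conv1 = c(c2, cb),  bott.conv2 = c(cb, cb),
      dec2.conv1 = c(2L * c2, c2), dec2.conv2 = c(c2, c2),
      dec1.conv1 = c(2L * c1, c1), dec1.conv2 = c(c1, c1)
    ),
    up = list(up2 = c(cb, c2), up1 = c(c2, c1)),
    out = c(c1, 3L)
  )
}

#' Build a 3D U-Net model
#'
#' Initializes convolution weights Kaiming-style (sd = sqrt(2 / fan-in)),
#' biases and batch-norm shifts at 0, batch-norm scales at 1, using the seed
#' in `config`.
#'
#' @param config a [unet_config()].
#' @return A `unet_model` with elements `config` and `params` (the trainable
#'   arrays).
#' @export
build_unet <- function(config) {
  if (!inherits(config, "unet_config")) stop("`config` must be a unet_config")
  plan <- unet_channel_plan(config$base_channels)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(config$seed)

  params <- list()
  for (nm in names(plan$conv)) {
    io <- plan$conv[[nm]]
    params[[paste0(nm, ".W")]] <-
      array(stats::rnorm(27 * io[1] * io[2], sd = sqrt(2 / (27 * io[1]))),
            dim = c(27L, io[1], io[2]))
    params[[paste0(nm, ".b")]] <- numeric(io[2])
    bn <- sub("conv", "bn", nm)
    params[[paste0(bn, ".gamma")]] <- rep(1, io[2])
    params[[paste0(bn, ".beta")]] <- numeric(io[2])
  }
  for (nm in names(plan$up)) {
    io <- plan$up[[nm]]
    params[[paste0(nm, ".W")]] <-
      array(stats::rnorm(8 * io[1] * io[2], sd = sqrt(2 / (8 * io[1]))),
            dim = c(8L, io[1], io[2]))
    params[[paste0(nm, ".b")]] <- numeric(io[2])
  }
  params[["out.W"]] <- matrix(stats::rnorm(plan$out[1] * plan$out[2],
                                           sd = sqrt(2 / plan$out[1])),
                              plan$out[1], plan$out[2])
  params[["out.b"]] <- numeric(plan$out[2])

  structure(list(config = config, params = params), class = "unet_model")
}

#' @export
print.unet_model <- function(x, ...) {
  cat(sprintf(
    "<unet_model> 5 composite layers, base width %d, %s trainable parameters\n",
    x$config$base_channels,
    format(count_parameters(x), big.mark = ",")))
  invisible(x)
}

#' Count trainable parameters
#'
#' Total number of trainable scalars: convolution and transposed-convolution
#' weights and biases plus batch-norm scales and shifts.
#'
#' @param model a `unet_model`.
#' @return Integer-valued count.
#' @export
count_parameters <- function(model) {
  stopifnot(inherits(model, "unet_model"))
  sum(vapply(model$params, length, numeric(1)))
}

check_input_dims <- function(d3) {
  if (any(d3 > 100L))
    stop("input dimensions (", paste(d3, collapse = ", "),
         ") exceed the 100-voxel-per-dimension design limit")
  if (any(d3 %% 4L != 0L))
    stop("input dimensions (", paste(d3, collapse = ", "),
         ") must be multiples of 4; use pad_for_network() first")
  if (any(d3 < 4L)) stop("input dimensions must be >= 4")
}

# Core forward pass on a plain (nx, ny, nz, 1) array. `training` enables
# dropout; normalization always uses the map's own statistics. Returns probs
# and, when keep = TRUE, every intermediate needed by unet_backward_core().
unet_forward_core <- function(model, x, training = FALSE, keep = FALSE) {
  p <- model$params
  drop_rate <- model$config$dropout_rate
  cc <- list()

  block <- function(x, name) {
    for (j in 1:2) {
      cv <- paste0(name, ".conv", j); bn <- paste0(name, ".bn", j)
      x <- conv3d_forward(x, p[[paste0(cv, ".W")]], p[[paste0(cv, ".b")]],
                          keep_cache = keep)
      if (keep) cc[[cv]] <<- attr(x, "cache")
      x <- bn_forward(x, p[[paste0(bn, ".gamma")]], p[[paste0(bn, ".beta")]],
                      keep_cache = keep)
      if (keep) { cc[[bn]] <<- attr(x, "cache"); cc[[paste0(bn, ".pre")]] <<- x }
      x <- relu_forward(x)
    }
    x
  }
  drop <- function(x, name) {
    r <- dropout_forward(x, drop_rate, training)
    if (keep) cc[[name]] <<- r$mask
    r$out
  }

  e1 <- block(x, "enc1")
  p1 <- maxpool_forward(drop(e1, "do1"), keep_cache = keep)
  if (keep) cc$pool1 <- attr(p1, "cache")
  e2 <- block(p1, "enc2")
  p2 <- maxpool_forward(drop(e2, "do2"), keep_cache = keep)
  if (keep) cc$pool2 <- attr(p2, "cache")
  bo <- block(p2, "bott")
  u2 <- convtrans_forward(drop(bo, "do3"), p$up2.W, p$up2.b, keep_cache = keep)
  if (keep) cc$up2 <- attr(u2, "cache")
  m2 <- abind4(u2, e2)
  d2 <- block(m2, "dec2")
  u1 <- convtrans_forward(drop(d2, "do4"), p$up1.W, p$up1.b, keep_cache = keep)
  if (keep) cc$up1 <- attr(u1, "cache")
  m1 <- abind4(u1, e1)
  d1 <- block(m1, "dec1")
  logits <- conv1_forward(d1, p$out.W, p$out.b, keep_cache = keep)
  if (keep) cc$out <- attr(logits, "cache")
  probs <- softmax_channels(logits)

  list(probs = probs, logits = logits, cache = if (keep) cc)
}

# concatenate two volumes along the channel axis
abind4 <- function(a, b) {
  da <- dim(a); db <- dim(b)
  out <- array(0, dim = c(da[1:3], da[4] + db[4]))
  out[, , , seq_len(da[4])] <- a
  out[, , , da[4] + seq_len(db[4])] <- b
  out
}

# Backward pass from d(loss)/d(logits); returns gradients named like params.
unet_backward_core <- function(model, dlogits, cache) {
  p <- model$params
  g <- list()

  block_bwd <- function(dy, name) {
    for (j in 2:1) {
      cv <- paste0(name, ".conv", j); bn <- paste0(name, ".bn", j)
      dy <- relu_backward(dy, cache[[paste0(bn, ".pre")]])
      r <- bn_backward(dy, p[[paste0(bn, ".gamma")]], cache[[bn]])
      g[[paste0(bn, ".gamma")]] <<- r$dgamma
      g[[paste0(bn, ".beta")]] <<- r$dbeta
      r2 <- conv3d_backward(r$dx, p[[paste0(cv, ".W")]], cache[[cv]])
      g[[paste0(cv, ".W")]] <<- r2$dW
      g[[paste0(cv, ".b")]] <<- r2$db
      dy <- r2$dx
    }
    dy
  }

  r <- conv1_backward(dlogits, p$out.W, cache$out)
  g$out.W <- r$dW; g$out.b <- r$db
  dm1 <- block_bwd(r$dx, "dec1")
  c1 <- model$config$base_channels
  du1 <- dm1[, , , seq_len(c1), drop = FALSE]
  de1_skip <- dm1[, , , c1 + seq_len(c1), drop = FALSE]
  r <- convtrans_backward(du1, p$up1.W, cache$up1)
  g$up1.W <- r$dW; g$up1.b <- r$db
  dd2 <- dropout_backward(r$dx, cache$do4)
  dm2 <- block_bwd(dd2, "dec2")
  c2 <- 2L * c1
  du2 <- dm2[, , , seq_len(c2), drop = FALSE]
  de2_skip <- dm2[, , , c2 + seq_len(c2), drop = FALSE]
  r <- convtrans_backward(du2, p$up2.W, cache$up2)
  g$up2.W <- r$dW; g$up2.b <- r$db
  dbo <- dropout_backward(r$dx, cache$do3)
  dp2 <- block_bwd(dbo, "bott")
  de2 <- maxpool_backward(dp2, cache$pool2)
  de2 <- dropout_backward(de2, cache$do2) + de2_skip
  dp1 <- block_bwd(de2, "enc2")
  de1 <- maxpool_backward(dp1, cache$pool1)
  de1 <- dropout_backward(de1, cache$do1) + de1_skip
  block_bwd(de1, "enc1")
  g
}

#' Construct a per-voxel class probability grid
#'
#' @param probs 4D array (nx, ny, nz, 3), class order (background, helix,
#'   sheet); each voxel's probabilities must be non-negative and sum to 1
#'   within 1e-5.
#' @param origin,voxel_size lattice geometry, as in [density_map()].
#' @return An object of class `probability_grid`.
#' @export
probability_grid <- function(probs, origin = c(0, 0, 0), voxel_size = c(1, 1, 1)) {
  if (!is.array(probs) || length(dim(probs)) != 4L || dim(probs)[4] != 3L)
    stop("`probs` must be a 4D (x, y, z, 3) array")
  s <- vol2mat(probs)
  if (any(s < -1e-8) || any(abs(rowSums(s) - 1) > 1e-5))
    stop("per-voxel probabilities must be non-negative and sum to 1")
  structure(list(probs = probs, origin = as.numeric(origin),
                 voxel_size = as.numeric(voxel_size)),
            class = "probability_grid")
}

#' @export
dim.probability_grid <- function(x) dim(x$probs)

#' Run the network on a preprocessed density map
#'
#' The map must be normalized, at 1 A per voxel, with every dimension a
#' multiple of 4 and at most 100 (see [normalize_density()] and
#' [pad_for_network()]). Normalization layers use the map's own per-channel
#' statistics; in evaluation mode (the default) dropout is disabled, so the
#' output is a deterministic function of the input.
#'
#' @param model a `unet_model`.
#' @param map a [density_map()] (or bare 3D array).
#' @param training logical; use batch statistics and dropout.
#' @return A [probability_grid()] on the lattice of `map`.
#' @export
unet_forward <- function(model, map, training = FALSE) {
  stopifnot(inherits(model, "unet_model"))
  if (inherits(map, "density_map")) {
    a <- map$data; origin <- map$origin; vs <- map$voxel_size
  } else {
    a <- map; origin <- c(0, 0, 0); vs <- c(1, 1, 1)
  }
  d <- dim(a)
  check_input_dims(d)
  dim(a) <- c(d, 1L)
  r <- unet_forward_core(model, a, training = training, keep = FALSE)
  probability_grid(r$probs, origin = origin, voxel_size = vs)
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a single file holding the trainable weights, the network
#' configuration, the class order and a format version.
#'
#' @param model a `unet_model`.
#' @param path checkpoint file path.
#' @return `path` invisibly for save; a `unet_model` for load.
#' @export
save_checkpoint <- function(model, path) {
  stopifnot(inherits(model, "unet_model"))
  saveRDS(list(format = "cryosse-checkpoint", version = 1L,
               config = model$config, params = model$params,
               class_order = c("background", "helix", "sheet")),
          path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop("checkpoint not found: ", path)
  ck <- readRDS(path)
  if (!identical(ck$format, "cryosse-checkpoint"))
    stop("not a cryosse checkpoint: ", path)
  structure(list(config = ck$config, params = ck$params),
            class = "unet_model")
}
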