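# Fully convolutional 3D segmentation network mapping an 8-channel
# (32,32,32) environment to a per-voxel zinc probability. Six convolutional
# layers with 3-voxel (1.5 A) filters except the fifth, which uses a wide
# 16-voxel (8 A) filter to capture long-range interactions; ReLU
# nonlinearities, dropout between layers 5 and 6, sigmoid output.

#' Network architecture specification
#'
#' Filter extents are fixed (3 voxels everywhere except the 16-voxel fifth
#' layer); per-layer channel widths are configurable and default to a small
#' profile that trains at desk scale.
#'
#' @param widths Hidden channel widths of layers 1-5 (layer 6 always
#'   outputs 1 channel).
#' @param dropout Dropout probability between layers 5 and 6 (default 0.1).
#' @param in_channels Number of input channels (default 8).
#' @return A list of class `network_spec`.
#' @export
network_spec <- function(widths = c(6, 4, 4, 2, 2), dropout = 0.1,
                         in_channels = 8) {
  stopifnot(length(widths) == 5, all(widths >= 1), dropout >= 0, dropout < 1)
  filters <- c(3L, 3L, 3L, 3L, 16L, 3L)
  channels <- c(in_channels, as.integer(widths), 1L)
  structure(list(filters = filters, channels = channels, dropout = dropout),
            class = "network_spec")
}

#' Build the segmentation network
#'
#' Initializes weights (He-scaled normal) for the layer stack described by
#' the spec. The resulting model maps an `[32,32,32,8]` voxel array to an
#' `[32,32,32,1]` array of probabilities in (0, 1), preserving spatial size
#' through zero padding.
#'
#' @param spec A [network_spec()].
#' @param seed Integer seed for weight initialization.
#' @return A list of class `metal3d_network` with per-layer weight arrays
#'   `[k,k,k,cin,cout]` and bias vectors.
#' @export
build_network <- function(spec = network_spec(), seed = 1) {
  stopifnot(inherits(spec, "network_spec"))
  .with_seed(seed, {
    layers <- vector("list", 6)
    for (l in 1:6) {
      k <- spec$filters[l]
      cin <- spec$channels[l]
      cout <- spec$channels[l + 1]
      fan_in <- k^3 * cin
      w <- array(stats::rnorm(k^3 * cin * cout, sd = sqrt(2 / fan_in)),
                 dim = c(k, k, k, cin, cout))
      layers[[l]] <- list(w = w, b = numeric(cout), k = k, cin = cin, cout = cout)
    }
    structure(list(layers = layers, spec = spec, seed = seed),
              class = "metal3d_network")
  })
}

.as_input_array <- function(x) {
  if (inherits(x, "voxel_grid")) x <- x$values
  stopifnot(is.array(x), length(dim(x)) == 4)
  x
}

relu <- function(x) {
  x[x < 0] <- 0
  x
}

#' Forward pass of the segmentation network
#'
#' @param model A `metal3d_network`.
#' @param x Input: a `voxel_grid` or array `[nx,ny,nz,cin]`.
#' @param train Keep intermediate activations (and apply dropout using
#'   `dropout_mask`)? Default `FALSE`.
#' @param dropout_mask Optional precomputed dropout mask for the layer-5
#'   output (same shape); supplied by the training loop so runs are seeded.
#' @return If `train = FALSE`, the `[nx,ny,nz,1]` probability array;
#'   otherwise a list with `output` and cached activations.
#' @export
network_forward <- function(model, x, train = FALSE, dropout_mask = NULL) {
  x <- .as_input_array(x)
  nxyz <- dim(x)[1:3]
  if (dim(x)[4] != model$layers[[1]]$cin) {
    stop(sprintf("input has %d channels, network expects %d",
                 dim(x)[4], model$layers[[1]]$cin), call. = FALSE)
  }
  acts <- list()   # pre-activation inputs per layer (for backward)
  h <- x
  for (l in 1:6) {
    ly <- model$layers[[l]]
    if (train) acts[[l]] <- h
    z <- conv3d_fwd(h, as.integer(nxyz), ly$cin, ly$w, ly$k, ly$cout, ly$b)
    if (l < 6) {
      h <- relu(z)
      if (l == 5 && train && !is.null(dropout_mask)) h <- h * dropout_mask
    } else {
      h <- 1 / (1 + exp(-z))
    }
  }
  if (!train) return(h)
  list(output = h, acts = acts)
}

# binary cross-entropy, mean over voxels
bce_loss <- function(p, y) {
  eps <- 1e-7
  p <- pmin(pmax(p, eps), 1 - eps)
  -mean(y * log(p) + (1 - y) * log(1 - p))
}

# full backward pass; returns list of per-layer gradients (gw, gb)
.network_backward <- function(model, fwd, y, dropout_mask = NULL) {
  p <- fwd$output
  nxyz <- dim(p)[1:3]
  nvox <- prod(dim(p))
  eps <- 1e-7
  pc <- pmin(pmax(p, eps), 1 - eps)
  # d(BCE)/dz for sigmoid output; clamp-consistent
  gz <- (pc - y) / nvox
  grads <- vector("list", 6)
  for (l in 6:1) {
    ly <- model$layers[[l]]
    inp <- fwd$acts[[l]]
    if (l == 5 && !is.null(dropout_mask)) {
      # gz here is already the gradient w.r.t. the (post-dropout) layer
      # output; fold the mask in before the ReLU derivative
      gz <- gz * dropout_mask
    }
    gwb <- conv3d_bwd_weights(inp, as.integer(nxyz), ly$cin, gz, ly$cout, ly$k)
    grads[[l]] <- gwb
    if (l > 1) {
      gin <- conv3d_bwd_input(gz, as.integer(nxyz), ly$cout, ly$w, ly$k, ly$cin)
      # ReLU derivative w.r.t. the previous layer's pre-activation: the
      # cached input of layer l is relu(z_{l-1}) (possibly masked), so the
      # derivative is 1 where that input is positive
      gz <- gin * (fwd$acts[[l]] > 0)
    }
  }
  grads
}

#' Configuration for smoke-scale training
#'
#' Defaults follow the published optimisation recipe: AdaDelta with a
#' stepped learning rate (lr 0.5, decay gamma 0.9 per epoch), binary
#' cross-entropy loss, batch size 150.
#'
#' @param lr Learning-rate scale (default 0.5).
#' @param gamma Per-epoch step decay (default 0.9).
#' @param batch_size Examples per optimisation step (default 150).
#' @param epochs Training epochs (default 12).
#' @param rho AdaDelta accumulator decay (default 0.9).
#' @param eps AdaDelta epsilon (default 1e-6).
#' @param seed Integer seed (shuffling, dropout).
#' @return A list of class `train_config`.
#' @export
train_config <- function(lr = 0.5, gamma = 0.9, batch_size = 150, epochs = 12,
                         rho = 0.9, eps = 1e-6, seed = 1) {
  stopifnot(lr > 0, gamma > 0, gamma <= 1, batch_size >= 1, epochs >= 1)
  structure(list(lr = lr, gamma = gamma, batch_size = batch_size,
                 epochs = epochs, rho = rho, eps = eps, seed = seed),
            class = "train_config")
}

#' Train the network on a small example set
#'
#' Desk-scale training loop (a few hundred examples at most): AdaDelta
#' updates of the binary cross-entropy between predicted and target voxel
#' grids, with per-epoch stepped learning rate and seeded shuffling and
#' dropout. Intended for smoke tests and small synthetic corpora, not for
#' reproducing a production model.
#'
#' @param model A `metal3d_network` from [build_network()].
#' @param examples List of lists with `input` (`voxel_grid` or
#'   `[nx,ny,nz,cin]` array) and `target` (`voxel_grid` or
#'   `[nx,ny,nz,1]` array).
#' @param config A [train_config()].
#' @return A list with `model` (trained) and `loss_trace` (mean BCE per
#'   epoch, evaluated on the training pass).
#' @export
train_smoke <- function(model, examples, config = train_config()) {
  stopifnot(inherits(model, "metal3d_network"), length(examples) >= 1)
  exs <- lapply(examples, function(e) {
    x <- .as_input_array(e$input)
    y <- if (inherits(e$target, "voxel_grid")) e$target$values else e$target
    stopifnot(is.array(y))
    if (length(dim(y)) == 3) dim(y) <- c(dim(y), 1L)
    if (!identical(dim(x)[1:3], dim(y)[1:3])) {
      stop("input and target grids have mismatched spatial shapes", call. = FALSE)
    }
    if (dim(x)[4] != model$layers[[1]]$cin) {
      stop("example channel count does not match the network input", call. = FALSE)
    }
    list(x = x, y = y)
  })

  # AdaDelta state
  state <- lapply(model$layers, function(ly) list(
    Eg_w = array(0, dim = dim(ly$w)), Ed_w = array(0, dim = dim(ly$w)),
    Eg_b = numeric(length(ly$b)), Ed_b = numeric(length(ly$b))
  ))
  dropout <- model$spec$dropout

  .with_seed(config$seed, {
    loss_trace <- numeric(config$epochs)
    for (epoch in seq_len(config$epochs)) {
      lr <- config$lr * config$gamma^(epoch - 1)
      ord <- sample(length(exs))
      batches <- split(ord, ceiling(seq_along(ord) / config$batch_size))
      epoch_loss <- 0
      for (batch in batches) {
        acc <- NULL
        batch_loss <- 0
        for (i in batch) {
          ex <- exs[[i]]
          mask <- NULL
          if (dropout > 0) {
            ly5 <- model$layers[[5]]
            mdim <- c(dim(ex$x)[1:3], ly5$cout)
            mask <- array(stats::rbinom(prod(mdim), 1, 1 - dropout) / (1 - dropout),
                          dim = mdim)
          }
          fwd <- network_forward(model, ex$x, train = TRUE, dropout_mask = mask)
          batch_loss <- batch_loss + bce_loss(fwd$output, ex$y)
          g <- .network_backward(model, fwd, ex$y, dropout_mask = mask)
          if (is.null(acc)) {
            acc <- g
          } else {
            for (l in 1:6) {
              acc[[l]]$gw <- acc[[l]]$gw + g[[l]]$gw
              acc[[l]]$gb <- acc[[l]]$gb + g[[l]]$gb
            }
          }
        }
        nb <- length(batch)
        for (l in 1:6) {
          gw <- acc[[l]]$gw / nb
          gb <- acc[[l]]$gb / nb
          st <- state[[l]]
          st$Eg_w <- config$rho * st$Eg_w + (1 - config$rho) * gw^2
          dw <- -sqrt(st$Ed_w + config$eps) / sqrt(st$Eg_w + config$eps) * gw
          st$Ed_w <- config$rho * st$Ed_w + (1 - config$rho) * dw^2
          model$layers[[l]]$w <- model$layers[[l]]$w + lr * dw
          st$Eg_b <- config$rho * st$Eg_b + (1 - config$rho) * gb^2
          db <- -sqrt(st$Ed_b + config$eps) / sqrt(st$Eg_b + config$eps) * gb
          st$Ed_b <- config$rho * st$Ed_b + (1 - config$rho) * db^2
          model$layers[[l]]$b <- model$layers[[l]]$b + lr * db
          state[[l]] <- st
        }
        epoch_loss <- epoch_loss + batch_loss
      }
      loss_trace[epoch] <- epoch_loss / length(exs)
    }
    list(model = model, loss_trace = loss_trace)
  })
}
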