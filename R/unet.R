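#' Build a compact U-Net for 2D segmentation
#'
#' Constructs an encoder/decoder network with skip connections, batch
#' normalization after every 3x3 convolution, and a final 1x1 convolution
#' (the segmentation head) producing one logit map per class at input
#' resolution. Downsampling uses 2x2 max pooling; upsampling uses
#' nearest-neighbour interpolation followed by a 3x3 convolution.
#'
#' Every tensor of the model — trainable weights and the non-trainable
#' batch-norm running statistics alike — is stored under a hierarchical name
#' and tagged with a role from
#' \code{conv_weight, conv_bias, bn_gamma, bn_beta, bn_running_mean,
#' bn_running_var, head_weight, head_bias}. The roles drive the
#' personalized/shared partition used in federated training (see
#' \code{\link{classify_parameters}}).
#'
#' Initialization is fan-in-scaled Gaussian (He) for convolutions, driven by
#' an explicit seed: two calls with the same arguments yield bitwise
#' identical parameters.
#'
#' @param in_channels number of input image channels (>= 1).
#' @param n_classes number of output classes including background (>= 2).
#' @param depth number of encoder resolution levels (>= 1); level widths
#'   double at each downsampling.
#' @param base_width channel width of the first level (>= 4).
#' @param seed integer seed for weight initialization.
#' @return an object of class \code{freqfed_unet}: a list with \code{arch},
#'   \code{params} (named list of arrays) and \code{roles} (named character
#'   vector parallel to \code{params}).
#' @examples
#' m <- build_unet(1, 3, depth = 2, base_width = 8, seed = 7)
#' table(m$roles)
#' @export
build_unet <- function(in_channels = 1L, n_classes = 4L, depth = 2L,
                       base_width = 8L, seed = 1L) {
  if (in_channels < 1L || n_classes < 2L || depth < 1L || base_width < 4L) {
    stop("invalid U-Net configuration: need in_channels >= 1, n_classes >= 2, ",
         "depth >= 1, base_width >= 4")
  }
  widths <- base_width * 2L^(seq_len(depth) - 1L)
  params <- list()
  roles <- character(0)
  add <- function(name, value, role) {
    params[[name]] <<- value
    roles[[name]] <<- role
  }
  conv_init <- function(cout, cin, k) {
    array(stats::rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
          c(cout, cin, k, k))
  }
  add_conv <- function(prefix, cin, cout, k = 3L) {
    add(paste0(prefix, ".weight"), conv_init(cout, cin, k), "conv_weight")
    add(paste0(prefix, ".bias"), numeric(cout), "conv_bias")
  }
  add_bn <- function(prefix, c) {
    add(paste0(prefix, ".gamma"), rep(1, c), "bn_gamma")
    add(paste0(prefix, ".beta"), numeric(c), "bn_beta")
    add(paste0(prefix, ".running_mean"), numeric(c), "bn_running_mean")
    add(paste0(prefix, ".running_var"), rep(1, c), "bn_running_var")
  }
  with_seed(seed, {
    cin <- in_channels
    for (i in seq_len(depth)) {
      w <- widths[i]
      add_conv(sprintf("enc%d.conv1", i), cin, w)
      add_bn(sprintf("enc%d.bn1", i), w)
      add_conv(sprintf("enc%d.conv2", i), w, w)
      add_bn(sprintf("enc%d.bn2", i), w)
      cin <- w
    }
    for (i in rev(seq_len(depth - 1L))) {
      w <- widths[i]
      add_conv(sprintf("up%d.conv", i), widths[i + 1L], w)
      add_bn(sprintf("up%d.bn", i), w)
      add_conv(sprintf("dec%d.conv1", i), 2L * w, w)
      add_bn(sprintf("dec%d.bn1", i), w)
      add_conv(sprintf("dec%d.conv2", i), w, w)
      add_bn(sprintf("dec%d.bn2", i), w)
    }
    add("head.weight",
        array(stats::rnorm(n_classes * widths[1L], sd = sqrt(1 / widths[1L])),
              c(n_classes, widths[1L], 1L, 1L)),
        "head_weight")
    add("head.bias", numeric(n_classes), "head_bias")
  })
  structure(list(
    arch = list(in_channels = as.integer(in_channels),
                n_classes = as.integer(n_classes),
                depth = as.integer(depth),
                base_width = as.integer(base_width),
                widths = as.integer(widths)),
    params = params,
    roles = roles
  ), class = "freqfed_unet")
}

#' @export
print.freqfed_unet <- function(x, ...) {
  a <- x$arch
  n_par <- sum(vapply(x$params, length, integer(1)))
  cat(sprintf(
    "<freqfed_unet> depth %d, base width %d, %d -> %d channels, %d tensors (%d values)\n",
    a$depth, a$base_width, a$in_channels, a$n_classes,
    length(x$params), n_par))
  invisible(x)
}

#' Forward pass of the U-Net
#'
#' Runs the network on a batch of images and returns per-pixel class
#' logits at input resolution.
#'
#' @param model a \code{freqfed_unet}.
#' @param x input array (H, W, C, N).
#' @param training if \code{TRUE}, batch norm uses batch statistics and
#'   the returned \code{running} list carries the updated running buffers
#'   (the caller decides whether to commit them to the model); otherwise
#'   the stored running statistics are used.
#' @param want_cache keep the layer caches needed for backpropagation.
#' @param raw return logits in the internal channels-last (H, W, N, C)
#'   layout instead of (H, W, C, N).
#' @return list with \code{logits}, \code{caches} and \code{running}.
#' @export
unet_forward <- function(model, x, training = FALSE, want_cache = FALSE,
                         raw = FALSE) {
  a <- model$arch
  p <- model$params
  stride <- 2L^(a$depth - 1L)
  d <- dim(x)
  if (length(d) != 4L || d[3L] != a$in_channels) {
    stop("input must be (H, W, ", a$in_channels, ", N)")
  }
  if (d[1L] %% stride != 0L || d[2L] %% stride != 0L) {
    stop("input height/width must be divisible by ", stride)
  }
  caches <- list()
  running <- list()
  cbr <- function(h, conv, bn, tag) {
    cf <- conv2d_forward(h, p[[paste0(conv, ".weight")]],
                         p[[paste0(conv, ".bias")]])
    bf <- bn_forward(cf$out,
                     p[[paste0(bn, ".gamma")]], p[[paste0(bn, ".beta")]],
                     p[[paste0(bn, ".running_mean")]],
                     p[[paste0(bn, ".running_var")]],
                     training = training)
    rf <- relu_forward(bf$out)
    if (training) {
      running[[paste0(bn, ".running_mean")]] <<- bf$running_mean
      running[[paste0(bn, ".running_var")]] <<- bf$running_var
    }
    if (want_cache) {
      caches[[tag]] <<- list(conv = cf$cache, bn = bf$cache, relu = rf$cache)
    }
    rf$out
  }
  h <- aperm(x, c(1L, 2L, 4L, 3L))
  skips <- list()
  for (i in seq_len(a$depth)) {
    h <- cbr(h, sprintf("enc%d.conv1", i), sprintf("enc%d.bn1", i),
             sprintf("enc%d.a", i))
    h <- cbr(h, sprintf("enc%d.conv2", i), sprintf("enc%d.bn2", i),
             sprintf("enc%d.b", i))
    if (i < a$depth) {
      skips[[i]] <- h
      mp <- maxpool_forward(h)
      if (want_cache) caches[[sprintf("pool%d", i)]] <- mp$cache
      h <- mp$out
    }
  }
  for (i in rev(seq_len(a$depth - 1L))) {
    up <- upsample_forward(h)
    if (want_cache) caches[[sprintf("upsample%d", i)]] <- up$cache
    h <- cbr(up$out, sprintf("up%d.conv", i), sprintf("up%d.bn", i),
             sprintf("up%d.a", i))
    if (want_cache) caches[[sprintf("skipdim%d", i)]] <- dim(h)[4L]
    h <- concat_channels(h, skips[[i]])
    h <- cbr(h, sprintf("dec%d.conv1", i), sprintf("dec%d.bn1", i),
             sprintf("dec%d.a", i))
    h <- cbr(h, sprintf("dec%d.conv2", i), sprintf("dec%d.bn2", i),
             sprintf("dec%d.b", i))
  }
  hf <- conv2d_forward(h, p[["head.weight"]], p[["head.bias"]])
  if (want_cache) caches[["head"]] <- hf$cache
  logits <- if (raw) hf$out else aperm(hf$out, c(1L, 2L, 4L, 3L))
  list(logits = logits, caches = caches, running = running)
}

# Backward pass matching unet_forward(want_cache = TRUE); dlogits in the
# internal (H, W, N, C) layout.
# Returns gradients for every trainable tensor, named like the parameters.
unet_backward <- function(model, caches, dlogits) {
  a <- model$arch
  p <- model$params
  grads <- list()
  cbr_bwd <- function(dh, conv, bn, tag) {
    cc <- caches[[tag]]
    dh <- relu_backward(dh, cc$relu)
    bb <- bn_backward(dh, cc$bn, p[[paste0(bn, ".gamma")]])
    grads[[paste0(bn, ".gamma")]] <<- bb$dgamma
    grads[[paste0(bn, ".beta")]] <<- bb$dbeta
    cb <- conv2d_backward(bb$dx, cc$conv)
    grads[[paste0(conv, ".weight")]] <<- cb$dw
    grads[[paste0(conv, ".bias")]] <<- cb$db
    cb$dx
  }
  hb <- conv2d_backward(dlogits, caches[["head"]])
  grads[["head.weight"]] <- hb$dw
  grads[["head.bias"]] <- hb$db
  dh <- hb$dx
  dskips <- list()
  for (i in seq_len(a$depth - 1L)) {
    dh <- cbr_bwd(dh, sprintf("dec%d.conv2", i), sprintf("dec%d.bn2", i),
                  sprintf("dec%d.b", i))
    dh <- cbr_bwd(dh, sprintf("dec%d.conv1", i), sprintf("dec%d.bn1", i),
                  sprintf("dec%d.a", i))
    nu <- caches[[sprintf("skipdim%d", i)]]
    dup <- dh[, , , seq_len(nu), drop = FALSE]
    dskips[[i]] <- dh[, , , nu + seq_len(dim(dh)[4L] - nu), drop = FALSE]
    dup <- cbr_bwd(dup, sprintf("up%d.conv", i), sprintf("up%d.bn", i),
                   sprintf("up%d.a", i))
    dh <- upsample_backward(dup, caches[[sprintf("upsample%d", i)]])
  }
  for (i in rev(seq_len(a$depth))) {
    if (i < a$depth) {
      dh <- maxpool_backward(dh, caches[[sprintf("pool%d", i)]])
      dh <- dh + dskips[[i]]
    }
    dh <- cbr_bwd(dh, sprintf("enc%d.conv2", i), sprintf("enc%d.bn2", i),
                  sprintf("enc%d.b", i))
    dh <- cbr_bwd(dh, sprintf("enc%d.conv1", i), sprintf("enc%d.bn1", i),
                  sprintf("enc%d.a", i))
  }
  grads
}

#' Predict label maps with a trained network
#'
#' Runs the network in evaluation mode (batch-norm running statistics) and
#' returns the per-pixel argmax class, 0-based so that 0 is background.
#'
#' @param model a \code{freqfed_unet}.
#' @param images array (H, W, C, N) or a single (H, W) matrix for C = 1.
#' @return integer array (H, W, N) of predicted labels in 0..n_classes-1.
#' @export
unet_predict <- function(model, images) {
  if (is.matrix(images)) {
    images <- array(images, c(dim(images), 1L, 1L))
  }
  logits <- unet_forward(model, images, training = FALSE, raw = TRUE)$logits
  d <- dim(logits)                       # (H, W, N, C)
  dim(logits) <- c(d[1L] * d[2L] * d[3L], d[4L])
  lab <- max.col(logits, ties.method = "first") - 1L
  array(as.integer(lab), c(d[1L], d[2L], d[3L]))
}

#' Extract or replace the full parameter set of a model
#'
#' @param model a \code{freqfed_unet}.
#' @return named list of parameter arrays.
#' @export
get_params <- function(model) model$params

#' @param params named list covering exactly the model's tensor names.
#' @rdname get_params
#' @export
set_params <- function(model, params) {
  if (!setequal(names(params), names(model$params))) {
    missing <- setdiff(names(model$params), names(params))
    extra <- setdiff(names(params), names(model$params))
    stop("parameter set does not match architecture; missing: [",
         paste(missing, collapse = ", "), "], unexpected: [",
         paste(extra, collapse = ", "), "]")
  }
  model$params[names(params)] <- params
  model
}

#' Save / load a model checkpoint as a named-tensor archive
#'
#' The checkpoint is a directory holding a JSON manifest (tensor name, role,
#' shape, dtype) and one CSV of flattened values, so it is portable and
#' diff-able.
#'
#' @param model a \code{freqfed_unet}.
#' @param path checkpoint directory (created if needed).
#' @return \code{save_checkpoint}: the path, invisibly.
#'   \code{load_checkpoint}: the restored model.
#' @export
save_checkpoint <- function(model, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    arch = model$arch,
    tensors = lapply(names(model$params), function(nm) {
      v <- model$params[[nm]]
      list(name = nm, role = unname(model$roles[[nm]]),
           shape = as.integer(dim(v) %||% length(v)), dtype = "double")
    })
  )
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  vals <- data.frame(
    name = rep(names(model$params),
               vapply(model$params, length, integer(1))),
    value = unlist(lapply(model$params, as.vector), use.names = FALSE)
  )
  utils::write.csv(vals, file.path(path, "values.csv"), row.names = FALSE)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  manifest <- jsonlite::read_json(file.path(path, "manifest.json"),
                                  simplifyVector = TRUE)
  a <- manifest$arch
  model <- build_unet(a$in_channels, a$n_classes, a$depth, a$base_width,
                      seed = 1L)
  vals <- utils::read.csv(file.path(path, "values.csv"))
  sp <- split(vals$value, factor(vals$name, levels = unique(vals$name)))
  for (nm in names(model$params)) {
    v <- sp[[nm]]
    if (is.null(v) || length(v) != length(model$params[[nm]])) {
      stop("checkpoint does not match architecture at tensor ", nm)
    }
    dim(v) <- dim(model$params[[nm]])
    model$params[[nm]] <- v
  }
  model
}
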