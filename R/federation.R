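# Federated orchestration.
#
# One server round: every client trains E local epochs on its own data,
# sends its shared tensors to the server, the server aggregates them under
# the configured strategy and sends each client its aggregate back.
# Personalized tensors never leave the client; raw images never cross the
# client boundary at all — the only objects exchanged are named shared
# tensors.

#' Federated experiment configuration
#'
#' @param K number of clients.
#' @param T number of server communication rounds (>= 0).
#' @param E local epochs per round (>= 0).
#' @param B minibatch size.
#' @param lr Adam learning rate. The full-scale default is 1e-4 with batch
#'   size 16; desk-scale experiments typically use 1e-3 with batch 4.
#' @param strategy one of \code{paf_fed} (personalized partition +
#'   frequency aggregation with reciprocal attention), \code{pf_fed} (same
#'   with uniform weights), \code{fedavg_fft} (everything shared, frequency
#'   aggregation, uniform), \code{fedavg}, \code{fedbn}, \code{silobn},
#'   \code{fedrep} (element-wise mean under the respective partitions) or
#'   \code{local} (no communication).
#' @param r_mode \code{"adaptive"} (r grows linearly from \code{r0} to
#'   \code{r1} over the rounds) or \code{"fixed"}.
#' @param r_fixed,r0,r1 threshold schedule parameters.
#' @param attention override the strategy's attention mode
#'   (\code{"reciprocal"} or \code{"uniform"}); \code{NULL} uses the
#'   strategy default.
#' @param partition override the strategy's partition preset; \code{NULL}
#'   uses the strategy default.
#' @param base_seed seed from which per-client seeds are derived.
#' @param augment apply random rotation (+/- 15 degrees) and flips during
#'   local training.
#' @param eval_every validate every this many rounds (0 disables the
#'   per-round validation metrics in the history).
#' @param depth,base_width architecture of the shared U-Net.
#' @return a \code{round_config} list.
#' @export
round_config <- function(K = 4L, T = 10L, E = 2L, B = 16L, lr = 1e-4,
                         strategy = c("paf_fed", "pf_fed", "fedavg_fft",
                                      "fedavg", "fedbn", "silobn", "fedrep",
                                      "local"),
                         r_mode = c("adaptive", "fixed"), r_fixed = 0.25,
                         r0 = 0, r1 = 0.5, attention = NULL,
                         partition = NULL, base_seed = 1L, augment = TRUE,
                         eval_every = 1L, depth = 2L, base_width = 8L) {
  strategy <- match.arg(strategy)
  r_mode <- match.arg(r_mode)
  if (K < 1L || T < 0L || E < 0L || B < 1L || lr < 0) {
    stop("invalid round configuration")
  }
  defaults <- list(
    paf_fed    = list(partition = "paf_fed", mode = "fft",
                      attention = "reciprocal"),
    pf_fed     = list(partition = "paf_fed", mode = "fft",
                      attention = "uniform"),
    fedavg_fft = list(partition = "fedavg", mode = "fft",
                      attention = "uniform"),
    fedavg     = list(partition = "fedavg", mode = "mean", attention = NULL),
    fedbn      = list(partition = "fedbn", mode = "mean", attention = NULL),
    silobn     = list(partition = "silobn", mode = "mean", attention = NULL),
    fedrep     = list(partition = "fedrep", mode = "mean", attention = NULL),
    local      = list(partition = "local", mode = "none", attention = NULL)
  )[[strategy]]
  structure(list(
    K = as.integer(K), T = as.integer(T), E = as.integer(E),
    B = as.integer(B), lr = lr, strategy = strategy,
    partition = partition %||% defaults$partition,
    agg_mode = defaults$mode,
    attention = attention %||% defaults$attention,
    r_mode = r_mode, r_fixed = r_fixed, r0 = r0, r1 = r1,
    base_seed = as.integer(base_seed), augment = isTRUE(augment),
    eval_every = as.integer(eval_every),
    depth = as.integer(depth), base_width = as.integer(base_width)
  ), class = "round_config")
}

# ---- Adam ------------------------------------------------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# ---- Augmentation ----------------------------------------------------------

# Nearest-neighbour rotation about the image center; out-of-range pixels get
# `fill`. Applied identically to an image and its label map.
rotate_nn <- function(m, angle_deg, fill = 0) {
  if (angle_deg == 0) return(m)
  H <- nrow(m); W <- ncol(m)
  th <- angle_deg * pi / 180
  ci <- (H + 1) / 2; cj <- (W + 1) / 2
  i <- matrix(seq_len(H), H, W) - ci
  j <- matrix(seq_len(W), H, W, byrow = TRUE) - cj
  si <- round(cos(th) * i - sin(th) * j + ci)
  sj <- round(sin(th) * i + cos(th) * j + cj)
  ok <- si >= 1 & si <= H & sj >= 1 & sj <= W
  out <- matrix(fill, H, W)
  out[ok] <- m[cbind(si[ok], sj[ok])]
  out
}

augment_pair <- function(img, lab) {
  if (stats::runif(1) < 0.5) {
    img <- img[rev(seq_len(nrow(img))), , drop = FALSE]
    lab <- lab[rev(seq_len(nrow(lab))), , drop = FALSE]
  }
  if (stats::runif(1) < 0.5) {
    img <- img[, rev(seq_len(ncol(img))), drop = FALSE]
    lab <- lab[, rev(seq_len(ncol(lab))), drop = FALSE]
  }
  ang <- stats::runif(1, -15, 15)
  img <- rotate_nn(img, ang, fill = 0)
  lab <- rotate_nn(lab, ang, fill = 0L)
  list(img = img, lab = lab)
}

# ---- Client state ----------------------------------------------------------

init_client <- function(id, model, dataset, base_seed) {
  seed <- base_seed + id
  rng <- with_seed(seed, get_rng_state())
  structure(list(id = id, model = model, dataset = dataset,
                 opt = adam_init(model$params), seed = seed,
                 rng = rng),
            class = "client_state")
}

# One training step on a minibatch; returns updated model/opt and the loss.
train_step <- function(model, opt, x, y, lr) {
  fwd <- unet_forward(model, x, training = TRUE, want_cache = TRUE,
                      raw = TRUE)
  d <- dim(fwd$logits)                   # (H, W, N, C)
  C <- d[4L]
  lm <- fwd$logits
  dim(lm) <- c(d[1L] * d[2L] * d[3L], C)
  Om <- row_softmax(lm)
  Gm <- one_hot(y, C)
  loss <- fused_loss(Om, Gm)
  dlogits <- fused_loss_grad_logits(Om, Gm)
  dim(dlogits) <- d
  grads <- unet_backward(model, fwd$caches, dlogits)
  # commit BN running statistics, then apply the optimizer to the trainables
  model$params[names(fwd$running)] <- fwd$running
  st <- adam_step(model$params, grads, opt, lr)
  model$params <- st$params
  list(model = model, opt = st$state, loss = loss)
}

#' Run one client's local update
#'
#' Merges the incoming shared tensors (if any) with the client's own
#' personalized tensors, trains \code{E} local epochs of minibatch Adam on
#' the fused Dice + cross-entropy loss, and returns the updated client
#' state together with the trained shared part. With \code{E = 0} the
#' incoming shared part is returned unchanged. The client's RNG stream
#' (shuffling, augmentation) is part of its state, so results do not depend
#' on when other clients run.
#'
#' @param state a \code{client_state}.
#' @param shared incoming named-tensor map of shared parameters, or
#'   \code{NULL} on the first round.
#' @param E number of local epochs.
#' @param config a \code{round_config} (batch size, lr, augmentation,
#'   partition).
#' @param spec the \code{partition_spec} in force.
#' @return list with the updated \code{state}, the shared part \code{W_R}
#'   and the mean training \code{loss} (NA when E = 0).
#' @export
client_update <- function(state, shared, E, config, spec) {
  if (!is.null(shared) && length(shared)) {
    sw <- split_weights(state$model, spec)
    state$model <- set_params(state$model, merge_weights(sw$W_H, shared))
  }
  tr <- dataset_split(state$dataset, "train")
  n_tr <- dim(tr$x)[4L]
  if (n_tr == 0L) stop("client ", state$id, " has an empty training set")
  losses <- numeric(0)
  if (E > 0L) {
    old_rng <- get_rng_state()
    on.exit(set_rng_state(old_rng), add = TRUE)
    set_rng_state(state$rng)
    B <- config$B
    for (ep in seq_len(E)) {
      ord <- sample.int(n_tr)
      for (b0 in seq(1L, n_tr, by = B)) {
        idx <- ord[b0:min(b0 + B - 1L, n_tr)]
        xb <- tr$x[, , , idx, drop = FALSE]
        yb <- tr$y[, , idx, drop = FALSE]
        if (config$augment) {
          for (q in seq_along(idx)) {
            a <- augment_pair(xb[, , 1L, q], yb[, , q])
            xb[, , 1L, q] <- a$img
            yb[, , q] <- a$lab
          }
        }
        st <- train_step(state$model, state$opt, xb, yb, config$lr)
        state$model <- st$model
        state$opt <- st$opt
        losses <- c(losses, st$loss)
      }
    }
    state$rng <- get_rng_state()
  }
  W_R <- split_weights(state$model, spec)$W_R
  list(state = state, W_R = W_R,
       loss = if (length(losses)) mean(losses) else NA_real_)
}

#' Run a federated training experiment
#'
#' Orchestrates the full loop: build one initial model, broadcast it to all
#' clients, then for each of the \code{T} rounds run every client's local
#' update (in deterministic id order), aggregate the shared tensors under
#' the configured strategy and send each client its aggregate. Personalized
#' tensors never leave their client.
#'
#' @param config a \code{\link{round_config}}.
#' @param datasets list of \code{config$K} \code{phantom_dataset}s (one per
#'   client; disjoint by construction).
#' @return list with \code{states} (each client's personalized model after
#'   its final local update — the algorithm's output), \code{history} (a
#'   data.frame with one row per round and client: round, client, loss, r,
#'   val_dsc, val_assd) and \code{final_shared} (the last server
#'   aggregate, which a continuing federation would merge at the start of
#'   the next round).
#' @export
run_federation <- function(config, datasets) {
  K <- config$K
  if (length(datasets) != K) {
    stop("expected ", K, " client datasets, got ", length(datasets))
  }
  C <- datasets[[1L]]$n_classes
  model0 <- build_unet(1L, C, config$depth, config$base_width,
                       seed = config$base_seed)
  spec <- classify_parameters(model0, config$partition)
  states <- lapply(seq_len(K), function(k) {
    init_client(k, model0, datasets[[k]], config$base_seed)
  })
  incoming <- vector("list", K)   # NULL on the first round: clients use W0
  hist <- list()
  for (t in seq_len(config$T) - 1L) {
    r <- r_schedule(t, config$T, mode = config$r_mode,
                    r_fixed = config$r_fixed, r0 = config$r0, r1 = config$r1)
    W_Rs <- vector("list", K)
    losses <- numeric(K)
    for (k in seq_len(K)) {
      up <- client_update(states[[k]], incoming[[k]], config$E, config, spec)
      states[[k]] <- up$state
      W_Rs[[k]] <- up$W_R
      losses[k] <- up$loss
    }
    incoming <- if (config$agg_mode == "none" ||
                    length(W_Rs[[1L]]) == 0L) {
      W_Rs                                    # no communication
    } else if (config$agg_mode == "mean") {
      avg <- lapply(names(W_Rs[[1L]]), function(nm) {
        Reduce(`+`, lapply(W_Rs, `[[`, nm)) / K
      })
      names(avg) <- names(W_Rs[[1L]])
      replicate(K, avg, simplify = FALSE)
    } else {
      aggregate_round(W_Rs, r = r, attention_mode = config$attention)
    }
    val <- rep(NA_real_, 2L)
    if (config$eval_every > 0L && (t + 1L) %% config$eval_every == 0L) {
      # validate each client's personalized model as trained this round;
      # the server aggregate only enters at the start of the next round
      rep_val <- evaluate_federation(states, split = "val")
      val <- c(rep_val$overall$dsc, rep_val$overall$assd)
    }
    hist[[t + 1L]] <- data.frame(round = t, client = seq_len(K),
                                 loss = losses, r = r,
                                 val_dsc = val[1L], val_assd = val[2L])
  }
  # The returned states are each client's personalized model after its
  # final local update — the algorithm's output. The last server aggregate
  # is exposed separately; merging it without local adaptation would pair
  # fresh shared weights with running statistics accumulated under the old
  # ones.
  history <- if (length(hist)) do.call(rbind, hist) else
    data.frame(round = integer(0), client = integer(0), loss = numeric(0),
               r = numeric(0), val_dsc = numeric(0), val_assd = numeric(0))
  list(states = states, history = history, config = config,
       final_shared = if (config$agg_mode != "none") incoming else NULL)
}

#' Evaluate a federation on held-out data
#'
#' Scores every client's model on its own held-out split with per-class DSC
#' and ASSD (foreground classes only, matching per-organ reporting).
#' Metrics are computed per image and averaged over the images where they
#' are defined; class-absent-from-both images are excluded, not
#' zero-filled.
#'
#' @param states list of \code{client_state}s.
#' @param split which split of each client's dataset to use.
#' @return a \code{metrics_report}: list with \code{per_client_class}
#'   (data.frame client x class), \code{client_avg}, \code{class_avg} and
#'   \code{overall} (mean DSC and ASSD across clients).
#' @export
evaluate_federation <- function(states, split = "test") {
  rows <- list()
  for (s in states) {
    te <- dataset_split(s$dataset, split)
    n_im <- dim(te$x)[4L]
    if (n_im == 0L) stop("client ", s$id, " has an empty ", split, " set")
    C <- s$dataset$n_classes
    pred <- unet_predict(s$model, te$x)
    for (cls in seq_len(C - 1L)) {
      ds_v <- numeric(n_im)
      as_v <- numeric(n_im)
      for (i in seq_len(n_im)) {
        ds_v[i] <- dsc(pred[, , i], te$y[, , i], cls)
        as_v[i] <- assd(pred[, , i], te$y[, , i], cls,
                        spacing = s$dataset$spacing)
      }
      d_ok <- ds_v[!is.na(ds_v)]
      a_ok <- as_v[!is.na(as_v)]
      rows[[length(rows) + 1L]] <- data.frame(
        client = s$id, class = cls,
        dsc = if (length(d_ok)) mean(d_ok) else NA_real_,
        assd = if (length(a_ok)) mean(a_ok) else NA_real_,
        n_images = n_im,
        n_excluded_dsc = sum(is.na(ds_v)),
        n_excluded_assd = sum(is.na(as_v)))
    }
  }
  per <- do.call(rbind, rows)
  agg_mean <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  client_avg <- do.call(rbind, lapply(split(per, per$client), function(g) {
    data.frame(client = g$client[1L], dsc = agg_mean(g$dsc),
               assd = agg_mean(g$assd))
  }))
  class_avg <- do.call(rbind, lapply(split(per, per$class), function(g) {
    data.frame(class = g$class[1L], dsc = agg_mean(g$dsc),
               assd = agg_mean(g$assd))
  }))
  structure(list(
    per_client_class = per, client_avg = client_avg, class_avg = class_avg,
    overall = list(dsc = agg_mean(client_avg$dsc),
                   assd = agg_mean(client_avg$assd))
  ), class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("<metrics_report>\n")
  print(x$per_client_class, row.names = FALSE)
  cat(sprintf("overall: DSC %.4f, ASSD %.4f\n",
              x$overall$dsc, x$overall$assd))
  invisible(x)
}
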