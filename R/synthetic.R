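# Synthetic multi-client phantom data.
#
# Each client draws 2D "abdominal phantom" images: elliptical organs on a
# dark background, each class with its own intensity regime, plus a global
# brightness/contrast shift, Gaussian noise and an occasional bright corner
# artifact. Statistical heterogeneity across clients is controlled by a
# single knob that simultaneously skews which organs appear (label-ratio
# imbalance) and shifts the intensity regime (modality/domain shift).

#' Create per-client data profiles with controllable heterogeneity
#'
#' At \code{heterogeneity = 0} all clients share one profile. As the knob
#' grows, each client increasingly favours one organ class (its prevalence
#' rises while the others fall) and acquires a client-specific brightness
#' shift, emulating both label-distribution skew and acquisition-domain
#' differences between sites. Deterministic in \code{seed}.
#'
#' @param K number of clients (>= 1).
#' @param heterogeneity skew strength in [0, 1].
#' @param seed integer seed.
#' @param n_classes total classes including background (>= 2).
#' @return list of K \code{client_profile} objects with fields
#'   \code{prevalence} (length C-1), \code{size_range} (fractions of the
#'   image side), \code{intensity} (per-class mean/sd), \code{brightness},
#'   \code{contrast}, \code{noise_sd} and \code{artifact_prob}.
#' @export
make_profiles <- function(K, heterogeneity, seed = 1L, n_classes = 4L) {
  if (K < 1L) stop("K must be >= 1")
  if (!is.finite(heterogeneity) || heterogeneity < 0 || heterogeneity > 1) {
    stop("heterogeneity must lie in [0, 1]")
  }
  C <- n_classes
  n_org <- C - 1L
  # organ intensity bands overlap (adjacent means ~1 sd apart): class
  # identity is ambiguous per pixel and must be learned from shape and
  # context, which keeps the task sample-hungry the way soft-tissue MRI is
  means <- c(0.30, seq(0.50, 0.74, length.out = n_org))
  sds <- c(0.06, rep(0.10, n_org))
  h <- heterogeneity
  with_seed(seed, {
    lapply(seq_len(K), function(k) {
      # label-ratio skew dominates: the favoured organ stays common while
      # the others become nearly absent at high heterogeneity, mirroring a
      # pronounced per-site category imbalance
      prev <- rep(0.65, n_org)
      fav <- ((k - 1L) %% n_org) + 1L
      prev[fav] <- prev[fav] + 0.3 * h
      prev[-fav] <- prev[-fav] - 0.7 * h
      prev <- prev + h * stats::runif(n_org, -0.02, 0.02)
      prev <- pmin(pmax(prev, 0.05), 0.98)
      # mild acquisition shift: same modality, different sites/scanners
      brightness <- if (K > 1L) {
        0.05 * h * (2 * (k - 1) / (K - 1) - 1)
      } else 0
      structure(list(
        prevalence = prev,
        size_range = c(0.12, 0.28),
        intensity = list(mean = means, sd = sds),
        brightness = brightness + h * stats::runif(1, -0.01, 0.01),
        contrast = 1 + h * stats::runif(1, -0.05, 0.05),
        noise_sd = 0.04,
        artifact_prob = 0.15,
        n_classes = C
      ), class = "client_profile")
    })
  })
}

# Render one ellipse into a label matrix (z-order: caller paints organs in
# class order, later classes overwrite earlier ones at overlaps).
.ellipse_mask <- function(H, W, cx, cy, ax, ay, theta) {
  i <- matrix(seq_len(H), H, W)
  j <- matrix(seq_len(W), H, W, byrow = TRUE)
  ct <- cos(theta); st <- sin(theta)
  xr <- (i - cx) * ct + (j - cy) * st
  yr <- -(i - cx) * st + (j - cy) * ct
  (xr / ax)^2 + (yr / ay)^2 <= 1
}

#' Generate one client's phantom dataset
#'
#' Draws \code{n} images of elliptical organs according to the profile's
#' prevalences, renders class intensities with the profile's brightness,
#' contrast and noise, occasionally stamps a bright corner artifact
#' (background-labelled, emulating acquisition artifacts), and tags an
#' 8:1:1 train/validation/test split (floor(n/10) each for validation and
#' test, remainder to train). Deterministic in \code{seed}.
#'
#' If an organ cannot be placed without covering more than half of an
#' already-placed one within the retry budget, the last attempt is kept
#' with a warning.
#'
#' @param profile a \code{client_profile} from \code{\link{make_profiles}}.
#' @param n number of images (>= 10 so the split is non-empty).
#' @param size image size \code{c(H, W)}.
#' @param n_classes total classes including background; defaults to the
#'   profile's.
#' @param seed integer seed.
#' @param spacing pixel spacing (mm).
#' @return a \code{phantom_dataset}: list with \code{images} (H x W x n
#'   array in [0, 1]), \code{labels} (integer H x W x n), \code{split}
#'   (character n-vector), \code{spacing} and \code{profile}.
#' @export
generate_dataset <- function(profile, n, size = c(32L, 32L),
                             n_classes = NULL, seed = 1L,
                             spacing = c(1, 1)) {
  if (n < 10L) stop("need n >= 10 for a non-empty 8:1:1 split")
  C <- n_classes %||% profile$n_classes
  if (C < 2L) stop("need at least 2 classes")
  H <- size[1L]; W <- size[2L]
  side <- min(H, W)
  imgs <- array(0, c(H, W, n))
  labs <- array(0L, c(H, W, n))
  mu <- profile$intensity$mean
  sd_i <- profile$intensity$sd
  with_seed(seed, {
    for (im in seq_len(n)) {
      lab <- matrix(0L, H, W)
      for (cls in seq_len(C - 1L)) {
        if (stats::runif(1) > profile$prevalence[cls]) next
        placed <- FALSE
        for (try in seq_len(20L)) {
          ax <- stats::runif(1, profile$size_range[1L],
                             profile$size_range[2L]) * side
          ax <- min(ax, (side - 3) / 2)
          ay <- ax * stats::runif(1, 0.6, 1)
          cx <- stats::runif(1, 1 + ax, H - ax)
          cy <- stats::runif(1, 1 + ay, W - ay)
          m <- .ellipse_mask(H, W, cx, cy, ax, ay,
                             stats::runif(1, 0, pi))
          # accept only placements that neither sit mostly on top of
          # earlier organs nor hide more than half of any one of them
          # (with at most two later organs this guarantees every placed
          # class keeps visible pixels)
          ok <- sum(m & lab > 0L) <= 0.5 * sum(m)
          if (ok) {
            for (prev_cls in seq_len(cls - 1L)) {
              n_prev <- sum(lab == prev_cls)
              if (n_prev > 0L &&
                  sum(m & lab == prev_cls) > 0.5 * n_prev) {
                ok <- FALSE
                break
              }
            }
          }
          if (ok) {
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          warning("organ placement retry budget exhausted; keeping overlap")
        }
        lab[m] <- cls
      }
      img <- matrix(mu[lab + 1L] +
                      stats::rnorm(H * W, sd = sd_i[lab + 1L]), H, W)
      img <- (img - 0.5) * profile$contrast + 0.5 + profile$brightness
      img <- img + stats::rnorm(H * W, sd = profile$noise_sd)
      if (stats::runif(1) < profile$artifact_prob) {
        r <- max(2L, round(0.12 * side))
        blob <- .ellipse_mask(H, W, r, r, r, r, 0)
        img[blob] <- pmin(img[blob] + 0.6, 1)
      }
      imgs[, , im] <- pmin(pmax(img, 0), 1)
      labs[, , im] <- lab
    }
    n_val <- n %/% 10L
    n_test <- n %/% 10L
    ord <- sample.int(n)
    split <- character(n)
    split[ord[seq_len(n - n_val - n_test)]] <- "train"
    split[ord[n - n_val - n_test + seq_len(n_val)]] <- "val"
    split[ord[n - n_test + seq_len(n_test)]] <- "test"
    structure(list(images = imgs, labels = labs, split = split,
                   spacing = spacing, n_classes = as.integer(C),
                   profile = profile),
              class = "phantom_dataset")
  })
}

#' @export
print.phantom_dataset <- function(x, ...) {
  d <- dim(x$images)
  cat(sprintf(
    "<phantom_dataset> %d images %dx%d, %d classes (train %d / val %d / test %d)\n",
    d[3L], d[1L], d[2L], x$n_classes,
    sum(x$split == "train"), sum(x$split == "val"), sum(x$split == "test")))
  invisible(x)
}

# Subset helper: images/labels of one split as (H, W, 1, N) input and
# (H, W, N) labels.
dataset_split <- function(ds, which) {
  idx <- which(ds$split == which)
  d <- dim(ds$images)
  x <- ds$images[, , idx, drop = FALSE]
  dim(x) <- c(d[1L], d[2L], 1L, length(idx))
  list(x = x, y = ds$labels[, , idx, drop = FALSE], idx = idx)
}

#' Export a phantom dataset as PNG pairs with a JSON manifest
#'
#' Writes \code{img_NNN.png} / \code{lab_NNN.png} pairs plus a
#' \code{manifest.json} recording the split, spacing and class count.
#' Requires the \pkg{png} package.
#'
#' @param ds a \code{phantom_dataset}.
#' @param dir output directory.
#' @return the directory, invisibly.
#' @export
export_dataset_png <- function(ds, dir) {
  if (!requireNamespace("png", quietly = TRUE)) {
    stop("the 'png' package is required for PNG export")
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  n <- dim(ds$images)[3L]
  for (i in seq_len(n)) {
    png::writePNG(ds$images[, , i], file.path(dir, sprintf("img_%03d.png", i)))
    png::writePNG(ds$labels[, , i] / 255,
                  file.path(dir, sprintf("lab_%03d.png", i)))
  }
  jsonlite::write_json(
    list(n = n, n_classes = ds$n_classes, split = ds$split,
         spacing = ds$spacing),
    file.path(dir, "manifest.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
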