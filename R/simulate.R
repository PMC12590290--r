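#' Synthetic micrograph simulator configuration
#'
#' The simulator emulates the regime that makes particle picking hard: many
#' roughly circular particles of similar diameter, densely packed over a
#' slowly varying background, buried in strong additive Gaussian noise, plus
#' unannotated irregular "contamination" blobs that exert false-positive
#' pressure. It produces exact ground-truth boxes, standing in for curated
#' micrograph collections in all tests.
#'
#' @param image_size Square image side in pixels.
#' @param n_particles Length-2 integer range `[min, max]` of particles per
#'   micrograph.
#' @param radius_mean,radius_jitter Particle radius mean and half-range in
#'   pixels (radius drawn uniformly in mean +/- jitter).
#' @param min_center_separation Minimum pairwise center distance in pixels,
#'   enforced by rejection sampling.
#' @param noise_sigma Gaussian noise standard deviation, expressed relative
#'   to the particle contrast (1 = noise sd equals particle depth).
#' @param n_distractors Unannotated irregular blobs per micrograph; they
#'   never intersect an annotated particle's box.
#' @param contrast Particle intensity depth (intensity units).
#' @param dark_particles Particles darker than background (the cryo-EM
#'   convention); set FALSE for bright-on-dark.
#' @param seed Integer seed; together with the image index it fully
#'   determines each micrograph.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(image_size = 128L, n_particles = c(5L, 15L),
                       radius_mean = 8, radius_jitter = 2,
                       min_center_separation = 12, noise_sigma = 0.8,
                       n_distractors = 2L, contrast = 1,
                       dark_particles = TRUE, seed = 1L) {
  stopifnot(min_center_separation >= 0, radius_mean > radius_jitter,
            radius_jitter >= 0, noise_sigma >= 0, contrast > 0,
            length(n_particles) == 2, n_particles[1] <= n_particles[2])
  structure(list(image_size = as.integer(image_size),
                 n_particles = as.integer(n_particles),
                 radius_mean = radius_mean, radius_jitter = radius_jitter,
                 min_center_separation = min_center_separation,
                 noise_sigma = noise_sigma,
                 n_distractors = as.integer(n_distractors),
                 contrast = contrast,
                 dark_particles = isTRUE(dark_particles),
                 seed = as.integer(seed)),
            class = "sim_config")
}

## run expr under a derived RNG state, restoring the caller's state after;
## makes the generator a pure function of (cfg$seed, index)
with_derived_seed <- function(seed, index, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed((as.numeric(seed) * 100003 + as.numeric(index) * 7919) %% 2147483629)
  force(expr)
}

## soft-edged radial profile: ~1 inside radius r, ~0 outside, 1.5 px edge
disk_profile <- function(d, r) 1 / (1 + exp((d - r) / 1.5))

#' Generate one synthetic micrograph with ground truth
#'
#' Fully determined by `(cfg$seed, index)`: the same pair always yields a
#' bitwise-identical image and annotations. Particle placement uses
#' rejection sampling honoring the minimum center separation; if placement
#' repeatedly fails (crowded configurations) fewer particles are returned
#' with a message. Each particle's ground-truth box is the tight square of
#' side `2 * radius` around its center.
#'
#' @param cfg A [sim_config()].
#' @param index Image index (1-based).
#' @return A list with `record` (a [micrograph()], raw intensities),
#'   `annos` (an [annotation_set()] for this image), and — for
#'   quality-control — `particle_boxes` / `distractor_boxes`, pixel-space
#'   corner boxes of the placed particles and distractor blobs.
#' @export
generate_micrograph <- function(cfg, index = 1L) {
  stopifnot(inherits(cfg, "sim_config"))
  with_derived_seed(cfg$seed, index, {
    S <- cfg$image_size
    id <- sprintf("sim_%05d.mrc", index)
    xs <- matrix(rep(seq_len(S) - 0.5, each = S), S, S)   # col coord (x)
    ys <- matrix(rep(seq_len(S) - 0.5, times = S), S, S)  # row coord (y)
    # slowly varying background: two low-frequency cosine sheets
    img <- matrix(0, S, S)
    for (k in 1:2) {
      fx <- stats::runif(1, 0.3, 1.2) / S
      fy <- stats::runif(1, 0.3, 1.2) / S
      ph <- stats::runif(1, 0, 2 * pi)
      img <- img + 0.15 * cfg$contrast *
        cos(2 * pi * (fx * xs + fy * ys) + ph)
    }

    n_want <- if (cfg$n_particles[1] == cfg$n_particles[2]) cfg$n_particles[1]
      else sample(cfg$n_particles[1]:cfg$n_particles[2], 1)
    centers <- matrix(0, 0, 2)
    radii <- numeric(0)
    attempts <- 0L
    while (nrow(centers) < n_want && attempts < 10L * n_want) {
      attempts <- attempts + 1L
      r <- stats::runif(1, cfg$radius_mean - cfg$radius_jitter,
                        cfg$radius_mean + cfg$radius_jitter)
      c_xy <- stats::runif(2, r + 1, S - r - 1)
      if (nrow(centers) > 0 &&
          min(sqrt(rowSums(sweep(centers, 2, c_xy, "-")^2))) <
            cfg$min_center_separation) next
      centers <- rbind(centers, c_xy)
      radii <- c(radii, r)
    }
    if (nrow(centers) < n_want)
      message("placement saturated: ", nrow(centers), "/", n_want,
              " particles placed for ", id)

    sgn <- if (cfg$dark_particles) -1 else 1
    for (i in seq_len(nrow(centers))) {
      d <- sqrt((xs - centers[i, 1])^2 + (ys - centers[i, 2])^2)
      img <- img + sgn * cfg$contrast * disk_profile(d, radii[i])
    }

    # particle boxes (pixel corners) used to keep distractors clear
    pboxes <- if (nrow(centers) > 0)
      cbind(centers[, 1] - radii, centers[, 2] - radii,
            centers[, 1] + radii, centers[, 2] + radii)
    else matrix(0, 0, 4)
    placed_d <- 0L
    dboxes <- matrix(0, 0, 4)
    tries <- 0L
    while (placed_d < cfg$n_distractors && tries < 50L * max(1L, cfg$n_distractors)) {
      tries <- tries + 1L
      ax <- stats::runif(1, 1.2, 2.2) * cfg$radius_mean
      ay <- stats::runif(1, 1.2, 2.2) * cfg$radius_mean
      th <- stats::runif(1, 0, pi)
      cc <- stats::runif(2, max(ax, ay), S - max(ax, ay))
      ext <- max(ax, ay)
      dbox <- c(cc[1] - ext, cc[2] - ext, cc[1] + ext, cc[2] + ext)
      if (nrow(pboxes) > 0) {
        overlap <- pboxes[, 1] < dbox[3] & pboxes[, 3] > dbox[1] &
          pboxes[, 2] < dbox[4] & pboxes[, 4] > dbox[2]
        if (any(overlap)) next
      }
      xr <- (xs - cc[1]) * cos(th) + (ys - cc[2]) * sin(th)
      yr <- -(xs - cc[1]) * sin(th) + (ys - cc[2]) * cos(th)
      d <- sqrt((xr / ax)^2 + (yr / ay)^2) * mean(c(ax, ay))
      img <- img + sgn * 0.6 * cfg$contrast *
        disk_profile(d, mean(c(ax, ay)))
      dboxes <- rbind(dboxes, dbox)
      placed_d <- placed_d + 1L
    }

    if (cfg$noise_sigma > 0)
      img <- img + matrix(stats::rnorm(S * S, 0,
                                       cfg$noise_sigma * cfg$contrast), S, S)

    images <- data.frame(id = index, micrograph_id = id,
                         width = S, height = S, stringsAsFactors = FALSE)
    annotations <- if (nrow(centers) > 0)
      data.frame(micrograph_id = id,
                 cx = centers[, 1] / S, cy = centers[, 2] / S,
                 w = 2 * radii / S, h = 2 * radii / S,
                 category_id = 1L, stringsAsFactors = FALSE)
    else data.frame(micrograph_id = character(0), cx = numeric(0),
                    cy = numeric(0), w = numeric(0), h = numeric(0),
                    category_id = integer(0))
    list(record = micrograph(img, id),
         annos = annotation_set(annotations, images),
         particle_boxes = pboxes, distractor_boxes = dboxes)
  })
}

#' Generate a synthetic dataset on disk
#'
#' Writes `n_images` micrographs (MRC float or PNG), a single COCO JSON with
#' all ground truth, a split manifest assigning images 8:1:1 to
#' train/val/test by index (indices with `index %% 10 < 8` train, `== 8`
#' val, `== 9` test), and optionally a ground-truth STAR file of particle
#' centers.
#'
#' @param cfg A [sim_config()].
#' @param n_images Number of micrographs.
#' @param out_dir Output directory (created if needed).
#' @param format "mrc" or "png".
#' @param truth_star Also write `truth.star` with all ground-truth centers.
#' @return Invisibly, a list with `coco`, `manifest`, `star` paths and the
#'   per-image file names.
#' @export
generate_dataset <- function(cfg, n_images, out_dir, format = c("mrc", "png"),
                             truth_star = TRUE) {
  format <- match.arg(format)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  all_ann <- list(); all_img <- list(); files <- character(n_images)
  truth <- list()
  for (i in seq_len(n_images)) {
    g <- generate_micrograph(cfg, i)
    fname <- sub("\\.mrc$", paste0(".", format), g$record$micrograph_id)
    path <- file.path(out_dir, fname)
    if (format == "mrc") {
      write_mrc(g$record$image, path)
    } else {
      im <- g$record$image
      rng <- range(im)
      png::writePNG((im - rng[1]) / max(rng[2] - rng[1], 1e-6), path)
    }
    files[i] <- fname
    a <- g$annos$annotations
    a$micrograph_id <- fname
    img_row <- g$annos$images
    img_row$micrograph_id <- fname
    all_ann[[i]] <- a
    all_img[[i]] <- img_row
    if (nrow(a) > 0)
      truth[[i]] <- data.frame(micrograph_name = fname,
                               x = a$cx * img_row$width,
                               y = a$cy * img_row$height,
                               score = 1, stringsAsFactors = FALSE)
  }
  annos <- annotation_set(do.call(rbind, all_ann), do.call(rbind, all_img))
  coco_path <- file.path(out_dir, "annotations.json")
  write_coco(annos, coco_path)
  split <- ifelse((seq_len(n_images) - 1L) %% 10L < 8L, "train",
                  ifelse((seq_len(n_images) - 1L) %% 10L == 8L, "val", "test"))
  manifest_path <- file.path(out_dir, "split.csv")
  utils::write.csv(data.frame(index = seq_len(n_images), file = files,
                              split = split),
                   manifest_path, row.names = FALSE)
  star_path <- NULL
  if (truth_star) {
    star_path <- file.path(out_dir, "truth.star")
    write_star(do.call(rbind, truth), star_path)
  }
  message("wrote ", n_images, " micrographs (",
          sum(split == "train"), " train / ", sum(split == "val"),
          " val / ", sum(split == "test"), " test) to ", out_dir)
  invisible(list(coco = coco_path, manifest = manifest_path,
                 star = star_path, files = files, split = split))
}

#' In-memory synthetic benchmark
#'
#' The default desk-scale benchmark: 200 training, 25 validation and 25 test
#' micrographs drawn from the default [sim_config()] (128 px images, radius
#' 8 +/- 2 px, 5-15 particles at >= 12 px separation, noise sd 0.8 x
#' contrast, 2 distractors).
#'
#' @param seed Simulator seed.
#' @param n_train,n_val,n_test Split sizes.
#' @param cfg Optional [sim_config()] override (its seed is replaced).
#' @return List with `train`, `val`, `test`; each element is a list of
#'   per-image lists `(record, boxes)` with `boxes` the normalized
#'   ground-truth matrix.
#' @export
synthetic_benchmark <- function(seed = 1L, n_train = 200L, n_val = 25L,
                                n_test = 25L, cfg = NULL) {
  if (is.null(cfg)) cfg <- sim_config(seed = seed) else cfg$seed <- seed
  make <- function(idx) lapply(idx, function(i) {
    g <- generate_micrograph(cfg, i)
    list(record = g$record,
         boxes = as.matrix(g$annos$annotations[, c("cx", "cy", "w", "h")]),
         annos = g$annos)
  })
  n <- n_train + n_val + n_test
  list(train = make(seq_len(n_train)),
       val = make(n_train + seq_len(n_val)),
       test = make(n_train + n_val + seq_len(n_test)))
}

#' Measured signal-to-noise ratio of a synthetic micrograph
#'
#' Contrast between the annotated particle interiors and the particle-free
#' background, divided by the background standard deviation; a
#' quality-control probe for the simulator. Capped at 1e6 for essentially
#' noise-free images.
#'
#' @param record A [micrograph()].
#' @param annos Its [annotation_set()] (must be non-empty).
#' @return Unitless ratio.
#' @export
measured_snr <- function(record, annos) {
  a <- annos$annotations[annos$annotations$micrograph_id ==
                           record$micrograph_id, ]
  if (nrow(a) == 0) stop("no annotations for ", record$micrograph_id)
  S <- ncol(record$image)
  xs <- matrix(rep(seq_len(ncol(record$image)) - 0.5,
                   each = nrow(record$image)),
               nrow(record$image), ncol(record$image))
  ys <- matrix(rep(seq_len(nrow(record$image)) - 0.5,
                   times = ncol(record$image)),
               nrow(record$image), ncol(record$image))
  inside <- matrix(FALSE, nrow(record$image), ncol(record$image))
  near <- inside
  for (i in seq_len(nrow(a))) {
    cx <- a$cx[i] * record$width; cy <- a$cy[i] * record$height
    r <- a$w[i] * record$width / 2
    d <- sqrt((xs - cx)^2 + (ys - cy)^2)
    inside <- inside | d <= 0.7 * r
    near <- near | d <= r + 4
  }
  bg <- record$image[!near]
  if (stats::sd(bg) < 1e-12) stop("zero background variance")
  contrast <- abs(mean(bg) - mean(record$image[inside]))
  min(contrast / stats::sd(bg), 1e6)
}
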