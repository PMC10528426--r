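# Synthetic ultra-widefield fundus generator. Emulates just enough structure
# for the pipeline to be exercised end to end without clinical images: a
# bright retinal ellipse on a black canvas with low-frequency shading and a
# few dark curvilinear vessels as detector distractors, a darker
# Gaussian-feathered macular disc whose centre is drawn from the empirical
# macula-position distribution, and -- for the AMD class -- bright
# drusen-like blobs plus dark pigment-like clumps confined to the macula.
# Lesion photometry is a free modelling choice, not a claim about real
# drusen appearance.

#' Configuration for the synthetic fundus generator
#'
#' Defaults reproduce the native acquisition geometry (3900 x 3072 px, macula
#' centre ~ N((1971, 1588), (46, 52)^2), 250 px macular radius); `scale`
#' shrinks every length linearly (e.g. `scale = 1/5` gives the 780 x 614
#' desk-scale mode used by the tests and worked examples).
#'
#' @param scale linear scale factor applied to all lengths (default 1).
#' @param image_width,image_height canvas size in px at scale 1.
#' @param macula_center_mean,macula_center_std mean and SD (x, y) of the
#'   Gaussian the macula centre is drawn from, at scale 1.
#' @param macula_radius macular disc / ROI radius in px at scale 1.
#' @param macula_depth intensity drop of the macular disc (8-bit units).
#' @param drusen_count_range integer interval of drusen blobs per AMD image.
#' @param drusen_brightness intensity delta of drusen blobs (positive;
#'   scalar, or an interval the per-image delta is drawn from).
#' @param drusen_radius_frac lesion radius interval as fraction of the
#'   macular radius.
#' @param pigment_count_range integer interval of pigment clumps per AMD image.
#' @param pigment_darkness intensity delta of pigment clumps (positive,
#'   applied as a darkening; scalar or per-image interval).
#' @param pigment_radius_frac as `drusen_radius_frac`, for pigment clumps.
#' @param background_noise_sd Gaussian pixel noise SD (8-bit units).
#' @param vessel_count integer interval (or scalar) of dark vessels drawn.
#' @param seed default master seed recorded in the config.
#' @return object of class `synth_config` (a validated list; all lengths
#'   already multiplied by `scale`).
#' @export
synth_config <- function(scale = 1,
                         image_width = 3900, image_height = 3072,
                         macula_center_mean = c(1971, 1588),
                         macula_center_std = c(46, 52),
                         macula_radius = 250,
                         macula_depth = 55,
                         drusen_count_range = c(3L, 10L),
                         drusen_brightness = 45,
                         drusen_radius_frac = c(0.04, 0.10),
                         pigment_count_range = c(2L, 8L),
                         pigment_darkness = 45,
                         pigment_radius_frac = c(0.05, 0.12),
                         background_noise_sd = 3,
                         vessel_count = c(2L, 6L),
                         seed = 1L) {
  if (length(vessel_count) == 1) vessel_count <- rep(vessel_count, 2)
  if (length(drusen_brightness) == 1) drusen_brightness <- rep(drusen_brightness, 2)
  if (length(pigment_darkness) == 1) pigment_darkness <- rep(pigment_darkness, 2)
  cfg <- list(
    width = as.integer(round(image_width * scale)),
    height = as.integer(round(image_height * scale)),
    center_mean = macula_center_mean * scale,
    center_std = macula_center_std * scale,
    radius = macula_radius * scale,
    macula_depth = macula_depth,
    drusen_count_range = as.integer(drusen_count_range),
    drusen_brightness = drusen_brightness,
    drusen_radius_frac = drusen_radius_frac,
    pigment_count_range = as.integer(pigment_count_range),
    pigment_darkness = pigment_darkness,
    pigment_radius_frac = pigment_radius_frac,
    noise_sd = background_noise_sd,
    vessel_count = as.integer(vessel_count),
    scale = scale,
    seed = as.integer(seed)
  )
  with(cfg, {
    if (radius <= 0) stop("invalid parameter 'macula_radius': must be > 0")
    if (any(drusen_count_range < 0)) stop("invalid parameter 'drusen_count_range': counts must be >= 0")
    if (any(pigment_count_range < 0)) stop("invalid parameter 'pigment_count_range': counts must be >= 0")
    if (any(vessel_count < 0)) stop("invalid parameter 'vessel_count': counts must be >= 0")
    if (center_mean[1] <= 0 || center_mean[1] >= width - 1 ||
        center_mean[2] <= 0 || center_mean[2] >= height - 1) {
      stop("invalid parameter 'macula_center_mean': must lie inside the image")
    }
    if (max(drusen_radius_frac, pigment_radius_frac) >= 1) {
      stop("invalid parameter 'drusen_radius_frac'/'pigment_radius_frac': ",
           "lesions must fit inside the macula radius")
    }
    if (noise_sd < 0) stop("invalid parameter 'background_noise_sd': must be >= 0")
  })
  structure(cfg, class = "synth_config")
}

# Deterministic per-record seed derived from a master seed (kept < 2^31).
derive_seed <- function(master, i) {
  as.integer((as.double(master) * 48271 + i * 7919) %% 2147483647)
}

# Stamp a feathered disc delta onto an image patch. Feather: full delta out
# to (1 - feather) * r, cosine ramp to 0 at r.
stamp_disc <- function(img, cx, cy, r, delta, feather = 0.35) {
  w <- ncol(img); h <- nrow(img)
  x0 <- max(0, floor(cx - r - 2)); x1 <- min(w - 1, ceiling(cx + r + 2))
  y0 <- max(0, floor(cy - r - 2)); y1 <- min(h - 1, ceiling(cy + r + 2))
  if (x0 > x1 || y0 > y1) return(img)
  xs <- x0:x1; ys <- y0:y1
  d <- sqrt(outer((ys - cy)^2, (xs - cx)^2, `+`))
  core <- (1 - feather) * r
  wgt <- ifelse(d <= core, 1,
                ifelse(d >= r, 0, 0.5 * (1 + cos(pi * (d - core) / (r - core)))))
  img[ys + 1, xs + 1] <- img[ys + 1, xs + 1] + delta * wgt
  img
}

# Background: bright retinal ellipse with radial falloff + low-frequency
# shading, near-black outside. Returns list(img, phase-independent base fun).
render_background <- function(cfg, shading_phase) {
  w <- cfg$width; h <- cfg$height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  a <- 0.47 * w; b <- 0.47 * h
  ex <- outer(rep(1, h), ((0:(w - 1)) - cx) / a)
  ey <- outer(((0:(h - 1)) - cy) / b, rep(1, w))
  rho2 <- ex^2 + ey^2
  base <- 150 - 25 * rho2 +
    4 * sin(2 * pi * (ex + shading_phase[1])) +
    4 * sin(2 * pi * (ey + shading_phase[2]))
  ifelse(rho2 <= 1, base, 5)
}

# Draw dark curvilinear vessels. Each vessel is a quadratic curve from the
# ellipse rim towards (but never inside 1.15x of) the macular disc.
stamp_vessels <- function(img, n, cfg, macula_center) {
  w <- cfg$width; h <- cfg$height
  cx <- (w - 1) / 2; cy <- (h - 1) / 2
  width_px <- max(1.2, 12 * cfg$scale)
  veins <- matrix(0, h, w)
  for (k in seq_len(n)) {
    th0 <- stats::runif(1, 0, 2 * pi)
    p0 <- c(cx + 0.44 * w * cos(th0), cy + 0.44 * h * sin(th0))
    th1 <- th0 + stats::runif(1, 2, 4.2)
    p2 <- c(cx + 0.30 * w * cos(th1), cy + 0.30 * h * sin(th1))
    mid <- (p0 + p2) / 2
    p1 <- mid + stats::runif(2, -0.12, 0.12) * c(w, h)
    tt <- seq(0, 1, length.out = 160)
    px <- (1 - tt)^2 * p0[1] + 2 * (1 - tt) * tt * p1[1] + tt^2 * p2[1]
    py <- (1 - tt)^2 * p0[2] + 2 * (1 - tt) * tt * p1[2] + tt^2 * p2[2]
    keep <- sqrt((px - macula_center[1])^2 + (py - macula_center[2])^2) >
      1.3 * cfg$radius + width_px
    # accumulate the vessel profile into a local weight matrix (in place;
    # stamping through the full image per dab would copy it every time)
    r <- width_px; core <- 0.4 * r
    for (i in which(keep)) {
      x0 <- max(0, floor(px[i] - r)); x1 <- min(w - 1, ceiling(px[i] + r))
      y0 <- max(0, floor(py[i] - r)); y1 <- min(h - 1, ceiling(py[i] + r))
      if (x0 > x1 || y0 > y1) next
      xs <- x0:x1; ys <- y0:y1
      dd <- sqrt(outer((ys - py[i])^2, (xs - px[i])^2, `+`))
      wg <- ifelse(dd <= core, 1,
                   ifelse(dd >= r, 0,
                          0.5 * (1 + cos(pi * (dd - core) / (r - core)))))
      veins[ys + 1, xs + 1] <- pmax(veins[ys + 1, xs + 1], wg)
    }
  }
  img - 35 * veins
}

# Rejection-sample a lesion centre/radius wholly inside the macula and not
# overlapping previously placed lesions (2 px clearance).
place_lesion <- function(existing, macula_center, macula_radius, r) {
  for (try in 1:200) {
    u <- stats::runif(1); th <- stats::runif(1, 0, 2 * pi)
    rho <- (macula_radius - r - 1) * sqrt(u)
    ctr <- macula_center + rho * c(cos(th), sin(th))
    ok <- TRUE
    for (e in existing) {
      if (sqrt(sum((ctr - e$center)^2)) < r + e$radius + 2) { ok <- FALSE; break }
    }
    if (ok) return(ctr)
  }
  stop("lesion geometry that cannot fit inside the macula radius: ",
       "reduce 'drusen_count_range'/'pigment_count_range' or lesion radius fractions")
}

#' Generate one synthetic fundus image with ground truth
#'
#' Deterministic: identical `(config, label, seed)` triples give bit-identical
#' images and ground truth. The macula centre is drawn from the configured
#' Gaussian; `"AMD"` images receive drusen-like bright blobs and
#' pigment-like dark clumps inside the macular disc (lesion deltas may be
#' configured as per-image intervals), `"Negative"` images receive none.
#'
#' @param config a [synth_config()].
#' @param label `"AMD"` or `"Negative"`.
#' @param seed integer seed for this image.
#' @return `list(image, truth)` where `truth` has fields `label`,
#'   `macula_center` (0-based x, y), `macula_radius` and `lesions` (list of
#'   `list(kind, center, radius, delta)`).
#' @export
generate_image <- function(config, label, seed) {
  stopifnot(inherits(config, "synth_config"))
  if (!label %in% c("AMD", "Negative")) {
    stop("invalid label '", label, "': must be \"AMD\" or \"Negative\"")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  ctr <- stats::rnorm(2, config$center_mean, config$center_std)
  ctr <- pmin(pmax(ctr, config$radius), c(config$width, config$height) - 1 - config$radius)
  phase <- stats::runif(2)
  img <- render_background(config, phase)
  # The macular darkening is drawn wider than the analysis ROI with its
  # feather ramp outside it, so the ROI interior is a flat plateau + noise
  # ("smooth texture" for the Negative class) and lesions are the only
  # structured deviations inside it. The flat core (1.125x the ROI radius)
  # also covers every ROI the stability study perturbs (radius jitter up to
  # +10%), keeping the plateau contract under segmentation perturbation.
  img <- stamp_disc(img, ctr[1], ctr[2], 1.5 * config$radius,
                    -config$macula_depth, feather = 0.25)

  lesions <- list()
  if (label == "AMD") {
    nd <- sample_int_range(config$drusen_count_range)
    np <- sample_int_range(config$pigment_count_range)
    # per-image lesion contrast (severity / acquisition variability)
    d_delta <- stats::runif(1, config$drusen_brightness[1],
                            config$drusen_brightness[2])
    p_delta <- stats::runif(1, config$pigment_darkness[1],
                            config$pigment_darkness[2])
    for (k in seq_len(nd)) {
      r <- stats::runif(1, config$drusen_radius_frac[1], config$drusen_radius_frac[2]) * config$radius
      c_k <- place_lesion(lesions, ctr, config$radius, r)
      lesions[[length(lesions) + 1]] <- list(kind = "drusen", center = c_k,
                                             radius = r, delta = d_delta)
    }
    for (k in seq_len(np)) {
      r <- stats::runif(1, config$pigment_radius_frac[1], config$pigment_radius_frac[2]) * config$radius
      c_k <- place_lesion(lesions, ctr, config$radius, r)
      lesions[[length(lesions) + 1]] <- list(kind = "pigment", center = c_k,
                                             radius = r, delta = -p_delta)
    }
    for (l in lesions) {
      img <- stamp_disc(img, l$center[1], l$center[2], l$radius, l$delta,
                        feather = 0.4)
    }
  }

  nv <- sample_int_range(config$vessel_count)
  img <- stamp_vessels(img, nv, config, ctr)

  if (config$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(length(img), 0, config$noise_sd),
                        nrow = nrow(img))
  }
  img <- round(pmin(pmax(img, 0), 255))

  truth <- list(label = label,
                macula_center = c(x = ctr[1], y = ctr[2]),
                macula_radius = config$radius,
                lesions = lesions)
  list(image = img, truth = truth)
}

sample_int_range <- function(rng) {
  if (rng[1] == rng[2]) return(rng[1])
  rng[1] + sample.int(rng[2] - rng[1] + 1L, 1L) - 1L
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Generate a labelled synthetic dataset
#'
#' Emits `n_amd + n_negative` records with `"AMD"` first, each generated with
#' a per-record seed derived deterministically from `seed`.
#'
#' @param n_amd,n_negative class counts (>= 0).
#' @param config a [synth_config()].
#' @param seed master seed.
#' @return list of `list(image, truth)` records.
#' @export
generate_dataset <- function(n_amd, n_negative, config, seed) {
  if (n_amd < 0 || n_negative < 0) stop("class counts must be >= 0")
  labels <- c(rep("AMD", n_amd), rep("Negative", n_negative))
  lapply(seq_along(labels), function(i) {
    generate_image(config, labels[i], derive_seed(seed, i))
  })
}

#' Write a synthetic dataset to disk (PNG + JSON sidecars + CSV manifest)
#'
#' @param records output of [generate_dataset()].
#' @param dir output directory (created if missing).
#' @return path of the manifest CSV, invisibly.
#' @export
write_dataset <- function(records, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(records), function(i) {
    rec <- records[[i]]
    id <- sprintf("case_%03d", i)
    img_path <- file.path(dir, paste0(id, ".png"))
    write_image(rec$image, img_path)
    side <- rec$truth
    side$center <- unname(side$macula_center)
    jsonlite::write_json(
      list(label = side$label, center = side$center,
           radius = side$macula_radius,
           lesions = lapply(side$lesions, function(l) {
             list(kind = l$kind, center = unname(l$center),
                  radius = l$radius, delta = l$delta)
           })),
      file.path(dir, paste0(id, ".json")), auto_unbox = TRUE, digits = NA)
    data.frame(case_id = id, path = img_path, label = rec$truth$label,
               center_x = rec$truth$macula_center[["x"]],
               center_y = rec$truth$macula_center[["y"]],
               radius = rec$truth$macula_radius)
  })
  manifest <- do.call(rbind, rows)
  mpath <- file.path(dir, "manifest.csv")
  utils::write.csv(manifest, mpath, row.names = FALSE)
  invisible(mpath)
}
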