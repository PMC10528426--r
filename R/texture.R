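# IBSI-style 2D texture matrix families computed from a discretised ROI
# (integer level matrix, NA outside the mask, levels 1..n_bins).
#
# Shared conventions (all exposed through the catalogue and documented in
# the methods vignette):
#  * pixel adjacency is the 8-neighbourhood (Chebyshev distance 1) unless a
#    family variant says otherwise;
#  * GLCM/GLRLM use the 4 unique 2D directions (1,0), (1,1), (0,1), (-1,1)
#    with two aggregation schemes: "avg" (features per direction, then
#    averaged) and "mrg" (counts merged over directions, then features);
#  * zone connectivity for GLSZM is 8 by default (a 4-connected variant is
#    part of the default catalogue); GLDZM distances are city-block steps to
#    the nearest outside-mask pixel with minimum 1;
#  * NGLDM dependence counts use |level difference| <= alpha (default 0);
#  * 0 * log(0) = 0 throughout; logs are base 2.

glcm_directions <- list(c(1L, 0L), c(1L, 1L), c(0L, 1L), c(-1L, 1L))

# Shift a matrix by (dx, dy) pixels (0-based image frame: x = col, y = row),
# padding with NA: result[r, c] = m[r - dy, c - dx].
shift_matrix <- function(m, dx, dy) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(NA_integer_, h, w)
  rlo <- max(1, 1 + dy); rhi <- min(h, h + dy)
  clo <- max(1, 1 + dx); chi <- min(w, w + dx)
  if (rlo > rhi || clo > chi) return(out)
  rs <- rlo:rhi; cs <- clo:chi
  out[rs, cs] <- m[rs - dy, cs - dx, drop = FALSE]
  out
}

xlog2 <- function(p) ifelse(p > 0, p * log2(p), 0)

# ---------------------------------------------------------------- GLCM ----

#' Grey-level co-occurrence matrices
#'
#' Counts symmetrised co-occurrences of level pairs at the given pixel
#' distance along each direction; only pairs with both pixels in the mask
#' contribute.
#'
#' @param d discretised ROI: integer level matrix (NA outside mask).
#' @param n_bins number of grey levels.
#' @param distance pixel offset length (default 1).
#' @param directions list of integer `c(dx, dy)` offsets.
#' @return list of `n_bins` x `n_bins` count matrices, one per direction.
#' @export
glcm_matrix <- function(d, n_bins, distance = 1,
                        directions = glcm_directions) {
  lapply(directions, function(dir) {
    s <- shift_matrix(d, dir[1] * distance, dir[2] * distance)
    ok <- !is.na(d) & !is.na(s)
    if (!any(ok)) {
      return(matrix(0, n_bins, n_bins))
    }
    i <- d[ok]; j <- s[ok]
    cnt <- matrix(tabulate((j - 1) * n_bins + i, nbins = n_bins * n_bins),
                  n_bins, n_bins)
    cnt + t(cnt)  # symmetrisation
  })
}

#' GLCM features from a normalised co-occurrence matrix
#'
#' @param P square co-occurrence probability matrix (entries sum to 1).
#' @return named numeric vector of the 25 GLCM features.
#' @export
glcm_features <- function(P) {
  if (abs(sum(P) - 1) > 1e-6) stop("GLCM must be normalised to sum 1")
  ng <- nrow(P)
  i <- row(P); j <- col(P)
  px <- rowSums(P); py <- colSums(P)
  mu <- sum(i * P)
  mux <- sum(seq_len(ng) * px); muy <- sum(seq_len(ng) * py)
  sigx <- sqrt(sum((seq_len(ng) - mux)^2 * px))
  sigy <- sqrt(sum((seq_len(ng) - muy)^2 * py))
  # diagonal / cross-diagonal probabilities
  pdm <- tapply(as.vector(P), as.vector(abs(i - j)), sum)          # k = 0..ng-1
  kd <- as.numeric(names(pdm))
  psm <- tapply(as.vector(P), as.vector(i + j), sum)               # k = 2..2ng
  ks <- as.numeric(names(psm))
  da <- sum(kd * pdm)
  sa <- sum(ks * psm)
  hxy <- -sum(xlog2(P))
  pxy <- outer(px, py)
  hxy1 <- -sum(ifelse(P > 0 & pxy > 0, P * log2(pxy), 0))
  hxy2 <- -sum(xlog2(pxy))
  hx <- -sum(xlog2(px))
  offdiag <- i != j
  corr <- if (sigx * sigy > 0) {
    (sum(i * j * P) - mux * muy) / (sigx * sigy)
  } else 1  # single-level convention
  c(
    joint_maximum = max(P),
    joint_average = mu,
    joint_variance = sum((i - mu)^2 * P),
    joint_entropy = hxy,
    difference_average = da,
    difference_variance = sum((kd - da)^2 * pdm),
    difference_entropy = -sum(xlog2(pdm)),
    sum_average = sa,
    sum_variance = sum((ks - sa)^2 * psm),
    sum_entropy = -sum(xlog2(psm)),
    angular_second_moment = sum(P^2),
    contrast = sum((i - j)^2 * P),
    dissimilarity = sum(abs(i - j) * P),
    inverse_difference = sum(P / (1 + abs(i - j))),
    inverse_difference_normalised = sum(P / (1 + abs(i - j) / ng)),
    inverse_difference_moment = sum(P / (1 + (i - j)^2)),
    inverse_difference_moment_normalised = sum(P / (1 + (i - j)^2 / ng^2)),
    inverse_variance = sum(P[offdiag] / (i[offdiag] - j[offdiag])^2),
    correlation = corr,
    autocorrelation = sum(i * j * P),
    cluster_tendency = sum((i + j - mux - muy)^2 * P),
    cluster_shade = sum((i + j - mux - muy)^3 * P),
    cluster_prominence = sum((i + j - mux - muy)^4 * P),
    information_correlation_1 = if (hx > 0) (hxy - hxy1) / hx else 0,
    information_correlation_2 = sqrt(max(0, 1 - exp(-2 * (hxy2 - hxy))))
  )
}

# Aggregate GLCM features over directions under scheme "avg" or "mrg".
glcm_family <- function(d, n_bins, distance = 1, agg = c("avg", "mrg")) {
  agg <- match.arg(agg)
  mats <- glcm_matrix(d, n_bins, distance)
  tot <- vapply(mats, sum, numeric(1))
  if (sum(tot) == 0) stop("GLCM: no valid in-mask pixel pairs at distance ",
                          distance)
  if (agg == "mrg") {
    M <- Reduce(`+`, mats)
    return(glcm_features(M / sum(M)))
  }
  use <- which(tot > 0)
  rowMeans(vapply(use, function(k) glcm_features(mats[[k]] / tot[k]),
                  numeric(25)))
}

# --------------------------------------------------------------- GLRLM ----

# Maximal-run decomposition of in-mask collinear pixels along one direction.
# Returns data.frame(level, length).
runs_in_direction <- function(d, dir) {
  h <- nrow(d); w <- ncol(d)
  key <- switch(paste(dir, collapse = ","),
                "1,0"  = row(d),              # horizontal lines
                "0,1"  = col(d),              # vertical lines
                "1,1"  = col(d) - row(d),     # down-right diagonals
                "-1,1" = col(d) + row(d),     # down-left diagonals
                stop("unsupported GLRLM direction"))
  # order pixels along each line: for all four directions, sorting by x
  # (then y for verticals) walks the line in the offset direction
  ord <- order(as.vector(key), as.vector(col(d)), as.vector(row(d)))
  v <- as.vector(d)[ord]
  k <- as.vector(key)[ord]
  brk <- c(TRUE, k[-1] != k[-length(k)])
  grp <- cumsum(brk)
  # run-length encode within lines; keys are made unique across lines and
  # NA (outside-mask) cells (coded -1) break every run
  nlev <- max(v, 1, na.rm = TRUE) + 2
  code <- grp * nlev + ifelse(is.na(v), -1, v)
  rr <- rle(code)
  keep <- rr$values %% nlev != nlev - 1  # drop the NA runs (-1 mod nlev)
  data.frame(level = as.integer(rr$values[keep] %% nlev),
             length = rr$lengths[keep])
}

#' Grey-level run-length matrices
#'
#' @inheritParams glcm_matrix
#' @return list of count matrices (levels x run length), one per direction.
#' @export
glrlm_matrix <- function(d, n_bins, directions = glcm_directions) {
  lapply(directions, function(dir) {
    rn <- runs_in_direction(d, dir)
    jmax <- max(1L, rn$length)
    m <- matrix(0, n_bins, jmax)
    if (nrow(rn) > 0) {
      for (q in seq_len(nrow(rn))) {
        m[rn$level[q], rn$length[q]] <- m[rn$level[q], rn$length[q]] + 1
      }
    }
    m
  })
}

# Generic feature skeleton shared by GLRLM / GLSZM / GLDZM / NGLDM: counts
# matrix M over (grey level i, second axis j), npix = in-mask pixel count.
rlm_skeleton <- function(M, npix, with_energy = FALSE) {
  ns <- sum(M)
  if (ns == 0) stop("empty counts matrix")
  # sparse triplet form: these matrices are mostly zeros (second axis runs
  # to the largest run/zone size observed)
  nz <- which(M != 0)
  cnt <- M[nz]
  i <- (nz - 1) %% nrow(M) + 1
  j <- (nz - 1) %/% nrow(M) + 1
  p <- cnt / ns
  mi <- rowsum(cnt, i); mj <- rowsum(cnt, j)
  mu_i <- sum(i * p); mu_j <- sum(j * p)
  out <- c(
    small_j = sum(cnt / j^2) / ns,
    large_j = sum(cnt * j^2) / ns,
    low_grey = sum(cnt / i^2) / ns,
    high_grey = sum(cnt * i^2) / ns,
    small_j_low_grey = sum(cnt / (i^2 * j^2)) / ns,
    small_j_high_grey = sum(cnt * i^2 / j^2) / ns,
    large_j_low_grey = sum(cnt * j^2 / i^2) / ns,
    large_j_high_grey = sum(cnt * i^2 * j^2) / ns,
    gl_non_uniformity = sum(mi^2) / ns,
    gl_non_uniformity_norm = sum(mi^2) / ns^2,
    j_non_uniformity = sum(mj^2) / ns,
    j_non_uniformity_norm = sum(mj^2) / ns^2,
    j_percentage = ns / npix,
    gl_variance = sum((i - mu_i)^2 * p),
    j_variance = sum((j - mu_j)^2 * p),
    j_entropy = -sum(xlog2(p))
  )
  if (with_energy) out <- c(out, j_energy = sum(p^2))
  out
}

glrlm_names <- c(
  "short_run_emphasis", "long_run_emphasis", "low_grey_level_run_emphasis",
  "high_grey_level_run_emphasis", "short_run_low_grey_level_emphasis",
  "short_run_high_grey_level_emphasis", "long_run_low_grey_level_emphasis",
  "long_run_high_grey_level_emphasis", "grey_level_non_uniformity",
  "grey_level_non_uniformity_normalised", "run_length_non_uniformity",
  "run_length_non_uniformity_normalised", "run_percentage",
  "grey_level_variance", "run_length_variance", "run_entropy")

#' GLRLM features under an aggregation scheme
#'
#' @inheritParams glcm_matrix
#' @param agg `"avg"` (per-direction features averaged) or `"mrg"` (run
#'   matrices merged first; the run-percentage denominator is then the pixel
#'   count times the number of directions).
#' @return named numeric vector of the 16 GLRLM features.
#' @export
glrlm_features <- function(d, n_bins, agg = c("avg", "mrg")) {
  agg <- match.arg(agg)
  npix <- sum(!is.na(d))
  if (npix == 0) stop("empty mask")
  mats <- glrlm_matrix(d, n_bins)
  if (agg == "avg") {
    f <- rowMeans(vapply(mats, rlm_skeleton, numeric(16), npix = npix))
  } else {
    jmax <- max(vapply(mats, ncol, integer(1)))
    M <- Reduce(`+`, lapply(mats, function(m) {
      cbind(m, matrix(0, nrow(m), jmax - ncol(m)))
    }))
    f <- rlm_skeleton(M, npix * length(mats))
  }
  stats::setNames(f, glrlm_names)
}

# --------------------------------------------------------------- zones ----

# 8- or 4-connected components of equal level; returns integer label matrix
# (NA outside mask). Adjacency edges between equal-level in-mask pixels are
# assembled with matrix shifts and resolved with igraph's component search.
label_zones <- function(d, connectivity = 8) {
  offs <- list(c(1, 0), c(0, 1))
  if (connectivity == 8) {
    offs <- c(offs, list(c(1, 1), c(-1, 1)))
  } else if (connectivity != 4) stop("connectivity must be 4 or 8")
  idx <- matrix(seq_along(d), nrow(d), ncol(d))
  edges <- lapply(offs, function(o) {
    sv <- shift_matrix(d, o[1], o[2])
    si <- shift_matrix(idx, o[1], o[2])
    same <- which(!is.na(d) & !is.na(sv) & d == sv)
    rbind(idx[same], si[same])
  })
  g <- igraph::graph_from_edgelist(t(do.call(cbind, edges)), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, length(d) - igraph::vcount(g)))
  comp <- igraph::components(g)$membership
  lab <- matrix(comp[seq_along(d)], nrow(d), ncol(d))
  lab[is.na(d)] <- NA_integer_
  lab
}

#' Grey-level size-zone matrix
#'
#' Zones are connected components of equal level (8-connected by default).
#'
#' @inheritParams glcm_matrix
#' @param connectivity 8 (default) or 4.
#' @return counts matrix (levels x zone size).
#' @export
glszm_matrix <- function(d, n_bins, connectivity = 8) {
  lab <- label_zones(d, connectivity)
  ok <- !is.na(lab)
  if (!any(ok)) stop("empty mask")
  sizes <- table(lab[ok])
  lev <- d[ok][match(as.integer(names(sizes)), lab[ok])]
  m <- matrix(0, n_bins, max(sizes))
  for (q in seq_along(sizes)) m[lev[q], sizes[q]] <- m[lev[q], sizes[q]] + 1
  m
}

glszm_names <- c(
  "small_zone_emphasis", "large_zone_emphasis",
  "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
  "small_zone_low_grey_level_emphasis", "small_zone_high_grey_level_emphasis",
  "large_zone_low_grey_level_emphasis", "large_zone_high_grey_level_emphasis",
  "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
  "zone_size_non_uniformity", "zone_size_non_uniformity_normalised",
  "zone_percentage", "grey_level_variance", "zone_size_variance",
  "zone_size_entropy")

#' GLSZM features
#' @inheritParams glszm_matrix
#' @return named numeric vector of the 16 GLSZM features.
#' @export
glszm_features <- function(d, n_bins, connectivity = 8) {
  npix <- sum(!is.na(d))
  f <- rlm_skeleton(glszm_matrix(d, n_bins, connectivity), npix)
  stats::setNames(f, glszm_names)
}

#' Grey-level distance-zone matrix
#'
#' Zone distance is the minimum over zone pixels of the city-block step
#' count to the nearest outside-mask pixel (minimum 1: a pixel touching the
#' mask border counts 1).
#'
#' @inheritParams glszm_matrix
#' @return counts matrix (levels x zone distance).
#' @export
gldzm_matrix <- function(d, n_bins, connectivity = 8) {
  mask <- !is.na(d)
  if (!any(mask)) stop("empty mask")
  pad <- matrix(0, nrow(d) + 2, ncol(d) + 2)
  pad[2:(nrow(d) + 1), 2:(ncol(d) + 1)] <- mask * 1
  dm <- EBImage::distmap(pad, metric = "manhattan")
  dist <- dm[2:(nrow(d) + 1), 2:(ncol(d) + 1), drop = FALSE]
  lab <- label_zones(d, connectivity)
  ok <- !is.na(lab)
  ids <- lab[ok]
  zmin <- tapply(dist[ok], ids, min)
  lev <- d[ok][match(as.integer(names(zmin)), ids)]
  m <- matrix(0, n_bins, max(zmin))
  for (q in seq_along(zmin)) m[lev[q], zmin[q]] <- m[lev[q], zmin[q]] + 1
  m
}

gldzm_names <- c(
  "small_distance_emphasis", "large_distance_emphasis",
  "low_grey_level_zone_emphasis", "high_grey_level_zone_emphasis",
  "small_distance_low_grey_level_emphasis",
  "small_distance_high_grey_level_emphasis",
  "large_distance_low_grey_level_emphasis",
  "large_distance_high_grey_level_emphasis",
  "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
  "zone_distance_non_uniformity", "zone_distance_non_uniformity_normalised",
  "zone_percentage", "grey_level_variance", "zone_distance_variance",
  "zone_distance_entropy")

#' GLDZM features
#' @inheritParams glszm_matrix
#' @return named numeric vector of the 16 GLDZM features.
#' @export
gldzm_features <- function(d, n_bins, connectivity = 8) {
  npix <- sum(!is.na(d))
  f <- rlm_skeleton(gldzm_matrix(d, n_bins, connectivity), npix)
  stats::setNames(f, gldzm_names)
}

# --------------------------------------------------------------- NGTDM ----

chebyshev_offsets <- function(dist) {
  g <- expand.grid(dx = -dist:dist, dy = -dist:dist)
  g <- g[!(g$dx == 0 & g$dy == 0), ]
  Map(c, g$dx, g$dy)
}

#' Neighbourhood grey-tone difference table
#'
#' For every in-mask pixel with at least one in-mask neighbour within
#' Chebyshev distance `dist`, the absolute difference between its level and
#' the mean level of those neighbours is accumulated per level.
#'
#' @inheritParams glcm_matrix
#' @param dist Chebyshev neighbourhood radius (default 1 = 8-neighbourhood).
#' @return data.frame with one row per level: `level`, `n` (pixel count),
#'   `p` (occupancy fraction), `s` (summed absolute differences).
#' @export
ngtdm_table <- function(d, n_bins, dist = 1) {
  nbr_sum <- matrix(0, nrow(d), ncol(d))
  nbr_cnt <- matrix(0, nrow(d), ncol(d))
  for (o in chebyshev_offsets(dist)) {
    s <- shift_matrix(d, o[1], o[2])
    has <- !is.na(s)
    nbr_sum[has] <- nbr_sum[has] + s[has]
    nbr_cnt <- nbr_cnt + has
  }
  use <- !is.na(d) & nbr_cnt > 0
  if (!any(use)) stop("NGTDM: no pixel has an in-mask neighbour")
  diffs <- abs(d[use] - nbr_sum[use] / nbr_cnt[use])
  lv <- d[use]
  n_i <- tabulate(lv, n_bins)
  s_i <- rep(0, n_bins)
  agg <- tapply(diffs, lv, sum)
  s_i[as.integer(names(agg))] <- agg
  data.frame(level = seq_len(n_bins), n = n_i, p = n_i / sum(n_i), s = s_i)
}

#' NGTDM features (Coarseness, Contrast, Busyness, Complexity, Strength)
#'
#' Conventions: sums run over present levels only; with fewer than two
#' present levels Contrast, Busyness and Strength are 0; the Coarseness and
#' Strength denominators carry a machine-epsilon guard against constant
#' regions.
#'
#' @inheritParams ngtdm_table
#' @return named numeric vector of the 5 NGTDM features.
#' @export
ngtdm_features <- function(d, n_bins, dist = 1) {
  tb <- ngtdm_table(d, n_bins, dist)
  pres <- tb[tb$n > 0, ]
  np <- nrow(pres)
  ntot <- sum(pres$n)
  eps <- .Machine$double.eps
  i <- pres$level; p <- pres$p; s <- pres$s
  coarseness <- 1 / (eps + sum(p * s))
  if (np < 2) {
    return(c(coarseness = coarseness, contrast = 0, busyness = 0,
             complexity = 0, strength = 0))
  }
  dij2 <- outer(i, i, function(a, b) (a - b)^2)
  pij <- outer(p, p)
  contrast <- (sum(pij * dij2) / (np * (np - 1))) * (sum(s) / ntot)
  busy_den <- sum(abs(outer(i * p, i * p, `-`)))
  busyness <- if (busy_den > 0) sum(p * s) / busy_den else 0
  absd <- sqrt(dij2)
  psi <- p * s
  cplx <- sum(absd * (outer(psi, rep(1, np)) + outer(rep(1, np), psi)) /
                (outer(p, rep(1, np)) + outer(rep(1, np), p))) / ntot
  strength <- sum((outer(p, rep(1, np)) + outer(rep(1, np), p)) * dij2) /
    (eps + sum(s))
  c(coarseness = coarseness, contrast = contrast, busyness = busyness,
    complexity = cplx, strength = strength)
}

# --------------------------------------------------------------- NGLDM ----

#' Neighbouring grey-level dependence matrix
#'
#' The dependence count of a pixel is the number of in-mask 8-neighbours
#' whose absolute level difference is `<= alpha`; the matrix counts pixels
#' over (level, dependence count + 1), so entries sum to the in-mask pixel
#' count.
#'
#' @inheritParams glcm_matrix
#' @param alpha coarseness tolerance on level differences (default 0).
#' @return counts matrix (levels x dependence count + 1).
#' @export
ngldm_matrix <- function(d, n_bins, alpha = 0) {
  mask <- !is.na(d)
  if (!any(mask)) stop("empty mask")
  dep <- matrix(0L, nrow(d), ncol(d))
  for (o in chebyshev_offsets(1)) {
    s <- shift_matrix(d, o[1], o[2])
    dep <- dep + (!is.na(s) & !is.na(d) & abs(s - d) <= alpha)
  }
  k <- dep[mask] + 1L
  lv <- d[mask]
  m <- matrix(0, n_bins, max(k))
  cnt <- table(factor(lv, levels = seq_len(n_bins)), factor(k, levels = seq_len(max(k))))
  m[, ] <- as.numeric(cnt)
  m
}

ngldm_names <- c(
  "low_dependence_emphasis", "high_dependence_emphasis",
  "low_grey_level_count_emphasis", "high_grey_level_count_emphasis",
  "low_dependence_low_grey_level_emphasis",
  "low_dependence_high_grey_level_emphasis",
  "high_dependence_low_grey_level_emphasis",
  "high_dependence_high_grey_level_emphasis",
  "grey_level_non_uniformity", "grey_level_non_uniformity_normalised",
  "dependence_count_non_uniformity",
  "dependence_count_non_uniformity_normalised",
  "dependence_count_percentage", "grey_level_variance",
  "dependence_count_variance", "dependence_count_entropy",
  "dependence_count_energy")

#' NGLDM features
#' @inheritParams ngldm_matrix
#' @return named numeric vector of the 17 NGLDM features.
#' @export
ngldm_features <- function(d, n_bins, alpha = 0) {
  npix <- sum(!is.na(d))
  f <- rlm_skeleton(ngldm_matrix(d, n_bins, alpha), npix, with_energy = TRUE)
  stats::setNames(f, ngldm_names)
}
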