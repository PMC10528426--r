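# Independent brute-force oracles for the texture matrix families and the
# scalar statistics. Deliberately written as plain per-pixel loops so they
# share no code path with the implementation they check.

oracle_glcm <- function(lv, n_bins, dir, distance = 1) {
  M <- matrix(0, n_bins, n_bins)
  h <- nrow(lv); w <- ncol(lv)
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c])) next
    r2 <- r + dir[2] * distance; c2 <- c + dir[1] * distance
    if (r2 < 1 || r2 > h || c2 < 1 || c2 > w || is.na(lv[r2, c2])) next
    i <- lv[r, c]; j <- lv[r2, c2]
    M[i, j] <- M[i, j] + 1
    M[j, i] <- M[j, i] + 1
  }
  M
}

oracle_runs <- function(lv, dir) {
  h <- nrow(lv); w <- ncol(lv)
  runs <- list()
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c])) next
    pr <- r - dir[2]; pc <- c - dir[1]
    prev_same <- pr >= 1 && pr <= h && pc >= 1 && pc <= w &&
      !is.na(lv[pr, pc]) && lv[pr, pc] == lv[r, c]
    if (prev_same) next  # not a run start
    len <- 0; rr <- r; cc <- c
    while (rr >= 1 && rr <= h && cc >= 1 && cc <= w &&
           !is.na(lv[rr, cc]) && lv[rr, cc] == lv[r, c]) {
      len <- len + 1; rr <- rr + dir[2]; cc <- cc + dir[1]
    }
    runs[[length(runs) + 1]] <- c(lv[r, c], len)
  }
  if (length(runs) == 0) return(matrix(numeric(0), 0, 2))
  do.call(rbind, runs)
}

oracle_runs_matrix <- function(lv, n_bins, dir) {
  rn <- oracle_runs(lv, dir)
  jmax <- max(1, rn[, 2])
  M <- matrix(0, n_bins, jmax)
  for (q in seq_len(nrow(rn))) M[rn[q, 1], rn[q, 2]] <- M[rn[q, 1], rn[q, 2]] + 1
  M
}

# Stack-based connected-component labelling of equal-level cells.
oracle_zones <- function(lv, connectivity = 8) {
  h <- nrow(lv); w <- ncol(lv)
  offs <- if (connectivity == 8) {
    list(c(-1,-1), c(-1,0), c(-1,1), c(0,-1), c(0,1), c(1,-1), c(1,0), c(1,1))
  } else list(c(-1,0), c(1,0), c(0,-1), c(0,1))
  lab <- matrix(NA_integer_, h, w)
  nz <- 0
  zones <- list()
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c]) || !is.na(lab[r, c])) next
    nz <- nz + 1
    stack <- list(c(r, c)); lab[r, c] <- nz
    cells <- list()
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      cells[[length(cells) + 1]] <- p
      for (o in offs) {
        rr <- p[1] + o[1]; cc <- p[2] + o[2]
        if (rr < 1 || rr > h || cc < 1 || cc > w) next
        if (is.na(lv[rr, cc]) || !is.na(lab[rr, cc])) next
        if (lv[rr, cc] == lv[r, c]) {
          lab[rr, cc] <- nz
          stack[[length(stack) + 1]] <- c(rr, cc)
        }
      }
    }
    zones[[nz]] <- list(level = lv[r, c], cells = do.call(rbind, cells))
  }
  list(labels = lab, zones = zones)
}

oracle_glszm <- function(lv, n_bins, connectivity = 8) {
  z <- oracle_zones(lv, connectivity)$zones
  sizes <- vapply(z, function(q) nrow(q$cells), numeric(1))
  M <- matrix(0, n_bins, max(1, sizes))
  for (q in seq_along(z)) {
    M[z[[q]]$level, sizes[q]] <- M[z[[q]]$level, sizes[q]] + 1
  }
  M
}

# Multi-source BFS city-block distance from outside-mask (minimum 1).
oracle_border_distance <- function(lv) {
  h <- nrow(lv); w <- ncol(lv)
  dist <- matrix(Inf, h, w)
  queue <- list()
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c])) next
    nb_out <- r == 1 || r == h || c == 1 || c == w ||
      is.na(lv[r - 1, c]) || is.na(lv[r + 1, c]) ||
      is.na(lv[r, c - 1]) || is.na(lv[r, c + 1])
    if (nb_out) { dist[r, c] <- 1; queue[[length(queue) + 1]] <- c(r, c) }
  }
  while (length(queue)) {
    p <- queue[[1]]; queue[[1]] <- NULL
    for (o in list(c(-1,0), c(1,0), c(0,-1), c(0,1))) {
      rr <- p[1] + o[1]; cc <- p[2] + o[2]
      if (rr < 1 || rr > h || cc < 1 || cc > w) next
      if (is.na(lv[rr, cc])) next
      if (dist[rr, cc] > dist[p[1], p[2]] + 1) {
        dist[rr, cc] <- dist[p[1], p[2]] + 1
        queue[[length(queue) + 1]] <- c(rr, cc)
      }
    }
  }
  dist
}

oracle_gldzm <- function(lv, n_bins, connectivity = 8) {
  z <- oracle_zones(lv, connectivity)$zones
  dist <- oracle_border_distance(lv)
  dmin <- vapply(z, function(q) {
    min(dist[q$cells])
  }, numeric(1))
  M <- matrix(0, n_bins, max(1, dmin))
  for (q in seq_along(z)) M[z[[q]]$level, dmin[q]] <- M[z[[q]]$level, dmin[q]] + 1
  M
}

oracle_ngtdm <- function(lv, n_bins, dist = 1) {
  h <- nrow(lv); w <- ncol(lv)
  n_i <- rep(0, n_bins); s_i <- rep(0, n_bins)
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c])) next
    nb <- c()
    for (dr in -dist:dist) for (dc in -dist:dist) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && !is.na(lv[rr, cc])) {
        nb <- c(nb, lv[rr, cc])
      }
    }
    if (length(nb) == 0) next
    i <- lv[r, c]
    n_i[i] <- n_i[i] + 1
    s_i[i] <- s_i[i] + abs(i - mean(nb))
  }
  list(n = n_i, s = s_i)
}

oracle_ngldm <- function(lv, n_bins, alpha = 0) {
  h <- nrow(lv); w <- ncol(lv)
  recs <- list()
  for (r in 1:h) for (c in 1:w) {
    if (is.na(lv[r, c])) next
    k <- 0
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0 && dc == 0) next
      rr <- r + dr; cc <- c + dc
      if (rr >= 1 && rr <= h && cc >= 1 && cc <= w && !is.na(lv[rr, cc]) &&
          abs(lv[rr, cc] - lv[r, c]) <= alpha) k <- k + 1
    }
    recs[[length(recs) + 1]] <- c(lv[r, c], k + 1)
  }
  recs <- do.call(rbind, recs)
  M <- matrix(0, n_bins, max(recs[, 2]))
  for (q in seq_len(nrow(recs))) {
    M[recs[q, 1], recs[q, 2]] <- M[recs[q, 1], recs[q, 2]] + 1
  }
  M
}

oracle_auc <- function(scores, labels, positive = "AMD") {
  ip <- which(labels == positive); im <- which(labels != positive)
  tot <- 0
  for (i in ip) for (j in im) {
    tot <- tot + (scores[i] > scores[j]) + 0.5 * (scores[i] == scores[j])
  }
  tot / (length(ip) * length(im))
}

oracle_icc_aov <- function(m) {
  df <- data.frame(y = as.vector(m),
                   case = factor(rep(seq_len(nrow(m)), ncol(m))))
  tab <- summary(stats::aov(y ~ case, data = df))[[1]]
  msb <- tab["case", "Mean Sq"]; msw <- tab["Residuals", "Mean Sq"]
  k <- ncol(m)
  (msb - msw) / (msb + (k - 1) * msw)
}

oracle_circle_count <- function(center, radius, extent) {
  n <- 0
  for (x in 0:(extent[1] - 1)) for (y in 0:(extent[2] - 1)) {
    if ((x - center[1])^2 + (y - center[2])^2 <= radius^2) n <- n + 1
  }
  n
}

oracle_dice_circles <- function(c1, c2, radius, extent) {
  a <- 0; b <- 0; ab <- 0
  for (x in 0:(extent[1] - 1)) for (y in 0:(extent[2] - 1)) {
    ina <- (x - c1[1])^2 + (y - c1[2])^2 <= radius^2
    inb <- (x - c2[1])^2 + (y - c2[2])^2 <= radius^2
    a <- a + ina; b <- b + inb; ab <- ab + (ina && inb)
  }
  2 * ab / (a + b)
}

# Random small discretised grid with a random mask; guarantees at least one
# horizontally adjacent in-mask pair.
random_grid <- function(n_bins = 5, max_side = 8) {
  repeat {
    h <- sample(2:max_side, 1); w <- sample(2:max_side, 1)
    lv <- matrix(sample.int(n_bins, h * w, replace = TRUE), h, w)
    lv[matrix(stats::runif(h * w) < 0.25, h, w)] <- NA_integer_
    ok <- FALSE
    for (r in 1:h) for (c in 1:(w - 1)) {
      if (!is.na(lv[r, c]) && !is.na(lv[r, c + 1])) ok <- TRUE
    }
    if (ok) return(lv)
  }
}

pad_to <- function(M, ncol_out) {
  if (ncol(M) >= ncol_out) return(M)
  cbind(M, matrix(0, nrow(M), ncol_out - ncol(M)))
}

expect_matrix_equal <- function(a, b, tol = 1e-8) {
  jm <- max(ncol(a), ncol(b))
  expect_equal(pad_to(a, jm), pad_to(b, jm), tolerance = tol,
               ignore_attr = TRUE)
}
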