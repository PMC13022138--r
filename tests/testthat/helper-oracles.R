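# Brute-force reference implementations used to validate the fast feature
# code. Everything here is written as literal per-pixel / per-zone loops with
# no shared code paths with the package internals.

# seeded evaluation that restores the caller's RNG state (test-local copy)
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  code
}

# connected components of equal values inside a mask, BFS, raster seed order
oracle_components <- function(values, mask, connectivity = 8) {
  nr <- nrow(values); nc <- ncol(values)
  offs <- if (connectivity == 8) {
    rbind(c(-1, -1), c(-1, 0), c(-1, 1), c(0, -1), c(0, 1),
          c(1, -1), c(1, 0), c(1, 1))
  } else rbind(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (cc0 in seq_len(nc)) for (rr0 in seq_len(nr)) {
    if (mask[rr0, cc0] != 1 || lab[rr0, cc0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(rr0, cc0)); lab[rr0, cc0] <- nxt
    while (length(queue)) {
      p <- queue[[1]]; queue <- queue[-1]
      for (k in seq_len(nrow(offs))) {
        r2 <- p[1] + offs[k, 1]; c2 <- p[2] + offs[k, 2]
        if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
        if (mask[r2, c2] == 1 && lab[r2, c2] == 0L &&
            values[r2, c2] == values[p[1], p[2]]) {
          lab[r2, c2] <- nxt
          queue[[length(queue) + 1]] <- c(r2, c2)
        }
      }
    }
  }
  lab
}

# size-zone matrix by explicit zone enumeration
oracle_glszm <- function(levels, mask, n_gray, connectivity = 8) {
  lev <- levels; lev[is.na(lev)] <- -1L
  lab <- oracle_components(lev, mask, connectivity)
  ks <- setdiff(unique(as.vector(lab)), 0L)
  sizes <- vapply(ks, function(k) sum(lab == k), integer(1))
  P <- matrix(0, n_gray, max(sizes))
  for (idx in seq_along(ks)) {
    g <- lev[lab == ks[idx]][1]
    P[g, sizes[idx]] <- P[g, sizes[idx]] + 1
  }
  P
}

# dependence matrix by explicit per-pixel neighbor counting
oracle_gldm <- function(levels, mask, n_gray, alpha = 0, delta = 1) {
  nr <- nrow(levels); nc <- ncol(levels)
  recs <- list(); n <- 0L
  for (cc0 in seq_len(nc)) for (rr0 in seq_len(nr)) {
    if (mask[rr0, cc0] != 1) next
    d <- 0L
    for (dr in -delta:delta) for (dc in -delta:delta) {
      if (dr == 0 && dc == 0) next
      r2 <- rr0 + dr; c2 <- cc0 + dc
      if (r2 < 1 || r2 > nr || c2 < 1 || c2 > nc) next
      if (mask[r2, c2] == 1 &&
          abs(levels[r2, c2] - levels[rr0, cc0]) <= alpha) d <- d + 1L
    }
    n <- n + 1L
    recs[[n]] <- c(as.integer(levels[rr0, cc0]), d + 1L)
  }
  dmax <- max(vapply(recs, `[`, integer(1), 2))
  P <- matrix(0, n_gray, dmax)
  for (r in recs) P[r[1], r[2]] <- P[r[1], r[2]] + 1
  P
}

# the 16 size-zone statistics from first principles (double loops)
oracle_glszm_features <- function(P, n_pixels) {
  Nz <- sum(P)
  sae <- lae <- gln <- szn <- lgl <- hgl <- salg <- sahg <- lalg <- lahg <- 0
  for (i in seq_len(nrow(P))) for (s in seq_len(ncol(P))) {
    v <- P[i, s]
    sae <- sae + v / s^2; lae <- lae + v * s^2
    lgl <- lgl + v / i^2; hgl <- hgl + v * i^2
    salg <- salg + v / (i^2 * s^2); sahg <- sahg + v * i^2 / s^2
    lalg <- lalg + v * s^2 / i^2; lahg <- lahg + v * i^2 * s^2
  }
  for (i in seq_len(nrow(P))) gln <- gln + sum(P[i, ])^2
  for (s in seq_len(ncol(P))) szn <- szn + sum(P[, s])^2
  mu_i <- 0; mu_s <- 0
  for (i in seq_len(nrow(P))) for (s in seq_len(ncol(P))) {
    mu_i <- mu_i + (P[i, s] / Nz) * i; mu_s <- mu_s + (P[i, s] / Nz) * s
  }
  glv <- zv <- ent <- 0
  for (i in seq_len(nrow(P))) for (s in seq_len(ncol(P))) {
    p <- P[i, s] / Nz
    glv <- glv + p * (i - mu_i)^2
    zv <- zv + p * (s - mu_s)^2
    if (p > 0) ent <- ent - p * log2(p)
  }
  c(sae / Nz, lae / Nz, gln / Nz, gln / Nz^2, szn / Nz, szn / Nz^2,
    Nz / n_pixels, glv, zv, ent, lgl / Nz, hgl / Nz, salg / Nz, sahg / Nz,
    lalg / Nz, lahg / Nz)
}

# the 14 dependence statistics from first principles
oracle_gldm_features <- function(P) {
  Nz <- sum(P)
  sde <- lde <- gln <- dn <- lgl <- hgl <- sdlg <- sdhg <- ldlg <- ldhg <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    v <- P[i, j]
    sde <- sde + v / j^2; lde <- lde + v * j^2
    lgl <- lgl + v / i^2; hgl <- hgl + v * i^2
    sdlg <- sdlg + v / (i^2 * j^2); sdhg <- sdhg + v * i^2 / j^2
    ldlg <- ldlg + v * j^2 / i^2; ldhg <- ldhg + v * i^2 * j^2
  }
  for (i in seq_len(nrow(P))) gln <- gln + sum(P[i, ])^2
  for (j in seq_len(ncol(P))) dn <- dn + sum(P[, j])^2
  mu_i <- 0; mu_j <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    mu_i <- mu_i + (P[i, j] / Nz) * i; mu_j <- mu_j + (P[i, j] / Nz) * j
  }
  glv <- dv <- ent <- 0
  for (i in seq_len(nrow(P))) for (j in seq_len(ncol(P))) {
    p <- P[i, j] / Nz
    glv <- glv + p * (i - mu_i)^2
    dv <- dv + p * (j - mu_j)^2
    if (p > 0) ent <- ent - p * log2(p)
  }
  c(sde / Nz, lde / Nz, gln / Nz, dn / Nz, dn / Nz^2, glv, dv, ent,
    lgl / Nz, hgl / Nz, sdlg / Nz, sdhg / Nz, ldlg / Nz, ldhg / Nz)
}

# per-pixel central-difference gradient with explicit edge clamping
oracle_gradient <- function(img) {
  nr <- nrow(img); nc <- ncol(img)
  out <- matrix(0, nr, nc)
  for (r in seq_len(nr)) for (c in seq_len(nc)) {
    gx <- img[min(r + 1, nr), c] - img[max(r - 1, 1), c]
    gy <- img[r, min(c + 1, nc)] - img[r, max(c - 1, 1)]
    out[r, c] <- sqrt(gx^2 + gy^2)
  }
  out
}

# draw a random quantized ROI: random levels on a random blobby mask
random_quantized_roi <- function(seed, size = 8, n_gray = 4) {
  with_seed(seed, {
    lev <- matrix(sample.int(n_gray, size * size, replace = TRUE), size, size)
    mask <- matrix(as.numeric(runif(size * size) < 0.8), size, size)
    if (sum(mask) < 4) mask[1:2, 1:2] <- 1
    lev[mask == 0] <- NA_integer_
    list(levels = lev, mask = mask, n_gray = as.integer(n_gray))
  })
}

# small deterministic test image: dark disc on a light background
disc_image <- function(h = 48, w = 48, radius = 12, dark = 60, light = 200) {
  img <- array(light, c(h, w, 3))
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  inside <- (g$r - h / 2)^2 + (g$c - w / 2)^2 <= radius^2
  for (k in 1:3) {
    ch <- img[, , k]
    ch[cbind(g$r[inside], g$c[inside])] <- dark
    img[, , k] <- ch
  }
  img
}

disc_mask <- function(h = 48, w = 48, radius = 12) {
  g <- expand.grid(r = seq_len(h), c = seq_len(w))
  matrix(as.numeric((g$r - h / 2)^2 + (g$c - w / 2)^2 <= radius^2), h, w)
}
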