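# Shape and scene fixtures, all built in code.

disk_mask <- function(r = 50, pad = 10) {
  n <- 2 * (r + pad)
  ctr <- n / 2
  d <- sqrt(outer((1:n - ctr)^2, (1:n - ctr)^2, "+"))
  d <= r
}

rect_mask <- function(rows = 20, cols = 40, pad = 20) {
  m <- matrix(FALSE, rows + 2 * pad, cols + 2 * pad)
  m[pad + seq_len(rows), pad + seq_len(cols)] <- TRUE
  m
}

plus_mask <- function(n = 40, w = 3) {
  m <- matrix(FALSE, n, n)
  mid <- n %/% 2
  m[(mid - w %/% 2):(mid + w %/% 2), 5:(n - 5)] <- TRUE
  m[5:(n - 5), (mid - w %/% 2):(mid + w %/% 2)] <- TRUE
  m
}

x_mask <- function(n = 41) {
  m <- matrix(FALSE, n, n)
  for (i in 1:n) {
    m[i, max(1, i - 1):min(n, i + 1)] <- TRUE
    j <- n + 1 - i
    m[i, max(1, j - 1):min(n, j + 1)] <- TRUE
  }
  m
}

rotate_mask <- function(mask, angle_deg, out = 160) {
  img <- EBImage::rotate(EBImage::Image(mask * 1), angle_deg,
                         output.dim = c(out, out), bg.col = 0)
  as.matrix(EBImage::imageData(img)) > 0.5
}

# small simulated lot shared across tests (deterministic)
tiny_lot <- local({
  lot <- NULL
  function() {
    if (is.null(lot)) lot <<- simulate_lot(sim_config(rng_seed = 7, n_rows = 1,
                                                      n_cols = 2))
    lot
  }
})

# brute-force endpoint / branch-point classification oracle
neighbor_count_oracle <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  out <- matrix(0L, nr, nc)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!mask[i, j]) next
    cnt <- 0L
    for (di in -1:1) for (dj in -1:1) {
      if (di == 0 && dj == 0) next
      ii <- i + di; jj <- j + dj
      if (ii >= 1 && jj >= 1 && ii <= nr && jj <= nc && mask[ii, jj])
        cnt <- cnt + 1L
    }
    out[i, j] <- cnt
  }
  out
}

# exhaustive pairing oracle for crossing resolution (independent angle math)
pairing_oracle <- function(angles_deg) {
  k <- length(angles_deg)
  pair_dev <- function(a, b) {
    d <- abs(((angles_deg[a] - angles_deg[b]) %% 360))
    d <- min(d, 360 - d)
    abs(d - 180)
  }
  if (k == 3) {
    cand <- list(c(1, 2), c(1, 3), c(2, 3))
    dev <- sapply(cand, function(p) pair_dev(p[1], p[2]))
    return(list(pairs = list(cand[[which.min(dev)]]),
                score = min(dev)))
  }
  cand <- list(list(c(1, 2), c(3, 4)), list(c(1, 3), c(2, 4)),
               list(c(1, 4), c(2, 3)))
  dev <- sapply(cand, function(pp)
    pair_dev(pp[[1]][1], pp[[1]][2]) + pair_dev(pp[[2]][1], pp[[2]][2]))
  single <- sapply(cand, function(pp)
    min(pair_dev(pp[[1]][1], pp[[1]][2]), pair_dev(pp[[2]][1], pp[[2]][2])))
  best <- order(round(dev, 6), round(single, 6))[1]
  list(pairs = cand[[best]], score = dev[best])
}

region_from_angles <- function(angles_deg) {
  arms <- lapply(angles_deg, function(a) {
    rad <- a * pi / 180
    list(dir = c(-cos(rad), sin(rad)), end = c(0, 0))
  })
  structure(list(center = c(0, 0), arms = arms, order = length(arms)),
            class = "crossing_region")
}

canon_pairs <- function(pairs) {
  ps <- lapply(pairs, sort)
  ps[order(vapply(ps, `[`, numeric(1), 1))]
}
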