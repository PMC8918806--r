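# Independent brute-force oracles used across the suite. These stay
# deliberately naive (direct enumeration) so they cannot share a defect
# with the implementation under test.

# exhaustive Otsu: best split t of an integer-valued image (levels 0..L)
# maximising between-class variance of classes {<= t} vs {> t}
brute_otsu <- function(values) {
  lev <- sort(unique(values))
  best_t <- NA
  best_v <- -Inf
  n <- length(values)
  for (t in lev[-length(lev)]) {
    g0 <- values[values <= t]
    g1 <- values[values > t]
    w0 <- length(g0) / n
    w1 <- 1 - w0
    v <- w0 * w1 * (mean(g0) - mean(g1))^2
    if (v > best_v + 1e-12) {
      best_v <- v
      best_t <- t
    }
  }
  best_t
}

# brute-force Euclidean distance map: for each foreground voxel the
# minimum distance to any background voxel
brute_edm <- function(mask) {
  d <- dim(mask)
  out <- array(0, d)
  bg <- which(mask == 0L, arr.ind = TRUE)
  fg <- which(mask == 1L, arr.ind = TRUE)
  for (i in seq_len(nrow(fg))) {
    v <- fg[i, ]
    out[v[1], v[2], v[3]] <- sqrt(min(rowSums(sweep(bg, 2, v)^2)))
  }
  out
}

# exhaustive overlap counts
brute_overlap <- function(m, t) {
  nM <- sum(m == 1L)
  nT <- sum(t == 1L)
  nMT <- sum(m == 1L & t == 1L)
  list(dice = 2 * nMT / (nM + nT), jaccard = nMT / (nM + nT - nMT),
       total_overlap = nMT / nT)
}

# brute-force average-linkage agglomeration with correlation distance;
# returns merge heights sorted (tree shape check without ordering details)
brute_average_linkage_heights <- function(mat) {
  n <- nrow(mat)
  dm <- as.matrix(as.dist(1 - cor(t(mat))))
  clusters <- as.list(seq_len(n))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    best_d <- Inf
    for (i in seq_len(length(clusters) - 1L))
      for (j in (i + 1L):length(clusters)) {
        dd <- mean(dm[clusters[[i]], clusters[[j]], drop = FALSE])
        if (dd < best_d - 1e-12) {
          best_d <- dd
          best <- c(i, j)
        }
      }
    heights <- c(heights, best_d)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}

# small random binary mask with both phases present
random_mask <- function(d, p = 0.5) {
  m <- array(rbinom(prod(d), 1, p), d)
  if (all(m == 1L)) m[1] <- 0L
  if (all(m == 0L)) m[1] <- 1L
  storage.mode(m) <- "integer"
  m
}
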