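# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force scans, hand formulas, enumeration.

# exhaustive between-class-variance scan over histogram bin edges,
# computing class statistics directly from the data
brute_otsu <- function(values, n_bins = 256L) {
  rng <- range(values)
  edges <- seq(rng[1], rng[2], length.out = n_bins + 1L)
  best <- -Inf; best_edge <- NA_real_
  for (e in edges[-c(1, length(edges))]) {
    lo <- values[values <= e]; hi <- values[values > e]
    if (length(lo) == 0L || length(hi) == 0L) next
    bcv <- length(lo) * length(hi) * (mean(lo) - mean(hi))^2
    if (bcv > best) { best <- bcv; best_edge <- e }
  }
  best_edge
}

# per-pixel histogram entropy in a disk window, replicate padding
brute_entropy_at <- function(gray, i, j, radius) {
  h <- nrow(gray); w <- ncol(gray)
  vals <- c()
  for (di in -radius:radius) for (dj in -radius:radius) {
    if (di^2 + dj^2 > radius^2) next
    ii <- min(max(i + di, 1L), h); jj <- min(max(j + dj, 1L), w)
    vals <- c(vals, gray[ii, jj])
  }
  p <- table(vals) / length(vals)
  -sum(p * log2(p))
}

# Jonckheere-Terpstra statistic, written independently of the package
jt_stat_oracle <- function(values, groups) {
  lev <- sort(unique(groups))
  j <- 0
  for (k in seq_along(lev)[-length(lev)]) for (l in (k + 1):length(lev)) {
    for (a in values[groups == lev[k]]) for (b in values[groups == lev[l]])
      j <- j + (a < b) + 0.5 * (a == b)
  }
  j
}

# exact JT p by full enumeration of assignments for 3 groups of size 2
jt_exact_p_222 <- function(values) {
  idx <- seq_along(values)
  js <- c()
  for (g1 in combn(idx, 2, simplify = FALSE)) {
    rest <- setdiff(idx, g1)
    for (g2 in combn(rest, 2, simplify = FALSE)) {
      g3 <- setdiff(rest, g2)
      lab <- integer(6); lab[g1] <- 1L; lab[g2] <- 2L; lab[g3] <- 3L
      js <- c(js, jt_stat_oracle(values, lab))
    }
  }
  js
}

# Breslow partial log-likelihood with delayed-entry risk sets,
# single covariate
breslow_loglik <- function(beta, entry, exit, event, x) {
  ll <- 0
  for (i in which(event == 1)) {
    risk <- entry < exit[i] & exit[i] <= exit
    ll <- ll + beta * x[i] - log(sum(exp(beta * x[risk])))
  }
  ll
}

# Ward agglomeration by the explicit centroid formula
# d(A, B) = sqrt(2 |A| |B| / (|A| + |B|)) * ||centroid_A - centroid_B||
ward_heights_oracle <- function(points) {
  clusters <- lapply(seq_len(nrow(points)), function(i) i)
  heights <- c()
  while (length(clusters) > 1L) {
    best <- Inf; pair <- NULL
    for (a in seq_along(clusters)) for (b in seq_along(clusters)) {
      if (a >= b) next
      na <- length(clusters[[a]]); nb <- length(clusters[[b]])
      ca <- colMeans(points[clusters[[a]], , drop = FALSE])
      cb <- colMeans(points[clusters[[b]], , drop = FALSE])
      d <- sqrt(2 * na * nb / (na + nb)) * sqrt(sum((ca - cb)^2))
      if (d < best) { best <- d; pair <- c(a, b) }
    }
    heights <- c(heights, best)
    clusters[[pair[1]]] <- c(clusters[[pair[1]]], clusters[[pair[2]]])
    clusters[[pair[2]]] <- NULL
  }
  heights
}

# classical pooled two-sample t, textbook formula
pooled_t_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  tt <- (mean(b) - mean(a)) / sqrt(sp2 * (1 / na + 1 / nb))
  list(t = tt, p = 2 * pt(abs(tt), na + nb - 2, lower.tail = FALSE))
}

# rotate an H x W x 3 image clockwise by 90 degrees
rot90_img <- function(a) {
  out <- array(0L, dim = c(dim(a)[2], dim(a)[1], 3))
  for (ch in 1:3) out[, , ch] <- t(a[nrow(a):1, , ch])
  out
}

# small labelled expression matrix
make_expr <- function(values, genes, samples) {
  m <- matrix(values, nrow = length(genes), byrow = TRUE,
              dimnames = list(genes, samples))
  m
}
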