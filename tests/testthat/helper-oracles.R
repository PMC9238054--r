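# Independent brute-force oracles used to verify the implementation.
# These deliberately share no code with the package internals.

# Otsu threshold by exhaustive search over all 255 cuts of a 256-bin
# histogram: maximize w0 * w1 * (mu0 - mu1)^2 computed directly from the
# binned values.
otsu_brute <- function(values) {
  v <- values[is.finite(values)]
  lo <- min(v); hi <- max(v)
  width <- (hi - lo) / 256
  bin <- pmin(floor((v - lo) / width) + 1, 256)
  mids <- lo + (bin - 0.5) * width
  best <- -Inf; best_cuts <- integer(0)
  for (t in 1:255) {
    below <- mids[bin <= t]; above <- mids[bin > t]
    if (!length(below) || !length(above)) next
    w0 <- length(below) / length(v)
    sb <- w0 * (1 - w0) * (mean(below) - mean(above))^2
    if (sb > best + 1e-15) {
      best <- sb; best_cuts <- t
    } else if (abs(sb - best) <= 1e-15) {
      best_cuts <- c(best_cuts, t)
    }
  }
  lo + mean(best_cuts) * width
}

# Paired t-test from the closed form.
paired_t_oracle <- function(x, y) {
  d <- x - y
  n <- length(d)
  tt <- mean(d) / (sd(d) / sqrt(n))
  list(t = tt, p = 2 * pt(-abs(tt), n - 1))
}

# OLS slope/intercept and slope p-value from the closed form.
ols_oracle <- function(x, y) {
  n <- length(x)
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  rss <- sum((y - alpha - beta * x)^2)
  se <- sqrt(rss / (n - 2) / sum((x - mean(x))^2))
  tt <- beta / se
  list(beta = beta, intercept = alpha, p = 2 * pt(-abs(tt), n - 2))
}

# Spearman rho as Pearson correlation of mid-ranks, p via the
# t-approximation.
spearman_oracle <- function(x, y) {
  rx <- rank(x); ry <- rank(y)
  n <- length(x)
  r <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(rho = r, p = 2 * pt(-abs(tt), n - 2))
}

# Per-pixel brute-force flow histogram for a hand-built label map.
histogram_brute <- function(mbr, valid, labels, edges = c(0, 5, 10, 15, 20, Inf),
                            cutoff = 0.5) {
  k <- max(labels)
  means <- rep(NA_real_, k)
  for (l in seq_len(k)) {
    in_l <- labels == l
    frac <- sum(valid & in_l) / sum(in_l)
    if (frac >= cutoff && any(valid & in_l)) {
      means[l] <- mean(mbr[valid & in_l])
    }
  }
  def <- means[!is.na(means)]
  counts <- numeric(length(edges) - 1)
  for (m in def) {
    for (b in seq_len(length(edges) - 1)) {
      if (m >= edges[b] && m < edges[b + 1]) counts[b] <- counts[b] + 1
    }
  }
  list(percent = 100 * counts / length(def), n_defined = length(def),
       means = means)
}

# Is every label a single 4-connected component?
labels_connected <- function(labels) {
  for (l in unique(as.vector(labels))) {
    cells <- which(labels == l, arr.ind = TRUE)
    seen <- rep(FALSE, nrow(cells))
    key <- paste(cells[, 1], cells[, 2])
    idx <- setNames(seq_len(nrow(cells)), key)
    queue <- 1L; seen[1] <- TRUE
    while (length(queue)) {
      cur <- cells[queue[1], ]; queue <- queue[-1]
      for (d in list(c(-1, 0), c(1, 0), c(0, -1), c(0, 1))) {
        nb <- idx[paste(cur[1] + d[1], cur[2] + d[2])]
        if (!is.na(nb) && !seen[nb]) {
          seen[nb] <- TRUE
          queue <- c(queue, nb)
        }
      }
    }
    if (!all(seen)) return(FALSE)
  }
  TRUE
}
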