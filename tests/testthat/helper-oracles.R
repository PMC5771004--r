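# Independent oracles, deliberately written with different algorithms than
# the package implementations they check.

# Otsu by explicit loop over every candidate threshold: maximise the
# between-class variance of {grey <= t} vs {grey > t}, lowest maximiser wins.
oracle_otsu <- function(grey) {
  v <- as.integer(grey)
  best_t <- NA_integer_
  best <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]
    hi <- v[v > t]
    if (length(lo) == 0L || length(hi) == 0L) next
    w0 <- length(lo) / length(v)
    bcv <- w0 * (1 - w0) * (mean(lo) - mean(hi))^2
    if (bcv > best + 1e-12) {
      best <- bcv
      best_t <- t
    }
  }
  best_t
}

# 8-connected component count by recursive-style flood fill over a queue.
oracle_component_count <- function(mask) {
  seen <- matrix(FALSE, nrow(mask), ncol(mask))
  count <- 0L
  for (j in seq_len(ncol(mask))) {
    for (i in seq_len(nrow(mask))) {
      if (!mask[i, j] || seen[i, j]) next
      count <- count + 1L
      queue <- list(c(i, j))
      seen[i, j] <- TRUE
      while (length(queue) > 0L) {
        p <- queue[[1]]
        queue <- queue[-1]
        for (di in -1:1) for (dj in -1:1) {
          ni <- p[1] + di; nj <- p[2] + dj
          if (ni >= 1 && nj >= 1 && ni <= nrow(mask) && nj <= ncol(mask) &&
              mask[ni, nj] && !seen[ni, nj]) {
            seen[ni, nj] <- TRUE
            queue[[length(queue) + 1L]] <- c(ni, nj)
          }
        }
      }
    }
  }
  count
}

# Brute-force k-NN: all pairwise distances computed pair by pair, full sort,
# lowest-index tie rule, majority vote (use odd k so the vote is decisive).
oracle_knn <- function(train, labels, query, k) {
  d <- apply(train, 1, function(row) sqrt(sum((row - query)^2)))
  nb <- order(d)[seq_len(k)]
  m <- sum(labels[nb])
  list(label = as.integer(2 * m > k), score = m / k,
       certainty = max(m, k - m) / k, neighbours = nb)
}

# Mann-Whitney AUC by exhaustive pair counting over all pos x neg pairs.
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) {
    for (q in neg) {
      total <- total + if (p > q) 1 else if (p == q) 0.5 else 0
    }
  }
  total / (length(pos) * length(neg))
}
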