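# Independent naive reference implementations used as oracles. These are
# deliberately written as plain double loops over the textbook definitions,
# sharing no code with the package internals.

naive_bss_wss <- function(x, labels) {
  cls <- sort(unique(labels), method = "radix")
  out <- data.frame(probe_id = rownames(x), bss = NA_real_, wss = NA_real_,
                    stringsAsFactors = FALSE)
  for (g in seq_len(nrow(x))) {
    grand <- mean(x[g, ])
    bss <- 0
    wss <- 0
    for (k in cls) {
      xk <- x[g, labels == k]
      bss <- bss + length(xk) * (mean(xk) - grand)^2
      for (v in xk) wss <- wss + (v - mean(xk))^2
    }
    out$bss[g] <- bss
    out$wss[g] <- wss
  }
  out
}

naive_dlda_fit <- function(x, labels) {
  cls <- sort(unique(labels), method = "radix")
  K <- length(cls)
  n <- ncol(x)
  means <- matrix(NA_real_, nrow(x), K, dimnames = list(rownames(x), cls))
  ss <- numeric(nrow(x))
  for (g in seq_len(nrow(x))) {
    for (k in cls) {
      xk <- x[g, labels == k]
      means[g, k] <- mean(xk)
      for (v in xk) ss[g] <- ss[g] + (v - mean(xk))^2
    }
  }
  list(classes = cls, means = means, pooled_var = ss / (n - K))
}

naive_dlda_predict <- function(fit, xnew) {
  scores <- numeric(length(fit$classes))
  names(scores) <- fit$classes
  for (k in fit$classes) {
    for (g in seq_len(nrow(fit$means)))
      scores[k] <- scores[k] +
        (xnew[g] - fit$means[g, k])^2 / fit$pooled_var[g]
  }
  list(class = fit$classes[which.min(scores)], scores = scores)
}

naive_nearest_centroid <- function(x, labels, xnew) {
  cls <- sort(unique(labels), method = "radix")
  d <- vapply(cls, function(k) {
    sum((xnew - rowMeans(x[, labels == k, drop = FALSE]))^2)
  }, numeric(1))
  cls[which.min(d)]
}

# O(n^3) complete-linkage agglomeration; returns merge heights in order.
naive_complete_linkage_heights <- function(m) {
  d <- as.matrix(dist(m))
  clusters <- as.list(seq_len(nrow(m)))
  heights <- numeric(0)
  while (length(clusters) > 1L) {
    best <- c(NA, NA)
    bestd <- Inf
    for (j in 2:length(clusters)) for (i in 1:(j - 1)) {
      dd <- max(d[clusters[[i]], clusters[[j]]])
      if (dd < bestd) {
        bestd <- dd
        best <- c(i, j)
      }
    }
    heights <- c(heights, bestd)
    clusters[[best[1]]] <- c(clusters[[best[1]]], clusters[[best[2]]])
    clusters[[best[2]]] <- NULL
  }
  heights
}
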