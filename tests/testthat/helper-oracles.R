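# Independent brute-force oracles. Deliberately naive: loops and exhaustive
# search, sharing no code with the implementation they check.

# exhaustive-search Otsu split of integer intensities in 0..maxval:
# tries every cutoff c (class A = values <= c, class B = values > c),
# maximizes between-class variance computed from raw values; ties resolved
# as the midpoint of the maximizing cutoffs; returned as a "vessel < t"
# threshold (cutoff + 1), mirroring the documented convention.
oracle_otsu <- function(values, maxval = 255L) {
  v <- as.vector(values)
  if (length(unique(v)) < 2L) return(NA_real_)
  best_bcv <- -Inf
  best_c <- integer(0)
  for (cc in 0:(maxval - 1L)) {
    a <- v[v <= cc]; b <- v[v > cc]
    if (length(a) == 0L || length(b) == 0L) next
    bcv <- length(a) * length(b) * (mean(a) - mean(b))^2
    if (bcv > best_bcv + 1e-9) {
      best_bcv <- bcv; best_c <- cc
    } else if (abs(bcv - best_bcv) <= 1e-9 * max(1, abs(best_bcv))) {
      best_c <- c(best_c, cc)
    }
  }
  (min(best_c) + max(best_c)) / 2 + 1
}

# recursive-free flood fill labelling with 8-connectivity, one pixel at a
# time off an explicit stack
oracle_label <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  nextlab <- 0L
  for (r0 in seq_len(h)) for (c0 in seq_len(w)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nextlab <- nextlab + 1L
    stack <- list(c(r0, c0))
    lab[r0, c0] <- nextlab
    while (length(stack) > 0L) {
      p <- stack[[length(stack)]]
      stack[[length(stack)]] <- NULL
      for (dr in -1:1) for (dc in -1:1) {
        r <- p[1L] + dr; c <- p[2L] + dc
        if (r >= 1L && r <= h && c >= 1L && c <= w &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nextlab
          stack[[length(stack) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# small-component removal via the flood-fill oracle
oracle_filter_components <- function(mask, min_px) {
  lab <- oracle_label(mask)
  out <- mask
  if (max(lab) == 0L) return(out)
  for (l in seq_len(max(lab))) {
    if (sum(lab == l) < min_px) out[lab == l] <- FALSE
  }
  out
}

# exclusion mask by direct euclidean distance to every saturated pixel
oracle_exclusion <- function(frame, saturation_fraction = 0.99, radius = 5,
                             maxval = 255L) {
  cutoff <- ceiling(saturation_fraction * maxval)
  sat <- frame[, , 1] >= cutoff & frame[, , 2] >= cutoff & frame[, , 3] >= cutoff
  h <- dim(frame)[1L]; w <- dim(frame)[2L]
  out <- matrix(FALSE, h, w)
  satpos <- which(sat, arr.ind = TRUE)
  if (nrow(satpos) == 0L) return(out)
  for (r in seq_len(h)) for (c in seq_len(w)) {
    for (k in seq_len(nrow(satpos))) {
      if (sqrt((r - satpos[k, 1L])^2 + (c - satpos[k, 2L])^2) <= radius) {
        out[r, c] <- TRUE
        break
      }
    }
  }
  out
}

# exhaustive 1-D 2-means of a window: every split of the sorted values,
# minimum within-cluster sum of squares, first minimal split; returns the
# centroid of the cluster containing `center_value`
oracle_two_means <- function(win, center_value) {
  v <- sort(win)
  m <- length(v)
  if (v[1L] == v[m]) return(center_value)
  best <- Inf; best_k <- 1L
  for (k in 1:(m - 1L)) {
    w1 <- v[1:k]; w2 <- v[(k + 1L):m]
    wss <- sum((w1 - mean(w1))^2) + sum((w2 - mean(w2))^2)
    if (wss < best - 1e-12) { best <- wss; best_k <- k }
  }
  if (center_value <= v[best_k]) mean(v[1:best_k]) else mean(v[(best_k + 1L):m])
}
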