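# Independent brute-force oracles. These deliberately share no code with
# the package internals they check.

# Connected-component labeling by queue-based flood fill in plain R.
oracle_label <- function(mask, connectivity) {
  nr <- nrow(mask)
  nc <- ncol(mask)
  nbr <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  labels <- matrix(0L, nr, nc)
  nxt <- 0L
  stack_i <- integer(nr * nc)
  stack_j <- integer(nr * nc)
  for (j in seq_len(nc)) {
    for (i in seq_len(nr)) {
      if (mask[i, j] == 0 || labels[i, j] != 0) next
      nxt <- nxt + 1L
      top <- 1L
      stack_i[1L] <- i
      stack_j[1L] <- j
      labels[i, j] <- nxt
      while (top > 0L) {
        pi <- stack_i[top]
        pj <- stack_j[top]
        top <- top - 1L
        for (k in seq_len(nrow(nbr))) {
          qi <- pi + nbr[k, 1L]
          qj <- pj + nbr[k, 2L]
          if (qi >= 1 && qi <= nr && qj >= 1 && qj <= nc &&
              mask[qi, qj] == 1 && labels[qi, qj] == 0) {
            labels[qi, qj] <- nxt
            top <- top + 1L
            stack_i[top] <- qi
            stack_j[top] <- qj
          }
        }
      }
    }
  }
  labels
}

# Remove foreground components below an area threshold (physical units).
oracle_remove_small <- function(mask, min_area_um2, pixel_size_um) {
  labels <- oracle_label(mask, 8)
  out <- mask
  for (lab in setdiff(unique(as.vector(labels)), 0L)) {
    if (sum(labels == lab) * pixel_size_um^2 < min_area_um2) {
      out[labels == lab] <- 0L
    }
  }
  out
}

# Fill enclosed background components below an area threshold.
oracle_fill_holes <- function(mask, max_area_um2, pixel_size_um) {
  labels <- oracle_label(1L - mask, 4)
  border <- unique(c(labels[1, ], labels[nrow(labels), ],
                     labels[, 1], labels[, ncol(labels)]))
  out <- mask
  for (lab in setdiff(unique(as.vector(labels)), c(0L, border))) {
    if (sum(labels == lab) * pixel_size_um^2 < max_area_um2) {
      out[labels == lab] <- 1L
    }
  }
  out
}

# Exhaustive threshold scan: try every cut point on a grid spanning the
# data (the values themselves, midpoints, and one point beyond each
# extreme), rule "predict poor iff value < cutoff". `bounds` restricts the
# cut-off domain (e.g. c(0, 1) for good-patch fractions).
oracle_best_accuracy <- function(values, is_poor, low_is_poor = TRUE,
                                 bounds = NULL) {
  cand <- sort(unique(c(values, range(values) + c(-1, 1),
                        (head(sort(unique(values)), -1) +
                         sort(unique(values))[-1]) / 2)))
  if (!is.null(bounds)) {
    cand <- c(bounds, cand[cand > bounds[1] & cand < bounds[2]])
  }
  accs <- vapply(cand, function(ct) {
    pred <- if (low_is_poor) values < ct else values > ct
    mean(pred == is_poor)
  }, numeric(1))
  max(accs)
}

random_mask <- function(nr = 50, nc = 50, p = 0.4) {
  matrix(as.integer(runif(nr * nc) < p), nr, nc)
}
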