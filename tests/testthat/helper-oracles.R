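# Independent oracles used across the suite. These are deliberately naive
# implementations kept separate from the package internals.

# Brute-force flood-fill labelling with 8-connectivity (BFS). Labels are
# assigned in column-major order of each component's first pixel, matching
# the canonical order used by label_components().
flood_fill_label <- function(mask) {
  nr <- nrow(mask); nc <- ncol(mask)
  lab <- matrix(0L, nr, nc)
  nxt <- 0L
  for (j in seq_len(nc)) for (i in seq_len(nr)) {
    if (!mask[i, j] || lab[i, j] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(i, j))
    lab[i, j] <- nxt
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0L && dj == 0L) next
        y <- p[1L] + di; x <- p[2L] + dj
        if (y >= 1L && y <= nr && x >= 1L && x <= nc &&
            mask[y, x] && lab[y, x] == 0L) {
          lab[y, x] <- nxt
          queue[[length(queue) + 1L]] <- c(y, x)
        }
      }
    }
  }
  lab
}

# Closed-form two-sided Welch t-test (no calls into stats::t.test).
welch_closed_form <- function(a, b) {
  na <- length(a); nb <- length(b)
  va <- sum((a - mean(a))^2) / (na - 1)
  vb <- sum((b - mean(b))^2) / (nb - 1)
  se2 <- va / na + vb / nb
  t <- (mean(a) - mean(b)) / sqrt(se2)
  df <- se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  list(t = t, df = df, p_value = 2 * stats::pt(-abs(t), df))
}

# Canonical form of a labelling so two labelings can be compared up to
# label permutation: relabel by first occurrence in column-major order.
canonical_labels <- function(lab) {
  fg <- which(lab > 0L)
  if (length(fg) == 0L) return(lab)
  map <- integer(max(lab))
  map[unique(lab[fg])] <- seq_along(unique(lab[fg]))
  lab[fg] <- map[lab[fg]]
  lab
}

# A small frame containing hand-placed constant-intensity square "cells"
# on a constant background; returns the frame and the cell specs.
square_cells_frame <- function(intensities, size = 9L, bg = 10,
                               dim = c(64L, 64L)) {
  px <- matrix(bg, dim[1], dim[2])
  origins <- list()
  step <- size + 6L
  k <- 0L
  for (i in seq_along(intensities)) {
    r0 <- 3L + (k %/% 3L) * step
    c0 <- 3L + (k %% 3L) * step
    px[r0:(r0 + size - 1L), c0:(c0 + size - 1L)] <- bg + intensities[i]
    origins[[i]] <- c(r0, c0)
    k <- k + 1L
  }
  list(frame = frame(px), origins = origins, size = size, bg = bg)
}
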