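# Independent oracles used to cross-check the pipeline's primitives.

# Flood-fill connected-component labelling (pure R, queue-based).
flood_fill_label <- function(mask, connectivity = 8) {
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  dirs <- if (connectivity == 4) {
    cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  } else {
    cbind(c(-1, 1, 0, 0, -1, -1, 1, 1), c(0, 0, -1, 1, -1, 1, -1, 1))
  }
  nxt <- 0L
  for (c0 in seq_len(W)) for (r0 in seq_len(H)) {
    if (!mask[r0, c0] || lab[r0, c0] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(r0, c0))
    lab[r0, c0] <- nxt
    while (length(queue)) {
      p <- queue[[length(queue)]]
      queue[[length(queue)]] <- NULL
      for (k in seq_len(nrow(dirs))) {
        r <- p[1] + dirs[k, 1]; c <- p[2] + dirs[k, 2]
        if (r >= 1 && r <= H && c >= 1 && c <= W &&
            mask[r, c] && lab[r, c] == 0L) {
          lab[r, c] <- nxt
          queue[[length(queue) + 1L]] <- c(r, c)
        }
      }
    }
  }
  lab
}

# Two labelings describe the same partition iff their contingency table
# has exactly one non-zero cell per row and per column.
same_partition <- function(lab1, lab2) {
  f1 <- lab1[lab1 > 0 | lab2 > 0]
  f2 <- lab2[lab1 > 0 | lab2 > 0]
  if (any((f1 == 0) != (f2 == 0))) return(FALSE)
  tab <- table(f1, f2)
  all(rowSums(tab > 0) == 1) && all(colSums(tab > 0) == 1)
}

# Gift-wrapping (Jarvis march) convex hull; returns indices.
giftwrap_hull <- function(x, y) {
  n <- length(x)
  if (n < 3) return(seq_len(n))
  start <- which.min(x + y * 1e-9)
  hull <- start
  repeat {
    p <- hull[length(hull)]
    q <- if (p == 1L) 2L else 1L
    for (r in seq_len(n)) {
      if (r == p) next
      cr <- (x[q] - x[p]) * (y[r] - y[p]) - (y[q] - y[p]) * (x[r] - x[p])
      d_r <- (x[r] - x[p])^2 + (y[r] - y[p])^2
      d_q <- (x[q] - x[p])^2 + (y[q] - y[p])^2
      if (cr < 0 || (cr == 0 && d_r > d_q)) q <- r
    }
    if (q == start) break
    hull <- c(hull, q)
    if (length(hull) > n) stop("gift wrap failed to close")
  }
  hull
}

shoelace <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

# Small, fast scene for unit tests: a 6 cm tap with a handful of
# laterals on a 450 x 350 px canvas at 50 px/cm.
tiny_model <- function(n_laterals = 5, seed = 1) {
  root_model_params(tap_length_cm = 6, n_laterals = n_laterals,
                    lateral_length_cm = list(mean = 1.2, sd = 0.4, min = 0.5),
                    seed = seed)
}

tiny_scene <- function(seed = 1, ...) {
  scene_params(image_size_px = c(450L, 350L), pixels_per_cm = 50,
               margin_top_cm = 0.6, seed = seed, ...)
}
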