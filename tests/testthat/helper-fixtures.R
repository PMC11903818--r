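# shared fixtures built in code

axis16 <- function() make_wavenumber_axis(1800, 948, 56.8)

small_scene <- function(seed = 3, n_plaques = 6, h = 128, w = 128, ...) {
  generate_scene(h, w, n_plaques, seed = seed, axis = axis16(), ...)
}

# independent flood-fill component counter (queue-based, 8-connectivity)
flood_fill_count <- function(mask, connectivity = 8) {
  m <- mask != 0
  seen <- matrix(FALSE, nrow(m), ncol(m))
  nbr <- if (connectivity == 8)
    cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  else cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  count <- 0L
  for (start in which(m & !seen)) {
    if (seen[start]) next
    count <- count + 1L
    queue <- start
    seen[start] <- TRUE
    while (length(queue)) {
      p <- queue[1]; queue <- queue[-1]
      i <- (p - 1) %% nrow(m) + 1; j <- (p - 1) %/% nrow(m) + 1
      for (k in seq_len(nrow(nbr))) {
        ii <- i + nbr[k, 1]; jj <- j + nbr[k, 2]
        if (ii >= 1 && ii <= nrow(m) && jj >= 1 && jj <= ncol(m) &&
            m[ii, jj] && !seen[ii, jj]) {
          seen[ii, jj] <- TRUE
          queue <- c(queue, (jj - 1) * nrow(m) + ii)
        }
      }
    }
  }
  count
}

# exhaustive 256-threshold Otsu oracle: scan every histogram split and
# maximize the between-class variance (plateau resolved at its middle)
otsu_oracle <- function(x, levels = 256) {
  breaks <- seq(0, 1, length.out = levels + 1)
  h <- hist(as.vector(x), breaks = breaks, plot = FALSE)
  counts <- h$counts; mids <- h$mids
  len <- length(counts)
  w1 <- cumsum(counts)
  w2 <- w1[len] + counts - w1
  cm <- counts * mids
  m1 <- cumsum(cm)
  m2 <- m1[len] + cm - m1
  v <- w1 * w2 * (m2 / w2 - m1 / w1)^2
  arg <- which(v == max(v, na.rm = TRUE))
  (mids[arg[1]] + mids[arg[length(arg)]]) / 2
}

# brute-force Mann-Whitney AUC with half-credit ties
auc_oracle <- function(y, s) {
  pos <- s[y == 1]; neg <- s[y == 0]
  if (!length(pos) || !length(neg)) return(NA_real_)
  tot <- 0
  for (a in pos) for (b in neg)
    tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(pos) * length(neg))
}

# tiny labeled ROI sample for training-path tests
toy_sample <- function(seed = 1, y = 1L, C = 3, case_id = "A") {
  set.seed(seed)
  patch <- array(stats::rnorm(64 * 64 * C, mean = 0.5, sd = 0.1),
                 c(64, 64, C))
  m <- matrix(0L, 64, 64)
  m[20:40, 20:40] <- 1L
  if (y == 1L) {
    patch[20:40, 20:40, 1] <- patch[20:40, 20:40, 1] + 0.5
    em <- m
  } else {
    em <- matrix(1L, 64, 64)
  }
  list(patch = patch, y = y, effective_mask = em, case_id = case_id,
       sample_id = paste0(case_id, "_1"), origin = c(row = 1, col = 1))
}
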