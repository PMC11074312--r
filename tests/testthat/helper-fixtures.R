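# Shared fixtures, built in code at test time.

# A label image of well-separated disks on a grid; returns labels plus the
# true centers/radii.
disk_labels <- function(n_rows = 3, n_cols = 4, radius = 10, spacing = 40,
                        margin = 25) {
  h <- margin * 2 + (n_rows - 1) * spacing
  w <- margin * 2 + (n_cols - 1) * spacing
  labels <- matrix(0L, h, w)
  centers <- expand.grid(
    y = margin + (seq_len(n_rows) - 1) * spacing,
    x = margin + (seq_len(n_cols) - 1) * spacing
  )
  for (k in seq_len(nrow(centers))) {
    for (r in 1:h) for (c in 1:w) {
      if ((r - centers$y[k])^2 + (c - centers$x[k])^2 <= radius^2) {
        labels[r, c] <- k
      }
    }
  }
  list(labels = labels, centers = centers, radius = radius)
}

# Brute-force O(n^2) nearest-neighbor oracle.
nn_oracle <- function(x, y) {
  n <- length(x)
  out <- numeric(n)
  for (i in seq_len(n)) {
    best <- Inf
    for (j in seq_len(n)) {
      if (i != j) {
        d <- sqrt((x[i] - x[j])^2 + (y[i] - y[j])^2)
        if (d < best) best <- d
      }
    }
    out[i] <- best
  }
  out
}

# Brute-force per-label mean-intensity oracle (explicit pixel loop).
measure_oracle <- function(labels, channel) {
  ids <- sort(unique(labels[labels > 0]))
  means <- numeric(length(ids))
  for (t in seq_along(ids)) {
    total <- 0; count <- 0
    for (r in seq_len(nrow(labels))) {
      for (c in seq_len(ncol(labels))) {
        if (labels[r, c] == ids[t]) {
          total <- total + channel[r, c]
          count <- count + 1
        }
      }
    }
    means[t] <- total / count
  }
  data.frame(label = ids, mean = means)
}

# Mean IoU between true disks and the nearest detected mask (exact, via
# linear pixel index sets).
mean_matched_iou <- function(labels, cells, truth) {
  h <- nrow(labels)
  det_pix <- split(which(labels > 0), labels[labels > 0])
  ious <- vapply(seq_len(nrow(truth)), function(i) {
    j <- which.min((cells$x - truth$x[i])^2 + (cells$y - truth$y[i])^2)
    lab <- as.character(cells$label[j])
    r <- truth$radius[i]
    cols <- max(1, floor(truth$x[i] - r)):min(ncol(labels), ceiling(truth$x[i] + r))
    rows <- max(1, floor(truth$y[i] - r)):min(h, ceiling(truth$y[i] + r))
    grid <- expand.grid(row = rows, col = cols)
    inside <- (grid$row - truth$y[i])^2 + (grid$col - truth$x[i])^2 <= r^2
    true_pix <- (grid$col[inside] - 1) * h + grid$row[inside]
    d <- det_pix[[lab]]
    inter <- length(intersect(true_pix, d))
    inter / (length(true_pix) + length(d) - inter)
  }, numeric(1))
  mean(ious)
}

# Greedy one-to-one matching of detected spots to true spots within a radius;
# returns counts for recall/precision.
match_spots <- function(det_x, det_y, true_x, true_y, radius = 2) {
  used <- rep(FALSE, length(true_x))
  tp <- 0
  for (i in seq_along(det_x)) {
    d2 <- (true_x - det_x[i])^2 + (true_y - det_y[i])^2
    d2[used] <- Inf
    j <- which.min(d2)
    if (length(j) == 1 && d2[j] <= radius^2) {
      used[j] <- TRUE
      tp <- tp + 1
    }
  }
  list(tp = tp, n_det = length(det_x), n_true = length(true_x))
}
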