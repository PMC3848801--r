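# Brute-force Ward oracle: at every step, recompute each candidate merge's
# increase in total within-cluster sum of squares from scratch (no
# centroid-update shortcuts), with the same lowest-index tie rule.
naive_ward <- function(x, k) {
  x <- as.matrix(x) * 1
  ess <- function(cols) {
    m <- x[, cols, drop = FALSE]
    sum(sweep(m, 1L, rowMeans(m))^2)
  }
  groups <- as.list(seq_len(ncol(x)))
  heights <- numeric(0)
  partition <- groups
  while (length(groups) > 1L) {
    best <- NULL; best_d <- Inf
    for (a in seq_along(groups)) for (b in seq_along(groups)) {
      if (b <= a) next
      d <- ess(c(groups[[a]], groups[[b]])) - ess(groups[[a]]) - ess(groups[[b]])
      if (d < best_d - 1e-12) { best <- c(a, b); best_d <- d }
    }
    heights <- c(heights, 2 * best_d)
    groups[[best[1L]]] <- c(groups[[best[1L]]], groups[[best[2L]]])
    groups <- groups[-best[2L]]
    if (length(groups) == k) partition <- groups
  }
  list(heights = heights, partition = partition)
}

# order-free signature of a partition (named membership vector)
canon_partition <- function(part) {
  grp <- split(names(part), part)
  unname(sort(vapply(grp, function(g) paste(sort(g), collapse = "+"),
                     character(1))))
}
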