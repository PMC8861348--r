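# Independent brute-force oracles, deliberately written with different
# algorithms than the package code they check.

# 6-connected flood fill over a logical array using an explicit queue
flood_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  offs <- rbind(c(-1, 0, 0), c(1, 0, 0), c(0, -1, 0), c(0, 1, 0),
                c(0, 0, -1), c(0, 0, 1))
  idx_all <- which(mask, arr.ind = TRUE)
  for (r in seq_len(nrow(idx_all))) {
    start <- idx_all[r, ]
    if (lab[start[1], start[2], start[3]] > 0L) next
    nxt <- nxt + 1L
    queue <- matrix(start, ncol = 3)
    lab[start[1], start[2], start[3]] <- nxt
    while (nrow(queue) > 0) {
      cur <- queue[1, ]; queue <- queue[-1, , drop = FALSE]
      for (k in 1:6) {
        nb <- cur + offs[k, ]
        if (any(nb < 1) || any(nb > d)) next
        if (mask[nb[1], nb[2], nb[3]] && lab[nb[1], nb[2], nb[3]] == 0L) {
          lab[nb[1], nb[2], nb[3]] <- nxt
          queue <- rbind(queue, nb)
        }
      }
    }
  }
  lab
}

# voxels within radius_mm of any voxel of `comp`, by direct distance
# computation over all voxel pairs (small masks only)
shell_voxels <- function(comp, radius_mm, spacing) {
  d <- dim(comp)
  ci <- which(comp, arr.ind = TRUE)
  out <- array(FALSE, d)
  all_idx <- which(!is.na(array(0, d)), arr.ind = TRUE)
  for (r in seq_len(nrow(all_idx))) {
    p <- all_idx[r, ]
    d2 <- min(colSums(((t(ci) - p) * spacing)^2))
    if (d2 <= radius_mm^2) out[p[1], p[2], p[3]] <- TRUE
  }
  out
}
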