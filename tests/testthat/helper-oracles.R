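# Independent oracles, kept deliberately naive and separate from the package
# implementation paths they check.

# Repeated halving by explicit loop.
oracle_dilution <- function(initial, divisions) {
  v <- initial
  if (divisions > 0) for (i in seq_len(divisions)) v <- v * 0.5
  v
}

# Bin an 8-bit intensity by explicit comparisons (low [0,100), mid [100,200),
# high [200,255]).
oracle_bin <- function(v) {
  if (v < 100) "low" else if (v < 200) "mid" else "high"
}

# Round-half-up 8-bit quantization, re-stated independently.
oracle_quantize8 <- function(x) min(max(floor(x + 0.5), 0), 255)

# Brute-force 3-D connected components (26-connectivity) by breadth-first
# search over an explicit neighbour loop; for small arrays only.
oracle_cc_3d <- function(mask) {
  d <- dim(mask)
  labels <- array(0L, d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || labels[z, y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- list(c(z, y, x))
    labels[z, y, x] <- nxt
    while (length(queue) > 0) {
      p <- queue[[1]]; queue <- queue[-1]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        if (dz == 0 && dy == 0 && dx == 0) next
        q <- p + c(dz, dy, dx)
        if (any(q < 1) || any(q > d)) next
        if (mask[q[1], q[2], q[3]] && labels[q[1], q[2], q[3]] == 0L) {
          labels[q[1], q[2], q[3]] <- nxt
          queue[[length(queue) + 1]] <- q
        }
      }
    }
  }
  labels
}

# Apply a rigid transform to a point with explicit 2x2 rotation-matrix
# arithmetic (degrees counter-clockwise, about `center`).
oracle_rt_point <- function(t, p, center) {
  a <- t$theta * pi / 180
  R <- matrix(c(cos(a), sin(a), -sin(a), cos(a)), 2, 2)
  as.numeric(R %*% (p - center) + center + c(t$tx, t$ty))
}

# Expected cell-count report computed directly from a phantom truth table:
# dilution-law intensity, quantized the way rasterization quantizes, then
# floored and binned.
oracle_truth_report <- function(truth, lrc_floor = 1) {
  q <- vapply(truth$cells$true_intensity, oracle_quantize8, numeric(1))
  lrc <- q >= lrc_floor
  bins <- vapply(q[lrc], oracle_bin, character(1))
  list(total = nrow(truth$cells),
       lrc_total = sum(lrc),
       per_bin = c(low = sum(bins == "low"), mid = sum(bins == "mid"),
                   high = sum(bins == "high")))
}
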