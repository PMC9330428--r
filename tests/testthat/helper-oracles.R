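# Brute-force oracles, deliberately written as naive loops so they stay
# independent of the vectorized / compiled implementation paths.

oracle_confusion <- function(pred, truth, class_id) {
  p <- as.vector(if (is.list(pred)) pred$voxels else pred)
  t <- as.vector(if (is.list(truth)) truth$voxels else truth)
  tp <- fp <- tn <- fn <- 0L
  for (i in seq_along(p)) {
    pi <- p[i] == class_id
    ti <- t[i] == class_id
    if (pi && ti) tp <- tp + 1L
    else if (pi && !ti) fp <- fp + 1L
    else if (!pi && ti) fn <- fn + 1L
    else tn <- tn + 1L
  }
  list(TP = tp, FP = fp, TN = tn, FN = fn)
}

oracle_metrics <- function(cc) {
  dv <- function(n, d) if (d == 0) 1.0 else n / d
  list(dice = dv(2 * cc$TP, 2 * cc$TP + cc$FP + cc$FN),
       specificity = dv(cc$TN, cc$TN + cc$FP),
       sensitivity = dv(cc$TP, cc$TP + cc$FN),
       accuracy = dv(cc$TP + cc$TN, cc$TP + cc$TN + cc$FP + cc$FN))
}

# End-aligned cube starts by exhaustive search over candidate offsets.
oracle_cube_offsets <- function(Z, len, stride) {
  if (Z <= len) return(0L)
  starts <- integer(0)
  s <- 0
  while (s + len <= Z) {
    starts <- c(starts, s)
    s <- s + stride
  }
  if (max(starts) + len < Z) starts <- c(starts, Z - len)
  as.integer(starts)
}

# Per-voxel score averaging by direct accumulation.
oracle_stitch <- function(score_cubes, offsets, source_shape) {
  K <- dim(score_cubes[[1]])[4]
  L <- dim(score_cubes[[1]])[1]
  acc <- array(0, c(source_shape, K))
  cnt <- array(0, source_shape)
  for (i in seq_along(score_cubes)) {
    for (zz in seq_len(L)) {
      z <- offsets[i] + zz
      if (z > source_shape[1]) next
      acc[z, , , ] <- acc[z, , , ] + score_cubes[[i]][zz, , , ]
      cnt[z, , ] <- cnt[z, , ] + 1
    }
  }
  for (k in seq_len(K)) acc[, , , k] <- acc[, , , k] / cnt
  acc
}

# 26-connected components by BFS in plain R.
oracle_label_components <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, d)
  nxt <- 0L
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    if (!mask[z, y, x] || lab[z, y, x] != 0L) next
    nxt <- nxt + 1L
    queue <- matrix(c(z, y, x), ncol = 3)
    lab[z, y, x] <- nxt
    while (nrow(queue)) {
      cur <- queue[1, , drop = FALSE]
      queue <- queue[-1, , drop = FALSE]
      for (dz in -1:1) for (dy in -1:1) for (dx in -1:1) {
        nz <- cur[1] + dz; ny <- cur[2] + dy; nx <- cur[3] + dx
        if (nz < 1 || ny < 1 || nx < 1 || nz > d[1] || ny > d[2] || nx > d[3]) next
        if (mask[nz, ny, nx] && lab[nz, ny, nx] == 0L) {
          lab[nz, ny, nx] <- nxt
          queue <- rbind(queue, c(nz, ny, nx))
        }
      }
    }
  }
  lab
}

# Independent transcription of the loss definition, loop-based.
loss_by_hand <- function(prob, target, smooth = 1) {
  K <- dim(prob)[4]
  d <- dim(target)
  ce <- 0; n <- 0
  S <- P <- Tt <- rep(0, K)
  for (x in seq_len(d[3])) for (y in seq_len(d[2])) for (z in seq_len(d[1])) {
    tv <- target[z, y, x] + 1
    ce <- ce - log(prob[z, y, x, tv]); n <- n + 1
    for (k in seq_len(K)) {
      P[k] <- P[k] + prob[z, y, x, k]
      if (tv == k) { S[k] <- S[k] + prob[z, y, x, k]; Tt[k] <- Tt[k] + 1 }
    }
  }
  dice <- (2 * S + smooth) / (P + Tt + smooth)
  ce / n + (1 - mean(dice))
}

rand_prob <- function(d, K, seed) {
  set.seed(seed)
  raw <- array(runif(prod(d) * K, 0.05, 1), c(d, K))
  tot <- apply(raw, 1:3, sum)
  for (k in seq_len(K)) raw[, , , k] <- raw[, , , k] / tot
  raw
}

# Small fixtures -------------------------------------------------------

tiny_phantom <- function(seed = 1L, stones = c(3, 6)) {
  generate_phantom(phantom_spec("desk", seed = seed, stone_diameters_mm = stones))
}

tiny_backbone <- function(name = "unet3d", K = 2L, depth = 2L, base = 2L,
                          seed = 1L) {
  build_backbone(backbone_config(name, depth, base, K), seed = seed)
}

# A registered constant scorer: always prefers one class everywhere.
constant_scorer <- function(K, favored = 1L) {
  function(cube) {
    s <- array(0, c(dim(cube), K))
    s[, , , favored + 1L] <- 1
    s
  }
}
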