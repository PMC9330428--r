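# Double-precision R reference implementation of the compact 3D U-Net /
# Res U-Net forward pass (training-mode batch norm), used as an independent
# oracle for the compiled network.  Mirrors the C++ layout exactly:
# feature matrices are (V x C) with voxel index v = z + Z*(y + Y*x), kernel
# offsets ordered dx-major then dy then dz.

ref_vol2col <- function(Xm, shp) {
  Z <- shp[1]; Y <- shp[2]; X <- shp[3]; C <- ncol(Xm)
  V <- Z * Y * X
  col <- matrix(0, V, 27 * C)
  t <- 0
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    for (c in seq_len(C)) {
      a <- array(Xm[, c], c(Z, Y, X))
      sh <- array(0, c(Z, Y, X))
      zs <- max(1, 1 - dz):min(Z, Z - dz)
      ys <- max(1, 1 - dy):min(Y, Y - dy)
      xs <- max(1, 1 - dx):min(X, X - dx)
      sh[zs, ys, xs] <- a[zs + dz, ys + dy, xs + dx]
      col[, t * C + c] <- as.vector(sh)
    }
    t <- t + 1
  }
  col
}

ref_unit <- function(Xm, shp, W, g, b, relu) {
  pre <- ref_vol2col(Xm, shp) %*% W
  mu <- colMeans(pre)
  va <- colMeans(pre^2) - mu^2
  xhat <- sweep(sweep(pre, 2, mu), 2, sqrt(va + 1e-5), "/")
  out <- sweep(sweep(xhat, 2, g, "*"), 2, b, "+")
  if (relu) out <- pmax(out, 0)
  out
}

ref_block <- function(Xm, shp, params, pre, residual) {
  if (!residual) {
    h <- ref_unit(Xm, shp, params[[paste0(pre, ".c1.W")]],
                  params[[paste0(pre, ".c1.g")]], params[[paste0(pre, ".c1.b")]], TRUE)
    return(ref_unit(h, shp, params[[paste0(pre, ".c2.W")]],
                    params[[paste0(pre, ".c2.g")]], params[[paste0(pre, ".c2.b")]], TRUE))
  }
  h <- ref_unit(Xm, shp, params[[paste0(pre, ".c1.W")]],
                params[[paste0(pre, ".c1.g")]], params[[paste0(pre, ".c1.b")]], TRUE)
  p2 <- ref_unit(h, shp, params[[paste0(pre, ".c2.W")]],
                 params[[paste0(pre, ".c2.g")]], params[[paste0(pre, ".c2.b")]], FALSE)
  sc <- if (!is.null(params[[paste0(pre, ".proj.W")]]))
    Xm %*% params[[paste0(pre, ".proj.W")]] else Xm
  pmax(p2 + sc, 0)
}

ref_pool <- function(Xm, si) {
  so <- si %/% 2L
  a <- array(0, c(so, ncol(Xm)))
  out <- matrix(0, prod(so), ncol(Xm))
  for (c in seq_len(ncol(Xm))) {
    v <- array(Xm[, c], si)
    r <- array(-Inf, so)
    for (dz in 0:1) for (dy in 0:1) for (dx in 0:1)
      r <- pmax(r, v[seq(1 + dz, si[1], 2), seq(1 + dy, si[2], 2),
                     seq(1 + dx, si[3], 2), drop = FALSE])
    out[, c] <- as.vector(r)
  }
  out
}

ref_up <- function(Xm, si, so) {
  out <- matrix(0, prod(so), ncol(Xm))
  iz <- (seq_len(so[1]) - 1) %/% 2 + 1
  iy <- (seq_len(so[2]) - 1) %/% 2 + 1
  ix <- (seq_len(so[3]) - 1) %/% 2 + 1
  for (c in seq_len(ncol(Xm))) {
    v <- array(Xm[, c], si)
    out[, c] <- as.vector(v[iz, iy, ix, drop = FALSE])
  }
  out
}

# Full forward in double precision; depth-2 topology (the oracle's scope).
ref_net_forward <- function(cube, params, residual, K) {
  shp <- dim(cube)
  x <- matrix(as.vector(cube), ncol = 1)
  e0 <- ref_block(x, shp, params, "enc0", residual)
  shp1 <- shp %/% 2L
  p1 <- ref_pool(e0, shp)
  e1 <- ref_block(p1, shp1, params, "enc1", residual)
  up <- ref_up(e1, shp1, shp)
  d0 <- ref_block(cbind(up, e0), shp, params, "dec0", residual)
  scores <- sweep(d0 %*% params[["head.W"]], 2, params[["head.b"]], "+")
  scores
}

ref_net_loss <- function(cube, target, params, residual, K) {
  scores <- ref_net_forward(cube, params, residual, K)
  p <- exp(scores - apply(scores, 1, max))
  p <- p / rowSums(p)
  combined_loss(array(p, c(dim(cube), K)), target, components = TRUE)
}
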