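# Combined segmentation loss: soft-Dice + voxel-mean cross-entropy with
# equal weights.  This R implementation is the user-facing surface and the
# reference the compiled training loss is tested against.

#' Combined soft-Dice + cross-entropy loss
#'
#' `loss = (1 - mean_c softDice_c) + mean_v(-log p[target])`, with the
#' per-class soft Dice `(2*sum(p_c t_c) + s) / (sum p_c + sum t_c + s)` and
#' smoothing constant `s = 1`.  A one-hot-correct prediction gives a
#' cross-entropy of 0 and a Dice term of 0; a uniform prediction over K
#' classes gives a cross-entropy of `log(K)` per voxel.
#'
#' @param prob 4D array `(Z, Y, X, K)` of per-voxel class probabilities
#'   (rows sum to 1).
#' @param target integer 3D array `(Z, Y, X)` of class ids in `0..K-1`.
#' @param smooth soft-Dice smoothing constant (default 1).
#' @param components if `TRUE`, return `list(total, ce, dice_loss)`.
#' @return scalar loss, or the component list.
#' @export
combined_loss <- function(prob, target, smooth = 1, components = FALSE) {
  dp <- dim(prob)
  if (length(dp) != 4) stop("prob must be a 4D (Z,Y,X,K) array")
  if (any(dp[1:3] != dim(target)))
    stop("prob and target shapes do not match")
  K <- dp[4]
  V <- prod(dp[1:3])
  pm <- matrix(prob, V, K)
  tv <- as.integer(target)
  if (any(tv < 0 | tv >= K)) stop("target ids must lie in 0..K-1")
  ce <- -mean(log(pmax(pm[cbind(seq_len(V), tv + 1L)], 1e-12)))
  dice <- numeric(K)
  for (k in seq_len(K)) {
    tk <- as.numeric(tv == k - 1L)
    dice[k] <- (2 * sum(pm[, k] * tk) + smooth) / (sum(pm[, k]) + sum(tk) + smooth)
  }
  dice_loss <- 1 - mean(dice)
  if (components) list(total = ce + dice_loss, ce = ce, dice_loss = dice_loss)
  else ce + dice_loss
}
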