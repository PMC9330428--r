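# Backbone registry.  A backbone is anything satisfying one contract: given
# a (Z, Y, X) cube it returns per-class scores (Z, Y, X, K).  Two reference
# backbones are implemented (compact 3D U-Net and Res U-Net); further
# architectures can be registered programmatically.

.backbone_registry <- new.env(parent = emptyenv())

#' Backbone configuration
#'
#' @param name `"unet3d"`, `"resunet3d"`, or any registered name.
#' @param depth number of resolution levels (cube dims must be divisible by
#'   `2^(depth-1)`).
#' @param base_channels channels at the top level; doubled per level.
#' @param out_classes 2 for stage 1 (background/kidney), 3 for stage 2.
#' @param in_channels input channels (1: normalized CT).
#' @return object of class `backbone_config`.
#' @export
backbone_config <- function(name = "unet3d", depth = 3L, base_channels = 8L,
                            out_classes = 2L, in_channels = 1L) {
  out_classes <- as.integer(out_classes)
  if (!out_classes %in% 2:3) stop("out_classes must be 2 or 3")
  if (depth < 1) stop("depth must be >= 1")
  structure(list(name = name, depth = as.integer(depth),
                 base_channels = as.integer(base_channels),
                 out_classes = out_classes, in_channels = as.integer(in_channels)),
            class = "backbone_config")
}

check_divisible <- function(cube_shape, depth) {
  div <- 2^(depth - 1)
  bad <- which(cube_shape %% div != 0)
  if (length(bad))
    stop(sprintf("cube axis %s (size %s) not divisible by 2^(depth-1) = %d",
                 paste(c("z", "y", "x")[bad], collapse = ","),
                 paste(cube_shape[bad], collapse = ","), div))
  invisible(TRUE)
}

#' Register a backbone builder
#'
#' @param name registry key.
#' @param builder `function(cfg, seed)` returning a list with elements
#'   `score` (`function(cube_array) -> (Z,Y,X,K) score array`) and,
#'   for trainable backbones, `params`/`state`/`cpp_cfg`.
#' @export
register_backbone <- function(name, builder) {
  assign(name, builder, envir = .backbone_registry)
  invisible(name)
}

#' List registered backbone names
#' @return character vector.
#' @export
list_backbones <- function() ls(.backbone_registry)

he_init <- function(nr, nc, fan_in) {
  matrix(rnorm(nr * nc, 0, sqrt(2 / fan_in)), nr, nc)
}

# Parameter/state initialization shared by the two reference backbones.
init_unet_params <- function(cfg, residual) {
  depth <- cfg$depth; base <- cfg$base_channels
  ch <- base * 2^(0:(depth - 1))
  params <- list(); state <- list()
  add_unit <- function(pre, cin, cout) {
    params[[paste0(pre, ".W")]] <<- he_init(27 * cin, cout, 27 * cin)
    params[[paste0(pre, ".g")]] <<- rep(1, cout)
    params[[paste0(pre, ".b")]] <<- rep(0, cout)
    state[[paste0(pre, ".rm")]] <<- rep(0, cout)
    state[[paste0(pre, ".rv")]] <<- rep(1, cout)
  }
  add_block <- function(pre, cin, cout) {
    add_unit(paste0(pre, ".c1"), cin, cout)
    add_unit(paste0(pre, ".c2"), cout, cout)
    if (residual && cin != cout)
      params[[paste0(pre, ".proj.W")]] <<- he_init(cin, cout, cin)
  }
  for (i in seq_len(depth)) {
    cin <- if (i == 1) cfg$in_channels else ch[i - 1]
    add_block(paste0("enc", i - 1), cin, ch[i])
  }
  if (depth > 1)
    for (i in seq_len(depth - 1))
      add_block(paste0("dec", i - 1), ch[i + 1] + ch[i], ch[i])
  params[["head.W"]] <- he_init(ch[1], cfg$out_classes, ch[1])
  params[["head.b"]] <- rep(0, cfg$out_classes)
  list(params = params, state = state)
}

build_reference_backbone <- function(cfg, seed, residual) {
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  ps <- init_unet_params(cfg, residual)
  net <- list(
    params = ps$params, state = ps$state,
    cpp_cfg = list(depth = cfg$depth, out_classes = cfg$out_classes,
                   residual = residual),
    cfg = cfg, trainable = TRUE)
  net$score <- function(cube) net_score(net, cube)
  class(net) <- "nephro_backbone"
  net
}

# Score a cube with a (possibly trained) reference backbone.  `net` may be
# stale inside closures after training; callers pass the current net.
net_score <- function(net, cube) {
  d <- dim(cube)
  check_divisible(d, net$cpp_cfg$depth)
  m <- cpp_net_predict(cube, net$params, net$state, net$cpp_cfg)
  array(m, c(d, net$cpp_cfg$out_classes))
}

#' Build a backbone from its configuration
#'
#' Looks the name up in the registry and returns a scorer object.  The two
#' reference backbones (`unet3d`, `resunet3d`) are trainable; externally
#' registered scorers need only implement the scoring contract.
#'
#' @param cfg a [backbone_config()].
#' @param seed seed for weight initialization.
#' @return a backbone object with at least a `$score` function mapping a
#'   `(Z, Y, X)` cube to `(Z, Y, X, out_classes)` scores.
#' @export
build_backbone <- function(cfg, seed = 1L) {
  builder <- get0(cfg$name, envir = .backbone_registry)
  if (is.null(builder))
    stop("unknown backbone '", cfg$name, "'; registered: ",
         paste(list_backbones(), collapse = ", "))
  builder(cfg, seed)
}

#' Per-class probabilities for one cube
#'
#' @param backbone a backbone object (or bare scoring function).
#' @param cube 3D array.
#' @param normalize if `TRUE` (default) apply per-voxel softmax so class
#'   scores sum to 1.
#' @return 4D array `(Z, Y, X, K)`.
#' @export
predict_cube <- function(backbone, cube, normalize = TRUE) {
  score <- if (is.function(backbone)) backbone
           else if (!is.null(backbone$params)) function(cube) net_score(backbone, cube)
           else backbone$score
  s <- score(cube)
  if (length(dim(s)) != 4 || any(dim(s)[1:3] != dim(cube)))
    stop("backbone scorer violated the shape contract")
  if (normalize) softmax4(s) else s
}

softmax4 <- function(s) {
  K <- dim(s)[4]
  m <- apply(s, 1:3, max)
  for (k in seq_len(K)) s[, , , k] <- exp(s[, , , k] - m)
  tot <- apply(s, 1:3, sum)
  for (k in seq_len(K)) s[, , , k] <- s[, , , k] / tot
  s
}

#' Save / load a trained backbone
#'
#' Weights go to an `.rds` checkpoint with a JSON sidecar describing the
#' architecture (both created at run time; nothing binary ships with the
#' package).
#'
#' @param net a trainable backbone.
#' @param path checkpoint path (`.rds`).
#' @return `path` (save) or the restored backbone (load).
#' @export
save_backbone <- function(net, path) {
  dir.create(dirname(path), recursive = TRUE, showWarnings = FALSE)
  saveRDS(list(params = net$params, state = net$state, cfg = net$cfg,
               cpp_cfg = net$cpp_cfg), path)
  sidecar <- sub("\\.rds$", ".json", path)
  jsonlite::write_json(net$cfg[c("name", "depth", "base_channels",
                                 "out_classes", "in_channels")],
                       sidecar, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_backbone
#' @export
load_backbone <- function(path) {
  x <- readRDS(path)
  net <- list(params = x$params, state = x$state, cpp_cfg = x$cpp_cfg,
              cfg = x$cfg, trainable = TRUE)
  net$score <- function(cube) net_score(net, cube)
  class(net) <- "nephro_backbone"
  net
}

# register the reference backbones at load time
.onLoad <- function(libname, pkgname) {
  register_backbone("unet3d", function(cfg, seed = 1L)
    build_reference_backbone(cfg, seed, residual = FALSE))
  register_backbone("resunet3d", function(cfg, seed = 1L)
    build_reference_backbone(cfg, seed, residual = TRUE))
}
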