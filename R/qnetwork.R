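# The species Q-network. Architecture: two 1x1 convolution layers (32 and
# 64 filters, stride 1) acting per pixel of the vr x vr observation, a
# fully-connected layer of 32 rectifier units, batch normalization and ReLU
# after each hidden layer, and a fully-connected tanh output with one
# Q-value per action (so every Q-value lies in (-1, 1)).
#
# The integer window codes are expanded at the network boundary into two
# binary channels (prey mask, predator mask); the numerics live in
# compiled code (src/qnet.cpp).

QNET_BN_MOMENTUM <- 0.99

#' Build a species Q-network
#'
#' Initialises all weights from the current R RNG stream (He-scaled normal
#' for the rectifier layers, Xavier-scaled for the tanh head), batch-norm
#' scales at 1 and running statistics at (0, 1). Two builds under the same
#' seed are identical.
#'
#' @param vr odd observation window size (default 9).
#' @param n_actions number of output Q-values (default 9).
#' @param n_conv1,n_conv2,n_fc hidden layer widths.
#' @return A `pp_qnet` environment holding the parameter tensors and the
#'   Adam optimizer state.
#' @export
build_qnetwork <- function(vr = 9, n_actions = 9,
                           n_conv1 = 32, n_conv2 = 64, n_fc = 32) {
  if (vr %% 2 != 1 || vr < 3) stop("vr must be odd and >= 3")
  npix <- vr * vr
  he <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(2 / nin)), nin, nout)
  xavier <- function(nin, nout) matrix(rnorm(nin * nout, sd = sqrt(1 / nin)), nin, nout)
  params <- list(
    W1 = he(2, n_conv1), b1 = numeric(n_conv1),
    g1 = rep(1, n_conv1), be1 = numeric(n_conv1),
    mu1 = numeric(n_conv1), va1 = rep(1, n_conv1),
    W2 = he(n_conv1, n_conv2), b2 = numeric(n_conv2),
    g2 = rep(1, n_conv2), be2 = numeric(n_conv2),
    mu2 = numeric(n_conv2), va2 = rep(1, n_conv2),
    W3 = he(npix * n_conv2, n_fc), b3 = numeric(n_fc),
    g3 = rep(1, n_fc), be3 = numeric(n_fc),
    mu3 = numeric(n_fc), va3 = rep(1, n_fc),
    W4 = xavier(n_fc, n_actions), b4 = numeric(n_actions))
  net <- new.env(parent = emptyenv())
  net$vr <- as.integer(vr)
  net$n_actions <- as.integer(n_actions)
  net$arch <- c(n_conv1 = n_conv1, n_conv2 = n_conv2, n_fc = n_fc)
  net$params <- params
  net$adam_m <- lapply(params[qnet_trainable()], function(p) p * 0)
  net$adam_v <- lapply(params[qnet_trainable()], function(p) p * 0)
  net$adam_t <- 0L
  class(net) <- "pp_qnet"
  net
}

qnet_trainable <- function() {
  c("W1", "b1", "g1", "be1", "W2", "b2", "g2", "be2",
    "W3", "b3", "g3", "be3", "W4", "b4")
}

#' Q-values of a batch of observations
#'
#' Inference-mode forward pass (batch normalization uses the running
#' statistics accumulated during training).
#'
#' @param net a `pp_qnet`.
#' @param obs either a `pp_obs`, a `vr x vr` code matrix, or a `B x vr^2`
#'   integer matrix of row-major window codes.
#' @return `B x n_actions` matrix of Q-values, each in (-1, 1).
#' @export
qnet_predict <- function(net, obs) {
  codes <- as_code_matrix(obs, net$vr)
  cpp_qnet_infer(net$params, codes, net$vr)
}

as_code_matrix <- function(obs, vr) {
  if (inherits(obs, "pp_obs")) return(matrix(obs_codes(obs), 1))
  if (is.matrix(obs)) {
    if (nrow(obs) == vr && ncol(obs) == vr)
      return(matrix(as.integer(t(obs)), 1))
    if (ncol(obs) == vr * vr)
      return(matrix(as.integer(obs), nrow(obs)))
  }
  if (is.vector(obs) && length(obs) == vr * vr) return(matrix(as.integer(obs), 1))
  stop("cannot interpret observation input")
}

#' Deep-copy a Q-network
#'
#' Networks are environments mutated in place by training; the target
#' network of the Bellman update is a clone.
#'
#' @param net a `pp_qnet`.
#' @return An independent copy.
#' @export
qnet_clone <- function(net) {
  cl <- new.env(parent = emptyenv())
  cl$vr <- net$vr
  cl$n_actions <- net$n_actions
  cl$arch <- net$arch
  cl$params <- lapply(net$params, function(p) p * 1)
  cl$adam_m <- lapply(net$adam_m, function(p) p * 1)
  cl$adam_v <- lapply(net$adam_v, function(p) p * 1)
  cl$adam_t <- net$adam_t
  class(cl) <- "pp_qnet"
  cl
}

# overwrite dst's parameters with src's (target refresh)
qnet_copy_params <- function(dst, src) {
  dst$params <- lapply(src$params, function(p) p * 1)
  invisible(dst)
}

#' Fold a Q-network into a fast behaviour policy
#'
#' Because the two 1x1 convolution layers act per pixel on a 3-valued code,
#' their inference-mode output takes only three values; the whole network
#' up to the first fully-connected layer collapses into a per-pixel,
#' per-code lookup table. The folded policy evaluates one observation in a
#' few thousand flops and is what the Monte Carlo engine consumes.
#'
#' @param net a `pp_qnet`.
#' @param eps exploration probability attached to the policy.
#' @return A folded policy list (fields `vr`, `base`, `D1`, `D2`, `W4`,
#'   `b4`, `eps`) understood by [mcs_step()] and [run_case()].
#' @export
fold_policy <- function(net, eps) {
  p <- net$params
  vr <- net$vr
  npix <- vr * vr
  bn_inf <- function(x, g, be, mu, va) g / sqrt(va + 1e-5) * (x - mu) + be
  pixel_vec <- function(code) {
    x <- c(code == 1, code == 2) + 0
    h1 <- pmax(bn_inf(drop(x %*% p$W1) + p$b1, p$g1, p$be1, p$mu1, p$va1), 0)
    pmax(bn_inf(drop(h1 %*% p$W2) + p$b2, p$g2, p$be2, p$mu2, p$va2), 0)
  }
  nch <- ncol(p$W2)
  nfc <- ncol(p$W3)
  Warr <- matrix(array(p$W3, dim = c(nch, npix, nfc)), nrow = nch)
  Mfor <- function(v) matrix(drop(v %*% Warr), npix, nfc)
  M0 <- Mfor(pixel_vec(0L))
  M1 <- Mfor(pixel_vec(1L))
  M2 <- Mfor(pixel_vec(2L))
  s3 <- p$g3 / sqrt(p$va3 + 1e-5)
  shift3 <- p$be3 - s3 * p$mu3
  list(vr = vr,
       base = s3 * (colSums(M0) + p$b3) + shift3,
       D1 = sweep(M1 - M0, 2, s3, "*"),
       D2 = sweep(M2 - M0, 2, s3, "*"),
       W4 = p$W4, b4 = p$b4, eps = eps)
}

#' Epsilon-greedy action selection
#'
#' With probability `eps` a uniformly random action; otherwise the action
#' with the highest Q-value, ties broken uniformly at random.
#'
#' @param net a `pp_qnet`.
#' @param obs an observation (see [qnet_predict()]).
#' @param eps exploration probability in `[0, 1]`.
#' @return Integer action in 1..n_actions (see [pp_actions()]).
#' @export
select_action <- function(net, obs, eps) {
  if (runif(1) < eps) return(sample.int(net$n_actions, 1))
  q <- qnet_predict(net, obs)[1, ]
  ties <- which(q == max(q))
  if (length(ties) == 1) ties else ties[sample.int(length(ties), 1)]
}

#' @export
print.pp_qnet <- function(x, ...) {
  cat(sprintf("pp_qnet: %d x %d window -> conv1x1(%d) -> conv1x1(%d) -> fc(%d) -> tanh(%d)\n",
              x$vr, x$vr, x$arch[["n_conv1"]], x$arch[["n_conv2"]],
              x$arch[["n_fc"]], x$n_actions))
  cat(sprintf("Adam steps taken: %d\n", x$adam_t))
  invisible(x)
}

#' Serialize a Q-network to a single archive file
#'
#' Writes a versioned archive (format `predpreyRL-qnet`, version 1)
#' containing the architecture descriptor and all parameter tensors;
#' optimizer state is not persisted. [load_qnetwork()] restores a network
#' whose forward pass is bit-identical.
#'
#' @param net a `pp_qnet`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
save_qnetwork <- function(net, path) {
  saveRDS(list(format = "predpreyRL-qnet", version = 1L,
               vr = net$vr, n_actions = net$n_actions, arch = net$arch,
               params = net$params),
          path)
  invisible(path)
}

#' @rdname save_qnetwork
#' @return For `load_qnetwork`, a restored `pp_qnet` (Adam state reset).
#' @export
load_qnetwork <- function(path) {
  x <- tryCatch(readRDS(path), error = function(e)
    stop("cannot read Q-network archive: ", conditionMessage(e)))
  if (!is.list(x) || !identical(x$format, "predpreyRL-qnet"))
    stop("file is not a predpreyRL Q-network archive")
  net <- build_qnetwork(x$vr, x$n_actions, x$arch[["n_conv1"]],
                        x$arch[["n_conv2"]], x$arch[["n_fc"]])
  net$params <- lapply(x$params, function(p) p * 1)
  net
}
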