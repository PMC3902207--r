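#' Autoencoder configuration
#'
#' Defaults follow the full-scale training setup: 100 hidden features,
#' target mean activation 0.035 with Kullback-Leibler sparseness weight
#' 90, L2 weight decay 0.3, 12 x 12 filters at stride 2, 500 optimizer
#' iterations. Tests and desk-scale runs shrink these.
#'
#' @param J Number of hidden feature maps.
#' @param target_activation Desired mean activation of each hidden
#'   feature (KL target).
#' @param beta Weight of the sparseness penalty.
#' @param decay L2 weight-decay coefficient on forward and backward
#'   weights.
#' @param filter_extent Filter side length in pixels.
#' @param stride Convolution stride.
#' @param max_iter L-BFGS iteration cap.
#' @return An `ae_config` list.
#' @export
ae_config <- function(J = 100L, target_activation = 0.035, beta = 90,
                      decay = 0.3, filter_extent = 12L, stride = 2L,
                      max_iter = 500L) {
  stopifnot(J >= 1L, target_activation > 0, target_activation < 1,
            beta >= 0, decay >= 0)
  structure(list(J = as.integer(J), target_activation = target_activation,
                 beta = beta, decay = decay,
                 filter_extent = as.integer(filter_extent),
                 stride = as.integer(stride),
                 max_iter = as.integer(max_iter)),
            class = "ae_config")
}

ae_pack <- function(W, b, What, bhat) c(W, b, What, bhat)

ae_unpack <- function(par, fe, J) {
  nw <- fe * fe * 3L * J
  W <- array(par[seq_len(nw)], c(fe, fe, 3L, J))
  b <- par[nw + seq_len(J)]
  What <- array(par[nw + J + seq_len(nw)], c(fe, fe, J, 3L))
  bhat <- par[2L * nw + J + 1:3]
  list(W = W, b = b, What = What, bhat = bhat)
}

# Central region of the reconstruction with full filter support: pixels
# x (1-based) with fe <= x <= P - fe + 1 receive all fe/stride
# overlapping placements.
ae_central <- function(P, fe) fe:(P - fe + 1L)

# Loss and gradient of the convolutional sparse autoencoder on a list of
# preprocessed patches (H x W x 3 arrays, all the same size). Returns the
# total loss with a gradient attribute when `grad = TRUE`.
ae_loss <- function(par, patches, config, grad = TRUE) {
  fe <- config$filter_extent
  J <- config$J
  s <- config$stride
  p <- ae_unpack(par, fe, J)
  S <- length(patches)
  P1 <- dim(patches[[1L]])[1]
  P2 <- dim(patches[[1L]])[2]
  cr <- ae_central(P1, fe)
  cc <- ae_central(P2, fe)
  npos_rec <- length(cr) * length(cc)
  hs <- vector("list", S)
  zs <- vector("list", S)
  dvh <- vector("list", S)
  psi1 <- 0
  hsum <- 0
  nh <- 0
  for (i in seq_len(S)) {
    v <- patches[[i]]
    z <- cpp_conv_valid(v, p$W, p$b, s)
    h <- sigmoid(z)
    vhat <- cpp_conv_transpose(h, p$What, p$bhat, s, P1, P2)
    diff <- array(0, dim(v))
    diff[cr, cc, ] <- vhat[cr, cc, ] - v[cr, cc, ]
    psi1 <- psi1 + 0.5 * sum(diff^2)
    hs[[i]] <- h
    zs[[i]] <- z
    dvh[[i]] <- diff
    hsum <- hsum + colSums(matrix(h, ncol = J))
    nh <- nh + prod(dim(h)[1:2])
  }
  psi1 <- psi1 / (npos_rec * S)
  q <- hsum / nh
  rho <- config$target_activation
  psi2 <- config$beta *
    sum(rho * log(rho / q) + (1 - rho) * log((1 - rho) / (1 - q)))
  psi3 <- config$decay / 2 * (sum(p$W^2) + sum(p$What^2))
  loss <- psi1 + psi2 + psi3
  if (!is.finite(loss)) stop("non-finite autoencoder loss")
  if (!grad) {
    attr(loss, "terms") <- c(psi1 = psi1, psi2 = psi2, psi3 = psi3)
    return(loss)
  }
  dW <- config$decay * p$W
  db <- rep(0, J)
  dWhat <- config$decay * p$What
  dbhat <- rep(0, 3)
  dkl_dq <- config$beta * (-rho / q + (1 - rho) / (1 - q)) / nh
  for (i in seq_len(S)) {
    D <- dvh[[i]] / (npos_rec * S)
    h <- hs[[i]]
    dWhat <- dWhat + aperm(cpp_conv_weight_grad(D, h, fe, fe, s),
                           c(1, 2, 4, 3))
    dbhat <- dbhat + colSums(matrix(D, ncol = 3L))
    dh <- cpp_conv_valid(D, aperm(p$What, c(1, 2, 4, 3)), rep(0, J), s)
    dh <- dh + array(rep(dkl_dq, each = prod(dim(h)[1:2])), dim(h))
    dz <- dh * h * (1 - h)
    dW <- dW + cpp_conv_weight_grad(patches[[i]], dz, fe, fe, s)
    db <- db + colSums(matrix(dz, ncol = J))
  }
  attr(loss, "gradient") <- ae_pack(dW, db, dWhat, dbhat)
  attr(loss, "terms") <- c(psi1 = psi1, psi2 = psi2, psi3 = psi3)
  loss
}

as_patch_array <- function(x) {
  px <- unclass(x)
  attributes(px) <- list(dim = dim(px))
  px
}

#' Train the convolutional sparse autoencoder
#'
#' Minimizes reconstruction error plus KL sparseness penalty plus L2
#' weight decay with L-BFGS (analytic gradients via backpropagation;
#' valid-only convolutions, linear decoder, reconstruction compared on
#' the fully supported central region of each patch).
#'
#' @param patches List of preprocessed patches ([image_rgb()] or
#'   `H x W x 3` arrays, identical sizes).
#' @param config An [ae_config()].
#' @param seed Seed for the small uniform weight initialization.
#' @return A `filter_bank` of kind `"autoencoder"` carrying forward and
#'   backward weights and the final loss terms.
#' @export
train_autoencoder <- function(patches, config = ae_config(), seed = 1L) {
  patches <- lapply(patches, as_patch_array)
  fe <- config$filter_extent
  J <- config$J
  d1 <- dim(patches[[1L]])
  if (d1[1] < 2L * fe || d1[2] < 2L * fe)
    stop("patches must be at least twice the filter extent for a ",
         "fully supported reconstruction region")
  n_par <- 2L * fe * fe * 3L * J + J + 3L
  par0 <- with_seed(seed, runif(n_par, -0.05, 0.05))
  iter <- 0L
  fn <- function(par) {
    iter <<- iter + 1L
    tryCatch(as.numeric(ae_loss(par, patches, config, grad = FALSE)),
             error = function(e)
               stop("non-finite loss at evaluation ", iter, call. = FALSE))
  }
  gr <- function(par) attr(ae_loss(par, patches, config), "gradient")
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = config$max_iter))
  p <- ae_unpack(opt$par, fe, J)
  final <- ae_loss(opt$par, patches, config, grad = FALSE)
  structure(list(W = p$W, b = p$b, What = p$What, bhat = p$bhat,
                 stride = config$stride, kind = "autoencoder",
                 gain = 1, config = config, loss = as.numeric(final),
                 loss_terms = attr(final, "terms"),
                 convergence = opt$convergence),
            class = "filter_bank")
}

#' Check the autoencoder gradient against finite differences
#'
#' Compares the backpropagated gradient with central finite differences
#' on randomly chosen coordinates of a random parameter vector.
#'
#' @param patches,config,seed As in [train_autoencoder()].
#' @param n_checks Number of coordinates to probe.
#' @param eps Finite-difference step.
#' @return Maximum relative error over the probed coordinates.
#' @export
ae_gradient_check <- function(patches, config, seed = 1L, n_checks = 40L,
                              eps = 1e-4) {
  patches <- lapply(patches, as_patch_array)
  fe <- config$filter_extent
  n_par <- 2L * fe * fe * 3L * config$J + config$J + 3L
  with_seed(seed, {
    par <- runif(n_par, -0.2, 0.2)
    idx <- sample.int(n_par, min(n_checks, n_par))
  })
  ana <- attr(ae_loss(par, patches, config), "gradient")[idx]
  num <- vapply(idx, function(i) {
    pp <- par; pp[i] <- pp[i] + eps
    pm <- par; pm[i] <- pm[i] - eps
    (as.numeric(ae_loss(pp, patches, config, grad = FALSE)) -
     as.numeric(ae_loss(pm, patches, config, grad = FALSE))) / (2 * eps)
  }, numeric(1L))
  max(abs(ana - num) / pmax(1e-6, abs(ana) + abs(num)))
}
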