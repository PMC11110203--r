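# Minimal convolutional network over per-patient symptom x plaque lift
# matrices: conv(3x3, 8) -> ReLU -> conv(3x3, 16) -> ReLU -> global average
# pool -> dense -> sigmoid output per plaque, binary cross-entropy,
# full-batch Adam.  Inputs are tiny (S x 3), so each 3x3 convolution is
# evaluated as nine shifted matrix products in base R; training is
# deterministic given the seed.

#' Training configuration for the convolutional correction model
#'
#' @param epochs Full-batch gradient steps.
#' @param lr Adam learning rate.
#' @param seed Integer seed for weight initialization.
#' @return A list of training settings.
#' @export
cnn_train_config <- function(epochs = 200, lr = 0.01, seed = 1L) {
  list(epochs = as.integer(epochs), lr = lr, seed = as.integer(seed))
}

# Gather-row table for a 3x3 kernel over an S x W grid, replicated for n
# samples.  Entry [r, j] is the row of the padded activation matrix
# (1 = zero-pad row) feeding offset j of output row r; positions are
# column-major, p = (v-1)*S + u.
conv_gather <- function(S, W, n) {
  P <- S * W
  idx1 <- matrix(0L, P, 9L)
  j <- 0L
  for (dv in -1:1) for (du in -1:1) {
    j <- j + 1L
    for (v in seq_len(W)) for (u in seq_len(S)) {
      uu <- u + du; vv <- v + dv
      p <- (v - 1L) * S + u
      if (uu >= 1 && uu <= S && vv >= 1 && vv <= W) idx1[p, j] <- (vv - 1L) * S + uu
    }
  }
  idxM <- matrix(0L, n * P, 9L)
  offs <- rep((seq_len(n) - 1L) * P, each = P)
  for (j in 1:9) idxM[, j] <- ifelse(rep(idx1[, j], n) == 0L, 0L, rep(idx1[, j], n) + offs)
  idxM + 1L  # 1 = pad row of the rbind(0, .) padded matrix
}

# kernel rows of the 72 x 16 weight matrix belonging to offset j
w2_rows <- function(j) seq(j, by = 9L, length.out = 8L)

cnn_input_cols <- function(arr) {
  # (n, S, W) array -> column vector ordered sample-major, position-minor
  matrix(as.vector(aperm(arr, c(2, 3, 1))), ncol = 1)
}

cnn_im2col1 <- function(X0, idxM) {
  x <- c(0, X0[, 1])
  X1 <- matrix(0, nrow(idxM), 9L)
  for (j in 1:9) X1[, j] <- x[idxM[, j]]
  X1
}

cnn_forward <- function(par, X1, idxM, n, P) {
  Z1 <- sweep(X1 %*% par$W1, 2, par$b1, "+")
  H1 <- pmax(Z1, 0)
  H1pad <- rbind(0, H1)
  Z2 <- matrix(par$b2, n * P, length(par$b2), byrow = TRUE)
  for (j in 1:9) Z2 <- Z2 + H1pad[idxM[, j], , drop = FALSE] %*% par$W2[w2_rows(j), ]
  H2 <- pmax(Z2, 0)
  G <- rowsum(H2, rep(seq_len(n), each = P), reorder = FALSE) / P
  Z3 <- sweep(G %*% par$W3, 2, par$b3, "+")
  list(Z1 = Z1, H1pad = H1pad, Z2 = Z2, G = G,
       Yhat = 1 / (1 + exp(-Z3)))
}

cnn_gradients <- function(par, fw, X1, idxM, Y, n, P) {
  K <- ncol(Y)
  dZ3 <- (fw$Yhat - Y) / (n * K)
  g <- list(W3 = crossprod(fw$G, dZ3), b3 = colSums(dZ3))
  dG <- dZ3 %*% t(par$W3)
  dH2 <- dG[rep(seq_len(n), each = P), , drop = FALSE] / P
  dZ2 <- dH2 * (fw$Z2 > 0)
  g$b2 <- colSums(dZ2)
  g$W2 <- par$W2 * 0
  dH1pad <- fw$H1pad * 0
  for (j in 1:9) {
    rows <- idxM[, j]
    g$W2[w2_rows(j), ] <- crossprod(fw$H1pad[rows, , drop = FALSE], dZ2)
    contrib <- dZ2 %*% t(par$W2[w2_rows(j), ])
    # for a fixed offset the source rows are distinct (pad row excepted),
    # so indexed addition is a faithful scatter
    dH1pad[rows, ] <- dH1pad[rows, ] + contrib
    dH1pad[1, ] <- 0
  }
  dZ1 <- dH1pad[-1, , drop = FALSE] * (fw$Z1 > 0)
  g$W1 <- crossprod(X1, dZ1)
  g$b1 <- colSums(dZ1)
  g
}

#' Train the convolutional correction model
#'
#' Learns to map a patient's zero-masked lift matrix to multi-label plaque
#' probabilities (one sigmoid output per plaque type).  The learned
#' mapping is later contrasted across patients to produce a pair-level
#' correction score, see [cnn_pair_scores()].
#'
#' @param pm A `patient_matrices` object from [build_patient_matrices()].
#' @param labels 0/1 matrix patients x plaque types, e.g. from
#'   [plaque_label_matrix()].
#' @param train_cfg A [cnn_train_config()].
#' @return A `plaquekg_cnn` model (weights, vocabularies, loss history).
#' @export
train_cnn <- function(pm, labels, train_cfg = cnn_train_config()) {
  arr <- pm$matrices
  n <- dim(arr)[1]; S <- dim(arr)[2]; W <- dim(arr)[3]
  stopifnot(nrow(labels) == n, ncol(labels) == W)
  const <- which(apply(labels, 2, function(y) length(unique(y)) < 2))
  if (length(const) > 0) {
    abort(sprintf("training error: plaque class '%s' has a single label value",
                  pm$plaques[const[1]]))
  }
  P <- S * W
  idxM <- conv_gather(S, W, n)
  X1 <- cnn_im2col1(cnn_input_cols(arr), idxM)

  set.seed(train_cfg$seed)
  he <- function(r, c) matrix(rnorm(r * c, 0, sqrt(2 / r)), r, c)
  par <- list(W1 = he(9, 8), b1 = rep(0, 8),
              W2 = he(72, 16), b2 = rep(0, 16),
              W3 = he(16, W), b3 = rep(0, W))
  m <- lapply(par, function(x) x * 0)
  v <- lapply(par, function(x) x * 0)
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  Y <- as.matrix(labels)
  loss_hist <- numeric(train_cfg$epochs)

  for (ep in seq_len(train_cfg$epochs)) {
    fw <- cnn_forward(par, X1, idxM, n, P)
    Yhat <- pmin(pmax(fw$Yhat, 1e-12), 1 - 1e-12)
    loss_hist[ep] <- -mean(Y * log(Yhat) + (1 - Y) * log(1 - Yhat))
    g <- cnn_gradients(par, fw, X1, idxM, Y, n, P)
    for (nm in names(par)) {
      m[[nm]] <- beta1 * m[[nm]] + (1 - beta1) * g[[nm]]
      v[[nm]] <- beta2 * v[[nm]] + (1 - beta2) * g[[nm]]^2
      mhat <- m[[nm]] / (1 - beta1^ep)
      vhat <- v[[nm]] / (1 - beta2^ep)
      par[[nm]] <- par[[nm]] - train_cfg$lr * mhat / (sqrt(vhat) + eps)
    }
  }
  structure(list(par = par, symptoms = pm$symptoms, plaques = pm$plaques,
                 S = S, W = W, loss = loss_hist, config = train_cfg),
            class = "plaquekg_cnn")
}

#' @export
print.plaquekg_cnn <- function(x, ...) {
  cat(sprintf("<plaquekg_cnn> %d x %d input, %d epochs, final loss %.4f\n",
              x$S, x$W, length(x$loss), x$loss[length(x$loss)]))
  invisible(x)
}

#' Predict per-plaque probabilities for patient matrices
#'
#' @param model A `plaquekg_cnn`.
#' @param pm A `patient_matrices` object with matching vocabularies.
#' @return Matrix patients x plaque types of probabilities in (0,1).
#' @export
cnn_predict <- function(model, pm) {
  arr <- pm$matrices
  n <- dim(arr)[1]
  stopifnot(dim(arr)[2] == model$S, dim(arr)[3] == model$W)
  P <- model$S * model$W
  idxM <- conv_gather(model$S, model$W, n)
  X1 <- cnn_im2col1(cnn_input_cols(arr), idxM)
  out <- cnn_forward(model$par, X1, idxM, n, P)$Yhat
  dimnames(out) <- list(dimnames(arr)[[1]], model$plaques)
  out
}

#' Pair-level correction scores from the patient-level model
#'
#' The model predicts plaque probabilities per patient; the pair score for
#' (s, t) is the mean predicted probability of t over patients exhibiting
#' s minus the mean over patients not exhibiting s, min-max rescaled to
#' [0,1] across all pairs.  An all-equal contrast maps to 0.5.
#'
#' @param model A `plaquekg_cnn`.
#' @param pm A `patient_matrices` object.
#' @param records Record tibble aligned with `pm`.
#' @return Tibble with `symptom`, `plaque`, `cnn_score` in [0,1].
#' @export
cnn_pair_scores <- function(model, pm, records) {
  probs <- cnn_predict(model, pm)
  n <- nrow(records)
  present <- matrix(FALSE, n, length(pm$symptoms), dimnames = list(NULL, pm$symptoms))
  for (i in seq_len(n)) present[i, intersect(records$symptoms[[i]], pm$symptoms)] <- TRUE
  grid <- tidyr::expand_grid(symptom = pm$symptoms, plaque = pm$plaques)
  contrast <- map_dbl(seq_len(nrow(grid)), function(r) {
    sel <- present[, grid$symptom[r]]
    if (all(sel) || !any(sel)) return(0)
    mean(probs[sel, grid$plaque[r]]) - mean(probs[!sel, grid$plaque[r]])
  })
  rng <- range(contrast)
  score <- if (diff(rng) == 0) rep(0.5, length(contrast)) else (contrast - rng[1]) / diff(rng)
  mutate(grid, cnn_score = score)
}
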