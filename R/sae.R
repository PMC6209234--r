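# Sparse autoencoder: one sigmoid hidden layer, linear reconstruction,
# KL-divergence sparsity penalty on mean hidden activations, L2 weight decay.
# Trained with L-BFGS on the analytic gradient.

sae_pack <- function(w1, b1, w2, b2) c(w1, b1, w2, b2)

sae_unpack <- function(par, d, h) {
  i <- 0
  w1 <- matrix(par[i + seq_len(d * h)], d, h); i <- i + d * h
  b1 <- par[i + seq_len(h)]; i <- i + h
  w2 <- matrix(par[i + seq_len(h * d)], h, d); i <- i + h * d
  b2 <- par[i + seq_len(d)]
  list(w1 = w1, b1 = b1, w2 = w2, b2 = b2)
}

sigmoid <- function(z) 1 / (1 + exp(-z))

# KL divergence between Bernoulli(rho) and Bernoulli(q), q clamped away from
# {0, 1} by eps.
kl_bernoulli <- function(rho, q, eps = 1e-8) {
  q <- pmin(pmax(q, eps), 1 - eps)
  rho * log(rho / q) + (1 - rho) * log((1 - rho) / (1 - q))
}

# Loss and gradient on the packed parameter vector; returns both so optim's
# fn/gr can share one forward pass via caching in the calling environment.
sae_objective <- function(par, x, h, rho, beta, lambda, eps = 1e-8) {
  n <- nrow(x)
  d <- ncol(x)
  p <- sae_unpack(par, d, h)
  z <- sweep(x %*% p$w1, 2, p$b1, "+")
  a <- sigmoid(z)
  xhat <- sweep(a %*% p$w2, 2, p$b2, "+")
  err <- xhat - x
  rho_hat <- colMeans(a)
  rho_c <- pmin(pmax(rho_hat, eps), 1 - eps)
  loss <- sum(err^2) / (2 * n) +
    beta * sum(kl_bernoulli(rho, rho_hat, eps)) +
    lambda / 2 * (sum(p$w1^2) + sum(p$w2^2))
  d_err <- err / n
  g_w2 <- crossprod(a, d_err) + lambda * p$w2
  g_b2 <- colSums(d_err)
  d_a <- tcrossprod(d_err, p$w2)
  kl_grad <- beta * (-rho / rho_c + (1 - rho) / (1 - rho_c)) / n
  d_a <- sweep(d_a, 2, kl_grad, "+")
  d_z <- d_a * a * (1 - a)
  g_w1 <- crossprod(x, d_z) + lambda * p$w1
  g_b1 <- colSums(d_z)
  list(loss = loss, grad = sae_pack(g_w1, g_b1, g_w2, g_b2))
}

#' Sparse autoencoder loss
#'
#' Mean squared reconstruction error (halved, averaged over samples) plus the
#' KL-divergence sparsity penalty `beta * sum_j KL(rho || rho_hat_j)` on the
#' mean hidden activations and the L2 weight decay
#' `lambda / 2 * (||W1||^2 + ||W2||^2)`. Mean activations are clamped to
#' `(eps, 1 - eps)` before the KL term.
#'
#' @param model a fitted or hand-built `sae` object (see [sae_fit()]).
#' @param batch numeric matrix of input rows (nonempty, finite).
#' @return scalar loss.
#' @export
sae_loss <- function(model, batch) {
  batch <- as.matrix(batch)
  if (!nrow(batch)) stop("batch is empty", call. = FALSE)
  if (!all(is.finite(batch))) stop("batch contains non-finite values",
                                   call. = FALSE)
  sae_objective(sae_pack(model$w1, model$b1, model$w2, model$b2), batch,
                model$hidden_size, model$sparsity_target,
                model$sparsity_weight, model$weight_decay)$loss
}

#' Sparse autoencoder loss gradient
#'
#' Analytic gradient of [sae_loss()] with respect to all weights and biases,
#' returned in the same layout as the model (`w1`, `b1`, `w2`, `b2`). Matches
#' central finite differences to high relative accuracy; used by the L-BFGS
#' optimizer in [sae_fit()].
#'
#' @inheritParams sae_loss
#' @return list with elements `w1`, `b1`, `w2`, `b2`.
#' @export
sae_grad <- function(model, batch) {
  batch <- as.matrix(batch)
  if (!nrow(batch)) stop("batch is empty", call. = FALSE)
  if (!all(is.finite(batch))) stop("batch contains non-finite values",
                                   call. = FALSE)
  g <- sae_objective(sae_pack(model$w1, model$b1, model$w2, model$b2), batch,
                     model$hidden_size, model$sparsity_target,
                     model$sparsity_weight, model$weight_decay)$grad
  sae_unpack(g, ncol(batch), model$hidden_size)
}

#' Train a sparse autoencoder
#'
#' Single hidden layer of `hidden_size` sigmoid units with linear
#' reconstruction, trained by batch gradient minimization of [sae_loss()]
#' with L-BFGS. Initialization is symmetric uniform scaled by fan-in/fan-out
#' and seeded, so training is deterministic given the seed. Hyper-parameter
#' defaults sit inside the search ranges used for model selection
#' (hidden size 10--100, sparsity target 0.05--0.9, sparsity weight 1--20,
#' weight decay 1e-6--1e-3).
#'
#' @param x numeric matrix of training rows (>= 2).
#' @param hidden_size number of hidden units.
#' @param sparsity_target target mean activation rho of each hidden unit.
#' @param sparsity_weight weight beta of the KL sparsity penalty.
#' @param weight_decay L2 penalty lambda on the weights.
#' @param max_iter maximum L-BFGS iterations.
#' @param tol projected-gradient tolerance passed to the optimizer.
#' @param seed integer seed for the weight initialization.
#' @return an object of class `sae` with weights, hyper-parameters,
#'   `loss_initial`, `loss` (final) and `trace` (objective evaluations).
#' @export
sae_fit <- function(x, hidden_size = 10, sparsity_target = 0.3,
                    sparsity_weight = 1, weight_decay = 1e-4,
                    max_iter = 500, tol = 1e-6, seed = 1) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("need at least 2 training rows", call. = FALSE)
  if (!all(is.finite(x))) stop("training data contains non-finite values",
                               call. = FALSE)
  d <- ncol(x)
  h <- as.integer(hidden_size)
  r <- sqrt(6 / (d + h))
  par0 <- with_seed(seed, c(stats::runif(d * h, -r, r), numeric(h),
                            stats::runif(h * d, -r, r), numeric(d)))
  trace_env <- new.env()
  trace_env$values <- numeric(0)
  cache <- new.env()
  evaluate <- function(par) {
    key <- par
    if (!is.null(cache$par) && identical(cache$par, key)) return(cache$res)
    res <- sae_objective(par, x, h, sparsity_target, sparsity_weight,
                         weight_decay)
    cache$par <- key
    cache$res <- res
    res
  }
  fn <- function(par) {
    v <- evaluate(par)$loss
    trace_env$values <- c(trace_env$values, v)
    v
  }
  gr <- function(par) evaluate(par)$grad
  loss0 <- sae_objective(par0, x, h, sparsity_target, sparsity_weight,
                         weight_decay)$loss
  opt <- stats::optim(par0, fn, gr, method = "L-BFGS-B",
                      control = list(maxit = max_iter, pgtol = tol))
  if (!is.finite(opt$value) || opt$value > loss0 + 1e-8) {
    stop(sprintf(paste0("autoencoder optimization diverged ",
                        "(initial loss %.6g, final %.6g); trace tail: %s"),
                 loss0, opt$value,
                 paste(signif(utils::tail(trace_env$values, 5), 6),
                       collapse = ", ")), call. = FALSE)
  }
  p <- sae_unpack(opt$par, d, h)
  structure(list(w1 = p$w1, b1 = p$b1, w2 = p$w2, b2 = p$b2,
                 hidden_size = h, sparsity_target = sparsity_target,
                 sparsity_weight = sparsity_weight,
                 weight_decay = weight_decay, loss_initial = loss0,
                 loss = opt$value, trace = trace_env$values,
                 iterations = opt$counts[["function"]], seed = seed),
            class = "sae")
}

#' @export
print.sae <- function(x, ...) {
  cat(sprintf("Sparse autoencoder: %d -> %d -> %d\n", ncol(x$w2),
              x$hidden_size, ncol(x$w2)))
  cat(sprintf("  rho %g, beta %g, lambda %g; loss %.6g (from %.6g)\n",
              x$sparsity_target, x$sparsity_weight, x$weight_decay,
              x$loss, x$loss_initial))
  invisible(x)
}

#' Encode or reconstruct with a trained autoencoder
#'
#' @param object a fitted `sae`.
#' @param newdata numeric matrix of rows to transform.
#' @param type `"encode"` for hidden activations, `"reconstruct"` for the
#'   decoded output.
#' @param ... unused.
#' @return numeric matrix.
#' @export
predict.sae <- function(object, newdata, type = c("encode", "reconstruct"),
                        ...) {
  type <- match.arg(type)
  newdata <- as.matrix(newdata)
  a <- sigmoid(sweep(newdata %*% object$w1, 2, object$b1, "+"))
  if (type == "encode") return(a)
  sweep(a %*% object$w2, 2, object$b2, "+")
}

#' Grid search for autoencoder hyper-parameters
#'
#' Exhaustively evaluates every combination of the supplied grids, training
#' on a seeded subset of the rows and scoring by held-out mean squared
#' reconstruction error. Combinations are visited in lexicographic order of
#' (hidden size, sparsity target, sparsity weight, weight decay) and ties
#' keep the first minimizer. Default grids span the model-selection ranges
#' (hidden 10--100, target 0.05--0.9, weight 1--20, decay 1e-6--1e-3).
#'
#' @param x numeric matrix of feature rows.
#' @param hidden_sizes,sparsity_targets,sparsity_weights,weight_decays grids.
#' @param val_x optional explicit validation rows; if `NULL`, a seeded
#'   `val_fraction` of `x` is held out.
#' @param val_fraction held-out fraction when `val_x` is `NULL`.
#' @param max_iter,seed passed to [sae_fit()].
#' @return list with `hidden_size`, `sparsity_target`, `sparsity_weight`,
#'   `weight_decay`, `validation_error` and the full `results` data frame.
#' @export
grid_search_sae <- function(x, hidden_sizes = c(10, 50, 100),
                            sparsity_targets = c(0.05, 0.1, 0.5, 0.9),
                            sparsity_weights = c(1, 5, 20),
                            weight_decays = c(1e-6, 1e-4, 1e-3),
                            val_x = NULL, val_fraction = 0.25,
                            max_iter = 200, seed = 1) {
  if (!length(hidden_sizes) || !length(sparsity_targets) ||
      !length(sparsity_weights) || !length(weight_decays)) {
    stop("empty hyper-parameter grid", call. = FALSE)
  }
  x <- as.matrix(x)
  if (is.null(val_x)) {
    n_val <- max(1L, round(nrow(x) * val_fraction))
    val_idx <- with_seed(derive_seed(seed, 999), sample.int(nrow(x), n_val))
    val_x <- x[val_idx, , drop = FALSE]
    train_x <- x[-val_idx, , drop = FALSE]
  } else {
    train_x <- x
    val_x <- as.matrix(val_x)
  }
  best <- NULL
  rows <- list()
  for (h in hidden_sizes) for (r in sparsity_targets)
    for (b in sparsity_weights) for (l in weight_decays) {
      fit <- sae_fit(train_x, h, r, b, l, max_iter = max_iter, seed = seed)
      rec <- predict(fit, val_x, type = "reconstruct")
      err <- mean((rec - val_x)^2)
      rows[[length(rows) + 1]] <- data.frame(
        hidden_size = h, sparsity_target = r, sparsity_weight = b,
        weight_decay = l, validation_error = err)
      if (is.null(best) || err < best$validation_error) {
        best <- list(hidden_size = h, sparsity_target = r,
                     sparsity_weight = b, weight_decay = l,
                     validation_error = err)
      }
    }
  best$results <- do.call(rbind, rows)
  best
}
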