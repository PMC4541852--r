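#' Fit a Fisher discriminant with Gaussian class densities
#'
#' Finds the direction w maximizing the Fisher criterion — the squared
#' difference of projected class means over the summed projected class
#' scatters — via the classic closed form
#' \eqn{w = S_w^{-1} (m_{soil} - m_{tree})}, where \eqn{S_w} is the pooled
#' within-class scatter matrix. A ridge \eqn{\epsilon = 10^{-6}
#' \mathrm{tr}(S_w)/d} guards near-singular scatter after aggressive PCA
#' truncation. A 1-D normal density is then fitted to each class's
#' projections \eqn{y = w^T x} (the projected space is one-dimensional for
#' two classes) and class priors are the training frequencies.
#'
#' @param x a samples x features numeric matrix of training rows.
#' @param labels two-class labels (soil/tree), at least 2 samples each.
#' @return an \linkS4class{FdaModel}.
#' @export
fdaFit <- function(x, labels) {
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("soil", "tree"))
  if (anyNA(labels)) stop("labels must be 'soil' or 'tree'")
  ns <- table(labels)
  if (any(ns == 0L)) stop("both classes must be present in training data")
  if (any(ns < 2L)) stop("each class needs at least 2 training samples")
  d <- ncol(x)
  xs <- x[labels == "soil", , drop = FALSE]
  xt <- x[labels == "tree", , drop = FALSE]
  ms <- colMeans(xs); mt <- colMeans(xt)
  cs <- sweep(xs, 2L, ms); ct <- sweep(xt, 2L, mt)
  sw <- crossprod(cs) + crossprod(ct)
  eps <- 1e-6 * sum(diag(sw)) / d
  if (eps <= 0) eps <- 1e-6
  w <- drop(solve(sw + diag(eps, d), ms - mt))
  ys <- drop(xs %*% w); yt <- drop(xt %*% w)
  vs <- stats::var(ys); vt <- stats::var(yt)
  floorVar <- max(stats::var(c(ys, yt)), 1) * 1e-12
  if (vs <= floorVar || vt <= floorVar) {
    warning("a class has (near-)zero projected variance; regularizing")
    vs <- max(vs, floorVar); vt <- max(vt, floorVar)
  }
  new("FdaModel", w = w,
      means = c(soil = mean(ys), tree = mean(yt)),
      vars = c(soil = vs, tree = vt),
      priors = c(soil = ns[["soil"]], tree = ns[["tree"]]) / sum(ns))
}

#' Classify rows with a fitted Fisher discriminant
#'
#' Projects each row onto the discriminant direction and computes the
#' posterior probability of each class from the prior-weighted 1-D normal
#' densities, normalized across the two classes. A row is graded
#' \code{tree} only when its tree posterior strictly exceeds the soil
#' posterior: on a tie the costly error — letting ground-collected fruit
#' into the tree line — is avoided by grading \code{soil}.
#'
#' @param model an \linkS4class{FdaModel}.
#' @param x a samples x features matrix (or a single row vector).
#' @return a data.frame with columns \code{label} (factor soil/tree),
#'   \code{soil} and \code{tree} (posteriors summing to 1 per row).
#' @export
fdaPredict <- function(model, x) {
  stopifnot(is(model, "FdaModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model@w))
    stop("row dimension ", ncol(x), " does not match the fitted ",
         length(model@w), " inputs")
  y <- drop(x %*% model@w)
  logp <- cbind(
    soil = stats::dnorm(y, model@means["soil"], sqrt(model@vars["soil"]),
                        log = TRUE) + log(model@priors["soil"]),
    tree = stats::dnorm(y, model@means["tree"], sqrt(model@vars["tree"]),
                        log = TRUE) + log(model@priors["tree"]))
  m <- apply(logp, 1L, max)
  post <- exp(logp - m)
  post <- post / rowSums(post)
  lab <- factor(ifelse(post[, "tree"] > post[, "soil"], "tree", "soil"),
                levels = c("soil", "tree"))
  data.frame(label = lab, soil = post[, "soil"], tree = post[, "tree"],
             row.names = NULL)
}

# ---- single-hidden-neuron sigmoid MLP, scaled conjugate gradient ----

# forward pass + MSE loss and analytic gradient for theta = c(iw, b1, ow, b2)
.mlpLossGrad <- function(theta, x, t) {
  d <- ncol(x); n <- nrow(x)
  iw <- theta[seq_len(d)]; b1 <- theta[d + 1L]
  ow <- theta[d + 2L]; b2 <- theta[d + 3L]
  h <- stats::plogis(drop(x %*% iw) + b1)
  out <- stats::plogis(ow * h + b2)
  e <- out - t
  loss <- mean(e^2)
  dOut <- (2 / n) * e * out * (1 - out)
  dH <- dOut * ow * h * (1 - h)
  grad <- c(drop(crossprod(x, dH)), sum(dH), sum(dOut * h), sum(dOut))
  list(loss = loss, grad = grad)
}

.mlpLoss <- function(theta, x, t) .mlpLossGrad(theta, x, t)$loss

# Scaled conjugate gradient minimizer (Moller 1993), sigma = 5e-5,
# lambda0 = 5e-7. Returns the weight vector, the loss at each accepted
# step, and whether the gradient tolerance was reached.
.scgMinimize <- function(theta, x, t, maxEpochs, tol,
                         sigma0 = 5e-5, lambda0 = 5e-7) {
  np <- length(theta)
  lg <- .mlpLossGrad(theta, x, t)
  fw <- lg$loss
  r <- -lg$grad
  p <- r
  lambda <- lambda0; lambdaBar <- 0
  success <- TRUE
  delta <- 0; mu <- 0
  trace <- fw
  k <- 1L
  while (k <= maxEpochs && sqrt(sum(r^2)) > tol) {
    p2 <- sum(p^2)
    if (p2 == 0) break
    if (success) {
      sigma <- sigma0 / sqrt(p2)
      gPlus <- .mlpLossGrad(theta + sigma * p, x, t)$grad
      s <- (gPlus + r) / sigma        # (grad(w + sigma p) - grad(w))/sigma
      delta <- sum(p * s)
    }
    delta <- delta + (lambda - lambdaBar) * p2
    if (delta <= 0) {                 # make the Hessian estimate positive
      lambdaBar <- 2 * (lambda - delta / p2)
      delta <- -delta + lambda * p2
      lambda <- lambdaBar
    }
    mu <- sum(p * r)
    alpha <- mu / delta
    fNew <- .mlpLoss(theta + alpha * p, x, t)
    Delta <- 2 * delta * (fw - fNew) / mu^2
    if (is.finite(Delta) && Delta >= 0) {   # accept the step
      theta <- theta + alpha * p
      fw <- fNew
      lgNew <- .mlpLossGrad(theta, x, t)
      if (!is.finite(lgNew$loss))
        stop("non-finite training loss at epoch ", k)
      rNew <- -lgNew$grad
      lambdaBar <- 0
      success <- TRUE
      if (k %% np == 0L) {            # restart along steepest descent
        p <- rNew
      } else {
        beta <- (sum(rNew^2) - sum(rNew * r)) / mu
        p <- rNew + beta * p
      }
      r <- rNew
      trace <- c(trace, fw)
      if (Delta >= 0.75) lambda <- lambda / 4
    } else {
      lambdaBar <- lambda
      success <- FALSE
    }
    if (!is.finite(Delta) || Delta < 0.25)
      lambda <- lambda + delta * (1 - max(Delta, 0)) / p2
    if (lambda > 1e100) break         # nothing left to gain
    k <- k + 1L
  }
  list(theta = theta, trace = trace,
       converged = sqrt(sum(r^2)) <= tol)
}

#' Train the single-hidden-neuron perceptron
#'
#' Fits the 1-hidden-neuron, 1-output sigmoid network by minimizing the
#' mean squared error between the network output and soil = 0 / tree = 1
#' targets, using scaled conjugate gradient backpropagation (step-size
#' parameters \eqn{\sigma = 5\times10^{-5}},
#' \eqn{\lambda_0 = 5\times10^{-7}}). Initial weights are drawn uniformly
#' from [-0.5, 0.5] under the mandatory seed, so training is fully
#' deterministic given (data, seed).
#'
#' @param x a samples x features numeric matrix.
#' @param labels two-class labels (soil/tree).
#' @param seed RNG seed for weight initialization (required).
#' @param maxEpochs iteration cap (default 1000).
#' @param tolerance stop when the gradient norm falls below this
#'   (default 1e-6).
#' @return an \linkS4class{MlpModel}.
#' @export
mlpFit <- function(x, labels, seed, maxEpochs = 1000L, tolerance = 1e-6) {
  if (missing(seed)) stop("'seed' is required; MLP training is seeded")
  x <- as.matrix(x)
  labels <- factor(as.character(labels), levels = c("soil", "tree"))
  if (anyNA(labels)) stop("labels must be 'soil' or 'tree'")
  if (nlevels(droplevels(labels)) != 2L)
    stop("both classes must be present in training data")
  t <- as.numeric(labels == "tree")
  d <- ncol(x)
  theta0 <- .withSeed(seed, stats::runif(d + 3L, -0.5, 0.5))
  fit <- .scgMinimize(theta0, x, t, as.integer(maxEpochs), tolerance)
  new("MlpModel",
      iw = fit$theta[seq_len(d)], b1 = fit$theta[d + 1L],
      ow = fit$theta[d + 2L], b2 = fit$theta[d + 3L],
      lossTrace = fit$trace, converged = fit$converged)
}

#' Score rows with a trained perceptron
#'
#' The score is the network output, strictly inside (0, 1); a row is
#' graded \code{tree} iff its score is at least 0.5.
#'
#' @param model an \linkS4class{MlpModel}.
#' @param x a samples x features matrix (or a single row vector).
#' @return a data.frame with columns \code{label} (factor soil/tree) and
#'   \code{score}.
#' @export
mlpPredict <- function(model, x) {
  stopifnot(is(model, "MlpModel"))
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  x <- as.matrix(x)
  if (ncol(x) != length(model@iw))
    stop("row dimension ", ncol(x), " does not match the fitted ",
         length(model@iw), " inputs")
  h <- stats::plogis(drop(x %*% model@iw) + model@b1)
  score <- stats::plogis(model@ow * h + model@b2)
  lab <- factor(ifelse(score >= 0.5, "tree", "soil"),
                levels = c("soil", "tree"))
  data.frame(label = lab, score = score, row.names = NULL)
}
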