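## Independent oracles. These deliberately avoid the package's optimizer
## code paths: the micro-system oracle works from closed forms, the grid
## searches enumerate, and the direct-weight optimizer minimizes the
## N-dimensional weight cost (reverse KL) that classical Bayesian ensemble
## refinement uses -- a reference method, never a production path here.

## closed-form cost curve of the micro system (prior (.5,.5), d2 = (1,0)):
## w2(k) = logistic(k/2), chi2 = (1-w2)^2,
## D_fwd = .5 ln(.5/w1) + .5 ln(.5/w2)
microCostOracle <- function(theta, kGrid = seq(0, 20, by = 1e-3)) {
  w2 <- stats::plogis(kGrid / 2)
  w1 <- 1 - w2
  cost <- theta * (0.5 * log(0.5 / w1) + 0.5 * log(0.5 / w2)) + (1 - w2)^2
  i <- which.min(cost)
  list(k = kGrid[i], cost = cost[i])
}

## exhaustive cost evaluation over a 2-D k grid for a tiny M = 2 system
## with uniform prior; vectorized over grid columns
gridSearchCost2D <- function(theta, obs, kMax = 8, step = 0.02) {
  d2 <- deviationMatrix(obs)
  n <- nrow(d2)
  p <- rep(1 / n, n)
  ks <- seq(0, kMax, by = step)
  K <- as.matrix(expand.grid(k1 = ks, k2 = ks))
  V <- d2 %*% t(K) / 2                      # n x G
  U <- exp(sweep(-V, 2, apply(-V, 2, max)))
  W <- sweep(U, 2, colSums(U), "/")
  cm <- calcMatrix(obs)
  avg <- crossprod(cm, W)                   # 2 x G
  r <- sweep(-avg, 1, unname(expValues(obs)), "+") / unname(sigmas(obs))
  chi <- colMeans(r * r)
  dkl <- colSums(p * log(p / W))
  cost <- theta * dkl + chi
  i <- which.min(cost)
  list(k = unname(K[i, ]), cost = cost[i])
}

## direct N-dimensional weight optimizer of cost(w) = theta * D_KL(w||w0)
## + chi2(w) (reverse KL), softmax-parameterized, analytic gradient
directWeightOpt <- function(theta, w0, obs, zInit = NULL, maxit = 5000) {
  cm <- calcMatrix(obs)
  sig <- unname(sigmas(obs))
  expv <- unname(expValues(obs))
  m <- ncol(cm)
  logw0 <- log(w0)
  fn <- function(z) {
    u <- exp(z - max(z)); w <- u / sum(u)
    r <- (expv - drop(crossprod(cm, w))) / sig
    theta * sum(w * (log(w) - logw0)) + mean(r * r)
  }
  gr <- function(z) {
    u <- exp(z - max(z)); w <- u / sum(u)
    r <- (expv - drop(crossprod(cm, w))) / sig
    gw <- theta * (log(w) - logw0 + 1) + drop(cm %*% (-(2 / m) * r / sig))
    w * (gw - sum(w * gw))
  }
  if (is.null(zInit)) zInit <- logw0
  o <- stats::optim(zInit, fn, gr, method = "L-BFGS-B",
                    control = list(maxit = maxit, factr = 1e1))
  u <- exp(o$par - max(o$par)); w <- u / sum(u)
  list(w = w, z = o$par, chi2 = chi2(w, obs),
       ep = ensemblePreservation(w, w0))
}

## bisect the direct optimizer's theta until its ensemble preservation
## matches the target (ep is monotone in theta)
directMatchEP <- function(epTarget, w0, obs, tol = 0.02) {
  lo <- log(1e-5); hi <- log(1e5); z <- NULL; d <- NULL
  for (i in 1:60) {
    mid <- (lo + hi) / 2
    d <- directWeightOpt(exp(mid), w0, obs, zInit = z)
    z <- d$z
    if (d$ep < epTarget) lo <- mid else hi <- mid
    if (abs(d$ep - epTarget) < tol) break
  }
  d
}

## bisect the umbrella refinement's theta to a target ensemble preservation
ureMatchEP <- function(epTarget, prior, obs, tol = 0.05) {
  lo <- log(1e-4); hi <- log(1e4); res <- NULL
  for (i in 1:50) {
    mid <- (lo + hi) / 2
    res <- optimizeK(exp(mid), prior, obs)
    if (res@ensemblePreservation < epTarget) lo <- mid else hi <- mid
    if (abs(res@ensemblePreservation - epTarget) < tol) break
  }
  res
}
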