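# Fast profiled maximum-likelihood machinery for intercept-only Gaussian
# models with one or two crossed random-intercept factors. Used by the
# parametric bootstrap, where tens of thousands of refits make a general
# mixed-model optimizer the bottleneck. Everything is computed from the
# factor cross-tabulations via the Woodbury identity, so the per-evaluation
# cost is O(q^3) in q = (number of trees + number of seasons), independent
# of the number of fruits.

# structure shared by all refits on the same design
.lmm_struct <- function(f1, f2 = NULL) {
  f1 <- droplevels(as.factor(f1))
  q1 <- nlevels(f1); i1 <- as.integer(f1)
  if (is.null(f2)) {
    list(n = length(i1), i1 = i1, i2 = NULL, q1 = q1, q2 = 0L,
         ZtZ = diag(tabulate(i1, q1)), cnt = tabulate(i1, q1))
  } else {
    f2 <- droplevels(as.factor(f2))
    q2 <- nlevels(f2); i2 <- as.integer(f2)
    ct <- matrix(0, q1, q2)
    tab <- table(f1, f2)
    ct[, ] <- tab
    ZtZ <- rbind(cbind(diag(tabulate(i1, q1)), ct),
                 cbind(t(ct), diag(tabulate(i2, q2))))
    list(n = length(i1), i1 = i1, i2 = i2, q1 = q1, q2 = q2, ZtZ = ZtZ,
         cnt = c(tabulate(i1, q1), tabulate(i2, q2)))
  }
}

# profiled ML deviance (-2 loglik) at variance ratios gamma = sd^2/sigma^2;
# gamma has one entry per factor present in the structure
.lmm_profiled_dev <- function(gamma, st, yty, Zty, suma, n) {
  if (any(!is.finite(gamma))) return(1e10)
  gamma <- pmax(gamma, 0)   # finite-difference steps may graze the boundary
  s <- sqrt(rep(gamma, times = c(st$q1, if (st$q2 > 0) st$q2)))
  B <- diag(length(s)) + (s %o% s) * st$ZtZ
  R <- tryCatch(chol(B), error = function(e) NULL)
  if (is.null(R)) return(1e10)
  logdetW <- 2 * sum(log(diag(R)))
  # quadratic forms w' W^-1 v = w'v - (s Z'w)' B^-1 (s Z'v)
  sy <- s * Zty; s1 <- s * st$cnt
  By <- backsolve(R, backsolve(R, sy, transpose = TRUE))
  B1 <- backsolve(R, backsolve(R, s1, transpose = TRUE))
  yWy <- yty - sum(sy * By)
  oWy <- suma - sum(s1 * By)
  oWo <- n - sum(s1 * B1)
  rss <- yWy - oWy^2 / oWo
  sig2 <- max(rss / n, 1e-12)
  n * (log(2 * pi * sig2) + 1) + logdetW
}

# minimized profiled ML deviance; gamma >= 0 with the boundary allowed
.lmm_mldev_min <- function(st, y, start = NULL) {
  yty <- sum(y * y); suma <- sum(y)
  Zty <- c(rowsum(y, st$i1)[, 1],
           if (st$q2 > 0) rowsum(y, st$i2)[, 1])
  k <- if (st$q2 > 0) 2L else 1L
  f <- function(g) .lmm_profiled_dev(g, st, yty, Zty, suma, st$n)
  if (is.null(start)) start <- rep(0.5, k)
  start <- pmax(start, 1e-4)
  opt <- stats::optim(start, f, method = "L-BFGS-B",
                      lower = rep(0, k), upper = rep(1e6, k),
                      control = list(factr = 1e9))
  # the boundary (all-zero) candidate, in case the optimizer stalls short
  dev0 <- f(rep(0, k))
  if (dev0 < opt$value) list(dev = dev0, gamma = rep(0, k))
  else list(dev = opt$value, gamma = opt$par)
}

# ML deviance of the intercept-only model with no random effects
.lmm_mldev_null0 <- function(y) {
  n <- length(y)
  sig2 <- max(sum((y - mean(y))^2) / n, 1e-12)
  n * (log(2 * pi * sig2) + 1)
}

# parameters (mu, sds, sigma) of the profiled fit, for simulating
.lmm_null_params <- function(st, y, gamma) {
  yty <- sum(y * y); suma <- sum(y)
  Zty <- c(rowsum(y, st$i1)[, 1],
           if (st$q2 > 0) rowsum(y, st$i2)[, 1])
  s <- sqrt(rep(gamma, times = c(st$q1, if (st$q2 > 0) st$q2)))
  B <- diag(length(s)) + (s %o% s) * st$ZtZ
  R <- chol(B)
  sy <- s * Zty; s1 <- s * st$cnt
  By <- backsolve(R, backsolve(R, sy, transpose = TRUE))
  B1 <- backsolve(R, backsolve(R, s1, transpose = TRUE))
  yWy <- yty - sum(sy * By)
  oWy <- suma - sum(s1 * By)
  oWo <- st$n - sum(s1 * B1)
  mu <- oWy / oWo
  sig2 <- max((yWy - oWy^2 / oWo) / st$n, 1e-12)
  list(mu = mu, sigma = sqrt(sig2), sds = sqrt(gamma * sig2))
}
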