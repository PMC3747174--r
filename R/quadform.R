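#' Null eigenvalue spectrum of the global statistic
#'
#' Under profile equality the statistic `V = nm/(n+m) d(P, Q)` behaves like
#' `sum_i beta_i chisq_1`, where the `beta_i` are the non-zero eigenvalues
#' of `J %*% Sigma`, `J` the 2s x 2s block matrix `[[I, -I], [-I, I]]` and
#' `Sigma` the joint profile covariance. Writing `J = K'K` with
#' `K = [I, -I]`, the non-zero eigenvalues of `K'K Sigma` equal those of the
#' s x s symmetric matrix `K Sigma K' = (m A - k B - k B' + n C) / (n + m)`,
#' which is what this function diagonalises.
#'
#' @param S A [joint_covariance()] object, or a bare 2s x 2s symmetric
#'   matrix (diagonalised through the same `K Sigma K'` reduction).
#' @param tol Relative truncation tolerance: eigenvalues in
#'   `[-tol * max, tol * max]` are set to zero; anything more negative is
#'   clipped with a warning (the covariance estimate is then numerically
#'   indefinite).
#' @return Numeric vector of positive eigenvalues in decreasing order
#'   (length 0 for a fully degenerate null, e.g. two identical lists).
#' @export
null_betas <- function(S, tol = 1e-12) {
  if (inherits(S, "joint_covariance")) {
    R <- (S$m * S$A - S$k * S$B - S$k * t(S$B) + S$n * S$C) / (S$n + S$m)
  } else {
    S <- as.matrix(S)
    d <- nrow(S)
    if (d != ncol(S) || d %% 2L != 0L)
      stop("'S' must be a 2s x 2s matrix or a joint_covariance")
    if (max(abs(S - t(S))) > 1e-8 * max(1, max(abs(S))))
      stop("'S' is not symmetric")
    s <- d %/% 2L
    i1 <- seq_len(s); i2 <- s + i1
    R <- S[i1, i1] - S[i1, i2] - S[i2, i1] + S[i2, i2]
  }
  asym <- max(abs(R - t(R)))
  if (asym > 1e-8 * max(1, max(abs(R))))
    stop("reduced covariance is not symmetric")
  R <- (R + t(R)) / 2
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(ev, 0)
  if (any(ev < -tol * mx))
    warning("covariance estimate has negative eigenvalues (min ",
            format(min(ev)), "); clipped to zero")
  ev <- ev[ev > tol * mx & ev > 0]
  sort(ev, decreasing = TRUE)
}

# Ruben-type series: P(sum beta_i X_i <= x) = sum_k a_k F_{s+2k}(x / b*)
# with b* = min(beta); all mixing weights are non-negative and sum to one,
# so the truncation error is bounded by the unassigned weight.
.qf_ruben <- function(beta, x, eps = 1e-10, kmax = 20000L, block = 256L) {
  s <- length(beta)
  bstar <- min(beta)
  la0 <- 0.5 * sum(log(bstar / beta))
  if (la0 < log(.Machine$double.xmin) / 2) return(NULL)   # hopeless spread
  r <- 1 - bstar / beta
  y <- x / bstar
  a <- numeric(kmax + 1L)
  g <- numeric(kmax)
  rp <- r
  a[1L] <- exp(la0)
  tot <- a[1L]
  cdf <- a[1L] * stats::pchisq(y, s)
  k <- 0L
  while (k < kmax && 1 - tot > eps) {
    hi <- min(k + block, kmax)
    for (j in (k + 1L):hi) { g[j] <- sum(rp); rp <- rp * r }
    for (kk in (k + 1L):hi) {
      a[kk + 1L] <- sum(g[1:kk] * a[kk:1]) / (2 * kk)
    }
    cdf <- cdf + sum(a[(k + 2L):(hi + 1L)] *
                       stats::pchisq(y, s + 2 * ((k + 1L):hi)))
    tot <- tot + sum(a[(k + 2L):(hi + 1L)])
    k <- hi
  }
  if (1 - tot > eps) return(NULL)
  min(max(1 - cdf, 0), 1)
}

# Imhof characteristic-function inversion via adaptive quadrature
.qf_imhof <- function(beta, x) {
  f <- function(u) {
    th <- 0.5 * colSums(atan(outer(beta, u))) - 0.5 * x * u
    rho <- exp(0.25 * colSums(log1p(outer(beta^2, u^2))))
    out <- sin(th) / (u * rho)
    out[u == 0] <- (sum(beta) - x) / 2
    out
  }
  r <- tryCatch(
    stats::integrate(f, 0, Inf, rel.tol = 1e-10, abs.tol = 1e-10,
                     subdivisions = 5000L, stop.on.error = FALSE),
    error = function(e) NULL)
  if (is.null(r)) return(NULL)
  list(p = min(max(0.5 + r$value / pi, 0), 1), err = r$abs.error)
}

# deterministic Monte-Carlo last resort; restores the caller's RNG state
.qf_mc <- function(beta, x, draws = 1e6L, seed = 8677164L) {
  s <- length(beta)
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  chunk <- 200000L
  hits <- 0
  done <- 0L
  while (done < draws) {
    nn <- min(chunk, draws - done)
    X <- matrix(stats::rnorm(s * nn)^2, nrow = s)
    hits <- hits + sum(colSums(beta * X) > x)
    done <- done + nn
  }
  hits / draws
}

#' Upper tail probability of a chi-square mixture
#'
#' Computes `P(sum_i beta_i chisq_1,i > x)` for non-negative weights
#' `beta`, the null distribution of the global profile-comparison
#' statistic. Equal-weight spectra are evaluated exactly through the scaled
#' chi-square distribution; otherwise an Imhof-type numerical inversion of
#' the characteristic function and a mixture-of-chi-squares series
#' (whichever attains the tighter error bound first) are used, targeting an
#' absolute error of 1e-6 or better. For pathological spectra where both
#' fail to converge, a deterministic seeded Monte-Carlo estimate (1e6
#' draws) is returned with a warning.
#'
#' @param beta Numeric vector of non-negative mixture weights; zeros are
#'   ignored.
#' @param x Evaluation point, `x >= 0`.
#' @return Tail probability in `[0, 1]`. If all weights are zero the
#'   statistic is identically zero: the function warns and returns 1 for
#'   `x = 0` (the p-value convention for identical profiles) and 0 for
#'   `x > 0`.
#' @seealso [qf_quantile()], [null_betas()]
#' @export
qf_upper_tail <- function(beta, x) {
  beta <- as.numeric(beta)
  if (any(!is.finite(beta)) || any(beta < 0))
    stop("'beta' must be finite and non-negative")
  if (!is.finite(x) || x < 0) stop("'x' must be finite and non-negative")
  beta <- beta[beta > 0]
  if (!length(beta)) {
    warning("all mixture weights are zero: the statistic is degenerate at 0")
    return(if (x <= 0) 1 else 0)
  }
  if (x == 0) return(1)
  s <- length(beta)
  if (max(beta) / min(beta) - 1 < 1e-9)         # sum = mean(beta) * chisq_s
    return(stats::pchisq(x / mean(beta), df = s, lower.tail = FALSE))
  im <- .qf_imhof(beta, x)
  if (!is.null(im) && im$err <= 1e-7) return(im$p)
  rb <- .qf_ruben(beta, x)
  if (!is.null(rb)) return(rb)
  if (!is.null(im) && im$err <= 1e-6) return(im$p)
  warning("quadrature did not reach the accuracy target; ",
          "falling back to seeded Monte Carlo (1e6 draws)")
  .qf_mc(beta, x)
}

#' Quantile of a chi-square mixture
#'
#' The threshold `v` with `P(sum_i beta_i chisq_1,i <= v) = prob`, i.e. the
#' critical value `v(alpha, s)` of the global test when
#' `prob = 1 - alpha`. Solved by bracketed root refinement of
#' [qf_upper_tail()]; the bracket uses the stochastic bounds
#' `max(beta) chisq_1 <= sum beta_i chisq_1,i <= max(beta) chisq_s`.
#'
#' @param beta Non-negative mixture weights, at least one positive.
#' @param prob Probability level in (0, 1).
#' @return The quantile (a non-negative scalar).
#' @export
qf_quantile <- function(beta, prob) {
  beta <- as.numeric(beta)
  beta <- beta[beta > 0]
  if (!length(beta)) stop("degenerate null: all mixture weights are zero")
  if (!is.finite(prob) || prob <= 0 || prob >= 1)
    stop("'prob' must be in (0, 1)")
  s <- length(beta)
  if (max(beta) / min(beta) - 1 < 1e-9)
    return(mean(beta) * stats::qchisq(prob, df = s))
  lo <- max(beta) * stats::qchisq(prob, df = 1) * 0.5
  hi <- max(beta) * stats::qchisq(prob, df = s) * 1.001
  f <- function(v) qf_upper_tail(beta, v) - (1 - prob)
  while (f(hi) > 0) hi <- hi * 2
  while (f(lo) < 0) lo <- lo / 2
  stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
}
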