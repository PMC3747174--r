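#' Covariance matrix of a functional profile
#'
#' The expanded profile is multinomial over disjoint cells, and the
#' contracted profile is a linear image of it (each class marginal sums the
#' cells containing that class). The resulting s x s covariance of the
#' scaled profile has entries
#' `sigma_ii = p_i (1 - p_i)` and `sigma_ij = p_ij - p_i p_j`,
#' where `p_ij` is the joint two-class marginal of [pair_marginal()].
#'
#' @param x An `expanded_profile` (plug-in estimate from the sample cell
#'   frequencies) or an `expanded_population` (exact population value).
#' @param ... Unused.
#' @return Symmetric s x s matrix with class identifiers as dimnames.
#' @export
profile_covariance <- function(x, ...) UseMethod("profile_covariance")

#' @export
profile_covariance.expanded_profile <- function(x, ...) {
  if (x$n == 0L) stop("empty expanded profile (n = 0)")
  .profile_cov(x)
}

#' @export
profile_covariance.expanded_population <- function(x, ...) .profile_cov(x)

.profile_cov <- function(x) {
  p <- .class_marginals(x)
  .marginal_matrix(x) - outer(p, p)
}

.zero_matrix <- function(class_order) {
  s <- length(class_order)
  matrix(0, s, s, dimnames = list(class_order, class_order))
}

#' Joint covariance of two (possibly overlapping) sample profiles
#'
#' For lists of sizes n and m sharing k genes, the centred and
#' `sqrt(nm/(n+m))`-scaled pair of contracted profiles is asymptotically
#' normal with a 2s x 2s covariance assembled from three s x s blocks:
#' \describe{
#'   \item{A}{`(k/n) Sigma_P0 + ((n-k)/n) Sigma_P1` -- covariance of list A,}
#'   \item{B}{`Sigma_P0` -- cross-covariance induced by the shared genes,}
#'   \item{C}{`(k/m) Sigma_P0 + ((m-k)/m) Sigma_Q1` -- covariance of list B,}
#' }
#' weighted into `[[m/(n+m) A, k/(n+m) B], [k/(n+m) B', n/(n+m) C]]`.
#' Terms with zero weight (k = 0, n = k or m = k) are dropped rather than
#' evaluated, so empty components never produce 0/0.
#'
#' @param dec A [decompose_pair()] result (or [new_pair_decomposition()]).
#'   Component covariances can also be supplied directly via `Sigma0`,
#'   `Sigma1`, `SigmaQ1` to evaluate the formula at population values.
#' @param Sigma0,Sigma1,SigmaQ1 Optional s x s matrices overriding the
#'   plug-in estimates for the shared and exclusive components.
#' @return Object of class `joint_covariance` with elements `Sigma`
#'   (2s x 2s), `A`, `B`, `C`, `n`, `m`, `k`, `class_order`.
#' @export
joint_covariance <- function(dec, Sigma0 = NULL, Sigma1 = NULL, SigmaQ1 = NULL) {
  stopifnot(inherits(dec, "pair_decomposition"))
  n <- dec$n; m <- dec$m; k <- dec$k
  if (n < 1L || m < 1L) stop("both lists must contain at least one gene")
  if (k > min(n, m)) stop("k cannot exceed min(n, m)")
  co <- dec$class_order
  zero <- .zero_matrix(co)

  S0 <- if (k > 0) {
    if (is.null(Sigma0)) profile_covariance(dec$P0) else Sigma0
  } else zero
  S1 <- if (n - k > 0) {
    if (is.null(Sigma1)) profile_covariance(dec$P1) else Sigma1
  } else zero
  SQ1 <- if (m - k > 0) {
    if (is.null(SigmaQ1)) profile_covariance(dec$Q1) else SigmaQ1
  } else zero

  A <- (k / n) * S0 + ((n - k) / n) * S1
  B <- if (k > 0) S0 else zero
  C <- (k / m) * S0 + ((m - k) / m) * SQ1

  w <- n + m
  Sigma <- rbind(cbind((m / w) * A, (k / w) * B),
                 cbind((k / w) * t(B), (n / w) * C))
  structure(list(Sigma = Sigma, A = A, B = B, C = C,
                 n = n, m = m, k = k, class_order = co),
            class = "joint_covariance")
}

#' @export
print.joint_covariance <- function(x, ...) {
  cat("Joint profile covariance: s =", length(x$class_order),
      " (n =", x$n, ", m =", x$m, ", k =", x$k, ")\n")
  invisible(x)
}

#' Export a covariance matrix as TSV
#'
#' Debugging aid: writes any matrix (e.g. the `Sigma` or block components of
#' [joint_covariance()]) with row and column names.
#'
#' @param mat Numeric matrix.
#' @param path File path.
#' @export
write_covariance_tsv <- function(mat, path) {
  utils::write.table(mat, path, sep = "\t", quote = FALSE, col.names = NA)
  invisible(path)
}
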