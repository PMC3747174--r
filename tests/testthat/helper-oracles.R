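# Independent oracles and fixture builders shared across the test files.
# Each oracle deliberately re-derives its quantity from first principles
# (loops, enumeration, brute-force linear algebra or Monte Carlo) so that it
# cannot share a code path with the implementation it checks.

# four genes over three overlapping classes; the package's running example
toy_annotation <- function() {
  annotation_index(
    list(g1 = "A1", g2 = c("A1", "A2"), g3 = c("A2", "A3"), g4 = "A3"),
    class_order = c("A1", "A2", "A3"))
}

# random gene -> class-subset annotation over s classes
random_annotation <- function(n_genes, s, p_unannotated = 0.1,
                              max_terms = 3L) {
  classes <- paste0("C", seq_len(s))
  mapping <- lapply(seq_len(n_genes), function(i) {
    if (runif(1) < p_unannotated) return(character())
    sample(classes, sample.int(min(max_terms, s), 1L))
  })
  names(mapping) <- paste0("g", seq_len(n_genes))
  annotation_index(mapping, class_order = classes)
}

# plain-loop subset-sum: marginal frequency of every class
oracle_contract <- function(e) {
  out <- numeric(length(e$class_order))
  names(out) <- e$class_order
  for (key in names(e$counts)) {
    for (cl in strsplit(key, ";", fixed = TRUE)[[1L]]) {
      out[cl] <- out[cl] + e$counts[[key]]
    }
  }
  out / e$n
}

# covariance via the explicit linear image M' Sigma_multinomial M of the
# multinomial cell covariance (n * Sigma_mult = diag(f) - f f')
oracle_profile_cov <- function(e) {
  f <- e$counts / e$n
  keys <- names(e$counts)
  M <- matrix(0, length(keys), length(e$class_order),
              dimnames = list(keys, e$class_order))
  for (i in seq_along(keys)) {
    for (cl in strsplit(keys[i], ";", fixed = TRUE)[[1L]]) M[i, cl] <- 1
  }
  t(M) %*% (diag(f, nrow = length(f)) - outer(f, f)) %*% M
}

# chi-square mixture upper tail by plain Monte Carlo
oracle_mc_tail <- function(beta, x, draws, chunk = 200000L) {
  s <- length(beta)
  hits <- 0; done <- 0
  while (done < draws) {
    nn <- min(chunk, draws - done)
    X <- matrix(rnorm(s * nn)^2, nrow = s)
    hits <- hits + sum(colSums(beta * X) > x)
    done <- done + nn
  }
  hits / draws
}

# Holm step-down by the textbook sorted loop
oracle_holm <- function(p) {
  s <- length(p)
  o <- order(p)
  adj <- numeric(s)
  running <- 0
  for (i in seq_len(s)) {
    running <- max(running, (s - i + 1) * p[o[i]])
    adj[o[i]] <- min(running, 1)
  }
  adj
}

# two-sided Fisher p by enumeration of all tables with the observed margins
oracle_fisher <- function(a, b, c, d) {
  r1 <- a + b; c1 <- a + c; n <- a + b + c + d
  lo <- max(0L, c1 - (n - r1)); hi <- min(r1, c1)
  probs <- vapply(lo:hi, function(x)
    exp(lchoose(r1, x) + lchoose(n - r1, c1 - x) - lchoose(n, c1)),
    numeric(1L))
  p_obs <- probs[a - lo + 1L]
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# non-zero eigenvalues of the literal 2s x 2s product J Sigma
oracle_full_betas <- function(Sigma2s) {
  s <- nrow(Sigma2s) %/% 2L
  I <- diag(s)
  J <- rbind(cbind(I, -I), cbind(-I, I))
  ev <- Re(eigen(J %*% Sigma2s, only.values = TRUE)$values)
  sort(ev[ev > 1e-10 * max(abs(ev), 1e-300)], decreasing = TRUE)
}

# random sampled decomposition from a common synthetic population
random_decomposition <- function(s, n, m, k, unannotated = 0.1) {
  pop <- synthetic_population(s, unannotated = unannotated)
  cfg <- scenario_config(pop, pop, n, m, k = k)
  simulate_pair(cfg)
}
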