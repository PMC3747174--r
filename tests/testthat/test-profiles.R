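test_that("expanded profiles count each gene once, in its exact class subset", {
  ann <- toy_annotation()
  e <- build_expanded(c("g1", "g2", "g3", "g4"), ann)
  expect_equal(e$n, 4L)
  expect_equal(e$counts[order(names(e$counts))],
               c("A1" = 1, "A1;A2" = 1, "A2;A3" = 1, "A3" = 1))
  expect_equal(sum(e$counts) / e$n, 1)

  # point mass: five genes annotated only in A1
  ann1 <- annotation_index(stats::setNames(as.list(rep("A1", 5)),
                                           paste0("x", 1:5)),
                           class_order = c("A1", "A2", "A3"))
  e1 <- build_expanded(paste0("x", 1:5), ann1)
  expect_equal(e1$counts, c(A1 = 5))

  # unannotated genes are excluded and reported
  ann2 <- annotation_index(list(a = "A1", b = "A2", c = character()),
                           class_order = c("A1", "A2"))
  e2 <- build_expanded(c("a", "b", "c"), ann2)
  expect_equal(e2$n, 2L)
  expect_equal(e2$n_unannotated, 1L)

  # ... or kept in an explicit empty cell on request
  e3 <- build_expanded(c("a", "b", "c"), ann2, include_unannotated = TRUE)
  expect_equal(e3$n, 3L)
  expect_equal(unname(e3$counts[names(e3$counts) == ""]), 1)

  expect_error(build_expanded(c("zz", "yy"), ann2), "no annotated genes")
  expect_warning(build_expanded(c("a", "a", "b"), ann2), "duplicated")
})

test_that("contraction reproduces the subset-sum marginals", {
  ann <- toy_annotation()
  e <- build_expanded(c("g1", "g2", "g3", "g4"), ann)
  expect_equal(contract(e)$p, c(A1 = 0.5, A2 = 0.5, A3 = 0.5))

  ann1 <- annotation_index(stats::setNames(as.list(rep("A1", 5)),
                                           paste0("x", 1:5)),
                           class_order = c("A1", "A2", "A3"))
  expect_equal(contract(build_expanded(paste0("x", 1:5), ann1))$p,
               c(A1 = 1, A2 = 0, A3 = 0))

  # every gene in all classes -> all marginals at the upper bound 1
  annall <- annotation_index(stats::setNames(
    rep(list(c("A1", "A2", "A3")), 4), paste0("y", 1:4)))
  expect_equal(contract(build_expanded(paste0("y", 1:4), annall))$p,
               c(A1 = 1, A2 = 1, A3 = 1))

  empty <- goCompare:::.new_expanded_profile(numeric(0), c("A1", "A2"))
  expect_error(contract(empty), "n = 0")
})

test_that("contracted marginals match an independent subset-sum oracle", {
  set.seed(421)
  for (rep in 1:25) {
    s <- sample(2:5, 1)
    ann <- random_annotation(sample(10:50, 1), s)
    genes <- names(ann$mapping)
    e <- tryCatch(build_expanded(genes, ann), error = function(e) NULL)
    if (is.null(e)) next
    expect_equal(contract(e)$p, oracle_contract(e))
    expect_equal(sum(e$counts) / e$n, 1)
  }
})

test_that("pairwise joint marginals follow the definition", {
  ann <- toy_annotation()
  e <- build_expanded(c("g1", "g2", "g3", "g4"), ann)
  expect_equal(pair_marginal(e, 1, 2), 0.25)
  expect_equal(pair_marginal(e, 1, 3), 0)
  expect_equal(pair_marginal(e, "A2", "A3"), 0.25)
  expect_error(pair_marginal(e, 2, 2), "must differ")

  # disjoint single-class annotations: all pairs at zero
  annd <- annotation_index(list(u = "A1", v = "A2", w = "A3"))
  ed <- build_expanded(c("u", "v", "w"), annd)
  for (i in 1:2) for (j in (i + 1):3)
    expect_equal(pair_marginal(ed, i, j), 0)
})

test_that("squared distance is the sum of squared marginal differences", {
  expect_equal(squared_distance(c(0.5, 0.5, 0.5), c(0.5, 0.5, 0.5)), 0)
  expect_equal(squared_distance(c(0.5, 0.5, 0.5), c(0.25, 0.5, 0.75)), 0.125)
  expect_equal(squared_distance(c(1, 0), c(0, 1)), 2)

  P <- structure(list(n = 4L, p = c(A = .2, B = .4), class_order = c("A", "B")),
                 class = "contracted_profile")
  Q <- structure(list(n = 9L, p = c(A = .1, B = .9), class_order = c("A", "B")),
                 class = "contracted_profile")
  expect_equal(squared_distance(P, Q), squared_distance(Q, P))
  Qbad <- Q; Qbad$class_order <- c("B", "A")
  expect_error(squared_distance(P, Qbad), "different class sets")
})

test_that("distance is bounded by the number of classes", {
  set.seed(99)
  for (rep in 1:50) {
    s <- sample(1:6, 1)
    p <- runif(s); q <- runif(s)
    expect_gte(squared_distance(p, q), 0)
    expect_lte(squared_distance(p, q), s)
  }
})

test_that("pair decomposition covers the overlap cases and recomposes", {
  ann <- toy_annotation()
  all4 <- c("g1", "g2", "g3", "g4")

  # identical lists: full overlap, exclusive parts empty
  dec <- decompose_pair(all4, all4, ann)
  expect_equal(c(dec$n, dec$m, dec$k), c(4L, 4L, 4L))
  expect_equal(dec$P1$n, 0L)
  expect_equal(dec$Q1$n, 0L)

  # disjoint lists
  dec2 <- decompose_pair(c("g1", "g2"), c("g3", "g4"), ann)
  expect_equal(dec2$k, 0L)
  expect_equal(dec2$P0$n, 0L)

  # partial overlap; count recomposition is exact
  dec3 <- decompose_pair(c("g1", "g2", "g3"), c("g2", "g3", "g4"), ann)
  expect_equal(dec3$k, 2L)
  full <- assemble_profiles(dec3)
  direct <- build_expanded(c("g1", "g2", "g3"), ann)
  expect_equal(full$P$counts[order(names(full$P$counts))],
               direct$counts[order(names(direct$counts))])
})

test_that("recomposition identities hold exactly on random list pairs", {
  set.seed(2026)
  for (rep in 1:1000) {
    s <- sample(2:5, 1)
    ann <- random_annotation(sample(8:30, 1), s, p_unannotated = 0.2)
    genes <- names(ann$mapping)
    A <- sample(genes, sample.int(length(genes), 1))
    B <- sample(genes, sample.int(length(genes), 1))
    dec <- decompose_pair(A, B, ann)
    expect_identical(dec$n, dec$k + dec$P1$n)
    expect_identical(dec$m, dec$k + dec$Q1$n)
    # n * Phat = k * Phat0 + (n - k) * Phat1 cell by cell (and m * Qhat)
    full <- assemble_profiles(dec)
    if (dec$n > 0) {
      pd <- build_expanded(A, ann)
      expect_equal(full$P$counts[order(names(full$P$counts))],
                   pd$counts[order(names(pd$counts))])
    }
    if (dec$m > 0) {
      qd <- build_expanded(B, ann)
      expect_equal(full$Q$counts[order(names(full$Q$counts))],
                   qd$counts[order(names(qd$counts))])
    }
  }
})

test_that("expanded profiles survive a TSV round trip", {
  ann <- toy_annotation()
  e <- build_expanded(c("g1", "g2", "g3", "g4"), ann)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_expanded_tsv(e, path)
  e2 <- read_expanded_tsv(path)
  expect_equal(e2$counts, e$counts)
  expect_equal(e2$class_order, e$class_order)
  expect_equal(e2$n, e$n)
})

test_that("population profiles validate, mix and contract", {
  pop <- expanded_population(
    stats::setNames(c(0.5, 0.3, 0.2), c("A1", "A1;A2", "")),
    class_order = c("A1", "A2"))
  expect_equal(contract(pop)$p, c(A1 = 0.8, A2 = 0.3))
  expect_error(expanded_population(c("A1" = 0.5), c("A1", "A2")), "sum to 1")
  expect_error(expanded_population(c("ZZ" = 1), c("A1", "A2")), "outside")

  pop2 <- expanded_population(c("A2" = 1), class_order = c("A1", "A2"))
  mixed <- mix_populations(list(pop, pop2), c(0.5, 0.5))
  expect_equal(contract(mixed)$p, c(A1 = 0.4, A2 = 0.65))
})
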