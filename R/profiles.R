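#' Annotation index over a fixed set of target classes
#'
#' Builds the gene-to-class lookup used by all profiling functions. Each gene
#' maps to the subset of the `s` target classes in which it is annotated;
#' classes outside `class_order` are dropped. The order of `class_order`
#' fixes the coordinate system of every profile and covariance matrix
#' derived from the index.
#'
#' @param mapping Either a named list (gene identifier -> character vector of
#'   class identifiers) or a two-column data frame (gene, class).
#' @param class_order Character vector of the `s` target class identifiers.
#'   Defaults to the sorted union of all classes present in `mapping`.
#' @return An object of class `annotation_index` with elements `mapping`
#'   (named list, each entry in `class_order` order) and `class_order`.
#' @examples
#' ann <- annotation_index(
#'   list(g1 = "A1", g2 = c("A1", "A2"), g3 = c("A2", "A3"), g4 = "A3"),
#'   class_order = c("A1", "A2", "A3"))
#' @export
annotation_index <- function(mapping, class_order = NULL) {
  if (is.data.frame(mapping)) {
    if (ncol(mapping) < 2L)
      stop("a data-frame 'mapping' needs at least two columns (gene, class)")
    mapping <- split(as.character(mapping[[2L]]), as.character(mapping[[1L]]))
  }
  if (!is.list(mapping) || is.null(names(mapping)) || any(!nzchar(names(mapping))))
    stop("'mapping' must be a named list or a two-column data frame")
  if (is.null(class_order))
    class_order <- sort(unique(unlist(mapping, use.names = FALSE)))
  class_order <- as.character(class_order)
  if (length(class_order) < 1L)
    stop("at least one target class is required")
  if (anyDuplicated(class_order))
    stop("duplicated identifiers in 'class_order'")
  # intersect() keeps class_order's order, giving each gene a canonical subset
  mapping <- lapply(mapping, function(x) intersect(class_order, as.character(x)))
  structure(list(mapping = mapping, class_order = class_order),
            class = "annotation_index")
}

#' @export
print.annotation_index <- function(x, ...) {
  cat("Annotation index:", length(x$mapping), "genes,",
      length(x$class_order), "target classes\n")
  invisible(x)
}

# canonical cell key: class names in class_order order, ";"-joined; "" = unannotated
.cell_key <- function(classes, class_order) {
  paste(intersect(class_order, classes), collapse = ";")
}

# cells x s numeric membership matrix from cell keys
.cell_members <- function(keys, class_order) {
  sets <- strsplit(keys, ";", fixed = TRUE)
  m <- vapply(sets, function(cl) class_order %in% cl,
              logical(length(class_order)))
  matrix(as.numeric(m), nrow = length(keys), ncol = length(class_order),
         byrow = TRUE, dimnames = list(keys, class_order))
}

.new_expanded_profile <- function(counts, class_order, n_unannotated = 0L) {
  counts <- counts[counts > 0]
  if (length(counts)) counts <- counts[order(names(counts))]
  structure(list(counts = counts,
                 n = as.integer(sum(counts)),
                 class_order = as.character(class_order),
                 n_unannotated = as.integer(n_unannotated)),
            class = "expanded_profile")
}

.prep_gene_list <- function(genes, label = "gene list") {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) {
    warning(sprintf("%d duplicated identifier(s) collapsed in %s",
                    sum(duplicated(genes)), label))
    genes <- unique(genes)
  }
  genes
}

.gene_cell_keys <- function(genes, ann) {
  vapply(genes,
         function(g) .cell_key(ann$mapping[[g]], ann$class_order),
         character(1L), USE.NAMES = TRUE)
}

# counts from a vector of cell keys; keys == "" are the unannotated genes
.expanded_from_keys <- function(keys, class_order, include_unannotated = FALSE) {
  unann <- sum(!nzchar(keys))
  if (!include_unannotated) keys <- keys[nzchar(keys)]
  counts <- if (length(keys)) {
    tb <- table(keys)
    stats::setNames(as.numeric(tb), names(tb))
  } else numeric(0)
  .new_expanded_profile(counts, class_order, n_unannotated = unann)
}

#' Expanded profile of a gene list
#'
#' The expanded profile records, for every non-empty combination of target
#' classes, how many genes are annotated in exactly that combination. Unlike
#' the plain ("contracted") profile its cells are mutually exclusive, so the
#' vector of cell counts is multinomial -- the distributional basis of all
#' inference in this package.
#'
#' Genes with no annotation among the target classes are excluded from the
#' profile by default; their number is kept in the `n_unannotated` field.
#' With `include_unannotated = TRUE` they are retained in a dedicated empty
#' cell (key `""`), so `n` counts all genes and the class frequencies are
#' relative to the full list.
#'
#' @param genes Character vector of gene identifiers (duplicates are
#'   collapsed with a warning; identifiers are case-sensitive).
#' @param ann An [annotation_index()].
#' @param include_unannotated Keep unannotated genes in an explicit empty
#'   cell instead of excluding them.
#' @return An object of class `expanded_profile`: `counts` (named numeric,
#'   cell key -> count), `n`, `class_order`, `n_unannotated`.
#' @examples
#' ann <- annotation_index(
#'   list(g1 = "A1", g2 = c("A1", "A2"), g3 = c("A2", "A3"), g4 = "A3"))
#' e <- build_expanded(c("g1", "g2", "g3", "g4"), ann)
#' e$counts
#' @export
build_expanded <- function(genes, ann, include_unannotated = FALSE) {
  stopifnot(inherits(ann, "annotation_index"))
  genes <- .prep_gene_list(genes)
  if (!length(genes)) stop("no annotated genes")
  keys <- .gene_cell_keys(genes, ann)
  if (!any(nzchar(keys))) stop("no annotated genes")
  .expanded_from_keys(keys, ann$class_order, include_unannotated)
}

#' @export
print.expanded_profile <- function(x, ...) {
  cat("Expanded profile: n =", x$n, "genes over", length(x$class_order),
      "classes (", length(x$counts), "occupied cells )\n")
  if (x$n_unannotated > 0)
    cat("  ", x$n_unannotated, "unannotated gene(s)",
        if ("" %in% names(x$counts)) "kept in the empty cell\n" else "excluded\n")
  invisible(x)
}

# relative cell frequencies shared by sample profiles and populations
.cell_freq <- function(x) {
  if (inherits(x, "expanded_population")) return(x$prob)
  if (x$n == 0L) stop("empty expanded profile (n = 0)")
  x$counts / x$n
}

# s x s matrix of joint marginals: entry (i, j) = share of genes annotated
# in both i and j; diagonal = plain class marginals
.marginal_matrix <- function(x) {
  f <- .cell_freq(x)
  M <- .cell_members(names(f), x$class_order)
  crossprod(M, f * M)
}

#' Contract an expanded profile to per-class marginal frequencies
#'
#' The contracted (plain) functional profile is the vector of relative
#' annotation frequencies per class. Since classes overlap, the entries may
#' sum to more than one. Works on sample profiles and on population
#' probability vectors.
#'
#' @param x An [build_expanded()] profile or an [expanded_population()].
#' @param ... Unused.
#' @return Object of class `contracted_profile`: `n` (NA for populations),
#'   `p` (named numeric of length `s`), `class_order`.
#' @export
contract <- function(x, ...) UseMethod("contract")

#' @export
contract.expanded_profile <- function(x, ...) {
  if (x$n == 0L) stop("cannot contract an empty profile (n = 0)")
  structure(list(n = x$n, p = .class_marginals(x), class_order = x$class_order),
            class = "contracted_profile")
}

#' @export
contract.expanded_population <- function(x, ...) {
  structure(list(n = NA_integer_, p = .class_marginals(x),
                 class_order = x$class_order),
            class = "contracted_profile")
}

.class_marginals <- function(x) {
  f <- .cell_freq(x)
  M <- .cell_members(names(f), x$class_order)
  stats::setNames(as.vector(crossprod(M, f)), x$class_order)
}

# absolute per-class counts of a sample expanded profile (exact integers)
.class_counts <- function(e) {
  M <- .cell_members(names(e$counts), e$class_order)
  stats::setNames(as.vector(crossprod(M, e$counts)), e$class_order)
}

#' @export
print.contracted_profile <- function(x, ...) {
  cat("Functional profile over", length(x$p), "classes",
      if (is.na(x$n)) "(population)\n" else paste0("(n = ", x$n, ")\n"))
  print(round(x$p, 4))
  invisible(x)
}

#' Joint two-class annotation frequency
#'
#' Fraction of genes annotated in both class `i` and class `j` (not
#' necessarily exclusively). This is the off-diagonal ingredient of the
#' profile covariance matrix.
#'
#' @param x Expanded profile or population.
#' @param i,j Class identifiers or positional indices; must differ (for
#'   `i == j` the marginal itself is the answer, see [contract()]).
#' @return A single frequency in `[0, 1]`.
#' @export
pair_marginal <- function(x, i, j) {
  co <- x$class_order
  pos <- function(k) if (is.character(k)) match(k, co) else as.integer(k)
  i <- pos(i); j <- pos(j)
  if (is.na(i) || is.na(j) || i < 1L || j < 1L || i > length(co) || j > length(co))
    stop("class index out of range")
  if (i == j) stop("i and j must differ; use contract() for a plain marginal")
  .marginal_matrix(x)[i, j]
}

#' Squared Euclidean distance between two functional profiles
#'
#' The dissimilarity measure underlying the global test:
#' `d(P, Q) = sum_i (p_i - q_i)^2` over the `s` per-class marginal
#' frequencies. Symmetric, non-negative, and zero exactly when the profiles
#' coincide; bounded by `s`.
#'
#' @param P,Q `contracted_profile` objects (or bare numeric vectors of equal
#'   length) on the same classes in the same order.
#' @return Non-negative scalar.
#' @export
squared_distance <- function(P, Q) {
  p <- if (inherits(P, "contracted_profile")) P$p else as.numeric(P)
  q <- if (inherits(Q, "contracted_profile")) Q$p else as.numeric(Q)
  if (inherits(P, "contracted_profile") && inherits(Q, "contracted_profile") &&
      !identical(P$class_order, Q$class_order))
    stop("profiles are defined on different class sets or orders")
  if (length(p) != length(q))
    stop("profiles have different lengths")
  sum((p - q)^2)
}

#' Decompose a pair of gene lists into shared and exclusive parts
#'
#' Two lists A (n genes) and B (m genes) may share k genes, with k ranging
#' from 0 (disjoint) to min(n, m) (one list inside the other). The sample
#' profiles then decompose as mixtures of the profile of the k shared genes
#' and the profiles of the exclusive parts, which is what makes the two
#' observed profiles correlated. This decomposition feeds the joint
#' covariance estimate of [joint_covariance()].
#'
#' @param listA,listB Character vectors of gene identifiers.
#' @param ann An [annotation_index()].
#' @param include_unannotated Keep unannotated genes (see
#'   [build_expanded()]); by default they are excluded before computing the
#'   overlap, so `n`, `m` and `k` refer to annotated genes only.
#' @return Object of class `pair_decomposition` with expanded profiles `P0`
#'   (shared), `P1` (A only), `Q1` (B only) and sizes `n`, `m`, `k`.
#' @export
decompose_pair <- function(listA, listB, ann, include_unannotated = FALSE) {
  stopifnot(inherits(ann, "annotation_index"))
  a <- .prep_gene_list(listA, "list A")
  b <- .prep_gene_list(listB, "list B")
  keysA <- .gene_cell_keys(a, ann)
  keysB <- .gene_cell_keys(b, ann)
  if (!include_unannotated) {
    a <- a[nzchar(keysA)]; keysA <- keysA[nzchar(keysA)]
    b <- b[nzchar(keysB)]; keysB <- keysB[nzchar(keysB)]
  }
  shared <- intersect(a, b)
  co <- ann$class_order
  new_pair_decomposition(
    P0 = .expanded_from_keys(keysA[match(shared, a)], co, include_unannotated),
    P1 = .expanded_from_keys(keysA[match(setdiff(a, shared), a)], co,
                             include_unannotated),
    Q1 = .expanded_from_keys(keysB[match(setdiff(b, shared), b)], co,
                             include_unannotated))
}

#' Assemble a pair decomposition from its component profiles
#'
#' Low-level constructor used by [decompose_pair()] and by the simulation
#' engine, where the shared/exclusive components are drawn directly.
#'
#' @param P0 Expanded profile of the k shared genes (may be empty, n = 0).
#' @param P1,Q1 Expanded profiles of the genes exclusive to each list.
#' @return A `pair_decomposition`.
#' @export
new_pair_decomposition <- function(P0, P1, Q1) {
  co <- P0$class_order
  if (!identical(P1$class_order, co) || !identical(Q1$class_order, co))
    stop("component profiles are defined on different class orders")
  k <- P0$n
  structure(list(P0 = P0, P1 = P1, Q1 = Q1,
                 n = k + P1$n, m = k + Q1$n, k = k, class_order = co),
            class = "pair_decomposition")
}

#' @export
print.pair_decomposition <- function(x, ...) {
  cat("Gene-list pair: n =", x$n, ", m =", x$m, ", shared k =", x$k, "\n")
  invisible(x)
}

# cell-count sum of expanded profiles (recomposition of the full lists)
.combine_expanded <- function(...) {
  parts <- list(...)
  co <- parts[[1L]]$class_order
  keys <- sort(unique(unlist(lapply(parts, function(e) names(e$counts)))))
  counts <- stats::setNames(numeric(length(keys)), keys)
  for (e in parts) {
    at <- match(names(e$counts), keys)      # by position: "" is a valid key
    counts[at] <- counts[at] + e$counts
  }
  .new_expanded_profile(counts, co,
                        n_unannotated = sum(vapply(parts, function(e)
                          e$n_unannotated, integer(1L))))
}

#' Full sample profiles of a decomposed pair
#'
#' Recomposes the expanded profiles of the complete lists A and B from the
#' shared and exclusive components (cell counts add exactly).
#'
#' @param dec A `pair_decomposition`.
#' @return List with expanded profiles `P` and `Q`.
#' @export
assemble_profiles <- function(dec) {
  stopifnot(inherits(dec, "pair_decomposition"))
  list(P = .combine_expanded(dec$P0, dec$P1),
       Q = .combine_expanded(dec$P0, dec$Q1))
}

#' Population expanded profile
#'
#' A probability vector over expanded cells, used as the data-generating
#' truth in simulations and power calculations. Cell keys are
#' `";"`-joined class identifiers; the empty key `""` is allowed and stands
#' for the unannotated fraction of the population.
#'
#' @param prob Named non-negative numeric vector over cell keys; normalised
#'   to sum to one (an error is raised if it is off by more than 1e-6).
#' @param class_order Character vector of the `s` class identifiers.
#' @return Object of class `expanded_population`.
#' @export
expanded_population <- function(prob, class_order) {
  class_order <- as.character(class_order)
  if (is.null(names(prob)))
    stop("'prob' must be named by cell keys")
  if (any(prob < 0)) stop("negative cell probabilities")
  keys <- vapply(strsplit(names(prob), ";", fixed = TRUE),
                 function(cl) {
                   if (length(cl) && !all(cl %in% class_order))
                     stop("cell key refers to a class outside 'class_order'")
                   .cell_key(cl, class_order)
                 }, character(1L))
  prob <- stats::setNames(as.numeric(prob), keys)
  if (anyDuplicated(keys)) prob <- tapply(prob, names(prob), sum)
  tot <- sum(prob)
  if (abs(tot - 1) > 1e-6)
    stop("cell probabilities must sum to 1 (got ", format(tot), ")")
  prob <- prob / tot
  prob <- prob[order(names(prob))]
  structure(list(prob = prob, class_order = class_order),
            class = "expanded_population")
}

#' @export
print.expanded_population <- function(x, ...) {
  cat("Expanded population over", length(x$class_order), "classes (",
      length(x$prob), "cells )\n")
  invisible(x)
}

#' Mix population profiles
#'
#' Convex combination of expanded populations on the same classes, used to
#' form the marginal population of a list whose shared and exclusive parts
#' come from different populations.
#'
#' @param pops List of `expanded_population` objects.
#' @param weights Non-negative weights, normalised internally.
#' @return An `expanded_population`.
#' @export
mix_populations <- function(pops, weights) {
  stopifnot(length(pops) == length(weights), all(weights >= 0), sum(weights) > 0)
  weights <- weights / sum(weights)
  co <- pops[[1L]]$class_order
  keys <- sort(unique(unlist(lapply(pops, function(p) names(p$prob)))))
  prob <- stats::setNames(numeric(length(keys)), keys)
  for (i in seq_along(pops)) {
    if (!identical(pops[[i]]$class_order, co))
      stop("populations are defined on different class orders")
    at <- match(names(pops[[i]]$prob), keys)    # positional: "" is a valid key
    prob[at] <- prob[at] + weights[i] * pops[[i]]$prob
  }
  expanded_population(prob, co)
}

#' Write / read an expanded profile as TSV
#'
#' Two-column tab-separated representation (`subset`, `count`) with cell
#' keys as `";"`-joined class identifiers. The class order is stored in a
#' `#classes:` header comment so the round trip is lossless.
#'
#' @param e An `expanded_profile`.
#' @param path File path.
#' @return `write_expanded_tsv` returns `path` invisibly;
#'   `read_expanded_tsv` returns an `expanded_profile`.
#' @export
write_expanded_tsv <- function(e, path) {
  stopifnot(inherits(e, "expanded_profile"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("#classes:", paste(e$class_order, collapse = ";")), con)
  writeLines("subset\tcount", con)
  if (length(e$counts))
    writeLines(paste(names(e$counts), e$counts, sep = "\t"), con)
  invisible(path)
}

#' @rdname write_expanded_tsv
#' @export
read_expanded_tsv <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^#classes:", lines, value = TRUE)
  if (!length(hdr)) stop("missing '#classes:' header in ", path)
  class_order <- strsplit(sub("^#classes:", "", hdr[1L]), ";", fixed = TRUE)[[1L]]
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(body)][-1L]                       # drop column header
  if (!length(body)) return(.new_expanded_profile(numeric(0), class_order))
  parts <- strsplit(body, "\t", fixed = TRUE)
  counts <- stats::setNames(
    as.numeric(vapply(parts, function(x) x[2L], character(1L))),
    vapply(parts, function(x) x[1L], character(1L)))
  .new_expanded_profile(counts, class_order)
}
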