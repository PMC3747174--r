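#' Class-by-class Fisher tests with Holm adjustment
#'
#' For each target class, tests whether the annotation frequency differs
#' between the two lists with a two-sided Fisher exact test on the 2 x 2
#' table (annotated in the class or not) x (list A or list B), then adjusts
#' the p-values for multiplicity with Holm's step-down procedure. Genes
#' present in both lists contribute to both columns; this is the
#' conventional usage for overlapping lists even though the two columns are
#' then not independent, and it is reported as such.
#'
#' @param listA,listB Character vectors of gene identifiers.
#' @param ann An [annotation_index()].
#' @param alpha Significance level applied to the Holm-adjusted p-values.
#' @param include_unannotated Count unannotated genes in the list totals
#'   (see [build_expanded()]).
#' @return A data frame of class `class_test_table` with one row per class:
#'   `class_id`, `count_a`, `n_a`, `count_b`, `n_b`, `raw_p`, `holm_p`,
#'   `significant`, `empty` (no annotated gene in either list; such classes
#'   get p = 1).
#' @export
class_fisher_tests <- function(listA, listB, ann, alpha = 0.05,
                               include_unannotated = FALSE) {
  eA <- build_expanded(listA, ann, include_unannotated = include_unannotated)
  eB <- build_expanded(listB, ann, include_unannotated = include_unannotated)
  class_fisher_counts(.class_counts(eA), eA$n, .class_counts(eB), eB$n,
                      alpha = alpha, class_ids = ann$class_order)
}

#' @rdname class_fisher_tests
#' @param countsA,countsB Per-class annotated-gene counts of each list.
#' @param n,m List sizes (counts of genes, not of annotations).
#' @param class_ids Optional class identifiers for the output rows.
#' @export
class_fisher_counts <- function(countsA, n, countsB, m, alpha = 0.05,
                                class_ids = NULL) {
  stopifnot(length(countsA) == length(countsB))
  if (is.null(class_ids))
    class_ids <- if (!is.null(names(countsA))) names(countsA)
      else paste0("class", seq_along(countsA))
  if (any(countsA > n) || any(countsB > m))
    stop("class counts exceed the list sizes")
  raw <- vapply(seq_along(countsA), function(i) {
    a <- countsA[i]; b <- countsB[i]
    if (a + b == 0) return(1)
    tab <- matrix(c(a, n - a, b, m - b), nrow = 2L)
    stats::fisher.test(tab)$p.value
  }, numeric(1L))
  raw <- pmin(pmax(raw, 0), 1)             # fisher.test may exceed 1 by eps
  holm <- holm_adjust(raw)
  structure(
    data.frame(class_id = class_ids,
               count_a = as.numeric(countsA), n_a = n,
               count_b = as.numeric(countsB), n_b = m,
               raw_p = pmin(raw, 1), holm_p = holm,
               significant = holm < alpha,
               empty = (countsA + countsB) == 0,
               row.names = NULL, stringsAsFactors = FALSE),
    class = c("class_test_table", "data.frame"))
}

#' Holm step-down p-value adjustment
#'
#' Family-wise error controlling adjustment used for the class-by-class
#' Fisher tests: sort the p-values, multiply the i-th smallest by
#' `s - i + 1`, enforce monotonicity with a running maximum and cap at 1.
#' Thin wrapper over [stats::p.adjust()] kept as the package's named
#' adjustment step.
#'
#' @param p Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "holm")
}

#' Chi-square homogeneity test on contracted class counts
#'
#' The textbook Pearson test applied to the 2 x s table of per-class
#' annotated-gene counts, with df = s' - 1 after dropping classes counted
#' in neither list. It deliberately ignores that classes overlap (a gene
#' annotated in several classes is counted several times), so its type I
#' error is not controlled for functional profiles; the test is provided
#' as the invalid baseline comparator used in the simulation study, not as
#' a recommended procedure.
#'
#' @param countsA,countsB Per-class annotated-gene counts of the two lists.
#' @return List with `statistic`, `df`, `p_value`, `dropped` (number of
#'   all-zero classes removed).
#' @export
chisq_homogeneity <- function(countsA, countsB) {
  stopifnot(length(countsA) == length(countsB))
  keep <- (countsA + countsB) > 0
  dropped <- sum(!keep)
  if (dropped > 0)
    warning(dropped, " class(es) with zero counts in both lists dropped")
  a <- countsA[keep]; b <- countsB[keep]
  if (length(a) < 2L)
    stop("fewer than two non-empty classes: homogeneity test undefined")
  if (sum(a) == 0 || sum(b) == 0)
    stop("one of the lists has no annotations in the retained classes")
  ct <- suppressWarnings(stats::chisq.test(rbind(a, b), correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value, dropped = dropped)
}

#' Combined global and class-by-class decision procedure
#'
#' The recommended analysis flow: (1) run the global profile test -- if it
#' is not significant, stop and report no difference (no class-by-class
#' testing is performed, which keeps the family-wise error at the global
#' test's level); (2) otherwise run per-class Fisher tests with Holm
#' adjustment -- if any class is significant, report those classes; (3) if
#' the global test rejected but no single class survives adjustment, either
#' point to the class with the smallest unadjusted p-value (`step3 =
#' "suggest"`, the default) or recommend re-testing at a less specific
#' ontology level (`step3 = "uplevel"`).
#'
#' @param listA,listB Character vectors of gene identifiers.
#' @param ann An [annotation_index()].
#' @param alpha Significance level for both stages.
#' @param step3 Behaviour when the global test rejects but no class is
#'   Holm-significant: `"suggest"` or `"uplevel"`.
#' @param include_unannotated See [build_expanded()].
#' @param warn_small See [compare_profiles()].
#' @return Object of class `combined_decision`: `global`
#'   (the `global_profile_test`), `classwise` (a `class_test_table`, or
#'   `NULL` when the global test did not reject), `outcome` (one of
#'   `"no_difference"`, `"classes_identified"`, `"suggested_class"`,
#'   `"recommend_higher_level"`) and `suggested_class`.
#' @export
combined_procedure <- function(listA, listB, ann, alpha = 0.05,
                               step3 = c("suggest", "uplevel"),
                               include_unannotated = FALSE,
                               warn_small = TRUE) {
  step3 <- match.arg(step3)
  global <- compare_lists(listA, listB, ann, alpha = alpha,
                          include_unannotated = include_unannotated,
                          warn_small = warn_small)
  classwise <- NULL
  suggested <- NA_character_
  if (!global$reject) {
    outcome <- "no_difference"
  } else {
    classwise <- class_fisher_tests(listA, listB, ann, alpha = alpha,
                                    include_unannotated = include_unannotated)
    if (any(classwise$significant)) {
      outcome <- "classes_identified"
    } else if (step3 == "suggest") {
      outcome <- "suggested_class"
      suggested <- classwise$class_id[which.min(classwise$raw_p)]
    } else {
      outcome <- "recommend_higher_level"
    }
  }
  structure(list(global = global, classwise = classwise, outcome = outcome,
                 suggested_class = suggested, alpha = alpha),
            class = "combined_decision")
}

#' @export
print.combined_decision <- function(x, ...) {
  cat("\nCombined global / class-by-class procedure (alpha =", x$alpha, ")\n")
  cat("Step 1 global test: p =", format(x$global$p_value, digits = 6),
      if (x$global$reject) "-> significant\n" else "-> not significant\n")
  switch(x$outcome,
    no_difference = cat("Outcome: no evidence of profile differences;",
                        "class-by-class testing skipped\n"),
    classes_identified = {
      sig <- x$classwise[x$classwise$significant, , drop = FALSE]
      cat("Outcome:", nrow(sig), "Holm-significant class(es):\n")
      print(sig[, c("class_id", "raw_p", "holm_p")], row.names = FALSE)
    },
    suggested_class = cat("Outcome: no class survives Holm adjustment;",
                          "suggested class (smallest raw p):",
                          x$suggested_class, "\n"),
    recommend_higher_level = cat("Outcome: no class survives Holm",
                                 "adjustment; consider a less specific",
                                 "ontology level\n"))
  invisible(x)
}

#' Export a class test table as TSV
#'
#' @param x A `class_test_table`.
#' @param path File path.
#' @export
write_class_table_tsv <- function(x, path) {
  stopifnot(inherits(x, "class_test_table"))
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
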