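#' Read a gene list from a plain-text file
#'
#' One identifier per line; blank lines and `#` comments (full-line or
#' trailing) are ignored. Identifiers are taken verbatim (case-sensitive).
#'
#' @param path File path.
#' @return Character vector of identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines)
  genes <- lines[nzchar(lines)]
  if (!length(genes)) stop("no gene identifiers found in ", path)
  genes
}

#' Read a two-column gene-to-class annotation TSV
#'
#' Columns: gene identifier, class identifier; no header, `#` comment lines
#' allowed. Duplicate (gene, class) rows collapse to one.
#'
#' @param path File path.
#' @param class_order Optional target classes passed to
#'   [annotation_index()].
#' @return An `annotation_index`.
#' @export
read_annotation_tsv <- function(path, class_order = NULL) {
  df <- utils::read.delim(path, header = FALSE, comment.char = "#",
                          colClasses = "character", quote = "")
  if (ncol(df) < 2L) stop("expected two tab-separated columns in ", path)
  annotation_index(df[, 1:2], class_order = class_order)
}

#' Read a GAF 2.x annotation file
#'
#' Uses column 2 (DB Object ID) and column 5 (GO ID); rows whose qualifier
#' (column 4) contains `NOT` are skipped, as are `!` comment lines and
#' malformed rows (fewer than 7 columns), whose count is reported.
#'
#' @param path File path.
#' @param evidence Optional character vector of evidence codes (column 7)
#'   to keep; default keeps all.
#' @param class_order Optional target classes passed to
#'   [annotation_index()].
#' @return An `annotation_index`.
#' @export
read_gaf <- function(path, evidence = NULL, class_order = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!startsWith(lines, "!") & nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  ok <- lengths(fields) >= 7L
  if (any(!ok))
    message(sum(!ok), " malformed GAF line(s) skipped")
  fields <- fields[ok]
  if (!length(fields)) stop("no usable annotation records in ", path)
  gene <- vapply(fields, `[`, character(1L), 2L)
  qual <- vapply(fields, `[`, character(1L), 4L)
  term <- vapply(fields, `[`, character(1L), 5L)
  evid <- vapply(fields, `[`, character(1L), 7L)
  keep <- !vapply(strsplit(qual, "|", fixed = TRUE),
                  function(q) "NOT" %in% q, logical(1L))
  if (!is.null(evidence)) keep <- keep & evid %in% evidence
  if (!any(keep)) stop("no usable annotation records in ", path)
  annotation_index(data.frame(gene = gene[keep], term = term[keep],
                              stringsAsFactors = FALSE),
                   class_order = class_order)
}

#' Read a minimal OBO 1.4 ontology file
#'
#' Parses `[Term]` stanzas: `id`, `name`, `namespace`, `is_a`,
#' `relationship: part_of`, `is_obsolete` and `alt_id`. Trailing `!`
#' comments on tag lines are stripped. Obsolete terms are retained in the
#' table (flagged) but carry no edges.
#'
#' @param path File path.
#' @return Object of class `ontology_graph`: `terms` (data frame with
#'   `id`, `name`, `namespace`, `obsolete`), `parents` (named list of
#'   `is_a` parents), `part_of` (named list), `alt_id` (named character
#'   vector alt -> primary).
#' @export
read_obo <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ids <- character(); names_ <- character(); ns <- character()
  obs <- logical()
  parents <- list(); part_of <- list(); alt <- character()
  cur <- NULL
  in_term <- FALSE
  flush <- function() {
    if (is.null(cur) || is.na(cur$id)) return()
    ids <<- c(ids, cur$id)
    names_ <<- c(names_, cur$name)
    ns <<- c(ns, cur$namespace)
    obs <<- c(obs, cur$obsolete)
    parents[[cur$id]] <<- if (cur$obsolete) character() else cur$is_a
    part_of[[cur$id]] <<- if (cur$obsolete) character() else cur$part_of
    if (length(cur$alt_id))
      alt[cur$alt_id] <<- cur$id
  }
  for (line in lines) {
    line <- sub("\\s*!.*$", "", line)
    line <- trimws(line)
    if (line == "[Term]") {
      flush()
      in_term <- TRUE
      cur <- list(id = NA_character_, name = NA_character_,
                  namespace = NA_character_, obsolete = FALSE,
                  is_a = character(), part_of = character(),
                  alt_id = character())
      next
    }
    if (startsWith(line, "[")) { flush(); in_term <- FALSE; cur <- NULL; next }
    if (!in_term || !nzchar(line)) next
    kv <- regmatches(line, regexec("^([a-z_]+):\\s*(.*)$", line))[[1L]]
    if (length(kv) < 3L) next
    key <- kv[2L]; val <- kv[3L]
    if (key == "id") cur$id <- val
    else if (key == "name") cur$name <- val
    else if (key == "namespace") cur$namespace <- val
    else if (key == "is_a") cur$is_a <- c(cur$is_a, trimws(val))
    else if (key == "alt_id") cur$alt_id <- c(cur$alt_id, val)
    else if (key == "is_obsolete") cur$obsolete <- identical(val, "true")
    else if (key == "relationship") {
      rv <- strsplit(trimws(val), "\\s+")[[1L]]
      if (length(rv) >= 2L && rv[1L] == "part_of")
        cur$part_of <- c(cur$part_of, rv[2L])
    }
  }
  flush()
  if (!length(ids)) stop("no [Term] stanzas found in ", path)
  structure(list(terms = data.frame(id = ids, name = names_, namespace = ns,
                                    obsolete = obs, stringsAsFactors = FALSE),
                 parents = parents, part_of = part_of, alt_id = alt),
            class = "ontology_graph")
}

#' @export
print.ontology_graph <- function(x, ...) {
  cat("Ontology graph:", nrow(x$terms), "terms (",
      sum(x$terms$obsolete), "obsolete ) in namespace(s):",
      paste(unique(stats::na.omit(x$terms$namespace)), collapse = ", "), "\n")
  invisible(x)
}

#' Cut an ontology namespace at a fixed level
#'
#' Level convention: the namespace root is level 1, so level L collects the
#' terms whose minimum `is_a` path length from the root is L - 1. Terms
#' reachable at several depths are assigned by their minimum depth. The
#' returned class order is lexicographic, giving reproducible profile
#' coordinates.
#'
#' @param g An [read_obo()] graph.
#' @param namespace Namespace name (e.g. `"molecular_function"`).
#' @param level Integer level, >= 1.
#' @return Object of class `level_cut`: `namespace`, `level`, `classes`.
#' @export
level_cut <- function(g, namespace, level) {
  stopifnot(inherits(g, "ontology_graph"), level >= 1)
  terms <- g$terms[!g$terms$obsolete & g$terms$namespace %in% namespace, ]
  if (!nrow(terms)) stop("no terms in namespace '", namespace, "'")
  in_ns <- terms$id
  has_parent <- vapply(in_ns, function(id)
    length(intersect(g$parents[[id]], in_ns)) > 0L, logical(1L))
  roots <- in_ns[!has_parent]
  if (length(roots) > 1L) {
    # terms tied in only by part_of are not candidate roots
    po <- vapply(roots, function(id)
      length(intersect(g$part_of[[id]], in_ns)) > 0L, logical(1L))
    roots <- roots[!po]
  }
  if (length(roots) != 1L)
    stop("expected a unique namespace root, found ", length(roots))
  # children map within the namespace
  children <- list()
  for (id in in_ns)
    for (p in intersect(g$parents[[id]], in_ns))
      children[[p]] <- c(children[[p]], id)
  depth <- stats::setNames(rep.int(NA_integer_, length(in_ns)), in_ns)
  depth[roots] <- 1L
  frontier <- roots
  d <- 1L
  while (length(frontier)) {
    d <- d + 1L
    nxt <- unique(unlist(children[frontier], use.names = FALSE))
    nxt <- nxt[!is.na(nxt) & is.na(depth[nxt])]
    depth[nxt] <- d
    frontier <- nxt
  }
  classes <- sort(names(depth)[!is.na(depth) & depth == level])
  if (!length(classes)) stop("no classes at level ", level,
                             " of namespace '", namespace, "'")
  structure(list(namespace = namespace, level = as.integer(level),
                 classes = classes),
            class = "level_cut")
}

#' @export
print.level_cut <- function(x, ...) {
  cat("Level", x$level, "cut of", x$namespace, ":",
      length(x$classes), "classes\n")
  invisible(x)
}

# ancestor-or-self closure over is_a (optionally + part_of), memoised
.ancestor_closure <- function(g, use_part_of = FALSE) {
  memo <- new.env(parent = emptyenv())
  up <- function(id) {
    if (!is.null(memo[[id]])) return(memo[[id]])
    memo[[id]] <- id                       # break cycles defensively
    ps <- g$parents[[id]]
    if (use_part_of) ps <- c(ps, g$part_of[[id]])
    out <- id
    for (p in ps) if (!is.null(g$parents[[p]]) || p %in% g$terms$id)
      out <- union(out, up(p))
    memo[[id]] <- out
    out
  }
  up
}

#' Project annotations onto a level cut
#'
#' Replaces each gene's annotated terms by their level-L ancestors: the
#' ancestor-or-self closure over `is_a` edges (and `part_of` when
#' requested), intersected with the classes of the cut. Alternate ids are
#' resolved to primary ids and obsolete terms dropped first. Genes whose
#' terms have no ancestor in the cut end up unannotated and are handled by
#' the profiling policy of [build_expanded()]. Projection is idempotent at
#' a fixed cut.
#'
#' @param ann Named list gene -> character vector of term ids, or an
#'   [annotation_index()] (its mapping is re-projected).
#' @param g An [read_obo()] graph.
#' @param cut A [level_cut()].
#' @param use_part_of Also traverse `part_of` edges.
#' @return An `annotation_index` over the classes of the cut.
#' @export
project_annotations <- function(ann, g, cut, use_part_of = FALSE) {
  stopifnot(inherits(g, "ontology_graph"), inherits(cut, "level_cut"))
  mapping <- if (inherits(ann, "annotation_index")) ann$mapping else ann
  if (!is.list(mapping) || is.null(names(mapping)))
    stop("'ann' must be a named list or an annotation_index")
  up <- .ancestor_closure(g, use_part_of = use_part_of)
  obsolete <- g$terms$id[g$terms$obsolete]
  projected <- lapply(mapping, function(terms) {
    terms <- as.character(terms)
    hit <- names(g$alt_id) %in% terms
    terms <- unique(c(setdiff(terms, names(g$alt_id)),
                      unname(g$alt_id[hit])))
    terms <- setdiff(terms, obsolete)
    terms <- terms[terms %in% g$terms$id]
    if (!length(terms)) return(character())
    intersect(unique(unlist(lapply(terms, up), use.names = FALSE)),
              cut$classes)
  })
  annotation_index(projected, class_order = cut$classes)
}
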