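## Chronogram: a rooted binary ultrametric dated tree. Internally an ape
## "phylo" with a node_age vector (ages in Ma, tips exactly 0) and class
## c("chronogram", "phylo"), so all of ape keeps working on it.

#' Construct a chronogram from an ape phylo
#'
#' Validates that the tree is rooted, binary (optionally resolving
#' polytomies with zero-length branches), has unique non-empty tip labels,
#' and is ultrametric to a relative tolerance of \code{tol} times the crown
#' age; passing trees are snapped to exactly ultrametric by resetting all
#' tip ages to 0.
#'
#' @param phy an \code{ape::phylo} with branch lengths in Ma.
#' @param tol relative ultrametricity tolerance (fraction of crown age).
#' @param resolve_polytomies if TRUE, multifurcations are resolved into
#'   binary nodes separated by zero-length branches (intended for
#'   parsimony-style analyses only; the birth-death likelihood requires a
#'   genuinely binary tree).
#' @return an object of class \code{c("chronogram", "phylo")} with a
#'   \code{node_age} element (ages for tips then internal nodes, in ape's
#'   node numbering).
#' @export
as_chronogram <- function(phy, tol = 1e-6, resolve_polytomies = FALSE) {
  if (!inherits(phy, "phylo")) stop2("expected an ape 'phylo' object")
  if (is.null(phy$edge.length)) stop2("tree has no branch lengths")
  if (anyNA(phy$edge.length)) stop2("tree has NA branch lengths")
  n <- length(phy$tip.label)
  if (n < 2) stop2("a chronogram needs at least 2 tips")
  if (is.null(phy$tip.label) || any(!nzchar(phy$tip.label)))
    stop2("all tips must be labeled")
  if (anyDuplicated(phy$tip.label))
    stop2("duplicate tip labels: ",
          paste(unique(phy$tip.label[duplicated(phy$tip.label)]), collapse = ", "))
  if (!ape::is.rooted(phy)) stop2("tree must be rooted")
  if (!ape::is.binary(phy)) {
    if (resolve_polytomies) {
      phy <- ape::multi2di(phy, random = FALSE)
      phy$edge.length[is.na(phy$edge.length)] <- 0
    } else {
      stop2("tree contains polytomies; set resolve_polytomies = TRUE ",
            "(parsimony analyses only)")
    }
  }
  depth <- ape::node.depth.edgelength(phy)
  present <- max(depth[seq_len(n)])
  age <- present - depth
  crown <- age[n + 1L]
  if (crown <= 0) stop2("crown age must be positive")
  dev <- max(abs(age[seq_len(n)]))
  if (dev > tol * crown)
    stop2(sprintf(
      "tree is not ultrametric: max tip-age deviation %.6g exceeds %.3g x crown age %.6g",
      dev, tol, crown))
  ## snap: tips exactly at the present
  age[seq_len(n)] <- 0
  ## parent strictly older than child
  pa <- age[phy$edge[, 1]]
  ch <- age[phy$edge[, 2]]
  internal_child <- phy$edge[, 2] > n
  if (any(pa < ch - 1e-12) ||
      (!resolve_polytomies && any(pa[internal_child] <= ch[internal_child])))
    stop2("parent node ages must be strictly greater than child ages")
  phy$edge.length <- pa - ch
  phy$node_age <- age
  class(phy) <- c("chronogram", "phylo")
  phy
}

#' Number of tips of a chronogram
#' @param tree a chronogram.
#' @export
n_tips <- function(tree) length(tree$tip.label)

#' Crown (root) age of a chronogram in Ma
#' @param tree a chronogram.
#' @export
crown_age <- function(tree) tree$node_age[length(tree$tip.label) + 1L]

## Minimal syntax pre-scan of a Newick string so parse errors can name a
## character position (ape does not report one).
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "")[[1]]
  depth <- 0L
  in_comment <- FALSE
  for (i in seq_along(chars)) {
    ch <- chars[i]
    if (in_comment) { if (ch == "]") in_comment <- FALSE; next }
    if (ch == "[") { in_comment <- TRUE; next }
    if (ch == "(") depth <- depth + 1L
    if (ch == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop2("malformed Newick: unmatched ')' at character ", i)
    }
    if (ch == ";" && depth > 0L)
      stop2("malformed Newick: ';' at character ", i,
            " inside an open '(' group")
  }
  if (in_comment) stop2("malformed Newick: unterminated '[' comment")
  if (depth > 0L)
    stop2("malformed Newick: ", depth, " unclosed '(' at character ",
          length(chars))
  if (!grepl(";", text, fixed = TRUE))
    stop2("malformed Newick: missing terminating ';' at character ",
          length(chars))
  invisible(TRUE)
}

## Strip BEAST/FigTree-style bracket comments ("[&...]" metadata).
strip_newick_comments <- function(text) gsub("\\[[^]]*\\]", "", text)

#' Parse a Newick string into a chronogram
#'
#' Branch lengths are mandatory and are interpreted as durations in Myr;
#' node ages are computed from root-to-tip path lengths. BEAST-style
#' bracket comments are stripped before parsing.
#'
#' @param text a Newick string (single tree).
#' @param tol,resolve_polytomies passed to \code{\link{as_chronogram}}.
#' @return a chronogram.
#' @export
parse_newick <- function(text, tol = 1e-6, resolve_polytomies = FALSE) {
  stopifnot(is.character(text), length(text) == 1L)
  text <- strip_newick_comments(text)
  check_newick_syntax(text)
  phy <- tryCatch(ape::read.tree(text = text),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(phy)) stop2("malformed Newick: ape failed to parse the string")
  if (inherits(phy, "multiPhylo")) {
    if (length(phy) != 1L) stop2("expected a single tree, got ", length(phy))
    phy <- phy[[1L]]
  }
  if (is.null(phy$edge.length))
    stop2("Newick string has no branch lengths; they are mandatory")
  as_chronogram(phy, tol = tol, resolve_polytomies = resolve_polytomies)
}

#' Write a chronogram as a Newick string (or file)
#'
#' @param tree a chronogram.
#' @param file optional path; when NULL the string is returned.
#' @param digits significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (is.null(file)) return(s)
  writeLines(s, file)
  invisible(s)
}

#' Read and subsample a posterior sample of dated trees
#'
#' Accepts a NEXUS TREES block (e.g. a BEAST output, metadata comments
#' stripped) or a multi-line Newick file, and returns \code{count} trees
#' drawn uniformly without replacement, seed-reproducibly.
#'
#' @param text file contents as a single string or character vector of
#'   lines, or a file path (see \code{is_path}).
#' @param count number of trees to draw.
#' @param seed integer seed for the subsampling.
#' @param is_path if TRUE, \code{text} is a file path.
#' @param tol,resolve_polytomies passed to \code{\link{as_chronogram}}.
#' @return list of chronograms, length \code{count}.
#' @export
parse_tree_sample <- function(text, count, seed = 1L, is_path = FALSE,
                              tol = 1e-6, resolve_polytomies = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  text <- paste(text, collapse = "\n")
  is_nexus <- grepl("^\\s*#nexus", text, ignore.case = TRUE)
  if (is_nexus) {
    tf <- tempfile(fileext = ".nex")
    on.exit(unlink(tf))
    writeLines(strip_newick_comments(text), tf)
    phys <- ape::read.nexus(tf)
    if (inherits(phys, "phylo")) phys <- list(phys)
  } else {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
    lines <- trimws(lines)
    lines <- lines[nzchar(lines)]
    phys <- lapply(lines, function(l) {
      l <- strip_newick_comments(l)
      check_newick_syntax(l)
      ape::read.tree(text = l)
    })
  }
  n_avail <- length(phys)
  if (n_avail < count)
    stop2("requested ", count, " trees but the file contains only ", n_avail)
  idx <- with_seed(seed, sample.int(n_avail, count, replace = FALSE))
  lapply(phys[idx], as_chronogram, tol = tol,
         resolve_polytomies = resolve_polytomies)
}

#' Branching times of a chronogram
#'
#' Ages of all internal nodes, sorted descending; the sufficient statistic
#' for homogeneous birth-death likelihoods.
#'
#' @param tree a chronogram.
#' @return object of class \code{branching_times}: list with \code{times}
#'   (descending, length \code{n_tips - 1}) and \code{n_tips}.
#' @export
branching_times <- function(tree) {
  stopifnot(inherits(tree, "chronogram"))
  n <- length(tree$tip.label)
  times <- sort(tree$node_age[(n + 1L):(n + tree$Nnode)], decreasing = TRUE)
  structure(list(times = times, n_tips = n), class = "branching_times")
}

as_branching_times <- function(x) {
  if (inherits(x, "branching_times")) return(x)
  if (inherits(x, "chronogram")) return(branching_times(x))
  if (is.numeric(x)) {
    times <- sort(x, decreasing = TRUE)
    return(structure(list(times = times, n_tips = length(times) + 1L),
                     class = "branching_times"))
  }
  stop2("cannot interpret input as branching times")
}

#' Read a tip-to-area table
#'
#' Two tab-separated columns: tip label and an area string over the coded
#' alphabet (e.g. \code{"AB"}). A header row is recognised when the first
#' field is one of tip/tip_label/label/taxon/species (case-insensitive).
#'
#' @param text table contents (string or lines) or a file path.
#' @param alphabet the coded area letters; default A (Africa), B (Asia),
#'   C (Australia), D (New World).
#' @param is_path if TRUE, \code{text} is a file path.
#' @return an \code{area_table}: named list mapping tip label to a sorted
#'   character vector of areas, with the alphabet as an attribute.
#' @export
read_area_table <- function(text, alphabet = c("A", "B", "C", "D"),
                            is_path = FALSE) {
  if (is_path) text <- readLines(text, warn = FALSE)
  lines <- unlist(strsplit(paste(text, collapse = "\n"), "\n", fixed = TRUE))
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop2("empty area table")
  fields <- strsplit(lines, "\t", fixed = TRUE)
  first <- tolower(trimws(fields[[1]][1]))
  if (first %in% c("tip", "tip_label", "label", "taxon", "species"))
    fields <- fields[-1]
  if (!length(fields)) stop2("area table has a header but no rows")
  out <- list()
  for (i in seq_along(fields)) {
    f <- trimws(fields[[i]])
    if (length(f) < 2L)
      stop2("area table row ", i, " does not have two tab-separated columns")
    tip <- f[1]; areas <- strsplit(f[2], "")[[1]]
    if (!length(areas))
      stop2("area table row ", i, " (tip '", tip, "'): empty range; ",
            "ranges must be non-empty")
    bad <- setdiff(areas, alphabet)
    if (length(bad))
      stop2("area table row ", i, " (tip '", tip, "'): unknown area letter(s) ",
            paste(bad, collapse = ", "))
    if (tip %in% names(out))
      stop2("area table row ", i, ": duplicate tip '", tip, "'")
    out[[tip]] <- sort(unique(areas))
  }
  structure(out, class = "area_table", alphabet = alphabet)
}

#' Write an area table to TSV
#' @param areas an \code{area_table}.
#' @param file optional output path.
#' @export
write_area_table <- function(areas, file = NULL) {
  lines <- vapply(names(areas),
                  function(t) paste0(t, "\t", paste(areas[[t]], collapse = "")),
                  character(1))
  if (is.null(file)) return(lines)
  writeLines(lines, file)
  invisible(lines)
}

#' Clade key of a node: the sorted set of descendant tip labels
#'
#' Used to match nodes of a representative tree against a posterior tree
#' sample (exact tip-set identity).
#'
#' @param tree a chronogram.
#' @param node ape node number.
#' @return character vector of sorted tip labels.
#' @export
clade_key <- function(tree, node) {
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  tips <- ape::extract.clade(tree, node)$tip.label
  sort(tips)
}

## All internal-node clade keys as "|"-joined strings, named by node number.
clade_key_strings <- function(tree) {
  n <- length(tree$tip.label)
  nodes <- (n + 1L):(n + tree$Nnode)
  keys <- vapply(nodes, function(nd) paste(clade_key(tree, nd), collapse = "|"),
                 character(1))
  names(keys) <- nodes
  keys
}
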