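## Tree input/output and manipulation for ultrametric time trees.
##
## Trees are ordinary ape "phylo" objects that have passed
## validate_ultrametric(): rooted, strictly binary, non-negative branch
## lengths, unique tip labels, and equal root-to-tip depths up to a relative
## tolerance (time-calibrated trees exported by Bayesian dating software
## carry rounding noise of that order).

#' Default relative ultrametricity tolerance
#'
#' Root-to-tip path lengths may differ by at most this fraction of the tree
#' depth before a tree is rejected as non-ultrametric.
#' @export
ULTRAMETRIC_RTOL <- 1e-6

#' Validate an ultrametric time tree
#'
#' Checks that `tree` is a rooted, strictly binary `phylo` object with
#' branch lengths on all edges, non-negative branch lengths, unique tip
#' labels, and root-to-tip path lengths equal within a relative tolerance.
#' Trees failing any check are rejected with a distinct error; nothing is
#' silently rescaled.
#'
#' @param tree A `phylo` object.
#' @param rtol Relative tolerance on root-to-tip depth differences,
#'   as a fraction of tree depth.
#' @return `tree`, invisibly, if all checks pass.
#' @export
validate_ultrametric <- function(tree, rtol = ULTRAMETRIC_RTOL) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' object")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  if (length(tree$edge.length) != nrow(tree$edge) || anyNA(tree$edge.length))
    stop("branch lengths missing on some edges")
  if (any(tree$edge.length < 0)) stop("negative branch length")
  n <- length(tree$tip.label)
  if (n < 2) stop("tree must have at least 2 tips")
  if (anyDuplicated(tree$tip.label)) stop("duplicate tip labels")
  # a basal polytomy makes ape read the tree as unrooted
  if (!ape::is.binary(tree) || !ape::is.rooted(tree))
    stop("polytomy: a strictly binary rooted tree is required")
  depths <- node_depths(tree)[seq_len(n)]
  span <- max(depths) - min(depths)
  if (span > rtol * max(depths))
    stop(sprintf("non-ultrametric: root-to-tip depths differ by %g (tolerance %g)",
                 span, rtol * max(depths)))
  invisible(tree)
}

## Root-to-node path lengths for all nodes (preorder pass).
node_depths <- function(tree) {
  n <- length(tree$tip.label)
  nn <- n + tree$Nnode
  d <- numeric(nn)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  len <- ape::reorder.phylo(tree, "postorder")$edge.length
  for (i in rev(seq_len(nrow(edge))))
    d[edge[i, 2]] <- d[edge[i, 1]] + len[i]
  d
}

#' Read an ultrametric tree from a Newick string or file
#'
#' Parses Newick (quoted labels and scientific-notation branch lengths are
#' accepted; bracketed comments are dropped) and validates the result as an
#' ultrametric binary time tree. Parse failures, polytomies, duplicate
#' labels and non-ultrametric trees each raise a distinct error.
#'
#' @param text Newick string (use exactly one of `text`/`file`).
#' @param file Path to a Newick file.
#' @param rtol Ultrametricity tolerance, see [validate_ultrametric()].
#' @return A validated `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL, rtol = ULTRAMETRIC_RTOL) {
  if (is.null(text) == is.null(file)) stop("supply exactly one of 'text' or 'file'")
  if (!is.null(file)) text <- paste(readLines(file, warn = FALSE), collapse = "")
  text <- gsub("\\[[^]]*\\]", "", text)  # strip bracketed annotations
  tree <- tryCatch(suppressWarnings(ape::read.tree(text = text)),
                   error = function(e) stop("Newick parse failure: ", conditionMessage(e)))
  if (is.null(tree)) stop("Newick parse failure: empty or malformed input")
  if (inherits(tree, "multiPhylo")) stop("multiple trees in input; use read_tree_set()")
  tree$tip.label <- gsub("^'(.*)'$", "\\1", tree$tip.label)
  validate_ultrametric(tree, rtol = rtol)
}

#' Write a tree to Newick
#'
#' @param tree A `phylo` object.
#' @param file Optional path; if `NULL` the Newick string is returned.
#' @param digits Number of significant digits for branch lengths.
#' @return Newick string (invisibly if written to a file).
#' @export
write_newick <- function(tree, file = NULL, digits = 12) {
  s <- ape::write.tree(tree, digits = digits)
  if (!is.null(file)) {
    writeLines(s, file)
    return(invisible(s))
  }
  s
}

#' Read a set of trees sharing one tip-label universe
#'
#' Reads several Newick trees (one per line, or a NEXUS trees block via
#' `format = "nexus"`) and validates each. Trees must all contain the same
#' tip labels.
#'
#' @param file Path to the tree file.
#' @param text Newick text with one tree per line (alternative to `file`).
#' @param format `"newick"` or `"nexus"`. NEXUS support is a thin
#'   extraction of the translated tree strings; annotation semantics are
#'   not interpreted.
#' @param rtol Ultrametricity tolerance.
#' @return A `multiPhylo` object of validated trees.
#' @export
read_tree_set <- function(file = NULL, text = NULL, format = c("newick", "nexus"),
                          rtol = ULTRAMETRIC_RTOL) {
  format <- match.arg(format)
  if (format == "nexus") {
    trees <- ape::read.nexus(file)
  } else {
    if (is.null(text)) text <- paste(readLines(file, warn = FALSE), collapse = "\n")
    text <- gsub("\\[[^]]*\\]", "", text)
    trees <- ape::read.tree(text = text)
  }
  if (inherits(trees, "phylo")) trees <- c(trees)  # promote to multiPhylo
  if (length(trees) == 0) stop("no trees in input")
  labs <- sort(trees[[1]]$tip.label)
  for (i in seq_along(trees)) {
    validate_ultrametric(trees[[i]], rtol = rtol)
    if (!identical(sort(trees[[i]]$tip.label), labs))
      stop("tree ", i, " does not share the tip-label universe of tree 1")
  }
  trees
}

#' Define a clade by a set of member tips
#'
#' A clade is addressed by the most recent common ancestor (MRCA) of the
#' listed tips; the clade comprises all descendants of that MRCA, which may
#' include tips not listed.
#'
#' @param name Clade name.
#' @param tips Character vector of tip labels (non-empty).
#' @return An object of class `clade_def`.
#' @export
clade_def <- function(name, tips) {
  tips <- unique(as.character(tips))
  if (length(tips) == 0) stop("clade tip set is empty")
  structure(list(name = as.character(name), tips = tips), class = "clade_def")
}

#' @export
print.clade_def <- function(x, ...) {
  cat("<clade_def>", x$name, "-", length(x$tips), "anchor tips\n")
  invisible(x)
}

## Resolve a clade_def to its MRCA node id; for a single listed tip the
## "clade" is that tip.
resolve_mrca <- function(tree, clade) {
  missing <- setdiff(clade$tips, tree$tip.label)
  if (length(missing) > 0)
    stop("unknown tip label(s): ", paste(missing, collapse = ", "))
  if (length(clade$tips) == 1) return(match(clade$tips, tree$tip.label))
  ape::getMRCA(tree, clade$tips)
}

## Tip labels spanned by a clade's MRCA subtree.
clade_members <- function(tree, clade) {
  node <- resolve_mrca(tree, clade)
  n <- length(tree$tip.label)
  if (node <= n) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Branching times of an ultrametric tree
#'
#' Ages (time before present, in the tree's time unit) of the internal
#' nodes, sorted in descending order. The first element is the crown age;
#' the length is the number of tips minus one. These are the sufficient
#' statistics for constant-rate birth-death likelihoods.
#'
#' @param tree A validated ultrametric `phylo`.
#' @return Numeric vector of node ages, descending.
#' @export
branching_times <- function(tree) {
  bt <- ape::branching.times(tree)
  sort(unname(bt), decreasing = TRUE)
}

#' Extract the MRCA subtree of a clade
#'
#' Returns the subtree rooted at the MRCA of the clade's listed tips,
#' containing all descendants of that MRCA (possibly more tips than were
#' listed). If the MRCA is the root, the whole tree is returned.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param clade A [clade_def()].
#' @return An ultrametric `phylo`.
#' @export
extract_clade <- function(tree, clade) {
  node <- resolve_mrca(tree, clade)
  n <- length(tree$tip.label)
  if (node <= n) stop("clade resolves to a single tip; no subtree to extract")
  if (node == n + 1) return(tree)
  ape::extract.clade(tree, node)
}

#' Graft a new tip into a clade at a random position
#'
#' Adds a tip of unknown placement to the tree, attaching it uniformly at
#' random: first an edge of the clade's MRCA subtree is drawn uniformly
#' (including the subtree's internal edges and pendant edges), then the
#' attachment height is drawn uniformly along that edge. The new pendant
#' branch length is chosen so the tree stays ultrametric; existing node
#' ages, including the crown age, are unchanged. Deterministic given
#' `seed`.
#'
#' @param tree A validated ultrametric `phylo`.
#' @param clade A [clade_def()] delimiting where the tip may attach.
#' @param label New tip label (must not collide with an existing tip).
#' @param seed Integer seed.
#' @return The enlarged, still-ultrametric `phylo`.
#' @export
graft_tip <- function(tree, clade, label, seed) {
  if (label %in% tree$tip.label) stop("label collision: ", label)
  node <- resolve_mrca(tree, clade)
  n <- length(tree$tip.label)
  if (node <= n) stop("clade resolves to a single tip; cannot graft inside it")
  set.seed(seed)
  # candidate edges: all edges within the MRCA subtree (child in subtree)
  desc <- subtree_nodes(tree, node)
  cand <- which(tree$edge[, 2] %in% setdiff(desc, node))
  if (length(cand) == 0) stop("empty clade: no edges available")
  e <- cand[sample.int(length(cand), 1)]
  pos <- runif(1) * tree$edge.length[e]  # distance below (rootward of) edge child
  out <- phytools::bind.tip(tree, tip.label = label,
                            where = tree$edge[e, 2], position = pos)
  validate_ultrametric(out)
}

## All node ids (tips + internals) in the subtree rooted at `node`, inclusive.
subtree_nodes <- function(tree, node) {
  edge <- tree$edge
  out <- node
  frontier <- node
  while (length(frontier) > 0) {
    kids <- edge[edge[, 1] %in% frontier, 2]
    out <- c(out, kids)
    frontier <- kids
  }
  out
}
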