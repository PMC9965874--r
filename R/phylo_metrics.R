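# phylo_metrics: Newick-level diagnostics — midpoint rooting, monophyly,
# stem and depth metrics in substitutions per site. Trees are consumed, not
# inferred; branch lengths are mandatory.

check_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    stop("tree must carry branch lengths on every edge")
  }
  if (any(tree$edge.length < 0)) stop("negative branch length")
  dup <- tree$tip.label[duplicated(tree$tip.label)]
  if (length(dup)) {
    stop("duplicate leaf label(s): ", paste(unique(dup), collapse = ", "))
  }
  invisible(tree)
}

#' Read / write Newick trees
#'
#' Thin wrappers over [ape::read.tree()] / [ape::write.tree()] that enforce
#' the package's tree contract: branch lengths present, leaf labels unique.
#' Support values stored as internal node labels are preserved but not
#' interpreted.
#'
#' @param text Newick string (or use `file`).
#' @param file Path to a Newick file.
#' @return A `phylo` object.
#' @export
read_newick <- function(text = NULL, file = NULL) {
  tree <- tryCatch(
    if (!is.null(text)) ape::read.tree(text = text) else ape::read.tree(file),
    error = function(e) NULL, warning = function(w) NULL
  )
  if (is.null(tree) || !inherits(tree, "phylo")) {
    stop("Newick parse error (unbalanced parentheses or malformed input)")
  }
  check_tree(tree)
}

#' @rdname read_newick
#' @param tree A `phylo` object.
#' @param digits Significant digits for branch lengths.
#' @export
write_newick <- function(tree, file = NULL, digits = 12L) {
  check_tree(tree)
  if (is.null(file)) {
    ape::write.tree(tree, digits = digits)
  } else {
    ape::write.tree(tree, file = file, digits = digits)
    invisible(file)
  }
}

# leaf labels descending from an internal node (or the tip itself)
tips_under <- function(tree, node) {
  ntip <- length(tree$tip.label)
  if (node <= ntip) return(tree$tip.label[node])
  ape::extract.clade(tree, node)$tip.label
}

#' Midpoint rooting
#'
#' Places the root at the midpoint of the longest leaf-to-leaf path, so that
#' the two maximal root-to-tip distances on either side are equal. Ties
#' between equally longest paths are broken by the lexicographically
#' smallest (sorted) leaf-label pair. If the midpoint falls exactly on an
#' internal node, that node becomes the root directly (no zero-length edge
#' is inserted). All pairwise leaf path lengths are preserved.
#'
#' @param tree A `phylo` with branch lengths, >= 2 leaves.
#' @param eps Tolerance for deciding that the midpoint coincides with a node.
#' @return A rooted `phylo`.
#' @export
midpoint_root <- function(tree, eps = 1e-9) {
  check_tree(tree)
  ntip <- length(tree$tip.label)
  if (ntip < 2L) stop("midpoint_root: need at least 2 leaves")
  D <- ape::dist.nodes(tree)
  DL <- D[seq_len(ntip), seq_len(ntip), drop = FALSE]
  diam <- max(DL)
  if (diam <= 0) stop("midpoint_root: zero-diameter tree")
  cand <- which(DL >= diam - eps & upper.tri(DL), arr.ind = TRUE)
  pair_labels <- apply(cand, 1L, function(rc) {
    paste(sort(tree$tip.label[rc]), collapse = "\r")
  })
  best <- cand[order(pair_labels)[1L], ]
  i <- best[[1L]]; j <- best[[2L]]
  half <- DL[i, j] / 2
  path <- ape::nodepath(tree, i, j)
  acc <- 0
  for (k in seq_len(length(path) - 1L)) {
    a <- path[[k]]; b <- path[[k + 1L]]
    len <- D[a, b]
    if (half <= acc + len + eps) {
      offset <- half - acc          # distance from a along edge (a, b)
      at_node <- if (offset <= eps) a else if (offset >= len - eps) b else NA
      if (!is.na(at_node)) {
        root_node <- at_node
        if (root_node <= ntip) stop("midpoint_root: midpoint on a leaf")
        cur_root <- ntip + 1L
        out <- if (root_node == cur_root) tree else
          ape::root(tree, node = root_node)
      } else {
        # midpoint strictly inside the edge: position is measured from the
        # rootward end of the edge in the tree's current orientation
        er <- which(tree$edge[, 1L] == a & tree$edge[, 2L] == b)
        if (length(er) == 1L) {
          out <- phytools::reroot(tree, node.number = b, position = offset)
        } else {
          er <- which(tree$edge[, 1L] == b & tree$edge[, 2L] == a)
          if (length(er) != 1L) stop("midpoint_root: path edge not found")
          out <- phytools::reroot(tree, node.number = a,
                                  position = len - offset)
        }
      }
      attr(out, "order") <- NULL
      return(check_tree(out))
    }
    acc <- acc + len
  }
  stop("midpoint_root: failed to locate midpoint")  # unreachable
}

#' Monophyly of a leaf set
#'
#' @param tree A rooted `phylo`.
#' @param labels Non-empty subset of the leaf labels.
#' @return A list with `monophyletic`, `mrca` (node number) and `intruders`
#'   (leaves under the MRCA that are not in `labels`).
#' @export
is_monophyletic <- function(tree, labels) {
  check_tree(tree)
  labels <- unique(labels)
  stopifnot(length(labels) >= 1L)
  unknown <- setdiff(labels, tree$tip.label)
  if (length(unknown)) {
    stop("unknown leaf label(s): ", paste(unknown, collapse = ", "))
  }
  if (length(labels) == 1L) {
    return(list(monophyletic = TRUE,
                mrca = match(labels, tree$tip.label),
                intruders = character()))
  }
  mrca <- ape::getMRCA(tree, labels)
  desc <- tips_under(tree, mrca)
  list(monophyletic = setequal(desc, labels), mrca = mrca,
       intruders = setdiff(desc, labels))
}

#' Clade branch-length metrics
#'
#' For a monophyletic leaf set: `stem_length` is the branch subtending the
#' MRCA (0 when the MRCA is the root), `mean_root_to_tip` the average
#' root-to-leaf path length over the clade, and `mean_mrca_to_tip` the
#' analogous depth measured from the MRCA. Units are those of the branch
#' lengths (substitutions per site for the trees this package targets).
#'
#' @param tree A rooted `phylo`.
#' @param labels Monophyletic leaf set (error otherwise, naming intruders).
#' @return A list with `stem_length`, `mean_root_to_tip`,
#'   `mean_mrca_to_tip` and `n_leaves`.
#' @export
clade_metrics <- function(tree, labels) {
  check_tree(tree)
  if (!ape::is.rooted(tree)) stop("clade_metrics: tree must be rooted")
  mono <- is_monophyletic(tree, labels)
  if (!mono$monophyletic) {
    stop("leaf set is not monophyletic; intruding leaves: ",
         paste(mono$intruders, collapse = ", "))
  }
  labels <- unique(labels)
  depths <- ape::node.depth.edgelength(tree)   # root-to-node distances
  tips <- match(labels, tree$tip.label)
  mrca <- mono$mrca
  stem_edge <- which(tree$edge[, 2L] == mrca)
  stem <- if (length(stem_edge)) tree$edge.length[[stem_edge]] else 0
  list(stem_length = stem,
       mean_root_to_tip = mean(depths[tips]),
       mean_mrca_to_tip = mean(depths[tips] - depths[[mrca]]),
       n_leaves = length(labels))
}
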