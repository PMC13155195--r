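#' Rooted full binary taxonomy trees
#'
#' An `ltn_tree` indexes the interior nodes of a rooted full binary tree over
#' `K` taxa. Each interior node `A` is identified with its descendant leaf
#' set and split into a left child `A_l` (the first child in stored Newick
#' order) and a right child `A_r`. The `d = K - 1` interior nodes are indexed
#' in depth-first preorder (root first, left subtree before right), and every
#' node-level vector in the package (log-odds, balances, node counts, model
#' parameters) follows this order. Branch lengths are ignored: the models use
#' topology only.
#'
#' @param tree A rooted tree: an [ape::phylo] object, a Newick string, or the
#'   path to a Newick file.
#' @param policy Resolution policy for multifurcations; only
#'   `"left-ladder"` is implemented (the first two children are joined under
#'   a new node, repeatedly, preserving child order).
#'
#' @return An object of class `ltn_tree` with elements
#'   \item{phy}{the binarized [ape::phylo] tree;}
#'   \item{K, d}{leaf and interior-node counts (`d = K - 1`);}
#'   \item{leaves}{taxon labels, in the tree's tip order;}
#'   \item{child_left, child_right}{signed child indices per interior node:
#'     positive values index interior nodes, negative values index leaves;}
#'   \item{in_leaf, left_leaf}{`K x d` 0/1 indicator matrices marking, for
#'     each interior node, its descendant leaves and its left-child leaves;}
#'   \item{ilr_basis}{the `K x d` orthonormal ilr contrast basis;}
#'   \item{node_labels}{stable display labels (`n<index>.<smallest leaf>`);}
#'   \item{binarized}{TRUE if multifurcations had to be resolved.}
#' @examples
#' tr <- ltn_tree("((u1,u2),(u3,u4));")
#' tr$d            # 3 interior nodes
#' tr$node_labels
#' @export
ltn_tree <- function(tree, policy = "left-ladder") {
  phy <- as_phylo_input(tree)
  policy <- match.arg(policy)
  if (length(phy$tip.label) < 2L) {
    stop("tree must have at least 2 leaves", call. = FALSE)
  }
  if (anyDuplicated(phy$tip.label)) {
    dups <- unique(phy$tip.label[duplicated(phy$tip.label)])
    stop("duplicate leaf labels: ", paste(dups, collapse = ", "),
         call. = FALSE)
  }
  nested <- phylo_to_nested(phy)
  res <- ladderize_nested(nested)
  binarized <- res$changed
  phy2 <- nested_to_phylo(res$node)
  build_ltn_tree(phy2, binarized)
}

#' Resolve multifurcations into a full binary tree
#'
#' Deterministically binarizes a rooted tree by left-laddering: at any node
#' with more than two children, the first two children (in stored Newick
#' order) are joined under a new interior node, and this is repeated until
#' the node is binary. Unbranched (single-child) interior nodes are
#' collapsed. A trifurcation `(a,b,c)` therefore becomes `((a,b),c)` and a
#' 4-leaf star becomes the caterpillar `(((a,b),c),d)`.
#'
#' @inheritParams ltn_tree
#' @return An `ltn_tree` (see [ltn_tree()]).
#' @export
binarize_tree <- function(tree, policy = "left-ladder") {
  ltn_tree(tree, policy = policy)
}

as_phylo_input <- function(tree) {
  if (inherits(tree, "ltn_tree")) {
    return(tree$phy)
  }
  if (inherits(tree, "phylo")) {
    return(tree)
  }
  if (is.character(tree) && length(tree) == 1L) {
    if (grepl("\\(", tree)) {
      return(ape::read.tree(text = tree))
    }
    if (!file.exists(tree)) {
      stop("tree file not found: ", tree, call. = FALSE)
    }
    return(ape::read.tree(tree))
  }
  stop("`tree` must be a phylo object, a Newick string, or a file path",
       call. = FALSE)
}

# nested-list representation: a leaf is its label (character scalar), an
# interior node is an unnamed list of children in stored order
phylo_to_nested <- function(phy) {
  K <- length(phy$tip.label)
  root <- K + 1L
  parent <- phy$edge[, 1L]
  child <- phy$edge[, 2L]
  rec <- function(node) {
    if (node <= K) {
      return(phy$tip.label[node])
    }
    kids <- child[parent == node]
    lapply(kids, rec)
  }
  rec(root)
}

ladderize_nested <- function(x) {
  changed <- FALSE
  rec <- function(x) {
    if (is.character(x)) {
      return(x)
    }
    while (length(x) == 1L) {  # collapse unbranched nodes
      changed <<- TRUE
      x <- x[[1L]]
      if (is.character(x)) {
        return(x)
      }
    }
    x <- lapply(x, rec)
    while (length(x) > 2L) {
      changed <<- TRUE
      x <- c(list(x[1:2]), x[-(1:2)])
    }
    x
  }
  list(node = rec(x), changed = changed)
}

nested_to_phylo <- function(nested) {
  tips <- character(0)
  count_leaves <- function(x) {
    if (is.character(x)) 1L else sum(vapply(x, count_leaves, integer(1)))
  }
  K <- count_leaves(nested)
  n_int <- K - 1L
  edge <- matrix(0L, nrow = 2L * n_int, ncol = 2L)
  tip_label <- character(K)
  e <- 0L
  tip_i <- 0L
  int_i <- K  # internal node numbers start at K + 1
  assign_node <- function(x) {
    if (is.character(x)) {
      tip_i <<- tip_i + 1L
      tip_label[tip_i] <<- x
      return(tip_i)
    }
    int_i <<- int_i + 1L
    me <- int_i
    for (ch in x) {
      id <- assign_node(ch)
      e <<- e + 1L
      edge[e, ] <<- c(me, id)
    }
    me
  }
  assign_node(nested)
  phy <- list(edge = edge, tip.label = tip_label, Nnode = n_int)
  class(phy) <- "phylo"
  attr(phy, "order") <- NULL
  phy
}

build_ltn_tree <- function(phy, binarized) {
  K <- length(phy$tip.label)
  d <- K - 1L
  if (phy$Nnode != d) {
    stop("tree is not a full binary tree after binarization", call. = FALSE)
  }
  parent <- phy$edge[, 1L]
  child <- phy$edge[, 2L]
  root <- K + 1L
  # DFS preorder over interior nodes; signed child indices
  node_of <- integer(K + d)           # ape id -> preorder index
  child_left <- integer(d)
  child_right <- integer(d)
  in_leaf <- matrix(0L, K, d)
  left_leaf <- matrix(0L, K, d)
  idx <- 0L
  rec <- function(node) {
    # returns (signed index, leaf indicator vector)
    if (node <= K) {
      v <- integer(K)
      v[node] <- 1L
      return(list(id = -node, leaves = v))
    }
    idx <<- idx + 1L
    me <- idx
    node_of[node] <<- me
    kids <- child[parent == node]
    if (length(kids) != 2L) {
      stop("interior node with ", length(kids), " children; tree not binary",
           call. = FALSE)
    }
    l <- rec(kids[1L])
    r <- rec(kids[2L])
    child_left[me] <<- l$id
    child_right[me] <<- r$id
    leaves <- l$leaves + r$leaves
    in_leaf[, me] <<- leaves
    left_leaf[, me] <<- l$leaves
    list(id = me, leaves = leaves)
  }
  rec(root)
  nl <- colSums(left_leaf)
  nr <- colSums(in_leaf) - nl
  # orthonormal ilr contrast basis: column a has +sqrt(nr/(nl(nl+nr))) on the
  # left leaves and -sqrt(nl/(nr(nl+nr))) on the right leaves
  right_leaf <- in_leaf - left_leaf
  V <- left_leaf * rep(sqrt(nr / (nl * (nl + nr))), each = K) -
    right_leaf * rep(sqrt(nl / (nr * (nl + nr))), each = K)
  first_leaf <- apply(in_leaf, 2L, function(z) {
    labs <- phy$tip.label[z == 1L]
    sort(labs)[1L]
  })
  structure(
    list(
      phy = phy, K = K, d = d, leaves = phy$tip.label,
      child_left = child_left, child_right = child_right,
      in_leaf = in_leaf, left_leaf = left_leaf,
      n_left = nl, n_right = nr,
      ilr_basis = V,
      node_labels = paste0("n", seq_len(d), ".", first_leaf),
      binarized = binarized
    ),
    class = "ltn_tree"
  )
}

#' @export
print.ltn_tree <- function(x, ...) {
  cat("ltn_tree: rooted full binary tree over", x$K, "taxa (",
      x$d, "interior nodes )\n")
  if (x$binarized) cat("  multifurcations resolved by left-laddering\n")
  cat("  leaves:", paste(utils::head(x$leaves, 6L), collapse = ", "),
      if (x$K > 6L) "..." else "", "\n")
  invisible(x)
}

#' Aggregate taxon counts to tree nodes
#'
#' Computes, for every sample and interior node `A`, the subtree total
#' `y(A)` (the summed counts of `A`'s descendant leaves) and the left-child
#' total `y(A_l)`. These node-level binomial counts, not the raw taxon
#' counts, are what the samplers consume: the multinomial sampling model is
#' equivalent to independent binomials `y(A_l) | y(A) ~ Bin(y(A), theta(A))`
#' down the tree.
#'
#' @param X An `n x K` matrix of non-negative integer counts with column
#'   names matching the tree's leaf labels (any column order).
#' @param tree An [ltn_tree()].
#' @return A list of class `node_counts`: `y` and `y_left` (`n x d`
#'   matrices, columns in node preorder), and `totals` (the per-sample
#'   sequencing depths `N_i`).
#' @examples
#' tr <- ltn_tree("((u1,u2),(u3,u4));")
#' X <- matrix(c(3, 1, 2, 0), 1, dimnames = list(NULL, paste0("u", 1:4)))
#' aggregate_node_counts(X, tr)$y    # 6 4 2
#' @export
aggregate_node_counts <- function(X, tree) {
  stopifnot(inherits(tree, "ltn_tree"))
  X <- as_count_matrix(X, tree)
  y <- X %*% tree$in_leaf
  y_left <- X %*% tree$left_leaf
  colnames(y) <- colnames(y_left) <- tree$node_labels
  structure(
    list(y = y, y_left = y_left, totals = rowSums(X)),
    class = "node_counts"
  )
}

as_count_matrix <- function(X, tree = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (is.vector(X)) X <- matrix(X, nrow = 1L, dimnames = list(NULL, names(X)))
  if (!is.numeric(X)) stop("counts must be numeric", call. = FALSE)
  if (anyNA(X)) stop("counts contain NA", call. = FALSE)
  if (any(X < 0)) stop("counts must be non-negative", call. = FALSE)
  if (any(abs(X - round(X)) > 1e-8)) {
    stop("counts must be integers", call. = FALSE)
  }
  X <- round(X)
  if (!is.null(tree)) {
    if (is.null(colnames(X))) {
      if (ncol(X) != tree$K) {
        stop("count matrix has ", ncol(X), " columns but tree has ", tree$K,
             " leaves", call. = FALSE)
      }
      colnames(X) <- tree$leaves
    } else {
      missing_in_tree <- setdiff(colnames(X), tree$leaves)
      missing_in_X <- setdiff(tree$leaves, colnames(X))
      if (length(missing_in_tree) || length(missing_in_X)) {
        stop("taxon labels do not match tree leaves; ",
             if (length(missing_in_tree)) {
               paste0("not in tree: ",
                      paste(missing_in_tree, collapse = ", "), "; ")
             } else "",
             if (length(missing_in_X)) {
               paste0("missing from table: ",
                      paste(missing_in_X, collapse = ", "))
             } else "",
             call. = FALSE)
      }
      X <- X[, tree$leaves, drop = FALSE]
    }
  }
  X
}
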