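# Internal indexed view of a rooted phylo: per-node children, parents,
# descendant tip sets, heights (max distance to a descendant tip), tip
# diameters (max cophenetic distance among descendant tips), and per-node
# distances to every descendant tip. Node ids follow ape convention:
# tips 1..n, internal nodes n+1..n+Nnode.
tree_index <- function(tree) {
  if (is.null(tree$edge.length)) abort("tree must have branch lengths")
  n_tip <- length(tree$tip.label)
  n_node <- n_tip + tree$Nnode
  parent <- integer(n_node)
  edge_len_to_parent <- numeric(n_node)
  children <- vector("list", n_node)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]; ch <- tree$edge[i, 2]
    parent[ch] <- p
    edge_len_to_parent[ch] <- tree$edge.length[i]
    children[[p]] <- c(children[[p]], ch)
  }
  root <- tree$edge[1, 1]
  while (parent[root] != 0L) root <- parent[root]

  po <- rev(preorder_nodes(children, root))   # postorder
  tips <- vector("list", n_node)
  tipdist <- vector("list", n_node)
  height <- numeric(n_node)
  diam <- numeric(n_node)
  for (v in po) {
    if (v <= n_tip) {
      tips[[v]] <- v
      tipdist[[v]] <- setNames(0, tree$tip.label[v])
      height[v] <- 0; diam[v] <- 0
    } else {
      ch <- children[[v]]
      hs <- numeric(length(ch))
      td <- vector("list", length(ch))
      for (k in seq_along(ch)) {
        e <- edge_len_to_parent[ch[k]]
        hs[k] <- height[ch[k]] + e
        td[[k]] <- tipdist[[ch[k]]] + e
      }
      tips[[v]] <- unlist(lapply(ch, function(c) tips[[c]]))
      tipdist[[v]] <- unlist(td)
      height[v] <- max(hs)
      through <- if (length(hs) >= 2L) sum(sort(hs, decreasing = TRUE)[1:2]) else 0
      diam[v] <- max(c(vapply(ch, function(c) diam[c], numeric(1)), through))
    }
  }
  list(tree = tree, n_tip = n_tip, n_node = n_node, root = root,
       parent = parent, children = children,
       edge_len_to_parent = edge_len_to_parent,
       tips = tips, tipdist = tipdist, height = height, diam = diam)
}

preorder_nodes <- function(children, root) {
  out <- integer(0)
  stack <- root
  while (length(stack) > 0L) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    out <- c(out, v)
    kids <- children[[v]]
    if (length(kids) > 0L) stack <- c(stack, rev(kids))
  }
  out
}

#' Cophenetic (patristic) distance between two tips
#'
#' Sum of branch lengths along the tree path between the two tips.
#'
#' @param tree Rooted `ape::phylo` with branch lengths.
#' @param tip_a,tip_b Tip labels.
#' @return Non-negative distance; 0 when `tip_a == tip_b`.
#' @export
cophenetic_distance <- function(tree, tip_a, tip_b) {
  ia <- match(tip_a, tree$tip.label)
  ib <- match(tip_b, tree$tip.label)
  if (is.na(ia) || is.na(ib)) {
    abort(paste0("unknown tip(s): ",
                 paste(c(tip_a, tip_b)[is.na(c(ia, ib))], collapse = ", ")))
  }
  if (ia == ib) return(0)
  depths <- ape::node.depth.edgelength(tree)
  mrca <- ape::getMRCA(tree, c(ia, ib))
  depths[ia] + depths[ib] - 2 * depths[mrca]
}

#' Per-node tip diameters
#'
#' Maximum cophenetic distance among descendant tips, for every node.
#'
#' @param tree Rooted `ape::phylo`.
#' @return Tibble with columns `node` (ape node id), `n_tips`, `diameter`.
#' @export
node_diameters <- function(tree) {
  ix <- tree_index(tree)
  tibble(node = seq_len(ix$n_node),
         n_tips = lengths(ix$tips),
         diameter = ix$diam)
}
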