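# Internal indexed view of a rooted ape::phylo, shared by the parsimony,
# ILS and simulation code. Node ids follow the ape convention: tips are
# 1..ntip, the root is ntip + 1.

build_tree_index <- function(tree) {
  tree <- validate_species_tree(tree)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    p <- tree$edge[i, 1]
    children[[p]] <- c(children[[p]], tree$edge[i, 2])
  }
  root <- ntip + 1L
  # postorder: children strictly before parents
  po <- integer(0)
  stack <- root
  seen <- integer(0)
  while (length(stack) > 0) {
    v <- stack[length(stack)]
    stack <- stack[-length(stack)]
    seen <- c(seen, v)
    stack <- c(stack, children[[v]])
  }
  po <- rev(seen)
  # tips below each node, as logical matrix nodes x ntip
  tipsets <- matrix(FALSE, nnode, ntip)
  for (v in po) {
    if (v <= ntip) tipsets[v, v] <- TRUE
    else for (ch in children[[v]]) tipsets[v, ] <- tipsets[v, ] | tipsets[ch, ]
  }
  blen <- rep(NA_real_, nnode)
  if (!is.null(tree$edge.length)) blen[tree$edge[, 2]] <- tree$edge.length
  list(tree = tree, ntip = ntip, nnode = nnode, root = root,
       parent = parent, children = children, postorder = po,
       tipsets = tipsets, labels = tree$tip.label, blen = blen)
}

# node ages measured backwards from the tips (all tips at 0); requires
# ultrametric-ish branch lengths only in the sense that ages are taken from
# the maximum root-to-node path, which is exact for ultrametric trees
node_times <- function(idx) {
  depth <- numeric(idx$nnode)
  for (v in rev(idx$postorder)) { # preorder
    if (v != idx$root) depth[v] <- depth[idx$parent[v]] + idx$blen[v]
  }
  max(depth) - depth
}
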