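# Shared fixtures, generated in code.

t5_ladder <- function() ape::read.tree(text = "((((A,B),C),D),E);")

# random valid presence/absence matrix over the given taxa
random_pa <- function(n_markers, taxa, p_missing = 0.15, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  states <- matrix(sample(c("0", "1"), n_markers * length(taxa), replace = TRUE),
                   n_markers, length(taxa), dimnames = list(NULL, taxa))
  mask <- matrix(runif(length(states)) < p_missing, nrow = n_markers)
  states[mask] <- "?"
  pa_matrix(states, marker_id = sprintf("rm%03d", seq_len(n_markers)))
}

# matrix of clean synapomorphies: one marker per internal clade of the tree
clade_markers <- function(tree, copies = 1) {
  idx <- retroils:::build_tree_index(tree)
  internal <- setdiff((idx$ntip + 1L):idx$nnode, idx$root)
  rows <- do.call(rbind, rep(lapply(internal, function(v) {
    ifelse(idx$tipsets[v, ], "1", "0")
  }), copies))
  colnames(rows) <- idx$labels
  pa_matrix(rows)
}

ladder_tree <- function(n, tau) {
  labs <- paste0("s", seq_len(n))
  nwk <- sprintf("(%s:%g,%s:%g)", labs[1], tau, labs[2], tau)
  depth <- tau
  for (i in 3:n) {
    depth <- depth + tau
    nwk <- sprintf("(%s:%g,%s:%g)", nwk, tau, labs[i], depth)
  }
  ape::read.tree(text = paste0(nwk, ";"))
}
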