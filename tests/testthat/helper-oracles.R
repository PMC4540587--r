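# Independent oracles, kept deliberately naive: exhaustive enumeration over
# origin branches and connected P-regions (and over all '?' resolutions),
# against which the dynamic-programming mapper is checked.

oracle_index <- function(tree) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  parent <- integer(nnode)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- vector("list", nnode)
  for (i in seq_len(nrow(tree$edge))) {
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]], tree$edge[i, 2])
  }
  # tip bitmask per node
  mask <- integer(nnode)
  fill <- function(v) {
    if (v <= ntip) { mask[v] <<- bitwShiftL(1L, v - 1L); return(mask[v]) }
    m <- 0L
    for (c_ in children[[v]]) m <- bitwOr(m, fill(c_))
    mask[v] <<- m
    m
  }
  fill(ntip + 1L)
  list(ntip = ntip, nnode = nnode, root = ntip + 1L, parent = parent,
       children = children, mask = mask, labels = tree$tip.label)
}

# all connected internal-node regions rooted at (and containing) internal v
oracle_regions <- function(oi, v) {
  ch_int <- oi$children[[v]][oi$children[[v]] > oi$ntip]
  choices <- lapply(ch_int, function(c_) c(list(integer(0)), oracle_regions(oi, c_)))
  out <- list(v)
  if (length(choices) == 0) return(out)
  combos <- list(integer(0))
  for (ch in choices) {
    combos <- unlist(lapply(combos, function(acc) {
      lapply(ch, function(r) c(acc, r))
    }), recursive = FALSE)
  }
  lapply(combos, function(cc) c(v, cc))
}

# minimal number of P branches over all valid (origin, region) assignments
# for a fully resolved 0/1 pattern given as a tip bitmask
oracle_min_p <- function(oi, ones_mask) {
  full <- bitwShiftL(1L, oi$ntip) - 1L
  if (ones_mask == 0L) return(0L)
  best <- Inf
  subtree_uniform <- function(node_mask) {
    inter <- bitwAnd(node_mask, ones_mask)
    inter == 0L || inter == node_mask
  }
  for (o in seq_len(oi$nnode)) {
    below <- oi$mask[o]
    outside <- bitwAnd(full, bitwNot(below))
    if (bitwAnd(ones_mask, outside) != 0L) next # a presence tip outside the origin
    # region-free mapping: direct 0->1 fixation on the origin branch
    if (bitwAnd(below, ones_mask) == below) best <- min(best, 0L)
    if (o <= oi$ntip) next
    for (region in oracle_regions(oi, o)) {
      frontier <- unlist(lapply(region, function(r) {
        setdiff(oi$children[[r]], region)
      }))
      ok <- all(vapply(frontier, function(f) subtree_uniform(oi$mask[f]), logical(1)))
      if (ok) best <- min(best, length(region))
    }
  }
  as.integer(best)
}

# same oracle with '?' tips: minimum over all resolutions
oracle_min_p_missing <- function(oi, obs) {
  qs <- which(obs == 2L)
  ones_base <- sum(bitwShiftL(1L, which(obs == 1L) - 1L))
  if (length(qs) == 0) return(oracle_min_p(oi, as.integer(ones_base)))
  best <- Inf
  for (bits in 0:(2^length(qs) - 1)) {
    extra <- 0L
    for (j in seq_along(qs)) {
      if (bitwAnd(bits, bitwShiftL(1L, j - 1L)) != 0L) {
        extra <- bitwOr(extra, bitwShiftL(1L, qs[j] - 1L))
      }
    }
    m <- bitwOr(as.integer(ones_base), extra)
    if (m == 0L) next # resolution with no presence tip at all: not comparable
    best <- min(best, oracle_min_p(oi, m))
  }
  as.integer(best)
}

# all rooted binary tree shapes with n leaves, as newick strings with
# leaves labelled t1..tn in traversal order
all_tree_shapes <- function(n) {
  shapes <- function(k) {
    if (k == 1) return(list("L"))
    out <- list()
    for (a in 1:(k %/% 2)) {
      la <- shapes(a); lb <- shapes(k - a)
      for (i in seq_along(la)) {
        jseq <- if (a == k - a) i:length(lb) else seq_along(lb)
        for (j in jseq) out <- c(out, list(list(la[[i]], lb[[j]])))
      }
    }
    out
  }
  lab <- function(s, counter) {
    if (identical(s, "L")) {
      counter$i <- counter$i + 1
      return(paste0("t", counter$i))
    }
    paste0("(", lab(s[[1]], counter), ",", lab(s[[2]], counter), ")")
  }
  vapply(shapes(n), function(s) {
    counter <- new.env(); counter$i <- 0
    paste0(lab(s, counter), ";")
  }, character(1))
}

# is the given tip set a clade of the tree (as a bitmask test)?
is_clade <- function(oi, ones_mask) {
  any(oi$mask == ones_mask)
}

# minimal retained_p for EVERY non-empty tip pattern at once (patterns are
# bitmask-indexed); same enumeration as oracle_min_p, vectorised over patterns
oracle_min_p_all <- function(tree) {
  oi <- oracle_index(tree)
  n <- oi$ntip
  pats <- 1:(2^n - 1)
  full <- bitwShiftL(1L, n) - 1L
  best <- rep(Inf, length(pats))
  for (o in seq_len(oi$nnode)) {
    below <- oi$mask[o]
    inside <- bitwAnd(pats, bitwNot(below)) == 0L # all presence tips under o
    best[pats == below] <- 0 # direct 0->1 fixation on the origin branch
    if (o <= oi$ntip) next
    for (region in oracle_regions(oi, o)) {
      frontier <- unlist(lapply(region, function(r) setdiff(oi$children[[r]], region)))
      valid <- inside
      for (f in frontier) {
        pf <- bitwAnd(pats, oi$mask[f])
        valid <- valid & (pf == 0L | pf == oi$mask[f])
      }
      best[valid] <- pmin(best[valid], length(region))
    }
  }
  as.integer(best)
}
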