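# Heuristic search for the most parsimonious tree: stepwise addition from
# jumbled taxon orders, refined by rooted nearest-neighbour-interchange
# hill-climbing. Trees are handled internally as nested pairs and scored
# through the same DP as map_character().

nest_leaf <- function(label) label
nest_node <- function(l, r) list(l, r)
is_nest_leaf <- function(t) is.character(t)

nest_newick <- function(t) {
  build <- function(x) {
    if (is_nest_leaf(x)) x else paste0("(", build(x[[1]]), ",", build(x[[2]]), ")")
  }
  paste0(build(t), ";")
}

nest_phylo <- function(t) ape::read.tree(text = nest_newick(t))

# all placements of leaf x: on every edge plus above the current root
nest_insertions <- function(t, x) {
  out <- list(nest_node(t, x))
  if (!is_nest_leaf(t)) {
    for (s in nest_insertions(t[[1]], x)) out <- c(out, list(nest_node(s, t[[2]])))
    for (s in nest_insertions(t[[2]], x)) out <- c(out, list(nest_node(t[[1]], s)))
  } else {
    out <- c(out, list()) # a leaf has only its stem edge, covered above
  }
  out
}

# rooted NNI neighbourhood: for every internal edge, the two alternative
# arrangements of the four incident subtrees
nest_nni <- function(t) {
  out <- list()
  if (is_nest_leaf(t)) return(out)
  l <- t[[1]]; r <- t[[2]]
  if (!is_nest_leaf(l)) {
    out <- c(out,
             list(nest_node(nest_node(l[[1]], r), l[[2]])),
             list(nest_node(nest_node(l[[2]], r), l[[1]])))
  }
  if (!is_nest_leaf(r)) {
    out <- c(out,
             list(nest_node(r[[1]], nest_node(l, r[[2]]))),
             list(nest_node(r[[2]], nest_node(l, r[[1]]))))
  }
  for (s in nest_nni(l)) out <- c(out, list(nest_node(s, r)))
  for (s in nest_nni(r)) out <- c(out, list(nest_node(l, s)))
  out
}

# total steps of the matrix on a nested tree
nest_score <- function(t, states, convention) {
  idx <- build_tree_index(nest_phylo(t))
  hit <- match(colnames(states), idx$labels)
  total <- 0L
  for (i in seq_len(nrow(states))) {
    obs <- rep(2L, idx$ntip)
    obs[hit[!is.na(hit)]] <- c("0" = 0L, "1" = 1L, "?" = 2L)[states[i, !is.na(hit)]]
    if (!any(obs == 1L)) next
    m <- map_dp(idx, obs)
    total <- total + mapping_steps(m, convention)
  }
  total
}

#' Search for the most parsimonious tree
#'
#' Builds stepwise-addition start trees, one per jumbled (randomised) taxon
#' input order, and refines each by nearest-neighbour-interchange
#' hill-climbing on the total step count; the best-scoring tree over all
#' jumbles is returned. Deterministic given `seed`. Ties keep the first tree
#' found. The defaults mirror classic polymorphism-parsimony practice
#' (7 jumbles, seed 11111).
#'
#' @inheritParams map_markers
#' @param n_jumbles number of randomised addition orders, `>= 1`.
#' @param seed RNG seed for the jumbles.
#' @return a list with elements `tree` (rooted `phylo`), `score`
#'   (a `tree_score` on the full matrix), `total_steps`, `seed`,
#'   `n_jumbles`.
#' @export
search_mpre <- function(x, n_jumbles = 7, seed = 11111,
                        convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  stopifnot(n_jumbles >= 1)
  taxa <- pa_taxa(x)
  if (length(taxa) < 3) stop("need at least 3 taxa to search", call. = FALSE)
  states <- pa_states(x)
  best <- NULL
  best_steps <- Inf
  set.seed(seed)
  for (j in seq_len(n_jumbles)) {
    ord <- sample(taxa)
    cand3 <- list(nest_node(nest_node(ord[1], ord[2]), ord[3]),
                  nest_node(nest_node(ord[1], ord[3]), ord[2]),
                  nest_node(nest_node(ord[2], ord[3]), ord[1]))
    sc3 <- vapply(cand3, nest_score, numeric(1), states = states, convention = convention)
    t_cur <- cand3[[which.min(sc3)]]
    for (tx in ord[-(1:3)]) {
      ins <- nest_insertions(t_cur, tx)
      sc <- vapply(ins, nest_score, numeric(1), states = states, convention = convention)
      t_cur <- ins[[which.min(sc)]]
    }
    s_cur <- nest_score(t_cur, states, convention)
    repeat {
      nb <- nest_nni(t_cur)
      if (length(nb) == 0) break
      sc <- vapply(nb, nest_score, numeric(1), states = states, convention = convention)
      if (min(sc) < s_cur) {
        t_cur <- nb[[which.min(sc)]]
        s_cur <- min(sc)
      } else break
    }
    if (s_cur < best_steps) {
      best <- t_cur
      best_steps <- s_cur
    }
  }
  tree <- nest_phylo(best)
  list(tree = tree, score = score_tree(x, tree, convention),
       total_steps = best_steps, seed = seed, n_jumbles = n_jumbles)
}
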