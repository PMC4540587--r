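#' Map a binary presence/absence character under polymorphism parsimony
#'
#' Felsenstein's polymorphism parsimony explains gene-tree/species-tree
#' conflict of an irreversible binary character by the retention of an
#' insertion *polymorphism* (state `P`) along a connected region of the tree:
#' a single origin (`0 -> 1` or `0 -> P`) followed by independent fixation of
#' the presence (`P -> 1`) or absence (`P -> 0`) allele in the descendant
#' lineages. No parallel origin and no loss after fixation are allowed — the
#' retrotransposon markers this models are treated as homoplasy-free.
#'
#' The mapping minimises the number of branches retaining the polymorphism
#' (`retained_p`, primary criterion) with the origin placed as low (recent)
#' as possible. Missing tips (`?`) are resolved by dynamic programming to the
#' assignment minimising `retained_p`; ties resolve `?` to `0` (conservative
#' with respect to inferring insertions). Tips absent from `pattern` are
#' treated as `?`.
#'
#' @param tree rooted `phylo`; the root carries the ancestral absence state.
#' @param pattern named character vector of tip states over `{"1","0","?"}`
#'   (numeric `0/1/NA` also accepted). Names must be tree tip labels.
#' @return an object of class `char_mapping`: a list with elements
#'   `origin` (ape node id of the branch carrying the origin, `NA` for
#'   all-absent patterns), `origin_type` (`"0->1"` or `"0->P"`),
#'   `states` (per-node state vector over `{"0","1","P"}`),
#'   `fixations_to_1`, `fixations_to_0`, `retained_p`, `resolved`
#'   (the inferred states of `?` tips), `n_presence_tips` and `empty`.
#' @examples
#' t5 <- ape::read.tree(text = "((((A,B),C),D),E);")
#' map_character(t5, c(A = "1", B = "0", C = "1", D = "0", E = "0"))
#' @export
map_character <- function(tree, pattern) {
  idx <- build_tree_index(tree)
  obs <- coerce_pattern(pattern, idx$labels)
  m <- map_dp(idx, obs)
  structure(c(m, list(tree = tree)), class = "char_mapping")
}

# pattern -> integer vector over tips: 0, 1, 2 (= '?')
coerce_pattern <- function(pattern, labels) {
  if (is.null(names(pattern)) || any(names(pattern) == "")) {
    stop("pattern must be a named vector of tip states", call. = FALSE)
  }
  unknown <- setdiff(names(pattern), labels)
  if (length(unknown) > 0) {
    stop("pattern references unknown taxon: ", unknown[1], call. = FALSE)
  }
  if (is.numeric(pattern)) {
    pattern <- ifelse(is.na(pattern), "?", as.character(pattern))
    names(pattern) <- names(pattern)
  }
  bad <- setdiff(unique(pattern), c("0", "1", "?"))
  if (length(bad) > 0) stop("invalid state in pattern: ", bad[1], call. = FALSE)
  obs <- rep(2L, length(labels))
  obs[match(names(pattern), labels)] <- c("0" = 0L, "1" = 1L, "?" = 2L)[pattern]
  if (all(obs == 2L)) stop("pattern has no scored (non-'?') entries", call. = FALSE)
  obs
}

# Core dynamic programme. Cost is lexicographic (retained_p, number of '?'
# tips resolved to 1), encoded as retained_p * BIG + n_question_ones.
# Per-node value functions:
#   f1   - node fixed 1 (origin at or above its branch), no origin below
#   fP   - node polymorphic, no origin below
#   f0k0 - node 0, no origin anywhere in its subtree
#   f0k1 - node 0, exactly one origin on an edge below it
map_dp <- function(idx, obs) {
  BIG <- 1e7
  INF <- 1e15
  n <- idx$nnode
  ntip <- idx$ntip
  f1 <- rep(INF, n); fP <- rep(INF, n); f0k0 <- rep(INF, n); f0k1 <- rep(INF, n)
  for (v in seq_len(ntip)) {
    if (obs[v] == 1L) f1[v] <- 0
    else if (obs[v] == 0L) f0k0[v] <- 0
    else { f0k0[v] <- 0; f1[v] <- 1 } # '?': resolving to 1 costs one tie-break unit
  }
  internal <- idx$postorder[idx$postorder > ntip]
  for (v in internal) {
    ch <- idx$children[[v]]
    f1[v] <- min(INF, sum(f1[ch]))
    below <- pmin(f0k0[ch], pmin(f1[ch], fP[ch]))
    fP[v] <- min(INF, BIG + sum(below))
    base0 <- sum(f0k0[ch])
    f0k0[v] <- min(INF, base0)
    # one child carries the single origin (or passes it further down)
    best <- INF
    for (j in seq_along(ch)) {
      c_j <- ch[j]
      carry <- min(f0k1[c_j], f1[c_j], fP[c_j])
      if (carry >= INF) next
      rest <- base0 - f0k0[c_j]
      if (rest >= INF) next
      best <- min(best, rest + carry)
    }
    f0k1[v] <- best
  }
  root <- idx$root
  if (!any(obs == 1L)) { # all-absent: empty mapping, zero steps
    states <- rep("0", n)
    return(list(origin = NA_integer_, origin_type = NA_character_,
                states = states, fixations_to_1 = 0L, fixations_to_0 = 0L,
                retained_p = 0L, resolved = resolved_states(idx, obs, states),
                n_presence_tips = 0L, empty = TRUE))
  }
  # origin strictly below the root is preferred (lowest feasible origin);
  # f1/fP at the root mean the origin sits on the root's own stem
  root_opts <- c(f0k1[root], f1[root], fP[root])
  pick <- which.min(root_opts)
  states <- rep(NA_character_, n)
  env <- new.env(parent = emptyenv())
  env$origin <- NA_integer_; env$origin_type <- NA_character_
  assign_state <- function(v, s, k) {
    states[v] <<- s
    if (v <= ntip) return(invisible(NULL))
    ch <- idx$children[[v]]
    if (s == "1") { for (c_j in ch) assign_state(c_j, "1", 0L); return(invisible(NULL)) }
    if (s == "P") {
      for (c_j in ch) {
        opts <- c(f0k0[c_j], f1[c_j], fP[c_j])
        assign_state(c_j, c("0", "1", "P")[which.min(opts)], 0L)
      }
      return(invisible(NULL))
    }
    # s == "0"
    if (k == 0L) { for (c_j in ch) assign_state(c_j, "0", 0L); return(invisible(NULL)) }
    base0 <- sum(f0k0[ch])
    deltas <- vapply(ch, function(c_j) {
      carry <- min(f0k1[c_j], f1[c_j], fP[c_j])
      rest <- base0 - f0k0[c_j]
      if (carry >= 1e15 || rest >= 1e15) Inf else rest + carry
    }, numeric(1))
    j <- which.min(deltas)
    for (jj in seq_along(ch)) {
      c_j <- ch[jj]
      if (jj != j) { assign_state(c_j, "0", 0L); next }
      opts <- c(f0k1[c_j], f1[c_j], fP[c_j])
      w <- which.min(opts)
      if (w == 1L) assign_state(c_j, "0", 1L)
      else if (w == 2L) { env$origin <- c_j; env$origin_type <- "0->1"; assign_state(c_j, "1", 0L) }
      else { env$origin <- c_j; env$origin_type <- "0->P"; assign_state(c_j, "P", 0L) }
    }
    invisible(NULL)
  }
  if (pick == 1L) assign_state(root, "0", 1L)
  else if (pick == 2L) { env$origin <- root; env$origin_type <- "0->1"; assign_state(root, "1", 0L) }
  else { env$origin <- root; env$origin_type <- "0->P"; assign_state(root, "P", 0L) }

  fix1 <- as.integer(env$origin_type == "0->1")
  fix0 <- 0L
  for (v in seq_len(n)) {
    if (v == root) next
    p <- idx$parent[v]
    if (states[p] == "P" && states[v] == "1") fix1 <- fix1 + 1L
    if (states[p] == "P" && states[v] == "0") fix0 <- fix0 + 1L
  }
  list(origin = env$origin, origin_type = env$origin_type, states = states,
       fixations_to_1 = fix1, fixations_to_0 = fix0,
       retained_p = sum(states == "P"),
       resolved = resolved_states(idx, obs, states),
       n_presence_tips = sum(states[seq_len(ntip)] == "1"),
       empty = FALSE)
}

resolved_states <- function(idx, obs, states) {
  q <- which(obs == 2L)
  stats::setNames(states[q], idx$labels[q])
}

#' @export
print.char_mapping <- function(x, ...) {
  if (x$empty) {
    cat("<char_mapping> all-absent pattern (no insertion inferred)\n")
    return(invisible(x))
  }
  cat(sprintf(paste0("<char_mapping> origin %s on node %d; fixations to 1/0: %d/%d; ",
                     "branches retaining polymorphism: %d\n"),
              x$origin_type, x$origin, x$fixations_to_1, x$fixations_to_0,
              x$retained_p))
  invisible(x)
}

mapping_steps <- function(m, convention) {
  if (m$empty) return(0L)
  switch(convention,
         fixations = m$fixations_to_1 + m$fixations_to_0,
         retentions = 1L + m$retained_p,
         stop("unknown step convention: ", convention, call. = FALSE))
}

#' Map every marker of a matrix onto a tree
#'
#' Vectorised front end to [map_character()]: one row per marker with the
#' origin branch, fixation counts, step count under the chosen convention,
#' the ILS duration (fixations to 1 + fixations to 0 - 1; conflict-free
#' markers have duration 0, reported as class `"<=1"`) and the duration class
#' `{"<=1","2","3",">=4"}`.
#'
#' @param x a `pa_tbl`.
#' @param tree rooted `phylo` containing every matrix taxon.
#' @param convention step-counting convention: `"fixations"` counts
#'   transitions to the presence and absence allele, `"retentions"` counts
#'   the origin plus branches retaining the polymorphism.
#' @return a tibble with columns `marker_id`, `origin`, `steps`,
#'   `fixations_to_1`, `fixations_to_0`, `retained_p`, `duration`, `class`,
#'   `conflict_free`, `informative`.
#' @export
map_markers <- function(x, tree, convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  idx <- build_tree_index(tree)
  check_taxa_on_tree(x, idx)
  s <- pa_states(x)
  obs_all <- matrix(2L, nrow(s), idx$ntip)
  hit <- match(colnames(s), idx$labels)
  obs_all[, hit] <- c("0" = 0L, "1" = 1L, "?" = 2L)[s]
  if (nrow(s) == 0) {
    return(tibble::tibble(marker_id = character(), origin = integer(),
                          steps = integer(), fixations_to_1 = integer(),
                          fixations_to_0 = integer(), retained_p = integer(),
                          n_presence_tips = integer(), duration = integer(),
                          class = character(), conflict_free = logical(),
                          informative = logical()))
  }
  rows <- lapply(seq_len(nrow(s)), function(i) {
    obs <- obs_all[i, ]
    if (!any(obs != 2L)) {
      stop("marker ", rownames(s)[i], " has no scored entries", call. = FALSE)
    }
    m <- map_dp(idx, obs)
    steps <- mapping_steps(m, convention)
    dur <- if (m$empty) NA_integer_ else max(0L, m$fixations_to_1 + m$fixations_to_0 - 1L)
    tibble::tibble(marker_id = rownames(s)[i],
                   origin = m$origin, steps = steps,
                   fixations_to_1 = m$fixations_to_1,
                   fixations_to_0 = m$fixations_to_0,
                   retained_p = m$retained_p,
                   n_presence_tips = m$n_presence_tips,
                   duration = dur,
                   class = duration_class(dur),
                   conflict_free = !m$empty && m$retained_p == 0L,
                   informative = !m$empty)
  })
  dplyr::bind_rows(rows)
}

duration_class <- function(d) {
  dplyr::case_when(is.na(d) ~ NA_character_,
                   d <= 1 ~ "<=1",
                   d == 2 ~ "2",
                   d == 3 ~ "3",
                   TRUE ~ ">=4")
}

check_taxa_on_tree <- function(x, idx) {
  missing <- setdiff(pa_taxa(x), idx$labels)
  if (length(missing) > 0) {
    stop("matrix taxa absent from tree: ", paste(utils::head(missing, 5), collapse = ", "),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Score a tree against a marker matrix
#'
#' Total parsimony steps, incongruent-marker count and ensemble consistency
#' and retention indices for a matrix mapped on a rooted tree. A marker is
#' *incongruent* (ILS-affected) when it needs more than one step; markers
#' with no presence state are uninformative and contribute zero steps. CI is
#' the ratio of the minimum conceivable steps (one per informative marker) to
#' the realised total; RI uses the per-marker worst case of one independent
#' fixation per presence tip.
#'
#' @inheritParams map_markers
#' @return an object of class `tree_score`; see [tidy.tree_score()] and
#'   [glance.tree_score()].
#' @export
score_tree <- function(x, tree, convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  per <- map_markers(x, tree, convention)
  new_tree_score(per, convention = convention)
}

new_tree_score <- function(per, convention) {
  inf <- per$informative
  total <- sum(per$steps)
  n_inc <- sum(inf & per$steps > 1)
  n_cf <- sum(inf & per$steps == 1)
  max_steps <- pmax(per$n_presence_tips, 1L)
  ci <- if (total > 0) sum(inf) / total else NA_real_
  denom <- sum(max_steps[inf] - 1L)
  ri <- if (denom > 0) (sum(max_steps[inf]) - sum(per$steps[inf])) / denom else NA_real_
  structure(list(per_character = per, convention = convention,
                 total_steps = total, n_incongruent = n_inc,
                 n_conflict_free = n_cf, n_uninformative = sum(!inf),
                 ci = ci, ri = ri),
            class = "tree_score")
}

#' @export
print.tree_score <- function(x, ...) {
  cat(sprintf(paste0("<tree_score> %d markers, convention = %s\n",
                     "  total steps %d | incongruent %d | conflict-free %d | ",
                     "uninformative %d\n  CI %.3f | RI %.3f\n"),
              nrow(x$per_character), x$convention, x$total_steps,
              x$n_incongruent, x$n_conflict_free, x$n_uninformative,
              x$ci, x$ri))
  invisible(x)
}

#' Tidy and summarise tree scores
#'
#' `tidy()` returns the per-marker step table, `glance()` a one-row summary.
#'
#' @param x a `tree_score`.
#' @param ... unused.
#' @method tidy tree_score
#' @export
tidy.tree_score <- function(x, ...) x$per_character

#' @rdname tidy.tree_score
#' @method glance tree_score
#' @export
glance.tree_score <- function(x, ...) {
  tibble::tibble(convention = x$convention, total_steps = x$total_steps,
                 n_incongruent = x$n_incongruent,
                 n_conflict_free = x$n_conflict_free,
                 n_uninformative = x$n_uninformative,
                 ci = x$ci, ri = x$ri)
}

#' Dollo parsimony score
#'
#' Baseline comparison to polymorphism parsimony: each marker is explained by
#' a single origin plus the minimal number of losses (`1 -> 0`), the
#' classical Dollo small-parsimony count. `?` tips are resolved to minimise
#' losses (ties to `0`).
#'
#' @inheritParams map_markers
#' @return a `tree_score` with `convention = "dollo"`.
#' @export
dollo_score <- function(x, tree) {
  idx <- build_tree_index(tree)
  check_taxa_on_tree(x, idx)
  s <- pa_states(x)
  rows <- lapply(seq_len(nrow(s)), function(i) {
    obs <- rep(2L, idx$ntip)
    obs[match(colnames(s), idx$labels)] <- c("0" = 0L, "1" = 1L, "?" = 2L)[s[i, ]]
    d <- dollo_dp(idx, obs)
    tibble::tibble(marker_id = rownames(s)[i], origin = d$origin,
                   steps = d$steps, fixations_to_1 = NA_integer_,
                   fixations_to_0 = NA_integer_, retained_p = NA_integer_,
                   n_presence_tips = d$n_presence_tips,
                   duration = NA_integer_, class = NA_character_,
                   conflict_free = d$informative && d$steps == 1,
                   informative = d$informative)
  })
  new_tree_score(dplyr::bind_rows(rows), convention = "dollo")
}

# Dollo small parsimony: states {0, 1}, single 0->1 origin, losses cost 1.
# Same lexicographic '?' tie-break as map_dp.
dollo_dp <- function(idx, obs) {
  BIG <- 1e7
  INF <- 1e15
  n <- idx$nnode; ntip <- idx$ntip
  g1 <- rep(INF, n); g0k0 <- rep(INF, n); g0k1 <- rep(INF, n)
  for (v in seq_len(ntip)) {
    if (obs[v] == 1L) g1[v] <- 0
    else if (obs[v] == 0L) g0k0[v] <- 0
    else { g0k0[v] <- 0; g1[v] <- 1 }
  }
  for (v in idx$postorder[idx$postorder > ntip]) {
    ch <- idx$children[[v]]
    # below the origin: each child is 1, or 0 via a loss on its stem
    g1[v] <- min(INF, sum(pmin(g1[ch], g0k0[ch] + BIG)))
    base0 <- sum(g0k0[ch])
    g0k0[v] <- min(INF, base0)
    best <- INF
    for (c_j in ch) {
      carry <- min(g0k1[c_j], g1[c_j])
      rest <- base0 - g0k0[c_j]
      if (carry < INF && rest < INF) best <- min(best, rest + carry)
    }
    g0k1[v] <- best
  }
  root <- idx$root
  if (!any(obs == 1L)) {
    return(list(origin = NA_integer_, steps = 0L, n_presence_tips = 0L,
                informative = FALSE))
  }
  tot <- min(g0k1[root], g1[root])
  losses <- floor((tot %% 1e15) / BIG)
  list(origin = NA_integer_, steps = as.integer(1L + losses),
       n_presence_tips = sum(obs == 1L) + as.integer(tot %% BIG),
       informative = TRUE)
}
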