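#' Candidate placements of a focal taxon or clade
#'
#' Removes the focal clade from the backbone tree and regrafts it onto every
#' branch of the remaining tree that lies within `region` (a set of taxa
#' whose spanned clade delimits the attachment area; the region's stem branch
#' is included, giving the "sister to the whole region" placement). When the
#' region covers the whole backbone, an additional placement as sister to
#' everything (a new root) is generated.
#'
#' @param backbone rooted `phylo` containing the focal taxa.
#' @param focal tip label(s) forming the focal clade.
#' @param region character vector of backbone taxa delimiting the attachment
#'   area; default: all non-focal taxa.
#' @return a named list of rooted `phylo` candidates; names describe the
#'   attachment branch by its subtended tips.
#' @export
placement_candidates <- function(backbone, focal, region = NULL) {
  backbone <- validate_species_tree(backbone)
  if (!all(focal %in% backbone$tip.label)) {
    stop("focal taxon absent from backbone: ",
         setdiff(focal, backbone$tip.label)[1], call. = FALSE)
  }
  rest <- setdiff(backbone$tip.label, focal)
  if (length(rest) < 2) stop("backbone too small after removing the focal clade",
                             call. = FALSE)
  if (is.null(region)) region <- rest
  region <- setdiff(region, focal)
  if (!all(region %in% rest)) {
    stop("region taxa absent from backbone", call. = FALSE)
  }
  pruned <- ape::drop.tip(backbone, focal)
  focal_nest <- if (length(focal) == 1) focal else {
    phylo_nest(ape::extract.clade(backbone, ape::getMRCA(backbone, focal)))
  }
  nest <- phylo_nest(pruned)
  graft_all <- function(t) {
    tips <- nest_tips(t)
    out <- list()
    if (all(tips %in% region)) { # attach on this branch (or as a new root)
      out <- c(out, list(list(tree = nest_node(t, focal_nest), at = tips)))
    }
    if (!is_nest_leaf(t)) {
      for (s in graft_all(t[[1]])) {
        out <- c(out, list(list(tree = nest_node(s$tree, t[[2]]), at = s$at)))
      }
      for (s in graft_all(t[[2]])) {
        out <- c(out, list(list(tree = nest_node(t[[1]], s$tree), at = s$at)))
      }
    }
    out
  }
  grafts <- graft_all(nest)
  labs <- vapply(grafts, function(g) paste(sort(g$at), collapse = "+"), character(1))
  keep <- !duplicated(labs)
  grafts <- grafts[keep]; labs <- labs[keep]
  out <- lapply(grafts, function(g) nest_phylo(g$tree))
  names(out) <- paste0("sister_to:", labs)
  attr(out, "focal") <- focal
  out
}

phylo_nest <- function(tree) {
  idx <- build_tree_index(tree)
  build <- function(v) {
    if (v <= idx$ntip) return(idx$labels[v])
    ch <- idx$children[[v]]
    if (length(ch) != 2) {
      stop("placement enumeration requires a binary backbone", call. = FALSE)
    }
    nest_node(build(ch[1]), build(ch[2]))
  }
  build(idx$root)
}

nest_tips <- function(t) {
  if (is_nest_leaf(t)) t else c(nest_tips(t[[1]]), nest_tips(t[[2]]))
}

#' Conflict-free support for alternative placements
#'
#' Counts, for each candidate topology, the markers *diagnostic* for it: the
#' marker must be conflict-free (single parsimony step) on that candidate
#' and its inferred origin branch must lie on the candidate's attachment
#' path — the branch subtending the focal clade's sibling or the branch
#' above the attachment node. Markers qualifying for more than one candidate
#' (including those with `?` in the taxa needed to discriminate two
#' placements) are counted for none, so each marker supports at most one
#' placement; markers merely compatible with a placement but irrelevant to
#' it never count. Candidates are returned in descending order of support.
#'
#' @param x a `pa_tbl` sharing its taxon set with the candidates.
#' @param candidates list of rooted `phylo` trees (see
#'   [placement_candidates()], which records the focal clade on the list).
#' @param focal tip label(s) of the focal clade; defaults to the attribute
#'   set by [placement_candidates()].
#' @return a tibble of class `support_profile` with `candidate`, `n_support`
#'   and `rank`; the per-marker attribution is attached as attribute
#'   `"attribution"`.
#' @export
support_counts <- function(x, candidates, focal = attr(candidates, "focal")) {
  if (is.null(focal)) {
    stop("`focal` is required when candidates do not come from placement_candidates()",
         call. = FALSE)
  }
  if (is.null(names(candidates))) {
    names(candidates) <- paste0("candidate_", seq_along(candidates))
  }
  taxa <- pa_taxa(x)
  for (nm in names(candidates)) {
    if (!setequal(candidates[[nm]]$tip.label, taxa)) {
      stop("candidate '", nm, "' does not share the matrix taxon set", call. = FALSE)
    }
  }
  s <- pa_states(x)
  qualifies <- sapply(candidates, function(tr) {
    idx <- build_tree_index(tr)
    # attachment path: the focal clade's sibling branch and the branch above
    # the attachment node (the focal stem itself is excluded: a marker equal
    # to the focal clade is compatible with every placement)
    f_node <- if (length(focal) == 1) match(focal, idx$labels) else {
      ape::getMRCA(tr, focal)
    }
    p <- idx$parent[f_node]
    path <- setdiff(idx$children[[p]], f_node)
    if (p != idx$root) path <- c(path, p)
    hit <- match(colnames(s), idx$labels)
    vapply(seq_len(nrow(s)), function(i) {
      obs <- rep(2L, idx$ntip)
      obs[hit] <- c("0" = 0L, "1" = 1L, "?" = 2L)[s[i, ]]
      if (!any(obs == 1L)) return(FALSE)
      m <- map_dp(idx, obs)
      m$retained_p == 0L && m$origin %in% path
    }, logical(1))
  })
  qualifies <- matrix(qualifies, nrow = nrow(s),
                      dimnames = list(rownames(s), names(candidates)))
  diagnostic <- rowSums(qualifies) == 1
  attribution <- tibble::tibble(
    marker_id = rownames(s),
    candidate = ifelse(diagnostic,
                       colnames(qualifies)[max.col(qualifies, ties.method = "first")],
                       NA_character_))
  counts <- colSums(qualifies & diagnostic)
  out <- tibble::tibble(candidate = names(counts), n_support = as.integer(counts)) |>
    dplyr::arrange(dplyr::desc(.data$n_support)) |>
    dplyr::mutate(rank = dplyr::row_number())
  attr(out, "attribution") <- attribution
  class(out) <- c("support_profile", class(out))
  out
}

#' Test a placement profile for hybridization-like asymmetry
#'
#' Under symmetric ILS the markers supporting the non-best placements are
#' expected to be spread evenly ("nearly symmetric"); ancient hybridization
#' instead over-represents one species-tree-incongruent alternative. The
#' check is a goodness-of-fit test of equal expected counts across the
#' non-best candidates: exact multinomial when the outcome space is small
#' enough to enumerate, Pearson chi-square otherwise. The flag is raised iff
#' uniformity is rejected at `alpha` and the deviating cell is an excess
#' (positive standardized residual). This formalisation of the verbal
#' symmetry argument is the package's own.
#'
#' @param profile a [support_counts()] result, or a named vector of counts
#'   (best candidate included).
#' @param alpha rejection level (default 0.05).
#' @param max_enumeration largest number of outcome compositions enumerated
#'   for the exact test before falling back to chi-square.
#' @return a one-row tibble: `flag`, `p_value`, `statistic`, `method`,
#'   `best`, `n_alternatives`.
#' @export
hybridization_check <- function(profile, alpha = 0.05, max_enumeration = 2e6) {
  if (inherits(profile, "support_profile")) {
    counts <- stats::setNames(profile$n_support, profile$candidate)
  } else {
    counts <- profile
  }
  if (length(counts) < 3) stop("need at least 3 candidates", call. = FALSE)
  if (all(counts == 0)) stop("all support counts are zero", call. = FALSE)
  if (is.null(names(counts))) names(counts) <- paste0("candidate_", seq_along(counts))
  best <- names(counts)[which.max(counts)]
  alt <- counts[names(counts) != best]
  n <- sum(alt); k <- length(alt)
  if (n == 0) {
    return(tibble::tibble(flag = FALSE, p_value = 1, statistic = 0,
                          method = "degenerate", best = best, n_alternatives = k))
  }
  expected <- n / k
  stat <- sum((alt - expected)^2 / expected)
  n_outcomes <- choose(n + k - 1, k - 1)
  if (n_outcomes <= max_enumeration) {
    p <- exact_multinomial_p(as.integer(alt))
    method <- "exact multinomial"
  } else {
    p <- stats::pchisq(stat, df = k - 1, lower.tail = FALSE)
    method <- "chi-square"
  }
  resid <- (alt - expected) / sqrt(expected)
  flag <- p < alpha && max(resid) > 0
  tibble::tibble(flag = flag, p_value = p, statistic = stat, method = method,
                 best = best, n_alternatives = k)
}

# Exact multinomial goodness-of-fit p-value vs the uniform null: sum of the
# probabilities of all outcomes no more probable than the observed one.
exact_multinomial_p <- function(obs) {
  n <- sum(obs); k <- length(obs)
  comps <- compositions(n, k)
  logp <- lgamma(n + 1) - rowSums(lgamma(comps + 1)) + n * log(1 / k)
  logp_obs <- lgamma(n + 1) - sum(lgamma(obs + 1)) + n * log(1 / k)
  sum(exp(logp[logp <= logp_obs + 1e-9]))
}

# all k-part compositions of n, as a matrix with one row per composition
compositions <- function(n, k) {
  if (k == 1) return(matrix(n, ncol = 1))
  out <- vector("list", n + 1)
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1)
    out[[first + 1]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}
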