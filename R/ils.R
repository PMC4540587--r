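#' ILS duration of a character mapping
#'
#' The minimum number of speciation events across which the insertion
#' polymorphism must have persisted, counted through the minimal number of
#' independently sorting lineages: `n` fixation events (transitions to the
#' presence or absence allele) imply persistence across `n - 1` speciation
#' events. Conflict-free markers (single step) return `0`, reported
#' downstream as duration class `"<=1"`.
#'
#' @param mapping a [map_character()] result.
#' @return integer duration; errors on an all-absent (empty) mapping.
#' @export
ils_duration <- function(mapping) {
  stopifnot(inherits(mapping, "char_mapping"))
  if (mapping$empty) {
    stop("ILS duration is undefined for an all-absent pattern", call. = FALSE)
  }
  max(0L, mapping$fixations_to_1 + mapping$fixations_to_0 - 1L)
}

#' Per-branch ILS summary
#'
#' Attributes every informative marker to its parsimony-inferred origin
#' branch and tallies, per branch: conflict-free insertions, ILS-affected
#' insertions by duration class (2 / 3 / >=4 speciation events), the
#' percentage of ILS-affected markers, and — when the tree carries branch
#' lengths in million years — the insertion rate per MY
#' (total markers / branch length). Branches on which no marker originated
#' report `pct_ils = NA` rather than 0.
#'
#' @inheritParams map_markers
#' @param lengths_unit `"my"` to interpret `tree$edge.length` as million
#'   years and compute insertion rates, `"none"` to skip rates.
#' @return a tibble of class `branch_ils` with one row per branch (branches
#'   are identified by the ape node id of their child end; `clade` is a
#'   list-column of subtended tip labels).
#' @export
branch_summary <- function(x, tree, convention = c("fixations", "retentions"),
                           lengths_unit = c("none", "my")) {
  convention <- match.arg(convention)
  lengths_unit <- match.arg(lengths_unit)
  idx <- build_tree_index(tree)
  if (lengths_unit == "my" && is.null(tree$edge.length)) {
    stop("insertion rates requested but the tree has no branch lengths", call. = FALSE)
  }
  per <- map_markers(x, tree, convention)
  per <- dplyr::filter(per, .data$informative)
  # every branch, labelled by its child node; the root row collects
  # insertions older than the basal divergence (origin on the root stem)
  nodes <- seq_len(idx$nnode)
  tab <- purrr::map_dfr(nodes, function(v) {
    here <- dplyr::filter(per, .data$origin == v)
    tibble::tibble(branch = v,
                   n_tips = sum(idx$tipsets[v, ]),
                   conflict_free = sum(here$conflict_free),
                   ils_2 = sum(here$class == "2"),
                   ils_3 = sum(here$class == "3"),
                   ils_4plus = sum(here$class == ">=4"),
                   total_markers = nrow(here))
  })
  tab <- dplyr::mutate(tab,
    pct_ils = dplyr::if_else(.data$total_markers > 0,
                             100 * (.data$total_markers - .data$conflict_free) /
                               .data$total_markers,
                             NA_real_))
  if (lengths_unit == "my") {
    tab$branch_length_my <- idx$blen[tab$branch]
    tab$insertion_rate <- ifelse(!is.na(tab$branch_length_my) & tab$branch_length_my > 0,
                                 tab$total_markers / tab$branch_length_my, NA_real_)
  }
  tab$clade <- lapply(tab$branch, function(v) idx$labels[idx$tipsets[v, ]])
  class(tab) <- c("branch_ils", class(tab))
  tab
}

#' Spearman rank correlation between per-branch quantities
#'
#' Spearman's rho with average ranks for ties; the two-sided p-value uses the
#' large-sample t approximation `t = rho * sqrt((n - 2) / (1 - rho^2))` on
#' `n - 2` degrees of freedom, the usual choice for a couple of dozen
#' internodes. Errors on constant input (rank correlation undefined).
#'
#' @param x,y numeric vectors of equal length `>= 4`; pairs with missing
#'   values are dropped.
#' @return a one-row tibble with `rho`, `p`, `n`.
#' @export
ils_correlate <- function(x, y) {
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 4) stop("need at least 4 complete pairs", call. = FALSE)
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    stop("rank correlation undefined for constant input", call. = FALSE)
  }
  rho <- stats::cor(rank(x), rank(y))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tval <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tval), df = n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n)
}

#' Per-partition ILS summary
#'
#' Fraction of ILS-affected markers per genomic partition (e.g. autosomes vs
#' the Z chromosome, or microchromosomes). Partitions are defined on the
#' `chromosome` metadata column, either by a named list of chromosome name
#' vectors or by a function mapping chromosome names to partition labels.
#' Markers whose chromosome matches no partition (or is missing) are
#' reported under `"unassigned"`, never silently dropped.
#'
#' @inheritParams map_markers
#' @param partitions named list of character vectors of chromosome names, or
#'   a function `chromosome -> partition label`.
#' @return a tibble with `partition`, `n_markers`, `n_ils`, `pct_ils`.
#' @export
partition_summary <- function(x, tree, partitions,
                              convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  if (is.null(x[["chromosome"]])) {
    stop("matrix has no `chromosome` metadata column", call. = FALSE)
  }
  per <- map_markers(x, tree, convention)
  per$chromosome <- x$chromosome[match(per$marker_id, x$marker_id)]
  if (is.function(partitions)) {
    per$partition <- vapply(per$chromosome, function(ch) {
      if (is.na(ch)) NA_character_ else as.character(partitions(ch))
    }, character(1))
  } else {
    lookup <- stats::setNames(rep(names(partitions), lengths(partitions)),
                              unlist(partitions))
    per$partition <- unname(lookup[per$chromosome])
  }
  per$partition[is.na(per$partition)] <- "unassigned"
  per |>
    dplyr::filter(.data$informative) |>
    dplyr::group_by(.data$partition) |>
    dplyr::summarise(n_markers = dplyr::n(),
                     n_ils = sum(.data$steps > 1),
                     pct_ils = 100 * .data$n_ils / .data$n_markers,
                     .groups = "drop")
}

#' Duration spectra for named radiations
#'
#' For each named radiation — a set of internodes given as the internal
#' branches of the clade spanned by the listed taxa (including the clade's
#' stem branch) — tallies the markers originating on those branches by full
#' integer ILS duration and reports the radiation's total percentage of
#' ILS-affected markers.
#'
#' @inheritParams map_markers
#' @param radiations named list; each element is a character vector of taxa
#'   whose spanned clade defines the radiation.
#' @return a tibble with `radiation`, `duration`, `n`, plus per-radiation
#'   totals `n_markers` and `pct_ils` repeated across rows.
#' @export
radiation_spectrum <- function(x, tree, radiations,
                               convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  idx <- build_tree_index(tree)
  per <- dplyr::filter(map_markers(x, tree, convention), .data$informative)
  purrr::map_dfr(names(radiations), function(nm) {
    taxa <- radiations[[nm]]
    miss <- setdiff(taxa, idx$labels)
    if (length(miss) > 0) stop("unknown taxa in radiation '", nm, "': ", miss[1],
                               call. = FALSE)
    mask <- idx$labels %in% taxa
    member <- vapply(seq_len(idx$nnode), function(v) {
      tips <- idx$tipsets[v, ]
      sum(tips) >= 2 && all(idx$labels[tips] %in% taxa)
    }, logical(1))
    here <- dplyr::filter(per, .data$origin %in% which(member))
    tot <- nrow(here)
    spec <- here |>
      dplyr::count(.data$duration, name = "n") |>
      dplyr::arrange(.data$duration)
    if (nrow(spec) == 0) spec <- tibble::tibble(duration = integer(), n = integer())
    dplyr::mutate(spec, radiation = nm, n_markers = tot,
                  pct_ils = if (tot > 0) 100 * sum(here$duration >= 2) / tot else NA_real_,
                  .before = 1)
  })
}

#' Most-parsimonious tree from a marker subset
#'
#' Convenience wrapper: restricts the matrix to the given markers (e.g. the
#' Z-chromosomal or microchromosomal subset) and reruns [search_mpre()] under
#' identical settings. Warns, but still runs, when fewer than 3 informative
#' markers remain.
#'
#' @inheritParams search_mpre
#' @param marker_ids markers to keep; alternatively a logical/integer row
#'   selector.
#' @return as [search_mpre()].
#' @export
subtree_tree <- function(x, marker_ids, n_jumbles = 7, seed = 11111,
                         convention = c("fixations", "retentions")) {
  convention <- match.arg(convention)
  if (is.character(marker_ids)) {
    keep <- x$marker_id %in% marker_ids
  } else {
    keep <- marker_ids
  }
  sub <- new_pa_tbl(x[keep, , drop = FALSE], taxa = pa_taxa(x))
  s <- pa_states(sub)
  n_inf <- sum(rowSums(s == "1") >= 2)
  if (n_inf < 3) {
    warning("fewer than 3 informative markers in subset; search may be unresolved",
            call. = FALSE)
  }
  search_mpre(sub, n_jumbles = n_jumbles, seed = seed, convention = convention)
}
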