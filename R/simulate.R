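#' Simulation configuration
#'
#' Bundles everything the marker-matrix generator needs. Branch lengths of
#' `tree` are in coalescent units (one unit = the expected time for two
#' lineages in a population to coalesce); [coalescent_units()] converts from
#' million years given an effective population size and generation time.
#' Defaults mirror a genome screen of a bird-scale radiation: 2,118 loci, a
#' 10% per-entry missing-data rate, ascertainment that drops plesiomorphic,
#' autapomorphic and all-absent patterns and requires at least 10 scored
#' taxa, and a chromosome scheme with macro-, micro- (< 20 Mb) and Z
#' chromosomes.
#'
#' @param tree rooted `phylo` with branch lengths in coalescent units.
#' @param n_loci number of retained loci to generate.
#' @param missing_rate per-entry probability of masking a state as `?`.
#' @param min_taxa minimum scored taxa for a locus to be retained.
#' @param drop_plesiomorphic,drop_autapomorphic,drop_all_absent ascertainment
#'   switches.
#' @param chromosomes tibble with columns `chromosome`, `proportion`,
#'   `type` (`"macro"`, `"micro"` or `"Z"`) and `size_mb`; see
#'   [default_chromosome_scheme()].
#' @param seed RNG seed (mandatory; the generator is deterministic given the
#'   config).
#' @return a `sim_config` list.
#' @export
sim_config <- function(tree, n_loci = 2118, missing_rate = 0.1, min_taxa = 10,
                       drop_plesiomorphic = TRUE, drop_autapomorphic = TRUE,
                       drop_all_absent = TRUE,
                       chromosomes = default_chromosome_scheme(), seed) {
  if (missing(seed)) stop("a seed is mandatory in sim_config()", call. = FALSE)
  tree <- validate_species_tree(tree)
  if (is.null(tree$edge.length)) {
    stop("species tree must carry branch lengths in coalescent units", call. = FALSE)
  }
  stopifnot(n_loci >= 1, missing_rate >= 0, missing_rate <= 1, min_taxa >= 2)
  structure(list(tree = tree, n_loci = as.integer(n_loci),
                 missing_rate = missing_rate, min_taxa = as.integer(min_taxa),
                 drop_plesiomorphic = drop_plesiomorphic,
                 drop_autapomorphic = drop_autapomorphic,
                 drop_all_absent = drop_all_absent,
                 chromosomes = tibble::as_tibble(chromosomes),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' @rdname sim_config
#' @details The default chromosome scheme assigns markers to the Z chromosome
#' and to microchromosomes with probabilities 114/2118 and 140/2118 (the
#' proportions of such markers in a genome-wide screen of the neoavian
#' radiation), the rest to macrochromosomes weighted by size.
#' @export
default_chromosome_scheme <- function() {
  macro <- tibble::tibble(chromosome = paste0("chr", 1:8),
                          size_mb = c(156, 119, 112, 70, 62, 36, 40, 28),
                          type = "macro")
  micro <- tibble::tibble(chromosome = paste0("chr", 11:17),
                          size_mb = c(18, 15, 12, 10, 8, 6, 4),
                          type = "micro")
  z <- tibble::tibble(chromosome = "chrZ", size_mb = 73, type = "Z")
  p_z <- 114 / 2118
  p_micro <- 140 / 2118
  macro$proportion <- (1 - p_z - p_micro) * macro$size_mb / sum(macro$size_mb)
  micro$proportion <- p_micro * micro$size_mb / sum(micro$size_mb)
  z$proportion <- p_z
  dplyr::bind_rows(macro, micro, z)
}

#' Convert absolute time to coalescent units
#'
#' `t / (2 * Ne * g)` with `t` in years: the only place the effective
#' population size enters the package.
#'
#' @param my time in million years.
#' @param ne (diploid) effective population size.
#' @param generation_time generation time in years.
#' @export
coalescent_units <- function(my, ne, generation_time = 1) {
  my * 1e6 / (2 * ne * generation_time)
}

#' Simulate one gene tree under the multispecies coalescent
#'
#' One haploid lineage is sampled per species; within each species-tree
#' branch any `k` extant lineages coalesce at rate `k (k - 1) / 2` per
#' coalescent unit, surviving lineages pass to the parent branch, and
#' coalescence continues above the root until a single lineage remains.
#' Draws from the current R RNG stream (seed it with [set.seed()] for
#' reproducibility).
#'
#' @param species_tree rooted `phylo`, branch lengths in coalescent units.
#' @return an object of class `gene_tree`; [gene_tree_phylo()] converts it to
#'   `phylo`.
#' @export
simulate_gene_tree <- function(species_tree) {
  idx <- build_tree_index(species_tree)
  if (any(is.na(idx$blen[-idx$root]))) {
    stop("species tree has missing branch lengths", call. = FALSE)
  }
  sim_gene_tree_idx(idx, node_times(idx))
}

sim_gene_tree_idx <- function(idx, times) {
  ntip <- idx$ntip
  n_g <- 2L * ntip - 1L
  parent_g <- integer(n_g)
  time_g <- numeric(n_g)
  species_g <- integer(n_g)
  time_g[seq_len(ntip)] <- times[seq_len(ntip)]
  species_g[seq_len(ntip)] <- seq_len(ntip)
  next_g <- ntip
  event_lineages <- vector("list", idx$nnode)
  lin <- vector("list", idx$nnode) # live lineages per species branch
  for (v in seq_len(ntip)) lin[[v]] <- v
  coalesce_in <- function(lins, t0, t1, sp) {
    k <- length(lins)
    t <- t0
    while (k >= 2) {
      t <- t + stats::rexp(1, rate = k * (k - 1) / 2)
      if (t >= t1) break
      pair <- sample.int(k, 2)
      next_g <<- next_g + 1L
      parent_g[lins[pair]] <<- next_g
      time_g[next_g] <<- t
      species_g[next_g] <<- sp
      lins <- c(lins[-pair], next_g)
      k <- k - 1L
    }
    lins
  }
  # ascending age, stably keeping descendants before ancestors on ties
  po_int <- idx$postorder[idx$postorder > ntip]
  order_internal <- po_int[order(times[po_int])]
  for (v in order_internal) {
    merged <- integer(0)
    for (ch in idx$children[[v]]) {
      merged <- c(merged, coalesce_in(lin[[ch]], times[ch], times[v], ch))
    }
    event_lineages[[v]] <- merged
    lin[[v]] <- merged
  }
  root <- idx$root
  lin[[root]] <- coalesce_in(lin[[root]], times[root], Inf, root)
  structure(list(parent = parent_g, time = time_g, species = species_g,
                 ntip = ntip, labels = idx$labels,
                 event_lineages = event_lineages),
            class = "gene_tree")
}

#' @rdname simulate_gene_tree
#' @param gt a `gene_tree`.
#' @export
gene_tree_phylo <- function(gt) {
  n_g <- length(gt$parent)
  root_g <- which(gt$parent == 0L)
  edge <- cbind(gt$parent[-root_g], seq_len(n_g)[-root_g])
  # renumber: tips keep 1..ntip, internals become ntip+1.. with the root first
  internal <- setdiff((gt$ntip + 1L):n_g, root_g)
  newid <- integer(n_g)
  newid[seq_len(gt$ntip)] <- seq_len(gt$ntip)
  newid[root_g] <- gt$ntip + 1L
  newid[internal] <- gt$ntip + 1L + seq_along(internal)
  len <- gt$time[gt$parent[-root_g]] - gt$time[-root_g]
  tr <- list(edge = cbind(newid[edge[, 1]], newid[edge[, 2]]),
             tip.label = gt$labels, Nnode = gt$ntip - 1L,
             edge.length = len)
  class(tr) <- "phylo"
  ape::reorder.phylo(tr, "cladewise")
}

# tip descendants (gene-node ids <= ntip) of every gene node
gene_tip_desc <- function(gt) {
  n_g <- length(gt$parent)
  desc <- matrix(FALSE, n_g, gt$ntip)
  desc[cbind(seq_len(gt$ntip), seq_len(gt$ntip))] <- TRUE
  for (v in order(gt$time)) { # children have smaller times than parents
    p <- gt$parent[v]
    if (p > 0L) desc[p, ] <- desc[p, ] | desc[v, ]
  }
  desc
}

#' Does a gene tree match the species-tree topology?
#'
#' `TRUE` iff every internal gene-tree bipartition corresponds to a species
#' clade (ignoring branch lengths).
#'
#' @param gt a `gene_tree`.
#' @param species_tree the generating rooted `phylo`.
#' @export
gene_tree_concordant <- function(gt, species_tree) {
  idx <- build_tree_index(species_tree)
  desc <- gene_tip_desc(gt)
  sp_clades <- apply(idx$tipsets, 1, function(r) paste(which(r), collapse = ","))
  g_int <- (gt$ntip + 1L):length(gt$parent)
  g_clades <- apply(desc[g_int, , drop = FALSE], 1,
                    function(r) paste(which(r), collapse = ","))
  all(g_clades %in% sp_clades)
}

#' Simulate a presence/absence marker matrix with known truth
#'
#' Per locus: draw a gene tree under the multispecies coalescent, place a
#' single insertion uniformly over the total gene-tree branch length
#' (infinite sites — no parallel insertion, no precise excision), score the
#' descendant tips as present, mask entries as missing, and apply the
#' ascertainment filters; rejected loci are redrawn so exactly `n_loci`
#' retained loci are returned. Each retained locus records its generating
#' truth: the species branch carrying the insertion and the true ILS
#' duration — the number of speciation events at which both alleles were
#' still segregating among the sampled ancestral lineages.
#'
#' @param config a [sim_config()].
#' @return a list of class `sim_result`: `matrix` (a `pa_tbl` with
#'   chromosome/coordinate/TSD metadata), `truth` (a tibble with
#'   `marker_id`, `origin_branch`, `n_presence`, `true_duration` — the
#'   genealogical count of speciation events with both alleles segregating —
#'   `true_ils`, and `pattern_duration`, the duration of the unmasked
#'   pattern on the generating tree), `n_attempts`, and the `config`.
#' @export
simulate_pa_matrix <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  idx <- build_tree_index(config$tree)
  times <- node_times(idx)
  ntip <- idx$ntip
  set.seed(config$seed)
  max_attempts <- 200L * config$n_loci + 1000L
  states <- matrix("0", config$n_loci, ntip, dimnames = list(NULL, idx$labels))
  truth <- vector("list", config$n_loci)
  kept <- 0L
  attempts <- 0L
  while (kept < config$n_loci) {
    attempts <- attempts + 1L
    if (attempts > max_attempts) {
      stop(sprintf(paste0("ascertainment too strict: %d attempts yielded %d/%d ",
                          "loci (missing_rate=%.2f, min_taxa=%d)"),
                   attempts - 1L, kept, config$n_loci, config$missing_rate,
                   config$min_taxa), call. = FALSE)
    }
    gt <- sim_gene_tree_idx(idx, times)
    has_parent <- gt$parent > 0L
    elen <- numeric(length(gt$parent))
    elen[has_parent] <- gt$time[gt$parent[has_parent]] - gt$time[has_parent]
    total <- sum(elen)
    u <- stats::runif(1, 0, total)
    v_ins <- which(cumsum(elen) >= u)[1]
    t_ins <- gt$time[v_ins] + (u - c(0, cumsum(elen))[v_ins])
    desc <- gene_tip_desc(gt)
    pattern <- ifelse(desc[v_ins, ], "1", "0")
    if (config$missing_rate > 0) {
      mask <- stats::runif(ntip) < config$missing_rate
      pattern[mask] <- "?"
    }
    n_scored <- sum(pattern != "?")
    n_pres <- sum(pattern == "1")
    if (n_scored < config$min_taxa) next
    if (config$drop_all_absent && n_pres == 0) next
    if (config$drop_plesiomorphic && n_pres == n_scored && n_scored > 0) next
    if (config$drop_autapomorphic && n_pres == 1) next
    kept <- kept + 1L
    states[kept, ] <- pattern
    truth[[kept]] <- locus_truth(gt, idx, times, v_ins, t_ins, desc)
  }
  truth <- dplyr::bind_rows(truth)
  truth$marker_id <- sprintf("sim%05d", seq_len(config$n_loci))
  truth <- dplyr::relocate(truth, "marker_id")
  meta <- draw_marker_meta(config)
  mat <- pa_matrix(states, marker_id = truth$marker_id, meta = meta)
  structure(list(matrix = mat, truth = truth, n_attempts = attempts,
                 config = config),
            class = "sim_result")
}

locus_truth <- function(gt, idx, times, v_ins, t_ins, desc) {
  ntip <- idx$ntip
  # gene nodes below (or at) the insertion edge carry the presence allele
  is_below <- vapply(seq_along(gt$parent), function(g) {
    while (g != 0L) {
      if (g == v_ins) return(TRUE)
      g <- gt$parent[g]
    }
    FALSE
  }, logical(1))
  seg <- 0L
  for (v in (ntip + 1L):idx$nnode) {
    t_s <- times[v]
    if (t_s >= t_ins) next # speciation predates the insertion
    lins <- gt$event_lineages[[v]]
    if (length(lins) < 2) next
    carriers <- is_below[lins]
    if (any(carriers) && any(!carriers)) seg <- seg + 1L
  }
  # the true ILS duration of the locus: the duration of its clean, unmasked
  # presence pattern mapped on the generating tree
  clean_map <- map_dp(idx, as.integer(desc[v_ins, ]))
  dur <- max(0L, clean_map$fixations_to_1 + clean_map$fixations_to_0 - 1L)
  # species branch containing the insertion point
  sp <- gt$species[v_ins]
  while (sp != idx$root && times[idx$parent[sp]] <= t_ins) sp <- idx$parent[sp]
  if (sp == idx$root && t_ins >= times[idx$root]) sp <- NA_integer_
  tibble::tibble(origin_branch = sp,
                 n_presence = sum(desc[v_ins, ]),
                 true_duration = dur,
                 true_ils = dur >= 2L,
                 segregating_events = seg)
}

draw_marker_meta <- function(config) {
  sch <- config$chromosomes
  n <- config$n_loci
  chr_i <- sample.int(nrow(sch), n, replace = TRUE, prob = sch$proportion)
  size_bp <- round(sch$size_mb[chr_i] * 1e6)
  start <- vapply(size_bp, function(s) sample.int(max(s - 600L, 1L), 1), integer(1))
  motifs <- vapply(seq_len(n), function(i) {
    paste(sample(c("A", "C", "G", "T"), 5, replace = TRUE), collapse = "")
  }, character(1))
  tibble::tibble(chromosome = sch$chromosome[chr_i],
                 start = start, end = start + 499L,
                 genic = stats::runif(n) < 0.5,
                 tsd_motif = motifs)
}

#' Compare parsimony estimates with simulated truth
#'
#' Runs the polymorphism-parsimony pipeline on a simulated matrix and joins
#' the per-locus truth. Duration agreement is scored on the reporting scale
#' of the duration classes: true and estimated durations of one or fewer
#' speciation events are both conflict-free (`"<=1"`), larger durations are
#' compared as integers. Parsimony counts the *minimal* number of
#' independently sorting lineages, so it can undercount deep coalescences —
#' agreement below 100% on short internodes is expected behaviour, not an
#' estimator bug.
#'
#' @param sim a [simulate_pa_matrix()] result.
#' @param convention step convention passed to [map_markers()].
#' @return a list: `per_locus` tibble (`marker_id`, `true_duration`,
#'   `segregating_events`, `est_duration`, `agree`, `agree_genealogical`),
#'   `agreement` and `genealogical_agreement` (fractions), `per_branch`
#'   tibble of estimated vs true per-branch ILS percentages. `true_duration`
#'   is the duration of the clean, unmasked pattern mapped on the generating
#'   tree; `segregating_events` counts the speciation events at which both
#'   alleles actually segregated among the sampled lineages. Parsimony
#'   undercounts the latter whenever deep coalescences sort into
#'   species-tree-concordant patterns (silent ILS), so genealogical
#'   agreement sits well below pattern agreement on short internodes.
#' @export
recover_parameters <- function(sim, convention = c("fixations", "retentions")) {
  stopifnot(inherits(sim, "sim_result"))
  convention <- match.arg(convention)
  est <- map_markers(sim$matrix, sim$config$tree, convention)
  per <- dplyr::left_join(sim$truth, est, by = "marker_id") |>
    dplyr::transmute(.data$marker_id,
                     true_duration = .data$true_duration,
                     segregating_events = .data$segregating_events,
                     est_duration = .data$duration,
                     true_origin = .data$origin_branch,
                     est_origin = .data$origin,
                     agree = pmax(.data$true_duration, 1L) == pmax(.data$est_duration, 1L),
                     agree_genealogical = pmax(.data$segregating_events, 1L) ==
                       pmax(.data$est_duration, 1L))
  per_branch <- dplyr::full_join(
    per |>
      dplyr::filter(!is.na(.data$true_origin)) |>
      dplyr::group_by(branch = .data$true_origin) |>
      dplyr::summarise(true_pct_ils = 100 * mean(.data$true_duration >= 2),
                       n_true = dplyr::n(), .groups = "drop"),
    per |>
      dplyr::group_by(branch = .data$est_origin) |>
      dplyr::summarise(est_pct_ils = 100 * mean(.data$est_duration >= 2),
                       n_est = dplyr::n(), .groups = "drop"),
    by = "branch")
  list(per_locus = per, agreement = mean(per$agree),
       genealogical_agreement = mean(per$agree_genealogical),
       per_branch = per_branch)
}
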