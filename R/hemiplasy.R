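#' Hemiplasy combinatorics under stochastic sorting
#'
#' A biallelic insertion polymorphism persisting across `n` speciation events
#' on a maximally pectinate (caterpillar) species tree leaves `L = n + 1`
#' independently sorting lineages, each of which fixes the presence or the
#' absence allele: `2^L` equiprobable fixation vectors. A vector is
#' *congruent* with the species tree when it is explainable with at most one
#' speciation event of polymorphism persistence — equivalently, when its
#' presence set is a clade of the caterpillar (including the empty and the
#' full set). There are exactly `2L` such vectors (`L` singletons, `L - 2`
#' non-trivial nested clades, empty, full), so the probability of hemiplasy
#' is `(2^L - 2L) / 2^L`.
#'
#' `enumerate_fates()` lists and classifies all `2^L` vectors;
#' `hemiplasy_table()` gives the closed-form counts per ILS duration;
#' `classify_pattern()` classifies a single vector.
#'
#' @param n_events number of speciation events the polymorphism persists
#'   across (`>= 1`; enumeration is bounded at 20, the closed form at 62).
#' @return `enumerate_fates()`: a tibble with one row per fixation vector
#'   (`pattern` as a `"10010"`-style string over the lineages ordered
#'   cherry-first, `n_presence`, `classification`).
#' @examples
#' sum(enumerate_fates(4)$classification == "hemiplasious") # 22
#' hemiplasy_table(3)$p_hemiplasy[3] # 0.5
#' @export
enumerate_fates <- function(n_events) {
  stopifnot(n_events >= 1, n_events <= 20)
  L <- n_events + 1L
  grid <- as.matrix(expand.grid(rep(list(c(0L, 1L)), L))[, L:1])
  colnames(grid) <- NULL
  cls <- apply(grid, 1, classify_vector)
  tibble::tibble(pattern = apply(grid, 1, paste, collapse = ""),
                 n_presence = rowSums(grid),
                 classification = cls)
}

# congruent iff presence set is a clade of the caterpillar whose lineages
# are ordered cherry-first: empty, full, any singleton, or a prefix {1..k}
classify_vector <- function(v) {
  k <- sum(v)
  L <- length(v)
  congruent <- k <= 1 || k == L || all(v[seq_len(k)] == 1L)
  if (congruent) "congruent" else "hemiplasious"
}

#' @rdname enumerate_fates
#' @param n_events_max compute rows for durations `1..n_events_max`
#'   (closed form, no enumeration; bounded at 62 for exact integer counts).
#' @return `hemiplasy_table()`: a tibble of class `hemiplasy_tbl` with
#'   columns `n_events`, `n_lineages`, `n_total`, `n_congruent`,
#'   `n_hemiplasious`, `p_hemiplasy`.
#' @export
hemiplasy_table <- function(n_events_max = 17) {
  stopifnot(n_events_max >= 1, n_events_max <= 62)
  n <- seq_len(n_events_max)
  L <- n + 1
  out <- tibble::tibble(n_events = n,
                        n_lineages = L,
                        n_total = 2^L,
                        n_congruent = 2 * L,
                        n_hemiplasious = 2^L - 2 * L,
                        p_hemiplasy = (2^L - 2 * L) / 2^L)
  class(out) <- c("hemiplasy_tbl", class(out))
  out
}

#' @rdname enumerate_fates
#' @param fixation_vector integer/logical vector of per-lineage allele fates
#'   (1 = presence fixed), or a `"10010"`-style string.
#' @param ladder_order optional lineage names giving the caterpillar order
#'   (cherry first); defaults to the vector's own order.
#' @return `classify_pattern()`: `"congruent"` or `"hemiplasious"`.
#' @export
classify_pattern <- function(fixation_vector, ladder_order = NULL) {
  if (is.character(fixation_vector) && length(fixation_vector) == 1) {
    fixation_vector <- as.integer(strsplit(fixation_vector, "")[[1]])
  }
  v <- as.integer(fixation_vector)
  if (!all(v %in% c(0L, 1L))) stop("fixation vector must be binary", call. = FALSE)
  if (!is.null(ladder_order)) {
    if (length(ladder_order) != length(v)) {
      stop("ladder order length does not match the fixation vector", call. = FALSE)
    }
    if (!is.null(names(fixation_vector))) v <- v[match(ladder_order, names(fixation_vector))]
  }
  classify_vector(v)
}

#' Caterpillar tree over given lineage labels
#'
#' The maximally pectinate rooted tree `((..((l1,l2),l3)..),lL)` used by the
#' hemiplasy enumeration; `l1` and `l2` form the cherry.
#'
#' @param labels lineage labels, cherry first.
#' @return a rooted `phylo`.
#' @export
caterpillar_tree <- function(labels) {
  stopifnot(length(labels) >= 2)
  nwk <- labels[1]
  for (l in labels[-1]) nwk <- paste0("(", nwk, ",", l, ")")
  ape::read.tree(text = paste0(nwk, ";"))
}
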