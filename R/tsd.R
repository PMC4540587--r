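#' Target-site-duplication motif statistics
#'
#' Position-wise nucleotide composition of the 5-bp target-site duplications
#' flanking the retrotransposon insertions: counts and frequencies per
#' position, sequence-logo information content (`IC_j = 2 - H_j` bits, with
#' `H_j` the Shannon entropy of position `j`, no small-sample correction),
#' and a per-position chi-square statistic against the uniform 1/4
#' expectation. `N` is dropped from the affected position only, not the
#' whole motif.
#'
#' @param motifs character vector of 5-letter motifs over `{A,C,G,T,N}`; a
#'   `pa_tbl` with a `tsd_motif` column is also accepted.
#' @return an object of class `motif_matrix` with elements `counts`,
#'   `frequencies` (4 x 5 matrices), `ic` (bits per position), `chisq`,
#'   `n` (motifs used per position).
#' @examples
#' mm <- motif_matrix(c("ACGTA", "ACGTT", "ACGTC"))
#' mm$ic
#' @export
motif_matrix <- function(motifs) {
  if (inherits(motifs, "pa_tbl")) {
    if (is.null(motifs[["tsd_motif"]])) {
      stop("matrix has no tsd_motif metadata column", call. = FALSE)
    }
    motifs <- stats::setNames(motifs$tsd_motif, motifs$marker_id)
  }
  motifs <- motifs[!is.na(motifs)]
  if (length(motifs) == 0) stop("no motifs supplied", call. = FALSE)
  motifs <- toupper(motifs)
  ids <- if (is.null(names(motifs))) as.character(seq_along(motifs)) else names(motifs)
  bad_len <- nchar(motifs) != 5L
  if (any(bad_len)) {
    stop("motif of wrong length for record(s): ",
         paste(utils::head(ids[bad_len], 5), collapse = ", "), call. = FALSE)
  }
  chars <- do.call(rbind, strsplit(motifs, ""))
  bad_sym <- setdiff(unique(as.vector(chars)), c("A", "C", "G", "T", "N"))
  if (length(bad_sym) > 0) {
    stop("invalid motif symbol '", bad_sym[1], "'", call. = FALSE)
  }
  nts <- c("A", "C", "G", "T")
  counts <- vapply(seq_len(5), function(j) {
    table(factor(chars[, j], levels = nts))
  }, numeric(4))
  dimnames(counts) <- list(nucleotide = nts, position = seq_len(5))
  n <- colSums(counts)
  freq <- sweep(counts, 2, pmax(n, 1), "/")
  h <- apply(freq, 2, function(p) {
    p <- p[p > 0]
    -sum(p * log2(p))
  })
  ic <- 2 - h
  chisq <- vapply(seq_len(5), function(j) {
    e <- n[j] / 4
    if (e == 0) return(NA_real_)
    sum((counts[, j] - e)^2 / e)
  }, numeric(1))
  structure(list(counts = counts, frequencies = freq, ic = ic,
                 chisq = chisq, n = n),
            class = "motif_matrix")
}

#' @export
print.motif_matrix <- function(x, ...) {
  cat("<motif_matrix>", max(x$n), "motifs\n")
  cat("IC (bits):", sprintf("%.3f", x$ic), "\n")
  print(round(x$frequencies, 3))
  invisible(x)
}

#' @rdname motif_matrix
#' @param x a `motif_matrix`.
#' @param ... unused.
#' @return `tidy()`: a long tibble (`position`, `nucleotide`, `count`,
#'   `frequency`, `ic`).
#' @method tidy motif_matrix
#' @export
tidy.motif_matrix <- function(x, ...) {
  tibble::as_tibble(as.data.frame.table(x$counts, responseName = "count")) |>
    dplyr::mutate(position = as.integer(as.character(.data$position)),
                  nucleotide = as.character(.data$nucleotide),
                  frequency = .data$count / x$n[.data$position],
                  ic = x$ic[.data$position])
}

#' Test for target-site preference
#'
#' Chi-square goodness of fit of each motif position against the uniform 1/4
#' nucleotide expectation, combined across the five positions by Fisher's
#' method (`-2 * sum(log p_j)` on `2 * 5` degrees of freedom). A small global
#' p indicates a target-site preference; near-equal frequencies at every
#' position leave it non-significant. The numeric operationalisation of
#' "near-equal frequencies" is the package's own.
#'
#' @param mm a [motif_matrix()] (or the motif vector / `pa_tbl` to build one
#'   from).
#' @param min_count minimum motifs required per position (default 20).
#' @return a tibble with per-position rows (`position`, `statistic`, `p`)
#'   and the Fisher combination attached as attributes `global_statistic`,
#'   `global_p`; also returned in the final row with `position = NA`.
#' @export
preference_test <- function(mm, min_count = 20) {
  if (!inherits(mm, "motif_matrix")) mm <- motif_matrix(mm)
  if (any(mm$n < min_count)) {
    stop("insufficient motif counts (need >= ", min_count, " per position)",
         call. = FALSE)
  }
  p <- stats::pchisq(mm$chisq, df = 3, lower.tail = FALSE)
  fisher_stat <- -2 * sum(log(pmax(p, .Machine$double.xmin)))
  global_p <- stats::pchisq(fisher_stat, df = 2 * length(p), lower.tail = FALSE)
  out <- tibble::tibble(position = c(seq_along(p), NA_integer_),
                        statistic = c(mm$chisq, fisher_stat),
                        p = c(p, global_p))
  attr(out, "global_statistic") <- fisher_stat
  attr(out, "global_p") <- global_p
  out
}
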