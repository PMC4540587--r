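#' Presence/absence marker matrices
#'
#' The central data object of the package is a tibble of class `pa_tbl` with
#' one row per retrotransposon marker. Recognised metadata columns are
#' `marker_id` (mandatory, unique), `chromosome`, `start`, `end` (1-based
#' inclusive coordinates), `genic` (logical: intronic vs putatively
#' intergenic) and `tsd_motif` (5-letter target-site-duplication motif over
#' A/C/G/T/N). Every remaining column is a taxon, holding the character
#' states `"1"` (insertion present), `"0"` (absent) or `"?"` (missing).
#' Polarity is fixed: `0` is the ancestral state and is never inferred.
#'
#' @param states character matrix (markers x taxa) over `{"1","0","?"}`, or a
#'   data frame of taxon columns.
#' @param marker_id marker identifiers; defaults to rownames or `m0001`-style
#'   ids.
#' @param meta optional tibble of per-marker metadata, row-matched to
#'   `states`.
#' @return a `pa_tbl` tibble.
#' @examples
#' m <- pa_matrix(rbind(c("1", "1", "0"), c("1", "0", "?")),
#'                marker_id = c("m1", "m2"))
#' pa_taxa(m)
#' @export
pa_matrix <- function(states, marker_id = NULL, meta = NULL) {
  if (is.data.frame(states)) states <- as.matrix(states)
  if (!is.matrix(states)) stop("`states` must be a matrix or data frame", call. = FALSE)
  mode(states) <- "character"
  if (is.null(colnames(states))) {
    colnames(states) <- paste0("t", seq_len(ncol(states)))
  }
  if (is.null(marker_id)) {
    marker_id <- rownames(states)
    if (is.null(marker_id)) {
      marker_id <- sprintf("m%04d", seq_len(nrow(states)))
    }
  }
  out <- tibble::tibble(marker_id = as.character(marker_id))
  if (!is.null(meta)) {
    meta <- tibble::as_tibble(meta)
    meta <- meta[setdiff(names(meta), "marker_id")]
    out <- dplyr::bind_cols(out, meta)
  }
  out <- dplyr::bind_cols(out, tibble::as_tibble(states))
  new_pa_tbl(out, taxa = colnames(states))
}

pa_meta_cols <- c("marker_id", "query_species", "chromosome", "start", "end",
                  "genic", "tsd_motif")

new_pa_tbl <- function(x, taxa) {
  x <- tibble::as_tibble(x)
  attr(x, "taxa") <- taxa
  class(x) <- unique(c("pa_tbl", class(x)))
  validate_pa(x)
}

#' @rdname pa_matrix
#' @param x a `pa_tbl`.
#' @export
pa_taxa <- function(x) {
  taxa <- attr(x, "taxa", exact = TRUE)
  if (is.null(taxa)) taxa <- setdiff(names(x), pa_meta_cols)
  taxa
}

#' Extract the state matrix of a `pa_tbl`
#'
#' @param x a `pa_tbl`.
#' @return character matrix (markers x taxa), rownames are marker ids.
#' @export
pa_states <- function(x) {
  taxa <- pa_taxa(x)
  s <- as.matrix(as.data.frame(x[taxa], check.names = FALSE))
  mode(s) <- "character"
  rownames(s) <- x$marker_id
  s
}

validate_pa <- function(x) {
  taxa <- pa_taxa(x)
  if (length(taxa) == 0) stop("presence/absence matrix has no taxon columns", call. = FALSE)
  if (anyDuplicated(x$marker_id)) {
    dup <- unique(x$marker_id[duplicated(x$marker_id)])
    stop("duplicate marker ids: ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(taxa)) stop("duplicate taxon names", call. = FALSE)
  s <- unlist(x[taxa], use.names = FALSE)
  bad <- !(s %in% c("0", "1", "?"))
  if (any(bad)) {
    stop("invalid character state(s): ",
         paste(unique(s[bad])[1:min(5, length(unique(s[bad])))], collapse = ", "),
         " (allowed: 0, 1, ?)", call. = FALSE)
  }
  if (!is.null(x[["tsd_motif"]])) {
    motifs <- x$tsd_motif[!is.na(x$tsd_motif)]
    if (any(nchar(motifs) != 5L)) {
      stop("tsd_motif entries must be 5 letters", call. = FALSE)
    }
  }
  if (!is.null(x[["start"]]) && !is.null(x[["end"]])) {
    ok <- is.na(x$start) | is.na(x$end) | x$start <= x$end
    if (!all(ok)) stop("marker coordinates with start > end", call. = FALSE)
  }
  invisible(x)
}

# normalize raw symbols: N and - are tolerated on input and mapped to '?'
normalize_states <- function(s, context = "input") {
  n_mapped <- sum(s %in% c("N", "n", "-"))
  s[s %in% c("N", "n", "-")] <- "?"
  if (n_mapped > 0) {
    warning(sprintf("%s: %d state(s) 'N'/'-' mapped to '?'", context, n_mapped),
            call. = FALSE)
  }
  s
}

#' @export
print.pa_tbl <- function(x, ...) {
  cat(sprintf("# Presence/absence matrix: %d markers x %d taxa\n",
              nrow(x), length(pa_taxa(x))))
  NextMethod()
}
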