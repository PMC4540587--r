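#' Read a presence/absence matrix
#'
#' Three dialects are supported:
#' * `"csv"` — wide CSV, rows are markers; metadata columns (`marker_id`,
#'   `chromosome`, `start`, `end`, `genic`, `tsd_motif`, `query_species`) are
#'   recognised by name, every other column is a taxon. Coordinates are
#'   1-based inclusive.
#' * `"phylip"` — discrete PHYLIP: `ntax nchar` header, then one row per
#'   taxon (name, whitespace, states over `0/1/?`).
#' * `"nexus"` — a NEXUS `DATA` block with `datatype=standard`.
#'
#' `'N'` and `'-'` in inputs are tolerated and mapped to `'?'` with a warning;
#' any other symbol is a format error naming the offending record.
#'
#' @param path file path.
#' @param format one of `"csv"`, `"phylip"`, `"nexus"`.
#' @return a [pa_matrix()] tibble; taxon order is preserved from the file.
#' @export
read_pa_matrix <- function(path, format = c("csv", "phylip", "nexus")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  switch(format,
         csv = read_pa_csv(path),
         phylip = read_pa_phylip(path),
         nexus = read_pa_nexus(path))
}

read_pa_csv <- function(path) {
  raw <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                         progress = FALSE)
  if (!"marker_id" %in% names(raw)) {
    stop("csv matrix must contain a marker_id column", call. = FALSE)
  }
  taxa <- setdiff(names(raw), pa_meta_cols)
  names(raw)[match(taxa, names(raw))] <- trimws(taxa)
  taxa <- trimws(taxa)
  if (length(taxa) == 0) stop("csv matrix has no taxon columns", call. = FALSE)
  states <- as.matrix(as.data.frame(raw[taxa], check.names = FALSE))
  states[] <- normalize_states(trimws(states), context = basename(path))
  meta <- raw[intersect(pa_meta_cols, names(raw))]
  for (col in intersect(c("start", "end"), names(meta))) {
    meta[[col]] <- as.integer(meta[[col]])
  }
  if ("genic" %in% names(meta)) meta$genic <- as.logical(meta$genic)
  pa_matrix(states, marker_id = raw$marker_id, meta = meta)
}

read_pa_phylip <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[trimws(lines) != ""]
  if (length(lines) == 0) stop("empty phylip file: ", path, call. = FALSE)
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1]), "\\s+")[[1]]))
  if (length(hdr) != 2 || anyNA(hdr)) {
    stop("malformed phylip header (line 1): expected 'ntax nchar'", call. = FALSE)
  }
  ntax <- hdr[1]; nchar_ <- hdr[2]
  if (length(lines) - 1 != ntax) {
    stop(sprintf("phylip file declares %d taxa but has %d data rows",
                 ntax, length(lines) - 1), call. = FALSE)
  }
  taxa <- character(ntax)
  states <- matrix("", nrow = nchar_, ncol = ntax)
  n_mapped <- 0L
  for (i in seq_len(ntax)) {
    ln <- trimws(lines[i + 1])
    parts <- strsplit(ln, "\\s+")[[1]]
    if (length(parts) < 2) {
      stop(sprintf("malformed phylip row (line %d): expected 'name states'", i + 1),
           call. = FALSE)
    }
    taxa[i] <- parts[1]
    chars <- strsplit(paste(parts[-1], collapse = ""), "")[[1]]
    if (length(chars) != nchar_) {
      stop(sprintf("phylip row for '%s' (line %d) has %d states, expected %d",
                   taxa[i], i + 1, length(chars), nchar_), call. = FALSE)
    }
    n_mapped <- n_mapped + sum(chars %in% c("N", "n", "-"))
    chars[chars %in% c("N", "n", "-")] <- "?"
    bad <- setdiff(unique(chars), c("0", "1", "?"))
    if (length(bad) > 0) {
      stop(sprintf("non-binary symbol '%s' in phylip row for '%s' (line %d)",
                   bad[1], taxa[i], i + 1), call. = FALSE)
    }
    states[, i] <- chars
  }
  if (anyDuplicated(taxa)) {
    stop("duplicate taxon in phylip file: ", taxa[duplicated(taxa)][1], call. = FALSE)
  }
  if (n_mapped > 0) {
    warning(sprintf("%s: %d state(s) 'N'/'-' mapped to '?'", basename(path), n_mapped),
            call. = FALSE)
  }
  colnames(states) <- taxa
  pa_matrix(states)
}

read_pa_nexus <- function(path) {
  dat <- ape::read.nexus.data(path)
  states <- do.call(cbind, lapply(dat, as.character))
  colnames(states) <- names(dat)
  states[] <- normalize_states(toupper(states), context = basename(path))
  bad <- setdiff(unique(as.vector(states)), c("0", "1", "?"))
  if (length(bad) > 0) {
    stop(sprintf("non-binary symbol '%s' in NEXUS matrix %s", bad[1], basename(path)),
         call. = FALSE)
  }
  pa_matrix(states)
}

#' Write a presence/absence matrix
#'
#' Round-trips with [read_pa_matrix()] in all three dialects. The PHYLIP
#' writer pads/truncates taxon names to 10 characters (classic strict PHYLIP);
#' CSV and NEXUS keep names untouched. NEXUS output declares
#' `datatype=standard` with `missing=?`.
#'
#' @param x a `pa_tbl`.
#' @inheritParams read_pa_matrix
#' @return `path`, invisibly.
#' @export
write_pa_matrix <- function(x, path, format = c("csv", "phylip", "nexus")) {
  format <- match.arg(format)
  validate_pa(x)
  switch(format,
         csv = {
           out <- x
           class(out) <- setdiff(class(out), "pa_tbl")
           readr::write_csv(out, path, progress = FALSE)
         },
         phylip = {
           s <- pa_states(x)
           taxa <- colnames(s)
           nm <- sprintf("%-10s", substr(taxa, 1, 10))
           rows <- vapply(seq_along(taxa),
                          function(i) paste0(nm[i], " ", paste(s[, i], collapse = "")),
                          character(1))
           writeLines(c(sprintf("%d %d", length(taxa), nrow(x)), rows), path)
         },
         nexus = {
           s <- pa_states(x)
           dat <- lapply(seq_len(ncol(s)), function(i) s[, i])
           names(dat) <- colnames(s)
           ape::write.nexus.data(dat, path, format = "standard", missing = "?",
                                 interleaved = FALSE)
         })
  invisible(path)
}

#' Read and write rooted trees in Newick format
#'
#' Thin wrappers around [ape::read.tree()] / [ape::write.tree()] that enforce
#' the package's contract: the tree must be rooted (an unrooted Newick, i.e. a
#' basal trifurcation, is rejected because Dollo-type polarity depends on the
#' root), leaf labels must be unique and non-empty, and branch lengths, when
#' present, must be non-negative.
#'
#' @param path file path.
#' @return a rooted `ape::phylo` object.
#' @export
read_species_tree <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("malformed Newick in ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  if (is.null(tr)) stop("malformed Newick in ", path, call. = FALSE)
  validate_species_tree(tr)
}

#' @rdname read_species_tree
#' @param tree a rooted `phylo`.
#' @export
write_species_tree <- function(tree, path) {
  validate_species_tree(tree)
  ape::write.tree(tree, file = path)
  invisible(path)
}

validate_species_tree <- function(tree) {
  if (!inherits(tree, "phylo")) stop("not a phylo object", call. = FALSE)
  tree$tip.label <- trimws(tree$tip.label)
  if (any(tree$tip.label == "")) stop("empty leaf label", call. = FALSE)
  if (anyDuplicated(tree$tip.label)) {
    stop("duplicate leaf label: ", tree$tip.label[duplicated(tree$tip.label)][1],
         call. = FALSE)
  }
  if (!ape::is.rooted(tree)) {
    stop("tree is unrooted (basal multifurcation); a rooted tree is required",
         call. = FALSE)
  }
  if (!is.null(tree$edge.length) && any(tree$edge.length < 0)) {
    stop("negative branch length", call. = FALSE)
  }
  tree
}

#' Remove uninformative markers
#'
#' Drops markers that carry no phylogenetic information about the radiation:
#' (a) fewer than `min_taxa` non-missing states, (b) plesiomorphic (all
#' scored states are `1`), (c) autapomorphic (exactly one `1`), (d) no
#' presence state at all. A marker is removed for the first matching reason
#' in that order. The filter matches the marker post-screening used for the
#' deposited matrices (default `min_taxa = 10`).
#'
#' @param x a `pa_tbl`.
#' @param min_taxa minimum number of scored (non-`?`) taxa, `>= 2`.
#' @return the filtered `pa_tbl`; the removal report is attached as attribute
#'   `"filter_report"` and available via [filter_report()].
#' @export
filter_informative <- function(x, min_taxa = 10) {
  stopifnot(min_taxa >= 2)
  s <- pa_states(x)
  n_scored <- rowSums(s != "?")
  n_pres <- rowSums(s == "1")
  reason <- rep(NA_character_, nrow(s))
  reason[is.na(reason) & n_scored < min_taxa] <- "too_few_taxa"
  reason[is.na(reason) & n_pres == n_scored & n_scored > 0] <- "plesiomorphic"
  reason[is.na(reason) & n_pres == 1] <- "autapomorphic"
  reason[is.na(reason) & n_pres == 0] <- "no_presence"
  keep <- is.na(reason)
  report <- tibble::tibble(marker_id = x$marker_id[!keep],
                           reason = reason[!keep])
  out <- x[keep, , drop = FALSE]
  out <- new_pa_tbl(out, taxa = pa_taxa(x))
  attr(out, "filter_report") <- report
  out
}

#' @rdname filter_informative
#' @export
filter_report <- function(x) {
  rep <- attr(x, "filter_report", exact = TRUE)
  if (is.null(rep)) tibble::tibble(marker_id = character(), reason = character()) else rep
}
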