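#' Promoter sequence with TSS-relative numbering
#'
#' Container for a promoter duplex: template and non-template strands (both
#' written 5'->3'), the position of the transcription start site (+1), an
#' optional mismatch window, and named interval annotations (e.g. the TATA box
#' or the TFIIE E-wing contact region). Positions are numbered relative to the
#' TSS with no position 0 (..., -2, -1, +1, +2, ...); intervals are half-open
#' `[start, end)` in that numbering.
#'
#' The template strand is the strand read by the polymerase. Outside the
#' mismatch window every position must be Watson-Crick complementary between
#' the strands; the constructor enforces this. Note that with both strands
#' written 5'->3', position `i` of the template pairs with position
#' `L + 1 - i` of the non-template strand.
#'
#' @param template Template strand, 5'->3', a single string over A/C/G/T.
#' @param non_template Non-template strand, 5'->3'. If `NULL`, the reverse
#'   complement of `template` is used.
#' @param tss_index 1-based index of the +1 site within the template strand.
#' @param mismatch_region Optional numeric `c(start, end)` in TSS-relative
#'   coordinates, half-open, marking a non-complementary window.
#' @param annotations Named list of `c(start, end)` TSS-relative intervals.
#' @return An object of class `promoter_sequence`.
#' @examples
#' ps <- promoter_sequence("ACGTACGTAC", tss_index = 7)
#' tss_positions(ps)
#' @export
promoter_sequence <- function(template, non_template = NULL, tss_index,
                              mismatch_region = NULL, annotations = list()) {
  tmpl <- toupper(template)
  stopifnot(is.character(tmpl), length(tmpl) == 1L, nchar(tmpl) > 0L)
  if (grepl("[^ACGT]", tmpl)) stop("template contains non-ACGT characters")
  if (is.null(non_template)) non_template <- revcomp(tmpl)
  ntmpl <- toupper(non_template)
  if (nchar(ntmpl) != nchar(tmpl))
    stop("template and non-template strands must have equal length")
  if (grepl("[^ACGT]", ntmpl)) stop("non-template contains non-ACGT characters")
  L <- nchar(tmpl)
  if (tss_index < 1L || tss_index > L) stop("tss_index outside the strand")

  ps <- structure(list(
    template = tmpl, non_template = ntmpl, tss_index = as.integer(tss_index),
    mismatch_region = mismatch_region, annotations = annotations
  ), class = "promoter_sequence")

  tb <- strsplit(tmpl, "")[[1]]
  nb <- strsplit(ntmpl, "")[[1]]
  comp <- tb == vapply(rev(nb), complement_base, "")
  mm_idx <- if (is.null(mismatch_region)) integer(0) else
    which(tss_positions(ps) %in% tss_interval_positions(ps, mismatch_region))
  bad <- which(!comp & !(seq_len(L) %in% mm_idx))
  if (length(bad))
    stop("non-complementary positions outside the mismatch region: ",
         paste(tss_positions(ps)[bad], collapse = ", "))
  ps
}

#' @export
print.promoter_sequence <- function(x, ...) {
  cat("promoter duplex, ", nchar(x$template), " bp; +1 at strand index ",
      x$tss_index, "\n", sep = "")
  cat("  template     5'-", x$template, "-3'\n", sep = "")
  cat("  non-template 5'-", x$non_template, "-3'\n", sep = "")
  if (!is.null(x$mismatch_region))
    cat("  mismatch window [", x$mismatch_region[1], ", ",
        x$mismatch_region[2], ")\n", sep = "")
  invisible(x)
}

#' TSS-relative positions of template-strand indices
#'
#' Maps 1-based indices along the template strand to TSS-relative numbering,
#' which skips 0: index `tss_index` is +1, index `tss_index - 1` is -1.
#'
#' @param ps A `promoter_sequence`.
#' @return Integer vector, one TSS-relative position per strand index.
#' @export
tss_positions <- function(ps) {
  idx <- seq_len(nchar(ps$template))
  off <- idx - ps$tss_index
  ifelse(off >= 0L, off + 1L, off)
}

#' Strand indices covered by a half-open TSS-relative interval
#'
#' @param ps A `promoter_sequence`.
#' @param interval `c(start, end)`, half-open, TSS-relative (no 0).
#' @return TSS-relative positions inside the interval (subset of
#'   `tss_positions(ps)`).
#' @export
tss_interval_positions <- function(ps, interval) {
  pos <- tss_positions(ps)
  pos[pos >= interval[1] & pos < interval[2]]
}

#' Strand indices (1-based) for a TSS-relative interval
#' @inheritParams tss_interval_positions
#' @return 1-based indices into the strand character vectors.
#' @export
tss_interval_index <- function(ps, interval) {
  pos <- tss_positions(ps)
  which(pos >= interval[1] & pos < interval[2])
}

#' @rdname promoter_sequence
#' @param x A base string.
#' @export
revcomp <- function(x) {
  paste(rev(vapply(strsplit(toupper(x), "")[[1]], complement_base, "")),
        collapse = "")
}

complement_base <- function(b) {
  switch(b, A = "T", T = "A", G = "C", C = "G",
         stop("invalid base: ", b))
}

#' Read a two-line plain-text sequence file (template, non-template)
#'
#' @param path File with the template strand on line 1 and the non-template
#'   strand on line 2, both 5'->3'.
#' @param tss_index 1-based +1 position within the template strand.
#' @param ... Passed to [promoter_sequence()].
#' @return A `promoter_sequence`.
#' @export
read_promoter <- function(path, tss_index, ...) {
  ln <- readLines(path, warn = FALSE)
  ln <- ln[nzchar(trimws(ln))]
  if (length(ln) < 2L) stop("expected two sequence lines in ", path)
  promoter_sequence(trimws(ln[1]), trimws(ln[2]), tss_index = tss_index, ...)
}

#' Write a promoter duplex as a two-line text file
#' @param ps A `promoter_sequence`.
#' @param path Output path.
#' @export
write_promoter <- function(ps, path) {
  writeLines(c(ps$template, ps$non_template), path)
  invisible(path)
}
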