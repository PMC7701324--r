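#' Pattern families
#'
#' The descriptor space is generated by six pattern modes over the alphabet
#' {A,C,G,U}:
#'
#' * `PsM`, `PsD`, `PsT` — ungapped position-specific k-mers (k = 1, 2, 3);
#' * `PsMGD` — a monomer, G gap positions, then a dimer (G in 1..3);
#' * `PsDGM` — a dimer, G gap positions, then a monomer (G in 1..3);
#' * `PsMGMGM` — three monomers separated by single gaps.
#'
#' A gap position (`-` in the rendered template) matches any nucleotide;
#' fixed positions must match exactly.
#'
#' @name pattern-modes
NULL

PATTERN_MODES <- c("PsM", "PsD", "PsT", "PsMGD", "PsDGM", "PsMGMGM")

#' Construct a gapped pattern
#'
#' @param blocks character vector of fixed-nucleotide blocks, e.g.
#'   `c("A", "CG")`.
#' @param gaps integer vector of gap lengths between consecutive blocks
#'   (length `length(blocks) - 1`; empty for ungapped patterns).
#' @return object of class `psgkm_pattern` with fields `blocks`, `gaps`,
#'   `template` (rendered string, `-` per gap position), `M` (total
#'   length) and `mode`.
#' @examples
#' gapped_pattern(c("A", "CG"), 2L)$template  # "A--CG"
#' @export
gapped_pattern <- function(blocks, gaps = integer(0)) {
  blocks <- toupper(as.character(blocks))
  gaps <- as.integer(gaps)
  if (length(gaps) != length(blocks) - 1L)
    stop("need exactly one gap length between each pair of blocks")
  if (any(grepl("[^ACGU]", blocks))) stop("blocks must be over {A,C,G,U}")
  if (length(gaps) && any(gaps < 1L)) stop("gap lengths must be >= 1")
  template <- blocks[1L]
  if (length(gaps))
    for (i in seq_along(gaps))
      template <- paste0(template, strrep("-", gaps[i]), blocks[i + 1L])
  sizes <- nchar(blocks)
  mode <- pattern_mode(sizes, gaps)
  structure(list(blocks = blocks, gaps = gaps, template = template,
                 M = nchar(template), mode = mode),
            class = "psgkm_pattern")
}

pattern_mode <- function(sizes, gaps) {
  if (length(gaps) == 0L) {
    if (length(sizes) == 1L && sizes <= 3L)
      return(c("PsM", "PsD", "PsT")[sizes])
  } else if (length(gaps) == 1L && identical(unname(sizes), c(1L, 2L))) {
    return("PsMGD")
  } else if (length(gaps) == 1L && identical(unname(sizes), c(2L, 1L))) {
    return("PsDGM")
  } else if (length(gaps) == 2L && identical(unname(sizes), c(1L, 1L, 1L))) {
    return("PsMGMGM")
  }
  "other"
}

#' @export
print.psgkm_pattern <- function(x, ...) {
  cat(sprintf("<psgkm_pattern> %s (mode %s, M = %d)\n", x$template, x$mode, x$M))
  invisible(x)
}

#' Render a pattern template
#'
#' @param pattern a [gapped_pattern()].
#' @return the template string: fixed blocks verbatim, one `-` per gap
#'   position.
#' @export
render_template <- function(pattern) {
  stopifnot(inherits(pattern, "psgkm_pattern"))
  pattern$template
}

#' Parse a template string into a pattern
#'
#' Inverse of [render_template()]. En/em dashes are normalised to runs of
#' `-` before parsing (some published pattern tables typeset gap runs that
#' way).
#'
#' @param template string over A/C/G/U and `-`.
#' @return a [gapped_pattern()].
#' @export
parse_template <- function(template) {
  template <- gsub("—", "--", gsub("–", "--", template))
  template <- toupper(template)
  if (grepl("[^ACGU-]", template)) stop("invalid template: ", template)
  if (grepl("^-|-$", template)) stop("template cannot start or end with a gap")
  chars <- strsplit(template, "")[[1L]]
  runs <- rle(chars == "-")
  blocks <- character(0); gaps <- integer(0)
  pos <- 1L
  for (i in seq_along(runs$lengths)) {
    len <- runs$lengths[i]
    if (runs$values[i]) gaps <- c(gaps, len)
    else blocks <- c(blocks, substr(template, pos, pos + len - 1L))
    pos <- pos + len
  }
  gapped_pattern(blocks, gaps)
}

# all length-k strings over {A,C,G,U} in lexicographic order (A<C<G<U),
# first position most significant
kmer_strings <- function(k) {
  g <- do.call(expand.grid, c(rep(list(RNA_ALPHABET), k),
                              stringsAsFactors = FALSE))
  do.call(paste0, g[rev(seq_len(k))])
}

#' Enumerate all patterns of a mode
#'
#' Counts are 4 (`PsM`), 16 (`PsD`), 64 (`PsT`), 192 (`PsMGD`: 64
#' fixed-nucleotide combinations for each gap length 1, 2, 3), 192
#' (`PsDGM`), and 64 (`PsMGMGM`, all of length 5). Order is canonical:
#' gap configuration ascending, then fixed-nucleotide string lexicographic
#' under A < C < G < U.
#'
#' @param mode one of `r paste0('\x60', PATTERN_MODES, '\x60', collapse = ", ")`.
#' @param gap_values gap lengths for the gapped two-block modes; the
#'   standard configuration `1:3` unless experimenting.
#' @return list of [gapped_pattern()] objects.
#' @export
enumerate_mode_patterns <- function(mode, gap_values = 1:3) {
  if (!mode %in% PATTERN_MODES) stop("unknown pattern mode: ", mode)
  switch(mode,
    PsM = lapply(kmer_strings(1L), gapped_pattern),
    PsD = lapply(kmer_strings(2L), gapped_pattern),
    PsT = lapply(kmer_strings(3L), gapped_pattern),
    PsMGD = do.call(c, lapply(gap_values, function(g)
      lapply(kmer_strings(3L), function(s)
        gapped_pattern(c(substr(s, 1L, 1L), substr(s, 2L, 3L)), g)))),
    PsDGM = do.call(c, lapply(gap_values, function(g)
      lapply(kmer_strings(3L), function(s)
        gapped_pattern(c(substr(s, 1L, 2L), substr(s, 3L, 3L)), g)))),
    PsMGMGM = lapply(kmer_strings(3L), function(s)
      gapped_pattern(c(substr(s, 1L, 1L), substr(s, 2L, 2L), substr(s, 3L, 3L)),
                     c(1L, 1L)))
  )
}

#' Match a pattern against one sequence window
#'
#' The binary position-specific indicator: 1 iff every fixed nucleotide of
#' the pattern equals the corresponding residue of the window of length `M`
#' starting at `start` (1-based); gap positions match any nucleotide.
#'
#' @param pattern a [gapped_pattern()] or a template string.
#' @param residues canonical residue string.
#' @param start 1-based window start; must satisfy
#'   `1 <= start <= nchar(residues) - M + 1`.
#' @return integer 0 or 1.
#' @export
pattern_match <- function(pattern, residues, start) {
  if (is.character(pattern)) pattern <- parse_template(pattern)
  M <- pattern$M
  if (start < 1L || start > nchar(residues) - M + 1L)
    stop(sprintf("start %d out of range for M = %d, sequence length %d",
                 start, M, nchar(residues)))
  window <- substr(residues, start, start + M - 1L)
  tchars <- strsplit(pattern$template, "")[[1L]]
  wchars <- strsplit(window, "")[[1L]]
  fixed <- tchars != "-"
  as.integer(all(tchars[fixed] == wchars[fixed]))
}
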