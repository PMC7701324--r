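#' Feature-family table
#'
#' The eleven feature types: FT1-FT3 are the ungapped position-specific
#' k-mers (k = 1, 2, 3), FT4-FT6 the monomer-gap-dimer patterns with gap
#' 1, 2, 3, FT7-FT9 the dimer-gap-monomer patterns with gap 1, 2, 3, FT10
#' the monomer-gap-monomer-gap-monomer patterns, and FT11 the GC-content.
#' `offsets` are the 0-based positions of the fixed nucleotides within a
#' pattern window; each family contributes `L - M + 1` windows per pattern.
#'
#' @keywords internal
feature_families <- function() {
  list(
    list(ft = "FT1",  mode = "PsM",     M = 1L, offsets = 0L,            gap = NA_integer_),
    list(ft = "FT2",  mode = "PsD",     M = 2L, offsets = c(0L, 1L),     gap = NA_integer_),
    list(ft = "FT3",  mode = "PsT",     M = 3L, offsets = c(0L, 1L, 2L), gap = NA_integer_),
    list(ft = "FT4",  mode = "PsMGD",   M = 4L, offsets = c(0L, 2L, 3L), gap = 1L),
    list(ft = "FT5",  mode = "PsMGD",   M = 5L, offsets = c(0L, 3L, 4L), gap = 2L),
    list(ft = "FT6",  mode = "PsMGD",   M = 6L, offsets = c(0L, 4L, 5L), gap = 3L),
    list(ft = "FT7",  mode = "PsDGM",   M = 4L, offsets = c(0L, 1L, 3L), gap = 1L),
    list(ft = "FT8",  mode = "PsDGM",   M = 5L, offsets = c(0L, 1L, 4L), gap = 2L),
    list(ft = "FT9",  mode = "PsDGM",   M = 6L, offsets = c(0L, 1L, 5L), gap = 3L),
    list(ft = "FT10", mode = "PsMGMGM", M = 5L, offsets = c(0L, 2L, 4L), gap = 1L)
  )
}

family_templates <- function(fam) {
  ks <- kmer_strings(length(fam$offsets))
  vapply(ks, function(s) {
    chars <- rep("-", fam$M)
    chars[fam$offsets + 1L] <- strsplit(s, "")[[1L]]
    paste(chars, collapse = "")
  }, character(1L), USE.NAMES = FALSE)
}

#' Enumerate the canonical descriptor space
#'
#' Lists every binary position-specific descriptor plus the terminal
#' GC-content descriptor, in canonical column order: feature types FT1-FT11
#' in order; within a type, patterns in lexicographic order (A < C < G < U);
#' within a pattern, window starts ascending. Each pattern of length M
#' contributes `L - M + 1` windows, which for the default 41-nt windows
#' gives per-type counts 164, 640, 2496, 2432, 2368, 2304, 2432, 2368,
#' 2304, 2368, and 1 — 19,877 descriptors in total.
#'
#' Descriptor names follow `"<FT>:<template>@<start>-<end>"` with 1-based
#' inclusive positions (e.g. `"FT5:A--CG@7-11"`), and `"FT11:GC"`.
#'
#' @param L window length, at least 6 (the longest pattern must fit).
#' @return a data.frame of class `psgkm_descriptors` with columns `index`,
#'   `type`, `mode`, `template`, `start`, `end`, `name`.
#' @export
enumerate_descriptors <- function(L = 41L) {
  L <- as.integer(L)
  if (L < 6L) stop("L must be >= 6 (longest pattern has length 6)")
  parts <- lapply(feature_families(), function(fam) {
    W <- L - fam$M + 1L
    tpl <- family_templates(fam)
    data.frame(
      type = fam$ft, mode = fam$mode,
      template = rep(tpl, each = W),
      start = rep(seq_len(W), times = length(tpl)),
      stringsAsFactors = FALSE)
  })
  d <- do.call(rbind, parts)
  d$end <- d$start + nchar(d$template) - 1L
  d <- rbind(d, data.frame(type = "FT11", mode = "GC", template = "GC",
                           start = NA_integer_, end = NA_integer_))
  d$name <- ifelse(d$type == "FT11", "FT11:GC",
                   paste0(d$type, ":", d$template, "@", d$start, "-", d$end))
  d$index <- seq_len(nrow(d))
  d <- d[, c("index", "type", "mode", "template", "start", "end", "name")]
  class(d) <- c("psgkm_descriptors", "data.frame")
  attr(d, "L") <- L
  d
}

#' Binary indicator string of a pattern along a sequence
#'
#' Slides the pattern over every admissible window of the sequence and
#' emits one digit per start position: 1 on a match, 0 otherwise. For the
#' dimer `GG` on `ACGGCGGUG` this yields `"00100100"`; for the trimer
#' `ACG` on `GUAGCACGG`, `"0000010"`.
#'
#' @param pattern a [gapped_pattern()] or template string.
#' @param residues canonical residue string, at least as long as the
#'   pattern.
#' @return string of `nchar(residues) - M + 1` binary digits.
#' @export
indicator_string <- function(pattern, residues) {
  if (is.character(pattern)) pattern <- parse_template(pattern)
  W <- nchar(residues) - pattern$M + 1L
  if (W < 1L) stop("sequence shorter than pattern")
  paste(vapply(seq_len(W), function(s) pattern_match(pattern, residues, s),
               integer(1L)), collapse = "")
}

#' GC-content of a sequence
#'
#' Percentage of guanine and cytosine residues:
#' `100 * (G + C) / (A + C + G + U)`.
#'
#' @param residues canonical residue string (non-empty).
#' @return numeric percentage in \[0, 100\].
#' @export
gc_content <- function(residues) {
  if (!length(residues) || any(!nzchar(residues))) stop("empty sequence")
  vapply(residues, function(s) {
    chars <- strsplit(s, "")[[1L]]
    100 * sum(chars %in% c("G", "C")) / length(chars)
  }, numeric(1L), USE.NAMES = FALSE)
}

# integer matrix (n x L) of residue codes 1..4 (A,C,G,U)
residue_codes <- function(residues, L) {
  m <- matrix(0L, nrow = length(residues), ncol = L)
  for (i in seq_along(residues))
    m[i, ] <- match(strsplit(residues[i], "")[[1L]], RNA_ALPHABET)
  m
}

#' Encode a dataset into the full descriptor matrix
#'
#' Produces the samples x descriptors feature matrix in canonical column
#' order: one column per binary position-specific indicator plus the final
#' GC-content column (a percentage in \[0, 100\]). The binary block is
#' one-hot per (family, window): for each sequence, each window of each
#' family matches exactly one fixed-nucleotide combination, so every 41-nt
#' row carries exactly 379 ones. The matrix is stored sparse.
#'
#' @param dataset a [psgkm_dataset()] of uniform length L >= 6.
#' @param normalize_gc divide the GC column by 100 (off by default; the
#'   natural scale is the percentage, the flag exists for optimiser
#'   conditioning experiments).
#' @return object of class `psgkm_features`: list with `x` (a
#'   `Matrix::dgCMatrix`, rows = samples, columns = descriptors),
#'   `descriptors`, `sample_ids`, `labels`, `L`.
#' @export
encode_dataset <- function(dataset, normalize_gc = FALSE) {
  stopifnot(inherits(dataset, "psgkm_dataset"))
  L <- dataset$L
  desc <- enumerate_descriptors(L)
  n <- length(dataset)
  if (n == 0L) {
    x <- Matrix::sparseMatrix(i = integer(0), j = integer(0), x = numeric(0),
                              dims = c(0L, nrow(desc)),
                              dimnames = list(NULL, desc$name))
    return(new_features(x, desc, dataset))
  }
  if (any(nchar(dataset$residues) != L)) stop("mixed sequence lengths")
  codes <- residue_codes(dataset$residues, L)
  fams <- feature_families()
  offset <- 0L
  rows <- vector("list", length(fams))
  cols <- vector("list", length(fams))
  for (f in seq_along(fams)) {
    fam <- fams[[f]]
    W <- L - fam$M + 1L
    k <- length(fam$offsets)
    # pattern rank of each (sequence, start): lexicographic code of the
    # residues at the fixed offsets, first offset most significant
    rank <- matrix(0L, nrow = n, ncol = W)
    for (o in fam$offsets)
      rank <- rank * 4L + (codes[, (1L + o):(W + o), drop = FALSE] - 1L)
    col <- offset + rank * W + rep(seq_len(W), each = n)  # n x W
    rows[[f]] <- rep(seq_len(n), times = W)
    cols[[f]] <- as.vector(col)
    offset <- offset + W * 4L^k
  }
  gc <- gc_content(dataset$residues)
  if (normalize_gc) gc <- gc / 100
  x <- Matrix::sparseMatrix(
    i = c(unlist(rows), seq_len(n)),
    j = c(unlist(cols), rep(offset + 1L, n)),
    x = c(rep(1, length(unlist(rows))), gc),
    dims = c(n, nrow(desc)),
    dimnames = list(dataset$ids, desc$name))
  new_features(x, desc, dataset)
}

new_features <- function(x, descriptors, dataset) {
  structure(list(x = x, descriptors = descriptors,
                 sample_ids = dataset$ids, labels = dataset$labels,
                 L = dataset$L),
            class = "psgkm_features")
}

#' @export
print.psgkm_features <- function(x, ...) {
  cat(sprintf("<psgkm_features> %d sample(s) x %d descriptors (L = %d)\n",
              nrow(x$x), ncol(x$x), x$L))
  invisible(x)
}

#' @export
dim.psgkm_features <- function(x) dim(x$x)

#' Encode only a subset of descriptors
#'
#' Fast path for prediction: computes just the named descriptors (e.g. the
#' 401 selected ones) by direct window matching, bit-identical to full
#' encoding followed by column selection.
#'
#' @param dataset a [psgkm_dataset()].
#' @param descriptors subset of an [enumerate_descriptors()] data.frame, or
#'   a character vector of descriptor names.
#' @param normalize_gc divide the GC column by 100, as in
#'   [encode_dataset()].
#' @return dense numeric matrix, rows = samples, columns = descriptors.
#' @export
encode_descriptors <- function(dataset, descriptors, normalize_gc = FALSE) {
  stopifnot(inherits(dataset, "psgkm_dataset"))
  if (is.character(descriptors)) {
    all_desc <- enumerate_descriptors(dataset$L)
    idx <- match(descriptors, all_desc$name)
    if (anyNA(idx)) stop("unknown descriptor name: ", descriptors[is.na(idx)][1L])
    descriptors <- all_desc[idx, ]
  }
  n <- length(dataset)
  out <- matrix(0, nrow = n, ncol = nrow(descriptors),
                dimnames = list(dataset$ids, descriptors$name))
  if (n == 0L) return(out)
  codes <- residue_codes(dataset$residues, dataset$L)
  for (j in seq_len(nrow(descriptors))) {
    d <- descriptors[j, ]
    if (d$type == "FT11") {
      out[, j] <- gc_content(dataset$residues) / (if (normalize_gc) 100 else 1)
      next
    }
    tchars <- strsplit(d$template, "")[[1L]]
    fixed <- which(tchars != "-")
    want <- match(tchars[fixed], RNA_ALPHABET)
    hit <- rep(TRUE, n)
    for (q in seq_along(fixed))
      hit <- hit & codes[, d$start + fixed[q] - 1L] == want[q]
    out[, j] <- as.numeric(hit)
  }
  out
}

#' Export / import a feature matrix as text
#'
#' `write_matrix` writes either a dense tab-delimited table (samples x
#' named columns, with id column) or a sparse triplet format
#' (`id<TAB>descriptor<TAB>value`, one line per non-zero). `read_matrix`
#' reads either format back; round-trips preserve values exactly.
#'
#' @param features a `psgkm_features` object.
#' @param path output path.
#' @param format `"dense"` or `"triplet"`.
#' @export
write_matrix <- function(features, path, format = c("dense", "triplet")) {
  format <- match.arg(format)
  if (format == "dense") {
    tab <- as.data.frame(as.matrix(features$x), check.names = FALSE)
    tab <- cbind(id = features$sample_ids, tab)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    tr <- Matrix::summary(features$x)
    tr <- tr[order(tr$i, tr$j), ]
    tab <- data.frame(id = features$sample_ids[tr$i],
                      descriptor = colnames(features$x)[tr$j],
                      value = tr$x)
    utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}

#' @rdname write_matrix
#' @param L window length of the descriptor space the file was written
#'   from (needed to rebuild canonical column order for triplet files).
#' @export
read_matrix <- function(path, format = c("dense", "triplet"), L = 41L) {
  format <- match.arg(format)
  desc <- enumerate_descriptors(L)
  if (format == "dense") {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE)
    ids <- as.character(tab$id)
    m <- as.matrix(tab[, -1L, drop = FALSE])
    if (!identical(colnames(m), desc$name))
      stop("column names do not match the canonical descriptor order")
    x <- methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
    rownames(x) <- ids
  } else {
    tab <- utils::read.table(path, sep = "\t", header = TRUE,
                             check.names = FALSE,
                             colClasses = c("character", "character", "numeric"))
    ids <- unique(tab$id)
    j <- match(tab$descriptor, desc$name)
    if (anyNA(j)) stop("unknown descriptor in triplet file: ",
                       tab$descriptor[is.na(j)][1L])
    x <- Matrix::sparseMatrix(i = match(tab$id, ids), j = j, x = tab$value,
                              dims = c(length(ids), nrow(desc)),
                              dimnames = list(ids, desc$name))
  }
  structure(list(x = x, descriptors = desc, sample_ids = rownames(x),
                 labels = NULL, L = L),
            class = "psgkm_features")
}
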