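#' @keywords internal
"_PACKAGE"

RNA_ALPHABET <- c("A", "C", "G", "U")

#' Canonicalize a residue string
#'
#' Uppercases the string and maps thymine (T) to uracil (U) so that every
#' sequence lives on the single canonical alphabet {A,C,G,U} under the
#' lexical order A < C < G < U. Pattern identity and descriptor naming rely
#' on this alphabet being unambiguous.
#'
#' @param residues character vector of raw residue strings.
#' @param strict logical; if `TRUE` (default) any character outside
#'   {A,C,G,U,T} (either case) is an error. If `FALSE` the offending
#'   elements are returned as `NA` with a warning so callers can drop them.
#' @return character vector of canonical residue strings (possibly with
#'   `NA` in lenient mode).
#' @examples
#' canonicalize("acgt")  # "ACGU"
#' @export
canonicalize <- function(residues, strict = TRUE) {
  if (length(residues) == 0L || any(!nzchar(residues)))
    stop("canonicalize: input residue strings must be non-empty")
  out <- chartr("T", "U", toupper(residues))
  bad <- grepl("[^ACGU]", out)
  if (any(bad)) {
    pos <- regexpr("[^ACGU]", out[bad][1L])
    if (strict) {
      stop(sprintf(
        "invalid residue '%s' at position %d of '%s'",
        substr(out[bad][1L], pos, pos), pos, residues[bad][1L]))
    }
    warning(sprintf("%d sequence(s) contain non-ACGU(T) residues; set to NA",
                    sum(bad)))
    out[bad] <- NA_character_
  }
  out
}

#' Construct a labeled fixed-length sequence dataset
#'
#' A dataset is an ordered collection of fixed-length RNA windows, each with
#' an id and an optional binary label (1 = modified site, 0 = non-site). In
#' strict mode every window must have length `L` and carry the candidate
#' cytosine at the central position `(L+1)/2` (position 21 for the default
#' 41-nt windows).
#'
#' @param ids character vector of unique record ids.
#' @param residues character vector of residue strings (canonicalized here).
#' @param labels optional integer vector of 0/1 labels (NA allowed).
#' @param L window length; defaults to the most common residue length.
#' @param strict logical; enforce uniform length `L` and the canonical
#'   alphabet. Lenient mode drops offending records with a warning.
#' @param central_c one of `"warn"` (default), `"error"`, `"ignore"`:
#'   behaviour when a record's central residue is not C.
#' @return an object of class `psgkm_dataset`: a list with elements
#'   `ids`, `residues`, `labels`, `L`.
#' @export
psgkm_dataset <- function(ids, residues, labels = NULL, L = NULL,
                          strict = TRUE, central_c = c("warn", "error", "ignore")) {
  central_c <- match.arg(central_c)
  stopifnot(length(ids) == length(residues))
  if (anyDuplicated(ids))
    stop("duplicate record ids: ", paste(unique(ids[duplicated(ids)])[1:1], collapse = ", "))
  if (!is.null(labels)) {
    stopifnot(length(labels) == length(ids))
    labels <- as.integer(labels)
    if (any(!is.na(labels) & !labels %in% c(0L, 1L)))
      stop("labels must be 0/1 (or NA)")
  }
  if (length(residues)) {
    residues <- canonicalize(residues, strict = strict)
    keep <- !is.na(residues)
    if (!all(keep)) {
      ids <- ids[keep]; residues <- residues[keep]
      if (!is.null(labels)) labels <- labels[keep]
    }
  }
  if (is.null(L)) {
    L <- if (length(residues)) as.integer(names(sort(table(nchar(residues)),
                                                     decreasing = TRUE))[1L]) else 41L
  }
  L <- as.integer(L)
  if (length(residues)) {
    len_ok <- nchar(residues) == L
    if (!all(len_ok)) {
      if (strict)
        stop(sprintf("record '%s' has length %d, expected L = %d",
                     ids[!len_ok][1L], nchar(residues[!len_ok][1L]), L))
      warning(sprintf("dropping %d record(s) with length != %d", sum(!len_ok), L))
      ids <- ids[len_ok]; residues <- residues[len_ok]
      if (!is.null(labels)) labels <- labels[len_ok]
    }
    if (central_c != "ignore" && L %% 2L == 1L) {
      centre <- (L + 1L) %/% 2L
      cc <- substr(residues, centre, centre) == "C"
      if (!all(cc)) {
        msg <- sprintf("%d record(s) lack a central C at position %d (first: '%s')",
                       sum(!cc), centre, ids[!cc][1L])
        if (central_c == "error") stop(msg) else warning(msg)
      }
    }
  }
  structure(list(ids = unname(as.character(ids)), residues = unname(residues),
                 labels = unname(labels), L = L),
            class = "psgkm_dataset")
}

#' @export
length.psgkm_dataset <- function(x) length(x$ids)

#' @export
`[.psgkm_dataset` <- function(x, i, ...) {
  structure(list(ids = x$ids[i], residues = x$residues[i],
                 labels = if (!is.null(x$labels)) x$labels[i],
                 L = x$L),
            class = "psgkm_dataset")
}

#' @export
print.psgkm_dataset <- function(x, ...) {
  cat(sprintf("<psgkm_dataset> %d sequence(s) of length %d nt\n", length(x), x$L))
  if (!is.null(x$labels)) {
    cat(sprintf("  labels: %d positive (5hmC), %d negative, %d unlabeled\n",
                sum(x$labels == 1L, na.rm = TRUE),
                sum(x$labels == 0L, na.rm = TRUE),
                sum(is.na(x$labels))))
  } else cat("  labels: none\n")
  invisible(x)
}

#' Read labeled sequence windows from FASTA
#'
#' Labels can come from a sidecar two-column TSV (id, 0/1; no header
#' required) or from a header suffix of the form `|label=0` / `|label=1`.
#' When both are present the TSV wins and any conflict is an error.
#'
#' @param path path to a FASTA file.
#' @param labels optional path to the label TSV, or a named 0/1 vector.
#' @param L expected window length (default 41); `NULL` infers it.
#' @param strict logical; strict validation (see [psgkm_dataset()]).
#' @param central_c central-cytosine policy, see [psgkm_dataset()].
#' @return a [psgkm_dataset()] with records in file order.
#' @export
read_fasta <- function(path, labels = NULL, L = 41L, strict = TRUE,
                       central_c = "warn") {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop("malformed FASTA '", path, "': ",
                                           conditionMessage(e)))
  if (length(set) == 0L) {
    warning("empty FASTA file: ", path)
    return(psgkm_dataset(character(), character(), L = L, strict = strict))
  }
  headers <- names(set)
  ids <- sub("\\|label=[01]$", "", headers)
  ids <- sub("\\s.*$", "", ids)
  header_lab <- rep(NA_integer_, length(headers))
  has <- grepl("\\|label=[01]$", headers)
  header_lab[has] <- as.integer(sub("^.*\\|label=([01])$", "\\1", headers[has]))
  lab <- header_lab
  if (!is.null(labels)) {
    map <- if (is.character(labels) && length(labels) == 1L && file.exists(labels))
      read_labels(labels) else labels
    tsv_lab <- unname(map[ids])
    conflict <- !is.na(tsv_lab) & !is.na(header_lab) & tsv_lab != header_lab
    if (any(conflict))
      stop("label conflict between TSV and FASTA header for id '",
           ids[conflict][1L], "'")
    lab <- ifelse(is.na(tsv_lab), header_lab, tsv_lab)
  }
  if (all(is.na(lab))) lab <- NULL
  psgkm_dataset(ids, as.character(set), labels = lab, L = L,
                strict = strict, central_c = central_c)
}

#' Read an id-to-label TSV
#'
#' @param path two-column tab-separated file: id, 0/1 label. A header line
#'   `id<TAB>label` is tolerated.
#' @return named integer vector of labels.
#' @export
read_labels <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", col.names = c("id", "label"))
  if (nrow(tab) && tab$id[1L] == "id") tab <- tab[-1L, , drop = FALSE]
  lab <- as.integer(tab$label)
  if (any(is.na(lab) | !lab %in% c(0L, 1L)))
    stop("labels in '", path, "' must be 0 or 1")
  stats::setNames(lab, tab$id)
}

#' Write a dataset as FASTA (and optionally a label TSV)
#'
#' @param dataset a [psgkm_dataset()].
#' @param path output FASTA path.
#' @param labels_path optional path for the sidecar id/label TSV.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(dataset, path, labels_path = NULL) {
  set <- Biostrings::BStringSet(dataset$residues)
  names(set) <- dataset$ids
  Biostrings::writeXStringSet(set, path, width = max(80L, dataset$L))
  if (!is.null(labels_path)) write_labels(dataset, labels_path)
  invisible(path)
}

#' @rdname write_fasta
#' @export
write_labels <- function(dataset, labels_path) {
  if (is.null(dataset$labels)) stop("dataset has no labels to write")
  utils::write.table(data.frame(id = dataset$ids, label = dataset$labels),
                     labels_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(labels_path)
}

#' Stratified holdout split
#'
#' Randomly separates a fraction of the records as an independent test set
#' while preserving the class proportions (the test set takes
#' `round(fraction * n_class)` records from each class). With the default
#' benchmark shape (1324 balanced records, fraction 0.10) this yields a
#' 1192-record training set and a 132-record independent set.
#'
#' @param dataset labeled [psgkm_dataset()] with both classes present.
#' @param fraction test proportion in (0, 1).
#' @param seed integer seed; the split is reproducible.
#' @return list with elements `train` and `test`, both `psgkm_dataset`.
#' @export
stratified_holdout <- function(dataset, fraction = 0.1, seed = 1L) {
  if (is.null(dataset$labels) || anyNA(dataset$labels))
    stop("stratified_holdout needs complete labels")
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)")
  classes <- sort(unique(dataset$labels))
  if (length(classes) < 2L) stop("both classes must be present")
  test_idx <- with_seed(seed, {
    unlist(lapply(classes, function(cl) {
      idx <- which(dataset$labels == cl)
      sample(idx, round(fraction * length(idx)))
    }))
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_along(dataset$ids), test_idx)
  list(train = dataset[train_idx], test = dataset[test_idx])
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's RNG state afterwards. `expr` is forced lazily after set.seed,
# so it evaluates in the caller's environment.
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}
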