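#' Mode groups of the binary descriptor space
#'
#' The 19,876 binary descriptors partition into four generation modes:
#' A = FT1-FT3 (ungapped position-specific k-mers, 3,300 descriptors at
#' L = 41), B = FT4-FT6 (monomer-gap-dimer, 7,104), C = FT7-FT9
#' (dimer-gap-monomer, 7,104), D = FT10 (monomer-gap-monomer-gap-monomer,
#' 2,368). GC-content (FT11) belongs to no group: it is preselected and
#' bypasses ranking.
#'
#' @param descriptors an [enumerate_descriptors()] data.frame.
#' @return named list of integer index vectors `A`, `B`, `C`, `D`, `GC`.
#' @export
mode_groups <- function(descriptors) {
  list(A  = descriptors$index[descriptors$type %in% c("FT1", "FT2", "FT3")],
       B  = descriptors$index[descriptors$type %in% c("FT4", "FT5", "FT6")],
       C  = descriptors$index[descriptors$type %in% c("FT7", "FT8", "FT9")],
       D  = descriptors$index[descriptors$type == "FT10"],
       GC = descriptors$index[descriptors$type == "FT11"])
}

#' Impurity-based importance ranking of one descriptor group
#'
#' Trains a random forest (Gini impurity splits, bootstrap resampling) on
#' the given columns and returns the mean decrease in impurity of each
#' descriptor across trees. Constant descriptors are never chosen as
#' splitters and receive importance 0.
#'
#' @param x numeric/sparse matrix restricted to one group (samples x
#'   group descriptors).
#' @param labels binary 0/1 vector, both classes present.
#' @param seed integer seed; ranking is deterministic given the seed.
#' @param num_trees number of trees (default 100).
#' @param mtry candidate splitters per node; default
#'   `floor(sqrt(ncol(x)))`.
#' @return non-negative importance vector, one entry per column of `x`.
#' @export
rank_group <- function(x, labels, seed = 1L, num_trees = 100L, mtry = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2L) stop("labels must contain both classes")
  if (min(table(labels)) < 2L) stop("need >= 2 samples per class")
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(ncol(x))))
  if (is.null(colnames(x))) colnames(x) <- paste0("d", seq_len(ncol(x)))
  fit <- ranger::ranger(
    x = x, y = factor(labels, levels = c(0L, 1L)),
    num.trees = num_trees, mtry = mtry,
    importance = "impurity", splitrule = "gini",
    replace = TRUE, seed = as.integer(seed), num.threads = 1L,
    verbose = FALSE)
  unname(fit$variable.importance)
}

#' Top-k selection with stable tie-breaking
#'
#' Returns the positions of the `k` highest importances. Ties at the
#' boundary are broken by canonical descriptor index ascending, and the
#' result is sorted by canonical index.
#'
#' @param importances numeric importance vector.
#' @param k number to keep, `k <= length(importances)`.
#' @return sorted integer positions into `importances`.
#' @export
select_top <- function(importances, k) {
  if (k > length(importances)) stop("k exceeds group size")
  ord <- order(-importances, seq_along(importances))
  sort(ord[seq_len(k)])
}

#' Mode-wise feature selection
#'
#' Trains one impurity-based ranker per mode group (A, B, C, D) and keeps
#' the top `k` descriptors of each; GC-content is always appended without
#' ranking. With the default `k = 100` the combined set has 401
#' descriptors. Callers must pass training rows only — in cross-validation
#' the selector is re-trained inside each fold.
#'
#' @param features a `psgkm_features` object (training rows only).
#' @param labels binary labels; defaults to `features$labels`.
#' @param k descriptors kept per group (default 100).
#' @param seed integer seed (per-group sub-seeds are derived from it).
#' @param num_trees,mtry forwarded to [rank_group()].
#' @return object of class `psgkm_selection`: list with `selected`
#'   (data.frame of the combined 4k + 1 descriptors in canonical order),
#'   `per_group` (named list of per-group selected index vectors),
#'   `importances` (named list of per-group importance vectors), `k`,
#'   `seed`, `n_train`.
#' @export
groupwise_select <- function(features, labels = NULL, k = 100L, seed = 1L,
                             num_trees = 100L, mtry = NULL) {
  stopifnot(inherits(features, "psgkm_features"))
  if (is.null(labels)) labels <- features$labels
  if (is.null(labels)) stop("labels required for selection")
  groups <- mode_groups(features$descriptors)
  per_group <- list(); importances <- list()
  for (gi in seq_along(c("A", "B", "C", "D"))) {
    g <- c("A", "B", "C", "D")[gi]
    idx <- groups[[g]]
    imp <- rank_group(features$x[, idx, drop = FALSE], labels,
                      seed = as.integer(seed) + gi,
                      num_trees = num_trees, mtry = mtry)
    importances[[g]] <- imp
    per_group[[g]] <- idx[select_top(imp, k)]
  }
  sel_idx <- sort(c(unlist(per_group, use.names = FALSE), groups$GC))
  structure(list(selected = features$descriptors[sel_idx, ],
                 per_group = per_group, importances = importances,
                 k = as.integer(k), seed = as.integer(seed),
                 n_train = nrow(features$x), L = features$L),
            class = "psgkm_selection")
}

#' @export
print.psgkm_selection <- function(x, ...) {
  cat(sprintf("<psgkm_selection> %d descriptors (k = %d per mode + GC), seed %d, %d training samples\n",
              nrow(x$selected), x$k, x$seed, x$n_train))
  invisible(x)
}

#' Cross-fold stable descriptors
#'
#' Intersects the combined selected sets of several selection runs (for
#' instance the 25 in-fold selections of 5 x 5-fold cross-validation) and
#' reports the descriptors present in every one. GC-content is excluded —
#' it is preselected, so its membership carries no information. Reported
#' with pattern template and 1-based start-end window positions.
#'
#' @param results list of `psgkm_selection` objects over the same
#'   descriptor universe.
#' @return data.frame of stable descriptors (columns `name`, `type`,
#'   `template`, `start`, `end`) in canonical order.
#' @export
stable_intersection <- function(results) {
  if (length(results) < 2L) stop("need at least two selection results")
  Ls <- vapply(results, function(r) as.integer(r$L %||% NA_integer_), integer(1L))
  if (length(unique(Ls)) != 1L)
    stop("selection results come from different descriptor universes (L mismatch)")
  descs <- lapply(results, function(r) r$selected)
  sets <- lapply(descs, function(d) d$name[d$type != "FT11"])
  common <- Reduce(intersect, sets)
  ref <- descs[[1L]]
  out <- ref[match(common, ref$name), c("name", "type", "template", "start", "end")]
  out <- out[order(match(out$name, ref$name)), ]
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a selection result to JSON
#'
#' @param selection a `psgkm_selection`.
#' @param path output JSON path.
#' @export
write_selection <- function(selection, path) {
  obj <- list(
    seed = selection$seed, k = selection$k, n_train = selection$n_train,
    selected = selection$selected$name,
    importance_summary = lapply(selection$importances, function(v)
      list(min = min(v), median = stats::median(v), max = max(v))))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
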