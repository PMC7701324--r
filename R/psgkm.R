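#' Fit a position-specific gapped k-mer site predictor
#'
#' The front-end fitting function. Given labeled fixed-length sequence
#' windows it (1) encodes every position-specific (gapped) k-mer binary
#' indicator plus GC-content, (2) reduces the space by mode-wise
#' random-forest impurity ranking to the top `k` descriptors per mode plus
#' GC (401 descriptors at the default `k = 100`), and (3) fits an
#' L2-regularised logistic regression on the reduced matrix. The returned
#' object predicts new windows with [predict.psgkm()].
#'
#' @param x a labeled [psgkm_dataset()], or a path to a FASTA file.
#' @param labels optional labels (TSV path or named vector) when `x` is a
#'   FASTA path; see [read_fasta()].
#' @param k descriptors kept per mode group (default 100).
#' @param seed integer seed for the selection forests.
#' @param num_trees,mtry forest settings, see [rank_group()].
#' @param lambda,maxit,tol,threshold logistic settings, see [fit_lr()].
#' @param features optional pre-computed `psgkm_features` for `x`.
#' @return object of class `psgkm`: list with `model` (a `psgkm_lr`),
#'   `selection` (a `psgkm_selection`), `L`, `k`, `seed`, `n_train`,
#'   `config` (resolved settings).
#' @examples
#' spec <- synthetic_spec(n_pos = 30, n_neg = 30, seed = 7,
#'                        plants = list(list(template = "A--CG", start = 7,
#'                                           p_pos = 0.9, p_neg = 0.1)))
#' ds <- generate_dataset(spec)
#' fit <- psgkm(ds, k = 5, seed = 1)
#' predict(fit, ds)[1:3, ]
#' @export
psgkm <- function(x, labels = NULL, k = 100L, seed = 1L,
                  num_trees = 100L, mtry = NULL,
                  lambda = 1, maxit = 1000L, tol = 1e-4, threshold = 0.5,
                  features = NULL) {
  dataset <- if (inherits(x, "psgkm_dataset")) x else
    read_fasta(x, labels = labels)
  if (is.null(dataset$labels)) stop("training requires labels")
  if (is.null(features)) features <- encode_dataset(dataset)
  sel <- groupwise_select(features, k = k, seed = seed,
                          num_trees = num_trees, mtry = mtry)
  xsel <- as.matrix(features$x[, sel$selected$index, drop = FALSE])
  colnames(xsel) <- sel$selected$name
  model <- fit_lr(xsel, dataset$labels, lambda = lambda, maxit = maxit,
                  tol = tol, threshold = threshold)
  config <- list(L = dataset$L, k = as.integer(k), seed = as.integer(seed),
                 num_trees = as.integer(num_trees),
                 mtry = if (is.null(mtry)) "sqrt" else as.integer(mtry),
                 lambda = lambda, maxit = as.integer(maxit), tol = tol,
                 threshold = threshold)
  structure(list(model = model, selection = sel, L = dataset$L,
                 k = as.integer(k), seed = as.integer(seed),
                 n_train = length(dataset), config = config),
            class = "psgkm")
}

#' @export
print.psgkm <- function(x, ...) {
  cat(sprintf("<psgkm> site predictor for %d-nt windows\n", x$L))
  cat(sprintf("  %d selected descriptors (k = %d per mode + GC), %d training sequences, seed %d\n",
              length(x$model$coefficients), x$k, x$n_train, x$seed))
  invisible(x)
}

#' @export
summary.psgkm <- function(object, ...) {
  w <- object$model$coefficients
  top <- order(-abs(w))[seq_len(min(10L, length(w)))]
  cat(sprintf("<psgkm> %d-nt windows, %d descriptors, %d training sequences\n",
              object$L, length(w), object$n_train))
  tab <- table(object$selection$selected$type)
  cat("  selected per feature type:",
      paste(names(tab), tab, sep = "=", collapse = " "), "\n")
  cat("  largest |coefficient| descriptors:\n")
  for (i in top)
    cat(sprintf("    %-24s %+.4f\n", names(w)[i], w[i]))
  invisible(object)
}

#' @export
coef.psgkm <- function(object, ...) coef(object$model)

#' Predict 5hmC sites for new sequence windows
#'
#' Encodes only the model's selected descriptors (a sparse fast path,
#' bit-identical to full encoding followed by column selection) and applies
#' the logistic model.
#'
#' @param object a fitted [psgkm()] model.
#' @param newdata a [psgkm_dataset()] or FASTA path; window length must
#'   equal the model's `L`.
#' @param ... unused.
#' @return data.frame with `id`, `probability`, `call` in input order.
#' @export
predict.psgkm <- function(object, newdata, ...) {
  dataset <- if (inherits(newdata, "psgkm_dataset")) newdata else
    read_fasta(newdata, L = object$L, central_c = "ignore")
  if (dataset$L != object$L)
    stop(sprintf("window length %d does not match the model's L = %d",
                 dataset$L, object$L))
  xsel <- encode_descriptors(dataset, object$selection$selected)
  pr <- predict(object$model, xsel)
  data.frame(id = dataset$ids, probability = pr$probability, call = pr$call,
             row.names = NULL)
}

#' Persist / restore a fitted model as JSON
#'
#' @param object a fitted [psgkm()] model.
#' @param path JSON path.
#' @return `write_model` returns `path` invisibly; `read_model` returns
#'   the restored `psgkm` object (probabilities round-trip exactly:
#'   coefficients are serialized at full precision).
#' @export
write_model <- function(object, path) {
  stopifnot(inherits(object, "psgkm"))
  obj <- list(
    class = "psgkm", L = object$L, k = object$k, seed = object$seed,
    n_train = object$n_train, config = object$config,
    threshold = object$model$threshold, lambda = object$model$lambda,
    # 17 significant digits round-trip IEEE doubles exactly
    intercept = sprintf("%.17g", object$model$intercept),
    descriptor_names = object$model$descriptor_names,
    coefficients = sprintf("%.17g", unname(object$model$coefficients)))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(obj$class, "psgkm")) stop("not a psgkm model file: ", path)
  desc_all <- enumerate_descriptors(obj$L)
  sel_idx <- match(obj$descriptor_names, desc_all$name)
  if (anyNA(sel_idx)) stop("model references unknown descriptors")
  w <- stats::setNames(as.numeric(obj$coefficients), obj$descriptor_names)
  model <- structure(list(coefficients = w, intercept = as.numeric(obj$intercept),
                          descriptor_names = obj$descriptor_names,
                          threshold = obj$threshold, lambda = obj$lambda,
                          convergence = NULL),
                     class = "psgkm_lr")
  selection <- structure(list(selected = desc_all[sel_idx, ],
                              per_group = NULL, importances = NULL,
                              k = obj$k, seed = obj$seed,
                              n_train = obj$n_train, L = obj$L),
                         class = "psgkm_selection")
  structure(list(model = model, selection = selection, L = obj$L,
                 k = obj$k, seed = obj$seed, n_train = obj$n_train,
                 config = obj$config),
            class = "psgkm")
}
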