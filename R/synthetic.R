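#' Specification of a synthetic benchmark
#'
#' Describes a labeled set of fixed-length windows: residues drawn i.i.d.
#' from a background distribution over {A,C,G,U}, optionally with planted
#' position-specific (gapped) motifs. A plant is a template string, a
#' 1-based start, and class-conditional probabilities `p_pos` / `p_neg`
#' that the template's fixed residues are written at that window in a
#' positive / negative sequence — gap positions are left as background
#' draws, so the planted signal is exactly a position-specific gapped
#' pattern. The central position is forced to C after planting when
#' `force_central_C` is set; a plant whose fixed residues would set the
#' central position to something other than C is a specification error, as
#' are two plants that disagree on a shared fixed position.
#'
#' @param n_pos,n_neg class sizes.
#' @param L window length (default 41).
#' @param background probability vector over A, C, G, U summing to 1.
#' @param plants list of plants; each a list with `template`, `start`,
#'   `p_pos`, `p_neg`.
#' @param force_central_C force the central residue to C (default TRUE).
#' @param seed integer seed.
#' @return object of class `psgkm_synth_spec`.
#' @export
synthetic_spec <- function(n_pos, n_neg, L = 41L, background = rep(0.25, 4),
                           plants = list(), force_central_C = TRUE,
                           seed = 1L) {
  L <- as.integer(L)
  if (abs(sum(background) - 1) > 1e-9 || any(background < 0))
    stop("background must be a probability vector summing to 1")
  centre <- if (L %% 2L == 1L) (L + 1L) %/% 2L else NA_integer_
  fixed_at <- list()  # position -> residue, for conflict detection
  for (p in plants) {
    pat <- parse_template(p$template)
    if (p$start < 1L || p$start + pat$M - 1L > L)
      stop("plant '", p$template, "' at start ", p$start,
           " does not fit in L = ", L)
    if (p$p_pos < 0 || p$p_pos > 1 || p$p_neg < 0 || p$p_neg > 1)
      stop("plant probabilities must be in [0, 1]")
    tchars <- strsplit(pat$template, "")[[1L]]
    for (o in which(tchars != "-")) {
      pos <- p$start + o - 1L
      if (force_central_C && !is.na(centre) && pos == centre &&
          tchars[o] != "C")
        stop("plant '", p$template, "' fixes the central position to '",
             tchars[o], "', conflicting with the forced central C")
      key <- as.character(pos)
      if (!is.null(fixed_at[[key]]) && fixed_at[[key]] != tchars[o])
        stop("plants conflict at position ", pos)
      fixed_at[[key]] <- tchars[o]
    }
  }
  structure(list(n_pos = as.integer(n_pos), n_neg = as.integer(n_neg),
                 L = L, background = background, plants = plants,
                 force_central_C = isTRUE(force_central_C),
                 seed = as.integer(seed)),
            class = "psgkm_synth_spec")
}

#' Generate a synthetic labeled dataset
#'
#' @param spec a [synthetic_spec()].
#' @return a labeled [psgkm_dataset()] with `n_pos` positive records
#'   followed by `n_neg` negative records; reproducible from `spec$seed`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "psgkm_synth_spec"))
  n <- spec$n_pos + spec$n_neg
  labels <- c(rep(1L, spec$n_pos), rep(0L, spec$n_neg))
  centre <- if (spec$L %% 2L == 1L) (spec$L + 1L) %/% 2L else NA_integer_
  residues <- with_seed(spec$seed, {
    vapply(seq_len(n), function(i) {
      chars <- sample(RNA_ALPHABET, spec$L, replace = TRUE,
                      prob = spec$background)
      for (p in spec$plants) {
        prob <- if (labels[i] == 1L) p$p_pos else p$p_neg
        if (stats::runif(1) < prob) {
          tchars <- strsplit(parse_template(p$template)$template, "")[[1L]]
          fixed <- which(tchars != "-")
          chars[p$start + fixed - 1L] <- tchars[fixed]
        }
      }
      if (spec$force_central_C && !is.na(centre)) chars[centre] <- "C"
      paste(chars, collapse = "")
    }, character(1L))
  })
  ids <- sprintf("%s%04d", ifelse(labels == 1L, "pos", "neg"),
                 c(seq_len(spec$n_pos), seq_len(spec$n_neg)))
  psgkm_dataset(ids, residues, labels = labels, L = spec$L,
                central_c = "ignore")
}

#' Benchmark-shaped synthetic specification
#'
#' A spec mirroring the published benchmark's shape: 662 positive and 662
#' negative 41-nt windows (1,324 in total) with a forced central C over a
#' uniform background, carrying a default set of moderately informative
#' plants — one per proposed gapped mode — so the full pipeline has signal
#' to find.
#'
#' @param seed integer seed (default 1).
#' @return a [synthetic_spec()].
#' @export
benchmark_like <- function(seed = 1L) {
  synthetic_spec(
    n_pos = 662L, n_neg = 662L, L = 41L,
    background = rep(0.25, 4),
    plants = list(
      list(template = "A-CG",  start = 7L,  p_pos = 0.50, p_neg = 0.20),
      list(template = "GG--U", start = 26L, p_pos = 0.45, p_neg = 0.15),
      list(template = "C-G-A", start = 15L, p_pos = 0.40, p_neg = 0.15)),
    force_central_C = TRUE, seed = seed)
}

#' Read a synthetic spec from a flat key-value config file
#'
#' Lines of the form `key = value`; plants are given as
#' `plant = <template> <start> <p_pos> <p_neg>` (repeatable), the
#' background as four comma-separated probabilities.
#'
#' @param path config file path.
#' @return a [synthetic_spec()].
#' @export
read_synth_config <- function(path) {
  kv <- read_config(path)
  plants <- lapply(kv[names(kv) == "plant"], function(v) {
    parts <- strsplit(trimws(v), "\\s+")[[1L]]
    if (length(parts) != 4L)
      stop("plant line needs: <template> <start> <p_pos> <p_neg>")
    list(template = parts[1L], start = as.integer(parts[2L]),
         p_pos = as.numeric(parts[3L]), p_neg = as.numeric(parts[4L]))
  })
  bg <- if ("background" %in% names(kv))
    as.numeric(strsplit(cfg_get(kv, "background"), ",")[[1L]]) else rep(0.25, 4)
  synthetic_spec(
    n_pos = as.integer(cfg_get(kv, "n_pos", 662L)),
    n_neg = as.integer(cfg_get(kv, "n_neg", 662L)),
    L = as.integer(cfg_get(kv, "L", 41L)),
    background = bg, plants = unname(plants),
    force_central_C = !identical(cfg_get(kv, "force_central_C", "true"), "false"),
    seed = as.integer(cfg_get(kv, "seed", 1L)))
}

cfg_get <- function(kv, key, default = NULL) {
  if (key %in% names(kv)) unname(kv[key][1L]) else default
}

# flat key=value config reader; returns a named character vector in file
# order (duplicate keys allowed, e.g. repeated `plant` lines)
read_config <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  keys <- trimws(sub("=.*$", "", lines))
  vals <- trimws(sub("^[^=]*=", "", lines))
  stats::setNames(vals, keys)
}
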