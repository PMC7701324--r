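# Fixtures built in code; no stored data files.

# small balanced dataset with an optional single plant
toy_dataset <- function(n_per_class = 20, L = 41, plant = NULL, seed = 1) {
  plants <- if (is.null(plant)) list() else list(plant)
  generate_dataset(synthetic_spec(n_per_class, n_per_class, L = L,
                                  plants = plants, seed = seed))
}

# brute-force pattern matcher, independent of pattern_match: compares the
# window character by character against the template
brute_match <- function(template, residues, start) {
  tchars <- strsplit(template, "")[[1L]]
  ok <- TRUE
  for (q in seq_along(tchars)) {
    r <- substr(residues, start + q - 1L, start + q - 1L)
    if (tchars[q] != "-" && tchars[q] != r) ok <- FALSE
  }
  as.integer(ok)
}

# Mann-Whitney rank statistic U / (P*N), ties counted half; independent
# oracle for the trapezoid auROC
mw_auc <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  gt <- outer(pos, neg, ">")
  eq <- outer(pos, neg, "==")
  (sum(gt) + 0.5 * sum(eq)) / (length(pos) * length(neg))
}

random_rna <- function(L) paste(sample(c("A", "C", "G", "U"), L, replace = TRUE),
                                collapse = "")
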