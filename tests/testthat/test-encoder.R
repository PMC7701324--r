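test_that("descriptor enumeration matches the closed form per family", {
  d41 <- enumerate_descriptors(41)
  counts <- table(d41$type)[paste0("FT", 1:11)]
  expect_equal(unname(c(counts)),
               c(164L, 640L, 2496L, 2432L, 2368L, 2304L,
                 2432L, 2368L, 2304L, 2368L, 1L))
  expect_equal(nrow(d41), 19877L)
  expect_equal(d41$name[nrow(d41)], "FT11:GC")  # GC always last

  d6 <- enumerate_descriptors(6)
  expect_equal(nrow(d6), 1257L)

  # property sweep: counts equal sum over families of (L - M + 1) * |family|
  Ms <- c(1, 2, 3, 4, 5, 6, 4, 5, 6, 5)
  sizes <- c(4, 16, 64, 64, 64, 64, 64, 64, 64, 64)
  for (L in seq(6, 60, by = 6)) {
    expect_equal(nrow(enumerate_descriptors(L)),
                 sum((L - Ms + 1) * sizes) + 1)
  }
  expect_error(enumerate_descriptors(5), ">= 6")
})

test_that("descriptor names encode type, template, and 1-based window", {
  d <- enumerate_descriptors(41)
  expect_true("FT5:A--CG@7-11" %in% d$name)
  row <- d[d$name == "FT5:A--CG@7-11", ]
  expect_equal(row$start, 7L)
  expect_equal(row$end, 11L)
  expect_equal(row$mode, "PsMGD")
})

test_that("indicator strings reproduce the worked examples", {
  expect_equal(indicator_string("GG", "ACGGCGGUG"), "00100100")
  expect_equal(indicator_string("ACG", "GUAGCACGG"), "0000010")
  expect_equal(indicator_string("A-CG", "AACGU"), "10")
  expect_error(indicator_string("A--CG", "ACG"), "shorter")
})

test_that("GC-content is the percentage of G and C residues", {
  expect_equal(gc_content("GGGG"), 100)
  expect_equal(gc_content("AUAU"), 0)
  expect_equal(gc_content("ACGGCGGUG"), 100 * 7 / 9, tolerance = 1e-12)
  expect_equal(round(gc_content("ACGGCGGUG"), 2), 77.78)
  expect_error(gc_content(""), "empty")
})

test_that("encoded rows are one-hot per family window", {
  ds <- toy_dataset(8, L = 41, seed = 3)
  fm <- encode_dataset(ds)
  expect_equal(dim(fm), c(16L, 19877L))
  binary <- fm$x[, -ncol(fm$x)]
  expect_true(all(binary@x %in% c(0, 1)))
  expect_equal(unname(Matrix::rowSums(binary)), rep(379, 16))
  gc_col <- fm$x[, ncol(fm$x)]
  expect_true(all(gc_col >= 0 & gc_col <= 100))
  expect_equal(unname(gc_col), gc_content(ds$residues))
})

test_that("single-descriptor values match the worked bit strings", {
  ds <- psgkm_dataset("s1", "ACGGCGGUG", L = 9, central_c = "ignore")
  fm <- encode_dataset(ds)
  # pattern GG at start 3 is bit 3 of "00100100"
  expect_equal(unname(fm$x[1, "FT2:GG@3-4"]), 1)
  expect_equal(unname(fm$x[1, "FT2:GG@1-2"]), 0)
  # full FT2:GG row of indicators equals the indicator string
  gg_cols <- paste0("FT2:GG@", 1:8, "-", 2:9)
  expect_equal(paste(fm$x[1, gg_cols], collapse = ""), "00100100")
})

test_that("the GC normalization flag rescales only the GC column", {
  ds <- toy_dataset(3, L = 9, seed = 29)
  raw <- encode_dataset(ds)
  norm <- encode_dataset(ds, normalize_gc = TRUE)
  expect_equal(unname(norm$x[, ncol(norm$x)]),
               unname(raw$x[, ncol(raw$x)]) / 100)
  expect_equal(norm$x[, -ncol(norm$x)], raw$x[, -ncol(raw$x)])
  direct <- encode_descriptors(ds, "FT11:GC", normalize_gc = TRUE)
  expect_equal(unname(direct[, 1]), unname(norm$x[, ncol(norm$x)]))
})

test_that("encoding an empty dataset yields a 0-row matrix", {
  ds <- psgkm_dataset(character(), character(), L = 41)
  fm <- encode_dataset(ds)
  expect_equal(dim(fm), c(0L, 19877L))
})

test_that("row permutation permutes the matrix rows identically", {
  ds <- toy_dataset(6, seed = 8)
  perm <- c(5, 1, 12, 3, 7, 2, 11, 4, 6, 8, 10, 9)
  fm1 <- encode_dataset(ds)
  fm2 <- encode_dataset(ds[perm])
  expect_equal(as.matrix(fm2$x), as.matrix(fm1$x)[perm, ])
})

test_that("subset encoding is bit-identical to full encoding", {
  ds <- toy_dataset(5, seed = 13)
  fm <- encode_dataset(ds)
  set.seed(2)
  pick <- sort(c(sample(19876, 60), 19877))
  sub <- fm$descriptors[pick, ]
  direct <- encode_descriptors(ds, sub)
  expect_equal(unname(direct), unname(as.matrix(fm$x[, pick])))
  # by name too
  byname <- encode_descriptors(ds, sub$name)
  expect_identical(direct, byname)
  expect_error(encode_descriptors(ds, "FT1:Z@1-1"), "unknown descriptor")
})

test_that("matrix export round-trips in dense and triplet formats", {
  ds <- toy_dataset(3, L = 9, seed = 5)
  fm <- encode_dataset(ds)
  for (format in c("dense", "triplet")) {
    path <- withr::local_tempfile(fileext = ".tsv")
    write_matrix(fm, path, format = format)
    back <- read_matrix(path, format = format, L = 9)
    expect_equal(as.matrix(back$x), as.matrix(fm$x))
  }
})
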