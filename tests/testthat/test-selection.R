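test_that("a perfect splitter dominates the impurity ranking", {
  set.seed(10)
  n <- 80
  labels <- rep(c(0L, 1L), each = n / 2)
  x <- matrix(rbinom(n * 30, 1, 0.5), nrow = n)
  x[, 17] <- labels                       # the perfect splitter
  x[, 5] <- 0                             # constant descriptor
  imp <- rank_group(x, labels, seed = 3)
  expect_length(imp, 30)
  expect_true(all(imp >= 0))
  expect_equal(which.max(imp), 17L)
  expect_equal(imp[5], 0)
  # determinism under a fixed seed
  expect_identical(imp, rank_group(x, labels, seed = 3))
  expect_false(identical(imp, rank_group(x, labels, seed = 4)))
  expect_error(rank_group(x, rep(1L, n), seed = 1), "both classes")
})

test_that("top-k selection is stable with canonical tie-breaking", {
  expect_equal(select_top(c(0.5, 0.1, 0.4), 2), c(1L, 3L))
  expect_equal(select_top(rep(1, 5), 2), c(1L, 2L))
  expect_equal(select_top(c(0.2, 0.9, 0.2), 3), 1:3)
  expect_error(select_top(c(1, 2), 3), "exceeds")
})

test_that("mode groups partition the binary descriptors", {
  g <- mode_groups(enumerate_descriptors(41))
  expect_equal(lengths(g)[c("A", "B", "C", "D")],
               c(A = 3300L, B = 7104L, C = 7104L, D = 2368L))
  expect_equal(sort(unname(unlist(g))), 1:19877)
})

test_that("groupwise selection returns 4k + 1 descriptors including GC", {
  ds <- toy_dataset(25, seed = 21,
                    plant = list(template = "A--CG", start = 7,
                                 p_pos = 1, p_neg = 0))
  fm <- encode_dataset(ds)
  sel <- groupwise_select(fm, k = 10, seed = 5, num_trees = 50)
  expect_s3_class(sel, "psgkm_selection")
  expect_equal(nrow(sel$selected), 41L)
  expect_true("FT11:GC" %in% sel$selected$name)
  expect_equal(anyDuplicated(sel$selected$name), 0L)
  # planted perfect splitter lands in group B's selection
  expect_true("FT5:A--CG@7-11" %in%
                fm$descriptors$name[sel$per_group$B])

  sel1 <- groupwise_select(fm, k = 1, seed = 5, num_trees = 50)
  expect_equal(nrow(sel1$selected), 5L)
  # deterministic under the seed
  sel2 <- groupwise_select(fm, k = 10, seed = 5, num_trees = 50)
  expect_identical(sel$selected$name, sel2$selected$name)
})

test_that("selection depends on the supplied training rows only", {
  ds <- toy_dataset(20, seed = 31)
  fm <- encode_dataset(ds)
  train <- 1:30
  sub <- fm
  sub$x <- fm$x[train, ]; sub$labels <- fm$labels[train]
  sub$sample_ids <- fm$sample_ids[train]
  sel_a <- groupwise_select(sub, k = 5, seed = 9, num_trees = 50)
  # permute the labels of the held-out rows; the selection must not move
  fm_perm <- fm
  fm_perm$labels[31:40] <- rev(fm_perm$labels[31:40])
  sub2 <- fm_perm
  sub2$x <- fm_perm$x[train, ]; sub2$labels <- fm_perm$labels[train]
  sub2$sample_ids <- fm_perm$sample_ids[train]
  sel_b <- groupwise_select(sub2, k = 5, seed = 9, num_trees = 50)
  expect_identical(sel_a$selected$name, sel_b$selected$name)
  expect_identical(sel_a$importances, sel_b$importances)
})

test_that("stable intersection keeps descriptors present in every set", {
  ds <- toy_dataset(25, seed = 41)
  fm <- encode_dataset(ds)
  sel <- groupwise_select(fm, k = 5, seed = 2, num_trees = 50)
  # idempotence: two identical results intersect to the set minus GC
  out <- stable_intersection(list(sel, sel))
  expect_setequal(out$name, setdiff(sel$selected$name, "FT11:GC"))
  expect_false("FT11:GC" %in% out$name)
  # start-end reporting style
  expect_true(all(grepl("@\\d+-\\d+$", out$name)))
  expect_true(all(out$end - out$start + 1L == nchar(out$template)))

  # disjoint selections intersect to nothing
  sel_b <- sel
  d <- fm$descriptors
  alt <- d[!d$name %in% sel$selected$name & d$type != "FT11", ][1:20, ]
  sel_b$selected <- rbind(alt, d[d$type == "FT11", ])
  expect_equal(nrow(stable_intersection(list(sel, sel_b))), 0L)

  # mismatched universes are an error
  sel_c <- sel; sel_c$L <- 21L
  expect_error(stable_intersection(list(sel, sel_c)), "universe")
  expect_error(stable_intersection(list(sel)), "at least two")
})

test_that("selection serializes to JSON with seed and feature names", {
  ds <- toy_dataset(15, seed = 51)
  fm <- encode_dataset(ds)
  sel <- groupwise_select(fm, k = 3, seed = 7, num_trees = 50)
  path <- withr::local_tempfile(fileext = ".json")
  write_selection(sel, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$seed, 7)
  expect_equal(obj$k, 3)
  expect_equal(obj$selected, sel$selected$name)
  expect_named(obj$importance_summary, c("A", "B", "C", "D"))
})
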