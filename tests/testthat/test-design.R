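test_that("pair enumeration reproduces the canonical design totals", {
  d <- build_design(24, 5, 500, 62)
  expect_equal(nrow(enumerate_within_pairs(d, "AB01")), 10)
  expect_equal(nrow(enumerate_between_pairs(d, "AB01")), 230)
  ab <- d$movies$movie_id[d$movies$role == "AB"]
  expect_equal(sum(vapply(ab, function(m) nrow(enumerate_within_pairs(d, m)),
                          0)), 240)
  expect_equal(sum(vapply(ab, function(m) nrow(enumerate_between_pairs(d, m)),
                          0)), 5520)
})

test_that("pair counts match closed forms over a grid of designs", {
  for (M in 1:4) for (R in 1:5) {
    d <- build_design(M, R, 100, 4)
    ab <- d$movies$movie_id[d$movies$role == "AB"]
    w <- sum(vapply(ab, function(m) nrow(enumerate_within_pairs(d, m)), 0))
    b <- sum(vapply(ab, function(m) nrow(enumerate_between_pairs(d, m)), 0))
    expect_equal(w, M * choose(R, 2))
    expect_equal(b, M * (M - 1) * choose(R, 2))
  }
})

test_that("within pairs are unordered (rep1 < rep2) and deterministic", {
  d <- tiny_design(n_repetitions = 5)
  p1 <- enumerate_within_pairs(d, "AB01")
  p2 <- enumerate_within_pairs(d, "AB01")
  expect_identical(p1, p2)
  expect_true(all(p1$rep_1 < p1$rep_2))
  expect_false(anyDuplicated(p1[, c("rep_1", "rep_2")]) > 0)
  b <- enumerate_between_pairs(d, "AB01")
  expect_true(all(b$rep_1 < b$rep_2))
  expect_true(all(b$movie_id_1 != b$movie_id_2))
})

test_that("degenerate designs behave as documented", {
  d1 <- build_design(1, 1, 100, 4)
  expect_equal(nrow(enumerate_within_pairs(d1, "AB01")), 0)
  expect_equal(nrow(enumerate_between_pairs(d1, "AB01")), 0)
  d2 <- build_design(1, 2, 100, 4)
  expect_equal(nrow(enumerate_within_pairs(d2, "AB01")), 1)
  d3 <- build_design(2, 2, 100, 4)
  expect_equal(nrow(enumerate_between_pairs(d3, "AB01")), 1)
})

test_that("triads pair BC with exactly one AB and XY with none", {
  d <- tiny_design()
  expect_equal(corresponding_ab(d, "BC01"), "AB01")
  expect_equal(corresponding_ab(d, "BC02"), "AB02")
  xy_triads <- d$movies$triad_id[d$movies$role == "XY"]
  ab_triads <- d$movies$triad_id[d$movies$role == "AB"]
  expect_length(intersect(xy_triads, ab_triads), 0)
  expect_error(corresponding_ab(d, "AB01"), "not a BC movie")
})

test_that("segment schedule tiles 13 s of content and the 14-s epoch", {
  d <- tiny_design()
  st <- d$segment_table
  expect_equal(st$end_s - st$start_s, c(2, 3, 1, 2, 5))
  expect_equal(st$start_s[-1], st$end_s[-nrow(st)])
  expect_equal(range(c(st$start_s, st$end_s)), c(0, 13))
  expect_equal(diff(d$epoch_window), 14)
  expect_equal(segment_window(d, "sim_second"), c(6, 8))
  expect_error(segment_window(d, "nope"), "unknown segment")
})

test_that("invalid design arguments are rejected", {
  expect_error(build_design(0, 5, 100, 4), "n_triads")
  expect_error(build_design(2, 0, 100, 4), "n_repetitions")
  expect_error(build_design(2, 5, 100, c("a", "a")), "duplicate channel")
  d <- tiny_design()
  expect_error(enumerate_within_pairs(d, "ZZ99"), "unknown movie_id")
  expect_error(enumerate_within_pairs(d, "BC01"), "AB movies")
})

test_that("the synthetic channel layout yields a symmetric neighbour graph", {
  d <- build_design(2, 2, 100, 9)
  g <- d$neighbor_graph
  expect_true(isSymmetric(unname(g)))
  expect_true(all(diag(g) == 0))
  expect_true(all(rowSums(g) >= 1))
})

test_that("designs serialise to JSON plus a BED-like segment table", {
  d <- tiny_design()
  path <- file.path(tempdir(), "design-export")
  write_design(d, path)
  meta <- jsonlite::read_json(file.path(path, "design.json"),
                              simplifyVector = TRUE)
  expect_equal(meta$n_triads, d$n_triads)
  seg <- utils::read.table(file.path(path, "segments.tsv"), header = TRUE,
                           sep = "\t")
  expect_equal(seg$segment, d$segment_table$segment)
  expect_equal(seg$end_s - seg$start_s, c(2, 3, 1, 2, 5))
  unlink(path, recursive = TRUE)
})
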