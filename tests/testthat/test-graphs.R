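test_that("patch template matches brute-force enumeration for w = 0..6", {
  for (w in 0:6) {
    g <- make_patch(w)
    expect_equal(g$t, (2 * w + 1)^2)
    expect_equal(unname(g$offsets), unname(brute_patch_offsets(w)))
  }
  expect_equal(unname(make_patch(0)$offsets), matrix(c(0L, 0L), ncol = 2))
  expect_true(any(make_patch(1)$offsets[, 1] == -1 &
                  make_patch(1)$offsets[, 2] == 1))
  expect_false(any(make_patch(1)$offsets[, 1] == 2))
  expect_error(make_patch(-1), "non-negative")
})

test_that("cross template has 4w+1 offsets on the central row and column", {
  for (w in 0:6) {
    g <- make_cross(w)
    expect_equal(g$t, 4 * w + 1)
    expect_setequal(paste(g$offsets[, 1], g$offsets[, 2]),
                    paste(brute_cross_offsets(w)[, 1],
                          brute_cross_offsets(w)[, 2]))
  }
  g1 <- make_cross(1)
  has <- function(a, b) any(g1$offsets[, 1] == a & g1$offsets[, 2] == b)
  expect_true(has(1, 0) && has(0, -1))
  expect_false(has(1, 1))
})

test_that("memconp template carries exactly the canonical 25 offsets", {
  g <- make_memconp()
  expect_equal(g$t, 25)
  has <- function(a, b) any(g$offsets[, 1] == a & g$offsets[, 2] == b)
  expect_true(has(3, -4))
  expect_false(has(2, 2))
  # symmetric under (a, b) -> (-a, -b)
  key <- paste(g$offsets[, 1], g$offsets[, 2])
  neg <- paste(-g$offsets[, 1], -g$offsets[, 2])
  expect_setequal(key, neg)
})

test_that("complete unipartite template enumerates ordered distinct slot pairs", {
  for (w in 0:5) {
    g <- make_complete(w)
    expect_equal(g$t, (2 * w) * (2 * w + 1))
    expect_equal(unname(g$slot_edges), unname(brute_complete_slot_pairs(w)))
  }
})

test_that("globrrc realization applies offsets and preserves length at boundaries", {
  g <- build_globrrcs(c(10, 40), make_patch(2), 100)
  expect_equal(nrow(g$conn), 25)
  expect_equal(unname(g$conn[1, ]), c(8L, 38L))
  expect_equal(unname(g$conn[25, ]), c(12L, 42L))
  # boundary: ends below 1 become placeholders, length unchanged
  gb <- build_globrrcs(c(1, 3), make_patch(2), 100)
  expect_equal(nrow(gb$conn), 25)
  expect_true(anyNA(gb$conn[, "i"]))
  expect_equal(sum(is.na(gb$conn[, "i"])), 10)  # a = -2, -1 give i < 1, 5 b's each
  # identity offsets
  gi <- build_globrrcs(c(5, 9), make_cross(0), 20)
  expect_equal(unname(gi$conn), matrix(c(5L, 9L), ncol = 2))
  expect_error(build_globrrcs(c(40, 10), make_patch(1), 100), "p < q")
  expect_error(build_globrrcs(c(90, 101), make_patch(1), 100), "out of sequence")
})

test_that("memconp degenerate realizations are placeholder-filled, not dropped", {
  # pair (5, 6): offset (1, 0) gives (6, 6) -> same residue at both ends
  g <- build_globrrcs(c(5, 6), make_memconp(), 50)
  expect_equal(nrow(g$conn), 25)
  same <- which(!is.na(g$conn[, 1]) & g$conn[, 1] == g$conn[, 2])
  expect_length(same, 0)
})

test_that("locrrc realization maps window slots and handles boundaries", {
  l <- build_locrrcs(50, make_complete(2), 100)
  expect_equal(nrow(l$conn), 20)
  expect_equal(unname(l$conn[1, ]), c(48L, 49L))  # slots (0,1)
  l0 <- build_locrrcs(50, make_complete(0), 100)
  expect_equal(nrow(l0$conn), 0)
  l1 <- build_locrrcs(1, make_complete(1), 100)
  expect_equal(nrow(l1$conn), 6)
  touches0 <- rowSums(is.na(l1$conn)) > 0
  expect_equal(sum(touches0), 4)  # ordered pairs touching the out-of-range slot
  expect_error(build_locrrcs(0, make_complete(1), 100), "out of sequence")
})

test_that("locrrc count law (2w)(2w+1) holds across centers and widths", {
  for (w in 0:5) for (center in c(1, 3, 25, 50)) {
    l <- build_locrrcs(center, make_complete(w), 50)
    expect_equal(nrow(l$conn), (2 * w) * (2 * w + 1))
  }
})

test_that("pair enumeration matches the closed form and the double loop", {
  expect_equal(nrow(enumerate_pairs(500, 1)), 124750)
  expect_equal(unname(enumerate_pairs(2, 1)), matrix(c(1L, 2L), ncol = 2))
  expect_equal(unname(enumerate_pairs(10, 5)), unname(brute_pairs(10, 5)))
  for (L in c(2, 7, 30)) {
    expect_equal(nrow(enumerate_pairs(L, 1)), L * (L - 1) / 2)
    expect_equal(unname(enumerate_pairs(L, 1)), unname(brute_pairs(L, 1)))
  }
  expect_error(enumerate_pairs(1, 1), ">= 2")
})

test_that("connection construction is deterministic", {
  a <- build_globrrcs(c(7, 20), make_memconp(), 60)
  b <- build_globrrcs(c(7, 20), make_memconp(), 60)
  expect_identical(a, b)
  expect_identical(enumerate_pairs(40, 3), enumerate_pairs(40, 3))
})

test_that("custom graph specs load from plain text with comments", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# a custom template", "0 0", "1 -1", "", "2 2  # trailing"), f)
  g <- read_graph_spec(f, "bipartite")
  expect_equal(g$t, 3)
  expect_equal(unname(g$offsets[2, ]), c(1L, -1L))
  fu <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("0 2", "2 0", "0 1"), fu)
  u <- read_graph_spec(fu, "unipartite", w = 1)
  expect_equal(u$t, 3)
  writeLines(c("0 0", "0 0"), f)
  expect_error(read_graph_spec(f, "bipartite"), "duplicate")
})
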