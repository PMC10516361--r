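sample_segments <- function() {
  data.frame(chain = "A",
             beg = c(10, 1, 31),
             end = c(30, 9, 40),
             code = c("H", "1", "2"))
}

test_that("topology XML writes and parses round-trip", {
  f <- withr::local_tempfile(fileext = ".xml")
  segs <- sample_segments()
  write_topology_xml(segs, f)
  back <- parse_topology_xml(f)
  expect_equal(back, segs)
})

test_that("parser handles empty chains and unknown types", {
  f <- withr::local_tempfile(fileext = ".xml")
  writeLines('<topology><chain id="A"/></topology>', f)
  expect_equal(nrow(parse_topology_xml(f)), 0)

  writeLines('<topology><chain id="A"><region beg="1" end="5" type="Z"/></chain></topology>', f)
  expect_warning(p <- parse_topology_xml(f), "unknown region type")
  expect_equal(p$code, "U")

  writeLines('<topology><chain id="A"><region beg="9" end="5" type="H"/></chain></topology>', f)
  expect_error(parse_topology_xml(f), "beg > end")
  writeLines("<topology><chain", f)
  expect_error(parse_topology_xml(f))
})

test_that("non-TM segments take the majority predicted label", {
  segs <- data.frame(chain = "A", beg = 1, end = 9, code = "1")
  pred <- data.frame(beg = 1, end = 20, label = "inside")
  expect_equal(redistribute_nontm(segs, pred)$code, "cytoplasmic")

  # 6 residues under outside, 4 under inside -> extracellular
  segs2 <- data.frame(chain = "A", beg = 1, end = 10, code = "L")
  pred2 <- data.frame(beg = c(1, 5), end = c(4, 30),
                      label = c("inside", "outside"))
  expect_equal(redistribute_nontm(segs2, pred2)$code, "extracellular")

  # 5/5 tie -> unknown
  pred3 <- data.frame(beg = c(1, 6), end = c(5, 30),
                      label = c("inside", "outside"))
  expect_equal(redistribute_nontm(segs2, pred3)$code, "unknown")

  # no overlap with any inside/outside segment -> unknown
  pred4 <- data.frame(beg = 100, end = 120, label = "inside")
  expect_equal(redistribute_nontm(segs2, pred4)$code, "unknown")
})

test_that("membrane codes pass through redistribution untouched", {
  segs <- data.frame(chain = "A", beg = c(1, 10, 31, 41, 50, 60),
                     end = c(9, 30, 40, 49, 59, 70),
                     code = c("1", "H", "2", "B", "F", "I"))
  pred <- data.frame(beg = 1, end = 70, label = "inside")
  out <- redistribute_nontm(segs, pred)
  expect_equal(out$code, c("cytoplasmic", "H", "cytoplasmic", "B", "F", "I"))
  # boundaries and coverage are never altered
  expect_equal(out[, c("beg", "end")], segs[, c("beg", "end")])
})

test_that("per-residue encoding covers, defaults and resolves overlap by document order", {
  segs <- data.frame(chain = "A", beg = 3, end = 5, code = "H")
  expect_equal(per_residue_topology(segs, 6), c("U", "U", "H", "H", "H", "U"))
  expect_equal(per_residue_topology(segs[0, ], 4), rep("U", 4))
  ov <- data.frame(chain = "A", beg = c(1, 3), end = c(4, 6),
                   code = c("H", "C"))
  expect_warning(v <- per_residue_topology(ov, 6), "overlap")
  expect_equal(v, c("H", "H", "C", "C", "C", "C"))
  expect_error(per_residue_topology(segs, 4), "outside")
  # non-overlapping coverage equals the non-U label count
  segs2 <- sample_segments()
  v2 <- per_residue_topology(segs2, 50)
  expect_equal(sum(v2 != "U"), sum(segs2$end - segs2$beg + 1))
})

test_that("qc_filter applies each criterion and reports missing fields", {
  rec <- data.frame(identifier = "p1", method = "X-ray", resolution = 1.8,
                    length = 240, tm_helix_count = 7,
                    tm_helix_lengths = "20;21;19;23;22;20;18")
  r1 <- qc_filter(rec, list(max_resolution = 3.0, min_helices = 1))
  expect_true(r1$pass)
  r2 <- qc_filter(rec, list(min_helices = 8))
  expect_false(r2$pass)
  expect_equal(r2$reasons, "tm_helix_count")
  r3 <- qc_filter(rec, list(methods = c("NMR", "EM")))
  expect_equal(r3$reasons, "method")
  rec$resolution <- NA
  r4 <- qc_filter(rec, list(max_resolution = 3.0))
  expect_equal(r4$reasons, "missing:resolution")
  expect_error(qc_filter(rec, list(min_length = 10, max_length = 5)),
               "contradictory")
})

test_that("qc_filter isolates exactly the violated criteria over mixed records", {
  ok <- data.frame(identifier = sprintf("ok%d", 1:7), method = "X-ray",
                   resolution = 2.0, length = 300, tm_helix_count = 7,
                   tm_helix_lengths = "20;21;19;23;22;20;18")
  bad <- ok[1:3, ]
  bad$identifier <- c("bad_res", "bad_len", "bad_helix")
  bad$resolution[1] <- 3.9
  bad$length[2] <- 30
  bad$tm_helix_count[3] <- 0
  bad$tm_helix_lengths[3] <- ""
  records <- rbind(ok, bad)
  res <- qc_filter(records, list(max_resolution = 3.0, min_length = 50,
                                 min_helices = 1))
  expect_equal(sum(res$pass), 7)
  expect_equal(res$reasons[res$pass], rep("", 7))
  expect_equal(res$reasons[!res$pass],
               c("resolution", "length", "tm_helix_count"))
})

test_that("qc passing sets shrink monotonically as criteria are added", {
  set.seed(7)
  n <- 200
  records <- data.frame(
    identifier = sprintf("r%03d", 1:n),
    method = sample(c("X-ray", "NMR", "EM"), n, replace = TRUE),
    resolution = round(runif(n, 1, 5), 2),
    length = sample(30:900, n, replace = TRUE),
    tm_helix_count = sample(0:14, n, replace = TRUE))
  records$tm_helix_lengths <- vapply(records$tm_helix_count, function(h)
    paste(sample(8:40, h, replace = TRUE), collapse = ";"), character(1))
  records$resolution[records$method == "NMR"] <- NA

  base <- list()
  additions <- list(list(methods = c("X-ray", "EM")),
                    list(max_resolution = 3.0),
                    list(min_length = 100),
                    list(max_length = 700),
                    list(min_helices = 1),
                    list(max_helices = 12),
                    list(min_helix_length = 12),
                    list(max_helix_length = 35))
  expect_true(all(qc_filter(records, base)$pass))
  acc <- base
  prev <- qc_filter(records, acc)$pass
  for (add in additions) {
    acc <- c(acc, add)
    cur <- qc_filter(records, acc)$pass
    expect_true(all(cur <= prev))   # never enlarges the passing set
    prev <- cur
  }
})

test_that("qc criteria load from a key-value config", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("max_resolution: 3.0", "min_helices: 1",
               "methods: [X-ray, EM]"), f)
  crit <- read_qc_criteria(f)
  expect_equal(crit$max_resolution, 3.0)
  expect_equal(crit$methods, c("X-ray", "EM"))
})
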