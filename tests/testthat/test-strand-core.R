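# The tube algebra: primitives, conservation, determinism, grammar safety.

test_that("atoms carry the configured unit length and weight atoms their own", {
  expect_equal(symbol_atom("S")$length_mer, 5)
  expect_equal(symbol_atom("IND", i = 2, t = 7)$length_mer, 7)
  expect_equal(symbol_atom("JOB", j = 3)$token, "B3")
  wt <- symbol_atom("WT", i = 1, j = 3, length_mer = 4)
  expect_equal(wt$token, "w_1_3")
  expect_equal(wt$length_mer, 4)
  expect_error(symbol_atom("WT", i = 1, j = 1), "length_mer")
})

test_that("strand text notation round-trips", {
  txt <- "sA1eB3sA2eB1sA2eB2w13w21w22"
  s <- strand_from_text(txt)
  expect_identical(strand_to_text(s), txt)
  expect_identical(strand_atoms(s)[1:4], c("s", "A1", "e", "B3"))
  expect_error(strand_from_text("sAxeB1"), "cannot parse")
})

test_that("strand_length recomputes symbolic lengths, weights from costs", {
  C <- costs_2x3()
  s <- strand_from_text("sA1eB3sA2eB1sA2eB2w13w21w22")
  expect_equal(strand_length(s, t = 5, costs = C), 60 + 1 + 1 + 2)
  expect_equal(strand_length(strand_from_text("sA1eB1"), t = 5), 20)
  expect_error(strand_length(s, t = 5), "costs")
})

test_that("merge, copy, detect, discard have multiset semantics", {
  x <- strand_from_text("sA1eB1")
  y <- strand_from_text("sA2eB2")
  t1 <- new_tube(x, 20)
  t2 <- new_tube(y, 20)
  merged <- tube_merge(t1, t2)
  expect_equal(tube_size(merged), 2L)
  expect_setequal(merged$strands, c(x, y))

  dup <- new_tube(c(x, x), c(20, 20))
  cp <- tube_copy(dup)
  expect_identical(sort(cp$strands), sort(dup$strands))
  expect_equal(tube_size(dup), 2L)  # original untouched

  expect_identical(tube_detect(new_tube()), "no")
  expect_identical(tube_detect(t1), "yes")

  dead <- tube_discard(t1)
  expect_error(tube_detect(dead), "discarded")
  expect_error(tube_merge(dead, t2), "discarded")
})

test_that("separation splits by motif containment and conserves content", {
  x <- strand_from_text("sA1eB1")
  y <- strand_from_text("sA2eB2")
  tb <- new_tube(c(x, y), c(20, 20))
  parts <- separation(tb, c("e", "B1"))
  expect_identical(parts$matched$strands, x)
  expect_identical(parts$remaining$strands, y)

  # universal motif: every pool strand contains the start delimiter
  pool <- anneal_ligate_pool(2, 3, k = 3)
  all_in <- separation(pool, "s")
  expect_equal(tube_size(all_in$matched), 216L)
  expect_equal(tube_size(all_in$remaining), 0L)

  expect_error(separation(tb, character()), "empty motif")
})

test_that("a job motif over the full 2x3 pool matches the enumerative count", {
  # independent count: triples over the 6 edge types containing a job-2 edge
  grid <- expand.grid(e1 = 1:6, e2 = 1:6, e3 = 1:6)
  job <- rep(1:3, times = 2)  # job index of each edge type
  expected <- sum(job[grid$e1] == 2 | job[grid$e2] == 2 | job[grid$e3] == 2)
  expect_equal(expected, 216 - 4^3)

  pool <- anneal_ligate_pool(2, 3, k = 3)
  parts <- separation(pool, c("e", "B2"))
  expect_equal(tube_size(parts$matched), expected)
  expect_equal(tube_size(parts$matched) + tube_size(parts$remaining), 216L)
})

test_that("selection keeps exactly the strands of the requested length", {
  short <- strand_from_text("sA1eB1sA1eB2")
  long <- strand_from_text("sA1eB1sA1eB2sA2eB3")
  tb <- new_tube(c(short, long, long), c(40, 60, 60))
  sel <- selection(tb, 60)
  expect_equal(tube_size(sel$selected), 2L)
  expect_identical(unique(sel$selected$strands), long)
  expect_identical(sel$remaining$strands, short)

  empty <- selection(new_tube(), 60)
  expect_equal(tube_size(empty$selected), 0L)
  expect_error(selection(tb, 0), "positive")
})

test_that("sort_split partitions by extreme lengths", {
  s <- vapply(1:3, function(i) strand_from_text(paste0("sA1eB", i)),
              character(1))
  three <- sort_split(new_tube(s, c(58, 60, 62)))
  expect_equal(three$shortest$lengths, 58)
  expect_equal(three$longest$lengths, 62)
  expect_equal(three$rest$lengths, 60)

  two <- sort_split(new_tube(s[c(1, 2, 2)], c(60, 65, 65)))
  expect_equal(tube_size(two$shortest), 1L)
  expect_equal(tube_size(two$longest), 2L)
  expect_equal(tube_size(two$rest), 0L)

  # single length class: everything is reported as shortest
  flat <- sort_split(new_tube(s[c(1, 1, 1, 1)], rep(60, 4)))
  expect_equal(tube_size(flat$shortest), 4L)
  expect_equal(tube_size(flat$longest), 0L)

  expect_error(sort_split(new_tube()), "nothing to sort")
})

test_that("append_tail grows every strand by the atom's length", {
  tb <- new_tube(strand_from_text("sA1eB3"), 20)
  out <- append_tail(tb, symbol_atom("WT", i = 1, j = 3, length_mer = 1))
  expect_identical(strand_to_text(out$strands), "sA1eB3w13")
  expect_equal(out$lengths, 21)
  expect_equal(tube_size(append_tail(new_tube(),
                                     symbol_atom("WT", i = 1, j = 1,
                                                 length_mer = 2))), 0L)
})

test_that("anneal_ligate_pool builds the complete k-edge pool", {
  one <- anneal_ligate_pool(1, 1, k = 1)
  expect_identical(one$strands, strand_from_text("sA1eB1"))

  pool <- anneal_ligate_pool(2, 3, k = 3)
  expect_equal(tube_size(pool), 6^3)
  expect_equal(length(unique(pool$strands)), 6^3)
  expect_true(all(pool$lengths == 4 * 3 * 5))
  expect_error(anneal_ligate_pool(2, 3, k = 0), "k must be")
})

test_that("tube_read is deterministic with a lexicographic tie-break", {
  x <- strand_from_text("sA1eB1")
  expect_identical(tube_read(new_tube(x, 20)), x)
  expect_error(tube_read(new_tube()), "no strand to read")

  sols <- vapply(solution_strands_2x3(), strand_from_text, character(1))
  tb <- new_tube(unname(sols), rep(64, length(sols)))
  expected <- sort(unname(sols), method = "radix")[1L]
  expect_identical(tube_read(tb), expected)
  expect_identical(strand_to_text(tube_read(tb)),
                   "sA1eB3sA2eB1sA2eB2w13w21w22")
})

test_that("splitting operations conserve the multiset exactly", {
  set.seed(42)
  pool <- anneal_ligate_pool(2, 3, k = 3)
  idx <- sample.int(tube_size(pool), 80, replace = TRUE)  # with duplicates
  tb <- new_tube(pool$strands[idx], pool$lengths[idx])
  for (motif in list(c("e", "B1"), c("s", "A2", "e"), "B3")) {
    parts <- separation(tb, motif)
    expect_same_multiset(tube_merge(parts$matched, parts$remaining), tb)
  }
  sel <- selection(tb, 60)
  expect_same_multiset(tube_merge(sel$selected, sel$remaining), tb)
  srt <- sort_split(tb)
  expect_same_multiset(
    tube_merge(tube_merge(srt$shortest, srt$longest), srt$rest), tb)
})

test_that("operations preserve the strand grammar", {
  C <- costs_2x3()
  pool <- generate_pool(2, 3)
  weighted <- append_weights(filter_individuals(filter_jobs(pool, 3), 2), C)
  # every strand still parses and decodes
  for (s in weighted$strands[seq(1, tube_size(weighted), by = 7)]) {
    dec <- decode_assignment(s, C)
    expect_true(is_feasible(dec$job_to_individual, 2, 3))
  }
})

test_that("op counting: one increment per primitive, monotone tube history", {
  ctr <- new_op_counter()
  tb <- new_tube(strand_from_text("sA1eB1"), 20)
  tube_detect(tb, counter = ctr)
  parts <- separation(tb, "s", counter = ctr)
  sel <- selection(parts$matched, 20, counter = ctr)
  expect_equal(op_count(ctr), 3L)
  expect_true(sel$selected$op_count >= parts$matched$op_count)
  expect_true(parts$matched$op_count >= tb$op_count)
})
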