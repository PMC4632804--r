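# Constraint-based codeword design, encoding, and the FASTA interface.

test_that("the run constraint bans runs longer than four, not runs of four", {
  expect_true(word_satisfies("TAAAA"))
  expect_false(word_satisfies("AAAAA"))
  expect_false(word_satisfies("AGGGGGA", constraint_set(alphabet = c("A", "G"),
                                                        max_run = 4)))
  expect_false(word_satisfies("CTATG"))  # G outside the default alphabet
})

test_that("gen_codeword is deterministic under a seed and honors constraints", {
  w1 <- gen_codeword(5, seed = 101)
  w2 <- gen_codeword(5, seed = 101)
  expect_identical(w1, w2)
  expect_equal(nchar(w1), 5L)
  expect_true(word_satisfies(w1))
  expect_error(gen_codeword(2, constraint_set(alphabet = "A", max_run = 1,
                                              max_mutations = 50)),
               "design failed after threshold")
})

test_that("build_code produces a full, valid vocabulary in labeled mode", {
  code <- build_code(m = 3, n = 5, t = 5, seed = 7)
  expect_length(code$words, 2 + 3 + 5 + 15)
  expect_true(all(nchar(code$words) == 5))
  expect_false(anyDuplicated(code$words) > 0)
  expect_equal(nrow(validate_code(code)), 0L)
})

test_that("algorithmic mode encodes cost as word length, zero cost as empty", {
  C <- costs_2x3()
  code <- build_code(C, mode = "algorithmic", seed = 3)
  for (i in 1:2) for (j in 1:3)
    expect_equal(nchar(code$words[[paste0("w_", i, "_", j)]]), C[i, j])
  Cz <- as_cost_matrix(rbind(c(0, 2, 1), c(1, 0, 3)))
  codez <- build_code(Cz, mode = "algorithmic", seed = 3)
  expect_identical(codez$words[["w_1_1"]], "")
  expect_equal(nrow(validate_code(codez)), 0L)  # empty words exempt
})

test_that("validate_code flags the single duplicated word of the bundled set", {
  code <- bundled_code()
  v <- validate_code(code)
  expect_equal(nrow(v), 1L)
  expect_identical(v$constraint, "distinctness")
  expect_identical(v$words, "w_1_3/w_2_4")
  # aside from that duplicate, alphabet and run rules hold throughout
  expect_false(any(v$constraint %in% c("alphabet", "homopolymer_run")))
  expect_true(all(vapply(code$words, word_satisfies, logical(1))))
})

test_that("probe G-count checking is available for longer probes", {
  code <- build_code(m = 2, n = 3, t = 5, seed = 5)
  cs <- constraint_set(probe_g_range = c(4, 6))
  v <- validate_code(code, cs)
  # 5-mer library words over A/T/C have all-A/T/G probes with G = #C <= 5;
  # the rule must report, per job, when the count falls outside 4..6
  counts <- vapply(1:3, function(j) {
    w <- strsplit(code$words[[paste0("B", j)]], "")[[1]]
    sum(w == "C")
  }, numeric(1))
  expect_equal(sum(v$constraint == "probe_g_count"),
               sum(counts < 4 | counts > 6))
})

test_that("encode_strand concatenates code words and errors on gaps", {
  code <- bundled_code()
  expect_identical(encode_strand(strand_from_text("sA1eB1"), code),
                   "CTATCTAAAAAACTCAATTA")
  small <- build_code(m = 1, n = 2, seed = 2)
  expect_error(encode_strand(strand_from_text("sA3eB1"), small),
               "no code word")
})

test_that("encode/decode round-trips every pipeline strand", {
  C <- costs_2x3()
  sol <- solve_uap(C)$solution_tube
  lab <- build_code(C, mode = "labeled", seed = 11)
  alg <- build_code(C, mode = "algorithmic", seed = 12)
  for (s in sol$strands) {
    expect_identical(decode_sequence(encode_strand(s, lab), lab), s)
    expect_identical(decode_sequence(encode_strand(s, alg), alg), s)
  }
})

test_that("encoded base length equals symbolic strand length in mer", {
  C <- costs_2x3()
  stage3 <- filter_individuals(filter_jobs(generate_pool(2, 3), 3), 2)
  weighted <- append_weights(stage3, C)
  code <- build_code(C, mode = "algorithmic", seed = 13)
  enc <- vapply(weighted$strands, encode_strand, character(1), code = code)
  expect_equal(unname(nchar(enc)), weighted$lengths)
})

test_that("linkers are junction reverse-complements, probes the job words", {
  expect_identical(revcomp("AACTC"), "GAGTT")
  x <- c("CTATC", "TTAAC")
  expect_identical(revcomp(revcomp(x)), x)

  code <- bundled_code()
  q <- linker_and_probe_set(code)
  expect_length(q, 2 * code$n)
  expect_identical(unname(q[paste0("probe_j", 1:5)]),
                   unname(code$words[paste0("B", 1:5)]))
  expect_identical(q[["linker_j1"]],
                   revcomp(paste0(code$words[["e"]], code$words[["B1"]],
                                  code$words[["s"]])))
})

test_that("codes survive a FASTA write/read round trip", {
  path <- withr::local_tempfile(fileext = ".fasta")
  code <- build_code(m = 2, n = 3, seed = 9)
  write_code_fasta(code, path)
  back <- read_code_fasta(path)
  expect_identical(back$words[names(code$words)], code$words)
  expect_equal(back$m, 2L)
  expect_equal(back$n, 3L)
})
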