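# Reference instances and their published strand listings, used across tests.

costs_3x5 <- function() {
  as_cost_matrix(rbind(c(5, 9, 1, 2, 7),
                       c(9, 8, 6, 4, 4),
                       c(4, 7, 8, 5, 2)))
}

costs_2x3 <- function() {
  as_cost_matrix(rbind(c(2, 4, 1),
                       c(1, 2, 3)))
}

# The known optimum of the 3x5 instance: j3,j4 -> i1; j2 -> i2; j1,j5 -> i3.
optimum_3x5 <- function() c(3L, 2L, 1L, 1L, 3L)

# The 36 surjective, job-complete strands of the 2x3 instance (stage 3 of
# the pipeline), in compact text notation.
stage3_strands_2x3 <- function() c(
  "sA1eB1sA1eB2sA2eB3", "sA1eB1sA1eB3sA2eB2", "sA1eB1sA2eB2sA1eB3",
  "sA1eB1sA2eB2sA2eB3", "sA1eB1sA2eB3sA1eB2", "sA1eB1sA2eB3sA2eB2",
  "sA1eB2sA1eB1sA2eB3", "sA1eB2sA1eB3sA2eB1", "sA1eB2sA2eB1sA1eB3",
  "sA1eB2sA2eB1sA2eB3", "sA1eB2sA2eB3sA1eB1", "sA1eB2sA2eB3sA2eB1",
  "sA1eB3sA1eB1sA2eB2", "sA1eB3sA1eB2sA2eB1", "sA1eB3sA2eB1sA1eB2",
  "sA1eB3sA2eB1sA2eB2", "sA1eB3sA2eB2sA1eB1", "sA1eB3sA2eB2sA2eB1",
  "sA2eB1sA1eB2sA1eB3", "sA2eB1sA1eB2sA2eB3", "sA2eB1sA1eB3sA1eB2",
  "sA2eB1sA1eB3sA2eB2", "sA2eB1sA2eB2sA1eB3", "sA2eB1sA2eB3sA1eB2",
  "sA2eB2sA1eB1sA1eB3", "sA2eB2sA1eB1sA2eB3", "sA2eB2sA1eB3sA1eB1",
  "sA2eB2sA1eB3sA2eB1", "sA2eB2sA2eB1sA1eB3", "sA2eB2sA2eB3sA1eB1",
  "sA2eB3sA1eB1sA1eB2", "sA2eB3sA1eB1sA2eB2", "sA2eB3sA1eB2sA1eB1",
  "sA2eB3sA1eB2sA2eB1", "sA2eB3sA2eB1sA1eB2", "sA2eB3sA2eB2sA1eB1")

# The six weighted solution strands of the 2x3 instance (stage 5).
solution_strands_2x3 <- function() c(
  "sA1eB3sA2eB1sA2eB2w13w21w22", "sA1eB3sA2eB2sA2eB1w13w21w22",
  "sA2eB1sA1eB3sA2eB2w13w21w22", "sA2eB1sA2eB2sA1eB3w13w21w22",
  "sA2eB2sA1eB3sA2eB1w13w21w22", "sA2eB2sA2eB1sA1eB3w13w21w22")

# The published nucleotide encodings of all 15 edge strands of the 3x5
# instance under the bundled codeword set.
edge_sequences_3x5 <- function() c(
  sA1eB1 = "CTATCTAAAAAACTCAATTA", sA1eB2 = "CTATCTAAAAAACTCCATTA",
  sA1eB3 = "CTATCTAAAAAACTCATCTA", sA1eB4 = "CTATCTAAAAAACTCCAAAC",
  sA1eB5 = "CTATCTAAAAAACTCATCCA", sA2eB1 = "CTATCCTTTTAACTCAATTA",
  sA2eB2 = "CTATCCTTTTAACTCCATTA", sA2eB3 = "CTATCCTTTTAACTCATCTA",
  sA2eB4 = "CTATCCTTTTAACTCCAAAC", sA2eB5 = "CTATCCTTTTAACTCATCCA",
  sA3eB1 = "CTATCTTCAAAACTCAATTA", sA3eB2 = "CTATCTTCAAAACTCCATTA",
  sA3eB3 = "CTATCTTCAAAACTCATCTA", sA3eB4 = "CTATCTTCAAAACTCCAAAC",
  sA3eB5 = "CTATCTTCAAAACTCATCCA")

# The published 125-base encoding of the 3x5 optimum's canonical strand
# (edges and weight tails in row-major (i, j) order).
solution_sequence_3x5 <- function() paste0(
  "CTATCTAAAAAACTCATCTACTATCTAAAAAACTCCAAAC",
  "CTATCCTTTTAACTCCATTACTATCTTCAAAACTCAATTA",
  "CTATCTTCAAAACTCATCCATTACATACCCATAATCCTTCTTAAC")

bundled_code <- function() {
  read_code_fasta(system.file("extdata", "codewords_3x5.fasta",
                              package = "dnassign"))
}

# multiset equality of two tubes' strand contents
expect_same_multiset <- function(a, b) {
  expect_identical(sort(a$strands, method = "radix"),
                   sort(b$strands, method = "radix"))
}

# canonical key of an assignment for set comparison
assignment_key <- function(a) paste(a, collapse = ",")
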