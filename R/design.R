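#' Constraint set for DNA codeword design
#'
#' The library strands are designed to hybridize cleanly with their probes:
#' \itemize{
#'   \item library words use a three-letter alphabet (A, T, C by default) —
#'     leaving G out of the library lowers secondary structure and reserves
#'     G-rich complements for the probes;
#'   \item no homopolymer run longer than `max_run` bases (default 4; a run
#'     of exactly four is allowed), keeping melting temperatures similar and
#'     avoiding unusual secondary structure;
#'   \item optionally, each probe must carry a G count within
#'     `probe_g_range` (classically 4-6 for longer probes; off by default,
#'     since 5-mer units cannot generally satisfy it);
#'   \item all words pairwise distinct, so motif separation is unambiguous.
#' }
#'
#' @param alphabet allowed library bases
#' @param max_run longest allowed homopolymer run
#' @param probe_g_range `NULL`, or `c(min, max)` G-count required of each
#'   probe (checked on job-word complements)
#' @param require_distinct enforce pairwise distinctness of words
#' @param max_mutations give up on a word after this many single-base
#'   mutations
#' @return a `constraint_set` object
#' @export
constraint_set <- function(alphabet = c("A", "T", "C"), max_run = 4,
                           probe_g_range = NULL, require_distinct = TRUE,
                           max_mutations = 1000L) {
  if (length(alphabet) == 0L || !all(alphabet %in% c("A", "C", "G", "T")))
    stop("alphabet must be a nonempty subset of A, C, G, T")
  if (max_run < 1) stop("max_run must be >= 1")
  if (!is.null(probe_g_range)) stopifnot(length(probe_g_range) == 2L)
  structure(list(alphabet = alphabet, max_run = as.integer(max_run),
                 probe_g_range = probe_g_range,
                 require_distinct = isTRUE(require_distinct),
                 max_mutations = as.integer(max_mutations)),
            class = "constraint_set")
}

# longest homopolymer run of a word ("" -> 0)
max_homopolymer <- function(word) {
  if (!nzchar(word)) return(0L)
  max(rle(strsplit(word, "", fixed = TRUE)[[1L]])$lengths)
}

#' Does a single word satisfy the alphabet and run constraints?
#'
#' @param word a nucleotide string
#' @param cs a [constraint_set()]
#' @return `TRUE` or `FALSE` (distinctness and probe rules are code-level
#'   checks; see [validate_code()])
#' @examples
#' word_satisfies("TAAAA")   # run of four: allowed
#' word_satisfies("AAAAA")   # run of five: rejected
#' @export
word_satisfies <- function(word, cs = constraint_set()) {
  chars <- strsplit(word, "", fixed = TRUE)[[1L]]
  all(chars %in% cs$alphabet) && max_homopolymer(word) <= cs$max_run
}

word_ok <- word_satisfies

#' Generate one codeword under the design constraints
#'
#' A random candidate word is drawn from the allowed alphabet and greedily
#' accepted if it satisfies the constraints; otherwise single-base mutations
#' are introduced one at a time until the constraints are met or
#' `max_mutations` is reached (then the design fails with an error). Given
#' the same RNG state (or `seed`) the same word is produced.
#'
#' @param t word length in bases (>= 1)
#' @param cs a [constraint_set()]
#' @param seed optional integer seed
#' @param avoid character vector of words the new word must differ from
#' @return a t-base word satisfying `cs`
#' @examples
#' gen_codeword(5, seed = 1)
#' @export
gen_codeword <- function(t, cs = constraint_set(), seed = NULL,
                         avoid = character()) {
  if (t < 1) stop("t must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  word <- sample(cs$alphabet, t, replace = TRUE)
  ok <- function(w) {
    s <- paste(w, collapse = "")
    word_ok(s, cs) && !(cs$require_distinct && s %in% avoid)
  }
  mutations <- 0L
  while (!ok(word)) {
    if (mutations >= cs$max_mutations)
      stop("design failed after threshold of ", cs$max_mutations,
           " mutations")
    pos <- sample.int(t, 1L)
    word[pos] <- sample(cs$alphabet, 1L)
    mutations <- mutations + 1L
  }
  paste(word, collapse = "")
}

#' Build a DNA code for an assignment instance
#'
#' Generates concrete nucleotide words for every symbol the pipeline uses:
#' the delimiters `s` and `e`, individuals `A1..Am`, jobs `B1..Bn`, and the
#' weight words `w_i_j`. Weight words come in two modes:
#' \describe{
#'   \item{`"algorithmic"`}{(length-encoded) `w_i_j` has length
#'     `costs[i,j] * u` bases, as the length-selection algorithm requires; a
#'     zero cost yields an empty word. Cost is carried by *length*, so
#'     weight words are exempt from the pairwise-distinctness rule (equal
#'     small costs over a three-letter alphabet could not otherwise be
#'     encoded).}
#'   \item{`"labeled"`}{every weight word is a t-mer like the rest of the
#'     vocabulary and distinctness applies to all words; this is the
#'     bookkeeping form used for printed tables and wet-lab export.}
#' }
#'
#' @param costs cost matrix; may be `NULL` in labeled mode if `m` and `n`
#'   are given
#' @param m,n instance dimensions (taken from `costs` when supplied)
#' @param t unit word length in bases
#' @param u bases per unit cost (algorithmic mode)
#' @param mode `"labeled"` or `"algorithmic"`
#' @param cs a [constraint_set()]
#' @param seed optional integer seed
#' @return a `dna_code` object: list with `words` (named character vector,
#'   names `s`, `e`, `A1..Am`, `B1..Bn`, `w_i_j`), `t`, `u`, `mode`, `m`, `n`
#' @examples
#' code <- build_code(m = 2, n = 3, seed = 1)
#' code$words[c("s", "e", "A1", "B1")]
#' @export
build_code <- function(costs = NULL, m = NULL, n = NULL, t = 5, u = 1,
                       mode = c("labeled", "algorithmic"),
                       cs = constraint_set(), seed = NULL) {
  mode <- match.arg(mode)
  if (!is.null(costs)) {
    costs <- as_cost_matrix(costs)
    m <- nrow(costs); n <- ncol(costs)
  }
  if (is.null(m) || is.null(n)) stop("supply `costs` or both `m` and `n`")
  if (mode == "algorithmic" && is.null(costs))
    stop("algorithmic (length-encoded) mode needs the cost matrix")
  if (!is.null(seed)) set.seed(seed)

  ids <- c("s", "e", paste0("A", seq_len(m)), paste0("B", seq_len(n)))
  words <- character(0)
  for (id in ids) {
    words[id] <- gen_codeword(t, cs, avoid = words)
  }
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      id <- paste0("w_", i, "_", j)
      if (mode == "labeled") {
        words[id] <- gen_codeword(t, cs, avoid = words)
      } else {
        len <- costs[i, j] * u
        words[id] <- if (len == 0) "" else gen_codeword(len, cs)
      }
    }
  }
  structure(list(words = words, t = t, u = u, mode = mode, m = m, n = n),
            class = "dna_code")
}

#' @export
print.dna_code <- function(x, ...) {
  cat(sprintf("<dna_code: %d words, t = %d, mode = %s, %d x %d instance>\n",
              length(x$words), x$t, x$mode, x$m, x$n))
  utils::str(utils::head(x$words, 8))
  invisible(x)
}

#' Validate a DNA code against a constraint set
#'
#' Checks every word for alphabet membership and homopolymer runs, all
#' nonempty words for pairwise distinctness (weight words are exempt in
#' length-encoded codes, where the tail's identity carries no information),
#' and, when `probe_g_range` is set, the G count of each job probe (the
#' complement of the job word).
#'
#' @param code a `dna_code`
#' @param cs a [constraint_set()]
#' @return a data frame of violations with columns `constraint`, `words`,
#'   `detail`; zero rows means the code is valid
#' @export
validate_code <- function(code, cs = constraint_set()) {
  stopifnot(inherits(code, "dna_code"))
  v <- list()
  add <- function(constraint, words, detail)
    v[[length(v) + 1L]] <<- data.frame(constraint = constraint,
                                       words = words, detail = detail)
  for (id in names(code$words)) {
    w <- code$words[[id]]
    if (!nzchar(w)) next
    chars <- strsplit(w, "", fixed = TRUE)[[1L]]
    bad <- setdiff(unique(chars), cs$alphabet)
    if (length(bad))
      add("alphabet", id, paste0(w, " uses ", paste(bad, collapse = ",")))
    run <- max_homopolymer(w)
    if (run > cs$max_run)
      add("homopolymer_run", id, paste0(w, " has a run of ", run))
  }
  if (cs$require_distinct) {
    w <- code$words
    if (code$mode == "algorithmic")
      w <- w[!grepl("^w_", names(w))]
    w <- w[nzchar(w)]
    dup_vals <- unique(w[duplicated(w)])
    for (val in dup_vals)
      add("distinctness", paste(names(w)[w == val], collapse = "/"),
          paste0("shared word ", val))
  }
  if (!is.null(cs$probe_g_range)) {
    for (j in seq_len(code$n)) {
      id <- paste0("B", j)
      probe <- revcomp(code$words[[id]])
      g <- sum(strsplit(probe, "", fixed = TRUE)[[1L]] == "G")
      if (g < cs$probe_g_range[1L] || g > cs$probe_g_range[2L])
        add("probe_g_count", id,
            paste0("probe ", probe, " has ", g, " G"))
    }
  }
  if (length(v) == 0L)
    return(data.frame(constraint = character(), words = character(),
                      detail = character()))
  do.call(rbind, v)
}

#' Encode a symbolic strand as nucleotides
#'
#' Concatenates the code words of the strand's atoms in order. Strings are
#' kept in the 3'-5' orientation in which the code words are written; use
#' [revcomp()] for the opposite strand.
#'
#' @param strand a strand (internal dotted form)
#' @param code a `dna_code` covering every atom of the strand
#' @return a nucleotide string
#' @examples
#' code <- build_code(m = 2, n = 3, seed = 1)
#' encode_strand(strand_from_text("sA1eB1"), code)
#' @export
encode_strand <- function(strand, code) {
  stopifnot(inherits(code, "dna_code"))
  toks <- strand_atoms(strand)
  missing <- setdiff(toks, names(code$words))
  if (length(missing))
    stop("no code word for atom(s): ", paste(missing, collapse = ", "))
  paste(code$words[toks], collapse = "")
}

#' Decode a nucleotide string back to a symbolic strand
#'
#' Parses the edge region positionally (each edge is `4 t` bases: `s`, an
#' individual word, `e`, a job word) and then the weight tail. The tail is
#' matched first against the expectation set by the grammar — one weight
#' word per decoded edge, in row-major (i, j) order, as the pipeline appends
#' them — and falls back to greedy longest-word matching for other layouts.
#' Zero-length weight words (zero costs in length-encoded codes) are
#' unrecoverable from the nucleotide string and are skipped.
#'
#' @param seq nucleotide string
#' @param code the `dna_code` used for encoding
#' @return the strand in internal dotted form
#' @export
decode_sequence <- function(seq, code) {
  stopifnot(inherits(code, "dna_code"))
  t <- code$t
  words <- code$words
  toks <- character(0)
  pos <- 1L
  n_total <- nchar(seq)
  lookup <- function(chunk, subset) {
    hit <- names(subset)[subset == chunk]
    if (length(hit) == 0L) stop("cannot decode chunk ", chunk)
    hit[1L]
  }
  a_words <- words[grepl("^A", names(words))]
  b_words <- words[grepl("^B", names(words))]
  while (pos + t - 1L <= n_total &&
         substr(seq, pos, pos + t - 1L) == words[["s"]]) {
    if (pos + 4L * t - 1L > n_total) stop("truncated edge unit")
    toks <- c(toks, "s",
              lookup(substr(seq, pos + t, pos + 2L * t - 1L), a_words))
    if (substr(seq, pos + 2L * t, pos + 3L * t - 1L) != words[["e"]])
      stop("expected delimiter e at position ", pos + 2L * t)
    toks <- c(toks, "e",
              lookup(substr(seq, pos + 3L * t, pos + 4L * t - 1L), b_words))
    pos <- pos + 4L * t
  }
  if (length(toks) == 0L) stop("sequence does not start with an edge unit")
  tail_seq <- substr(seq, pos, n_total)
  # expected tail: weight word per decoded edge, row-major (i, j)
  ii <- as.integer(sub("^A", "", toks[grepl("^A", toks)]))
  jj <- as.integer(sub("^B", "", toks[grepl("^B", toks)]))
  ord <- order(ii, jj)
  expected <- paste0("w_", ii[ord], "_", jj[ord])
  if (paste(words[expected], collapse = "") == tail_seq)
    return(strand_string(c(toks, expected[nzchar(words[expected])])))
  # fallback: greedy longest-match over weight words
  w_words <- words[grepl("^w_", names(words))]
  w_words <- w_words[order(-nchar(w_words))]
  while (nzchar(tail_seq)) {
    hit <- which(vapply(w_words, function(w)
      nzchar(w) && startsWith(tail_seq, w), logical(1)))
    if (length(hit) == 0L) stop("cannot decode weight tail ", tail_seq)
    toks <- c(toks, names(w_words)[hit[1L]])
    tail_seq <- substr(tail_seq, nchar(w_words[hit[1L]]) + 1L,
                       nchar(tail_seq))
  }
  strand_string(toks)
}

#' Reverse complement of a nucleotide string
#'
#' @param x character vector of nucleotide strings
#' @return the base-wise Watson-Crick reverse complements
#' @examples
#' revcomp("AACTC")  # "GAGTT"
#' @export
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  unname(out)
}

#' Linker and probe oligonucleotides for a code
#'
#' The pool-assembly phase needs, for each job j, the complementary linker
#' spanning the `e B_j s` junction (so consecutive edge units hybridize and
#' can be ligated) and the job probe `B_j` used for motif separation.
#' Returns the reverse complements of the junction words plus the job probe
#' words.
#'
#' @param code a `dna_code`
#' @return named character vector: `linker_j1..jn` (reverse complements of
#'   `e + B_j + s`) followed by `probe_j1..jn` (the job words)
#' @export
linker_and_probe_set <- function(code) {
  stopifnot(inherits(code, "dna_code"))
  jn <- seq_len(code$n)
  junctions <- paste0(code$words[["e"]], code$words[paste0("B", jn)],
                      code$words[["s"]])
  out <- c(revcomp(junctions), unname(code$words[paste0("B", jn)]))
  names(out) <- c(paste0("linker_j", jn), paste0("probe_j", jn))
  out
}

## ---- FASTA input/output -------------------------------------------------

#' Read and write DNA codes as FASTA
#'
#' Record ids follow the vocabulary: `s`, `e`, `A1..Am`, `B1..Bn`, `w_i_j`.
#'
#' @param path FASTA file path
#' @param t unit word length (checked against the non-weight records)
#' @param u bases per unit cost
#' @param mode `"labeled"` or `"algorithmic"` (see [build_code()])
#' @return `read_code_fasta()` returns a `dna_code`;
#'   `write_code_fasta()` returns `path` invisibly
#' @export
read_code_fasta <- function(path, t = NULL, u = 1,
                            mode = c("labeled", "algorithmic")) {
  mode <- match.arg(mode)
  set <- Biostrings::readDNAStringSet(path)
  words <- as.character(set)
  names(words) <- names(set)
  need <- c("s", "e")
  if (!all(need %in% names(words)))
    stop("code FASTA must contain records `s` and `e`")
  m <- sum(grepl("^A[0-9]+$", names(words)))
  n <- sum(grepl("^B[0-9]+$", names(words)))
  if (m == 0L || n == 0L)
    stop("code FASTA must contain A<i> and B<j> records")
  if (is.null(t)) t <- nchar(words[["s"]])
  unit <- c("s", "e", paste0("A", seq_len(m)), paste0("B", seq_len(n)))
  if (any(nchar(words[unit]) != t))
    stop("all unit words must have length t = ", t)
  structure(list(words = words, t = t, u = u, mode = mode, m = m, n = n),
            class = "dna_code")
}

#' @rdname read_code_fasta
#' @param code a `dna_code`
#' @export
write_code_fasta <- function(code, path) {
  stopifnot(inherits(code, "dna_code"))
  w <- code$words[nzchar(code$words)]
  set <- Biostrings::DNAStringSet(w)
  names(set) <- names(w)
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Write a tube's strands as a nucleotide FASTA library
#'
#' Each strand is encoded with the given code and written in the 3'-5'
#' orientation of the code words (noted in the record descriptions).
#'
#' @param tube a `dna_tube`
#' @param code a `dna_code`
#' @param path output FASTA path
#' @return `path`, invisibly
#' @export
write_strand_fasta <- function(tube, code, path) {
  check_tube(tube)
  seqs <- vapply(tube$strands, encode_strand, character(1), code = code)
  set <- Biostrings::DNAStringSet(unname(seqs))
  names(set) <- paste0(vapply(tube$strands, strand_to_text, character(1)),
                       " orientation=3'-5'")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
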