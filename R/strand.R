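#' Symbol atoms and symbolic strands
#'
#' Strands in the simulator are *symbolic*: ordered sequences of symbol atoms
#' rather than nucleotide strings. The atom vocabulary is
#' \describe{
#'   \item{`s`, `e`}{delimiter words marking the start and interior of an
#'     edge unit; both have unit length `t` mer.}
#'   \item{`A1..Am`}{individual words, length `t` mer.}
#'   \item{`B1..Bn`}{job words, length `t` mer.}
#'   \item{`w_i_j`}{weight (cost) words; in length-encoded mode the word for
#'     edge (i,j) has length `c[i,j] * u` mer, so total strand length encodes
#'     total assignment cost.}
#' }
#' A pool strand for an n-job instance follows the grammar
#' `(s A_i e B_j)^k (w_i_j)*`: k edge units, each meaning "job j is assigned
#' to individual i", optionally followed by weight tails.
#'
#' Internally a strand is a single character scalar of dot-delimited tokens
#' with a leading and trailing dot, e.g. `".s.A1.e.B3.s.A2.e.B1.w_1_3."`.
#' This makes motif containment a fixed-substring search, which is what keeps
#' tubes of several hundred thousand strands fast to filter.
#'
#' @param kind one of `"S"`, `"E"`, `"IND"`, `"JOB"`, `"WT"`
#' @param i individual index (IND and WT atoms)
#' @param j job index (JOB and WT atoms)
#' @param t unit word length in mer (all non-weight atoms)
#' @param length_mer explicit atom length in mer (WT atoms)
#' @return `symbol_atom()` returns a list with fields `kind`, `token` and
#'   `length_mer`, of class `"symbol_atom"`.
#' @examples
#' symbol_atom("IND", i = 2)
#' symbol_atom("WT", i = 1, j = 3, length_mer = 4)
#' @export
symbol_atom <- function(kind = c("S", "E", "IND", "JOB", "WT"),
                        i = NULL, j = NULL, t = 5, length_mer = NULL) {
  kind <- match.arg(kind)
  token <- switch(kind,
    S = "s",
    E = "e",
    IND = {
      stopifnot(is.numeric(i), i >= 1)
      paste0("A", as.integer(i))
    },
    JOB = {
      stopifnot(is.numeric(j), j >= 1)
      paste0("B", as.integer(j))
    },
    WT = {
      stopifnot(is.numeric(i), i >= 1, is.numeric(j), j >= 1)
      paste0("w_", as.integer(i), "_", as.integer(j))
    }
  )
  len <- if (kind == "WT") {
    if (is.null(length_mer)) stop("WT atoms need an explicit `length_mer`")
    length_mer
  } else {
    t
  }
  if (len < 0) stop("atom length must be nonnegative")
  structure(list(kind = kind, token = token, length_mer = as.numeric(len)),
            class = "symbol_atom")
}

#' @export
print.symbol_atom <- function(x, ...) {
  cat(sprintf("<atom %s (%s), %g mer>\n", x$token, x$kind, x$length_mer))
  invisible(x)
}

## ---- internal token-string helpers -------------------------------------

# wrap a character vector of tokens into the canonical dotted strand form
strand_string <- function(tokens) {
  paste0(".", paste(tokens, collapse = "."), ".")
}

#' Split a strand into its atom tokens
#'
#' @param strand a strand in internal dotted form (character scalar)
#' @return character vector of tokens, e.g. `c("s","A1","e","B3")`
#' @export
strand_atoms <- function(strand) {
  stopifnot(is.character(strand), length(strand) == 1L)
  toks <- strsplit(strand, ".", fixed = TRUE)[[1L]]
  toks[nzchar(toks)]
}

#' Convert between strand objects and compact text notation
#'
#' The compact notation is the conventional one-line rendering of a strand,
#' e.g. `"sA1eB3sA2eB1sA2eB2w13w21w22"`. It is unambiguous only for
#' single-digit indices (m, n <= 9); use the internal dotted form beyond that.
#'
#' @param text compact strand text
#' @return `strand_from_text()` returns the internal dotted strand string;
#'   `strand_to_text()` the compact rendering.
#' @examples
#' s <- strand_from_text("sA1eB3sA2eB1w13")
#' strand_to_text(s)
#' @export
strand_from_text <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  toks <- regmatches(text, gregexpr("w[0-9][0-9]|A[0-9]+|B[0-9]+|s|e", text))[[1L]]
  if (paste(toks, collapse = "") != text)
    stop("cannot parse strand text: ", text)
  toks <- ifelse(grepl("^w", toks),
                 sub("^w([0-9])([0-9])$", "w_\\1_\\2", toks),
                 toks)
  strand_string(toks)
}

#' @rdname strand_from_text
#' @param strand a strand in internal dotted form
#' @export
strand_to_text <- function(strand) {
  toks <- strand_atoms(strand)
  toks <- sub("^w_([0-9]+)_([0-9]+)$", "w\\1\\2", toks)
  paste(toks, collapse = "")
}

# edge unit token string for (i, j): "s.Ai.e.Bj" (no outer dots)
edge_unit <- function(i, j) paste0("s.A", i, ".e.B", j)

# motif (vector of tokens) -> fixed search pattern in dotted form
motif_pattern <- function(motif) {
  if (length(motif) == 0L || any(!nzchar(motif)))
    stop("empty motif")
  paste0(".", paste(motif, collapse = "."), ".")
}

#' Length of a strand in mer
#'
#' Recomputes the symbolic length of a strand from its atoms: every
#' non-weight atom contributes `t` mer, weight atom `w_i_j` contributes
#' `costs[i, j] * u` mer.
#'
#' @param strand strand in internal dotted form
#' @param t unit word length (mer)
#' @param costs cost matrix (needed only when the strand carries weight atoms)
#' @param u mer per unit cost
#' @return numeric length in mer
#' @export
strand_length <- function(strand, t = 5, costs = NULL, u = 1) {
  toks <- strand_atoms(strand)
  wt <- grepl("^w_", toks)
  len <- sum(!wt) * t
  if (any(wt)) {
    if (is.null(costs)) stop("weight atoms present: `costs` is required")
    idx <- do.call(rbind, lapply(strsplit(toks[wt], "_", fixed = TRUE),
                                 function(p) as.integer(p[2:3])))
    len <- len + sum(costs[idx]) * u
  }
  len
}
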