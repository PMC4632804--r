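#' Test tubes: multisets of symbolic strands
#'
#' A tube is the unit of state in Adleman-Lipton computing: a multiset of
#' single strands. Here it is an S3 object holding a character vector of
#' strand strings (duplicates allowed: the vector *is* the multiset), a
#' parallel numeric vector of strand lengths in mer, and an `op_count` field
#' recording how many primitive tube operations were applied along the tube's
#' history (incremented once per primitive; used for operation-count
#' accounting of the pipeline).
#'
#' Tubes are immutable values: every operation returns new tube objects and
#' leaves its arguments untouched. For the primitives whose laboratory
#' semantics empty an argument tube (Merge, Discard), the caller simply stops
#' using the old handle; `tube_discard()` additionally returns an explicitly
#' dead handle on which further operations raise an error.
#'
#' @param strands character vector of strands in internal dotted form
#' @param lengths numeric vector of strand lengths (mer), parallel to
#'   `strands`
#' @param ops initial operation count
#' @return a `dna_tube` object
#' @seealso [separation()], [selection()], [sort_split()], [append_tail()],
#'   [anneal_ligate_pool()], [tube_read()]
#' @examples
#' tb <- new_tube(c(strand_from_text("sA1eB1"), strand_from_text("sA2eB2")),
#'                lengths = c(20, 20))
#' tube_size(tb)
#' tube_detect(tb)
#' @export
new_tube <- function(strands = character(), lengths = numeric(length(strands)),
                     ops = 0L) {
  if (length(strands) != length(lengths))
    stop("`strands` and `lengths` must be parallel vectors")
  structure(list(strands = as.character(strands),
                 lengths = as.numeric(lengths),
                 op_count = as.integer(ops),
                 discarded = FALSE),
            class = "dna_tube")
}

#' @export
print.dna_tube <- function(x, ...) {
  if (x$discarded) {
    cat("<tube: discarded>\n")
    return(invisible(x))
  }
  cat(sprintf("<tube: %d strand(s), %d op(s) applied>\n",
              length(x$strands), x$op_count))
  show <- utils::head(x$strands, 6L)
  for (s in show) cat("  ", strand_to_text(s), "\n", sep = "")
  if (length(x$strands) > 6L) cat("  ...\n")
  invisible(x)
}

#' Number of strands in a tube
#' @param tube a `dna_tube`
#' @return integer multiset size
#' @export
tube_size <- function(tube) {
  check_tube(tube)
  length(tube$strands)
}

check_tube <- function(tube) {
  if (!inherits(tube, "dna_tube")) stop("not a tube")
  if (isTRUE(tube$discarded)) stop("operation on a discarded tube handle")
  invisible(tube)
}

## ---- operation counting -------------------------------------------------

#' Operation counter for tube primitives
#'
#' An environment-based counter that every tube primitive increments by one
#' when passed via its `counter` argument. [solve_uap()] threads one counter
#' through all five pipeline steps so the total primitive-operation count of
#' a run can be compared with its predicted linear form in m and n.
#'
#' @return an op-counter environment with field `count`
#' @examples
#' ctr <- new_op_counter()
#' tb <- new_tube()
#' tube_detect(tb, counter = ctr)
#' op_count(ctr)
#' @export
new_op_counter <- function() {
  env <- new.env(parent = emptyenv())
  env$count <- 0L
  class(env) <- "op_counter"
  env
}

#' @rdname new_op_counter
#' @param counter an op-counter
#' @export
op_count <- function(counter) counter$count

bump <- function(counter, k = 1L) {
  if (!is.null(counter)) counter$count <- counter$count + as.integer(k)
  invisible(NULL)
}

# derive the op_count carried by tubes produced from inputs `...`
next_ops <- function(..., k = 1L) {
  inputs <- vapply(list(...), function(t) t$op_count, integer(1))
  as.integer(max(0L, inputs) + k)
}

## ---- the primitives -----------------------------------------------------

#' Merge two tubes
#'
#' Stores the multiset union of the two tubes in the returned tube; the
#' laboratory operation leaves the second tube empty, so the caller should
#' drop both old handles.
#'
#' @param t1,t2 tubes
#' @param counter optional [new_op_counter()] to increment
#' @return the union tube
#' @export
tube_merge <- function(t1, t2, counter = NULL) {
  check_tube(t1); check_tube(t2)
  bump(counter)
  new_tube(c(t1$strands, t2$strands), c(t1$lengths, t2$lengths),
           ops = next_ops(t1, t2))
}

#' Copy a tube
#'
#' @inheritParams tube_merge
#' @param tube a tube
#' @return a tube with contents identical to `tube`
#' @export
tube_copy <- function(tube, counter = NULL) {
  check_tube(tube)
  bump(counter)
  new_tube(tube$strands, tube$lengths, ops = next_ops(tube))
}

#' Detect whether a tube holds at least one strand
#'
#' @inheritParams tube_copy
#' @return `"yes"` if the tube is nonempty, `"no"` otherwise
#' @export
tube_detect <- function(tube, counter = NULL) {
  check_tube(tube)
  bump(counter)
  if (length(tube$strands) > 0L) "yes" else "no"
}

#' Discard a tube
#'
#' @inheritParams tube_copy
#' @return an emptied, dead tube handle; any further operation on it errors
#' @export
tube_discard <- function(tube, counter = NULL) {
  check_tube(tube)
  bump(counter)
  out <- new_tube(ops = next_ops(tube))
  out$discarded <- TRUE
  out
}

#' Separate strands by motif containment
#'
#' Splits a tube by whether each strand contains at least one of the given
#' motifs as a contiguous atom subsequence. Both output tubes are returned,
#' so either reading of the operation (keep-if-contains, or remove-and-keep-
#' the-rest) is available to the caller; their multiset union is exactly the
#' input.
#'
#' @param tube a tube
#' @param motifs a character vector of atom tokens (a single motif), or a
#'   list of such vectors
#' @param counter optional op counter
#' @return list with tubes `matched` (strands containing a motif) and
#'   `remaining`
#' @examples
#' tb <- new_tube(c(strand_from_text("sA1eB1"), strand_from_text("sA2eB2")),
#'                c(20, 20))
#' separation(tb, c("e", "B1"))$matched
#' @export
separation <- function(tube, motifs, counter = NULL) {
  check_tube(tube)
  if (!is.list(motifs)) motifs <- list(motifs)
  if (length(motifs) == 0L) stop("empty motif")
  pats <- vapply(motifs, motif_pattern, character(1))
  hit <- rep(FALSE, length(tube$strands))
  for (p in pats) hit <- hit | grepl(p, tube$strands, fixed = TRUE)
  bump(counter)
  ops <- next_ops(tube)
  list(matched  = new_tube(tube$strands[hit],  tube$lengths[hit],  ops = ops),
       remaining = new_tube(tube$strands[!hit], tube$lengths[!hit], ops = ops))
}

#' Select strands of an exact length
#'
#' @param tube a tube
#' @param L target length in mer (> 0)
#' @param counter optional op counter
#' @return list with tubes `selected` (strands of length exactly `L`) and
#'   `remaining`
#' @export
selection <- function(tube, L, counter = NULL) {
  check_tube(tube)
  if (!is.numeric(L) || length(L) != 1L || L <= 0) stop("L must be positive")
  hit <- tube$lengths == L
  bump(counter)
  ops <- next_ops(tube)
  list(selected  = new_tube(tube$strands[hit],  tube$lengths[hit],  ops = ops),
       remaining = new_tube(tube$strands[!hit], tube$lengths[!hit], ops = ops))
}

#' Sort a tube into shortest / longest / remaining strands
#'
#' All strands attaining the minimum length go to `shortest`, all attaining
#' the maximum to `longest`, the rest to `rest`. When every strand shares one
#' length the whole tube is reported as `shortest` and `longest` is empty:
#' the pipeline's only consumer of this operation reads the shortest class.
#'
#' @param tube a nonempty tube
#' @param counter optional op counter
#' @return list of tubes `shortest`, `longest`, `rest`
#' @export
sort_split <- function(tube, counter = NULL) {
  check_tube(tube)
  if (length(tube$strands) == 0L) stop("nothing to sort")
  lo <- min(tube$lengths)
  hi <- max(tube$lengths)
  is_lo <- tube$lengths == lo
  is_hi <- if (hi > lo) tube$lengths == hi else rep(FALSE, length(tube$lengths))
  mid <- !(is_lo | is_hi)
  bump(counter)
  ops <- next_ops(tube)
  list(shortest = new_tube(tube$strands[is_lo], tube$lengths[is_lo], ops = ops),
       longest  = new_tube(tube$strands[is_hi], tube$lengths[is_hi], ops = ops),
       rest     = new_tube(tube$strands[mid],   tube$lengths[mid],   ops = ops))
}

#' Append an atom to the tail of every strand
#'
#' @param tube a tube
#' @param atom a [symbol_atom()]
#' @param counter optional op counter
#' @return tube with `atom` appended to every strand; lengths grow by the
#'   atom's length
#' @export
append_tail <- function(tube, atom, counter = NULL) {
  check_tube(tube)
  if (!inherits(atom, "symbol_atom")) stop("`atom` must be a symbol_atom")
  bump(counter)
  if (length(tube$strands) == 0L)
    return(new_tube(ops = next_ops(tube)))
  new_tube(paste0(tube$strands, atom$token, "."),
           tube$lengths + atom$length_mer,
           ops = next_ops(tube))
}

#' Assemble the combinatorial pool of k-edge strands
#'
#' Models the annealing/ligation/denaturation phase of pool construction:
#' starting from the m*n edge units `s A_i e B_j` and their complementary
#' linkers, hybridization followed by ligation and melting yields (after
#' length selection) exactly the set of all k-fold edge concatenations. The
#' simulator constructs that set directly — all `(m*n)^k` strands — rather
#' than simulating base pairing; the op counter advances by 4 (merge,
#' annealing, ligation, denaturation).
#'
#' @param m number of individuals
#' @param n number of jobs (defines the edge vocabulary `A_1..A_m` x
#'   `B_1..B_n`)
#' @param k number of edges per strand (>= 1)
#' @param t unit word length in mer
#' @param counter optional op counter
#' @return tube of all `(m*n)^k` k-edge strands, each of length `4*k*t` mer
#' @export
anneal_ligate_pool <- function(m, n, k, t = 5, counter = NULL) {
  if (k < 1) stop("k must be >= 1")
  stopifnot(m >= 1, n >= 1)
  ij <- expand.grid(j = seq_len(n), i = seq_len(m))  # row-major in (i, j)
  edges <- edge_unit(ij$i, ij$j)
  # grow the pool one edge position at a time (cheaper than a k-way paste)
  strands <- edges
  for (pos in seq_len(k - 1L))
    strands <- paste0(rep(strands, each = length(edges)), ".", edges)
  strands <- paste0(".", strands, ".")
  bump(counter, 4L)
  new_tube(strands, rep(4 * k * t, length(strands)), ops = 4L)
}

#' Read one strand from a tube
#'
#' Returns exactly one strand. The laboratory operation describes an
#' arbitrary molecule; for reproducibility the simulator breaks the tie
#' deterministically, returning the lexicographically least strand (C-locale
#' ordering of the token-string form).
#'
#' @param tube a nonempty tube
#' @param counter optional op counter
#' @return a single strand (internal dotted form)
#' @export
tube_read <- function(tube, counter = NULL) {
  check_tube(tube)
  if (length(tube$strands) == 0L) stop("no strand to read")
  bump(counter)
  sort(tube$strands, method = "radix")[1L]
}
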