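#' The five-step strand pipeline
#'
#' The molecular algorithm solves an unbalanced assignment instance by brute
#' parallelism over DNA strands:
#' \enumerate{
#'   \item build the pool of all `(m*n)^n` n-edge strands (every way of
#'     writing down n job-to-individual edges);
#'   \item keep strands that mention every job — on n-edge strands this
#'     forces each job to appear exactly once;
#'   \item keep strands that mention every individual at least once
#'     (surjectivity);
#'   \item append, for each edge (i,j) present in a strand, a weight tail of
#'     length `costs[i,j] * u` mer, so strand length = `4*n*t + u * Z` with
#'     Z the assignment cost;
#'   \item extract the shortest strands: they encode exactly the
#'     minimum-cost assignments.
#' }
#' The functions below expose the steps individually; [solve_uap()] runs
#' them in order.
#'
#' @name uap_pipeline
NULL

#' Step 1: generate the combinatorial strand pool
#'
#' @param m individuals
#' @param n jobs (`m < n`)
#' @param t unit word length (mer)
#' @param counter optional op counter
#' @return tube of all `(m*n)^n` n-edge strands of length `4*n*t` mer
#' @export
generate_pool <- function(m, n, t = 5, counter = NULL) {
  if (m >= n) stop("not an unbalanced instance (need m < n)")
  if (m < 1) stop("need at least one individual")
  pool <- anneal_ligate_pool(m, n, k = n, t = t, counter = counter)
  # every assembled strand starts with a delimiter word; retain those, then
  # keep the full-length (n-edge, 4nt-mer) class
  sep <- separation(pool, "s", counter = counter)
  sel <- selection(sep$matched, 4 * n * t, counter = counter)
  sel$selected
}

#' Step 2: require every job exactly once
#'
#' Iterates over jobs k = 1..n, each round keeping the strands that contain
#' the motif `(e, B_k)`; on n-edge strands completeness of all n jobs forces
#' each to occur exactly once. Each round costs 4 primitive operations
#' (separation, discard, copy, discard).
#'
#' @param tube tube of n-edge pool strands
#' @param n number of jobs
#' @param counter optional op counter
#' @return the job-complete tube
#' @export
filter_jobs <- function(tube, n, counter = NULL) {
  t2 <- tube
  for (k in seq_len(n)) {
    parts <- separation(t2, c("e", paste0("B", k)), counter = counter)
    t3 <- parts$matched
    tube_discard(t2, counter = counter)
    t2 <- tube_copy(t3, counter = counter)
    tube_discard(t3, counter = counter)
  }
  t2
}

#' Step 3: require every individual at least once
#'
#' Iterates over individuals k = 1..m keeping strands containing the motif
#' `(s, A_k, e)`; 4 primitive operations per round.
#'
#' @param tube output of [filter_jobs()]
#' @param m number of individuals
#' @param counter optional op counter
#' @return the surjectivity-filtered tube
#' @export
filter_individuals <- function(tube, m, counter = NULL) {
  t2 <- tube
  for (k in seq_len(m)) {
    parts <- separation(t2, c("s", paste0("A", k), "e"), counter = counter)
    t4 <- parts$matched
    tube_discard(t2, counter = counter)
    t2 <- tube_copy(t4, counter = counter)
    tube_discard(t4, counter = counter)
  }
  t2
}

#' Step 4: append cost-encoding weight tails
#'
#' Double loop over edges (i, j), row-major: strands containing edge (i, j)
#' are separated out, get one weight atom `w_i_j` of length `costs[i,j] * u`
#' appended, and are merged back. After the job filter each edge occurs at
#' most once per strand, so each strand ends with one tail atom per edge, in
#' row-major (i, j) order, and final length is `4*n*t + u * Z`.
#'
#' @param tube surjectivity-filtered tube of n-edge strands
#' @param costs validated cost matrix
#' @param u mer per unit cost (>= 1)
#' @param counter optional op counter
#' @return the weighted tube
#' @export
append_weights <- function(tube, costs, u = 1, counter = NULL) {
  costs <- as_cost_matrix(costs)
  if (u < 1 || u != round(u)) stop("u must be a positive integer")
  t2 <- tube
  for (i in seq_len(nrow(costs))) {
    for (j in seq_len(ncol(costs))) {
      parts <- separation(t2, c("s", paste0("A", i), "e", paste0("B", j)),
                          counter = counter)
      t5 <- parts$matched
      t2 <- parts$remaining
      if (tube_detect(t5, counter = counter) == "yes") {
        wt <- symbol_atom("WT", i = i, j = j, length_mer = costs[i, j] * u)
        t5 <- append_tail(t5, wt, counter = counter)
        t2 <- tube_merge(t2, t5, counter = counter)
        tube_discard(t5, counter = counter)
      }
    }
  }
  t2
}

#' Step 5: extract the minimum-length strands
#'
#' @param tube weighted tube (nonempty)
#' @param counter optional op counter
#' @return tube of all strands attaining the minimum length
#' @export
select_shortest <- function(tube, counter = NULL) {
  if (tube_size(tube) == 0L) stop("no feasible assignment")
  sort_split(tube, counter = counter)$shortest
}

#' Decode a strand into a job-to-individual assignment
#'
#' Reads the edges `s A_i e B_j` off a grammar-valid strand and returns the
#' assignment they spell, together with its total cost. All orderings of the
#' same edge set decode to the same assignment.
#'
#' @param strand a strand (internal dotted form); weight tails are ignored
#' @param costs the cost matrix of the instance
#' @return list with `job_to_individual` (integer vector indexed by job) and
#'   `cost`
#' @examples
#' C <- as_cost_matrix(rbind(c(2, 4, 1), c(1, 2, 3)))
#' decode_assignment(strand_from_text("sA1eB3sA2eB1sA2eB2"), C)
#' @export
decode_assignment <- function(strand, costs) {
  costs <- as_cost_matrix(costs, integer_costs = FALSE)
  n <- ncol(costs)
  toks <- strand_atoms(strand)
  toks <- toks[!grepl("^w_", toks)]
  is_i <- grepl("^A", toks)
  is_j <- grepl("^B", toks)
  ii <- as.integer(sub("^A", "", toks[is_i]))
  jj <- as.integer(sub("^B", "", toks[is_j]))
  if (length(ii) != length(jj) || length(jj) == 0L)
    stop("not a valid assignment strand")
  if (anyDuplicated(jj) || !setequal(jj, seq_len(n)))
    stop("not a valid assignment strand: jobs must each occur exactly once")
  if (any(ii > nrow(costs))) stop("individual index outside the instance")
  map <- integer(n)
  map[jj] <- ii
  list(job_to_individual = map, cost = sum(costs[cbind(map, seq_len(n))]))
}

#' Solve an unbalanced assignment instance with the strand pipeline
#'
#' Runs the five steps in order on the full combinatorial pool, decodes all
#' shortest strands, and returns the minimum cost, the set of distinct
#' optimal assignments, the tube sizes after each stage, and the primitive-
#' operation count of the run (which is exactly `8 + 4n + 4m + 5mn`).
#'
#' @param costs cost matrix (coerced via [as_cost_matrix()]; integer costs)
#' @param t unit word length in mer
#' @param u mer per unit cost
#' @param pool_cap refuse instances whose pool `(m*n)^n` exceeds this size
#' @return an object of class `uap_solution`: list with `m`, `n`, `t`, `u`,
#'   `min_cost`, `assignments` (list of integer job-to-individual vectors),
#'   `solution_strand_count`, `stage_counts`, `op_count`, and `read_strand`
#'   (the strand reported by the deterministic [tube_read()])
#' @examples
#' C <- rbind(c(2, 4, 1), c(1, 2, 3))
#' solve_uap(C)
#' @export
solve_uap <- function(costs, t = 5, u = 1, pool_cap = 1e7) {
  costs <- as_cost_matrix(costs)
  m <- nrow(costs); n <- ncol(costs)
  if ((m * n)^n > pool_cap)
    stop("pool size (m*n)^n = ", format((m * n)^n, big.mark = ","),
         " exceeds pool_cap; use brute_force_min() for instances this large")
  ctr <- new_op_counter()
  pool <- generate_pool(m, n, t = t, counter = ctr)
  jobs_ok <- filter_jobs(pool, n, counter = ctr)
  indiv_ok <- filter_individuals(jobs_ok, m, counter = ctr)
  weighted <- append_weights(indiv_ok, costs, u = u, counter = ctr)
  sol <- select_shortest(weighted, counter = ctr)
  best <- tube_read(sol, counter = ctr)

  decoded <- lapply(sol$strands, decode_assignment, costs = costs)
  keys <- vapply(decoded, function(d) paste(d$job_to_individual,
                                            collapse = ","), character(1))
  uniq <- decoded[!duplicated(keys)]
  structure(list(
    m = m, n = n, t = t, u = u,
    min_cost = uniq[[1L]]$cost,
    assignments = lapply(uniq, `[[`, "job_to_individual"),
    solution_strand_count = tube_size(sol),
    stage_counts = c(pool = tube_size(pool),
                     job_filtered = tube_size(jobs_ok),
                     individual_filtered = tube_size(indiv_ok),
                     weighted = tube_size(weighted),
                     solution = tube_size(sol)),
    op_count = op_count(ctr),
    read_strand = best,
    solution_tube = sol
  ), class = "uap_solution")
}

#' @export
print.uap_solution <- function(x, ...) {
  cat(sprintf("Unbalanced assignment: %d individuals x %d jobs\n", x$m, x$n))
  cat(sprintf("  minimum cost Z = %g\n", x$min_cost))
  for (a in x$assignments) {
    parts <- split(seq_along(a), a)
    txt <- vapply(names(parts), function(i)
      sprintf("i%s <- {%s}", i, paste0("j", parts[[i]], collapse = ",")),
      character(1))
    cat("  optimum:", paste(txt, collapse = "  "), "\n")
  }
  cat(sprintf("  solution strands: %d   stage sizes: %s   ops: %d\n",
              x$solution_strand_count,
              paste(x$stage_counts[1:3], collapse = " -> "),
              x$op_count))
  cat("  read:", strand_to_text(x$read_strand), "\n")
  invisible(x)
}
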