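#' Exact brute-force solver for the unbalanced assignment problem
#'
#' Enumerates every onto mapping of the n jobs to the m individuals (m^n
#' candidate mappings, filtered to surjections), evaluates the total cost of
#' each, and returns the minimum together with *all* minimizers. This is the
#' independent oracle against which the strand pipeline is verified: it never
#' touches the tube machinery, so agreement between the two is a genuine
#' cross-check. Real-valued costs are accepted here.
#'
#' @param costs cost matrix (m rows, n columns, `m < n`; real costs allowed)
#' @param cap refuse instances with more than `cap` candidate mappings
#' @return list with `min_cost` and `optima`, a list of integer
#'   job-to-individual vectors (job j is assigned to individual `optima[[k]][j]`)
#' @examples
#' brute_force_min(rbind(c(2, 4, 1), c(1, 2, 3)))
#' @export
brute_force_min <- function(costs, cap = 1e7) {
  costs <- as_cost_matrix(costs, integer_costs = FALSE)
  m <- nrow(costs); n <- ncol(costs)
  if (m^n > cap) stop("m^n too large for exhaustive enumeration")
  grid <- as.matrix(do.call(expand.grid,
                            c(rep(list(seq_len(m)), n),
                              list(KEEP.OUT.ATTRS = FALSE))))
  onto <- rowSums(vapply(seq_len(m), function(i) rowSums(grid == i) > 0,
                         logical(nrow(grid)))) == m
  grid <- grid[onto, , drop = FALSE]
  z <- rowSums(vapply(seq_len(n), function(j) costs[grid[, j], j],
                      numeric(nrow(grid))))
  best <- min(z)
  opt <- grid[z == best, , drop = FALSE]
  list(min_cost = best,
       optima = lapply(seq_len(nrow(opt)),
                       function(r) as.integer(opt[r, ])))
}

#' Number of onto mappings from n jobs to m individuals
#'
#' Inclusion-exclusion count of surjections,
#' `sum_k (-1)^k C(m,k) (m-k)^n`; returns 0 when `m > n`.
#'
#' @param m individuals
#' @param n jobs
#' @return the surjection count (numeric, exact for the sizes in scope)
#' @examples
#' surjection_count(2, 3)  # 6
#' surjection_count(3, 5)  # 150
#' @export
surjection_count <- function(m, n) {
  stopifnot(m >= 1, n >= 1)
  if (m > n) return(0)
  k <- 0:m
  sum((-1)^k * choose(m, k) * (m - k)^n)
}

#' Closed-form tube sizes after pipeline stages 1-3
#'
#' Stage 1 holds all `(m*n)^n` edge sequences; stage 2 the job-complete ones,
#' `n! * m^n` (each job placed once in some order, each independently given
#' an individual); stage 3 the surjective ones, `n! * surjection_count(m,n)`.
#'
#' @param m individuals
#' @param n jobs (`m < n`)
#' @return named numeric vector with elements `pool`, `job_filtered`,
#'   `individual_filtered`
#' @examples
#' stage_counts(2, 3)  # 216 48 36
#' @export
stage_counts <- function(m, n) {
  if (m >= n) stop("not an unbalanced instance (need m < n)")
  c(pool = (m * n)^n,
    job_filtered = factorial(n) * m^n,
    individual_filtered = factorial(n) * surjection_count(m, n))
}

#' Feasibility of an assignment
#'
#' An assignment is feasible when every job maps to exactly one individual in
#' `1..m` and every individual's load lies in `[1, n - m + 1]` (the upper
#' bound follows from all loads being >= 1 and summing to n).
#'
#' @param assignment integer vector of length n; element j is the individual
#'   of job j
#' @param m individuals
#' @param n jobs
#' @return `TRUE` or `FALSE`
#' @export
is_feasible <- function(assignment, m, n) {
  assignment <- as.integer(assignment)
  if (length(assignment) != n) stop("assignment must cover jobs 1..n")
  if (anyNA(assignment)) stop("assignment must cover jobs 1..n")
  if (any(assignment < 1L | assignment > m)) return(FALSE)
  loads <- tabulate(assignment, nbins = m)
  all(loads >= 1L) && all(loads <= n - m + 1L)
}
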