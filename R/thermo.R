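#' Nearest-neighbor duplex parameters
#'
#' Loads a nearest-neighbor parameter table: enthalpy and entropy
#' contributions of the 16 stacked dinucleotides plus the two duplex
#' initiation terms (one per terminal A·T or G·C pair). The default table is
#' the unified oligonucleotide parameter set of SantaLucia (1998), shipped
#' as a plain-text TSV; any table in the same format can be supplied, which
#' keeps the thermodynamic layer pluggable.
#'
#' Values in the file follow the standard sign convention (negative =
#' favorable binding); [duplex_energy()] reports positive binding
#' magnitudes.
#'
#' @param path TSV file with columns `param`, `dH_kcal_mol`, `dS_cal_molK`;
#'   default is the table shipped with the package
#' @return an `nn_params` object: list with `stack_dH`, `stack_dS` (named
#'   over the 16 dinucleotides), `init_dH`, `init_dS` (named `AT`, `GC`) and
#'   `label`
#' @export
nn_params <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "nn_stacks.tsv", package = "dnassign",
                        mustWork = TRUE)
    label <- "unified SantaLucia 1998"
  } else {
    label <- basename(path)
  }
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stacks <- tab[!grepl("^init_", tab$param), ]
  if (nrow(stacks) != 16L || anyDuplicated(stacks$param))
    stop("parameter table must cover the 16 dinucleotide stacks")
  inits <- tab[grepl("^init_", tab$param), ]
  structure(list(
    stack_dH = stats::setNames(stacks$dH_kcal_mol, stacks$param),
    stack_dS = stats::setNames(stacks$dS_cal_molK, stacks$param),
    init_dH = stats::setNames(inits$dH_kcal_mol, sub("^init_", "", inits$param)),
    init_dS = stats::setNames(inits$dS_cal_molK, sub("^init_", "", inits$param)),
    label = label
  ), class = "nn_params")
}

terminal_class <- function(base) if (base %in% c("A", "T")) "AT" else "GC"

#' Duplex binding energies of a perfect-match hybrid
#'
#' Sums nearest-neighbor stack contributions over consecutive dinucleotides
#' of `seq`, plus one initiation term per duplex end, for the perfect-match
#' duplex of `seq` with its complement. Following the convention of probe
#' binding tables, results are reported as positive magnitudes: `dH` in
#' kcal/mol, `dS` in cal/(mol K), and the free energy
#' `dG = dH - T * dS / 1000` kcal/mol at temperature `T`.
#'
#' @param seq a nucleotide string over A, C, G, T (length >= 2)
#' @param temperature temperature in kelvin (default 310.15 K = 37 C)
#' @param params an [nn_params()] table
#' @return a `duplex_energy` object: list with `dH`, `dS`, `dG`,
#'   `temperature`
#' @examples
#' duplex_energy("CTATCTAAAA")
#' @export
duplex_energy <- function(seq, temperature = 310.15, params = nn_params()) {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
  if (length(chars) < 2L) stop("no stacks: sequence must have length >= 2")
  if (!all(chars %in% c("A", "C", "G", "T")))
    stop("invalid base in sequence")
  stacks <- paste0(chars[-length(chars)], chars[-1L])
  dH <- sum(params$stack_dH[stacks]) +
    params$init_dH[[terminal_class(chars[1L])]] +
    params$init_dH[[terminal_class(chars[length(chars)])]]
  dS <- sum(params$stack_dS[stacks]) +
    params$init_dS[[terminal_class(chars[1L])]] +
    params$init_dS[[terminal_class(chars[length(chars)])]]
  # report binding magnitudes (positive)
  dH <- -dH
  dS <- -dS
  structure(list(dH = dH, dS = dS,
                 dG = dH - temperature * dS / 1000,
                 temperature = temperature),
            class = "duplex_energy")
}

#' @export
print.duplex_energy <- function(x, ...) {
  cat(sprintf(
    "<duplex energy at %.2f K: dH = %.2f kcal/mol, dS = %.2f cal/(mol K), dG = %.3f kcal/mol>\n",
    x$temperature, x$dH, x$dS, x$dG))
  invisible(x)
}

#' Probe/library binding-energy table for all edge strands
#'
#' Encodes each edge strand `s A_i e B_j` with the given code, computes its
#' duplex binding energies, and summarizes each energy column by mean and
#' standard deviation over all probe/library interactions.
#'
#' @param code a `dna_code`
#' @param edges optional two-column matrix of (i, j) pairs; default all
#'   `m * n` edges in row-major order
#' @param temperature kelvin
#' @param params an [nn_params()] table
#' @return list with `table` (data frame: `edge`, `dH`, `dS`, `dG`) and
#'   `summary` (data frame with rows `Average` and `Standard Deviation`)
#' @export
energy_table <- function(code, edges = NULL, temperature = 310.15,
                         params = nn_params()) {
  stopifnot(inherits(code, "dna_code"))
  if (is.null(edges)) {
    edges <- as.matrix(expand.grid(j = seq_len(code$n), i = seq_len(code$m)))
    edges <- edges[, c("i", "j"), drop = FALSE]
  }
  rows <- lapply(seq_len(nrow(edges)), function(r) {
    i <- edges[r, 1L]; j <- edges[r, 2L]
    seq <- encode_strand(strand_string(c("s", paste0("A", i), "e",
                                         paste0("B", j))), code)
    en <- duplex_energy(seq, temperature = temperature, params = params)
    data.frame(edge = sprintf("sA%deB%d", i, j),
               dH = en$dH, dS = en$dS, dG = en$dG)
  })
  tab <- do.call(rbind, rows)
  summ <- data.frame(
    statistic = c("Average", "Standard Deviation"),
    dH = c(mean(tab$dH), stats::sd(tab$dH)),
    dS = c(mean(tab$dS), stats::sd(tab$dS)),
    dG = c(mean(tab$dG), stats::sd(tab$dG)))
  list(table = tab, summary = summ)
}

#' Write an energy table as TSV
#'
#' One row per edge (`edge`, `dH`, `dS`, `dG`), followed by `Average` and
#' `Standard Deviation` rows.
#'
#' @param energies result of [energy_table()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_energy_table <- function(energies, path) {
  tab <- energies$table
  summ <- energies$summary
  names(summ)[1L] <- "edge"
  out <- rbind(tab, summ)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
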