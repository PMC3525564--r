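#' Create a cell described by its mtDNA molecule counts
#'
#' A `molecule_cell` is the state of the molecule-level drift simulator: the
#' number of mutant (m.3243A>G) and wild-type mtDNA molecules in one cell.
#'
#' @param mutant Integer count of mutant molecules (>= 0).
#' @param wildtype Integer count of wild-type molecules (>= 0).
#'
#' @return An object of class `molecule_cell` with fields `mutant` and
#'   `wildtype`. A live cell carries at least one molecule; a cell with zero
#'   molecules can be represented (it arises transiently as a flagged dead
#'   daughter) and is reported by [is_dead()].
#' @examples
#' cell <- molecule_cell(1206, 594)
#' heteroplasmy(cell)
#' @export
molecule_cell <- function(mutant, wildtype) {
  mutant <- check_count(mutant, "mutant")
  wildtype <- check_count(wildtype, "wildtype")
  structure(list(mutant = mutant, wildtype = wildtype), class = "molecule_cell")
}

#' Heteroplasmy (mutation load) of a cell
#'
#' The fraction of a cell's mtDNA molecules carrying the mutant allele,
#' `mutant / (mutant + wildtype)` for a [molecule_cell()], or the aggregate
#' `sum(k) / sum(n)` over segregation units for a [unit_cell()].
#'
#' @param cell A `molecule_cell` or `unit_cell`.
#' @return A fraction in `[0, 1]`.
#' @export
heteroplasmy <- function(cell) UseMethod("heteroplasmy")

#' @export
heteroplasmy.molecule_cell <- function(cell) {
  total <- cell$mutant + cell$wildtype
  if (total < 1L) stop("dead cell: no molecules", call. = FALSE)
  cell$mutant / total
}

#' Is a cell dead (zero molecules or zero units)?
#'
#' @param cell A `molecule_cell` or `unit_cell`.
#' @return `TRUE` if the cell holds no molecules (or no units).
#' @export
is_dead <- function(cell) UseMethod("is_dead")

#' @export
is_dead.molecule_cell <- function(cell) (cell$mutant + cell$wildtype) < 1L

#' @export
print.molecule_cell <- function(x, ...) {
  total <- x$mutant + x$wildtype
  cat(sprintf("<molecule_cell> %d mutant + %d wild-type = %d molecules",
              x$mutant, x$wildtype, total))
  if (total >= 1L) cat(sprintf(" (heteroplasmy %.3f)", x$mutant / total))
  cat("\n")
  invisible(x)
}
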