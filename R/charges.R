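#' Normalize partial charges to a target monomer charge
#'
#' Shifts a set of raw (e.g. RESP-derived) partial charges uniformly so that
#' they sum exactly to the target formal charge of the monomer:
#' \deqn{q_i = q_i^0 - \frac{\sum_j q_j^0 - Q_{tg}}{N}}
#' where \eqn{N} is the number of atoms in the monomer.  The uniform shift
#' preserves charge differences between atoms while closing the net-charge
#' budget, which is what makes a multi-monomer chain exactly neutralisable
#' by an integer number of counterions.
#'
#' @param q0 numeric vector of raw partial charges in e (nonempty)
#' @param Qtg target net charge of the monomer in e (0 or -1 for the
#'   polymers shipped with the package)
#' @return an object of class `charge_set`: list with elements `q0`, `q`
#'   (adjusted charges), `Qtg` and `N`
#' @export
#' @examples
#' normalize_charges(c(0.3, -0.5, 0.1), 0)$q      # shift of +0.1/3 each
#' sum(normalize_charges(c(-0.4, -0.4, -0.4), -1)$q)  # exactly -1
normalize_charges <- function(q0, Qtg = 0) {
  if (length(q0) == 0L) stop("empty charge list")
  if (!is.numeric(q0) || anyNA(q0)) stop("charges must be numeric and non-missing")
  if (!is.numeric(Qtg) || length(Qtg) != 1L) stop("Qtg must be a single number")
  N <- length(q0)
  q <- q0 - (sum(q0) - Qtg) / N
  structure(list(q0 = q0, q = q, Qtg = Qtg, N = N), class = "charge_set")
}

#' @export
print.charge_set <- function(x, ...) {
  cat(sprintf("<charge_set> N = %d, Qtg = %g e, sum(q) = %.9f e\n",
              x$N, x$Qtg, sum(x$q)))
  invisible(x)
}
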