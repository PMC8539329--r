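#' Construct a monomer template
#'
#' A monomer template bundles everything the chain builder needs to know
#' about one repeat unit: its atoms (element, mass, raw partial charge,
#' electronegative-atom role), its internal bond pattern, the ordered
#' backbone atoms that join the main chain, its formal charge state, and
#' hydrogen-bond donor pairs.  Raw charges are normalized to the formal
#' charge with [normalize_charges()] at build time.
#'
#' Two geometry conventions are supported.  `kind = "vinyl"` places the
#' backbone atoms on the shared all-trans zigzag and positions every other
#' atom by an offset from a named parent backbone atom (the `oy` component
#' flips sign on alternate monomers, giving a syndiotactic chain).
#' `kind = "unit"` carries explicit local coordinates for the whole repeat
#' (used for the guar trisaccharide), translated along the chain axis per
#' repeat.
#'
#' @param name identifier, e.g. "AM"
#' @param atoms data.frame with columns `name`, `element`, `charge`, `role`
#'   and either `parent`,`ox`,`oy`,`oz` (vinyl) or `x`,`y`,`z` (unit).
#'   Masses are filled from the fixed atomic mass table.
#' @param bonds two-column character matrix of bonded atom-name pairs
#' @param backbone character vector of backbone atom names, in chain order
#' @param charge_state integer formal charge (0 or -1)
#' @param hbond_donors two-column character matrix of (heavy atom, hydrogen)
#'   pairs, or NULL
#' @param kind "vinyl" or "unit"
#' @return object of class `monomer_template`
#' @export
monomer_template <- function(name, atoms, bonds, backbone, charge_state = 0L,
                             hbond_donors = NULL, kind = c("vinyl", "unit")) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(atoms), nrow(atoms) > 0L)
  if (anyDuplicated(atoms$name)) stop("duplicate atom names in monomer ", name)
  atoms$mass <- atomic_mass(atoms$element)
  if (sum(atoms$mass) <= 0) stop("non-positive monomer mass")
  bonds <- as.matrix(bonds)
  if (!all(bonds %in% atoms$name)) {
    stop("bond references undeclared atom in monomer ", name)
  }
  if (length(backbone) == 0L || !all(backbone %in% atoms$name)) {
    stop("backbone atoms must be declared atoms")
  }
  bkey <- function(a, b) paste(pmin(a, b), pmax(a, b))
  have <- bkey(bonds[, 1L], bonds[, 2L])
  if (length(backbone) > 1L) {
    need <- bkey(backbone[-length(backbone)], backbone[-1L])
    if (!all(need %in% have)) {
      stop("backbone atoms are not mutually bonded in order in monomer ", name)
    }
  }
  if (!is.null(hbond_donors)) {
    hbond_donors <- as.matrix(hbond_donors)
    if (!all(hbond_donors %in% atoms$name)) stop("donor references undeclared atom")
  }
  q <- normalize_charges(atoms$charge, charge_state)$q
  stopifnot(abs(sum(q) - charge_state) <= 0.01)
  structure(list(
    name = name, atoms = atoms, bonds = bonds, backbone = backbone,
    charge_state = as.integer(charge_state), hbond_donors = hbond_donors,
    kind = kind
  ), class = "monomer_template")
}

#' @export
print.monomer_template <- function(x, ...) {
  comp <- table(x$atoms$element)
  cat(sprintf("<monomer_template> %s: %s, mass %.4f g/mol, charge %d e\n",
              x$name,
              paste0(names(comp), comp, collapse = " "),
              sum(x$atoms$mass), x$charge_state))
  invisible(x)
}

.monomer_env <- new.env(parent = emptyenv())

#' Retrieve a monomer template by name
#'
#' @param name one of the registered monomer identifiers
#'   (see [list_monomers()])
#' @return a `monomer_template`
#' @export
get_monomer <- function(name) {
  if (!length(ls(.monomer_env))) .register_builtin_monomers()
  if (!exists(name, envir = .monomer_env, inherits = FALSE)) {
    stop("unknown monomer: ", name)
  }
  get(name, envir = .monomer_env, inherits = FALSE)
}

#' List registered monomer identifiers
#' @return character vector
#' @export
list_monomers <- function() {
  if (!length(ls(.monomer_env))) .register_builtin_monomers()
  sort(ls(.monomer_env))
}
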