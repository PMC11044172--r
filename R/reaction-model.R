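#' Element vectors: heavy-atom counts plus net formal charge
#'
#' The currency of reaction balancing. An element vector holds per-element
#' heavy-atom counts (hydrogen is never recorded: a mass- and charge-balanced
#' equation leaves no degree of freedom for a hydrogen imbalance) and the net
#' formal charge.
#'
#' @param smiles a single molecule SMILES string.
#' @return an object of class `element_vector`: a list with `counts`
#'   (named integer vector, no `"H"` key) and `charge` (integer).
#' @examples
#' \donttest{
#' element_vector("CC(=O)O")   # C2 O2, charge 0
#' element_vector("[NH4+]")    # N1, charge +1; hydrogens dropped
#' }
#' @export
element_vector <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) == 1L)
  can <- canonical_smiles(smiles)
  if (is.na(can)) stop("unparseable SMILES: ", smiles)
  comp <- .mol_composition(can)
  structure(list(counts = comp$counts, charge = as.integer(comp$charge)),
            class = "element_vector")
}

ev_zero <- function() {
  structure(list(counts = integer(0), charge = 0L), class = "element_vector")
}

ev_add <- function(a, b) {
  els <- union(names(a$counts), names(b$counts))
  counts <- stats::setNames(integer(length(els)), els)
  counts[names(a$counts)] <- counts[names(a$counts)] + a$counts
  counts[names(b$counts)] <- counts[names(b$counts)] + b$counts
  counts <- counts[counts != 0L]
  structure(list(counts = counts, charge = a$charge + b$charge),
            class = "element_vector")
}

ev_scale <- function(a, k) {
  structure(list(counts = a$counts * as.integer(k),
                 charge = a$charge * as.integer(k)),
            class = "element_vector")
}

# Signed map over elements + "charge" pseudo-key so one code path covers atoms
# and electrons; zero entries are dropped.
ev_as_delta <- function(a) {
  d <- as.numeric(a$counts)
  names(d) <- names(a$counts)
  if (a$charge != 0L) d[["charge"]] <- a$charge
  d[d != 0]
}

#' @export
print.element_vector <- function(x, ...) {
  body <- if (length(x$counts))
    paste(names(x$counts), x$counts, sep = ":", collapse = " ") else "(no heavy atoms)"
  cat("<element_vector> ", body, "  charge ", x$charge, "\n", sep = "")
  invisible(x)
}

#' Construct a reaction record
#'
#' A reaction record carries reactants, agents (reagents), solvents and
#' products as lists of canonical molecule SMILES, plus optional positive
#' integer stoichiometric coefficients aligned over `c(reactants, products)`.
#' Agents and solvents never enter balance sums until the balancer explicitly
#' promotes them to reactants.
#'
#' @param reactants,products character vectors of molecule SMILES; each must
#'   be non-empty for a valid record.
#' @param agents,solvents character vectors of candidate molecule SMILES
#'   (may be empty).
#' @param id record identifier.
#' @param stoichiometry optional integer vector, one coefficient per reactant
#'   and product, each in `[1, max_coeff]`.
#' @param canonicalize sanitize and canonicalize all molecules (default). An
#'   unparseable molecule raises an error naming the fragment and record id.
#' @return an object of class `reaction_record`.
#' @export
reaction_record <- function(reactants, products, agents = character(0),
                            solvents = character(0), id = "rxn",
                            stoichiometry = NULL, canonicalize = TRUE) {
  if (!length(reactants) || !length(products))
    stop("record '", id, "': reactants and products must each be non-empty")
  fields <- list(reactants = as.character(reactants),
                 agents = as.character(agents),
                 solvents = as.character(solvents),
                 products = as.character(products))
  if (canonicalize) {
    for (f in names(fields)) {
      can <- canonical_smiles(fields[[f]])
      bad <- which(is.na(can))
      if (length(bad))
        stop("record '", id, "': unparseable ", f, " fragment '",
             fields[[f]][bad[1]], "'")
      fields[[f]] <- can
    }
  }
  if (!is.null(stoichiometry)) {
    stoichiometry <- as.integer(stoichiometry)
    if (length(stoichiometry) != length(fields$reactants) + length(fields$products))
      stop("record '", id, "': stoichiometry must align with reactants ++ products")
    if (any(stoichiometry < 1L))
      stop("record '", id, "': stoichiometric coefficients must be positive")
  }
  structure(list(id = id, reactants = fields$reactants, agents = fields$agents,
                 solvents = fields$solvents, products = fields$products,
                 stoichiometry = stoichiometry),
            class = "reaction_record")
}

#' @export
print.reaction_record <- function(x, ...) {
  cat("<reaction_record> ", x$id, "\n  ", serialize_reaction(x, "uspto3"), "\n",
      sep = "")
  if (!is.null(x$stoichiometry))
    cat("  coefficients:", paste(x$stoichiometry, collapse = " "), "\n")
  invisible(x)
}

#' Parse a reaction SMILES line
#'
#' Two dialects are supported: `"uspto3"`, the three-field form
#' `reactants>agents>products` in which the middle field carries reagents,
#' and `"plain2"`, the two-field form `reactants>>products`. Fragments are
#' split on `'.'`, sanitized and canonicalized.
#'
#' @param text a reaction SMILES line.
#' @param dialect `"uspto3"` or `"plain2"`.
#' @param id record identifier used in error messages.
#' @return a [reaction_record()].
#' @examples
#' \donttest{
#' parse_reaction("CC(=O)O.CO>O=S(=O)(O)O>COC(C)=O", "uspto3")
#' parse_reaction("Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1", "plain2")
#' }
#' @export
parse_reaction <- function(text, dialect = c("uspto3", "plain2"), id = "rxn") {
  dialect <- match.arg(dialect)
  stopifnot(is.character(text), length(text) == 1L)
  fields <- strsplit(text, ">", fixed = TRUE)[[1]]
  n_expect <- if (dialect == "uspto3") 3L else 3L  # "a>>b" splits into a,"",b
  if (length(fields) != 3L)
    stop("record '", id, "': expected ", if (dialect == "uspto3") "3 '>'-separated"
         else "2 '>>'-separated", " fields, got malformed line")
  if (dialect == "plain2" && nzchar(fields[2]))
    stop("record '", id, "': plain2 dialect cannot carry an agents field")
  split_frag <- function(s) {
    if (!nzchar(s)) return(character(0))
    strsplit(s, ".", fixed = TRUE)[[1]]
  }
  reaction_record(reactants = split_frag(fields[1]),
                  agents = split_frag(fields[2]),
                  products = split_frag(fields[3]),
                  id = id)
}

#' Serialize a reaction record to a reaction SMILES line
#'
#' Round trip: `parse_reaction(serialize_reaction(r, d), d)` yields a record
#' with the same canonical fragment multisets per field. The `plain2` dialect
#' cannot carry agents; they are dropped with a warning.
#'
#' @inheritParams parse_reaction
#' @param rec a [reaction_record()].
#' @return a reaction SMILES string.
#' @export
serialize_reaction <- function(rec, dialect = c("uspto3", "plain2")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(rec, "reaction_record"))
  if (!length(rec$reactants) || !length(rec$products))
    stop("record '", rec$id, "': cannot serialize with empty reactants or products")
  join <- function(x) paste(x, collapse = ".")
  if (dialect == "uspto3") {
    paste0(join(rec$reactants), ">", join(rec$agents), ">", join(rec$products))
  } else {
    if (length(rec$agents))
      warning("record '", rec$id, "': plain2 dialect drops ", length(rec$agents),
              " agent(s)")
    paste0(join(rec$reactants), ">>", join(rec$products))
  }
}

ev_side_sum <- function(mols, coeffs = NULL) {
  acc <- ev_zero()
  for (i in seq_along(mols)) {
    ev <- element_vector(mols[[i]])
    k <- if (is.null(coeffs)) 1L else coeffs[[i]]
    acc <- ev_add(acc, ev_scale(ev, k))
  }
  acc
}

#' Atom and charge imbalance of a reaction record
#'
#' Subtracts the left-hand-side element and charge counts from the
#' right-hand-side counts, hydrogen excluded. Agents and solvents are never
#' included. Stoichiometric coefficients, when present on the record, are
#' applied as multipliers.
#'
#' @param rec a [reaction_record()].
#' @return a list of class `imbalance_report`: `delta` (named numeric, RHS
#'   minus LHS, `"charge"` pseudo-key for the net-charge difference; zero
#'   entries dropped), `lhs_surplus` and `rhs_surplus` (element names with
#'   delta < 0 and > 0), and `balanced` (logical).
#' @examples
#' \donttest{
#' r <- parse_reaction("Nc1ccc(O)cc1.CC(=O)OC(C)=O>>CC(=O)Nc1ccc(O)cc1", "plain2")
#' reaction_imbalance(r)$delta  # C -2, O -2: the acetic acid byproduct is missing
#' }
#' @export
reaction_imbalance <- function(rec) {
  stopifnot(inherits(rec, "reaction_record"))
  nr <- length(rec$reactants)
  cr <- if (is.null(rec$stoichiometry)) NULL else rec$stoichiometry[seq_len(nr)]
  cp <- if (is.null(rec$stoichiometry)) NULL else rec$stoichiometry[-seq_len(nr)]
  lhs <- ev_side_sum(rec$reactants, cr)
  rhs <- ev_side_sum(rec$products, cp)
  delta <- ev_as_delta(ev_add(rhs, ev_scale(lhs, -1L)))
  structure(list(delta = delta,
                 lhs_surplus = names(delta)[delta < 0],
                 rhs_surplus = names(delta)[delta > 0],
                 balanced = length(delta) == 0L),
            class = "imbalance_report")
}

#' @export
print.imbalance_report <- function(x, ...) {
  if (x$balanced) {
    cat("<imbalance_report> balanced\n")
  } else {
    cat("<imbalance_report> delta (RHS-LHS): ",
        paste(names(x$delta), x$delta, sep = ":", collapse = " "), "\n", sep = "")
  }
  invisible(x)
}

# Elements (incl. "charge") present on each side, coefficients ignored.
.side_element_sets <- function(rec) {
  lhs <- ev_side_sum(rec$reactants)
  rhs <- ev_side_sum(rec$products)
  setof <- function(ev) {
    s <- names(ev$counts)
    if (ev$charge != 0L) s <- c(s, "charge")
    s
  }
  list(lhs = setof(lhs), rhs = setof(rhs))
}
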