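#' Default help-species library
#'
#' A curated, ordered library of 32 small molecules and ions that occur most
#' frequently as side products in organic synthesis, ranging from water to
#' chlorobenzene. Order is significant: it breaks ties when several species
#' balance a reaction equally well. Fully user-overridable: any character
#' vector of SMILES (e.g. read with [read_help_species()]) can be passed to
#' the balancing functions in its place.
#'
#' Salts are recorded in covalent form (e.g. `Cl[Na]`) so every entry is a
#' single '.'-free fragment.
#'
#' @return named character vector of 32 canonical SMILES.
#' @export
default_help_species <- function() {
  lib <- c(
    water            = "O",
    ammonia          = "N",
    `hydrogen chloride` = "Cl",
    `hydrogen bromide`  = "Br",
    `hydrogen iodide`   = "I",
    `carbon dioxide` = "O=C=O",
    `carbon monoxide` = "[C-]#[O+]",
    nitrogen         = "N#N",
    oxygen           = "O=O",
    methanol         = "CO",
    ethanol          = "CCO",
    `acetic acid`    = "CC(=O)O",
    `formic acid`    = "OC=O",
    formaldehyde     = "C=O",
    acetaldehyde     = "CC=O",
    acetone          = "CC(C)=O",
    methane          = "C",
    `hydrogen sulfide` = "S",
    `sulfur dioxide` = "O=S=O",
    `sodium chloride` = "Cl[Na]",
    `sodium bromide` = "Br[Na]",
    `potassium chloride` = "Cl[K]",
    `lithium chloride`   = "Cl[Li]",
    chloride         = "[Cl-]",
    bromide          = "[Br-]",
    hydroxide        = "[OH-]",
    proton           = "[H+]",
    sodium           = "[Na+]",
    potassium        = "[K+]",
    `hydrogen cyanide` = "C#N",
    phenol           = "Oc1ccccc1",
    chlorobenzene    = "Clc1ccccc1"
  )
  stats::setNames(canonical_smiles(lib), names(lib))
}

#' Read a help-species library from a plain-text file
#'
#' One SMILES per line; order is significant. Blank lines and lines starting
#' with `#` are skipped.
#'
#' @param path file path.
#' @return character vector of canonical SMILES.
#' @export
read_help_species <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) stop("no species in ", path)
  can <- canonical_smiles(lines)
  if (anyNA(can)) stop("unparseable species in ", path, ": ", lines[is.na(can)][1])
  can
}

# Reduced row echelon form with partial pivoting.
.rref <- function(A, tol = 1e-9) {
  m <- nrow(A); n <- ncol(A)
  pivots <- integer(0)
  row <- 1L
  for (col in seq_len(n)) {
    if (row > m) break
    p <- which.max(abs(A[row:m, col])) + row - 1L
    if (abs(A[p, col]) < tol) next
    if (p != row) A[c(row, p), ] <- A[c(p, row), ]
    A[row, ] <- A[row, ] / A[row, col]
    others <- setdiff(seq_len(m), row)
    A[others, ] <- A[others, ] - outer(A[others, col], A[row, ])
    pivots <- c(pivots, col)
    row <- row + 1L
  }
  list(R = A, pivots = pivots)
}

# Minimal positive integer nullspace vector of A with all entries in
# [1, max_coeff]; NULL if none. Minimality: smallest coefficient sum, ties by
# lexicographic order of the coefficient vector. Enumerates the free-variable
# grid after Gauss-Jordan elimination; with the coefficient cap the grid is
# small for any realistic reaction.
.solve_integer_nullspace <- function(A, max_coeff = 6L, max_free = 8L) {
  n <- ncol(A)
  if (n == 0L) return(NULL)
  if (all(abs(A) < 1e-12)) return(rep(1L, n))  # unconstrained (e.g. H-only species)
  rr <- .rref(A)
  piv <- rr$pivots
  free <- setdiff(seq_len(n), piv)
  d <- length(free)
  if (d == 0L) return(NULL)          # only the trivial solution
  if (d > max_free) return(NULL)     # degenerate system; reject as implausible
  Fm <- rr$R[seq_along(piv), free, drop = FALSE]
  grid <- as.matrix(expand.grid(rep(list(seq_len(max_coeff)), d)))
  Xf <- t(grid)                                   # d x M
  Xp <- -Fm %*% Xf                                # |piv| x M
  ok_int <- colSums(abs(Xp - round(Xp)) > 1e-6) == 0
  Xp <- round(Xp)
  ok_rng <- colSums(Xp < 1L | Xp > max_coeff) == 0
  keep <- which(ok_int & ok_rng)
  if (!length(keep)) return(NULL)
  X <- matrix(0L, nrow = n, ncol = length(keep))
  X[piv, ] <- Xp[, keep, drop = FALSE]
  X[free, ] <- Xf[, keep, drop = FALSE]
  sums <- colSums(X)
  cand <- which(sums == min(sums))
  if (length(cand) > 1L) {
    ord <- do.call(order, lapply(seq_len(n), function(i) X[i, cand]))
    cand <- cand[ord[1]]
  }
  as.integer(X[, cand[1]])
}

# Build the conservation matrix for element vectors on the two sides:
# rows = elements (+ charge when present), columns = lhs (+) then rhs (-).
.conservation_matrix <- function(lhs_evs, rhs_evs) {
  els <- unique(unlist(c(lapply(lhs_evs, function(e) names(e$counts)),
                         lapply(rhs_evs, function(e) names(e$counts)))))
  any_charge <- any(vapply(c(lhs_evs, rhs_evs), function(e) e$charge != 0L, logical(1)))
  rows <- c(els, if (any_charge) "charge")
  n <- length(lhs_evs) + length(rhs_evs)
  A <- matrix(0, nrow = length(rows), ncol = n, dimnames = list(rows, NULL))
  fill <- function(ev, j, sign) {
    if (length(ev$counts)) A[names(ev$counts), j] <<- sign * ev$counts
    if (any_charge) A["charge", j] <<- sign * ev$charge
  }
  for (i in seq_along(lhs_evs)) fill(lhs_evs[[i]], i, 1)
  for (i in seq_along(rhs_evs)) fill(rhs_evs[[i]], length(lhs_evs) + i, -1)
  A
}

# Matrix-level solver used by solve_stoichiometry and by the brute-force test
# oracle's feasibility comparisons.
solve_stoich_evs <- function(lhs_evs, rhs_evs, max_coeff = 6L) {
  if (!length(lhs_evs) || !length(rhs_evs)) return(NULL)
  A <- .conservation_matrix(lhs_evs, rhs_evs)
  .solve_integer_nullspace(A, max_coeff = max_coeff)
}

#' Solve integer stoichiometry for a reaction record
#'
#' Finds the minimal positive-integer stoichiometric coefficients (hydrogen
#' excluded, formal charge included) with every coefficient at most
#' `max_coeff`. Large coefficients signal implausible balances - reactions
#' needing them are usually missing species or are polymerizations - so an
#' upper limit of six is imposed by default. Minimality means the smallest
#' coefficient sum; remaining ties are broken by lexicographic order over the
#' aligned coefficient vector.
#'
#' @param rec a [reaction_record()].
#' @param max_coeff coefficient cap (default 6).
#' @return integer vector aligned over `c(reactants, products)`, or `NULL`
#'   when no solution exists under the cap.
#' @examples
#' \donttest{
#' solve_stoichiometry(parse_reaction("N#N>>N", "plain2"))   # 1, 2
#' solve_stoichiometry(parse_reaction("CCCCCCC>>C", "plain2"))  # NULL: needs 7
#' }
#' @export
solve_stoichiometry <- function(rec, max_coeff = 6L) {
  stopifnot(inherits(rec, "reaction_record"))
  solve_stoich_evs(lapply(rec$reactants, element_vector),
                   lapply(rec$products, element_vector),
                   max_coeff = max_coeff)
}

.with_additions <- function(rec, lhs_add = character(0), rhs_add = character(0)) {
  reaction_record(reactants = c(rec$reactants, lhs_add),
                  products = c(rec$products, rhs_add),
                  agents = rec$agents, solvents = rec$solvents,
                  id = rec$id, canonicalize = FALSE)
}

.balance_outcome <- function(status, completed = NULL, added_lhs = list(),
                             added_rhs = list(), loop_count = 0L) {
  structure(list(status = status, completed = completed,
                 added_lhs = added_lhs, added_rhs = added_rhs,
                 loop_count = loop_count),
            class = "balance_outcome")
}

#' @export
print.balance_outcome <- function(x, ...) {
  cat("<balance_outcome> ", x$status, " (", x$loop_count, " loop(s))\n", sep = "")
  fmt <- function(adds) paste(vapply(adds, function(a)
    paste0(a$smiles, " [", a$provenance, "]"), character(1)), collapse = ", ")
  if (length(x$added_lhs)) cat("  added LHS: ", fmt(x$added_lhs), "\n", sep = "")
  if (length(x$added_rhs)) cat("  added RHS: ", fmt(x$added_rhs), "\n", sep = "")
  if (!is.null(x$completed))
    cat("  completed: ", serialize_reaction(x$completed, "uspto3"), "\n", sep = "")
  invisible(x)
}

.added_entry <- function(smiles, provenance) list(smiles = smiles, provenance = provenance)

# Best single help species (or pair) on the RHS for a reaction whose LHS has
# an atom/charge surplus. All candidates are solved; the one with the smallest
# total coefficient sum wins, ties broken by library order. Returns
# list(rhs_add =, coeffs =) or NULL.
.help_rhs_search <- function(rec, library, max_coeff, max_help_per_side = 2L) {
  lhs_evs <- lapply(rec$reactants, element_vector)
  rhs_evs <- lapply(rec$products, element_vector)
  lib_evs <- lapply(library, element_vector)
  best <- NULL
  consider <- function(add_idx) {
    sol <- solve_stoich_evs(lhs_evs, c(rhs_evs, lib_evs[add_idx]), max_coeff)
    if (is.null(sol)) return()
    score <- sum(sol)
    if (is.null(best) || score < best$score)
      best <<- list(rhs_add = library[add_idx], coeffs = sol, score = score)
  }
  for (i in seq_along(library)) consider(i)
  if (!is.null(best)) return(best[c("rhs_add", "coeffs")])
  if (max_help_per_side >= 2L && length(library) >= 2L) {
    for (i in seq_len(length(library) - 1L))
      for (j in seq((i + 1L), length(library))) consider(c(i, j))
    if (!is.null(best)) return(best[c("rhs_add", "coeffs")])
  }
  NULL
}

#' Complete a reaction by adding help species
#'
#' For a reaction with a left-hand-side atom surplus, help species from the
#' library are added to the RHS: every single species (and, failing that,
#' every pair, at most two per side) is solved for integer stoichiometry and
#' the addition with the smallest total coefficient sum is chosen, ties
#' broken by library order. In `"both"` mode (surplus on both sides) help is
#' also allowed on the LHS, at lower priority: each library entry is
#' tentatively added to the LHS and the updated reaction re-enters the
#' RHS help search.
#'
#' @param rec a [reaction_record()].
#' @param library ordered character vector of help-species SMILES.
#' @param side `"rhs"` (LHS surplus) or `"both"` (surplus on both sides).
#' @param max_coeff stoichiometric coefficient cap.
#' @param max_help_per_side at most this many help species per side.
#' @return a `balance_outcome` with status `COMPLETE_HELP`, or `NULL`.
#' @export
complete_with_help_species <- function(rec, library = default_help_species(),
                                       side = c("rhs", "both"), max_coeff = 6L,
                                       max_help_per_side = 2L) {
  side <- match.arg(side)
  library <- unname(library)
  if (side == "rhs") {
    hit <- .help_rhs_search(rec, library, max_coeff, max_help_per_side)
    if (is.null(hit)) return(NULL)
    completed <- .with_additions(rec, rhs_add = hit$rhs_add)
    completed$stoichiometry <- hit$coeffs
    return(.balance_outcome("COMPLETE_HELP", completed,
                            added_rhs = lapply(hit$rhs_add, .added_entry,
                                               provenance = "help")))
  }
  # both-side surplus: LHS entries tried sequentially, each re-entering the
  # RHS search on the updated record
  for (i in seq_along(library)) {
    rec2 <- .with_additions(rec, lhs_add = library[i])
    imb <- reaction_imbalance(rec2)
    if (imb$balanced) {
      completed <- rec2
      completed$stoichiometry <- rep(1L, length(rec2$reactants) + length(rec2$products))
      return(.balance_outcome("COMPLETE_HELP", completed,
                              added_lhs = list(.added_entry(library[i], "help"))))
    }
    sol <- solve_stoichiometry(rec2, max_coeff)
    if (!is.null(sol)) {
      completed <- rec2
      completed$stoichiometry <- sol
      return(.balance_outcome("COMPLETE_HELP", completed,
                              added_lhs = list(.added_entry(library[i], "help"))))
    }
    hit <- .help_rhs_search(rec2, library, max_coeff, max_help_per_side)
    if (!is.null(hit)) {
      completed <- .with_additions(rec2, rhs_add = hit$rhs_add)
      completed$stoichiometry <- hit$coeffs
      return(.balance_outcome("COMPLETE_HELP", completed,
                              added_lhs = list(.added_entry(library[i], "help")),
                              added_rhs = lapply(hit$rhs_add, .added_entry,
                                                 provenance = "help")))
    }
  }
  NULL
}

#' Element-coverage fallback confidence score
#'
#' Default candidate-ranking score used when no external atom mapper is
#' plugged in: the fraction of product heavy atoms whose element is available
#' in surplus-free quantity from the reactants. Deterministic, bounded in
#' `[0, 1]`, higher is better. An atom-mapping confidence scorer satisfying
#' the same contract (`function(rec) -> numeric in [0,1]`) can be supplied
#' anywhere a `scorer` argument is accepted.
#'
#' @param rec a [reaction_record()].
#' @return numeric in `[0, 1]`.
#' @export
fallback_score <- function(rec) {
  lhs <- ev_side_sum(rec$reactants)
  rhs <- ev_side_sum(rec$products)
  total <- sum(rhs$counts)
  if (total == 0) return(if (length(rec$reactants)) 1 else 0)
  covered <- sum(pmin(rhs$counts,
                      ifelse(names(rhs$counts) %in% names(lhs$counts),
                             lhs$counts[names(rhs$counts)], 0)))
  covered / total
}

#' Promote the best reagent/solvent candidate to the reactants
#'
#' For a reaction with a right-hand-side atom surplus (at least one reactant
#' missing), each candidate from the deduplicated, order-preserving pool of
#' recorded agents and solvents is promoted to the reactants in turn and the
#' resulting reaction is ranked by the scorer; the highest-confidence
#' promotion is returned. The caller treats the updated reaction as a new
#' record and re-enters the balancing loop.
#'
#' @param rec a [reaction_record()].
#' @param candidates character vector of candidate SMILES; defaults to
#'   `agents ++ solvents` of the record, deduplicated.
#' @param scorer a `function(rec) -> numeric in [0,1]`.
#' @return `NULL` when the pool is empty, else a list with `record` (the
#'   promoted reaction), `candidate` (its SMILES) and `confidence` (`NA` when
#'   a single candidate made ranking unnecessary).
#' @export
complete_with_candidates <- function(rec, candidates = NULL, scorer = fallback_score) {
  if (is.null(candidates)) candidates <- c(rec$agents, rec$solvents)
  candidates <- unique(candidates)
  if (!length(candidates)) return(NULL)
  promote <- function(cand) {
    out <- rec
    out$reactants <- c(out$reactants, cand)
    out$agents <- out$agents[out$agents != cand]
    out$solvents <- out$solvents[out$solvents != cand]
    out
  }
  if (length(candidates) == 1L)
    return(list(record = promote(candidates), candidate = candidates,
                confidence = NA_real_))
  scores <- vapply(candidates, function(cand) scorer(promote(cand)), numeric(1))
  best <- which.max(scores)  # ties: first candidate in pool order
  list(record = promote(candidates[best]), candidate = candidates[best],
       confidence = scores[[best]])
}

#' Classify and balance a reaction record
#'
#' The full heuristic balancing loop. A reaction is complete when every
#' element and the net formal charge (hydrogen excluded) balance between the
#' two sides. In order, the loop (1) accepts an already-balanced record,
#' (2) solves integer stoichiometry when both sides carry identical element
#' sets, (3) resolves an LHS-only surplus by adding help species to the RHS,
#' (4) resolves an RHS-only surplus by promoting a recorded reagent/solvent
#' candidate to the reactants and re-entering the loop with the updated
#' record, and (5) for a surplus on both sides tries candidates first
#' (LHS additions have priority) and then help species on both sides.
#' Reactions that exhaust these options are classified `LHS_INSUFFICIENT`
#' (a reactant is missing; includes both-side surpluses) or
#' `RHS_INSUFFICIENT` (a product is missing).
#'
#' @param rec a [reaction_record()].
#' @param library ordered help-species SMILES, default [default_help_species()].
#' @param scorer candidate-ranking score, default [fallback_score()].
#' @param max_coeff stoichiometric coefficient cap (default 6).
#' @param max_loops cap on candidate-promotion/help re-entries (default 3).
#' @param max_help_per_side at most this many help species per side (default 2).
#' @return a `balance_outcome`: `status` one of `COMPLETE_ORIGINAL`,
#'   `COMPLETE_STOICH`, `COMPLETE_REAGENT`, `COMPLETE_HELP`,
#'   `LHS_INSUFFICIENT`, `RHS_INSUFFICIENT`; for complete outcomes,
#'   `completed` holds the exactly conserved reaction with its stoichiometry
#'   and `added_lhs`/`added_rhs` record every addition with provenance
#'   (`reagent`, `solvent` or `help`).
#' @examples
#' \donttest{
#' classify_and_balance(parse_reaction("CC(=O)O.CO>>COC(C)=O.O", "plain2"))
#' }
#' @export
classify_and_balance <- function(rec, library = default_help_species(),
                                 scorer = fallback_score, max_coeff = 6L,
                                 max_loops = 3L, max_help_per_side = 2L) {
  library <- unname(library)
  .classify_loop(rec, library, scorer, max_coeff, max_loops, max_help_per_side,
                 added_lhs = list(), added_rhs = list(), loop_count = 0L)
}

.finalize_status <- function(added_lhs, added_rhs, coeffs) {
  prov <- vapply(c(added_lhs, added_rhs), function(a) a$provenance, character(1))
  if (any(prov %in% c("reagent", "solvent"))) "COMPLETE_REAGENT"
  else if (any(prov == "help")) "COMPLETE_HELP"
  else if (any(coeffs != 1L)) "COMPLETE_STOICH"
  else "COMPLETE_ORIGINAL"
}

.classify_loop <- function(rec, library, scorer, max_coeff, max_loops,
                           max_help_per_side, added_lhs, added_rhs, loop_count) {
  finalize <- function(completed, coeffs, extra_lhs = list(), extra_rhs = list()) {
    completed$stoichiometry <- coeffs
    all_lhs <- c(added_lhs, extra_lhs)
    all_rhs <- c(added_rhs, extra_rhs)
    .balance_outcome(.finalize_status(all_lhs, all_rhs, coeffs), completed,
                     all_lhs, all_rhs, loop_count)
  }
  insufficient <- function(imb) {
    status <- if (length(imb$rhs_surplus)) "LHS_INSUFFICIENT" else "RHS_INSUFFICIENT"
    .balance_outcome(status, NULL, added_lhs, added_rhs, loop_count)
  }
  work <- rec
  work$stoichiometry <- NULL
  imb <- reaction_imbalance(work)

  # (1) balanced as given (all coefficients 1)
  if (imb$balanced)
    return(finalize(work, rep(1L, length(work$reactants) + length(work$products))))

  # (2) identical element sets on both sides: integer stoichiometry
  sets <- .side_element_sets(work)
  if (setequal(sets$lhs, sets$rhs)) {
    sol <- solve_stoichiometry(work, max_coeff)
    if (!is.null(sol)) return(finalize(work, sol))
  }

  if (loop_count >= max_loops) return(insufficient(imb))

  lhs_surplus <- length(imb$lhs_surplus) > 0L
  rhs_surplus <- length(imb$rhs_surplus) > 0L

  # (3) LHS surplus only: help species to the RHS
  if (lhs_surplus && !rhs_surplus) {
    out <- complete_with_help_species(work, library, side = "rhs",
                                      max_coeff = max_coeff,
                                      max_help_per_side = max_help_per_side)
    if (is.null(out)) return(insufficient(imb))
    return(finalize(out$completed, out$completed$stoichiometry,
                    extra_rhs = out$added_rhs))
  }

  # (4)/(5) RHS surplus (alone or with LHS surplus): candidates first
  pool <- unique(c(work$agents, work$solvents))
  if (length(pool)) {
    promo <- complete_with_candidates(work, pool, scorer)
    prov <- if (promo$candidate %in% rec$solvents &&
                !(promo$candidate %in% rec$agents)) "solvent" else "reagent"
    return(.classify_loop(promo$record, library, scorer, max_coeff, max_loops,
                          max_help_per_side,
                          added_lhs = c(added_lhs,
                                        list(.added_entry(promo$candidate, prov))),
                          added_rhs = added_rhs, loop_count = loop_count + 1L))
  }

  # (5) both-side surplus with candidates exhausted: help on the LHS too,
  # one species at a time, each update re-entering the loop as a new record
  if (lhs_surplus && rhs_surplus) {
    lhs_help_used <- sum(vapply(added_lhs, function(a) a$provenance == "help",
                                logical(1)))
    if (lhs_help_used < max_help_per_side) {
      for (sp in library) {
        work2 <- .with_additions(work, lhs_add = sp)
        res <- .classify_loop(work2, library, scorer, max_coeff, max_loops,
                              max_help_per_side,
                              added_lhs = c(added_lhs,
                                            list(.added_entry(sp, "help"))),
                              added_rhs = added_rhs,
                              loop_count = loop_count + 1L)
        if (startsWith(res$status, "COMPLETE")) return(res)
      }
    }
  }
  insufficient(imb)
}
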