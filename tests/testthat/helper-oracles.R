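# Independent brute-force oracles. These deliberately avoid the package's
# RREF solver and ordered search: feasibility is decided by exhaustive
# enumeration so the two routes can disagree.

# Exhaustive coefficient-grid search for the minimal balanced integer
# stoichiometry. evs_lhs / evs_rhs are lists of element_vector objects.
grid_solve_oracle <- function(evs_lhs, evs_rhs, max_coeff = 6L) {
  n <- length(evs_lhs) + length(evs_rhs)
  els <- unique(unlist(c(lapply(c(evs_lhs, evs_rhs), function(e) names(e$counts)))))
  row_of <- function(ev) {
    v <- stats::setNames(numeric(length(els) + 1L), c(els, "charge"))
    v[names(ev$counts)] <- ev$counts
    v["charge"] <- ev$charge
    v
  }
  M <- cbind(sapply(evs_lhs, row_of), -sapply(evs_rhs, row_of))
  if (is.null(dim(M))) M <- matrix(M, nrow = length(els) + 1L)
  grid <- as.matrix(expand.grid(rep(list(seq_len(max_coeff)), n)))
  resid <- M %*% t(grid)
  ok <- which(colSums(abs(resid)) == 0)
  if (!length(ok)) return(NULL)
  X <- grid[ok, , drop = FALSE]
  sums <- rowSums(X)
  cand <- which(sums == min(sums))
  if (length(cand) > 1L) {
    ord <- do.call(order, lapply(seq_len(n), function(i) X[cand, i]))
    cand <- cand[ord[1]]
  }
  as.integer(X[cand[1], ])
}

ev_of <- function(counts, charge = 0L) {
  structure(list(counts = counts[counts != 0L], charge = as.integer(charge)),
            class = "element_vector")
}

# Random small element-vector systems with identical element sets on the two
# sides (the precondition of the stoichiometry solver).
random_ev_system <- function(n_lhs = 2L, n_rhs = 2L, elements = c("C", "N", "O")) {
  repeat {
    mk <- function() ev_of(stats::setNames(sample(0:3, length(elements), TRUE),
                                           elements))
    lhs <- replicate(n_lhs, mk(), simplify = FALSE)
    rhs <- replicate(n_rhs, mk(), simplify = FALSE)
    present <- function(evs) sort(unique(unlist(lapply(evs, function(e) names(e$counts)))))
    if (length(present(lhs)) && identical(present(lhs), present(rhs)))
      return(list(lhs = lhs, rhs = rhs))
  }
}

# Brute-force completability oracle under the paper's side policy:
# candidates (agents ++ solvents) may be promoted to the LHS; help species go
# to the RHS; help on the LHS only when the original delta has surplus on
# both sides. Exhausts all subsets (<= 2 help per side, <= 2 candidates) with
# the full coefficient grid.
brute_force_completable <- function(rec, library, max_coeff = 6L) {
  base_imb <- reaction_imbalance(rec)
  if (base_imb$balanced) return(TRUE)
  pool <- unique(c(rec$agents, rec$solvents))
  lib_evs <- lapply(library, element_vector)
  subsets_upto2 <- function(k) {
    out <- list(integer(0))
    for (i in seq_len(k)) out <- c(out, list(i))
    if (k >= 2L)
      for (i in seq_len(k - 1L)) for (j in seq((i + 1L), k)) out <- c(out, list(c(i, j)))
    out
  }
  # candidate promotion is only licensed by an RHS surplus
  cand_sets <- if (length(base_imb$rhs_surplus))
    subsets_upto2(length(pool)) else list(integer(0))
  help_sets <- subsets_upto2(length(library))
  allow_lhs_help <- length(base_imb$lhs_surplus) > 0L && length(base_imb$rhs_surplus) > 0L
  lhs_help_sets <- if (allow_lhs_help) help_sets else list(integer(0))
  base_lhs <- lapply(rec$reactants, element_vector)
  base_rhs <- lapply(rec$products, element_vector)
  for (cs in cand_sets) {
    lhs1 <- c(base_lhs, lapply(pool[cs], element_vector))
    for (hl in lhs_help_sets) {
      lhs2 <- c(lhs1, lib_evs[hl])
      for (hr in help_sets) {
        rhs2 <- c(base_rhs, lib_evs[hr])
        sol <- grid_solve_oracle(lhs2, rhs2, max_coeff)
        if (!is.null(sol)) return(TRUE)
      }
    }
  }
  FALSE
}
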