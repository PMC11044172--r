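# Substituent fragment pools. Each fragment is a (prefix, suffix) pair of
# SMILES spellings with identical heavy-atom formula: the prefix form attaches
# through its last written atom, the suffix form through its first, so the
# same substituent can sit on either side of a template bond.
.fragment_pools <- function() {
  alkyl <- list(
    list(prefix = "C",      suffix = "C"),
    list(prefix = "CC",     suffix = "CC"),
    list(prefix = "CCC",    suffix = "CCC"),
    list(prefix = "CCCC",   suffix = "CCCC"),
    list(prefix = "CCCCC",  suffix = "CCCCC"),
    list(prefix = "CCCCCC", suffix = "CCCCCC"),
    list(prefix = "CC(C)",  suffix = "C(C)C"),
    list(prefix = "CC(C)C", suffix = "CC(C)C"),
    list(prefix = "CCC(C)", suffix = "C(C)CC"),
    list(prefix = "CCCC(C)", suffix = "C(C)CCC")
  )
  aryl <- list(
    list(prefix = "c1ccccc1",   suffix = "c1ccccc1"),
    list(prefix = "Cc1ccccc1",  suffix = "c1ccc(C)cc1"),
    list(prefix = "Clc1ccccc1", suffix = "c1ccc(Cl)cc1"),
    list(prefix = "Brc1ccccc1", suffix = "c1ccc(Br)cc1"),
    list(prefix = "Fc1ccccc1",  suffix = "c1ccc(F)cc1"),
    list(prefix = "COc1ccccc1", suffix = "c1ccc(OC)cc1")
  )
  list(alkyl = alkyl, aryl = aryl, all = c(alkyl, aryl),
       halogens = c("Cl", "Br", "I"))
}

#' Reaction templates for the synthetic generator
#'
#' Five classic organic transformations, each instantiated from substituent
#' fragment pools and exactly balanced by construction (verified at
#' generation time): Fischer esterification, amide coupling, anhydride
#' acylation (amine or alcohol nucleophile; with 4-aminophenol this yields
#' the paracetamol synthesis), SN2 halide substitution by an amine, and
#' Williamson ether synthesis. Every template names its byproduct - water,
#' the hydrogen halide or the carboxylic acid - which is what reaction
#' databases most often omit.
#'
#' @return named list of template functions; each takes a sampled fragment
#'   set and returns `list(reactants, products, byproduct_index)` where
#'   `byproduct_index` points into `products`.
#' @export
reaction_templates <- function() {
  list(
    esterification = function(fr) {
      acid <- paste0(fr$r1$prefix, "C(=O)O")
      alcohol <- paste0(fr$r2$prefix, "O")
      ester <- paste0(fr$r2$prefix, "OC(=O)", fr$r1$suffix)
      list(reactants = c(acid, alcohol), products = c(ester, "O"),
           byproduct_index = 2L)
    },
    amide_coupling = function(fr) {
      acid <- paste0(fr$r1$prefix, "C(=O)O")
      amide <- paste0(fr$r1$prefix, "C(=O)N", fr$r2$suffix)
      list(reactants = c(acid, .amine_of(fr$r2)), products = c(amide, "O"),
           byproduct_index = 2L)
    },
    anhydride_acylation = function(fr) {
      anhydride <- paste0(fr$r1$prefix, "C(=O)OC(=O)", fr$r1$suffix)
      nucleophile <- if (fr$amine) .amine_of(fr$r2) else paste0(fr$r2$prefix, "O")
      prod <- paste0(fr$r1$prefix, if (fr$amine) "C(=O)N" else "C(=O)O", fr$r2$suffix)
      acid <- paste0(fr$r1$prefix, "C(=O)O")
      list(reactants = c(anhydride, nucleophile), products = c(prod, acid),
           byproduct_index = 2L)
    },
    sn2_amination = function(fr) {
      halide <- paste0(fr$r1$prefix, fr$x)
      prod <- paste0(fr$r1$prefix, "N", fr$r2$suffix)
      list(reactants = c(halide, .amine_of(fr$r2)), products = c(prod, fr$x),
           byproduct_index = 2L)
    },
    williamson_ether = function(fr) {
      halide <- paste0(fr$r1$prefix, fr$x)
      alcohol <- paste0(fr$r2$prefix, "O")
      ether <- paste0(fr$r2$prefix, "O", fr$r1$suffix)
      list(reactants = c(halide, alcohol), products = c(ether, fr$x),
           byproduct_index = 2L)
    }
  )
}

# 4-aminophenol enters the amine pool so the anhydride template can emit the
# paracetamol synthesis (acetylation of 4-aminophenol with acetic anhydride).
# Its para-substitution cannot be spelled as an append-at-end prefix, so the
# amine molecule itself is carried explicitly.
.amine_extra <- list(amine_smiles = "Nc1ccc(O)cc1", suffix = "c1ccc(O)cc1")

.amine_of <- function(frag) {
  if (!is.null(frag$amine_smiles)) frag$amine_smiles else paste0(frag$prefix, "N")
}

.sample_fragments <- function(template_name, pools) {
  fr <- list()
  fr$r1 <- pools$all[[sample.int(length(pools$all), 1L)]]
  if (template_name == "anhydride_acylation") {
    fr$amine <- stats::runif(1) < 0.5
    r2_pool <- if (fr$amine) c(pools$all, list(.amine_extra)) else pools$all
  } else if (template_name %in% c("amide_coupling", "sn2_amination")) {
    r2_pool <- c(pools$all, list(.amine_extra))
  } else {
    r2_pool <- pools$all
  }
  fr$r2 <- r2_pool[[sample.int(length(r2_pool), 1L)]]
  if (template_name %in% c("sn2_amination", "williamson_ether"))
    fr$x <- pools$halogens[[sample.int(3L, 1L)]]
  fr
}

#' Generate balanced synthetic reaction records
#'
#' Samples templates and substituent fragments under a fixed seed and emits
#' exactly balanced reaction records; every record is verified with
#' [reaction_imbalance()] at generation time and generation aborts on any
#' imbalance. Optionally a spectator solvent is attached to the record's
#' solvent list (it never enters balance sums).
#'
#' @param n number of records.
#' @param seed RNG seed (generation is deterministic given `seed`).
#' @param templates template list, default [reaction_templates()].
#' @param solvent_prob probability of attaching a spectator solvent.
#' @return list of [reaction_record()]s; each carries attributes
#'   `byproduct` (canonical SMILES of the template byproduct) and
#'   `template` (template name).
#' @examples
#' \donttest{
#' rxns <- generate_reactions(5, seed = 1)
#' serialize_reaction(rxns[[1]], "plain2")
#' }
#' @export
generate_reactions <- function(n, seed = 1L, templates = reaction_templates(),
                               solvent_prob = 0) {
  stopifnot(length(templates) >= 1L, n >= 0L)
  if (n == 0L) return(list())
  pools <- .fragment_pools()
  solvents <- c("CCOCC", "ClCCl", "Cc1ccccc1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(as.integer(seed))
  out <- vector("list", n)
  for (i in seq_len(n)) {
    t_idx <- sample.int(length(templates), 1L)
    t_name <- names(templates)[t_idx]
    fr <- .sample_fragments(t_name, pools)
    spec <- templates[[t_idx]](fr)
    solv <- if (stats::runif(1) < solvent_prob)
      solvents[[sample.int(length(solvents), 1L)]] else character(0)
    rec <- reaction_record(reactants = spec$reactants, products = spec$products,
                           solvents = solv,
                           id = sprintf("syn-%s-%05d", t_name, i))
    imb <- reaction_imbalance(rec)
    if (!imb$balanced)
      stop("template '", t_name, "' produced an imbalanced reaction: ",
           serialize_reaction(rec, "plain2"))
    attr(rec, "byproduct") <- rec$products[[spec$byproduct_index]]
    attr(rec, "template") <- t_name
    out[[i]] <- rec
  }
  out
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv())) get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

#' Corrupt a balanced reaction by deleting one participant
#'
#' Removes one molecule to create a record with a known missing participant,
#' mirroring the hidden-molecule protocol: `drop_byproduct` removes the
#' template byproduct (side RHS), `drop_reactant` removes one reactant
#' (side LHS). The main product is never removed.
#'
#' @param rec a balanced [reaction_record()] from [generate_reactions()].
#' @param strategy `"drop_byproduct"` or `"drop_reactant"`.
#' @param seed RNG seed for the reactant choice.
#' @return list of class `corrupted_reaction`: `record` (imbalanced),
#'   `side` (`"LHS"` or `"RHS"`), `truth` (the removed canonical SMILES).
#' @export
corrupt_reaction <- function(rec, strategy = c("drop_byproduct", "drop_reactant"),
                             seed = 1L) {
  strategy <- match.arg(strategy)
  stopifnot(inherits(rec, "reaction_record"))
  if (strategy == "drop_byproduct") {
    by <- attr(rec, "byproduct")
    idx <- if (!is.null(by)) match(by, rec$products) else
      if (length(rec$products) > 1L) length(rec$products) else NA_integer_
    if (is.na(idx) || length(rec$products) < 2L)
      stop("record '", rec$id, "' has no removable byproduct")
    truth <- rec$products[[idx]]
    out <- rec
    out$products <- out$products[-idx]
    side <- "RHS"
  } else {
    if (length(rec$reactants) < 2L)
      stop("record '", rec$id, "' has a single reactant; cannot drop one")
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(as.integer(seed))
    idx <- sample.int(length(rec$reactants), 1L)
    truth <- rec$reactants[[idx]]
    out <- rec
    out$reactants <- out$reactants[-idx]
    side <- "LHS"
  }
  out$stoichiometry <- NULL
  attr(out, "byproduct") <- NULL
  structure(list(record = out, side = side, truth = truth),
            class = "corrupted_reaction")
}
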