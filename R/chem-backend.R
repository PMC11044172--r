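#' @importFrom ChemmineOB convertFormat
NULL

# Per-session caches keyed by input SMILES. Reaction corpora reuse a small set
# of fragments heavily, so memoisation removes almost all toolkit calls.
.chem_cache <- new.env(parent = emptyenv())

.cache_get <- function(store, key) {
  e <- get0(store, envir = .chem_cache)
  if (is.null(e)) return(NULL)
  get0(key, envir = e)
}

.cache_set <- function(store, key, value) {
  e <- get0(store, envir = .chem_cache)
  if (is.null(e)) {
    e <- new.env(parent = emptyenv())
    assign(store, e, envir = .chem_cache)
  }
  assign(key, value, envir = e)
  value
}

.ob_convert <- function(from, to, text) {
  # OpenBabel prints parse warnings on stderr; suppress so batch runs stay quiet
  out <- suppressWarnings(ChemmineOB::convertFormat(from, to, text))
  out
}

#' Canonicalize a SMILES string
#'
#' Sanitizes and canonicalizes molecule SMILES with the OpenBabel toolkit.
#' Unparseable input yields `NA_character_`; use [smiles_valid()] for a
#' logical test. Canonicalization is idempotent.
#'
#' @param smiles character vector of molecule SMILES (no reaction arrows).
#' @return character vector of canonical SMILES, `NA` where invalid.
#' @examples
#' \donttest{
#' canonical_smiles(c("OC(C)=O", "CC(=O)O"))  # same molecule, same output
#' }
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    hit <- .cache_get("canon", s)
    if (!is.null(hit)) return(hit)
    if (!.delimiters_balanced(s)) return(.cache_set("canon", s, NA_character_))
    out <- .ob_convert("SMI", "CAN", paste0(s, "\n"))
    out <- strsplit(out, "[\t\n]")[[1]]
    out <- if (length(out) && nzchar(out[[1]])) out[[1]] else NA_character_
    .cache_set("canon", s, out)
  }, character(1), USE.NAMES = FALSE)
}

# Branch and bracket delimiters must pair up. The toolkit silently repairs
# unclosed parentheses, but a string with mismatched delimiters is not valid
# SMILES (model decodes produce these routinely).
.delimiters_balanced <- function(s) {
  chars <- strsplit(s, "", fixed = TRUE)[[1]]
  for (pair in list(c("(", ")"), c("[", "]"))) {
    depth <- cumsum((chars == pair[1]) - (chars == pair[2]))
    if (any(depth < 0) || depth[length(depth)] != 0) return(FALSE)
  }
  TRUE
}

#' Test SMILES validity
#'
#' @param smiles character vector.
#' @return logical vector, `TRUE` where the toolkit sanitizes the string.
#' @export
smiles_valid <- function(smiles) {
  !is.na(canonical_smiles(smiles))
}

# Parse an OpenBabel "report" chunk into counts + charge.
.parse_report <- function(chunk) {
  f <- regmatches(chunk, regexpr("FORMULA: [^\n]*", chunk))
  if (!length(f)) return(NULL)
  formula <- trimws(sub("FORMULA:", "", f))
  formula <- sub("[+-][0-9]*$", "", formula)  # charge suffix lives in TOTAL CHARGE
  ch <- regmatches(chunk, regexpr("TOTAL CHARGE: *-?[0-9]+", chunk))
  charge <- if (length(ch)) as.integer(sub("TOTAL CHARGE: *", "", ch)) else 0L
  toks <- regmatches(formula, gregexpr("[A-Z][a-z]?[0-9]*", formula))[[1]]
  counts <- integer(0)
  for (t in toks) {
    el <- sub("[0-9]*$", "", t)
    n <- sub("^[A-Za-z]+", "", t)
    n <- if (nzchar(n)) as.integer(n) else 1L
    counts[el] <- (if (el %in% names(counts)) counts[[el]] else 0L) + n
  }
  counts <- counts[names(counts) != "H"]
  counts <- counts[counts > 0L]
  list(counts = counts, charge = charge)
}

# Heavy-atom composition + net formal charge for one molecule SMILES.
.mol_composition <- function(smiles) {
  hit <- .cache_get("comp", smiles)
  if (!is.null(hit)) return(hit)
  rep_txt <- .ob_convert("SMI", "report", paste0(smiles, "\n"))
  comp <- .parse_report(rep_txt)
  if (is.null(comp)) stop("cannot derive composition for SMILES: ", smiles)
  .cache_set("comp", smiles, comp)
}
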