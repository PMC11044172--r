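#' Read reaction records from a file
#'
#' Two plain-text formats are supported: reaction-SMILES lines (one reaction
#' per line, dialect auto-detected per line from the field count) and JSONL
#' records `{"id", "rxn", "reagents": [...], "solvents": [...]}` where `rxn`
#' is a two-field reaction SMILES and reagents/solvents are separate
#' attribute lists. Unsanitizable records are tagged unusable and returned
#' separately rather than aborting the run.
#'
#' @param path input file.
#' @param format `"auto"`, `"smiles"` or `"jsonl"`.
#' @return list with `records` (list of [reaction_record()]) and `failures`
#'   (data.frame of id + error message for unusable lines).
#' @export
read_reactions <- function(path, format = c("auto", "smiles", "jsonl")) {
  format <- match.arg(format)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (format == "auto")
    format <- if (length(lines) && startsWith(trimws(lines[1]), "{")) "jsonl"
              else "smiles"
  records <- list()
  failures <- data.frame(id = character(0), error = character(0))
  for (i in seq_along(lines)) {
    res <- tryCatch({
      if (format == "jsonl") {
        obj <- jsonlite::fromJSON(lines[i], simplifyVector = TRUE)
        rxn <- parse_reaction(obj$rxn, "plain2", id = obj$id %||% paste0("rec-", i))
        rxn$agents <- canonical_smiles(as.character(obj$reagents %||% character(0)))
        rxn$solvents <- canonical_smiles(as.character(obj$solvents %||% character(0)))
        if (anyNA(c(rxn$agents, rxn$solvents)))
          stop("unparseable reagent/solvent in record ", rxn$id)
        rxn
      } else {
        n_arrows <- lengths(regmatches(lines[i], gregexpr(">", lines[i], fixed = TRUE)))
        dialect <- if (grepl(">>", lines[i], fixed = TRUE) && n_arrows == 2L)
          "plain2" else "uspto3"
        parse_reaction(trimws(lines[i]), dialect, id = paste0("rec-", i))
      }
    }, error = function(e) e)
    if (inherits(res, "error")) {
      failures <- rbind(failures,
                        data.frame(id = paste0("rec-", i),
                                   error = conditionMessage(res)))
    } else {
      records[[length(records) + 1L]] <- res
    }
  }
  list(records = records, failures = failures)
}

#' Write reaction records as JSONL
#'
#' @param records list of [reaction_record()]s.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_reactions <- function(records, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (rec in records) {
    # agents travel in the reagents attribute, not the rxn string
    bare <- rec
    bare$agents <- character(0)
    writeLines(jsonlite::toJSON(
      list(id = rec$id, rxn = serialize_reaction(bare, "plain2"),
           reagents = as.list(rec$agents), solvents = as.list(rec$solvents)),
      auto_unbox = TRUE), con)
  }
  invisible(path)
}

.dedupe_records <- function(records) {
  keys <- vapply(records, function(r)
    paste(paste(sort(r$reactants), collapse = "."), ">",
          paste(sort(c(r$agents, r$solvents)), collapse = "."), ">",
          paste(sort(r$products), collapse = ".")), character(1))
  keep <- !duplicated(keys)
  list(records = records[keep], n_duplicates = sum(!keep))
}

#' Batch-balance reaction records
#'
#' Classifies every record with [classify_and_balance()] after removing
#' duplicate reactions (canonical fragment multisets per field) and reports
#' run statistics in the style of a completion-results table: counts and
#' percentages of usable records per outcome category, which always sum to
#' the usable record count.
#'
#' @param input list of [reaction_record()]s, or a file path for
#'   [read_reactions()].
#' @param library,scorer,max_coeff,max_loops balancer configuration.
#' @param out_path optional JSONL path for per-record outcomes.
#' @return a `run_manifest`: `counts` (named integer), `percentages`,
#'   `n_input`, `n_usable`, `n_duplicates`, `n_unusable`, and `results`
#'   (per-record data.frame with status, added molecules and the completed
#'   reaction string).
#' @export
run_balance <- function(input, library = default_help_species(),
                        scorer = fallback_score, max_coeff = 6L,
                        max_loops = 3L, out_path = NULL) {
  n_unusable <- 0L
  if (is.character(input) && length(input) == 1L) {
    parsed <- read_reactions(input)
    records <- parsed$records
    n_unusable <- nrow(parsed$failures)
  } else records <- input
  n_input <- length(records) + n_unusable
  dd <- .dedupe_records(records)
  records <- dd$records

  statuses <- c("COMPLETE_ORIGINAL", "COMPLETE_STOICH", "COMPLETE_REAGENT",
                "COMPLETE_HELP", "LHS_INSUFFICIENT", "RHS_INSUFFICIENT")
  rows <- vector("list", length(records))
  for (i in seq_along(records)) {
    out <- classify_and_balance(records[[i]], library = library,
                                scorer = scorer, max_coeff = max_coeff,
                                max_loops = max_loops)
    rows[[i]] <- data.frame(
      id = records[[i]]$id, status = out$status,
      added_lhs = paste(vapply(out$added_lhs, `[[`, "", "smiles"),
                        collapse = "."),
      added_rhs = paste(vapply(out$added_rhs, `[[`, "", "smiles"),
                        collapse = "."),
      completed = if (!is.null(out$completed))
        serialize_reaction(out$completed, "plain2") else NA_character_,
      coefficients = if (!is.null(out$completed))
        paste(out$completed$stoichiometry, collapse = " ") else NA_character_)
  }
  results <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), status = character(0))
  counts <- stats::setNames(vapply(statuses, function(s)
    sum(results$status == s), integer(1)), statuses)
  manifest <- structure(list(
    counts = counts,
    percentages = if (length(records)) round(100 * counts / length(records), 1)
                  else counts * NA_real_,
    n_input = n_input, n_usable = length(records),
    n_duplicates = dd$n_duplicates, n_unusable = n_unusable,
    results = results), class = "run_manifest")
  if (!is.null(out_path)) {
    con <- file(out_path, "w"); on.exit(close(con))
    for (i in seq_len(nrow(results)))
      writeLines(jsonlite::toJSON(as.list(results[i, ]), auto_unbox = TRUE,
                                  na = "null"), con)
  }
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest> ", x$n_usable, " usable record(s) (",
      x$n_duplicates, " duplicate(s), ", x$n_unusable, " unusable)\n", sep = "")
  for (s in names(x$counts))
    cat(sprintf("  %-20s %6d  %5.1f%%\n", s, x$counts[[s]],
                x$percentages[[s]]))
  invisible(x)
}

#' Run the full completion pipeline
#'
#' Stage one classifies every record with the balancer; only records it
#' leaves species-insufficient reach stage two, where the trained masked
#' language model proposes missing molecules on the side the balancer named
#' and every proposal is re-verified by the balancer. No record is processed
#' by both stages as complete: the stages are exclusive.
#'
#' @param input records or a file path, as in [run_balance()].
#' @param fit a trained `mlm_fit`; required before any processing starts.
#' @param max_len_enum enumeration bound for the model stage.
#' @inheritParams run_balance
#' @return a `pipeline_manifest` with the balancer manifest, the model-stage
#'   statuses (`COMPLETED_MLM`, `COMPLETED_MLM_PLUS_BALANCER`, `INCOMPLETE`)
#'   and a combined per-record results table.
#' @export
run_pipeline <- function(input, fit, max_len_enum = 30L,
                         library = default_help_species(),
                         scorer = fallback_score, max_coeff = 6L,
                         max_loops = 3L) {
  if (!inherits(fit, "mlm_fit"))
    stop("a trained mlm_fit is required before any records are processed")
  balance <- run_balance(input, library = library, scorer = scorer,
                         max_coeff = max_coeff, max_loops = max_loops)
  records <- if (is.character(input)) read_reactions(input)$records else input
  records <- .dedupe_records(records)$records
  insufficient <- which(!startsWith(balance$results$status, "COMPLETE"))
  mlm_rows <- vector("list", length(insufficient))
  for (k in seq_along(insufficient)) {
    i <- insufficient[k]
    res <- complete_reaction(records[[i]], fit, max_len_enum = max_len_enum,
                             library = library, scorer = scorer,
                             max_coeff = max_coeff, max_loops = max_loops)
    mlm_rows[[k]] <- data.frame(
      id = records[[i]]$id, status = res$status,
      proposed = if (!is.null(res$chosen)) res$chosen$smiles else NA_character_,
      side = res$side)
  }
  mlm_results <- if (length(mlm_rows)) do.call(rbind, mlm_rows) else
    data.frame(id = character(0), status = character(0),
               proposed = character(0), side = character(0))
  mlm_statuses <- c("COMPLETED_MLM", "COMPLETED_MLM_PLUS_BALANCER", "INCOMPLETE")
  mlm_counts <- stats::setNames(vapply(mlm_statuses, function(s)
    sum(mlm_results$status == s), integer(1)), mlm_statuses)
  structure(list(balance = balance, mlm_counts = mlm_counts,
                 mlm_results = mlm_results),
            class = "pipeline_manifest")
}

#' @export
print.pipeline_manifest <- function(x, ...) {
  print(x$balance)
  cat("  model stage (", sum(!startsWith(x$balance$results$status, "COMPLETE")),
      " insufficient record(s)):\n", sep = "")
  for (s in names(x$mlm_counts))
    cat(sprintf("  %-28s %6d\n", s, x$mlm_counts[[s]]))
  invisible(x)
}

#' Serialize a run manifest to JSON
#'
#' @param manifest a `run_manifest` or `pipeline_manifest`.
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  x <- unclass(manifest)
  if (!is.null(x$balance)) x$balance <- unclass(x$balance)
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}
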