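# End-to-end orchestration: harmonize -> block -> encode -> compare ->
# classify -> (evaluate when a gold standard is supplied).

#' Pipeline configuration
#'
#' Bundles every stage's settings and validates them up front, before any
#' computation touches the data.
#'
#' @param columns named list mapping the canonical column names
#'   (`record_id`, `name`, `mother_name`, `date_of_birth`, `gender`,
#'   `municipality_code`) to the column names found in the input CSVs.
#' @param date_dialect input date dialect, see [harmonize_config()].
#' @param segment_bits,num_hashes see [filter_config()].
#' @param mode `"hybrid"` or `"full"` comparison.
#' @param cutoffs a [cutoff_config()].
#' @param block_cap see [build_candidate_pairs()].
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(columns = NULL, date_dialect = "iso",
                            segment_bits = c(name = 50, mother_name = 50,
                                             date_of_birth = 40,
                                             municipality_code = 20,
                                             gender = 20),
                            num_hashes = 2L, mode = c("hybrid", "full"),
                            cutoffs = cutoff_config(), block_cap = Inf) {
  canonical <- c("record_id", linkage_attributes())
  if (is.null(columns)) {
    columns <- as.list(stats::setNames(canonical, canonical))
  }
  if (!all(canonical %in% names(columns))) {
    stop("columns mapping must cover: ", paste(canonical, collapse = ", "))
  }
  cfg <- structure(list(
    columns = columns,
    harmonize = harmonize_config(date_dialect),
    filter = filter_config(segment_bits, num_hashes),
    mode = match.arg(mode),
    cutoffs = cutoffs,
    block_cap = block_cap
  ), class = "pipeline_config")
  if (!inherits(cutoffs, "cutoff_config")) stop("cutoffs must be a cutoff_config")
  cfg
}

#' Load a pipeline configuration from YAML
#'
#' Recognized keys: `columns`, `date_dialect`, `segment_bits`,
#' `num_hashes`, `mode`, `cutoffs` (with `upper`, `lower`, `shift_step`,
#' `max_rounds`), `block_cap`.
#'
#' @param path YAML file.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(y$columns)) args$columns <- y$columns
  if (!is.null(y$date_dialect)) args$date_dialect <- y$date_dialect
  if (!is.null(y$segment_bits)) args$segment_bits <- unlist(y$segment_bits)
  if (!is.null(y$num_hashes)) args$num_hashes <- y$num_hashes
  if (!is.null(y$mode)) args$mode <- y$mode
  if (!is.null(y$cutoffs)) args$cutoffs <- do.call(cutoff_config, y$cutoffs)
  if (!is.null(y$block_cap)) args$block_cap <- y$block_cap
  do.call(pipeline_config, args)
}

#' Read a person file and map its columns
#'
#' @param path CSV (UTF-8, header row) or an already-loaded data.frame.
#' @param config a [pipeline_config()] supplying the column mapping.
#' @return data.frame with canonical column names, all character.
#' @export
read_person_file <- function(path, config = pipeline_config()) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  }
  out <- data.frame(row.names = seq_len(nrow(df)))
  for (canon in c("record_id", linkage_attributes())) {
    src <- config$columns[[canon]]
    if (!src %in% names(df)) {
      stop("input file lacks mapped column '", src, "' (for ", canon, ")")
    }
    out[[canon]] <- as.character(df[[src]])
  }
  out
}

#' Read a gold-standard pair file
#'
#' @param path CSV with columns `id_a`, `id_b`, or a data.frame.
#' @export
read_gold_file <- function(path) {
  df <- if (is.data.frame(path)) path else {
    utils::read.csv(path, colClasses = "character", fileEncoding = "UTF-8")
  }
  if (!all(c("id_a", "id_b") %in% names(df))) {
    stop("gold-standard file needs columns id_a and id_b")
  }
  data.frame(id_a = as.character(df$id_a), id_b = as.character(df$id_b),
             stringsAsFactors = FALSE)
}

.stage_log <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(fmt, ...))
}

#' Run the full linkage pipeline
#'
#' Stages run in order: harmonize, block, encode, compare, classify and,
#' when a gold standard is supplied, evaluate. The evaluation universe is
#' the union of candidate pairs and gold pairs, so gold pairs the blocking
#' missed are counted as false negatives. Deterministic for fixed inputs
#' and config.
#'
#' @param file_a,file_b input CSVs or data.frames.
#' @param config a [pipeline_config()].
#' @param gold optional gold-standard pairs (path or data.frame).
#' @param out_dir optional directory for stage artifacts (`matches.csv`,
#'   `non_matches.csv`, `dubious.csv`, `comparisons.csv`, and
#'   `accuracy.json` when evaluated).
#' @param verbose log per-stage record/pair counts.
#' @return list with `harmonized_a`, `harmonized_b`, `candidate_pairs`,
#'   `comparisons`, `decisions`, `matches` (after one-to-one dedup),
#'   `non_matches`, `dubious`, and `report` (`NULL` without gold).
#' @export
run_pipeline <- function(file_a, file_b, config = pipeline_config(),
                         gold = NULL, out_dir = NULL, verbose = TRUE) {
  raw_a <- read_person_file(file_a, config)
  raw_b <- read_person_file(file_b, config)
  .stage_log(verbose, "read: %d records (A), %d records (B)",
             nrow(raw_a), nrow(raw_b))

  ha <- harmonize_records(raw_a, config$harmonize)
  hb <- harmonize_records(raw_b, config$harmonize)
  .stage_log(verbose, "harmonize: %d unblockable in A, %d in B",
             length(unblockable_records(ha)), length(unblockable_records(hb)))

  pairs <- build_candidate_pairs(ha, hb, config$block_cap)
  .stage_log(verbose, "block: %d candidate pairs", nrow(pairs))

  fa <- encode_records(ha, config$filter)
  fb <- encode_records(hb, config$filter)
  .stage_log(verbose, "encode: %d-bit composite filters", ncol(fa))

  comparisons <- compare_pairs(pairs, fa, fb, mode = config$mode)
  decisions <- classify_all(comparisons, config$cutoffs)
  matches <- best_match_dedup(decisions)
  non_matches <- decisions[decisions$label == "non_match", , drop = FALSE]
  dubious <- decisions[decisions$label == "dubious", , drop = FALSE]
  .stage_log(verbose,
             "classify (%s): %d matches (after dedup), %d non-matches, %d dubious",
             config$mode, nrow(matches), nrow(non_matches), nrow(dubious))

  report <- NULL
  if (!is.null(gold)) {
    gold <- read_gold_file(gold)
    universe <- unique(rbind(pairs[c("id_a", "id_b")],
                             gold[c("id_a", "id_b")]))
    report <- accuracy_report(matches[c("id_a", "id_b")], gold, universe,
                              scored = comparisons,
                              ids_a = ha$record_id, ids_b = hb$record_id)
    .stage_log(verbose, "evaluate: TP %d FP %d FN %d",
               report$counts$tp, report$counts$fp, report$counts$fn)
  }

  result <- list(harmonized_a = ha, harmonized_b = hb,
                 candidate_pairs = pairs, comparisons = comparisons,
                 decisions = decisions, matches = matches,
                 non_matches = non_matches, dubious = dubious,
                 report = report)

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    cols <- c("id_a", "id_b", "score", "round")
    utils::write.csv(matches[cols], file.path(out_dir, "matches.csv"),
                     row.names = FALSE)
    utils::write.csv(non_matches[cols], file.path(out_dir, "non_matches.csv"),
                     row.names = FALSE)
    utils::write.csv(dubious[cols], file.path(out_dir, "dubious.csv"),
                     row.names = FALSE)
    utils::write.csv(comparisons, file.path(out_dir, "comparisons.csv"),
                     row.names = FALSE)
    if (!is.null(report)) {
      jsonlite::write_json(
        list(counts = report$counts[c("tp", "fp", "tn", "fn")],
             metrics = report$metrics[c("sensitivity", "specificity", "ppv")],
             best_cutoff = if (!is.null(report$roc)) report$roc$best_cutoff),
        file.path(out_dir, "accuracy.json"), auto_unbox = TRUE, digits = NA)
      if (!is.null(report$roc)) {
        utils::write.csv(report$roc$roc, file.path(out_dir, "roc.csv"),
                         row.names = FALSE)
      }
    }
  }
  result
}
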