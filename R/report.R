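#' Classification report for a call set
#'
#' Orchestrates scoring, classification and context annotation, and
#' assembles the composition tables: quality-class percentages and
#' per-class context percentages.
#'
#' @param cs an `indel_callset` (e.g. from [read_indel_vcf()]).
#' @param reference reference sequences; required unless contexts are
#'   already annotated.
#' @param thresholds a [quality_thresholds()] object.
#' @return A list of class `classify_report`: `callset` (annotated),
#'   `class_table` (class, n, percent), `context_tables` (one data frame
#'   per stratum `all`/`high`/`low`).
#' @export
classify_report <- function(cs, reference = NULL,
                            thresholds = quality_thresholds()) {
  stopifnot(inherits(cs, "indel_callset"))
  if (nrow(cs$calls) && !all(cs$calls$normalized)) {
    if (is.null(reference)) {
      stop("un-normalized calls: supply a reference")
    }
    cs <- normalize_calls(cs, reference)
  }
  cs <- annotate_quality(cs, thresholds)
  if (nrow(cs$calls) && any(cs$calls$context == "unset")) {
    if (is.null(reference)) {
      stop("contexts not annotated: supply a reference")
    }
    cs <- annotate_context(cs, reference)
  }
  if (!nrow(cs$calls)) {
    warning("empty call set: report tables are empty", call. = FALSE)
    return(structure(list(callset = cs,
                          class_table = data.frame(),
                          context_tables = list()),
                     class = "classify_report"))
  }
  cls <- class_composition(cs)
  cls$percent <- round(100 * cls$proportion, 1)
  ctx <- lapply(c(all = "all", high = "high", low = "low"),
                function(s) {
                  tab <- context_composition(cs, stratum = s)
                  tab$percent <- round(100 * tab$proportion, 1)
                  tab
                })
  structure(list(callset = cs, class_table = cls, context_tables = ctx),
            class = "classify_report")
}

#' @export
print.classify_report <- function(x, ...) {
  cat("Quality-class composition (n =", n_calls(x$callset), "):\n")
  if (nrow(x$class_table)) {
    print(x$class_table[, c("class", "n", "percent")], row.names = FALSE)
  }
  invisible(x)
}

#' Concordance table across depth floors
#'
#' Mirrors the coverage-stratified concordance layout: one row per depth
#' floor (default `{0, 1, 20, 40, 60, 80}`) with the concordant and
#' set-specific percentages under the chosen match mode.
#'
#' @param a,b normalized `indel_callset`s.
#' @param depth_a,depth_b per-locus depth tables (see
#'   [compare_callsets()]); e.g. [callset_depth_table()].
#' @param floors integer vector of depth floors.
#' @param mode `"exact"` or `"position"`.
#' @return Data frame: `depth_floor`, `concordant`, `a_specific`,
#'   `b_specific` (percent, 1 decimal), `n_intersection`,
#'   `n_a_specific`, `n_b_specific`.
#' @export
concordance_table <- function(a, b, depth_a = NULL, depth_b = NULL,
                              floors = c(0L, 1L, 20L, 40L, 60L, 80L),
                              mode = "exact") {
  rows <- lapply(floors, function(fl) {
    r <- compare_callsets(a, b, mode = mode, depth_a = depth_a,
                          depth_b = depth_b, depth_floor = fl)
    data.frame(depth_floor = fl,
               concordant = round(r$rate_concordant, 1),
               a_specific = round(r$rate_a_specific, 1),
               b_specific = round(r$rate_b_specific, 1),
               n_intersection = r$n_intersection,
               n_a_specific = r$n_a_specific,
               n_b_specific = r$n_b_specific,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Venn-style concordance summary
#'
#' Counts and percentages of the intersection and set-specific
#' compartments of one comparison, as a JSON-ready list.
#'
#' @param result a [compare_callsets()] result.
#' @param labels length-2 character: names of the two sets.
#' @return A list with `mode`, `depth_floor`, `counts`, `percent`.
#' @export
venn_summary <- function(result, labels = c("A", "B")) {
  stopifnot(inherits(result, "concordance_result"))
  list(mode = result$mode, depth_floor = result$depth_floor,
       counts = stats::setNames(
         list(result$n_intersection, result$n_a_specific,
              result$n_b_specific),
         c("intersection", paste0(labels[1L], "_specific"),
           paste0(labels[2L], "_specific"))),
       percent = stats::setNames(
         list(round(result$rate_concordant, 1),
              round(result$rate_a_specific, 1),
              round(result$rate_b_specific, 1)),
         c("intersection", paste0(labels[1L], "_specific"),
           paste0(labels[2L], "_specific"))))
}

#' Validation (PPV) report
#'
#' Tabulates positive predictive values from tested/valid counts, with
#' an optional large-INDEL (> 5 bp) stratum, percentages to one decimal.
#'
#' @param categories character vector of row labels.
#' @param n_tested,n_valid integer vectors, one entry per category.
#' @param n_tested_large,n_valid_large optional large-INDEL strata.
#' @return Data frame with `category`, `n_tested`, `n_valid`, `ppv`
#'   (and the large-stratum columns when supplied).
#' @examples
#' validation_report("intersection", 160, 152)   # PPV 95.0
#' @export
validation_report <- function(categories, n_tested, n_valid,
                              n_tested_large = NULL,
                              n_valid_large = NULL) {
  out <- data.frame(category = categories, n_tested = n_tested,
                    n_valid = n_valid,
                    ppv = round(ppv(n_tested, n_valid), 1),
                    stringsAsFactors = FALSE)
  if (!is.null(n_tested_large)) {
    out$n_tested_large <- n_tested_large
    out$n_valid_large <- n_valid_large
    out$ppv_large <- ifelse(n_tested_large > 0,
                            round(100 * n_valid_large / n_tested_large,
                                  1), NA_real_)
  }
  out
}

#' Score a call set against validation truth
#'
#' Marks each call valid when a truth record matches it under the chosen
#' predicate, and reports PPV overall and for the large-INDEL stratum.
#'
#' @param calls,truth normalized `indel_callset`s.
#' @param match `"validation"` (position + same variation type, the
#'   predicate used against amplicon resequencing truth), `"exact"`, or
#'   `"position"`.
#' @return A list: `per_call` (data frame with a `valid` column),
#'   `table` (a [validation_report()] row).
#' @export
validate_against_truth <- function(calls, truth,
                                   match = c("validation", "exact",
                                             "position")) {
  match <- match.arg(match)
  stopifnot(inherits(calls, "indel_callset"),
            inherits(truth, "indel_callset"))
  cc <- calls$calls; tc <- truth$calls
  if ((nrow(cc) && !all(cc$normalized)) ||
      (nrow(tc) && !all(tc$normalized))) {
    stop("both call sets must be left-normalized")
  }
  key_of <- switch(match,
    exact = call_key,
    position = locus_key,
    validation = function(df) paste(df$chrom, df$pos, df$itype,
                                    sep = "\r"))
  valid <- key_of(cc) %in% key_of(tc)
  large <- cc$size > 5L
  tab <- validation_report(
    categories = calls$label, n_tested = nrow(cc), n_valid = sum(valid),
    n_tested_large = sum(large), n_valid_large = sum(valid & large))
  per_call <- cc[, c("chrom", "pos", "ref", "alt", "size")]
  per_call$valid <- valid
  list(per_call = per_call, table = tab)
}

#' Large-INDEL fraction of a call set
#'
#' Count and percentage of calls of size greater than 5 bp.
#'
#' @param cs an `indel_callset`, or an integer total count when
#'   `n_large` is given.
#' @param n_large optional large-call count (to compute from printed
#'   counts directly).
#' @return A list with `n`, `n_large`, `percent` (1 decimal).
#' @examples
#' large_indel_fraction(2009, 176)   # 8.8 percent
#' @export
large_indel_fraction <- function(cs, n_large = NULL) {
  if (inherits(cs, "indel_callset")) {
    n <- nrow(cs$calls)
    n_large <- sum(cs$calls$size > 5L)
  } else {
    n <- as.integer(cs)
    stopifnot(!is.null(n_large))
  }
  list(n = n, n_large = n_large,
       percent = if (n > 0) round(100 * n_large / n, 1) else NA_real_)
}

#' Run manifest
#'
#' JSON-ready record of a command invocation (inputs, parameters, seed,
#' package version) sufficient to re-run deterministic paths
#' bit-identically.
#'
#' @param command command name.
#' @param inputs named list of input paths.
#' @param parameters named list of parameters.
#' @param seed integer seed (or `NULL`).
#' @param path optional path to write the manifest JSON to.
#' @return The manifest list, invisibly when written to `path`.
#' @export
run_manifest <- function(command, inputs = list(), parameters = list(),
                         seed = NULL, path = NULL) {
  m <- list(command = command,
            package = "indelqc",
            version = as.character(utils::packageVersion("indelqc")),
            timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
            seed = seed, inputs = inputs, parameters = parameters)
  if (!is.null(path)) {
    jsonlite::write_json(m, path, auto_unbox = TRUE, pretty = TRUE,
                         null = "null")
    return(invisible(m))
  }
  m
}
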