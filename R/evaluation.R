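#' Labeled drug sets for recall evaluation
#'
#' Holds the two reference labelings used to score a screen: drugs
#' whose original indication is the target disease class, and drugs
#' without that original indication that are in clinical trials for it.
#' The two sets are disjoint by construction of the trial set.
#'
#' @param original Character vector: drugs with the class as original
#'   indication.
#' @param trial Character vector: drugs in trials for the class (must
#'   not overlap `original`).
#' @param universe Character vector: all screened drugs (superset of
#'   both).
#' @return A `moa_labels` object.
#' @export
label_sets <- function(original, trial, universe) {
  original <- unique(as.character(original))
  trial <- unique(as.character(trial))
  universe <- unique(as.character(universe))
  if (length(intersect(original, trial))) {
    abort(sprintf("labels overlap (trial drugs must lack the original indication): %s",
                  paste(intersect(original, trial), collapse = ", ")))
  }
  out <- setdiff(c(original, trial), universe)
  if (length(out)) {
    abort(sprintf("labeled drug(s) outside the universe: %s",
                  paste(out, collapse = ", ")))
  }
  structure(
    list(original_indication = sort(original), trial_evidence = sort(trial),
         universe = sort(universe)),
    class = "moa_labels"
  )
}

#' @export
print.moa_labels <- function(x, ...) {
  cat(sprintf("<moa_labels> %d original-indication, %d trial, universe %d\n",
              length(x$original_indication), length(x$trial_evidence),
              length(x$universe)))
  invisible(x)
}

#' Recall-style metrics of an inferred drug set
#'
#' Scores a set of inferred drugs against [label_sets()]: recall on the
#' original-indication set, recall on the trial set, the number of
#' inferences, and the confirmed fraction (share of inferred drugs in
#' either labeled set).  Percentages are reported to one decimal.  A
#' metric whose denominator is empty is undefined and reported as `NA`,
#' never as zero.
#'
#' @param inferred Character vector of inferred drugs (subset of the
#'   label universe).
#' @param labels A [label_sets()] object.
#' @return A one-row tibble: `n_inferred`, `n_original`, `n_trial`,
#'   `n_confirmed`, `recall_original_pct`, `recall_trial_pct`,
#'   `confirmed_pct`.
#' @examples
#' labels <- label_sets(original = c("a", "b", "d", "e"), trial = "f",
#'                      universe = letters[1:6])
#' recall_metrics(c("a", "b", "c"), labels)
#' @export
recall_metrics <- function(inferred, labels) {
  stopifnot(inherits(labels, "moa_labels"))
  inferred <- unique(as.character(inferred))
  out <- setdiff(inferred, labels$universe)
  if (length(out)) {
    abort(sprintf("inferred drug(s) outside the label universe: %s",
                  paste(out, collapse = ", ")))
  }
  pct <- function(num, den) if (den == 0) NA_real_ else round(100 * num / den, 1)
  n_orig_hit <- length(intersect(inferred, labels$original_indication))
  n_trial_hit <- length(intersect(inferred, labels$trial_evidence))
  n_confirmed <- length(intersect(
    inferred, union(labels$original_indication, labels$trial_evidence)
  ))
  tibble(
    n_inferred = length(inferred),
    n_original = n_orig_hit,
    n_trial = n_trial_hit,
    n_confirmed = n_confirmed,
    recall_original_pct = pct(n_orig_hit, length(labels$original_indication)),
    recall_trial_pct = pct(n_trial_hit, length(labels$trial_evidence)),
    confirmed_pct = pct(n_confirmed, length(inferred))
  )
}

#' Knowledge-source ablation of a screen
#'
#' Re-runs the full-drug screen with the terminal and relational
#' knowledge restricted to each provenance subset (drug-target facts
#' are always retained — without an initial trigger no column could
#' infer anything) and scores each restricted screen against the
#' labels, alongside the complete knowledge base.
#'
#' @param kb A `moa_kb` object.
#' @param source_subsets List of character vectors of source tags; by
#'   default each of `cancer_genes`, `go`, `text_mining` alone.  Tags
#'   must be drawn from the recognised vocabulary; a subset whose tags
#'   match no facts simply infers nothing.
#' @param disease_class,map,policy Passed to [infer_all()].
#' @param labels A [label_sets()] object whose universe covers the
#'   registered drugs.
#' @return A `moa_ablation` object; its `table` has one row per subset
#'   plus a final `"all"` row, with the recall metrics and the inferred
#'   drug set as a list-column.
#' @export
source_ablation <- function(kb,
                            source_subsets = list("cancer_genes", "go",
                                                  "text_mining"),
                            disease_class = "cancer",
                            map = disease_class_map(disease_class),
                            policy = engine_policy(),
                            labels = NULL) {
  for (s in source_subsets) {
    bad <- setdiff(s, SOURCE_TAGS)
    if (length(bad)) {
      abort(sprintf("unknown source tag(s): %s", paste(bad, collapse = ", ")))
    }
  }
  run_one <- function(kb_sub, label_txt) {
    screen <- infer_all(kb_sub, disease_class, map, policy)
    inferred <- inferred_drugs(screen)
    metrics <- if (!is.null(labels)) {
      recall_metrics(inferred, labels)
    } else {
      tibble(n_inferred = length(inferred))
    }
    mutate(metrics, sources = label_txt, inferred = list(inferred),
           .before = 1)
  }
  rows <- map(source_subsets, function(s) {
    run_one(filter_kb_sources(kb, s), paste(sort(s), collapse = "+"))
  })
  rows <- c(rows, list(run_one(kb, "all")))
  structure(
    list(table = list_rbind(rows), disease_class = disease_class,
         policy = policy),
    class = "moa_ablation"
  )
}

#' @export
print.moa_ablation <- function(x, ...) {
  cat(sprintf("<moa_ablation> %s, %d source subset(s) + full KB\n",
              x$disease_class, nrow(x$table) - 1L))
  print(select(x$table, -"inferred"), ...)
  invisible(x)
}

#' Text table of an ablation result
#'
#' Renders the ablation as a compact source-by-metric text table
#' (sources as columns, label rows and totals as rows).
#'
#' @param x A `moa_ablation` object.
#' @return Character vector of lines, invisibly; also printed.
#' @export
format_ablation_table <- function(x) {
  tb <- x$table
  cols <- tb$sources
  fmt_pct <- function(v) ifelse(is.na(v), "-", sprintf("%.1f%%", v))
  rows <- list(c("Total inferences", sprintf("%d", tb$n_inferred)))
  if ("n_original" %in% names(tb)) {
    rows <- c(
      list(c("Original indication", sprintf("%d", tb$n_original)),
           c("Trial evidence", sprintf("%d", tb$n_trial))),
      rows,
      list(c("% confirmed", fmt_pct(tb$confirmed_pct)))
    )
  }
  widths <- pmax(nchar(cols), 12L)
  header <- paste(c(sprintf("%-22s", ""),
                    sprintf(paste0("%", widths, "s"), cols)), collapse = "  ")
  body <- vapply(rows, function(r) {
    paste(c(sprintf("%-22s", r[[1]]),
            sprintf(paste0("%", widths, "s"), r[-1])), collapse = "  ")
  }, character(1))
  lines <- c(header, body)
  cat(lines, sep = "\n")
  invisible(lines)
}
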