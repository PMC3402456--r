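#' Write a screen's chains as JSON
#'
#' Serializes a [infer_all()] result to the package's chain-exchange
#' JSON: per drug the contradiction verdict and the list of chains,
#' each chain a classification plus its ordered triggers with rule ids
#' and support facts.  Output is byte-stable for identical inputs
#' (drugs and chains are already deterministically ordered).
#'
#' @param screen A `moa_screen` object.
#' @param path Output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
write_chains_json <- function(screen, path = NULL) {
  payload <- list(
    disease_class = screen$disease_class,
    policy = unclass(screen$policy),
    drugs = map(screen$results, inference_to_list)
  )
  json <- jsonlite::toJSON(payload, auto_unbox = TRUE, pretty = TRUE,
                           digits = NA, null = "null")
  if (!is.null(path)) {
    writeLines(json, path)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

inference_to_list <- function(x) {
  chains <- map(x$chain_info$chain, function(i) {
    steps <- filter(x$chains, .data$chain == i)
    list(
      classification = x$chain_info$classification[[i]],
      triggers = map(seq_len(nrow(steps)), function(k) {
        list(step = steps$step[[k]], action = steps$action[[k]],
             target = steps$target[[k]], rule = steps$rule[[k]],
             support = as.list(steps$support[[k]]))
      })
    )
  })
  list(verdict = x$report$verdict, blocked = x$blocked, chains = chains)
}

#' Read chains JSON back into a trigger-level tibble
#'
#' @param path Path to a file written by [write_chains_json()].
#' @return A tibble (`chain`, `drug`, `step`, `action`, `target`,
#'   `rule`, `support`) with globally unique chain ids, suitable for
#'   [validate_chains()].
#' @export
read_chains_json <- function(path) {
  obj <- jsonlite::read_json(path)
  rows <- list()
  cid <- 0L
  for (drug in names(obj$drugs)) {
    for (ch in obj$drugs[[drug]]$chains) {
      cid <- cid + 1L
      for (tr in ch$triggers) {
        rows[[length(rows) + 1L]] <- tibble(
          chain = cid, drug = drug, step = as.integer(tr$step),
          action = tr$action, target = tr$target, rule = tr$rule,
          support = list(unlist(tr$support))
        )
      }
    }
  }
  if (length(rows) == 0) {
    return(tibble(chain = integer(), drug = character(), step = integer(),
                  action = character(), target = character(),
                  rule = character(), support = list()))
  }
  list_rbind(rows)
}
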