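#' Match cases to control candidates on exact covariate keys
#'
#' One-to-one exact matching on the triple (birth year, screening year,
#' mammographic system), the design used to assemble matched screening
#' case-control cohorts. When several candidates share a key, selection
#' follows a seeded random permutation, so results are deterministic given
#' the seed and invariant to the input row order (records are sorted by
#' `woman_id` before permuting). Unmatched cases are reported, never
#' silently dropped.
#'
#' @param cases Data frame of case records (`woman_id`, `birth_year`,
#'   `screening_year`, `system`).
#' @param pool Data frame of control candidates, same columns.
#' @param seed Integer seed controlling candidate selection.
#' @return A list with `pairs` (data frame: `case_id`, `control_id`,
#'   `birth_year`, `screening_year`, `system`) and `unmatched` (character
#'   vector of case `woman_id`s without an available candidate).
#' @export
match_cases <- function(cases, pool, seed) {
  if (nrow(cases) && nrow(pool) &&
      length(intersect(cases$woman_id, pool$woman_id))) {
    stop("woman_id appears in both the case list and the candidate pool")
  }
  if (anyDuplicated(cases$woman_id)) stop("duplicate woman_id among cases")
  if (anyDuplicated(pool$woman_id)) stop("duplicate woman_id among candidates")

  cases <- cases[order(cases$woman_id), , drop = FALSE]
  pool <- pool[order(pool$woman_id), , drop = FALSE]
  key <- function(df) paste(df$birth_year, df$screening_year, df$system,
                            sep = "\r")
  case_key <- key(cases)
  pool_key <- key(pool)

  set.seed(as.integer(seed))
  perm <- sample.int(nrow(pool))
  pool_order <- pool[perm, , drop = FALSE]
  pool_key_order <- pool_key[perm]
  used <- logical(nrow(pool_order))

  case_id <- control_id <- character(0)
  by <- sy <- integer(0)
  sys <- character(0)
  unmatched <- character(0)
  for (i in seq_len(nrow(cases))) {
    j <- which(!used & pool_key_order == case_key[i])
    if (length(j)) {
      j <- j[1]
      used[j] <- TRUE
      case_id <- c(case_id, cases$woman_id[i])
      control_id <- c(control_id, pool_order$woman_id[j])
      by <- c(by, cases$birth_year[i])
      sy <- c(sy, cases$screening_year[i])
      sys <- c(sys, as.character(cases$system[i]))
    } else {
      unmatched <- c(unmatched, cases$woman_id[i])
    }
  }
  list(
    pairs = data.frame(
      case_id = case_id, control_id = control_id,
      birth_year = by, screening_year = sy, system = sys,
      stringsAsFactors = FALSE
    ),
    unmatched = unmatched
  )
}

#' Summarize a cohort by age band, mammographic system and cancer type
#'
#' Age is screening year minus birth year (the tables only carry years).
#' Bands are `<55`, `55-59`, `60-64`, `>64`; percentages are rounded to the
#' nearest integer within each status group.
#'
#' @param records Cohort data frame (see [read_cohort()]).
#' @return An object of class `cohort_summary`: a list of data frames
#'   (`age`, `system`, `cancer_type`), each with counts and integer
#'   percentages per status group.
#' @export
cohort_summary <- function(records) {
  records$age <- records$screening_year - records$birth_year
  records$age_band <- cut(records$age, breaks = c(-Inf, 54, 59, 64, Inf),
                          labels = c("<55", "55-59", "60-64", ">64"))
  tab <- function(var, data) {
    out <- list()
    for (st in c("case", "control")) {
      sub <- data[data$status == st, , drop = FALSE]
      n <- nrow(sub)
      counts <- table(sub[[var]])
      if (length(counts) == 0) next
      out[[st]] <- data.frame(
        level = names(counts),
        status = st,
        count = as.integer(counts),
        percent = if (n > 0) as.integer(round(100 * as.integer(counts) / n))
                  else integer(length(counts)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  }
  cases <- records[records$status == "case", , drop = FALSE]
  n_type <- nrow(cases)
  type_counts <- table(cases$cancer_type[nzchar(cases$cancer_type)])
  structure(list(
    n = table(records$status),
    age = tab("age_band", records),
    system = tab("system", records),
    cancer_type = data.frame(
      level = names(type_counts),
      count = as.integer(type_counts),
      percent = if (n_type > 0)
        as.integer(round(100 * as.integer(type_counts) / n_type))
        else integer(length(type_counts)),
      stringsAsFactors = FALSE
    )
  ), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat("Cohort summary\n")
  cat(sprintf("  cases: %d, controls: %d\n",
              x$n[["case"]], x$n[["control"]]))
  cat("Age bands:\n")
  print(x$age, row.names = FALSE)
  cat("Mammographic system:\n")
  print(x$system, row.names = FALSE)
  if (nrow(x$cancer_type)) {
    cat("Cancer type (cases):\n")
    print(x$cancer_type, row.names = FALSE)
  }
  invisible(x)
}
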