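# ASRS symptom-checklist scoring.
#
# The 18-item adult ADHD self-report scale rates each symptom 0-3; an item
# rated 2 ("often") or 3 ("very often") counts as one positive symptom.
# Items split 9/9 into inattention and hyperactivity-impulsivity domains.

#' Default item-to-domain assignment
#'
#' Items 1-9 inattention, 10-18 hyperactivity-impulsivity (DSM symptom
#' ordering). Override by passing a custom map to [score_asrs()].
#'
#' @return Character vector of length 18 with values "inattention" /
#'   "hyperactivity_impulsivity".
#' @export
default_asrs_domains <- function() {
  rep(c("inattention", "hyperactivity_impulsivity"), each = 9L)
}

#' Score an ASRS response into symptom counts
#'
#' @param items Integer vector of 18 item responses, each in 0..3.
#' @param domain_map Character vector of length 18 assigning each item to
#'   "inattention" or "hyperactivity_impulsivity", 9 items each.
#' @return Named list `total` (0-18), `inattention` (0-9),
#'   `hyperactivity_impulsivity` (0-9); `total` is always the sum of the two
#'   domain counts.
#' @export
score_asrs <- function(items, domain_map = default_asrs_domains()) {
  items <- as.integer(items)
  if (length(items) != 18L || anyNA(items) ||
      any(items < 0L | items > 3L)) {
    stop("ASRS responses must be 18 integers, each in 0..3")
  }
  domain_map <- as.character(domain_map)
  if (length(domain_map) != 18L ||
      sum(domain_map == "inattention") != 9L ||
      sum(domain_map == "hyperactivity_impulsivity") != 9L) {
    stop("domain_map must assign 18 items, 9 per domain")
  }
  positive <- items >= 2L
  inatt <- sum(positive[domain_map == "inattention"])
  hyper <- sum(positive[domain_map == "hyperactivity_impulsivity"])
  list(total = inatt + hyper, inattention = inatt,
       hyperactivity_impulsivity = hyper)
}

#' Score ASRS columns of a subject-metadata table
#'
#' Expects columns `asrs_01` .. `asrs_18`; appends `symptoms_total`,
#' `symptoms_inattention`, `symptoms_hyperactivity` columns.
#'
#' @param metadata Data frame with one row per subject.
#' @param domain_map See [score_asrs()].
#' @return The input data frame with the three score columns added.
#' @export
score_asrs_table <- function(metadata, domain_map = default_asrs_domains()) {
  cols <- sprintf("asrs_%02d", 1:18)
  missing <- setdiff(cols, names(metadata))
  if (length(missing) > 0L) {
    stop("metadata is missing ASRS columns: ", paste(missing, collapse = ", "))
  }
  scores <- t(apply(as.matrix(metadata[cols]), 1L, function(it) {
    s <- score_asrs(it, domain_map)
    c(s$total, s$inattention, s$hyperactivity_impulsivity)
  }))
  metadata$symptoms_total <- scores[, 1L]
  metadata$symptoms_inattention <- scores[, 2L]
  metadata$symptoms_hyperactivity <- scores[, 3L]
  metadata
}
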