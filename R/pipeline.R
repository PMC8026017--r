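# End-to-end convenience wrappers: transcripts dir -> profiles CSV ->
# correlation table. Thin CLI front-ends live in inst/scripts/.

#' Windowed attribute profiles for a transcript directory
#'
#' Reads every `.txt` transcript, tokenizes, removes stop-words (and
#' numerals), and computes the windowed mean attributes per subject.
#'
#' @param transcripts_dir Directory of UTF-8 transcripts, one per subject.
#' @param stopwords A `stopword_list`, a path to a list file, or a language
#'   tag ("pt"/"en") for a bundled list.
#' @param cfg A [window_config()].
#' @param out Optional CSV path for the profile table.
#' @param ... Passed to [profile_narrative()] (`tnw`, `re_mode`, ...).
#' @return Profile data frame (one row per subject), invisibly when written.
#' @export
attributes_pipeline <- function(transcripts_dir, stopwords = "pt",
                                cfg = window_config(), out = NULL, ...) {
  stops <- if (inherits(stopwords, "stopword_list")) stopwords
           else if (stopwords %in% c("pt", "en")) default_stopwords(stopwords)
           else read_stopwords(stopwords)
  seqs <- lapply(read_transcripts(transcripts_dir),
                 function(t) remove_stopwords(tokenize(t), stops))
  profiles <- profile_cohort(seqs, cfg, ...)
  if (!is.null(out)) {
    utils::write.csv(profiles, out, row.names = FALSE)
    return(invisible(profiles))
  }
  profiles
}

#' Correlation tables from profiles and subject metadata
#'
#' @param profiles Profile data frame (or CSV path) from
#'   [attributes_pipeline()].
#' @param metadata Subject metadata data frame (or CSV path) with ASRS item
#'   columns and covariates.
#' @param covariates Covariate column names; `NULL` for the unadjusted
#'   analysis, [DEFAULT_COVARIATES] for the adjusted one.
#' @param family_size,alpha Passed to [correlation_table()].
#' @param out Optional CSV path.
#' @return Correlation-result data frame, invisibly when written.
#' @export
correlate_pipeline <- function(profiles, metadata, covariates = NULL,
                               family_size = 4L, alpha = 0.05, out = NULL) {
  if (is.character(profiles)) {
    profiles <- utils::read.csv(profiles, stringsAsFactors = FALSE)
  }
  if (is.character(metadata)) {
    metadata <- utils::read.csv(metadata, stringsAsFactors = FALSE)
  }
  cohort <- build_cohort_table(profiles, metadata)
  tab <- correlation_table(cohort, covariates = covariates %||% character(0),
                           family_size = family_size, alpha = alpha)
  if (!is.null(out)) {
    utils::write.csv(tab, out, row.names = FALSE)
    return(invisible(tab))
  }
  tab
}

#' Run the full pipeline on an in-memory synthetic cohort
#'
#' Profiles the cohort's narratives (no stop-word stage: synthetic tokens are
#' not natural language), scores the ASRS items and returns the correlation
#' table.
#'
#' @param cohort A `synthetic_cohort` from [generate_cohort()].
#' @param covariates As in [correlate_pipeline()].
#' @param cfg A [window_config()].
#' @param family_size,alpha Passed to [correlation_table()].
#' @return Correlation-result data frame.
#' @export
cohort_pipeline <- function(cohort, covariates = NULL,
                            cfg = window_config(), family_size = 4L,
                            alpha = 0.05) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  profiles <- profile_cohort(cohort$narratives, cfg)
  cohort_tab <- build_cohort_table(profiles, cohort$metadata)
  correlation_table(cohort_tab, covariates = covariates %||% character(0),
                    family_size = family_size, alpha = alpha)
}
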