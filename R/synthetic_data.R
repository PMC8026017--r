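# Synthetic narratives and cohorts with known recurrence structure.
#
# The narrative generator is a three-branch token process: with probability
# p_repeat the previous token is emitted again (driving self-loops, L1); with
# probability p_backref a token is drawn uniformly from the most recent `lag`
# distinct tokens (driving repeated edges and directed cycles, hence RE and
# LSC); otherwise a fresh, previously unused word is drawn uniformly from the
# vocabulary (recycling an arbitrary non-previous word once the vocabulary is
# exhausted). The back-reference pool excludes the immediately preceding
# token, so the three branches control L1, RE/LSC and novelty separately.

# run `code` under a temporary RNG state seeded with `seed`; the caller's
# RNG state is restored afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Generate one synthetic narrative token stream
#'
#' Tokens are synthetic strings ("w001", "w002", ...), never real words, so
#' the generator does not interact with stop-word lists.
#'
#' @param length Number of tokens to emit.
#' @param vocab_size Vocabulary size (>= 2).
#' @param p_repeat Probability of repeating the previous token (drives L1).
#' @param p_backref Probability of re-emitting one of the last `lag` distinct
#'   tokens, excluding the immediately preceding one (drives RE and LSC).
#'   `p_repeat + p_backref` must be <= 1; the remaining mass emits a fresh,
#'   previously unused vocabulary word (uniform), so with
#'   `p_repeat = p_backref = 0` and `vocab_size >= length` the stream is
#'   entirely distinct. A narrative that exhausts the vocabulary falls back
#'   to a uniform draw excluding the previous token.
#' @param lag Size of the back-reference pool of recent distinct tokens.
#' @param subject_id Identifier for the resulting sequence.
#' @param seed Optional integer seed; the caller's RNG state is untouched.
#' @return A `token_sequence` of `length` tokens.
#' @export
generate_narrative <- function(length = 180L, vocab_size = 120L,
                               p_repeat = 0.10, p_backref = 0.20,
                               lag = 7L, subject_id = "sim", seed = NULL) {
  stopifnot(length >= 1L, vocab_size >= 2L, lag >= 2L)
  if (p_repeat < 0 || p_backref < 0 || p_repeat + p_backref > 1) {
    stop("invalid probability mass: need p_repeat, p_backref >= 0 and ",
         "p_repeat + p_backref <= 1")
  }
  with_seed(seed, {
    vocab <- sprintf("w%03d", seq_len(vocab_size))
    toks <- character(length)
    unused <- sample(vocab)          # fresh words, pre-shuffled draw order
    toks[1L] <- unused[1L]
    unused <- unused[-1L]
    recency <- toks[1L]              # distinct tokens, most recent first
    draw_fresh <- function(prev) {
      if (base::length(unused) > 0L) {
        tok <- unused[1L]
        unused <<- unused[-1L]
        tok
      } else {
        pool <- setdiff(vocab, prev)
        pool[sample.int(base::length(pool), 1L)]
      }
    }
    if (length >= 2L) {
      u <- stats::runif(length - 1L)
      for (i in 2:length) {
        prev <- toks[i - 1L]
        if (u[i - 1L] < p_repeat) {
          tok <- prev
        } else if (u[i - 1L] < p_repeat + p_backref) {
          pool <- setdiff(recency[seq_len(min(lag, base::length(recency)))],
                          prev)
          tok <- if (base::length(pool) == 0L) draw_fresh(prev)
                 else pool[sample.int(base::length(pool), 1L)]
        } else {
          tok <- draw_fresh(prev)
        }
        toks[i] <- tok
        recency <- c(tok, recency[recency != tok])
      }
    }
    token_sequence(toks, subject_id = subject_id)
  })
}

#' Cohort generator parameters
#'
#' Defaults emulate the descriptives of a young-adult community sample:
#' symptom counts over 0-18 with mean about 7.7 and SD about 5.2 (drawn
#' beta-binomially), age 26 (4), IQ 119 (8), 17 (3) years of education,
#' BDI 11 (7), STAI state 46 (12) / trait 44 (13), UPPS 101 (24). The
#' symptom count S is linked to the narrative process by increasing
#' p_repeat(S), decreasing p_backref(S) and increasing narrative length(S);
#' covariates are drawn independently of S unless `confound_via_bdi` is set.
#'
#' @param n_subjects Cohort size (default 58).
#' @param base_p_repeat,slope_p_repeat p_repeat(S) = base + slope * S.
#' @param base_p_backref,slope_p_backref p_backref(S) = base + slope * S.
#' @param base_length,length_per_symptom length(S) = base + incr * S, tokens.
#' @param length_sd Inter-subject narrative-length noise (SD in tokens,
#'   independent of S); lengths are floored at the default window length so
#'   every narrative supports at least one full window.
#' @param vocab_size,lag Narrative-process parameters (see
#'   [generate_narrative()]).
#' @param symptom_shape1,symptom_shape2 Beta parameters of the beta-binomial
#'   symptom distribution over 0..18 (defaults fit the mean/SD above).
#' @param confound_via_bdi If `TRUE`, the depression score becomes a linear
#'   function of S (plus noise) and the narrative process is driven by the
#'   BDI-derived signal instead of S directly — an injected confound that an
#'   adjusted (partial) analysis should remove.
#' @return A list of class `cohort_params`.
#' @export
cohort_params <- function(n_subjects = 58L,
                          base_p_repeat = 0.05, slope_p_repeat = 0.010,
                          base_p_backref = 0.25, slope_p_backref = -0.010,
                          base_length = 180L, length_per_symptom = 4L,
                          length_sd = 25,
                          vocab_size = 120L, lag = 7L,
                          symptom_shape1 = 0.97, symptom_shape2 = 1.30,
                          confound_via_bdi = FALSE) {
  out <- structure(as.list(environment()), class = "cohort_params")
  p_rep <- base_p_repeat + slope_p_repeat * c(0, 18)
  p_back <- base_p_backref + slope_p_backref * c(0, 18)
  if (any(p_rep < 0) || any(p_back < 0) || any(p_rep + p_back > 1)) {
    stop("linkage slopes push probabilities outside [0,1] over S in 0..18")
  }
  if (base_length < 2L) stop("base_length must be at least 2 tokens")
  out
}

#' Generate a synthetic cohort
#'
#' Per subject: a symptom count S is drawn from the beta-binomial symptom
#' distribution; an 18-item ASRS vector consistent with S is built (positive
#' symptoms rated 2 or 3, the rest 0 or 1, positions random); covariates are
#' drawn from the population distributions; and one narrative is generated
#' from p_repeat(S), p_backref(S) and length(S). Scoring the generated item
#' vectors recovers S exactly, so the whole pipeline has ground truth.
#'
#' @param params A [cohort_params()] object.
#' @param seed Integer seed; identical params + seed give byte-identical
#'   cohorts.
#' @return A list of class `synthetic_cohort`: `narratives` (list of
#'   `token_sequence`), `metadata` (data frame in the pipeline's metadata
#'   layout), `symptoms` (the true S per subject).
#' @export
generate_cohort <- function(params = cohort_params(), seed = 1L) {
  stopifnot(inherits(params, "cohort_params"))
  with_seed(seed, {
    n <- params$n_subjects
    ids <- sprintf("sub%03d", seq_len(n))
    p_i <- stats::rbeta(n, params$symptom_shape1, params$symptom_shape2)
    S <- stats::rbinom(n, 18L, p_i)

    items <- t(vapply(S, function(s) {
      it <- sample(0:1, 18L, replace = TRUE)
      if (s > 0L) it[sample.int(18L, s)] <- sample(2:3, s, replace = TRUE)
      it
    }, integer(18L)))

    clip <- function(x, lo, hi) pmin(hi, pmax(lo, x))
    age <- round(clip(stats::rnorm(n, 26, 4), 18, 45))
    iq <- round(clip(stats::rnorm(n, 119, 8), 85, 145))
    edu <- round(clip(stats::rnorm(n, 17, 3), 9, 25))
    bdi <- round(clip(stats::rnorm(n, 11, 7), 0, 40))
    stai_s <- round(clip(stats::rnorm(n, 46, 12), 20, 80))
    stai_t <- round(clip(stats::rnorm(n, 44, 13), 20, 80))
    upps <- round(clip(stats::rnorm(n, 101, 24), 45, 180))

    # narrative driver: S itself, or a BDI-mediated signal when confounded
    if (params$confound_via_bdi) {
      bdi <- round(clip(1.5 * S + stats::rnorm(n, 4, 3), 0, 40))
      driver <- clip(bdi / 1.5, 0, 18)
    } else {
      driver <- S
    }

    lengths <- pmax(30L, round(params$base_length +
                                 params$length_per_symptom * driver +
                                 stats::rnorm(n, 0, params$length_sd)))
    narratives <- vector("list", n)
    for (i in seq_len(n)) {
      narratives[[i]] <- generate_narrative(
        length = lengths[i],
        vocab_size = params$vocab_size,
        p_repeat = params$base_p_repeat + params$slope_p_repeat * driver[i],
        p_backref = params$base_p_backref + params$slope_p_backref * driver[i],
        lag = params$lag,
        subject_id = ids[i])
    }
    names(narratives) <- ids

    metadata <- data.frame(subject_id = ids, stringsAsFactors = FALSE)
    for (j in 1:18) metadata[[sprintf("asrs_%02d", j)]] <- items[, j]
    metadata$age <- age
    metadata$iq <- iq
    metadata$education_years <- edu
    metadata$bdi <- bdi
    metadata$stai_state <- stai_s
    metadata$stai_trait <- stai_t
    metadata$upps_total <- upps

    structure(list(narratives = narratives, metadata = metadata,
                   symptoms = S, params = params),
              class = "synthetic_cohort")
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("<synthetic_cohort: %d subjects, symptom counts %d-%d (mean %.1f)>\n",
              length(x$narratives), min(x$symptoms), max(x$symptoms),
              mean(x$symptoms)))
  invisible(x)
}

#' Write a synthetic cohort in the pipeline's on-disk formats
#'
#' Produces `transcripts/<subject_id>.txt` (one line of space-separated
#' tokens per narrative) and `subjects.csv`, directly consumable by
#' [read_transcripts()] and the correlation stage.
#'
#' @param cohort A `synthetic_cohort`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  tdir <- file.path(dir, "transcripts")
  dir.create(tdir, recursive = TRUE, showWarnings = FALSE)
  for (seq in cohort$narratives) {
    writeLines(paste(seq$tokens, collapse = " "),
               file.path(tdir, paste0(seq$subject_id, ".txt")))
  }
  utils::write.csv(cohort$metadata, file.path(dir, "subjects.csv"),
                   row.names = FALSE)
  invisible(dir)
}
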