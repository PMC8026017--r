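# Moving-window verbosity control.
#
# Graph size scales mechanically with narrative length, so attributes are
# computed on fixed-length overlapping token windows and averaged per
# narrative. Defaults: 30-word windows with 50% overlap.

#' Window configuration
#'
#' @param window_length Tokens per window (default 30).
#' @param overlap Overlap between consecutive windows as a fraction of the
#'   window length, in [0, 1) (default 0.5). The step between window starts
#'   is `max(1, round(window_length * (1 - overlap)))`.
#' @return A list of class `window_config`.
#' @export
window_config <- function(window_length = 30, overlap = 0.5) {
  stopifnot(window_length >= 2, overlap >= 0, overlap < 1)
  step <- max(1L, as.integer(round(window_length * (1 - overlap))))
  structure(list(window_length = as.integer(window_length),
                 overlap = overlap, step = step),
            class = "window_config")
}

#' Split a token stream into moving windows
#'
#' Windows start at offsets 0, step, 2*step, ... and only full-length windows
#' are emitted — trailing tokens not covered by a final full window are
#' dropped, so every windowed graph is built from the same number of tokens.
#' A stream shorter than the window length yields a single window holding all
#' of its tokens.
#'
#' @param tokens Character vector (or `token_sequence`).
#' @param cfg A [window_config()].
#' @return List of character vectors.
#' @export
make_windows <- function(tokens, cfg = window_config()) {
  if (inherits(tokens, "token_sequence")) tokens <- tokens$tokens
  stopifnot(is.character(tokens), inherits(cfg, "window_config"))
  if (length(tokens) == 0L) stop("empty token stream: nothing to window")
  L <- length(tokens)
  W <- cfg$window_length
  if (L < W) return(list(tokens))
  starts <- seq.int(1L, L - W + 1L, by = cfg$step)
  lapply(starts, function(s) tokens[s:(s + W - 1L)])
}

#' Windowed attribute profile of one narrative
#'
#' Computes the 15 speech-graph attributes on each moving window and averages
#' them component-wise (unweighted mean over windows). `TNW`, the verbosity
#' measure, defaults to the cleaned (post-stop-word) token count and can be
#' switched to the raw pre-removal count.
#'
#' @param seq A `token_sequence` (cleaned tokens).
#' @param cfg A [window_config()].
#' @param tnw "clean" (default) or "raw".
#' @param ... Passed to [compute_attributes()] (`re_mode`, `distances`).
#' @return A list of class `narrative_profile`: `subject_id`, `tnw`,
#'   `window_count`, `mean_attributes` (named numeric, length 15).
#' @export
profile_narrative <- function(seq, cfg = window_config(),
                              tnw = c("clean", "raw"), ...) {
  stopifnot(inherits(seq, "token_sequence"))
  tnw <- match.arg(tnw)
  if (length(seq$tokens) == 0L) {
    stop("empty narrative for subject '", seq$subject_id,
         "': no tokens left after stop-word removal")
  }
  wins <- make_windows(seq$tokens, cfg)
  per_window <- vapply(wins, function(w) unclass(compute_attributes(w, ...)),
                       numeric(length(ATTRIBUTE_NAMES)))
  means <- rowMeans(per_window)
  structure(list(subject_id = seq$subject_id,
                 tnw = if (tnw == "clean") length(seq$tokens)
                       else seq$raw_token_count,
                 window_count = length(wins),
                 mean_attributes = means),
            class = "narrative_profile")
}

#' @export
print.narrative_profile <- function(x, ...) {
  cat(sprintf("<narrative_profile '%s': TNW = %d, %d window(s)>\n",
              x$subject_id, x$tnw, x$window_count))
  print(round(x$mean_attributes, 4))
  invisible(x)
}

#' Windowed profiles for a set of narratives
#'
#' @param seqs List of `token_sequence` objects (e.g. cleaned transcripts of
#'   a cohort), or a named list of token character vectors.
#' @param cfg A [window_config()].
#' @param ... Passed to [profile_narrative()].
#' @return Data frame with one row per subject: `subject_id`, `TNW`,
#'   `window_count` and the 15 mean attributes.
#' @export
profile_cohort <- function(seqs, cfg = window_config(), ...) {
  seqs <- lapply(seq_along(seqs), function(i) {
    s <- seqs[[i]]
    if (inherits(s, "token_sequence")) s
    else token_sequence(s, subject_id = names(seqs)[i] %||% as.character(i))
  })
  rows <- lapply(seqs, function(s) {
    p <- profile_narrative(s, cfg, ...)
    cbind(data.frame(subject_id = p$subject_id, TNW = p$tnw,
                     window_count = p$window_count,
                     stringsAsFactors = FALSE),
          as.data.frame(as.list(p$mean_attributes)))
  })
  do.call(rbind, rows)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
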