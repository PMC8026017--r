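# Correlation stage: Spearman and covariate-adjusted (partial) Spearman
# correlations with Bonferroni thresholds, arranged as an attributes-by-
# symptom-scales table.

#' Spearman rank correlation with t-approximation p-value
#'
#' r is the Pearson correlation of average ranks (midranks for ties); the
#' two-sided p-value uses the t approximation with n - 2 degrees of freedom.
#'
#' @param x,y Numeric vectors of equal length, n >= 4.
#' @return Named list `r`, `p`, `n`.
#' @export
spearman_cor <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 4L,
            !anyNA(x), !anyNA(y))
  n <- length(x)
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0) stop("constant input: 'x' has zero rank variance")
  if (stats::sd(ry) == 0) stop("constant input: 'y' has zero rank variance")
  r <- stats::cor(rx, ry)
  list(r = r, p = .t_pvalue(r, df = n - 2L), n = n)
}

.t_pvalue <- function(r, df) {
  r <- min(1, max(-1, r))
  if (abs(r) >= 1) return(.Machine$double.xmin)  # keep p strictly positive
  tval <- r * sqrt(df / (1 - r^2))
  max(2 * stats::pt(-abs(tval), df = df), .Machine$double.xmin)
}

#' Partial Spearman correlation
#'
#' All variables are rank-transformed (midranks); the x- and y-ranks are each
#' residualized by least squares on the covariate ranks plus an intercept,
#' and r is the Pearson correlation of the residuals. The two-sided p-value
#' uses the t approximation with n - 2 - k degrees of freedom, k the number
#' of covariates. With no covariates this reduces exactly to [spearman_cor()].
#'
#' @param x,y Numeric vectors of equal length.
#' @param covariates Numeric matrix / data frame with one column per
#'   covariate (or `NULL` for the unadjusted correlation).
#' @return Named list `r`, `p`, `n`, `k`.
#' @export
partial_spearman <- function(x, y, covariates = NULL) {
  n <- length(x)
  stopifnot(length(y) == n, !anyNA(x), !anyNA(y))
  if (is.null(covariates) || NCOL(covariates) == 0L ||
      (is.matrix(covariates) && ncol(covariates) == 0L)) {
    out <- spearman_cor(x, y)
    return(list(r = out$r, p = out$p, n = n, k = 0L))
  }
  Z <- as.matrix(covariates)
  stopifnot(nrow(Z) == n, !anyNA(Z))
  k <- ncol(Z)
  if (n <= k + 2L) stop("need n > k + 2 observations for ", k, " covariates")
  rx <- rank(x)
  ry <- rank(y)
  if (stats::sd(rx) == 0) stop("constant input: 'x' has zero rank variance")
  if (stats::sd(ry) == 0) stop("constant input: 'y' has zero rank variance")
  RZ <- apply(Z, 2L, rank)
  X <- cbind(1, RZ)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) stop("rank-deficient covariates: collinear ranks")
  ex <- stats::residuals(stats::lm.fit(X, rx))
  ey <- stats::residuals(stats::lm.fit(X, ry))
  if (stats::sd(ex) == 0 || stats::sd(ey) == 0) {
    stop("degenerate control: residuals are constant after adjustment")
  }
  r <- stats::cor(ex, ey)
  list(r = r, p = .t_pvalue(r, df = n - 2L - k), n = n, k = k)
}

#' Bonferroni-corrected per-test threshold
#'
#' @param alpha Family-wise error rate in (0, 1).
#' @param m Number of comparisons (>= 1).
#' @return `alpha / m`.
#' @examples
#' bonferroni_threshold(0.05, 4) # 0.0125
#' @export
bonferroni_threshold <- function(alpha = 0.05, m = 4L) {
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  if (!is.numeric(m) || length(m) != 1L || m < 1) {
    stop("m must be a positive integer")
  }
  alpha / m
}

COHORT_ATTRIBUTES <- c("TNW", "RE", "L1", "LSC", "ASP")
SYMPTOM_SCALES <- c(total = "symptoms_total",
                    inattention = "symptoms_inattention",
                    hyperactivity_impulsivity = "symptoms_hyperactivity")

#' Default covariate column set for the adjusted analysis
#'
#' Age, IQ, years of education, depression (BDI), state and trait anxiety
#' (STAI) and impulsivity (UPPS total) — the confounder set of the adjusted
#' correlation table.
#'
#' @export
DEFAULT_COVARIATES <- c("age", "iq", "education_years", "bdi",
                        "stai_state", "stai_trait", "upps_total")

#' Join windowed profiles with scored metadata into the analysis table
#'
#' @param profiles Data frame from [profile_cohort()] (one row per subject,
#'   `subject_id`, `TNW` and the mean attributes).
#' @param metadata Subject metadata data frame with `subject_id`,
#'   `asrs_01..asrs_18` and covariate columns; ASRS columns are scored with
#'   [score_asrs_table()] if the symptom-count columns are absent.
#' @return Data frame with one row per subject holding the analyzed
#'   attributes, the three symptom counts and the covariates.
#' @export
build_cohort_table <- function(profiles, metadata) {
  if (!all(c("symptoms_total", "symptoms_inattention",
             "symptoms_hyperactivity") %in% names(metadata))) {
    metadata <- score_asrs_table(metadata)
  }
  merged <- merge(profiles, metadata, by = "subject_id", sort = TRUE)
  if (nrow(merged) == 0L) stop("no subjects shared between profiles and metadata")
  merged
}

#' Attribute-by-symptom correlation table
#'
#' Correlates the five analyzed measures (TNW plus the four windowed graph
#' attributes RE, L1, LSC, ASP) with the three symptom scales (total,
#' inattention, hyperactivity-impulsivity). With an empty covariate set this
#' is the plain Spearman analysis; with covariates each cell is a partial
#' Spearman correlation. Graph-attribute cells are flagged against the
#' Bonferroni threshold `alpha / family_size`; TNW, reported alongside the
#' tested family, is flagged at the nominal `alpha`.
#'
#' @param cohort Data frame from [build_cohort_table()].
#' @param covariates Character vector of covariate column names (default
#'   none; use [DEFAULT_COVARIATES] for the adjusted analysis).
#' @param family_size Bonferroni family size (default 4: RE, L1, LSC, ASP).
#' @param alpha Family-wise alpha (default 0.05).
#' @return Data frame with one row per attribute x scale: `attribute`,
#'   `scale`, `r`, `p`, `n`, `covariates`, `threshold`,
#'   `significant_bonferroni`.
#' @export
correlation_table <- function(cohort, covariates = character(0),
                              family_size = 4L, alpha = 0.05) {
  needed <- c(COHORT_ATTRIBUTES, unname(SYMPTOM_SCALES), covariates)
  missing <- setdiff(needed, names(cohort))
  if (length(missing) > 0L) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "))
  }
  for (col in needed) {
    if (anyNA(cohort[[col]])) stop("missing values in column '", col, "'")
  }
  Z <- if (length(covariates) > 0L) as.matrix(cohort[covariates]) else NULL
  thr_graph <- bonferroni_threshold(alpha, family_size)
  rows <- list()
  for (attr_name in COHORT_ATTRIBUTES) {
    for (scale_name in names(SYMPTOM_SCALES)) {
      res <- tryCatch(
        partial_spearman(cohort[[attr_name]],
                         cohort[[SYMPTOM_SCALES[[scale_name]]]], Z),
        error = function(e) {
          stop("correlation (", attr_name, ", ", scale_name, "): ",
               conditionMessage(e), call. = FALSE)
        })
      thr <- if (attr_name == "TNW") alpha else thr_graph
      rows[[length(rows) + 1L]] <- data.frame(
        attribute = attr_name, scale = scale_name,
        r = res$r, p = res$p, n = res$n,
        covariates = paste(covariates, collapse = ";"),
        threshold = thr,
        significant_bonferroni = res$p < thr,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}
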