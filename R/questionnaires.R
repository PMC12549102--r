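#' Distress questionnaire scores
#'
#' Container for one participant's SSAI, STAI, PSS and EPDS scores. Any score
#' may be NA (not administered). Ranges follow the instruments: SSAI/STAI are
#' 20-item scales scored 20-80, PSS is 0-40, EPDS is 0-30.
#'
#' @param ssai,stai,pss,epds Scores (numeric or NA).
#' @return Object of class `distress_scores`.
#' @export
distress_scores <- function(ssai = NA, stai = NA, pss = NA, epds = NA) {
  structure(list(ssai = ssai, stai = stai, pss = pss, epds = epds),
            class = "distress_scores")
}

.instrument_ranges <- list(ssai = c(20, 80), stai = c(20, 80),
                           pss = c(0, 40), epds = c(0, 30))

#' Validate questionnaire scores
#'
#' Passes valid (or missing) scores through; an out-of-range score raises an
#' error naming the instrument.
#'
#' @param s A [distress_scores()].
#' @return `s`, unchanged, if all present scores are in range.
#' @export
validate_scores <- function(s) {
  stopifnot(inherits(s, "distress_scores"))
  for (nm in names(.instrument_ranges)) {
    v <- s[[nm]]
    rg <- .instrument_ranges[[nm]]
    if (!is.na(v) && (v < rg[1] || v > rg[2]))
      stop(sprintf("%s score %s outside valid range [%g, %g]",
                   toupper(nm), format(v), rg[1], rg[2]))
  }
  s
}

#' Symptom flags from questionnaire cutoffs
#'
#' Inclusive thresholds: PSS >= 15 flags stress, EPDS >= 10 flags depression,
#' SSAI >= 40 state anxiety and STAI >= 40 trait anxiety. Missing scores give
#' missing flags, not FALSE.
#'
#' @param s A validated [distress_scores()].
#' @return Named logical vector `c(ssai_positive, stai_positive,
#'   pss_positive, epds_positive)` with NA where the score was missing.
#' @export
flag_symptoms <- function(s) {
  s <- validate_scores(s)
  c(ssai_positive = if (is.na(s$ssai)) NA else s$ssai >= 40,
    stai_positive = if (is.na(s$stai)) NA else s$stai >= 40,
    pss_positive  = if (is.na(s$pss))  NA else s$pss >= 15,
    epds_positive = if (is.na(s$epds)) NA else s$epds >= 10)
}

#' Flag a whole covariate table
#'
#' @param covariates data.frame with columns among SSAI, STAI, PSS, EPDS
#'   (case-insensitive).
#' @return data.frame of `*_positive` logical columns, one row per subject.
#' @export
flag_cohort <- function(covariates) {
  nm <- tolower(names(covariates))
  get_col <- function(k) if (k %in% nm) covariates[[which(nm == k)[1]]] else NA
  rows <- lapply(seq_len(nrow(covariates)), function(i) {
    s <- distress_scores(ssai = get_col("ssai")[i][[1]],
                         stai = get_col("stai")[i][[1]],
                         pss = get_col("pss")[i][[1]],
                         epds = get_col("epds")[i][[1]])
    as.list(flag_symptoms(s))
  })
  do.call(rbind, lapply(rows, as.data.frame))
}
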