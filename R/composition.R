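# Across-lot composition summaries and the CV > 10% variability screen.

#' Summary statistics for one component across lots
#'
#' Mean, range and coefficient of variation (CV, percent) of a component's
#' concentration across ingredient samples. The CV uses the sample (n - 1)
#' standard deviation: `cv_pct = 100 * sd(x) / mean(x)`.
#'
#' @param values Numeric vector, one concentration per sample (>= 2 values).
#' @return A list: `mean`, `min`, `max`, `cv_pct`.
#' @examples
#' summarize_samples(c(30.87, 44.25, 24.19, 23.27, 21.89,
#'                     26.61, 48.61, 27.77, 29.3, 25.12))
#' @export
summarize_samples <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) {
    stop("degrees-of-freedom error: need at least 2 values", call. = FALSE)
  }
  m <- mean(values)
  if (m == 0) stop("CV undefined: mean is zero", call. = FALSE)
  list(mean = m, min = min(values), max = max(values),
       cv_pct = 100 * stats::sd(values) / m)
}

#' Flag components with high across-lot variability
#'
#' Returns, in input order, the components whose CV strictly exceeds the
#' threshold (default 10%), the screen used to call a feed component
#' "highly variable" across lots.
#'
#' @param cv_by_component Named numeric vector of CVs in percent.
#' @param threshold Flagging threshold in percent (default 10).
#' @return Character vector of flagged component names.
#' @export
flag_high_variation <- function(cv_by_component, threshold = 10) {
  if (threshold < 0) stop("threshold must be nonnegative", call. = FALSE)
  if (any(cv_by_component < 0, na.rm = TRUE)) {
    stop("CVs must be nonnegative", call. = FALSE)
  }
  names(cv_by_component)[which(cv_by_component > threshold)]
}

#' Composition summary table across ingredient lots
#'
#' Runs [summarize_samples()] over every proximate component and amino acid
#' of an ingredients table and applies the variability flag.
#'
#' @inheritParams predictor_table
#' @param threshold CV flagging threshold in percent.
#' @return A `data.frame`: component, mean, min, max, cv_pct, flagged.
#' @export
summarize_composition <- function(ingredients, threshold = 10) {
  pt <- predictor_table(ingredients)
  comps <- c(proximate_components(), aa_components())
  cols <- c(stats::setNames(names(.prox_cols), names(.prox_cols)), .aa_cols())
  rows <- lapply(comps, function(comp) {
    v <- if (comp %in% names(pt)) pt[[comp]] else ingredients[[cols[[comp]]]]
    s <- summarize_samples(v)
    data.frame(component = comp, mean = s$mean, min = s$min, max = s$max,
               cv_pct = s$cv_pct, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$flagged <- out$component %in%
    flag_high_variation(stats::setNames(out$cv_pct, out$component), threshold)
  out
}
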