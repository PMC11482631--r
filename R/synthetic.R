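# Synthetic feeding-trial generator: two-square 11 x 3 incomplete Latin
# square design and marker/digesta simulation from configurable ground
# truth. Stands in for the unpublished pig-level assays so the full
# AID -> endogenous -> SID chain can be validated end to end.

#' Build a two-square incomplete Latin square trial design
#'
#' Each of the two squares holds `n_diets` pigs over `n_periods` periods;
#' within a square, pig i receives diet `(i + o_j) mod n_diets` in period j,
#' with distinct random period offsets `o_j` per square, so every diet
#' appears exactly once per square-period and each pig gets distinct diets.
#' Pig labels are then shuffled. With the default 11 diets and 3 periods this
#' yields 22 pigs, 66 pig-period assignments, and 6 replicates per diet.
#'
#' @param diet_ids Diet labels; default the ten RSC test diets plus `NFREE`.
#' @param n_periods Number of periods per pig (must be < number of diets).
#' @param seed Integer seed governing offsets and the pig shuffle.
#' @return A `data.frame`: pig_id, square, period, diet_id.
#' @export
build_design <- function(diet_ids = c(paste0("RSC", 1:10), "NFREE"),
                         n_periods = 3, seed = 1) {
  n_diets <- length(diet_ids)
  if (n_periods >= n_diets) {
    stop("design error: need n_periods < number of diets", call. = FALSE)
  }
  set.seed(seed)
  n_pigs <- 2 * n_diets
  pig_order <- sample(sprintf("P%02d", seq_len(n_pigs)))
  rows <- list()
  for (sq in 1:2) {
    offsets <- sample(0:(n_diets - 1), n_periods)
    pigs <- pig_order[((sq - 1) * n_diets + 1):(sq * n_diets)]
    for (i in seq_len(n_diets)) {
      for (j in seq_len(n_periods)) {
        rows[[length(rows) + 1]] <- data.frame(
          pig_id = pigs[i], square = sq, period = j,
          diet_id = diet_ids[((i - 1 + offsets[j]) %% n_diets) + 1],
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  out[order(out$pig_id, out$period), , drop = FALSE]
}

#' Ground truth for a simulated trial
#'
#' Bundles the quantities the generator treats as true: per-ingredient,
#' per-component SID (%), basal endogenous losses (g/kg DM intake), DM
#' digestibility of the test and nitrogen-free diets, assay noise CV, and
#' the diet-formulation constants (40% RSC inclusion, 0.30% TiO2, analyzed
#' diet DM defaults of 91.3% / 90.3% for test / N-free diets).
#'
#' @param true_sid Numeric matrix, rows = components (CP + amino acids),
#'   columns = ingredient sample ids, entries in percent.
#' @param true_endogenous Named numeric vector, g/kg DM intake.
#' @param dm_digestibility True DM digestibility of test diets, in (0, 1).
#' @param nfree_dm_digestibility Same for the nitrogen-free diet.
#' @param noise_cv Lognormal CV of multiplicative assay noise (default 0.05).
#' @param diet_dm,nfree_dm Analyzed diet DM, percent air-dry.
#' @param inclusion RSC inclusion rate in the test diets (fraction).
#' @param marker_pct TiO2 inclusion, percent air-dry.
#' @param seed Integer seed for the noise draws.
#' @return A list of class `"trial_truth"`.
#' @export
trial_truth <- function(true_sid, true_endogenous,
                        dm_digestibility = 0.75, nfree_dm_digestibility = 0.90,
                        noise_cv = 0.05, diet_dm = 91.3, nfree_dm = 90.3,
                        inclusion = 0.40, marker_pct = 0.30, seed = 1) {
  stopifnot(is.matrix(true_sid), !is.null(rownames(true_sid)),
            !is.null(colnames(true_sid)))
  if (dm_digestibility <= 0 || dm_digestibility >= 1 ||
      nfree_dm_digestibility <= 0 || nfree_dm_digestibility >= 1) {
    stop("DM digestibility must lie in (0, 1)", call. = FALSE)
  }
  if (noise_cv < 0) stop("noise_cv must be nonnegative", call. = FALSE)
  structure(list(true_sid = true_sid, true_endogenous = true_endogenous,
                 dm_digestibility = dm_digestibility,
                 nfree_dm_digestibility = nfree_dm_digestibility,
                 noise_cv = noise_cv, diet_dm = diet_dm, nfree_dm = nfree_dm,
                 inclusion = inclusion, marker_pct = marker_pct, seed = seed),
            class = "trial_truth")
}

#' Ground truth mirroring the bundled tables
#'
#' Convenience constructor: true SID taken from the bundled SID table and
#' endogenous losses from the bundled nitrogen-free results, so a noise-free
#' simulated trial reproduces the published treatment means.
#'
#' @param fixtures Output of [rsc_fixtures()].
#' @param ... Passed on to [trial_truth()].
#' @export
fixture_truth <- function(fixtures = rsc_fixtures(), ...) {
  sid <- fixtures$sid
  samples <- fixtures$ingredients$sample_id
  m <- as.matrix(sid[samples])
  rownames(m) <- sid$component
  trial_truth(true_sid = m, true_endogenous = fixtures$endogenous, ...)
}

.lognormal_eps <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  stats::rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)  # mean exactly 1
}

#' Simulate diet and digesta assays for a trial
#'
#' Forms test diets as `inclusion` x ingredient composition (air-dry) with
#' the TiO2 marker, then generates per-pig-period digesta on a DM basis:
#' the digesta marker is concentrated by DM disappearance,
#' `T_d = T_r / (1 - DM digestibility)`, and each component's digesta
#' concentration is `(diet_dm_conc * (1 - SID/100) + IAA_end) * (T_d / T_r)`
#' times a mean-one lognormal assay error per pig-period-component. The
#' nitrogen-free digesta carries the endogenous flow only. Implied negative
#' flows (true SID above 100 exceeding the endogenous supply) are floored at
#' zero with a warning.
#'
#' @param ingredients Ingredients table supplying each test diet's RSC lot.
#' @param truth A [trial_truth()] object.
#' @param design A [build_design()] table; test diet ids must match
#'   `colnames(truth$true_sid)`.
#' @param nfree_diet_id Diet id of the nitrogen-free treatment.
#' @return A list: `diets` (diets schema), `digesta` (digesta schema, N-free
#'   observations included), `endogenous` (the true losses, for reference).
#' @export
generate_trial <- function(ingredients, truth, design, nfree_diet_id = "NFREE") {
  comp_cols <- c(CP = "cp", .aa_cols())
  test_ids <- setdiff(unique(design$diet_id), nfree_diet_id)
  unmapped <- setdiff(test_ids, ingredients$sample_id)
  if (length(unmapped)) {
    stop("design diets without a matching ingredient: ",
         paste(unmapped, collapse = ", "), call. = FALSE)
  }
  ing <- ingredients[match(test_ids, ingredients$sample_id), , drop = FALSE]

  # --- diets table (air-dry %) ---
  diets <- data.frame(diet_id = c(test_ids, nfree_diet_id),
                      dm = c(rep(truth$diet_dm, length(test_ids)), truth$nfree_dm),
                      stringsAsFactors = FALSE)
  for (comp in names(comp_cols)) {
    cl <- comp_cols[[comp]]
    diets[[cl]] <- c(truth$inclusion * ing[[cl]], if (comp == "CP") 0 else NA)
  }
  diets$marker_pct <- truth$marker_pct
  diets <- diets[c("diet_id", "dm", "cp", "marker_pct", unname(.aa_cols()))]

  # --- digesta (g/kg DM) ---
  set.seed(truth$seed)
  t_r <- to_dm_basis(truth$marker_pct, truth$diet_dm) * 10
  t_r_nf <- to_dm_basis(truth$marker_pct, truth$nfree_dm) * 10
  t_d <- t_r / (1 - truth$dm_digestibility)
  t_d_nf <- t_r_nf / (1 - truth$nfree_dm_digestibility)
  floored <- 0L
  digesta <- design
  digesta$marker_g_kg_dm <- ifelse(design$diet_id == nfree_diet_id, t_d_nf, t_d)
  for (comp in names(comp_cols)) {
    cl <- comp_cols[[comp]]
    end <- if (comp %in% names(truth$true_endogenous)) {
      truth$true_endogenous[[comp]]
    } else 0
    conc <- numeric(nrow(design))
    for (k in seq_len(nrow(design))) {
      id <- design$diet_id[k]
      if (id == nfree_diet_id) {
        flow <- end
        ratio <- t_d_nf / t_r_nf
      } else {
        diet_dm_conc <- to_dm_basis(truth$inclusion * ing[[cl]][match(id, test_ids)],
                                    truth$diet_dm) * 10
        sid_true <- truth$true_sid[comp, id]
        flow <- diet_dm_conc * (1 - sid_true / 100) + end
        ratio <- t_d / t_r
      }
      if (flow < 0) { flow <- 0; floored <- floored + 1L }
      conc[k] <- flow * ratio
    }
    digesta[[cl]] <- conc * .lognormal_eps(nrow(design), truth$noise_cv)
  }
  if (floored > 0) {
    warning(floored, " implied negative digesta flow(s) floored at 0", call. = FALSE)
  }
  digesta <- digesta[c("pig_id", "period", "diet_id", "marker_g_kg_dm",
                       "cp", unname(.aa_cols()))]
  list(diets = diets, digesta = digesta, endogenous = truth$true_endogenous)
}

#' Recovery report for a simulated trial
#'
#' Compares estimated treatment-mean digestibility against the generating
#' truth: per-component bias (`mean(estimate - truth)`) and RMSE across
#' ingredients, plus, when fitted models are supplied, the recovered slope of
#' each prediction equation.
#'
#' @param truth The [trial_truth()] used to generate the data.
#' @param estimates A [digestibility_table()] of the SID estimates.
#' @param models Optional named list of `"sid_model"` objects.
#' @return A list: `components` (data.frame component, bias, rmse) and
#'   `slopes` (data.frame response, predictor, slope; `NULL` without models).
#' @export
recovery_report <- function(truth, estimates, models = NULL) {
  comps <- intersect(estimates$component, rownames(truth$true_sid))
  if (length(comps) == 0) {
    stop("component sets of truth and estimates do not overlap", call. = FALSE)
  }
  samples <- intersect(colnames(truth$true_sid), names(estimates))
  if (length(samples) == 0) {
    stop("ingredient sets of truth and estimates do not overlap", call. = FALSE)
  }
  rows <- lapply(comps, function(comp) {
    est <- as.numeric(estimates[estimates$component == comp, samples])
    tru <- truth$true_sid[comp, samples]
    data.frame(component = comp, bias = mean(est - tru),
               rmse = sqrt(mean((est - tru)^2)), stringsAsFactors = FALSE)
  })
  slopes <- NULL
  if (!is.null(models)) {
    slopes <- do.call(rbind, lapply(models, function(m) {
      data.frame(response = m$response,
                 predictor = paste(m$predictors, collapse = "+"),
                 slope = if (length(m$coefficients)) unname(m$coefficients[1]) else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  list(components = do.call(rbind, rows), slopes = slopes)
}
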