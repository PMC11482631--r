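# Marker-ratio digestibility chain: apparent ileal digestibility (AID) from
# TiO2 ratios, basal endogenous losses from the nitrogen-free diet, and the
# standardized ileal digestibility (SID) correction, plus treatment-level
# ANOVA summaries.

#' Convert an air-dry concentration to a dry-matter basis
#'
#' Diet assays are reported per unit air-dry mass while the marker equations
#' work per unit dry matter; the conversion divides by the DM fraction.
#'
#' @param conc_airdry Concentration on an air-dry basis (any unit per mass).
#' @param dm_pct Dry-matter content, % (0 < dm_pct <= 100).
#' @return Concentration on a DM basis, same unit.
#' @examples
#' to_dm_basis(17.71, 90.85)  # 19.49% of DM
#' @export
to_dm_basis <- function(conc_airdry, dm_pct) {
  if (any(dm_pct <= 0 | dm_pct > 100)) {
    stop("dm_pct must lie in (0, 100]", call. = FALSE)
  }
  conc_airdry / (dm_pct / 100)
}

#' Apparent ileal digestibility from marker ratios
#'
#' AID (%) of a dietary component is estimated from the shift in the
#' indigestible-marker ratio between diet and ileal digesta:
#' `AID = 100 * (1 - (aa_d * t_r) / (aa_r * t_d))`. All four concentrations
#' must share the DM basis (g/kg DM). No clamping is applied; values can be
#' negative or exceed 100.
#'
#' @param aa_d,t_d Component and TiO2 concentration in ileal digesta, g/kg DM.
#' @param aa_r,t_r Component and TiO2 concentration in the diet, g/kg DM.
#' @return AID in percent.
#' @export
compute_aid <- function(aa_d, t_d, aa_r, t_r) {
  if (any(aa_r == 0) || any(t_d == 0)) {
    stop("undefined marker ratio: aa_r and t_d must be nonzero", call. = FALSE)
  }
  100 * (1 - (aa_d * t_r) / (aa_r * t_d))
}

#' Basal endogenous loss from the nitrogen-free diet
#'
#' Ileal flow of a component of non-dietary origin, per kg of DM intake:
#' `IAA_end = aa_d * t_r / t_d`, with all concentrations from the
#' nitrogen-free treatment on a DM basis.
#'
#' @param aa_d_nfree Component concentration in N-free-diet digesta, g/kg DM.
#' @param t_r_nfree TiO2 concentration in the N-free diet, g/kg DM.
#' @param t_d_nfree TiO2 concentration in the N-free digesta, g/kg DM.
#' @return Basal endogenous loss, g/kg DM intake.
#' @export
compute_endogenous <- function(aa_d_nfree, t_r_nfree, t_d_nfree) {
  if (any(t_d_nfree == 0)) {
    stop("undefined marker ratio: t_d_nfree must be nonzero", call. = FALSE)
  }
  aa_d_nfree * t_r_nfree / t_d_nfree
}

#' Standardized ileal digestibility
#'
#' Corrects AID upward for the basal endogenous loss:
#' `SID = AID + 100 * iaa_end / diet_conc_dm`. The denominator is the dietary
#' concentration of the component in g/kg DM. (The source method's notation
#' reuses the digesta symbol here; only the dietary reading reproduces the
#' published SID tables from the published AID, diet and endogenous values,
#' so that is what this function implements.) SID is never below AID for
#' nonnegative endogenous losses, and is not clamped at 100.
#'
#' @param aid_pct Apparent ileal digestibility, %.
#' @param iaa_end Basal endogenous loss, g/kg DM intake.
#' @param diet_conc_dm Dietary concentration of the component, g/kg DM.
#' @return SID in percent.
#' @examples
#' compute_sid(70.29, 21.24, to_dm_basis(17.71, 90.85) * 10)  # 81.19
#' @export
compute_sid <- function(aid_pct, iaa_end, diet_conc_dm) {
  if (any(diet_conc_dm <= 0)) {
    stop("diet_conc_dm must be positive", call. = FALSE)
  }
  if (any(iaa_end < 0)) {
    stop("iaa_end must be nonnegative", call. = FALSE)
  }
  aid_pct + 100 * iaa_end / diet_conc_dm
}

# Compact letter display by insert-and-absorb from a logical matrix of
# significant pairwise differences. Groups ordered by decreasing mean get
# earlier letters.
.letter_groups <- function(signif_pair, means) {
  g <- names(means)
  ord <- g[order(-means)]
  sets <- list(ord)
  for (i in seq_along(g)) {
    for (j in seq_along(g)) {
      if (i < j && isTRUE(signif_pair[g[i], g[j]])) {
        k <- 1
        while (k <= length(sets)) {
          s <- sets[[k]]
          if (all(c(g[i], g[j]) %in% s)) {
            sets[[k]] <- setdiff(s, g[i])
            sets <- append(sets, list(setdiff(s, g[j])))
          }
          k <- k + 1
        }
        # absorb sets contained in another
        keep <- !vapply(seq_along(sets), function(a) {
          any(vapply(seq_along(sets), function(b) {
            a != b && all(sets[[a]] %in% sets[[b]]) &&
              !(all(sets[[b]] %in% sets[[a]]) && a < b)
          }, logical(1)))
        }, logical(1))
        sets <- sets[keep]
      }
    }
  }
  # order letter sets by the rank of their best member
  best <- vapply(sets, function(s) min(match(s, ord)), numeric(1))
  sets <- sets[order(best)]
  out <- stats::setNames(rep("", length(g)), g)
  for (k in seq_along(sets)) {
    for (m in sets[[k]]) out[m] <- paste0(out[m], letters[k])
  }
  if (length(sets) == 1) out[] <- "a"
  out
}

#' Treatment-level digestibility summary
#'
#' One-way ANOVA summary of per-replicate digestibility values grouped by
#' ingredient: group means, a single pooled SEM (`sqrt(MSE / n)` with `n` the
#' average replicate count per group, matching the one-SEM-per-row table
#' convention), the ANOVA F-test p-value, and Tukey-HSD letter groups at
#' `alpha` (groups sharing a letter are not separated). Values with
#' within-group |Z| above `z_cutoff` are excluded before summarization;
#' set `z_cutoff = Inf` to keep everything.
#'
#' @param values Numeric vector of per-replicate digestibility values (%).
#' @param group Ingredient/treatment label per value.
#' @param alpha Significance level for the pairwise letters.
#' @param z_cutoff Within-group Z-score magnitude beyond which a replicate is
#'   dropped as an outlier (default 3).
#' @return A list with elements `table` (data.frame: group, n, mean, letters),
#'   `sem`, `p_value`, `mse`, and `n_excluded`.
#' @export
summarize_treatments <- function(values, group, alpha = 0.05, z_cutoff = 3) {
  group <- as.character(group)
  ok <- stats::complete.cases(values, group)
  values <- values[ok]; group <- group[ok]
  # outlier screen per treatment cell
  z <- stats::ave(values, group, FUN = function(v) {
    s <- stats::sd(v)
    if (!is.finite(s) || s == 0) return(rep(0, length(v)))
    (v - mean(v)) / s
  })
  keep <- abs(z) <= z_cutoff
  n_excluded <- sum(!keep)
  values <- values[keep]; group <- group[keep]
  sizes <- table(group)
  if (length(sizes) < 2 || any(sizes < 2)) {
    stop("degrees-of-freedom error: need >= 2 groups with >= 2 replicates each",
         call. = FALSE)
  }
  f <- factor(group)
  means <- tapply(values, f, mean)
  sse <- sum((values - stats::ave(values, f))^2)
  if (sse <= 1e-10 * max(sum(values^2), 1)) {
    # zero residual variance: F degenerate, separation decided by the means
    mse <- 0
    p <- if (stats::var(means) == 0) 1 else 0
    sig <- outer(means, means, function(a, b) a != b)
    dimnames(sig) <- list(names(means), names(means))
  } else {
    fit <- stats::aov(values ~ f)
    an <- stats::anova(fit)
    mse <- an[["Mean Sq"]][2]
    p <- an[["Pr(>F)"]][1]
    tk <- stats::TukeyHSD(fit, conf.level = 1 - alpha)$f
    sig <- matrix(FALSE, length(means), length(means),
                  dimnames = list(names(means), names(means)))
    pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
    for (k in seq_along(pairs)) {
      a <- pairs[[k]][1]; b <- pairs[[k]][2]
      sig[a, b] <- sig[b, a] <- tk[k, "p adj"] < alpha
    }
  }
  lets <- .letter_groups(sig, means)
  tab <- data.frame(group = names(means), n = as.integer(sizes[names(means)]),
                    mean = as.numeric(means), letters = lets[names(means)],
                    row.names = NULL, stringsAsFactors = FALSE)
  list(table = tab, sem = sqrt(mse / mean(sizes)), p_value = p, mse = mse,
       n_excluded = n_excluded)
}

#' Estimate AID and SID from a digesta table
#'
#' Runs the full marker chain on per-pig-period digesta assays: converts the
#' analyzed diet concentrations to g/kg DM, estimates basal endogenous losses
#' from the nitrogen-free-diet observations (mean ileal flow across its
#' replicates) unless `endogenous` is supplied, then computes per-replicate
#' AID and SID for every component assayed in both diet and digesta.
#'
#' @param diets Diets table (see [read_feed_table()]); must contain the
#'   nitrogen-free diet row when `endogenous` is `NULL`.
#' @param digesta Digesta table on a DM basis.
#' @param endogenous Optional named vector of basal losses, g/kg DM intake;
#'   when `NULL` it is computed from the `nfree_diet_id` observations.
#' @param nfree_diet_id Diet label of the nitrogen-free treatment.
#' @return A long `data.frame` (pig_id, period, diet_id, component, aid, sid)
#'   with the endogenous-loss vector attached as attribute `"endogenous"`.
#' @export
estimate_digestibility <- function(diets, digesta, endogenous = NULL,
                                   nfree_diet_id = "NFREE") {
  comp_cols <- c(CP = "cp", .aa_cols())
  # dietary concentrations, g/kg DM (air-dry % -> % of DM -> g/kg DM)
  diet_dm <- diets$dm
  conc_r <- lapply(comp_cols, function(cl) to_dm_basis(diets[[cl]], diet_dm) * 10)
  conc_r <- do.call(cbind, conc_r)
  rownames(conc_r) <- diets$diet_id
  t_r <- stats::setNames(to_dm_basis(diets$marker_pct, diet_dm) * 10, diets$diet_id)

  nfree <- digesta$diet_id == nfree_diet_id
  if (is.null(endogenous)) {
    if (!any(nfree)) {
      stop("no '", nfree_diet_id, "' observations to estimate endogenous losses from",
           call. = FALSE)
    }
    if (!nfree_diet_id %in% diets$diet_id) {
      stop("diet table lacks the nitrogen-free diet '", nfree_diet_id, "'", call. = FALSE)
    }
    nf <- digesta[nfree, , drop = FALSE]
    flows <- vapply(comp_cols, function(cl) {
      mean(compute_endogenous(nf[[cl]], t_r[nfree_diet_id], nf$marker_g_kg_dm))
    }, numeric(1))
    endogenous <- stats::setNames(flows, names(comp_cols))
  }

  test <- digesta[!nfree, , drop = FALSE]
  unknown <- setdiff(unique(test$diet_id), diets$diet_id)
  if (length(unknown)) {
    stop("digesta references diets absent from the diet table: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  }
  out <- do.call(rbind, lapply(names(comp_cols), function(comp) {
    cl <- comp_cols[[comp]]
    aa_r <- conc_r[test$diet_id, comp]
    usable <- !is.na(aa_r) & aa_r > 0 & !is.na(test[[cl]])
    if (!any(usable)) return(NULL)
    d <- test[usable, , drop = FALSE]
    aa_r <- aa_r[usable]
    aid <- compute_aid(d[[cl]], d$marker_g_kg_dm, aa_r, t_r[d$diet_id])
    end <- if (comp %in% names(endogenous)) endogenous[[comp]] else NA_real_
    sid <- if (is.na(end)) rep(NA_real_, nrow(d)) else compute_sid(aid, end, aa_r)
    data.frame(pig_id = d$pig_id, period = d$period, diet_id = d$diet_id,
               component = comp, aid = aid, sid = sid,
               row.names = NULL, stringsAsFactors = FALSE)
  }))
  attr(out, "endogenous") <- endogenous
  out
}

#' Tabulate treatment means of estimated digestibility
#'
#' Applies [summarize_treatments()] per component to the long output of
#' [estimate_digestibility()] and lays the result out like the published
#' digestibility tables: one row per component, one column per ingredient,
#' plus the pooled SEM and ANOVA p-value.
#'
#' @param estimates Output of [estimate_digestibility()].
#' @param which `"sid"` or `"aid"`.
#' @inheritParams summarize_treatments
#' @return A `data.frame` with columns `component`, one per ingredient,
#'   `mean`, `sem`, `p_value`, and a parallel `letters` data.frame attached
#'   as attribute `"letters"`.
#' @export
digestibility_table <- function(estimates, which = c("sid", "aid"),
                                alpha = 0.05, z_cutoff = 3) {
  which <- match.arg(which)
  comps <- unique(estimates$component)
  groups <- unique(estimates$diet_id)
  rows <- lapply(comps, function(comp) {
    e <- estimates[estimates$component == comp, ]
    v <- e[[which]]
    if (all(is.na(v))) return(NULL)
    s <- summarize_treatments(v, e$diet_id, alpha = alpha, z_cutoff = z_cutoff)
    m <- stats::setNames(s$table$mean, s$table$group)[groups]
    l <- stats::setNames(s$table$letters, s$table$group)[groups]
    list(comp = comp, means = m, letters = l, sem = s$sem, p = s$p_value)
  })
  rows <- Filter(Negate(is.null), rows)
  vals <- do.call(rbind, lapply(rows, function(r) r$means))
  out <- data.frame(component = vapply(rows, `[[`, "", "comp"), vals,
                    mean = rowMeans(vals),
                    sem = vapply(rows, `[[`, 0, "sem"),
                    p_value = vapply(rows, `[[`, 0, "p"),
                    row.names = NULL, check.names = FALSE,
                    stringsAsFactors = FALSE)
  lets <- data.frame(component = out$component,
                     do.call(rbind, lapply(rows, function(r) r$letters)),
                     row.names = NULL, check.names = FALSE,
                     stringsAsFactors = FALSE)
  attr(out, "letters") <- lets
  out
}
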