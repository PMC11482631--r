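# Correlation screen and stepwise OLS prediction equations relating SID to
# chemical composition and processing heat.

#' Pearson correlation matrix with significance tiers
#'
#' Pairwise Pearson correlations among named numeric variables with two-sided
#' p-values from the t distribution on n - 2 degrees of freedom, and
#' significance tiers at 0.05 / 0.01. A zero-variance variable yields `NA`
#' cells (flagged, not an error); each pair needs at least 3 complete
#' observations.
#'
#' @param variables A data.frame (or named list) of equal-length numeric
#'   vectors.
#' @return A list of matrices `r`, `p`, `n`, and character `stars`
#'   (`""`, `"*"`, `"**"`), of class `"pearson_matrix"`.
#' @export
pearson_matrix <- function(variables) {
  df <- as.data.frame(variables)
  k <- ncol(df)
  nm <- names(df)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(nm, nm))
  for (i in seq_len(k)) {
    for (j in i:k) {
      ok <- stats::complete.cases(df[[i]], df[[j]])
      nn <- sum(ok)
      n[i, j] <- n[j, i] <- nn
      if (nn < 3) stop("need >= 3 complete observations per pair", call. = FALSE)
      if (stats::sd(df[[i]][ok]) == 0 || stats::sd(df[[j]][ok]) == 0) next
      rr <- stats::cor(df[[i]][ok], df[[j]][ok])
      r[i, j] <- r[j, i] <- rr
      if (i == j) {
        r[i, j] <- 1; p[i, j] <- 0
      } else {
        tt <- rr * sqrt((nn - 2) / max(1 - rr^2, .Machine$double.eps))
        p[i, j] <- p[j, i] <- 2 * stats::pt(-abs(tt), df = nn - 2)
      }
    }
  }
  stars <- ifelse(is.na(p), "", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
  structure(list(r = r, p = p, n = n, stars = stars), class = "pearson_matrix")
}

#' @export
print.pearson_matrix <- function(x, digits = 2, ...) {
  cat("Pearson correlation matrix (", nrow(x$r), " variables)\n", sep = "")
  m <- matrix(paste0(formatC(x$r, digits = digits, format = "f"), x$stars),
              nrow(x$r), ncol(x$r), dimnames = dimnames(x$r))
  m[is.na(x$r)] <- "NA"
  print(m, quote = FALSE, ...)
  cat("* p < 0.05, ** p < 0.01\n")
  invisible(x)
}

.model_from_lm <- function(fit, response, n) {
  s <- summary(fit)
  cf <- stats::coef(fit)
  preds <- setdiff(names(cf), "(Intercept)")
  p <- if (length(preds) == 0) {
    NA_real_
  } else {
    fs <- s$fstatistic
    stats::pf(fs[[1]], fs[[2]], fs[[3]], lower.tail = FALSE)
  }
  structure(list(
    response = response,
    predictors = preds,
    intercept = unname(cf["(Intercept)"]),
    coefficients = if (length(preds)) cf[preds] else stats::setNames(numeric(0), character(0)),
    r2 = if (length(preds)) s$r.squared else 0,
    adj_r2 = if (length(preds)) s$adj.r.squared else 0,
    rsd = s$sigma,
    p_value = p,
    n = n,
    fit = fit
  ), class = "sid_model")
}

#' Ordinary least-squares prediction equation
#'
#' Fits `y ~ x` by OLS and reports the metrics used to rank candidate
#' prediction equations: R², adjusted R², the residual standard error
#' `rsd = sqrt(SSE / (n - p - 1))` (the "RSD" of the published equations),
#' and the overall F-test p-value.
#'
#' @param x A data.frame or matrix of predictors (columns named).
#' @param y Numeric response vector.
#' @param response Label for the response (used in printing).
#' @return An object of class `"sid_model"`.
#' @export
ols_fit <- function(x, y, response = "y") {
  x <- as.data.frame(x)
  if (nrow(x) != length(y)) stop("x and y lengths differ", call. = FALSE)
  if (nrow(x) <= ncol(x) + 1) {
    stop("need n > number of predictors + 1", call. = FALSE)
  }
  dat <- cbind(.y = y, x)
  fit <- stats::lm(.y ~ ., data = dat)
  alias <- names(which(is.na(stats::coef(fit))))
  if (length(alias)) {
    stop("collinearity error: rank-deficient predictors (",
         paste(alias, collapse = ", "), ")", call. = FALSE)
  }
  .model_from_lm(fit, response, length(y))
}

#' Stepwise selection of a prediction equation
#'
#' Classical p-value stepwise regression: at each step the candidate with the
#' smallest partial-F p-value enters if that p-value is at most `p_enter`;
#' included predictors whose partial p-value rises to `p_remove` or above are
#' then dropped; iteration stops when nothing changes. Ties are broken by
#' candidate input order, so the procedure is deterministic.
#'
#' @param candidates A data.frame of candidate predictors.
#' @param y Numeric response.
#' @param p_enter Entry threshold (default 0.05).
#' @param p_remove Removal threshold (default 0.10; must be >= `p_enter`).
#' @inheritParams ols_fit
#' @return An object of class `"sid_model"` (intercept-only when no candidate
#'   qualifies).
#' @export
stepwise_select <- function(candidates, y, p_enter = 0.05, p_remove = 0.10,
                            response = "y") {
  candidates <- as.data.frame(candidates)
  if (ncol(candidates) == 0) stop("candidates must be nonempty", call. = FALSE)
  if (p_remove < p_enter) {
    stop("configuration error: p_remove must be >= p_enter (cycling risk)",
         call. = FALSE)
  }
  partial_p <- function(included) {
    # p-value of each included predictor's coefficient t-test (== partial F)
    dat <- cbind(.y = y, candidates[included])
    s <- summary(stats::lm(.y ~ ., data = dat))$coefficients
    stats::setNames(s[match(included, rownames(s)), "Pr(>|t|)"], included)
  }
  included <- character(0)
  repeat {
    changed <- FALSE
    pool <- setdiff(names(candidates), included)
    if (length(pool) && length(y) > length(included) + 2) {
      entry_p <- vapply(pool, function(cand) {
        dat <- cbind(.y = y, candidates[c(included, cand)])
        s <- summary(stats::lm(.y ~ ., data = dat))$coefficients
        if (!cand %in% rownames(s)) return(NA_real_)  # collinear with included
        s[cand, "Pr(>|t|)"]
      }, numeric(1))
      if (any(!is.na(entry_p)) && min(entry_p, na.rm = TRUE) <= p_enter) {
        best <- pool[which.min(entry_p)]  # first minimum = input-order tie-break
        included <- c(included, best)
        changed <- TRUE
      }
    }
    if (length(included)) {
      pp <- partial_p(included)
      if (max(pp) >= p_remove) {
        included <- setdiff(included, names(which.max(pp)))
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  if (length(included) == 0) {
    fit <- stats::lm(y ~ 1)
    return(.model_from_lm(fit, response, length(y)))
  }
  ols_fit(candidates[included], y, response = response)
}

#' Evaluate a fitted prediction equation on a new composition
#'
#' @param model A `"sid_model"`.
#' @param composition Named list/vector supplying every model predictor.
#' @return Predicted response (numeric scalar).
#' @examples
#' fx <- rsc_fixtures()
#' m <- ols_fit(predictor_table(fx$ingredients)["NDF"],
#'              as.numeric(fx$sid[fx$sid$component == "Lys",
#'                                fx$ingredients$sample_id]),
#'              response = "SID_Lys")
#' predict_from_model(m, c(NDF = 30.19))
#' @export
predict_from_model <- function(model, composition) {
  stopifnot(inherits(model, "sid_model"))
  missing <- setdiff(model$predictors, names(composition))
  if (length(missing)) {
    stop("missing predictor(s): ", paste(missing, collapse = ", "), call. = FALSE)
  }
  vals <- unlist(composition[model$predictors], use.names = FALSE)
  model$intercept + sum(model$coefficients * vals)
}

#' @export
predict.sid_model <- function(object, newdata, ...) {
  if (is.data.frame(newdata)) {
    apply(newdata, 1, function(row) predict_from_model(object, as.list(row)))
  } else {
    predict_from_model(object, newdata)
  }
}

#' Render a fitted equation as text
#'
#' @param model A `"sid_model"`.
#' @param digits Decimals for the coefficients (default 3, the convention of
#'   the published equations).
#' @return A single string such as `"SID_Lys = 100.107 - 1.229*NDF"`.
#' @export
equation_text <- function(model, digits = 3) {
  fmt <- function(v) formatC(abs(v), digits = digits, format = "f")
  rhs <- fmt(model$intercept)
  if (model$intercept < 0) rhs <- paste0("-", rhs)
  for (p in model$predictors) {
    b <- model$coefficients[[p]]
    rhs <- paste0(rhs, if (b < 0) " - " else " + ", fmt(b), "*", p)
  }
  paste(model$response, "=", rhs)
}

#' @export
print.sid_model <- function(x, ...) {
  cat(equation_text(x), "\n", sep = "")
  cat(sprintf("  n = %d, R2 = %.3f, adj R2 = %.3f, RSD = %.3f, p = %s\n",
              x$n, x$r2, x$adj_r2, x$rsd,
              if (is.na(x$p_value)) "NA" else format.pval(x$p_value, digits = 3)))
  invisible(x)
}
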