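# Survival comparison of subtypes. The standard estimators (product-limit
# curves, log-rank test, Cox partial-likelihood fits, Harrell's C) are
# computed through the survival package; this module wraps them in the
# pipeline's contracts (at-risk tables, pairwise and scheme-level hazard
# ratios, Gleason-adjusted models per endpoint).

#' Kaplan-Meier product-limit estimate
#'
#' @param times event/censoring times (> 0, months).
#' @param events 0/1 event indicators.
#' @return data.frame of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `surv` at every distinct observed time. S(0) = 1 is implicit.
#' @export
km_estimate <- function(times, events) {
  .check_surv(times, events)
  fit <- survival::survfit(survival::Surv(times, events) ~ 1)
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, surv = fit$surv)
  class(out) <- c("km_curve", "data.frame")
  out
}

.check_surv <- function(times, events) {
  if (length(times) == 0L) stop("empty survival input")
  if (length(times) != length(events)) stop("times/events length mismatch")
  if (any(is.na(times)) || any(is.na(events))) stop("missing survival values")
  if (any(times <= 0)) stop("times must be strictly positive")
  if (!all(events %in% c(0, 1))) stop("events must be 0/1")
  invisible(TRUE)
}

#' Log-rank test across groups
#'
#' @param times,events survival input as in [km_estimate()].
#' @param groups per-observation group labels (>= 2 non-empty groups).
#' @return list with `statistic` (chi-square), `df`, `p_value`.
#' @export
logrank_test <- function(times, events, groups) {
  .check_surv(times, events)
  groups <- as.factor(groups)
  if (nlevels(droplevels(groups)) < 2L) stop("log-rank needs >= 2 groups")
  if (sum(events) < 1L) stop("log-rank needs at least one event")
  fit <- survival::survdiff(survival::Surv(times, events) ~ groups)
  df <- length(fit$n) - 1L
  list(statistic = fit$chisq, df = df,
       p_value = pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional hazards fit
#'
#' Fits a Cox model by maximum partial likelihood with the Efron tie
#' correction by default, and reports hazard ratios with 95% Wald
#' intervals (z = 1.959964) and Harrell's C-index of the model's linear
#' predictor.
#'
#' @param times,events survival input.
#' @param covariates numeric design matrix or data.frame (one column per
#'   covariate; factors must be pre-coded).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @return object of class `cox_fit`: data.frame `coefficients`
#'   (`term`, `beta`, `hr`, `ci_lower`, `ci_upper`, `se`, `p_wald`) plus
#'   attributes `c_index`, `ties`, `iter`, `n`, `n_event`.
#' @export
cox_fit <- function(times, events, covariates, ties = c("efron", "breslow")) {
  ties <- match.arg(ties)
  .check_surv(times, events)
  if (sum(events) < 1L) stop("Cox fit needs at least one event")
  xm <- as.matrix(as.data.frame(covariates))
  storage.mode(xm) <- "double"
  if (qr(cbind(1, xm))$rank < ncol(xm) + 1L)
    stop("design matrix is rank deficient")
  fit <- survival::coxph(survival::Surv(times, events) ~ xm, ties = ties)
  if (any(!is.finite(coef(fit))))
    stop("Cox fit failed to converge to finite coefficients")
  if (any(abs(coef(fit)) > 15))
    warning("very large |beta|: possible monotone likelihood (separation)")
  beta <- coef(fit)
  se <- sqrt(diag(fit$var))
  co <- data.frame(term = colnames(xm), beta = unname(beta),
                   hr = exp(unname(beta)),
                   ci_lower = exp(unname(beta) - .Z95 * se),
                   ci_upper = exp(unname(beta) + .Z95 * se),
                   se = unname(se),
                   p_wald = 2 * pnorm(-abs(unname(beta) / se)),
                   stringsAsFactors = FALSE)
  structure(co, class = c("cox_fit", "data.frame"),
            c_index = unname(summary(fit)$concordance["C"]),
            ties = ties, iter = fit$iter,
            n = fit$n, n_event = fit$nevent,
            loglik = fit$loglik)
}

#' Harrell's concordance index
#'
#' Fraction of comparable pairs (usable under censoring) in which the
#' higher risk score accompanies the earlier event; tied scores count
#' one half.
#'
#' @param times,events survival input.
#' @param risk_scores numeric per-observation risk scores (higher =
#'   higher predicted hazard).
#' @return C in \[0, 1\].
#' @export
concordance_index <- function(times, events, risk_scores) {
  .check_surv(times, events)
  if (length(risk_scores) != length(times))
    stop("risk_scores length mismatch")
  cc <- survival::concordance(survival::Surv(times, events) ~ risk_scores,
                              reverse = TRUE)
  cnt <- cc$count
  if (sum(cnt[c("concordant", "discordant", "tied.x")]) == 0)
    stop("no comparable pairs under censoring")
  unname(cc$concordance)
}

.GLEASON_ORDINAL <- c(lt7 = 0, eq7 = 1, gt7 = 2)

#' Per-endpoint survival comparison of a scheme's subtypes
#'
#' For each endpoint: Kaplan-Meier curves and a log-rank test across
#' subtypes; univariable pairwise hazard ratios between all subtype pairs
#' (reference = the less aggressive class of the pair, in the scheme's
#' aggressiveness order); a scheme-level hazard ratio coding the scheme
#' as the binary indicator "most aggressive subtype vs rest" (or ordinal
#' aggressiveness 2/1/0 with `scheme_coding = "ordinal"`); and optionally
#' the same model adjusted for Gleason category entered as ordinal 0/1/2
#' for lt7/eq7/gt7. Subtype pairs with zero events are reported as
#' non-estimable rather than failing.
#'
#' @param assignments a `subtype_assignment` data.frame.
#' @param clinical a `clinical_table` from [read_clinical()] or
#'   [generate_cohort()].
#' @param class_order subtype labels from most to least aggressive
#'   (default: the scheme's order stored in the assignment scores
#'   column order).
#' @param endpoints endpoints to analyze (default: those present).
#' @param adjust_gleason also fit Gleason-adjusted models (default TRUE
#'   when `gleason_category` is present).
#' @param scheme_coding `"binary"` (default) or `"ordinal"`.
#' @return list of class `outcome_report`, one element per endpoint:
#'   `km` (per-subtype `km_curve`s), `logrank`, `pairwise` (data.frame of
#'   pairwise HRs), `scheme` (`cox_fit`), `scheme_adjusted` (or NULL),
#'   `c_index`, `c_index_adjusted`.
#' @export
subtype_outcome_report <- function(assignments, clinical,
                                   class_order = NULL, endpoints = NULL,
                                   adjust_gleason = NULL,
                                   scheme_coding = c("binary", "ordinal")) {
  scheme_coding <- match.arg(scheme_coding)
  common <- intersect(assignments$sample_id, clinical$sample_id)
  if (length(common) == 0L) stop("assignments and clinical share no samples")
  cls <- assignments$class[match(common, assignments$sample_id)]
  cl <- clinical[match(common, clinical$sample_id), , drop = FALSE]
  if (is.null(class_order)) {
    sc <- sub("^score_", "", grep("^score_", names(assignments), value = TRUE))
    class_order <- if (length(sc)) sc else sort(unique(cls))
  }
  present <- class_order[class_order %in% unique(cls)]
  if (length(present) < 2L) stop("need at least 2 subtypes with samples")
  if (is.null(endpoints)) {
    endpoints <- sub("_time$", "", grep("_time$", names(cl), value = TRUE))
  }
  if (is.null(adjust_gleason))
    adjust_gleason <- "gleason_category" %in% names(cl)
  gle <- if (adjust_gleason)
    unname(.GLEASON_ORDINAL[as.character(cl$gleason_category)]) else NULL
  report <- list()
  for (ep in endpoints) {
    tt <- cl[[paste0(ep, "_time")]]
    ev <- cl[[paste0(ep, "_event")]]
    ok <- !(is.na(tt) | is.na(ev))
    res <- list()
    res$km <- lapply(setNames(present, present), function(k) {
      idx <- ok & cls == k
      km_estimate(tt[idx], ev[idx])
    })
    res$logrank <- logrank_test(tt[ok], ev[ok], cls[ok])
    pairs <- t(combn(present, 2L))
    pw <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      # class_order is most-aggressive-first: pairs[i,1] is the more
      # aggressive of the pair, pairs[i,2] the reference
      agg <- pairs[i, 1L]; ref <- pairs[i, 2L]
      idx <- ok & cls %in% c(agg, ref)
      row <- data.frame(comparison = paste0(agg, "_vs_", ref),
                        hr = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_wald = NA_real_,
                        n = sum(idx), n_event = sum(ev[idx]),
                        estimable = FALSE, stringsAsFactors = FALSE)
      ev_a <- sum(ev[idx & cls == agg]); ev_r <- sum(ev[idx & cls == ref])
      if (ev_a >= 1 && ev_r >= 1) {
        f <- tryCatch(cox_fit(tt[idx], ev[idx],
                              data.frame(x = as.numeric(cls[idx] == agg))),
                      error = function(e) NULL, warning = function(w) NULL)
        if (!is.null(f)) {
          row$hr <- f$hr; row$ci_lower <- f$ci_lower
          row$ci_upper <- f$ci_upper; row$p_wald <- f$p_wald
          row$estimable <- TRUE
        }
      }
      row
    }))
    scheme_x <- if (scheme_coding == "binary")
      as.numeric(cls == present[1L])
    else (length(present) - match(cls, present))  # most aggressive highest
    res$scheme <- cox_fit(tt[ok], ev[ok], data.frame(scheme = scheme_x[ok]))
    res$c_index <- attr(res$scheme, "c_index")
    res$scheme_adjusted <- NULL
    res$c_index_adjusted <- NA_real_
    if (adjust_gleason && !all(is.na(gle))) {
      use <- ok & !is.na(gle)
      res$scheme_adjusted <- cox_fit(
        tt[use], ev[use],
        data.frame(scheme = scheme_x[use], gleason = gle[use]))
      res$c_index_adjusted <- attr(res$scheme_adjusted, "c_index")
    }
    res$pairwise <- pw
    report[[ep]] <- res
  }
  structure(report, class = "outcome_report",
            scheme = assignments$scheme[1L], class_order = present)
}
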