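#' Pearson correlation with t-test p-value and Fisher-z 95% interval
#'
#' Product-moment correlation computed from first principles: two-sided
#' p-value via the t transform `t = r sqrt((n-2) / (1-r^2))` on `n - 2`
#' degrees of freedom, and the confidence interval via the Fisher
#' z-transform with standard error `1 / sqrt(n - 3)`.
#'
#' @param x,y numeric vectors of equal length, n >= 3, finite, each with
#'   nonzero variance.
#' @param conf confidence level (default 0.95).
#' @return list with `r`, `p_value`, `ci95` (length-2), `n`.
#' @export
pearson_with_ci <- function(x, y, conf = 0.95) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_("x and y must have equal length")
  if (n < 3L) stop_("need at least 3 observations (got %d)", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("values must be finite")
  sx <- x - mean(x); sy <- y - mean(y)
  vx <- sum(sx^2); vy <- sum(sy^2)
  if (vx == 0 || vy == 0) stop_("zero variance: correlation undefined")
  r <- sum(sx * sy) / sqrt(vx * vy)
  r <- clamp(r, -1, 1)
  p <- if (abs(r) >= 1) 0 else {
    tt <- r * sqrt((n - 2) / (1 - r^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  ci <- if (n > 3 && abs(r) < 1) {
    z <- atanh(r)
    se <- 1 / sqrt(n - 3)
    crit <- stats::qnorm(1 - (1 - conf) / 2)
    tanh(c(z - crit * se, z + crit * se))
  } else c(NA_real_, NA_real_)
  list(r = r, p_value = p, ci95 = ci, n = n)
}

#' Ordinary least-squares simple linear regression
#'
#' Normal-equation fit of `y = intercept + slope * x` with the slope
#' standard error and two-sided t-test p-value for the slope, plus the
#' Pearson correlation of the pair (with its own p and interval). By the
#' axes convention of the figures this package mirrors, `x` is the
#' structural (CT/emphysema) or first-named variable.
#'
#' @param x,y numeric vectors of equal length, n >= 3.
#' @return list of class `lobe_regression`: `slope`, `slope_se`,
#'   `p_value_slope`, `intercept`, `pearson_r`, `p_value_r`, `ci95_r`, `n`.
#' @export
linear_regression <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  n <- length(x)
  if (length(y) != n) stop_("x and y must have equal length")
  if (n < 3L) stop_("need at least 3 observations (got %d)", n)
  if (any(!is.finite(x)) || any(!is.finite(y))) stop_("values must be finite")
  sxx <- sum((x - mean(x))^2)
  if (sxx == 0) stop_("degenerate x: zero variance")
  sxy <- sum((x - mean(x)) * (y - mean(y)))
  slope <- sxy / sxx
  intercept <- mean(y) - slope * mean(x)
  resid <- y - intercept - slope * x
  ss_res <- sum(resid^2)
  slope_se <- sqrt(ss_res / (n - 2) / sxx)
  p_slope <- if (slope_se == 0) {
    if (slope == 0) 1 else 0
  } else 2 * stats::pt(-abs(slope / slope_se), df = n - 2)
  pc <- if (sum((y - mean(y))^2) > 0) {
    pearson_with_ci(x, y)
  } else list(r = NA_real_, p_value = NA_real_, ci95 = c(NA_real_, NA_real_), n = n)
  structure(list(slope = slope, slope_se = slope_se, p_value_slope = p_slope,
                 intercept = intercept, pearson_r = pc$r, p_value_r = pc$p_value,
                 ci95_r = pc$ci95, n = n),
            class = "lobe_regression")
}

#' @export
print.lobe_regression <- function(x, ...) {
  cat(sprintf("<regression: slope = %.4g +/- %.4g (p = %.3g), r = %.3f (p = %.3g), n = %d>\n",
              x$slope, x$slope_se, x$p_value_slope, x$pearson_r, x$p_value_r, x$n))
  invisible(x)
}

reg_row <- function(pair, fit) {
  if (is.null(fit)) {
    return(data.frame(pair = pair, n = NA_integer_, slope = NA_real_,
                      slope_se = NA_real_, p_value_slope = NA_real_,
                      pearson_r = NA_real_, p_value_r = NA_real_,
                      ci95_lo = NA_real_, ci95_hi = NA_real_,
                      computable = FALSE, stringsAsFactors = FALSE))
  }
  data.frame(pair = pair, n = fit$n, slope = fit$slope, slope_se = fit$slope_se,
             p_value_slope = fit$p_value_slope, pearson_r = fit$pearson_r,
             p_value_r = fit$p_value_r, ci95_lo = fit$ci95_r[1],
             ci95_hi = fit$ci95_r[2], computable = TRUE,
             stringsAsFactors = FALSE)
}

safe_reg <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3L) return(NULL)
  tryCatch(linear_regression(x[ok], y[ok]), error = function(e) NULL)
}

#' Cohort comparison report
#'
#' Reproduces the three-level comparison structure of a lobar multi-modality
#' study on a cohort of score tables:
#' (a) per-subject correlations of the five lobar CT percent-emphysema
#' values against each relative score (gas-MRI ventilation share, SPECT
#' ventilation and perfusion shares);
#' (b) pooled lobar regressions across all subjects for the
#' emphysema-vs-score and between-modality pairings;
#' (c) whole-lung regressions against supplied lung-function covariates
#' (FEV1 percent-predicted, FEV1/FVC).
#'
#' Subjects missing a modality contribute NA to that pairing and are
#' excluded per-analysis; any requested correlation with fewer than three
#' complete lobe pairs is reported as not computable rather than dropped.
#'
#' @param tables data.frame of stacked [lobar_score_table()] rows (one or
#'   more subjects).
#' @param covariates optional data.frame with columns subject_id,
#'   fev1_pct_pred, fev1_fvc_pct.
#' @return list of class `cohort_report`: `per_subject` (data.frame of
#'   per-subject 5-lobe correlations), `pooled` (data.frame of pooled
#'   lobar regressions), `whole_lung` (data.frame of lung-function
#'   regressions, NULL without covariates).
#' @export
run_cohort_comparison <- function(tables, covariates = NULL) {
  stopifnot(is.data.frame(tables))
  need <- c("subject_id", "lobe", "ct_emphysema_pct", "hpx_rel_vent_pct",
            "hpx_abs_vent_pct", "spect_vent_pct", "spect_perf_pct")
  if (!all(need %in% names(tables))) {
    stop_("score table lacks columns: %s",
          paste(setdiff(need, names(tables)), collapse = ", "))
  }
  lobes <- tables[tables$lobe %in% LOBE_NAMES, ]
  wl <- tables[tables$lobe == "whole_lung", ]
  subjects <- unique(tables$subject_id)
  if (length(subjects) < 2L) {
    warning("cohort has fewer than 2 subjects; pooled estimates equal the single subject",
            call. = FALSE)
  }

  per_pairings <- c(hpx_rel_vent_pct = "emphysema_vs_hpx_rel_vent",
                    spect_vent_pct = "emphysema_vs_spect_vent",
                    spect_perf_pct = "emphysema_vs_spect_perf")
  per_subject <- do.call(rbind, lapply(subjects, function(s) {
    st <- lobes[lobes$subject_id == s, ]
    do.call(rbind, lapply(names(per_pairings), function(col) {
      fit <- safe_reg(st$ct_emphysema_pct, st[[col]])
      cbind(data.frame(subject_id = s, stringsAsFactors = FALSE),
            reg_row(per_pairings[[col]], fit))
    }))
  }))

  pooled_defs <- list(
    emphysema_vs_hpx_rel_vent = c("ct_emphysema_pct", "hpx_rel_vent_pct"),
    emphysema_vs_hpx_abs_vent = c("ct_emphysema_pct", "hpx_abs_vent_pct"),
    emphysema_vs_spect_perf = c("ct_emphysema_pct", "spect_perf_pct"),
    emphysema_vs_spect_vent = c("ct_emphysema_pct", "spect_vent_pct"),
    hpx_rel_vent_vs_spect_perf = c("hpx_rel_vent_pct", "spect_perf_pct"),
    hpx_rel_vent_vs_spect_vent = c("hpx_rel_vent_pct", "spect_vent_pct"),
    spect_vent_vs_spect_perf = c("spect_vent_pct", "spect_perf_pct")
  )
  pooled <- do.call(rbind, lapply(names(pooled_defs), function(p) {
    cols <- pooled_defs[[p]]
    reg_row(p, safe_reg(lobes[[cols[1]]], lobes[[cols[2]]]))
  }))

  whole_lung <- NULL
  if (!is.null(covariates)) {
    stopifnot(is.data.frame(covariates), "subject_id" %in% names(covariates))
    m <- merge(wl, covariates, by = "subject_id")
    defs <- expand.grid(score = c("hpx_abs_vent_pct", "ct_emphysema_pct"),
                        covariate = intersect(c("fev1_pct_pred", "fev1_fvc_pct"),
                                              names(covariates)),
                        stringsAsFactors = FALSE)
    whole_lung <- do.call(rbind, lapply(seq_len(nrow(defs)), function(i) {
      sc <- defs$score[i]; cv <- defs$covariate[i]
      reg_row(paste0(sc, "_vs_", cv), safe_reg(m[[sc]], m[[cv]]))
    }))
  }

  structure(list(per_subject = per_subject, pooled = pooled,
                 whole_lung = whole_lung),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  star <- function(p) ifelse(is.finite(p) & p < 0.05, "*", "")
  cat("Pooled lobar regressions (x = first-named variable):\n")
  p <- x$pooled
  for (i in seq_len(nrow(p))) {
    if (!p$computable[i]) {
      cat(sprintf("  %-28s not computable (< 3 complete pairs)\n", p$pair[i]))
    } else {
      cat(sprintf("  %-28s slope = %7.3f +/- %.3f (p = %.3g)%s  r = %6.3f (p = %.3g)%s  n = %d\n",
                  p$pair[i], p$slope[i], p$slope_se[i], p$p_value_slope[i],
                  star(p$p_value_slope[i]), p$pearson_r[i], p$p_value_r[i],
                  star(p$p_value_r[i]), p$n[i]))
    }
  }
  if (!is.null(x$whole_lung)) {
    cat("Whole-lung vs lung function:\n")
    w <- x$whole_lung
    for (i in seq_len(nrow(w))) {
      if (!w$computable[i]) {
        cat(sprintf("  %-40s not computable\n", w$pair[i]))
      } else {
        cat(sprintf("  %-40s r = %6.3f (p = %.3g)%s  n = %d\n",
                    w$pair[i], w$pearson_r[i], w$p_value_r[i],
                    star(w$p_value_r[i]), w$n[i]))
      }
    }
  }
  cat(sprintf("Per-subject 5-lobe correlations: %d subjects x %d pairings\n",
              length(unique(x$per_subject$subject_id)),
              length(unique(x$per_subject$pair))))
  invisible(x)
}
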