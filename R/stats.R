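#' Sidak-adjusted per-comparison significance level
#'
#' For m comparisons at familywise level alpha, the adjusted
#' per-comparison level is \code{1 - (1 - alpha)^(1/m)}, which satisfies
#' \code{(1 - alpha')^m = 1 - alpha} exactly.
#'
#' @param alpha familywise error rate.
#' @param m number of comparisons.
#' @return adjusted level alpha'.
#' @export
sidak_alpha <- function(alpha, m) {
  stopifnot(alpha > 0, alpha < 1, m >= 1)
  1 - (1 - alpha)^(1 / m)
}

#' Per-slice patient/control comparison of normalized crystal area
#'
#' Compares the mean normalized crystal area between the two groups at
#' every image slice with a two-sample Welch test, controlling the
#' familywise error over the slices at level \code{alpha} with the Sidak
#' adjustment.  On cohorts with a papillary-dermis-restricted crystal
#' burden, significant slices should concentrate in the band.
#'
#' @param profiles_patients,profiles_controls lists of [area_profile()]
#'   data frames, all with the same slice count.
#' @param alpha familywise significance level; default 0.05.
#' @return data frame with one row per slice: \code{slice_index},
#'   \code{mean_patient}, \code{mean_control}, \code{mean_diff},
#'   \code{p_value}, \code{significant}; the Sidak level used is attached
#'   as attribute \code{"alpha_adjusted"}.
#' @export
per_slice_comparison <- function(profiles_patients, profiles_controls,
                                 alpha = 0.05) {
  if (length(profiles_patients) < 2L || length(profiles_controls) < 2L)
    stop("each group needs at least 2 profiles")
  m <- nrow(profiles_patients[[1L]])
  get_mat <- function(profiles) {
    vapply(profiles, function(p) {
      if (nrow(p) != m) stop("profiles have differing slice counts")
      p$normalized_area
    }, numeric(m))
  }
  xp <- get_mat(profiles_patients)   # m x n_patients
  xc <- get_mat(profiles_controls)
  a_adj <- sidak_alpha(alpha, m)
  res <- do.call(rbind, lapply(seq_len(m), function(k) {
    a <- xp[k, ]; b <- xc[k, ]
    p <- if (sd(a) == 0 && sd(b) == 0) {
      if (mean(a) == mean(b)) 1 else 0
    } else {
      t.test(a, b)$p.value
    }
    data.frame(slice_index = profiles_patients[[1L]]$slice_index[k],
               mean_patient = mean(a), mean_control = mean(b),
               mean_diff = mean(a) - mean(b), p_value = p)
  }))
  res$significant <- res$p_value < a_adj
  attr(res, "alpha_adjusted") <- a_adj
  res
}

#' Two-group comparison of a per-subject statistic
#'
#' Two-sided two-sample t-test of e.g. nCCV between patients and
#' controls.  Welch's unequal-variance form is the default because
#' patient and control spreads can differ severalfold; a pooled-variance
#' option is provided.  If both groups are constant the test degenerates:
#' p = 1 when the means agree, and a separation flag with p = 0 when they
#' do not.
#'
#' @param x_patients,x_controls numeric vectors, each of length >= 2.
#' @param var_equal use the pooled-variance form; default \code{FALSE}
#'   (Welch).
#' @return list with \code{t}, \code{df}, \code{p}, per-group
#'   \code{means} and \code{sds}, and a \code{degenerate} flag.
#' @export
group_t_test <- function(x_patients, x_controls, var_equal = FALSE) {
  stopifnot(length(x_patients) >= 2L, length(x_controls) >= 2L)
  means <- c(patient = mean(x_patients), control = mean(x_controls))
  sds <- c(patient = sd(x_patients), control = sd(x_controls))
  if (sds[1] == 0 && sds[2] == 0) {
    eq <- means[1] == means[2]
    return(list(t = if (eq) 0 else Inf, df = NA_real_,
                p = if (eq) 1 else 0,
                means = means, sds = sds, degenerate = TRUE))
  }
  tt <- t.test(x_patients, x_controls, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, means = means, sds = sds, degenerate = FALSE)
}

# Mann-Whitney AUC with ties counted one half, via midranks.
auc_rank <- function(scores, labels) {
  r <- rank(scores)
  n1 <- sum(labels)
  n0 <- sum(!labels)
  (sum(r[labels]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC area under the curve with bootstrap confidence interval
#'
#' Discrimination of a score (e.g. nCCV) between two groups.  The AUC is
#' the Mann-Whitney U statistic divided by \code{n1 * n0}, with tied
#' pairs counted one half; the confidence interval is a seeded stratified
#' (within-group) percentile bootstrap.
#'
#' @param scores numeric scores.
#' @param labels logical (or coercible) class labels; \code{TRUE} =
#'   positive (patient).
#' @param conf_level confidence level; default 0.95.
#' @param n_boot bootstrap resamples; default 2000.
#' @param seed RNG seed for the bootstrap; default 1.
#' @return list with \code{auc}, \code{ci_low}, \code{ci_high},
#'   \code{n_pos}, \code{n_neg}.
#' @export
roc_auc <- function(scores, labels, conf_level = 0.95, n_boot = 2000L,
                    seed = 1L) {
  labels <- as.logical(labels)
  stopifnot(length(scores) == length(labels), !anyNA(labels))
  if (!any(labels) || all(labels))
    stop("both classes must be present for ROC analysis")
  auc <- auc_rank(scores, labels)
  pos <- scores[labels]
  neg <- scores[!labels]
  set.seed(seed)
  boots <- vapply(seq_len(n_boot), function(i) {
    bp <- sample(pos, replace = TRUE)
    bn <- sample(neg, replace = TRUE)
    auc_rank(c(bp, bn), rep(c(TRUE, FALSE), c(length(bp), length(bn))))
  }, numeric(1))
  qs <- quantile(boots, c((1 - conf_level) / 2, (1 + conf_level) / 2),
                 names = FALSE)
  list(auc = auc, ci_low = qs[1], ci_high = qs[2],
       n_pos = length(pos), n_neg = length(neg))
}

#' Correlation between two paired measurements
#'
#' Pearson product-moment or Spearman rank correlation with a two-sided
#' p-value, as used to relate nCCV to age or to leukocyte cystine level.
#'
#' @param x,y paired numeric vectors, n >= 3.
#' @param method \code{"pearson"} or \code{"spearman"}.
#' @return list with \code{estimate} (r or rho), \code{p}, \code{n},
#'   \code{method}.
#' @export
correlation <- function(x, y, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(x) == length(y), length(x) >= 3L)
  if (sd(x) == 0 || sd(y) == 0)
    stop("correlation is undefined for a zero-variance input")
  ct <- suppressWarnings(cor.test(x, y, method = method, exact = FALSE))
  list(estimate = unname(ct$estimate), p = ct$p.value, n = length(x),
       method = method)
}

#' Coefficient of variation of repeat acquisitions
#'
#' Repeatability of nCCV across re-acquisitions of the same site:
#' \code{CV = 100 * SD / mean} (sample SD, n - 1 denominator), in percent.
#'
#' @param repeats numeric vector of repeat measurements, n >= 2.
#' @return CV in percent.
#' @export
repeatability_cv <- function(repeats) {
  stopifnot(length(repeats) >= 2L)
  m <- mean(repeats)
  if (m <= 0) stop("CV is undefined for a non-positive mean")
  100 * sd(repeats) / m
}

#' Convert leukocyte cystine level to granulocyte cystine level
#'
#' Granulocyte cystine is obtained from the mixed-leukocyte assay value
#' by multiplying by 1.95.
#'
#' @param leukocyte_level cystine level in nmol/mg protein half-cystine
#'   (vectorised, nonnegative).
#' @return granulocyte cystine level, same units.
#' @export
granulocyte_from_leukocyte <- function(leukocyte_level) {
  stopifnot(is.numeric(leukocyte_level))
  if (any(leukocyte_level < 0))
    stop("cystine levels must be nonnegative")
  1.95 * leukocyte_level
}

#' Pediatric eGFR by the bedside Schwartz equation
#'
#' \code{eGFR = k * height / serum creatinine} with k = 0.413, in
#' mL/min/1.73 m^2.
#'
#' @param height_cm height in cm (> 0, vectorised).
#' @param serum_creatinine_mg_dl serum creatinine in mg/dL (> 0).
#' @param k proportionality constant; default 0.413.
#' @return estimated GFR in mL/min/1.73 m^2.
#' @export
egfr_schwartz <- function(height_cm, serum_creatinine_mg_dl, k = 0.413) {
  if (any(height_cm <= 0) || any(serum_creatinine_mg_dl <= 0))
    stop("height and creatinine must be positive")
  k * height_cm / serum_creatinine_mg_dl
}

#' Association between standardized nCCV and a clinical outcome
#'
#' Fits a maximum-likelihood logistic regression (binary outcome) or
#' ordinary least squares (continuous outcome) with the z-scored nCCV as
#' the main predictor plus optional covariates, and reports the effect
#' per 1 SD of nCCV: an odds ratio for binary outcomes, a slope for
#' continuous ones, each with a Wald 95\% confidence interval and Wald
#' chi-square.  nCCV is standardized within the analyzed subset (after
#' any restriction and listwise deletion), so effects are per cohort-SD.
#' Pre-specified clinical models are expressed through \code{covariates}
#' and \code{restrict} (e.g. CKD stage adjusted for age and eGFR among
#' transplant-free subjects; hypothyroidism adjusted for sex at age >= 9).
#'
#' @param records data frame of per-subject records; must contain
#'   \code{nccv_um3}, the outcome, and any covariates.
#' @param outcome outcome column name.
#' @param kind \code{"binary"} (logistic) or \code{"continuous"} (OLS).
#' @param covariates character vector of covariate column names.
#' @param restrict optional predicate \code{function(records)} returning
#'   a logical vector, applied before fitting.
#' @param conf_level Wald confidence level; default 0.95.
#' @return an object of class \code{"nccv_association"}: \code{outcome},
#'   \code{kind}, \code{effect} (OR or slope per SD), \code{ci_low},
#'   \code{ci_high}, \code{wald_chi_square}, \code{p_value},
#'   \code{covariates}, \code{n}, and a \code{separation} flag (set, with
#'   a warning, when the logistic fit is quasi-separated rather than
#'   silently divergent).
#' @export
association <- function(records, outcome, kind = c("binary", "continuous"),
                        covariates = character(0), restrict = NULL,
                        conf_level = 0.95) {
  kind <- match.arg(kind)
  stopifnot(is.data.frame(records), "nccv_um3" %in% names(records))
  miss <- setdiff(c(outcome, covariates), names(records))
  if (length(miss))
    stop("unknown field(s): ", paste(miss, collapse = ", "),
         "; available: ", paste(names(records), collapse = ", "))
  if (!is.null(restrict)) records <- records[restrict(records), , drop = FALSE]
  cols <- c("nccv_um3", outcome, covariates)
  keep <- complete.cases(records[, cols, drop = FALSE])
  n_dropped <- sum(!keep)
  records <- records[keep, , drop = FALSE]
  n <- nrow(records)
  if (n < 10L)
    stop("fewer than 10 complete records for outcome '", outcome, "'")
  if (n_dropped > 0)
    message(n_dropped, " record(s) dropped by listwise deletion; n = ", n)
  if (n <= length(covariates) + 2L)
    stop("too few records for the number of parameters")

  dat <- records
  dat$nccv_z <- as.numeric(scale(dat$nccv_um3))
  fml <- stats::reformulate(c("nccv_z", covariates), response = outcome)
  separation <- FALSE
  if (kind == "binary" && length(unique(dat[[outcome]])) < 2L)
    separation <- TRUE  # degenerate outcome: nothing to discriminate
  if (kind == "binary") {
    fit <- withCallingHandlers(
      glm(fml, data = dat, family = binomial()),
      warning = function(w) {
        if (grepl("fitted probabilities numerically 0 or 1|did not converge",
                  conditionMessage(w))) {
          separation <<- TRUE
          invokeRestart("muffleWarning")
        }
      })
  } else {
    fit <- lm(fml, data = dat)
  }
  beta <- coef(fit)[["nccv_z"]]
  se <- sqrt(vcov(fit)["nccv_z", "nccv_z"])
  if (!separation && kind == "binary" && abs(beta) > 15) separation <- TRUE
  if (separation)
    warning("quasi-complete separation detected for outcome '", outcome,
            "'; estimates are unreliable")
  z <- qnorm((1 + conf_level) / 2)
  chi2 <- (beta / se)^2
  p <- pchisq(chi2, df = 1, lower.tail = FALSE)
  trans <- if (kind == "binary") exp else identity
  structure(list(outcome = outcome, kind = kind,
                 effect = trans(beta),
                 ci_low = trans(beta - z * se),
                 ci_high = trans(beta + z * se),
                 wald_chi_square = chi2, p_value = p,
                 covariates = covariates, n = n,
                 separation = separation),
            class = "nccv_association")
}

#' @export
print.nccv_association <- function(x, ...) {
  lab <- if (x$kind == "binary") "OR" else "slope"
  cat(sprintf("%s ~ nCCV (per SD)%s: %s = %.3g [%.3g, %.3g], chi2 = %.2f, p = %.3g, n = %d%s\n",
              x$outcome,
              if (length(x$covariates))
                paste0(" + ", paste(x$covariates, collapse = " + "))
              else "",
              lab, x$effect, x$ci_low, x$ci_high, x$wald_chi_square,
              x$p_value, x$n,
              if (x$separation) "  [separation!]" else ""))
  invisible(x)
}
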