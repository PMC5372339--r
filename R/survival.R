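#' Split samples by clustering on a signature
#'
#' Clusters samples on the expression of the signature features (Pearson
#' correlation distance, complete linkage) and cuts the dendrogram into `k`
#' groups, labelled `1, 2, ...` by decreasing size.  Signature features
#' absent from the matrix are reported in a warning (validation cohorts
#' rarely measure the full signature).
#'
#' @param expr features x samples log2 expression matrix.
#' @param signature character vector of signature feature names.
#' @param k number of groups, default 2.
#' @return list with `groups` (named labels), `present` and `absent` feature
#'   names.
#' @export
split_by_signature <- function(expr, signature, k = 2L) {
  present <- intersect(signature, rownames(expr))
  absent <- setdiff(signature, rownames(expr))
  if (length(absent))
    warning(length(absent), " of ", length(signature),
            " signature features absent: ", paste(absent, collapse = ", "))
  if (length(present) < 2L)
    stop("need >= 2 signature features present", call. = FALSE)
  if (ncol(expr) < 4L) stop("need >= 4 samples", call. = FALSE)
  sub <- t(expr[present, , drop = FALSE])
  if (all(apply(sub, 2, stats::sd) == 0))
    stop("all signature features constant", call. = FALSE)
  lab <- hcluster_cut(sub, distance = "pearson", linkage = "complete", k = k)
  sizes <- sort(table(lab), decreasing = TRUE)
  relabel <- stats::setNames(seq_along(sizes), names(sizes))
  groups <- stats::setNames(unname(relabel[as.character(lab)]), names(lab))
  list(groups = groups, present = present, absent = absent)
}

#' Kaplan-Meier estimate per group
#'
#' Product-limit estimator with Greenwood variance and log-scale confidence
#' bands, one step function per group.
#'
#' @param surv a [survival_table()] data frame.
#' @param group column name holding the group label, default `"group"`.
#' @param conf_level confidence level, default 0.95.
#' @return data frame of step tables: `group`, `time`, `n_risk`, `n_event`,
#'   `surv`, `lower`, `upper`.
#' @export
km_estimate <- function(surv, group = "group", conf_level = 0.95) {
  stopifnot(inherits(surv, "survival_table"))
  if (sum(surv$event) < 1L) stop("need >= 1 event", call. = FALSE)
  g <- factor(surv[[group]])
  fit <- survival::survfit(survival::Surv(time, event) ~ g, data = surv,
                           conf.type = "log", conf.int = conf_level)
  s <- summary(fit, censored = TRUE)
  grp <- if (is.null(s$strata)) rep(levels(g)[1], length(s$time))
  else sub("^g=", "", as.character(s$strata))
  data.frame(group = grp, time = s$time, n_risk = s$n.risk,
             n_event = s$n.event, surv = s$surv,
             lower = s$lower, upper = s$upper, stringsAsFactors = FALSE)
}

#' Log-rank test, optionally stratified
#'
#' Observed-minus-expected log-rank comparison of the survival curves across
#' groups; with strata, per-stratum O-E contributions and variances are
#' summed before forming the chi-squared statistic.
#'
#' @param surv a [survival_table()].
#' @param group column with the group label.
#' @param strata optional column with the stratum.
#' @return list with `chisq`, `df`, `p`.
#' @export
logrank_test <- function(surv, group = "group", strata = NULL) {
  stopifnot(inherits(surv, "survival_table"))
  g <- factor(surv[[group]])
  if (nlevels(g) < 2L) stop("need >= 2 groups", call. = FALSE)
  d <- data.frame(time = surv$time, event = surv$event, g = g)
  if (!is.null(strata)) {
    d$s <- factor(surv[[strata]])
    fit <- survival::survdiff(survival::Surv(time, event) ~ g +
                                survival::strata(s), data = d)
  } else {
    fit <- survival::survdiff(survival::Surv(time, event) ~ g, data = d)
  }
  df <- length(fit$n) - 1L
  list(chisq = unname(fit$chisq), df = df,
       p = stats::pchisq(fit$chisq, df, lower.tail = FALSE))
}

#' Cox proportional-hazards ratio for a group variable
#'
#' Partial-likelihood fit (Efron tie handling) of the group effect, adjusted
#' for optional covariates and/or stratified; reports the hazard ratio for
#' the group variable with a Wald confidence interval.
#'
#' @param surv a [survival_table()].
#' @param group column with the (binary or factor) group variable; the HR
#'   reported is for the second level vs the first.
#' @param covariates character vector of covariate column names.
#' @param strata optional stratum column.
#' @param conf_level confidence level, default 0.95.
#' @return list with `hr`, `ci` (length 2), `p`, `coef`, `fit`.
#' @export
cox_hr <- function(surv, group = "group", covariates = character(),
                   strata = NULL, conf_level = 0.95) {
  stopifnot(inherits(surv, "survival_table"))
  d <- as.data.frame(surv)
  d$.group <- factor(d[[group]])
  for (cv in covariates)
    if (length(unique(d[[cv]])) < 2L)
      stop("covariate '", cv, "' is constant", call. = FALSE)
  rhs <- c(".group", covariates,
           if (!is.null(strata)) sprintf("survival::strata(%s)", strata))
  form <- stats::as.formula(paste("survival::Surv(time, event) ~",
                                  paste(rhs, collapse = " + ")))
  fit <- tryCatch(
    survival::coxph(form, data = d, ties = "efron"),
    warning = function(w) stop("Cox fit did not converge cleanly: ",
                               conditionMessage(w), call. = FALSE))
  co <- summary(fit, conf.int = conf_level)
  idx <- grep("^\\.group", rownames(co$coefficients))[1]
  list(hr = unname(co$coefficients[idx, "exp(coef)"]),
       ci = unname(co$conf.int[idx, c(3, 4)]),
       p = unname(co$coefficients[idx, "Pr(>|z|)"]),
       coef = unname(co$coefficients[idx, "coef"]),
       fit = fit)
}
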