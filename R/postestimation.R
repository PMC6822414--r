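#' Willingness to accept with delta-method standard errors
#'
#' Marginal willingness to accept (WTA) for each non-cost attribute:
#' `WTA_k = -beta_k / beta_cost`, compensation in the cost attribute's units
#' (shillings per individual per year) per unit increase in the attribute's
#' code. Standard errors use the delta method with gradient
#' `(-1/beta_cost, beta_k/beta_cost^2)` applied to the relevant 2x2 block of
#' the robust (clustered) covariance, matching how robust standard errors
#' are reported alongside the coefficients.
#'
#' @param res an `mnl_fit`.
#' @param attrs the `dce_attributes` object the model was fitted under.
#' @param cost_attribute name of the monetary attribute; defaults to the
#'   set's `cost = yes` attribute.
#' @param include_optout also report a WTA for the opt-out ASC? Default
#'   FALSE: the ASC is not an attribute.
#' @return data frame with rows per attribute: `wta`, `se`.
#' @export
wta <- function(res, attrs, cost_attribute = NULL, include_optout = FALSE) {
  stopifnot(inherits(res, "mnl_fit"), inherits(attrs, "dce_attributes"))
  if (is.null(cost_attribute)) {
    ic <- vapply(attrs$attributes, `[[`, TRUE, "cost")
    if (!any(ic)) stop("attribute set has no cost attribute", call. = FALSE)
    cost_attribute <- names(attrs$attributes)[ic][1L]
  }
  b <- res$beta_hat
  V <- res$cov_robust
  if (!(cost_attribute %in% names(b)))
    stop("cost attribute '", cost_attribute, "' not in the fitted model",
         call. = FALSE)
  bc <- b[[cost_attribute]]
  if (!is.finite(bc) || abs(bc) < 1e-12)
    stop("cost coefficient is numerically zero; WTA undefined", call. = FALSE)
  targets <- setdiff(names(b), cost_attribute)
  if (!include_optout) targets <- setdiff(targets, "optout")
  est <- se <- numeric(length(targets))
  for (i in seq_along(targets)) {
    k <- targets[i]
    est[i] <- -b[[k]] / bc
    g <- c(-1 / bc, b[[k]] / bc^2)
    block <- V[c(k, cost_attribute), c(k, cost_attribute)]
    se[i] <- sqrt(drop(t(g) %*% block %*% g))
  }
  data.frame(attribute = targets, wta = est, se = se, row.names = targets)
}

#' Attribute relative-importance scores
#'
#' For each attribute the maximum utility effect is the absolute coefficient
#' times the attribute's level-code range (`|beta_k| * (max - min)`); the
#' relative importance is each maximum effect's share of the total. The
#' opt-out ASC is excluded -- it is not an attribute.
#'
#' @param beta named coefficient vector covering the set's attributes (extra
#'   entries such as the ASC are ignored). Linear coding only.
#' @param attrs the `dce_attributes` object.
#' @return data frame with `max_effect` and `share` per attribute; shares
#'   sum to 1.
#' @export
relative_importance <- function(beta, attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  nms <- names(attrs$attributes)
  if (any(vapply(attrs$attributes, `[[`, "", "coding") != "linear"))
    stop("relative importance is defined for linear-coded attributes",
         call. = FALSE)
  miss <- setdiff(nms, names(beta))
  if (length(miss))
    stop("beta missing coefficients: ", paste(miss, collapse = ", "),
         call. = FALSE)
  rng <- attribute_ranges(attrs)
  eff <- abs(as.numeric(beta[nms])) * rng
  tot <- sum(eff)
  if (tot <= 0)
    stop("all coefficients zero; importance shares undefined", call. = FALSE)
  data.frame(attribute = nms, max_effect = eff, share = eff / tot,
             row.names = nms)
}

#' Combined post-estimation report
#'
#' Coefficients with robust standard errors and significance stars, WTA with
#' delta-method standard errors, and relative-importance shares in one table.
#'
#' @inheritParams wta
#' @return an object of class `dce_report` (a data frame with a print
#'   method).
#' @export
post_estimates <- function(res, attrs, cost_attribute = NULL) {
  w <- wta(res, attrs, cost_attribute)
  ri <- relative_importance(res$beta_hat, attrs)
  se <- sqrt(diag(res$cov_robust))
  p <- 2 * stats::pnorm(-abs(res$beta_hat / se))
  out <- data.frame(
    parameter = names(res$beta_hat),
    coefficient = as.numeric(res$beta_hat),
    robust_se = as.numeric(se),
    sig = sig_stars(p),
    wta = NA_real_, wta_se = NA_real_,
    max_effect = NA_real_, importance = NA_real_,
    row.names = names(res$beta_hat))
  out[rownames(w), c("wta", "wta_se")] <- w[, c("wta", "se")]
  out[rownames(ri), c("max_effect", "importance")] <- ri[, c("max_effect", "share")]
  structure(out, class = c("dce_report", "data.frame"))
}

#' @export
print.dce_report <- function(x, ...) {
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "", sprintf("%.4f", v)))
  print(df, right = FALSE)
  invisible(x)
}
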