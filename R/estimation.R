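# Internal: sort a choice_data frame and build the index structures the
# likelihood code needs. Groups (choice observations) are (respondent, task);
# rows within a group are alternatives.
mnl_index <- function(data, include_optout = TRUE) {
  stopifnot(inherits(data, "choice_data"))
  params <- attr(data, "params")
  df <- as.data.frame(data)
  df <- df[order(df$respondent_id, df$task_id, df$alt_id), , drop = FALSE]
  dropped <- 0L
  if (!include_optout) {
    grp <- paste(df$respondent_id, df$task_id)
    oo_chosen <- unique(grp[df$is_optout == 1L & df$chosen == 1L])
    dropped <- length(oo_chosen)
    df <- df[!(grp %in% oo_chosen) & df$is_optout == 0L, , drop = FALSE]
    params <- setdiff(params, "optout")
    if (!nrow(df)) stop("no observations left after dropping opt-out choices",
                        call. = FALSE)
  }
  grp <- paste(df$respondent_id, df$task_id)
  tid <- match(grp, unique(grp))
  gsize <- tabulate(tid)
  if (any(gsize < 2L))
    stop("each choice observation needs at least 2 alternatives", call. = FALSE)
  if (any(tapply(df$chosen, tid, sum) != 1L))
    stop("each choice observation needs exactly one chosen row", call. = FALSE)
  list(X = as.matrix(df[, params, drop = FALSE]),
       tid = tid, gsize = gsize,
       chosen = df$chosen == 1L,
       resp_of_group = df$respondent_id[!duplicated(tid)],
       params = params, n_obs = max(tid),
       n_respondents = length(unique(df$respondent_id)),
       dropped_optout_tasks = dropped)
}

# Internal: log-likelihood, score, Fisher information and per-group scores of
# the MNL at beta. The information X'(diag(p)-pp')X does not involve the
# outcome, so Newton steps use the exact Hessian.
mnl_parts <- function(beta, idx, want = c("ll", "grad", "info", "scores")) {
  X <- idx$X; tid <- idx$tid
  u <- drop(X %*% beta)
  m <- stats::ave(u, tid, FUN = max)
  e <- exp(u - m)
  denom <- rowsum(e, tid)                       # G x 1, group order 1..G
  p <- e / denom[tid, 1L]
  out <- list(ll = sum(log(p[idx$chosen])))
  if (any(c("grad", "info", "scores") %in% want)) {
    W <- rowsum(p * X, tid)                     # G x K: E[x | group]
    S <- X[idx$chosen, , drop = FALSE] - W      # per-group score
    out$grad <- colSums(S)
    out$scores <- S
    if ("info" %in% want)
      out$info <- crossprod(X * p, X) - crossprod(W)
  }
  out
}

#' MNL log-likelihood of a choice dataset
#'
#' Sum over choice observations of the log softmax probability of the chosen
#' alternative; finite for any finite `beta` and invariant to adding a
#' constant to all utilities within a task.
#'
#' @param beta coefficient vector (length K, order of the data's utility
#'   columns).
#' @param data a `choice_data` object.
#' @return scalar log-likelihood.
#' @export
mnl_loglik <- function(beta, data) {
  idx <- mnl_index(data)
  if (length(beta) != ncol(idx$X))
    stop("beta must have length ", ncol(idx$X), call. = FALSE)
  mnl_parts(as.numeric(beta), idx, want = "ll")$ll
}

#' Fit a main-effects multinomial logit
#'
#' Maximum likelihood by Newton-Raphson with the analytic score and Fisher
#' information (the MNL log-likelihood is globally concave, so the optimum is
#' start-point invariant). Reports two covariance matrices: classical
#' (inverse information) and a cluster-robust sandwich with scores summed
#' within respondent -- the defensible choice for panel data where each
#' respondent answers several tasks. No small-sample degrees-of-freedom
#' correction is applied to the sandwich.
#'
#' @param data a `choice_data` object.
#' @param include_optout keep the opt-out alternative? With `FALSE`
#'   (forced choice) opt-out rows are removed, tasks where the opt-out was
#'   chosen are dropped (count reported in the result), and the ASC is not
#'   estimated.
#' @param start starting coefficients (default zeros).
#' @param tol convergence tolerance on the score norm (default 1e-8).
#' @param cluster cluster the robust covariance by respondent (default TRUE;
#'   FALSE gives the heteroscedasticity-robust per-observation sandwich).
#' @param max_iter Newton iteration cap.
#' @return an object of class `mnl_fit`: named `beta_hat`, `cov_classical`,
#'   `cov_robust`, `ll_final`, `ll_null` (equal-shares baseline), `K`,
#'   `n_obs`, `n_respondents`, `converged`, `grad_norm`,
#'   `dropped_optout_tasks`.
#' @export
fit_mnl <- function(data, include_optout = TRUE, start = NULL, tol = 1e-8,
                    cluster = TRUE, max_iter = 500L) {
  idx <- mnl_index(data, include_optout = include_optout)
  K <- ncol(idx$X)
  # internal max-abs column scaling: the monetary column (codes in the
  # thousands of shillings) otherwise dominates the information matrix and
  # wrecks its conditioning; results are transformed back to original units
  scale_ <- apply(abs(idx$X), 2L, max)
  scale_[scale_ == 0] <- 1
  idx$X <- sweep(idx$X, 2L, scale_, `/`)
  beta <- if (is.null(start)) numeric(K) else as.numeric(start) * scale_
  if (length(beta) != K) stop("start must have length ", K, call. = FALSE)

  converged <- FALSE
  note <- NULL
  parts <- mnl_parts(beta, idx, want = c("ll", "grad", "info"))
  for (it in seq_len(max_iter)) {
    gnorm <- sqrt(sum(parts$grad^2))
    if (gnorm <= tol) { converged <- TRUE; break }
    if (rcond(parts$info) < 1e-12) {
      note <- "information matrix numerically singular (non-identified model)"
      break
    }
    step <- solve(parts$info, parts$grad)
    # step-halving safeguards the (rare) overshoot far from the optimum
    for (h in 0:30) {
      cand <- beta + step / 2^h
      cand_parts <- mnl_parts(cand, idx, want = c("ll", "grad", "info"))
      if (cand_parts$ll >= parts$ll - 1e-12) break
    }
    beta <- cand
    parts <- cand_parts
  }
  gnorm <- sqrt(sum(parts$grad^2))
  if (gnorm <= tol) converged <- TRUE

  ok_info <- rcond(parts$info) >= 1e-12
  cov_classical <- if (ok_info) solve(parts$info) else
    matrix(NA_real_, K, K)
  if (!ok_info) converged <- FALSE
  if (ok_info) {
    S <- if (cluster) rowsum(parts$scores, idx$resp_of_group) else parts$scores
    B <- crossprod(S)
    cov_robust <- cov_classical %*% B %*% cov_classical
    cov_robust <- (cov_robust + t(cov_robust)) / 2
  } else cov_robust <- cov_classical
  # back to original units: beta_j / s_j, cov_jk / (s_j s_k)
  beta <- beta / scale_
  cov_classical <- cov_classical / tcrossprod(scale_)
  cov_robust <- cov_robust / tcrossprod(scale_)
  dimnames(cov_classical) <- dimnames(cov_robust) <- list(idx$params, idx$params)

  structure(list(
    beta_hat = stats::setNames(beta, idx$params),
    cov_classical = cov_classical, cov_robust = cov_robust,
    ll_final = parts$ll,
    ll_null = sum(log(1 / idx$gsize)),
    K = K, n_obs = idx$n_obs, n_respondents = idx$n_respondents,
    converged = converged, grad_norm = gnorm, iterations = it,
    cluster = cluster, include_optout = include_optout,
    dropped_optout_tasks = idx$dropped_optout_tasks, note = note),
    class = "mnl_fit")
}

sig_stars <- function(p) {
  # the three conventional significance levels: 0.1%, 1%, 5%
  ifelse(p < 0.001, "***", ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "")))
}

#' @export
print.mnl_fit <- function(x, ...) {
  cat("Main-effects MNL", if (!x$include_optout) " (forced choice)", "\n", sep = "")
  se <- sqrt(diag(x$cov_robust))
  z <- x$beta_hat / se
  p <- 2 * stats::pnorm(-abs(z))
  tab <- data.frame(coefficient = sprintf("% .4f", x$beta_hat),
                    robust_se = sprintf("(%.4f)", se),
                    sig = sig_stars(p), row.names = names(x$beta_hat))
  print(tab)
  fs <- fit_stats(x)
  cat(sprintf("Log-likelihood (final) %.4f | null %.4f\n", x$ll_final, x$ll_null))
  cat(sprintf("AIC %.2f  BIC %.2f  adj. rho-sq %.2f\n", fs$aic, fs$bic, fs$adj_rho2))
  cat(sprintf("observations %d  decision makers %d%s\n", x$n_obs, x$n_respondents,
              if (x$dropped_optout_tasks > 0)
                sprintf("  (dropped %d opt-out tasks)", x$dropped_optout_tasks)
              else ""))
  if (!x$converged) cat("WARNING: not converged",
                        if (!is.null(x$note)) paste0(" -- ", x$note), "\n", sep = "")
  invisible(x)
}

#' Model fit statistics
#'
#' `AIC = 2K - 2 ll`, `BIC = K ln(n) - 2 ll`, and the adjusted rho-squared
#' `1 - (ll - K) / ll_baseline`. The baseline defaults to the equal-shares
#' null log-likelihood; software conventions differ (some report a
#' constants-only or starting-value baseline), so a user-supplied baseline is
#' accepted and recorded.
#'
#' @param res an `mnl_fit` (or any list with `ll_final`, `K`, `n_obs`,
#'   `ll_null`).
#' @param baseline optional baseline log-likelihood for the adjusted
#'   rho-squared.
#' @return list with `aic`, `bic`, `adj_rho2`, `baseline_used`.
#' @export
fit_stats <- function(res, baseline = NULL) {
  if (is.null(res$ll_final) || is.null(res$K) || is.null(res$n_obs))
    stop("res must carry ll_final, K and n_obs", call. = FALSE)
  if (res$n_obs <= 0) stop("n_obs must be positive", call. = FALSE)
  ll0 <- if (is.null(baseline)) res$ll_null else as.numeric(baseline)
  list(aic = 2 * res$K - 2 * res$ll_final,
       bic = res$K * log(res$n_obs) - 2 * res$ll_final,
       adj_rho2 = 1 - (res$ll_final - res$K) / ll0,
       baseline_used = if (is.null(baseline)) "equal_shares" else "user_supplied")
}

# ---------------------------------------------------------------------------
# Panel mixed logit (MMNL) by simulated maximum likelihood
# ---------------------------------------------------------------------------

# Internal: van der Corput radical-inverse sequence in the given base.
radical_inverse <- function(n, base) {
  out <- numeric(length(n))
  f <- 1 / base
  x <- n
  while (any(x > 0)) {
    out <- out + f * (x %% base)
    x <- x %/% base
    f <- f / base
  }
  out
}

#' Quasi-random normal draws (Halton sequence)
#'
#' Standard-normal draws from inverted Halton sequences, one prime base per
#' dimension, with the first `drop` points discarded (the customary burn-in
#' that removes the sequence's initial correlation).
#'
#' @param n number of draws.
#' @param dim number of dimensions.
#' @param drop points discarded at the start (default 100).
#' @return `n` x `dim` matrix of N(0,1) quasi-random deviates.
#' @export
halton_normal <- function(n, dim, drop = 100L) {
  primes <- c(2, 3, 5, 7, 11, 13, 17, 19, 23, 29, 31, 37, 41, 43, 47)
  if (dim > length(primes))
    stop("halton_normal supports up to ", length(primes), " dimensions",
         call. = FALSE)
  idx <- seq_len(n) + drop
  u <- vapply(primes[seq_len(dim)], function(b) radical_inverse(idx, b),
              numeric(n))
  stats::qnorm(matrix(u, nrow = n))
}

# Internal: structures for the simulated likelihood. Requires a complete
# panel: equal group size J so utilities reshape to a J x G matrix.
mmnl_index <- function(data, random_coefs, n_draws, draw_type, seed) {
  idx <- mnl_index(data, include_optout = TRUE)
  J <- unique(idx$gsize)
  if (length(J) != 1L)
    stop("mixed logit requires a complete panel (equal alternatives per task)",
         call. = FALSE)
  ridx <- match(idx$params, idx$params)  # identity; kept for clarity
  rpos <- match(random_coefs, idx$params)
  if (anyNA(rpos))
    stop("unknown random coefficient: ",
         paste(random_coefs[is.na(rpos)], collapse = ", "), call. = FALSE)
  R <- length(rpos)
  n_resp <- idx$n_respondents
  draw_type <- match.arg(draw_type, c("halton", "pseudorandom"))
  if (n_draws < 1L) stop("n_draws must be >= 1", call. = FALSE)
  if (draw_type == "halton") {
    # contiguous blocks of the sequence per respondent: interleaving would
    # hand each respondent a strided (badly clustered) subsequence
    z <- halton_normal(n_resp * n_draws, R)
  } else {
    set.seed(as.integer(seed))
    z <- matrix(stats::rnorm(n_resp * n_draws * R), ncol = R)
  }
  # z[(r-1)*n_draws + d, ] is respondent r's draw d
  scale_ <- apply(abs(idx$X), 2L, max)
  scale_[scale_ == 0] <- 1
  idx$X <- sweep(idx$X, 2L, scale_, `/`)
  resp_code <- match(idx$resp_of_group, unique(idx$resp_of_group))
  c(idx, list(J = J, rpos = rpos, z = z, n_draws = n_draws,
              scale_ = scale_,
              resp_code_of_group = resp_code,
              resp_code_of_row = resp_code[idx$tid]))
}

# Internal: simulated log-likelihood at (means, sds); per respondent the log
# of the average over draws of the product over tasks of MNL probabilities.
mmnl_simll <- function(means, sds, mx) {
  X <- mx$X; J <- mx$J
  G <- mx$n_obs; n_resp <- mx$n_respondents
  base_u <- drop(X %*% means)
  Xr <- X[, mx$rpos, drop = FALSE]
  L <- matrix(0, n_resp, mx$n_draws)          # per-respondent panel log-lik
  for (d in seq_len(mx$n_draws)) {
    zd <- mx$z[(seq_len(n_resp) - 1L) * mx$n_draws + d, , drop = FALSE]
    u <- base_u + drop((Xr * zd[mx$resp_code_of_row, , drop = FALSE]) %*% abs(sds))
    um <- matrix(u, nrow = J)                 # rows = alternatives, cols = groups
    m <- um[1L, ]
    for (j in seq_len(J)[-1L]) m <- pmax(m, um[j, ])
    denom <- colSums(exp(sweep(um, 2L, m)))
    logp <- u[mx$chosen] - (m + log(denom))   # one entry per group
    L[, d] <- rowsum(logp, mx$resp_code_of_group)[, 1L]
  }
  mr <- apply(L, 1L, max)
  sum(mr + log(rowMeans(exp(L - mr))))
}

#' Simulated panel mixed-logit log-likelihood
#'
#' Evaluates the simulated log-likelihood at given coefficient means and
#' standard deviations without fitting. When all `sds` are zero every draw
#' coincides and the value equals [mnl_loglik()] at `means` exactly.
#'
#' @param data a `choice_data` object (complete panel).
#' @param means length-K coefficient means.
#' @param sds named vector of standard deviations for the random
#'   coefficients (names must match utility columns); coefficients not named
#'   are fixed.
#' @param n_draws draws per respondent (default 500).
#' @param draw_type `"halton"` (default) or `"pseudorandom"`.
#' @param seed RNG seed (pseudorandom draws only).
#' @return scalar simulated log-likelihood.
#' @export
mmnl_loglik <- function(data, means, sds, n_draws = 500L,
                        draw_type = "halton", seed = 1L) {
  mx <- mmnl_index(data, names(sds), n_draws, draw_type, seed)
  if (length(means) != ncol(mx$X))
    stop("means must have length ", ncol(mx$X), call. = FALSE)
  mmnl_simll(as.numeric(means) * mx$scale_,
             as.numeric(sds) * mx$scale_[mx$rpos], mx)
}

#' Fit a panel mixed multinomial logit
#'
#' Simulated maximum likelihood: each respondent's likelihood contribution is
#' the average over draws of the product over their tasks of MNL
#' probabilities at the drawn coefficients (normal heterogeneity), which
#' relaxes the independence-of-irrelevant-alternatives property of the plain
#' MNL. Halton draws by default; deterministic given `seed` and the draw
#' settings. Standard errors come from the numerical Hessian of the
#' simulated log-likelihood.
#'
#' @param data a `choice_data` object (complete panel).
#' @param random_coefs names of the coefficients given normal heterogeneity;
#'   defaults to all non-ASC utility columns.
#' @param n_draws draws per respondent (default 500 Halton).
#' @param draw_type `"halton"` or `"pseudorandom"`.
#' @param seed seed for pseudorandom draws.
#' @param start optional start values `c(means, sds)`; defaults to the MNL
#'   estimates with small positive sds.
#' @param max_iter BFGS iteration cap.
#' @return an object of class `mmnl_fit`: `means`, `sds` (reported
#'   non-negative), `se_means`, `se_sds`, `sim_ll`, `n_draws`, `draw_type`,
#'   `seed`, `converged`.
#' @export
fit_mmnl <- function(data, random_coefs = NULL, n_draws = 500L,
                     draw_type = "halton", seed = 1L, start = NULL,
                     max_iter = 300L) {
  idx0 <- mnl_index(data)
  if (is.null(random_coefs)) random_coefs <- setdiff(idx0$params, "optout")
  mx <- mmnl_index(data, random_coefs, n_draws, draw_type, seed)
  K <- ncol(mx$X); R <- length(mx$rpos)
  if (is.null(start)) {
    mnl <- fit_mnl(data)
    start <- c(mnl$beta_hat, 0.1 / mx$scale_[mx$rpos])
  }
  stopifnot(length(start) == K + R)
  # optimize in scaled units (see fit_mnl); transform back afterwards
  sc <- c(mx$scale_, mx$scale_[mx$rpos])
  neg <- function(theta) -mmnl_simll(theta[seq_len(K)], theta[K + seq_len(R)], mx)
  opt <- stats::optim(as.numeric(start) * sc, neg, method = "BFGS",
                      hessian = TRUE,
                      control = list(maxit = max_iter, reltol = 1e-10))
  se <- rep(NA_real_, K + R)
  if (rcond(opt$hessian) > 1e-12) se <- sqrt(pmax(diag(solve(opt$hessian)), 0))
  par <- opt$par / sc
  se <- se / sc
  structure(list(
    means = stats::setNames(par[seq_len(K)], mx$params),
    sds = stats::setNames(abs(par[K + seq_len(R)]), random_coefs),
    se_means = stats::setNames(se[seq_len(K)], mx$params),
    se_sds = stats::setNames(se[K + seq_len(R)], random_coefs),
    sim_ll = -opt$value, n_draws = n_draws, draw_type = draw_type,
    seed = seed, converged = opt$convergence == 0L,
    n_obs = mx$n_obs, n_respondents = mx$n_respondents,
    K = K + R), class = "mmnl_fit")
}

#' @export
print.mmnl_fit <- function(x, ...) {
  cat("Panel mixed logit (", x$draw_type, ", ", x$n_draws, " draws)\n", sep = "")
  tab <- data.frame(mean = sprintf("% .4f", x$means),
                    se = sprintf("(%.4f)", x$se_means),
                    row.names = names(x$means))
  tab$sd <- ""
  tab$sd_se <- ""
  ri <- match(names(x$sds), names(x$means))
  tab$sd[ri] <- sprintf("%.4f", x$sds)
  tab$sd_se[ri] <- sprintf("(%.4f)", x$se_sds)
  print(tab)
  cat(sprintf("Simulated log-likelihood %.4f  (obs %d, respondents %d)\n",
              x$sim_ll, x$n_obs, x$n_respondents))
  if (!x$converged) cat("WARNING: not converged\n")
  invisible(x)
}
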