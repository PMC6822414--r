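#' Analytic MNL choice probabilities of a design
#'
#' Softmax probabilities `p_j = exp(x_j'b) / sum_m exp(x_m'b)` per task,
#' computed with a max-utility shift so the result is invariant to adding a
#' constant to all utilities within a task.
#'
#' @param design a `dce_design`.
#' @param beta coefficient vector of length K (original units).
#' @return list of probability vectors, one per task; each sums to 1.
#' @export
analytic_choice_probabilities <- function(design, beta) {
  stopifnot(inherits(design, "dce_design"))
  K <- n_params(design$attrs)
  beta <- as.numeric(beta)
  if (length(beta) != K)
    stop("beta must have length K = ", K, call. = FALSE)
  lapply(design_matrices(design), function(X) {
    u <- drop(X %*% beta)
    p <- exp(u - max(u))
    p / sum(p)
  })
}

#' Simulate random-utility choices and rankings
#'
#' The synthetic-data generator. Each respondent faces every task of the
#' design; utilities are `U = X beta_true + eps` with independent standard
#' Gumbel noise drawn as `-log(-log(u))`, `u ~ U(0,1)`. The chosen
#' alternative is the utility argmax, so first choices follow the MNL model
#' exactly; the full ranking by descending utility is exploded-logit
#' consistent. With 31 respondents and 8 tasks this emulates the pilot: 248
#' choice observations over 744 alternative rows.
#'
#' Optionally a normal random-coefficient layer (`random_sds`) draws each
#' respondent's coefficient vector as `beta_true + sds * z`, generating
#' panel-mixed-logit data for recovery tests. The pure MNL process uses no
#' respondent effect.
#'
#' @param design a `dce_design`.
#' @param beta_true length-K true coefficient vector.
#' @param n_respondents number of simulated respondents (pilot: 31).
#' @param seed integer RNG seed; identical inputs give identical datasets.
#' @param ranks emit a full best-to-worst ranking column? (default TRUE).
#' @param random_sds optional length-K vector of normal standard deviations
#'   for respondent-level coefficient heterogeneity (0 = fixed).
#' @return a `choice_data` data frame in long format: `respondent_id`,
#'   `task_id`, `alt_id`, `is_optout`, `chosen`, `rank`, plus the K encoded
#'   utility columns named by [param_names()].
#' @export
simulate_choices <- function(design, beta_true, n_respondents, seed = 1L,
                             ranks = TRUE, random_sds = NULL) {
  stopifnot(inherits(design, "dce_design"), n_respondents >= 1L)
  attrs <- design$attrs
  K <- n_params(attrs)
  beta_true <- as.numeric(beta_true)
  if (length(beta_true) != K)
    stop("beta_true must have length K = ", K, call. = FALSE)
  if (!is.null(random_sds)) {
    random_sds <- as.numeric(random_sds)
    if (length(random_sds) != K || any(random_sds < 0))
      stop("random_sds must be K non-negative numbers", call. = FALSE)
  }
  Xs <- design_matrices(design)
  Xall <- do.call(rbind, Xs)                       # (n_tasks*J) x K
  J <- n_alternatives(design)
  S <- length(Xs)
  task_id <- rep(seq_len(S), each = J)
  alt_id <- rep(seq_len(J), times = S)
  is_oo <- if (design$optout) as.integer(alt_id == J) else 0L

  set.seed(as.integer(seed))
  out <- vector("list", n_respondents)
  for (r in seq_len(n_respondents)) {
    b <- beta_true
    if (!is.null(random_sds)) b <- b + random_sds * stats::rnorm(K)
    eps <- -log(-log(stats::runif(S * J)))
    u <- drop(Xall %*% b) + eps
    rk <- unlist(lapply(split(u, task_id), function(x)
      rank(-x, ties.method = "first")), use.names = FALSE)
    out[[r]] <- data.frame(
      respondent_id = r, task_id = task_id, alt_id = alt_id,
      is_optout = is_oo, chosen = as.integer(rk == 1L),
      rank = if (ranks) rk else NA_integer_)
  }
  df <- do.call(rbind, out)
  df <- cbind(df, as.data.frame(Xall[rep(seq_len(nrow(Xall)), n_respondents), ,
                                     drop = FALSE], row.names = NULL))
  rownames(df) <- NULL
  as_choice_data(df, param_names(attrs))
}

#' Validate and class a long-format choice dataset
#'
#' Enforces the dataset invariants: exactly one `chosen = 1` per
#' (respondent, task); when ranks are present they are a permutation of
#' `1..J` within each task and rank 1 coincides with the chosen row.
#'
#' @param df a data frame with columns `respondent_id`, `task_id`, `alt_id`,
#'   `is_optout`, `chosen`, optionally `rank`, plus utility columns.
#' @param params character vector naming the utility columns, in order.
#' @return `df` with class `choice_data` and attribute `params`.
#' @export
as_choice_data <- function(df, params) {
  need <- c("respondent_id", "task_id", "alt_id", "is_optout", "chosen")
  miss <- setdiff(c(need, params), names(df))
  if (length(miss))
    stop("choice data missing columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!nrow(df)) stop("choice data has no rows", call. = FALSE)
  key <- paste(df$respondent_id, df$task_id, df$alt_id)
  if (anyDuplicated(key)) {
    dup <- key[duplicated(key)][1L]
    stop("duplicate (respondent, task, alt) key: ", dup, call. = FALSE)
  }
  grp <- paste(df$respondent_id, df$task_id)
  nchosen <- tapply(df$chosen, grp, sum)
  bad <- names(nchosen)[nchosen != 1L]
  if (length(bad))
    stop("each (respondent, task) needs exactly one chosen row; violated at: ",
         paste(utils::head(bad, 3L), collapse = "; "), call. = FALSE)
  if ("rank" %in% names(df) && !anyNA(df$rank)) {
    ok <- tapply(seq_len(nrow(df)), grp, function(i) {
      r <- df$rank[i]
      setequal(r, seq_along(i)) && df$chosen[i][r == 1L] == 1L
    })
    if (!all(ok))
      stop("ranks must be a 1..J permutation per task with rank 1 chosen; ",
           "violated at: ", names(ok)[!ok][1L], call. = FALSE)
  }
  structure(df, params = params, class = c("choice_data", "data.frame"))
}

#' @export
print.choice_data <- function(x, ...) {
  cat("Choice data: ", length(unique(x$respondent_id)), " respondents, ",
      length(unique(paste(x$respondent_id, x$task_id))), " choice observations, ",
      nrow(x), " rows\n", sep = "")
  NextMethod()
}
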