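#' Full-factorial candidate profile set
#'
#' Enumerates every combination of level indices across the attributes of a
#' set (the full factorial); rows are candidate non-opt-out profiles.
#' @param attrs a `dce_attributes` object.
#' @return integer matrix, one column per attribute, one row per profile.
#' @export
full_candidate_set <- function(attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  grid <- expand.grid(lapply(attrs$attributes, function(a) seq_along(a$codes)),
                      KEEP.OUT.ATTRS = FALSE)
  m <- as.matrix(grid)
  storage.mode(m) <- "integer"
  rownames(m) <- NULL
  m
}

new_dce_design <- function(tasks, attrs, optout) {
  structure(list(tasks = tasks, attrs = attrs, optout = isTRUE(optout)),
            class = "dce_design")
}

#' Construct a choice design from explicit tasks
#'
#' @param tasks list of integer matrices; each matrix holds one task's
#'   non-opt-out alternatives as rows of 1-based level indices (columns in
#'   attribute order). The opt-out, when present, is implicit and always last.
#' @param attrs the `dce_attributes` object the indices refer to.
#' @param optout append the opt-out alternative to every task? Defaults to
#'   the set's `optout_asc`.
#' @return a `dce_design` object.
#' @export
dce_design <- function(tasks, attrs, optout = attrs$optout_asc) {
  stopifnot(inherits(attrs, "dce_attributes"), is.list(tasks), length(tasks) >= 1L)
  na <- length(attrs$attributes)
  tasks <- lapply(tasks, function(t) {
    t <- as.matrix(t)
    storage.mode(t) <- "integer"
    if (ncol(t) != na)
      stop("task has ", ncol(t), " columns; expected one per attribute (",
           na, ")", call. = FALSE)
    colnames(t) <- names(attrs$attributes)
    t
  })
  nalt <- vapply(tasks, nrow, 1L)
  if (length(unique(nalt)) != 1L)
    stop("all tasks must have the same number of alternatives", call. = FALSE)
  for (s in seq_along(tasks))
    if (anyDuplicated(tasks[[s]]))
      stop("task ", s, ": duplicate non-opt-out alternatives", call. = FALSE)
  if (isTRUE(optout) && !attrs$optout_asc)
    stop("attribute set has no opt-out ASC", call. = FALSE)
  new_dce_design(tasks, attrs, optout)
}

#' @export
print.dce_design <- function(x, ...) {
  cat("DCE design: ", length(x$tasks), " tasks x ", n_alternatives(x),
      " alternatives", if (x$optout) " (last = opt-out)" else "",
      ", K = ", n_params(x$attrs), "\n", sep = "")
  invisible(x)
}

#' Alternatives per task (including the opt-out if present)
#' @param design a `dce_design`.
#' @export
n_alternatives <- function(design) {
  nrow(design$tasks[[1L]]) + as.integer(design$optout)
}

#' Encoded design matrices, one per task
#'
#' @param design a `dce_design`.
#' @param rescale_cost divide the cost attribute's codes by 1000 (shillings
#'   expressed per 1000) to condition the information matrix; coefficients on
#'   the rescaled column are per-1000 units.
#' @return list of J x K numeric matrices (opt-out row last when present).
#' @export
design_matrices <- function(design, rescale_cost = FALSE) {
  stopifnot(inherits(design, "dce_design"))
  attrs <- design$attrs
  lapply(design$tasks, function(t) {
    rows <- lapply(seq_len(nrow(t)), function(j)
      encode_alternative(attrs, t[j, ], is_optout = FALSE))
    if (design$optout)
      rows <- c(rows, list(encode_alternative(attrs, is_optout = TRUE)))
    X <- do.call(rbind, rows)
    if (rescale_cost) X <- rescale_cost_columns(X, attrs)
    X
  })
}

rescale_cost_columns <- function(X, attrs) {
  for (a in attrs$attributes) if (a$cost && a$coding == "linear")
    X[, a$name] <- X[, a$name] / 1000
  X
}

rescale_cost_beta <- function(beta, attrs) {
  # coefficient transform matching rescale_cost_columns (x/1000 <-> b*1000)
  for (a in attrs$attributes) if (a$cost && a$coding == "linear")
    beta[a$name] <- beta[a$name] * 1000
  beta
}

#' MNL Fisher information of a design at point priors
#'
#' The information that drives D-efficiency:
#' \deqn{I = \sum_s X_s' (\mathrm{diag}(p_s) - p_s p_s') X_s}
#' with `X_s` the encoded matrix of task `s` and `p_s` the MNL choice
#' probabilities at the prior coefficients.
#'
#' @param design a `dce_design`.
#' @param priors coefficient vector of length K (original units; when
#'   `rescale_cost = TRUE` the cost coefficient is transformed internally).
#' @param rescale_cost see [design_matrices()]; default TRUE for numerical
#'   conditioning of the monetary column.
#' @return symmetric positive semidefinite K x K matrix.
#' @export
mnl_information <- function(design, priors, rescale_cost = TRUE) {
  stopifnot(inherits(design, "dce_design"))
  K <- n_params(design$attrs)
  priors <- as.numeric(priors)
  if (length(priors) != K)
    stop("priors must have length K = ", K, call. = FALSE)
  names(priors) <- param_names(design$attrs)
  if (rescale_cost) priors <- rescale_cost_beta(priors, design$attrs)
  Xs <- design_matrices(design, rescale_cost = rescale_cost)
  info <- matrix(0, K, K, dimnames = list(names(priors), names(priors)))
  for (X in Xs) {
    u <- drop(X %*% priors)
    p <- exp(u - max(u))
    p <- p / sum(p)
    info <- info + crossprod(X * p, X) - tcrossprod(crossprod(X, p))
  }
  (info + t(info)) / 2
}

#' D-error of a design
#'
#' `det(I^-1)^(1/K)` at the point priors -- the criterion D-efficient design
#' software minimizes. Returns `Inf` (not an error) when the information
#' matrix is singular, i.e. the design cannot identify all K coefficients.
#'
#' @inheritParams mnl_information
#' @return positive scalar, possibly `Inf`.
#' @export
d_error <- function(design, priors, rescale_cost = TRUE) {
  info <- mnl_information(design, priors, rescale_cost = rescale_cost)
  K <- ncol(info)
  ld <- determinant(info, logarithm = TRUE)
  if (ld$sign <= 0 || !is.finite(ld$modulus)) return(Inf)
  if (rcond(info) < 1e-12) return(Inf)
  exp(-as.numeric(ld$modulus) / K)
}

#' Search for a D-efficient design by coordinate exchange
#'
#' Multi-start coordinate exchange: from a random design, sweep over every
#' (task, alternative, attribute) position trying each level and accepting
#' only strict D-error improvements; stop when a full pass makes no change or
#' `max_passes` is reached; keep the best design across starts. The opt-out
#' alternative is fixed and never exchanged. Exchanges that would duplicate
#' an alternative within its task are skipped. Deterministic given `seed`.
#'
#' @param attrs a `dce_attributes` object.
#' @param n_tasks number of choice tasks.
#' @param n_alts non-opt-out alternatives per task (default 2).
#' @param priors length-K prior coefficients; defaults to
#'   [prior_vector()] of the set.
#' @param seed integer RNG seed.
#' @param n_starts random restarts (default 5).
#' @param max_passes cap on full coordinate sweeps per start (default 25).
#' @return list with `design` (a `dce_design`), `score` (list: `d_error`,
#'   `information`, `priors`), and `trace` (accepted D-errors of the winning
#'   start, non-increasing).
#' @export
optimize_design <- function(attrs, n_tasks, n_alts = 2L,
                            priors = prior_vector(attrs),
                            seed = 1L, n_starts = 5L, max_passes = 25L) {
  stopifnot(inherits(attrs, "dce_attributes"), n_tasks >= 1L, n_alts >= 1L)
  cand <- full_candidate_set(attrs)
  if (nrow(cand) < n_alts)
    stop("infeasible: ", n_alts, " distinct alternatives requested but only ",
         nrow(cand), " profiles exist", call. = FALSE)
  priors <- as.numeric(priors)
  if (length(priors) != n_params(attrs))
    stop("priors must have length K = ", n_params(attrs), call. = FALSE)
  nlev <- vapply(attrs$attributes, function(a) length(a$codes), 1L)
  na <- length(nlev)

  set.seed(as.integer(seed))
  best <- NULL
  for (st in seq_len(n_starts)) {
    # random start: distinct profiles within each task (repair by redraw)
    tasks <- lapply(seq_len(n_tasks), function(s)
      cand[sample.int(nrow(cand), n_alts), , drop = FALSE])
    des <- dce_design(tasks, attrs)
    cur <- d_error(des, priors)
    trace <- cur
    for (pass in seq_len(max_passes)) {
      improved <- FALSE
      for (s in seq_len(n_tasks)) for (j in seq_len(n_alts)) for (a in seq_len(na)) {
        cur_lev <- des$tasks[[s]][j, a]
        for (l in seq_len(nlev[a])) {
          if (l == cur_lev) next
          cand_task <- des$tasks[[s]]
          cand_task[j, a] <- l
          if (anyDuplicated(cand_task)) next
          trial <- des
          trial$tasks[[s]] <- cand_task
          de <- d_error(trial, priors)
          if (de < cur - 1e-12) {   # strict improvement only
            des <- trial
            cur <- de
            cur_lev <- l
            trace <- c(trace, cur)
            improved <- TRUE
          }
        }
      }
      if (!improved) break
    }
    if (is.null(best) || cur < best$d_error) {
      best <- list(design = des, d_error = cur, trace = trace)
    }
  }
  info <- mnl_information(best$design, priors)
  list(design = best$design,
       score = list(d_error = best$d_error, information = info, priors = priors),
       trace = best$trace)
}

#' Design diagnostics: level balance, overlap, dominance
#'
#' @param design a `dce_design`.
#' @return list with `level_freq` (per attribute, counts of each level over
#'   all non-opt-out alternatives), `overlap` (per task, number of attributes
#'   identical across all non-opt-out alternatives) and `dominated` (per
#'   task, TRUE when one alternative is weakly better than every other on all
#'   sign-ordered attributes and strictly better on at least one).
#' @export
design_diagnostics <- function(design) {
  stopifnot(inherits(design, "dce_design"))
  attrs <- design$attrs
  nlev <- vapply(attrs$attributes, function(a) length(a$codes), 1L)
  all_rows <- do.call(rbind, design$tasks)
  level_freq <- lapply(seq_along(nlev), function(a)
    tabulate(all_rows[, a], nbins = nlev[a]))
  names(level_freq) <- names(attrs$attributes)
  overlap <- vapply(design$tasks, function(t)
    sum(apply(t, 2L, function(col) length(unique(col)) == 1L)), 1L)
  # signed desirability: higher is better given the expected sign
  sgn <- vapply(attrs$attributes, function(a)
    switch(a$sign, positive = 1, negative = -1, none = 0), 0)
  dominated <- vapply(design$tasks, function(t) {
    codes <- vapply(seq_along(attrs$attributes), function(a)
      attrs$attributes[[a]]$codes[t[, a]], numeric(nrow(t)))
    codes <- matrix(codes, nrow = nrow(t))
    val <- sweep(codes, 2L, sgn, `*`)[, sgn != 0, drop = FALSE]
    for (i in seq_len(nrow(t))) {
      others <- setdiff(seq_len(nrow(t)), i)
      dom <- all(vapply(others, function(o)
        all(val[i, ] >= val[o, ]) && any(val[i, ] > val[o, ]), TRUE))
      if (length(others) && dom) return(TRUE)
    }
    FALSE
  }, TRUE)
  list(level_freq = level_freq, overlap = overlap, dominated = dominated)
}

#' Write / read a design as CSV
#'
#' One row per task x alternative with `task_id`, `alt_id`, `is_optout`, a
#' `<attribute>_label` and a `<attribute>_code` column per attribute. A
#' `#`-prefixed header line records the attribute-set name and any seed so
#' the file is self-describing; [read_design_csv()] skips it.
#'
#' @param design a `dce_design`.
#' @param path output file.
#' @param seed optional seed recorded in the header comment.
#' @export
write_design_csv <- function(design, path, seed = NA) {
  stopifnot(inherits(design, "dce_design"))
  attrs <- design$attrs
  rows <- list()
  for (s in seq_along(design$tasks)) {
    t <- design$tasks[[s]]
    J <- nrow(t) + as.integer(design$optout)
    for (j in seq_len(J)) {
      oo <- design$optout && j == J
      r <- list(task_id = s, alt_id = j, is_optout = as.integer(oo))
      for (a in attrs$attributes) {
        i <- if (oo) NA_integer_ else t[j, a$name]
        r[[paste0(a$name, "_label")]] <- if (oo) "" else a$labels[i]
        r[[paste0(a$name, "_code")]] <- if (oo) NA_real_ else a$codes[i]
      }
      rows[[length(rows) + 1L]] <- r
    }
  }
  df <- do.call(rbind.data.frame, c(rows, stringsAsFactors = FALSE))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# capdce design; config=", attrs$name,
                    "; config_sha=", config_hash(attrs),
                    "; seed=", seed), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' @rdname write_design_csv
#' @param attrs the attribute set the file refers to.
#' @export
read_design_csv <- function(path, attrs) {
  stopifnot(inherits(attrs, "dce_attributes"))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("task_id", "alt_id", "is_optout")
  if (!all(need %in% names(df)))
    stop("design CSV missing columns: ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  tasks <- lapply(split(df, df$task_id), function(d) {
    d <- d[order(d$alt_id), , drop = FALSE]
    d <- d[d$is_optout == 0L, , drop = FALSE]
    m <- vapply(attrs$attributes, function(a) {
      idx <- match(d[[paste0(a$name, "_code")]], a$codes)
      if (anyNA(idx))
        stop("unknown code for attribute '", a$name, "' in ", path, call. = FALSE)
      idx
    }, integer(nrow(d)))
    matrix(as.integer(m), nrow = nrow(d),
           dimnames = list(NULL, names(attrs$attributes)))
  })
  optout <- any(df$is_optout == 1L)
  dce_design(unname(tasks[order(as.integer(names(tasks)))]), attrs,
             optout = optout)
}

config_hash <- function(attrs) {
  # stable content hash of the attribute set (md5 of its deparsed fields)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(unclass(attrs)[c("name", "optout_asc", "optout_prior")]), f)
  cat(vapply(attrs$attributes, function(a)
    paste(deparse(unclass(a)), collapse = ""), ""), file = f, append = TRUE)
  unname(tools::md5sum(f))
}
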