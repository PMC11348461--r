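#' Ordinary least squares fit with QSAR validation statistics
#'
#' Fits `y = b0 + X b` by least squares and reports the statistics the
#' heuristic-method (HM) stage is judged by: the coefficient of
#' determination `r2 = 1 - SSres/SStot`, the residual variance
#' `s2 = SSres/(n - k - 1)`, the F statistic, and (when `n > k + 2`) the
#' leave-one-out cross-validated `r2cv`.  Descriptors are used raw — no
#' centering or scaling — so coefficients stay comparable to descriptor
#' tables as computed.
#'
#' @param X Numeric matrix, `n x k` (named columns recommended).
#' @param y Numeric response, length `n`.
#' @param compute_r2cv Compute the leave-one-out statistic (default TRUE).
#' @return An object of class `"linear_model"`: list with `descriptors`,
#'   `coefficients` (named, length `k`), `intercept`, `r2`, `r2cv`,
#'   `f_stat`, `s2`, `n`, `k`, `fitted`, `residuals`.
#' @details A constant response is a degenerate input, not an error:
#'   `r2` is defined as 0 (with a warning) so screening pipelines do not
#'   abort.  A rank-deficient `X` is an error naming the collinear columns.
#' @export
fit_ols <- function(X, y, compute_r2cv = TRUE) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  n <- nrow(X); k <- ncol(X)
  if (length(y) != n) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (n <= k + 1L) {
    stop("need n > k + 1 observations (n = ", n, ", k = ", k, ")",
         call. = FALSE)
  }
  Xd <- cbind(`(Intercept)` = 1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    dropped <- colnames(Xd)[qr_x$pivot[seq.int(qr_x$rank + 1L, ncol(Xd))]]
    stop("design matrix is rank deficient; collinear column(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }
  coefs <- qr.coef(qr_x, y)
  fitted <- drop(Xd %*% coefs)
  resid <- y - fitted
  ss_res <- sum(resid^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: r2 defined as 0")
    r2 <- 0
  } else {
    r2 <- 1 - ss_res / ss_tot
  }
  s2 <- ss_res / (n - k - 1L)
  f_stat <- if (1 - r2 < 1e-12) Inf else f_statistic(r2, k = k, n = n)
  model <- structure(
    list(descriptors = colnames(X),
         coefficients = coefs[-1L],
         intercept = unname(coefs[1L]),
         r2 = r2, r2cv = NA_real_, f_stat = f_stat, s2 = s2,
         n = n, k = k, fitted = fitted, residuals = resid),
    class = "linear_model"
  )
  if (compute_r2cv && n > k + 2L) {
    model$r2cv <- loo_r2cv(X, y)
  }
  model
}

#' @export
print.linear_model <- function(x, ...) {
  cat("<linear_model> k = ", x$k, ", n = ", x$n, "\n", sep = "")
  cat("  descriptors:", paste(x$descriptors, collapse = ", "), "\n")
  cat(sprintf("  r2 = %.4f  r2cv = %.4f  F = %.3f  s2 = %.5f\n",
              x$r2, x$r2cv, x$f_stat, x$s2))
  invisible(x)
}

#' @export
predict.linear_model <- function(object, newdata, ...) {
  X <- if (inherits(newdata, "descriptor_table")) {
    missing <- setdiff(object$descriptors, newdata$descriptor_names)
    if (length(missing)) {
      stop("descriptor(s) absent from table: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    newdata$values[, object$descriptors, drop = FALSE]
  } else {
    as.matrix(newdata)[, object$descriptors, drop = FALSE]
  }
  drop(X %*% object$coefficients) + object$intercept
}

#' Leave-one-out cross-validated R2
#'
#' Computes `r2cv = 1 - PRESS/SStot`, where PRESS is the sum of squared
#' prediction errors with each observation predicted by the model fitted to
#' the other `n - 1`.  Uses the exact hat-matrix identity
#' `e_(i) = e_i / (1 - h_ii)`, so the cost is a single fit.
#'
#' @inheritParams fit_ols
#' @return The `r2cv` value (at most 1; can be negative for poor models).
#' @export
loo_r2cv <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X); k <- ncol(X)
  if (n <= k + 2L) stop("need n > k + 2 for leave-one-out", call. = FALSE)
  Xd <- cbind(1, X)
  qr_x <- qr(Xd)
  if (qr_x$rank < ncol(Xd)) {
    stop("design matrix is rank deficient", call. = FALSE)
  }
  Q1 <- qr.Q(qr_x)
  h <- rowSums(Q1^2)
  if (any(h > 1 - 1e-10)) {
    stop("leave-one-out refit singular after deleting row(s): ",
         paste(which(h > 1 - 1e-10), collapse = ", "), call. = FALSE)
  }
  resid <- y - drop(Xd %*% qr.coef(qr_x, y))
  press <- sum((resid / (1 - h))^2)
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) {
    warning("constant response: r2cv defined as 0")
    return(0)
  }
  1 - press / ss_tot
}

#' F statistic of a linear model
#'
#' `F = (r2/k) / ((1 - r2)/(n - k - 1))` — the usual ANOVA F for the
#' regression against the intercept-only model, written in terms of `r2`.
#'
#' @param object A `"linear_model"`, or a bare `r2` value (then supply
#'   `k` and `n`).
#' @param k Number of descriptors (when `object` is numeric).
#' @param n Sample size (when `object` is numeric).
#' @return The F value; `r2 = 0` gives 0.  A (numerically) perfect fit is
#'   signalled as an error rather than returning a number.
#' @export
f_statistic <- function(object, k = NULL, n = NULL) {
  if (inherits(object, "linear_model")) {
    r2 <- object$r2; k <- object$k; n <- object$n
  } else {
    r2 <- object
    if (is.null(k) || is.null(n)) {
      stop("supply `k` and `n` with a bare r2 value", call. = FALSE)
    }
  }
  if (r2 < 0 || r2 > 1) stop("`r2` must lie in [0, 1]", call. = FALSE)
  if (1 - r2 < 1e-12) {
    stop("perfect fit (r2 = 1): F statistic undefined", call. = FALSE)
  }
  (r2 / k) / ((1 - r2) / (n - k - 1))
}

#' Greedy forward selection of descriptors
#'
#' The HM model-building stage: starting from the empty model, repeatedly
#' add the descriptor that maximises the refitted model's `r2`
#' (equivalently, minimises the residual sum of squares), recording the
#' fitted model at every size up to `k_max`.  Ties are broken by
#' descriptor-name order; candidate additions that make the design matrix
#' singular are skipped.  The trace supports plots of `r2`, `r2cv` and `s2`
#' against descriptor count.
#'
#' @param table A (screened) [descriptor_table()].
#' @param k_max Largest model size to trace; capped at `floor(n/3) - 1`
#'   (the sample-size rule `n >= 3(k+1)`) and at `p`.
#' @return An object of class `"selection_trace"`: list with `models` (one
#'   `"linear_model"` per size `1..k_reached`), `chosen_k` (`NA` until
#'   [breaking_point()] is applied), `n`.
#' @export
forward_select <- function(table, k_max = NULL) {
  stopifnot(inherits(table, "descriptor_table"))
  n <- length(table$compound_ids)
  p <- length(table$descriptor_names)
  cap <- floor(n / 3) - 1L
  if (is.null(k_max)) k_max <- cap
  k_max <- min(k_max, cap, p)
  if (k_max < 1L) stop("no admissible model size (n = ", n, ")", call. = FALSE)

  selected <- character(0)
  models <- vector("list", k_max)
  remaining <- sort(table$descriptor_names)
  y <- table$activity
  for (k in seq_len(k_max)) {
    best_ss <- Inf; best_d <- NULL; best_model <- NULL
    for (d in remaining) {  # name order => deterministic tie-break
      Xc <- table$values[, c(selected, d), drop = FALSE]
      qr_c <- qr(cbind(1, Xc))
      if (qr_c$rank < ncol(Xc) + 1L) next
      ss <- sum(qr.resid(qr_c, y)^2)
      if (ss < best_ss - 1e-12) {
        best_ss <- ss; best_d <- d
      }
    }
    if (is.null(best_d)) {
      warning("no admissible descriptor at step ", k, "; trace truncated")
      models <- models[seq_len(k - 1L)]
      break
    }
    selected <- c(selected, best_d)
    remaining <- setdiff(remaining, best_d)
    models[[k]] <- fit_ols(table$values[, selected, drop = FALSE], y)
  }
  structure(list(models = models, chosen_k = NA_integer_, n = n),
            class = "selection_trace")
}

#' @export
print.selection_trace <- function(x, ...) {
  tab <- trace_table(x)
  cat("<selection_trace> n = ", x$n, ", k up to ", nrow(tab), "\n", sep = "")
  print(tab, row.names = FALSE)
  if (!is.na(x$chosen_k)) cat("chosen k =", x$chosen_k, "\n")
  invisible(x)
}

#' Tabulate a selection trace
#'
#' @param trace A `"selection_trace"`.
#' @return `data.frame` with columns `k`, `added`, `r2`, `r2cv`, `s2`,
#'   `f_stat` — the table behind descriptor-count diagnostic plots.
#' @export
trace_table <- function(trace) {
  stopifnot(inherits(trace, "selection_trace"))
  do.call(rbind, lapply(seq_along(trace$models), function(k) {
    m <- trace$models[[k]]
    data.frame(k = k, added = m$descriptors[k], r2 = m$r2, r2cv = m$r2cv,
               s2 = m$s2, f_stat = m$f_stat, stringsAsFactors = FALSE)
  }))
}

#' Breaking-point choice of model size
#'
#' Scans a forward-selection trace for the smallest size `k` at which the
#' gain `r2(k+1) - r2(k)` falls below `tol` — the point beyond which adding
#' descriptors no longer pays ("breaking point") — and additionally caps
#' the answer so the sample-size condition `n >= 3(k+1)` holds.  If every
#' gain is at least `tol`, the largest traced size under the cap is
#' returned.
#'
#' @param trace A `"selection_trace"` (or a bare numeric `r2` sequence).
#' @param tol Minimum worthwhile `r2` gain; default 0.02.
#' @param n Sample size (taken from the trace when omitted).
#' @return The chosen `k` (integer).
#' @export
breaking_point <- function(trace, tol = 0.02, n = NULL) {
  if (inherits(trace, "selection_trace")) {
    r2 <- vapply(trace$models, `[[`, numeric(1), "r2")
    if (is.null(n)) n <- trace$n
  } else {
    r2 <- as.numeric(trace)
    if (is.null(n)) stop("supply `n` with a bare r2 sequence", call. = FALSE)
  }
  if (!length(r2)) stop("empty trace", call. = FALSE)
  cap <- max(1L, floor(n / 3) - 1L)
  k_max <- min(length(r2), cap)
  chosen <- k_max
  if (k_max >= 2L) {
    gains <- diff(r2)[seq_len(k_max - 1L)]
    below <- which(gains < tol)
    if (length(below)) chosen <- below[1L]
  }
  as.integer(chosen)
}
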