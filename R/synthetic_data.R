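#' Specification of a synthetic descriptor table
#'
#' Describes a compounds-by-descriptors table with the statistical
#' structure the screening and model-building stages assume: independent
#' standard-normal base descriptors, a block of degenerate (constant or
#' all-zero) columns, a block of near-collinear pairs, and a planted
#' response — linear over a known support, or a `{+,-,*,/}` expression —
#' plus Gaussian noise.  This emulates the 39 x 551 descriptor matrix the
#' study's screening stage consumed, at configurable size.
#'
#' @param n_compounds Number of rows.
#' @param n_descriptors Number of descriptor columns (`d1..dp`).
#' @param n_degenerate Columns made degenerate (alternating all-zero and
#'   constant).
#' @param n_collinear_pairs Pairs `(x, x')` built as
#'   `x' = r x + sqrt(1 - r^2) e` with target correlation `collinear_r`.
#' @param collinear_r Target pairwise correlation; default 0.99.
#' @param response_kind `"linear"` or `"expression"`.
#' @param true_support Descriptor labels the response depends on; defaults
#'   to the first columns after the degenerate/collinear blocks.
#' @param true_coefficients Coefficients over `true_support` (linear case);
#'   defaults to `1, 2, 3, ...`.
#' @param true_expression Expression string over `true_support` using only
#'   `+ - * /` and parentheses (expression case), e.g. `"d1 + d2 * d3"`.
#' @param intercept Intercept of the linear response (default 0).
#' @param noise_sd Gaussian noise s.d. in log-activity units.
#' @param marginal `"normal"` (default) or `"lognormal"` descriptor
#'   marginals.
#' @param seed Integer seed.
#' @return An object of class `"synthetic_spec"`.
#' @export
synthetic_spec <- function(n_compounds, n_descriptors, n_degenerate = 0L,
                           n_collinear_pairs = 0L, collinear_r = 0.99,
                           response_kind = c("linear", "expression"),
                           true_support = NULL, true_coefficients = NULL,
                           true_expression = NULL, intercept = 0,
                           noise_sd = 0, marginal = c("normal", "lognormal"),
                           seed = 1L) {
  response_kind <- match.arg(response_kind)
  marginal <- match.arg(marginal)
  n_compounds <- as.integer(n_compounds)
  n_descriptors <- as.integer(n_descriptors)
  n_degenerate <- as.integer(n_degenerate)
  n_collinear_pairs <- as.integer(n_collinear_pairs)
  if (noise_sd < 0) stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!(collinear_r > 0 && collinear_r < 1)) {
    stop("`collinear_r` must be in (0, 1)", call. = FALSE)
  }

  labels <- paste0("d", seq_len(n_descriptors))
  reserved <- n_degenerate + 2L * n_collinear_pairs
  if (is.null(true_support)) {
    k_default <- if (response_kind == "linear") 2L else 3L
    if (reserved + k_default > n_descriptors) {
      stop("spec leaves no room for a default support", call. = FALSE)
    }
    true_support <- labels[seq.int(reserved + 1L, reserved + k_default)]
  }
  true_support <- as.character(true_support)
  if (!all(true_support %in% labels)) {
    stop("`true_support` must name descriptors d1..d", n_descriptors,
         call. = FALSE)
  }
  if (n_degenerate + 2L * n_collinear_pairs + length(true_support) >
      n_descriptors) {
    stop("n_degenerate + 2*n_collinear_pairs + |true_support| exceeds ",
         "n_descriptors", call. = FALSE)
  }
  if (response_kind == "linear") {
    if (is.null(true_coefficients)) {
      true_coefficients <- seq_along(true_support)
    }
    if (length(true_coefficients) != length(true_support)) {
      stop("`true_coefficients` must match `true_support`", call. = FALSE)
    }
  } else {
    if (is.null(true_expression)) {
      stop("`true_expression` required for an expression response",
           call. = FALSE)
    }
    validate_expression_string(true_expression, true_support)
  }
  structure(
    list(n_compounds = n_compounds, n_descriptors = n_descriptors,
         n_degenerate = n_degenerate, n_collinear_pairs = n_collinear_pairs,
         collinear_r = collinear_r, response_kind = response_kind,
         true_support = true_support,
         true_coefficients = true_coefficients,
         true_expression = true_expression, intercept = intercept,
         noise_sd = noise_sd, marginal = marginal, seed = as.integer(seed)),
    class = "synthetic_spec"
  )
}

# Allow only arithmetic over the declared support in a planted expression.
validate_expression_string <- function(expr_string, support) {
  e <- tryCatch(parse(text = expr_string)[[1L]],
                error = function(err) stop("unparseable `true_expression`: ",
                                           conditionMessage(err), call. = FALSE))
  check <- function(node) {
    if (is.name(node)) {
      if (!as.character(node) %in% support) {
        stop("`true_expression` uses a symbol outside `true_support`: ",
             as.character(node), call. = FALSE)
      }
    } else if (is.call(node)) {
      op <- as.character(node[[1L]])
      if (!op %in% c("+", "-", "*", "/", "(")) {
        stop("`true_expression` may only use + - * / ( ): found ", op,
             call. = FALSE)
      }
      for (i in seq.int(2L, length(node))) check(node[[i]])
    } else if (!is.numeric(node)) {
      stop("unsupported token in `true_expression`", call. = FALSE)
    }
    invisible(NULL)
  }
  check(e)
  invisible(e)
}

#' Generate a synthetic descriptor table with known ground truth
#'
#' Draws the table described by a [synthetic_spec()]: i.i.d. base
#' descriptors, degenerate columns (alternating all-zero and constant
#' 3.2), collinear pairs `x' = r x + sqrt(1 - r^2) e`, and the planted
#' response plus `N(0, noise_sd^2)` noise.  Deterministic for a fixed
#' seed.
#'
#' @param spec A [synthetic_spec()].
#' @return A list with `table` (a validated [descriptor_table()]) and
#'   `truth`: the spec echo plus `noiseless_response`, `degenerate_labels`,
#'   `collinear_pairs` (data.frame of label pairs).
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  n <- spec$n_compounds
  p <- spec$n_descriptors
  labels <- paste0("d", seq_len(p))

  with_seed(spec$seed, {
    vals <- matrix(stats::rnorm(n * p), nrow = n, dimnames = list(NULL, labels))
    if (spec$marginal == "lognormal") vals <- exp(vals)

    degen <- character(0)
    if (spec$n_degenerate > 0L) {
      degen <- labels[seq_len(spec$n_degenerate)]
      for (j in seq_along(degen)) {
        vals[, degen[j]] <- if (j %% 2L == 1L) 0 else 3.2
      }
    }
    pairs <- data.frame(base = character(0), derived = character(0),
                        stringsAsFactors = FALSE)
    if (spec$n_collinear_pairs > 0L) {
      start <- spec$n_degenerate
      for (j in seq_len(spec$n_collinear_pairs)) {
        a <- labels[start + 2L * j - 1L]
        b <- labels[start + 2L * j]
        vals[, b] <- spec$collinear_r * vals[, a] +
          sqrt(1 - spec$collinear_r^2) * stats::rnorm(n)
        pairs <- rbind(pairs, data.frame(base = a, derived = b,
                                         stringsAsFactors = FALSE))
      }
    }

    noiseless <- if (spec$response_kind == "linear") {
      drop(vals[, spec$true_support, drop = FALSE] %*% spec$true_coefficients) +
        spec$intercept
    } else {
      env <- as.data.frame(vals[, spec$true_support, drop = FALSE])
      as.numeric(eval(parse(text = spec$true_expression)[[1L]], envir = env))
    }
    activity <- noiseless +
      if (spec$noise_sd > 0) stats::rnorm(n, sd = spec$noise_sd) else 0

    list(
      table = descriptor_table(vals, activity),
      truth = list(spec = spec, noiseless_response = noiseless,
                   degenerate_labels = degen, collinear_pairs = pairs)
    )
  })
}

#' Score recovery of planted structure
#'
#' Measures how well a selection or an evolved model recovered the planted
#' ground truth: support recovery (is the true support contained in the
#' selection?), coefficient error for a refitted linear model, and the
#' RMSE of evolved-model predictions against the noiseless response.
#'
#' @param truth The `truth` element of [generate_synthetic()].
#' @param selected Character vector of selected descriptors (linear case).
#' @param model A `"linear_model"` whose named coefficients are compared to
#'   the planted ones (optional).
#' @param predictions Evolved-model predictions over the generated rows
#'   (expression case, optional).
#' @return A list with `support_recovered` (logical or `NA`),
#'   `coefficient_rmse` (`NA` unless `model` given), `expression_rmse`
#'   (`NA` unless `predictions` given).
#' @export
score_recovery <- function(truth, selected = NULL, model = NULL,
                           predictions = NULL) {
  spec <- truth$spec
  out <- list(support_recovered = NA, coefficient_rmse = NA_real_,
              expression_rmse = NA_real_)
  if (!is.null(selected)) {
    out$support_recovered <- all(spec$true_support %in% selected)
  }
  if (!is.null(model)) {
    stopifnot(inherits(model, "linear_model"))
    est <- model$coefficients[spec$true_support]
    est[is.na(est)] <- 0
    out$coefficient_rmse <- sqrt(mean((est - spec$true_coefficients)^2))
  }
  if (!is.null(predictions)) {
    if (length(predictions) != length(truth$noiseless_response)) {
      stop("`predictions` length must match the generated table", call. = FALSE)
    }
    if (anyNA(predictions)) {
      out$expression_rmse <- Inf
    } else {
      out$expression_rmse <-
        sqrt(mean((predictions - truth$noiseless_response)^2))
    }
  }
  out
}
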