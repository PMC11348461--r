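#' Model-quality statistics for a prediction vector
#'
#' Computes the comparison statistics used for both the linear and evolved
#' models: `r2` as the squared Pearson correlation between predicted and
#' observed (the convention that remains meaningful for a nonlinear model,
#' where it diverges from `1 - SSres/SStot`), `mse` as the mean squared
#' residual with divisor `n`, and `rmse = sqrt(mse)`.  The OLS-internal
#' `r2` and degrees-of-freedom-corrected `s2` live on the
#' `"linear_model"` object instead; the two conventions are deliberately
#' kept apart.
#'
#' @param predicted,observed Equal-length numeric vectors without invalid
#'   markers (`NA`).
#' @return An object of class `"model_metrics"`: list with `r2`, `mse`,
#'   `rmse`, `n`, `residuals` (predicted - observed).
#' @details If either vector has zero variance the correlation is
#'   undefined: `r2` is returned as `NA` with a warning while `mse` is
#'   still computed.
#' @export
model_metrics <- function(predicted, observed) {
  if (length(predicted) != length(observed) || !length(predicted)) {
    stop("`predicted` and `observed` must have equal non-zero length",
         call. = FALSE)
  }
  if (anyNA(predicted) || anyNA(observed)) {
    stop("invalid marker (NA) among inputs at position(s): ",
         paste(which(is.na(predicted) | is.na(observed)), collapse = ", "),
         call. = FALSE)
  }
  resid <- predicted - observed
  mse <- mean(resid^2)
  if (stats::sd(predicted) == 0 || stats::sd(observed) == 0) {
    warning("zero-variance input: r2 undefined (NA)")
    r2 <- NA_real_
  } else {
    r2 <- stats::cor(predicted, observed)^2
  }
  structure(list(r2 = r2, mse = mse, rmse = sqrt(mse),
                 n = length(predicted), residuals = resid),
            class = "model_metrics")
}

#' @export
print.model_metrics <- function(x, ...) {
  cat(sprintf("<model_metrics> n = %d  r2 = %.4f  mse = %.4f  rmse = %.4f\n",
              x$n, x$r2, x$mse, x$rmse))
  invisible(x)
}

#' Signed difference between a linear-model prediction and the log target
#'
#' `predicted - log10(inhibition %)` — the quantity tabulated as the linear
#' model's per-compound "Difference", reported to 3 decimals when compared
#' against printed cells.
#'
#' @param predicted Predicted log-activity value(s).
#' @param inhibition_pct Experimental inhibition percentage(s) in
#'   `(0, 100]`.
#' @param compound_id Optional labels for error messages.
#' @return Signed residual(s) in log-activity units.
#' @export
hm_difference <- function(predicted, inhibition_pct, compound_id = NULL) {
  predicted - log_activity(inhibition_pct, compound_id = compound_id)
}

#' Compare linear and evolved model columns on a compound table
#'
#' Builds the per-compound comparison behind the train/test model contest:
#' observed log target, both model predictions, both signed residuals, plus
#' per-split [model_metrics()] for each model and a verdict of which model
#' attains the higher `r2` and the lower MSE on each split.
#'
#' @param table A `"compound_table"` (see [load_table1_fixture()]) or any
#'   data.frame with columns `compound_id`, `target_log`, `hm_predicted`,
#'   `gep_model`, `is_test`.
#' @param split Optional `"split_spec"` overriding the table's `is_test`
#'   flags.
#' @param hm_column,gep_column Names of the two prediction columns
#'   (swappable, e.g. for antisymmetry checks).
#' @return An object of class `"comparison_table"`: `rows` (per-compound
#'   data.frame), `summary` (one row per model x split with `r2`, `mse`,
#'   `rmse`, `n`), `verdict` (per split: `"gep"`, `"hm"` or `"tie"` on the
#'   joint higher-r2 / lower-mse criterion).
#' @export
compare_models <- function(table, split = NULL,
                           hm_column = "hm_predicted",
                           gep_column = "gep_model") {
  df <- as.data.frame(table)
  needed <- c("compound_id", "target_log", hm_column, gep_column)
  missing_cols <- setdiff(needed, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  is_test <- if (!is.null(split)) {
    stopifnot(inherits(split, "split_spec"))
    df$compound_id %in% split$test_ids
  } else if ("is_test" %in% names(df)) {
    df$is_test
  } else {
    stop("no split information: supply `split` or an `is_test` column",
         call. = FALSE)
  }

  rows <- data.frame(
    compound_id = df$compound_id,
    observed = df$target_log,
    hm_predicted = df[[hm_column]],
    gep_predicted = df[[gep_column]],
    hm_residual = df[[hm_column]] - df$target_log,
    gep_residual = df[[gep_column]] - df$target_log,
    split = ifelse(is_test, "test", "train"),
    stringsAsFactors = FALSE
  )

  summarise <- function(sub) {
    hm <- model_metrics(sub$hm_predicted, sub$observed)
    gep <- model_metrics(sub$gep_predicted, sub$observed)
    list(hm = hm, gep = gep)
  }
  splits <- list(train = rows[rows$split == "train", ],
                 test = rows[rows$split == "test", ])
  splits <- splits[vapply(splits, nrow, integer(1)) > 0]
  mets <- lapply(splits, summarise)

  summary_df <- do.call(rbind, lapply(names(mets), function(sp) {
    do.call(rbind, lapply(c("hm", "gep"), function(mod) {
      m <- mets[[sp]][[mod]]
      data.frame(split = sp, model = mod, r2 = m$r2, mse = m$mse,
                 rmse = m$rmse, n = m$n, stringsAsFactors = FALSE)
    }))
  }))

  verdict <- lapply(mets, function(m) {
    if (isTRUE(all.equal(m$gep$r2, m$hm$r2)) &&
        isTRUE(all.equal(m$gep$mse, m$hm$mse))) {
      "tie"
    } else if (m$gep$r2 > m$hm$r2 && m$gep$mse < m$hm$mse) {
      "gep"
    } else if (m$hm$r2 > m$gep$r2 && m$hm$mse < m$gep$mse) {
      "hm"
    } else {
      "mixed"
    }
  })

  structure(list(rows = rows, summary = summary_df, verdict = verdict,
                 metrics = mets),
            class = "comparison_table")
}

#' @export
print.comparison_table <- function(x, ...) {
  cat("<comparison_table> ", nrow(x$rows), " compounds\n", sep = "")
  print(x$summary, row.names = FALSE, digits = 4)
  for (sp in names(x$verdict)) {
    cat("  ", sp, " verdict: ", x$verdict[[sp]], "\n", sep = "")
  }
  invisible(x)
}

#' Headline statistics recomputed from the bundled table
#'
#' Recomputes, from the fixture's printed model columns, every summary
#' statistic the study reports: the evolved model's squared Pearson `r2`
#' and MSE on the 30 training and 9 test compounds (against the
#' self-consistent log targets and, separately, against the verbatim
#' printed GEP Target cells), and the linear model's `r2`, MSE and
#' residual variance `s2` (at `k = 2`) under both the 39-row and 30-row
#' conventions — which sample the study used for its linear headline is
#' unstated, so both are reported.
#'
#' @param table A `"compound_table"`; defaults to the bundled fixture.
#' @return A `data.frame` with columns `quantity`, `value`, `n`.
#' @export
headline_statistics <- function(table = load_table1_fixture()) {
  tr <- table[!table$is_test, ]
  te <- table[table$is_test, ]
  hm_k <- 2L  # breaking-point model size
  s2 <- function(pred, obs, k) sum((pred - obs)^2) / (length(obs) - k - 1L)
  m <- function(pred, obs) model_metrics(pred, obs)

  gep_tr <- m(tr$gep_model, tr$target_log)
  gep_te <- m(te$gep_model, te$target_log)
  gep_tr_p <- m(tr$gep_model, tr$gep_target_printed)
  gep_te_p <- m(te$gep_model, te$gep_target_printed)
  hm_all <- m(table$hm_predicted, table$target_log)
  hm_tr <- m(tr$hm_predicted, tr$target_log)

  data.frame(
    quantity = c("gep_train_r2", "gep_train_mse",
                 "gep_test_r2", "gep_test_mse",
                 "gep_train_r2_printed_target", "gep_train_mse_printed_target",
                 "gep_test_r2_printed_target", "gep_test_mse_printed_target",
                 "hm_r2_39", "hm_mse_39", "hm_s2_39",
                 "hm_r2_30", "hm_mse_30", "hm_s2_30"),
    value = c(gep_tr$r2, gep_tr$mse, gep_te$r2, gep_te$mse,
              gep_tr_p$r2, gep_tr_p$mse, gep_te_p$r2, gep_te_p$mse,
              hm_all$r2, hm_all$mse,
              s2(table$hm_predicted, table$target_log, hm_k),
              hm_tr$r2, hm_tr$mse,
              s2(tr$hm_predicted, tr$target_log, hm_k)),
    n = c(gep_tr$n, gep_tr$n, gep_te$n, gep_te$n,
          gep_tr_p$n, gep_tr_p$n, gep_te_p$n, gep_te_p$n,
          hm_all$n, hm_all$n, hm_all$n, hm_tr$n, hm_tr$n, hm_tr$n),
    stringsAsFactors = FALSE
  )
}
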