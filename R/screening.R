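#' Drop degenerate descriptor columns
#'
#' Removes descriptors that carry no information: columns that are entirely
#' zero or constant (zero variance).  This is the first of the three
#' pre-selection pruning rules applied before any model building.
#'
#' @param table A [descriptor_table()].
#' @return A list with elements `table` (the pruned [descriptor_table()])
#'   and `dropped_degenerate` (character vector of removed names).
#' @export
drop_degenerate <- function(table) {
  stopifnot(inherits(table, "descriptor_table"))
  v <- table$values
  rng <- apply(v, 2L, function(col) diff(range(col)))
  degenerate <- table$descriptor_names[rng == 0]
  keep <- setdiff(table$descriptor_names, degenerate)
  if (!length(keep)) {
    warning("all descriptors are degenerate; empty table returned")
  }
  list(table = subset_descriptors(table, keep),
       dropped_degenerate = degenerate)
}

#' Drop one member of each overly-correlated descriptor pair
#'
#' The second pruning rule: for every descriptor pair whose absolute Pearson
#' correlation exceeds `r_max`, the member less correlated (in absolute
#' value) with the activity is removed.  Pairs are processed in decreasing
#' `|r|`; exact ties in activity correlation are broken by descriptor-name
#' order, so the result is deterministic across platforms.
#'
#' @param table A [descriptor_table()].
#' @param r_max Correlation threshold in `(0, 1]`; default 0.95.
#' @return A list with `table` (pruned) and `dropped_intercorrelated`, a
#'   `data.frame` with columns `kept`, `dropped`, `r`.
#' @export
drop_intercorrelated <- function(table, r_max = 0.95) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!(r_max > 0 && r_max <= 1)) stop("`r_max` must be in (0, 1]", call. = FALSE)
  nm <- table$descriptor_names
  p <- length(nm)
  empty <- data.frame(kept = character(), dropped = character(),
                      r = numeric(), stringsAsFactors = FALSE)
  if (p < 2L) return(list(table = table, dropped_intercorrelated = empty))

  cmat <- suppressWarnings(stats::cor(table$values))
  cmat[!is.finite(cmat)] <- 0   # zero-variance columns correlate with nothing
  ract <- abs(activity_correlations(table))

  ut <- which(upper.tri(cmat) & abs(cmat) > r_max, arr.ind = TRUE)
  if (!nrow(ut)) return(list(table = table, dropped_intercorrelated = empty))
  rvals <- cmat[ut]
  ord <- order(-abs(rvals), nm[ut[, 1L]], nm[ut[, 2L]])
  ut <- ut[ord, , drop = FALSE]
  rvals <- rvals[ord]

  alive <- stats::setNames(rep(TRUE, p), nm)
  rec <- vector("list", nrow(ut))
  for (j in seq_len(nrow(ut))) {
    a <- nm[ut[j, 1L]]; b <- nm[ut[j, 2L]]
    if (!alive[a] || !alive[b]) next
    # keep the member more correlated with activity; name order on exact tie
    if (ract[a] > ract[b] || (ract[a] == ract[b] && a < b)) {
      keep <- a; drop <- b
    } else {
      keep <- b; drop <- a
    }
    alive[drop] <- FALSE
    rec[[j]] <- data.frame(kept = keep, dropped = drop, r = rvals[j],
                           stringsAsFactors = FALSE)
  }
  rec <- do.call(rbind, rec[!vapply(rec, is.null, logical(1))])
  if (is.null(rec)) rec <- empty
  list(table = subset_descriptors(table, nm[alive]),
       dropped_intercorrelated = rec)
}

#' Drop descriptors with negligible activity correlation
#'
#' The third pruning rule: descriptors whose absolute Pearson correlation
#' with the activity falls below `r_min` are removed.
#'
#' @param table A [descriptor_table()].
#' @param r_min Threshold in `[0, 1)`; default 0.05.
#' @return A list with `table` (pruned) and `dropped_low_relevance`, a
#'   `data.frame` with columns `descriptor`, `r_activity`.
#' @export
drop_low_relevance <- function(table, r_min = 0.05) {
  stopifnot(inherits(table, "descriptor_table"))
  if (!(r_min >= 0 && r_min < 1)) stop("`r_min` must be in [0, 1)", call. = FALSE)
  ract <- activity_correlations(table)
  low <- abs(ract) < r_min
  rep_df <- data.frame(descriptor = table$descriptor_names[low],
                       r_activity = unname(ract[low]),
                       stringsAsFactors = FALSE)
  list(table = subset_descriptors(table, table$descriptor_names[!low]),
       dropped_low_relevance = rep_df)
}

#' Screen a descriptor table with the three pruning rules
#'
#' Applies, in order: removal of degenerate (constant/zero) columns, removal
#' of one member of each pair correlated beyond `r_max`, and removal of
#' descriptors correlated with the activity below `r_min`.  The study names
#' these three rules but no cutoffs; the defaults are conventional QSAR
#' screening values and both are overridable.
#'
#' @param table A [descriptor_table()].
#' @param r_max Pairwise-correlation ceiling (rule b); default 0.95.
#' @param r_min Activity-correlation floor (rule c); default 0.05.
#' @return A list of class `"screening_report"`: `table` (the surviving
#'   [descriptor_table()]), `surviving` (names), `dropped_degenerate`,
#'   `dropped_intercorrelated`, `dropped_low_relevance`, and the thresholds
#'   used.
#' @export
screen_descriptors <- function(table, r_max = 0.95, r_min = 0.05) {
  s1 <- drop_degenerate(table)
  s2 <- drop_intercorrelated(s1$table, r_max = r_max)
  s3 <- drop_low_relevance(s2$table, r_min = r_min)
  structure(
    list(table = s3$table,
         surviving = s3$table$descriptor_names,
         dropped_degenerate = s1$dropped_degenerate,
         dropped_intercorrelated = s2$dropped_intercorrelated,
         dropped_low_relevance = s3$dropped_low_relevance,
         r_max = r_max, r_min = r_min,
         original = table$descriptor_names),
    class = "screening_report"
  )
}

#' @export
print.screening_report <- function(x, ...) {
  cat("<screening_report>\n",
      "  original descriptors : ", length(x$original), "\n",
      "  degenerate dropped   : ", length(x$dropped_degenerate), "\n",
      "  intercorrelated drop : ", nrow(x$dropped_intercorrelated),
      " (|r| > ", x$r_max, ")\n",
      "  low relevance dropped: ", nrow(x$dropped_low_relevance),
      " (|r| < ", x$r_min, ")\n",
      "  surviving            : ", length(x$surviving), "\n", sep = "")
  invisible(x)
}

#' Write a screening report as delimited text
#'
#' @param report A `"screening_report"`.
#' @param path Output file path (tab-separated).
#' @return `path`, invisibly.
#' @export
write_screening_report <- function(report, path) {
  stopifnot(inherits(report, "screening_report"))
  rows <- rbind(
    if (length(report$dropped_degenerate))
      data.frame(rule = "degenerate", descriptor = report$dropped_degenerate,
                 detail = "", stringsAsFactors = FALSE),
    if (nrow(report$dropped_intercorrelated))
      data.frame(rule = "intercorrelated",
                 descriptor = report$dropped_intercorrelated$dropped,
                 detail = sprintf("kept=%s r=%.4f",
                                  report$dropped_intercorrelated$kept,
                                  report$dropped_intercorrelated$r),
                 stringsAsFactors = FALSE),
    if (nrow(report$dropped_low_relevance))
      data.frame(rule = "low_relevance",
                 descriptor = report$dropped_low_relevance$descriptor,
                 detail = sprintf("r_activity=%.4f",
                                  report$dropped_low_relevance$r_activity),
                 stringsAsFactors = FALSE),
    data.frame(rule = "surviving", descriptor = report$surviving, detail = "",
               stringsAsFactors = FALSE)
  )
  utils::write.table(rows, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

# |r| of each descriptor with the activity; zero-variance columns get 0.
activity_correlations <- function(table) {
  r <- suppressWarnings(as.vector(stats::cor(table$values, table$activity)))
  r[!is.finite(r)] <- 0
  stats::setNames(r, table$descriptor_names)
}

# Column subset preserving the descriptor_table contract.
subset_descriptors <- function(table, keep) {
  descriptor_table(table$values[, keep, drop = FALSE], table$activity,
                   compound_ids = table$compound_ids,
                   descriptor_names = keep)
}
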