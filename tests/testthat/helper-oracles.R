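# Independent reference implementations used to cross-check the package.
# These deliberately use different algorithms from the code under test.

ops4 <- c("+", "-", "*", "/")

# OLS by explicit normal equations, (X'X)^-1 X'y.
oracle_ols <- function(X, y) {
  Xd <- cbind(1, X)
  beta <- solve(t(Xd) %*% Xd, t(Xd) %*% y)
  fitted <- drop(Xd %*% beta)
  ss_res <- sum((y - fitted)^2)
  ss_tot <- sum((y - mean(y))^2)
  list(intercept = beta[1L], coefficients = drop(beta[-1L]),
       r2 = 1 - ss_res / ss_tot,
       s2 = ss_res / (nrow(X) - ncol(X) - 1L))
}

# Leave-one-out R2cv by literally refitting n times.
oracle_loo_r2cv <- function(X, y) {
  n <- nrow(X)
  press <- sum(vapply(seq_len(n), function(i) {
    fit <- oracle_ols(X[-i, , drop = FALSE], y[-i])
    pred <- sum(c(1, X[i, ]) * c(fit$intercept, fit$coefficients))
    (y[i] - pred)^2
  }, numeric(1)))
  1 - press / sum((y - mean(y))^2)
}

# Pearson correlation straight from the covariance formula.
oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# Karva decoding by level-boundary arithmetic: compute the node count of
# each level from the arities of the previous one, then link parents to
# children recursively with per-level consumption counters.  Returns a
# nested list (op/l/r or term).
oracle_decode <- function(gene) {
  is_fun <- function(s) s %in% ops4
  levels <- list(1L)
  pos <- 1L
  repeat {
    cur <- levels[[length(levels)]]
    width <- 2L * sum(is_fun(gene[cur]))
    if (width == 0L) break
    levels[[length(levels) + 1L]] <- seq.int(pos + 1L, pos + width)
    pos <- pos + width
  }
  counters <- integer(length(levels))
  build <- function(idx, lev) {
    s <- gene[idx]
    if (!is_fun(s)) return(list(term = s))
    kids <- levels[[lev + 1L]]
    c1 <- kids[counters[lev + 1L] + 1L]
    c2 <- kids[counters[lev + 1L] + 2L]
    counters[lev + 1L] <<- counters[lev + 1L] + 2L
    list(op = s, l = build(c1, lev + 1L), r = build(c2, lev + 1L))
  }
  build(1L, 1L)
}

oracle_render <- function(node) {
  if (!is.null(node$term)) return(node$term)
  paste0("(", oracle_render(node$l), node$op, oracle_render(node$r), ")")
}

# Direct recursive single-row evaluation with the same guarded-division
# and finiteness rules.
oracle_eval <- function(node, row) {
  if (!is.null(node$term)) return(unname(row[[node$term]]))
  a <- oracle_eval(node$l, row)
  b <- oracle_eval(node$r, row)
  if (is.na(a) || is.na(b)) return(NA_real_)
  v <- switch(node$op,
              "+" = a + b, "-" = a - b, "*" = a * b,
              "/" = if (abs(b) < 1e-12) NA_real_ else a / b)
  if (!is.na(v) && !is.finite(v)) NA_real_ else v
}

# Evaluate a multigenic chromosome the oracle way.
oracle_predict <- function(chromosome, X, linking = "+") {
  trees <- lapply(chromosome$genes, oracle_decode)
  vapply(seq_len(nrow(X)), function(i) {
    vals <- vapply(trees, oracle_eval, numeric(1), row = X[i, ])
    if (anyNA(vals)) return(NA_real_)
    v <- if (linking == "+") sum(vals) else prod(vals)
    if (!is.finite(v)) NA_real_ else v
  }, numeric(1))
}

# Random full-rank regression problem.
random_problem <- function(n, k, seed) {
  set.seed(seed)
  X <- matrix(rnorm(n * k), n, k, dimnames = list(NULL, paste0("x", seq_len(k))))
  y <- rnorm(n)
  list(X = X, y = y)
}

# Small random descriptor table.
random_table <- function(n, p, seed) {
  set.seed(seed)
  descriptor_table(matrix(rnorm(n * p), n, p,
                          dimnames = list(NULL, paste0("d", seq_len(p)))),
                   rnorm(n))
}
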