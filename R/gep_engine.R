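#' @keywords internal
"_PACKAGE"

# The fixed operational function set of the evolved models.
GEP_FUNCTIONS <- c("+", "-", "*", "/")

#' Karva tail length
#'
#' Gene length bookkeeping of the Karva encoding: a gene with head length
#' `h` over functions of maximum arity `a = 2` needs a tail of
#' `h (a - 1) + 1 = h + 1` terminals so that any head content decodes into
#' a complete tree.
#'
#' @param head_length Head length (`>= 1`).
#' @return The tail length, `head_length + 1`.
#' @export
tail_length <- function(head_length) {
  if (any(head_length < 1L)) stop("`head_length` must be >= 1", call. = FALSE)
  as.integer(head_length) + 1L
}

#' Gene-expression-programming configuration
#'
#' Collects every control parameter of the evolutionary search.  Defaults
#' are conventional GEP settings (the study's own control-parameter values
#' are unpublished): 3 genes of head length 7 linked by `+`, population
#' 100, 500 generations, per-symbol mutation 0.044, inversion 0.1, one- and
#' two-point recombination 0.3 each, elitism 1.
#'
#' @param terminal_set Character vector of descriptor names usable as
#'   terminals.
#' @param head_length Gene head length.
#' @param n_genes Genes per chromosome.
#' @param population_size Individuals per generation (`>= 2`).
#' @param n_generations Generation budget.
#' @param p_mutation Per-symbol mutation probability.
#' @param p_inversion Per-chromosome head-inversion probability.
#' @param p_recombination_1pt,p_recombination_2pt Per-pair recombination
#'   probabilities.
#' @param elitism Number of best individuals copied unchanged (`>= 1`).
#' @param linking_function Operator joining gene sub-trees: `"+"` or `"*"`.
#' @param seed Integer seed making a run fully reproducible.
#' @return An object of class `"gep_config"`.
#' @export
gep_config <- function(terminal_set, head_length = 7L, n_genes = 3L,
                       population_size = 100L, n_generations = 500L,
                       p_mutation = 0.044, p_inversion = 0.1,
                       p_recombination_1pt = 0.3, p_recombination_2pt = 0.3,
                       elitism = 1L, linking_function = "+", seed = 1L) {
  terminal_set <- as.character(terminal_set)
  if (!length(terminal_set)) stop("`terminal_set` must be non-empty", call. = FALSE)
  if (anyDuplicated(terminal_set)) stop("duplicated terminals", call. = FALSE)
  if (any(terminal_set %in% GEP_FUNCTIONS)) {
    stop("terminal names may not collide with the function set", call. = FALSE)
  }
  head_length <- as.integer(head_length)
  if (head_length < 1L) stop("`head_length` must be >= 1", call. = FALSE)
  population_size <- as.integer(population_size)
  if (population_size < 2L) stop("`population_size` must be >= 2", call. = FALSE)
  elitism <- as.integer(elitism)
  if (elitism < 1L || elitism >= population_size) {
    stop("`elitism` must satisfy 1 <= elitism < population_size", call. = FALSE)
  }
  probs <- c(p_mutation = p_mutation, p_inversion = p_inversion,
             p_recombination_1pt = p_recombination_1pt,
             p_recombination_2pt = p_recombination_2pt)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  linking_function <- match.arg(linking_function, c("+", "*"))
  structure(
    list(terminal_set = terminal_set, head_length = head_length,
         n_genes = as.integer(n_genes), population_size = population_size,
         n_generations = as.integer(n_generations), p_mutation = p_mutation,
         p_inversion = p_inversion,
         p_recombination_1pt = p_recombination_1pt,
         p_recombination_2pt = p_recombination_2pt,
         elitism = elitism, linking_function = linking_function,
         function_set = GEP_FUNCTIONS, seed = as.integer(seed)),
    class = "gep_config"
  )
}

#' Construct a chromosome from gene symbol vectors
#'
#' @param genes List of character vectors, one per gene, each of length
#'   `head_length + tail_length(head_length)`; head positions hold
#'   functions or terminals, tail positions terminals only.
#' @param head_length Head length shared by all genes.
#' @param terminals Allowed terminal symbols (for validation).
#' @return An object of class `"gep_chromosome"`.
#' @export
new_chromosome <- function(genes, head_length, terminals) {
  chrom <- structure(list(genes = genes, head_length = as.integer(head_length)),
                     class = "gep_chromosome")
  validate_chromosome(chrom, terminals)
  chrom
}

#' Validate a chromosome
#'
#' Checks the Karva validity contract: constant gene length
#' `2*head_length + 1`, head symbols drawn from functions plus terminals,
#' tail symbols terminals only.
#'
#' @param chromosome A `"gep_chromosome"`.
#' @param terminals Allowed terminal symbols.
#' @return The chromosome, invisibly; errors on violation.
#' @export
validate_chromosome <- function(chromosome, terminals) {
  h <- chromosome$head_length
  len <- h + tail_length(h)
  for (g in seq_along(chromosome$genes)) {
    gene <- chromosome$genes[[g]]
    if (length(gene) != len) {
      stop("gene ", g, " has length ", length(gene), "; expected ", len,
           call. = FALSE)
    }
    head_ok <- gene[seq_len(h)] %in% c(GEP_FUNCTIONS, terminals)
    tail_ok <- gene[seq.int(h + 1L, len)] %in% terminals
    if (!all(head_ok)) {
      stop("gene ", g, ": unknown head symbol(s) ",
           paste(gene[seq_len(h)][!head_ok], collapse = ", "), call. = FALSE)
    }
    if (!all(tail_ok)) {
      stop("gene ", g, ": non-terminal symbol in tail (",
           paste(gene[seq.int(h + 1L, len)][!tail_ok], collapse = ", "), ")",
           call. = FALSE)
    }
  }
  invisible(chromosome)
}

#' Draw a random valid chromosome
#'
#' Head positions are sampled uniformly from functions plus terminals, tail
#' positions from terminals only, so every draw is valid by construction.
#' Uses the current RNG stream.
#'
#' @param config A [gep_config()].
#' @return A `"gep_chromosome"`.
#' @export
random_chromosome <- function(config) {
  h <- config$head_length
  t_len <- tail_length(h)
  head_alphabet <- c(GEP_FUNCTIONS, config$terminal_set)
  genes <- lapply(seq_len(config$n_genes), function(g) {
    c(sample(head_alphabet, h, replace = TRUE),
      sample(config$terminal_set, t_len, replace = TRUE))
  })
  structure(list(genes = genes, head_length = h), class = "gep_chromosome")
}

#' @export
format.gep_chromosome <- function(x, ...) {
  vapply(x$genes, paste, character(1), collapse = " ")
}

#' @export
print.gep_chromosome <- function(x, ...) {
  cat("<gep_chromosome> head =", x$head_length, "\n")
  for (s in format(x)) cat(" ", s, "\n")
  invisible(x)
}

#' Parse gene strings back into a chromosome
#'
#' Inverse of `format()` on a chromosome: each gene is a space-separated
#' symbol string, so evolved models serialised as text round-trip.
#'
#' @param gene_strings Character vector of space-separated gene strings.
#' @param head_length Head length.
#' @param terminals Allowed terminals (for validation).
#' @return A `"gep_chromosome"`.
#' @export
parse_chromosome <- function(gene_strings, head_length, terminals) {
  genes <- lapply(strsplit(gene_strings, " +"), function(g) g[nzchar(g)])
  new_chromosome(genes, head_length, terminals)
}

# Level-order (breadth-first) decoding of one gene's K-expression into
# parallel node arrays.  Node k's children are the next two unassigned
# positions; scanning stops once every created node has its children.
decode_gene <- function(gene) {
  n_max <- length(gene)
  left <- rep(NA_integer_, n_max)
  right <- rep(NA_integer_, n_max)
  used <- 1L
  k <- 1L
  while (k <= used) {
    if (gene[k] %in% GEP_FUNCTIONS) {
      left[k] <- used + 1L
      right[k] <- used + 2L
      used <- used + 2L
      if (used > n_max) stop("gene too short to decode", call. = FALSE)
    }
    k <- k + 1L
  }
  idx <- seq_len(used)
  list(sym = gene[idx], left = left[idx], right = right[idx])
}

#' Express a chromosome into its expression tree
#'
#' Decodes each gene's K-expression breadth-first (level order): symbols
#' are read left to right, every function node consuming the next two
#' unassigned positions as children; trailing unused symbols are ignored.
#' Gene sub-trees are joined by the linking function.
#'
#' @param chromosome A `"gep_chromosome"`.
#' @param linking_function `"+"` or `"*"`; joined left to right.
#' @return An object of class `"expression_tree"`: list with `genes`
#'   (decoded node arrays `sym`, `left`, `right`), `linking`,
#'   `terminals_used`.
#' @export
express <- function(chromosome, linking_function = "+") {
  stopifnot(inherits(chromosome, "gep_chromosome"))
  linking_function <- match.arg(linking_function, c("+", "*"))
  decoded <- lapply(chromosome$genes, decode_gene)
  terms <- unique(unlist(lapply(decoded, function(g) {
    g$sym[!(g$sym %in% GEP_FUNCTIONS)]
  })))
  structure(list(genes = decoded, linking = linking_function,
                 terminals_used = terms, chromosome = chromosome),
            class = "expression_tree")
}

# Evaluate one decoded gene over a row-matrix of terminal values.
# Returns an n-vector; NA marks the invalid-evaluation state (divisor
# magnitude < 1e-12 or non-finite intermediate).
eval_gene <- function(gene, X) {
  ev <- function(i) {
    s <- gene$sym[i]
    if (is.na(gene$left[i])) return(X[, s])
    a <- ev(gene$left[i])
    b <- ev(gene$right[i])
    out <- switch(s,
                  "+" = a + b,
                  "-" = a - b,
                  "*" = a * b,
                  "/" = {
                    r <- a / b
                    r[abs(b) < 1e-12] <- NA_real_
                    r
                  })
    out[!is.finite(out) & !is.na(out)] <- NA_real_
    out
  }
  ev(1L)
}

#' Evaluate an expression tree
#'
#' Arithmetic evaluation of the decoded model over one row (a named
#' vector) or a full descriptor matrix.  Any division whose divisor
#' magnitude is below `1e-12`, and any non-finite intermediate, marks that
#' row's value as invalid (`NA`) — numerical artifacts are never allowed to
#' masquerade as predictions.
#'
#' @param tree An `"expression_tree"`.
#' @param data Named numeric vector (one compound) or numeric matrix /
#'   [descriptor_table()] with one column per terminal.
#' @return Numeric vector of model values, `NA` where invalid.
#' @export
evaluate_expression <- function(tree, data) {
  stopifnot(inherits(tree, "expression_tree"))
  X <- if (inherits(data, "descriptor_table")) {
    data$values
  } else if (is.matrix(data)) {
    data
  } else if (is.numeric(data) && !is.null(names(data))) {
    matrix(data, nrow = 1L, dimnames = list(NULL, names(data)))
  } else {
    stop("`data` must be a named vector, matrix or descriptor_table",
         call. = FALSE)
  }
  missing <- setdiff(tree$terminals_used, colnames(X))
  if (length(missing)) {
    stop("terminal(s) absent from data: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  vals <- lapply(tree$genes, function(g) eval_gene(g, X))
  out <- Reduce(if (tree$linking == "+") `+` else `*`, vals)
  out[!is.finite(out) & !is.na(out)] <- NA_real_
  unname(out)
}

#' Render an expression tree as infix text
#'
#' @param tree An `"expression_tree"`.
#' @return A single string, gene sub-expressions parenthesised and joined
#'   by the linking function.
#' @export
render_expression <- function(tree) {
  stopifnot(inherits(tree, "expression_tree"))
  one <- function(g, i) {
    if (is.na(g$left[i])) return(g$sym[i])
    paste0("(", one(g, g$left[i]), g$sym[i], one(g, g$right[i]), ")")
  }
  paste(vapply(tree$genes, function(g) one(g, 1L), character(1)),
        collapse = paste0(" ", tree$linking, " "))
}

#' @export
print.expression_tree <- function(x, ...) {
  cat("<expression_tree>", render_expression(x), "\n")
  invisible(x)
}

#' Fitness of a chromosome on training data
#'
#' `f = 1000 / (1 + RMSE)` between the expressed model's predictions and
#' the observed activities: bounded by 1000 (perfect), monotone in RMSE.
#' A chromosome whose model is invalid on any training row scores 0, so
#' selection can never reward guarded-division artifacts.
#'
#' @param chromosome A `"gep_chromosome"` (or an `"expression_tree"`).
#' @param X Numeric matrix of descriptor values (named columns).
#' @param y Observed activities.
#' @param linking_function Linking operator used when expressing a raw
#'   chromosome.
#' @return Non-negative fitness value.
#' @export
gep_fitness <- function(chromosome, X, y, linking_function = "+") {
  tree <- if (inherits(chromosome, "expression_tree")) chromosome
          else express(chromosome, linking_function)
  if (!length(y)) stop("empty training data", call. = FALSE)
  pred <- evaluate_expression(tree, X)
  if (anyNA(pred)) return(0)
  1000 / (1 + sqrt(mean((pred - y)^2)))
}

#' Fitness-proportionate (roulette-wheel) parent selection
#'
#' Samples parent indices with replacement, each individual drawn with
#' probability proportional to its fitness; zero-fitness individuals are
#' never selected.  If every fitness is zero the draw falls back to
#' uniform, with a warning.
#'
#' @param fitnesses Non-negative fitness vector.
#' @param n_parents Number of parents to draw.
#' @return Integer vector of selected indices.
#' @export
select_parents <- function(fitnesses, n_parents) {
  if (any(fitnesses < 0)) stop("fitnesses must be non-negative", call. = FALSE)
  if (all(fitnesses == 0)) {
    warning("all fitnesses zero: uniform parent selection")
    return(sample.int(length(fitnesses), n_parents, replace = TRUE))
  }
  sample.int(length(fitnesses), n_parents, replace = TRUE, prob = fitnesses)
}

#' Per-symbol mutation
#'
#' Each symbol is independently resampled with probability `p_mutation`:
#' head positions from functions plus terminals, tail positions from
#' terminals only — validity is preserved by construction.
#'
#' @param chromosome A `"gep_chromosome"`.
#' @param p_mutation Per-symbol probability.
#' @param terminals Terminal alphabet.
#' @return The mutated `"gep_chromosome"`.
#' @export
mutate_chromosome <- function(chromosome, p_mutation, terminals) {
  h <- chromosome$head_length
  len <- h + tail_length(h)
  head_alphabet <- c(GEP_FUNCTIONS, terminals)
  genes <- lapply(chromosome$genes, function(gene) {
    hit <- stats::runif(len) < p_mutation
    if (any(hit[seq_len(h)])) {
      idx <- which(hit[seq_len(h)])
      gene[idx] <- sample(head_alphabet, length(idx), replace = TRUE)
    }
    tail_idx <- which(hit) ; tail_idx <- tail_idx[tail_idx > h]
    if (length(tail_idx)) {
      gene[tail_idx] <- sample(terminals, length(tail_idx), replace = TRUE)
    }
    gene
  })
  structure(list(genes = genes, head_length = h), class = "gep_chromosome")
}

#' One- or two-point recombination
#'
#' Crossover over the concatenated chromosome: cut point(s) are chosen
#' uniformly and the flanked segments exchanged.  Because head and tail
#' alphabets align positionally between equal-shape parents, children are
#' valid automatically.
#'
#' @param parent_a,parent_b Equal-shape `"gep_chromosome"` objects.
#' @param mode `"one-point"` or `"two-point"`.
#' @return List of two children (`"gep_chromosome"`).
#' @export
recombine <- function(parent_a, parent_b, mode = c("one-point", "two-point")) {
  mode <- match.arg(mode)
  h <- parent_a$head_length
  if (h != parent_b$head_length ||
      length(parent_a$genes) != length(parent_b$genes)) {
    stop("parents have different shapes", call. = FALSE)
  }
  a <- unlist(parent_a$genes)
  b <- unlist(parent_b$genes)
  len <- length(a)
  if (mode == "one-point") {
    cut <- sample.int(len - 1L, 1L)
    seg <- seq.int(cut + 1L, len)
  } else {
    cuts <- sort(sample.int(len - 1L, 2L))
    seg <- seq.int(cuts[1L] + 1L, cuts[2L])
  }
  ca <- a; cb <- b
  ca[seg] <- b[seg]
  cb[seg] <- a[seg]
  gene_len <- h + tail_length(h)
  rebuild <- function(v) {
    genes <- unname(split(unname(v), rep(seq_along(parent_a$genes),
                                         each = gene_len)))
    structure(list(genes = genes, head_length = h), class = "gep_chromosome")
  }
  list(rebuild(ca), rebuild(cb))
}

#' Head-segment inversion
#'
#' Reverses a randomly chosen contiguous segment within one gene's head;
#' the tail is untouched, so validity is preserved.
#'
#' @param chromosome A `"gep_chromosome"`.
#' @return The inverted `"gep_chromosome"`.
#' @export
invert_chromosome <- function(chromosome) {
  h <- chromosome$head_length
  g <- sample.int(length(chromosome$genes), 1L)
  ends <- sort(sample.int(h, 2L, replace = TRUE))
  seg <- seq.int(ends[1L], ends[2L])
  gene <- chromosome$genes[[g]]
  gene[seg] <- rev(gene[seg])
  chromosome$genes[[g]] <- gene
  chromosome
}

#' Run the evolutionary search
#'
#' Seeded, fully reproducible GEP run: random initial population, fitness
#' evaluation, elitist fitness-proportionate selection, one-/two-point
#' recombination, per-symbol mutation and head inversion, for
#' `n_generations` generations or until a (numerically) perfect individual
#' appears (`fitness >= 1000 - 1e-9`).
#'
#' @param config A [gep_config()].
#' @param X Numeric matrix (named columns) or [descriptor_table()].
#' @param y Observed activities; taken from the table when `X` is a
#'   [descriptor_table()] and `y` is missing.
#' @return An object of class `"gep_result"`: `best` chromosome,
#'   `best_tree`, `best_fitness`, `train_rmse`,
#'   `best_fitness_per_generation`, `train_predictions`, `generations_run`,
#'   `config` (echo).
#' @export
evolve <- function(config, X, y = NULL) {
  stopifnot(inherits(config, "gep_config"))
  if (inherits(X, "descriptor_table")) {
    if (is.null(y)) y <- X$activity
    X <- X$values
  }
  X <- as.matrix(X)
  missing_terms <- setdiff(config$terminal_set, colnames(X))
  if (length(missing_terms)) {
    stop("terminal(s) absent from X: ", paste(missing_terms, collapse = ", "),
         call. = FALSE)
  }
  if (is.null(y) || !length(y)) stop("empty training response", call. = FALSE)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (is.null(config$seed)) stop("`config$seed` is required", call. = FALSE)

  with_seed(config$seed, {
    pop_n <- config$population_size
    pop <- lapply(seq_len(pop_n), function(i) random_chromosome(config))
    best_per_gen <- numeric(0)
    best_fit <- -Inf
    best_chrom <- NULL
    gen <- 0L
    repeat {
      gen <- gen + 1L
      fits <- vapply(pop, function(ch) {
        gep_fitness(ch, X, y, linking_function = config$linking_function)
      }, numeric(1))
      gen_best <- which.max(fits)
      if (fits[gen_best] > best_fit) {
        best_fit <- fits[gen_best]
        best_chrom <- pop[[gen_best]]
      }
      best_per_gen[gen] <- max(fits)
      if (best_per_gen[gen] >= 1000 - 1e-9 || gen >= config$n_generations) break

      elite_idx <- order(fits, decreasing = TRUE)[seq_len(config$elitism)]
      n_children <- pop_n - config$elitism
      parent_idx <- select_parents(fits, n_children)
      children <- pop[parent_idx]

      if (n_children >= 2L) {
        for (j in seq(1L, n_children - 1L, by = 2L)) {
          if (stats::runif(1) < config$p_recombination_1pt) {
            pair <- recombine(children[[j]], children[[j + 1L]], "one-point")
            children[[j]] <- pair[[1L]]; children[[j + 1L]] <- pair[[2L]]
          }
          if (stats::runif(1) < config$p_recombination_2pt) {
            pair <- recombine(children[[j]], children[[j + 1L]], "two-point")
            children[[j]] <- pair[[1L]]; children[[j + 1L]] <- pair[[2L]]
          }
        }
      }
      children <- lapply(children, mutate_chromosome,
                         p_mutation = config$p_mutation,
                         terminals = config$terminal_set)
      children <- lapply(children, function(ch) {
        if (stats::runif(1) < config$p_inversion) invert_chromosome(ch) else ch
      })
      pop <- c(pop[elite_idx], children)
    }

    best_tree <- express(best_chrom, config$linking_function)
    preds <- evaluate_expression(best_tree, X)
    structure(
      list(best = best_chrom, best_tree = best_tree, best_fitness = best_fit,
           train_rmse = if (anyNA(preds)) NA_real_
                        else sqrt(mean((preds - y)^2)),
           best_fitness_per_generation = best_per_gen,
           train_predictions = preds, generations_run = gen,
           config = config),
      class = "gep_result"
    )
  })
}

#' @export
print.gep_result <- function(x, ...) {
  cat("<gep_result> generations:", x$generations_run,
      " best fitness:", format(x$best_fitness, digits = 8), "\n")
  cat("  model:", render_expression(x$best_tree), "\n")
  cat(sprintf("  training RMSE: %.6g\n", x$train_rmse))
  invisible(x)
}

#' Predict from an evolved model
#'
#' Evaluates the best expression tree on new descriptor rows.  Rows where
#' the model is invalid (guarded division / non-finite) are returned as
#' `NA` and reported with a warning — never silently dropped.
#'
#' @param object A `"gep_result"`.
#' @param newdata Numeric matrix or [descriptor_table()] containing every
#'   terminal column.
#' @param ... Unused.
#' @return Numeric vector of predictions (`NA` where invalid).
#' @export
predict.gep_result <- function(object, newdata, ...) {
  pred <- evaluate_expression(object$best_tree, newdata)
  if (anyNA(pred)) {
    warning("model invalid on row(s): ",
            paste(which(is.na(pred)), collapse = ", "))
  }
  pred
}
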