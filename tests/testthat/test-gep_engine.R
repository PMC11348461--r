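terms2 <- c("a", "b")

chrom_from <- function(..., head_length) {
  new_chromosome(list(...), head_length, terms2)
}

test_that("tail length follows the Karva construction for binary operators", {
  expect_equal(tail_length(7), 8L)
  expect_equal(tail_length(1), 2L)
  expect_equal(tail_length(10), 11L)
  expect_error(tail_length(0), ">= 1")
})

test_that("expression decoding is level-order with unused symbols ignored", {
  # head 3, gene "+ * a b b a a": tree (b*b)+a
  g <- c("+", "*", "a", "b", "b", "a", "a")
  ch <- chrom_from(g, head_length = 3)
  tree <- express(ch)
  expect_equal(render_expression(tree), "((b*b)+a)")
  expect_equal(evaluate_expression(tree, c(a = 1, b = 2)), 5)
  # root terminal: the bare terminal, trailing symbols ignored
  g2 <- c("a", "+", "b", "b", "a", "a", "b")
  tree2 <- express(chrom_from(g2, head_length = 3))
  expect_equal(render_expression(tree2), "a")
  expect_equal(evaluate_expression(tree2, c(a = 3.5, b = 0)), 3.5)
  # function in tail is rejected
  expect_error(new_chromosome(list(c("+", "a", "b", "a", "/", "a", "b")),
                              3, terms2), "tail")
})

test_that("decoding and evaluation agree with independent recursive oracles", {
  cfg <- gep_config(terminal_set = paste0("t", 1:5), head_length = 7,
                    n_genes = 1, seed = 1)
  set.seed(42)
  X <- matrix(rnorm(3 * 5), 3, 5, dimnames = list(NULL, paste0("t", 1:5)))
  for (i in 1:500) {
    ch <- random_chromosome(cfg)
    tree <- express(ch)
    node <- oracle_decode(ch$genes[[1]])
    expect_identical(render_expression(tree), oracle_render(node))
    expect_equal(evaluate_expression(tree, X),
                 oracle_predict(ch, X, linking = "+"))
  }
})

test_that("multigenic evaluation, linking and guarded division behave", {
  cfg <- gep_config(terminal_set = paste0("t", 1:4), head_length = 5,
                    n_genes = 3, seed = 2)
  set.seed(7)
  X <- matrix(rnorm(40), 10, 4, dimnames = list(NULL, paste0("t", 1:4)))
  for (i in 1:200) {
    ch <- random_chromosome(cfg)
    for (linking in c("+", "*")) {
      expect_equal(evaluate_expression(express(ch, linking), X),
                   oracle_predict(ch, X, linking = linking))
    }
  }
  # division by (near-)zero marks the row invalid rather than returning Inf
  div <- new_chromosome(list(c("/", "a", "b", "a", "b")), 2, terms2)
  tree <- express(div)
  expect_true(is.na(evaluate_expression(tree, c(a = 1, b = 0))))
  expect_true(is.na(evaluate_expression(tree, c(a = 1, b = 1e-13))))
  expect_equal(evaluate_expression(tree, c(a = 6, b = 2)), 3)
  expect_error(evaluate_expression(tree, c(a = 1)), "absent")
})

test_that("fitness is 1000/(1+RMSE) with zero reserved for invalid models", {
  X <- matrix(c(1, 2, 3), 3, 1, dimnames = list(NULL, "a"))
  ident <- new_chromosome(list(c("a", "a", "a")), 1, "a")
  expect_equal(gep_fitness(ident, X, c(1, 2, 3)), 1000)
  rmse <- sqrt(mean((c(1, 2, 3) - c(1, 2, 5))^2))  # sqrt(4/3)
  expect_equal(gep_fitness(ident, X, c(1, 2, 5)), 1000 / (1 + rmse))
  # invalid on any row => 0
  bad <- new_chromosome(list(c("/", "a", "a", "a", "a")), 2, "a")
  X0 <- matrix(c(1, 0, 2), 3, 1, dimnames = list(NULL, "a"))
  expect_equal(gep_fitness(bad, X0, c(1, 1, 1)), 0)
})

test_that("roulette selection is fitness-proportionate", {
  set.seed(123)
  # equal fitnesses: empirical frequencies uniform within 3 sigma
  draws <- select_parents(rep(2, 5), 1e5)
  freq <- tabulate(draws, 5)
  expect_true(all(abs(freq - 2e4) < 3 * sqrt(1e5 * 0.2 * 0.8)))
  # all mass on one individual
  expect_true(all(select_parents(c(0, 7, 0), 500) == 2L))
  # zero-fitness individuals are never drawn
  draws2 <- select_parents(c(5, 0, 5), 1e4)
  expect_false(any(draws2 == 2L))
  expect_warning(select_parents(c(0, 0), 10), "uniform")
})

test_that("genetic operators preserve chromosome validity", {
  cfg <- gep_config(terminal_set = paste0("t", 1:4), head_length = 6,
                    n_genes = 2, seed = 3)
  set.seed(11)
  ch <- random_chromosome(cfg)
  expect_identical(mutate_chromosome(ch, 0, cfg$terminal_set)$genes, ch$genes)
  # p = 1: every tail symbol is a terminal (and validity holds)
  full <- mutate_chromosome(ch, 1, cfg$terminal_set)
  for (g in full$genes) {
    expect_true(all(g[7:13] %in% cfg$terminal_set))
  }
  for (i in 1:1000) {
    m <- mutate_chromosome(random_chromosome(cfg), 0.3, cfg$terminal_set)
    expect_silent(validate_chromosome(m, cfg$terminal_set))
  }
})

test_that("recombination exchanges segments and preserves validity", {
  cfg <- gep_config(terminal_set = paste0("t", 1:4), head_length = 5,
                    n_genes = 2, seed = 4)
  set.seed(21)
  a <- random_chromosome(cfg)
  kids <- recombine(a, a, "one-point")
  expect_identical(kids[[1]]$genes, a$genes)
  expect_identical(kids[[2]]$genes, a$genes)
  for (i in 1:1000) {
    p1 <- random_chromosome(cfg)
    p2 <- random_chromosome(cfg)
    mode <- if (i %% 2) "one-point" else "two-point"
    kids <- recombine(p1, p2, mode)
    expect_silent(validate_chromosome(kids[[1]], cfg$terminal_set))
    expect_silent(validate_chromosome(kids[[2]], cfg$terminal_set))
    # per-position symbol multiset is conserved across the pair
    pa <- unlist(p1$genes); pb <- unlist(p2$genes)
    ka <- unlist(kids[[1]]$genes); kb <- unlist(kids[[2]]$genes)
    swapped <- ka != pa
    expect_identical(ka[swapped], pb[swapped])
    expect_identical(kb[swapped], pa[swapped])
    expect_identical(kb[!swapped], pb[!swapped])
  }
  cfg3 <- gep_config(terminal_set = cfg$terminal_set, head_length = 4, seed = 1)
  expect_error(recombine(a, random_chromosome(cfg3)), "shapes")
})

test_that("inversion reverses a head segment and never touches tails", {
  cfg <- gep_config(terminal_set = paste0("t", 1:4), head_length = 6,
                    n_genes = 2, seed = 5)
  set.seed(31)
  for (i in 1:1000) {
    ch <- random_chromosome(cfg)
    inv <- invert_chromosome(ch)
    expect_silent(validate_chromosome(inv, cfg$terminal_set))
    for (g in seq_along(ch$genes)) {
      expect_identical(inv$genes[[g]][7:13], ch$genes[[g]][7:13])
      # head content conserved as a multiset
      expect_identical(sort(inv$genes[[g]][1:6]), sort(ch$genes[[g]][1:6]))
    }
  }
})

test_that("evolution is reproducible, elitist and size-preserving", {
  set.seed(55)
  X <- matrix(rnorm(60), 20, 3, dimnames = list(NULL, paste0("t", 1:3)))
  y <- X[, 1] + X[, 2] * X[, 3]
  cfg <- gep_config(terminal_set = paste0("t", 1:3), head_length = 4,
                    population_size = 30, n_generations = 40, seed = 9)
  r1 <- evolve(cfg, X, y)
  r2 <- evolve(cfg, X, y)
  expect_identical(r1, r2)
  # best fitness never decreases under elitism
  expect_true(all(diff(r1$best_fitness_per_generation) >= -1e-12))
  # predictions echo the training evaluation of the best tree
  expect_equal(r1$train_predictions,
               evaluate_expression(r1$best_tree, X))
  # an exactly representable target stops the run early at fitness 1000
  y_easy <- X[, 2]
  r3 <- evolve(gep_config(terminal_set = paste0("t", 1:3), head_length = 3,
                          population_size = 50, n_generations = 200, seed = 2),
               X, y_easy)
  expect_equal(r3$best_fitness, 1000)
  expect_lt(r3$generations_run, 200)
  expect_equal(r3$train_rmse, 0, tolerance = 1e-12)
})

test_that("chromosome serialization round-trips through text", {
  cfg <- gep_config(terminal_set = c("x1", "x2"), head_length = 4, seed = 6)
  set.seed(41)
  ch <- random_chromosome(cfg)
  back <- parse_chromosome(format(ch), 4, cfg$terminal_set)
  expect_identical(back$genes, ch$genes)
  expect_identical(render_expression(express(back)),
                   render_expression(express(ch)))
})

test_that("prediction from an evolved model reports invalid rows", {
  div <- new_chromosome(list(c("/", "a", "b", "a", "b")), 2, terms2)
  fake <- structure(list(best = div, best_tree = express(div)),
                    class = "gep_result")
  X <- matrix(c(1, 1, 2, 0), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(p <- predict(fake, X), "row")
  expect_equal(p[1], 0.5)
  expect_true(is.na(p[2]))
  expect_length(predict(fake, matrix(c(4, 2), 1, 2,
                                     dimnames = list(NULL, c("a", "b")))), 1L)
})
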