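# Dynamic Bayesian network stage: panel alignment, BGe scoring, sampling.

make_lagged_pair_data <- function(n, beta = 0.9, seed = 7L, sd = 1) {
  set.seed(seed)
  A <- stats::rnorm(n)
  X <- cbind(A = A, B = stats::rnorm(n))
  Y <- cbind(A = stats::rnorm(n), B = beta * A + stats::rnorm(n, sd = sd))
  transition_data(X, Y)
}

test_that("panel alignment log-transforms and z-scores per mediator", {
  co <- generate_cohort(0L, 8L, 0L, seed = 2L, n_healthy = 0L)
  panel <- align_panel(co, group = "moderate")
  expect_s3_class(panel, "cs_panel")
  expect_equal(dim(panel$values)[1], 8L)
  expect_equal(dim(panel$values)[2], length(default_schedule()$times_h))
  for (med in panel$mediators) {
    v <- panel$values[, , med]
    expect_lt(abs(mean(v)), 1e-10)
    expect_equal(sqrt(mean((v - mean(v))^2)), 1, tolerance = 1e-10)
  }
  # monotone transform: z-scored values preserve latent-level ranks
  map0 <- default_mediator_map(0)
  co0 <- generate_cohort(0L, 6L, 6L, seed = 3L, mediator_map = map0,
                         n_healthy = 0L)
  co0 <- co0[co0$mediator %in% c("MCP1", "MIG", "IP10", "IL6", "IFNg"), ]
  p0 <- align_panel(co0)
  lv <- matrix(co0$latent_level[co0$mediator == "MCP1"],
               nrow = length(unique(co0$patient_id)), byrow = TRUE)
  z <- p0$values[, , "MCP1"]
  expect_equal(stats::cor(as.vector(z), as.vector(lv), method = "spearman"),
               1)
})

test_that("alignment flags degenerate inputs", {
  expect_error(align_panel(generate_cohort(0L, 0L, 0L, seed = 1L,
                                           n_healthy = 0L)), "empty")
  # noise-free healthy-only cohort: every mediator is constant
  co <- generate_cohort(0L, 0L, 0L, seed = 1L, n_healthy = 3L,
                        mediator_map = default_mediator_map(0))
  expect_error(align_panel(co), "zero variance")
})

test_that("duplicating a cohort leaves panel statistics unchanged", {
  co <- generate_cohort(0L, 6L, 0L, seed = 4L, n_healthy = 0L)
  co2 <- co
  co2$patient_id <- paste0(co2$patient_id, "bis")
  both <- rbind(co, co2)
  class(both) <- class(co)
  p1 <- align_panel(co)
  p2 <- align_panel(both)
  expect_equal(p2$values[seq_along(p1$patients), , ], p1$values,
               ignore_attr = TRUE)
})

test_that("transitions pair consecutive slots within patients only", {
  co <- generate_cohort(0L, 5L, 0L, seed = 5L, n_healthy = 0L)
  tr <- make_transitions(align_panel(co))
  n_slots <- length(default_schedule()$times_h)
  expect_equal(nrow(tr$X), 5L * (n_slots - 1L))
  expect_equal(colnames(tr$X), sort(unique(co$mediator)))
})

test_that("BGe local scores match the numerical-integration oracle", {
  set.seed(42)
  x <- stats::rnorm(50)
  for (d in c(1L, 2L)) {
    h <- bge_hyperparams(d)
    cf <- chemoswitch:::cs_log_subset_marginal(matrix(x, ncol = 1,
                                                      dimnames = list(NULL, "A")), h)
    expect_lt(abs(cf - bge_oracle_1d(x, h)), 1e-4)
  }
  # empty parent set through the public interface
  dat <- transition_data(matrix(stats::rnorm(50), ncol = 1,
                                dimnames = list(NULL, "A")),
                         matrix(x, ncol = 1, dimnames = list(NULL, "A")))
  h1 <- bge_hyperparams(1)
  expect_lt(abs(bge_local_score("A", character(0), dat, h1) -
                  bge_oracle_1d(x, h1)), 1e-4)
})

test_that("a true lagged parent increases the local score", {
  dat <- make_lagged_pair_data(200)
  gain <- bge_local_score("B", "A", dat) -
    bge_local_score("B", character(0), dat)
  expect_gt(gain, 0)
  # doubling the dataset strengthens, but does not simply double, the evidence
  dat2 <- transition_data(rbind(dat$X, dat$X), rbind(dat$Y, dat$Y))
  gain2 <- bge_local_score("B", "A", dat2) -
    bge_local_score("B", character(0), dat2)
  expect_gt(gain2, gain)
  expect_false(isTRUE(all.equal(gain2, 2 * gain)))
  expect_error(bge_local_score("B", "A", make_lagged_pair_data(3)),
               "too few")
})

test_that("equivalent structures score identically (score equivalence)", {
  set.seed(12)
  n <- 40
  A <- stats::rnorm(n)
  B <- 0.7 * A + stats::rnorm(n, sd = 0.6)
  C <- -0.5 * B + stats::rnorm(n, sd = 0.8)
  M <- cbind(A = A, B = B, C = C)
  dat <- transition_data(M, M)  # static data embedded as one transition
  h <- bge_hyperparams(3)
  total <- function(ord) {
    s <- 0
    for (k in seq_along(ord)) {
      s <- s + bge_local_score(ord[k], ord[seq_len(k - 1)], dat, h)
    }
    s
  }
  perms <- list(c("A", "B", "C"), c("A", "C", "B"), c("B", "A", "C"),
                c("B", "C", "A"), c("C", "A", "B"), c("C", "B", "A"))
  scores <- vapply(perms, total, numeric(1))
  expect_lt(max(scores) - min(scores), 1e-8)
})

test_that("the sampler is reproducible and respects its boundaries", {
  dat <- make_lagged_pair_data(100)
  p1 <- mh_sample_structures(dat, fan_in = 2L, iters = 2000L, seed = 5L)
  p2 <- mh_sample_structures(dat, fan_in = 2L, iters = 2000L, seed = 5L)
  expect_identical(p1$freq, p2$freq)
  pb <- mh_sample_structures(dat, fan_in = 2L, iters = 101L, burn_in = 100L,
                             seed = 5L)
  expect_true(all(pb$freq %in% c(0, 1)))
  expect_error(mh_sample_structures(dat, fan_in = 0L, iters = 10L), "fan_in")
  expect_error(mh_sample_structures(dat, iters = 10L, burn_in = 20L),
               "burn_in")
})

test_that("the true lagged direction dominates its reverse", {
  dat <- make_lagged_pair_data(300, seed = 7L)
  post <- mh_sample_structures(dat, fan_in = 2L, iters = 10000L, seed = 7L)
  expect_gt(post$freq["A", "B"], post$freq["B", "A"])
})

test_that("MCMC frequencies converge to the enumeration posterior", {
  dat <- make_lagged_pair_data(120, beta = 0.4, seed = 9L)
  ex <- exact_posterior_edges(dat, fan_in = 2L)
  mc <- mh_sample_structures(dat, fan_in = 2L, iters = 15000L, seed = 9L)
  expect_lt(max(abs(ex$freq - mc$freq)), 0.05)
})

test_that("consensus thresholding is deterministic with a closed rule", {
  f <- matrix(c(0.5, 0.2, 0.8, 0.49), 2, 2,
              dimnames = list(c("A", "B"), c("A", "B")))
  post <- structure(list(freq = f), class = "cs_posterior")
  net <- consensus_network(post, 0.5)
  expect_setequal(paste(net$from, net$to), c("A A", "A B"))  # 0.5 included
  empty <- structure(list(freq = f * 0), class = "cs_posterior")
  expect_equal(nrow(consensus_network(empty, 0.5)), 0L)
  expect_error(consensus_network(post, 0), "threshold")
})

test_that("recovery metrics behave at the extremes and under ties", {
  med <- c("A", "B")
  truth <- data.frame(from = "A", to = "B")
  perfect <- structure(list(freq = matrix(c(0, 0, 1, 0), 2, 2,
                                          dimnames = list(med, med))),
                       class = "cs_posterior")
  mp <- recovery_metrics(perfect, truth)
  expect_equal(c(mp$precision, mp$recall, mp$auroc), c(1, 1, 1))
  # constant scores: midranks give exactly chance AUROC
  flat <- structure(list(freq = matrix(0.3, 2, 2,
                                       dimnames = list(med, med))),
                    class = "cs_posterior")
  expect_equal(recovery_metrics(flat, truth)$auroc, 0.5)
  # random scores vs random truth: near-chance AUROC on a large universe
  set.seed(31)
  med20 <- paste0("m", 1:20)
  rnd <- structure(list(freq = matrix(stats::runif(400), 20, 20,
                                      dimnames = list(med20, med20))),
                   class = "cs_posterior")
  truth_rnd <- expand.grid(from = med20, to = med20,
                           stringsAsFactors = FALSE)
  truth_rnd <- truth_rnd[sample.int(400, 80), ]
  expect_lt(abs(recovery_metrics(rnd, truth_rnd)$auroc - 0.5), 0.1)
  expect_warning(
    empty <- recovery_metrics(flat, truth[0, , drop = FALSE],
                              threshold = 0.9),
    "empty truth")
  expect_equal(empty$precision, 1)
})

test_that("edge recovery improves with cohort size on average", {
  probe <- function(n, s) {
    co <- generate_cohort(0L, n, 0L, seed = s,
                          mediator_map = default_mediator_map(0.3),
                          n_healthy = 0L)
    trans <- make_transitions(align_panel(co, group = "moderate"))
    post <- exact_posterior_edges(trans, fan_in = 3L)
    truth <- switch_true_edges()
    med <- trans$mediators
    bys <- c("TNFa", "IL1b", "IL10")
    all_e <- expand.grid(from = med, to = med, stringsAsFactors = FALSE)
    neg <- all_e[all_e$from %in% bys | all_e$to %in% bys, ]
    m <- recovery_metrics(post, truth, universe = rbind(truth, neg))
    c(precision = m$precision, recall = m$recall)
  }
  seeds <- 1:5
  small <- rowMeans(vapply(seeds, function(s) probe(30L, s), numeric(2)))
  large <- rowMeans(vapply(seeds, function(s) probe(90L, s), numeric(2)))
  expect_gte(large[["precision"]], small[["precision"]])
  expect_gte(large[["recall"]], small[["recall"]])
})
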