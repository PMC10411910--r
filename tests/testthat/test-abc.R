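test_that("population summaries use size correction only when sizes given", {
  set.seed(23)
  n <- 2000
  nuc <- rpois(n, 2); cyt <- rpois(n, 5)
  s <- summarize_population(nuc, cyt)
  expect_equal(unname(s["fano_nuclear"]), 1, tolerance = 0.1)
  expect_equal(unname(s["fano_cytoplasmic"]), 1, tolerance = 0.1)
  sizes <- runif(n, 7, 14)
  cyt_sc <- rpois(n, sizes / 2)
  s2 <- summarize_population(nuc, cyt_sc, sizes = sizes)
  expect_lt(abs(s2[["fano_cytoplasmic"]] - 1), 0.12)
  expect_error(summarize_population(integer(0), integer(0)), "empty")
})

test_that("degenerate tolerance returns the prior", {
  obs <- c(mean_nuclear = 0.7, mean_cytoplasmic = 3.3,
           fano_nuclear = 0.75, fano_cytoplasmic = 0.62)
  post <- abc_rejection(obs, S = 3, R = 3, n_proposals = 2000,
                        tolerance_quantile = 1, seed = 5)
  expect_equal(nrow(post$draws), 2000)
  # accepted draws are indistinguishable from the log-uniform prior
  for (p in c("k_A", "k_B", "k_C")) {
    ks <- stats::ks.test(log10(post$draws[[p]]), "punif",
                         log10(0.1), log10(1000))
    expect_gt(ks$p.value, 0.01)
  }
})

test_that("ABC recovers the rates of a known synthetic dataset", {
  truth <- model_spec(3, 3, 10, 10, 5)
  ps <- sample_population(truth, 2000, seed = 31)
  obs <- summarize_population(ps$nuclear, ps$cytoplasmic)
  post <- abc_rejection(obs, S = 3, R = 3, n_proposals = 10000,
                        tolerance_quantile = 0.01, seed = 6)
  sm <- posterior_summary(post)
  kc <- sm[sm$parameter == "k_C", ]
  expect_gt(kc$upper, 5); expect_lt(kc$lower, 5)  # truth inside 95% CI
  # the posterior median is inside an order of magnitude of the truth
  expect_gt(kc$median, 5 / 5); expect_lt(kc$median, 5 * 5)
  expect_true(all(post$draws$distance <= post$tolerance))
})

test_that("lower nuclear-export data pull the k_C posterior down", {
  mk_obs <- function(kC) {
    m <- steady_state_moments(model_spec(3, 3, 10, 10, kC))
    c(mean_nuclear = m$mean_nuclear, mean_cytoplasmic = m$mean_cytoplasmic,
      fano_nuclear = m$fano_nuclear, fano_cytoplasmic = m$fano_cytoplasmic)
  }
  slow <- abc_rejection(mk_obs(1), 3, 3, n_proposals = 6000,
                        tolerance_quantile = 0.02, seed = 7)
  fast <- abc_rejection(mk_obs(20), 3, 3, n_proposals = 6000,
                        tolerance_quantile = 0.02, seed = 7)
  med <- function(p) median(p$draws$k_C)
  expect_lt(med(slow), med(fast))
})

test_that("distances are invariant to rescaling a summary component", {
  set.seed(8)
  sims <- cbind(a = runif(50, 1, 2), b = runif(50, 10, 20))
  obs <- c(a = 1.5, b = 15)
  d1 <- subpoisson:::abc_distances(sims, obs)
  sims2 <- sims; sims2[, "b"] <- sims2[, "b"] * 1000
  d2 <- subpoisson:::abc_distances(sims2, c(a = 1.5, b = 15000))
  expect_equal(d1, d2, tolerance = 1e-12)
})

test_that("acceptance count is non-decreasing in the tolerance", {
  obs <- c(mean_nuclear = 0.7, mean_cytoplasmic = 3.3,
           fano_nuclear = 0.75, fano_cytoplasmic = 0.62)
  n_acc <- vapply(c(0.005, 0.02, 0.1, 0.5), function(q) {
    nrow(abc_rejection(obs, 3, 3, n_proposals = 2000,
                       tolerance_quantile = q, seed = 9)$draws)
  }, numeric(1))
  expect_true(all(diff(n_acc) >= 0))
})

test_that("model selection rejects single-step candidates for
           sub-Poissonian data and is degenerate for Poissonian data", {
  truth <- model_spec(3, 3, 10, 10, 5)
  ps <- sample_population(truth, 2000, seed = 41)
  obs <- summarize_population(ps$nuclear, ps$cytoplasmic)
  cands <- expand.grid(S = c(1, 2, 3), R = c(1, 3))
  mc <- model_selection(obs, cands, n_proposals = 3000, seed = 10)
  expect_equal(sum(mc$probability), 1)
  expect_lt(sum(mc$probability[mc$S == 1]), 0.01)
  # Poissonian data cannot discriminate: no near-certain winner
  obs_pois <- c(mean_nuclear = 0.7, mean_cytoplasmic = 3.3,
                fano_nuclear = 1, fano_cytoplasmic = 1)
  mc2 <- model_selection(obs_pois, cands, n_proposals = 3000, seed = 11)
  expect_lt(max(mc2$probability), 0.9)
  expect_gt(sum(mc2$probability > 0.05), 1)
  # a single candidate gets probability 1
  mc3 <- model_selection(obs, data.frame(S = 3, R = 3),
                         n_proposals = 2000, seed = 12)
  expect_equal(mc3$probability, 1)
})

test_that("posterior summaries report medians and central intervals", {
  post <- structure(
    list(draws = tibble::tibble(k_A = rep(2, 200), k_B = rep(3, 200),
                                k_C = rep(4, 200),
                                distance = rep(0, 200)),
         S = 3, R = 3),
    class = "abc_posterior")
  sm <- posterior_summary(post)
  expect_equal(sm$median, c(2, 3, 4))
  expect_equal(sm$upper - sm$lower, c(0, 0, 0))  # zero-width for constants
  post$draws <- post$draws[1:50, ]
  expect_warning(posterior_summary(post), "100")
})

test_that("posterior tables round-trip with their provenance sidecar", {
  obs <- c(mean_nuclear = 0.7, mean_cytoplasmic = 3.3,
           fano_nuclear = 0.8, fano_cytoplasmic = 0.7)
  post <- abc_rejection(obs, 2, 2, n_proposals = 500,
                        tolerance_quantile = 0.1, seed = 13)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_abc_posterior(post, path)
  side <- yaml::read_yaml(paste0(path, ".yml"))
  expect_equal(side$seed, 13)
  expect_equal(side$n_proposals, 500)
  back <- utils::read.delim(path)
  expect_equal(nrow(back), nrow(post$draws))
})
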