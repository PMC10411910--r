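test_that("model_spec validates its inputs and units", {
  expect_s3_class(model_spec(3, 3, 10, 10, 5), "model_spec")
  expect_error(model_spec(0, 1, 1, 1, 1), "S")
  expect_error(model_spec(1, 0, 1, 1, 1), "R")
  expect_error(model_spec(1, 1, -1, 1, 1), "positive")
  expect_error(model_spec(1, 1, 1, 1, 1, time_unit = "absolute"), "k_D")
  expect_error(model_spec(1, 1, 1, 1, 1, chromatin = c(1, -1)), "chromatin")
  # effective-lifetime units pin the effective degradation rate at 1
  expect_error(model_spec(1, 3, 1, 1, 1, k_D = 1,
                          time_unit = "effective_lifetime"), "effective")
  sp <- model_spec(2, 3, 1, 1, 1)
  expect_equal(sp$k_D, 3)
  expect_equal(effective_degradation_rate(sp), 1)
})

test_that("model_spec round-trips through YAML", {
  path <- withr::local_tempfile(fileext = ".yml")
  sp <- model_spec(3, 2, 10, 5, 2, chromatin = c(0.3, 0.7))
  write_model_spec(sp, path)
  sp2 <- read_model_spec(path)
  expect_equal(sp2[setdiff(names(sp2), "chromatin")],
               sp[setdiff(names(sp), "chromatin")])
  expect_equal(unname(sp2$chromatin), unname(sp$chromatin))
})

test_that("build_network emits the expected reactions", {
  # minimal constitutive scheme: synthesis, export, decay
  n1 <- build_network(model_spec(1, 1, 1, 2, 4, k_D = 1,
                                 time_unit = "absolute"))
  expect_equal(ncol(n1$stoich), 3)
  expect_setequal(n1$species, c("U1", "MN", "MC1"))
  # S = 3, R = 3: 2 remodeling + synthesis + export + 3 decay
  n3 <- build_network(model_spec(3, 3, 10, 10, 5))
  expect_equal(ncol(n3$stoich), 7)
  expect_equal(sum(n3$role == "remodel"), 2)
  expect_equal(sum(n3$role == "decay"), 3)
  # telegraph: + opening and closing
  nt <- build_network(model_spec(1, 1, 1, 1, 1, k_D = 1,
                                 chromatin = c(1, 1),
                                 time_unit = "absolute"))
  expect_equal(ncol(nt$stoich), 5)
  expect_true("U0" %in% nt$species)
  # promoter states are conserved by every reaction
  for (net in list(n1, n3, nt)) {
    prom <- grep("^U", net$species)
    expect_true(all(colSums(net$stoich[prom, , drop = FALSE]) == 0))
  }
})

test_that("single-step synthesis gives exactly Poissonian moments", {
  # product-form invariance: any R, any rates
  for (R in c(1L, 2L, 4L)) {
    sp <- model_spec(1, R, 1, 10^runif(1, -1, 1), 10^runif(1, -1, 1))
    m <- steady_state_moments(sp)
    expect_equal(m$fano_nuclear, 1, tolerance = 1e-8)
    expect_equal(m$fano_cytoplasmic, 1, tolerance = 1e-8)
    expect_lt(abs(m$cov_nuc_cyto), 1e-8)
  }
})

test_that("moment solutions are internally consistent", {
  set.seed(42)
  for (i in 1:6) {
    sp <- random_spec(telegraph = i %% 3 == 0)
    m <- steady_state_moments(sp)
    sp_names <- rownames(m$second_moments)
    prom <- grep("^U", sp_names)
    mc <- grep("^MC", sp_names)
    mn <- match("MN", sp_names)
    # promoter occupancies are probabilities summing to one
    expect_equal(sum(m$means[prom]), 1, tolerance = 1e-9)
    expect_true(all(m$means > -1e-12))
    # symmetric PSD covariance
    expect_equal(m$second_moments, t(m$second_moments))
    expect_gt(min(eigen(m$second_moments, symmetric = TRUE,
                        only.values = TRUE)$values), -1e-8)
    # derived ratios match the matrix entries
    expect_equal(m$fano_nuclear,
                 m$second_moments[mn, mn] / m$means[[mn]])
    expect_equal(m$fano_cytoplasmic,
                 sum(m$second_moments[mc, mc]) / sum(m$means[mc]))
    expect_equal(m$cov_nuc_cyto, sum(m$second_moments[mn, mc]))
  }
})

test_that("mean_expression matches the renewal closed form and the solver", {
  expect_equal(mean_expression(model_spec(1, 1, 1, 2, 4, k_D = 1,
                                          time_unit = "absolute")),
               c(nuclear = 0.5, cytoplasmic = 2))
  # S = 3, k_A = k_B = 10: lambda = 1 / (2/10 + 1/10) = 10/3
  sp <- model_spec(3, 3, 10, 10, 5)
  me <- mean_expression(sp)
  expect_equal(unname(me["cytoplasmic"]), 10 / 3, tolerance = 1e-12)
  m <- steady_state_moments(sp)
  expect_equal(m$mean_nuclear, unname(me["nuclear"]), tolerance = 1e-9)
  expect_equal(m$mean_cytoplasmic, unname(me["cytoplasmic"]),
               tolerance = 1e-9)
  # extra steps vanish as k_A -> infinity
  fast <- mean_expression(model_spec(2, 1, 1e9, 3, 1, k_D = 1,
                                     time_unit = "absolute"))
  expect_equal(unname(fast["cytoplasmic"]), 3, tolerance = 1e-6)
  expect_error(mean_expression(model_spec(1, 1, 1, 1, 1, k_D = 1,
                                          chromatin = c(1, 1),
                                          time_unit = "absolute")),
               "chromatin")
})

test_that("rescaling all rates leaves Fano factors and covariance unchanged", {
  set.seed(5)
  sp <- model_spec(3, 2, 4, 7, 2, k_D = 3, time_unit = "absolute")
  m1 <- steady_state_moments(sp)
  for (f in c(0.1, 13)) {
    sp2 <- model_spec(3, 2, 4 * f, 7 * f, 2 * f, k_D = 3 * f,
                      time_unit = "absolute")
    m2 <- steady_state_moments(sp2)
    expect_equal(m2$fano_nuclear, m1$fano_nuclear, tolerance = 1e-9)
    expect_equal(m2$fano_cytoplasmic, m1$fano_cytoplasmic, tolerance = 1e-9)
    expect_equal(m2$cov_nuc_cyto, m1$cov_nuc_cyto, tolerance = 1e-9)
  }
})

test_that("covariance sign tracks the cytoplasmic noise regime", {
  set.seed(31)
  for (i in 1:60) {
    sp <- random_spec(multi_step = TRUE)          # sub-Poissonian
    m <- steady_state_moments(sp)
    expect_lt(m$fano_cytoplasmic, 1 + 1e-9)
    expect_lt(m$cov_nuc_cyto, 0)
    sp <- random_spec(telegraph = TRUE)           # super-Poissonian
    m <- steady_state_moments(sp)
    expect_gt(m$fano_cytoplasmic, 1 - 1e-9)
    expect_gt(m$cov_nuc_cyto, 0)
  }
})
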