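test_that("mixed-connective aggregation interpolates between t-norm and t-conorm", {
  expect_equal(aggregate_gad(c(0.8, 0.6), alpha = 1), 0.6)
  expect_equal(aggregate_gad(c(0.8, 0.6), alpha = 0), 0.8)
  expect_equal(aggregate_gad(c(0.8, 0.6), alpha = 0.5), 0.7)
  expect_equal(aggregate_gad(c(0.3, 0.9), alpha = 1, "prodprobsum"), 0.27)
  expect_equal(aggregate_gad(c(0.3, 0.9), alpha = 0, "prodprobsum"),
               1 - 0.7 * 0.1)
  # missing MADs are excluded (aggregation over present probes)
  expect_equal(aggregate_gad(c(0.8, NA, 0.6), alpha = 1), 0.6)
  expect_error(aggregate_gad(numeric(0), 0.5), "empty")
  expect_error(aggregate_gad(NA_real_, 0.5), "empty")
  expect_error(aggregate_gad(c(0.5, 1.2), 0.5), "\\[0, 1\\]")
  expect_error(aggregate_gad(0.5, 1.5), "alpha")
})

test_that("aggregation matches a brute-force recomputation on random MAD vectors", {
  set.seed(99)
  for (i in 1:50) {
    m <- runif(sample(1:20, 1))
    a <- runif(1)
    expect_equal(aggregate_gad(m, a, "minmax"),
                 a * min(m) + (1 - a) * max(m), tolerance = 1e-12)
    expect_equal(aggregate_gad(m, a, "prodprobsum"),
                 a * prod(m) + (1 - a) * (1 - prod(1 - m)), tolerance = 1e-12)
  }
  # GAD convexity for min/max at every alpha
  set.seed(100)
  for (i in 1:20) {
    m <- runif(sample(1:15, 1))
    a <- runif(1)
    g <- aggregate_gad(m, a)
    expect_gte(g, min(m))
    expect_lte(g, max(m))
  }
})

test_that("MADs delegate to the model's membership family", {
  mod <- one_probe_model(0.5, 0.5)
  expect_equal(unname(compute_mads(c(pr = 0.37), mod, "fMG1")), 0.5)
  mod2 <- one_probe_model(0.8, 0.2)
  expect_equal(compute_mads(c(pr = 1), mod2, "fMG3"),
               c(pr = membership_binomial(1, 0.2)))
  expect_error(compute_mads(c(other = 0.5), mod, "fMG1"), "no model probes")

  # at the class prototype, gaussian MADs are all 1
  co <- make_separable_cohort(seed = 12)
  mg <- lamda_fit(co$expr, co$classes, family = "gaussian", alpha = 1)
  proto <- mg$params$params$fMG3$mu
  expect_equal(unname(compute_mads(proto, mg, "fMG3")),
               rep(1, length(proto)))
})

test_that("the molecular grade score follows the normalized fMG3 membership and its decision rules", {
  # memberships 0.8 / 0.2 -> score 0.2, grade 1-like
  m <- one_probe_model(0.8, 0.2)
  x <- matrix(1, 1, 1, dimnames = list("pr", "t1"))
  call <- classify_samples(m, x)
  expect_equal(call$score, 0.2)
  expect_identical(call$label, "fMG1")
  expect_false(call$equivocal)

  # boundary 0.5 is grade 3-like (inclusive) and equivocal
  call <- classify_samples(one_probe_model(0.6, 0.6), x)
  expect_equal(call$score, 0.5)
  expect_identical(call$label, "fMG3")
  expect_true(call$equivocal)

  # 0.49 -> fMG1 and equivocal; 0.52 equivocal but fMG3; 0.525 not equivocal
  call <- classify_samples(one_probe_model(0.51, 0.49), x)
  expect_equal(call$score, 0.49)
  expect_identical(call$label, "fMG1")
  expect_true(call$equivocal)
  call <- classify_samples(one_probe_model(0.48, 0.52), x)
  expect_equal(call$score, 0.52)
  expect_identical(call$label, "fMG3")
  expect_true(call$equivocal)
  call <- classify_samples(one_probe_model(0.475, 0.525), x)
  expect_false(call$equivocal)
})

test_that("swapping the class prototypes maps the score to its complement", {
  co <- make_separable_cohort(seed = 13)
  mod <- lamda_fit(co$expr, co$classes, alpha = 0.8)
  swapped <- mod
  swapped$params$params <- swapped$params$params[c("fMG3", "fMG1")]
  names(swapped$params$params) <- c("fMG1", "fMG3")
  s1 <- classify_samples(mod, co$expr)$score
  s2 <- classify_samples(swapped, co$expr)$score
  expect_equal(s2, 1 - s1, tolerance = 1e-12)
})

test_that("zero total GAD degrades to an equivocal 0.5 score with a warning", {
  # gaussian memberships underflow to 0 far from both class centers
  bounds <- structure(list(min = c(pr = 0), max = c(pr = 1),
                           degenerate = c(pr = FALSE)),
                      class = "standardization_bounds")
  params <- structure(list(family = "gaussian", classes = c("fMG1", "fMG3"),
                           params = list(fMG1 = list(mu = c(pr = 0), sigma = c(pr = 0.01)),
                                         fMG3 = list(mu = c(pr = 0.02), sigma = c(pr = 0.01)))),
                      class = "membership_params")
  mod <- structure(list(probes = "pr", family = "gaussian",
                        connective = "minmax", alpha = 1, nic = FALSE,
                        bounds = bounds, params = params,
                        classes = c("fMG1", "fMG3")),
                   class = "lamda_model")
  x <- matrix(1, 1, 1, dimnames = list("pr", "t1"))
  expect_warning(call <- classify_samples(mod, x), "zero total GAD")
  expect_equal(call$score, 0.5)
  expect_true(call$equivocal)
})

test_that("classification is frozen and deterministic, tolerates limited missing probes, refuses beyond the cap", {
  sim <- simulate_cohort(sim_config(n_grade1 = 15, n_grade3 = 15, n_grade2 = 5,
                                    n_informative = 10, n_noise = 40, seed = 31))
  keep <- sim$labels$grade %in% c("1", "3")
  mod <- lamda_fit(sim$expr[, keep], sim$labels$grade[keep],
                   probes = sim$truth$informative_probes)
  before <- unserialize(serialize(mod, NULL))
  c1 <- classify_samples(mod, sim$expr)
  c2 <- classify_samples(mod, sim$expr)
  expect_identical(c1, c2)
  expect_identical(mod, before)  # model not mutated by classification

  # one of ten probes absent: message + renormalized aggregation
  x_miss <- sim$expr[setdiff(rownames(sim$expr), mod$probes[1]), ]
  expect_message(cm <- classify_samples(mod, x_miss), "1 of 10")
  expect_equal(nrow(cm), ncol(sim$expr))
  # 3 of 10 absent exceeds the 20% cap
  x_bad <- sim$expr[setdiff(rownames(sim$expr), mod$probes[1:3]), ]
  expect_error(classify_samples(mod, x_bad), "missing")
})

test_that("the non-informative class flags calls weaker than the flat 0.5 profile", {
  mod <- one_probe_model(0.9, 0.1)
  mod$nic <- TRUE
  # x = 1: MAD 0.9 to fMG1 beats the 0.5 NIC profile -> confident
  strong <- classify_samples(mod, matrix(1, 1, 1, dimnames = list("pr", "a")))
  expect_false(strong$low_confidence)
  # x = 0.5: both MADs sqrt(0.9 * 0.1) ~= 0.3 < 0.5 -> low confidence
  weak <- classify_samples(mod, matrix(0.5, 1, 1, dimnames = list("pr", "b")))
  expect_true(weak$low_confidence)
  # NIC off by default: no column
  expect_false("low_confidence" %in%
                 names(classify_samples(one_probe_model(0.9, 0.1),
                                        matrix(0.5, 1, 1,
                                               dimnames = list("pr", "c")))))
})

test_that("alpha grid search picks the resubstitution-optimal exigency, ties to the stricter value", {
  co <- make_separable_cohort(seed = 15)
  mod <- lamda_fit(co$expr, co$classes)
  expect_true(mod$alpha %in% seq(0.5, 1, 0.1))
  # separable data is classified perfectly at every alpha -> tie -> alpha = 1
  expect_equal(mod$alpha, 1)
  expect_error(lamda_fit(co$expr, co$classes, alpha = 2), "alpha")
  expect_error(lamda_fit(co$expr, co$classes, probes = character(0)),
               "non-empty")
})

test_that("model and call serialization round-trip", {
  co <- make_separable_cohort(seed = 16)
  mod <- lamda_fit(co$expr, co$classes)
  path <- withr::local_tempfile(fileext = ".json")
  write_signature(mod, path)
  mod2 <- read_signature(path)
  expect_equal(classify_samples(mod2, co$expr), classify_samples(mod, co$expr))

  calls <- classify_samples(mod, co$expr)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_calls(calls, tsv)
  df <- read.delim(tsv)
  expect_identical(names(df),
                   c("sample_id", "gad1", "gad3", "score", "label", "equivocal"))
  expect_equal(df$score, calls$score, tolerance = 1e-12)
})
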