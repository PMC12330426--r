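test_that("BAG is exactly predicted minus chronological with a strict join", {
  ph <- data.frame(subject_id = c("a", "b"), age = c(45, 50),
                   sex = c("F", "M"), site = c(1, 2), diagnosis = c(0, 1))
  pred <- data.frame(subject_id = c("a", "b"), predicted_age = c(50, 50))
  b <- compute_bag(pred, ph)
  expect_equal(b$bag[b$subject_id == "a"], 5)
  expect_equal(b$bag[b$subject_id == "b"], 0)
  expect_equal(nrow(b), 2)
  pred2 <- data.frame(subject_id = c("a", "zz"), predicted_age = c(1, 2))
  expect_error(compute_bag(pred2, ph), "zz")
  expect_error(compute_bag(data.frame(subject_id = "a"), ph),
               "predicted_age")
})

test_that("age-bias correction undoes prediction shrinkage", {
  set.seed(80)
  n <- 500
  age <- runif(n, 30, 70)
  dx <- rbinom(n, 1, 0.4)
  true_bag <- 7 * dx + rnorm(n, sd = 2)
  # a shrunk predictor: slope 0.7 towards the mean, plus offset
  pred <- 15 + 0.7 * (age + true_bag) + rnorm(n, sd = 0.5)
  ph <- data.frame(subject_id = sprintf("S%03d", 1:n), age = age,
                   sex = "F", site = 1, diagnosis = dx)
  pr <- data.frame(subject_id = ph$subject_id, predicted_age = pred)
  raw <- compute_bag(pr, ph)
  corr <- compute_bag(pr, ph, bias_correct = TRUE, reference = dx == 0)
  d_raw <- mean(raw$bag[dx == 1]) - mean(raw$bag[dx == 0])
  d_corr <- mean(corr$bag[dx == 1]) - mean(corr$bag[dx == 0])
  expect_equal(d_raw, 0.7 * 7, tolerance = 0.5)
  expect_equal(d_corr, 7, tolerance = 0.5)
  # corrected BAG no longer depends on age among controls
  expect_lt(abs(cor(corr$bag[dx == 0], age[dx == 0])), 0.1)
})

test_that("the association GLM is exact in the noiseless linear case", {
  set.seed(81)
  d <- synth_bag_table(100, slope = 0)
  d$attention <- 2 * d$bag
  res <- suppressWarnings(   # lm flags the essentially perfect fit
    fit_association_glm(d, "attention", glm_design(age_filter_min = NULL)))
  expect_equal(res$beta, 2, tolerance = 1e-8)
  expect_lt(res$p, 1e-12)
  expect_gt(res$partial_r, 0.999)
  expect_equal(res$n, 100)
  expect_equal(sign(res$partial_r), sign(res$beta))
  expect_equal(unname(res$ci_low), res$beta - qt(0.975, res$df) * res$se)
})

test_that("the age filter restricts the analysis sample", {
  set.seed(82)
  d <- synth_bag_table(200, slope = -0.5)
  d$age <- runif(200, 20, 60)
  res <- fit_association_glm(d, "attention", glm_design(age_filter_min = 38))
  expect_equal(res$n, sum(d$age > 38))
  expect_lt(res$n, 200)
})

test_that("type-I error of the BAG test is nominal under the null", {
  set.seed(83)
  reps <- 200
  p <- vapply(seq_len(reps), function(i) {
    d <- synth_bag_table(120, slope = 0)
    fit_association_glm(d, "attention", glm_design(age_filter_min = NULL))$p
  }, numeric(1))
  rate <- mean(p < 0.05)
  expect_gte(rate, 0.02)
  expect_lte(rate, 0.09)
})

test_that("a planted partial correlation is recovered at n = 150", {
  g <- run_glm_recovery(seed = 84, n_reps = 60)
  expect_equal(g$mean_r, -0.3, tolerance = 0.1)
  expect_gte(g$sign_rate, 0.95)
})

test_that("BH adjustment matches the hand-applied step-up rule", {
  expect_equal(fdr_correct(0.03), 0.03)
  expect_equal(fdr_correct(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_correct(rep(1, 5)), rep(1, 5))
  set.seed(85)
  for (i in 1:20) {
    p <- runif(sample(2:12, 1))
    adj <- fdr_correct(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_true(all(adj >= p))
    expect_equal(order(adj[order(p)]), seq_along(p))  # monotone in p
  }
  expect_error(fdr_correct(c(0.1, 1.2)), "0, 1")
  expect_error(fdr_correct(c(0.1, -0.2)), "0, 1")
})

test_that("the association suite applies FDR within the declared families", {
  set.seed(86)
  nets <- c("SCN", "AUD", "SMN", "VSN", "CCN", "DMN", "CBN")
  tabs <- list()
  for (mod in c("sfnc", "dfnc")) {
    tabs[[length(tabs) + 1]] <- synth_bag_table(120, scope = "wide",
                                                modality = mod)
    for (net in nets)
      tabs[[length(tabs) + 1]] <- synth_bag_table(120, scope = net,
                                                  modality = mod)
  }
  res <- run_association_suite(tabs, design = glm_design(age_filter_min = NULL))
  sub <- res[res$family == "subnetwork" & res$outcome == "attention", ]
  expect_equal(nrow(sub), 14)            # 7 networks x 2 modalities
  wide <- res[res$family == "wide" & res$outcome == "attention", ]
  expect_equal(nrow(wide), 2)
  expect_true(all(res$p_fdr >= res$p))
  # single-test family: adjusted equals raw
  res1 <- run_association_suite(list(synth_bag_table(120, scope = "SCN")),
                                outcomes = "attention",
                                design = glm_design(age_filter_min = NULL))
  expect_equal(res1$p_fdr, res1$p)
  expect_error(run_association_suite(tabs, outcomes = "absent_score",
                                     design = glm_design(NULL)),
               "absent_score")
})

test_that("only networks carrying signal survive FDR", {
  set.seed(87)
  hits <- 0; reps <- 10
  nets <- c("SCN", "AUD", "SMN", "VSN", "CCN", "DMN", "CBN")
  for (i in seq_len(reps)) {
    tabs <- lapply(nets, function(net)
      synth_bag_table(150, slope = if (net == "SCN") -1.2 else 0,
                      scope = net, modality = "sfnc", noise_sd = 3))
    res <- run_association_suite(tabs, outcomes = "attention",
                                 design = glm_design(age_filter_min = NULL))
    scn_sig <- res$significant[res$scope == "SCN"]
    null_sig <- res$significant[res$scope != "SCN"]
    if (scn_sig && !any(null_sig)) hits <- hits + 1
  }
  expect_gte(hits, 9)
})

test_that("confidence intervals and p-values are two-sided consistent", {
  set.seed(88)
  for (i in 1:30) {
    d <- synth_bag_table(100, slope = runif(1, -0.6, 0.6))
    res <- fit_association_glm(d, "working_memory",
                               glm_design(age_filter_min = NULL))
    excludes_zero <- res$ci_low > 0 || res$ci_high < 0
    expect_equal(excludes_zero, res$p < 0.05)
    expect_equal(sign(res$partial_r), sign(res$beta))
  }
})
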