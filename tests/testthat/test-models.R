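test_that("analytic gradients match finite differences (graph convolution)", {
  set.seed(51)
  spec <- model_spec("graph_conv", graph_layer_sizes = c(4, 3))
  Ms <- lapply(1:3, function(i) rand_corr(6))
  y <- rnorm(3)
  params <- connage:::gcn_init(spec, c(6, 6))
  lg <- connage:::gcn_loss_grad(params, Ms, y, spec)
  for (nm in names(params)) {
    idx <- 1L
    eps <- 1e-6
    p1 <- params; p2 <- params
    p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2[[nm]][idx] <- p2[[nm]][idx] - eps
    num <- (connage:::gcn_loss_grad(p1, Ms, y, spec)$loss -
            connage:::gcn_loss_grad(p2, Ms, y, spec)$loss) / (2 * eps)
    expect_equal(lg$grads[[nm]][idx], num, tolerance = 1e-5)
  }
})

test_that("analytic gradients match finite differences (bidirectional LSTM)", {
  set.seed(52)
  spec <- model_spec("bilstm", hidden_units = 5, recurrent_layers = 2,
                     dropout = 0)
  seqs <- lapply(1:3, function(i) matrix(rnorm(7 * 4), 7, 4))
  y <- rnorm(3)
  params <- connage:::lstm_init(spec, c(7, 4))
  lg <- connage:::lstm_loss_grad(params, seqs, y, spec)
  for (nm in names(params)) {
    idx <- min(3L, length(params[[nm]]))
    eps <- 1e-6
    p1 <- params; p2 <- params
    p1[[nm]][idx] <- p1[[nm]][idx] + eps
    p2[[nm]][idx] <- p2[[nm]][idx] - eps
    num <- (connage:::lstm_loss_grad(p1, seqs, y, spec)$loss -
            connage:::lstm_loss_grad(p2, seqs, y, spec)$loss) / (2 * eps)
    expect_equal(lg$grads[[nm]][idx], num, tolerance = 1e-5)
  }
})

test_that("ridge recovers a noiseless linear age signal", {
  set.seed(60)
  n <- 300; p <- 50
  X <- matrix(rnorm(n * p), n)
  beta <- rnorm(p)
  age <- 60 + drop(X %*% beta)
  fit <- train_predictor(X, age, model_spec("ridge", ridge_penalty = 1e-4),
                         training_config(folds = 5, seed = 2))
  expect_gte(mean(fit$training$fold_r), 0.99)
  expect_lt(mean(abs(predict_age(fit, X) - age)), 0.5)
})

test_that("permuted labels yield null validation performance", {
  set.seed(61)
  n <- 200; p <- 40
  X <- matrix(rnorm(n * p), n)
  age <- runif(n, 20, 80)
  fit <- train_predictor(X, sample(age), model_spec("ridge"),
                         training_config(folds = 5, seed = 3))
  expect_lt(abs(mean(fit$training$fold_r)), 0.15)
})

test_that("prediction is deterministic, order-invariant and shape-checked", {
  set.seed(62)
  n <- 80; p <- 10
  X <- matrix(rnorm(n * p), n)
  age <- 50 + X[, 1] * 5 + rnorm(n)
  fit <- train_predictor(X, age, model_spec("ridge"),
                         training_config(folds = 4, seed = 5))
  # duplicated rows get identical predictions
  pr <- predict_age(fit, X[c(1, 1, 2), ])
  expect_identical(pr[1], pr[2])
  # permutation invariance
  perm <- sample(n)
  expect_equal(predict_age(fit, X[perm, ]), predict_age(fit, X)[perm])
  expect_error(predict_age(fit, X[, 1:5]), "expected 10")
})

test_that("neural training is seed-reproducible and fold-leakage-free", {
  set.seed(63)
  n <- 60
  seqs <- lapply(1:n, function(i) matrix(rnorm(5 * 4), 5, 4))
  age <- runif(n, 30, 70)
  spec <- model_spec("bilstm", hidden_units = 4, recurrent_layers = 1,
                     dropout = 0)
  cfg <- training_config(epochs = 3, folds = 3, batch_size = 16, seed = 9)
  a <- train_predictor(seqs, age, spec, cfg, modality = "dfnc")
  b <- train_predictor(seqs, age, spec, cfg, modality = "dfnc")
  expect_identical(a$params, b$params)
  expect_identical(a$training$fold_mae, b$training$fold_mae)
  # folds partition the subjects
  expect_equal(sort(unique(a$training$fold_id)), 1:3)
  expect_length(a$training$fold_id, n)
  # multi-scan subjects stay within one fold
  ids <- rep(sprintf("P%02d", 1:20), each = 3)
  c2 <- train_predictor(seqs, age, spec, cfg, subject_ids = ids,
                        modality = "dfnc")
  spans <- tapply(c2$training$fold_id, ids, function(f) length(unique(f)))
  expect_true(all(spans == 1))
})

test_that("evaluate_predictions reports r and MAE with degenerate handling", {
  expect_equal(evaluate_predictions(1:10, 1:10), list(r = 1, mae = 0))
  ev <- evaluate_predictions(1:10 + 5, 1:10)
  expect_equal(ev$r, 1); expect_equal(ev$mae, 5)
  set.seed(64)
  a <- rnorm(50); b <- rnorm(50)
  ev2 <- evaluate_predictions(a, b)
  expect_equal(ev2$r, oracle_pearson(a, b), tolerance = 1e-12)
  expect_equal(ev2$mae, mean(abs(a - b)), tolerance = 1e-12)
  expect_warning(ev3 <- evaluate_predictions(rep(5, 10), 1:10), "constant")
  expect_true(is.na(ev3$r))
  expect_equal(ev3$mae, mean(abs(5 - 1:10)))
})

test_that("sub-network models localize a network-restricted aging signal", {
  cfg <- cohort_config(n_subjects = 150, n_components = 12, n_frames = 200,
                       aging_slope = 0.008, n_states = 1,
                       aging_edge_fraction = 0.5, seed = 71)
  atlas <- make_atlas(paste0("IC", 1:12), rep(c("SCN", "DMN"), each = 6))
  # restrict the aging mask to within-SCN edges only
  probe <- simulate_cohort(cohort_config(n_subjects = 1, n_components = 12,
                                         n_frames = 2, seed = cfg$seed))
  shared <- probe$structure
  mask <- matrix(0, 12, 12)
  mask[1:6, 1:6] <- 1; diag(mask) <- 0
  shared$edge_mask <- mask
  shared$state_offsets <- list(matrix(0, 12, 12))
  co <- simulate_cohort(cfg, shared = shared)
  sfncs <- lapply(lapply(co$timecourses, prep_timecourses), static_fnc)
  models <- build_subnetwork_models(sfncs, co$phenotypes$age, atlas,
                                    model_spec("ridge"),
                                    training_config(folds = 5, seed = 8),
                                    modality = "sfnc")
  expect_named(models, c("SCN", "DMN"))
  r_scn <- mean(models$SCN$training$fold_r)
  r_dmn <- mean(models$DMN$training$fold_r)
  expect_gt(r_scn, 0.6)
  expect_lt(abs(r_dmn), 0.35)
  expect_gt(r_scn, r_dmn)
})

test_that("seven networks yield seven sub-network models", {
  cfg <- cohort_config(n_subjects = 40, n_components = 14, n_frames = 80,
                       seed = 72)
  co <- simulate_cohort(cfg)
  atlas <- synthetic_atlas(14)
  sfncs <- lapply(co$timecourses, static_fnc)
  models <- build_subnetwork_models(sfncs, co$phenotypes$age, atlas,
                                    model_spec("ridge"),
                                    training_config(folds = 4, seed = 2),
                                    modality = "sfnc")
  expect_length(models, 7)
  expect_setequal(names(models), atlas_networks(atlas))
  expect_true(all(vapply(models, inherits, logical(1), "trained_predictor")))
})
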