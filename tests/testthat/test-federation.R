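test_that("client updates honour E = 0 and zero learning rate contracts", {
  ds <- small_federation_data(K = 1, n = 12)[[1]]
  model <- build_unet(1, 4, 2, 8, seed = 3)
  spec <- classify_parameters(model, "paf_fed")
  state <- freqfed:::init_client(1, model, ds, base_seed = 3)
  cfg <- round_config(K = 1, T = 1, E = 1, B = 4, lr = 1e-3,
                      strategy = "paf_fed", base_seed = 3)

  # E = 0: the returned shared part is exactly the merged incoming one
  incoming <- split_weights(model, spec)$W_R
  incoming <- lapply(incoming, function(w) { w[] <- w + 0.1; w })
  up0 <- client_update(state, incoming, 0, cfg, spec)
  expect_identical(up0$W_R[names(incoming)], incoming)

  # lr = 0: trainable weights unchanged, BN running stats may move
  cfg0 <- round_config(K = 1, T = 1, E = 2, B = 4, lr = 0,
                       strategy = "paf_fed", base_seed = 3)
  upz <- client_update(state, NULL, 2, cfg0, spec)
  stats_roles <- c("bn_running_mean", "bn_running_var")
  for (nm in names(model$params)) {
    if (model$roles[[nm]] %in% stats_roles) next
    expect_identical(upz$state$model$params[[nm]], model$params[[nm]])
  }
  moved <- any(vapply(names(model$params)[model$roles %in% stats_roles],
                      function(nm) {
                        !identical(upz$state$model$params[[nm]],
                                   model$params[[nm]])
                      }, logical(1)))
  expect_true(moved)
})

test_that("local training reduces the fused loss on a fixed small client", {
  prof <- make_profiles(1, 0, seed = 2)[[1]]
  ds <- generate_dataset(prof, 10, seed = 6)   # 8 training samples
  model <- build_unet(1, 4, 2, 8, seed = 9)
  spec <- classify_parameters(model, "local")
  state <- freqfed:::init_client(1, model, ds, base_seed = 9)
  cfg <- round_config(K = 1, T = 1, E = 5, B = 8, lr = 1e-3,
                      strategy = "local", base_seed = 9, augment = FALSE)
  first <- client_update(state, NULL, 1, cfg, spec)
  rest <- client_update(first$state, NULL, 4, cfg, spec)
  expect_lt(rest$loss, first$loss)
})

test_that("T = 0 returns initialized models and an empty history", {
  dss <- small_federation_data(K = 2, n = 12)
  cfg <- round_config(K = 2, T = 0, E = 1, strategy = "fedavg",
                      base_seed = 5)
  res <- run_federation(cfg, dss)
  expect_identical(nrow(res$history), 0L)
  m0 <- build_unet(1, 4, 2, 8, seed = 5)
  expect_identical(res$states[[1]]$model$params, m0$params)
  expect_error(run_federation(cfg, dss[1]), "expected 2")
})

test_that("with one client the frequency strategy follows the local trajectory", {
  ds <- small_federation_data(K = 1, n = 12)
  cfg_p <- round_config(K = 1, T = 3, E = 1, B = 4, lr = 1e-3,
                        strategy = "paf_fed", base_seed = 11, eval_every = 0)
  cfg_l <- round_config(K = 1, T = 3, E = 1, B = 4, lr = 1e-3,
                        strategy = "local", base_seed = 11, eval_every = 0)
  res_p <- run_federation(cfg_p, ds)
  res_l <- run_federation(cfg_l, ds)
  expect_equal(res_p$history$loss, res_l$history$loss, tolerance = 1e-8)
  for (nm in names(res_l$states[[1]]$model$params)) {
    expect_lt(max(abs(res_p$states[[1]]$model$params[[nm]] -
                        res_l$states[[1]]$model$params[[nm]])), 1e-6)
  }
})

test_that("frequency aggregation at r = 1 with uniform weights reproduces FedAvg", {
  dss <- small_federation_data(K = 2, n = 12)
  cfg_avg <- round_config(K = 2, T = 3, E = 1, B = 4, lr = 1e-3,
                          strategy = "fedavg", base_seed = 13,
                          eval_every = 0)
  cfg_fft <- round_config(K = 2, T = 3, E = 1, B = 4, lr = 1e-3,
                          strategy = "paf_fed", partition = "fedavg",
                          attention = "uniform", r_mode = "fixed",
                          r_fixed = 1, base_seed = 13, eval_every = 0)
  res_a <- run_federation(cfg_avg, dss)
  res_f <- run_federation(cfg_fft, dss)
  expect_equal(res_a$history$loss, res_f$history$loss, tolerance = 1e-6)
  for (nm in names(res_a$states[[1]]$model$params)) {
    expect_lt(max(abs(res_a$states[[1]]$model$params[[nm]] -
                        res_f$states[[1]]$model$params[[nm]])), 1e-6)
  }
})

test_that("identical configs and seeds reproduce the history exactly", {
  dss <- small_federation_data(K = 2, n = 12)
  cfg <- round_config(K = 2, T = 2, E = 1, B = 4, lr = 1e-3,
                      strategy = "paf_fed", base_seed = 17, eval_every = 1)
  h1 <- run_federation(cfg, dss)$history
  h2 <- run_federation(cfg, dss)$history
  expect_identical(h1, h2)
})

test_that("personalized tensors never change during a communication round", {
  # E = 0 isolates the server round: whatever the server does, tensors
  # tagged personalized must come back bit-identical
  dss <- small_federation_data(K = 3, n = 12)
  for (strat in c("paf_fed", "fedrep", "silobn")) {
    cfg <- round_config(K = 3, T = 2, E = 0, strategy = strat,
                        base_seed = 19, eval_every = 0)
    res <- run_federation(cfg, dss)
    m0 <- build_unet(1, 4, 2, 8, seed = 19)
    spec <- classify_parameters(m0, cfg$partition)
    for (k in 1:3) {
      for (nm in names(m0$params)) {
        if (spec$param_class[[nm]] == "personalized") {
          expect_identical(res$states[[k]]$model$params[[nm]],
                           m0$params[[nm]])
        }
      }
    }
  }
})

test_that("evaluation scores a perfect predictor at DSC 1 and ASSD 0", {
  # toy client whose "model" is replaced by injecting its labels: use a
  # dataset with a single constant organ layout the net cannot miss is
  # brittle; instead evaluate the metric path directly on equal maps.
  prof <- make_profiles(1, 0, seed = 8)[[1]]
  ds <- generate_dataset(prof, 12, seed = 10)
  te <- freqfed:::dataset_split(ds, "test")
  for (i in seq_len(dim(te$y)[3])) {
    for (cl in 1:3) {
      d <- dsc(te$y[, , i], te$y[, , i], cl)
      a <- assd(te$y[, , i], te$y[, , i], cl)
      if (!is.na(d)) expect_identical(d, 1)
      if (!is.na(a)) expect_identical(a, 0)
    }
  }
})

test_that("report averages are the arithmetic means of their entries", {
  dss <- small_federation_data(K = 2, n = 12)
  cfg <- round_config(K = 2, T = 1, E = 1, B = 4, lr = 1e-3,
                      strategy = "fedavg", base_seed = 23, eval_every = 0)
  res <- run_federation(cfg, dss)
  rep <- evaluate_federation(res$states, split = "test")
  per <- rep$per_client_class
  for (k in unique(per$client)) {
    expect_equal(rep$client_avg$dsc[rep$client_avg$client == k],
                 mean(per$dsc[per$client == k], na.rm = TRUE))
  }
  expect_equal(rep$overall$dsc, mean(rep$client_avg$dsc, na.rm = TRUE))
})
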