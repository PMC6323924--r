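test_that("stage labels combine exhaustively to the five conformations", {
  expect_equal(combine_labels("in", "in"), "CIDI")
  expect_equal(combine_labels("out", "in"), "CIDO")
  expect_equal(combine_labels("in", "out"), "CODI")
  expect_equal(combine_labels("out", "out"), "CODO")
  expect_equal(combine_labels("intermediate", "in"), "wCD")
  expect_equal(combine_labels("intermediate", "out"), "wCD")
  expect_equal(combine_labels("intermediate", NA), "wCD")
  expect_error(combine_labels("sideways", "in"), "dfg_class")
  expect_error(combine_labels("in", "up"), "ac_class")

  # splitting a conformation inverts the combination
  confs <- c("CIDI", "CIDO", "CODI", "CODO", "wCD")
  sp <- kinconform:::split_conformation(confs)
  expect_equal(combine_labels(sp$dfg_class, sp$ac_class), confs)
})

test_that("imputation is the identity on complete tables", {
  tab <- random_descriptor_table(20, seed = 1)
  lab <- rep(c("A", "B"), 10)
  expect_equal(impute_missing(tab, lab), tab)
})

test_that("imputation restores the shared value among identical rows", {
  row <- as.list(setNames(c(4, 2, 7, 1, 3, 0.5, -120, 9), descriptor_names()))
  tab <- dplyr::bind_rows(replicate(12, tibble::as_tibble(row),
                                    simplify = FALSE))
  tab$d3_phe_proj_x[5] <- NA
  out <- impute_missing(tab, rep("X", 12), seed = 3)
  expect_equal(out$d3_phe_proj_x[5], 7, tolerance = 1e-9)
})

test_that("imputed values track the own-cluster mean", {
  dat <- make_descriptor_dataset(n_per_class = 40, separation = 3,
                                 missing_rate = 0.1, seed = 9)
  full <- make_descriptor_dataset(n_per_class = 40, separation = 3,
                                  missing_rate = 0, seed = 9)
  out <- impute_missing(dat, dat$conformation, seed = 9)
  centroids <- full |>
    dplyr::group_by(conformation) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(descriptor_names()), mean))
  err_own <- c(); err_other <- c()
  for (d in descriptor_names()) {
    miss <- which(is.na(dat[[d]]))
    for (i in miss) {
      own <- centroids[[d]][centroids$conformation == dat$conformation[i]]
      other <- centroids[[d]][centroids$conformation != dat$conformation[i]]
      err_own <- c(err_own, abs(out[[d]][i] - own))
      err_other <- c(err_other, min(abs(out[[d]][i] - other)))
    }
  }
  expect_lt(mean(err_own), mean(err_other))
})

test_that("a fully-missing column cannot be imputed", {
  tab <- random_descriptor_table(10, seed = 2)
  tab$d5_phe_proj_z <- NA_real_
  expect_error(impute_missing(tab, rep("A", 10)), "fully-missing")
})

test_that("training is deterministic given data and seed", {
  dat <- make_descriptor_dataset(n_per_class = 15, separation = 2, seed = 4,
                                 missing_rate = 0.05)
  m1 <- train_conformation_forest(dat, n_trees = 100, seed = 11)
  m2 <- train_conformation_forest(dat, n_trees = 100, seed = 11)
  probe <- random_descriptor_table(5, seed = 12)
  expect_equal(predict(m1, probe), predict(m2, probe))
  expect_equal(m1$oob, m2$oob)
})

test_that("training errors on degenerate class structure", {
  dat <- make_descriptor_dataset(n_per_class = 10, separation = 2, seed = 5)
  only_in <- dat[dat$dfg_class == "in", ]
  expect_error(train_conformation_forest(only_in[only_in$ac_class == "in", ],
                                         n_trees = 50),
               "at least two")
  expect_error(train_conformation_forest(dplyr::select(dat, -conformation,
                                                       -dfg_class, -ac_class)),
               "conformation")
})

test_that("class probabilities sum to one and pick the centroid class", {
  dat <- make_descriptor_dataset(n_per_class = 30, separation = 3, seed = 6)
  centro <- dat |>
    dplyr::group_by(conformation) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(descriptor_names()), mean))
  for (seed in 1:10) {
    m <- train_conformation_forest(dat, n_trees = 150, seed = seed)
    pred <- predict(m, centro)
    psum <- pred$p_cidi + pred$p_cido + pred$p_codi + pred$p_codo + pred$p_wcd
    expect_equal(psum, rep(1, 5), tolerance = 1e-9)
    expect_equal(pred$label, centro$conformation)
  }
})

test_that("an all-missing vector still yields a normalized prediction", {
  dat <- make_descriptor_dataset(n_per_class = 15, separation = 3, seed = 7)
  m <- train_conformation_forest(dat, n_trees = 100, seed = 1)
  probe <- random_descriptor_table(1, seed = 1)
  probe[1, ] <- NA_real_
  pred <- predict(m, probe)
  expect_true(pred$low_confidence)
  expect_equal(pred$p_cidi + pred$p_cido + pred$p_codi + pred$p_codo +
                 pred$p_wcd, 1, tolerance = 1e-9)
})

test_that("duplicating every row does not worsen the out-of-bag error", {
  dat <- make_descriptor_dataset(n_per_class = 20, separation = 1, seed = 8)
  m1 <- train_conformation_forest(dat, n_trees = 300, seed = 2)
  m2 <- train_conformation_forest(dplyr::bind_rows(dat, dat),
                                  n_trees = 300, seed = 2)
  expect_lte(m2$oob$overall, m1$oob$overall + 0.02)
})

test_that("stage 2 leans on the DFG-class feature when it is informative", {
  # descriptors pure noise; the alphaC state depends only on the DFG class
  set.seed(31)
  n <- 120
  tab <- random_descriptor_table(n, seed = 31)
  dfg <- rep(c("in", "out"), each = n / 2)
  ac <- ifelse(dfg == "in", "in", "out")
  tab$dfg_class <- dfg
  tab$ac_class <- ac
  m <- train_conformation_forest(tab, n_trees = 200, seed = 3)
  imp <- tidy(m)
  dfg_imp <- sum(imp$importance[imp$stage == "alphac" &
                                  imp$term %in% c("dfg_in", "dfg_out",
                                                  "dfg_intermediate")])
  expect_gt(dfg_imp, 0)
  expect_lt(m$oob$stage2, 0.05)
})

test_that("model archives round-trip and refuse version mismatches", {
  dat <- make_descriptor_dataset(n_per_class = 10, separation = 3, seed = 10)
  m <- train_conformation_forest(dat, n_trees = 50, seed = 1)
  path <- tempfile(fileext = ".rds")
  save_conf_forest(m, path)
  m2 <- load_conf_forest(path)
  probe <- random_descriptor_table(3, seed = 13)
  expect_equal(predict(m2, probe), predict(m, probe))
  bad <- m
  bad$version <- 99L
  saveRDS(bad, path)
  expect_error(load_conf_forest(path), "version")
})
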