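make_gaussian_dataset <- function(n_per_class = 60, sep = 1, noise = 0.02,
                                  seed = 900, n_subjects = 3) {
  # feature rows built directly: one spectral bump per class + noise,
  # renormalized like real decoding features
  set.seed(seed)
  centers <- c(`ACC-control` = 10, `HPC-control` = 20,
               `ACC-STZ` = 30, `HPC-STZ` = 40)
  feats <- NULL; labs <- NULL; subj <- NULL; sess <- NULL
  for (cl in names(centers)) {
    mu <- exp(-((1:50) - centers[[cl]])^2 / 18) * sep + 0.5
    m <- matrix(pmax(0, rep(mu, each = n_per_class) +
                        rnorm(n_per_class * 50, 0, noise)),
                nrow = n_per_class)
    feats <- rbind(feats, m / rowSums(m))
    labs <- c(labs, rep(cl, n_per_class))
    subj <- c(subj, paste0(sub(".*-", "", cl),
                           rep(seq_len(n_subjects), length.out = n_per_class)))
    sess <- c(sess, paste0(sub(".*-", "", cl),
                           rep(seq_len(n_subjects * 2), length.out = n_per_class)))
  }
  structure(list(features = feats,
                 labels = factor(labs, levels = thetadyn:::PHENOTYPE_CLASSES),
                 subject_id = subj, session_id = sess,
                 feature_range = c(1, 50)),
            class = "phenotype_dataset")
}

test_that("the dataset builder restricts, renormalizes and aligns features", {
  coh <- separable_cohort()
  ds <- separable_dataset()
  expect_equal(dim(ds$features), c(length(coh) * 16, 50))
  expect_equal(unname(rowSums(ds$features)), rep(1, nrow(ds$features)),
               tolerance = 1e-9)
  expect_equal(as.vector(table(ds$labels)), rep(length(coh) * 4, 4))

  # two leads with identical spectra give identical feature rows
  s <- coh[[1]]
  prof <- session_spectral_profile(s)
  sp <- prof$spectra
  sp[[2]] <- sp[[1]]; sp[[2]]$lead_id <- s$leads$lead_id[2]
  ds2 <- build_phenotype_dataset(sp, s$leads)
  expect_identical(ds2$features[1, ], ds2$features[2, ])
})

test_that("a separable cohort decodes almost perfectly and improves with training size", {
  ds <- separable_dataset()
  sw <- training_size_sweep(ds, sizes = c(5, 15, 40), n_iter = 40, seed = 3,
                            posterior = TRUE)
  means <- sapply(sw, function(s) mean(s$accuracy))
  ses <- sapply(sw, function(s) sd(s$accuracy) / sqrt(length(s$accuracy)))
  expect_gt(means[["40"]], 0.95)
  # non-decreasing within 2 SE
  expect_true(all(diff(means) > -(2 * (ses[-1] + ses[-length(ses)]) + 0.005)))
  # confusion matrices are row-stochastic and accuracy is their weighted trace
  for (s in sw) {
    expect_equal(unname(rowSums(s$confusion)), rep(1, 4), tolerance = 1e-9)
    expect_true(all(s$misclass >= 0))
    expect_equal(sum(s$misclass), 1, tolerance = 1e-9)
  }
  # posteriors concentrate on the true class for the separable cohort
  expect_true(all(diag(sw[["40"]]$posterior) > 0.5))
})

test_that("indistinguishable classes decode at chance", {
  ds <- make_gaussian_dataset(n_per_class = 40, sep = 0, noise = 0.01)
  sw <- training_size_sweep(ds, sizes = 20, n_iter = 40, seed = 5,
                            posterior = FALSE)
  expect_lt(abs(mean(sw[["20"]]$accuracy) - 0.25), 0.08)
})

test_that("label shuffling brings accuracy to 25% with equally likely outcomes", {
  ds <- separable_dataset()
  nl <- shuffled_null(ds, size = 40, n_iter = 200, seed = 7)
  se <- sd(nl$accuracy) / sqrt(length(nl$accuracy))
  expect_lt(abs(nl$mean - 0.25), 2 * se + 0.01)
  expect_true(nl$ci95[1] <= 0.25 && 0.25 <= nl$ci95[2])
  expect_true(all(abs(nl$misclass - 0.25) < 0.05))
})

test_that("leave-one-unit-out designs evaluate each unit against the rest", {
  ds <- make_gaussian_dataset(n_per_class = 60, n_subjects = 3)
  lo <- leave_one_group_out(ds, "subject_id", per_class = 30, n_iter = 5, seed = 9)
  expect_equal(nrow(lo), 6)  # 3 subjects x 2 groups
  expect_true(all(lo$accuracy > 0.9))

  # a unit with shuffled-phenotype features drops to chance, others unaffected
  ds2 <- ds
  corrupt <- ds2$subject_id == "STZ1"
  set.seed(1)
  ds2$features[corrupt, ] <- ds2$features[sample(which(!corrupt), sum(corrupt)), ]
  lo2 <- leave_one_group_out(ds2, "subject_id", per_class = 30, n_iter = 5, seed = 9)
  expect_lt(lo2$accuracy[lo2$unit == "STZ1"], 0.5)
  expect_true(all(lo2$accuracy[!(lo2$unit %in% c("STZ1"))] > 0.85))

  # leave-session-out on a 2-session-per-unit design: one row per session
  lo3 <- leave_one_group_out(make_gaussian_dataset(n_per_class = 30, n_subjects = 1),
                             "session_id", per_class = 10, n_iter = 3, seed = 2)
  expect_equal(nrow(lo3), 4)

  expect_error(leave_one_group_out(ds, "subject_id", per_class = 50, n_iter = 2),
               "sampling error")
})

test_that("identical seeds reproduce the resampling protocols exactly", {
  ds <- separable_dataset()
  a <- training_size_sweep(ds, sizes = 10, n_iter = 10, seed = 11, posterior = FALSE)
  b <- training_size_sweep(ds, sizes = 10, n_iter = 10, seed = 11, posterior = FALSE)
  expect_identical(a[["10"]]$accuracy, b[["10"]]$accuracy)
  n1 <- shuffled_null(ds, size = 10, n_iter = 10, seed = 12)
  n2 <- shuffled_null(ds, size = 10, n_iter = 10, seed = 12)
  expect_identical(n1$accuracy, n2$accuracy)
})
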