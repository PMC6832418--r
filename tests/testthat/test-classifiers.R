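# small separable two-blob problem shared across cases
blob_problem <- function(n_per = 60, seed = 21, gap = 6) {
  set.seed(seed)
  x <- rbind(matrix(rnorm(2 * n_per), ncol = 2),
             matrix(rnorm(2 * n_per, mean = gap), ncol = 2))
  colnames(x) <- c("f1", "f2")
  list(x = x, y = rep(c(1L, 2L), each = n_per))
}

test_that("balanced sampling caps at availability and is seed-deterministic", {
  x <- matrix(runif(210 * 2), ncol = 2)
  y <- rep(c(1L, 2L), c(100, 110))
  s <- balanced_sample(x, y, per_class = 10, seed = 5)
  expect_equal(unname(table(s$labels)), c(10L, 10L), ignore_attr = TRUE)

  y2 <- rep(c(1L, 2L), c(5, 205))
  s2 <- balanced_sample(x, y2, per_class = 10, seed = 5)
  expect_equal(as.vector(table(s2$labels)), c(5L, 10L))

  s3 <- balanced_sample(x, y, per_class = 10, seed = 5)
  expect_identical(s$indices, s3$indices)
  s4 <- balanced_sample(x, y, per_class = 10, seed = 6)
  expect_false(identical(s$indices, s4$indices))

  expect_error(balanced_sample(x, NULL, 10), "labels")
})

test_that("all four families separate two well-separated blobs perfectly", {
  prob <- blob_problem()
  for (fam in c("lda", "lr", "svm", "rf")) {
    spec <- fit_classifier(classifier_spec(fam, seed = 1), prob$x, prob$y)
    expect_identical(predict(spec, prob$x), prob$y,
                     info = paste("family", fam))
  }
})

test_that("fitting rejects degenerate inputs", {
  prob <- blob_problem()
  expect_error(fit_classifier(classifier_spec("rf"), prob$x,
                              rep(1L, nrow(prob$x))), "single class")
  bad <- prob$x; bad[1, 1] <- NA
  expect_error(fit_classifier(classifier_spec("rf"), bad, prob$y),
               "non-finite")
  expect_error(fit_classifier(classifier_spec("rf"), prob$x, NULL),
               "labels")
  noname <- prob$x; colnames(noname) <- NULL
  expect_error(fit_classifier(classifier_spec("rf"), noname, prob$y),
               "named")
})

test_that("random forest predictions are reproducible under a fixed seed", {
  prob <- blob_problem(gap = 2.5)
  set.seed(99)
  held <- matrix(rnorm(2 * 100, mean = 1.2), ncol = 2,
                 dimnames = list(NULL, c("f1", "f2")))
  p1 <- predict(fit_classifier(classifier_spec("rf", seed = 7),
                               prob$x, prob$y), held)
  p2 <- predict(fit_classifier(classifier_spec("rf", seed = 7),
                               prob$x, prob$y), held)
  expect_identical(p1, p2)
})

test_that("probability outputs are normalized and consistent with hard labels", {
  set.seed(31)
  x <- matrix(rnorm(50 * 3), ncol = 3,
              dimnames = list(NULL, c("f1", "f2", "f3")))
  y <- as.integer(1 + (x[, 1] + 0.5 * x[, 2] + rnorm(50, sd = 0.3) > 0) +
                    (x[, 3] > 1))
  for (fam in c("lda", "lr", "rf")) {
    spec <- fit_classifier(classifier_spec(fam, seed = 3), x, y)
    p <- predict_prob(spec, x)
    expect_equal(unname(rowSums(p)), rep(1, nrow(x)), tolerance = 1e-9)
    expect_true(all(p >= 0))
    agree <- as.integer(colnames(p)[max.col(p, ties.method = "first")])
    expect_identical(agree, predict(spec, x), info = fam)
  }
  spec <- fit_classifier(classifier_spec("svm"), x, y)
  expect_error(predict_prob(spec, x), "probabilities")
})

test_that("two-class logistic regression returns a full probability matrix", {
  prob <- blob_problem(gap = 2)
  spec <- fit_classifier(classifier_spec("lr"), prob$x, prob$y)
  p <- predict_prob(spec, prob$x)
  expect_equal(dim(p), c(nrow(prob$x), 2))
  expect_equal(unname(rowSums(p)), rep(1, nrow(prob$x)), tolerance = 1e-9)
})

test_that("prediction refuses mismatched feature columns by name", {
  prob <- blob_problem()
  spec <- fit_classifier(classifier_spec("lda"), prob$x, prob$y)
  bad <- prob$x
  colnames(bad) <- c("f1", "other")
  expect_error(predict(spec, bad), "other")
  expect_error(predict(spec, prob$x[, 1, drop = FALSE]), "f2")
})

test_that("LDA is invariant to training-row permutation", {
  prob <- blob_problem(gap = 2)
  set.seed(17)
  perm <- sample(nrow(prob$x))
  p1 <- predict(fit_classifier(classifier_spec("lda"), prob$x, prob$y),
                prob$x)
  p2 <- predict(fit_classifier(classifier_spec("lda"), prob$x[perm, ],
                               prob$y[perm]), prob$x)
  expect_identical(p1, p2)
})

test_that("optional z-scoring applies the training transform at prediction", {
  prob <- blob_problem()
  wide <- prob$x %*% diag(c(1000, 0.001))
  colnames(wide) <- c("f1", "f2")
  spec <- fit_classifier(classifier_spec("svm", scale = TRUE),
                         wide, prob$y)
  expect_identical(predict(spec, wide), prob$y)
})

test_that("fitted models survive a save/load round trip", {
  prob <- blob_problem()
  spec <- fit_classifier(classifier_spec("rf", seed = 2), prob$x, prob$y)
  f <- withr::local_tempfile(fileext = ".rds")
  save_classifier(spec, f)
  back <- load_classifier(f)
  expect_identical(predict(back, prob$x), predict(spec, prob$x))
  saveRDS(list(format = "something-else"), f)
  expect_error(load_classifier(f), "model file")
})
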