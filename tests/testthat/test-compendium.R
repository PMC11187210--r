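test_that("coverage filter removes features below half detection, strictly", {
  m <- matrix(1, 3, 100)
  m[1, 1:51] <- NA  # observed in 49 -> removed
  m[2, 1:50] <- NA  # observed in 50 -> retained
  rownames(m) <- c("f49", "f50", "f100")
  out <- filter_low_coverage(m)
  expect_identical(rownames(out), c("f50", "f100"))

  # coverages 0.0 .. 0.9 over 10 samples -> 5 survive
  m2 <- matrix(NA_real_, 10, 10)
  for (i in 1:10) if (i > 1) m2[i, seq_len(i - 1)] <- 1
  expect_equal(nrow(filter_low_coverage(m2)), 5L)
  expect_error(filter_low_coverage(matrix(NA_real_, 2, 4)), "coverage")
})

test_that("minimum imputation fills every gap with the global minimum", {
  m <- matrix(c(0.003, 0.5, NA, 0.9, NA, 0.1), 3, 2)
  out <- impute_missing_min(m)
  expect_false(anyNA(out))
  expect_equal(out[cbind(c(3, 2), c(1, 2))], c(0.003, 0.003))
  expect_equal(attr(out, "global_min"), 0.003)

  complete <- matrix(1:6, 3, 2)
  expect_equal(unclass(impute_missing_min(complete))[1:6], 1:6,
               ignore_attr = TRUE)
})

test_that("log2(PPM+1) transform hits its fixed points", {
  expect_equal(log_transform_ppm(matrix(0))[1], 0)
  expect_equal(log_transform_ppm(matrix(1e-6))[1], 1)
  expect_equal(log_transform_ppm(matrix(1))[1], log2(1000001))
  expect_error(log_transform_ppm(matrix(-0.1)), "non-negative")
})

test_that("replicate filter drops discordant groups at R^2 < 0.9", {
  set.seed(5)
  base <- rnorm(200)
  make_pair <- function(r) cbind(base, vector_with_cor(base, r))
  m <- cbind(make_pair(0.95), make_pair(sqrt(0.89)), make_pair(1))
  colnames(m) <- paste0(rep(c("a", "b", "c"), each = 2), "_r", 1:2)
  md <- toy_metadata(c("a", "b", "c"))
  out <- filter_replicates(m, md, r2_min = 0.9)
  expect_setequal(out$dropped, c("b_r1", "b_r2"))      # R^2 = 0.89
  expect_true(all(c("a_r1", "a_r2") %in% colnames(out$matrix)))  # 0.9025
  expect_true(all(c("c_r1", "c_r2") %in% colnames(out$matrix)))  # identical

  # in a trio, only the single offender is dropped
  trio <- cbind(base, base + rnorm(200, 0, 0.05), vector_with_cor(base, 0.3))
  colnames(trio) <- paste0("t_r", 1:3)
  md3 <- data.frame(sample_id = colnames(trio), condition_id = "t",
                    replicate = 1:3, batch = "b", is_reference = FALSE)
  out3 <- filter_replicates(trio, md3)
  expect_identical(out3$dropped, "t_r3")
})

test_that("reference centering zeroes the reference and keeps contrasts", {
  m <- matrix(c(1, 2, 3, 4, 10, 20), 2, 3,
              dimnames = list(c("f1", "f2"), c("ref_r1", "ref_r2", "x_r1")))
  md <- data.frame(sample_id = colnames(m),
                   condition_id = c("ref", "ref", "x"),
                   batch = "b1", is_reference = c(TRUE, TRUE, FALSE))
  out <- center_to_reference(m, md)
  expect_equal(rowMeans(out[, 1:2]), c(f1 = 0, f2 = 0))
  expect_equal(out[, "x_r1"], c(f1 = 10 - 2, f2 = 20 - 3))

  # within-batch differences between non-reference samples are untouched
  set.seed(8)
  m2 <- matrix(rnorm(40), 4, 10,
               dimnames = list(paste0("f", 1:4), paste0("s", 1:10)))
  md2 <- data.frame(sample_id = colnames(m2),
                    condition_id = rep(c("ref", "a", "b", "c", "d"), 2),
                    batch = rep(c("b1", "b2"), each = 5),
                    is_reference = rep(c(TRUE, FALSE, FALSE, FALSE, FALSE), 2))
  out2 <- center_to_reference(m2, md2)
  expect_equal(out2[, "s2"] - out2[, "s3"], m2[, "s2"] - m2[, "s3"])

  md_bad <- md2
  md_bad$is_reference[md_bad$batch == "b2"] <- FALSE
  expect_error(center_to_reference(m2, md_bad), "b2")
})

test_that("compendium compilation is deterministic and leaves no gaps", {
  gt <- generate_ground_truth(400, 25, 4, 3, seed = 2)
  cc <- generate_matched_compendia(gt)
  c1 <- compile_compendium(cc$proteome, cc$metadata)
  c2 <- compile_compendium(cc$proteome, cc$metadata)
  expect_identical(c1$values, c2$values)
  expect_false(anyNA(c1$values))
  expect_true(all(is.finite(c1$values)))
  expect_equal(unname(colSums(c1$fractions)), rep(1, ncol(c1$fractions)),
               tolerance = 1e-9)
})

test_that("replicate correlations exceed random-pair correlations", {
  gt <- generate_ground_truth(400, 25, 4, 3, seed = 4)
  cc <- generate_matched_compendia(gt)
  h <- replicate_correlation_histogram(cc$transcriptome, cc$metadata,
                                       n_random_pairs = 50, seed = 9)
  expect_gt(median(h$replicate), median(h$random))

  # exact-copy replicates correlate at 1; zero random pairs is valid
  m <- matrix(rnorm(40), 10, 4,
              dimnames = list(NULL, c("a_r1", "a_r2", "b_r1", "b_r2")))
  m[, 2] <- m[, 1]; m[, 4] <- m[, 3]
  h2 <- replicate_correlation_histogram(m, toy_metadata(c("a", "b")),
                                        n_random_pairs = 0)
  expect_equal(h2$replicate, rep(1, 2), tolerance = 1e-12)
  expect_length(h2$random, 0)
})
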