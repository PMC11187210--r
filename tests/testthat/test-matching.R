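test_that("identical decompositions self-match with r = 1", {
  pd <- planted_decomposable(300, 30, 4, seed = 21)
  M <- pd$M0
  colnames(M) <- paste0("IC", 1:4)
  m <- match_components(M, M, 0.25)
  self <- m[m$pi == m$ti, ]
  expect_equal(nrow(self), 4L)
  expect_equal(self$r, rep(1, 4), tolerance = 1e-12)
})

test_that("the 0.25 correlation threshold is a hard boundary", {
  set.seed(22)
  v <- rnorm(400)
  M_t <- cbind(IC1 = v)
  rownames(M_t) <- paste0("g", 1:400)
  below <- cbind(P1 = vector_with_cor(v, 0.24, seed = 1))
  above <- cbind(P1 = vector_with_cor(v, 0.26, seed = 1))
  rownames(below) <- rownames(above) <- rownames(M_t)
  expect_equal(nrow(match_components(M_t, below, 0.25)), 0L)
  expect_equal(nrow(match_components(M_t, above, 0.25)), 1L)

  # matching is sign-flip invariant and symmetric in |r|
  m1 <- match_components(M_t, above, 0.25)
  m2 <- match_components(M_t, -above, 0.25)
  expect_equal(abs(m1$r), abs(m2$r), tolerance = 1e-12)
})

test_that("planted links including lumped modules are fully recovered", {
  gt <- generate_ground_truth(1000, 30, 8, 5, seed = 23)
  set.seed(24)
  noise_t <- matrix(rnorm(length(gt$M0_t), 0, 0.1 * max(abs(gt$M0_t))),
                    nrow(gt$M0_t))
  M_t <- gt$M0_t + noise_t
  Mp0 <- planted_proteome_weights(gt)
  M_p <- Mp0 + matrix(rnorm(length(Mp0), 0, 0.1 * max(abs(Mp0))), nrow(Mp0))
  m <- match_components(M_t, M_p, 0.25)
  planted <- unlist(lapply(names(gt$lumping_map), function(p) {
    paste(p, colnames(gt$M0_t)[gt$lumping_map[[p]]])
  }))
  found <- paste(m$pi, m$ti)
  expect_gte(mean(planted %in% found), 0.95)
  expect_equal(mean(found %in% planted), 1)
  # the lumped module matched more than one transcriptome module
  lumped <- names(gt$lumping_map)[lengths(gt$lumping_map) > 1][1]
  expect_gte(sum(m$pi == lumped), 2L)
})

test_that("recall arithmetic and bounds hold", {
  r <- compute_recall(paste0("g", 1:8), paste0("g", c(1:4, 9:20)))
  expect_equal(r$pi_recall, 0.5)
  expect_equal(r$ti_recall, 0.25)
  expect_length(r$both, 4L)

  same <- compute_recall(letters[1:5], letters[1:5])
  expect_equal(c(same$pi_recall, same$ti_recall), c(1, 1))
  disj <- compute_recall(letters[1:5], letters[6:10])
  expect_equal(c(disj$pi_recall, disj$ti_recall), c(0, 0))
  flagged <- compute_recall(character(0), letters[1:3])
  expect_true(is.na(flagged$pi_recall))
  expect_equal(flagged$quadrant, "undefined")

  for (s in 1:10) {
    set.seed(s)
    a <- sample(letters, sample(5:15, 1))
    b <- sample(letters, sample(5:15, 1))
    expect_lte(length(compute_recall(a, b)$both), min(length(a), length(b)))
  }
})

test_that("DiMA flags planted shifts and nothing else", {
  sc <- simulate_dima_scenario("proteome-dominant", shift = 5, seed = 31)
  d <- dima(sc$ti_activity, sc$pi_activity, sc$metadata, sc$metadata)
  expect_setequal(d$conditions$condition[d$conditions$differential],
                  sc$perturbed)

  # identical series: no differential conditions, correlation 1
  same <- dima(sc$ti_activity, sc$ti_activity, sc$metadata, sc$metadata)
  expect_equal(same$correlation, 1, tolerance = 1e-12)
  expect_equal(sum(same$conditions$differential), 0L)
  expect_equal(classify_dominance(same), "neutral")

  # an arbitrarily wide band flags nothing
  wide <- dima(sc$ti_activity, sc$pi_activity, sc$metadata, sc$metadata,
               band = 1e6)
  expect_equal(sum(wide$conditions$differential), 0L)

  short <- sc$metadata[1:2, ]
  expect_error(dima(sc$ti_activity[1:2], sc$pi_activity[1:2], short, short),
               "matched conditions")
})

test_that("dominance classification follows the differential sides", {
  make_dima <- function(sides) {
    structure(list(conditions = data.frame(
      condition = paste0("c", seq_along(sides)),
      ti_activity = 0, pi_activity = 0, diff = 0,
      differential = sides != "none", side = sides),
      correlation = 0.9, band = 1.5), class = "dima_result")
  }
  expect_equal(classify_dominance(make_dima(rep("ti", 6))),
               "transcriptome-dominant")
  expect_equal(classify_dominance(make_dima(rep("pi", 6))),
               "proteome-dominant")
  expect_equal(classify_dominance(make_dima(rep("none", 10))), "neutral")
  expect_equal(classify_dominance(make_dima(c(rep("ti", 3), rep("pi", 3)))),
               "neutral")
  # ti/pi exchange swaps the label
  lab1 <- classify_dominance(make_dima(c(rep("ti", 7), "pi")))
  lab2 <- classify_dominance(make_dima(c(rep("pi", 7), "ti")))
  expect_equal(lab1, "transcriptome-dominant")
  expect_equal(lab2, "proteome-dominant")
})

test_that("dominance scenarios classify correctly across seeds", {
  for (cl in c("neutral", "transcriptome-dominant", "proteome-dominant")) {
    hits <- vapply(1:10, function(s) {
      sc <- simulate_dima_scenario(cl, seed = s)
      d <- dima(sc$ti_activity, sc$pi_activity, sc$metadata, sc$metadata)
      classify_dominance(d) == cl
    }, TRUE)
    expect_gte(mean(hits), 0.9)
  }
})

test_that("DiMM tables align signs and flag one-sided members", {
  set.seed(25)
  w <- setNames(rnorm(100), paste0("g", 1:100))
  tab <- dimm_table(w, w, paste0("g", 1:10), paste0("g", 1:10))
  expect_equal(tab$ti_weight, tab$pi_weight, tolerance = 1e-12)
  expect_equal(sum(tab$in_both), 10L)

  # anti-correlated copy is flipped so the correlation is positive
  tab2 <- dimm_table(w, -w, paste0("g", 1:10), paste0("g", 5:14))
  expect_gt(cor(tab2$ti_weight, tab2$pi_weight), 0.99)
  one_sided <- tab2[tab2$feature == "g2", ]
  expect_true(one_sided$in_ti && !one_sided$in_pi && !one_sided$in_both)
})

test_that("matched subsetting restricts features and conditions", {
  gt <- generate_ground_truth(300, 22, 3, 2, seed = 26)
  cc <- generate_matched_compendia(gt)
  sub <- matched_subset(cc$transcriptome, cc$metadata,
                        features = gt$coverage_mask,
                        conditions = gt$condition_ids[1:10])
  expect_setequal(rownames(sub$matrix),
                  intersect(gt$gene_ids, gt$coverage_mask))
  expect_setequal(unique(sub$metadata$condition_id), gt$condition_ids[1:10])
  expect_identical(colnames(sub$matrix), sub$metadata$sample_id)
})
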