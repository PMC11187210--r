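test_that("K-squared statistic agrees with an external oracle", {
  # expected values computed once with an independent implementation of
  # the D'Agostino-Pearson omnibus test and frozen here
  x <- c(0.12, -0.55, 1.34, 0.03, -0.91, 0.47, 2.10, -0.22, 0.68, -1.40,
         0.09, 0.33, -0.76, 1.02, -0.18, 0.55, -2.30, 0.41, 0.00, 0.87)
  expect_equal(dagostino_k2(x), 2.214415202813, tolerance = 1e-9)
  expect_equal(dagostino_k2(c(x, 8.0)), 34.302218468917, tolerance = 1e-9)
  expect_equal(dagostino_k2(rep(1, 20)), 0)
  expect_error(dagostino_k2(1:5), "at least 8")
})

test_that("weight thresholding recovers planted outliers of both signs", {
  set.seed(7)
  w <- c(rnorm(500, 0, 0.01), rep(c(0.8, -0.8), c(3, 2)))
  names(w) <- paste0("g", seq_along(w))
  # the K-squared plateau for a 505-gene vector sits below the
  # compendium-scale default cutoff, so the cutoff is set per length
  th <- threshold_component(w, cutoff = 100)
  expect_setequal(th$members, paste0("g", 501:505))
  expect_true(th$threshold < 0.8 && th$threshold > 0.05)

  # no outliers exist in a constant vector
  expect_length(threshold_component(setNames(rep(1, 20), 1:20))$members, 0)

  # near-normal weights yield an empty membership at any cutoff
  set.seed(8)
  wn <- setNames(rnorm(300), paste0("g", 1:300))
  expect_length(threshold_component(wn, cutoff = 550)$members, 0)
})

test_that("hypergeometric enrichment matches direct summation", {
  background <- paste0("g", 1:1000)
  regulon <- list(reg1 = background[1:20], reg2 = background[900:1000])
  members <- c(background[1:5], background[21:25])  # 5 of 20 in reg1
  res <- enrich_regulators(members, regulon, background)
  oracle <- hyper_tail_oracle(5, 20, 10, 1000)
  r1 <- res[res$regulator == "reg1", ]
  expect_equal(r1$pvalue, oracle, tolerance = 1e-12)
  expect_equal(r1$precision, 0.5)
  expect_equal(r1$recall, 0.25)
  expect_equal(r1$overlap, 5L)
  expect_equal(res$adjusted_pvalue,
               p.adjust(res$pvalue[order(res$adjusted_pvalue)], "BH"),
               tolerance = 1e-12)

  # perfect overlap: members identical to a 10-gene regulon
  perfect <- enrich_regulators(background[1:10],
                               list(r = background[1:10]), background)
  expect_lt(perfect$pvalue, 1e-20)
  expect_equal(perfect$precision, 1)
  expect_equal(perfect$recall, 1)

  # disjoint sets are not significant; empty members give empty output
  disj <- enrich_regulators(background[500:509],
                            list(r = background[1:20]), background)
  expect_gt(disj$pvalue, 0.5)
  expect_equal(nrow(enrich_regulators(character(0), regulon, background)), 0L)
})

test_that("pairwise regulon unions capture jointly regulated modules", {
  background <- paste0("g", 1:500)
  db <- list(A = background[1:10], B = background[11:20])
  members <- background[1:20]
  res <- enrich_regulators(members, db, background, include_pairs = TRUE)
  expect_equal(res$regulator[1], "A/B")
  expect_equal(res$precision[1], 1)
  expect_equal(res$recall[1], 1)
})

test_that("components are categorized from membership and enrichment", {
  set.seed(9)
  n <- 800
  genes <- paste0("g", 1:n)
  M <- cbind(
    reg = c(rep(0.3, 12), rnorm(n - 12, 0, 0.005)),
    single = c(rnorm(n - 1, 0, 0.005), 0.9),
    orphan = c(rnorm(n - 6, 0, 0.005), rep(0.25, 6)))
  rownames(M) <- genes
  dec <- structure(list(M = M, component_ev = c(0.4, 0.1, 0.05)),
                   class = "ica_decomposition")
  db <- list(regX = genes[1:12], regY = genes[300:340])
  ims <- characterize_components(dec, db, k2_cutoff = 100)
  expect_equal(ims[[1]]$category, "regulatory")
  expect_equal(ims[[1]]$name, "regX")
  expect_equal(ims[[2]]$category, "technical/single-gene")
  expect_equal(ims[[3]]$category, "uncharacterized")

  cur <- data.frame(component_index = 3, category = "biological",
                    name = "motility")
  ims2 <- characterize_components(dec, db, curation = cur, k2_cutoff = 100)
  expect_equal(ims2[[3]]$category, "biological")
  expect_equal(ims2[[3]]$name, "motility")
})

test_that("invariance statistics partition mass exactly", {
  set.seed(10)
  n_prot <- 50
  fr <- matrix(rlnorm(n_prot * 20, -4, 0.1), n_prot, 20,
               dimnames = list(paste0("p", 1:n_prot), paste0("s", 1:20)))
  # planted variant module: strong condition-driven fold changes
  fr[1:10, ] <- fr[1:10, ] * matrix(rep(exp(rnorm(20, 0, 1.5)), each = 10), 10)
  fr <- sweep(fr, 2, colSums(fr), "/")
  st <- invariance_stats(fr, paste0("p", 1:10))
  expect_equal(sum(st$summary$mass_share), 1, tolerance = 1e-9)
  in_part <- st$proteins[st$proteins$in_imodulon, ]
  out_part <- st$proteins[!st$proteins$in_imodulon, ]
  expect_gt(median(in_part$cv), median(out_part$cv))

  # fixed-point checks of the CV rule
  con <- matrix(c(rep(0.5, 4), 0.001 * exp(c(-2, 2, -2, 2))), 2, 4,
                byrow = TRUE, dimnames = list(c("flat", "wild"), NULL))
  con <- rbind(con, other = 1 - colSums(con))
  st2 <- invariance_stats(con, "flat")
  expect_true(st2$proteins$invariant[st2$proteins$protein == "flat"])
  expect_equal(st2$proteins$cv[st2$proteins$protein == "flat"], 0)
  wild_cv <- st2$proteins$cv[st2$proteins$protein == "wild"]
  expect_false(st2$proteins$invariant[st2$proteins$protein == "wild"])
  expect_gt(wild_cv, 1)
})
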