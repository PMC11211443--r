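test_that("stomach fullness matches its definition and transform", {
  expect_equal(stomach_fullness(0, 1.5), 0)
  expect_equal(stomach_fullness(0.02, 1.02), 0.02)
  # sqrt transform of a fullness of 0.04 is 0.2
  expect_equal(stomach_fullness(0.04, 1.04, sqrt_transform = TRUE), 0.2)
  expect_error(stomach_fullness(2, 1.5), "total")
})

test_that("PSIRI reproduces worked examples and its defining identity", {
  # one taxon in every stomach -> 100%
  one <- data.frame(fish_id = c("s1", "s2"), prey_taxon = "A",
                    count = c(2L, 7L), weight_mg = c(1, 9))
  expect_equal(psiri(one)$psiri_pct, 100)

  # two stomachs, disjoint taxa -> 50/50
  comp <- psiri(two_stomach_toy())
  expect_equal(sort(comp$psiri_pct), c(50, 50))
  expect_equal(comp$fo_pct, c(50, 50))
  expect_equal(comp$pn_pct, c(100, 100))

  # sum-to-100 identity on arbitrary tables (property, seeded)
  for (s in 1:5) {
    st <- random_stomachs(n = 10 + s, k = 5, seed = s)
    expect_equal(sum(psiri(st)$psiri_pct), 100, tolerance = 1e-9)
  }

  # invariant to uniform weight rescaling (mg -> g)
  st <- random_stomachs(seed = 99)
  st_g <- transform(st, weight_mg = weight_mg / 1000)
  expect_equal(psiri(st)$psiri_pct, psiri(st_g)$psiri_pct,
               tolerance = 1e-12)

  expect_error(psiri(data.frame(fish_id = "s1", prey_taxon = "A",
                                count = 0L, weight_mg = 0)), "empty")
})

test_that("%FO is non-increasing when prey-free stomachs are added", {
  st <- random_stomachs(n = 8, k = 3, seed = 2)
  base_fo <- psiri(st)$fo_pct[psiri(st)$prey_taxon == "A"]
  extra <- data.frame(fish_id = paste0("x", 1:4), prey_taxon = "B",
                      count = 1L, weight_mg = 1)
  grown_comp <- psiri(rbind(st, extra))
  expect_lte(grown_comp$fo_pct[grown_comp$prey_taxon == "A"], base_fo)
})

test_that("grouping threshold merges minor taxa into Other, preserving 100", {
  st <- random_stomachs(n = 15, k = 6, seed = 7)
  full <- psiri(st)
  thr <- 3.5
  res <- apply_grouping_threshold(st, threshold = thr)
  minor <- full$prey_taxon[full$psiri_pct <= thr]
  major <- full$prey_taxon[full$psiri_pct > thr]
  if (length(minor) > 0)
    expect_true("Other" %in% res$composition$prey_taxon)
  expect_setequal(setdiff(res$composition$prey_taxon, "Other"), major)
  expect_equal(sum(res$composition$psiri_pct), 100, tolerance = 1e-9)
  # PSIRI is additive under pooling: Other equals the sum of its parts
  if (length(minor) > 0)
    expect_equal(
      res$composition$psiri_pct[res$composition$prey_taxon == "Other"],
      sum(full$psiri_pct[full$prey_taxon %in% minor]), tolerance = 1e-9)
  # all taxa above threshold: identity
  res_all <- apply_grouping_threshold(st, threshold = 0)
  expect_setequal(res_all$composition$prey_taxon, full$prey_taxon)
  # threshold 100: everything becomes Other at 100%
  res_none <- apply_grouping_threshold(st, threshold = 100)
  expect_equal(res_none$composition$prey_taxon, "Other")
  expect_equal(res_none$composition$psiri_pct, 100, tolerance = 1e-9)
})

test_that("per-stomach PSIRI matrix rows sum to 100", {
  st <- random_stomachs(n = 9, k = 4, seed = 3)
  m <- psiri_matrix(st)
  expect_equal(unname(rowSums(m)), rep(100, nrow(m)), tolerance = 1e-9)
  # grouping map collapses columns consistently
  grp <- setNames(c("A", "Other", "Other", "D"), LETTERS[1:4])
  m2 <- psiri_matrix(st, grp)
  expect_setequal(colnames(m2), c("A", "D", "Other"))
  expect_equal(unname(rowSums(m2)), rep(100, nrow(m2)), tolerance = 1e-9)
})

test_that("empty stomach summary counts and stratifies", {
  # the study's arithmetic: 12 empty of 525 analyzed = 2.3%
  s <- empty_stomach_summary(seq_len(525), c(rep(TRUE, 12), rep(FALSE, 513)))
  expect_equal(s$overall$pct_empty, 100 * 12 / 525, tolerance = 1e-12)
  expect_equal(round(s$overall$pct_empty, 1), 2.3)

  expect_equal(empty_stomach_summary(1:10, rep(FALSE, 10))$overall$pct_empty, 0)

  # 3 of 4 empties in July mirrors a 75% monthly share
  s2 <- empty_stomach_summary(1:8, c(TRUE, TRUE, TRUE, FALSE,
                                     TRUE, FALSE, FALSE, FALSE),
                              strata = data.frame(month = rep(c(7, 8),
                                                              each = 4)))
  jul <- s2$by_stratum[s2$by_stratum$month == 7, ]
  expect_equal(jul$x.pct_empty, 75)
})
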