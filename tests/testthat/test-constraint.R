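test_that("decile assignment orders by s_het with alphabetical tie-break", {
  tab <- data.frame(gene = sprintf("g%02d", 1:10),
                    s_het = seq(0.01, 0.10, by = 0.01))
  ent <- assign_deciles(tab)
  expect_equal(ent$decile[ent$gene == "g10"], 10L)
  expect_equal(ent$decile[ent$gene == "g01"], 1L)

  tab20 <- data.frame(gene = sprintf("g%02d", 1:20),
                      s_het = (1:20) / 100)
  ent20 <- assign_deciles(tab20)
  expect_equal(as.integer(table(ent20$decile)), rep(2L, 10))

  # all-tied values: the stable sort falls back to the symbol, so the
  # alphabetically first gene lands in decile 1 and so on
  tied <- data.frame(gene = rev(letters[1:10]), s_het = rep(0.05, 10))
  ent_tied <- assign_deciles(tied)
  expect_equal(ent_tied$gene, letters[1:10])
  expect_equal(ent_tied$decile, 1:10)

  expect_error(assign_deciles(data.frame(gene = "a", s_het = 0.1)),
               "at least 10")
  expect_error(assign_deciles(data.frame(gene = letters[1:10],
                                         s_het = c(rep(0.1, 9), NA))),
               "non-finite")
})

test_that("decile sizes differ by at most one and remainder goes low", {
  set.seed(5)
  for (n in c(10, 23, 101, 1007)) {
    ent <- assign_deciles(data.frame(gene = sprintf("g%04d", 1:n),
                                     s_het = runif(n)))
    sizes <- as.integer(table(factor(ent$decile, levels = 1:10)))
    expect_lte(diff(range(sizes)), 1L)
    expect_true(all(diff(sizes) <= 0))  # extras absorbed by low deciles
    expect_equal(sum(sizes), n)
  }
})

test_that("decile assignment is invariant to input row order", {
  set.seed(8)
  tab <- data.frame(gene = sprintf("g%03d", 1:57),
                    s_het = round(runif(57), 2))  # rounded to force ties
  ent <- assign_deciles(tab)
  for (i in 1:5) {
    perm <- tab[sample(nrow(tab)), ]
    expect_identical(assign_deciles(perm), ent)
  }
})

test_that("top-decile selection is nested in k and hits the extremes", {
  tab <- data.frame(gene = sprintf("g%02d", 1:20), s_het = (1:20) / 100)
  ent <- assign_deciles(tab)
  expect_setequal(select_top_deciles(ent, 10)$members, tab$gene)
  expect_setequal(select_top_deciles(ent, 2)$members,
                  c("g17", "g18", "g19", "g20"))
  ent10 <- assign_deciles(data.frame(gene = sprintf("g%02d", 1:10),
                                     s_het = (1:10) / 100))
  expect_equal(select_top_deciles(ent10, 1)$members, "g10")
  for (k in 1:9)
    expect_true(all(select_top_deciles(ent, k)$members %in%
                      select_top_deciles(ent, k + 1)$members))
  expect_error(select_top_deciles(ent, 0), "1..10")
  expect_error(select_top_deciles(ent, 11), "1..10")
})

test_that("burden test matches closed-form ANOVA on constructed flags", {
  tab <- data.frame(gene = sprintf("g%04d", 1:1000),
                    s_het = (1:1000) / 1000)
  ent <- assign_deciles(tab)

  # perfectly balanced: 5 flagged in every decile -> no between-decile
  # variation, F exactly 0
  bal <- unlist(lapply(split(ent$gene, ent$decile), head, 5))
  b <- decile_burden_test(ent, bal)
  expect_equal(b$per_decile$fraction_flagged, rep(0.05, 10))
  expect_equal(b$anova_F, 0)
  expect_equal(sum(b$per_decile$n_flagged), 50L)

  # flags confined to the top decile: with 50 of 100 flagged there,
  # SSB = 22.5 (df 9), SSW = 25 (df 990), so F = 2.5 / (25/990) = 99
  top50 <- head(ent$gene[ent$decile == 10], 50)
  b2 <- decile_burden_test(ent, top50)
  expect_equal(b2$anova_F, 99, tolerance = 1e-10)
  expect_lt(b2$trend_p, 1e-10)

  # the whole top decile flagged: zero within-group variance
  b3 <- suppressWarnings(decile_burden_test(ent, ent$gene[ent$decile == 10]))
  expect_equal(b3$per_decile$fraction_flagged, c(rep(0, 9), 1))
  expect_lt(b3$anova_p, 1e-10)

  # disjoint flagged list: counts still returned, statistics undefined
  b4 <- decile_burden_test(ent, c("nope1", "nope2"))
  expect_equal(b4$per_decile$n_flagged, rep(0L, 10))
  expect_true(is.na(b4$anova_F) && is.na(b4$trend_p))
})

test_that("trend p-value is calibrated under random flagging", {
  tab <- data.frame(gene = sprintf("g%04d", 1:1000),
                    s_het = (1:1000) / 1000)
  ent <- assign_deciles(tab)
  set.seed(101)
  pvals <- replicate(500, {
    decile_burden_test(ent, sample(ent$gene, 50))$trend_p
  })
  frac <- mean(pvals < 0.05)
  expect_gte(frac, 0.03)
  expect_lte(frac, 0.08)
})

test_that("constraint TSV reader honors a pre-binned decile override", {
  p <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = letters[1:12], s_het = (1:12) / 12),
                     p, sep = "\t", quote = FALSE, row.names = FALSE)
  tab <- read_constraint_table(p)
  expect_true(all(c("gene", "s_het", "decile") %in% names(tab)))

  p2 <- tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = letters[1:12],
                                decile = rep(c(1, 10), 6)),
                     p2, sep = "\t", quote = FALSE, row.names = FALSE)
  tab2 <- read_constraint_table(p2)
  expect_equal(tab2$decile, rep(c(1L, 10L), 6))
  expect_setequal(select_top_deciles(tab2, 1)$members,
                  letters[1:12][c(FALSE, TRUE)])
})
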