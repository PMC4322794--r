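test_that("the set statistic is the member median with the even-size convention", {
  stats <- toy_stats(c(1, 2, 3, 10, -4))
  expect_equal(as.numeric(gene_set_median(stats, c("g1", "g2", "g3"))), 2)
  expect_equal(as.numeric(gene_set_median(stats, c("g1", "g2", "g3", "g4"))),
               2.5)
  expect_equal(as.numeric(gene_set_median(stats, "g5")), -4)
  # members outside the universe are ignored but counted
  m <- gene_set_median(stats, c("g1", "g2", "g3", "nope"))
  expect_equal(as.numeric(m), 2)
  expect_equal(attr(m, "n_ignored"), 1)
  expect_error(gene_set_median(stats, c("x", "y")), "no set member")
})

test_that("exhaustive enumeration reproduces the hand-derived size-1 null", {
  stats <- toy_stats(c(3, -1, 0, 1))
  res <- run_gsa(stats, one_set("g1"), exhaustive = TRUE, quiet = TRUE)
  # null medians over all size-1 subsets are {3, -1, 0, 1}
  expect_equal(tidy(res)$p_distinct_up, 1 / 4)
  expect_equal(tidy(res)$p_distinct_down, 4 / 4)
  expect_equal(tidy(res)$p_nondirectional, 1 / 4)
})

test_that("fully tied statistics give p = 1, never spurious significance", {
  stats <- toy_stats(rep(0, 10))
  res <- run_gsa(stats, one_set(c("g1", "g2", "g3")), n_perm = 200,
                 seed = 1, quiet = TRUE)
  expect_equal(tidy(res)$p_distinct_up, 1)
  expect_equal(tidy(res)$p_distinct_down, 1)
  expect_equal(tidy(res)$p_nondirectional, 1)
})

test_that("sign-flipping every statistic exchanges the distinct tails exactly", {
  withr::local_seed(11)
  stats <- toy_stats(rnorm(60))
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("S1", "S2"),
    genes = list(sprintf("g%d", 1:7), sprintf("g%d", 20:29))))
  r1 <- run_gsa(stats, coll, n_perm = 500, seed = 5, quiet = TRUE)
  stats_flipped <- stats
  stats_flipped$log2fc <- -stats_flipped$log2fc
  r2 <- run_gsa(stats_flipped, coll, n_perm = 500, seed = 5, quiet = TRUE)
  expect_equal(tidy(r1)$p_distinct_up, tidy(r2)$p_distinct_down)
  expect_equal(tidy(r1)$p_distinct_down, tidy(r2)$p_distinct_up)
  expect_equal(tidy(r1)$p_nondirectional, tidy(r2)$p_nondirectional)
})

test_that("raising the members' statistics never increases p_distinct_up", {
  withr::local_seed(21)
  base <- rnorm(80)
  members <- sprintf("g%d", 1:9)
  p_for <- function(shift) {
    v <- base
    v[1:9] <- v[1:9] + shift
    res <- run_gsa(toy_stats(v), one_set(members), n_perm = 400, seed = 9,
                   quiet = TRUE)
    tidy(res)$p_distinct_up
  }
  ps <- vapply(c(0, 0.25, 0.5, 1, 2), p_for, numeric(1))
  expect_true(all(diff(ps) <= 0))
})

test_that("results are bit-identical for identical seed and inputs", {
  withr::local_seed(31)
  stats <- toy_stats(rnorm(100))
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("S1", "S2", "S3"),
    genes = list(sprintf("g%d", 1:6), sprintf("g%d", 10:21),
                 sprintf("g%d", 50:54))))
  r1 <- run_gsa(stats, coll, n_perm = 300, seed = 17, quiet = TRUE)
  r2 <- run_gsa(stats, coll, n_perm = 300, seed = 17, quiet = TRUE)
  expect_identical(r1, r2)
})

test_that("p-values lie in (0, 1], sets outside the universe are skipped", {
  withr::local_seed(41)
  stats <- toy_stats(rnorm(40))
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("in", "out"),
    genes = list(sprintf("g%d", 1:5), c("absent1", "absent2"))))
  expect_message(res <- run_gsa(stats, coll, n_perm = 100, seed = 1),
                 "skipped")
  tab <- tidy(res)
  expect_equal(tab$set_id, "in")
  expect_equal(res$skipped$set_id, "out")
  pcols <- grep("^p_", names(tab), value = TRUE)
  pv <- unlist(tab[pcols])
  pv <- pv[!is.na(pv)]
  expect_true(all(pv > 0 & pv <= 1))
  expect_true(all(tab$n_universe <= tab$n_genes))
})

test_that("mixed-directional classes score the sign-restricted subsets", {
  # 6 genes: 3 positive, 3 negative; set = two positive + one negative gene
  stats <- toy_stats(c(2, 1, 0.5, -0.5, -1, -2))
  res <- run_gsa(stats, one_set(c("g1", "g2", "g4")), exhaustive = TRUE,
                 quiet = TRUE)
  tab <- tidy(res)
  expect_equal(tab$n_up, 2)
  expect_equal(tab$n_down, 1)
  # observed up-median = median(2, 1) = 1.5; nulls are medians of the
  # C(3,2) = 3 pairs from {2, 1, 0.5}: {1.5, 1.25, 0.75} -> p = 1/3
  expect_equal(tab$stat_median_up, 1.5)
  expect_equal(tab$p_mixed_up, 1 / 3)
  # observed down-median = -0.5, nulls {-0.5, -1, -2}: p(left tail) = 3/3
  expect_equal(tab$p_mixed_down, 1)
})

test_that("exhaustive mode refuses universes beyond the cap", {
  withr::local_seed(51)
  stats <- toy_stats(rnorm(300))
  expect_error(run_gsa(stats, one_set(sprintf("g%d", 1:6)),
                       exhaustive = TRUE, exhaustive_cap = 1000,
                       quiet = TRUE),
               "cap")
})

test_that("GSA tables are written sorted by p with set_id tiebreak", {
  withr::local_seed(61)
  stats <- toy_stats(rep(0, 20))
  coll <- gene_set_collection(tibble::tibble(
    set_id = c("zed", "alpha", "mid"),
    genes = list(sprintf("g%d", 1:3), sprintf("g%d", 4:6),
                 sprintf("g%d", 7:9))))
  res <- run_gsa(stats, coll, n_perm = 50, seed = 1, quiet = TRUE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_gsa_table(res, path)
  tab <- readr::read_tsv(path, show_col_types = FALSE)
  # all p tie at 1 -> alphabetical by set_id
  expect_equal(tab$set_id, c("alpha", "mid", "zed"))
  expect_equal(nrow(tab), 3)
})

test_that("glance summarises the run and autoplot returns a ggplot", {
  withr::local_seed(71)
  stats <- toy_stats(rnorm(50))
  res <- run_gsa(stats, one_set(sprintf("g%d", 1:8)), n_perm = 100,
                 seed = 2, quiet = TRUE)
  g <- glance(res)
  expect_equal(g$n_sets, 1)
  expect_equal(g$universe_size, 50)
  expect_equal(g$n_perm, 100)
  expect_s3_class(autoplot(res), "ggplot")
})
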