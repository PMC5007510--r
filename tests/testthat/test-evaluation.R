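# evaluation: labelling, truncated ROC, jackknife, curves, comparison

test_that("label_targets applies jackknife superfamily labelling", {
  bench <- benchmark_dataset(data.frame(
    seq_id = c("q", "a", "b"), family_id = c("f1", "f1", "f2"),
    superfamily_id = c("SF1", "SF1", "SF2"), stringsAsFactors = FALSE))
  labs <- label_targets("q", bench)
  expect_equal(labs, c(a = "positive", b = "negative"))
  expect_error(label_targets("zz", bench), "unknown query")

  # sole member of its superfamily: zero positives
  tb <- toy_benchmark()
  expect_equal(sum(label_targets("c1", tb) == "positive"), 0)

  # 3 superfamilies of sizes 3/2/1, query in the first -> 2 pos, 3 neg
  labs3 <- label_targets("a1", tb)
  expect_equal(sum(labs3 == "positive"), 2)
  expect_equal(sum(labs3 == "negative"), 3)

  # exclude-same-family flips same-family members to ignore
  labs4 <- label_targets("a1", tb, exclude_same_family = TRUE)
  expect_equal(labs4[["a2"]], "ignore")
  expect_equal(labs4[["a3"]], "positive")  # same SF, different family
})

test_that("roc_n matches its definition on canonical cases", {
  # perfect ranking -> 1 for every n
  perfect <- c(TRUE, TRUE, FALSE, FALSE, FALSE)
  for (n in c(1, 2, 50)) expect_equal(roc_of_pattern(perfect, n), 1)
  # all positives below the first n false positives -> 0
  worst <- c(FALSE, FALSE, TRUE, TRUE)
  for (n in c(1, 2)) expect_equal(roc_of_pattern(worst, n), 0)
  # [+,-,+,-] with n = 2: (1 + 2) / (2 * 2) = 0.75
  expect_equal(roc_of_pattern(c(TRUE, FALSE, TRUE, FALSE), 2), 0.75)
  # oracle agrees
  expect_equal(oracle_roc_n(c(TRUE, FALSE, TRUE, FALSE), 2, 2, 2), 0.75)
})

test_that("roc_n handles absent entries and degenerate label sets", {
  labs <- c(a = "positive", b = "positive", c = "negative", d = "negative")
  # positive 'b' absent from the ranking ranks after all false positives
  rl <- ranking_list("q", "p", c("a", "c", "d"), c(3, 2, 1))
  # order a(+), c(-), d(-): TP(1)=1, TP(2)=1 -> 2/(2*2) = 0.5
  expect_equal(roc_n(rl, labs, 2), 0.5)
  # negatives absent from the ranking become virtual false positives
  rl2 <- ranking_list("q", "p", c("a", "b"), c(2, 1))
  # both FPs virtual, both positives returned: (2+2)/(2*2) = 1
  expect_equal(roc_n(rl2, labs, 2), 1)
  # zero negatives: fraction of positives returned
  labs_pos <- c(a = "positive", b = "positive")
  expect_equal(roc_n(ranking_list("q", "p", "a", 1), labs_pos, 5), 0.5)
  # zero positives errors
  expect_error(roc_n(rl, c(c = "negative"), 1), "no positives")
  # ignored entries are dropped before scoring
  labs_ig <- c(a = "positive", b = "ignore", c = "negative")
  rl3 <- ranking_list("q", "p", c("b", "a", "c"), c(3, 2, 1))
  expect_equal(roc_n(rl3, labs_ig, 1), 1)
})

test_that("roc_n equals the brute-force oracle on exhaustive small cases", {
  for (len in 1:6) {
    for (code in 0:(2^len - 1)) {
      is_pos <- as.logical(bitwAnd(bitwShiftR(code, 0:(len - 1)), 1L))
      if (!any(is_pos)) next
      for (n in c(1, 2, 5)) {
        expect_identical(roc_of_pattern(is_pos, n),
                         oracle_roc_n(is_pos, sum(is_pos), sum(!is_pos), n))
      }
    }
  }
})

test_that("roc_n is monotone under (-,+) -> (+,-) swaps and consistent at full truncation", {
  set.seed(23)
  for (i in 1:40) {
    len <- sample(4:12, 1)
    is_pos <- sample(c(TRUE, FALSE), len, replace = TRUE)
    if (!any(is_pos)) is_pos[1] <- TRUE
    n <- sample(c(1, 2, 3, 50), 1)
    base <- roc_of_pattern(is_pos, n)
    swaps <- which(!is_pos[-len] & is_pos[-1])
    for (s in swaps) {
      better <- is_pos
      better[c(s, s + 1)] <- c(TRUE, FALSE)
      expect_gte(roc_of_pattern(better, n), base)
    }
    # n >= #negatives: equals full AUC by exhaustive pair counting
    if (any(!is_pos)) {
      pos_rank <- which(is_pos)
      neg_rank <- which(!is_pos)
      pairs <- outer(pos_rank, neg_rank, `<`)
      auc <- mean(pairs)
      expect_equal(roc_of_pattern(is_pos, len), auc)
    }
  }
})

test_that("jackknife evaluation matches hand-computed values and excludes self", {
  tb <- toy_benchmark()
  # query a1: ranking a2(+), b1(-), a3(+), b2(-), c1(-), self included
  r1 <- ranking_list("a1", "p", c("a2", "b1", "a3", "b2", "c1", "a1"),
                     c(6, 5, 4, 3, 2, 1))
  # labels: a2,a3 positive; b1,b2,c1 negative. ROC1 = 1/(1*2) = 0.5,
  # ROC50: m=3, TP = 1+2+2 -> 5/(3*2)
  r2 <- ranking_list("b1", "p", c("b2", "a1", "a2", "a3", "c1"),
                     c(5, 4, 3, 2, 1))
  # b2 positive first: ROC1 = 1, ROC50: m=4, TP=1 each -> 4/(4*1) = 1
  s <- jackknife_evaluate(list(r1, r2), tb)
  expect_equal(s$per_query$roc1, c(0.5, 1))
  expect_equal(s$per_query$roc50, c(5 / 6, 1))
  expect_equal(s$mean_roc1, 0.75)
  expect_equal(s$mean_roc50, (5 / 6 + 1) / 2)

  # self-exclusion: moving the self-hit to the top changes nothing
  r1b <- ranking_list("a1", "p", c("a1", "a2", "b1", "a3", "b2", "c1"),
                      c(7, 6, 5, 4, 3, 2))
  s2 <- jackknife_evaluate(list(r1b, r2), tb)
  expect_equal(s2$per_query$roc1, s$per_query$roc1)
  expect_equal(s2$per_query$roc50, s$per_query$roc50)

  # sole-member query is reported non-evaluable and excluded from means
  r3 <- ranking_list("c1", "p", c("a1", "b1"), c(2, 1))
  s3 <- jackknife_evaluate(list(r1, r2, r3), tb)
  expect_false(s3$per_query$evaluable[3])
  expect_equal(s3$mean_roc1, 0.75)

  # label-perfect rankings give means of exactly 1
  perfect <- lapply(c("a1", "a2", "a3", "b1", "b2"), function(q) {
    labs <- label_targets(q, tb)
    ord <- order(labs != "positive")
    ranking_list(q, "p", names(labs)[ord], rev(seq_along(labs)))
  })
  sp <- jackknife_evaluate(perfect, tb)
  expect_equal(sp$mean_roc1, 1)
  expect_equal(sp$mean_roc50, 1)
})

test_that("exceedance curve is the empirical survival function", {
  mk <- function(scores) {
    structure(list(per_query = data.frame(
      query_id = paste0("q", seq_along(scores)), roc1 = scores,
      roc50 = scores, n_pos = 1, n_neg = 1, evaluable = TRUE)),
      class = "eval_summary")
  }
  c1 <- exceedance_curve(mk(c(1, 1)), "roc1")
  expect_true(all(c1$fraction == 1))

  c2 <- exceedance_curve(mk(c(0.2, 0.8)), "roc1")
  expect_equal(c2$threshold, c(0, 0.2, 0.8))
  expect_equal(c2$fraction, c(1, 1, 0.5))

  set.seed(31)
  scores <- round(runif(100), 3)
  c3 <- exceedance_curve(mk(scores), "roc50")
  oracle <- vapply(c3$threshold, function(t) sum(sort(scores) >= t) / 100,
                   numeric(1))
  expect_equal(c3$fraction, oracle)
  expect_equal(c3$fraction[1], 1)
  expect_false(is.unsorted(rev(c3$fraction)))
})

test_that("pairwise comparison counts wins, ties and losses", {
  mk <- function(scores) {
    structure(list(per_query = data.frame(
      query_id = paste0("q", seq_along(scores)), roc1 = scores,
      roc50 = scores, n_pos = 1, n_neg = 1, evaluable = TRUE)),
      class = "eval_summary")
  }
  a <- mk(c(0.5, 0.7, 0.9))
  expect_equal(pairwise_compare(a, a)$ties, 3)
  z <- mk(c(0, 0, 0))
  one <- mk(c(1, 1, 1))
  expect_equal(pairwise_compare(one, z)$wins, 3)
  expect_error(pairwise_compare(a, mk(c(0.1, 0.2))), "query-set mismatch")

  set.seed(37)
  sa <- runif(50); sb <- runif(50)
  pc <- pairwise_compare(mk(sa), mk(sb))
  # brute-force comparison loop
  w <- t <- l <- 0
  for (i in 1:50) {
    d <- sa[i] - sb[i]
    if (d > 1e-9) w <- w + 1 else if (d < -1e-9) l <- l + 1 else t <- t + 1
  }
  expect_equal(c(pc$wins, pc$ties, pc$losses), c(w, t, l))
})

test_that("benchmark container enforces hierarchy invariants", {
  expect_error(benchmark_dataset(data.frame(
    seq_id = c("a", "a"), family_id = c("f", "f"),
    superfamily_id = c("S", "S"))), "duplicate seq_ids")
  expect_error(benchmark_dataset(data.frame(
    seq_id = c("a", "b"), family_id = c("f", "f"),
    superfamily_id = c("S1", "S2"))), "more than one superfamily")
  expect_warning(benchmark_dataset(data.frame(
    seq_id = c("a", "b"), family_id = c("f", "g"),
    superfamily_id = c("S1", "S1"))), "fewer than 2 superfamilies")

  # TSV round trip preserves records and summary counts
  tb <- toy_benchmark()
  path <- tempfile(fileext = ".tsv")
  write_benchmark_tsv(tb, path)
  back <- read_benchmark_tsv(path)
  expect_equal(back$records, tb$records)
  expect_equal(benchmark_summary(back),
               list(n_sequences = 6L, n_families = 4L, n_superfamilies = 3L))
})
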