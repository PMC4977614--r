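# Consensus deleteriousness vote and intolerance sub-stage.

calls_df <- function(mt, pp, pr, sf) {
  data.frame(mutation_taster = mt, polyphen2 = pp, provean = pr, sift = sf,
             stringsAsFactors = FALSE)
}

test_that("vote needs >= 3 deleterious calls; missing is no vote", {
  D <- "deleterious"; T_ <- "tolerated"
  expect_true(consensus_deleterious(calls_df(D, D, D, T_)))
  expect_false(consensus_deleterious(calls_df(D, D, T_, T_)))
  expect_true(consensus_deleterious(calls_df(D, D, D, NA)))
  expect_false(consensus_deleterious(calls_df(D, D, NA, NA)))
  expect_error(consensus_deleterious(data.frame(sift = D, bogus = D,
                                                polyphen2 = D,
                                                mutation_taster = D)),
               "keyed exactly")
  expect_error(consensus_deleterious(calls_df("maybe", D, D, D)), "calls")
})

test_that("the vote is symmetric under predictor permutation", {
  set.seed(13)
  vals <- c("deleterious", "tolerated", NA)
  for (rep in 1:30) {
    draw <- sample(vals, 4, replace = TRUE)
    base <- consensus_deleterious(calls_df(draw[1], draw[2], draw[3],
                                           draw[4]))
    perm <- sample(draw)
    expect_equal(consensus_deleterious(calls_df(perm[1], perm[2], perm[3],
                                                perm[4])),
                 base)
  }
})

test_that("intolerance counts qualifying sources and flags unassessed genes", {
  p <- data.frame(intol_inhouse = c(10, 80, NA, 30),
                  intol_esp = c(20, 90, NA, NA),
                  intol_exac = c(15, NA, NA, NA))
  r <- passes_intolerance(p, max_pct = 25, min_sources = 2)
  # rows 3 and 4 have fewer than min_sources percentiles available: they
  # pass with the unassessed flag (intolerance is supplementary evidence)
  expect_equal(r$pass, c(TRUE, FALSE, TRUE, TRUE))
  expect_equal(r$unassessed, c(FALSE, FALSE, TRUE, TRUE))
  # boundary: percentile equal to max_pct qualifies (<=)
  expect_true(passes_intolerance(data.frame(intol_inhouse = 25,
                                            intol_esp = NA,
                                            intol_exac = NA),
                                 max_pct = 25, min_sources = 1)$pass)
  expect_error(passes_intolerance(data.frame(intol_inhouse = 101,
                                             intol_esp = NA,
                                             intol_exac = NA)),
               "percentiles")
  expect_error(passes_intolerance(p, min_sources = 4), "min_sources")
})

test_that("evaluate_coding: vote gate, splicing bypass, synonymous rejection, sub-stage counts", {
  set.seed(17)
  n <- 12
  del <- function(k) c(rep("deleterious", k), rep("tolerated", 4 - k))
  votes <- c(4, 3, 3, 3, 2, 2, 1, 0, 4, 2, 3, 0)
  ann <- list(mutation_taster = character(n), polyphen2 = character(n),
              provean = character(n), sift = character(n),
              intol_inhouse = runif(n, 0, 100))
  for (i in seq_len(n)) {
    d <- del(votes[i])
    ann$mutation_taster[i] <- d[1]; ann$polyphen2[i] <- d[2]
    ann$provean[i] <- d[3]; ann$sift[i] <- d[4]
  }
  region <- rep("missense", n)
  region[9] <- "splicing"      # high-impact: bypasses the vote
  region[10] <- "other_coding" # synonymous-like: manual review
  co <- mk_cohort(n, region = region, ann = ann)
  ev <- evaluate_coding(co)
  # 4 missense variants pass the vote (votes >= 3, rows 1:4 and 11)
  expect_equal(sum(ev$verdict[region == "missense"]), 5L)
  expect_true(ev$verdict[9])       # splicing retained
  expect_true(ev$high_impact[9])
  expect_false(ev$verdict[10])     # other_coding rejected...
  expect_match(ev$review_reason[10], "manual review")
  expect_equal(ev$n_post_vote, 6L)
  expect_lte(ev$n_post_intolerance, ev$n_post_vote)
  # disabled sub-stage is the identity on counts
  off <- evaluate_coding(co, intolerance_action = "off")
  expect_equal(off$n_post_intolerance, off$n_post_vote)
  # gate mode never keeps more than flag mode
  gate <- evaluate_coding(co, intolerance_action = "gate")
  expect_true(all(ev$verdict | !gate$verdict))
  expect_error(evaluate_coding(mk_cohort(1, region = "utr3")), "coding")
})
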