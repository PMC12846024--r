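truth6 <- function(n, motion = "M1", category = "target") {
  data.frame(trial_id = sprintf("T%03d", seq_len(n)), motion = motion,
             category = category, stringsAsFactors = FALSE)
}

test_that("retrospective ambiguity labeling is exactly the misclassified set", {
  tr <- truth6(150)
  d_all_right <- make_decisions(tr$trial_id, rep("M1", 150))
  expect_length(label_ambiguous(d_all_right, tr), 0)
  out <- rep("M1", 150); out[c(3, 77, 150)] <- "M2"
  d3 <- make_decisions(tr$trial_id, out)
  expect_equal(sort(label_ambiguous(d3, tr)),
               sort(tr$trial_id[c(3, 77, 150)]))
  # guards: no REJECT inputs, target category only
  out_rej <- out; out_rej[5] <- "REJECT"
  expect_error(label_ambiguous(make_decisions(tr$trial_id, out_rej), tr),
               "no-rejection")
  tr_mix <- tr; tr_mix$category[1] <- "unknown"
  expect_error(label_ambiguous(d3, tr_mix), "target")
})

test_that("accuracy is correct-accepted over accepted and undefined when all rejected", {
  tr <- truth6(150)
  out <- rep("M1", 150); out[1:15] <- "M2"  # 135 correct, none rejected
  expect_equal(accuracy(make_decisions(tr$trial_id, out), tr), 0.9)
  expect_true(is.na(accuracy(make_decisions(tr$trial_id,
                                            rep("REJECT", 150)), tr)))
  # rejecting every misclassified trial and no correct one gives 1.0
  out2 <- rep("M1", 150); out2[1:15] <- "REJECT"
  expect_equal(accuracy(make_decisions(tr$trial_id, out2), tr), 1.0)
  # removing only misclassified trials can never lower accuracy
  withr::with_seed(5, {
    for (i in 1:25) {
      o <- sample(c("M1", "M2"), 60, replace = TRUE)  # truth is all M1
      base <- mean(o == "M1")
      o_rej <- o
      wrong <- which(o != "M1")
      if (length(wrong))
        o_rej[sample(wrong, sample(length(wrong), 1))] <- "REJECT"
      d <- make_decisions(truth6(60)$trial_id, o_rej)
      stopifnot(isTRUE(accuracy(d, truth6(60)) >= base))
    }
    succeed()
  })
})

test_that("rejection rate is per-category rejected over total and conserves counts", {
  tr <- rbind(truth6(100), truth6(50, motion = "RadialFlexion",
                                  category = "unknown"))
  tr$trial_id <- sprintf("T%03d", seq_len(150))
  out <- rep("M1", 150)
  out[101:121] <- "REJECT"  # 21 of 50 unknown rejected
  d <- make_decisions(tr$trial_id, out)
  expect_equal(rejection_rate(d, tr, "unknown"), 0.42)
  expect_equal(rejection_rate(d, tr, "target"), 0)
  expect_true(is.na(rejection_rate(d, tr, "nontarget")))
  expect_equal(rejection_rate(make_decisions(tr$trial_id,
                                             rep("REJECT", 150)), tr,
                              "target"), 1.0)
  # accepted + rejected = total, exactly
  m <- merge(d, tr, by = "trial_id")
  for (cat in c("target", "unknown"))
    expect_equal(sum(!m$rejected[m$category == cat]) +
                   sum(m$rejected[m$category == cat]),
                 sum(m$category == cat))
})

test_that("rejection precision is unintended-over-rejected, undefined at zero rejections", {
  tr <- truth6(100)
  out <- rep("M1", 100); out[1:20] <- "REJECT"
  d <- make_decisions(tr$trial_id, out)
  expect_equal(rejection_precision(d, tr$trial_id[c(1:11, 50:70)]), 0.55)
  expect_true(is.na(rejection_precision(make_decisions(tr$trial_id,
                                                       rep("M1", 100)),
                                        tr$trial_id[1:5])))
  expect_equal(rejection_precision(d, tr$trial_id[1:20]), 1.0)
})

test_that("operating-point selection minimizes distance to (0, 1) with ties to smaller", {
  expect_equal(select_operating_point(c(1, 2), c(0.3, 0), c(0.5, 1))$param, 2)
  # hand-computed: sqrt(.2^2+.4^2)=0.4472 vs sqrt(.4^2+.1^2)=0.4123
  sel <- select_operating_point(c(0.5, 0.9), c(0.2, 0.4), c(0.6, 0.9))
  expect_equal(sel$param, 0.9)
  expect_equal(sel$distance, sqrt(0.4^2 + 0.1^2), tolerance = 1e-12)
  expect_equal(select_operating_point(5, 0.9, 0.1)$param, 5)
  tie <- select_operating_point(c(2, 1), c(0.3, 0.3), c(0.7, 0.7))
  expect_equal(tie$param, 1)
  expect_error(select_operating_point(numeric(0), numeric(0), numeric(0)))
})

test_that("paired tests use the pair count for Bonferroni and handle degenerate columns", {
  A <- c(0.8, 0.9, 0.7, 0.85)
  tab <- data.frame(A = A, B = A - c(0.12, 0.08, 0.11, 0.09),
                    C = A, D = A - c(0.3, 0.28, 0.33, 0.29))
  st <- paired_tests(tab)
  expect_equal(nrow(st), 6)              # 4 systems -> 6 pairs
  expect_equal(unique(st$alpha_adj), 0.05 / 6)
  # identical columns: t = 0, p = 1
  ac <- st[st$system_a == "A" & st$system_b == "C", ]
  expect_equal(ac$t, 0)
  expect_equal(ac$p, 1)
  expect_equal(ac$mean_diff, 0)
  # cross-check one pair against stats::t.test directly
  ab <- st[st$system_a == "A" & st$system_b == "B", ]
  ref <- t.test(tab$A, tab$B, paired = TRUE)
  expect_equal(ab$t, unname(ref$statistic))
  expect_equal(ab$p, ref$p.value)
  expect_equal(ab$mean_diff, 10)
  # 3 mechanisms -> 3 pairs, alpha = 0.05/3
  st3 <- paired_tests(tab[, c("B", "C", "D")])
  expect_equal(nrow(st3), 3)
  expect_equal(unique(st3$alpha_adj), 0.05 / 3)
  # undefined sessions dropped pairwise
  tab$B[2] <- NA
  st_na <- paired_tests(tab[, c("A", "B")])
  expect_equal(st_na$n, 3)
})

test_that("a session evaluation satisfies the structural decision contracts", {
  ev <- cached_session_eval()
  rep <- ev$report
  expect_setequal(rep$mechanism,
                  c("baseline", "ocsvm", "bpnn_entropy", "ovr_ro"))
  base <- rep[rep$mechanism == "baseline", ]
  expect_equal(base$rr_target, 0)
  expect_equal(base$rr_unknown, 0)
  expect_equal(base$rr_nontarget, 0)
  expect_true(is.na(base$rp_ambiguous))  # zero rejections -> undefined
  ok <- !is.na(rep$accuracy)
  expect_true(all(rep$accuracy[ok] >= 0 & rep$accuracy[ok] <= 1))
  rr <- unlist(rep[, c("rr_target", "rr_ambiguous", "rr_unknown",
                       "rr_nontarget")])
  expect_true(all(rr[!is.na(rr)] >= 0 & rr[!is.na(rr)] <= 1))
  # ambiguous ids are a subset of target test trials
  tt <- ev$bundle$split$test
  expect_true(all(ev$ambiguous$svm %in%
                    tt$trial_id[tt$category == "target"]))
  expect_true(all(ev$ambiguous$bpnn %in%
                    tt$trial_id[tt$category == "target"]))
})
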