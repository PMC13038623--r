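test_that("Welch t reproduces the reference baseline statistics", {
  s <- reference_baseline_summaries()
  w <- function(v) {
    r <- s[s$variable == v, ]
    welch_t(meanA = r$mean_nsbvd, sdA = r$sd_nsbvd, nA = 15,
            meanB = r$mean_control, sdB = r$sd_control, nB = 15)
  }
  expect_equal(w("npc")$t, 2.756, tolerance = 0.02)
  expect_equal(w("pfv")$t, -4.024, tolerance = 0.02)
  expect_equal(w("near_phoria")$t, -1.335, tolerance = 0.02)
  expect_lt(w("npc")$p, 0.05)
  expect_lt(w("pfv")$p, 0.001)
  expect_gt(w("near_phoria")$p, 0.05)
})

test_that("Welch t identities: antisymmetry, summaries = raw, degenerate inputs", {
  set.seed(50)
  a <- rnorm(12, 5, 2); b <- rnorm(15, 4, 1)
  r1 <- welch_t(a, b)
  # matches stats::t.test
  ref <- t.test(a, b)
  expect_equal(r1$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(r1$df, unname(ref$parameter), tolerance = 1e-12)
  expect_equal(r1$p, ref$p.value, tolerance = 1e-12)
  # swapping groups negates t, preserves p
  r2 <- welch_t(b, a)
  expect_equal(r2$t, -r1$t)
  expect_equal(r2$p, r1$p)
  # summary form equals raw form
  r3 <- welch_t(meanA = mean(a), sdA = sd(a), nA = length(a),
                meanB = mean(b), sdB = sd(b), nB = length(b))
  expect_equal(r3$t, r1$t, tolerance = 1e-12)
  # identical constants: t = 0, p = 1
  expect_equal(welch_t(rep(2, 5), rep(2, 6))[c("t", "p")], list(t = 0, p = 1))
  expect_warning(rz <- welch_t(rep(1, 5), rep(2, 5)), "infinite")
  expect_true(is.infinite(rz$t))
})

test_that("Mann-Whitney U handles orderings, symmetry and matches the exact test", {
  # extreme ordering: all B exceed A
  expect_equal(mann_whitney(c(1, 2), c(3, 4))$U, 0)
  # identical multisets: Z = 0
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$Z, 0)
  # exact enumeration matches wilcox.test; normal approximation is close
  set.seed(51)
  for (i in 1:10) {
    a <- rnorm(4); b <- rnorm(4, 0.8)
    mine <- mann_whitney(a, b)
    ref <- wilcox.test(a, b, exact = TRUE)
    expect_equal(mine$U, unname(ref$statistic))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
    # normal approximation with continuity correction stays within 0.05
    approx_p <- 2 * pnorm(-abs(mine$Z))
    expect_lt(abs(approx_p - mine$p), 0.05)
  }
  # larger samples use the tie-corrected normal approximation
  a <- c(rnorm(15), 3); b <- c(rnorm(15), 3)  # one tie
  mine <- mann_whitney(a, b)
  ref <- wilcox.test(a, b, correct = TRUE, exact = FALSE)
  expect_equal(mine$p, ref$p.value, tolerance = 1e-9)
  expect_error(mann_whitney(numeric(0), 1), "empty")
})

test_that("chi-square reproduces the matched-sex-ratio case and scales as N phi^2", {
  r <- chi_square(matrix(c(7, 7, 8, 8), 2))
  expect_equal(r$chisq, 0)
  expect_equal(r$p, 1)
  # perfect association of 15/0 vs 0/15
  expect_equal(chi_square(matrix(c(15, 0, 0, 15), 2))$chisq, 30)
  # doubling all counts doubles chi-square
  tab <- matrix(c(9, 4, 6, 11), 2)
  expect_equal(chi_square(2 * tab)$chisq, 2 * chi_square(tab)$chisq,
               tolerance = 1e-12)
  # row/column swap invariance
  expect_equal(chi_square(tab[2:1, ])$chisq, chi_square(tab)$chisq)
  expect_equal(chi_square(tab[, 2:1])$chisq, chi_square(tab)$chisq)
  # agrees with the uncorrected reference implementation
  ref <- suppressWarnings(chisq.test(tab, correct = FALSE))
  expect_equal(chi_square(tab)$chisq, unname(ref$statistic), tolerance = 1e-12)
  expect_error(chi_square(matrix(c(0, 0, 3, 4), 2)), "zero margin")
})

test_that("the normality gate routes clean and heavy-tailed data sensibly", {
  # Gaussian draws pass the gate in most repetitions (expected rate
  # 0.95^2 ~ 0.90; bound set 3 binomial SDs below)
  set.seed(52)
  normal_rate <- mean(replicate(100, {
    normality_gate(rnorm(15), rnorm(15)) == "normal"
  }))
  expect_gt(normal_rate, 0.80)
  # heavy tails (t with 1 df) are flagged nearly always
  heavy_rate <- mean(replicate(100, {
    normality_gate(rt(15, 1), rt(15, 1)) == "non_normal"
  }))
  expect_gt(heavy_rate, 0.90)
  # degenerate constant samples are non-normal by convention
  expect_equal(normality_gate(rep(1, 5), rnorm(5)), "non_normal")
  expect_error(normality_gate(c(1, 2), rnorm(5)), "n >= 3")
})

test_that("baseline comparison flags the genuinely different variables", {
  # power simulation at the reference effect sizes: NPC (expected power
  # ~0.74 at these summaries) and PFV (~0.97) should flag often, NFV
  # (null) rarely; bounds are set ~3 binomial SDs from those expectations
  hits <- t(vapply(1:100, function(s) {
    tab <- simulate_clinical_table(seed = s)
    cb <- compare_baseline(tab)
    c(npc = cb$significant[cb$variable == "npc"],
      pfv = cb$significant[cb$variable == "pfv"],
      nfv = cb$significant[cb$variable == "nfv"])
  }, logical(3)))
  expect_gt(mean(hits[, "npc"]), 0.55)
  expect_gt(mean(hits[, "pfv"]), 0.85)
  expect_lt(mean(hits[, "nfv"]), 0.15)
  # identical groups: no excess of significant flags
  set.seed(53)
  null_flags <- mean(replicate(30, {
    tab <- simulate_clinical_table(seed = sample.int(1e6, 1))
    tab$npc <- rnorm(30, 5, 1)  # overwrite with a null variable
    cb <- compare_baseline(tab)
    cb$significant[cb$variable == "npc"]
  }))
  expect_lt(null_flags, 0.25)
  # sex row uses chi-square and is never significant for matched groups
  cb <- compare_baseline(simulate_clinical_table(seed = 1))
  expect_equal(cb$test[cb$variable == "sex"], "chi_square")
  expect_equal(cb$p[cb$variable == "sex"], 1)
  expect_error(compare_baseline(data.frame(group = "nsbvd", npc = 1)),
               "both groups")
})

test_that("subtype rules reproduce the diagnostic criteria", {
  # convergence insufficiency: marked near exophoria, receded NPC, weak PFV
  expect_equal(as.character(classify_subtype(list(
    near_phoria = -8, distance_phoria = -2, npc = 7, near_pfv = 10))), "CI")
  # mid-normal values: no subtype
  expect_length(classify_subtype(list(
    near_phoria = -3, distance_phoria = -1, npc = 5,
    near_pfv = 20, near_nfv = 15, distance_pfv = 20, distance_nfv = 10,
    ac_a = 4)), 0)
  # divergence insufficiency from distance esophoria + weak distance NFV
  expect_equal(as.character(classify_subtype(list(
    distance_phoria = 5, distance_nfv = 3))), "DI")
  # convergence excess: near esophoria, high AC/A, weak near NFV
  expect_equal(as.character(classify_subtype(list(
    near_phoria = 4, ac_a = 6, near_nfv = 10))), "CE")
  # missing fields exclude a rule rather than failing it
  out <- classify_subtype(list(near_phoria = -8))
  expect_true("CI" %in% attr(out, "skipped"))
  # purity: identical input, identical output
  m <- list(near_phoria = -8, distance_phoria = -2, npc = 7, near_pfv = 10)
  expect_identical(classify_subtype(m), classify_subtype(m))
  # the rule table is data-driven: dropping CI rows disables CI
  rules <- nsbvd_criteria()
  out2 <- classify_subtype(m, rules[rules$subtype != "CI", ])
  expect_false("CI" %in% out2)
})
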