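make_assoc <- function(id, freq, OR, pval, n_cases = 5000, n_controls = 5000) {
  data.frame(id = id, risk_allele = "A", freq = freq, OR = OR, pval = pval,
             n_cases = n_cases, n_controls = n_controls,
             stringsAsFactors = FALSE)
}

test_that("association tables read, validate, and carry effective n", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\trisk_allele\tfreq\tOR\tpval\tn_cases\tn_controls",
               "rs1\tA\t0.30\t1.25\t1e-12\t4000\t6000",
               "rs2\tG\t0.10\t1.40\t1e-9\t2000\t2000"), path)
  tab <- read_assoc(path)
  expect_equal(nrow(tab), 2L)
  expect_equal(tab$eff_n, c(2 / (1 / 4000 + 1 / 6000), 2000))

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("id\tfreq\tOR\tpval\tn_cases\tn_controls",
               "rs1\t1.2\t1.25\t1e-12\t4000\t6000"), bad)
  expect_error(read_assoc(bad), "frequencies")
})

test_that("greedy selection follows power ordering and the r2 threshold", {
  tab <- make_assoc(paste0("rs", 1:5),
                    freq = c(0.3, 0.2, 0.4, 0.1, 0.25),
                    OR = c(1.2, 1.3, 1.15, 1.4, 1.25),
                    pval = c(1e-10, 1e-9, 1e-12, 1e-8, 0.01),
                    n_cases = c(9000, 3000, 9000, 2000, 9000),
                    n_controls = c(9000, 3000, 9000, 2000, 9000))
  # rs5 fails significance; r2 couples rs1-rs3 and rs2-rs4
  ids <- tab$id
  r2 <- matrix(0, 5, 5, dimnames = list(ids, ids))
  r2["rs1", "rs3"] <- r2["rs3", "rs1"] <- 0.8
  r2["rs2", "rs4"] <- r2["rs4", "rs2"] <- 0.3
  sel <- greedy_select(tab, r2 = r2, r2_max = 0.005, alpha = 5e-8)

  # brute-force re-execution of the rule
  keep <- tab[tab$pval <= 5e-8, ]
  keep$eff_n <- 2 / (1 / keep$n_cases + 1 / keep$n_controls)
  keep <- keep[order(-keep$eff_n, keep$pval), ]
  acc <- character(0)
  for (i in seq_len(nrow(keep))) {
    if (all(r2[keep$id[i], acc] <= 0.005)) acc <- c(acc, keep$id[i])
  }
  expect_equal(sel$id, acc)
  # rs3 beats rs1 on p-value at equal power and excludes it via r2;
  # rs2 enters; rs4 is excluded by its r2 with rs2
  expect_equal(sel$id, c("rs3", "rs2"))

  # all-independent and perfectly-correlated corner cases
  expect_equal(greedy_select(tab, r2 = NULL)$id, c("rs3", "rs1", "rs2", "rs4"))
  two <- make_assoc(c("a", "b"), c(0.3, 0.3), c(1.2, 1.2), c(1e-10, 1e-10),
                    n_cases = c(9000, 1000), n_controls = c(9000, 1000))
  r2two <- matrix(1, 2, 2, dimnames = list(c("a", "b"), c("a", "b")))
  expect_equal(greedy_select(two, r2 = r2two)$id, "a")

  # missing r2 entries exclude conservatively
  r2small <- matrix(0, 1, 1, dimnames = list("rs3", "rs3"))
  warns <- capture_warnings(sel2 <- greedy_select(tab, r2 = r2small))
  expect_match(warns, "missing r2", all = TRUE)
  expect_equal(sel2$id, "rs3")
})

test_that("winner's-curse correction shrinks, is odd, and vanishes for huge z", {
  cc <- qnorm(1 - 5e-8 / 2)
  s <- 0.02

  # far above threshold: negligible correction
  b_big <- 30 * s
  expect_lt(abs(winners_curse_correct(b_big, s) - b_big) / b_big, 1e-3)

  # just at threshold: strict shrinkage toward zero
  b_edge <- cc * s
  corr <- winners_curse_correct(b_edge, s)
  expect_lt(corr, b_edge)
  expect_gt(corr, 0)

  # odd symmetry
  expect_equal(winners_curse_correct(-b_edge, s), -corr)

  # non-significant input refused
  expect_error(winners_curse_correct(0.5 * cc * s, s), "not significant")

  # se back-computed from the p-value
  b <- log(1.3)
  p <- 2 * (1 - pnorm(6))
  expect_equal(winners_curse_correct(b, se = NA, p_value = p),
               winners_curse_correct(b, se = b / 6))
})

test_that("correction reduces bias in a truncated-reporting simulation", {
  set.seed(77)
  s <- 0.018; beta <- 4 * s  # true z = 4: only lucky draws reach significance
  cc <- qnorm(1 - 5e-8 / 2)
  n_rep <- 2e4
  z <- rnorm(n_rep, mean = beta / s)
  z <- z[abs(z) >= cc]  # condition on significance
  b_obs <- z * s
  b_corr <- vapply(b_obs, winners_curse_correct, numeric(1), se = s)
  expect_lt(abs(mean(b_corr) - beta), abs(mean(b_obs) - beta))
  expect_gt(mean(b_obs), beta)  # raw estimates are inflated
})

test_that("per-SNP liability variance: null, symmetry, small-effect expansion", {
  spec <- disease_spec(f = 0.1, h2 = 0.5)
  expect_equal(snp_variance_explained(0.3, 1, spec), 0)

  # allele-label invariance
  expect_equal(snp_variance_explained(0.3, 1.4, spec),
               snp_variance_explained(0.7, 1 / 1.4, spec), tolerance = 1e-10)

  # monotone in the odds ratio
  vs <- vapply(c(1.05, 1.1, 1.2, 1.4, 1.8), snp_variance_explained,
               numeric(1), freq = 0.3, spec = spec)
  expect_true(all(diff(vs) > 0))

  # first-order expansion: V ~ 2p(1-p) (f(1-f) log R / phi(T))^2 for R near 1
  f <- 0.1; p <- 0.3; R <- 1.05
  approx <- 2 * p * (1 - p) * (f * (1 - f) * log(R) / dnorm(qnorm(1 - f)))^2
  expect_equal(snp_variance_explained(p, R, spec), approx, tolerance = 0.05)
})

test_that("per-SNP variance matches a genotype-level simulation oracle", {
  spec <- disease_spec(f = 0.1, h2 = 0.5)
  p <- 0.3; R <- 1.6
  v_analytic <- snp_variance_explained(p, R, spec)

  # reconstruct the genotype risks the model implies, then simulate
  q <- c((1 - p)^2, 2 * p * (1 - p), p^2)
  o0 <- uniroot(function(lo) {
    odds <- exp(lo) * R^(0:2); sum(q * odds / (1 + odds)) - spec$f
  }, c(-10, 5), tol = 1e-12)$root
  fj <- exp(o0) * R^(0:2) / (1 + exp(o0) * R^(0:2))
  mj <- spec$threshold - qnorm(1 - fj)

  n_draw <- 2e5
  set.seed(31)
  geno <- sample(0:2, n_draw, replace = TRUE, prob = q)
  liab <- mj[geno + 1] + rnorm(n_draw)
  # liability decomposition: genotype term variance over total variance
  v_emp <- var(mj[geno + 1]) / var(liab)
  se <- sd((mj[geno + 1] - mean(mj[geno + 1]))^2) / sqrt(n_draw)
  expect_lt(abs(v_emp - v_analytic), max(3e-4, 3 * se))
  # and the implied genotype risks reproduce the population frequency
  expect_lt(abs(mean(liab >= spec$threshold) - spec$f),
            three_se(spec$f, n_draw))
})

test_that("total pi sums independent contributions and reports both variants", {
  spec <- disease_spec(f = 0.05, h2 = 0.4)
  one <- make_assoc("rs1", 0.25, 1.3, 1e-10)
  empty <- total_pi(one[0, ], spec)
  expect_equal(empty$pi_raw, 0)

  two <- rbind(one, transform(one, id = "rs1b"))
  r1 <- total_pi(one, spec)
  r2 <- total_pi(two, spec)
  expect_equal(r2$total_variance_raw, 2 * r1$total_variance_raw)

  # borderline-significant effects: corrected pi strictly below raw pi
  borderline <- make_assoc(paste0("rs", 1:4), c(0.2, 0.3, 0.4, 0.15),
                           c(1.18, 1.22, 1.15, 1.3),
                           pval = c(2e-8, 1e-8, 3e-8, 4e-8))
  rb <- total_pi(borderline, spec)
  expect_lt(rb$pi_corrected, rb$pi_raw)
  expect_gt(rb$pi_corrected, 0)
})
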