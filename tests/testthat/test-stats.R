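test_that("one-way repeated measures matches a hand-computed decomposition", {
  # 4 subjects x 3 levels, values fixed; brute-force sums of squares
  y <- matrix(c(4, 6, 5,
                3, 5, 7,
                6, 7, 9,
                2, 4, 6), 4, 3, byrow = TRUE)
  d <- data.frame(subject = rep(1:4, 3), level = rep(c("a", "b", "c"), each = 4),
                  value = as.vector(y))
  an <- rm_anova(d, dv = "value", within = "level")
  grand <- mean(y)
  ss_level <- 4 * sum((colMeans(y) - grand)^2)
  ss_subj <- 3 * sum((rowMeans(y) - grand)^2)
  ss_tot <- sum((y - grand)^2)
  ss_err <- ss_tot - ss_level - ss_subj
  F_expected <- (ss_level / 2) / (ss_err / 6)
  row <- an[an$effect == "level", ]
  expect_equal(row$ss, ss_level)
  expect_equal(row$ss_error, ss_err)
  expect_equal(row$df1, 2)
  expect_equal(row$df2, 6)
  expect_equal(row$F, F_expected)
  expect_equal(row$p, pf(F_expected, 2, 6, lower.tail = FALSE))
})

test_that("the mixed decomposition reproduces aov error strata exactly", {
  set.seed(41)
  d <- expand.grid(subject = 1:8, w1 = c("a", "b", "c"), w2 = c("x", "y"))
  d$group <- ifelse(d$subject <= 4, "G1", "G2")
  d$value <- rnorm(nrow(d)) + 0.5 * as.numeric(factor(d$w1)) +
    0.4 * (d$group == "G1") * as.numeric(factor(d$w2))
  an <- rm_anova(d, dv = "value", within = c("w1", "w2"), between = "group")
  da <- d
  for (col in c("subject", "w1", "w2", "group")) da[[col]] <- factor(da[[col]])
  aa <- summary(stats::aov(value ~ group * w1 * w2 +
                             Error(subject / (w1 * w2)), data = da))
  grab <- function(stratum, effect) {
    tab <- aa[[stratum]][[1]]
    i <- match(effect, trimws(rownames(tab)))
    c(ss = tab[i, "Sum Sq"], df = tab[i, "Df"], F = tab[i, "F value"])
  }
  checks <- list(
    list("Error: subject", "group", "group"),
    list("Error: subject:w1", "w1", "w1"),
    list("Error: subject:w1", "group:w1", "group:w1"),
    list("Error: subject:w2", "w2", "w2"),
    list("Error: subject:w2", "group:w2", "group:w2"),
    list("Error: subject:w1:w2", "w1:w2", "w1:w2"),
    list("Error: subject:w1:w2", "group:w1:w2", "group:w1:w2"))
  for (ck in checks) {
    ref <- grab(ck[[1]], ck[[2]])
    row <- an[an$effect == ck[[3]], ]
    expect_equal(row$ss, unname(ref["ss"]), tolerance = 1e-10)
    expect_equal(row$df1, unname(ref["df"]))
    expect_equal(row$F, unname(ref["F"]), tolerance = 1e-10)
  }
})

test_that("Greenhouse-Geisser epsilon agrees with the multivariate route", {
  skip_if_not_installed("car")
  set.seed(42)
  n <- 12
  d <- expand.grid(subject = 1:n, w1 = c("a", "b", "c", "d"))
  d$group <- ifelse(d$subject <= n / 2, "G1", "G2")
  # induce a sphericity violation with an AR-like covariance
  base <- rnorm(n)
  d$value <- rnorm(nrow(d), sd = 0.5) +
    base[d$subject] * as.numeric(factor(d$w1))
  an <- rm_anova(d, dv = "value", within = "w1", between = "group")
  Y <- matrix(NA, n, 4)
  lev <- c("a", "b", "c", "d")
  for (j in 1:4) {
    sel <- d$w1 == lev[j]
    Y[, j] <- d$value[sel][order(d$subject[sel])]
  }
  grp <- factor(ifelse(seq_len(n) <= n / 2, "G1", "G2"))
  av <- car::Anova(stats::lm(Y ~ grp), idata = data.frame(w1 = factor(lev)),
                   idesign = ~w1, type = 3)
  s <- summary(av, multivariate = FALSE)
  eps_car <- s$pval.adjustments["w1", "GG eps"]
  expect_equal(an$epsilon[an$effect == "w1"], unname(eps_car),
               tolerance = 1e-10)
  expect_equal(an$p_gg[an$effect == "group:w1"],
               unname(s$pval.adjustments["grp:w1", "Pr(>F[GG])"]),
               tolerance = 1e-10)
})

test_that("epsilon bounds and the conservativeness of the correction hold", {
  set.seed(43)
  for (rep in 1:20) {
    k <- sample(3:5, 1)
    n <- sample(6:12, 1)
    d <- expand.grid(subject = seq_len(n), w = letters[seq_len(k)])
    d$value <- rnorm(nrow(d)) + rnorm(n)[d$subject] * runif(k)[as.integer(factor(d$w))]
    an <- rm_anova(d, dv = "value", within = "w")
    eps <- an$epsilon[an$effect == "w"]
    expect_gte(eps, 1 / (k - 1))
    expect_lte(eps, 1)
    expect_gte(an$p_gg[an$effect == "w"], an$p[an$effect == "w"])
  }
  # two-level factor: epsilon is 1 and correction changes nothing
  d2 <- expand.grid(subject = 1:6, w = c("a", "b"))
  d2$value <- rnorm(12)
  an2 <- rm_anova(d2, dv = "value", within = "w")
  expect_equal(an2$epsilon[an2$effect == "w"], 1)
  expect_equal(an2$p_gg[an2$effect == "w"], an2$p[an2$effect == "w"])
})

test_that("compound-symmetric data give epsilon near 1", {
  set.seed(44)
  n <- 200; k <- 5
  # exchangeable covariance: shared subject effect + iid noise
  Y <- matrix(rnorm(n), n, k) + matrix(rnorm(n * k), n, k)
  d <- data.frame(subject = rep(seq_len(n), k),
                  w = rep(letters[1:k], each = n), value = as.vector(Y))
  an <- rm_anova(d, dv = "value", within = "w")
  expect_gt(an$epsilon[an$effect == "w"], 0.9)
})

test_that("rm_anova rejects unbalanced or degenerate inputs", {
  d <- expand.grid(subject = 1:4, w = c("a", "b"))
  d$value <- rnorm(8)
  expect_error(rm_anova(d[-1, ], dv = "value", within = "w"), "unbalanced")
  d_dup <- rbind(d, d[1, ])
  expect_error(rm_anova(d_dup, dv = "value", within = "w"),
               "more than one observation")
  d$group <- c("G1", "G1", "G1", "G2")[d$subject]
  expect_error(rm_anova(d, dv = "value", within = "w", between = "group"),
               "2 subjects per group")
  expect_error(rm_anova(d, dv = "value", within = "nope"), "column missing")
})

test_that("uncorrected tests inflate type-I error where GG restores it", {
  set.seed(45)
  n <- 10; k <- 4
  # strongly non-spherical null: one dominant random component
  lam <- c(6, 1, 0.3, 0.1)
  n_sims <- 800
  p_raw <- p_gg <- numeric(n_sims)
  for (s in seq_len(n_sims)) {
    Y <- sapply(seq_len(k), function(j) rnorm(n, sd = sqrt(lam[j])))
    Y <- Y + rnorm(n)                      # subject offsets (no true effect)
    d <- data.frame(subject = rep(seq_len(n), k),
                    w = rep(letters[1:k], each = n), value = as.vector(Y))
    an <- rm_anova(d, dv = "value", within = "w")
    p_raw[s] <- an$p[an$effect == "w"]
    p_gg[s] <- an$p_gg[an$effect == "w"]
  }
  expect_gt(mean(p_raw < 0.05), 0.07)          # inflated without correction
  expect_lte(mean(p_gg < 0.05), 0.06)          # restored by GG
})

test_that("Bonferroni pairwise comparisons multiply p by the pair count", {
  set.seed(46)
  d <- data.frame(subject = 1:30,
                  group = rep(c("English", "Chinese", "Thai"), each = 10))
  d$value <- rnorm(30) + (d$group == "English") * 2
  out <- bonferroni_pairwise(d, "group")
  expect_equal(nrow(out), 3)
  expect_equal(out$p_adj, pmin(1, out$p_raw * 3))
  expect_true(all(out$p_adj <= 1))
  # a raw p of ~0.4 caps at 1 with 3 pairs
  d0 <- d; d0$value <- rnorm(30)
  out0 <- bonferroni_pairwise(d0, "group")
  expect_true(any(out0$p_adj == 1) || all(out0$p_raw < 1 / 3))
  expect_error(bonferroni_pairwise(d[d$group == "Thai", ], "group"),
               "single level")
})

test_that("Bonferroni familywise error stays at or below the nominal level", {
  set.seed(47)
  n_sims <- 2000
  fw <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    d <- data.frame(subject = 1:18, group = rep(c("A", "B", "C"), each = 6),
                    value = rnorm(18))
    fw[s] <- any(bonferroni_pairwise(d, "group")$p_adj < 0.05)
  }
  # binomial 3-sigma margin around 0.05
  expect_lte(mean(fw), 0.05 + 3 * sqrt(0.05 * 0.95 / n_sims))
})

test_that("Spearman correlation handles monotone data, ties and small n", {
  x <- c(1, 2, 3, 4, 5, 6, 7, 8, 9, 10, 11, 12)
  expect_equal(spearman_cor(x, exp(x))$rho, 1)
  expect_equal(spearman_cor(x, -x^3)$rho, -1)
  # invariance under strictly monotone transforms
  set.seed(48)
  a <- rnorm(15); b <- rnorm(15)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(exp(a), b)$rho)
  expect_equal(spearman_cor(a, b)$rho, spearman_cor(a, qlogis(pnorm(b)))$rho)
  # ties: brute-force average-rank oracle
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8, 9, 10, 11, 3)
  yt <- c(2, 1, 4, 4, 6, 7, 7, 9, 8, 12, 11, 2)
  rho_oracle <- stats::cor(rank(xt), rank(yt))
  res <- spearman_cor(xt, yt)
  expect_equal(res$rho, rho_oracle)
  expect_equal(res$rho, unname(stats::cor.test(xt, yt,
                                               method = "spearman",
                                               exact = FALSE)$estimate))
  # t-approximation p at n >= 10 matches the closed form
  tstat <- res$rho * sqrt((12 - 2) / (1 - res$rho^2))
  expect_equal(res$p, 2 * pt(abs(tstat), 10, lower.tail = FALSE))
  # small n: exact permutation against cor.test's exact p (no ties)
  xs <- c(3, 1, 4, 1.5, 5, 9)
  ys <- c(2, 7, 1, 8, 2.5, 6)
  res_s <- spearman_cor(xs, ys)
  ref <- stats::cor.test(xs, ys, method = "spearman", exact = TRUE)
  expect_equal(res_s$rho, unname(ref$estimate))
  expect_equal(res_s$p, ref$p.value, tolerance = 1e-10)
  expect_equal(res_s$method, "exact permutation")
  # degenerate input flagged
  expect_true(spearman_cor(rep(1, 5), 1:5)$degenerate)
  expect_error(spearman_cor(1:2, 1:2), "at least 3")
})

test_that("follow-up ANOVAs slice the table by the requested factor", {
  set.seed(49)
  d <- expand.grid(subject = 1:6, w = c("a", "b"), g = c("X", "Y"))
  d$subject <- paste0(d$g, d$subject)
  d$value <- rnorm(nrow(d)) + (d$g == "X" & d$w == "b") * 2
  out <- follow_up_anovas(d, "g", dv = "value", within = "w")
  expect_named(out, c("X", "Y"))
  expect_lt(out$X$p[out$X$effect == "w"], 0.05)
  expect_gt(out$Y$p[out$Y$effect == "w"], 0.05)
})

test_that("the validation suite is deterministic under a fixed seed", {
  des <- tiny_design(groups = c(English = 2, Chinese = 2), standards = 4,
                     deviants = 4, seed = 1)
  des$blocks <- des$blocks[1, , drop = FALSE]
  fam <- build_wavelet_family(28, 50, 11, 9, 512)
  mid <- c(default_montage()$midline, "M2")
  args <- list(designs = list(d = des), effects = "group:session",
               n_sims = 2, seed = 77,
               within = c("session", "condition", "location"),
               channels = mid, fam = fam)
  r1 <- do.call(type1_power_suite, args)
  r2 <- do.call(type1_power_suite, args)
  expect_identical(r1, r2)
  expect_true(all(r1$rate >= r1$ci_lo & r1$rate <= r1$ci_hi))
})
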