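test_that("group summaries: hand means/SDs, single samples flagged", {
  psi <- data.frame(
    sample_id = c("a", "b", "c", "d", "e", "f", "g"),
    bin_id = "x",
    psi = c(1, 1, 1, 0.2, 0.4, 0.6, 0.5))
  meta <- data.frame(
    sample_id = c("a", "b", "c", "d", "e", "f", "g"),
    genotype = c("WT", "WT", "WT", "mdm", "mdm", "mdm", "WT"),
    muscle = c(rep("EDL", 6), "psoas"))
  s <- summarize_groups(make_psi_table(psi, meta))
  wt <- s[s$genotype == "WT" & s$muscle == "EDL", ]
  expect_equal(wt$mean_psi, 1); expect_equal(wt$sd_psi, 0)
  md <- s[s$genotype == "mdm", ]
  expect_equal(md$mean_psi, 0.4); expect_equal(md$sd_psi, 0.2)
  single <- s[s$muscle == "psoas", ]
  expect_equal(single$n, 1L); expect_equal(single$sd_psi, 0)
  expect_true(single$single_sample)
})

test_that("missing PSI is excluded from n; empty cells are dropped loudly", {
  psi <- data.frame(sample_id = c("a", "b", "c", "d"), bin_id = "x",
                    psi = c(0.5, NA, NA, NA))
  meta <- data.frame(sample_id = c("a", "b", "c", "d"),
                     genotype = c("WT", "WT", "mdm", "mdm"),
                     muscle = "EDL")
  expect_warning(s <- summarize_groups(make_psi_table(psi, meta)),
                 "dropped")
  expect_equal(nrow(s), 1L)
  expect_equal(s$n, 1L)
})

test_that("pooled SD reproduces the small-sample formula", {
  expect_equal(pooled_sd(3, 0.1, 3, 0.1), 0.1)
  expect_equal(pooled_sd(3, 0, 3, 0), 0)
  expect_equal(pooled_sd(4, 0.2, 3, 0.1), sqrt(0.028), tolerance = 1e-12)
  expect_error(pooled_sd(1, 0.1, 1, 0.1), "n1 \\+ n2 > 2")
})

test_that("pooled SD is symmetric and degree-1 homogeneous", {
  set.seed(3)
  for (i in 1:25) {
    n1 <- sample(2:9, 1); n2 <- sample(2:9, 1)
    s1 <- runif(1); s2 <- runif(1); k <- runif(1, 0.1, 10)
    expect_equal(pooled_sd(n1, s1, n2, s2), pooled_sd(n2, s2, n1, s1))
    expect_equal(pooled_sd(n1, k * s1, n2, k * s2),
                 k * pooled_sd(n1, s1, n2, s2))
  }
})

test_that("dPSI sign convention and antisymmetry", {
  summ <- data.frame(
    bin_id = "x", genotype = c("WT", "mdm"), muscle = "EDL",
    n = 3L, mean_psi = c(0.9, 0.6), sd_psi = c(0.05, 0.05),
    single_sample = FALSE)
  dp <- delta_psi(summ)
  expect_equal(dp$dpsi, -0.3)  # higher WT inclusion is negative
  expect_equal(dp$sd_pooled, 0.05)
  swapped <- delta_psi(summ, mutant = "WT", reference = "mdm")
  expect_equal(swapped$dpsi, -dp$dpsi)
  expect_equal(swapped$sd_pooled, dp$sd_pooled)
  # equal means -> zero
  summ$mean_psi <- c(0.7, 0.7)
  expect_equal(delta_psi(summ)$dpsi, 0)
})

test_that("unmatched bins are skipped with a warning", {
  summ <- data.frame(
    bin_id = c("x", "y"), genotype = c("WT", "mdm"), muscle = "EDL",
    n = 3L, mean_psi = 0.5, sd_psi = 0.1, single_sample = FALSE)
  expect_warning(dp <- delta_psi(summ), "unmatched")
  expect_equal(nrow(dp), 0L)
})

test_that("dPSI stays within [-1, 1] on random summaries", {
  set.seed(9)
  summ <- expand.grid(bin_id = letters[1:10], genotype = c("WT", "mdm"),
                      muscle = c("EDL", "psoas"), stringsAsFactors = FALSE)
  summ$n <- 4L
  summ$mean_psi <- runif(nrow(summ))
  summ$sd_psi <- runif(nrow(summ), 0, 0.2)
  dp <- delta_psi(summ)
  expect_true(all(dp$dpsi >= -1 & dp$dpsi <= 1))
  expect_equal(nrow(dp), 20L)
})

random_anova_data <- function(effects = c(g = 0, m = 0, gm = 0), sigma = 0.1) {
  cells <- expand.grid(genotype = c("WT", "mdm"),
                       muscle = c("EDL", "psoas", "soleus"),
                       stringsAsFactors = FALSE)
  d <- do.call(rbind, lapply(seq_len(nrow(cells)), function(i) {
    n <- sample(2:6, 1)  # unbalanced
    g <- cells$genotype[i]; mus <- cells$muscle[i]
    mu <- 0.5 + effects["g"] * (g == "mdm") +
      effects["m"] * (mus == "psoas") +
      effects["gm"] * (g == "mdm" & mus == "soleus")
    data.frame(genotype = g, muscle = mus, psi = rnorm(n, mu, sigma))
  }))
  d$sample_id <- sprintf("s%03d", seq_len(nrow(d)))
  d$bin_id <- "x"
  d
}

as_table <- function(d) {
  make_psi_table(d[, c("sample_id", "bin_id", "psi")],
                 d[, c("sample_id", "genotype", "muscle")])
}

test_that("Type III ANOVA matches the design-matrix least-squares oracle", {
  set.seed(21)
  for (i in 1:20) {
    d <- random_anova_data()
    got <- anova_two_way(as_table(d), "x")
    want <- ls_anova_oracle(d)
    expect_equal(got$F, want$F, tolerance = 1e-8)
    expect_equal(got$p, want$p, tolerance = 1e-8)
    expect_equal(got$df, want$df)
  }
})

test_that("balanced designs: Type I and Type III sums of squares coincide", {
  set.seed(22)
  cells <- expand.grid(genotype = c("WT", "mdm"),
                       muscle = c("EDL", "psoas", "soleus"),
                       stringsAsFactors = FALSE)
  d <- cells[rep(seq_len(nrow(cells)), each = 4), ]
  d$psi <- rnorm(nrow(d), 0.5, 0.1)
  d$sample_id <- sprintf("s%03d", seq_len(nrow(d)))
  d$bin_id <- "x"
  got <- anova_two_way(as_table(d), "x")
  fit <- lm(psi ~ genotype * muscle, data = d)
  type1 <- anova(fit)
  expect_equal(got$F, type1$`F value`[1:3], tolerance = 1e-10)
})

test_that("an injected genotype effect is detected with high power", {
  set.seed(23)
  hits <- 0L
  for (i in 1:20) {
    cells <- expand.grid(genotype = c("WT", "mdm"),
                         muscle = c("EDL", "psoas", "soleus"),
                         stringsAsFactors = FALSE)
    d <- cells[rep(seq_len(nrow(cells)), each = 5), ]
    d$psi <- rnorm(nrow(d), 0.4 + 0.3 * (d$genotype == "mdm"), 0.05)
    d$sample_id <- sprintf("s%03d", seq_len(nrow(d)))
    d$bin_id <- "x"
    res <- anova_two_way(as_table(d), "x")
    if (res$p[res$effect == "genotype"] < 0.001) hits <- hits + 1L
  }
  expect_gte(hits, 19L)
})

test_that("ANOVA input validation", {
  d <- data.frame(sample_id = c("a", "b"), bin_id = "x", psi = c(0.4, 0.5),
                  genotype = "WT", muscle = c("EDL", "psoas"))
  expect_error(anova_two_way(as_table(d), "x"), "2 observed levels")
  expect_null(anova_two_way(make_psi_table(
    data.frame(sample_id = "a", bin_id = "x", psi = NA_real_),
    data.frame(sample_id = "a", genotype = "WT", muscle = "EDL")), "x"))
})

test_that("Holm step-down: hand cases and missing-value propagation", {
  one <- sequential_bonferroni(0.03)
  expect_equal(one$p_adjusted, 0.03)
  h <- sequential_bonferroni(c(0.01, 0.04, 0.03), alpha = 0.05)
  expect_equal(h$p_adjusted, c(0.03, 0.06, 0.06))
  expect_equal(h$significant, c(TRUE, FALSE, FALSE))
  none <- sequential_bonferroni(rep(1, 5))
  expect_false(any(none$significant))
  na <- sequential_bonferroni(c(0.01, NA, 0.04))
  expect_true(is.na(na$p_adjusted[2]))
  expect_equal(na$p_adjusted[c(1, 3)], c(0.02, 0.04))
})

test_that("Holm agrees with the reference implementation and nests between
           Bonferroni and raw rejections", {
  set.seed(31)
  for (i in 1:50) {
    m <- sample(1:30, 1)
    p <- runif(m)^sample(1:3, 1)
    h <- sequential_bonferroni(p, alpha = 0.05)
    expect_equal(h$p_adjusted, p.adjust(p, method = "holm"))
    bonf <- p.adjust(p, method = "bonferroni") <= 0.05
    expect_true(all(h$significant[bonf]))        # Bonferroni subset of Holm
    expect_true(all(p[h$significant] <= 0.05))   # Holm subset of raw
  }
})

test_that("a larger declared family size is more conservative", {
  p <- c(0.01, 0.002, 0.2)
  small <- sequential_bonferroni(p, m = 3)
  big <- sequential_bonferroni(p, m = 142)
  expect_true(all(big$p_adjusted >= small$p_adjusted))
  expect_error(sequential_bonferroni(p, m = 2), "family size")
})

test_that("compare_splicing wires dPSI, ANOVA and Holm together", {
  set.seed(41)
  profile <- default_titin_psi_profile()
  sim <- simulate_splice_counts(
    splice_sim_config(profile, junction_coverage = 400, overdispersion = 0,
                      n_per_group = 4, seed = 77))
  m <- toy_model(400)
  m$bins <- m$bins[m$bins$bin_id %in% unique(profile$bin_id), ]
  tab <- build_psi_table(sim$counts, m, sim$metadata)
  res <- compare_splicing(tab, alpha = 0.05)
  expect_true(all(c("dpsi", "sd_pooled", "p_value", "p_adjusted",
                    "significant") %in% names(res)))
  # PEVK exon 124 was injected down in mdm EDL and soleus, flat in psoas
  e124 <- res[res$bin_id == "124", ]
  expect_lt(e124$dpsi[e124$muscle == "EDL"], -0.25)
  expect_lt(abs(e124$dpsi[e124$muscle == "psoas"]), 0.1)
  expect_true(all(e124$significant))
  # an uninjected Mex5 soleus contrast stays near zero
  e346 <- res[res$bin_id == "346" & res$muscle == "soleus", ]
  expect_lt(abs(e346$dpsi), 0.05)
})
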