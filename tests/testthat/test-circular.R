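test_that("circular mean and resultant length match hand vector sums", {
  m <- circ_mean_rho(c(45, 45, 45))
  expect_equal(m$mean_deg, 45)
  expect_equal(m$rho, 1)
  # antipodal pair: zero resultant, undefined mean
  m <- circ_mean_rho(c(0, 180))
  expect_equal(m$rho, 0)
  expect_false(m$defined)
  expect_true(is.na(m$mean_deg))
  # hand-computed vector sum for {10, 20, 30}
  m <- circ_mean_rho(c(10, 20, 30))
  expect_equal(m$mean_deg, 20, tolerance = 1e-9)
  expect_equal(m$rho, 0.9899, tolerance = 1e-4)
  # wrap-around sample straddling north
  m <- circ_mean_rho(c(350, 10))
  expect_equal(m$mean_deg, 0, tolerance = 1e-9)
})

test_that("rho is 1 only for identical angles and rotation rotates the mean", {
  set.seed(31)
  for (i in 1:10) {
    x <- rvonmises(20, runif(1, 0, 360), runif(1, 0.5, 10))
    m <- circ_mean_rho(x)
    expect_true(m$rho >= 0 && m$rho <= 1)
    expect_lt(m$rho, 1)
    shift <- runif(1, 0, 360)
    m2 <- circ_mean_rho((x + shift) %% 360)
    expect_equal(m2$mean_deg, (m$mean_deg + shift) %% 360, tolerance = 1e-8)
    expect_equal(m2$rho, m$rho, tolerance = 1e-12)
  }
  expect_equal(circ_mean_rho(rep(123.4, 7))$rho, 1)
})

test_that("Watson-Williams is null on copies and powerful on separation", {
  set.seed(32)
  a <- rvonmises(20, 100, 5)
  r <- suppressWarnings(watson_williams(a, a))
  expect_equal(r$statistic, 0, tolerance = 1e-9)
  expect_equal(r$p_value, 1, tolerance = 1e-9)
  # 90 degree separation at kappa 5 is overwhelming at n = 20
  b <- rvonmises(20, 190, 5)
  r <- watson_williams(a, b)
  expect_lt(r$p_value, 1e-6)
  # statistic and p are rotation invariant; means rotate along
  shift <- 73.2
  r2 <- watson_williams((a + shift) %% 360, (b + shift) %% 360)
  expect_equal(r2$statistic, r$statistic, tolerance = 1e-9)
  expect_equal(r2$p_value, r$p_value, tolerance = 1e-9)
  expect_equal(r2$group_means, (r$group_means + shift) %% 360,
               tolerance = 1e-6)
  # degenerate: all angles identical
  r3 <- suppressWarnings(watson_williams(rep(10, 6), rep(10, 6)))
  expect_equal(r3$p_value, 1)
})

test_that("Watson U2 is zero on copies and flags separated clusters", {
  a <- c(0, 1, 2, 3, 4)
  r <- suppressWarnings(watson_two_sample(a, a, mode = "table"))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_bracket, "> 0.10")
  # two tight antipodal clusters: statistic near its maximum; the exact
  # conditional p equals the share of circularly contiguous label
  # assignments, computed here by full enumeration of all C(10,5) splits
  b <- c(180, 181, 182, 183, 184)
  u_obs <- suppressWarnings(watson_two_sample(a, b, mode = "table"))$statistic
  pool <- c(a, b)
  combos <- utils::combn(10, 5)
  u_all <- apply(combos, 2, function(ix)
    sparrowtrack:::.watson_u2_stat(pool[ix], pool[-ix]))
  p_exact <- mean(u_all >= u_obs - 1e-12)
  set.seed(33)
  r <- suppressWarnings(watson_two_sample(a, b, mode = "permutation",
                                          n_perm = 4000))
  expect_lt(abs(r$p_value - p_exact), 0.015)
  expect_lt(r$p_value, 0.05)
})

test_that("Watson U2 is invariant under common rotation and handles ties", {
  set.seed(34)
  a <- rvonmises(12, 40, 3); b <- rvonmises(15, 90, 3)
  u0 <- sparrowtrack:::.watson_u2_stat(a, b)
  for (shift in c(10, 123.4, 359)) {
    u1 <- sparrowtrack:::.watson_u2_stat((a + shift) %% 360,
                                         (b + shift) %% 360)
    expect_equal(u1, u0, tolerance = 1e-10)
  }
  # fully tied data
  expect_equal(sparrowtrack:::.watson_u2_stat(rep(5, 6), rep(5, 8)), 0)
})

test_that("permutation p-values agree with the critical-value brackets", {
  set.seed(35)
  agree <- logical(30)
  for (i in 1:30) {
    sep <- sample(c(0, 40, 120), 1)
    a <- rvonmises(18, 0, 2); b <- rvonmises(18, sep, 2)
    tb <- suppressWarnings(watson_two_sample(a, b, mode = "table"))
    pm <- suppressWarnings(watson_two_sample(a, b, mode = "permutation",
                                             n_perm = 600))
    agree[i] <- switch(tb$p_bracket,
                       "> 0.10" = pm$p_value > 0.08,
                       "< 0.10" = pm$p_value < 0.13 && pm$p_value > 0.03,
                       "< 0.05" = pm$p_value < 0.08 && pm$p_value > 0.005,
                       "< 0.01" = pm$p_value < 0.02)
  }
  expect_gte(mean(agree), 0.95)
})
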