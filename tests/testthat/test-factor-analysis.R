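test_that("phi correlations follow the 2x2 closed form", {
  x <- c(1, 1, 1, 0, 0, 0, 0, 1)
  y <- c(1, 1, 0, 0, 0, 0, 1, 1)
  r <- correlation_matrix(cbind(A = x, B = y))
  a <- sum(x == 1 & y == 1); b <- sum(x == 1 & y == 0)
  cc <- sum(x == 0 & y == 1); d <- sum(x == 0 & y == 0)
  phi <- (a * d - b * cc) /
    sqrt((a + b) * (cc + d) * (a + cc) * (b + d))
  expect_equal(r["A", "B"], phi, tolerance = 1e-12)
  expect_equal(diag(r), c(A = 1, B = 1))

  expect_equal(correlation_matrix(cbind(A = x, B = x))["A", "B"], 1)
  expect_equal(correlation_matrix(cbind(A = x, B = 1 - x))["A", "B"], -1)
  expect_error(correlation_matrix(cbind(A = x, B = rep(1, 8))),
               "'B' is constant")
})

test_that("principal components reproduce closed-form eigenstructure", {
  # identity correlations: every component explains 100/n %
  id <- diag(4); dimnames(id) <- list(paste0("I", 1:4), paste0("I", 1:4))
  lt <- pca_components(id, 4)
  expect_equal(lt$eigenvalues, rep(1, 4))
  expect_equal(lt$pct_explained, rep(25, 4))
  expect_equal(sum(lt$eigenvalues), 4)

  # equicorrelation r: eigenvalues 1+(p-1)r and (p-1 copies of) 1-r
  p <- 5; r <- 0.4
  eq <- matrix(r, p, p); diag(eq) <- 1
  dimnames(eq) <- list(paste0("I", 1:p), paste0("I", 1:p))
  lt2 <- pca_components(eq, p)
  expect_equal(lt2$eigenvalues, c(1 + (p - 1) * r, rep(1 - r, p - 1)),
               tolerance = 1e-10)
  expect_equal(sum(lt2$eigenvalues), p, tolerance = 1e-10)
  expect_equal(tail(lt2$cum_pct_explained, 1), 100, tolerance = 1e-8)
  # loadings reconstruct the correlation matrix at full rank
  expect_equal(lt2$loadings %*% t(lt2$loadings), eq, tolerance = 1e-8,
               ignore_attr = TRUE)

  # rank-1 structure: first eigenvalue equals the item count
  ones <- matrix(1, 3, 3)
  expect_equal(pca_components(ones, 1)$eigenvalues[1], 3, tolerance = 1e-10)

  expect_error(pca_components(eq, 9), "exceeds")
  neg <- matrix(c(1, 2, 2, 1), 2)
  expect_error(pca_components(neg, 2), "positive semidefinite")
})

test_that("varimax preserves communalities and maximises the criterion", {
  set.seed(26)
  # simple-structure loadings are a fixed point up to sign/order
  simple <- rbind(matrix(c(rep(0.8, 5), rep(0, 5)), 5, 2),
                  matrix(c(rep(0, 5), rep(0.7, 5)), 5, 2))
  rownames(simple) <- paste0("I", 1:10)
  rot <- varimax_rotate(simple, normalize = TRUE)
  expect_equal(abs(rot$loadings), abs(simple), tolerance = 1e-6,
               ignore_attr = TRUE)

  for (i in 1:5) {
    raw <- matrix(runif(16, -0.7, 0.9), 8, 2)
    rownames(raw) <- paste0("I", 1:8)
    rot <- varimax_rotate(raw, normalize = FALSE)
    # communalities conserved
    expect_equal(rowSums(rot$loadings^2), rowSums(raw^2),
                 tolerance = 1e-8, ignore_attr = TRUE)
    # rotation matrix orthogonal
    rm <- attr(rot, "rotmat")
    expect_equal(t(rm) %*% rm, diag(2), tolerance = 1e-10)
    # criterion not below the brute-force angle-grid maximum
    crit <- scaleforge:::varimax_criterion(rot$loadings)
    expect_gte(crit, scaleforge:::varimax_criterion(raw) - 1e-12)
    expect_gte(crit, grid_varimax_max(raw) - 1e-5)
  }
})

test_that("items are assigned by dominant loading with graded quality", {
  load <- rbind(I1 = c(0.62, 0.10), I2 = c(0.41, 0.05),
                I3 = c(0.39, 0.20), I4 = c(-0.45, 0.10),
                I5 = c(0.50, -0.50), I6 = c(0.55, 0.45))
  lt <- scaleforge:::new_loadings_table(load, eigenvalues = colSums(load^2),
                                        n_items = 6)
  asg <- assign_items(lt)
  expect_equal(asg$quality,
               c("adequate", "low", "very_low", "negative", "adequate",
                 "adequate"))
  # tie: lowest component index, flagged as cross-loading
  expect_equal(asg$component[asg$item_id == "I5"], "PC1")
  expect_true(asg$cross_loading[asg$item_id == "I5"])
  expect_true(asg$cross_loading[asg$item_id == "I6"])   # 0.45 >= 0.75*0.55
  expect_false(asg$cross_loading[asg$item_id == "I1"])
})

test_that("Cronbach's alpha matches its closed forms", {
  # two parallel items with phi = 0.5: Spearman-Brown alpha = 2r/(1+r)
  x <- c(1, 1, 1, 0, 0, 0, 0, 1)
  y <- c(1, 1, 0, 0, 0, 0, 1, 1)
  m <- cbind(x, y)
  r <- cor(x, y)
  expect_equal(r, 0.5, tolerance = 1e-12)
  expect_equal(cronbach_alpha(m), 2 * r / (1 + r), tolerance = 1e-12)
  expect_equal(cronbach_alpha(m), 2 / 3, tolerance = 1e-12)

  # identical items: alpha = 1
  expect_equal(cronbach_alpha(cbind(x, x, x)), 1)
  # exactly uncorrelated equal-variance items: alpha = 0
  u <- cbind(c(0, 0, 1, 1), c(0, 1, 0, 1))
  expect_equal(cronbach_alpha(u), 0)
  expect_error(cronbach_alpha(cbind(c(1, 1), c(0, 0))), "variance")
  # alpha invariant to shifting one item by a constant (real-valued case)
  set.seed(27)
  z <- matrix(rnorm(60), 20, 3)
  z2 <- z; z2[, 2] <- z2[, 2] + 5
  expect_equal(cronbach_alpha(z), cronbach_alpha(z2), tolerance = 1e-12)
})

test_that("alpha grows with test length at fixed loading (Spearman-Brown)", {
  set.seed(28)
  gen <- function(k) {
    f <- rnorm(3000)
    sapply(seq_len(k), function(i)
      as.integer(0.7 * f + sqrt(1 - 0.49) * rnorm(3000) > 0))
  }
  alphas <- vapply(c(3, 6, 12), function(k) cronbach_alpha(gen(k)),
                   numeric(1))
  expect_true(all(diff(alphas) > 0))
})

test_that("KMO reproduces the anti-image hand computation", {
  eq <- matrix(0.5, 3, 3); diag(eq) <- 1
  expect_equal(kmo(eq), 0.75 / (0.75 + 1 / 3), tolerance = 1e-10)
  expect_equal(kmo(eq), 0.6923, tolerance = 1e-4)

  # vanishing correlations: partials equal the raw correlations, so the
  # index tends to its no-common-variance value of 1/2 (closed form for
  # equicorrelation eps: KMO = (1+2*eps)^2 / (1 + (1+2*eps)^2))
  near <- diag(4) + matrix(0.01, 4, 4) - diag(0.01, 4)
  expect_equal(kmo(near), (1.02^2) / (1 + 1.02^2), tolerance = 1e-4)
  # partial structure dominating the marginals drives the index down:
  # adjacent-only (moving-average) correlation has partials that spread
  # beyond the marginal band
  ma <- diag(6); for (i in 1:5) ma[i, i + 1] <- ma[i + 1, i] <- 0.4
  expect_lt(kmo(ma), 0.5)

  # independent oracle on a 4-variable matrix: partial correlations by
  # regression residuals
  set.seed(29)
  z <- matrix(rnorm(400), 100, 4) %*% matrix(runif(16, -1, 1), 4, 4)
  r <- cor(z)
  partials <- matrix(0, 4, 4)
  for (i in 1:3) for (j in (i + 1):4) {
    others <- setdiff(1:4, c(i, j))
    ri <- lm.fit(cbind(1, z[, others]), z[, i])$residuals
    rj <- lm.fit(cbind(1, z[, others]), z[, j])$residuals
    partials[i, j] <- partials[j, i] <- cor(ri, rj)
  }
  off <- upper.tri(r)
  expected <- sum(r[off]^2) / (sum(r[off]^2) + sum(partials[off]^2))
  expect_equal(kmo(r), expected, tolerance = 1e-10)

  sing <- matrix(1, 3, 3)
  expect_error(kmo(sing), "singular")
})

test_that("the area report recovers planted structure and stays area-local", {
  cfg <- sim_config(n_subjects = 1200,
                    items_per_area = c(emotional = 21, dissociative = 6,
                                       psychopathological = 9),
                    factors_per_area = c(3, 2, 3), loading = 0.8,
                    missing_rate = 0, n_informative = 5, n_fixed = 4,
                    n_fixed_informative = 2)
  study <- simulate_study(cfg, seed = 41)
  rep_emo <- area_report(study$data, area = "emotional", n_components = 3)
  expect_s3_class(rep_emo, "area_report")
  expect_equal(rep_emo$n_items, 21)
  # congruence of rotated loadings with the planted per-factor pattern
  planted <- study$truth$loadings[study$data$catalog$area == "emotional", 1:3]
  cong <- tucker_congruence(rep_emo$loadings$loadings, planted)
  expect_true(all(cong > 0.9))
  expect_gt(rep_emo$alpha, 0.6)
  expect_true(rep_emo$kmo >= 0 && rep_emo$kmo <= 1)

  # separation contract: the emotional report ignores other areas' items
  emo_ids <- study$data$catalog$item_id[study$data$catalog$area == "emotional"]
  direct <- area_report(study$data$responses[, emo_ids], n_components = 3)
  expect_equal(rep_emo$loadings$loadings, direct$loadings$loadings,
               tolerance = 1e-10)
  expect_equal(rep_emo$alpha, direct$alpha)

  expect_error(area_report(study$data, area = "dissociative",
                           n_components = 7), "components")
})
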