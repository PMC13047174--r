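test_that("temporal moments are the per-feature mean and n-1 SD", {
  mom <- temporal_moments(cbind(a = c(0.1, 0.2, 0.3), b = c(0.1, 0.1, 0.1)))
  expect_equal(mom$mu, c(0.2, 0.1))
  expect_equal(mom$sigma, c(0.1, 0))
  expect_error(temporal_moments(rbind(c(0.1, 0.3), c(0.2, 0.4))), ">= 3 time points")
})

test_that("an exact power law is recovered to machine precision", {
  mu <- 10^seq(-3, -1, length.out = 40)
  mom <- data.frame(feature_id = seq_along(mu), mu = mu, sigma = 0.2 * mu^0.8)
  fit <- fit_taylor(mom)
  expect_equal(fit$beta, 0.8, tolerance = 1e-10)
  expect_equal(fit$V, 0.2, tolerance = 1e-10)
  expect_equal(fit$r_squared, 1, tolerance = 1e-10)
  expect_equal(fit$n_features_used, 40)
})

test_that("uninformative features are excluded and counted", {
  mu <- 10^seq(-3, -1, length.out = 25)
  mom <- data.frame(mu = c(mu, 0, 0.1), sigma = c(0.2 * mu^0.8, 0.1, 0))
  fit <- fit_taylor(mom)
  expect_equal(fit$n_excluded, 2)
  expect_error(fit_taylor(mom, min_features = 30), "minimum 30")
})

test_that("the fitted parameters are invariant to the log base", {
  set.seed(8)
  mu <- 10^runif(50, -3, -1)
  sigma <- 0.3 * mu^0.7 * exp(rnorm(50, 0, 0.1))
  fit <- fit_taylor(data.frame(mu = mu, sigma = sigma))
  ln_fit <- lm(log(sigma) ~ log(mu)) # same regression in natural log
  expect_equal(fit$beta, unname(coef(ln_fit)[2]))
  expect_equal(fit$V, exp(unname(coef(ln_fit)[1])))
})

test_that("parameter recovery holds across the (V, beta) grid", {
  # per-cell medians over seeds, then the median across the grid cells
  cell_beta <- cell_v <- c()
  for (V in c(0.1, 0.2, 0.4)) {
    for (beta in c(0.5, 0.75, 1.0)) {
      errs <- vapply(1:6, function(s) {
        x <- simulate_taylor_subject(200, V, beta,
          depth = 1e5,
          seed = round(1e4 * V + 100 * beta) + s
        )
        fit <- fit_taylor(temporal_moments(x / rowSums(x)))
        c(abs(fit$beta - beta), abs(fit$V - V) / V)
      }, numeric(2))
      cell_beta <- c(cell_beta, median(errs[1, ]))
      cell_v <- c(cell_v, median(errs[2, ]))
    }
  }
  expect_lte(median(cell_beta), 0.05)
  expect_lte(median(cell_v), 0.20)
})

test_that("standardization centers and scales on the reference group", {
  set.seed(9)
  fits <- data.frame(
    subject_id = paste0("s", 1:20),
    group = rep(c("adult", "toddler"), c(15, 5)),
    V = c(rlnorm(15, log(0.2), 0.2), rlnorm(5, log(0.5), 0.2)),
    beta = rnorm(20, 0.75, 0.05)
  )
  z <- standardize_params(fits, "adult")
  ref <- z[z$group == "adult", ]
  expect_equal(mean(ref$z_V), 0)
  expect_equal(sd(ref$z_V), 1)
  expect_equal(mean(ref$z_beta), 0)
  expect_equal(sd(ref$z_beta), 1)
  # a fit sitting at the reference mean lands at the origin
  at_mean <- fits[1, ]
  at_mean$V <- mean(ref$V)
  at_mean$beta <- mean(ref$beta)
  z1 <- standardize_params(rbind(fits, at_mean), "adult")
  expect_equal(unlist(z1[nrow(z1), c("z_V", "z_beta")]),
    c(z_V = 0, z_beta = 0),
    tolerance = 1e-10
  )
  expect_error(standardize_params(fits[1:2, ], "adult"), "at least 3")
})

test_that("reference regions nest and contain their center", {
  set.seed(10)
  z <- data.frame(z_V = rnorm(100), z_beta = rnorm(100))
  r68 <- reference_region(z, 0.68)
  r98 <- reference_region(z, 0.98)
  expect_true(all(r98$axes > r68$axes))
  # every point inside the 68% region is inside the 98% region
  in68 <- in_region(r68, z)
  in98 <- in_region(r98, z)
  expect_true(all(in98[in68]))
  expect_true(in_region(r68, matrix(r68$center, 1)))
  expect_error(reference_region(z[1:3, ], 0.68), "at least 5")
})

test_that("per-subject fits inherit group labels and skip short series", {
  coh <- small_cohort(21, n_subjects = c(toddler = 3, adult = 5))
  fits <- fit_taylor_subjects(coh$taxa, coh$metadata)
  expect_equal(nrow(fits), 8)
  expect_setequal(unique(fits$group), c("toddler", "adult"))
  expect_true(all(fits$V > 0) && all(fits$r_squared <= 1))

  short <- coh$metadata[coh$metadata$timepoint <= 2 |
    coh$metadata$subject_id != "tod01", ]
  short_ft <- feature_table(
    as.matrix(coh$taxa)[short$sample_id, , drop = FALSE]
  )
  expect_warning(
    fit_taylor_subjects(short_ft, short),
    "'tod01' has < 3 time points"
  )
})
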