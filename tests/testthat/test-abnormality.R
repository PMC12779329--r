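test_that("HOI selection follows the smaller-mean-z rule with tie-breaks", {
  z <- zscores_from_list(list(
    dominated = list(left = c(-1, -1, -1, -1, -1), right = c(0, 0, 0, 0, 0)),
    close     = list(left = c(-0.2, -0.2, -0.2, -0.2, 0),
                     right = c(-0.3, -0.3, -0.3, -0.3, 0)),
    tied      = list(left = c(-1, 0, 0, 1, 0.5), right = c(0, -1, 1, 0, -0.5)),
    tied_all  = list(left = c(1, -1, 1, -1, 0), right = c(-1, 1, -1, 1, 0))
  ))
  hoi <- select_hoi(z)
  side <- setNames(hoi$hoi_side, hoi$subject_id)
  expect_equal(side[["dominated"]], "left")
  expect_equal(side[["close"]], "right")      # -0.3 < -0.2
  expect_equal(side[["tied"]], "right")       # equal means, right whole-z smaller
  expect_equal(side[["tied_all"]], "left")    # full tie falls back to left
  expect_equal(hoi$whole_hoi_z[hoi$subject_id == "tied"], -0.5)
  expect_equal(unname(unlist(hoi[hoi$subject_id == "dominated",
                                 c("z_CA-DG", "z_SRLM", "z_subiculum", "z_tail")])),
               c(-1, -1, -1, -1))
})

test_that("HOI selection demands both hemispheres", {
  z <- zscores_from_list(list(s1 = list(left = rep(0, 5))))
  expect_error(select_hoi(z), "Both hemispheres")
})

control_zscores <- function(n, seed, shift = 0) {
  set.seed(seed)
  ids <- sprintf("c%04d", seq_len(n))
  purrr::map(ids, function(id) {
    tibble::tibble(subject_id = id,
                   hemisphere = rep(hemispheres(), each = 5),
                   region = rep(all_regions(), 2),
                   z = rnorm(10) + shift)
  }) |> purrr::list_rbind()
}

control_demographics <- function(z) {
  tibble::tibble(subject_id = unique(z$subject_id),
                 group = factor("control", group_levels()),
                 sex = factor("female", c("female", "male")),
                 age_at_scan = 40, scanner = factor("A"))
}

test_that("the pooled reference recovers (0, I) for independent normal z", {
  z <- control_zscores(4000, seed = 31)
  ref <- fit_reference(z, control_demographics(z), mode = "pooled")
  expect_equal(ref$n, 8000)
  expect_true(all(abs(ref$mu) < 3 / sqrt(8000) * 1.5))
  expect_lt(max(abs(ref$C - diag(4))), 0.05)
})

test_that("hoi mode shifts mu negative but keeps the covariance spectrum", {
  z <- control_zscores(4000, seed = 32)
  dem <- control_demographics(z)
  hoi <- fit_reference(z, dem, mode = "hoi")
  pooled <- fit_reference(z, dem, mode = "pooled")
  expect_true(all(hoi$mu < pooled$mu))   # selection of the worse side
  ev_h <- eigen(hoi$C, symmetric = TRUE, only.values = TRUE)$values
  ev_p <- eigen(pooled$C, symmetric = TRUE, only.values = TRUE)$values
  # selecting the hemisphere with the smaller mean compresses variance along
  # the mean direction; the remaining spectrum is untouched
  expect_true(all(abs(ev_h[1:3] - ev_p[1:3]) < 0.1))
  expect_lt(ev_h[4], ev_p[4] - 0.1)
})

test_that("identical control vectors give a singularity error", {
  z <- control_zscores(4, seed = 33)
  z$z <- rep(c(0.5, -1, 0.2, 0.1, 0), 8)[seq_len(nrow(z))]
  z$z <- rep(rep(c(0.5, -1, 0.2, 0.1, 0), 2), 4)
  expect_warning(
    expect_error(fit_reference(z, control_demographics(z)), "singular"),
    "controls")
})

test_that("mahalanobis_score matches its definition and the explicit-inverse oracle", {
  # Euclidean case: identity covariance, centred at 0
  ref <- structure(list(mu = rep(0, 4), C = diag(4), n = 100, mode = "hoi",
                        regions = hoi_regions()),
                   class = "control_reference")
  expect_equal(mahalanobis_score(rep(0, 4), ref), 0)
  expect_equal(mahalanobis_score(rep(1, 4), ref), 2)

  set.seed(34)
  A <- matrix(rnorm(16), 4)
  C <- crossprod(A) + diag(4) * 0.5
  mu <- rnorm(4)
  ref2 <- structure(list(mu = mu, C = C, n = 100, mode = "hoi",
                         regions = hoi_regions()),
                    class = "control_reference")
  Z <- matrix(rnorm(4000), ncol = 4)
  got <- mahalanobis_score(Z, ref2)
  Cinv <- solve(C)  # oracle: explicit inverse quadratic form
  want <- apply(Z, 1, function(z) sqrt(drop(t(z - mu) %*% Cinv %*% (z - mu))))
  expect_lt(max(abs(got - want) / pmax(want, 1e-12)), 1e-10)
  expect_error(mahalanobis_score(rep(0, 3), ref2), "dimension|4-dim")
})

test_that("the score is direction-agnostic and monotone in displacement", {
  set.seed(35)
  A <- matrix(rnorm(16), 4)
  ref <- structure(list(mu = rnorm(4), C = crossprod(A) + diag(4), n = 50,
                        mode = "hoi", regions = hoi_regions()),
                   class = "control_reference")
  for (i in 1:20) {
    v <- rnorm(4)
    expect_equal(mahalanobis_score(ref$mu + v, ref),
                 mahalanobis_score(ref$mu - v, ref))
    m1 <- mahalanobis_score(ref$mu + v, ref)
    m2 <- mahalanobis_score(ref$mu + 1.7 * v, ref)
    expect_gt(m2, m1)
  }
})

test_that("the score is invariant under common invertible re-parameterization", {
  set.seed(36)
  n <- 400
  X <- matrix(rnorm(n * 4), ncol = 4) %*% matrix(c(2, .5, 0, 0,
                                                   .5, 1, .3, 0,
                                                   0, .3, 1, .2,
                                                   0, 0, .2, 1), 4)
  subj <- rnorm(4) * 2
  ref_of <- function(M) {
    structure(list(mu = colMeans(M), C = cov(M), n = nrow(M), mode = "pooled",
                   regions = hoi_regions()), class = "control_reference")
  }
  base <- mahalanobis_score(subj, ref_of(X))
  for (i in 1:10) {
    T <- matrix(rnorm(16), 4)
    while (abs(det(T)) < 0.1) T <- matrix(rnorm(16), 4)
    got <- mahalanobis_score(drop(subj %*% T), ref_of(X %*% T))
    expect_equal(got, base, tolerance = 1e-8)
  }
})

test_that("M^2 of matched Gaussian controls follows chi-squared(4)", {
  set.seed(37)
  A <- matrix(rnorm(16), 4)
  C <- crossprod(A) + diag(4) * 0.3
  mu <- rnorm(4)
  Z <- matrix(rnorm(5000 * 4), ncol = 4) %*% chol(C)
  Z <- sweep(Z, 2, mu, `+`)
  ref <- structure(list(mu = mu, C = C, n = 5000, mode = "pooled",
                        regions = hoi_regions()), class = "control_reference")
  m2 <- mahalanobis_score(Z, ref)^2
  ks <- suppressWarnings(stats::ks.test(m2, "pchisq", df = 4))
  expect_gt(ks$p.value, 0.01)
})

test_that("score_abnormality wires HOI, reference and score together", {
  co <- simulate_cohort(sim_config(n_control = 40, n_responder = 5,
                                   n_nonresponder = 5,
                                   clinical_covariates = FALSE), seed = 38)
  model <- fit_normative(co$volumes, co$demographics)
  z <- zscore(co$volumes, co$demographics, model)
  res <- score_abnormality(z, co$demographics)
  expect_equal(nrow(res), 50)
  expect_true(all(res$mahalanobis >= 0))
  ref <- attr(res, "reference")
  expect_s3_class(ref, "control_reference")
  expect_equal(ref$n, 40)
  # recomputing one subject by hand agrees
  i <- which(res$subject_id == res$subject_id[7])
  zi <- unlist(res[i, c("z_CA-DG", "z_SRLM", "z_subiculum", "z_tail")])
  expect_equal(res$mahalanobis[i], mahalanobis_score(unname(zi), ref))
})
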