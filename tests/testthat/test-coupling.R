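# MI signature scoring, SF-target coupling, randomization test and sign
# agreement.

test_that("mi_score is zero-centered and monotone in signature expression", {
  samples <- paste0("s", 1:6)
  vals <- rbind(
    sig1 = c(10, 10, 10, 2, 2, 2),
    sig2 = c(20, 18, 22, 3, 4, 3),
    other = runif(6, 0, 10)
  )
  colnames(vals) <- samples
  expr <- omics_matrix(vals, "expression")
  sc <- mi_score(expr, c("sig1", "sig2"))
  expect_equal(mean(sc$mi_score), 0, tolerance = 1e-12)
  expect_true(all(sc$mi_score[1:3] > sc$mi_score[4:6]))
  expect_error(mi_score(expr, "sig1"), "fewer than 2")
})

test_that("sample at the cohort mean of every signature gene scores zero", {
  vals <- rbind(sig1 = c(2, 4, 8), sig2 = c(1, 3, 9))
  # log2(x+1) means: sample 2 sits at the mean for a symmetric design
  vals <- rbind(sig1 = 2^c(1, 2, 3) - 1, sig2 = 2^c(2, 3, 4) - 1)
  colnames(vals) <- paste0("s", 1:3)
  sc <- mi_score(omics_matrix(vals, "expression"), c("sig1", "sig2"))
  expect_equal(sc$mi_score[2], 0, tolerance = 1e-12)
})

test_that("sf_target_coupling recovers perfect and null coupling", {
  set.seed(17)
  prof <- setNames(rnorm(20), paste0("s", 1:20))
  psi_vals <- rbind(
    t1 = rank(prof) * 5,       # same ranks as profile
    t2 = rank(prof) * 4 + 1,
    t3 = runif(20, 0, 100)
  )
  colnames(psi_vals) <- names(prof)
  psi <- omics_matrix(pmin(psi_vals, 100), "psi")
  res <- sf_target_coupling(prof, psi, c("t1", "t2"))
  expect_equal(res$median_rho, 1)
  expect_error(sf_target_coupling(prof, psi, character(0)), "no target")
})

coupling_sim <- function(seed = 23, slope = 10) {
  cfg <- generator_config(seed = seed, n_tissues = 2,
                          n_tumor_per_tissue = 25, n_normal_per_tissue = 20,
                          n_sfs = 10, n_background_genes = 120,
                          n_signature_genes = 20, n_exons = 80,
                          n_targets = 40, coupling_slope = slope)
  generate_cohorts(cfg)
}

test_that("randomization test flags planted coupling and respects add-one", {
  sim <- coupling_sim()
  tumor_ids <- sim$samples$sample_id[sim$samples$condition == "tumor"]
  expr <- omics_values(sim$expression)
  psi_tumor <- omics_matrix(omics_values(sim$psi)[, tumor_ids], "psi")
  rt <- randomization_test(
    psi_tumor, sim$truth$target_exons,
    expr[sim$truth$planted_sf_id, tumor_ids],
    sim$expression, focal_id = sim$truth$planted_sf_id,
    B = 99, seed = 4)
  expect_s3_class(rt, "randomization_test")
  expect_lt(rt$p_one_tailed, 0.05)
  expect_gte(rt$p_one_tailed, 1 / 100)
  expect_gt(rt$observed_median_rho, 0)
  # deterministic under seed
  rt2 <- randomization_test(
    psi_tumor, sim$truth$target_exons,
    expr[sim$truth$planted_sf_id, tumor_ids],
    sim$expression, focal_id = sim$truth$planted_sf_id,
    B = 99, seed = 4)
  expect_identical(rt$background_medians, rt2$background_medians)
  # pool exhausted without replacement is an error
  expect_error(randomization_test(
    psi_tumor, sim$truth$target_exons,
    expr[sim$truth$planted_sf_id, tumor_ids],
    sim$expression, focal_id = sim$truth$planted_sf_id,
    B = 10000, seed = 4), "smaller than B")
  td <- tidy(rt)
  expect_equal(td$p_value, rt$p_one_tailed)
})

test_that("randomization p is invariant to monotone profile transforms", {
  sim <- coupling_sim(seed = 29)
  tumor_ids <- sim$samples$sample_id[sim$samples$condition == "tumor"]
  expr <- omics_values(sim$expression)
  psi_tumor <- omics_matrix(omics_values(sim$psi)[, tumor_ids], "psi")
  prof <- expr[sim$truth$planted_sf_id, tumor_ids]
  base_args <- list(psi_tumor, sim$truth$target_exons, prof,
                    sim$expression, focal_id = sim$truth$planted_sf_id,
                    B = 50, seed = 9)
  r1 <- do.call(randomization_test, base_args)
  base_args[[3]] <- exp(prof / max(prof) * 3)  # strictly monotone transform
  r2 <- do.call(randomization_test, base_args)
  expect_identical(r1$observed_median_rho, r2$observed_median_rho)
  expect_identical(r1$p_one_tailed, r2$p_one_tailed)
})

test_that("per-exon MI correlation recovers planted signs in tumors", {
  sim <- coupling_sim(seed = 37)
  mi <- mi_score(sim$expression, sim$signature_genes)
  rhos <- per_exon_mi_correlation(sim$psi, mi, sim$samples)
  expect_true(all(c("exon_id", "tissue", "rho", "p_value") %in% names(rhos)))
  # targets are coupled to the SF, which anticorrelates with proliferation:
  # the majority of defined target correlations should be negative
  tg <- rhos[rhos$exon_id %in% sim$truth$target_exons & !is.na(rhos$rho), ]
  expect_gt(mean(tg$rho < 0), 0.5)
})

test_that("constant PSI yields an undefined MI correlation, not zero", {
  samples <- tiny_samples(5, 0, "lung")
  vals <- rbind(flat = rep(50, 5), varying = c(10, 20, 30, 40, 50))
  colnames(vals) <- samples$sample_id
  psi <- omics_matrix(vals, "psi")
  mi <- tibble::tibble(sample_id = samples$sample_id,
                       mi_score = c(1, 2, 3, 4, 5))
  rhos <- per_exon_mi_correlation(psi, mi, samples)
  expect_true(is.na(rhos$rho[rhos$exon_id == "flat"]))
  expect_equal(rhos$rho[rhos$exon_id == "varying"], 1)
})

test_that("sign agreement test matches the binomial oracle", {
  calls <- tibble::tibble(
    exon_id = paste0("e", 1:10), tissue = "lung",
    dpsi = c(rep(-10, 9), -10), significant = TRUE)
  rhos <- tibble::tibble(
    exon_id = paste0("e", 1:10), tissue = "lung",
    rho = c(rep(-0.5, 9), 0.5))
  res <- sign_agreement_test(calls, rhos)
  expect_equal(res$k, 9)
  expect_equal(res$p_two_sided, 0.021484375)
  # half agreement is chance
  rhos$rho <- rep(c(-0.5, 0.5), 5)
  expect_equal(sign_agreement_test(calls, rhos)$p_two_sided, 1)
  expect_error(sign_agreement_test(calls[0, ], rhos), "no \\(exon")
})
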