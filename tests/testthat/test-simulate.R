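test_that("simulations are deterministic given the seed", {
  a <- simulate_dti(seed = 6)
  b <- simulate_dti(seed = 6)
  expect_identical(a$network$positive_pairs, b$network$positive_pairs)
  expect_identical(a$protein_features, b$protein_features)
  expect_identical(a$drug_features, b$drug_features)

  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_simulation(a, d1); write_simulation(b, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
  expect_false(identical(simulate_dti(seed = 7)$network$positive_pairs,
                         a$network$positive_pairs))
})

test_that("simulated tables have the pipeline's shapes and ranges", {
  sim <- simulate_dti(seed = 6)
  expect_identical(ncol(sim$protein_features), 257L)
  expect_identical(ncol(sim$drug_features), 616L)
  expect_equal(unname(rowSums(sim$protein_features[, -1])),
               rep(1, nrow(sim$protein_features)))
  bits <- as.matrix(sim$drug_features[, -1])
  expect_true(all(bits %in% c(0L, 1L)))
  s <- network_summary(sim$network)
  expect_gt(s$n_positive, 0)
  expect_lt(s$n_positive, s$n_possible)
})

test_that("degenerate densities are rejected", {
  expect_error(simulate_dti(density = 0), "density")
  expect_error(simulate_dti(density = 1), "density")
  expect_error(simulate_dti(n_drugs = 2, n_targets = 2, density = 0.99,
                            latent_dim = 1, seed = 1), "degenerate")
})

test_that("simulated files feed the real pipeline readers", {
  dir <- withr::local_tempdir()
  sim <- simulate_dti(seed = 8)
  write_simulation(sim, dir, pssms = TRUE, protein_length = c(10L, 15L))
  net <- read_interactions(file.path(dir, "interactions.tsv"),
                           drugs = sim$network$drugs,
                           targets = sim$network$targets)
  expect_identical(nrow(net$positive_pairs), nrow(sim$network$positive_pairs))
  fps <- read_fingerprints(file.path(dir, "fingerprints.tsv"))
  expect_identical(fps$drug_id, sim$drug_features$drug_id)
  pssm_files <- list.files(file.path(dir, "pssm"), full.names = TRUE)
  expect_length(pssm_files, length(sim$network$targets))
  p <- parse_pssm(pssm_files[1])
  expect_identical(ncol(p$scores), 20L)
})

test_that("recovered signal strengthens as feature noise shrinks", {
  aucs <- vapply(c(2, 0.6, 0), function(nz) {
    pairs <- simulated_pairs(simulate_dti(noise = nz, seed = 11))
    cv <- suppressWarnings(cross_validate(pairs, seed = 7, k = 50))
    cv$summary$mean[cv$summary$metric == "auc"]
  }, numeric(1))
  expect_true(all(diff(aucs) >= -0.05))   # non-decreasing up to sampling error
  expect_gt(aucs[3], aucs[1])
})

test_that("a zero-dimensional latent space carries no signal", {
  pairs <- simulated_pairs(simulate_dti(latent_dim = 0, seed = 11))
  cv <- suppressWarnings(cross_validate(pairs, seed = 7, k = 50))
  auc <- cv$summary$mean[cv$summary$metric == "auc"]
  expect_gte(auc, 0.4)
  expect_lte(auc, 0.6)
})
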