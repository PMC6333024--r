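test_that("default pedigree reproduces the 13 x 15 family structure", {
  ped <- simulate_pedigree(seed = 1)
  expect_equal(nrow(ped$individuals), 195)
  expect_equal(length(unique(ped$individuals$family)), 13)
  expect_equal(unname(table(ped$individuals$family)[ped$families$family]),
               rep(15L, 13), ignore_attr = TRUE)
  expect_equal(as.vector(table(ped$families$type)[c("BCr", "BCs", "F2")]),
               c(4L, 5L, 4L))
  # every family traces to founders through an F1 hybrid
  expect_true(all(ped$families$hybrid_cat %in% paste0("C", 1:3)))
  expect_true(all(ped$families$hybrid_hdt %in% paste0("HdT", 1:3)))
})

test_that("pedigree handles minimal specs, rejects bad ones, is deterministic", {
  tiny <- simulate_pedigree(pedigree_spec(n_families = 1, family_types = "F2",
                                          individuals_per_family = 2), seed = 5)
  expect_equal(nrow(tiny$individuals), 2)
  expect_error(pedigree_spec(n_families = 0), "positive")
  expect_error(pedigree_spec(family_types = c("BC", rep("F2", 12))), "BCr")
  a <- simulate_pedigree(seed = 99); b <- simulate_pedigree(seed = 99)
  expect_identical(a$individuals, b$individuals)
  expect_identical(a$families, b$families)
})

test_that("genotype simulation respects rates and determinism", {
  ped <- simulate_pedigree(seed = 2)
  p1 <- simulate_genotypes(ped, n_markers = 1000, invariant_fraction = 0.02,
                           missing_rate = 0, seed = 3)
  expect_equal(length(p1$invariant_markers), 20)  # floor(0.02 * 1000)
  expect_true(all(apply(p1$genotypes[, p1$invariant_markers], 2, is_invariant)))
  expect_false(anyNA(p1$genotypes))
  expect_true(all(p1$genotypes %in% 0:2))
  expect_equal(nrow(p1$map), 1000)
  p2 <- simulate_genotypes(ped, n_markers = 1000, invariant_fraction = 0.02,
                           missing_rate = 0, seed = 3)
  expect_identical(p1$genotypes, p2$genotypes)
  expect_error(simulate_genotypes(ped, 100, missing_rate = 1.5), "\\[0, 1\\]")
})

test_that("gene dropping is Mendelian-consistent and F2 segregation is 1:2:1", {
  ped <- simulate_pedigree(seed = 7)
  pan <- simulate_genotypes(ped, n_markers = 2000, missing_rate = 0,
                            invariant_fraction = 0, seed = 8)
  fam <- ped$families
  ind <- ped$individuals
  for (k in seq_len(nrow(fam))) {
    d1 <- pan$hybrid_dosages[, fam$family[k]]
    d2 <- if (fam$type[k] == "F2") d1 else pan$founder_dosages[, fam$parent2[k]]
    G <- pan$genotypes[ind$family == fam$family[k], , drop = FALSE]
    # a gamete from a parent with dosage 0 or 2 is fixed; dosage 1 gives 0 or 1
    min_off <- (d1 == 2) + (d2 == 2)
    max_off <- (d1 > 0) + (d2 > 0)
    expect_true(all(t(G) >= min_off & t(G) <= max_off))
  }
  # F2 families at markers where the hybrid is heterozygous: dosages ~ 1:2:1
  f2 <- fam$family[fam$type == "F2"]
  counts <- c(`0` = 0, `1` = 0, `2` = 0)
  for (f in f2) {
    het <- pan$hybrid_dosages[, f] == 1
    G <- pan$genotypes[ind$family == f, het, drop = FALSE]
    counts <- counts + table(factor(G, levels = 0:2))
  }
  expect_gt(sum(counts), 10000)
  chi <- stats::chisq.test(counts, p = c(0.25, 0.5, 0.25))
  expect_gt(chi$p.value, 0.001)
})

test_that("phenotype simulator calibrates variances and honors structure", {
  ped <- simulate_pedigree(seed = 4)
  pan <- simulate_genotypes(ped, n_markers = 800, missing_rate = 0,
                            invariant_fraction = 0, seed = 5)
  ts <- trait_spec("t", variance_components = c(genotype = 0.46, permanent = 0,
                   poptype = 0.02, plot = 0.05, interaction = 0.1,
                   residual = 0.37), n_qtl = 150, year_means = c(10, 11, 12))
  sim <- simulate_phenotypes(pan, ped, list(ts), seed = 6)
  ph <- sim$phenotypes
  expect_equal(nrow(ph), 585)
  # genetic variance rescaled to hit sigma_g^2 exactly in-sample
  expect_equal(stats::var(sim$truth$t$true_breeding_values), 0.46,
               tolerance = 1e-10)
  # breeding value equals QTL effects times dosages (after centering)
  Wq <- impute_missing(pan$genotypes)[, sim$truth$t$true_qtl_ids]
  g_direct <- drop(Wq %*% sim$truth$t$true_qtl_effects)
  expect_equal(unname(sim$truth$t$true_breeding_values),
               unname(g_direct - mean(g_direct)), tolerance = 1e-12)
  # realized h2 over replicates stays near the specified ratio
  h2s <- sapply(1:20, function(s) {
    tr <- simulate_phenotypes(pan, ped, list(ts), seed = 100 + s)$truth$t
    tr$realized_h2
  })
  expect_equal(mean(h2s), 0.46, tolerance = 0.02)
})

test_that("genotype-only variance gives records differing just by year means", {
  ped <- simulate_pedigree(pedigree_spec(n_families = 2,
                                         family_types = c("F2", "BCr"),
                                         individuals_per_family = 5), seed = 3)
  pan <- simulate_genotypes(ped, n_markers = 200, missing_rate = 0,
                            invariant_fraction = 0, seed = 3)
  ts <- trait_spec("t", variance_components = c(genotype = 1, permanent = 0,
                   poptype = 0, plot = 0, interaction = 0, residual = 0),
                   n_qtl = 50, year_means = c(5, 7, 9))
  ph <- simulate_phenotypes(pan, ped, list(ts), seed = 2)$phenotypes
  wide <- stats::reshape(ph[, c("individual", "year", "value")],
                         idvar = "individual", timevar = "year",
                         direction = "wide")
  expect_equal(wide$value.2 - wide$value.1, rep(2, 10))
  expect_equal(wide$value.3 - wide$value.2, rep(2, 10))
})

test_that("score traits are thresholded into the requested levels", {
  ped <- simulate_pedigree(seed = 9)
  pan <- simulate_genotypes(ped, n_markers = 300, missing_rate = 0,
                            invariant_fraction = 0, seed = 9)
  ts <- trait_spec("score5", type = "score", score_levels = 5, n_qtl = 50)
  ph <- simulate_phenotypes(pan, ped, list(ts), seed = 10)$phenotypes
  expect_true(all(ph$value %in% 1:5))
  occ <- table(ph$value)
  expect_equal(length(occ), 5L)            # every class occupied
  expect_lt(max(occ) / min(occ), 1.5)      # roughly equal occupancy
  expect_error(trait_spec("bad", type = "score", score_levels = 1), ">= 2")
})

test_that("panel round-trips through the tab-separated files", {
  ped <- simulate_pedigree(pedigree_spec(n_families = 2,
                                         family_types = c("BCr", "F2"),
                                         individuals_per_family = 4), seed = 1)
  pan <- simulate_genotypes(ped, n_markers = 50, missing_rate = 0.1, seed = 1)
  gf <- tempfile(fileext = ".tsv"); mf <- tempfile(fileext = ".tsv")
  write_panel(pan, gf, mf)
  back <- read_panel(gf, mf)
  expect_identical(back$genotypes, pan$genotypes)
  expect_identical(back$map, pan$map)
})

test_that("lmm record generator reproduces its nominal variances", {
  vc <- c(genotype = 0.5, permanent = 0, poptype = 0.02, plot = 0.05,
          interaction = 0.1, residual = 0.33)
  vars <- sapply(1:30, function(s) {
    d <- simulate_lmm_records(vc, seed = s)
    stats::var(d$value - c(10, 11, 12)[d$year])  # year means removed
  })
  expect_equal(mean(vars), sum(vc), tolerance = 0.1 * sum(vc))
})
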