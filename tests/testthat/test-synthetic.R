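printed_targets <- list(
  ## per-category values the templates were calibrated against
  cortexN = c(paucimannose = 3.1, "high-mannose" = 62.6,
              "mono-antennary" = 19.0, "bi-antennary" = 13.6,
              "tri-antennary" = 1.7, "tetra-antennary" = 0.14,
              hybrid = 5.5, bisected = 30.3, galactose = 13.5,
              fucose = 34.7, NeuAc = 1.9, NeuGc = 0),
  cerebellumN = c(paucimannose = 1.2, "high-mannose" = 61.1,
                  "mono-antennary" = 13.0, "bi-antennary" = 21.7,
                  "tri-antennary" = 2.6, "tetra-antennary" = 0.32,
                  hybrid = 8.3, bisected = 34.4, galactose = 14.1,
                  fucose = 35.3, NeuAc = 2.9, NeuGc = 0))

test_that("truth templates reproduce the published category totals within one point", {
  for (tmpl in names(printed_targets)) {
    tp <- make_truth_profile(tmpl)
    expect_equal(sum(tp), 100, tolerance = 1e-9)
    ca <- truth_categories(tp)
    tgt <- printed_targets[[tmpl]]
    expect_true(all(abs(ca[names(tgt)] - tgt) < 1),
                label = paste(tmpl, "category deviation"))
  }
  ## O-glycome: overall and within-subtype targets
  to <- make_truth_profile("cortexO")
  co <- truth_categories(to)
  expect_equal(unname(co$overall["O-GalNAc"]), 84.1, tolerance = 1)
  expect_equal(unname(co$overall["O-Man"]), 10.7, tolerance = 1)
  expect_equal(unname(co$o_galnac["core1"]), 90.0, tolerance = 1)
  expect_equal(unname(co$o_man["M1"]), 77.2, tolerance = 1)
  ## plasma: complex, NeuGc-dominated
  pl <- truth_categories(make_truth_profile("plasmaN"))
  expect_gt(unname(pl["NeuGc"]), 50)
  expect_gt(unname(pl["bi-antennary"]), 50)
})

test_that("custom truth profiles are validated", {
  lib <- builtin_glycan_library("N")
  ok <- make_truth_profile("custom", lib, custom = c("Man-5" = 100))
  expect_identical(names(ok), "1579")
  expect_error(make_truth_profile("custom", lib, custom = c("Man-5" = 90)),
               "sum to 100")
  expect_error(make_truth_profile("custom", lib), "named")
})

test_that("spectra are deterministic in the seed", {
  tp <- make_truth_profile("cortexN")
  s1 <- simulate_spectrum(tp, sim_config(), seed = 42)
  s2 <- simulate_spectrum(tp, sim_config(), seed = 42)
  expect_identical(s1, s2)
  s3 <- simulate_spectrum(tp, sim_config(), seed = 43)
  expect_false(identical(s1$peaks, s3$peaks))

  trip1 <- simulate_endoh_triplet(tp, sim_config(), seed = 9)
  trip2 <- simulate_endoh_triplet(tp, sim_config(), seed = 9)
  expect_identical(trip1, trip2)

  design <- data.frame(group = "A", template = "cortexN", n = 2)
  expect_identical(simulate_cohort(design, seed = 3),
                   simulate_cohort(design, seed = 3))
})

test_that("noise-free simulation is recovered exactly end to end", {
  lib <- builtin_glycan_library("N")
  tp <- make_truth_profile("cortexN", lib)
  sp <- simulate_spectrum(tp, noise_free_config(), seed = 1)
  prof <- relative_abundances(annotate(sp, lib))
  expect_equal(prof$abundance[match(names(tp), prof$label)],
               unname(as.numeric(tp)), tolerance = 1e-9)
  ca <- category_abundances(prof, lib)
  expect_equal(ca, truth_categories(tp), tolerance = 1e-6)
})

test_that("noise peaks stay below the S/N threshold and real peaks above it", {
  tp <- make_truth_profile("cortexN")
  sp <- simulate_spectrum(tp, sim_config(), seed = 8)
  n_real <- length(tp)
  expect_true(all(sp$peaks$snr >= 6 | sp$peaks$intensity <
                    6 * 1.4826 * 1.25 * sim_config()$noise_level))
  ann <- annotate(sp, builtin_glycan_library("N"))
  expect_identical(nrow(ann), n_real)
})

test_that("Endo H triplets put each fraction in the right spectrum", {
  lib <- builtin_glycan_library("N")
  cfg <- noise_free_config()

  man5 <- make_truth_profile("custom", lib, custom = c("Man-5" = 100))
  trip <- simulate_endoh_triplet(man5, cfg, seed = 2)
  expect_identical(nrow(trip$post$peaks), 0L)    # fully removed
  expect_equal(trip$endoh$peaks$mz,
               composition_mz(endoh_product(parse_short_name("Man-5"))),
               tolerance = 1e-9)

  fa1b <- make_truth_profile("custom", lib, custom = c("FA1B" = 60,
                                                       "Man-5" = 40))
  trip2 <- simulate_endoh_triplet(fa1b, cfg, seed = 2, post_scale = 1)
  i_pre <- which(abs(trip2$pre$peaks$mz - 1835.93) < 0.1)
  i_post <- which(abs(trip2$post$peaks$mz - 1835.93) < 0.1)
  expect_equal(trip2$post$peaks$intensity[i_post],
               trip2$pre$peaks$intensity[i_pre], tolerance = 1e-9)

  ## designated mixture: residual survives in post
  mix <- make_truth_profile("custom", lib, custom = c("FA1BH4" = 50,
                                                      "FA1B" = 50))
  trip3 <- simulate_endoh_triplet(mix, cfg, seed = 2, post_scale = 1)
  i <- which(abs(trip3$post$peaks$mz - 2040.03) < 0.1)
  j <- which(abs(trip3$pre$peaks$mz - 2040.03) < 0.1)
  expect_equal(trip3$post$peaks$intensity[i] /
                 trip3$pre$peaks$intensity[j], 0.5, tolerance = 1e-9)
})

test_that("per-group effects rescale the targeted categories and renormalise", {
  lib <- builtin_glycan_library("N")
  design <- data.frame(group = c("CTX", "CBLM"),
                       template = "cortexN", n = 1)
  eff <- list(CBLM = c(paucimannose = 1.2 / 3.1))
  coh <- simulate_cohort(design, eff, noise_free_config(), seed = 4)
  ctx <- truth_categories(coh$truth$CTX, lib)
  cb <- truth_categories(coh$truth$CBLM, lib)
  expect_equal(unname(cb["paucimannose"]), 1.2,
               tolerance = 0.05)                 # renormalisation is gentle
  expect_equal(sum(as.numeric(coh$truth$CBLM)), 100, tolerance = 1e-9)
  expect_equal(unname(ctx["paucimannose"]), 3.1, tolerance = 0.05)

  ## n = 1 groups cannot be tested downstream
  m <- spectra_category_matrix(coh$spectra, lib)
  expect_error(one_way_anova(split(m[, "paucimannose"],
                                   c("CTX", "CBLM"))), "fewer than 2")
})

test_that("the realized truth log scores per-sample recovery", {
  lib <- builtin_glycan_library("N")
  design <- data.frame(group = "CTX", template = "cortexN", n = 3)
  coh <- simulate_cohort(design, config = sim_config(), seed = 21)
  m <- spectra_category_matrix(coh$spectra, lib)
  for (sid in rownames(m)) {
    rt <- truth_categories(coh$realized[[sid]], lib)
    expect_equal(m[sid, ], rt, tolerance = 1e-6)
  }
})
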