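test_that("the sensitivity rule follows glycan class", {
  expect_identical(endoh_sensitive(parse_short_name("Man-5")), "sensitive")
  expect_identical(endoh_sensitive(parse_short_name("Man-9")), "sensitive")
  expect_identical(endoh_sensitive(parse_short_name("A1BH5")), "sensitive")
  expect_identical(endoh_sensitive(parse_short_name("FA1BH4")), "sensitive")
  expect_identical(endoh_sensitive(parse_short_name("FA1B")), "insensitive")
  expect_identical(endoh_sensitive(parse_short_name("F2A2G1")),
                   "insensitive")
  expect_identical(endoh_sensitive(parse_short_name("Man-3")), "insensitive")
  expect_error(endoh_sensitive(parse_short_name("C1S2")), "N-glycans only")
})

test_that("product bookkeeping removes one core GlcNAc and the core fucose", {
  p <- endoh_product(parse_short_name("Man-5"))
  expect_identical(composition_label(p), "Hex5HexNAc1")
  expect_identical(p$end_state, "endoh_product")

  expect_error(endoh_product(parse_short_name("FA1B")), "insensitive")

  ## exact product mass identity against the atom-level oracle
  lib <- builtin_glycan_library("N")
  mc <- mass_constants()
  for (e in lib) {
    s <- e$structures[[1]]
    if (endoh_sensitive(s) == "insensitive") next
    prod_mz <- composition_mz(endoh_product(s))
    expect_equal(prod_mz,
                 e$exact_mz - mc$residues[["hexnac"]] -
                   s$core_fucose * mc$residues[["dhex"]],
                 tolerance = 1e-6, label = s$short_name)
    cc <- endoh_product(s)$counts
    expect_equal(prod_mz,
                 oracle_mz(cc[["hex"]], cc[["hexnac"]], cc[["dhex"]],
                           cc[["neuac"]], cc[["neugc"]], "endoh_product"),
                 tolerance = 1e-9)
  }
})

test_that("core-fucosylated and unfucosylated parents give one indistinguishable product", {
  lib <- builtin_glycan_library("N")
  f2 <- lib[["2418"]]$structures[[1]]            # core + antenna fucose
  f1 <- Filter(function(s) s$short_name == "F1A1G1BH4",
               lib[["2244"]]$structures)[[1]]    # antenna fucose only
  expect_identical(f2$core_fucose, 1L)
  expect_identical(f1$core_fucose, 0)
  expect_equal(composition_mz(endoh_product(f2)),
               composition_mz(endoh_product(f1)), tolerance = 1e-9)
  ## ...and the shared product shows up once, with both parents listed
  tab <- endoh_product_table(lib)
  shared <- tab[vapply(tab$parents, function(p) "2418" %in% p, logical(1)), ]
  expect_identical(nrow(shared), 1L)
  expect_setequal(shared$parents[[1]], c("2244", "2418"))
})

test_that("noise-free triplets reproduce the structure rule for every unambiguous mass", {
  lib <- builtin_glycan_library("N")
  for (tmpl in c("cortexN", "cerebellumN")) {
    truth <- make_truth_profile(tmpl, lib)
    trip <- simulate_endoh_triplet(truth, noise_free_config(), seed = 5)
    calls <- infer_sensitivity(trip$pre, trip$endoh, trip$post, lib)
    frac <- vapply(lib[calls$label], `[[`, numeric(1),
                   "endoh_sensitive_fraction")
    unambiguous <- frac %in% c(0, 1)
    expect_identical(
      calls$call[unambiguous],
      unname(ifelse(frac[unambiguous] == 1, "sensitive", "insensitive")))
    ## sensitive parents vanish completely; insensitive ones persist
    expect_true(all(calls$removal_fraction[frac == 1] > 0.99))
    expect_true(all(calls$removal_fraction[frac == 0] < 0.01))
    ## released products corroborate every sensitive call
    expect_true(all(calls$product_observed[frac == 1]))
    ## the designated hybrid/complex mixture is called mixed
    expect_identical(calls$call[calls$label == "2040"], "mixed")
    expect_equal(calls$removal_fraction[calls$label == "2040"], 0.5,
                 tolerance = 0.05)
  }
})

test_that("a missing scaling reference or unclassified mass fails loudly", {
  lib <- builtin_glycan_library("N")
  truth <- make_truth_profile("custom", lib,
                              custom = c("Man-5" = 60, "A1B" = 40))
  trip <- simulate_endoh_triplet(truth, noise_free_config(), seed = 1)
  expect_error(
    infer_sensitivity(trip$pre, trip$endoh, trip$post, lib,
                      reference = "FA1B"),
    "not detected")
  ## the insensitive A1B can serve as reference instead
  calls <- infer_sensitivity(trip$pre, trip$endoh, trip$post, lib,
                             reference = "A1B")
  expect_identical(calls$call[calls$label == "1579"], "sensitive")

  libO <- builtin_glycan_library("O")
  truthO <- make_truth_profile("cortexO", libO)
  expect_error(simulate_endoh_triplet(truthO, noise_free_config(), seed = 1),
               "classification")
})

test_that("inference holds up under realistic acquisition noise", {
  lib <- builtin_glycan_library("N")
  truth <- make_truth_profile("cortexN", lib)
  trip <- simulate_endoh_triplet(truth, sim_config(), seed = 11)
  calls <- suppressWarnings(
    infer_sensitivity(trip$pre, trip$endoh, trip$post, lib))
  frac <- vapply(lib[calls$label], `[[`, numeric(1),
                 "endoh_sensitive_fraction")
  ## complete removal is robust to intensity noise; persistence is measured
  ## through two noisy intensities, so a resistant glycan may drift into the
  ## mixed band but can never look fully removed
  expect_true(all(calls$call[frac == 1] == "sensitive"))
  expect_true(all(calls$call[frac == 0] != "sensitive"))
  expect_true(all(calls$removal_fraction[frac == 0] < 0.5))
  expect_identical(calls$call[calls$label == "2040"], "mixed")
})
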