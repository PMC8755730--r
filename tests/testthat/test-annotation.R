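make_spec <- function(mz, intensity = rep(100, length(mz)),
                      snr = rep(50, length(mz)), ...) {
  glycan_spectrum(data.frame(mz = mz, intensity = intensity, snr = snr), ...)
}

test_that("annotation applies the S/N cutoff and the mass tolerance", {
  lib <- builtin_glycan_library("N")
  sp <- make_spec(1579.8, snr = 50)
  ann <- annotate(sp, lib, tolerance = 0.5, snr_min = 6)
  expect_identical(ann$label, "1579")
  expect_equal(ann$delta, 1579.8 - lib[["1579"]]$exact_mz, tolerance = 1e-9)

  ## S/N below the cutoff: no annotation
  expect_identical(nrow(annotate(make_spec(1579.8, snr = 5), lib)), 0L)
  ## borderline passes: the rule is snr >= snr_min
  expect_identical(nrow(annotate(make_spec(1579.8, snr = 6), lib)), 1L)
  ## outside tolerance: unmatched
  ann2 <- annotate(make_spec(1580.9), lib, tolerance = 0.5)
  expect_identical(nrow(ann2), 0L)
  expect_identical(nrow(attr(ann2, "unmatched")), 1L)
  ## tolerance 0 annotates only exact masses
  exact <- make_spec(lib[["1579"]]$exact_mz)
  expect_identical(annotate(exact, lib, tolerance = 0)$label, "1579")
})

test_that("equidistant peaks break ties to the lower mass with a warning", {
  lib <- glycan_library(list(
    glycan_entry(parse_short_name("Man-5")),
    glycan_entry(parse_short_name("Man-6"))))
  mid <- mean(library_mz(lib))
  expect_warning(ann <- annotate(make_spec(mid), lib, tolerance = 150),
                 "equidistant")
  expect_identical(ann$label, "1579")
})

test_that("annotation is invariant to peak order and spectra without S/N fail loudly", {
  lib <- builtin_glycan_library("N")
  mzs <- c(1579.8, 1835.9, 2070.0, 2214.1)
  a1 <- annotate(make_spec(mzs, intensity = 1:4), lib)
  a2 <- annotate(make_spec(rev(mzs), intensity = 4:1), lib)
  expect_identical(a1$label, a2$label)
  expect_identical(a1$intensity, a2$intensity)

  no_snr <- make_spec(mzs, snr = rep(NA_real_, 4))
  expect_error(annotate(no_snr, lib), "estimation is disabled")
  expect_error(annotate(make_spec(1579.8), glycan_library(list())), "empty")
})

test_that("relative abundances normalise to 100% and reject empty input", {
  lib <- builtin_glycan_library("N")
  one <- relative_abundances(annotate(make_spec(1579.8), lib))
  expect_equal(one$abundance, 100)

  three <- relative_abundances(annotate(
    make_spec(c(1579.8, 1835.9, 2070.0), intensity = c(1, 1, 2)), lib))
  expect_equal(sort(three$abundance), c(25, 25, 50))
  expect_equal(sum(three$abundance), 100, tolerance = 1e-6)

  k <- 4
  eq <- relative_abundances(annotate(
    make_spec(c(1579.8, 1835.9, 2070.0, 2214.1)), lib))
  expect_equal(eq$abundance, rep(100 / k, k))

  empty <- annotate(make_spec(1579.8, snr = 1), lib)
  expect_error(relative_abundances(empty), "empty profile")
})

test_that("profiles are invariant under global intensity rescaling", {
  lib <- builtin_glycan_library("N")
  mzs <- c(1579.8, 1835.9, 2070.0)
  p1 <- relative_abundances(annotate(make_spec(mzs, intensity = c(5, 3, 2)),
                                     lib))
  p2 <- relative_abundances(annotate(make_spec(mzs,
                                               intensity = 1e4 * c(5, 3, 2)),
                                     lib))
  expect_equal(p1$abundance, p2$abundance, tolerance = 1e-12)
})

test_that("group aggregation reports mean and SEM with zero-filled masses", {
  lib <- builtin_glycan_library("N")
  prof <- function(mzs, int)
    relative_abundances(annotate(make_spec(mzs, intensity = int), lib))
  p1 <- prof(c(1579.8, 1835.9), c(10, 90))
  p2 <- prof(c(1579.8, 1835.9), c(20, 80))

  two <- aggregate_profiles(list(p1, p2))
  expect_equal(two$mean[two$label == "1579"], 15)
  expect_equal(two$sem[two$label == "1579"], 5)          # sd 7.071 / sqrt(2)

  same <- aggregate_profiles(list(p1, p1))
  expect_true(all(same$sem == 0))

  single <- aggregate_profiles(list(p1))
  expect_equal(single$mean, p1$abundance[match(single$label, p1$label)])
  expect_true(all(is.na(single$sem)))

  ## mass absent from one profile counts as zero
  p3 <- prof(c(1579.8, 1835.9, 2070.0), c(10, 80, 10))
  mix <- aggregate_profiles(list(p1, p3))
  expect_equal(mix$mean[mix$label == "2070"], 5)
})

test_that("top-k ranking matches a direct sort oracle and breaks ties by mass", {
  gp <- function(labels, mzs, means) {
    structure(data.frame(label = labels, exact_mz = mzs, mean = means,
                         sem = NA_real_),
              class = c("group_profile", "data.frame"))
  }
  g1 <- gp(c("a", "b", "c"), c(1100, 1200, 1300), c(50, 30, 20))
  g2 <- gp(c("a", "b", "c"), c(1100, 1200, 1300), c(10, 50, 40))
  ## oracle: rank by cross-group means
  oracle <- names(sort(-c(a = 30, b = 40, c = 30)))
  tk <- top_k(list(g1 = g1, g2 = g2), 3)
  expect_identical(tk$label[1], "b")
  ## a and c tie at 30: ascending mass puts a first
  expect_identical(tk$label[2:3], c("a", "c"))
  expect_identical(sort(tk$label), sort(oracle))

  ## identical groups: ranking equals the within-group ranking
  expect_identical(top_k(list(g1, g1), 3)$label, c("a", "b", "c"))
  ## k beyond the mass count returns everything
  expect_identical(nrow(top_k(list(g1), 10)), 3L)
})

test_that("category abundances follow the rule table and the splitting policy", {
  lib <- builtin_glycan_library("N")
  prof <- function(labels, ab)
    structure(data.frame(label = labels,
                         exact_mz = library_mz(lib)[labels],
                         abundance = ab),
              class = c("glycome_profile", "data.frame"))

  all_man5 <- category_abundances(prof("1579", 100), lib)
  expect_equal(unname(all_man5["high-mannose"]), 100)
  expect_true(all(all_man5[setdiff(names(all_man5), "high-mannose")] == 0))

  half <- category_abundances(prof(c("1579", "2040"), c(50, 50)), lib)
  expect_equal(unname(half[c("high-mannose", "mono-antennary", "hybrid",
                             "bisected", "fucose")]),
               c(50, 50, 50, 50, 50))

  ## fractional policy splits the 2040 mass across its two isomers
  frac <- category_abundances(prof("2040", 100), lib, policy = "fractional")
  expect_equal(unname(frac[c("mono-antennary", "bi-antennary", "hybrid",
                             "fucose")]),
               c(50, 50, 50, 100))

  ## unknown mass: strict policy errors, lenient warns
  bad <- prof("1579", 100); bad$label <- "9999"
  expect_error(category_abundances(bad, lib), "9999")
})

test_that("an O-profile concentrated on the 1257 glycan is pure sialylated core 1", {
  libO <- builtin_glycan_library("O")
  prof <- structure(data.frame(label = "1257",
                               exact_mz = libO[["1257"]]$exact_mz,
                               abundance = 100),
                    class = c("glycome_profile", "data.frame"))
  ca <- category_abundances(prof, libO)
  expect_equal(unname(ca$overall[c("O-GalNAc", "NeuAc")]), c(100, 100))
  expect_equal(unname(ca$o_galnac[c("core1", "core2")]), c(100, 0))
})

test_that("percent change from the cross-region mean reproduces the table arithmetic", {
  m <- rbind(paucimannose = c(3.1, 2.6, 2.6, 1.2))
  pc <- percent_change_matrix(m)
  expect_equal(unname(pc[1, 4]), 100 * (1.2 - 2.375) / 2.375,
               tolerance = 1e-9)
  expect_equal(round(unname(pc[1, 4]), 1), -49.5)

  eq <- percent_change_matrix(rbind(c(2, 2, 2)))
  expect_true(all(eq == 0))
  expect_equal(unname(percent_change_matrix(rbind(c(2, 4)))[1, ]),
               c(-100 / 3, 100 / 3), tolerance = 1e-9)
  expect_true(all(is.na(percent_change_matrix(rbind(c(0, 0))))))
})

test_that("mutually exclusive N classes sum to 100 on library-consistent profiles", {
  lib <- builtin_glycan_library("N")
  for (tmpl in c("cortexN", "cerebellumN", "plasmaN")) {
    tp <- make_truth_profile(tmpl, lib)
    ca <- truth_categories(tp)
    expect_equal(sum(ca[n_glycan_classes()]), 100, tolerance = 0.5)
  }
})
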