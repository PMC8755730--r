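## Truth templates: per-mass relative abundances (percent) keyed by library
## short name. Per-mass abundances are not published at main-text resolution,
## so these allocations were derived once from the printed per-category
## table totals so that the mutually exclusive N-glycan classes match them
## exactly and every cross-cutting category (hybrid, bisected, galactose,
## fucose, NeuAc, NeuGc; O-glycan subtypes and cores) lands within one
## percentage point. They are study conditions, not tuning knobs.
.TEMPLATES <- list(
  cortexN = c(
    "Man-3" = 0.31, "FMan-3" = 2.79,
    "Man-5" = 45.07, "Man-6" = 7.51, "Man-7" = 5.01, "Man-8" = 3.13,
    "Man-9" = 1.88,
    "FA1B" = 12.5, "A1B" = 0.5, "A1BH5" = 1.6, "A1H5" = 0.2,
    "FA1BH4" = 2.0, "FA1BH5" = 1.5, "F2A1G1BH4" = 0.7,
    "FA2G1B" = 7.5, "FA2B" = 2.2, "F2A2G1" = 1.5, "A2G2S1" = 0.5,
    "FA2G2S2" = 1.9,
    "A3G3" = 0.4, "FA3B" = 1.3,
    "A4G4" = 0.14),
  cerebellumN = c(
    "Man-3" = 0.2, "FMan-3" = 1.0,
    "Man-5" = 44.0, "Man-6" = 7.3, "Man-7" = 4.9, "Man-8" = 3.1,
    "Man-9" = 1.8,
    "FA1B" = 4.3, "A1B" = 0.4, "A1BH5" = 1.5, "A1H5" = 0.2,
    "FA1BH4" = 3.0, "FA1BH5" = 2.6, "F2A1G1BH4" = 1.0,
    "FA2G1B" = 7.88, "FA2B" = 9.22, "F2A2G1" = 1.7, "A2G2S1" = 0.7,
    "FA2G2S1B" = 2.2,
    "A3G3" = 0.3, "FA3B" = 2.3,
    "A4G4" = 0.32),
  plasmaN = c(
    "A2G2S2Gc" = 40, "FA2G2S2Gc" = 27, "A2G2S2" = 8, "A2G2S1" = 6,
    "F2A2G1" = 4, "A3G3" = 5, "A4G4" = 2, "FA2G2S2" = 4,
    "Man-5" = 2, "Man-6" = 2),
  cortexO = c(
    "C1" = 1.73, "C1S1" = 4.46, "C1S2" = 64.0, "C1S1S1Gc" = 0.8,
    "C1S2Gc" = 0.2, "C1F1" = 4.5,
    "C2G1S2" = 6.69, "C2G1F1" = 1.72,
    "M1G1S1" = 5.5, "M1G1S2" = 0.427, "M1G1S1Gc" = 0.3, "M1G1F1" = 2.033,
    "M2G2S1" = 2.119, "M2G2S1F1" = 0.321,
    "C2G1S1" = 3.87, "C1F1S1" = 1.33)   # ambiguous-subtype masses
)

#' Ground-truth glycome profile for a simulation template
#'
#' Maps a named template (or a custom per-mass profile) onto the fixture
#' library, returning per-mass percentages that sum to 100. The built-in
#' templates emulate the published per-category composition of the male
#' mouse cortex/cerebellum N-glycome, the mouse plasma N-glycome and the
#' cortex O-glycome.
#'
#' @param template `"cortexN"`, `"cerebellumN"`, `"plasmaN"`, `"cortexO"`
#'   or `"custom"`.
#' @param library a `glycan_library`; defaults to the built-in one of the
#'   matching glycan type.
#' @param custom for `template = "custom"`: named numeric vector (short
#'   name -> percent) summing to 100.
#' @return named numeric vector of class `truth_profile` (library label ->
#'   percent, summing to 100), with the library kept as an attribute.
#' @export
make_truth_profile <- function(template = c("cortexN", "cerebellumN",
                                            "plasmaN", "cortexO", "custom"),
                               library = NULL, custom = NULL) {
  template <- match.arg(template)
  if (template == "custom") {
    if (is.null(custom) || is.null(names(custom)))
      stop("make_truth_profile(): template 'custom' needs a named `custom` ",
           "vector")
    if (abs(sum(custom) - 100) > 1e-6)
      stop("make_truth_profile(): custom profile must sum to 100 (got ",
           format(sum(custom)), ")")
    weights <- custom
  } else {
    weights <- .TEMPLATES[[template]]
  }
  gtype <- if (grepl("O$", template)) "O"
           else if (template == "custom") NULL else "N"
  if (is.null(library)) {
    if (is.null(gtype))
      stop("make_truth_profile(): custom templates need an explicit library")
    library <- builtin_glycan_library(gtype)
  }
  labs <- vapply(names(weights), function(nm)
    as.character(.entry_by_name(library, nm)$label), character(1))
  prof <- stats::setNames(as.numeric(weights), labs)
  prof <- 100 * prof / sum(prof)
  structure(prof, class = "truth_profile", library = library)
}

#' Category profile of a truth (or realized) vector
#'
#' Treats a named abundance vector (library label -> percent) as a glycome
#' profile and runs [category_abundances()] on it; the ground-truth side of
#' recovery scoring.
#'
#' @param truth named numeric vector (e.g. a `truth_profile` or one entry
#'   of a cohort's `realized` log).
#' @param library defaults to the library attached to `truth`.
#' @param ... passed to [category_abundances()].
#' @return see [category_abundances()].
#' @export
truth_categories <- function(truth, library = attr(truth, "library"), ...) {
  if (is.null(library))
    stop("truth_categories(): no library attached; pass one explicitly")
  prof <- structure(
    data.frame(label = names(truth),
               exact_mz = library_mz(library)[names(truth)],
               abundance = as.numeric(truth)),
    class = c("glycome_profile", "data.frame"))
  category_abundances(prof, library, ...)
}

#' Simulation configuration
#'
#' Bundles the acquisition-noise model: multiplicative log-normal intensity
#' noise, uniform mass-calibration error, Poisson-placed sub-threshold
#' noise peaks, and the S/N injection rule (peak intensity divided by the
#' nominal noise level).
#'
#' @param intensity_log_sd log-space SD of the multiplicative intensity
#'   noise (default 0.15).
#' @param calibration_da half-width of the uniform m/z calibration error
#'   (default 0.2 Da).
#' @param noise_density noise peaks per Da across the window (default
#'   0.05).
#' @param base_intensity intensity corresponding to 100% relative abundance.
#' @param noise_level scale of the noise-peak intensities (drawn uniformly
#'   between 0.5 and 5.5 times this value). The injected S/N divides each
#'   intensity by the robust noise floor of that distribution,
#'   `1.4826 * MAD = 1.853 * noise_level`, the same quantity
#'   [estimate_snr()] estimates from the spectrum itself; noise peaks
#'   therefore always land below S/N 3.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(intensity_log_sd = 0.15, calibration_da = 0.2,
                       noise_density = 0.05, base_intensity = 1e5,
                       noise_level = 5) {
  stopifnot(intensity_log_sd >= 0, calibration_da >= 0, noise_density >= 0,
            base_intensity > 0, noise_level > 0)
  structure(list(intensity_log_sd = intensity_log_sd,
                 calibration_da = calibration_da,
                 noise_density = noise_density,
                 base_intensity = base_intensity,
                 noise_level = noise_level),
            class = "sim_config")
}

## peaks for one spectrum given per-mass truth intensities (internal; caller
## handles seeding). The realized per-mass composition (after intensity
## noise, before jitter/thresholding) is attached for recovery scoring.
.simulate_peaks <- function(mz, rel_intensity, config, window) {
  n <- length(mz)
  inten <- config$base_intensity * (rel_intensity / 100) *
    stats::rlnorm(n, 0, config$intensity_log_sd)
  mz_obs <- mz + stats::runif(n, -config$calibration_da,
                              config$calibration_da)
  noise_floor <- 1.4826 * 1.25 * config$noise_level  # robust floor of the
  snr <- inten / noise_floor                         # noise-peak intensities
  n_noise <- stats::rpois(1, config$noise_density * diff(window))
  realized <- stats::setNames(100 * inten / sum(inten),
                              format(mz, digits = 10))
  if (n_noise > 0) {
    nmz <- stats::runif(n_noise, window[1], window[2])
    ninten <- config$noise_level * stats::runif(n_noise, 0.5, 5.5)
    mz_obs <- c(mz_obs, nmz)
    inten <- c(inten, ninten)
    snr <- c(snr, ninten / noise_floor)
  }
  out <- data.frame(mz = mz_obs, intensity = inten, snr = snr)
  attr(out, "realized") <- realized
  out
}

#' Simulate a MALDI spectrum from a truth profile
#'
#' One peak per truth mass with intensity proportional to abundance times
#' log-normal noise, m/z jittered by the calibration error and S/N injected
#' from the configured noise level, plus Poisson-placed noise peaks below
#' the S/N threshold. Fully determined by `seed`.
#'
#' @param truth a `truth_profile` (or named vector label -> percent).
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param ... metadata passed to [glycan_spectrum()].
#' @return a `glycan_spectrum`.
#' @export
simulate_spectrum <- function(truth, config = sim_config(), seed = 1, ...) {
  library <- attr(truth, "library")
  meta <- list(...)
  gtype <- meta$glycan_type
  if (is.null(gtype))
    gtype <- if (!is.null(library))
      library[[1]]$glycan_type else "N"
  window <- if (gtype == "N") c(1000, 5000) else c(500, 3000)
  mz <- if (!is.null(library)) {
    vapply(names(truth), function(l) library[[l]]$exact_mz, numeric(1))
  } else as.numeric(names(truth))
  withr::with_seed(seed, {
    peaks <- .simulate_peaks(mz, as.numeric(truth), config, window)
    sp <- do.call(glycan_spectrum,
                  c(list(peaks = peaks, glycan_type = gtype), meta))
    ## per-sample realized composition (after intensity noise): the ground
    ## truth an annotation pipeline can be scored against for this replicate
    sp$realized_truth <- stats::setNames(unname(attr(peaks, "realized")),
                                         names(truth))
    sp
  })
}

#' Simulate an Endo H differential-digestion triplet
#'
#' Emits the three spectra of the differential-digestion design: `pre`
#' (PNGase F release of an untreated aliquot; all parent masses), `endoh`
#' (Endo H release; product masses of the sensitive fraction) and `post`
#' (PNGase F after Endo H; the insensitive fraction of each parent, i.e.
#' complex/paucimannose glycans plus the resistant share of designated
#' mixed masses). The post digest receives its own overall intensity scale
#' (`post_scale`) so that cross-spectrum scaling via the insensitive
#' reference is actually exercised.
#'
#' @param truth a `truth_profile` over an N-glycan library with Endo H
#'   classifications.
#' @param config a [sim_config()].
#' @param seed integer seed.
#' @param post_scale relative spotting efficiency of the post digest.
#' @param ... metadata passed to the spectra.
#' @return named list of `glycan_spectrum`s: `pre`, `endoh`, `post`.
#' @export
simulate_endoh_triplet <- function(truth, config = sim_config(), seed = 1,
                                   post_scale = 0.7, ...) {
  library <- attr(truth, "library")
  if (is.null(library))
    stop("simulate_endoh_triplet(): truth profile must carry its library")
  entries <- library[names(truth)]
  frac <- vapply(entries, `[[`, numeric(1), "endoh_sensitive_fraction")
  if (anyNA(frac))
    stop("simulate_endoh_triplet(): masses without an Endo H ",
         "classification: ",
         paste(names(truth)[is.na(frac)], collapse = ", "))
  mz <- vapply(entries, `[[`, numeric(1), "exact_mz")
  window <- c(1000, 5000)

  prod_tab <- endoh_product_table(library)
  keep <- vapply(prod_tab$parents, function(p) any(p %in% names(truth)),
                 logical(1))
  prod_tab <- prod_tab[keep, , drop = FALSE]
  prod_int <- vapply(seq_len(nrow(prod_tab)), function(k) {
    par <- intersect(prod_tab$parents[[k]], names(truth))
    sum(truth[par] * frac[par])
  }, numeric(1))

  post_truth <- as.numeric(truth) * (1 - frac)
  withr::with_seed(seed, {
    pre <- do.call(glycan_spectrum, c(list(
      peaks = .simulate_peaks(mz, as.numeric(truth), config, window),
      glycan_type = "N", treatment = "pngasef"), list(...)))
    endoh <- do.call(glycan_spectrum, c(list(
      peaks = .simulate_peaks(prod_tab$product_mz, prod_int, config, window),
      glycan_type = "N", treatment = "endoh"), list(...)))
    cfg_post <- config
    cfg_post$base_intensity <- config$base_intensity * post_scale
    keep_post <- post_truth > 0
    post <- do.call(glycan_spectrum, c(list(
      peaks = .simulate_peaks(mz[keep_post], post_truth[keep_post],
                              cfg_post, window),
      glycan_type = "N", treatment = "pngasef_post_endoh"), list(...)))
    list(pre = pre, endoh = endoh, post = post)
  })
}

#' Simulate a multi-group cohort with known truth
#'
#' For each design row the group truth is the template profile with the
#' per-category multiplicative effects applied (masses are scaled by the
#' effect of every category their representative structure carries) and
#' renormalised to 100; `n` replicate spectra are then drawn.
#'
#' @param design data.frame with columns `group` (label), `template`
#'   (template name) and `n` (replicates); optional `region`/`sex` columns
#'   are carried into the spectra.
#' @param effects named list: group -> named numeric vector
#'   (category -> multiplier).
#' @param config a [sim_config()].
#' @param seed integer seed; each spectrum gets a distinct derived seed.
#' @param library optional shared library.
#' @return list of class `sim_cohort`: `spectra` (named list), `design`,
#'   `truth` (named list of per-group truth profiles).
#' @export
simulate_cohort <- function(design, effects = list(), config = sim_config(),
                            seed = 1, library = NULL) {
  stopifnot(all(c("group", "template", "n") %in% names(design)))
  spectra <- list(); truth <- list(); realized <- list()
  samp <- data.frame()
  for (i in seq_len(nrow(design))) {
    g <- design$group[i]
    prof <- make_truth_profile(design$template[i], library = library)
    lib <- attr(prof, "library")
    eff <- effects[[g]]
    if (!is.null(eff)) {
      mult <- rep(1, length(prof))
      for (j in seq_along(prof)) {
        cats <- classify(lib[[names(prof)[j]]]$structures[[1]])
        hit <- intersect(names(eff), cats)
        if (length(hit)) mult[j] <- prod(eff[hit])
      }
      prof[] <- 100 * (prof * mult) / sum(prof * mult)
    }
    truth[[g]] <- prof
    for (r in seq_len(design$n[i])) {
      sid <- sprintf("%s_%02d", g, r)
      meta <- list(sample_id = sid)
      if ("region" %in% names(design)) meta$region <- design$region[i]
      if ("sex" %in% names(design)) meta$sex <- design$sex[i]
      sp_seed <- (seed * 10007L + i * 211L + r * 17L) %% .Machine$integer.max
      spectra[[sid]] <- do.call(simulate_spectrum,
                                c(list(truth = prof, config = config,
                                       seed = sp_seed), meta))
      realized[[sid]] <- spectra[[sid]]$realized_truth
      samp <- rbind(samp, data.frame(sample_id = sid, group = g))
    }
  }
  structure(list(spectra = spectra, design = design, samples = samp,
                 truth = truth, realized = realized),
            class = "sim_cohort")
}
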