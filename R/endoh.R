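#' Endo H sensitivity of a structure
#'
#' Endoglycosidase H cleaves between the two core GlcNAc residues of
#' high-mannose and hybrid N-glycans only; complex and paucimannose
#' structures are left intact.
#'
#' @param s an N-glycan `glycan_structure`.
#' @param hybrid_min_mannose passed to [classify()].
#' @return `"sensitive"` or `"insensitive"`.
#' @export
endoh_sensitive <- function(s, hybrid_min_mannose = 4) {
  stopifnot(inherits(s, "glycan_structure"))
  if (s$glycan_class != "N")
    stop("endoh_sensitive(): Endo H acts on N-glycans only")
  cats <- classify(s, hybrid_min_mannose = hybrid_min_mannose)
  if ("high-mannose" %in% cats || "hybrid" %in% cats) "sensitive"
  else "insensitive"
}

#' Composition of the Endo H cleavage product
#'
#' Cleavage between the two core GlcNAc residues leaves the reducing GlcNAc
#' (and any core fucose on it) behind on the peptide: the released product
#' is the parent minus one HexNAc and minus its core fucoses, with the
#' retained core GlcNAc as the new reducing end. Products of a
#' core-fucosylated parent and of the same glycan without core fucose
#' therefore coincide.
#'
#' @param parent a `glycan_structure` (or a `glycan_composition` plus
#'   `core_fucose`) that is Endo H sensitive.
#' @param core_fucose used only when `parent` is a bare composition.
#' @return a `glycan_composition` with `end_state = "endoh_product"`.
#' @export
endoh_product <- function(parent, core_fucose = 0) {
  if (inherits(parent, "glycan_structure")) {
    if (endoh_sensitive(parent) != "insensitive") {
      comp <- structure_to_composition(parent)
      core_fucose <- parent$core_fucose
    } else {
      stop("endoh_product(): '", parent$short_name,
           "' is Endo H insensitive; no product is formed")
    }
  } else if (inherits(parent, "glycan_composition")) {
    comp <- parent
  } else stop("endoh_product(): need a glycan_structure or glycan_composition")
  comp_add(comp, hexnac = -1, dhex = -core_fucose,
           end_state = "endoh_product")
}

#' Product-mass library for an Endo H digest
#'
#' Derives the released-product masses of every (at least partially)
#' sensitive parent in a library. Distinct parents whose products coincide
#' share one product mass (the placeholder case).
#'
#' @param library a `glycan_library` of N-glycans.
#' @return data.frame with `product_mz`, `product_label` and the list-column
#'   `parents` of parent labels.
#' @export
endoh_product_table <- function(library) {
  rows <- list()
  for (lab in names(library)) {
    e <- library[[lab]]
    if (e$glycan_type != "N" || is.na(e$endoh_sensitive_fraction) ||
        e$endoh_sensitive_fraction <= 0) next
    ## products of every sensitive isomer (isomers with and without core
    ## fucose can release different products from one parent mass)
    sens <- Filter(function(x) endoh_sensitive(x) == "sensitive",
                   e$structures)
    if (!length(sens)) next
    prods <- unique(lapply(sens, function(s) {
      prod <- endoh_product(s)
      list(mz = composition_mz(prod), comp = composition_label(prod))
    }))
    rows[[lab]] <- do.call(rbind, lapply(prods, function(p)
      data.frame(parent = lab, product_mz = p$mz,
                 product_composition = p$comp)))
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) return(data.frame(product_mz = numeric(),
                                      product_label = numeric(),
                                      parents = I(list())))
  key <- round(tab$product_mz, 6)
  agg <- lapply(split(tab, key), function(d)
    data.frame(product_mz = d$product_mz[1],
               product_label = floor(d$product_mz[1]),
               product_composition = d$product_composition[1],
               parents = I(list(d$parent))))
  out <- do.call(rbind, agg)
  out <- out[order(out$product_mz), ]
  rownames(out) <- NULL
  out
}

#' Infer Endo H sensitivity from a differential-digestion triplet
#'
#' Compares parent-glycan intensities between the PNGase F spectrum of an
#' untreated aliquot (`pre`) and the PNGase F spectrum acquired after Endo H
#' treatment (`post`). Because the two spectra are not on a common intensity
#' scale, `post` is rescaled so that a designated Endo H *insensitive*
#' reference glycan has equal intensity in both. The removal fraction of
#' each parent is then `r = 1 - post/pre` (clamped to `[0, 1]`), and the
#' call is `sensitive` for `r >= thresholds["high"]`, `insensitive` for
#' `r <= thresholds["low"]`, and `mixed` in between. Detection of the
#' corresponding released product mass in the Endo H spectrum is reported as
#' corroboration.
#'
#' @param pre,post PNGase F `glycan_spectrum`s before/after Endo H.
#' @param endoh the Endo H release spectrum (product masses), or `NULL` to
#'   skip corroboration.
#' @param library parent-mass `glycan_library`.
#' @param reference short name of the insensitive scaling reference
#'   (default `"FA1B"`, the dominant Endo H resistant brain glycan).
#' @param thresholds named vector with `low` and `high` removal-fraction
#'   cutoffs.
#' @param tolerance,snr_min annotation parameters.
#' @return data.frame of class `endoh_calls`: `label`, `pre_intensity`,
#'   `post_intensity` (rescaled), `removal_fraction`, `call`,
#'   `product_observed`.
#' @export
infer_sensitivity <- function(pre, endoh, post, library,
                              reference = "FA1B",
                              thresholds = c(low = 0.1, high = 0.9),
                              tolerance = 0.5, snr_min = 6) {
  stopifnot(all(c("low", "high") %in% names(thresholds)))
  ann_pre <- annotate(pre, library, tolerance, snr_min)
  ## the pre spectrum decides which parents are assessed; in post we only
  ## measure the remaining intensity, so no detection threshold is applied
  ## (a weak surviving peak must not masquerade as complete removal)
  ann_post <- annotate(post, library, tolerance, snr_min = 0)
  ref_entry <- .entry_by_name(library, reference)
  ref_lab <- as.character(ref_entry$label)
  i_pre <- match(ref_lab, ann_pre$label)
  i_post <- match(ref_lab, ann_post$label)
  if (is.na(i_pre) || is.na(i_post))
    stop("infer_sensitivity(): scaling reference '", reference,
         "' not detected in both PNGase F spectra")
  scale <- ann_pre$intensity[i_pre] / ann_post$intensity[i_post]

  ## product corroboration from the Endo H release spectrum
  prod_tab <- endoh_product_table(library)
  observed_parents <- character()
  if (!is.null(endoh) && nrow(prod_tab)) {
    for (k in seq_len(nrow(prod_tab))) {
      pk <- endoh$peaks
      hit <- any(!is.na(pk$snr) & pk$snr >= snr_min &
                   abs(pk$mz - prod_tab$product_mz[k]) <= tolerance)
      if (hit)
        observed_parents <- c(observed_parents, prod_tab$parents[[k]])
    }
  }

  rows <- lapply(seq_len(nrow(ann_pre)), function(i) {
    lab <- ann_pre$label[i]
    j <- match(lab, ann_post$label)
    post_int <- if (is.na(j)) 0 else ann_post$intensity[j] * scale
    r <- 1 - post_int / ann_pre$intensity[i]
    r <- min(max(r, 0), 1)
    call <- if (r >= thresholds[["high"]]) "sensitive"
            else if (r <= thresholds[["low"]]) "insensitive"
            else "mixed"
    data.frame(label = lab, pre_intensity = ann_pre$intensity[i],
               post_intensity = post_int, removal_fraction = r,
               call = call, product_observed = lab %in% observed_parents)
  })
  extras <- setdiff(ann_post$label, ann_pre$label)
  ## extras below the detection threshold are noise picked up because the
  ## post spectrum is annotated without an S/N cutoff; only confident peaks
  ## are worth a warning
  extras <- extras[ann_post$snr[match(extras, ann_post$label)] >= snr_min]
  if (length(extras))
    warning("infer_sensitivity(): masses only present after Endo H were ",
            "skipped: ", paste(extras, collapse = ", "))
  out <- do.call(rbind, rows)
  class(out) <- c("endoh_calls", "data.frame")
  out
}
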