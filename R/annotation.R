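#' Annotate a spectrum against a glycan library
#'
#' A peak is annotated when its S/N passes the cutoff and its m/z lies
#' within `tolerance` of a library exact mass. When several library masses
#' fall within tolerance the nearest wins; exact ties (within 1e-9 Da) break
#' deterministically to the lower mass, with a warning. Each peak maps to at
#' most one library mass and each library mass keeps only its most intense
#' in-tolerance peak (ties by distance), so a noise spike cannot displace
#' the analyte peak.
#'
#' @param spec a `glycan_spectrum`.
#' @param library a `glycan_library` of the matching glycan type.
#' @param tolerance matching tolerance in Da (default 0.5, the
#'   integer-label regime of externally calibrated TOF data).
#' @param snr_min minimum signal-to-noise ratio (default 6).
#' @param snr_estimate when peaks carry no S/N: `TRUE` to fall back to
#'   [estimate_snr()], `FALSE` to fail (the default mirrors instrument-S/N
#'   practice).
#' @return data.frame of class `annotated_peaks`: one row per annotated peak
#'   with `mz`, `intensity`, `snr`, `label`, `exact_mz`, `delta`
#'   (observed - theoretical), plus attributes `unmatched` (peaks passing
#'   S/N but matching nothing) and `spectrum` metadata.
#' @export
annotate <- function(spec, library, tolerance = 0.5, snr_min = 6,
                     snr_estimate = FALSE) {
  stopifnot(inherits(spec, "glycan_spectrum"),
            inherits(library, "glycan_library"), tolerance >= 0)
  if (!length(library)) stop("annotate(): empty library")
  p <- spec$peaks
  if (nrow(p) && all(is.na(p$snr))) {
    if (!snr_estimate)
      stop("annotate(): spectrum carries no S/N and estimation is disabled; ",
           "set snr_estimate = TRUE or provide an snr column")
    p <- estimate_snr(spec)$peaks
  }
  pass <- which(!is.na(p$snr) & p$snr >= snr_min & p$in_window)
  lib_mz <- library_mz(library)
  lib_label <- names(library)
  hit <- data.frame(peak = integer(), lib = integer(), delta = numeric())
  for (i in pass) {
    d <- p$mz[i] - lib_mz
    ad <- abs(d)
    j <- which(ad <= tolerance + 1e-12)
    if (!length(j)) next
    best <- j[order(ad[j], lib_mz[j])][1]
    others <- j[abs(ad[j] - ad[best]) <= 1e-9]
    if (length(others) > 1) {
      warning(sprintf(
        "annotate(): peak %.4f equidistant between library masses; %s",
        p$mz[i], "assigned to the lower mass"))
      best <- others[which.min(lib_mz[others])]
    }
    hit <- rbind(hit, data.frame(peak = i, lib = best, delta = d[best]))
  }
  ## one peak per library mass: keep the most intense in-tolerance peak
  ## (the analyte peak, not a nearby noise spike), ties by distance
  if (nrow(hit)) {
    hit <- hit[order(hit$lib, -p$intensity[hit$peak], abs(hit$delta)), ]
    hit <- hit[!duplicated(hit$lib), ]
  }
  ann <- data.frame(
    mz = p$mz[hit$peak], intensity = p$intensity[hit$peak],
    snr = p$snr[hit$peak],
    label = lib_label[hit$lib],
    exact_mz = lib_mz[hit$lib],
    delta = hit$delta, row.names = NULL)
  ann <- ann[order(ann$exact_mz), , drop = FALSE]
  rownames(ann) <- NULL
  attr(ann, "unmatched") <- p[setdiff(pass, hit$peak), , drop = FALSE]
  attr(ann, "sample_id") <- spec$sample_id
  attr(ann, "meta") <- spec[c("region", "sex", "species", "glycan_type",
                              "treatment")]
  class(ann) <- c("annotated_peaks", "data.frame")
  ann
}

#' Relative abundances of annotated glycans
#'
#' The relative abundance of each glycan is its peak intensity divided by
#' the summed intensity of all annotated glycans in the spectrum, in
#' percent.
#'
#' @param annotated an `annotated_peaks` data.frame from [annotate()].
#' @return data.frame of class `glycome_profile` with `label`, `exact_mz`,
#'   `abundance` (percent, summing to 100) and the sample metadata as
#'   attributes.
#' @export
relative_abundances <- function(annotated) {
  stopifnot(inherits(annotated, "annotated_peaks"))
  if (nrow(annotated) == 0)
    stop("relative_abundances(): no annotated peaks in this spectrum ",
         "(empty profile)")
  total <- sum(annotated$intensity)
  prof <- data.frame(label = annotated$label,
                     exact_mz = annotated$exact_mz,
                     abundance = 100 * annotated$intensity / total)
  attr(prof, "sample_id") <- attr(annotated, "sample_id")
  attr(prof, "meta") <- attr(annotated, "meta")
  class(prof) <- c("glycome_profile", "data.frame")
  prof
}

#' Mean and SEM of profiles within a group
#'
#' Masses are unioned across profiles with absent masses counted as 0%.
#' SEM is the sample standard deviation over sqrt(n), reported only for
#' n >= 2.
#'
#' @param profiles list of `glycome_profile` objects belonging to one group.
#' @param group_key optional named list/character identifying the group.
#' @return data.frame of class `group_profile` with `label`, `exact_mz`,
#'   `mean`, `sem`, and attribute `n`.
#' @export
aggregate_profiles <- function(profiles, group_key = NULL) {
  stopifnot(length(profiles) >= 1)
  labs <- unique(unlist(lapply(profiles, `[[`, "label")))
  mzs <- unlist(lapply(profiles, function(p) p$exact_mz[match(labs, p$label)]))
  mz <- tapply(mzs, rep(labs, length(profiles)), function(v) v[!is.na(v)][1])
  mat <- vapply(profiles, function(p) {
    v <- p$abundance[match(labs, p$label)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(labs)))
  mat <- matrix(mat, nrow = length(labs))
  n <- ncol(mat)
  out <- data.frame(
    label = labs,
    exact_mz = as.numeric(mz[labs]),
    mean = rowMeans(mat),
    sem = if (n >= 2) apply(mat, 1, stats::sd) / sqrt(n) else NA_real_)
  out <- out[order(out$exact_mz), ]
  rownames(out) <- NULL
  attr(out, "n") <- n
  attr(out, "group_key") <- group_key
  class(out) <- c("group_profile", "data.frame")
  out
}

#' Most abundant masses averaged across groups
#'
#' Ranks library masses by their mean relative abundance averaged across the
#' supplied group profiles (the "averaged across regions" convention of the
#' top-10 figures). Ties break by ascending mass, so the ranking is stable.
#'
#' @param groups list of `group_profile` objects.
#' @param k how many masses to return.
#' @return data.frame with `label`, `exact_mz`, `mean_abundance` and the
#'   per-group means, ordered by rank.
#' @export
top_k <- function(groups, k = 10) {
  stopifnot(k >= 1, length(groups) >= 1)
  labs <- unique(unlist(lapply(groups, `[[`, "label")))
  per <- vapply(groups, function(g) {
    v <- g$mean[match(labs, g$label)]
    v[is.na(v)] <- 0
    v
  }, numeric(length(labs)))
  per <- matrix(per, nrow = length(labs),
                dimnames = list(labs, names(groups)))
  mz <- vapply(labs, function(l) {
    for (g in groups) {
      i <- match(l, g$label)
      if (!is.na(i)) return(g$exact_mz[i])
    }
    NA_real_
  }, numeric(1))
  ord <- order(-rowMeans(per), mz)
  sel <- ord[seq_len(min(k, length(labs)))]
  out <- data.frame(label = labs[sel], exact_mz = mz[sel],
                    mean_abundance = rowMeans(per)[sel])
  cbind(out, as.data.frame(per[sel, , drop = FALSE], row.names = FALSE))
}

## categories of one library entry under a splitting policy: a named weight
## vector (category -> fraction of the entry's abundance)
.entry_category_weights <- function(entry, policy = "representative",
                                    hybrid_min_mannose = 4) {
  structs <- if (policy == "representative") entry$structures[1]
             else entry$structures
  w <- 1 / length(structs)
  out <- numeric()
  for (s in structs) {
    cats <- classify(s, hybrid_min_mannose = hybrid_min_mannose)
    for (cat in cats) out[cat] <- sum(out[cat], w, na.rm = TRUE)
  }
  out
}

#' Category abundances of a glycome profile
#'
#' Sums the relative abundance of all masses carrying each structural
#' category. With the default `"representative"` policy a mass contributes
#' its full abundance to every category of its primary (literature-assigned)
#' structure; with `"fractional"` it is split equally across its isomers.
#'
#' For O-glycans the result additionally carries within-subtype maps:
#' core 1 vs core 2 abundances renormalised to 100 within the O-GalNAc
#' subtype and M1 vs M2 within O-Man, plus renormalised fucose/NeuAc/NeuGc
#' shares. Masses flagged ambiguous between subtypes contribute to the
#' overall categories but to neither subtype.
#'
#' @param profile a `glycome_profile`.
#' @param library the `glycan_library` the profile was annotated against.
#' @param policy `"representative"` or `"fractional"`.
#' @param strict error (rather than warn) when a profile mass has no library
#'   entry.
#' @param hybrid_min_mannose passed to [classify()].
#' @return for N-glycans a named numeric vector over
#'   [n_glycan_categories()]; for O-glycans a list with elements `overall`,
#'   `o_galnac`, `o_man` (class `o_category_profile`).
#' @export
category_abundances <- function(profile, library,
                                policy = c("representative", "fractional"),
                                strict = TRUE, hybrid_min_mannose = 4) {
  policy <- match.arg(policy)
  stopifnot(inherits(profile, "glycome_profile") ||
              inherits(profile, "group_profile"))
  abund_col <- if (inherits(profile, "glycome_profile")) "abundance" else "mean"
  idx <- match(profile$label, names(library))
  if (anyNA(idx)) {
    msg <- paste("category_abundances(): masses not in library:",
                 paste(profile$label[is.na(idx)], collapse = ", "))
    if (strict) stop(msg) else warning(msg)
    profile <- profile[!is.na(idx), ]
    idx <- idx[!is.na(idx)]
  }
  entries <- library[idx]
  gtype <- unique(vapply(entries, `[[`, character(1), "glycan_type"))
  if (length(gtype) > 1)
    stop("category_abundances(): profile mixes N- and O-glycan masses")
  cats <- if (gtype == "N") n_glycan_categories() else o_glycan_categories()
  overall <- stats::setNames(numeric(length(cats)), cats)
  for (i in seq_along(entries)) {
    w <- .entry_category_weights(entries[[i]], policy, hybrid_min_mannose)
    keep <- intersect(names(w), cats)
    ## masses that cannot be assigned to a subtype with confidence count
    ## toward the modification categories only
    if (entries[[i]]$ambiguous_subtype)
      keep <- setdiff(keep, c("O-GalNAc", "O-Man",
                              "core1", "core2", "M1", "M2"))
    overall[keep] <- overall[keep] + profile[[abund_col]][i] * w[keep]
  }
  if (gtype == "N") return(overall)

  subtype_map <- function(subtype, cores) {
    sel <- vapply(entries, function(e)
      !e$ambiguous_subtype &&
        e$structures[[1]]$glycan_class == subtype, logical(1))
    tot <- sum(profile[[abund_col]][sel])
    out <- stats::setNames(numeric(length(cores) + 3),
                           c(cores, "fucose", "NeuAc", "NeuGc"))
    if (tot == 0) return(out)
    for (i in which(sel)) {
      w <- .entry_category_weights(entries[[i]], policy)
      keep <- intersect(names(w), names(out))
      out[keep] <- out[keep] + profile[[abund_col]][i] * w[keep]
    }
    100 * out / tot
  }
  structure(list(overall = overall,
                 o_galnac = subtype_map("O-GalNAc", c("core1", "core2")),
                 o_man = subtype_map("O-Man", c("M1", "M2"))),
            class = "o_category_profile")
}

#' Percent change of category values from the cross-region mean
#'
#' The heat-map transform: each cell is 100 x (region value - mean over
#' regions) / mean over regions. Categories whose cross-region mean is zero
#' are undefined and returned as NA.
#'
#' @param category_matrix numeric matrix, rows = categories, columns =
#'   regions (or any groups).
#' @return matrix of the same shape, in percent.
#' @export
percent_change_matrix <- function(category_matrix) {
  stopifnot(is.matrix(category_matrix), ncol(category_matrix) >= 2)
  m <- rowMeans(category_matrix)
  out <- 100 * sweep(category_matrix, 1, m, "-") / ifelse(m == 0, NA, m)
  out
}
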