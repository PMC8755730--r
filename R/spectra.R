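#' Construct a centroided spectrum
#'
#' A peak list plus the sample metadata the downstream statistics need.
#' Peaks are sorted by m/z and deduplicated (peaks closer than 1e-6 Da are
#' collapsed, keeping the most intense). Peaks outside the acquisition
#' window are retained but flagged.
#'
#' @param peaks data.frame with columns `mz`, `intensity` and optionally
#'   `snr`.
#' @param sample_id sample identifier.
#' @param region one of cortex, hippocampus, striatum, cerebellum, plasma.
#' @param sex male or female.
#' @param species mouse or human.
#' @param glycan_type `"N"` or `"O"`; sets the default acquisition window
#'   (1000-5000 for N, 500-3000 for O).
#' @param treatment glycan release: `"pngasef"`, `"endoh"` or
#'   `"pngasef_post_endoh"`.
#' @param mz_window numeric length-2 acquisition window; defaults from
#'   `glycan_type`.
#' @return object of class `glycan_spectrum`.
#' @export
glycan_spectrum <- function(peaks, sample_id = "sample",
                            region = c("cortex", "hippocampus", "striatum",
                                       "cerebellum", "plasma"),
                            sex = c("male", "female"),
                            species = c("mouse", "human"),
                            glycan_type = c("N", "O"),
                            treatment = c("pngasef", "endoh",
                                          "pngasef_post_endoh"),
                            mz_window = NULL) {
  region <- match.arg(region); sex <- match.arg(sex)
  species <- match.arg(species); glycan_type <- match.arg(glycan_type)
  treatment <- match.arg(treatment)
  if (is.null(mz_window))
    mz_window <- if (glycan_type == "N") c(1000, 5000) else c(500, 3000)
  stopifnot(is.data.frame(peaks),
            all(c("mz", "intensity") %in% names(peaks)))
  if (!"snr" %in% names(peaks)) peaks$snr <- rep(NA_real_, nrow(peaks))
  peaks <- peaks[, c("mz", "intensity", "snr")]
  if (nrow(peaks)) {
    if (any(peaks$mz <= 0)) stop("glycan_spectrum(): m/z must be positive")
    if (any(peaks$intensity < 0))
      stop("glycan_spectrum(): intensities must be non-negative")
    peaks <- peaks[order(peaks$mz, -peaks$intensity), , drop = FALSE]
    keep <- c(TRUE, diff(peaks$mz) > 1e-6)
    peaks <- peaks[keep, , drop = FALSE]
    rownames(peaks) <- NULL
  }
  peaks$in_window <- peaks$mz >= mz_window[1] & peaks$mz <= mz_window[2]
  structure(list(peaks = peaks, sample_id = sample_id, region = region,
                 sex = sex, species = species, glycan_type = glycan_type,
                 treatment = treatment, mz_window = mz_window),
            class = "glycan_spectrum")
}

#' @export
print.glycan_spectrum <- function(x, ...) {
  cat(sprintf(
    "<glycan_spectrum> %s: %d peaks, %s %s %s-glycans (%s), window %g-%g\n",
    x$sample_id, nrow(x$peaks), x$species, x$region, x$glycan_type,
    x$treatment, x$mz_window[1], x$mz_window[2]))
  invisible(x)
}

.col_alias <- function(nms) {
  key <- tolower(gsub("[^a-z0-9]", "", tolower(nms)))
  out <- nms
  out[key %in% c("mz", "mass", "mperz")] <- "mz"
  out[key %in% c("intensity", "int", "i", "area")] <- "intensity"
  out[key %in% c("snr", "sn", "s2n", "signaltonoise")] <- "snr"
  out
}

#' Read a centroided peak list
#'
#' Delimited text with a header naming at least m/z and intensity columns
#' (aliases `m/z`, `mz`, `mass`; `intensity`, `int`; `snr`, `s/n` — case
#' insensitive). Lines starting with `#` are comments. TSV is the default
#' dialect; CSV is chosen by file extension or `dialect = "csv"`.
#'
#' @param source file path.
#' @param dialect `"auto"`, `"tsv"` or `"csv"`.
#' @param ... metadata passed on to [glycan_spectrum()] (`sample_id`,
#'   `region`, ...).
#' @return a `glycan_spectrum`.
#' @export
read_peaklist <- function(source, dialect = c("auto", "tsv", "csv"), ...) {
  dialect <- match.arg(dialect)
  if (dialect == "auto")
    dialect <- if (grepl("\\.csv$", source, ignore.case = TRUE)) "csv" else "tsv"
  sep <- if (dialect == "csv") "," else "\t"
  raw <- utils::read.table(source, header = TRUE, sep = sep, comment.char = "#",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  names(raw) <- .col_alias(names(raw))
  for (col in c("mz", "intensity"))
    if (!col %in% names(raw))
      stop("read_peaklist(): required column '", col, "' missing in ", source)
  if (nrow(raw) == 0) {
    warning("read_peaklist(): ", source, " contains a header but no peaks")
    return(glycan_spectrum(data.frame(mz = numeric(), intensity = numeric()),
                           ...))
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !raw[[col]] %in% c("", "NA"))
    if (length(bad))
      stop("read_peaklist(): non-numeric value '", raw[[col]][bad[1]],
           "' in column '", col, "', data row ", bad[1], " of ", source)
    v
  }
  peaks <- data.frame(mz = num("mz"), intensity = num("intensity"))
  if ("snr" %in% names(raw)) peaks$snr <- num("snr")
  glycan_spectrum(peaks, ...)
}

#' Write a peak list as delimited text
#' @param spec a `glycan_spectrum`.
#' @param path output file.
#' @param dialect `"tsv"` or `"csv"`.
#' @return `path`, invisibly.
#' @export
write_peaklist <- function(spec, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(spec, "glycan_spectrum"))
  out <- spec$peaks[, c("mz", "intensity", "snr")]
  utils::write.table(format(out, digits = 15, trim = TRUE, scientific = FALSE),
                     path, sep = if (dialect == "csv") "," else "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Estimate signal-to-noise ratios from local intensity spread
#'
#' For peaks lacking an instrument-provided S/N, the noise level around a
#' peak is taken as 1.4826 times the median absolute deviation of the
#' intensities of neighbouring peaks (within `window`/2 on either side,
#' excluding the peak itself); the S/N is the peak intensity over that
#' level. File-provided S/N values always win and are never overwritten.
#'
#' @param spec a `glycan_spectrum` with intensities.
#' @param window width in Da of the neighbourhood used for the noise
#'   estimate.
#' @return the spectrum with `snr` filled where it was absent.
#' @export
estimate_snr <- function(spec, window = 200) {
  stopifnot(inherits(spec, "glycan_spectrum"))
  p <- spec$peaks
  need <- which(is.na(p$snr))
  if (!length(need)) return(spec)
  few <- FALSE
  for (i in need) {
    nb <- which(abs(p$mz - p$mz[i]) <= window / 2)
    nb <- setdiff(nb, i)
    if (length(nb) < 5) { few <- TRUE; next }       # snr stays NA
    noise <- 1.4826 * stats::median(abs(p$intensity[nb] -
                                          stats::median(p$intensity[nb])))
    if (noise == 0) {
      ## degenerate flat neighbourhood: a clear spike still gets a call,
      ## an indistinguishable peak stays unassessed
      p$snr[i] <- if (p$intensity[i] > max(p$intensity[nb])) Inf else NA_real_
    } else {
      p$snr[i] <- p$intensity[i] / noise
    }
  }
  if (few)
    warning("estimate_snr(): some peaks had fewer than 5 neighbours within ",
            window, " Da; their S/N is left unassigned")
  spec$peaks <- p
  spec
}

#' Read a cohort design table
#'
#' CSV with columns `sample_id, path, region, sex, species, glycan_type,
#' treatment` describing one spectrum per row.
#'
#' @param path CSV file.
#' @return data.frame.
#' @export
read_design <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  req <- c("sample_id", "path", "region", "sex", "species", "glycan_type",
           "treatment")
  miss <- setdiff(req, names(d))
  if (length(miss))
    stop("read_design(): missing columns: ", paste(miss, collapse = ", "))
  d
}
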