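#' Build a glycan library entry
#'
#' One record per annotated mass: all isomeric structures sharing that
#' composition, the exact theoretical m/z, a display label, and the Endo H
#' behaviour of the isomer set. The first structure is the representative
#' (primary) assignment used by the default category-splitting policy.
#'
#' @param structures list of `glycan_structure` objects sharing one
#'   composition (checked).
#' @param endoh_sensitive_fraction fraction of the signal at this mass that
#'   behaves Endo H sensitive. Defaults to the structure rule when all
#'   isomers agree; masses carrying a genuine mixture (such as a
#'   hybrid/complex pair) must set it explicitly.
#' @param ambiguous_subtype O-glycans only: `TRUE` when the mass cannot be
#'   assigned to O-GalNAc vs O-Man with confidence; such masses are excluded
#'   from within-subtype normalisation.
#' @return object of class `glycan_entry`.
#' @export
glycan_entry <- function(structures, endoh_sensitive_fraction = NULL,
                         ambiguous_subtype = FALSE) {
  if (inherits(structures, "glycan_structure")) structures <- list(structures)
  stopifnot(length(structures) >= 1,
            all(vapply(structures, inherits, TRUE, "glycan_structure")))
  mzs <- vapply(structures, structure_mz, numeric(1))
  if (diff(range(mzs)) > 1e-6)
    stop("glycan_entry(): isomers do not share one composition mass")
  comp <- structure_to_composition(structures[[1]])
  gclass <- structures[[1]]$glycan_class
  type <- if (gclass == "N") "N" else "O"
  if (is.null(endoh_sensitive_fraction)) {
    if (type == "N") {
      sens <- vapply(structures, function(s)
        endoh_sensitive(s) == "sensitive", logical(1))
      endoh_sensitive_fraction <-
        if (all(sens)) 1 else if (!any(sens)) 0 else
          stop("glycan_entry(): isomers disagree on Endo H sensitivity; ",
               "set endoh_sensitive_fraction explicitly for ",
               composition_label(comp))
    } else endoh_sensitive_fraction <- NA_real_
  }
  structure(list(
    exact_mz = mzs[[1]],
    label = mz_label(mzs[[1]], comp$end_state),
    composition = comp,
    structures = structures,
    short_names = vapply(structures, `[[`, character(1), "short_name"),
    glycan_type = type,
    endoh_sensitive_fraction = endoh_sensitive_fraction,
    ambiguous_subtype = isTRUE(ambiguous_subtype)
  ), class = "glycan_entry")
}

#' Assemble a glycan library
#'
#' @param entries list of [glycan_entry()] records; must have distinct exact
#'   masses.
#' @return object of class `glycan_library` (a named list of entries keyed by
#'   display label, sorted by mass, with an `as.data.frame` method).
#' @export
glycan_library <- function(entries) {
  stopifnot(all(vapply(entries, inherits, TRUE, "glycan_entry")))
  mz <- vapply(entries, `[[`, numeric(1), "exact_mz")
  if (anyDuplicated(round(mz, 6)))
    stop("glycan_library(): duplicate entry masses")
  entries <- entries[order(mz)]
  names(entries) <- vapply(entries, function(e) as.character(e$label),
                           character(1))
  structure(entries, class = "glycan_library")
}

#' @export
print.glycan_library <- function(x, ...) {
  cat(sprintf("<glycan_library> %d masses (%s)\n", length(x),
              paste(unique(vapply(x, `[[`, character(1), "glycan_type")),
                    collapse = "+")))
  print(as.data.frame(x))
  invisible(x)
}

#' @export
as.data.frame.glycan_library <- function(x, ...) {
  data.frame(
    label = vapply(x, function(e) as.numeric(e$label), numeric(1)),
    exact_mz = round(vapply(x, `[[`, numeric(1), "exact_mz"), 4),
    composition = vapply(x, function(e) composition_label(e$composition),
                         character(1)),
    short_names = vapply(x, function(e) paste(e$short_names, collapse = "/"),
                         character(1)),
    glycan_type = vapply(x, `[[`, character(1), "glycan_type"),
    endoh_fraction = vapply(x, `[[`, numeric(1), "endoh_sensitive_fraction"),
    ambiguous_subtype = vapply(x, `[[`, logical(1), "ambiguous_subtype"),
    row.names = NULL
  )
}

#' Exact masses of a library
#' @param library a `glycan_library`.
#' @return numeric vector, ascending.
#' @export
library_mz <- function(library) {
  vapply(library, `[[`, numeric(1), "exact_mz")
}

## quick lookup by short name (representative or isomer)
.entry_by_name <- function(library, short_name) {
  for (e in library) if (short_name %in% e$short_names) return(e)
  stop("no library entry carries the short name '", short_name, "'")
}

#' The built-in fixture library
#'
#' Covers every glycan named in the figures and tables this package
#' reproduces, plus enough additional structures to populate all structural
#' categories: the high-mannose series Man-5..Man-9, paucimannose species,
#' the fucosylated/bisected mono- and bi-antennary structures that dominate
#' the brain, the hybrid/complex isomer pairs at 2070, 2040 and 2244, the
#' Endo H "#" pair at 2418, sialylated complex plasma glycans (NeuAc and
#' NeuGc forms), and the sialylated core 1 / core 2 O-GalNAc and core M1/M2
#' O-mannose alditols including the NeuGc ladder and the ambiguous-subtype
#' masses. Candidate structures carrying the alpha-Gal epitope are excluded.
#'
#' @param type `"N"`, `"O"` or `"both"`.
#' @return a `glycan_library`.
#' @export
builtin_glycan_library <- function(type = c("both", "N", "O")) {
  type <- match.arg(type)
  P <- parse_short_name
  n_entries <- list(
    glycan_entry(P("Man-3")),
    glycan_entry(P("FMan-3")),
    glycan_entry(P("Man-4")),
    glycan_entry(P("Man-5")),
    glycan_entry(P("Man-6")),
    glycan_entry(P("Man-7")),
    glycan_entry(P("Man-8")),
    glycan_entry(P("Man-9")),
    glycan_entry(P("FA1")),
    glycan_entry(P("A1B")),
    glycan_entry(P("FA1B")),
    glycan_entry(P("A1H5")),
    ## 2070: predominantly the bisected hybrid, with the plasma-type
    ## bi-antennary galactosylated glycan as the alternative isomer;
    ## differential digestion showed essentially complete Endo H removal
    glycan_entry(list(P("A1BH5"), P("A2G2")), endoh_sensitive_fraction = 1),
    ## 2040: a genuine mixture of a fucosylated bisected hybrid and a
    ## fucosylated branched complex glycan; partially Endo H sensitive
    glycan_entry(list(P("FA1BH4"), P("FA2G1")),
                 endoh_sensitive_fraction = 0.5),
    ## 2244: bisected hybrid, previously mis-assigned as complex; the
    ## antenna-fucosylated F1A1G1BH4 shares the mass, and its Endo H product
    ## coincides with that of the core+antenna fucosylated F2A1G1BH4 (2418)
    glycan_entry(list(P("FA1BH5"), P("FA2G2"),
                      glycan_structure("F1A1G1BH4", "N", n_antennae = 1,
                                       bisecting = TRUE, core_fucose = 0,
                                       antenna_fucose = 1, galactose = 1,
                                       hybrid_mannose = 4)),
                 endoh_sensitive_fraction = 1),
    glycan_entry(P("FA2B")),
    ## 2214: two complex isomers, fully Endo H insensitive
    glycan_entry(list(P("F2A2G1"), P("F2A1G1B"))),
    ## 2418: core+antenna fucosylated bisected hybrid (the "#" parent)
    glycan_entry(P("F2A1G1BH4")),
    glycan_entry(P("FA2G1B")),
    glycan_entry(P("FA2G2B")),
    glycan_entry(P("FA2G2S1B")),
    glycan_entry(P("A2G2S1")),
    glycan_entry(P("A2G2S2")),
    glycan_entry(P("A2G2S2Gc")),
    glycan_entry(P("FA2G2S2")),
    glycan_entry(P("FA2G2S2Gc")),
    glycan_entry(P("A3G3")),
    glycan_entry(P("FA3B")),
    glycan_entry(P("A4G4"))
  )
  o_entries <- list(
    glycan_entry(P("C1")),
    glycan_entry(P("C1F1")),
    glycan_entry(P("C1S1")),
    glycan_entry(P("C1S2")),
    glycan_entry(P("C1S1S1Gc")),
    glycan_entry(P("C1S2Gc")),
    glycan_entry(P("C2G1F1")),
    glycan_entry(P("C2G1S2")),
    glycan_entry(P("M1G1F1")),
    glycan_entry(P("M1G1S1")),
    glycan_entry(P("M1G1S1Gc")),
    glycan_entry(P("M1G1S2")),
    glycan_entry(P("M2G2S1")),
    glycan_entry(P("M2G2S1F1")),
    ## masses whose composition fits both subtypes; excluded from
    ## within-subtype normalisation
    glycan_entry(list(P("C2G1S1"), P("M2G1S1")), ambiguous_subtype = TRUE),
    glycan_entry(list(P("C1F1S1"), P("M1F1S1")), ambiguous_subtype = TRUE)
  )
  glycan_library(switch(type,
                        N = n_entries,
                        O = o_entries,
                        both = c(n_entries, o_entries)))
}

#' Write a glycan library to JSON
#'
#' The on-disk schema stores, per entry: display label, exact m/z, residue
#' composition with end state, the isomer structures with their topology
#' descriptors, the Endo H sensitive fraction and the subtype-ambiguity
#' flag.
#'
#' @param library a `glycan_library`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_glycan_library <- function(library, path) {
  recs <- lapply(unname(library), function(e) {
    list(
      label = as.numeric(e$label),
      exact_mz = e$exact_mz,
      composition = c(as.list(e$composition$counts),
                      list(end_state = e$composition$end_state)),
      glycan_type = e$glycan_type,
      endoh_sensitive_fraction = e$endoh_sensitive_fraction,
      ambiguous_subtype = e$ambiguous_subtype,
      structures = lapply(e$structures, function(s)
        s[c("short_name", "glycan_class", "n_antennae", "bisecting",
            "core_fucose", "antenna_fucose", "galactose", "sialic",
            "hybrid_mannose", "hex_core", "o_core")])
    )
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' Read a glycan library from JSON
#' @param path file written by [write_glycan_library()].
#' @return a `glycan_library`.
#' @export
read_glycan_library <- function(path) {
  recs <- jsonlite::read_json(path)
  entries <- lapply(recs, function(r) {
    structures <- lapply(r$structures, function(s)
      glycan_structure(s$short_name, s$glycan_class,
                       n_antennae = s$n_antennae,
                       bisecting = isTRUE(s$bisecting),
                       core_fucose = s$core_fucose,
                       antenna_fucose = s$antenna_fucose,
                       galactose = s$galactose,
                       sialic = as.character(unlist(s$sialic)),
                       hybrid_mannose = s$hybrid_mannose,
                       hex_core = s$hex_core,
                       o_core = s$o_core))
    glycan_entry(structures,
                 endoh_sensitive_fraction = {
                   v <- r$endoh_sensitive_fraction
                   if (is.null(v) || identical(v, "NA") || is.na(v)) NA_real_
                   else as.numeric(v)
                 },
                 ambiguous_subtype = isTRUE(r$ambiguous_subtype))
  })
  glycan_library(entries)
}
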