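#' Glycan structure descriptors
#'
#' A topology-light description of a glycan: enough to derive its residue
#' composition, its structural categories and a canonical residue tree for
#' fragment enumeration, without committing to linkage positions.
#'
#' For N-glycans the short-name letters follow the convention used throughout
#' the figures this package reproduces: F fucose, A antenna, G galactose,
#' S sialic acid, B bisecting GlcNAc, H hybrid (total mannose count);
#' `Man-k` names the high-mannose/paucimannose series. O-glycan names start
#' with the core (`C1`, `C2` for O-GalNAc cores 1/2; `M1`, `M2` for O-mannose
#' cores) followed by optional F/G/S tokens. An `SGc` token (or `Gc` suffix)
#' marks N-glycolylneuraminic acid instead of N-acetyl.
#'
#' @param short_name display name (stored, not re-derived).
#' @param glycan_class `"N"`, `"O-GalNAc"` or `"O-Man"`.
#' @param n_antennae number of GlcNAc-initiated antennae (0-4); the bisecting
#'   GlcNAc is not an antenna.
#' @param bisecting logical flag for the bisecting GlcNAc.
#' @param core_fucose,antenna_fucose fucose counts by attachment site. Core
#'   fucose sits on the reducing GlcNAc and is removed together with it by
#'   Endo H; antenna fucose (Lewis-type) survives.
#' @param galactose number of galactose residues on antennae (N) or extending
#'   the core (O).
#' @param sialic character vector of sialic acids, each `"NeuAc"` or
#'   `"NeuGc"`.
#' @param hybrid_mannose total mannose count of a hybrid N-glycan (the
#'   H-number); 0 for non-hybrid structures.
#' @param hex_core for `Man-k`/paucimannose N-glycans, the total mannose
#'   count; ignored otherwise.
#' @param o_core `"none"`, `"core1"`, `"core2"`, `"M1"` or `"M2"`.
#' @return object of class `glycan_structure`.
#' @seealso [parse_short_name()], [structure_to_composition()], [classify()]
#' @export
glycan_structure <- function(short_name, glycan_class = "N",
                             n_antennae = 0, bisecting = FALSE,
                             core_fucose = 0, antenna_fucose = 0,
                             galactose = 0, sialic = character(),
                             hybrid_mannose = 0, hex_core = 0,
                             o_core = "none") {
  glycan_class <- match.arg(glycan_class, c("N", "O-GalNAc", "O-Man"))
  o_core <- match.arg(o_core, c("none", "core1", "core2", "M1", "M2"))
  if (length(sialic) && !all(sialic %in% c("NeuAc", "NeuGc")))
    stop("glycan_structure(): sialic must be 'NeuAc'/'NeuGc'")
  if (glycan_class == "O-GalNAc" && !o_core %in% c("core1", "core2"))
    stop("glycan_structure(): O-GalNAc requires o_core core1 or core2")
  if (glycan_class == "O-Man" && !o_core %in% c("M1", "M2"))
    stop("glycan_structure(): O-Man requires o_core M1 or M2")
  if (glycan_class == "N" && o_core != "none")
    stop("glycan_structure(): N-glycans take o_core = 'none'")
  if (n_antennae < 0 || n_antennae > 4)
    stop("glycan_structure(): n_antennae must be 0-4")
  if (glycan_class == "N" && n_antennae == 0 && hex_core == 0)
    stop("glycan_structure(): an N-glycan needs antennae or a Man-k core")
  if (glycan_class == "N" && n_antennae == 0 &&
      (bisecting || galactose > 0 || length(sialic) > 0 || antenna_fucose > 0))
    stop("glycan_structure(): Man-k structures carry no antenna decorations")
  if (glycan_class == "N" && hybrid_mannose > 0 && hybrid_mannose < 3)
    stop("glycan_structure(): a hybrid H-number below 3 is inconsistent ",
         "with the trimannosyl core")
  structure(list(short_name = short_name, glycan_class = glycan_class,
                 n_antennae = n_antennae, bisecting = isTRUE(bisecting),
                 core_fucose = core_fucose, antenna_fucose = antenna_fucose,
                 galactose = galactose, sialic = sialic,
                 hybrid_mannose = hybrid_mannose, hex_core = hex_core,
                 o_core = o_core),
            class = "glycan_structure")
}

#' @export
print.glycan_structure <- function(x, ...) {
  cat(sprintf("<glycan_structure> %s (%s): %s\n", x$short_name,
              x$glycan_class,
              composition_label(structure_to_composition(x))))
  invisible(x)
}

## split the sialic-acid token run "S2", "S1SGc1", "S2Gc", ... into a vector
.parse_sialic_tokens <- function(txt) {
  if (!nzchar(txt)) return(character())
  m <- gregexpr("S(\\d*)(Gc)?", txt, perl = TRUE)[[1]]
  toks <- regmatches(txt, gregexpr("S(\\d*)(Gc)?", txt, perl = TRUE))[[1]]
  if (!length(toks) || sum(nchar(toks)) != nchar(txt))
    stop("parse_short_name(): cannot parse sialic-acid token '", txt, "'")
  out <- character()
  for (tok in toks) {
    gc <- grepl("Gc$", tok)
    n <- sub("Gc$", "", sub("^S", "", tok))
    n <- if (nzchar(n)) as.integer(n) else 1L
    out <- c(out, rep(if (gc) "NeuGc" else "NeuAc", n))
  }
  out
}

#' Parse a glycan short name
#'
#' Understands `Man-k` (k = 1-9, optionally fucosylated as `FMan-k`), the
#' `[Fx][Ay][Gz][Sw][B][Hn]` N-glycan grammar and the `C1/C2/M1/M2`-prefixed
#' O-glycan grammar (see [glycan_structure()]). Letter counts default to 1
#' when omitted (`F` means `F1`).
#'
#' The name does not encode where fucoses sit; by default the first fucose is
#' taken as core fucose and any further ones as antenna fucose. Library
#' entries may override placement when enzymatic evidence demands it.
#'
#' @param name character scalar.
#' @return a `glycan_structure`.
#' @examples
#' parse_short_name("Man-5")
#' parse_short_name("F2A2G1")
#' parse_short_name("A1BH5")
#' parse_short_name("C1S2")    # di-sialylated core 1 O-GalNAc
#' @export
parse_short_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  ## high-mannose / paucimannose series, optional core fucose
  m <- regexec("^(F(\\d*))?Man-([1-9])$", name, perl = TRUE)[[1]]
  if (m[1] != -1) {
    g <- regmatches(name, list(m))[[1]]
    fuc <- if (nzchar(g[2])) { if (nzchar(g[3])) as.integer(g[3]) else 1L } else 0L
    return(glycan_structure(name, "N", n_antennae = 0, core_fucose = fuc,
                            hex_core = as.integer(g[4])))
  }
  ## O-glycans: core prefix then F/G/S tokens in any order
  if (grepl("^(C1|C2|M1|M2)", name)) {
    core <- substr(name, 1, 2)
    rest <- substring(name, 3)
    fuc <- 0L; gal <- 0L; sial <- character()
    while (nzchar(rest)) {
      tok <- regmatches(rest, regexpr("^(S\\d*(Gc)?|F\\d*|G\\d*)", rest,
                                      perl = TRUE))
      if (!length(tok) || !nzchar(tok))
        stop("parse_short_name(): cannot parse '", name,
             "' (offending token '", rest, "')", call. = FALSE)
      if (startsWith(tok, "S")) {
        sial <- c(sial, .parse_sialic_tokens(tok))
      } else {
        k <- sub("^[FG]", "", tok)
        k <- if (nzchar(k)) as.integer(k) else 1L
        if (startsWith(tok, "F")) fuc <- fuc + k else gal <- gal + k
      }
      rest <- substring(rest, nchar(tok) + 1)
    }
    return(glycan_structure(
      name,
      glycan_class = if (core %in% c("C1", "C2")) "O-GalNAc" else "O-Man",
      o_core = c(C1 = "core1", C2 = "core2", M1 = "M1", M2 = "M2")[[core]],
      core_fucose = 0, antenna_fucose = fuc, galactose = gal,
      sialic = sial))
  }
  ## complex / hybrid N-glycans
  m <- regexec("^(?:F(\\d*))?(?:A(\\d*))?(?:G(\\d*))?((?:S\\d*(?:Gc)?)*)(B)?(?:H(\\d*))?$",
               name, perl = TRUE)[[1]]
  bad_token <- function() {
    ## report the first character run that the grammar does not accept
    left <- gsub("(F\\d*)|(A\\d*)|(G\\d*)|(S\\d*(Gc)?)|(B)|(H\\d*)", "",
                 name, perl = TRUE)
    stop("parse_short_name(): cannot parse '", name, "' (offending token '",
         if (nzchar(left)) left else name, "')", call. = FALSE)
  }
  if (m[1] == -1 || !nzchar(name)) bad_token()
  g <- regmatches(name, list(m))[[1]]
  ## regexec gives "" both for an absent group and for a letter without a
  ## count; disambiguate against the name itself
  cnt <- function(letter, capture) {
    if (!grepl(paste0(letter, "(\\d|[A-Z]|$)"), name)) return(0L)
    if (nzchar(capture)) as.integer(capture) else 1L
  }
  fuc <- cnt("F", g[2]); ant <- cnt("A", g[3]); gal <- cnt("G", g[4])
  sial <- .parse_sialic_tokens(g[5])
  bis <- nzchar(g[6])
  hyb <- if (grepl("H(\\d|$)", name)) {
    if (nzchar(g[7])) as.integer(g[7]) else 1L
  } else 0L
  if (ant == 0 && fuc == 0 && gal == 0 && !bis && hyb == 0 && !length(sial))
    bad_token()
  if (ant == 0)
    stop("parse_short_name(): '", name,
         "' has antenna decorations but no antenna (A) token")
  glycan_structure(name, "N", n_antennae = ant, bisecting = bis,
                   core_fucose = min(fuc, 1L),
                   antenna_fucose = max(fuc - 1L, 0L),
                   galactose = gal, sialic = sial, hybrid_mannose = hyb)
}

#' Derive the residue composition of a structure
#'
#' N-glycans: HexNAc = 2 core GlcNAc + antennae + bisecting; Hex = 3 + Gal
#' for complex, H-number + Gal for hybrid, and the mannose count directly for
#' the Man-k series. O-glycans: the core base plus galactose extensions.
#' Fucoses map to dHex and sialic acids to NeuAc/NeuGc.
#'
#' @param s a `glycan_structure`.
#' @param end_state reducing-end state for the derived composition; defaults
#'   to free reducing end for N-glycans and alditol for O-glycans.
#' @return a `glycan_composition`.
#' @examples
#' composition_label(structure_to_composition(parse_short_name("FA1BH4")))
#' @export
structure_to_composition <- function(s, end_state = NULL) {
  stopifnot(inherits(s, "glycan_structure"))
  if (is.null(end_state))
    end_state <- if (s$glycan_class == "N") "free_reducing" else "alditol"
  neuac <- sum(s$sialic == "NeuAc"); neugc <- sum(s$sialic == "NeuGc")
  dhex <- s$core_fucose + s$antenna_fucose
  if (s$glycan_class == "N") {
    if (s$n_antennae == 0) {            # Man-k series
      hex <- s$hex_core; hexnac <- 2L
    } else {
      hexnac <- 2L + s$n_antennae + as.integer(s$bisecting)
      hex <- if (s$hybrid_mannose > 0) s$hybrid_mannose + s$galactose
             else 3L + s$galactose
    }
  } else {
    base_hex    <- c(core1 = 1L, core2 = 1L, M1 = 1L, M2 = 1L)[[s$o_core]]
    base_hexnac <- c(core1 = 1L, core2 = 2L, M1 = 1L, M2 = 2L)[[s$o_core]]
    hex <- base_hex + s$galactose
    hexnac <- base_hexnac
  }
  glycan_composition(hex = hex, hexnac = hexnac, dhex = dhex,
                     neuac = neuac, neugc = neugc, end_state = end_state)
}

#' Theoretical m/z of a structure (convenience wrapper)
#' @inheritParams structure_to_composition
#' @param adduct passed to [composition_mz()].
#' @export
structure_mz <- function(s, end_state = NULL, adduct = "sodium") {
  composition_mz(structure_to_composition(s, end_state), adduct)
}

#' Structural categories of a glycan
#'
#' N-glycans receive exactly one mutually exclusive main class —
#' `paucimannose` (2 core GlcNAc, 1-4 Hex, optional core fucose),
#' `high-mannose` (2 core GlcNAc, 5-9 Hex, no fucose or sialic acid) or an
#' antennarity class `mono-/bi-/tri-/tetra-antennary` counting
#' GlcNAc-initiated antennae (hybrids are absorbed into the antennary
#' classes) — plus independent cross-cutting flags: `hybrid` (at least one
#' antenna and H-number >= `hybrid_min_mannose`), `bisected`, `galactose`,
#' `fucose`, `NeuAc`, `NeuGc`. O-glycans receive their subtype
#' (`O-GalNAc`/`O-Man`), core (`core1`/`core2`/`M1`/`M2`) and the
#' `fucose`/`NeuAc`/`NeuGc` flags.
#'
#' @param s a `glycan_structure`.
#' @param hybrid_min_mannose smallest H-number that still counts as hybrid
#'   (default 4; configurable because the boundary between a trimmed hybrid
#'   and a complex glycan is a convention).
#' @return character vector of category labels.
#' @examples
#' classify(parse_short_name("Man-5"))   # high-mannose
#' classify(parse_short_name("FA1BH4"))  # mono-antennary + hybrid + ...
#' @export
classify <- function(s, hybrid_min_mannose = 4) {
  stopifnot(inherits(s, "glycan_structure"))
  comp <- structure_to_composition(s)
  fuc  <- comp$counts[["dhex"]] > 0
  flags <- c(if (fuc) "fucose",
             if (comp$counts[["neuac"]] > 0) "NeuAc",
             if (comp$counts[["neugc"]] > 0) "NeuGc")
  if (s$glycan_class != "N") {
    return(c(s$glycan_class, s$o_core, flags))
  }
  if (s$n_antennae == 0) {
    main <- if (s$hex_core <= 4) "paucimannose" else "high-mannose"
  } else {
    main <- c("mono-antennary", "bi-antennary",
              "tri-antennary", "tetra-antennary")[s$n_antennae]
  }
  hybrid <- s$n_antennae >= 1 && s$hybrid_mannose >= hybrid_min_mannose
  c(main,
    if (hybrid) "hybrid",
    if (s$bisecting) "bisected",
    if (s$galactose > 0) "galactose",
    flags)
}

#' Mutually exclusive N-glycan main classes
#' @return character vector of the six class labels, in table order.
#' @export
n_glycan_classes <- function() {
  c("paucimannose", "high-mannose", "mono-antennary", "bi-antennary",
    "tri-antennary", "tetra-antennary")
}

#' All N-glycan category labels in table order
#' @return character vector.
#' @export
n_glycan_categories <- function() {
  c(n_glycan_classes(), "hybrid", "bisected", "galactose", "fucose",
    "NeuAc", "NeuGc")
}

#' All O-glycan category labels in table order
#' @return character vector.
#' @export
o_glycan_categories <- function() {
  c("O-GalNAc", "O-Man", "fucose", "NeuAc", "NeuGc",
    "core1", "core2", "M1", "M2")
}
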