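#' @keywords internal
"_PACKAGE"

## Monoisotopic atomic masses (Da). Electron mass is ignored; it is far below
## any matching tolerance used on TOF data.
.ATOMIC_MASS <- c(
  C  = 12,
  H  = 1.007825,
  N  = 14.003074,
  O  = 15.994915,
  Na = 22.989770
)

#' Monoisotopic mass of a molecular formula
#'
#' @param counts named integer vector of atom counts, names among
#'   `C`, `H`, `N`, `O`, `Na`.
#' @return mass in Da.
#' @examples
#' formula_mass(c(C = 2, H = 6, O = 1)) # free-reducing-end terminal adjustment
#' @export
formula_mass <- function(counts) {
  if (is.null(names(counts)) || !all(names(counts) %in% names(.ATOMIC_MASS)))
    stop("formula_mass(): atom names must be among ",
         paste(names(.ATOMIC_MASS), collapse = ", "))
  sum(.ATOMIC_MASS[names(counts)] * counts)
}

## Molecular formulas of in-chain permethylated residues. Calibrated so that
## sum(residues) + terminal adjustment gives the intact permethylated glycan:
## a standalone permethylated monosaccharide is residue + C2H6O, and every
## glycosidic bond costs exactly C2H6O, so branching topology never affects
## the composition mass.
.RESIDUE_FORMULA <- list(
  hex    = c(C =  9, H = 16, O = 5),
  hexnac = c(C = 11, H = 19, N = 1, O = 5),
  dhex   = c(C =  8, H = 14, O = 4),
  neuac  = c(C = 16, H = 27, N = 1, O = 8),
  neugc  = c(C = 17, H = 29, N = 1, O = 9)
)

.END_FORMULA <- list(
  ## free reducing end after permethylation (anomeric OMe + ring terminus)
  free_reducing = c(C = 2, H = 6, O = 1),
  ## reduced (alditol) terminus from beta-elimination: reduction opens the
  ## ring and methylation adds one extra methyl relative to the reducing end
  alditol       = c(C = 3, H = 10, O = 1),
  ## the GlcNAc retained after Endo H cleavage becomes the new reducing end
  endoh_product = c(C = 2, H = 6, O = 1)
)

.RESIDUE_ORDER <- c("hex", "hexnac", "dhex", "neuac", "neugc")

#' Permethylated residue and terminal mass constants
#'
#' All values are derived from atomic monoisotopic masses through the
#' molecular formulas of the in-chain permethylated residues, not copied from
#' the literature.
#'
#' @return named list with `residues` (Da per residue type), `ends`
#'   (terminal adjustments per end state), `adducts` (currently sodium) and
#'   `ch2` (the methyl/hydroxyl exchange unit used for fragment scars and
#'   display-label bookkeeping).
#' @export
mass_constants <- function() {
  list(
    residues = vapply(.RESIDUE_FORMULA, formula_mass, numeric(1)),
    ends     = vapply(.END_FORMULA, formula_mass, numeric(1)),
    adducts  = c(sodium = unname(.ATOMIC_MASS["Na"])),
    ch2      = formula_mass(c(C = 1, H = 2)),
    h2o      = formula_mass(c(H = 2, O = 1)),
    h        = unname(.ATOMIC_MASS["H"])
  )
}

#' Monosaccharide composition of a glycan
#'
#' The unit of mass calculation: counts of the five residue classes resolved
#' by MALDI-TOF of permethylated glycans, plus the reducing-end state.
#' N-glycans released by PNGase F keep a free reducing end, O-glycans released
#' by reductive beta-elimination are alditols, and Endo H products retain the
#' distal core GlcNAc as a new reducing end.
#'
#' @param hex,hexnac,dhex,neuac,neugc non-negative residue counts.
#' @param end_state one of `"free_reducing"`, `"alditol"`, `"endoh_product"`.
#' @return object of class `glycan_composition`.
#' @examples
#' glycan_composition(hex = 5, hexnac = 2)            # Man-5
#' glycan_composition(hex = 1, hexnac = 1, neuac = 2, # di-sialyl core 1
#'                    end_state = "alditol")
#' @export
glycan_composition <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0,
                               neugc = 0,
                               end_state = c("free_reducing", "alditol",
                                             "endoh_product")) {
  end_state <- match.arg(end_state)
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex,
              neuac = neuac, neugc = neugc)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("glycan_composition(): residue counts must be non-negative integers")
  if (sum(counts) < 1)
    stop("glycan_composition(): empty composition (no residues)")
  structure(list(counts = counts, end_state = end_state),
            class = "glycan_composition")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(composition_label(x), sprintf("[%s]", x$end_state), "\n")
  invisible(x)
}

#' Compact composition label such as "Hex5HexNAc2"
#' @param comp a `glycan_composition`.
#' @return character scalar.
#' @export
composition_label <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  pretty <- c(hex = "Hex", hexnac = "HexNAc", dhex = "dHex",
              neuac = "NeuAc", neugc = "NeuGc")
  nz <- comp$counts[comp$counts > 0]
  paste0(pretty[names(nz)], nz, collapse = "")
}

#' Theoretical m/z of a permethylated glycan
#'
#' Sum of permethylated residue masses plus the terminal adjustment for the
#' reducing-end state plus the adduct mass. MALDI of permethylated glycans is
#' dominated by the singly charged sodiated ion, so `[M+Na]+` is the default
#' and only built-in adduct.
#'
#' @param comp a `glycan_composition`.
#' @param adduct adduct name; only `"sodium"` is supported.
#' @return theoretical m/z in Da.
#' @examples
#' composition_mz(glycan_composition(hex = 5, hexnac = 2)) # 1579.78
#' @export
composition_mz <- function(comp, adduct = "sodium") {
  if (!inherits(comp, "glycan_composition"))
    stop("composition_mz(): `comp` must be a glycan_composition")
  mc <- mass_constants()
  if (!adduct %in% names(mc$adducts))
    stop("composition_mz(): unsupported adduct '", adduct, "'")
  if (!comp$end_state %in% names(mc$ends))
    stop("composition_mz(): unknown end_state '", comp$end_state, "'")
  sum(mc$residues[names(comp$counts)] * comp$counts) +
    mc$ends[[comp$end_state]] + mc$adducts[[adduct]]
}

#' Integer display label for a theoretical m/z
#'
#' Mirrors how peaks are labelled in the figures this library is matched
#' against: free-reducing-end N-glycan labels drop the fractional part, while
#' alditol (O-glycan) labels round to the nearest integer. Labels are for
#' display only; all matching uses exact masses.
#'
#' @param mz exact theoretical m/z.
#' @param end_state reducing-end state the label convention depends on.
#' @return integer label.
#' @export
mz_label <- function(mz, end_state = "free_reducing") {
  if (end_state == "alditol") round(mz) else floor(mz)
}

#' Arithmetic on compositions (internal)
#' @noRd
comp_add <- function(comp, hex = 0, hexnac = 0, dhex = 0, neuac = 0,
                     neugc = 0, end_state = comp$end_state) {
  counts <- comp$counts + c(hex = hex, hexnac = hexnac, dhex = dhex,
                            neuac = neuac, neugc = neugc)
  glycan_composition(counts[["hex"]], counts[["hexnac"]], counts[["dhex"]],
                     counts[["neuac"]], counts[["neugc"]],
                     end_state = end_state)
}
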