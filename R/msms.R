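#' Canonical residue tree of a structure
#'
#' Expands the topology descriptors into a fixed residue tree for fragment
#' enumeration. Linkage positions never affect permethylated fragment
#' masses, so the layout is a reproducibility convention: core
#' GlcNAc-GlcNAc-Man with the two arm mannoses; antennae
#' (GlcNAc - optional Gal - optional NeuAc/NeuGc) seeded alternately on the
#' 3- and 6-arm; the bisecting GlcNAc on the core mannose; core fucose on
#' the reducing GlcNAc; antenna fucose on the first antenna GlcNAc;
#' additional mannoses of the Man-k / hybrid series distributed round-robin
#' over the free arms. O-glycan cores follow the core 1/2 and M1/M2
#' definitions with galactose extending the arm GlcNAc (or the core Gal for
#' core 1) and sialic acids capping outermost positions.
#'
#' @param s a `glycan_structure`.
#' @return data.frame with columns `id`, `residue`
#'   (hex/hexnac/dhex/neuac/neugc) and `parent` (0 for the reducing-end
#'   root).
#' @export
structure_to_tree <- function(s) {
  stopifnot(inherits(s, "glycan_structure"))
  res <- character(); par <- integer()
  add <- function(residue, parent) {
    res[[length(res) + 1L]] <<- residue
    par[[length(par) + 1L]] <<- parent
    length(res)
  }
  if (s$glycan_class == "N") {
    g1 <- add("hexnac", 0L)                       # reducing GlcNAc
    g2 <- add("hexnac", g1)
    nhex <- if (s$n_antennae == 0) s$hex_core
            else if (s$hybrid_mannose > 0) s$hybrid_mannose else 3L
    ## mannose core: beta-Man then the two arms, extras round-robin as
    ## chains on 6-arm then 3-arm
    mb <- add("hex", g2); arms <- integer()
    if (nhex >= 2) arms[1] <- add("hex", mb)      # 3-arm
    if (nhex >= 3) arms[2] <- add("hex", mb)      # 6-arm
    extra <- nhex - min(nhex, 3L)
    if (extra > 0) {
      tips <- c(arms[min(2, length(arms))], arms[1])
      for (k in seq_len(extra)) {
        slot <- ((k - 1) %% 2) + 1
        tips[slot] <- add("hex", tips[slot])
      }
    }
    for (f in seq_len(s$core_fucose)) add("dhex", g1)
    if (s$bisecting) add("hexnac", mb)
    gal_left <- s$galactose; sial <- s$sialic; fuc_left <- s$antenna_fucose
    for (a in seq_len(s$n_antennae)) {
      base <- if (s$hybrid_mannose > 0) arms[1]   # antennae on the 3-arm
              else arms[((a - 1) %% length(arms)) + 1]
      gn <- add("hexnac", base)
      tip <- gn
      if (gal_left > 0) { tip <- add("hex", gn); gal_left <- gal_left - 1 }
      if (length(sial)) {
        add(if (sial[1] == "NeuAc") "neuac" else "neugc", tip)
        sial <- sial[-1]
      }
      if (fuc_left > 0) { add("dhex", gn); fuc_left <- fuc_left - 1 }
    }
  } else {
    root <- add(if (s$o_core %in% c("core1", "core2")) "hexnac" else "hex", 0L)
    sial <- s$sialic; gal_left <- s$galactose; fuc_left <- s$antenna_fucose
    arm_tips <- integer()
    if (s$o_core == "core1") {
      arm_tips <- add("hex", root)                # core Gal
    } else if (s$o_core == "core2") {
      coregal <- add("hex", root)
      gn <- add("hexnac", root)
      tip <- gn
      if (gal_left > 0) { tip <- add("hex", gn); gal_left <- gal_left - 1 }
      if (fuc_left > 0) { add("dhex", gn); fuc_left <- fuc_left - 1 }
      arm_tips <- c(tip, coregal)
    } else {                                      # M1 / M2
      n_gn <- if (s$o_core == "M1") 1L else 2L
      for (k in seq_len(n_gn)) {
        gn <- add("hexnac", root)
        tip <- gn
        if (gal_left > 0) { tip <- add("hex", gn); gal_left <- gal_left - 1 }
        if (fuc_left > 0) { add("dhex", gn); fuc_left <- fuc_left - 1 }
        arm_tips <- c(arm_tips, tip)
      }
    }
    ## remaining decorations: sialic acids cap the arm tips, then the root
    caps <- c(arm_tips, root)
    for (k in seq_along(sial))
      add(if (sial[k] == "NeuAc") "neuac" else "neugc",
          caps[((k - 1) %% length(caps)) + 1])
    for (k in seq_len(fuc_left)) add("dhex", root)
    for (k in seq_len(gal_left)) add("hex", arm_tips[1])
  }
  tree <- data.frame(id = seq_along(res), residue = res, parent = par)
  comp <- structure_to_composition(s)
  got <- table(factor(tree$residue, levels = names(comp$counts)))
  if (!all(got == comp$counts))
    stop("structure_to_tree(): tree residues disagree with the derived ",
         "composition for '", s$short_name, "'")
  tree
}

## m/z of one fragment component
## root_frag: contains the molecular reducing end; n_lost: child subtrees
## cut away (each leaves a demethylated scar, -CH2); a non-root fragment is
## B-type at its top cut (+CH2), which reproduces the standard sodiated
## oxonium masses and makes every single-cleavage B/Y pair sum to
## parent m/z + Na exactly.
.fragment_mz <- function(residues, root_frag, n_lost, end_state) {
  mc <- mass_constants()
  sum(mc$residues[residues]) +
    (if (root_frag) mc$ends[[end_state]] else mc$ch2) -
    n_lost * mc$ch2 + mc$adducts[["sodium"]]
}

#' Enumerate glycosidic fragment ions
#'
#' Cuts every combination of up to `max_breaks` glycosidic bonds of the
#' canonical residue tree and returns each resulting connected piece as a
#' fragment ion: B-type (non-reducing piece), Y-type (reducing piece) or
#' internal (both kinds of cut). Fragments are deduplicated by residue
#' multiset, scar count and terminal type. With `ions = c("B","Y","C","Z")`
#' the single-cleavage C (B + H2O) and Z (Y - H2O) companions are added.
#'
#' @param s a `glycan_structure`.
#' @param max_breaks 1-3 simultaneous bond breaks.
#' @param ions ion types; default B and Y (sodiated, singly charged).
#' @param end_state reducing-end state of the parent (defaults per class).
#' @return data.frame of class `fragment_ions`: `mz`, `type`, `n_cleavages`,
#'   `scars`, `residues` (multiset signature), with the parent m/z as an
#'   attribute.
#' @export
enumerate_fragments <- function(s, max_breaks = 3, ions = c("B", "Y"),
                                end_state = NULL) {
  stopifnot(inherits(s, "glycan_structure"))
  if (!is.numeric(max_breaks) || max_breaks < 1 || max_breaks > 3)
    stop("enumerate_fragments(): max_breaks must be between 1 and 3")
  ions <- match.arg(ions, c("B", "Y", "C", "Z"), several.ok = TRUE)
  if (is.null(end_state))
    end_state <- if (s$glycan_class == "N") "free_reducing" else "alditol"
  tree <- structure_to_tree(s)
  n <- nrow(tree)
  edges <- which(tree$parent > 0)                 # edge i: parent[i] -- i
  mc <- mass_constants()
  seen <- new.env(parent = emptyenv())
  rows <- list()
  emit <- function(members, cuts_in_set) {
    root_frag <- 1L %in% members
    ## children cut away from this piece: cut edges whose parent is inside
    lost <- sum(tree$parent[cuts_in_set] %in% members)
    residues <- sort(tree$residue[members])
    type <- if (root_frag) "Y" else if (lost == 0) "B" else "internal"
    key <- paste(type, lost, paste(residues, collapse = "+"))
    if (!is.null(seen[[key]])) return()
    mz <- .fragment_mz(residues, root_frag, lost, end_state)
    seen[[key]] <- TRUE
    rows[[length(rows) + 1L]] <<- data.frame(
      mz = mz, type = type, n_cleavages = length(cuts_in_set),
      scars = lost, residues = paste(residues, collapse = "+"))
  }
  for (k in seq_len(min(max_breaks, length(edges)))) {
    ## index-based combinations: combn() would misread a single edge id as
    ## a count
    cut_sets <- utils::combn(seq_along(edges), k, simplify = FALSE)
    for (cut in lapply(cut_sets, function(i) edges[i])) {
      ## component labels with the cut edges removed
      parent <- tree$parent
      parent[cut] <- 0L
      comp_id <- seq_len(n)
      for (i in seq_len(n))                       # parents precede children
        if (parent[i] > 0) comp_id[i] <- comp_id[parent[i]]
      for (cid in unique(comp_id))
        emit(which(comp_id == cid), cut)
    }
  }
  out <- do.call(rbind, rows)
  if (any(c("C", "Z") %in% ions)) {
    extra <- out[out$n_cleavages == 1 & out$type %in% c("B", "Y"), ]
    cz <- list()
    if ("C" %in% ions && any(extra$type == "B")) {
      b <- extra[extra$type == "B", ]
      b$mz <- b$mz + mc$h2o; b$type <- "C"
      cz <- c(cz, list(b))
    }
    if ("Z" %in% ions && any(extra$type == "Y")) {
      y <- extra[extra$type == "Y", ]
      y$mz <- y$mz - mc$h2o; y$type <- "Z"
      cz <- c(cz, list(y))
    }
    out <- rbind(out, do.call(rbind, cz))
  }
  out <- out[out$type %in% c(ions, "internal"), , drop = FALSE]
  out <- out[order(out$mz), ]
  rownames(out) <- NULL
  attr(out, "parent_mz") <- structure_mz(s, end_state)
  attr(out, "short_name") <- s$short_name
  class(out) <- c("fragment_ions", "data.frame")
  out
}

#' Match theoretical fragments to an MS2 peak list
#'
#' Greedy nearest matching: fragments are visited in order of increasing
#' distance to their closest observed peak and each observed peak is
#' consumed at most once.
#'
#' @param fragments a `fragment_ions` data.frame.
#' @param ms2 data.frame with an `mz` column (and optionally `intensity`),
#'   or a `glycan_spectrum`.
#' @param tolerance matching tolerance in Da.
#' @return the matched subset of `fragments` with columns `obs_mz` and
#'   `delta` added.
#' @export
match_ms2 <- function(fragments, ms2, tolerance = 0.5) {
  stopifnot(tolerance > 0)
  if (inherits(ms2, "glycan_spectrum")) ms2 <- ms2$peaks
  if (nrow(ms2) == 0) {
    warning("match_ms2(): empty MS2 peak list")
    out <- fragments[0, ]
    out$obs_mz <- numeric(0); out$delta <- numeric(0)
    return(out)
  }
  obs <- sort(ms2$mz)
  cand <- do.call(rbind, lapply(seq_len(nrow(fragments)), function(i) {
    d <- abs(obs - fragments$mz[i])
    j <- which.min(d)
    if (d[j] <= tolerance)
      data.frame(frag = i, obs = j, dist = d[j]) else NULL
  }))
  taken <- logical(length(obs)); keep <- integer(); omz <- numeric()
  if (!is.null(cand)) {
    cand <- cand[order(cand$dist), ]
    for (r in seq_len(nrow(cand))) {
      i <- cand$frag[r]
      d <- abs(obs - fragments$mz[i]); d[taken] <- Inf
      j <- which.min(d)
      if (is.finite(d[j]) && d[j] <= tolerance) {
        taken[j] <- TRUE; keep <- c(keep, i); omz <- c(omz, obs[j])
      }
    }
  }
  out <- fragments[keep, , drop = FALSE]
  out$obs_mz <- omz
  out$delta <- out$obs_mz - out$mz
  out[order(out$mz), , drop = FALSE]
}

#' Rank candidate isomers of one parent mass by MS2 evidence
#'
#' For each candidate the theoretical fragment set is computed; fragments
#' whose m/z (within tolerance) occurs in no other candidate's set are its
#' diagnostic fragments. Candidates are scored by matched diagnostic
#' fragments, ties broken by total matched fragments. When two or more
#' candidates each match at least one diagnostic fragment the verdict is
#' `"co-present"`; when none does, `"ambiguous"`.
#'
#' @param candidates list of `glycan_structure`s sharing one composition, or
#'   a `glycan_entry`.
#' @param ms2 observed MS2 peaks (data.frame or `glycan_spectrum`).
#' @param tolerance Da.
#' @param max_breaks passed to [enumerate_fragments()].
#' @return list of class `isomer_ranking`: `evidence` data.frame (one row
#'   per candidate: name, matched totals, diagnostics), `verdict`, `note`.
#' @export
rank_isomers <- function(candidates, ms2, tolerance = 0.5, max_breaks = 3) {
  if (inherits(candidates, "glycan_entry")) candidates <- candidates$structures
  stopifnot(length(candidates) >= 1)
  mzs <- vapply(candidates, structure_mz, numeric(1))
  if (diff(range(mzs)) > 1e-6)
    stop("rank_isomers(): candidates must share one composition")
  frag_sets <- lapply(candidates, enumerate_fragments, max_breaks = max_breaks)
  diag_flag <- lapply(seq_along(candidates), function(i) {
    others <- unlist(lapply(frag_sets[-i], `[[`, "mz"))
    vapply(frag_sets[[i]]$mz, function(m)
      !length(others) || all(abs(others - m) > tolerance), logical(1))
  })
  ev <- do.call(rbind, lapply(seq_along(candidates), function(i) {
    matched <- match_ms2(frag_sets[[i]], ms2, tolerance)
    diag_mz <- frag_sets[[i]]$mz[diag_flag[[i]]]
    diag_matched <- sum(vapply(matched$mz, function(m)
      any(abs(diag_mz - m) < 1e-9), logical(1)))
    data.frame(candidate = candidates[[i]]$short_name,
               n_theoretical = nrow(frag_sets[[i]]),
               n_diagnostic = sum(diag_flag[[i]]),
               matched_total = nrow(matched),
               matched_diagnostic = diag_matched)
  }))
  ev <- ev[order(-ev$matched_diagnostic, -ev$matched_total, ev$candidate), ]
  rownames(ev) <- NULL
  with_diag <- sum(ev$matched_diagnostic > 0)
  verdict <- if (length(candidates) == 1) "single-candidate"
             else if (with_diag >= 2) "co-present"
             else if (with_diag == 1) ev$candidate[1]
             else "ambiguous"
  note <- if (length(candidates) == 1)
    "only one candidate structure; ranking is trivial" else NA_character_
  structure(list(evidence = ev, verdict = verdict, note = note),
            class = "isomer_ranking")
}

#' @export
print.isomer_ranking <- function(x, ...) {
  cat("<isomer_ranking> verdict:", x$verdict, "\n")
  print(x$evidence)
  invisible(x)
}

#' Simulate an MS2 spectrum from one or more structures
#'
#' Emits every theoretical B/Y fragment (up to `max_breaks` cleavages) of
#' each structure at its exact m/z, with intensities proportional to the
#' mixture weights; a fragment shared between structures sums.
#'
#' @param structures list of `glycan_structure`s (a single structure is
#'   wrapped).
#' @param weights mixture weights, recycled to length.
#' @param max_breaks cleavage depth.
#' @return data.frame with `mz` and `intensity`.
#' @export
simulate_ms2 <- function(structures, weights = 1, max_breaks = 2) {
  if (inherits(structures, "glycan_structure")) structures <- list(structures)
  weights <- rep_len(weights, length(structures))
  peaks <- do.call(rbind, lapply(seq_along(structures), function(i) {
    fr <- enumerate_fragments(structures[[i]], max_breaks = max_breaks)
    data.frame(mz = fr$mz, intensity = 100 * weights[i])
  }))
  agg <- stats::aggregate(intensity ~ mz, peaks, sum)
  agg[order(agg$mz), ]
}
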