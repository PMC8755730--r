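# Independent oracles: everything here recomputes masses and enumerations
# from first principles (atomic formulas, explicit edge-subset cuts, direct
# sums of squares) without touching the package's constant tables or its
# enumeration code paths.

ORACLE_ATOMS <- c(C = 12, H = 1.007825, N = 14.003074, O = 15.994915,
                  Na = 22.989770)

`%||%` <- function(a, b) if (is.null(a)) b else a

# atoms of one in-chain permethylated residue
oracle_residue_atoms <- function(residue) {
  switch(residue,
    hex    = c(C = 9, H = 16, N = 0, O = 5, Na = 0),
    hexnac = c(C = 11, H = 19, N = 1, O = 5, Na = 0),
    dhex   = c(C = 8, H = 14, N = 0, O = 4, Na = 0),
    neuac  = c(C = 16, H = 27, N = 1, O = 8, Na = 0),
    neugc  = c(C = 17, H = 29, N = 1, O = 9, Na = 0),
    stop("unknown residue ", residue))
}

oracle_end_atoms <- function(end_state) {
  switch(end_state,
    free_reducing = c(C = 2, H = 6, N = 0, O = 1, Na = 0),
    alditol       = c(C = 3, H = 10, N = 0, O = 1, Na = 0),
    endoh_product = c(C = 2, H = 6, N = 0, O = 1, Na = 0),
    stop("unknown end state ", end_state))
}

# sodiated m/z from residue counts, by summing atoms first
oracle_mz <- function(hex = 0, hexnac = 0, dhex = 0, neuac = 0, neugc = 0,
                      end_state = "free_reducing") {
  counts <- c(hex = hex, hexnac = hexnac, dhex = dhex, neuac = neuac,
              neugc = neugc)
  atoms <- oracle_end_atoms(end_state)
  atoms[["Na"]] <- atoms[["Na"]] + 1
  for (r in names(counts))
    atoms <- atoms + counts[[r]] * oracle_residue_atoms(r)
  sum(ORACLE_ATOMS[names(atoms)] * atoms)
}

# brute-force fragment enumeration: cut every subset of <= max_breaks tree
# edges, label components by breadth-first flooding over the remaining
# adjacency, and price each component by atom bookkeeping (+CH2 at a
# non-reducing top, -CH2 per severed child).
oracle_fragments <- function(tree, max_breaks, end_state) {
  ch2 <- sum(ORACLE_ATOMS[c("C", "H", "H")])
  edges <- tree$id[tree$parent > 0]
  adj <- function(cut) {
    keep <- setdiff(edges, cut)
    nb <- lapply(seq_len(nrow(tree)), function(i) integer())
    for (e in keep) {
      p <- tree$parent[e]
      nb[[e]] <- c(nb[[e]], p); nb[[p]] <- c(nb[[p]], e)
    }
    nb
  }
  out <- list()
  for (k in seq_len(min(max_breaks, length(edges)))) {
    cut_idx <- utils::combn(seq_along(edges), k, simplify = FALSE)
    for (cut in lapply(cut_idx, function(i) edges[i])) {
      nb <- adj(cut)
      unvisited <- rep(TRUE, nrow(tree))
      while (any(unvisited)) {
        start <- which(unvisited)[1]
        comp <- start; frontier <- start; unvisited[start] <- FALSE
        while (length(frontier)) {
          nxt <- unique(unlist(nb[frontier]))
          nxt <- nxt[unvisited[nxt]]
          unvisited[nxt] <- FALSE
          comp <- c(comp, nxt); frontier <- nxt
        }
        has_root <- 1 %in% comp
        lost <- sum(tree$parent[cut] %in% comp)
        atoms <- c(C = 0, H = 0, N = 0, O = 0, Na = 1)
        for (i in comp) atoms <- atoms + oracle_residue_atoms(tree$residue[i])
        mz <- sum(ORACLE_ATOMS[names(atoms)] * atoms) - lost * ch2 +
          (if (has_root) sum(ORACLE_ATOMS[names(oracle_end_atoms(end_state))] *
                               oracle_end_atoms(end_state)) else ch2)
        type <- if (has_root) "Y" else if (lost == 0) "B" else "internal"
        key <- paste(type, lost,
                     paste(sort(tree$residue[comp]), collapse = "+"))
        if (is.null(out[[key]])) out[[key]] <- mz
      }
    }
  }
  sort(unname(unlist(out)))
}

# direct between/within sums of squares
oracle_anova_F <- function(groups) {
  all <- unlist(groups)
  grand <- mean(all)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - grand)^2,
                    numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  dfb <- length(groups) - 1
  dfw <- length(all) - length(groups)
  (ssb / dfb) / (ssw / dfw)
}

# shared fixtures
noise_free_config <- function() {
  sim_config(intensity_log_sd = 0, calibration_da = 0, noise_density = 0)
}

truth_as_profile <- function(truth, library = attr(truth, "library")) {
  structure(
    data.frame(label = names(truth),
               exact_mz = library_mz(library)[names(truth)],
               abundance = as.numeric(truth)),
    class = c("glycome_profile", "data.frame"))
}
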