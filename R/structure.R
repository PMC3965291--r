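#' Load a nucleosome (or any) structure from a PDB file
#'
#' Parses the file with `bio3d`, keeps the first model, resolves
#' alternate locations by retaining the highest-occupancy conformer per
#' atom, and drops hydrogens (all distance work here is heavy-atom only).
#'
#' @param path Path to a PDB file.
#' @return An object of class `structure_model`: list with `atoms`, a
#'   `data.frame` (chain, resno, resid, elety, x, y, z).
#' @export
load_structure <- function(path) {
  if (!file.exists(path)) stop("load_structure: file not found: ", path)
  pdb <- bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE, verbose = FALSE)
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("load_structure: no atoms in file")
  ## highest-occupancy altloc per (chain, residue, atom name)
  if (!is.null(a$alt) && any(!is.na(a$alt) & a$alt != "")) {
    key <- paste(a$chain, a$resno, a$elety)
    occ <- ifelse(is.na(a$o), 1, a$o)
    best <- tapply(seq_len(nrow(a)), key, function(i) i[which.max(occ[i])])
    a <- a[sort(unlist(best)), ]
  }
  elem <- if (!is.null(a$elesy) && any(!is.na(a$elesy) & nzchar(trimws(a$elesy))))
    trimws(a$elesy) else substr(trimws(a$elety), 1, 1)
  elem[is.na(elem)] <- ""
  a <- a[toupper(elem) != "H", ]
  structure(list(atoms = data.frame(chain = a$chain, resno = a$resno,
                                    resid = trimws(a$resid),
                                    elety = trimws(a$elety),
                                    x = a$x, y = a$y, z = a$z)),
            class = "structure_model")
}

dna_resids <- c("DA", "DT", "DG", "DC")
dna_resids_legacy <- c("A", "T", "G", "C")
phosphate_oxygens <- c("OP1", "OP2", "O5'", "O3'", "O1P", "O2P")

dna_chain_ids <- function(atoms) {
  is_dna <- atoms$resid %in% dna_resids
  if (!any(is_dna)) is_dna <- atoms$resid %in% dna_resids_legacy
  unique(atoms$chain[is_dna])
}

#' Distances from a lysine's nitrogens to the DNA phosphate backbone
#'
#' For each histone H3 copy, computes the Euclidean distances from the
#' target lysine's main-chain amide nitrogen (`N`) and side-chain
#' terminal nitrogen (`NZ`) to every DNA backbone phosphate oxygen
#' (OP1/OP2/O5'/O3'; legacy O1P/O2P accepted) within `cutoff`.
#'
#' @param structure A [load_structure()] result.
#' @param h3_chains Chain ids of the H3 copies; by default, all
#'   non-DNA chains carrying a lysine at `residue_number` (pass
#'   explicitly for structures where that heuristic is too broad).
#' @param residue_number Residue number of the lysine (default 64).
#' @param cutoff Maximum reported distance, Angstrom (default 10).
#' @return A `data.frame` of class `contact_table`: (h3_chain,
#'   source_atom in `c("N", "NZ")`, dna_chain, dna_resno, dna_atom,
#'   distance). Chains with a truncated side chain (no NZ) contribute
#'   main-chain rows only, with a warning.
#' @export
k64_dna_contacts <- function(structure, h3_chains = NULL,
                             residue_number = 64, cutoff = 10) {
  stopifnot(inherits(structure, "structure_model"))
  atoms <- structure$atoms
  dna_ch <- dna_chain_ids(atoms)
  if (length(dna_ch) == 0) stop("k64_dna_contacts: no DNA chains found")
  if (is.null(h3_chains)) {
    cand <- setdiff(unique(atoms$chain), dna_ch)
    h3_chains <- cand[vapply(cand, function(ch)
      any(atoms$chain == ch & atoms$resno == residue_number &
            atoms$resid == "LYS"), TRUE)]
    if (length(h3_chains) == 0)
      stop("k64_dna_contacts: no chain has LYS at residue ", residue_number)
  } else {
    for (ch in h3_chains)
      if (!any(atoms$chain == ch & atoms$resno == residue_number &
               atoms$resid == "LYS"))
        stop("k64_dna_contacts: chain ", ch, " lacks LYS at residue ",
             residue_number)
  }
  targets <- atoms[atoms$chain %in% dna_ch &
                     atoms$elety %in% phosphate_oxygens, ]
  if (nrow(targets) == 0) stop("k64_dna_contacts: no phosphate oxygens")
  tm <- as.matrix(targets[, c("x", "y", "z")])

  rows <- list()
  for (ch in h3_chains) {
    res <- atoms[atoms$chain == ch & atoms$resno == residue_number, ]
    for (src in c("N", "NZ")) {
      s <- res[res$elety == src, ]
      if (nrow(s) == 0) {
        if (src == "NZ")
          warning("k64_dna_contacts: chain ", ch,
                  " has a truncated side chain (no NZ); rows omitted")
        next
      }
      d <- sqrt(colSums((t(tm) - as.numeric(s[1, c("x", "y", "z")]))^2))
      keep <- d <= cutoff
      if (any(keep))
        rows[[length(rows) + 1L]] <- data.frame(
          h3_chain = ch, source_atom = src,
          dna_chain = targets$chain[keep],
          dna_resno = targets$resno[keep],
          dna_atom = targets$elety[keep],
          distance = d[keep])
    }
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(h3_chain = character(0), source_atom = character(0),
               dna_chain = character(0), dna_resno = integer(0),
               dna_atom = character(0), distance = numeric(0))
  rownames(out) <- NULL
  class(out) <- c("contact_table", "data.frame")
  out
}

#' Average side-chain nitrogen-to-DNA distance over H3 copies
#'
#' For each H3 copy in a contact table, takes the minimum side-chain
#' NZ-to-phosphate-oxygen distance, then averages over copies. This
#' operationalises the "average side-chain nitrogen-to-DNA distance" of
#' a lateral-surface lysine in a nucleosome with two H3 copies.
#'
#' @param table A `contact_table` from [k64_dna_contacts()] containing
#'   NZ rows for at least one chain.
#' @return Mean of the per-copy minimum NZ distances, Angstrom.
#' @export
average_sidechain_distance <- function(table) {
  nz <- table[table$source_atom == "NZ", ]
  if (nrow(nz) == 0) stop("average_sidechain_distance: no NZ rows")
  mean(tapply(nz$distance, nz$h3_chain, min))
}

#' Write a synthetic nucleosome-like PDB fixture
#'
#' Generates a small **synthetic** structure (this is not a deposited
#' crystal structure) emulating the K64 neighbourhood of a nucleosome:
#' two H3-like protein chains (A, E), each with a full lysine 64, facing
#' short DNA backbone fragments (chains I, J). The geometry is built so
#' that each copy's main-chain amide nitrogen sits at hydrogen-bond
#' distance (`n_distances`, default 2.9 Angstrom) from a phosphate
#' oxygen and the nearest side-chain NZ-to-phosphate-oxygen distances
#' are `nz_min_distances` (default 5.8 and 6.4 Angstrom, so their mean
#' is 6.1). Useful for testing contact-geometry code without
#' downloading coordinates.
#'
#' @param path Output PDB path.
#' @param nz_min_distances Per-copy nearest NZ-to-oxygen distances,
#'   Angstrom (length 2).
#' @param n_distances Per-copy main-chain N-to-oxygen distances,
#'   Angstrom (length 2).
#' @return `path`, invisibly.
#' @export
write_synthetic_nucleosome_pdb <- function(path,
                                           nz_min_distances = c(5.8, 6.4),
                                           n_distances = c(2.9, 2.9)) {
  stopifnot(length(nz_min_distances) == 2, length(n_distances) == 2)
  fmt <- function(serial, name, resid, chain, resno, x, y, z) {
    sprintf("ATOM  %5d %-4s %3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
            serial, ifelse(nchar(name) < 4, paste0(" ", name), name),
            resid, chain, resno, x, y, z)
  }
  lines <- character(0); serial <- 0L
  add <- function(name, resid, chain, resno, x, y, z) {
    serial <<- serial + 1L
    lines[length(lines) + 1L] <<- fmt(serial, name, resid, chain, resno,
                                      x, y, z)
  }
  copies <- list(list(chain = "A", dna = "I", origin = c(0, 0, 0)),
                 list(chain = "E", dna = "J", origin = c(100, 0, 0)))
  for (i in 1:2) {
    cp <- copies[[i]]; o <- cp$origin
    ## lysine 64: extended side chain along +x, backbone near origin
    add("N",  "LYS", cp$chain, 64, o[1] + 0.0, o[2] + 0.0, o[3])
    add("CA", "LYS", cp$chain, 64, o[1] + 1.5, o[2] + 0.0, o[3])
    add("C",  "LYS", cp$chain, 64, o[1] + 2.0, o[2] - 1.4, o[3])
    add("O",  "LYS", cp$chain, 64, o[1] + 1.3, o[2] - 2.4, o[3])
    add("CB", "LYS", cp$chain, 64, o[1] + 2.4, o[2] + 1.2, o[3])
    add("CG", "LYS", cp$chain, 64, o[1] + 3.9, o[2] + 1.2, o[3])
    add("CD", "LYS", cp$chain, 64, o[1] + 4.6, o[2] + 2.5, o[3])
    add("CE", "LYS", cp$chain, 64, o[1] + 6.1, o[2] + 2.5, o[3])
    nz <- c(o[1] + 6.8, o[2] + 3.8, o[3])
    add("NZ", "LYS", cp$chain, 64, nz[1], nz[2], nz[3])
    ## DNA fragment: phosphate group with OP1 placed at the target
    ## distances from N (nucleotide 1) and NZ (nucleotide 2)
    dn <- n_distances[i]; dz <- nz_min_distances[i]
    add("P",   "DG", cp$dna, 1, o[1] - dn - 1.5, o[2], o[3])
    add("OP1", "DG", cp$dna, 1, o[1] - dn, o[2], o[3])
    add("OP2", "DG", cp$dna, 1, o[1] - dn - 2.2, o[2] + 1.3, o[3])
    add("O5'", "DG", cp$dna, 1, o[1] - dn - 2.0, o[2] - 1.3, o[3])
    add("O3'", "DG", cp$dna, 1, o[1] - dn - 3.0, o[2] - 2.3, o[3])
    add("P",   "DC", cp$dna, 2, nz[1] + dz + 1.5, nz[2], nz[3])
    add("OP1", "DC", cp$dna, 2, nz[1] + dz, nz[2], nz[3])
    add("OP2", "DC", cp$dna, 2, nz[1] + dz + 2.2, nz[2] + 1.3, nz[3])
    add("O5'", "DC", cp$dna, 2, nz[1] + dz + 2.0, nz[2] - 1.3, nz[3])
    add("O3'", "DC", cp$dna, 2, nz[1] + dz + 3.0, nz[2] - 2.3, nz[3])
  }
  writeLines(c(lines, "END"), path)
  invisible(path)
}
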