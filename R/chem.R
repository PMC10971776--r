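# Peptide-to-molecule construction.
#
# A molecule is a list with class "mg_mol":
#   atoms: data.frame(element, formal_charge, chirality, aromatic,
#                     hybridization, radical_electrons, in_ring, component)
#   bonds: data.frame(a1, a2, order, aromatic, stereo, in_ring, conjugated)
# Atom indices are 1-based; every hydrogen is an explicit atom.

.mg_cache <- new.env(parent = emptyenv())

.validate_sequence <- function(sequence) {
  if (!is.character(sequence) || length(sequence) != 1L || is.na(sequence) ||
      nchar(sequence) == 0L) {
    stop("invalid sequence: must be a non-empty amino-acid string")
  }
  letters1 <- strsplit(sequence, "", fixed = TRUE)[[1]]
  bad <- which(!letters1 %in% .AA_CODES)
  if (length(bad) > 0L) {
    stop(sprintf("invalid sequence: non-canonical residue '%s' at position %d",
                 letters1[bad[1]], bad[1]))
  }
  letters1
}

# hybridization assignment; deterministic from the template annotations:
# H atoms "S"; aromatic atoms SP2; any triple bond SP; any double bond SP2;
# nitrogens attached to a carbon bearing a double bond to O or N (amide /
# guanidine) SP2; everything else SP3
.assign_hybridization <- function(element, aromatic, a1, a2, order) {
  n <- length(element)
  hyb <- rep("SP3", n)
  maxord <- rep(0L, n)
  for (k in seq_along(a1)) {
    maxord[a1[k]] <- max(maxord[a1[k]], order[k])
    maxord[a2[k]] <- max(maxord[a2[k]], order[k])
  }
  hyb[maxord >= 2L] <- "SP2"
  hyb[maxord >= 3L] <- "SP"
  hyb[aromatic] <- "SP2"
  # carbons with a double bond to O or N
  pi_c <- rep(FALSE, n)
  dbl <- which(order == 2L)
  for (k in dbl) {
    i <- a1[k]; j <- a2[k]
    if (element[i] == "C" && element[j] %in% c("O", "N")) pi_c[i] <- TRUE
    if (element[j] == "C" && element[i] %in% c("O", "N")) pi_c[j] <- TRUE
  }
  for (k in seq_along(a1)) {
    i <- a1[k]; j <- a2[k]
    if (element[i] == "N" && pi_c[j]) hyb[i] <- "SP2"
    if (element[j] == "N" && pi_c[i]) hyb[j] <- "SP2"
  }
  hyb[element == "H"] <- "S"
  hyb
}

.finalize_molecule <- function(element, chirality, aromatic_a,
                               a1, a2, order, aromatic_b) {
  # valence completion: add explicit hydrogens
  n_heavy <- length(element)
  deg_order <- rep(0L, n_heavy)
  for (k in seq_along(a1)) {
    deg_order[a1[k]] <- deg_order[a1[k]] + order[k]
    deg_order[a2[k]] <- deg_order[a2[k]] + order[k]
  }
  n_h <- .STD_VALENCE[element] - deg_order
  if (any(n_h < 0L)) stop("internal error: negative implicit hydrogen count")
  h_parent <- rep(seq_len(n_heavy), n_h)
  n_all <- n_heavy + length(h_parent)
  element <- c(element, rep("H", length(h_parent)))
  chirality <- c(chirality, rep("none", length(h_parent)))
  aromatic_a <- c(aromatic_a, rep(FALSE, length(h_parent)))
  a1 <- c(a1, h_parent)
  a2 <- c(a2, n_heavy + seq_along(h_parent))
  order <- c(order, rep(1L, length(h_parent)))
  aromatic_b <- c(aromatic_b, rep(FALSE, length(h_parent)))

  hyb <- .assign_hybridization(element, aromatic_a, a1, a2, order)

  g <- igraph::make_graph(rbind(a1, a2), n = n_all, directed = FALSE)
  comp <- igraph::components(g)$membership
  br <- igraph::bridges(g)
  in_ring_b <- rep(TRUE, length(a1))
  in_ring_b[as.integer(br)] <- FALSE
  in_ring_a <- rep(FALSE, n_all)
  in_ring_a[unique(c(a1[in_ring_b], a2[in_ring_b]))] <- TRUE

  # conjugation: both endpoints pi-capable (SP2 or SP), neither a hydrogen
  conj <- hyb[a1] %in% c("SP2", "SP") & hyb[a2] %in% c("SP2", "SP")

  structure(list(
    atoms = data.frame(
      element = element,
      formal_charge = 0L,
      chirality = chirality,
      aromatic = aromatic_a,
      hybridization = hyb,
      radical_electrons = 0L,
      in_ring = in_ring_a,
      component = as.integer(comp),
      stringsAsFactors = FALSE
    ),
    bonds = data.frame(
      a1 = a1, a2 = a2, order = order, aromatic = aromatic_b,
      stereo = "none", in_ring = in_ring_b, conjugated = conj,
      stringsAsFactors = FALSE
    )
  ), class = "mg_mol")
}

#' Build an explicit-hydrogen peptide molecule from a sequence
#'
#' Residues are instantiated from curated templates and joined by amide
#' bonds, eliminating one water per junction; termini are left neutral
#' (free -NH2 and -COOH) and every hydrogen is an explicit atom.
#'
#' @param sequence Amino-acid string over the 20 canonical one-letter codes.
#' @return An object of class `mg_mol` (a connected molecule).
#' @examples
#' m <- build_peptide("G")
#' molecular_formula(m)  # C2 H5 N1 O2
#' @export
build_peptide <- function(sequence) {
  key <- paste0("seq:", sequence)
  hit <- .mg_cache[[key]]
  if (!is.null(hit)) return(hit)
  letters1 <- .validate_sequence(sequence)
  n_res <- length(letters1)
  element <- character(0); chirality <- character(0); aromatic_a <- logical(0)
  a1 <- integer(0); a2 <- integer(0); order <- integer(0); aromatic_b <- logical(0)
  prev_c <- NA_integer_
  for (i in seq_len(n_res)) {
    tpl <- residue_template(letters1[i])
    keep <- seq_along(tpl$element)
    drop_oxt <- i < n_res
    if (drop_oxt) keep <- keep[keep != tpl$oxt]
    remap <- rep(NA_integer_, length(tpl$element))
    remap[keep] <- length(element) + seq_along(keep)
    element <- c(element, tpl$element[keep])
    chirality <- c(chirality, tpl$chirality[keep])
    aromatic_a <- c(aromatic_a, tpl$aromatic[keep])
    kb <- !(drop_oxt & (tpl$bond_a1 == tpl$oxt | tpl$bond_a2 == tpl$oxt))
    a1 <- c(a1, remap[tpl$bond_a1[kb]])
    a2 <- c(a2, remap[tpl$bond_a2[kb]])
    order <- c(order, tpl$bond_order[kb])
    aromatic_b <- c(aromatic_b, tpl$bond_aromatic[kb])
    if (i > 1L) {
      a1 <- c(a1, prev_c)
      a2 <- c(a2, remap[tpl$backbone_n])
      order <- c(order, 1L)
      aromatic_b <- c(aromatic_b, FALSE)
    }
    prev_c <- remap[tpl$carbonyl_c]
  }
  m <- .finalize_molecule(element, chirality, aromatic_a, a1, a2, order,
                          aromatic_b)
  .mg_cache[[key]] <- m
  m
}

#' Join two molecules as disconnected components
#'
#' The disjoint union of the two inputs, with no bond added between them
#' (the molecular-graph analogue of joining SMILES strings with `.`).
#' Atom order is `a`'s atoms followed by `b`'s atoms.
#'
#' @param a,b Molecules of class `mg_mol`, each with at least one atom.
#' @return An `mg_mol` whose component count is the sum of the inputs'.
#' @export
combine <- function(a, b) {
  if (!inherits(a, "mg_mol") || !inherits(b, "mg_mol") ||
      nrow(a$atoms) == 0L || nrow(b$atoms) == 0L) {
    stop("combine() requires two non-empty molecules")
  }
  off <- nrow(a$atoms)
  atoms <- rbind(a$atoms, b$atoms)
  atoms$component <- c(a$atoms$component,
                       b$atoms$component + max(a$atoms$component))
  bonds_b <- b$bonds
  bonds_b$a1 <- bonds_b$a1 + off
  bonds_b$a2 <- bonds_b$a2 + off
  structure(list(atoms = atoms, bonds = rbind(a$bonds, bonds_b)),
            class = "mg_mol")
}

#' Molecular formula of a molecule
#'
#' @param m An `mg_mol`.
#' @return Named integer vector of per-element atom counts, in element
#'   order C, H, N, O, S (absent elements omitted).
#' @export
molecular_formula <- function(m) {
  stopifnot(inherits(m, "mg_mol"))
  tab <- table(m$atoms$element)
  ord <- intersect(c("C", "H", "N", "O", "S"), names(tab))
  out <- as.integer(tab[ord])
  names(out) <- ord
  out
}

#' Number of connected components of a molecule
#' @param m An `mg_mol`.
#' @return Integer count.
#' @export
n_components <- function(m) max(m$atoms$component)

# V2000 molblock serialization (coordinates are zero; only topology and
# bond orders matter downstream)
.to_molblock <- function(m) {
  na <- nrow(m$atoms); nb <- nrow(m$bonds)
  header <- c("", "  mhcgraph", "",
              sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", na, nb))
  atoms <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
                   m$atoms$element)
  ord <- ifelse(m$bonds$aromatic, 4L, m$bonds$order)
  bonds <- sprintf("%3d%3d%3d  0  0  0  0", m$bonds$a1, m$bonds$a2, ord)
  paste(c(header, atoms, bonds, "M  END", ""), collapse = "\n")
}

#' Emit a SMILES string for a molecule
#'
#' Serialization is delegated to OpenBabel (via ChemmineOB) from a V2000
#' molblock of the explicit-hydrogen structure; disconnected components are
#' separated by `.`. Only chemical equivalence (formula and bond multiset
#' under re-parsing) is guaranteed, not a particular canonical form.
#'
#' @param m An `mg_mol`.
#' @return A single SMILES string.
#' @export
to_smiles <- function(m) {
  stopifnot(inherits(m, "mg_mol"))
  out <- ChemmineOB::convertFormat("MOL", "SMI", .to_molblock(m))
  smi <- strsplit(out, "[\t\n ]")[[1]][1]
  if (is.na(smi) || !nzchar(smi)) stop("SMILES conversion failed")
  smi
}

#' Parse a SMILES string to a molecular formula (round-trip support)
#'
#' Uses OpenBabel to parse; implicit hydrogens are counted.
#'
#' @param smiles A SMILES string.
#' @return Named integer vector of element counts, as [molecular_formula()].
#' @export
smiles_formula <- function(smiles) {
  sdf <- ChemmineR::smiles2sdf(smiles)
  mf <- ChemmineR::MF(sdf, addH = TRUE)
  parts <- regmatches(mf, gregexpr("[A-Z][a-z]?[0-9]*", mf))[[1]]
  el <- sub("[0-9]+$", "", parts)
  ct <- as.integer(ifelse(grepl("[0-9]+$", parts),
                          sub("^[A-Za-z]+", "", parts), "1"))
  names(ct) <- el
  ord <- intersect(c("C", "H", "N", "O", "S"), el)
  ct[ord]
}

#' Read amino-acid sequences from a FASTA file
#'
#' @param path Path to a FASTA file (one record per chain).
#' @return Named character vector of sequences.
#' @export
read_sequences <- function(path) {
  if (!requireNamespace("Biostrings", quietly = TRUE)) {
    stop("Biostrings is required to read FASTA input")
  }
  ss <- Biostrings::readAAStringSet(path)
  seqs <- as.character(ss)
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}
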