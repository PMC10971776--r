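# Curated heavy-atom templates for the 20 canonical amino acids.
#
# Each template lists the heavy atoms of the FREE amino acid (backbone
# N, CA, C, O plus the carboxyl hydroxyl oxygen OXT, then the side chain)
# and its bonds with Kekule orders (1/2/3) and aromatic flags. Hydrogens
# are not stored: they are added at build time by valence completion
# (H:1, C:4, N:3, O:2, S:2; all atoms neutral, no radicals), which keeps
# the templates short and makes formula conservation checkable.
#
# Stereo convention: the alpha carbon of every residue except glycine is
# tagged "CCW" (L-configuration); threonine's CB is tagged "CW" and
# isoleucine's CB "CCW" for their second stereocentre. Bond stereo is
# always "none" (no cis/trans perception is attempted).

.STD_VALENCE <- c(H = 1L, C = 4L, N = 3L, O = 2L, S = 2L)

.AA_CODES <- c("A", "R", "N", "D", "C", "E", "Q", "G", "H", "I",
               "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# bond spec strings: "X-Y" single, "X=Y" double, "X:Y" aromatic (Kekule
# order given separately below for aromatic rings)
.aa_template_spec <- function() {
  bb_atoms <- c(N = "N", CA = "C", C = "C", O = "O", OXT = "O")
  bb_bonds <- list(c("N", "CA", 1, FALSE), c("CA", "C", 1, FALSE),
                   c("C", "O", 2, FALSE), c("C", "OXT", 1, FALSE))
  sc <- list(
    A = list(atoms = c(CB = "C"), bonds = list(c("CA", "CB", 1, FALSE))),
    R = list(atoms = c(CB = "C", CG = "C", CD = "C", NE = "N", CZ = "C",
                       NH1 = "N", NH2 = "N"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD", 1, FALSE), c("CD", "NE", 1, FALSE),
                          c("NE", "CZ", 1, FALSE), c("CZ", "NH1", 2, FALSE),
                          c("CZ", "NH2", 1, FALSE))),
    N = list(atoms = c(CB = "C", CG = "C", OD1 = "O", ND2 = "N"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "OD1", 2, FALSE), c("CG", "ND2", 1, FALSE))),
    D = list(atoms = c(CB = "C", CG = "C", OD1 = "O", OD2 = "O"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "OD1", 2, FALSE), c("CG", "OD2", 1, FALSE))),
    C = list(atoms = c(CB = "C", SG = "S"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "SG", 1, FALSE))),
    E = list(atoms = c(CB = "C", CG = "C", CD = "C", OE1 = "O", OE2 = "O"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD", 1, FALSE), c("CD", "OE1", 2, FALSE),
                          c("CD", "OE2", 1, FALSE))),
    Q = list(atoms = c(CB = "C", CG = "C", CD = "C", OE1 = "O", NE2 = "N"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD", 1, FALSE), c("CD", "OE1", 2, FALSE),
                          c("CD", "NE2", 1, FALSE))),
    G = list(atoms = character(0), bonds = list()),
    # imidazole, NE2-H tautomer: CG=CD2 and ND1=CE1
    H = list(atoms = c(CB = "C", CG = "C", ND1 = "N", CE1 = "C",
                       NE2 = "N", CD2 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "ND1", 1, TRUE), c("ND1", "CE1", 2, TRUE),
                          c("CE1", "NE2", 1, TRUE), c("NE2", "CD2", 1, TRUE),
                          c("CD2", "CG", 2, TRUE))),
    I = list(atoms = c(CB = "C", CG1 = "C", CG2 = "C", CD1 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG1", 1, FALSE),
                          c("CB", "CG2", 1, FALSE), c("CG1", "CD1", 1, FALSE))),
    L = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD1", 1, FALSE), c("CG", "CD2", 1, FALSE))),
    K = list(atoms = c(CB = "C", CG = "C", CD = "C", CE = "C", NZ = "N"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD", 1, FALSE), c("CD", "CE", 1, FALSE),
                          c("CE", "NZ", 1, FALSE))),
    M = list(atoms = c(CB = "C", CG = "C", SD = "S", CE = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "SD", 1, FALSE), c("SD", "CE", 1, FALSE))),
    F = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C",
                       CE1 = "C", CE2 = "C", CZ = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD1", 2, TRUE), c("CD1", "CE1", 1, TRUE),
                          c("CE1", "CZ", 2, TRUE), c("CZ", "CE2", 1, TRUE),
                          c("CE2", "CD2", 2, TRUE), c("CD2", "CG", 1, TRUE))),
    P = list(atoms = c(CB = "C", CG = "C", CD = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD", 1, FALSE), c("CD", "N", 1, FALSE))),
    S = list(atoms = c(CB = "C", OG = "O"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "OG", 1, FALSE))),
    T = list(atoms = c(CB = "C", OG1 = "O", CG2 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "OG1", 1, FALSE),
                          c("CB", "CG2", 1, FALSE))),
    W = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C", NE1 = "N",
                       CE2 = "C", CE3 = "C", CZ2 = "C", CZ3 = "C", CH2 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD1", 2, TRUE), c("CD1", "NE1", 1, TRUE),
                          c("NE1", "CE2", 1, TRUE), c("CE2", "CD2", 2, TRUE),
                          c("CD2", "CG", 1, TRUE), c("CE2", "CZ2", 1, TRUE),
                          c("CZ2", "CH2", 2, TRUE), c("CH2", "CZ3", 1, TRUE),
                          c("CZ3", "CE3", 2, TRUE), c("CE3", "CD2", 1, TRUE))),
    Y = list(atoms = c(CB = "C", CG = "C", CD1 = "C", CD2 = "C",
                       CE1 = "C", CE2 = "C", CZ = "C", OH = "O"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG", 1, FALSE),
                          c("CG", "CD1", 2, TRUE), c("CD1", "CE1", 1, TRUE),
                          c("CE1", "CZ", 2, TRUE), c("CZ", "CE2", 1, TRUE),
                          c("CE2", "CD2", 2, TRUE), c("CD2", "CG", 1, TRUE),
                          c("CZ", "OH", 1, FALSE))),
    V = list(atoms = c(CB = "C", CG1 = "C", CG2 = "C"),
             bonds = list(c("CA", "CB", 1, FALSE), c("CB", "CG1", 1, FALSE),
                          c("CB", "CG2", 1, FALSE)))
  )
  out <- list()
  for (code in .AA_CODES) {
    s <- sc[[code]]
    atoms <- c(bb_atoms, s$atoms)
    bonds <- c(bb_bonds, s$bonds)
    chir <- rep("none", length(atoms))
    names(chir) <- names(atoms)
    if (code != "G") chir["CA"] <- "CCW"
    if (code == "T") chir["CB"] <- "CW"
    if (code == "I") chir["CB"] <- "CCW"
    nm <- names(atoms)
    b1 <- match(vapply(bonds, `[[`, "", 1L), nm)
    b2 <- match(vapply(bonds, `[[`, "", 2L), nm)
    ord <- as.integer(vapply(bonds, `[[`, "", 3L))
    arom_b <- as.logical(vapply(bonds, `[[`, "", 4L))
    arom_a <- rep(FALSE, length(atoms))
    arom_a[unique(c(b1[arom_b], b2[arom_b]))] <- TRUE
    out[[code]] <- list(
      code = code,
      atom_name = nm,
      element = unname(atoms),
      chirality = unname(chir),
      aromatic = arom_a,
      bond_a1 = b1, bond_a2 = b2,
      bond_order = ord, bond_aromatic = arom_b,
      backbone_n = match("N", nm),
      carbonyl_c = match("C", nm),
      oxt = match("OXT", nm)
    )
  }
  out
}

.template_env <- new.env(parent = emptyenv())

#' Residue template lookup
#'
#' Returns the curated template for a one-letter amino-acid code: heavy
#' atoms (element, chirality tag, aromatic flag) and bonds (Kekule order,
#' aromatic flag) of the free amino acid, plus backbone attachment indices.
#'
#' @param code One-letter code, one of the 20 canonical amino acids.
#' @return A list describing the template (see source for fields).
#' @export
residue_template <- function(code) {
  if (is.null(.template_env$tpl)) .template_env$tpl <- .aa_template_spec()
  if (!code %in% .AA_CODES) stop("unknown residue code: ", code)
  .template_env$tpl[[code]]
}

#' Molecular formulas of the free amino acids derived from templates
#'
#' @return Named list mapping one-letter code to a named integer vector of
#'   element counts (including hydrogens by valence completion).
#' @export
residue_formulas <- function() {
  out <- lapply(.AA_CODES, function(code) {
    m <- build_peptide(code)
    molecular_formula(m)
  })
  names(out) <- .AA_CODES
  out
}
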