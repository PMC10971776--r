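# Graph featurization: one-hot node (31) and edge (12) feature encoding.
#
# Node slot layout (fixed order, total 31):
#   element one-hot {H,C,N,O,S}                 5
#   hybridization one-hot {SP3,SP2,SP,S,SP3D,SP3D2}  6
#   degree one-hot 0..5 (all neighbours, H included) 6
#   bonded-hydrogen count one-hot 0..4          5
#   chirality one-hot {CCW,CW,other}            3
#   aromatic flag                               1
#   ring flag                                   1
#   formal charge one-hot {-1,0,+1}             3
#   radical electron count (numeric)            1
# Edge slot layout (total 12):
#   bond type one-hot {single,aromatic,double,triple} 4
#   stereo one-hot {any,cis,E,none,trans,Z}     6
#   ring flag                                   1
#   conjugated flag                             1

.ELEMENTS <- c("H", "C", "N", "O", "S")
.HYBRIDIZATIONS <- c("SP3", "SP2", "SP", "S", "SP3D", "SP3D2")
.CHIRALITIES <- c("CCW", "CW", "other")
.BOND_TYPES <- c("single", "aromatic", "double", "triple")
.STEREO_TYPES <- c("any", "cis", "E", "none", "trans", "Z")

#' Node feature width
#' @export
NODE_FEATURE_DIM <- 31L

#' Edge feature width
#' @export
EDGE_FEATURE_DIM <- 12L

.one_hot <- function(idx, width, n) {
  m <- matrix(0, n, width)
  ok <- !is.na(idx) & idx >= 1L & idx <= width
  if (any(!ok)) stop("encoding error: value outside one-hot range")
  m[cbind(seq_len(n), idx)] <- 1
  m
}

#' Node feature matrix of a molecule
#'
#' One row per atom, 31 columns in the fixed slot order documented in the
#' package source. Degree counts all bonded neighbours including explicit
#' hydrogens; the hydrogen count is the number of H neighbours.
#'
#' @param m An `mg_mol`.
#' @return Numeric matrix `n_atoms x 31`.
#' @export
node_features <- function(m) {
  stopifnot(inherits(m, "mg_mol"))
  n <- nrow(m$atoms)
  deg <- rep(0L, n); hcount <- rep(0L, n)
  a1 <- m$bonds$a1; a2 <- m$bonds$a2
  for (k in seq_along(a1)) {
    deg[a1[k]] <- deg[a1[k]] + 1L
    deg[a2[k]] <- deg[a2[k]] + 1L
    if (m$atoms$element[a2[k]] == "H") hcount[a1[k]] <- hcount[a1[k]] + 1L
    if (m$atoms$element[a1[k]] == "H") hcount[a2[k]] <- hcount[a2[k]] + 1L
  }
  chir <- match(m$atoms$chirality, .CHIRALITIES)
  chir[is.na(chir)] <- 3L  # "other"
  cbind(
    .one_hot(match(m$atoms$element, .ELEMENTS), 5L, n),
    .one_hot(match(m$atoms$hybridization, .HYBRIDIZATIONS), 6L, n),
    .one_hot(deg + 1L, 6L, n),
    .one_hot(hcount + 1L, 5L, n),
    .one_hot(chir, 3L, n),
    as.numeric(m$atoms$aromatic),
    as.numeric(m$atoms$in_ring),
    .one_hot(m$atoms$formal_charge + 2L, 3L, n),
    as.numeric(m$atoms$radical_electrons)
  )
}

#' Node feature vector for one atom
#' @param m An `mg_mol`.
#' @param atom_index 1-based atom index.
#' @return Numeric vector of length 31.
#' @export
node_feature_vector <- function(m, atom_index) {
  stopifnot(atom_index >= 1L, atom_index <= nrow(m$atoms))
  node_features(m)[atom_index, ]
}

.edge_features_undirected <- function(m) {
  nb <- nrow(m$bonds)
  type <- ifelse(m$bonds$aromatic, "aromatic",
                 c("single", "double", "triple")[m$bonds$order])
  cbind(
    .one_hot(match(type, .BOND_TYPES), 4L, nb),
    .one_hot(match(m$bonds$stereo, .STEREO_TYPES), 6L, nb),
    as.numeric(m$bonds$in_ring),
    as.numeric(m$bonds$conjugated)
  )
}

#' Edge feature vector for one bond
#' @param m An `mg_mol`.
#' @param bond_index 1-based row index into `m$bonds`.
#' @return Numeric vector of length 12.
#' @export
edge_feature_vector <- function(m, bond_index) {
  stopifnot(bond_index >= 1L, bond_index <= nrow(m$bonds))
  .edge_features_undirected(m)[bond_index, ]
}

#' Ring membership of atoms and bonds
#'
#' A bond is in a ring iff it is not a bridge of the molecular graph; an
#' atom is in a ring iff it is incident to at least one non-bridge bond.
#'
#' @param m An `mg_mol`.
#' @return List with logical vectors `atoms` and `bonds`.
#' @export
ring_membership <- function(m) {
  list(atoms = m$atoms$in_ring, bonds = m$bonds$in_ring)
}

#' Featurize a molecule as a graph sample
#'
#' Each undirected bond contributes two directed edges carrying identical
#' feature vectors.
#'
#' @param m An `mg_mol`.
#' @param label Optional binary label (1 = binding).
#' @return An object of class `mg_graph`: list with `x` (n x 31),
#'   `edge_index` (2 x m, 1-based), `edge_attr` (m x 12), `y`, `n_nodes`.
#' @export
featurize_molecule <- function(m, label = NA_real_) {
  x <- node_features(m)
  ef <- .edge_features_undirected(m)
  ei <- cbind(rbind(m$bonds$a1, m$bonds$a2), rbind(m$bonds$a2, m$bonds$a1))
  structure(list(
    x = x,
    edge_index = ei,
    edge_attr = rbind(ef, ef),
    y = label,
    n_nodes = nrow(x)
  ), class = "mg_graph")
}

#' Featurize an MHC pseudo-sequence / peptide pair
#'
#' Builds both chains, joins them as one molecule with two disconnected
#' components (MHC atoms first), and encodes the combined graph.
#'
#' @param mhc_seq MHC pseudo-sequence (canonical letters).
#' @param peptide_seq Candidate peptide sequence.
#' @param label Binary label (1 = binding), optional.
#' @return An `mg_graph` over the combined two-component molecule.
#' @export
featurize_pair <- function(mhc_seq, peptide_seq, label = NA_real_) {
  m <- combine(build_peptide(mhc_seq), build_peptide(peptide_seq))
  g <- featurize_molecule(m, label)
  g$n_components <- n_components(m)
  g
}
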