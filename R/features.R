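# Feature sets for Fa classification: MACCS keys, folded ECFP6, an
# 18-descriptor H-bond/flexibility/ring set, a wider 2D physicochemical
# set, and the 2D set extended with 3D shape descriptors from one
# embedded, forcefield-minimized conformer. Every set records its exact
# roster in the returned attributes, since descriptor availability is
# toolkit-dependent.

hbflex_smarts <- c(
  hbd            = "[#7,#8;!H0]",
  hba            = "[#7,#8]",
  hba_n          = "[#7]",
  hba_o          = "[#8]",
  nh_oh_h1       = "[#7,#8;H1]",
  nh_oh_h2       = "[#7,#8;H2]",
  nh_oh_h3       = "[#7,#8;H3]",
  rbc            = "[!$(*#*)&!D1]-!@[!$(*#*)&!D1]",
  amide_bonds    = "C(=O)[NX3]",
  heavy_atoms    = "[!#1]",
  heteroatoms    = "[!#6;!#1]",
  halogens       = "[F,Cl,Br,I]",
  sp3_carbons    = "[CX4]",
  carbons        = "[#6]",
  ring_atoms     = "[R]",
  ring_bonds     = "*@*",
  aromatic_atoms = "[a]",
  aromatic_bonds = "[a]:[a]",
  bonds          = "*~*",
  ring_heteroatoms = "[R;!#6]"
)

# 18 H-bond / flexibility / ring-character descriptors from SMARTS counts
hbflex_descriptors <- function(smiles) {
  cts <- smarts_counts(smiles, hbflex_smarts)
  tibble::tibble(
    hbd = cts$hbd,
    hba = cts$hba,
    hba_n = cts$hba_n,
    hba_o = cts$hba_o,
    nh_oh_hydrogens = cts$nh_oh_h1 + 2 * cts$nh_oh_h2 + 3 * cts$nh_oh_h3,
    rotatable_bonds = cts$rbc,
    amide_bonds = cts$amide_bonds,
    heavy_atoms = cts$heavy_atoms,
    heteroatoms = cts$heteroatoms,
    halogens = cts$halogens,
    sp3_carbons = cts$sp3_carbons,
    fraction_csp3 = ifelse(cts$carbons > 0, cts$sp3_carbons / cts$carbons, 0),
    ring_atoms = cts$ring_atoms,
    ring_bonds = cts$ring_bonds,
    # single-component structures: cyclomatic number = bonds - atoms + 1
    ring_count = pmax(cts$bonds - cts$heavy_atoms + 1, 0),
    aromatic_atoms = cts$aromatic_atoms,
    aromatic_bonds = cts$aromatic_bonds,
    ring_heteroatoms = cts$ring_heteroatoms
  )
}

group_smarts <- c(
  nitro = "[NX3](=O)=O,[NX3+](=O)[O-]",
  carboxylic_acid = "C(=O)[OX2H1]",
  ester = "C(=O)O[#6]",
  hydroxyl = "[OX2H]",
  ether = "[OD2]([#6])[#6]",
  primary_amine = "[NX3;H2;!$(NC=O)]",
  secondary_amine = "[NX3;H1;!$(NC=O)]",
  tertiary_amine = "[NX3;H0;!$(NC=O);!$(N=*)]",
  sulfonamide = "S(=O)(=O)N",
  nitrile = "C#N",
  carbonyl = "[CX3]=[OX1]",
  n_atoms_c = "[#6]",
  n_atoms_n = "[#7]",
  n_atoms_o = "[#8]",
  n_atoms_s = "[#16]",
  n_atoms_p = "[#15]",
  n_atoms_f = "[F]",
  n_atoms_cl = "[Cl]",
  n_atoms_br = "[Br]",
  n_atoms_i = "[I]"
)

# 2D physicochemical set: the 18 H-bond/flexibility descriptors plus bulk
# properties and functional-group / element counts
phys2d_descriptors <- function(smiles) {
  hb <- hbflex_descriptors(smiles)
  props <- ob_properties(smiles)
  # the nitro SMARTS has a comma alternative that Open Babel handles as two
  # patterns; query them separately
  grp <- smarts_counts(smiles, c(
    group_smarts[!names(group_smarts) %in% "nitro"],
    nitro_a = "[NX3](=O)=O", nitro_b = "[NX3+](=O)[O-]"))
  grp$nitro <- grp$nitro_a + grp$nitro_b
  grp$nitro_a <- NULL; grp$nitro_b <- NULL
  dplyr::bind_cols(
    tibble::tibble(mw = props$mw, logp = props$logp, tpsa = props$tpsa,
                   mr = props$mr),
    hb, tibble::as_tibble(grp)
  )
}

# 3D shape descriptors from one embedded conformer: gyration-tensor and
# inertia-based measures on heavy-atom coordinates (unit masses)
shape3d_names <- c("rg", "span", "max_dist", "asphericity", "acylindricity",
                   "shape_anisotropy", "pbf_rmsd", "npr1", "npr2")

shape3d_from_coords <- function(coords) {
  xyz <- as.matrix(coords[coords$element != "H", c("x", "y", "z")])
  n <- nrow(xyz)
  if (n < 3) return(stats::setNames(rep(NA_real_, 9), shape3d_names))
  xyz <- sweep(xyz, 2, colMeans(xyz))
  S <- crossprod(xyz) / n           # gyration tensor
  ev <- sort(eigen(S, symmetric = TRUE, only.values = TRUE)$values) # l1<=l2<=l3
  rg2 <- sum(ev)
  d <- sqrt(rowSums(xyz^2))
  pd <- as.matrix(stats::dist(xyz))
  asph <- ev[3] - 0.5 * (ev[1] + ev[2])
  acyl <- ev[2] - ev[1]
  kappa2 <- if (rg2 > 0) (asph^2 + 0.75 * acyl^2) / rg2^2 else 0
  # principal moments of inertia (unit masses)
  I <- diag(rep(sum(rowSums(xyz^2)), 3)) - crossprod(xyz)
  iev <- sort(eigen(I, symmetric = TRUE, only.values = TRUE)$values)
  c(rg = sqrt(rg2), span = max(d), max_dist = max(pd),
    asphericity = asph, acylindricity = acyl, shape_anisotropy = kappa2,
    pbf_rmsd = sqrt(ev[1]),
    npr1 = if (iev[3] > 0) iev[1] / iev[3] else NA_real_,
    npr2 = if (iev[3] > 0) iev[2] / iev[3] else NA_real_)
}

#' Featurize parent structures for Fa classification
#'
#' Builds the feature matrix for one of the named feature sets:
#' \describe{
#'   \item{maccs}{166 MACCS structural keys (binary).}
#'   \item{ecfp6}{Extended-connectivity fingerprint of radius 3, OR-folded
#'     to 2048 bits (binary).}
#'   \item{hbflex18}{18 hydrogen-bonding / flexibility / ring-character
#'     descriptors (real-valued).}
#'   \item{phys2d}{The 18 above plus bulk properties (molecular weight,
#'     logP, TPSA, molar refractivity) and functional-group and element
#'     counts (real-valued).}
#'   \item{phys3d}{phys2d plus nine 3D shape descriptors computed from one
#'     embedded conformer minimized with a MMFF94-family forcefield;
#'     embedding failures leave the 3D block missing-coded.}
#' }
#'
#' @param parents Character vector of single-component SMILES.
#' @param set_id One of `"maccs"`, `"ecfp6"`, `"hbflex18"`, `"phys2d"`,
#'   `"phys3d"`.
#' @return A numeric matrix (rows = molecules) with attributes `roster`
#'   (column names), `type` (`"binary"` or `"real"`), `set_id`, and
#'   `failed_3d` (logical vector, phys3d only).
#' @export
featurize <- function(parents, set_id = c("maccs", "ecfp6", "hbflex18",
                                          "phys2d", "phys3d")) {
  set_id <- match.arg(set_id)
  if (any(n_components(parents) > 1L, na.rm = TRUE)) {
    stop("featurize expects single-component parent structures",
         call. = FALSE)
  }
  if (set_id == "maccs") {
    X <- ob_fingerprints(parents, "MACCS")
    type <- "binary"
  } else if (set_id == "ecfp6") {
    X <- ob_fingerprints(parents, "ECFP6", fold_bits = 2048L)
    type <- "binary"
  } else if (set_id == "hbflex18") {
    X <- as.matrix(hbflex_descriptors(parents))
    type <- "real"
  } else if (set_id == "phys2d") {
    X <- as.matrix(phys2d_descriptors(parents))
    type <- "real"
  } else {
    X2 <- as.matrix(phys2d_descriptors(parents))
    coords <- ob_conformer_coords(parents)
    X3 <- t(vapply(coords, function(cc) {
      if (is.null(cc)) stats::setNames(rep(NA_real_, 9), shape3d_names)
      else shape3d_from_coords(cc)
    }, numeric(9)))
    colnames(X3) <- shape3d_names
    X <- cbind(X2, X3)
    type <- "real"
    attr(X, "failed_3d") <- vapply(coords, is.null, logical(1))
  }
  storage.mode(X) <- "double"
  attr(X, "roster") <- colnames(X)
  attr(X, "type") <- type
  attr(X, "set_id") <- set_id
  X
}
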