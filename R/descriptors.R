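#' The eight-descriptor chemical-space panel
#'
#' Fixed column order of the descriptor panel used for profiling, PCA and
#' all tables the package writes: AlogP, molecular weight, rotatable
#' bonds, rings, aromatic rings, hydrogen-bond acceptors, donors, and
#' fractional polar surface area.
#'
#' @format character vector of eight column names.
#' @export
DESCRIPTOR_COLS <- c("alogp", "mw", "n_rotatable", "n_rings",
                     "n_aromatic_rings", "hba", "hbd", "fpsa")

# rough exposed surface area (A^2) attributed to one apolar heavy atom,
# used only to turn TPSA into a fractional polar surface area
APOLAR_ATOM_AREA <- 21

# descriptor counts for one explicit-H molecular graph
graph_counts <- function(g) {
  el <- g$atoms$element
  heavy <- el != "H"
  hv_idx <- g$atoms$idx[heavy]
  b <- g$bonds
  is_h <- function(i) el[match(i, g$atoms$idx)] == "H"
  el_of <- function(i) el[match(i, g$atoms$idx)]

  # Lipinski counts: HBA = N + O atoms; HBD = hydrogens on N or O
  hba <- sum(el %in% c("N", "O"))
  hbd <- 0L
  if (nrow(b)) {
    on_no <- (is_h(b$a1) & el_of(b$a2) %in% c("N", "O")) |
             (is_h(b$a2) & el_of(b$a1) %in% c("N", "O"))
    hbd <- sum(on_no)
  }

  bh <- b[!is_h(b$a1) & !is_h(b$a2), , drop = FALSE]
  gh <- igraph::graph_from_data_frame(
    data.frame(from = as.character(bh$a1), to = as.character(bh$a2)),
    directed = FALSE,
    vertices = data.frame(name = as.character(hv_idx)))
  n_comp <- igraph::components(gh)$no
  # smallest-set-of-smallest-rings size == cyclomatic number per component
  n_rings <- nrow(bh) - length(hv_idx) + n_comp

  ar <- bh[bh$type == "ar", , drop = FALSE]
  if (nrow(ar)) {
    va <- unique(c(ar$a1, ar$a2))
    ga <- igraph::graph_from_data_frame(
      data.frame(from = as.character(ar$a1), to = as.character(ar$a2)),
      directed = FALSE, vertices = data.frame(name = as.character(va)))
    n_aromatic <- nrow(ar) - length(va) + igraph::components(ga)$no
  } else n_aromatic <- 0L

  # rotatable: non-ring single bonds between non-terminal heavy atoms,
  # excluding amide C-N bonds (SYBYL "am" plus an explicit C(=O)-N check)
  hdeg <- igraph::degree(gh)
  deg_of <- function(i) hdeg[as.character(i)]
  bridge_ids <- igraph::bridges(gh)
  in_ring <- rep(TRUE, nrow(bh))
  if (nrow(bh)) {
    in_ring[] <- TRUE
    in_ring[as.integer(bridge_ids)] <- FALSE  # bridges are acyclic bonds
  }
  carbonyl_c <- unique(c(
    bh$a1[bh$type == "2" & el_of(bh$a2) == "O"],
    bh$a2[bh$type == "2" & el_of(bh$a1) == "O"]))
  carbonyl_c <- carbonyl_c[el_of(carbonyl_c) == "C"]
  n_rot <- 0L
  if (nrow(bh)) {
    amide <- (bh$type == "am") |
      (bh$a1 %in% carbonyl_c & el_of(bh$a2) == "N") |
      (bh$a2 %in% carbonyl_c & el_of(bh$a1) == "N")
    rot <- bh$type == "1" & !in_ring & !amide &
      deg_of(bh$a1) >= 2 & deg_of(bh$a2) >= 2
    n_rot <- sum(rot)
  }

  list(hba = hba, hbd = hbd, n_rings = as.integer(n_rings),
       n_aromatic_rings = as.integer(n_aromatic), n_rotatable = as.integer(n_rot),
       n_carbon = sum(el == "C"),
       n_heavy = sum(heavy),
       n_apolar = sum(heavy & !(el %in% c("N", "O", "S", "P"))))
}

# assigned tetrahedral stereocenters on carbon, read off the canonical
# isomeric SMILES ("[C@...]" atoms; aromatic carbons cannot carry them)
chiral_carbon_count <- function(can_smiles) {
  vapply(can_smiles, function(s) {
    m <- gregexpr("\\[C@", s)[[1]]
    if (m[1] == -1L) 0L else length(m)
  }, integer(1), USE.NAMES = FALSE)
}

#' Compute the molecular descriptor panel
#'
#' For each molecule: additive atom-contribution AlogP (Wildman-Crippen),
#' molecular weight (Da), rotatable-bond count (non-ring single bonds
#' between non-terminal heavy atoms, amides excluded), ring count (SSSR),
#' aromatic ring count, Lipinski hydrogen-bond acceptors (N+O) and donors
#' (NH+OH), fractional polar surface area (TPSA over a topological estimate
#' of total surface area), and chirality counts.
#'
#' @param x library data frame from [read_library()] (columns `id`,
#'   `smiles`) or a character vector of SMILES.
#' @return data frame with one row per molecule: `id`, the eight panel
#'   descriptors, `n_chiral_c`, `n_carbon` and `f_chirality`
#'   (`NA` for carbon-free molecules).
#' @examples
#' \dontrun{compute_descriptors(c(ethanol = "CCO", benzene = "c1ccccc1"))}
#' @export
compute_descriptors <- function(x) {
  if (is.character(x)) {
    ids <- if (!is.null(names(x))) names(x) else sprintf("MOL%04d", seq_along(x))
    smiles <- unname(x)
  } else {
    stopifnot(is.data.frame(x), all(c("id", "smiles") %in% names(x)))
    ids <- x$id; smiles <- x$smiles
  }
  if (!length(smiles)) stop("no molecules supplied", call. = FALSE)
  can <- canonical_smiles(smiles)
  if (any(!nzchar(can))) {
    stop("unparsable structures: ",
         paste(ids[!nzchar(can)], collapse = ", "), call. = FALSE)
  }

  sdf <- ChemmineR::smiles2sdf(stats::setNames(can, ids))
  props <- ChemmineR::propOB(sdf)

  counts <- lapply(can, function(s) graph_counts(mol_graph(s)))
  get <- function(f) vapply(counts, function(cc) as.numeric(cc[[f]]), numeric(1))
  n_heavy <- get("n_heavy")
  if (any(n_heavy == 0)) {
    stop("structure with no heavy atoms: ",
         paste(ids[n_heavy == 0], collapse = ", "), call. = FALSE)
  }

  tpsa <- props$TPSA
  total_sa <- tpsa + APOLAR_ATOM_AREA * get("n_apolar")
  fpsa <- ifelse(total_sa > 0, pmin(1, tpsa / total_sa), 0)

  n_chiral <- chiral_carbon_count(can)
  n_carbon <- get("n_carbon")
  out <- data.frame(
    id = ids,
    alogp = props$logP,
    mw = props$MW,
    n_rotatable = as.integer(get("n_rotatable")),
    n_rings = as.integer(get("n_rings")),
    n_aromatic_rings = as.integer(get("n_aromatic_rings")),
    hba = as.integer(get("hba")),
    hbd = as.integer(get("hbd")),
    fpsa = fpsa,
    n_chiral_c = as.integer(n_chiral),
    n_carbon = as.integer(n_carbon),
    f_chirality = ifelse(n_carbon > 0, n_chiral / n_carbon, NA_real_),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  out
}

#' Fraction of carbon atoms that are chiral centers
#'
#' Counts assigned tetrahedral stereocenters on carbon and divides by the
#' total carbon count. Unassigned or merely potential centers are not
#' counted, so libraries are expected to carry explicit stereochemistry.
#'
#' @param smiles character vector of SMILES.
#' @return numeric vector in `[0, 1]`; `NA` with a warning for carbon-free
#'   molecules, for which the fraction is undefined.
#' @export
f_chirality <- function(smiles) {
  can <- canonical_smiles(smiles)
  if (any(!nzchar(can))) stop("unparsable SMILES input", call. = FALSE)
  n_carbon <- vapply(can, function(s) graph_counts(mol_graph(s))$n_carbon,
                     numeric(1), USE.NAMES = FALSE)
  if (any(n_carbon == 0)) {
    warning("carbon-free molecule: F-chirality undefined, returning NA",
            call. = FALSE)
  }
  ifelse(n_carbon > 0, chiral_carbon_count(can) / n_carbon, NA_real_)
}
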