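# ---- low-level structure handling (Open Babel via ChemmineOB) ----

#' Canonicalize a SMILES string
#'
#' Converts a SMILES string to Open Babel's canonical isomeric form. The
#' canonical string retains tetrahedral stereo annotations, so two writings
#' of the same structure map to the same string while enantiomers stay
#' distinct. This is the structure key used for deduplication.
#'
#' @param smiles character vector of SMILES strings.
#' @return character vector of canonical SMILES; `""` for unparsable input.
#' @export
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(trimws(s))) return("")
    out <- tryCatch(
      ChemmineOB::convertFormat("SMI", "CAN", paste0(trimws(s), "\n")),
      error = function(e) ""
    )
    # output is "smiles\ttitle\n"; strip title and whitespace
    trimws(sub("[\t\n].*$", "", out))
  }, character(1), USE.NAMES = FALSE)
}

# Parse one SMILES into an explicit-hydrogen molecular graph via a mol2
# round trip. Atom elements come from the SYBYL atom type ("C.ar" -> "C"),
# bond types are "1", "2", "3", "ar" (aromatic) or "am" (amide).
mol_graph <- function(smiles) {
  m2 <- tryCatch(
    ChemmineOB::convertFormat("SMI", "MOL2", paste0(trimws(smiles), "\n"),
                              options = data.frame(names = "h", args = "")),
    error = function(e) ""
  )
  if (!nzchar(m2)) stop("unparsable SMILES: ", smiles, call. = FALSE)
  lines <- strsplit(m2, "\n", fixed = TRUE)[[1]]
  sect <- grep("^@<TRIPOS>", lines)
  get_section <- function(tag) {
    i <- match(paste0("@<TRIPOS>", tag), lines)
    if (is.na(i)) return(character(0))
    nxt <- sect[sect > i]
    end <- if (length(nxt)) min(nxt) - 1L else length(lines)
    if (end < i + 1L) return(character(0))
    lines[(i + 1L):end]
  }
  atom_lines <- get_section("ATOM")
  bond_lines <- get_section("BOND")
  if (!length(atom_lines)) stop("structure has no atoms: ", smiles, call. = FALSE)
  af <- strsplit(trimws(atom_lines), "[[:space:]]+")
  atoms <- data.frame(
    idx = vapply(af, function(x) as.integer(x[1]), integer(1)),
    element = vapply(af, function(x) sub("\\..*$", "", x[6]), character(1)),
    stringsAsFactors = FALSE
  )
  if (length(bond_lines)) {
    bf <- strsplit(trimws(bond_lines), "[[:space:]]+")
    bonds <- data.frame(
      a1 = vapply(bf, function(x) as.integer(x[2]), integer(1)),
      a2 = vapply(bf, function(x) as.integer(x[3]), integer(1)),
      type = vapply(bf, function(x) x[4], character(1)),
      stringsAsFactors = FALSE
    )
  } else {
    bonds <- data.frame(a1 = integer(0), a2 = integer(0), type = character(0),
                        stringsAsFactors = FALSE)
  }
  list(atoms = atoms, bonds = bonds)
}

# heavy-atom count of a (single-fragment) SMILES, from its graph
heavy_atom_count <- function(smiles) {
  g <- mol_graph(smiles)
  sum(g$atoms$element != "H")
}

# ---- library ingestion ----

#' Read a molecule library from a SMILES or SDF file
#'
#' SMILES files hold one record per line (`SMILES[ whitespace id]`); SDF
#' files are V2000 multi-record files. Every entry is canonicalized on
#' input. Unparsable entries are skipped with a warning naming the line or
#' record number.
#'
#' @param path file path.
#' @param format `"smiles"` or `"sdf"`.
#' @param source tag recorded with every molecule (defaults to the file name).
#' @return a data frame with columns `id`, `smiles` (canonical isomeric
#'   SMILES), `key` (structure key, identical to `smiles`) and `source`.
#'   The number of skipped entries is attached as attribute `n_skipped`.
#' @export
read_library <- function(path, format = c("smiles", "sdf"), source = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(source)) source <- basename(path)

  if (format == "smiles") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)) & !grepl("^\\s*#", lines))
    raw_smi <- character(0); ids <- character(0); where <- integer(0)
    for (i in keep) {
      parts <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      raw_smi <- c(raw_smi, parts[1])
      ids <- c(ids, if (length(parts) > 1) paste(parts[-1], collapse = " ")
               else sprintf("MOL%04d", i))
      where <- c(where, i)
    }
    can <- canonical_smiles(raw_smi)
    bad <- which(!nzchar(can))
    for (b in bad) {
      warning(sprintf("line %d: unparsable SMILES '%s' skipped",
                      where[b], raw_smi[b]), call. = FALSE)
    }
    ok <- nzchar(can)
    lib <- data.frame(id = ids[ok], smiles = can[ok], key = can[ok],
                      source = rep(source, sum(ok)), stringsAsFactors = FALSE)
    n_skipped <- sum(!ok)
  } else {
    sdf <- suppressWarnings(ChemmineR::read.SDFset(path))
    valid <- ChemmineR::validSDF(sdf)
    n_skipped <- sum(!valid)
    for (b in which(!valid)) {
      warning(sprintf("SDF record %d invalid, skipped", b), call. = FALSE)
    }
    sdf <- sdf[valid]
    if (length(sdf) == 0) stop("no parsable records in ", path, call. = FALSE)
    smi <- vapply(seq_along(sdf), function(i) {
      txt <- paste(ChemmineR::sdf2str(sdf[[i]]), collapse = "\n")
      out <- tryCatch(
        ChemmineOB::convertFormat("SDF", "CAN", paste0(txt, "\n")),
        error = function(e) "")
      trimws(sub("[\t\n].*$", "", out))
    }, character(1))
    ids <- ChemmineR::sdfid(sdf)
    ids[!nzchar(ids)] <- sprintf("MOL%04d", which(!nzchar(ids)))
    bad <- which(!nzchar(smi))
    for (b in bad) {
      warning(sprintf("SDF record %d: conversion failed, skipped", b),
              call. = FALSE)
    }
    ok <- nzchar(smi)
    n_skipped <- n_skipped + sum(!ok)
    lib <- data.frame(id = ids[ok], smiles = smi[ok], key = smi[ok],
                      source = rep(source, sum(ok)), stringsAsFactors = FALSE)
  }
  if (nrow(lib) == 0) stop("no parsable records in ", path, call. = FALSE)
  attr(lib, "n_skipped") <- n_skipped
  lib
}

# ---- normalization ----

#' Keep the largest fragment of each structure
#'
#' Salts and adducts are reduced to a single connected component: the
#' fragment with the most heavy atoms is retained, ties broken by larger
#' molecular weight, then by lexicographically smallest canonical SMILES.
#' Single-fragment structures pass through unchanged.
#'
#' @param lib library data frame from [read_library()], or a character
#'   vector of SMILES.
#' @return same shape as the input, with multi-fragment structures replaced
#'   by their largest fragment (keys recomputed).
#' @export
largest_fragment <- function(lib) {
  pick <- function(smi) {
    frags <- strsplit(smi, ".", fixed = TRUE)[[1]]
    if (length(frags) == 1) return(smi)
    hv <- vapply(frags, heavy_atom_count, numeric(1))
    cand <- which(hv == max(hv))
    if (length(cand) > 1) {
      sdf <- ChemmineR::smiles2sdf(stats::setNames(frags[cand],
                                                   paste0("f", seq_along(cand))))
      mw <- ChemmineR::propOB(sdf)$MW
      cand <- cand[mw == max(mw)]
    }
    if (length(cand) > 1) {
      can <- canonical_smiles(frags[cand])
      cand <- cand[order(can)][1]
    }
    canonical_smiles(frags[cand[1]])
  }
  if (is.character(lib)) return(vapply(lib, pick, character(1), USE.NAMES = FALSE))
  multi <- grepl(".", lib$smiles, fixed = TRUE)
  if (any(multi)) {
    lib$smiles[multi] <- vapply(lib$smiles[multi], pick, character(1))
    lib$key[multi] <- lib$smiles[multi]
  }
  lib
}

#' Remove duplicate structures from a library
#'
#' Two records are duplicates when their stereo-aware canonical structure
#' keys coincide; enantiomers carry distinct keys and are both kept. The
#' first record in input order is retained for each key.
#'
#' @param lib library data frame with columns `id` and `key`.
#' @return list with `library` (deduplicated data frame) and `duplicates`
#'   (data frame of `kept_id`, `removed_id` pairs; zero rows if none).
#' @export
deduplicate <- function(lib) {
  stopifnot(is.data.frame(lib), nrow(lib) >= 1, all(c("id", "key") %in% names(lib)))
  first <- !duplicated(lib$key)
  kept_for <- lib$id[first][match(lib$key, lib$key[first])]
  dup <- data.frame(kept_id = kept_for[!first], removed_id = lib$id[!first],
                    stringsAsFactors = FALSE)
  out <- lib[first, , drop = FALSE]
  rownames(out) <- NULL
  list(library = out, duplicates = dup)
}
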