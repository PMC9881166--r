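## Structure input/output: parse mmCIF/PDB (via bio3d), identify the two
## major rRNA chains, extract per-residue phosphate coordinates, and
## read/write tabular orientation results.

## modified nucleotides -> parent base (common rRNA modifications)
MODIFIED_NT <- c(
  "1MA" = "A", "2MA" = "A", "A2M" = "A", "MIA" = "A", "T6A" = "A", "6MZ" = "A",
  "MA6" = "A", "12A" = "A", "2MG" = "G", "7MG" = "G", "G7M" = "G", "M2G" = "G",
  "OMG" = "G", "YG"  = "G", "1MG" = "G", "QUO" = "G", "5MC" = "C", "OMC" = "C",
  "4OC" = "C", "CBV" = "C", "5MU" = "U", "4SU" = "U", "H2U" = "U", "PSU" = "U",
  "OMU" = "U", "UR3" = "U", "3AU" = "U", "70U" = "U", "DHU" = "U"
)

AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
         "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
         "MSE", "SEC", "PYL")

## one-letter base for a residue name, NA if not RNA-like
base_letter <- function(resid) {
  resid <- toupper(trimws(resid))
  out <- ifelse(resid %in% c("A", "C", "G", "U"), resid,
                unname(MODIFIED_NT[resid]))
  out
}

residue_key <- function(resno, insert) {
  ins <- ifelse(is.na(insert) | insert == "" | insert == "?", "", insert)
  paste0(resno, ins)
}

#' Construct a structure object from an atom table
#'
#' Low-level constructor used by the file readers and the synthetic-fixture
#' generator. The atom table requires columns \code{elety} (atom name),
#' \code{elesy} (element), \code{resid} (residue name), \code{chain},
#' \code{resno}, \code{insert}, \code{x}, \code{y}, \code{z}, \code{o}
#' (occupancy).
#'
#' @param atoms data.frame of atom records.
#' @param accession structure identifier for reporting.
#' @param resolution resolution in Angstrom, or NA.
#' @param source_format "mmCIF", "PDB" or "memory".
#' @param lsu_chain,ssu_chain optional explicit rRNA chain assignment; when
#'   NULL the chains are selected automatically (see
#'   \code{\link{select_rrna_chains}}).
#' @return an object of class \code{rad_structure}.
#' @export
rad_structure <- function(atoms, accession = "unknown", resolution = NA_real_,
                          source_format = "memory",
                          lsu_chain = NULL, ssu_chain = NULL) {
  need <- c("elety", "elesy", "resid", "chain", "resno", "insert",
            "x", "y", "z", "o")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ", paste(miss, collapse = ", "))
  if (!all(is.finite(as.matrix(atoms[, c("x", "y", "z")]))))
    stop("non-finite coordinates in atom records")
  atoms$insert[is.na(atoms$insert)] <- ""
  atoms$key <- residue_key(atoms$resno, atoms$insert)
  atoms$base <- base_letter(atoms$resid)

  ## keep highest-occupancy altloc per (chain, residue, atom); tie -> first
  ## alphabetically (bio3d exposes altloc in 'alt' when present)
  if (!is.null(atoms$alt)) {
    atoms$alt[is.na(atoms$alt)] <- ""
    atoms$.ord <- seq_len(nrow(atoms))
    ord <- order(atoms$chain, atoms$key, atoms$elety, -atoms$o, atoms$alt)
    atoms <- atoms[ord, ]
    dup <- duplicated(atoms[, c("chain", "key", "elety")])
    atoms <- atoms[!dup, ]
    atoms <- atoms[order(atoms$.ord), , drop = FALSE]
    atoms$.ord <- NULL
  }
  rownames(atoms) <- NULL

  x <- structure(list(atoms = atoms, accession = accession,
                      resolution = resolution, source_format = source_format,
                      lsu_chain = lsu_chain, ssu_chain = ssu_chain),
                 class = "rad_structure")
  if (is.null(lsu_chain) && is.null(ssu_chain)) {
    sel <- select_rrna_chains(x)
    x$lsu_chain <- sel$lsu
    x$ssu_chain <- sel$ssu
  }
  x
}

#' @export
print.rad_structure <- function(x, ...) {
  cat("rad_structure", x$accession, "(", x$source_format, ")\n")
  cat("  chains:", paste(unique(x$atoms$chain), collapse = " "), "\n")
  cat("  LSU rRNA chain:", x$lsu_chain %||% "-",
      " SSU rRNA chain:", x$ssu_chain %||% "-", "\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a ribosome structure from mmCIF or PDB
#'
#' Parses all chains, classifies residues as RNA/protein/other by residue
#' name (modified nucleotides map to their parent base), keeps the
#' highest-occupancy alternate conformer and identifies the LSU and SSU
#' rRNA chains.
#'
#' @param path file path (.cif / .pdb; gzipped variants as bio3d supports).
#' @param format optional override: "mmCIF" or "PDB" (default from extension).
#' @param accession identifier used in reports (default: file base name).
#' @param lsu_chain,ssu_chain optional explicit chain IDs, required when more
#'   than two qualifying rRNA chains make automatic assignment ambiguous.
#' @return a \code{\link{rad_structure}}.
#' @export
read_structure <- function(path, format = NULL, accession = NULL,
                           lsu_chain = NULL, ssu_chain = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(format)) {
    format <- if (grepl("\\.cif(\\.gz)?$", path, ignore.case = TRUE))
      "mmCIF" else "PDB"
  }
  if (is.null(accession))
    accession <- sub("\\.(cif|pdb)(\\.gz)?$", "", basename(path),
                     ignore.case = TRUE)
  pdb <- tryCatch(
    if (format == "mmCIF") suppressWarnings(bio3d::read.cif(path))
    else suppressWarnings(bio3d::read.pdb(path)),
    error = function(e) stop("failed to parse ", basename(path), " as ",
                             format, ": ", conditionMessage(e)))
  a <- pdb$atom
  if (is.null(a) || nrow(a) == 0) stop("no atom records in ", basename(path))
  atoms <- data.frame(
    elety = trimws(a$elety), elesy = trimws(a$elesy %||% ""),
    resid = trimws(a$resid), chain = as.character(a$chain),
    resno = as.integer(a$resno),
    insert = ifelse(is.na(a$insert), "", as.character(a$insert)),
    x = a$x, y = a$y, z = a$z,
    o = ifelse(is.na(a$o), 1, a$o),
    alt = ifelse(is.na(a$alt %||% NA), "", as.character(a$alt %||% "")),
    stringsAsFactors = FALSE)
  st <- rad_structure(atoms, accession = accession, resolution = NA_real_,
                      source_format = format,
                      lsu_chain = lsu_chain, ssu_chain = ssu_chain)
  unk <- with(st$atoms, unique(resid[is.na(base) & !(resid %in% AA3) &
                                       !(resid %in% c("HOH", "MG", "K", "NA", "ZN"))]))
  if (length(unk))
    warning("unmapped residue names retained as non-RNA: ",
            paste(utils::head(unk, 10), collapse = " "))
  st
}

## per-chain residue table, in order of first appearance in the file
chain_residue_table <- function(structure, chain) {
  a <- structure$atoms[structure$atoms$chain == chain, , drop = FALSE]
  if (nrow(a) == 0) stop("no atoms in chain ", chain)
  idx <- !duplicated(a$key)
  data.frame(key = a$key[idx], resno = a$resno[idx], insert = a$insert[idx],
             resid = a$resid[idx], base = a$base[idx],
             stringsAsFactors = FALSE)
}

## RNA chains and their residue counts (residues with an assignable base)
rna_chain_lengths <- function(structure) {
  a <- structure$atoms
  rna <- a[!is.na(a$base), , drop = FALSE]
  if (nrow(rna) == 0) return(integer(0))
  counts <- vapply(split(rna$key, rna$chain),
                   function(k) length(unique(k)), integer(1))
  sort(counts, decreasing = TRUE)
}

#' Identify the LSU and SSU rRNA chains
#'
#' Among RNA chains longer than 500 residues the longest is taken as the LSU
#' rRNA and the second longest as the SSU rRNA. A lone qualifying chain is
#' classified by length: 500-2000 residues is an isolated SSU, above 2000 an
#' isolated LSU (16S is about 1540 nt, 23S about 2900 nt, and eukaryotic
#' homologs are larger in the same order). Chains at or below 500 residues
#' are never selected.
#'
#' @param structure a \code{rad_structure}.
#' @param min_len minimum rRNA chain length (default 500).
#' @return list(lsu = chain ID or NULL, ssu = chain ID or NULL).
#' @export
select_rrna_chains <- function(structure, min_len = 500) {
  lens <- rna_chain_lengths(structure)
  if (length(lens) == 0) stop("no rRNA found: structure contains no RNA chains")
  qual <- lens[lens > min_len]
  if (length(qual) == 0)
    stop("no rRNA found: no RNA chain exceeds ", min_len, " residues")
  if (length(qual) == 1) {
    if (qual[1] > 2000) return(list(lsu = names(qual)[1], ssu = NULL))
    return(list(lsu = NULL, ssu = names(qual)[1]))
  }
  if (length(qual) > 2)
    warning("more than two qualifying rRNA chains (",
            paste(names(qual), qual, sep = ":", collapse = ", "),
            "); picking the two longest — supply lsu_chain/ssu_chain to override")
  list(lsu = names(qual)[1], ssu = names(qual)[2])
}

#' Extract ordered phosphate-atom coordinates
#'
#' One coordinate per residue carrying a P atom, in residue order. Residues
#' lacking a P atom (commonly the 5' terminal residue) are skipped and
#' reported in the \code{"skipped"} attribute.
#'
#' @param structure a \code{rad_structure}.
#' @param chain chain ID.
#' @param residues optional character vector of residue keys (resno + insert
#'   code) to restrict to; default all residues of the chain.
#' @return N x 3 matrix with residue keys as row names.
#' @export
extract_p_atoms <- function(structure, chain, residues = NULL) {
  a <- structure$atoms
  sel <- a$chain == chain & a$elety == "P"
  a <- a[sel, , drop = FALSE]
  tab <- chain_residue_table(structure, chain)
  keys <- tab$key
  if (!is.null(residues)) {
    bad <- setdiff(residues, keys)
    if (length(bad)) stop("requested residues absent from chain ", chain, ": ",
                          paste(utils::head(bad, 5), collapse = " "))
    keys <- keys[keys %in% residues]
  }
  hit <- match(keys, a$key)
  skipped <- keys[is.na(hit)]
  keys <- keys[!is.na(hit)]
  hit <- hit[!is.na(hit)]
  if (length(keys) == 0) stop("no P atoms found in chain ", chain)
  out <- as.matrix(a[hit, c("x", "y", "z")])
  rownames(out) <- keys
  attr(out, "skipped") <- skipped
  out
}

## RNA sequence of a chain as an uppercase string (U alphabet, N for unmapped)
chain_sequence <- function(structure, chain) {
  tab <- chain_residue_table(structure, chain)
  b <- tab$base
  b[is.na(b)] <- "N"
  paste(b, collapse = "")
}

#' Write / read an orientation result table
#'
#' Tab-separated table of per-structure, per-domain angle decompositions with
#' core bookkeeping, written at full precision so it round-trips losslessly
#' through \code{read_orientation_table}.
#'
#' @param records data.frame with columns \code{accession}, \code{domain},
#'   \code{phi}, \code{theta}, \code{psi}, \code{dx_norm}, \code{n_core},
#'   \code{core_rmsd} (extra columns are preserved).
#' @param path output file path.
#' @return the file path, invisibly.
#' @export
write_orientation_table <- function(records, path) {
  records <- as.data.frame(records)
  if (nrow(records) == 0) stop("no records to write")
  need <- c("accession", "domain", "phi", "theta", "psi", "dx_norm",
            "n_core", "core_rmsd")
  miss <- setdiff(need, names(records))
  if (length(miss)) stop("records lack columns: ", paste(miss, collapse = ", "))
  records <- records[, c(need, setdiff(names(records), need)), drop = FALSE]
  fmt <- records
  num <- vapply(fmt, is.numeric, logical(1))
  fmt[num] <- lapply(fmt[num], function(v) sprintf("%.17g", v))
  utils::write.table(fmt, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

#' @rdname write_orientation_table
#' @export
read_orientation_table <- function(path) {
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Apply a rigid transform to all coordinates of a structure
#'
#' @param structure a \code{rad_structure}.
#' @param transform a \code{rad_transform}.
#' @return the transformed \code{rad_structure}.
#' @export
transform_structure <- function(structure, transform) {
  xyz <- apply_transform(transform,
                         as.matrix(structure$atoms[, c("x", "y", "z")]))
  structure$atoms[, c("x", "y", "z")] <- xyz
  structure
}

#' Write a structure as minimal mmCIF
#'
#' Emits a single-model PDBx/mmCIF atom_site loop (label and author
#' numbering both recorded). Used to serialize synthetic fixtures in a form
#' the reader round-trips exactly at the printed precision.
#'
#' @param structure a \code{rad_structure}.
#' @param path output path (.cif).
#' @return the path, invisibly.
#' @export
write_structure_cif <- function(structure, path) {
  a <- structure$atoms
  hdr <- c(
    paste0("data_", gsub("[^A-Za-z0-9_-]", "_", structure$accession)),
    "#", "loop_",
    paste0("_atom_site.",
           c("group_PDB", "id", "type_symbol", "label_atom_id", "label_alt_id",
             "label_comp_id", "label_asym_id", "label_entity_id",
             "label_seq_id", "pdbx_PDB_ins_code", "Cartn_x", "Cartn_y",
             "Cartn_z", "occupancy", "B_iso_or_equiv", "auth_seq_id",
             "auth_comp_id", "auth_asym_id", "auth_atom_id",
             "pdbx_PDB_model_num")))
  ins <- ifelse(a$insert == "", "?", a$insert)
  rows <- sprintf(
    "ATOM %d %s %s . %s %s 1 %d %s %.3f %.3f %.3f %.2f 0.00 %d %s %s %s 1",
    seq_len(nrow(a)), ifelse(a$elesy == "", "X", a$elesy), a$elety, a$resid,
    a$chain, a$resno, ins, a$x, a$y, a$z, a$o, a$resno, a$resid, a$chain,
    a$elety)
  writeLines(c(hdr, rows, "#"), path)
  invisible(path)
}
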