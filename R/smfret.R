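## smFRET probe-distance analysis: distances between published labeling
## sites, and the response of those distances to body/head rotation
## (sigmoidal and power-law fits).

#' Probe-site and probe-pair specifications
#'
#' A site names a molecule (resolved to a chain via an explicit chain map,
#' by rRNA role for "16S"/"23S", or by sequence match against supplied
#' reference protein sequences), a residue set (author numbering) and an
#' atom rule: a single CA atom or the geometric center of the residue set's
#' atoms.
#'
#' @param molecule molecule label, e.g. "S6", "L9", "16S", "23S".
#' @param residues integer residue numbers.
#' @param atom "CA" or "center".
#' @return list of class \code{probe_site}.
#' @export
probe_site <- function(molecule, residues, atom = c("CA", "center")) {
  structure(list(molecule = molecule, residues = as.integer(residues),
                 atom = match.arg(atom)), class = "probe_site")
}

#' @param label pair label.
#' @param site_a,site_b \code{probe_site}s.
#' @rdname probe_site
#' @export
probe_spec <- function(label, site_a, site_b) {
  structure(list(label = label, site_a = site_a, site_b = site_b),
            class = "probe_spec")
}

#' Built-in probe pairs from published smFRET designs
#'
#' S6 residue 41 CA to L9 residue 11 CA; S11 residue 75 CA to L9 residue 11
#' CA; and the geometric centers of the turns of 16S h44 (U1450-G1453) and
#' 23S H101 (C2853-U2865).
#'
#' @return named list of \code{probe_spec}s.
#' @export
builtin_probe_specs <- function() {
  list(
    S6_L9 = probe_spec("S6_L9", probe_site("S6", 41, "CA"),
                       probe_site("L9", 11, "CA")),
    S11_L9 = probe_spec("S11_L9", probe_site("S11", 75, "CA"),
                        probe_site("L9", 11, "CA")),
    h44_H101 = probe_spec("h44_H101",
                          probe_site("16S", 1450:1453, "center"),
                          probe_site("23S", 2853:2865, "center")))
}

## chain for a molecule label; NULL if unresolvable
resolve_chain <- function(structure, molecule, chain_map = NULL,
                          ref_seqs = NULL, min_identity = 0.6) {
  if (!is.null(chain_map) && molecule %in% names(chain_map))
    return(chain_map[[molecule]])
  if (molecule == "16S") return(structure$ssu_chain)
  if (molecule == "23S") return(structure$lsu_chain)
  if (!is.null(ref_seqs) && molecule %in% names(ref_seqs))
    return(match_protein_chain(structure, ref_seqs[[molecule]], min_identity))
  NULL
}

AA1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C", GLN = "Q",
         GLU = "E", GLY = "G", HIS = "H", ILE = "I", LEU = "L", LYS = "K",
         MET = "M", PHE = "F", PRO = "P", SER = "S", THR = "T", TRP = "W",
         TYR = "Y", VAL = "V", MSE = "M", SEC = "U", PYL = "O")

## best-matching protein chain by global sequence identity to a reference
match_protein_chain <- function(structure, ref_seq, min_identity = 0.6) {
  a <- structure$atoms
  prot <- a[a$resid %in% names(AA1), , drop = FALSE]
  best <- NULL; best_id <- 0
  for (ch in unique(prot$chain)) {
    tab <- chain_residue_table(structure, ch)
    tab <- tab[tab$resid %in% names(AA1), , drop = FALSE]
    if (nrow(tab) < 10) next
    seq <- paste(AA1[tab$resid], collapse = "")
    aln <- Biostrings::pairwiseAlignment(
      Biostrings::AAString(seq), Biostrings::AAString(ref_seq),
      substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 1,
      type = "global-local")
    ident <- Biostrings::pid(aln) / 100
    if (is.na(ident)) next
    if (ident > best_id) { best_id <- ident; best <- ch }
  }
  if (best_id >= min_identity) best else NULL
}

## resolved site point, or NULL with a reason
resolve_site <- function(structure, site, chain_map = NULL, ref_seqs = NULL,
                         min_identity = 0.6) {
  ch <- resolve_chain(structure, site$molecule, chain_map, ref_seqs,
                      min_identity)
  if (is.null(ch)) return(NULL)
  a <- structure$atoms
  sel <- a$chain == ch & a$resno %in% site$residues
  if (site$atom == "CA") sel <- sel & a$elety == "CA"
  a <- a[sel, , drop = FALSE]
  if (nrow(a) == 0 ||
      length(unique(a$resno)) < length(unique(site$residues))) return(NULL)
  colMeans(as.matrix(a[, c("x", "y", "z")]))
}

#' Distance between two probe sites
#'
#' Euclidean distance between the resolved site points. Structures where a
#' site cannot be resolved (missing chain, residue or atom) yield NA with
#' the reason in the \code{"report"} attribute, mirroring the practice of
#' only scoring structures that contain the labeled residues.
#'
#' @param structure a \code{\link{rad_structure}}.
#' @param spec a \code{\link{probe_spec}}.
#' @param chain_map named list mapping molecule labels to chain IDs.
#' @param ref_seqs named list of reference protein sequences (one-letter)
#'   for sequence-based chain identification.
#' @param min_identity identity floor for sequence-based identification.
#' @return distance in Angstrom, or NA.
#' @export
probe_distance <- function(structure, spec, chain_map = NULL,
                           ref_seqs = NULL, min_identity = 0.6) {
  pa <- resolve_site(structure, spec$site_a, chain_map, ref_seqs, min_identity)
  pb <- resolve_site(structure, spec$site_b, chain_map, ref_seqs, min_identity)
  if (is.null(pa) || is.null(pb)) {
    out <- NA_real_
    attr(out, "report") <- paste0(
      structure$accession, ": unresolvable site for ", spec$label, " (",
      if (is.null(pa)) spec$site_a$molecule else spec$site_b$molecule, ")")
    return(out)
  }
  sqrt(sum((pa - pb)^2))
}

#' Fit a sigmoidal (tanh) distance response
#'
#' Least-squares fit of \code{y = a + b * tanh((x - x0) / w)}; the reported
#' responsive range is \code{[x0 - w, x0 + w]}, where the curve covers the
#' central ~76 percent of its amplitude.
#'
#' @param x angles (degrees), at least 5 points spanning more than 1 degree.
#' @param y distances (Angstrom).
#' @return list(baseline, amplitude, midpoint, width, responsive_range,
#'   residuals, converged).
#' @export
fit_sigmoid <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 5 || diff(range(x)) <= 1)
    stop("need >= 5 points spanning more than 1 degree")
  if (stats::sd(y) < 1e-9)
    return(list(baseline = mean(y), amplitude = 0, midpoint = NA_real_,
                width = NA_real_, responsive_range = c(NA_real_, NA_real_),
                residuals = y - mean(y), converged = FALSE))
  start <- list(a = mean(y), b = (max(y) - min(y)) / 2 *
                  sign(stats::cor(x, y)),
                x0 = stats::median(x), w = diff(range(x)) / 4)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * tanh((x - x0) / w), start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(baseline = NA_real_, amplitude = NA_real_,
                midpoint = NA_real_, width = NA_real_,
                responsive_range = c(NA_real_, NA_real_),
                residuals = rep(NA_real_, length(y)), converged = FALSE))
  p <- as.list(stats::coef(fit))
  list(baseline = p$a, amplitude = p$b, midpoint = p$x0, width = abs(p$w),
       responsive_range = c(p$x0 - abs(p$w), p$x0 + abs(p$w)),
       residuals = stats::residuals(fit), converged = TRUE)
}

#' Fit a power-law distance response
#'
#' Least-squares fit of \code{y = a + b * (x - min(x) + 1)^c} (the shift
#' keeps the base positive over the data range).
#'
#' @param x angles (degrees).
#' @param y distances (Angstrom).
#' @return list(offset, scale, exponent, residuals, converged).
#' @export
fit_powerlaw <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 4) stop("need >= 4 points")
  if (stats::sd(y) < 1e-9)
    return(list(offset = mean(y), scale = 0, exponent = 0,
                residuals = y - mean(y), converged = FALSE))
  xs <- x - min(x) + 1
  start <- list(a = min(y), b = max(diff(range(y)), 1e-3), c = 1)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ a + b * xs^c, start = start,
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit))
    return(list(offset = NA_real_, scale = NA_real_, exponent = NA_real_,
                residuals = rep(NA_real_, length(y)), converged = FALSE))
  p <- as.list(stats::coef(fit))
  list(offset = p$a, scale = p$b, exponent = p$c,
       residuals = stats::residuals(fit), converged = TRUE)
}

#' Correlate probe distances with a rotation angle
#'
#' Pearson and Spearman correlation between a distance column and an angle
#' column over a record table, with an optional resolution filter (only
#' structures at the given resolution or better are used, when a
#' \code{resolution} column is present).
#'
#' @param records data.frame with the named columns.
#' @param distance,angle column names.
#' @param max_resolution Angstrom; default 5.
#' @return list(pearson, spearman, n).
#' @export
correlate_distances <- function(records, distance, angle,
                                max_resolution = 5) {
  df <- as.data.frame(records)
  if (!is.null(df$resolution))
    df <- df[is.na(df$resolution) | df$resolution <= max_resolution, ]
  x <- df[[angle]]; y <- df[[distance]]
  ok <- is.finite(x) & is.finite(y)
  list(pearson = stats::cor(x[ok], y[ok], method = "pearson"),
       spearman = stats::cor(x[ok], y[ok], method = "spearman"),
       n = sum(ok))
}
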