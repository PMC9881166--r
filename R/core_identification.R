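## Core identification: residue-level correspondence between a model's rRNA
## and the reference, head/body partition of the SSU, and iterative pruning
## to a structurally conserved core with RMSD near 1 A.

#' Analysis parameter set
#'
#' Collects the tunable alignment/pruning/decomposition parameters with
#' their defaults. Alignment scores follow a standard nucleotide scheme
#' (match +2, mismatch -1, gap open 5, gap extend 1, all as magnitudes).
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_ext gap penalties (positive magnitudes).
#' @param min_score_frac alignment-quality floor: the global alignment score
#'   divided by the maximal attainable score (match x shorter length) must
#'   reach this fraction, else the alignment is rejected.
#' @param spatial_filter initial spatial-consistency cutoff (Angstrom):
#'   after the first superposition, matched pairs deviating more than this
#'   are dropped before pruning starts.
#' @param target_rmsd core pruning target (Angstrom).
#' @param min_core_body,min_core_head minimum core sizes (LSU and SSU body
#'   use \code{min_core_body}).
#' @param theta_tol tilt angle (degrees) below which the tilt direction psi
#'   is reported as undefined.
#' @param degenerate_tol rotation angle (degrees) below which screw-axis
#'   decomposition is treated as degenerate.
#' @return a named list of class \code{rad_params}.
#' @export
rad_params <- function(match = 2, mismatch = -1, gap_open = 5, gap_ext = 1,
                       min_score_frac = 0.2, spatial_filter = 8,
                       target_rmsd = 1.0, min_core_body = 100,
                       min_core_head = 50, theta_tol = 0.25,
                       degenerate_tol = 0.25) {
  structure(list(match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_ext = gap_ext, min_score_frac = min_score_frac,
                 spatial_filter = spatial_filter, target_rmsd = target_rmsd,
                 min_core_body = min_core_body, min_core_head = min_core_head,
                 theta_tol = theta_tol, degenerate_tol = degenerate_tol),
            class = "rad_params")
}

#' Align a model rRNA sequence to the reference
#'
#' Global (Needleman-Wunsch) pairwise alignment of the model sequence
#' against the reference sequence, yielding a one-to-one residue
#' correspondence with reference numbering preserved across gaps. This
#' stands in for a multiple-alignment/structure-alignment step: downstream
#' results depend only on the pruned spatial core, which this correspondence
#' also yields.
#'
#' @param model_seq,ref_seq RNA sequences (strings over A/C/G/U/N).
#' @param model_ids residue keys of the model sequence, in sequence order
#'   (default \code{1:nchar}).
#' @param ref_ids reference residue numbers, in sequence order.
#' @param params a \code{\link{rad_params}} list.
#' @param domain label stored on the correspondence.
#' @return data.frame of class \code{rad_correspondence} with columns
#'   \code{model_id} (character) and \code{ref_id} (integer), plus
#'   attributes \code{identity} (fraction of aligned positions with equal
#'   base) and \code{score}.
#' @export
align_to_reference <- function(model_seq, ref_seq, model_ids = NULL,
                               ref_ids = NULL, params = rad_params(),
                               domain = "unknown") {
  nm <- nchar(model_seq); nr <- nchar(ref_seq)
  if (nm == 0 || nr == 0) stop("empty sequence")
  if (is.null(model_ids)) model_ids <- as.character(seq_len(nm))
  if (is.null(ref_ids)) ref_ids <- seq_len(nr)
  stopifnot(length(model_ids) == nm, length(ref_ids) == nr)

  dna <- function(s) Biostrings::DNAString(chartr("Uu", "Tt", s))
  sub <- Biostrings::nucleotideSubstitutionMatrix(
    match = params$match, mismatch = params$mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    dna(model_seq), dna(ref_seq), substitutionMatrix = sub,
    gapOpening = params$gap_open, gapExtension = params$gap_ext,
    type = "global")
  sc <- Biostrings::score(aln)
  if (sc / (params$match * min(nm, nr)) < params$min_score_frac)
    stop("alignment failed: score ", format(sc),
         " below quality floor for sequences of length ", nm, "/", nr)

  pa <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1]]
  sa <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1]]
  ip <- cumsum(pa != "-")
  is <- cumsum(sa != "-")
  both <- pa != "-" & sa != "-"
  pairs <- data.frame(model_id = model_ids[ip[both]],
                      ref_id = as.integer(ref_ids[is[both]]),
                      stringsAsFactors = FALSE)
  attr(pairs, "identity") <- mean(pa[both] == sa[both])
  attr(pairs, "score") <- sc
  attr(pairs, "domain") <- domain
  class(pairs) <- c("rad_correspondence", "data.frame")
  pairs
}

#' Partition an SSU correspondence into head and body
#'
#' Splits matched SSU residues by membership of the reference residue number
#' in a fixed head-residue set given in reference numbering; everything else
#' is body. Minimum-size guards reject degenerate partitions.
#'
#' @param correspondence SSU \code{rad_correspondence}.
#' @param head_set integer vector of head residue numbers in reference
#'   numbering (see \code{\link{load_head_definition}}).
#' @param min_head,min_body minimum residue counts.
#' @return list(head = correspondence, body = correspondence).
#' @export
partition_head_body <- function(correspondence, head_set,
                                min_head = 50, min_body = 100) {
  in_head <- correspondence$ref_id %in% head_set
  head <- correspondence[in_head, , drop = FALSE]
  body <- correspondence[!in_head, , drop = FALSE]
  if (nrow(head) < min_head)
    stop("head partition too small (", nrow(head), " < ", min_head, ")")
  if (nrow(body) < min_body)
    stop("body partition too small (", nrow(body), " < ", min_body, ")")
  attr(head, "domain") <- "SSU_head"; class(head) <- class(correspondence)
  attr(body, "domain") <- "SSU_body"; class(body) <- class(correspondence)
  list(head = head, body = body)
}

#' Packaged head-residue definition (16S numbering)
#'
#' Loads the shipped operational definition of the SSU head: the 16S rRNA
#' 3' major domain, residues 921-1396 in E. coli numbering. This is a fixed,
#' versioned residue list; synthetic references carry their own head
#' definitions instead.
#'
#' @param path optional alternative definition file (one residue number or
#'   \code{start-end} range per line; \code{#} comments allowed).
#' @return sorted integer vector of residue numbers.
#' @export
load_head_definition <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ecoli_16s_head_residues.txt",
                        package = "radkit", mustWork = TRUE)
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  out <- unlist(lapply(ln, function(s) {
    if (grepl("-", s)) {
      ab <- as.integer(strsplit(s, "-")[[1]])
      seq.int(ab[1], ab[2])
    } else as.integer(s)
  }))
  sort(unique(out))
}

#' Prune a correspondence to a structurally conserved core
#'
#' Iterative spatial pruning: superpose the current core P atoms (Kabsch),
#' stop when the RMSD reaches the target; otherwise remove residues whose
#' deviation exceeds twice the current RMSD (or, if none qualify, the worst
#' 5 percent) and repeat. An initial spatial-consistency filter drops pairs
#' deviating more than \code{params$spatial_filter} after the first
#' superposition. RMSD decreases monotonically across iterations.
#'
#' @param correspondence a \code{rad_correspondence}.
#' @param model_xyz P-atom coordinates of the model, rows named by model
#'   residue key.
#' @param ref_xyz P-atom coordinates of the reference, rows named by
#'   reference residue number.
#' @param params a \code{\link{rad_params}}.
#' @param min_core minimum core size; pruning stops (with
#'   \code{converged = FALSE}) rather than shrink below it.
#' @return object of class \code{rad_coremap}: list(correspondence, core,
#'   core_rmsd, n_core, iterations, converged, transform) where
#'   \code{transform} maps model core coordinates onto the reference.
#' @export
prune_core <- function(correspondence, model_xyz, ref_xyz,
                       params = rad_params(), min_core = params$min_core_body) {
  keep <- correspondence$model_id %in% rownames(model_xyz) &
    as.character(correspondence$ref_id) %in% rownames(ref_xyz)
  core <- correspondence[keep, , drop = FALSE]
  if (nrow(core) < min_core)
    stop("only ", nrow(core), " matched residues with P atoms on both sides (< ",
         min_core, ")")
  coords <- function(cr) list(m = model_xyz[cr$model_id, , drop = FALSE],
                              r = ref_xyz[as.character(cr$ref_id), , drop = FALSE])

  iter <- 0L
  converged <- FALSE
  fit <- NULL
  history <- numeric(0)
  repeat {
    iter <- iter + 1L
    xy <- coords(core)
    fit <- superpose(xy$r, xy$m)
    history <- c(history, fit$rmsd)
    dev <- sqrt(rowSums((apply_transform(fit$transform, xy$m) - xy$r)^2))
    if (iter == 1L && any(dev > params$spatial_filter) &&
        sum(dev <= params$spatial_filter) >= min_core) {
      core <- core[dev <= params$spatial_filter, , drop = FALSE]
      next
    }
    if (fit$rmsd <= params$target_rmsd) {
      ## target reached: expel any remaining gross outliers (e.g. register
      ## errors of about one backbone step) before accepting the core; the
      ## absolute floor keeps this terminating under pure coordinate noise
      drop <- dev > max(2 * fit$rmsd, 2 * params$target_rmsd)
      if (!any(drop) || nrow(core) - sum(drop) < min_core) {
        converged <- TRUE; break
      }
      core <- core[!drop, , drop = FALSE]
      next
    }
    drop <- dev > 2 * fit$rmsd
    if (!any(drop)) {
      k <- max(1L, floor(0.05 * nrow(core)))
      drop <- rank(-dev, ties.method = "first") <= k
    }
    if (nrow(core) - sum(drop) < min_core) break
    core <- core[!drop, , drop = FALSE]
    if (iter > 100) break
  }
  if (!converged)
    warning("core pruning stopped at RMSD ", format(fit$rmsd, digits = 4),
            " A with ", nrow(core), " residues (target ",
            params$target_rmsd, " A)")
  structure(list(correspondence = correspondence, core = core,
                 core_rmsd = fit$rmsd, n_core = nrow(core),
                 iterations = iter, converged = converged,
                 transform = fit$transform, rmsd_history = history),
            class = "rad_coremap")
}

#' @export
print.rad_coremap <- function(x, ...) {
  cat("rad_coremap:", x$n_core, "core residues of",
      nrow(x$correspondence), "matched; RMSD",
      format(x$core_rmsd, digits = 4), "A in", x$iterations,
      "iterations", if (!x$converged) "(not converged)", "\n")
  invisible(x)
}
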