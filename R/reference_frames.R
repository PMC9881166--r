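## Reference frames: fixed body and head rotation axes, their positions and
## the psi = 0 tilt directions, constructed from a classical reference
## structure plus body-rotated and head-rotated companion structures.

#' Bundle a classical reference structure with its domain definitions
#'
#' Prepares the classical (unrotated) reference for use as the coordinate
#' origin: stores rRNA sequences, per-residue P coordinates and the residue
#' sets that define the SSU head and the zero-tilt anchor directions, all in
#' the reference's own residue numbering.
#'
#' @param structure classical \code{\link{rad_structure}} with LSU and SSU
#'   rRNA chains.
#' @param head_set integer residue numbers (SSU) forming the head; default
#'   the packaged 16S definition (\code{\link{load_head_definition}}).
#' @param body_anchor integer SSU residue numbers whose centroid anchors the
#'   body zero-tilt direction (default: packaged h44 set).
#' @param head_anchor_from,head_anchor_to integer SSU residue numbers; the
#'   head zero-tilt direction is the projected vector from the centroid of
#'   the first set to the centroid of the second (default: packaged E-site
#'   and A-site codon-region proxies).
#' @return object of class \code{rad_reference}.
#' @export
make_reference <- function(structure, head_set = NULL, body_anchor = NULL,
                           head_anchor_from = NULL, head_anchor_to = NULL) {
  if (is.null(structure$lsu_chain) || is.null(structure$ssu_chain))
    stop("reference structure must contain both LSU and SSU rRNA chains")
  anchors <- load_zero_tilt_anchors()
  if (is.null(head_set)) head_set <- load_head_definition()
  if (is.null(body_anchor)) body_anchor <- anchors$body_anchor
  if (is.null(head_anchor_from)) head_anchor_from <- anchors$head_anchor_from
  if (is.null(head_anchor_to)) head_anchor_to <- anchors$head_anchor_to

  lsu_tab <- chain_residue_table(structure, structure$lsu_chain)
  ssu_tab <- chain_residue_table(structure, structure$ssu_chain)
  lsu_xyz <- extract_p_atoms(structure, structure$lsu_chain)
  ssu_xyz <- extract_p_atoms(structure, structure$ssu_chain)
  ## reference ids are the author residue numbers; insert codes are not
  ## expected in reference entries
  rownames(lsu_xyz) <- as.character(lsu_tab$resno[match(rownames(lsu_xyz),
                                                        lsu_tab$key)])
  rownames(ssu_xyz) <- as.character(ssu_tab$resno[match(rownames(ssu_xyz),
                                                        ssu_tab$key)])
  structure2 <- structure
  structure(list(structure = structure2,
                 lsu_seq = chain_sequence(structure, structure$lsu_chain),
                 ssu_seq = chain_sequence(structure, structure$ssu_chain),
                 lsu_ids = lsu_tab$resno, ssu_ids = ssu_tab$resno,
                 lsu_xyz = lsu_xyz, ssu_xyz = ssu_xyz,
                 head_set = as.integer(head_set),
                 body_anchor = as.integer(body_anchor),
                 head_anchor_from = as.integer(head_anchor_from),
                 head_anchor_to = as.integer(head_anchor_to)),
            class = "rad_reference")
}

load_zero_tilt_anchors <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "ecoli_zero_tilt_anchors.txt",
                        package = "radkit", mustWork = TRUE)
  ln <- readLines(path)
  ln <- trimws(sub("#.*", "", ln))
  ln <- ln[nzchar(ln)]
  out <- list()
  for (s in ln) {
    kv <- strsplit(s, "\t")[[1]]
    rng <- as.integer(strsplit(kv[2], "-")[[1]])
    out[[kv[1]]] <- seq.int(rng[1], rng[2])
  }
  out
}

## centroid of reference SSU P atoms over a residue-number set
ref_centroid <- function(reference, ids, what = "anchor") {
  xyz <- reference$ssu_xyz[rownames(reference$ssu_xyz) %in%
                             as.character(ids), , drop = FALSE]
  if (nrow(xyz) == 0) stop("no reference P atoms found for ", what, " residues")
  unname(colMeans(xyz))
}

## core maps of a (reference-companion) model against the reference, for the
## domains named in `domains`
model_core_maps <- function(model, reference, domains, params = rad_params()) {
  out <- list()
  if (any(c("lsu") %in% domains)) {
    if (is.null(model$lsu_chain)) stop("model lacks an LSU rRNA chain")
    tab <- chain_residue_table(model, model$lsu_chain)
    corr <- align_to_reference(chain_sequence(model, model$lsu_chain),
                               reference$lsu_seq, model_ids = tab$key,
                               ref_ids = reference$lsu_ids, params = params,
                               domain = "LSU")
    out$lsu <- prune_core(corr, extract_p_atoms(model, model$lsu_chain),
                          reference$lsu_xyz, params,
                          min_core = params$min_core_body)
  }
  if (any(c("body", "head") %in% domains)) {
    if (is.null(model$ssu_chain)) stop("model lacks an SSU rRNA chain")
    tab <- chain_residue_table(model, model$ssu_chain)
    corr <- align_to_reference(chain_sequence(model, model$ssu_chain),
                               reference$ssu_seq, model_ids = tab$key,
                               ref_ids = reference$ssu_ids, params = params,
                               domain = "SSU")
    part <- partition_head_body(corr, reference$head_set,
                                min_head = params$min_core_head,
                                min_body = params$min_core_body)
    ssu_xyz <- extract_p_atoms(model, model$ssu_chain)
    if ("body" %in% domains)
      out$body <- prune_core(part$body, ssu_xyz, reference$ssu_xyz, params,
                             min_core = params$min_core_body)
    if ("head" %in% domains)
      out$head <- prune_core(part$head, ssu_xyz, reference$ssu_xyz, params,
                             min_core = params$min_core_head)
  }
  out
}

## core coordinates (model, reference) for a core map
core_coords <- function(coremap, model, chain, reference, which_ref) {
  m <- extract_p_atoms(model, chain, residues = coremap$core$model_id)
  keep <- coremap$core$model_id %in% rownames(m)
  cr <- coremap$core[keep, , drop = FALSE]
  list(m = m[cr$model_id, , drop = FALSE],
       r = reference[[which_ref]][as.character(cr$ref_id), , drop = FALSE])
}

make_frame <- function(domain, axis_direction, axis_point, zero_tilt,
                       frame_of, reference_angle, provenance) {
  zt <- zero_tilt - sum(zero_tilt * axis_direction) * axis_direction
  if (sqrt(sum(zt^2)) < 1e-6)
    stop("zero-tilt anchor direction is (nearly) parallel to the rotation axis")
  structure(list(domain = domain, axis_direction = unname(unitv(axis_direction)),
                 axis_point = unname(as.numeric(axis_point)),
                 zero_tilt_direction = unname(unitv(zt)), frame_of = frame_of,
                 reference_angle = reference_angle, provenance = provenance),
            class = "rad_frame")
}

#' @export
print.rad_frame <- function(x, ...) {
  cat("rad_frame (", x$domain, "): axis [",
      paste(sprintf("%.4f", x$axis_direction), collapse = ", "),
      "] through [", paste(sprintf("%.2f", x$axis_point), collapse = ", "),
      "]; reference rotation ", sprintf("%.3f", x$reference_angle),
      " deg\n", sep = "")
  invisible(x)
}

## shared machinery for the two frame constructors
build_frame_impl <- function(classical_ref, rotated, domain, params) {
  frame_core <- if (domain == "body") "lsu" else "body"
  dom_core <- if (domain == "body") "body" else "head"
  maps <- model_core_maps(rotated, classical_ref, c(frame_core, dom_core),
                          params)
  ## (1) superpose the rotated structure's frame core onto the classical
  T1 <- maps[[frame_core]]$transform
  ## (2) rigid transform carrying the classical domain core onto the
  ##     (frame-aligned) rotated domain core
  chain <- if (dom_core == "body" || dom_core == "head")
    rotated$ssu_chain else rotated$lsu_chain
  cc <- core_coords(maps[[dom_core]], rotated, chain, classical_ref, "ssu_xyz")
  rot_in_frame <- apply_transform(T1, cc$m)
  fit <- superpose(rot_in_frame, cc$r)
  T2 <- fit$transform
  ## (3) screw axis anchored at the classical domain centroid
  centroid <- colMeans(cc$r)
  sc <- screw_axis(T2, anchor = centroid, tol = params$degenerate_tol)
  if (sc$degenerate || sc$angle < 1)
    stop("degenerate reference pair: rotation between classical and ",
         domain, "-rotated reference is ", format(sc$angle, digits = 3),
         " deg (< 1 deg)")
  ## (4) screw_axis returns the axis of a right-handed rotation by +angle,
  ##     so the classical -> rotated sense is positive by construction
  ## (5) zero-tilt direction from the packaged anchors
  if (domain == "body") {
    zt <- ref_centroid(classical_ref, classical_ref$body_anchor,
                       "body zero-tilt anchor") - sc$point
  } else {
    zt <- ref_centroid(classical_ref, classical_ref$head_anchor_to,
                       "head A-site anchor") -
      ref_centroid(classical_ref, classical_ref$head_anchor_from,
                   "head E-site anchor")
  }
  make_frame(domain, sc$direction, sc$point, zt,
             frame_of = if (domain == "body") "LSU_core" else "SSU_body_core",
             reference_angle = sc$angle,
             provenance = list(classical = classical_ref$structure$accession,
                               rotated = rotated$accession,
                               package = "radkit"))
}

#' Build the body (or head) reference frame
#'
#' \code{build_body_frame} defines the body rotation axis from the rigid
#' transform relating the SSU body cores of a classical and a body-rotated
#' reference structure, after aligning both on the LSU core; the zero-tilt
#' direction points from the axis toward the h44 anchor centroid, projected
#' perpendicular to the axis. \code{build_head_frame} is analogous with the
#' SSU body core as the frame of reference and the E-site to A-site anchor
#' vector defining the zero-tilt direction.
#'
#' @param classical_ref a \code{\link{rad_reference}}.
#' @param rotated the body- or head-rotated companion
#'   \code{\link{rad_structure}}.
#' @param params a \code{\link{rad_params}}.
#' @return a \code{rad_frame}.
#' @export
build_body_frame <- function(classical_ref, rotated, params = rad_params()) {
  build_frame_impl(classical_ref, rotated, "body", params)
}

#' @rdname build_body_frame
#' @export
build_head_frame <- function(classical_ref, rotated, params = rad_params()) {
  build_frame_impl(classical_ref, rotated, "head", params)
}

#' Save / load reference frames
#'
#' Frames are serialized as JSON at full double precision, with provenance,
#' and round-trip exactly.
#'
#' @param frames list with elements \code{body} and/or \code{head}, each a
#'   \code{rad_frame}.
#' @param path file path.
#' @return \code{load_frames} returns the frame list.
#' @export
save_frames <- function(frames, path) {
  ser <- lapply(frames, function(f) {
    f$axis_direction <- sprintf("%.17g", f$axis_direction)
    f$axis_point <- sprintf("%.17g", f$axis_point)
    f$zero_tilt_direction <- sprintf("%.17g", f$zero_tilt_direction)
    f$reference_angle <- sprintf("%.17g", f$reference_angle)
    unclass(f)
  })
  jsonlite::write_json(ser, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_frames
#' @export
load_frames <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(ser, function(f) {
    structure(list(domain = f$domain,
                   axis_direction = as.numeric(f$axis_direction),
                   axis_point = as.numeric(f$axis_point),
                   zero_tilt_direction = as.numeric(f$zero_tilt_direction),
                   frame_of = f$frame_of,
                   reference_angle = as.numeric(f$reference_angle),
                   provenance = f$provenance),
              class = "rad_frame")
  })
}
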