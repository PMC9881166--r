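## Synthetic pseudo-ribosome fixtures: seeded point clouds with exactly
## known domain orientations, so every pipeline stage can be exercised and
## validated without any external structure files. Clouds are smoothed,
## confined random walks with RNA-backbone-like P-P spacing (~5.9 A) rather
## than uniform balls, so that core pruning behaves realistically.

#' Specification for a synthetic fixture
#'
#' Default residue counts (1980 LSU, 789 SSU body, 360 SSU head) follow the
#' mean core sizes observed for real LSU-SSU assemblies, so that synthetic
#' runs exercise the pipeline at realistic problem sizes.
#'
#' @param seed integer RNG seed; the generator is fully deterministic given
#'   the spec.
#' @param n_lsu,n_body,n_head residue counts.
#' @param body_truth,head_truth lists \code{list(phi, theta, psi, dx)} with
#'   angles in degrees and \code{dx} a 3-vector (Angstrom) requested as
#'   residual translation (canonicalized by the generator; see
#'   \code{\link{generate_model}}).
#' @param noise_sigma isotropic Gaussian coordinate noise (Angstrom).
#' @param dropout fraction of residues randomly removed from the model.
#' @param ref_body_angle,ref_head_angle pure rotations (degrees) applied to
#'   build the body-rotated and head-rotated reference companions.
#' @return a list of class \code{fixture_spec}.
#' @export
fixture_spec <- function(seed = 1, n_lsu = 1980, n_body = 789, n_head = 360,
                         body_truth = list(phi = 0, theta = 0, psi = 0,
                                           dx = c(0, 0, 0)),
                         head_truth = list(phi = 0, theta = 0, psi = 0,
                                           dx = c(0, 0, 0)),
                         noise_sigma = 0, dropout = 0,
                         ref_body_angle = 8, ref_head_angle = 15) {
  stopifnot(n_lsu >= 100, n_body >= 100, n_head >= 50,
            noise_sigma >= 0, dropout >= 0, dropout < 1)
  structure(list(seed = as.integer(seed), n_lsu = n_lsu, n_body = n_body,
                 n_head = n_head, body_truth = body_truth,
                 head_truth = head_truth, noise_sigma = noise_sigma,
                 dropout = dropout, ref_body_angle = ref_body_angle,
                 ref_head_angle = ref_head_angle),
            class = "fixture_spec")
}

## confined smoothed random walk: n points, ~5.9 A spacing, radius ~ rmax
walk_cloud <- function(n, center, rmax, step = 5.9) {
  x <- matrix(0, n, 3)
  pos <- c(0, 0, 0)
  dir <- unitv(stats::rnorm(3))
  for (i in seq_len(n)) {
    x[i, ] <- pos
    ## soft spherical confinement: free diffusion inside, steep repulsion
    ## near the boundary, so the cloud fills its radius fairly uniformly
    pull <- -(sqrt(sum(pos^2)) / rmax)^5 * 2 *
      if (sum(pos^2) > 0) unitv(pos) else c(0, 0, 0)
    dir <- unitv(0.6 * dir + stats::rnorm(3, sd = 0.7) + pull)
    pos <- pos + step * dir
  }
  sweep(x, 2, -center)
}

rand_seq <- function(n) sample(c("A", "C", "G", "U"), n, replace = TRUE)

## assemble a rad_structure from per-domain P coordinates and bases
assemble_structure <- function(accession, lsu_xyz, lsu_seq, body_xyz,
                               body_seq, head_xyz, head_seq,
                               body_resno = NULL, head_resno = NULL) {
  nb <- nrow(body_xyz); nh <- nrow(head_xyz)
  if (is.null(body_resno)) body_resno <- seq_len(nb)
  if (is.null(head_resno)) head_resno <- nb + seq_len(nh)
  atoms <- data.frame(
    elety = "P", elesy = "P",
    resid = c(lsu_seq, body_seq, head_seq),
    chain = c(rep("A", nrow(lsu_xyz)), rep("B", nb + nh)),
    resno = c(seq_len(nrow(lsu_xyz)), body_resno, head_resno),
    insert = "",
    x = c(lsu_xyz[, 1], body_xyz[, 1], head_xyz[, 1]),
    y = c(lsu_xyz[, 2], body_xyz[, 2], head_xyz[, 2]),
    z = c(lsu_xyz[, 3], body_xyz[, 3], head_xyz[, 3]),
    o = 1, stringsAsFactors = FALSE)
  rad_structure(atoms, accession = accession, source_format = "memory",
                lsu_chain = "A", ssu_chain = "B")
}

#' Generate the synthetic reference triple
#'
#' Builds a classical pseudo-ribosome (LSU + SSU body + SSU head point
#' clouds), a body-rotated companion (whole SSU rotated by
#' \code{ref_body_angle} about a fixed axis through the body centroid) and a
#' head-rotated companion (head rotated by \code{ref_head_angle} about a
#' fixed axis through the head centroid). The classical structure is wrapped
#' as a \code{\link{rad_reference}} with the fixture's own head definition
#' and zero-tilt anchor sets.
#'
#' @param spec a \code{\link{fixture_spec}}.
#' @return list(classical, body_rotated, head_rotated, reference, spec,
#'   info) where \code{info} records the generating axes and angles.
#' @export
generate_reference_fixture <- function(spec = fixture_spec()) {
  set.seed(spec$seed)
  lsu <- walk_cloud(spec$n_lsu, c(0, 0, 0), 60)
  body <- walk_cloud(spec$n_body, c(105, 0, 0), 55)
  head <- walk_cloud(spec$n_head, c(105, 75, 18), 50)
  lsu_seq <- rand_seq(spec$n_lsu)
  body_seq <- rand_seq(spec$n_body)
  head_seq <- rand_seq(spec$n_head)

  body_axis <- unitv(c(0.25, 0.10, 0.96))
  body_point <- colMeans(body)
  head_axis <- unitv(c(0.90, 0.35, 0.25))
  head_point <- colMeans(head)

  Rb <- rot_axis_angle(body_axis, spec$ref_body_angle)
  Tb <- rad_transform(Rb, body_point - as.numeric(Rb %*% body_point))
  Rh <- rot_axis_angle(head_axis, spec$ref_head_angle)
  Th <- rad_transform(Rh, head_point - as.numeric(Rh %*% head_point))

  classical <- assemble_structure("SYNREF-CLASSICAL", lsu, lsu_seq,
                                  body, body_seq, head, head_seq)
  body_rotated <- assemble_structure("SYNREF-BODYROT", lsu, lsu_seq,
                                     apply_transform(Tb, body), body_seq,
                                     apply_transform(Tb, head), head_seq)
  head_rotated <- assemble_structure("SYNREF-HEADROT", lsu, lsu_seq,
                                     body, body_seq,
                                     apply_transform(Th, head), head_seq)

  head_ids <- spec$n_body + seq_len(spec$n_head)
  reference <- make_reference(
    classical, head_set = head_ids,
    body_anchor = (spec$n_body - 49):spec$n_body,
    head_anchor_from = spec$n_body + 1:8,
    head_anchor_to = spec$n_body + (spec$n_head - 7):spec$n_head)

  list(classical = classical, body_rotated = body_rotated,
       head_rotated = head_rotated, reference = reference, spec = spec,
       info = list(body_axis = body_axis, body_point = body_point,
                   body_angle = spec$ref_body_angle, head_axis = head_axis,
                   head_point = head_point,
                   head_angle = spec$ref_head_angle))
}

#' Build the reference frames of a synthetic fixture
#'
#' Convenience wrapper running \code{\link{build_body_frame}} and
#' \code{\link{build_head_frame}} on the fixture's reference triple.
#'
#' @param fixture output of \code{\link{generate_reference_fixture}}.
#' @param params a \code{\link{rad_params}}.
#' @return list(body, head) of \code{rad_frame}s.
#' @export
fixture_frames <- function(fixture, params = rad_params()) {
  list(body = build_body_frame(fixture$reference, fixture$body_rotated,
                               params),
       head = build_head_frame(fixture$reference, fixture$head_rotated,
                               params))
}

## canonical residual translation: remove the component of d along (R - I) a,
## so that the axis point chosen by the generator is the minimizer and the
## requested translation is exactly the recoverable one
canonical_dx <- function(R, frame, d) {
  w <- as.numeric((R - diag(3)) %*% frame$axis_direction)
  ww <- sum(w * w)
  if (ww > 1e-18) d - (sum(w * d) / ww) * w else d
}

## affine domain transform realizing (phi, theta, psi, dx) in a frame
truth_transform <- function(frame, truth) {
  th <- truth$theta %||% 0
  R <- reconstruct_rotation(frame, truth$phi %||% 0, th, truth$psi %||% 0)
  d <- canonical_dx(R, frame, as.numeric(truth$dx %||% c(0, 0, 0)))
  p <- frame$axis_point
  list(transform = rad_transform(R, p - as.numeric(R %*% p) + d),
       delta_x = d)
}

#' Generate a model with exactly known domain orientations
#'
#' Applies \code{body_truth} in the LSU frame and \code{head_truth} in the
#' body frame using the supplied frames' axes and zero-tilt directions, then
#' places the whole model with a random global rigid transform, adds seeded
#' Gaussian coordinate noise and random residue dropout. The requested
#' residual translation \code{dx} is canonicalized (its component along
#' \code{(R - I) R_ref} is removed) so the recorded truth is exactly the
#' minimal-residual translation the decomposition is defined to recover.
#'
#' @param spec a \code{\link{fixture_spec}} carrying truths, noise and
#'   dropout.
#' @param fixture the reference fixture
#'   (\code{\link{generate_reference_fixture}}); must share the spec's
#'   residue counts.
#' @param frames frames from \code{\link{fixture_frames}}.
#' @return list(structure, truth) where \code{truth} has per-domain
#'   \code{phi}, \code{theta}, \code{psi} (NA when theta = 0),
#'   \code{delta_x}, \code{delta_x_norm}.
#' @export
generate_model <- function(spec, fixture, frames) {
  set.seed(spec$seed + 1000003L)
  ref <- fixture$reference
  nb <- fixture$spec$n_body; nh <- fixture$spec$n_head
  lsu <- fixture$reference$lsu_xyz
  ssu <- fixture$reference$ssu_xyz
  body <- ssu[seq_len(nb), , drop = FALSE]
  head <- ssu[nb + seq_len(nh), , drop = FALSE]

  bt <- truth_transform(frames$body, spec$body_truth)
  ht <- truth_transform(frames$head, spec$head_truth)
  body_m <- apply_transform(bt$transform, body)
  head_m <- apply_transform(bt$transform, apply_transform(ht$transform, head))

  ## random global placement
  G <- rad_transform(rot_axis_angle(unitv(stats::rnorm(3)),
                                    stats::runif(1, 10, 170)),
                     stats::runif(3, -30, 30))
  lsu_m <- apply_transform(G, lsu)
  body_m <- apply_transform(G, body_m)
  head_m <- apply_transform(G, head_m)

  noisy <- function(x) x + matrix(stats::rnorm(length(x), sd = spec$noise_sigma),
                                  nrow(x), 3)
  if (spec$noise_sigma > 0) {
    lsu_m <- noisy(lsu_m); body_m <- noisy(body_m); head_m <- noisy(head_m)
  }

  lsu_tab <- chain_residue_table(ref$structure, ref$structure$lsu_chain)
  ssu_tab <- chain_residue_table(ref$structure, ref$structure$ssu_chain)
  keep <- function(n) stats::runif(n) >= spec$dropout
  kl <- keep(nrow(lsu_m)); kb <- keep(nb); kh <- keep(nh)

  st <- assemble_structure(paste0("SYNMODEL-", spec$seed),
                           lsu_m[kl, , drop = FALSE], lsu_tab$base[kl],
                           body_m[kb, , drop = FALSE],
                           ssu_tab$base[seq_len(nb)][kb],
                           head_m[kh, , drop = FALSE],
                           ssu_tab$base[nb + seq_len(nh)][kh],
                           body_resno = which(kb),
                           head_resno = nb + which(kh))
  truth_of <- function(tr, built) {
    th <- tr$theta %||% 0
    list(phi = tr$phi %||% 0, theta = th,
         psi = if (th > 0) tr$psi %||% 0 else NA_real_,
         delta_x = built$delta_x,
         delta_x_norm = sqrt(sum(built$delta_x^2)))
  }
  list(structure = st,
       truth = list(body = truth_of(spec$body_truth, bt),
                    head = truth_of(spec$head_truth, ht),
                    seed = spec$seed))
}

#' Mutate residue identities and introduce short indels
#'
#' Exercises the sequence-alignment stage across "organisms": substitutes
#' bases at the given rate and introduces short deletions and insertions
#' (insertions carry insertion codes and interpolated coordinates), leaving
#' coordinates of retained residues unchanged.
#'
#' @param structure a \code{\link{rad_structure}}.
#' @param substitution_rate,indel_rate per-residue rates in [0, 1).
#' @param seed RNG seed.
#' @return a modified \code{rad_structure}.
#' @export
mutate_sequence <- function(structure, substitution_rate = 0, indel_rate = 0,
                            seed = 1) {
  set.seed(seed)
  atoms <- structure$atoms
  for (ch in unique(atoms$chain[!is.na(atoms$base)])) {
    tab <- chain_residue_table(structure, ch)
    n <- nrow(tab)
    ## substitutions
    sub_at <- which(stats::runif(n) < substitution_rate)
    for (i in sub_at) {
      new <- sample(setdiff(c("A", "C", "G", "U"), tab$base[i]), 1)
      atoms$resid[atoms$chain == ch & atoms$key == tab$key[i]] <- new
    }
    ## deletions
    del_at <- which(stats::runif(n) < indel_rate / 2)
    if (length(del_at))
      atoms <- atoms[!(atoms$chain == ch & atoms$key %in% tab$key[del_at]), ]
    ## insertions (after surviving residues, insert code "A")
    ins_at <- which(stats::runif(n) < indel_rate / 2)
    ins_at <- setdiff(ins_at, c(del_at, n))
    for (i in ins_at) {
      here <- atoms$chain == ch & atoms$key == tab$key[i]
      nxt <- atoms$chain == ch & atoms$key == tab$key[i + 1]
      if (!any(here) || !any(nxt)) next
      row <- atoms[which(here)[1], , drop = FALSE]
      row$resid <- sample(c("A", "C", "G", "U"), 1)
      row$insert <- "A"
      row[, c("x", "y", "z")] <-
        (as.numeric(atoms[which(here)[1], c("x", "y", "z")]) +
           as.numeric(atoms[which(nxt)[1], c("x", "y", "z")])) / 2 +
        stats::rnorm(3, sd = 0.5)
      at <- max(which(here))
      atoms <- rbind(atoms[seq_len(at), ], row,
                     atoms[-seq_len(at), , drop = FALSE])
    }
  }
  atoms$key <- NULL; atoms$base <- NULL
  rad_structure(atoms, accession = structure$accession,
                resolution = structure$resolution,
                source_format = structure$source_format,
                lsu_chain = structure$lsu_chain,
                ssu_chain = structure$ssu_chain)
}
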