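## Angle decomposition: express the net rigid transform of the SSU body (in
## the LSU frame) or head (in the SSU body frame) as a primary rotation phi
## about the fixed reference axis, a tilt theta about the line of nodes in
## direction psi, a rotation center x_c on the reference axis and a residual
## translation delta_x. Convention: rotation = Rot(T, theta) %*% Rot(R_ref, phi)
## (tilt applied after the primary rotation), matching the view that tilting
## re-orients the body-fixed rotation axis.

#' Net rigid transform of a domain relative to the reference
#'
#' Superposes the model onto the reference via the frame-of-reference core
#' (LSU core for the body, SSU body core for the head) and, in that common
#' frame, returns the rigid transform carrying the reference domain core
#' onto the model domain core.
#'
#' @param model a \code{\link{rad_structure}}.
#' @param reference a \code{\link{rad_reference}}.
#' @param domain "body" or "head".
#' @param params a \code{\link{rad_params}}.
#' @param cores optional precomputed core maps (list with elements
#'   \code{lsu}, \code{body}, \code{head} as needed).
#' @return list(transform, cores, domain_centroid) where
#'   \code{domain_centroid} is the centroid of the reference domain core.
#' @export
net_domain_transform <- function(model, reference, domain = c("body", "head"),
                                 params = rad_params(), cores = NULL) {
  domain <- match.arg(domain)
  frame_core <- if (domain == "body") "lsu" else "body"
  if (domain == "body" && is.null(model$lsu_chain))
    stop("body angles need an LSU rRNA chain (isolated SSU: head only)")
  need <- setdiff(c(frame_core, domain), names(cores))
  if (length(need))
    cores <- c(cores, model_core_maps(model, reference, need, params))
  T1 <- cores[[frame_core]]$transform
  cc <- core_coords(cores[[domain]], model, model$ssu_chain, reference,
                    "ssu_xyz")
  model_in_frame <- apply_transform(T1, cc$m)
  fit <- superpose(model_in_frame, cc$r)
  list(transform = fit$transform, cores = cores, fit_rmsd = fit$rmsd,
       domain_centroid = colMeans(cc$r))
}

#' Decompose a rigid transform into RAD coordinates
#'
#' Splits the rotation into the primary angle \code{phi} about the fixed
#' reference axis and a tilt \code{theta} about the line of nodes, whose
#' azimuth \code{psi} is measured right-handed about the reference axis from
#' the frame's zero-tilt direction. The rotation center \code{x_c} is the
#' point on the reference axis minimizing the residual translation
#' \code{delta_x}. When \code{theta} is below \code{theta_tol} the tilt
#' direction is undefined (psi = NA) and \code{phi} falls back to the signed
#' rotation about the reference axis.
#'
#' @param transform a \code{rad_transform} (reference domain -> model domain,
#'   in the frame-of-reference coordinates).
#' @param frame a \code{rad_frame}.
#' @param theta_tol degrees; tilt below this is treated as zero for psi.
#' @return object of class \code{rad_angles} with elements \code{domain},
#'   \code{phi}, \code{theta}, \code{psi} (degrees), \code{x_c},
#'   \code{delta_x}, \code{delta_x_norm} (Angstrom), \code{rotated_axis},
#'   \code{psi_defined}.
#' @export
rad_decompose <- function(transform, frame, theta_tol = 0.25) {
  R <- transform$R
  a <- frame$axis_direction
  z0 <- frame$zero_tilt_direction
  Rhat <- as.numeric(R %*% a)
  theta <- vector_angle_deg(a, Rhat)

  if (theta >= theta_tol) {
    Tn <- unitv(crossp(a, Rhat))          # line of nodes; tilt by +theta
    psi <- signed_angle_about(a, z0, Tn)
    Rphi <- t(rot_axis_angle(Tn, theta)) %*% R   # pure rotation about a
    phi <- signed_angle_about(a, z0, as.numeric(Rphi %*% z0))
    psi_defined <- TRUE
  } else {
    psi <- NA_real_
    phi <- signed_angle_about(a, z0, as.numeric(R %*% z0))
    psi_defined <- FALSE
  }

  ## x_c: point on the reference axis line minimizing |(R - I) x + t|.
  ## Below the tilt tolerance (R - I) is near-singular along the axis, the
  ## residual is flat in s and the minimizer is not identifiable: anchor at
  ## the frame's axis point instead.
  M <- R - diag(3)
  b <- as.numeric(M %*% frame$axis_point) + transform$t
  d <- as.numeric(M %*% a)
  dd <- sum(d * d)
  s <- if (psi_defined && dd > 1e-18) -sum(d * b) / dd else 0
  x_c <- frame$axis_point + s * a
  delta_x <- as.numeric(M %*% x_c) + transform$t

  structure(list(domain = frame$domain, phi = phi, theta = theta, psi = psi,
                 psi_defined = psi_defined, x_c = x_c, delta_x = delta_x,
                 delta_x_norm = sqrt(sum(delta_x^2)), rotated_axis = Rhat),
            class = "rad_angles")
}

#' @export
print.rad_angles <- function(x, ...) {
  cat(sprintf("rad_angles (%s): phi %.2f deg, theta %.2f deg, psi %s, |dx| %.2f A\n",
              x$domain, x$phi, x$theta,
              if (x$psi_defined) sprintf("%.2f deg", x$psi) else "undefined",
              x$delta_x_norm))
  invisible(x)
}

#' Rebuild the rotation matrix from RAD angles
#'
#' Inverse of the angular part of \code{\link{rad_decompose}}:
#' \code{Rot(T(psi), theta) \%*\% Rot(R_ref, phi)} with the line of nodes
#' \code{T(psi)} obtained by rotating the frame's zero-tilt direction by
#' \code{psi} about the reference axis.
#'
#' @param frame a \code{rad_frame}.
#' @param phi,theta,psi angles in degrees (psi ignored when theta = 0).
#' @return 3x3 rotation matrix.
#' @export
reconstruct_rotation <- function(frame, phi, theta, psi = 0) {
  a <- frame$axis_direction
  Rphi <- rot_axis_angle(a, phi)
  if (abs(theta) < 1e-12) return(Rphi)
  Tn <- as.numeric(rot_axis_angle(a, psi) %*% frame$zero_tilt_direction)
  rot_axis_angle(Tn, theta) %*% Rphi
}

#' Euler-Rodrigues angle between two orientations
#'
#' The single net rotation angle relating two rotations,
#' \code{arccos((trace(Ra Rb^T) - 1)/2)}, in degrees. Symmetric and zero iff
#' the rotations are equal.
#'
#' @param a,b \code{rad_transform} objects or 3x3 rotation matrices.
#' @return angle in [0, 180] degrees.
#' @export
er_angle <- function(a, b) {
  rotation_angle_deg(as_rotation(a) %*% t(as_rotation(b)))
}

#' Tilt difference between two orientations
#'
#' The angle formed by the current (rotated) primary axes of two structures:
#' \code{arccos((Ra R_ref) . (Rb R_ref))}. Independent of the primary
#' rotation of either structure, since rotating about the body-fixed axis
#' leaves that axis unchanged.
#'
#' @param a,b \code{rad_transform} objects or 3x3 rotation matrices.
#' @param frame a \code{rad_frame} supplying the reference axis.
#' @return angle in [0, 180] degrees.
#' @export
delta_theta <- function(a, b, frame) {
  u <- frame$axis_direction
  va <- as.numeric(as_rotation(a) %*% u)
  vb <- as.numeric(as_rotation(b) %*% u)
  vector_angle_deg(va, vb)
}

#' Nearest neighbors within an ensemble of orientations
#'
#' For \code{metric = "er_angle"}, the nearest neighbor of each structure is
#' the one minimizing the pairwise Euler-Rodrigues angle. For
#' \code{metric = "phi_gap"}, structures are ordered by \code{phi} and the
#' sequential angle differences are reported.
#'
#' @param ensemble for "er_angle": a named list of \code{rad_transform}s (or
#'   rotation matrices); for "phi_gap": a named numeric vector of phi values
#'   (degrees).
#' @param metric "er_angle" or "phi_gap".
#' @return data.frame; for "er_angle" columns \code{accession},
#'   \code{neighbor}, \code{distance}; for "phi_gap" columns
#'   \code{accession}, \code{next_accession}, \code{phi}, \code{next_phi},
#'   \code{gap} (sorted by phi).
#' @export
nearest_neighbors <- function(ensemble, metric = c("er_angle", "phi_gap")) {
  metric <- match.arg(metric)
  if (metric == "phi_gap") {
    phi <- sort(unlist(ensemble))
    n <- length(phi)
    if (n < 2) stop("need at least two structures")
    return(data.frame(accession = names(phi)[-n],
                      next_accession = names(phi)[-1],
                      phi = unname(phi[-n]), next_phi = unname(phi[-1]),
                      gap = unname(diff(phi)), stringsAsFactors = FALSE))
  }
  n <- length(ensemble)
  if (n < 2) stop("need at least two structures")
  nm <- names(ensemble)
  if (is.null(nm)) nm <- as.character(seq_len(n))
  D <- matrix(0, n, n)
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    D[i, j] <- D[j, i] <- er_angle(ensemble[[i]], ensemble[[j]])
  diag(D) <- Inf
  k <- apply(D, 1, which.min)
  data.frame(accession = nm, neighbor = nm[k],
             distance = D[cbind(seq_len(n), k)], stringsAsFactors = FALSE)
}

#' Full RAD analysis of one structure
#'
#' Runs the pipeline end to end for a model: sequence alignment to the
#' reference, head/body partition, core pruning, rigid superposition and
#' angle decomposition for the requested domains. Isolated SSUs support the
#' head domain only.
#'
#' @param model a \code{\link{rad_structure}}.
#' @param reference a \code{\link{rad_reference}}.
#' @param frames list with \code{rad_frame} elements \code{body} and
#'   \code{head} (see \code{\link{build_body_frame}}).
#' @param domain "body", "head" or "both".
#' @param params a \code{\link{rad_params}}.
#' @return object of class \code{rad_result}: list(accession, body, head,
#'   cores, table) where \code{table} is a per-domain data.frame suitable
#'   for \code{\link{write_orientation_table}}.
#' @export
analyze_structure <- function(model, reference, frames,
                              domain = c("both", "body", "head"),
                              params = rad_params()) {
  domain <- match.arg(domain)
  wanted <- if (domain == "both") c("body", "head") else domain
  if (is.null(model$lsu_chain)) wanted <- setdiff(wanted, "body")
  if (length(wanted) == 0)
    stop("no analyzable domain: body angles need an LSU rRNA chain")
  cores <- NULL
  res <- list(accession = model$accession)
  rows <- list()
  for (d in wanted) {
    nt <- net_domain_transform(model, reference, d, params, cores = cores)
    cores <- nt$cores
    ang <- rad_decompose(nt$transform, frames[[d]],
                         theta_tol = params$theta_tol)
    res[[d]] <- list(angles = ang, transform = nt$transform)
    cm <- cores[[d]]
    rows[[d]] <- data.frame(
      accession = model$accession, domain = d, phi = ang$phi,
      theta = ang$theta, psi = ang$psi, dx_norm = ang$delta_x_norm,
      n_core = cm$n_core, core_rmsd = cm$core_rmsd,
      frame_core_rmsd = cores[[if (d == "body") "lsu" else "body"]]$core_rmsd,
      stringsAsFactors = FALSE)
  }
  res$cores <- cores
  res$table <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  class(res) <- "rad_result"
  res
}

#' @export
print.rad_result <- function(x, ...) {
  cat("rad_result:", x$accession, "\n")
  print(x$table, digits = 4)
  invisible(x)
}
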